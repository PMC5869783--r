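sub_of <- function(bundle, ...) {
  assign_subgroups(bundle, determine_eligibility(bundle), ...)
}

test_that("screened normotensive persons always score q = 1", {
  b <- record_bundle(
    persons = make_persons(3),
    screenings = dplyr::bind_rows(lapply(paste0("p", 1:3), function(id)
      screening_row(id, "2013-02-01", 110, 70))))
  qr <- q_normotension(sub_of(b))
  expect_identical(qr$q, rep(1, 3))
  expect_error(q_normotension(sub_of(suspected_bundle())), "category")
})

test_that("pre-HT q requires a risk assessment on/after screening, in-window", {
  mk <- function(service_date = NULL) {
    b <- record_bundle(
      persons = make_persons(1),
      screenings = screening_row("p1", "2013-03-01", 130, 85),
      services = if (!is.null(service_date))
        service_row("p1", service_date, "ht_cvd_risk_assessment"))
    q_pre_ht(sub_of(b), b$services)$q
  }
  expect_identical(mk("2013-03-11"), 1)  # 10 days after screening
  expect_identical(mk("2013-03-01"), 1)  # same day counts (on/after)
  expect_identical(mk(), 0)              # no service at all
  expect_identical(mk("2013-02-20"), 0)  # before the screening
  expect_identical(mk("2014-01-05"), 0)  # outside the study window
})

test_that("suspected-HT confirmation honours the 60-day window boundaries", {
  mk <- function(offset, via = c("followup", "screening"), window = 60) {
    via <- match.arg(via)
    day <- d("2013-02-01") + offset
    b <- suspected_bundle(
      screen = "2013-02-01",
      followups = if (via == "followup")
        service_row("p1", day, "follow_up_bp", sbp = 150, dbp = 95),
      screenings_extra = if (via == "screening")
        screening_row("p1", day, 150, 95))
    q_suspected(sub_of(b), b$screenings, b$followups,
                criteria_config(confirmation_window_days = window))$q
  }
  expect_identical(mk(59), 1)
  expect_identical(mk(60), 1)   # inclusive upper bound
  expect_identical(mk(61), 0)
  expect_identical(mk(0), 0)    # same-day repeat does not confirm
  expect_identical(mk(30, via = "screening"), 1)  # repeat screening counts
})

test_that("randomised follow-up offsets agree with a day-difference oracle", {
  withr::local_seed(13)
  n <- 50
  offsets <- sample(0:120, n, replace = TRUE)
  persons <- make_persons(n)
  scr <- dplyr::bind_rows(lapply(1:n, function(i)
    screening_row(paste0("p", i), "2013-03-15", 150, 95)))
  fu <- dplyr::bind_rows(lapply(1:n, function(i)
    service_row(paste0("p", i), d("2013-03-15") + offsets[i],
                "follow_up_bp", sbp = 150, dbp = 95)))
  b <- record_bundle(persons = persons, screenings = scr, followups = fu)
  qr <- q_suspected(sub_of(b), b$screenings, b$followups)
  oracle <- vapply(seq_len(n), function(i) offsets[i] > 0 && offsets[i] <= 60,
                   logical(1))
  expect_identical(qr$criterion_met[match(paste0("p", 1:n), qr$person_id)],
                   oracle)
})

test_that("widening the confirmation window never lowers q_suspected", {
  withr::local_seed(17)
  n <- 30
  persons <- make_persons(n)
  scr <- dplyr::bind_rows(lapply(1:n, function(i)
    screening_row(paste0("p", i), "2013-02-01", 160, 100)))
  fu <- dplyr::bind_rows(lapply(1:n, function(i)
    service_row(paste0("p", i), d("2013-02-01") + sample(1:150, 1),
                "follow_up_bp", sbp = 150, dbp = 95)))
  b <- record_bundle(persons = persons, screenings = scr, followups = fu)
  sub <- sub_of(b)
  prev <- rep(0, n)
  for (w in c(10, 30, 60, 90, 150)) {
    q <- q_suspected(sub, b$screenings, b$followups,
                     criteria_config(confirmation_window_days = w))$q
    expect_true(all(q >= prev))
    prev <- q
  }
  expect_identical(sum(prev), as.numeric(n))  # all offsets <= 150
})

test_that("the diagnosed cascade evaluates every Table-style criterion", {
  mk <- function(services = NULL, followups = NULL, diagnoses =
                   diagnosis_row("p1", "2013-03-03")) {
    b <- suspected_bundle(screen = "2013-02-01", sbp = 160, dbp = 100,
                          services = services, followups = followups,
                          diagnoses = diagnoses)
    diagnosed_cascade(sub_of(b), b$diagnoses, b$services, b$followups)
  }
  # diagnosis 30 days after screening; treatment at day 100 of the year
  got <- mk(services = service_row("p1", "2013-06-01", "ht_treatment_start"))
  expect_true(got$diagnosed_ht)
  expect_identical(got$diagnosis_date, d("2013-03-03"))
  expect_true(got$treated_timely)
  expect_false(got$cvd_risk_assessed || got$cvd_risk_reduced ||
                 got$bp_controlled)

  # treatment exactly at / one day past the 183-day window
  expect_true(mk(services = service_row(
    "p1", d("2013-03-03") + 183, "ht_treatment_start"))$treated_timely)
  expect_false(mk(services = service_row(
    "p1", d("2013-03-03") + 184, "ht_treatment_start"))$treated_timely)

  # diagnosis before the initial screening does not qualify
  expect_false(mk(diagnoses = diagnosis_row("p1", "2013-01-20"))$diagnosed_ht)

  # lipid panel after diagnosis -> assessed; a second improved panel -> reduced
  panel <- function(date, chol, ldl) service_row(
    "p1", date, "lipid_panel", total_chol = chol, ldl = ldl, hdl = 45)
  expect_true(mk(services = panel("2013-04-01", 240, 150))$cvd_risk_assessed)
  expect_false(mk(services = panel("2013-04-01", 240, 150))$cvd_risk_reduced)
  two <- mk(services = dplyr::bind_rows(panel("2013-04-01", 240, 150),
                                        panel("2013-06-01", 240, 140)))
  expect_true(two$cvd_risk_reduced)   # LDL strictly lower, chol not greater
  worse <- mk(services = dplyr::bind_rows(panel("2013-04-01", 240, 150),
                                          panel("2013-06-01", 245, 140)))
  expect_false(worse$cvd_risk_reduced)
  # an incomplete panel (missing HDL) does not count as assessment
  expect_false(mk(services = service_row(
    "p1", "2013-04-01", "lipid_panel", total_chol = 240,
    ldl = 150))$cvd_risk_assessed)

  # BP control: under 140/90 on the latest follow-up, or below the initial
  fup <- function(date, sbp, dbp) service_row("p1", date, "follow_up_bp",
                                              sbp = sbp, dbp = dbp)
  expect_true(mk(followups = fup("2013-05-01", 130, 80))$bp_controlled)
  expect_true(mk(followups = fup("2013-05-01", 150, 95))$bp_controlled)
  # 150/95 < initial 160/100 on both components
  expect_false(mk(followups = fup("2013-05-01", 160, 100))$bp_controlled)
  # only the latest follow-up counts
  expect_false(mk(followups = dplyr::bind_rows(
    fup("2013-05-01", 130, 80), fup("2013-08-01", 165, 102)))$bp_controlled)
  # follow-ups before the diagnosis are ignored
  expect_false(mk(followups = fup("2013-02-10", 130, 80))$bp_controlled)
})

test_that("undiagnosed persons carry no downstream flags", {
  b <- suspected_bundle(services = service_row("p1", "2013-05-01",
                                               "ht_treatment_start"))
  got <- diagnosed_cascade(sub_of(b), b$diagnoses, b$services, b$followups)
  expect_false(got$diagnosed_ht)
  expect_false(any(got$treated_timely, got$cvd_risk_assessed,
                   got$bp_controlled, got$cvd_risk_reduced))
})

test_that("individual EC is the q-u product over the need population", {
  expect_identical(compute_individual_ec(1, 1), 1)
  expect_identical(compute_individual_ec(0.5, 1), 0.5)
  expect_identical(compute_individual_ec(c(1, 0.7, NA), c(0, 0, 0)),
                   c(0, 0, 0))
  expect_error(compute_individual_ec(1, 1, n = 0), "need population")
  expect_error(compute_individual_ec(2, 1), "0, 1")
  expect_error(compute_individual_ec(1, 0.5), "u must be")
})

test_that("cascade implications hold on generated cohorts", {
  for (seed in 1:3) {
    b <- generate_cohort(thailand2013_preset(4000), "stochastic", seed = seed)
    res <- assess_cohort(b)
    dxed <- res[!is.na(res$diagnosed_ht), ]
    expect_true(all(!dxed$cvd_risk_reduced | dxed$cvd_risk_assessed))
    un <- dxed[!dxed$diagnosed_ht, ]
    expect_false(any(un$treated_timely | un$cvd_risk_assessed |
                       un$bp_controlled | un$cvd_risk_reduced))
    scr <- res[res$eligible & res$screened, ]
    expect_true(all(scr$q %in% c(0, 1)))
    expect_true(all(res$ec[res$eligible] <=
                      as.numeric(res$screened[res$eligible])))
  }
})
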