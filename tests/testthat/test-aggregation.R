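test_that("a cohort with no suspected persons leaves diagnosed nodes undefined", {
  b <- record_bundle(
    persons = make_persons(4),
    screenings = dplyr::bind_rows(
      screening_row("p1", "2013-02-01", 110, 70),
      screening_row("p2", "2013-02-01", 130, 85)))
  casc <- build_cascade(assess_cohort(b))
  undef <- casc$node %in% c("treated_timely", "cvd_risk_assessed",
                            "bp_controlled", "cvd_risk_reduced")
  expect_true(all(is.na(casc$proportion[undef])))
  expect_identical(casc$numerator[casc$node == "screened"], 2)
  expect_identical(casc$proportion[casc$node == "screened"], 0.5)
})

test_that("a 20-person hand fixture tallies every cascade node", {
  # 12 screened of 20 eligible: 6 normal, 4 pre-HT (3 assessed),
  # 2 suspected (1 confirmed, 1 diagnosed -> treated + assessed, not
  # controlled, not reduced)
  persons <- make_persons(20)
  scr <- dplyr::bind_rows(
    lapply(paste0("p", 1:6), screening_row, date = "2013-02-01",
           sbp = 110, dbp = 70),
    lapply(paste0("p", 7:10), screening_row, date = "2013-02-01",
           sbp = 130, dbp = 85),
    lapply(paste0("p", 11:12), screening_row, date = "2013-02-01",
           sbp = 160, dbp = 100))
  services <- dplyr::bind_rows(
    lapply(paste0("p", 7:9), service_row, date = "2013-03-01",
           code = "ht_cvd_risk_assessment"),
    service_row("p11", "2013-04-15", "ht_treatment_start"),
    service_row("p11", "2013-04-20", "lipid_panel", total_chol = 240,
                ldl = 150, hdl = 45))
  followups <- service_row("p12", "2013-03-01", "follow_up_bp",
                           sbp = 150, dbp = 95)
  b <- record_bundle(persons = persons, screenings = scr,
                     services = services,
                     diagnoses = diagnosis_row("p11", "2013-03-10"),
                     followups = followups)
  casc <- build_cascade(assess_cohort(b))
  want <- c(eligible = 20, screened = 12, normotension = 6, pre_ht = 4,
            suspected_ht = 2, pre_ht_risk_assessed = 3,
            suspected_confirmed_60d = 1, diagnosed = 1, treated_timely = 1,
            cvd_risk_assessed = 1, bp_controlled = 0, cvd_risk_reduced = 0)
  expect_identical(stats::setNames(casc$numerator, casc$node), want)
  expect_identical(casc$denominator[casc$node == "pre_ht_risk_assessed"], 4)
})

test_that("province summaries obey the ec = coverage x effectiveness identity", {
  # province 1: coverage 0.6, all screened meet their criterion
  # province 2: coverage 0.4, half of the screened meet it
  p1 <- make_persons(10, "a", province = 1L)
  p2 <- make_persons(10, "b", province = 2L)
  scr <- dplyr::bind_rows(
    lapply(paste0("a", 1:6), screening_row, date = "2013-02-01",
           sbp = 110, dbp = 70),
    lapply(paste0("b", 1:4), screening_row, date = "2013-02-01",
           sbp = 130, dbp = 85))
  services <- dplyr::bind_rows(
    lapply(paste0("b", 1:2), service_row, date = "2013-03-01",
           code = "ht_cvd_risk_assessment"))
  b <- record_bundle(persons = dplyr::bind_rows(p1, p2),
                     screenings = scr, services = services)
  prov <- summarize_provinces(assess_cohort(b))
  expect_equal(prov$coverage, c(0.6, 0.4))
  expect_equal(prov$effectiveness, c(1.0, 0.5))
  expect_equal(prov$ec, c(0.6, 0.2))
  expect_equal(prov$ec, prov$coverage * prov$effectiveness)
  expect_true(all(prov$ec <= prov$coverage))
})

test_that("provinces with no eligible persons are omitted with a warning", {
  persons <- dplyr::bind_rows(
    make_persons(3, "a", province = 1L),
    make_persons(2, "b", province = 2L, birth = "2005-01-01"))
  res <- assess_cohort(record_bundle(persons = persons))
  expect_warning(prov <- summarize_provinces(res), "no eligible")
  expect_identical(prov$province_code, 1L)
})

test_that("identical provinces give an undefined correlation, not 1", {
  prov <- tibble::tibble(province_code = 1:5, n_persons = 100L,
                         n_eligible = 100L, n_screened = 50L,
                         coverage = 0.5, effectiveness = 0.9, ec = 0.45)
  nat <- national_summary(prov)
  expect_true(is.na(nat$correlation$pearson_r))
})

test_that("exactly proportional provinces give pearson r = 1", {
  cov <- seq(0.2, 0.9, length.out = 8)
  prov <- tibble::tibble(province_code = 1:8, n_persons = 100L,
                         n_eligible = 100L,
                         n_screened = as.integer(100 * cov),
                         coverage = cov, effectiveness = 0.8,
                         ec = 0.8 * cov)
  nat <- national_summary(prov)
  expect_equal(nat$correlation$pearson_r, 1.0, tolerance = 1e-12)
  expect_lt(nat$correlation$p_value, 0.001)
  expect_true(nat$provincial_min_ec <= nat$provincial_mean_ec &&
                nat$provincial_mean_ec <= nat$provincial_max_ec)
  expect_equal(nat$gap_stats$mean, mean(cov - 0.8 * cov))
})

test_that("fewer than three provinces leave the correlation undefined", {
  prov <- tibble::tibble(province_code = 1:2, n_persons = 10L,
                         n_eligible = 10L, n_screened = c(4L, 6L),
                         coverage = c(0.4, 0.6), effectiveness = c(1, 1),
                         ec = c(0.4, 0.6))
  expect_true(is.na(national_summary(prov)$correlation$pearson_r))
})

test_that("province-varying stochastic EC tracks its per-province expectation", {
  preset <- province_varying_preset(n_persons = 150000, seed = 1)
  b <- generate_cohort(preset, "stochastic", seed = 42)
  res <- assess_cohort(b)
  prov <- summarize_provinces(res)
  eff <- preset$province_effects
  sh <- preset$subgroup_shares
  p_scr <- stats::plogis(stats::qlogis(preset$p_screened) +
                           eff$shift_screened)
  qbar <- sh[1] +
    sh[2] * stats::plogis(stats::qlogis(preset$p_pre_assessed) +
                            eff$shift_quality) +
    sh[3] * stats::plogis(stats::qlogis(preset$p_susp_confirmed) +
                            eff$shift_quality)
  expected <- (p_scr * qbar)[match(prov$province_code, eff$province_code)]
  se <- sqrt(expected * (1 - expected) / prov$n_eligible)
  inside <- abs(prov$ec - expected) <= 3 * se
  expect_gte(mean(inside), 0.95)
  # the spread should be wide, echoing strong provincial heterogeneity
  expect_gt(max(prov$coverage) - min(prov$coverage), 0.3)
})

test_that("pooled national numerators equal the sum of provincial numerators", {
  b <- generate_cohort(province_varying_preset(30000, seed = 2),
                       "stochastic", seed = 8)
  res <- assess_cohort(b)
  pooled <- build_cascade(res)
  prov_casc <- lapply(sort(unique(res$province_code)), function(p)
    build_cascade(res[res$province_code == p, ]))
  summed <- Reduce(`+`, lapply(prov_casc, function(cc) cc$numerator))
  expect_identical(pooled$numerator, summed)
})
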