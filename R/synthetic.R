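# Synthetic cohort generator.
#
# Emulates the structure of a restricted national claims extract: a need
# population, a screening branch, BP subgroups, and dated service /
# diagnosis / follow-up events that satisfy or fail each effectiveness
# criterion. Two modes:
#   exact_quota — deterministic branch counts (round-half-up with
#     largest-remainder correction), so the pipeline must recover the
#     cascade exactly;
#   stochastic  — independent per-person Bernoulli draws, for
#     sampling-variability and province-heterogeneity testing.

#' Construct a cohort generator preset
#'
#' A preset fixes the marginal cascade structure of a generated cohort:
#' the screening probability, the BP subgroup shares among screened, and
#' the conditional probability of each downstream criterion being met.
#' Branches are independent (the joint structure is a modelling choice;
#' only marginals are targeted), except that risk reduction is nested
#' within risk assessment.
#'
#' @param n_persons Cohort size.
#' @param n_provinces Number of provinces (codes `1..n_provinces`).
#' @param p_screened Probability an eligible person is screened in-window.
#' @param subgroup_shares Length-3 numeric `(normotension, pre_ht,
#'   suspected_ht)` summing to 1.
#' @param p_pre_assessed P(risk assessment | pre-HT).
#' @param p_susp_confirmed P(repeat BP within the confirmation window |
#'   suspected).
#' @param p_susp_diagnosed P(HT diagnosis | suspected).
#' @param p_dx_treated,p_dx_assessed,p_dx_controlled P(criterion |
#'   diagnosed).
#' @param p_dx_risk_reduced P(lipid improvement | diagnosed); must not
#'   exceed `p_dx_assessed` (reduction requires assessment).
#' @param ineligible_fraction Fraction of generated persons that fail the
#'   need criteria (split evenly between under-age, prior-HT and
#'   not-in-registry), to exercise eligibility determination.
#' @param age_sex_structure Data frame with columns `age_min`, `age_max`,
#'   `share` for the eligible age bands, and attribute-free `p_female`
#'   handled via the `p_female` argument.
#' @param p_female Probability a person is female.
#' @param province_effects Optional data frame `province_code`,
#'   `shift_screened`, `shift_quality`: logit-scale shifts applied (in
#'   stochastic mode) to `p_screened` and to the pre-HT assessment /
#'   confirmation probabilities.
#' @param name Preset label (recorded in run manifests).
#' @return A list of class `generator_preset`.
#' @export
cohort_preset <- function(n_persons,
                          n_provinces = 76L,
                          p_screened,
                          subgroup_shares,
                          p_pre_assessed,
                          p_susp_confirmed,
                          p_susp_diagnosed,
                          p_dx_treated,
                          p_dx_assessed,
                          p_dx_controlled,
                          p_dx_risk_reduced,
                          ineligible_fraction = 0,
                          age_sex_structure = default_age_structure(),
                          p_female = 0.5,
                          province_effects = NULL,
                          name = "custom") {
  probs <- c(p_screened = p_screened, p_pre_assessed = p_pre_assessed,
             p_susp_confirmed = p_susp_confirmed,
             p_susp_diagnosed = p_susp_diagnosed,
             p_dx_treated = p_dx_treated, p_dx_assessed = p_dx_assessed,
             p_dx_controlled = p_dx_controlled,
             p_dx_risk_reduced = p_dx_risk_reduced,
             ineligible_fraction = ineligible_fraction,
             p_female = p_female)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (length(subgroup_shares) != 3 || abs(sum(subgroup_shares) - 1) > 1e-9) {
    stop("subgroup_shares must be 3 proportions summing to 1", call. = FALSE)
  }
  if (p_dx_risk_reduced > p_dx_assessed) {
    stop("p_dx_risk_reduced cannot exceed p_dx_assessed ",
         "(risk reduction requires assessment)", call. = FALSE)
  }
  if (abs(sum(age_sex_structure$share) - 1) > 1e-9) {
    stop("age_sex_structure shares must sum to 1", call. = FALSE)
  }
  structure(list(
    n_persons = as.integer(n_persons),
    n_provinces = as.integer(n_provinces),
    p_screened = p_screened,
    subgroup_shares = stats::setNames(as.numeric(subgroup_shares),
                                      bp_categories),
    p_pre_assessed = p_pre_assessed,
    p_susp_confirmed = p_susp_confirmed,
    p_susp_diagnosed = p_susp_diagnosed,
    p_dx_treated = p_dx_treated,
    p_dx_assessed = p_dx_assessed,
    p_dx_controlled = p_dx_controlled,
    p_dx_risk_reduced = p_dx_risk_reduced,
    ineligible_fraction = ineligible_fraction,
    age_sex_structure = tibble::as_tibble(age_sex_structure),
    p_female = p_female,
    province_effects = province_effects,
    name = name
  ), class = "generator_preset")
}

# eligible age bands: ~38% aged 15-34, remainder split 42/20 between the
# middle and older bands
default_age_structure <- function() {
  tibble::tibble(
    age_min = c(15L, 35L, 60L),
    age_max = c(34L, 59L, 89L),
    share = c(0.38, 0.42, 0.20)
  )
}

#' The Thailand-2013 replication preset
#'
#' Generator preset reproducing the national hypertension screening
#' cascade observed in the 2013 Thai universal-coverage claims data:
#' 54.6% screening coverage; 65.1% / 28.9% / 6.0% normotension / pre-HT /
#' suspected-HT shares among screened; 82.6% risk assessment among pre-HT;
#' 38.0% 60-day confirmation and 9.2% diagnosis among suspected; and
#' 36.5% timely treatment, 21.8% CVD risk assessment, 50.8% BP control,
#' 0.7% risk reduction among the newly diagnosed.
#'
#' @param n_persons Cohort size (default one million).
#' @return A `generator_preset`.
#' @export
thailand2013_preset <- function(n_persons = 1e6) {
  cohort_preset(
    n_persons = n_persons,
    n_provinces = 76L,
    p_screened = 0.546,
    subgroup_shares = c(0.651, 0.289, 0.060),
    p_pre_assessed = 0.826,
    p_susp_confirmed = 0.380,
    p_susp_diagnosed = 0.092,
    p_dx_treated = 0.365,
    p_dx_assessed = 0.218,
    p_dx_controlled = 0.508,
    p_dx_risk_reduced = 0.007,
    ineligible_fraction = 0,
    name = "thailand2013"
  )
}

#' A province-heterogeneous preset
#'
#' The Thailand-2013 preset with logit-normal province effects on the
#' screening probability (and, attenuated, on the quality criteria),
#' producing a wide provincial coverage spread for qualitative testing of
#' the provincial summaries. Stochastic mode only.
#'
#' @param n_persons Cohort size.
#' @param effect_sd Standard deviation of the logit-scale province effect
#'   on screening; the quality shift uses half this value.
#' @param seed Seed for drawing the per-province effects (stored in the
#'   preset, so the preset itself is deterministic).
#' @return A `generator_preset`.
#' @export
province_varying_preset <- function(n_persons = 2e5, effect_sd = 1.0,
                                    seed = 1L) {
  base <- thailand2013_preset(n_persons)
  eff <- withr::with_seed(as.integer(seed), {
    tibble::tibble(
      province_code = seq_len(base$n_provinces),
      shift_screened = stats::rnorm(base$n_provinces, 0, effect_sd),
      shift_quality = stats::rnorm(base$n_provinces, 0, effect_sd / 2)
    )
  })
  base$province_effects <- eff
  base$name <- "province_varying"
  base
}

#' @export
print.generator_preset <- function(x, ...) {
  cat(sprintf("<generator_preset '%s'> n = %s, %d provinces\n", x$name,
              format(x$n_persons, big.mark = ","), x$n_provinces))
  cat(sprintf("  p_screened = %.3f; shares = %.3f / %.3f / %.3f\n",
              x$p_screened, x$subgroup_shares[1], x$subgroup_shares[2],
              x$subgroup_shares[3]))
  cat(sprintf("  pre assessed %.3f | susp confirmed %.3f, diagnosed %.3f\n",
              x$p_pre_assessed, x$p_susp_confirmed, x$p_susp_diagnosed))
  cat(sprintf("  dx treated %.3f, assessed %.3f, controlled %.3f, reduced %.3f\n",
              x$p_dx_treated, x$p_dx_assessed, x$p_dx_controlled,
              x$p_dx_risk_reduced))
  invisible(x)
}

# ---- internal machinery ---------------------------------------------------

# deterministic branch counts for exact-quota mode, shared with ground_truth
quota_counts <- function(preset) {
  n <- preset$n_persons
  n_inelig <- quota_count(n, preset$ineligible_fraction)
  n_elig <- n - n_inelig
  n_scr <- quota_count(n_elig, preset$p_screened)
  cat_counts <- largest_remainder(n_scr, preset$subgroup_shares)
  n_pre <- cat_counts[2]; n_susp <- cat_counts[3]
  n_dx <- quota_count(n_susp, preset$p_susp_diagnosed)
  n_ass <- quota_count(n_dx, preset$p_dx_assessed)
  list(
    n_persons = n, n_ineligible = n_inelig, n_eligible = n_elig,
    n_screened = n_scr,
    n_norm = cat_counts[1], n_pre = n_pre, n_susp = n_susp,
    n_pre_ok = quota_count(n_pre, preset$p_pre_assessed),
    n_conf = quota_count(n_susp, preset$p_susp_confirmed),
    n_dx = n_dx,
    n_tx = quota_count(n_dx, preset$p_dx_treated),
    n_ass = n_ass,
    n_ctl = quota_count(n_dx, preset$p_dx_controlled),
    n_red = min(quota_count(n_dx, preset$p_dx_risk_reduced), n_ass)
  )
}

# logit-shift a probability, identity when shift is 0/NULL
shift_p <- function(p, shift) {
  if (is.null(shift)) return(rep(p, 1))
  stats::plogis(stats::qlogis(p) + shift)
}

#' Expected cascade for a preset (generator ground truth)
#'
#' The cascade the assessment pipeline is expected to recover from
#' [generate_cohort()]: exact integer counts in `exact_quota` mode,
#' expected counts (preset parameters times expected denominators) in
#' `stochastic` mode. Used as the oracle in pipeline-recovery tests.
#'
#' @param preset A [cohort_preset()].
#' @param mode `"exact_quota"` or `"stochastic"`.
#' @return A `cascade_table` tibble.
#' @export
ground_truth <- function(preset, mode = c("exact_quota", "stochastic")) {
  mode <- match.arg(mode)
  if (mode == "exact_quota") {
    q <- quota_counts(preset)
    num <- c(q$n_eligible, q$n_screened, q$n_norm, q$n_pre, q$n_susp,
             q$n_pre_ok, q$n_conf, q$n_dx, q$n_tx, q$n_ass, q$n_ctl, q$n_red)
    den <- c(q$n_persons, q$n_eligible, rep(q$n_screened, 3),
             q$n_pre, q$n_susp, q$n_susp, rep(q$n_dx, 4))
  } else {
    n <- preset$n_persons
    e <- n * (1 - preset$ineligible_fraction)
    s <- e * preset$p_screened
    cats <- s * preset$subgroup_shares
    d <- cats[3] * preset$p_susp_diagnosed
    num <- c(e, s, cats[1], cats[2], cats[3],
             cats[2] * preset$p_pre_assessed,
             cats[3] * preset$p_susp_confirmed, d,
             d * preset$p_dx_treated, d * preset$p_dx_assessed,
             d * preset$p_dx_controlled, d * preset$p_dx_risk_reduced)
    den <- c(n, e, rep(s, 3), cats[2], cats[3], cats[3], rep(d, 4))
  }
  new_cascade_table(cascade_nodes, num, den)
}

#' Generate a synthetic cohort bundle
#'
#' Builds a valid [record_bundle()] whose cascade structure follows the
#' preset. Persons carry ages, sexes and provinces; screened persons get a
#' raw SBP/DBP reading drawn from their assigned subgroup's BP region (the
#' pipeline must re-derive the category from the values); downstream
#' events get dates that satisfy or fail each criterion's window. Failed
#' criteria are realised about half as "no event" and half as an
#' out-of-window (or otherwise non-qualifying) event, so both failure
#' paths of every criterion occur.
#'
#' Initial screenings fall in the first nine months of the study window so
#' confirmation and treatment windows can close inside it. Follow-up BP
#' events emitted for the blood-pressure-control criterion are dated after
#' the confirmation window, so they never double as a timely confirmation.
#'
#' @param preset A [cohort_preset()].
#' @param mode `"exact_quota"` (deterministic branch counts) or
#'   `"stochastic"` (independent Bernoulli draws per person).
#' @param seed Integer seed; the same preset, mode and seed always yield a
#'   byte-identical bundle. Required.
#' @param study A [study_config()] supplying the event-date window.
#' @return A [record_bundle()] passing [validate_bundle()].
#' @export
generate_cohort <- function(preset, mode = c("exact_quota", "stochastic"),
                            seed, study = study_config()) {
  mode <- match.arg(mode)
  stopifnot(inherits(preset, "generator_preset"))
  if (missing(seed)) stop("seed is required", call. = FALSE)
  withr::local_seed(as.integer(seed))

  n <- preset$n_persons
  start <- study$study_year_start
  end <- study$study_year_end
  ref <- study$reference_date_for_age
  window_days <- as.integer(end - start) + 1L
  screen_span <- max(1L, as.integer(round(window_days * 0.75)))

  ids <- sprintf("P%08d", seq_len(n))
  province <- runif_int(n, 1L, preset$n_provinces)
  sex <- ifelse(stats::runif(n) < preset$p_female, "female", "male")

  # --- eligibility strata ---------------------------------------------
  inelig_kind <- rep(NA_character_, n)
  kinds <- c("under_age", "prior_ht", "not_in_registry")
  if (mode == "exact_quota") {
    k <- quota_count(n, preset$ineligible_fraction)
    if (k > 0) {
      idx <- sample_from(seq_len(n), k)
      inelig_kind[idx] <- rep(kinds, length.out = k)[sample.int(k)]
    }
  } else {
    hit <- stats::runif(n) < preset$ineligible_fraction
    inelig_kind[hit] <- sample(kinds, sum(hit), replace = TRUE)
  }
  eligible <- is.na(inelig_kind)

  # --- ages / birth dates ----------------------------------------------
  bands <- preset$age_sex_structure
  band_i <- sample.int(nrow(bands), n, replace = TRUE, prob = bands$share)
  age <- runif_int(n, bands$age_min[band_i], bands$age_max[band_i])
  under <- !eligible & inelig_kind == "under_age"
  age[under] <- runif_int(sum(under), 5L, preset$age_sex_structure$age_min[1] - 1L)
  birth_date <- birth_date_for_age(age, ref)

  in_registry <- eligible | inelig_kind != "not_in_registry"

  persons <- tibble::tibble(
    person_id = ids, birth_date = birth_date, sex = sex,
    province_code = province, in_civil_registry = in_registry)

  prior <- which(!eligible & inelig_kind == "prior_ht")
  registry <- tibble::tibble(
    person_id = ids[prior],
    condition = rep("hypertension", length(prior)),
    registration_date = start - runif_int(length(prior), 1L, 1095L))

  # --- cascade branch flags --------------------------------------------
  scr <- conf <- dx <- pre_ok <- tx <- ass <- ctl <- red <- rep(FALSE, n)
  cat <- rep(NA_character_, n)
  if (mode == "exact_quota") {
    q <- quota_counts(preset)
    scr_idx <- sample_from(which(eligible), q$n_screened)
    scr[scr_idx] <- TRUE
    perm <- scr_idx[sample.int(length(scr_idx))]
    cat[perm] <- rep(bp_categories, times = c(q$n_norm, q$n_pre, q$n_susp))
    pre_idx <- which(cat == "pre_ht")
    susp_idx <- which(cat == "suspected_ht")
    pre_ok[sample_from(pre_idx, q$n_pre_ok)] <- TRUE
    conf[sample_from(susp_idx, q$n_conf)] <- TRUE
    dx_idx <- sample_from(susp_idx, q$n_dx)
    dx[dx_idx] <- TRUE
    tx[sample_from(dx_idx, q$n_tx)] <- TRUE
    ass_idx <- sample_from(dx_idx, q$n_ass)
    ass[ass_idx] <- TRUE
    ctl[sample_from(dx_idx, q$n_ctl)] <- TRUE
    red[sample_from(ass_idx, q$n_red)] <- TRUE
  } else {
    eff <- preset$province_effects
    sh_scr <- if (is.null(eff)) rep(0, n) else
      eff$shift_screened[match(province, eff$province_code)]
    sh_q <- if (is.null(eff)) rep(0, n) else
      eff$shift_quality[match(province, eff$province_code)]
    scr <- eligible & stats::runif(n) < shift_p(preset$p_screened, sh_scr)
    u <- stats::runif(n)
    cum <- cumsum(preset$subgroup_shares)
    cat[scr] <- bp_categories[1 + (u[scr] >= cum[1]) + (u[scr] >= cum[2])]
    pre_ok <- cat == "pre_ht" & !is.na(cat) &
      stats::runif(n) < shift_p(preset$p_pre_assessed, sh_q)
    is_susp <- !is.na(cat) & cat == "suspected_ht"
    conf <- is_susp & stats::runif(n) < shift_p(preset$p_susp_confirmed, sh_q)
    dx <- is_susp & stats::runif(n) < preset$p_susp_diagnosed
    tx <- dx & stats::runif(n) < preset$p_dx_treated
    ass <- dx & stats::runif(n) < preset$p_dx_assessed
    ctl <- dx & stats::runif(n) < preset$p_dx_controlled
    p_red_given_ass <- if (preset$p_dx_assessed > 0)
      preset$p_dx_risk_reduced / preset$p_dx_assessed else 0
    red <- ass & stats::runif(n) < p_red_given_ass
    pre_ok[is.na(pre_ok)] <- FALSE
  }

  # --- initial screenings ----------------------------------------------
  scr_i <- which(scr)
  sdate <- rep(as.Date(NA), n)
  sdate[scr_i] <- start + runif_int(length(scr_i), 0L, screen_span - 1L)
  bp <- draw_bp(cat, scr_i)
  screenings <- tibble::tibble(
    person_id = ids[scr_i], event_date = sdate[scr_i],
    sbp = bp$sbp[scr_i], dbp = bp$dbp[scr_i])

  coin <- stats::runif(n) < 0.5  # "late event" vs "no event" for failures

  # --- pre-HT risk-assessment services ---------------------------------
  ra_pos <- which(cat == "pre_ht" & pre_ok)
  ra_date <- sdate[ra_pos] +
    runif_int(length(ra_pos), 0L, pmin(60L, as.integer(end - sdate[ra_pos])))
  ra_neg <- which(cat == "pre_ht" & !pre_ok & coin)
  ra_neg_date <- sdate[ra_neg] - runif_int(length(ra_neg), 1L, 30L)
  keep <- ra_neg_date >= start
  ra_neg <- ra_neg[keep]; ra_neg_date <- ra_neg_date[keep]
  services_ra <- service_rows(ids[c(ra_pos, ra_neg)],
                              c(ra_date, ra_neg_date),
                              "ht_cvd_risk_assessment")

  # --- confirmation follow-up BP ---------------------------------------
  cf_pos <- which(conf)
  cf_date <- sdate[cf_pos] + runif_int(length(cf_pos), 1L, 60L)
  # late-confirmation events are suppressed for diagnosed+controlled
  # persons: their control follow-up must stay the latest BP on file
  cf_neg <- which(!is.na(cat) & cat == "suspected_ht" & !conf & coin &
                    !(dx & ctl))
  cf_neg_date <- sdate[cf_neg] +
    runif_int(length(cf_neg), 61L,
              pmin(150L, as.integer(end - sdate[cf_neg])))
  fu_conf <- service_rows(ids[c(cf_pos, cf_neg)], c(cf_date, cf_neg_date),
                          "follow_up_bp",
                          sbp = bp$sbp[c(cf_pos, cf_neg)],
                          dbp = bp$dbp[c(cf_pos, cf_neg)])

  # --- diagnoses --------------------------------------------------------
  dx_pos <- which(dx)
  ddate <- rep(as.Date(NA), n)
  ddate[dx_pos] <- sdate[dx_pos] +
    runif_int(length(dx_pos), 0L, pmin(30L, as.integer(end - sdate[dx_pos])))
  dx_neg <- which(!is.na(cat) & cat == "suspected_ht" & !dx & coin)
  dx_neg_date <- sdate[dx_neg] - runif_int(length(dx_neg), 1L, 60L)
  keep <- dx_neg_date >= start
  dx_neg <- dx_neg[keep]; dx_neg_date <- dx_neg_date[keep]
  all_dx <- c(dx_pos, dx_neg)
  diagnoses <- tibble::tibble(
    person_id = ids[all_dx],
    event_date = c(ddate[dx_pos], dx_neg_date),
    icd10_code = sample(paste0("I1", 0:5), length(all_dx), replace = TRUE))

  # --- treatment starts -------------------------------------------------
  tx_pos <- which(tx)
  tx_date <- ddate[tx_pos] +
    runif_int(length(tx_pos), 0L,
              pmin(183L, as.integer(end - ddate[tx_pos])))
  tx_neg <- which(dx & !tx & coin)
  tx_room <- as.integer(end - ddate[tx_neg])
  keep <- tx_room >= 184L
  tx_neg <- tx_neg[keep]
  tx_neg_date <- ddate[tx_neg] +
    runif_int(length(tx_neg), 184L, pmin(273L, tx_room[keep]))
  services_tx <- service_rows(ids[c(tx_pos, tx_neg)],
                              c(tx_date, tx_neg_date), "ht_treatment_start")

  # --- lipid panels -----------------------------------------------------
  lp1 <- which(ass)
  lp1_date <- ddate[lp1] +
    runif_int(length(lp1), 0L, pmin(45L, as.integer(end - ddate[lp1])))
  chol1 <- runif_int(length(lp1), 190L, 260L)
  ldl1 <- runif_int(length(lp1), 110L, 170L)
  hdl1 <- runif_int(length(lp1), 35L, 60L)
  lp_neg <- which(dx & !ass & coin)
  lp_neg_date <- ddate[lp_neg] - runif_int(length(lp_neg), 1L, 45L)
  keep <- lp_neg_date >= start
  lp_neg <- lp_neg[keep]; lp_neg_date <- lp_neg_date[keep]

  # second panel: improved for risk-reduced, strictly worse for a coin-half
  # of the assessed-but-not-reduced
  red_in_lp1 <- which(red[lp1])
  worse_in_lp1 <- which(!red[lp1] & coin[lp1])
  second_i <- c(red_in_lp1, worse_in_lp1)
  lp2_date <- lp1_date[second_i] +
    runif_int(length(second_i), 1L,
              pmax(1L, pmin(40L, as.integer(end - lp1_date[second_i]))))
  nred <- length(red_in_lp1)
  chol2 <- c(chol1[red_in_lp1] - runif_int(nred, 5L, 30L),
             chol1[worse_in_lp1] + runif_int(length(worse_in_lp1), 1L, 20L))
  ldl2 <- c(ldl1[red_in_lp1] - runif_int(nred, 5L, 25L),
            ldl1[worse_in_lp1] + runif_int(length(worse_in_lp1), 0L, 15L))
  hdl2 <- hdl1[second_i]
  services_lp <- dplyr::bind_rows(
    service_rows(ids[lp1], lp1_date, "lipid_panel",
                 total_chol = chol1, ldl = ldl1, hdl = hdl1),
    service_rows(ids[lp_neg], lp_neg_date, "lipid_panel",
                 total_chol = runif_int(length(lp_neg), 190L, 260L),
                 ldl = runif_int(length(lp_neg), 110L, 170L),
                 hdl = runif_int(length(lp_neg), 35L, 60L)),
    service_rows(ids[lp1][second_i], lp2_date, "lipid_panel",
                 total_chol = chol2, ldl = ldl2, hdl = hdl2))

  # --- control follow-up BP --------------------------------------------
  conf_window <- 60L
  ctl_pos <- which(ctl)
  base_date <- pmax(ddate[ctl_pos], sdate[ctl_pos] + conf_window) + 1L
  ctl_date <- base_date +
    runif_int(length(ctl_pos), 0L,
              pmax(0L, pmin(20L, as.integer(end - base_date))))
  ctl_sbp <- runif_int(length(ctl_pos), 110L, 135L)
  ctl_dbp <- runif_int(length(ctl_pos), 70L, 85L)
  ctl_neg <- which(dx & !ctl & coin)
  nbase <- pmax(ddate[ctl_neg], sdate[ctl_neg] + conf_window) + 1L
  ctl_neg_date <- nbase +
    runif_int(length(ctl_neg), 0L,
              pmax(0L, pmin(20L, as.integer(end - nbase))))
  fu_ctl <- service_rows(ids[c(ctl_pos, ctl_neg)],
                         c(ctl_date, ctl_neg_date), "follow_up_bp",
                         sbp = c(ctl_sbp, bp$sbp[ctl_neg]),
                         dbp = c(ctl_dbp, bp$dbp[ctl_neg]))

  services <- dplyr::bind_rows(services_ra, services_tx, services_lp) |>
    dplyr::arrange(.data$person_id, .data$event_date, .data$service_code)
  followups <- dplyr::bind_rows(fu_conf, fu_ctl) |>
    dplyr::arrange(.data$person_id, .data$event_date)
  diagnoses <- dplyr::arrange(diagnoses, .data$person_id, .data$event_date)
  screenings <- dplyr::arrange(screenings, .data$person_id, .data$event_date)

  record_bundle(persons, screenings, services, diagnoses, registry,
                followups)
}

# birth date uniform within the interval giving exactly `age` completed
# years at `ref`; vectorised via the (few) unique ages
birth_date_for_age <- function(age, ref) {
  out <- rep(as.Date(NA), length(age))
  for (a in unique(age)) {
    i <- which(age == a)
    hi <- seq(ref, by = paste0("-", a, " years"), length.out = 2)[2]
    lo <- seq(ref, by = paste0("-", a + 1, " years"), length.out = 2)[2]
    span <- as.integer(hi - lo)
    out[i] <- lo + runif_int(length(i), 1L, span)
  }
  out
}

# raw BP readings inside each subgroup's region; two sub-regions per
# non-normal category so both arms of the and/or rule occur
draw_bp <- function(cat, scr_i) {
  n <- length(cat)
  sbp <- rep(NA_integer_, n)
  dbp <- rep(NA_integer_, n)
  arm <- stats::runif(n) < 0.5
  i <- intersect(which(!is.na(cat) & cat == "normotension"), scr_i)
  sbp[i] <- runif_int(length(i), 90L, 119L)
  dbp[i] <- runif_int(length(i), 60L, 79L)
  i <- intersect(which(!is.na(cat) & cat == "pre_ht" & arm), scr_i)
  sbp[i] <- runif_int(length(i), 120L, 139L)   # systolic-driven pre-HT
  dbp[i] <- runif_int(length(i), 60L, 89L)
  i <- intersect(which(!is.na(cat) & cat == "pre_ht" & !arm), scr_i)
  sbp[i] <- runif_int(length(i), 90L, 119L)    # diastolic-driven pre-HT
  dbp[i] <- runif_int(length(i), 80L, 89L)
  i <- intersect(which(!is.na(cat) & cat == "suspected_ht" & arm), scr_i)
  sbp[i] <- runif_int(length(i), 140L, 220L)   # systolic-driven
  dbp[i] <- runif_int(length(i), 60L, 119L)
  i <- intersect(which(!is.na(cat) & cat == "suspected_ht" & !arm), scr_i)
  dbp[i] <- runif_int(length(i), 90L, 120L)    # diastolic-driven
  sbp[i] <- dbp[i] + runif_int(length(i), 1L, pmax(1L, 139L - dbp[i]))
  list(sbp = sbp, dbp = dbp)
}

service_rows <- function(person_id, event_date, code, sbp = NA_integer_,
                         dbp = NA_integer_, total_chol = NA_integer_,
                         ldl = NA_integer_, hdl = NA_integer_) {
  k <- length(person_id)
  tibble::tibble(
    person_id = person_id,
    event_date = as.Date(event_date, origin = "1970-01-01"),
    service_code = rep(code, k),
    sbp = rep_len(as.integer(sbp), k),
    dbp = rep_len(as.integer(dbp), k),
    total_chol = rep_len(as.integer(total_chol), k),
    ldl = rep_len(as.integer(ldl), k),
    hdl = rep_len(as.integer(hdl), k))
}
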