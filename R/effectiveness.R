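# Per-subgroup effectiveness criteria (Q) and the diagnosed-case cascade.
#
# Q is binary by default: a screened person scores 1 iff the criterion for
# their BP subgroup is met. The criteria are evaluated from dated event
# records; all date comparisons are day-granular.

assert_category <- function(assignments, expected) {
  if (nrow(assignments) == 0) return(invisible(TRUE))
  bad <- is.na(assignments$category) | assignments$category != expected
  if (any(bad)) {
    stop(sprintf("expected only category '%s' assignments, got %d other row(s)",
                 expected, sum(bad)), call. = FALSE)
  }
  invisible(TRUE)
}

q_result <- function(person_id, met, criterion) {
  tibble::tibble(
    person_id = person_id,
    q = as.numeric(met),
    criterion_applied = criterion,
    criterion_met = met
  )
}

#' Q criterion for the normotensive subgroup
#'
#' The criterion is "at least one BP measurement in the year", which a
#' screened normotensive person satisfies by construction: Q = 1.
#'
#' @param assignments Rows of [assign_subgroups()] output with
#'   `category == "normotension"` (anything else is an error).
#' @return A tibble `person_id`, `q`, `criterion_applied`, `criterion_met`.
#' @export
q_normotension <- function(assignments) {
  assert_category(assignments, "normotension")
  q_result(assignments$person_id, rep(TRUE, nrow(assignments)), "bp_measured")
}

#' Q criterion for the pre-hypertensive subgroup
#'
#' Q = 1 iff a hypertension & cardiovascular risk-assessment service event
#' exists for the person, dated within the study window and on or after the
#' initial screening date (risk assessment is a post-screening step).
#'
#' @param assignments Rows of [assign_subgroups()] output with
#'   `category == "pre_ht"`.
#' @param services The bundle `services` table.
#' @param study A [study_config()].
#' @return A tibble `person_id`, `q`, `criterion_applied`, `criterion_met`.
#' @export
q_pre_ht <- function(assignments, services, study = study_config()) {
  assert_category(assignments, "pre_ht")
  ra <- services[services$service_code == "ht_cvd_risk_assessment" &
                   services$event_date >= study$study_year_start &
                   services$event_date <= study$study_year_end,
                 c("person_id", "event_date")]
  hit <- dplyr::inner_join(
    assignments[, c("person_id", "initial_screening_date")], ra,
    by = "person_id", relationship = "many-to-many")
  ok_ids <- unique(hit$person_id[hit$event_date >= hit$initial_screening_date])
  q_result(assignments$person_id, assignments$person_id %in% ok_ids,
           "risk_assessed")
}

#' Q criterion for the suspected-hypertension subgroup
#'
#' Q = 1 iff a repeat BP measurement — a later screening record or a
#' follow-up BP service event — exists with a date strictly after the
#' initial screening and at most `confirmation_window_days` later
#' (default 60 days; a same-day repeat does not confirm).
#'
#' @param assignments Rows of [assign_subgroups()] output with
#'   `category == "suspected_ht"`.
#' @param screenings The bundle `screenings` table.
#' @param followups Follow-up BP events (`service_code == "follow_up_bp"`).
#' @param criteria A [criteria_config()].
#' @return A tibble `person_id`, `q`, `criterion_applied`, `criterion_met`.
#' @export
q_suspected <- function(assignments, screenings, followups,
                        criteria = criteria_config()) {
  assert_category(assignments, "suspected_ht")
  rep_bp <- dplyr::bind_rows(
    screenings[, c("person_id", "event_date")],
    followups[followups$service_code == "follow_up_bp",
              c("person_id", "event_date")]
  )
  hit <- dplyr::inner_join(
    assignments[, c("person_id", "initial_screening_date")], rep_bp,
    by = "person_id", relationship = "many-to-many")
  delta <- as.integer(hit$event_date - hit$initial_screening_date)
  ok_ids <- unique(hit$person_id[delta > 0L &
                                   delta <= criteria$confirmation_window_days])
  q_result(assignments$person_id, assignments$person_id %in% ok_ids,
           "timely_confirmation")
}

#' Diagnosed-case cascade indicators for suspected-hypertension persons
#'
#' Evaluates, for each suspected-HT person, the newly-diagnosed cascade:
#'
#' * `diagnosed_ht` — a hypertension diagnosis (ICD-10 prefix in
#'   `study$ht_icd10_prefixes`) dated within the study window and on or
#'   after the initial screening; `diagnosis_date` is the earliest such.
#' * `treated_timely` — a treatment-start service within
#'   `treatment_window_days` of the diagnosis date (inclusive of day 0).
#' * `cvd_risk_assessed` — a lipid panel carrying all required lipid
#'   fields, dated on or after the diagnosis.
#' * `bp_controlled` — the latest follow-up BP on or after the diagnosis is
#'   under control (SBP < 140 and DBP < 90 by default) *or* strictly below
#'   the initial screening reading on both components.
#' * `cvd_risk_reduced` — among assessed persons, the latest qualifying
#'   lipid panel improves on the first: total cholesterol and LDL both not
#'   greater, at least one strictly lower.
#'
#' All downstream flags are `FALSE` when `diagnosed_ht` is `FALSE`, and
#' `cvd_risk_reduced` implies `cvd_risk_assessed`.
#'
#' @param assignments Rows of [assign_subgroups()] output with
#'   `category == "suspected_ht"`.
#' @param diagnoses,services,followups Bundle event tables.
#' @param study A [study_config()].
#' @param criteria A [criteria_config()].
#' @return A tibble with `person_id`, `diagnosed_ht`, `diagnosis_date`,
#'   `treated_timely`, `cvd_risk_assessed`, `bp_controlled`,
#'   `cvd_risk_reduced`.
#' @export
diagnosed_cascade <- function(assignments, diagnoses, services, followups,
                              study = study_config(),
                              criteria = criteria_config()) {
  assert_category(assignments, "suspected_ht")
  base <- assignments[, c("person_id", "initial_screening_date",
                          "initial_sbp", "initial_dbp")]

  ht_regex <- paste0("^(", paste(study$ht_icd10_prefixes, collapse = "|"), ")")
  dx <- diagnoses[grepl(ht_regex, diagnoses$icd10_code) &
                    diagnoses$event_date >= study$study_year_start &
                    diagnoses$event_date <= study$study_year_end,
                  c("person_id", "event_date")]
  dx <- dplyr::inner_join(base, dx, by = "person_id",
                          relationship = "many-to-many")
  dx <- dx[dx$event_date >= dx$initial_screening_date, , drop = FALSE]
  dx_first <- if (nrow(dx) == 0) {
    tibble::tibble(person_id = character(),
                   diagnosis_date = as.Date(character()))
  } else {
    dx |>
      dplyr::group_by(.data$person_id) |>
      dplyr::summarise(diagnosis_date = min(.data$event_date),
                       .groups = "drop")
  }

  out <- dplyr::left_join(base, dx_first, by = "person_id")
  out$diagnosed_ht <- !is.na(out$diagnosis_date)
  diag <- out[out$diagnosed_ht, , drop = FALSE]

  flag_false <- rep(FALSE, nrow(out))
  out$treated_timely <- out$cvd_risk_assessed <- flag_false
  out$bp_controlled <- out$cvd_risk_reduced <- flag_false
  if (nrow(diag) == 0) {
    return(out[, c("person_id", "diagnosed_ht", "diagnosis_date",
                   "treated_timely", "cvd_risk_assessed", "bp_controlled",
                   "cvd_risk_reduced")])
  }

  # timely treatment start
  tx <- services[services$service_code == "ht_treatment_start",
                 c("person_id", "event_date")]
  tx <- dplyr::inner_join(diag[, c("person_id", "diagnosis_date")], tx,
                          by = "person_id", relationship = "many-to-many")
  dtx <- as.integer(tx$event_date - tx$diagnosis_date)
  treated_ids <- unique(tx$person_id[dtx >= 0L &
                                       dtx <= criteria$treatment_window_days])

  # qualifying lipid panels on/after diagnosis
  req <- criteria$cvd_assessment_required_lipids
  lp <- services[services$service_code == "lipid_panel", , drop = FALSE]
  lp <- lp[rowSums(is.na(lp[, req, drop = FALSE])) == 0, , drop = FALSE]
  lp <- dplyr::inner_join(
    diag[, c("person_id", "diagnosis_date")],
    lp[, c("person_id", "event_date", "total_chol", "ldl")],
    by = "person_id", relationship = "many-to-many")
  lp <- lp[lp$event_date >= lp$diagnosis_date, , drop = FALSE]
  lp_sum <- lp |>
    dplyr::arrange(.data$person_id, .data$event_date) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::summarise(
      n_panels = dplyr::n(),
      chol_first = dplyr::first(.data$total_chol),
      ldl_first = dplyr::first(.data$ldl),
      chol_last = dplyr::last(.data$total_chol),
      ldl_last = dplyr::last(.data$ldl),
      .groups = "drop")
  assessed_ids <- lp_sum$person_id
  improved <- lp_sum$n_panels >= 2L &
    lp_sum$chol_last <= lp_sum$chol_first &
    lp_sum$ldl_last <= lp_sum$ldl_first &
    (lp_sum$chol_last < lp_sum$chol_first | lp_sum$ldl_last < lp_sum$ldl_first)
  reduced_ids <- lp_sum$person_id[improved]

  # latest follow-up BP on/after diagnosis
  fu <- followups[followups$service_code == "follow_up_bp",
                  c("person_id", "event_date", "sbp", "dbp")]
  fu <- dplyr::inner_join(
    diag[, c("person_id", "diagnosis_date", "initial_sbp", "initial_dbp")],
    fu, by = "person_id", relationship = "many-to-many")
  fu <- fu[fu$event_date >= fu$diagnosis_date, , drop = FALSE]
  fu_last <- fu |>
    dplyr::arrange(.data$person_id, .data$event_date) |>
    dplyr::group_by(.data$person_id) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup()
  controlled <- (fu_last$sbp < criteria$bp_control_sbp_max &
                   fu_last$dbp < criteria$bp_control_dbp_max) |
    (fu_last$sbp < fu_last$initial_sbp & fu_last$dbp < fu_last$initial_dbp)
  controlled_ids <- fu_last$person_id[controlled]

  out$treated_timely <- out$diagnosed_ht & out$person_id %in% treated_ids
  out$cvd_risk_assessed <- out$diagnosed_ht & out$person_id %in% assessed_ids
  out$bp_controlled <- out$diagnosed_ht & out$person_id %in% controlled_ids
  out$cvd_risk_reduced <- out$diagnosed_ht & out$person_id %in% reduced_ids
  out[, c("person_id", "diagnosed_ht", "diagnosis_date", "treated_timely",
          "cvd_risk_assessed", "bp_controlled", "cvd_risk_reduced")]
}

#' Individual effective coverage
#'
#' The effective coverage delivered to one person in the need population:
#' `EC = Q * U | N = 1`, the product of the quality score and the
#' utilization indicator, defined only over persons with need.
#'
#' @param q Quality score(s) in `[0, 1]` (binary under default scoring).
#' @param u Utilization indicator(s) in `{0, 1}`.
#' @param n Need indicator(s); must all equal 1 (EC is undefined off the
#'   need population — restrict before aggregating).
#' @return Numeric vector `q * u`.
#' @examples
#' compute_individual_ec(1, 1)    # screened, criterion met
#' compute_individual_ec(0.5, 1)  # weighted scoring
#' compute_individual_ec(1, 0)    # unscreened: no coverage delivered
#' @export
compute_individual_ec <- function(q, u, n = 1) {
  if (any(is.na(n)) || any(n != 1)) {
    stop("EC is defined only over the need population (n = 1)", call. = FALSE)
  }
  if (any(q < 0 | q > 1, na.rm = TRUE)) stop("q must lie in [0, 1]", call. = FALSE)
  if (!all(u %in% c(0, 1))) stop("u must be 0 or 1", call. = FALSE)
  out <- as.numeric(q) * as.numeric(u)
  out[u == 0] <- 0  # unscreened persons contribute 0 even when q is undefined
  out
}
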