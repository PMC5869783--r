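#' Study configuration: who counts as needing screening, and when
#'
#' Defines the screening target (need) population and the observation
#' window. Defaults describe a calendar-year 2013 national programme:
#' residents of the 76 provinces, aged 15 or older (completed years at the
#' window start), registered in the civil registration system, with no
#' hypertension diagnosis before the window start.
#'
#' @param study_year_start,study_year_end Observation window (Dates).
#' @param min_age_years Minimum age in completed years at
#'   `reference_date_for_age`.
#' @param included_provinces Integer province codes in scope.
#' @param ht_icd10_prefixes ICD-10 code prefixes counted as hypertension
#'   (default `I10`–`I15`).
#' @param reference_date_for_age Date at which age is evaluated; defaults to
#'   the window start.
#' @return A list of class `study_config`.
#' @export
study_config <- function(study_year_start = as.Date("2013-01-01"),
                         study_year_end = as.Date("2013-12-31"),
                         min_age_years = 15L,
                         included_provinces = 1:76,
                         ht_icd10_prefixes = paste0("I1", 0:5),
                         reference_date_for_age = study_year_start) {
  study_year_start <- as.Date(study_year_start)
  study_year_end <- as.Date(study_year_end)
  reference_date_for_age <- as.Date(reference_date_for_age)
  stopifnot(study_year_start < study_year_end, min_age_years >= 0)
  structure(list(
    study_year_start = study_year_start,
    study_year_end = study_year_end,
    min_age_years = as.integer(min_age_years),
    included_provinces = as.integer(included_provinces),
    ht_icd10_prefixes = as.character(ht_icd10_prefixes),
    reference_date_for_age = reference_date_for_age
  ), class = "study_config")
}

#' Effectiveness criteria configuration
#'
#' Tunable parameters of the per-subgroup quality (Q) criteria.
#'
#' @param confirmation_window_days Days after the initial screening within
#'   which a repeat BP measurement confirms a suspected-hypertension
#'   screening (default 60; the window is exclusive of day 0 and inclusive
#'   of the last day).
#' @param treatment_window_days Days after diagnosis within which a started
#'   treatment counts as timely (default 183, i.e. six months).
#' @param bp_control_sbp_max,bp_control_dbp_max Exclusive control cutoffs in
#'   mmHg for follow-up blood pressure (defaults 140/90).
#' @param cvd_assessment_required_lipids Lipid fields a panel must carry to
#'   count as a cardiovascular risk assessment for diagnosed cases.
#' @param q_scoring `"binary_subgroup"` (default): Q is the person's own
#'   subgroup criterion. `"strict"`: diagnosed persons must additionally
#'   meet every diagnosed-cascade criterion for Q = 1.
#' @return A list of class `criteria_config`.
#' @export
criteria_config <- function(confirmation_window_days = 60L,
                            treatment_window_days = 183L,
                            bp_control_sbp_max = 140L,
                            bp_control_dbp_max = 90L,
                            cvd_assessment_required_lipids =
                              c("total_chol", "ldl", "hdl"),
                            q_scoring = c("binary_subgroup", "strict")) {
  q_scoring <- match.arg(q_scoring)
  stopifnot(confirmation_window_days > 0, treatment_window_days > 0)
  stopifnot(all(cvd_assessment_required_lipids %in% lipid_fields))
  structure(list(
    confirmation_window_days = as.integer(confirmation_window_days),
    treatment_window_days = as.integer(treatment_window_days),
    bp_control_sbp_max = as.integer(bp_control_sbp_max),
    bp_control_dbp_max = as.integer(bp_control_dbp_max),
    cvd_assessment_required_lipids = cvd_assessment_required_lipids,
    q_scoring = q_scoring
  ), class = "criteria_config")
}

#' Read study/criteria configuration from a YAML file
#'
#' Key names match the argument names of [study_config()] and
#' [criteria_config()], under top-level keys `study` and `criteria`
#' (both optional; omitted keys take their defaults).
#'
#' @param path Path to a YAML file.
#' @return A list with elements `study` and `criteria`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  study <- do.call(study_config, raw$study %||% list())
  criteria <- do.call(criteria_config, raw$criteria %||% list())
  list(study = study, criteria = criteria)
}
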