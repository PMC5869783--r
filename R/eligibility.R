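#' Determine the need population for hypertension screening
#'
#' Assigns every person in the bundle a need indicator `eligible`
#' (N in the effective-coverage formula). A person is eligible iff
#'
#' * age at `config$reference_date_for_age` is at least
#'   `config$min_age_years` completed years,
#' * their province is in `config$included_provinces`,
#' * they are in the civil registry, and
#' * there is no hypertension evidence dated strictly before the study
#'   window start: neither a registry entry with condition
#'   `"hypertension"` nor a diagnosis whose ICD-10 code starts with one of
#'   `config$ht_icd10_prefixes`.
#'
#' A diagnosis made *during* the study window does not exclude: such
#' persons remain in the screening target and enter the newly-diagnosed
#' branch of the cascade.
#'
#' Exactly one exclusion reason is recorded per ineligible person, with
#' precedence `under_age` > `excluded_province` > `not_in_registry` >
#' `prior_ht_diagnosis` (a missing birth date is its own reason when
#' `on_missing_birth_date = "exclude"`).
#'
#' @param bundle A [record_bundle()].
#' @param config A [study_config()].
#' @param on_missing_birth_date `"error"` (default) or `"exclude"`.
#' @return A tibble with columns `person_id`, `eligible`,
#'   `exclusion_reason` (NA when eligible).
#' @export
determine_eligibility <- function(bundle, config = study_config(),
                                  on_missing_birth_date = c("error", "exclude")) {
  stopifnot(inherits(bundle, "record_bundle"),
            inherits(config, "study_config"))
  on_missing_birth_date <- match.arg(on_missing_birth_date)
  persons <- bundle$persons

  if (anyNA(persons$birth_date) && on_missing_birth_date == "error") {
    stop("persons with missing birth_date present; set ",
         "on_missing_birth_date = \"exclude\" to drop them from the need ",
         "population", call. = FALSE)
  }
  age <- completed_years(persons$birth_date, config$reference_date_for_age)

  ht_regex <- paste0("^(", paste(config$ht_icd10_prefixes, collapse = "|"), ")")
  prior_reg <- bundle$registry$person_id[
    bundle$registry$condition == "hypertension" &
      bundle$registry$registration_date < config$study_year_start]
  prior_dx <- bundle$diagnoses$person_id[
    grepl(ht_regex, bundle$diagnoses$icd10_code) &
      bundle$diagnoses$event_date < config$study_year_start]
  prior_ht <- persons$person_id %in% c(prior_reg, prior_dx)

  reason <- rep(NA_character_, nrow(persons))
  reason[prior_ht] <- "prior_ht_diagnosis"
  reason[!persons$in_civil_registry] <- "not_in_registry"
  reason[!(persons$province_code %in% config$included_provinces)] <-
    "excluded_province"
  reason[!is.na(age) & age < config$min_age_years] <- "under_age"
  reason[is.na(persons$birth_date)] <- "missing_birth_date"

  tibble::tibble(
    person_id = persons$person_id,
    eligible = is.na(reason),
    exclusion_reason = reason
  )
}
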