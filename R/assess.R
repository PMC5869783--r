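#' Assess a cohort end to end
#'
#' Runs eligibility, subgroup classification, the per-subgroup Q criteria
#' and the diagnosed-case cascade over a record bundle, returning one row
#' per person with everything downstream aggregation needs.
#'
#' Under the default `q_scoring = "binary_subgroup"`, Q is the person's own
#' subgroup criterion (BP measured / risk assessed / timely confirmation);
#' the diagnosed-cascade indicators are reported alongside but not folded
#' into Q. Under `"strict"` scoring, a diagnosed person's Q additionally
#' requires every diagnosed-cascade criterion.
#'
#' @param bundle A [record_bundle()].
#' @param study A [study_config()].
#' @param criteria A [criteria_config()].
#' @param age_bands Lower bounds of the age bands used for stratified
#'   reporting (upper band open-ended).
#' @param on_missing_birth_date Passed to [determine_eligibility()].
#' @return A tibble of class `ec_results`, one row per person:
#'   demographics (`province_code`, `sex`, `age`, `age_band`), `eligible` +
#'   `exclusion_reason`, `screened` (U), `category`, the initial screening
#'   reading, `criterion_met`, `q`, `ec`, and the diagnosed-cascade flags.
#'   For ineligible persons all downstream fields are NA; for eligible
#'   unscreened persons `q` is NA and `ec` is 0.
#' @export
assess_cohort <- function(bundle, study = study_config(),
                          criteria = criteria_config(),
                          age_bands = c(15, 35, 60),
                          on_missing_birth_date = c("error", "exclude")) {
  eligibility <- determine_eligibility(bundle, study,
                                       on_missing_birth_date = on_missing_birth_date)
  subgroups <- assign_subgroups(bundle, eligibility, study)

  followups_all <- dplyr::bind_rows(
    bundle$followups,
    bundle$services[bundle$services$service_code == "follow_up_bp", ,
                    drop = FALSE])

  by_cat <- split(subgroups[subgroups$screened, , drop = FALSE],
                  subgroups$category[subgroups$screened])
  q_parts <- list(
    q_normotension(by_cat$normotension),
    q_pre_ht(by_cat$pre_ht, bundle$services, study),
    q_suspected(by_cat$suspected_ht, bundle$screenings, followups_all,
                criteria)
  )
  q_all <- dplyr::bind_rows(q_parts)
  casc <- diagnosed_cascade(by_cat$suspected_ht, bundle$diagnoses,
                            bundle$services, followups_all, study, criteria)

  res <- bundle$persons |>
    dplyr::left_join(eligibility, by = "person_id") |>
    dplyr::left_join(subgroups, by = "person_id") |>
    dplyr::left_join(q_all, by = "person_id") |>
    dplyr::left_join(casc, by = "person_id")

  res$age <- completed_years(res$birth_date, study$reference_date_for_age)
  breaks <- c(age_bands, Inf)
  labels <- c(paste0(utils::head(age_bands, -1), "-",
                     utils::tail(age_bands, -1) - 1),
              paste0(utils::tail(age_bands, 1), "+"))
  res$age_band <- cut(res$age, breaks = breaks, labels = labels,
                      right = FALSE)

  if (criteria$q_scoring == "strict") {
    dxed <- !is.na(res$diagnosed_ht) & res$diagnosed_ht
    res$q[dxed] <- as.numeric(res$criterion_met[dxed] &
                                res$treated_timely[dxed] &
                                res$cvd_risk_assessed[dxed] &
                                res$bp_controlled[dxed] &
                                res$cvd_risk_reduced[dxed])
  }

  res$ec <- NA_real_
  elig <- res$eligible
  res$ec[elig] <- compute_individual_ec(
    q = ifelse(res$screened[elig], res$q[elig], NA_real_),
    u = as.numeric(res$screened[elig]))

  out <- res[, c("person_id", "province_code", "sex", "age", "age_band",
                 "eligible", "exclusion_reason", "screened",
                 "initial_screening_date", "initial_sbp", "initial_dbp",
                 "category", "criterion_met", "q", "ec", "diagnosed_ht",
                 "diagnosis_date", "treated_timely", "cvd_risk_assessed",
                 "bp_controlled", "cvd_risk_reduced")]
  class(out) <- c("ec_results", class(out))
  out
}
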