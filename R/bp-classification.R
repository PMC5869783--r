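bp_categories <- c("normotension", "pre_ht", "suspected_ht")

#' Classify a blood-pressure reading
#'
#' Three-way classification of a systolic/diastolic pair:
#'
#' * `suspected_ht` — SBP >= 140 and/or DBP >= 90 mmHg;
#' * `pre_ht` — SBP 120–139 and/or DBP 80–89 mmHg (and not suspected);
#' * `normotension` — SBP < 120 and DBP < 80 mmHg.
#'
#' The "and/or" rule gives precedence suspected > pre-HT > normotension:
#' crossing either threshold is sufficient, whatever the other reading
#' (e.g. 115/85 is pre-HT, 135/92 is suspected).
#'
#' @param sbp,dbp Integer vectors in mmHg. Must lie on the physiologic grid
#'   (SBP 50–300, DBP 30–200, DBP < SBP); out-of-range input is an error —
#'   such rows should be removed upstream by bundle validation.
#' @return A factor with levels `normotension`, `pre_ht`, `suspected_ht`.
#' @examples
#' classify_bp(c(118L, 125L, 135L, 140L, 120L), c(78L, 70L, 92L, 90L, 80L))
#' @export
classify_bp <- function(sbp, dbp) {
  sbp <- as.integer(sbp)
  dbp <- as.integer(dbp)
  if (length(sbp) != length(dbp)) stop("sbp and dbp lengths differ", call. = FALSE)
  bad <- is.na(sbp) | is.na(dbp) | sbp < 50L | sbp > 300L |
    dbp < 30L | dbp > 200L | dbp >= sbp
  if (any(bad)) {
    stop(sprintf("%d reading(s) outside the physiologic grid (SBP 50-300, DBP 30-200, DBP < SBP)",
                 sum(bad)), call. = FALSE)
  }
  cat <- ifelse(sbp >= 140L | dbp >= 90L, "suspected_ht",
                ifelse(sbp >= 120L | dbp >= 80L, "pre_ht", "normotension"))
  factor(cat, levels = bp_categories)
}

#' Assign screening status and BP subgroup to the eligible population
#'
#' For every eligible person, determines utilization `screened`
#' (U in the effective-coverage formula: at least one screening record
#' dated inside the study window) and, when screened, the *initial
#' screening* — the earliest in-window screening record, ties on the same
#' date broken by higher SBP, then higher DBP, then file order — and its
#' BP subgroup via [classify_bp()]. Follow-up BP service events never
#' count as the initial screening. Ineligible persons get no assignment.
#'
#' @param bundle A [record_bundle()].
#' @param eligibility Output of [determine_eligibility()].
#' @param config A [study_config()].
#' @return A tibble with one row per eligible person: `person_id`,
#'   `screened`, `initial_screening_date`, `initial_sbp`, `initial_dbp`,
#'   `category` (all but `person_id`/`screened` NA when unscreened).
#' @export
assign_subgroups <- function(bundle, eligibility, config = study_config()) {
  stopifnot(inherits(bundle, "record_bundle"))
  eligible_ids <- eligibility$person_id[eligibility$eligible]

  s <- bundle$screenings
  s <- s[s$person_id %in% eligible_ids &
           s$event_date >= config$study_year_start &
           s$event_date <= config$study_year_end, , drop = FALSE]
  first <- s |>
    dplyr::arrange(.data$person_id, .data$event_date,
                   dplyr::desc(.data$sbp), dplyr::desc(.data$dbp)) |>
    dplyr::distinct(.data$person_id, .keep_all = TRUE)

  out <- tibble::tibble(person_id = eligible_ids) |>
    dplyr::left_join(first, by = "person_id") |>
    dplyr::rename(initial_screening_date = "event_date",
                  initial_sbp = "sbp", initial_dbp = "dbp") |>
    dplyr::mutate(screened = !is.na(.data$initial_screening_date))
  out$category <- factor(NA_character_, levels = bp_categories)
  if (any(out$screened)) {
    out$category[out$screened] <-
      classify_bp(out$initial_sbp[out$screened], out$initial_dbp[out$screened])
  }
  out[, c("person_id", "screened", "initial_screening_date",
          "initial_sbp", "initial_dbp", "category")]
}
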