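#' Record bundle: the six-file individual-level schema
#'
#' An administrative cohort is represented as a *record bundle*: six tables
#' emulating an outpatient health-promotion claims extract. The tables are
#'
#' * `persons` — `person_id`, `birth_date`, `sex` (`"male"`/`"female"`),
#'   `province_code` (integer), `in_civil_registry` (logical);
#' * `screenings` — blood-pressure screening events: `person_id`,
#'   `event_date`, `sbp`, `dbp` (integer mmHg);
#' * `services` — post-screening service events: `person_id`, `event_date`,
#'   `service_code` (one of `ht_cvd_risk_assessment`, `lipid_panel`,
#'   `ht_treatment_start`, `follow_up_bp`) plus optional `sbp`/`dbp`
#'   (follow-up BP only) and `total_chol`/`ldl`/`hdl` in mg/dL
#'   (lipid panel only);
#' * `diagnoses` — `person_id`, `event_date`, `icd10_code`;
#' * `registry` — chronic-disease registry entries: `person_id`,
#'   `condition` (`"hypertension"`/`"other"`), `registration_date`;
#' * `followups` — follow-up BP measurements, same columns as `services`
#'   with `service_code == "follow_up_bp"`.
#'
#' Schema invariants: person ids unique; screening readings inside the
#' physiologic grid (50–300 / 30–200 mmHg, diastolic below systolic);
#' follow-up rows carry BP readings and lipid panels carry all lipid fields;
#' every event row must reference a person present in `persons` (orphan
#' events are validation errors, never silently joined).
#'
#' @param persons,screenings,services,diagnoses,registry,followups
#'   Data frames with the columns above; missing tables default to empty.
#' @return An object of class `record_bundle` (a named list of tibbles).
#' @seealso [read_bundle()], [write_bundle()], [validate_bundle()]
#' @export
record_bundle <- function(persons = NULL, screenings = NULL, services = NULL,
                          diagnoses = NULL, registry = NULL, followups = NULL) {
  b <- list(
    persons    = coerce_table(persons, "persons"),
    screenings = coerce_table(screenings, "screenings"),
    services   = coerce_table(services, "services"),
    diagnoses  = coerce_table(diagnoses, "diagnoses"),
    registry   = coerce_table(registry, "registry"),
    followups  = coerce_table(followups, "followups")
  )
  structure(b, class = "record_bundle")
}

bundle_tables <- c("persons", "screenings", "services", "diagnoses",
                   "registry", "followups")

service_codes <- c("ht_cvd_risk_assessment", "lipid_panel",
                   "ht_treatment_start", "follow_up_bp")

lipid_fields <- c("total_chol", "ldl", "hdl")

# column prototypes; services and followups share the ServiceRecord schema
table_prototype <- function(table) {
  date0 <- as.Date(character())
  switch(table,
    persons = tibble::tibble(
      person_id = character(), birth_date = date0, sex = character(),
      province_code = integer(), in_civil_registry = logical()),
    screenings = tibble::tibble(
      person_id = character(), event_date = date0,
      sbp = integer(), dbp = integer()),
    services = ,
    followups = tibble::tibble(
      person_id = character(), event_date = date0, service_code = character(),
      sbp = integer(), dbp = integer(),
      total_chol = integer(), ldl = integer(), hdl = integer()),
    diagnoses = tibble::tibble(
      person_id = character(), event_date = date0, icd10_code = character()),
    registry = tibble::tibble(
      person_id = character(), condition = character(),
      registration_date = date0),
    stop("unknown table: ", table, call. = FALSE)
  )
}

coerce_table <- function(x, table) {
  proto <- table_prototype(table)
  if (is.null(x)) return(proto)
  x <- tibble::as_tibble(x)
  missing <- setdiff(names(proto), names(x))
  if (length(missing) > 0) {
    stop(sprintf("table '%s' is missing column(s): %s",
                 table, paste(missing, collapse = ", ")), call. = FALSE)
  }
  x <- x[names(proto)]
  for (col in names(proto)) {
    if (inherits(proto[[col]], "Date")) {
      x[[col]] <- as.Date(x[[col]])
    } else if (is.integer(proto[[col]])) {
      x[[col]] <- as.integer(x[[col]])
    } else if (is.logical(proto[[col]])) {
      x[[col]] <- as.logical(x[[col]])
    } else {
      x[[col]] <- as.character(x[[col]])
    }
  }
  x
}

#' @export
print.record_bundle <- function(x, ...) {
  cat("<record_bundle>\n")
  for (tab in bundle_tables) {
    cat(sprintf("  %-10s %8d rows\n", tab, nrow(x[[tab]])))
  }
  invisible(x)
}

#' Row counts of a record bundle
#'
#' @param bundle A [record_bundle()].
#' @return Named integer vector of row counts, one per table.
#' @export
bundle_counts <- function(bundle) {
  vapply(bundle[bundle_tables], nrow, integer(1))
}

# ---- row-level invariant checks ------------------------------------------

icd10_pattern <- "^[A-Z][0-9]+(\\.[0-9]+)?$"

# returns a named list of logical vectors (TRUE = row violates that check)
row_violations <- function(bundle, table) {
  x <- bundle[[table]]
  persons <- bundle$persons
  out <- list()
  if (table == "persons") {
    out$duplicate_person_id <- duplicated(x$person_id) | is.na(x$person_id)
    out$missing_birth_date <- is.na(x$birth_date)
    out$invalid_sex <- !(x$sex %in% c("male", "female"))
    out$province_out_of_range <- is.na(x$province_code) |
      x$province_code < 1L | x$province_code > 76L
    out$missing_registry_flag <- is.na(x$in_civil_registry)
    return(out)
  }
  out$orphan_event <- !(x$person_id %in% persons$person_id)
  if (table == "screenings") {
    out$missing_date <- is.na(x$event_date)
    out$sbp_out_of_range <- is.na(x$sbp) | x$sbp < 50L | x$sbp > 300L
    out$dbp_out_of_range <- is.na(x$dbp) | x$dbp < 30L | x$dbp > 200L
    out$dbp_not_below_sbp <- !is.na(x$sbp) & !is.na(x$dbp) & x$dbp >= x$sbp
  } else if (table %in% c("services", "followups")) {
    out$missing_date <- is.na(x$event_date)
    out$invalid_service_code <- !(x$service_code %in% service_codes)
    if (table == "followups") {
      out$invalid_service_code <- out$invalid_service_code |
        (x$service_code %in% setdiff(service_codes, "follow_up_bp"))
    }
    is_fu <- x$service_code == "follow_up_bp"
    is_lp <- x$service_code == "lipid_panel"
    has_bp <- !is.na(x$sbp) | !is.na(x$dbp)
    lipids_all <- !is.na(x$total_chol) & !is.na(x$ldl) & !is.na(x$hdl)
    lipids_any <- !is.na(x$total_chol) | !is.na(x$ldl) | !is.na(x$hdl)
    out$bp_fields_mismatch <- (is_fu & (is.na(x$sbp) | is.na(x$dbp))) |
      (!is_fu & has_bp)
    out$lipid_fields_mismatch <- (is_lp & !lipids_all) | (!is_lp & lipids_any)
    out$bp_reading_out_of_range <- is_fu & !is.na(x$sbp) & !is.na(x$dbp) &
      (x$sbp < 50L | x$sbp > 300L | x$dbp < 30L | x$dbp > 200L | x$dbp >= x$sbp)
  } else if (table == "diagnoses") {
    out$missing_date <- is.na(x$event_date)
    out$invalid_icd10 <- is.na(x$icd10_code) | !grepl(icd10_pattern, x$icd10_code)
  } else if (table == "registry") {
    out$missing_date <- is.na(x$registration_date)
    out$invalid_condition <- !(x$condition %in% c("hypertension", "other"))
  }
  out
}

#' Validate a record bundle against the schema invariants
#'
#' Checks every declared invariant of the six-file schema and reports the
#' number of violating rows per (table, check). The bundle is valid iff all
#' counts are zero.
#'
#' @param bundle A [record_bundle()].
#' @return A tibble of class `bundle_validation` with columns `table`,
#'   `check`, `n_violations`.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "record_bundle"))
  rows <- lapply(bundle_tables, function(tab) {
    v <- row_violations(bundle, tab)
    tibble::tibble(
      table = tab,
      check = names(v),
      n_violations = unname(vapply(v, function(z) sum(z, na.rm = TRUE),
                                   integer(1)))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bundle_validation", class(out))
  out
}

#' @export
print.bundle_validation <- function(x, ...) {
  total <- sum(x$n_violations)
  cat(sprintf("<bundle_validation> %d violation(s)\n", total))
  bad <- x[x$n_violations > 0, ]
  if (nrow(bad) > 0) print(tibble::as_tibble(bad), n = Inf)
  invisible(x)
}

#' Is a validation report clean?
#'
#' @param report Output of [validate_bundle()].
#' @return `TRUE` iff no invariant is violated.
#' @export
is_valid_bundle <- function(report) {
  sum(report$n_violations) == 0
}

# ---- readers / writers ----------------------------------------------------

bundle_files <- c(
  persons = "persons.csv", screenings = "screenings.csv",
  services = "services.csv", diagnoses = "diagnoses.csv",
  registry = "registry.csv", followups = "followups.csv"
)

readr_spec <- function(table) {
  c <- readr::col_character; i <- readr::col_integer
  D <- readr::col_date; l <- readr::col_logical
  switch(table,
    persons = readr::cols(person_id = c(), birth_date = D(), sex = c(),
                          province_code = i(), in_civil_registry = l()),
    screenings = readr::cols(person_id = c(), event_date = D(),
                             sbp = i(), dbp = i()),
    services = ,
    followups = readr::cols(person_id = c(), event_date = D(),
                            service_code = c(), sbp = i(), dbp = i(),
                            total_chol = i(), ldl = i(), hdl = i()),
    diagnoses = readr::cols(person_id = c(), event_date = D(),
                            icd10_code = c()),
    registry = readr::cols(person_id = c(), condition = c(),
                           registration_date = D())
  )
}

#' Read a record bundle from a directory of CSV files
#'
#' Reads the six canonical files (`persons.csv`, `screenings.csv`,
#' `services.csv`, `diagnoses.csv`, `registry.csv`, `followups.csv`;
#' UTF-8, header row, ISO-8601 dates) and enforces the schema invariants.
#'
#' In `strict` mode any malformed value or invariant violation (including
#' orphan events) is fatal. In `permissive` mode violating rows are dropped
#' and counted; the drop tally is attached as attribute `"drop_report"`.
#' A missing file is always fatal.
#'
#' @param path Directory containing the six files.
#' @param strictness `"strict"` (default) or `"permissive"`.
#' @return A validated [record_bundle()].
#' @export
read_bundle <- function(path, strictness = c("strict", "permissive")) {
  strictness <- match.arg(strictness)
  missing <- bundle_files[!file.exists(file.path(path, bundle_files))]
  if (length(missing) > 0) {
    stop("missing bundle file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  raw <- list()
  drops <- list()
  for (tab in bundle_tables) {
    f <- file.path(path, bundle_files[[tab]])
    x <- readr::read_csv(f, col_types = readr_spec(tab), progress = FALSE)
    probs <- readr::problems(x)
    if (nrow(probs) > 0 && strictness == "strict") {
      stop(sprintf("malformed value(s) in %s (e.g. line %d, column %d)",
                   bundle_files[[tab]], probs$row[1], probs$col[1]),
           call. = FALSE)
    }
    # in permissive mode malformed cells become NA and the affected rows
    # are dropped by the invariant checks below
    raw[[tab]] <- x
  }
  bundle <- record_bundle(raw$persons, raw$screenings, raw$services,
                          raw$diagnoses, raw$registry, raw$followups)
  # invariant enforcement; persons first so orphan checks see the kept set
  for (tab in bundle_tables) {
    v <- row_violations(bundle, tab)
    bad <- Reduce(`|`, v)
    if (any(bad)) {
      if (strictness == "strict") {
        first <- names(v)[vapply(v, any, logical(1))][1]
        stop(sprintf("invariant violation in %s: %s (%d row(s))",
                     bundle_files[[tab]], first, sum(bad)), call. = FALSE)
      }
      per_check <- vapply(v, function(z) sum(z), integer(1))
      drops[[length(drops) + 1]] <- tibble::tibble(
        table = tab, check = names(per_check),
        n_dropped = unname(per_check))[per_check > 0, ]
      bundle[[tab]] <- bundle[[tab]][!bad, , drop = FALSE]
    }
  }
  drop_report <- if (length(drops) > 0) dplyr::bind_rows(drops) else
    tibble::tibble(table = character(), check = character(),
                   n_dropped = integer())
  attr(bundle, "drop_report") <- drop_report
  bundle
}

#' Write a record bundle to a directory of CSV files
#'
#' Writes the canonical six-file layout (see [read_bundle()]). Writing is
#' deterministic: identical bundles produce byte-identical files, and
#' `read_bundle(write_bundle(b))` restores `b` field-wise.
#'
#' @param bundle A valid [record_bundle()].
#' @param path Output directory (created if absent).
#' @return Invisibly, a named character vector of the six file paths.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "record_bundle"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", path, call. = FALSE)
  }
  paths <- character(0)
  for (tab in bundle_tables) {
    f <- file.path(path, bundle_files[[tab]])
    readr::write_csv(bundle[[tab]], f, na = "", progress = FALSE)
    paths[[tab]] <- f
  }
  invisible(paths)
}
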