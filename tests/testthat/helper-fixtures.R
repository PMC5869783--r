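# Handcrafted fixtures built in code; dates are inside the default
# calendar-2013 study window unless a test says otherwise.

d <- function(x) as.Date(x)

make_persons <- function(n, prefix = "p", birth = "1980-06-15",
                         province = 1L, registry = TRUE) {
  tibble::tibble(
    person_id = paste0(prefix, seq_len(n)),
    birth_date = d(birth),
    sex = rep(c("female", "male"), length.out = n),
    province_code = as.integer(province),
    in_civil_registry = registry)
}

screening_row <- function(id, date, sbp, dbp) {
  tibble::tibble(person_id = id, event_date = d(date),
                 sbp = as.integer(sbp), dbp = as.integer(dbp))
}

service_row <- function(id, date, code, sbp = NA, dbp = NA,
                        total_chol = NA, ldl = NA, hdl = NA) {
  tibble::tibble(person_id = id, event_date = d(date), service_code = code,
                 sbp = as.integer(sbp), dbp = as.integer(dbp),
                 total_chol = as.integer(total_chol),
                 ldl = as.integer(ldl), hdl = as.integer(hdl))
}

diagnosis_row <- function(id, date, code = "I10") {
  tibble::tibble(person_id = id, event_date = d(date), icd10_code = code)
}

registry_row <- function(id, date, condition = "hypertension") {
  tibble::tibble(person_id = id, condition = condition,
                 registration_date = d(date))
}

# one suspected-HT person with a screening on `screen_date`, plus whatever
# events the caller supplies
suspected_bundle <- function(screen = "2013-02-01", sbp = 150, dbp = 95,
                             services = NULL, diagnoses = NULL,
                             followups = NULL, screenings_extra = NULL) {
  record_bundle(
    persons = make_persons(1),
    screenings = dplyr::bind_rows(
      screening_row("p1", screen, sbp, dbp), screenings_extra),
    services = services, diagnoses = diagnoses, followups = followups)
}

assess1 <- function(bundle, ...) {
  res <- assess_cohort(bundle, ...)
  res[res$person_id == "p1", ]
}
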