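# Cascade, provincial and national aggregation of per-person results.

cascade_nodes <- c(
  "eligible", "screened", "normotension", "pre_ht", "suspected_ht",
  "pre_ht_risk_assessed", "suspected_confirmed_60d", "diagnosed",
  "treated_timely", "cvd_risk_assessed", "bp_controlled", "cvd_risk_reduced")

new_cascade_table <- function(node, numerator, denominator) {
  out <- tibble::tibble(
    node = node,
    numerator = as.numeric(numerator),
    denominator = as.numeric(denominator),
    proportion = ifelse(denominator > 0, numerator / denominator, NA_real_)
  )
  class(out) <- c("cascade_table", class(out))
  out
}

#' @export
print.cascade_table <- function(x, ...) {
  cat("<cascade_table>\n")
  pct <- ifelse(is.na(x$proportion), "   --",
                sprintf("%5.1f", 100 * x$proportion))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-24s %12s / %-12s %s%%\n", x$node[i],
                format(x$numerator[i], big.mark = ","),
                format(x$denominator[i], big.mark = ","), pct[i]))
  }
  invisible(x)
}

#' Build the care-cascade table from per-person results
#'
#' Tallies every node of the screening-and-control pathway: the eligible
#' (need) population; the screened among eligible; the three BP subgroups
#' among screened; risk assessment among pre-HT; 60-day confirmation and
#' diagnosis among suspected HT; and the four service/outcome indicators
#' among newly diagnosed. The three diagnosed-service proportions and both
#' outcome proportions all use the diagnosed count as denominator.
#'
#' An empty denominator yields an undefined proportion (`NA`), never 0.
#'
#' @param results An `ec_results` tibble from [assess_cohort()]; filter it
#'   first for a stratified cascade (by province, sex, age band, ...).
#' @return A `cascade_table` tibble: `node`, `numerator`, `denominator`,
#'   `proportion`.
#' @export
build_cascade <- function(results) {
  n_persons <- nrow(results)
  elig <- results[results$eligible, , drop = FALSE]
  n_elig <- nrow(elig)
  scr <- elig[elig$screened, , drop = FALSE]
  n_scr <- nrow(scr)
  n_cat <- table(scr$category)
  pre <- scr[scr$category == "pre_ht", , drop = FALSE]
  susp <- scr[scr$category == "suspected_ht", , drop = FALSE]
  n_dx <- sum(susp$diagnosed_ht)
  num <- c(
    n_elig, n_scr,
    n_cat[["normotension"]], n_cat[["pre_ht"]], n_cat[["suspected_ht"]],
    sum(pre$criterion_met),
    sum(susp$criterion_met),
    n_dx,
    sum(susp$treated_timely), sum(susp$cvd_risk_assessed),
    sum(susp$bp_controlled), sum(susp$cvd_risk_reduced))
  den <- c(
    n_persons, n_elig,
    n_scr, n_scr, n_scr,
    nrow(pre), nrow(susp), nrow(susp),
    n_dx, n_dx, n_dx, n_dx)
  new_cascade_table(cascade_nodes, num, den)
}

#' Provincial coverage, effectiveness and effective-coverage summaries
#'
#' For each province: crude coverage (mean U over the eligible
#' population), effectiveness (mean Q among the screened) and effective
#' coverage (mean Q*U over the eligible). Under binary scoring these
#' satisfy `ec = coverage * effectiveness` and `ec <= coverage`.
#'
#' Provinces with no eligible persons are omitted with a warning.
#'
#' @param results An `ec_results` tibble from [assess_cohort()].
#' @param include_cascade Attach a per-province `cascade_table` list-column?
#' @return A tibble, one row per province: `province_code`, `n_persons`,
#'   `n_eligible`, `n_screened`, `coverage`, `effectiveness`, `ec`.
#' @export
summarize_provinces <- function(results, include_cascade = FALSE) {
  empty <- results |>
    dplyr::group_by(.data$province_code) |>
    dplyr::summarise(n_eligible = sum(.data$eligible), .groups = "drop")
  dead <- empty$province_code[empty$n_eligible == 0]
  if (length(dead) > 0) {
    warning("omitting ", length(dead),
            " province(s) with no eligible persons: ",
            paste(utils::head(dead, 5), collapse = ", "), call. = FALSE)
  }
  out <- results |>
    dplyr::filter(!(.data$province_code %in% dead)) |>
    dplyr::group_by(.data$province_code) |>
    dplyr::summarise(
      n_persons = dplyr::n(),
      n_eligible = sum(.data$eligible),
      n_screened = sum(.data$eligible & .data$screened),
      coverage = .data$n_screened / .data$n_eligible,
      effectiveness = ifelse(.data$n_screened > 0,
                             mean(.data$q[.data$eligible & .data$screened]),
                             NA_real_),
      ec = mean(.data$ec[.data$eligible]),
      .groups = "drop") |>
    dplyr::arrange(.data$province_code)
  if (include_cascade) {
    out$cascade <- lapply(out$province_code, function(p) {
      build_cascade(results[results$province_code == p, , drop = FALSE])
    })
  }
  out
}

#' National summary: pooled cascade, provincial spread, gap and correlation
#'
#' Aggregates provincial summaries and per-person results into the national
#' view: the pooled cascade over all persons; the unweighted provincial
#' mean, minimum and maximum of effective coverage (the population-weighted
#' pooled EC is reported alongside); mean provincial crude coverage;
#' statistics of the per-province gap `coverage - ec`; and the Pearson
#' correlation between provincial coverage and EC with a two-sided p-value
#' (t approximation, via [stats::cor.test()]).
#'
#' With fewer than 3 provinces, or zero variance on either axis, the
#' correlation is reported as undefined (`NA`), not as 1.
#'
#' @param provinces Output of [summarize_provinces()].
#' @param results The matching `ec_results` tibble (for the pooled cascade
#'   and population-weighted EC); optional.
#' @return A list of class `national_summary`.
#' @export
national_summary <- function(provinces, results = NULL) {
  if (nrow(provinces) == 0) {
    warning("no provinces with eligible persons; national summary is undefined",
            call. = FALSE)
    out <- list(
      cascade = if (!is.null(results)) build_cascade(results) else NULL,
      pooled_ec = NA_real_, provincial_mean_ec = NA_real_,
      provincial_min_ec = NA_real_, provincial_max_ec = NA_real_,
      provincial_mean_coverage = NA_real_,
      gap_stats = list(min = NA_real_, max = NA_real_, mean = NA_real_),
      correlation = list(pearson_r = NA_real_, p_value = NA_real_, n = 0L))
    class(out) <- "national_summary"
    return(out)
  }
  ec <- provinces$ec
  gap <- provinces$coverage - ec
  if (nrow(provinces) >= 3 &&
      stats::sd(provinces$coverage) > 0 && stats::sd(ec) > 0) {
    ct <- stats::cor.test(provinces$coverage, ec, method = "pearson")
    correlation <- list(pearson_r = unname(ct$estimate),
                        p_value = ct$p.value, n = nrow(provinces))
  } else {
    correlation <- list(pearson_r = NA_real_, p_value = NA_real_,
                        n = nrow(provinces))
  }
  out <- list(
    cascade = if (!is.null(results)) build_cascade(results) else NULL,
    pooled_ec = if (!is.null(results))
      mean(results$ec[results$eligible]) else NA_real_,
    provincial_mean_ec = mean(ec),
    provincial_min_ec = min(ec),
    provincial_max_ec = max(ec),
    provincial_mean_coverage = mean(provinces$coverage),
    gap_stats = list(min = min(gap), max = max(gap), mean = mean(gap)),
    correlation = correlation
  )
  class(out) <- "national_summary"
  out
}

#' @export
print.national_summary <- function(x, ...) {
  cat("<national_summary>\n")
  pc <- function(v) ifelse(is.na(v), "--", sprintf("%.1f%%", 100 * v))
  cat(sprintf("  provincial mean EC: %s (range %s - %s)\n",
              pc(x$provincial_mean_ec), pc(x$provincial_min_ec),
              pc(x$provincial_max_ec)))
  cat(sprintf("  provincial mean coverage: %s\n",
              pc(x$provincial_mean_coverage)))
  cat(sprintf("  pooled EC: %s\n", pc(x$pooled_ec)))
  cat(sprintf("  coverage-EC gap: mean %s (range %s - %s)\n",
              pc(x$gap_stats$mean), pc(x$gap_stats$min), pc(x$gap_stats$max)))
  if (!is.na(x$correlation$pearson_r)) {
    cat(sprintf("  coverage~EC Pearson r = %.3f (p = %.3g, n = %d)\n",
                x$correlation$pearson_r, x$correlation$p_value,
                x$correlation$n))
  } else {
    cat("  coverage~EC correlation: undefined\n")
  }
  if (!is.null(x$cascade)) print(x$cascade)
  invisible(x)
}
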