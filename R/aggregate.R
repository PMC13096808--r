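# Tabular analyses of pegRNA efficiency screens: conflicting-duplicate
# exclusion, PBS-length group summaries, fold-change normalization to
# no-modification controls, and a plain Welch two-sample comparison. The
# wider significance battery (ANOVA, Kruskal-Wallis, Dunnett, Box-Cox)
# used around such screens is deliberately not re-implemented here; those
# are routine calls to standard statistics facilities.

#' Remove pegRNAs with conflicting efficiency records
#'
#' A pegRNA id reported with two or more DIFFERENT efficiency values
#' outside the replicate structure is unreliable and removed entirely;
#' exact duplicate rows collapse to one. When a `replicate` column is
#' present, distinct values in distinct replicates are legitimate and only
#' within-replicate conflicts are removed.
#'
#' @param table Tibble with at least `pegrna_id` and `efficiency`
#'   (optionally `replicate`).
#' @return The filtered tibble; excluded ids are in
#'   `attr(, "excluded")` (a tibble `pegrna_id`, `n_values`).
#' @export
dedupe_conflicting <- function(table) {
  table <- as_tibble(table)
  if (!all(c("pegrna_id", "efficiency") %in% names(table))) {
    abort("table needs `pegrna_id` and `efficiency` columns")
  }
  if (!nrow(table)) abort("table is empty")
  table <- distinct(table)
  keys <- if ("replicate" %in% names(table)) {
    c("pegrna_id", "replicate")
  } else "pegrna_id"
  conflicts <- table |>
    group_by(across(all_of(keys))) |>
    summarise(n_values = dplyr::n_distinct(.data$efficiency),
              .groups = "drop") |>
    filter(.data$n_values > 1L)
  bad <- unique(conflicts$pegrna_id)
  out <- filter(table, !.data$pegrna_id %in% bad)
  attr(out, "excluded") <- if (nrow(conflicts)) {
    conflicts |>
      group_by(.data$pegrna_id) |>
      summarise(n_values = max(.data$n_values), .groups = "drop")
  } else {
    tibble(pegrna_id = character(), n_values = integer())
  }
  if (length(bad)) {
    inform(sprintf("excluded %d pegRNA id(s) with conflicting values: %s",
                   length(bad), paste(bad, collapse = ", ")))
  }
  out
}

#' Mean efficiency by PBS length
#'
#' Per-group (default: construct type and editor) and per-PBS-length
#' summary: n, mean, SD. Rows with a single observation get SD 0 and an
#' `n1` flag rather than NA. With `ngg_only = TRUE` rows whose `pam` does
#' not match NGG are dropped first.
#'
#' @param table Deduped efficiency tibble with `pbs_length`,
#'   `efficiency` and the grouping columns.
#' @param group_keys Extra grouping columns present in `table`.
#'   Default `c("construct_type", "editor")` (missing ones are ignored).
#' @param ngg_only Pre-filter to NGG PAM rows (needs a `pam` column).
#' @return Summary tibble, one row per (group, PBS length).
#' @export
mean_by_pbs_length <- function(table,
                               group_keys = c("construct_type", "editor"),
                               ngg_only = FALSE) {
  table <- as_tibble(table)
  if (!all(c("pbs_length", "efficiency") %in% names(table))) {
    abort("table needs `pbs_length` and `efficiency` columns")
  }
  if (ngg_only) {
    if (!"pam" %in% names(table)) abort("ngg_only needs a `pam` column")
    table <- filter(table, grepl("^.GG$", .data$pam))
  }
  keys <- intersect(group_keys, names(table))
  table |>
    group_by(across(all_of(c(keys, "pbs_length")))) |>
    summarise(n = dplyr::n(),
              mean_efficiency = mean(.data$efficiency),
              sd_efficiency = ifelse(dplyr::n() > 1L,
                                     sd(.data$efficiency), 0),
              n1 = dplyr::n() == 1L,
              .groups = "drop") |>
    arrange(across(all_of(c(keys, "pbs_length"))))
}

#' Fold change versus a control group
#'
#' Ratio of replicate means (not the mean of per-replicate ratios),
#' matching how screen heatmaps are normalized to their no-modification
#' control. A control mean below `control_floor` raises the near-zero
#' flag, since fold changes over tiny denominators are unstable.
#'
#' @param values Numeric efficiencies of the modified construct.
#' @param control_values Numeric efficiencies of the control.
#' @param control_floor Flag threshold for the control mean. Default 0.5.
#' @return One-row tibble: `fold`, `mean_value`, `mean_control`,
#'   `low_control`.
#' @export
fold_change_vs_control <- function(values, control_values,
                                   control_floor = 0.5) {
  if (!length(values) || !length(control_values)) {
    abort("both groups need at least one value")
  }
  mc <- mean(control_values)
  if (mc <= 0) abort("control mean must be positive")
  tibble(fold = mean(values) / mc,
         mean_value = mean(values), mean_control = mc,
         low_control = mc < control_floor)
}

#' Welch two-sample comparison
#'
#' Unpaired two-tailed Welch t-test (unequal variances), the simplest of
#' the test family used for pairwise screen comparisons.
#'
#' @param a,b Numeric vectors, n >= 2 each.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_a`,
#'   `mean_b`.
#' @export
two_sample_compare <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    abort("each group needs at least 2 observations")
  }
  tt <- t.test(a, b, var.equal = FALSE)
  tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b))
}
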