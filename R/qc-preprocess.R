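# Data trimming, exclusions, outlier flagging and normality checks applied to
# a long-format phenotype table before the robustness analysis.

#' Per-phenotype trimming bounds
#'
#' @param phenotype Phenotype names.
#' @param lower,upper Numeric bounds in the phenotype's units (`NA` = no
#'   bound). Bounds are inclusive: a value equal to a bound is retained.
#' @return A `trim_bounds` tibble.
#' @export
trim_bounds <- function(phenotype, lower = NA_real_, upper = NA_real_) {
  bad <- setdiff(phenotype, .PHENOTYPES)
  if (length(bad) > 0) {
    abort(paste0("unknown phenotype(s) in bounds: ", paste(bad, collapse = ", ")))
  }
  out <- tibble::tibble(
    phenotype = phenotype,
    lower = rep_len(as.numeric(lower), length(phenotype)),
    upper = rep_len(as.numeric(upper), length(phenotype))
  )
  both <- !is.na(out$lower) & !is.na(out$upper)
  if (any(out$lower[both] > out$upper[both])) {
    abort("lower bound exceeds upper bound")
  }
  class(out) <- c("trim_bounds", class(out))
  out
}

#' Default theory-based trimming bounds
#'
#' Yields are capped at 0.61 g/g — the maximum theoretical ethanol yield on
#' glucose (0.51 g/g) plus a 0.1 g/g experimental-error allowance — and cell
#' dry weight at 39.6 g/L, the maximum biomass concentration attainable from
#' the strongest medium. Growth rate and lag have no upper bound. All
#' phenotypes have lower bound 0 (negative rates and yields are physically
#' meaningless). Bounds are inclusive.
#'
#' @return A `trim_bounds` tibble covering the five phenotypes.
#' @export
#' @examples
#' default_trim_bounds()
default_trim_bounds <- function() {
  trim_bounds(
    phenotype = .PHENOTYPES,
    lower = 0,
    upper = c(NA, NA, 39.6, 0.61, 0.61)
  )
}

#' Trim a phenotype table against theoretical bounds
#'
#' Individual values outside their phenotype's (inclusive) bounds are removed;
#' other phenotypes of the same well are untouched — trimming is value-level,
#' not well-level. The returned report counts removals per phenotype and
#' bound.
#'
#' @param table A phenotype table.
#' @param bounds A [trim_bounds()] table (default [default_trim_bounds()]).
#' @return List with `table` (the trimmed table) and `report` (a `qc_report`).
#' @export
trim_values <- function(table, bounds = default_trim_bounds()) {
  assert_phenotype_table(table)
  if (!inherits(bounds, "trim_bounds")) {
    bounds <- trim_bounds(bounds$phenotype, bounds$lower, bounds$upper)
  }
  n_input <- nrow(table)
  idx <- match(table$phenotype, bounds$phenotype)
  lo <- bounds$lower[idx]
  hi <- bounds$upper[idx]
  below <- !is.na(table$value) & !is.na(lo) & table$value < lo
  above <- !is.na(table$value) & !is.na(hi) & table$value > hi
  drop <- below | above

  rule_counts <- function(which, suffix) {
    if (!any(which)) return(NULL)
    table(paste0(table$phenotype[which], suffix))
  }
  by_rule <- c(rule_counts(below, "_below_lower"),
               rule_counts(above, "_above_upper"))
  report <- structure(
    list(
      n_input = n_input,
      n_trimmed = sum(drop),
      n_retained = n_input - sum(drop),
      by_rule = as.list(by_rule),
      normality = NULL
    ),
    class = "qc_report"
  )
  list(table = table[!drop, , drop = FALSE], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat("  input:    ", x$n_input, "values\n")
  cat("  trimmed:  ", x$n_trimmed, "\n")
  cat("  retained: ", x$n_retained, "\n")
  if (length(x$by_rule) > 0) {
    for (r in names(x$by_rule)) cat("   -", r, ":", x$by_rule[[r]], "\n")
  }
  if (!is.null(x$n_outliers_flagged)) {
    cat("  outliers flagged (not removed):", x$n_outliers_flagged, "\n")
  }
  if (!is.null(x$normality)) {
    cat("  Shapiro-Wilk p-values:\n")
    for (i in seq_len(nrow(x$normality))) {
      cat("   -", x$normality$phenotype[i], ":",
          format(x$normality$p_value[i], digits = 3), "\n")
    }
  }
  invisible(x)
}

#' Exclude ethanol yields measured under ethanol perturbation
#'
#' When ethanol is itself the perturbing compound, its consumption and
#' production during cultivation cannot be separated, so every
#' `ethanol_yield` record from the `ethanol` group is removed. No other
#' record is touched.
#'
#' @param table A phenotype table.
#' @return The filtered table.
#' @export
exclude_ethanol_yield_under_ethanol <- function(table) {
  assert_phenotype_table(table)
  drop <- table$phenotype == "ethanol_yield" & !is.na(table$group) &
    table$group == "ethanol"
  table[!drop, , drop = FALSE]
}

#' Flag extreme values by the quantile method
#'
#' Per phenotype (pooling all strains, conditions and replicates), values
#' strictly below the `q_low` quantile or strictly above the `q_high` quantile
#' are flagged `outlier` in `qc_flags`. Quantiles use linear interpolation
#' between order statistics. Flagged values are NOT removed; they stay in the
#' downstream robustness input.
#'
#' @param table A (trimmed) phenotype table.
#' @param q_low,q_high Flagging quantiles, defaults 0.001 and 0.999.
#' @return The table with updated `qc_flags`.
#' @export
flag_outliers <- function(table, q_low = 0.001, q_high = 0.999) {
  assert_phenotype_table(table, need_flags = TRUE)
  if (q_low >= q_high) abort("`q_low` must be smaller than `q_high`")
  flagged <- rep(FALSE, nrow(table))
  for (p in unique(table$phenotype)) {
    i <- which(table$phenotype == p & !is.na(table$value))
    if (length(i) < 2) next
    qs <- stats::quantile(table$value[i], probs = c(q_low, q_high),
                          names = FALSE, type = 7)
    flagged[i] <- table$value[i] < qs[1] | table$value[i] > qs[2]
  }
  table$qc_flags <- add_flag(table$qc_flags, "outlier", flagged)
  table
}

#' Shapiro-Wilk normality check per phenotype
#'
#' Advisory only: the result is recorded, no value is filtered. Phenotypes
#' with fewer than 3 non-missing values are skipped with a warning. For more
#' than 5000 values (the test's upper limit) an evenly spaced subsample of the
#' order statistics is tested, which preserves the shape of the distribution
#' and keeps the check deterministic.
#'
#' @param table A phenotype table.
#' @return Tibble with `phenotype`, `n`, `statistic`, `p_value`.
#' @export
normality_check <- function(table) {
  assert_phenotype_table(table)
  rows <- lapply(unique(table$phenotype), function(p) {
    v <- table$value[table$phenotype == p & !is.na(table$value)]
    n <- length(v)
    if (n < 3) {
      warn(paste0("phenotype ", p, " has fewer than 3 values; normality check skipped"))
      return(NULL)
    }
    if (n > 5000) {
      v <- sort(v)[round(seq(1, n, length.out = 5000))]
    }
    if (length(unique(v)) == 1) {
      warn(paste0("phenotype ", p, " is constant; normality check skipped"))
      return(NULL)
    }
    sw <- stats::shapiro.test(v)
    tibble::tibble(phenotype = p, n = n,
                   statistic = unname(sw$statistic),
                   p_value = sw$p.value)
  })
  dplyr::bind_rows(rows)
}

#' Run the full QC stage
#'
#' Applies, in order: bound trimming, the ethanol-under-ethanol yield
#' exclusion, quantile outlier flagging (flag only) and the Shapiro normality
#' check. Trimming and the exclusion touch disjoint criteria, so their order
#' does not affect the result.
#'
#' @param table A raw phenotype table.
#' @param bounds Trimming bounds.
#' @param q_low,q_high Outlier-flagging quantiles.
#' @return List with `table` (clean, flagged) and `report` (`qc_report` with
#'   per-rule counts and normality results).
#' @export
qc_phenotype_table <- function(table, bounds = default_trim_bounds(),
                               q_low = 0.001, q_high = 0.999) {
  assert_phenotype_table(table, need_flags = TRUE)
  n_input <- nrow(table)
  trimmed <- trim_values(table, bounds)
  excluded <- exclude_ethanol_yield_under_ethanol(trimmed$table)
  n_excluded <- nrow(trimmed$table) - nrow(excluded)
  flagged <- flag_outliers(excluded, q_low = q_low, q_high = q_high)
  normality <- normality_check(flagged)

  report <- trimmed$report
  report$n_input <- n_input
  report$by_rule$ethanol_yield_under_ethanol <- n_excluded
  report$n_excluded <- n_excluded
  report$n_retained <- nrow(flagged)
  report$n_outliers_flagged <- sum(grepl("(^|,)outlier(,|$)", flagged$qc_flags))
  report$normality <- normality
  list(table = flagged, report = report)
}
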