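# Rank-correlation analyses linking performance and robustness, their
# sample-size-based standard errors, and group-vs-reference performance tests.

#' Spearman rank correlation with two-sided p-value
#'
#' Average ranks are used for ties; the p-value is the two-sided
#' t-approximation (ties make the exact null distribution unavailable).
#'
#' @param x,y Numeric vectors of equal length (>= 4 complete pairs), each with
#'   at least 2 distinct values.
#' @return List with `r`, `p` and `n` (complete pairs used).
#' @export
#' @examples
#' spearman(1:5, c(3, 1, 2, 5, 4))$r  # 0.6
spearman <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) abort("at least 4 complete pairs are required")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("correlation undefined for a constant vector")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Sample-size-based standard error of a rank correlation
#'
#' `se = (1 - r^2) / sqrt(n - 1)`. The error shrinks with larger samples and
#' stronger correlations; at `|r| = 0.7` and `n = 24` strains it is about 0.1.
#'
#' @param r Correlation coefficient in \[-1, 1\].
#' @param n Sample size (>= 2).
#' @return The standard error (>= 0).
#' @export
#' @examples
#' correlation_se(-0.7, 24)
correlation_se <- function(r, n) {
  if (any(abs(r) > 1)) abort("`r` must lie in [-1, 1]")
  if (any(n < 2)) abort("`n` must be at least 2")
  (1 - r^2) / sqrt(n - 1)
}

# internal: spearman that returns a reason instead of erroring
safe_spearman <- function(x, y) {
  tryCatch({
    s <- spearman(x, y)
    list(r = s$r, p = s$p, n = s$n, reason = NA_character_)
  }, error = function(e) {
    list(r = NA_real_, p = NA_real_, n = sum(!is.na(x) & !is.na(y)),
         reason = conditionMessage(e))
  })
}

#' Per-strain mean performance
#'
#' Performance of a strain for a phenotype is the mean of its retained values
#' over all conditions and replicates.
#'
#' @param table A QC'd phenotype table.
#' @return Tibble `strain, phenotype, performance, n_values`.
#' @export
strain_performance <- function(table) {
  assert_phenotype_table(table)
  table %>%
    dplyr::filter(!is.na(.data$value)) %>%
    dplyr::group_by(.data$strain, .data$phenotype) %>%
    dplyr::summarise(performance = mean(.data$value),
                     n_values = dplyr::n(), .groups = "drop")
}

#' Performance-robustness trade-off correlations
#'
#' For every (performance phenotype, robustness phenotype) pair, the Spearman
#' correlation across strains between per-strain mean performance and
#' per-strain robustness, with two-sided p-value and the sample-size-based
#' standard error. The diagonal (`same_phenotype = TRUE`) carries the headline
#' trade-offs; the full matrix shows cross-phenotype structure. Pairs with
#' fewer than 4 strains or a constant vector are reported with a reason.
#'
#' @param table A QC'd phenotype table.
#' @param rvals A robustness table from [robustness_table()].
#' @return Tibble `performance_phenotype, robustness_phenotype,
#'   same_phenotype, spearman_r, p_value, se, n, reason`.
#' @export
performance_robustness_tradeoffs <- function(table, rvals) {
  perf <- strain_performance(table)
  rv <- rvals %>% dplyr::filter(!is.na(.data$R))
  phenos_p <- unique(perf$phenotype)
  phenos_r <- unique(rv$phenotype)

  rows <- list()
  for (pp in phenos_p) {
    for (pr in phenos_r) {
      d <- dplyr::inner_join(
        perf[perf$phenotype == pp, c("strain", "performance")],
        rv[rv$phenotype == pr, c("strain", "R")],
        by = "strain"
      )
      s <- safe_spearman(d$performance, d$R)
      rows[[paste(pp, pr)]] <- tibble::tibble(
        performance_phenotype = pp, robustness_phenotype = pr,
        same_phenotype = pp == pr,
        spearman_r = s$r, p_value = s$p,
        se = ifelse(is.na(s$r), NA_real_, correlation_se(s$r, s$n)),
        n = s$n, reason = s$reason
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Record-level correlations between phenotype pairs
#'
#' Pairwise Spearman correlations between phenotypes at the level of single
#' wells (strain x condition x replicate), reported over the whole table
#' (`group = "all"`) and stratified by perturbation group.
#'
#' @param table A QC'd phenotype table.
#' @param by_group Add one entry per group per pair (default `TRUE`).
#' @return Tibble `phenotype_x, phenotype_y, group, spearman_r, p_value, n,
#'   reason`.
#' @export
cross_phenotype_correlations <- function(table, by_group = TRUE) {
  assert_phenotype_table(table)
  wide <- table %>%
    dplyr::select("strain", "condition", "group", "replicate", "phenotype",
                  "value") %>%
    tidyr::pivot_wider(names_from = "phenotype", values_from = "value")
  phenos <- intersect(.PHENOTYPES, names(wide))
  strata <- list(all = wide)
  if (by_group) {
    for (g in unique(stats::na.omit(wide$group))) {
      strata[[g]] <- wide[!is.na(wide$group) & wide$group == g, ]
    }
  }
  rows <- list()
  pairs <- utils::combn(phenos, 2, simplify = FALSE)
  for (s_name in names(strata)) {
    d <- strata[[s_name]]
    for (pair in pairs) {
      s <- safe_spearman(d[[pair[1]]], d[[pair[2]]])
      rows[[paste(s_name, pair[1], pair[2])]] <- tibble::tibble(
        phenotype_x = pair[1], phenotype_y = pair[2], group = s_name,
        spearman_r = s$r, p_value = s$p, n = s$n, reason = s$reason
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Compare a perturbation group with a reference group
#'
#' Two-sample, two-sided Wilcoxon rank-sum (Mann-Whitney) test of a
#' phenotype's pooled record-level values in `group` against those in the
#' reference group (hexoses by default — the benign sugar conditions).
#'
#' @param table A QC'd phenotype table.
#' @param phenotype Phenotype to compare.
#' @param group Group to test.
#' @param reference Reference group (default `"hexoses"`).
#' @param alpha Significance level for the label (default 0.05).
#' @return Tibble `phenotype, group, reference, statistic, p_value, n_group,
#'   n_reference, significant`.
#' @export
group_vs_reference_test <- function(table, phenotype, group,
                                    reference = "hexoses", alpha = 0.05) {
  assert_phenotype_table(table)
  x <- table$value[table$phenotype == phenotype & table$group == group &
                     !is.na(table$value)]
  y <- table$value[table$phenotype == phenotype & table$group == reference &
                     !is.na(table$value)]
  if (length(x) == 0 || length(y) == 0) {
    abort(paste0("empty group for phenotype ", phenotype, ": ",
                 if (length(x) == 0) group else reference))
  }
  if (length(x) < 3 || length(y) < 3) {
    abort("both groups need at least 3 values")
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  tibble::tibble(
    phenotype = phenotype, group = group, reference = reference,
    statistic = unname(wt$statistic), p_value = wt$p.value,
    n_group = length(x), n_reference = length(y),
    significant = wt$p.value < alpha
  )
}

#' Scatter plot of a performance-robustness trade-off
#'
#' Visualization only (a regression line indicates direction, not inference).
#' Requires ggplot2.
#'
#' @param table A QC'd phenotype table.
#' @param rvals A robustness table.
#' @param phenotype Phenotype to plot.
#' @return A ggplot object.
#' @export
plot_tradeoff <- function(table, rvals, phenotype) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("ggplot2 is required for plotting")
  }
  d <- dplyr::inner_join(
    strain_performance(table) %>% dplyr::filter(.data$phenotype == !!phenotype),
    rvals %>% dplyr::filter(.data$phenotype == !!phenotype),
    by = c("strain", "phenotype")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$performance, y = .data$R)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::labs(
      x = paste0("mean performance (", .PHENOTYPE_UNITS[[phenotype]], ")"),
      y = "robustness", title = phenotype
    ) +
    ggplot2::theme_minimal()
}
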