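# Culture-transfer analysis: improvement of the maximum specific growth rate
# between a first and a second cultivation in the same medium.
#
#   %P = (mu_max2 - mu_max1) / mu_max1 * 100
#
# When mu_max1 = 0 and mu_max2 > 0 the ratio is infinite; such records carry
# an infinite sentinel that is later replaced by the maximum finite %P of the
# dataset. When both rates are 0 the record carries no improvement
# information and is missing.

#' Percentage improvement of the maximum specific growth rate
#'
#' Vectorized. Returns `Inf` as the sentinel for growth appearing only in the
#' second cultivation (resolve at table level with [resolve_infinities()]) and
#' `NA` when both rates are zero. %P is invariant to rescaling both rates by
#' the same positive constant and is never below -100.
#'
#' @param mu1,mu2 First- and second-cultivation maximum specific growth rates
#'   (1/h, >= 0).
#' @return Numeric vector of percentages (may contain `Inf` and `NA`).
#' @export
#' @examples
#' percent_improvement(0.2, 0.3)  # 50
percent_improvement <- function(mu1, mu2) {
  if (any(mu1 < 0, na.rm = TRUE) || any(mu2 < 0, na.rm = TRUE)) {
    abort("growth rates must be non-negative")
  }
  out <- (mu2 - mu1) / mu1 * 100
  out[mu1 == 0 & mu2 > 0] <- Inf
  out[mu1 == 0 & mu2 == 0] <- NA_real_
  out
}

#' Build transfer records from two cultivations
#'
#' Joins the first- and second-cultivation `mu_max` values on (strain,
#' condition, replicate) and computes %P per record. Inputs may be full
#' phenotype tables (they are filtered to `mu_max`) or any tibble with a
#' `mu_max` column.
#'
#' @param first,second Phenotype tables (or tibbles with `strain, condition,
#'   group, replicate, mu_max`) for the two cultivations.
#' @return Tibble `strain, condition, group, replicate, mu_max_1, mu_max_2,
#'   percent_improvement, substituted, qc_flags`.
#' @export
transfer_records <- function(first, second) {
  pick <- function(x, suffix) {
    if ("phenotype" %in% names(x)) {
      x <- x[x$phenotype == "mu_max", ]
      x <- dplyr::rename(x, mu_max = "value")
    }
    need <- c("strain", "condition", "replicate", "mu_max")
    missing <- setdiff(need, names(x))
    if (length(missing) > 0) {
      abort(paste0("cultivation table is missing column(s): ",
                   paste(missing, collapse = ", ")))
    }
    if (!"group" %in% names(x)) x$group <- NA_character_
    x[, c("strain", "condition", "group", "replicate", "mu_max")]
  }
  f <- pick(first); s <- pick(second)
  d <- dplyr::inner_join(f, s, by = c("strain", "condition", "group",
                                      "replicate"),
                         suffix = c("_1", "_2"))
  d$percent_improvement <- percent_improvement(d$mu_max_1, d$mu_max_2)
  d$substituted <- FALSE
  d$qc_flags <- ifelse(
    !is.na(d$mu_max_1) & !is.na(d$mu_max_2) &
      d$mu_max_1 == 0 & d$mu_max_2 == 0,
    "no_growth_both", ""
  )
  d
}

#' Replace infinite improvement sentinels
#'
#' Every infinite %P (growth only in the second cultivation) is set to the
#' maximum finite %P of the whole dataset, with `substituted = TRUE`. Finite
#' values are never changed, and no substituted value can exceed the
#' pre-existing finite maximum. If every %P is infinite there is no finite
#' maximum and the operation fails.
#'
#' @param records Tibble from [transfer_records()].
#' @return The records with sentinels resolved.
#' @export
resolve_infinities <- function(records) {
  p <- records$percent_improvement
  inf <- is.infinite(p)
  if (!any(inf)) return(records)
  finite <- p[is.finite(p)]
  if (length(finite) == 0) {
    abort("all improvement values are infinite; no finite maximum exists")
  }
  records$percent_improvement[inf] <- max(finite)
  records$substituted <- records$substituted | inf
  records
}

#' Summarize the culture-transfer improvement
#'
#' Per strain: mean %P across all perturbations, with the SD computed over
#' the replicate means (the triplicate spread). Per group: the Spearman
#' correlation between first- and second-cultivation rates over the pooled
#' records. Also counts how many strains exceed each improvement threshold.
#' Thin strata are skipped with a reason. Call [resolve_infinities()] first;
#' remaining infinite sentinels are an error.
#'
#' @param records Resolved transfer records.
#' @param thresholds Improvement thresholds in percent (default 20 and 50).
#' @return List of tibbles: `strains` (`strain, mean_improvement, sd_replicates,
#'   n_records`), `groups` (`group, spearman_r, p_value, n, reason`),
#'   `thresholds` (`threshold, n_strains`).
#' @export
transfer_summary <- function(records, thresholds = c(20, 50)) {
  if (any(is.infinite(records$percent_improvement))) {
    abort("records contain unresolved infinite sentinels; run resolve_infinities() first")
  }
  strains <- records %>%
    dplyr::filter(!is.na(.data$percent_improvement)) %>%
    dplyr::group_by(.data$strain) %>%
    dplyr::summarise(
      mean_improvement = mean(.data$percent_improvement),
      sd_replicates = stats::sd(
        tapply(.data$percent_improvement, .data$replicate, mean)
      ),
      n_records = dplyr::n(),
      .groups = "drop"
    )

  groups <- records %>%
    dplyr::filter(!is.na(.data$group)) %>%
    dplyr::group_by(.data$group) %>%
    dplyr::group_modify(function(d, key) {
      s <- safe_spearman(d$mu_max_1, d$mu_max_2)
      tibble::tibble(spearman_r = s$r, p_value = s$p, n = s$n,
                     reason = s$reason)
    }) %>%
    dplyr::ungroup()

  thr <- tibble::tibble(
    threshold = thresholds,
    n_strains = vapply(
      thresholds,
      function(t) sum(strains$mean_improvement >= t, na.rm = TRUE),
      integer(1)
    )
  )
  list(strains = strains, groups = groups, thresholds = thr)
}

#' Correlation between transfer improvement and robustness
#'
#' Spearman correlation, per phenotype, between each strain's mean %P and its
#' robustness. Reported whether or not significant; phenotypes with fewer
#' than 4 strains are skipped with a reason.
#'
#' @param records Resolved transfer records.
#' @param rvals A robustness table from [robustness_table()].
#' @return Tibble `phenotype, spearman_r, p_value, se, n, reason`.
#' @export
improvement_robustness_correlation <- function(records, rvals) {
  if (any(is.infinite(records$percent_improvement))) {
    abort("records contain unresolved infinite sentinels; run resolve_infinities() first")
  }
  per_strain <- records %>%
    dplyr::filter(!is.na(.data$percent_improvement)) %>%
    dplyr::group_by(.data$strain) %>%
    dplyr::summarise(mean_improvement = mean(.data$percent_improvement),
                     .groups = "drop")
  rv <- rvals %>% dplyr::filter(!is.na(.data$R))
  rows <- lapply(unique(rv$phenotype), function(p) {
    d <- dplyr::inner_join(per_strain,
                           rv[rv$phenotype == p, c("strain", "R")],
                           by = "strain")
    s <- safe_spearman(d$mean_improvement, d$R)
    tibble::tibble(
      phenotype = p, spearman_r = s$r, p_value = s$p,
      se = ifelse(is.na(s$r), NA_real_, correlation_se(s$r, s$n)),
      n = s$n, reason = s$reason
    )
  })
  dplyr::bind_rows(rows)
}
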