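# The robustness statistic and its per-strain / per-group summaries.
#
# Robustness of a strain S for phenotype i over a perturbation set P is the
# negative Fano factor of the phenotype across perturbations, normalized by
# the grand mean m of the phenotype over all strains:
#
#   R_{S,i,P} = -(sigma^2 / xbar) * (1 / m)
#
# sigma^2 is the sample variance (denominator n - 1) across conditions, xbar
# the mean across conditions. R is always <= 0; 0 means perfectly consistent
# behaviour; more negative means less robust. R is invariant to rescaling the
# phenotype's unit, because sigma^2 scales with c^2 and xbar * m with c^2.

#' Robustness of one condition series
#'
#' @param values Phenotype values of one strain and replicate across the
#'   perturbation set (missing values are dropped; at least 2 must remain).
#' @param m Grand mean of the phenotype across all strains (> 0); see
#'   [normalization_constants()].
#' @return The robustness statistic (dimensionless, <= 0); exactly 0 when the
#'   series is constant.
#' @export
#' @examples
#' robustness(c(1, 2, 3), m = 2)  # -0.25
robustness <- function(values, m) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    abort("at least 2 non-missing values are required")
  }
  if (length(m) != 1 || is.na(m) || m <= 0) {
    abort("`m` must be a single positive number")
  }
  xbar <- mean(values)
  if (xbar <= 0) {
    abort("the mean across perturbations must be positive")
  }
  s2 <- stats::var(values)
  if (s2 == 0) return(0)
  -(s2 / xbar) / m
}

#' Grand-mean normalization constants per phenotype
#'
#' The constant `m` for a phenotype is the arithmetic mean over every retained
#' value (all strains, conditions and replicates) of the QC'd table.
#' Phenotypes without values are skipped with a warning.
#'
#' @param table A phenotype table that passed QC.
#' @return Tibble with `phenotype` and `m`.
#' @export
normalization_constants <- function(table) {
  assert_phenotype_table(table)
  out <- table %>%
    dplyr::filter(!is.na(.data$value)) %>%
    dplyr::group_by(.data$phenotype) %>%
    dplyr::summarise(m = mean(.data$value), .groups = "drop")
  empty <- setdiff(unique(table$phenotype), out$phenotype)
  if (length(empty) > 0) {
    warn(paste0("no values for phenotype(s): ", paste(empty, collapse = ", "),
                "; skipped"))
  }
  out
}

#' Robustness table per strain and phenotype
#'
#' The statistic is computed per replicate over the replicate's available
#' conditions (missing conditions are dropped pairwise), then averaged across
#' replicates; the spread across replicates is reported as the standard error
#' of the mean. Strain x phenotype entries with insufficient data (fewer than
#' `min_conditions` conditions in every replicate, or a non-positive mean) are
#' reported with `NA` and a reason rather than dropped.
#'
#' @param table A QC'd phenotype table.
#' @param norms Normalization constants; defaults to
#'   [normalization_constants()] of `table`. Pass the full-table constants
#'   explicitly when computing on a subset (see [group_influence()]).
#' @param min_conditions Minimum conditions per replicate series (default 2).
#' @return Tibble with `strain, phenotype, R, sem, n_replicates,
#'   n_conditions_used, reason`.
#' @export
robustness_table <- function(table, norms = NULL, min_conditions = 2) {
  assert_phenotype_table(table)
  if (is.null(norms)) {
    norms <- normalization_constants(table)
  }
  per_rep <- table %>%
    dplyr::filter(!is.na(.data$value)) %>%
    dplyr::group_by(.data$strain, .data$phenotype, .data$replicate) %>%
    dplyr::summarise(
      n_c = dplyr::n(),
      xbar = mean(.data$value),
      s2 = stats::var(.data$value),
      .groups = "drop"
    ) %>%
    dplyr::left_join(norms, by = "phenotype") %>%
    dplyr::mutate(
      valid = .data$n_c >= min_conditions & .data$xbar > 0 & !is.na(.data$m),
      R_rep = dplyr::if_else(.data$valid & .data$s2 > 0,
                             -(.data$s2 / .data$xbar) / .data$m,
                             dplyr::if_else(.data$valid, 0, NA_real_))
    )

  per_rep %>%
    dplyr::group_by(.data$strain, .data$phenotype) %>%
    dplyr::summarise(
      n_replicates = sum(.data$valid),
      R = dplyr::if_else(sum(.data$valid) > 0,
                         mean(.data$R_rep[.data$valid]), NA_real_),
      sem = dplyr::if_else(
        sum(.data$valid) > 1,
        stats::sd(.data$R_rep[.data$valid]) / sqrt(sum(.data$valid)),
        dplyr::if_else(sum(.data$valid) == 1, 0, NA_real_)
      ),
      n_conditions_used = as.integer(min(.data$n_c[.data$valid],
                                         .Machine$integer.max)),
      reason = dplyr::if_else(
        sum(.data$valid) > 0, NA_character_,
        "insufficient conditions or non-positive mean"
      ),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      n_conditions_used = dplyr::if_else(.data$n_replicates > 0,
                                         .data$n_conditions_used, NA_integer_)
    ) %>%
    dplyr::select("strain", "phenotype", "R", "sem", "n_replicates",
                  "n_conditions_used", "reason")
}

#' Mean robustness of a strain across phenotypes
#'
#' The unweighted arithmetic mean of a strain's per-phenotype robustness
#' values — the figure of merit used to rank strains overall.
#'
#' @param rvals A robustness table from [robustness_table()].
#' @param strain A single strain label, or `NULL` for all strains.
#' @return A single number when `strain` is given (NA if the strain has no
#'   values), otherwise a tibble `strain, mean_R, n_phenotypes`.
#' @export
mean_robustness <- function(rvals, strain = NULL) {
  summary <- rvals %>%
    dplyr::filter(!is.na(.data$R)) %>%
    dplyr::group_by(.data$strain) %>%
    dplyr::summarise(mean_R = mean(.data$R),
                     n_phenotypes = dplyr::n(), .groups = "drop")
  if (is.null(strain)) return(summary)
  i <- match(strain, summary$strain)
  if (is.na(i)) return(NA_real_)
  summary$mean_R[i]
}

#' Influence of each perturbation group on robustness
#'
#' For every strain x phenotype, robustness is recomputed after removing one
#' group of conditions and compared with the all-conditions value, using the
#' SAME grand-mean constants `m` as the all-conditions run so that the ratio
#' isolates the change in the strain's dispersion. A ratio < 1 means the
#' excluded group was degrading robustness (`negative_impact`); >= 1 means the
#' group was neutral or beneficial to remove (`neutral_or_positive`);
#' `undefined` when the all-conditions robustness is exactly 0. Excluding a
#' group with no matching conditions returns a ratio of exactly 1.
#'
#' @param table A QC'd phenotype table.
#' @param groups Group labels to exclude, one at a time (default: every group
#'   present in the table).
#' @param min_conditions Passed to [robustness_table()].
#' @return Tibble `strain, phenotype, excluded_group, ratio, classification,
#'   R_all, R_excluding`.
#' @export
group_influence <- function(table, groups = NULL, min_conditions = 2) {
  assert_phenotype_table(table)
  norms <- normalization_constants(table)
  r_all <- robustness_table(table, norms = norms,
                            min_conditions = min_conditions) %>%
    dplyr::select("strain", "phenotype", R_all = "R")
  if (is.null(groups)) groups <- unique(stats::na.omit(table$group))

  rows <- lapply(groups, function(g) {
    sub <- table[is.na(table$group) | table$group != g, , drop = FALSE]
    r_ex <- robustness_table(sub, norms = norms,
                             min_conditions = min_conditions) %>%
      dplyr::select("strain", "phenotype", R_excluding = "R")
    dplyr::left_join(r_all, r_ex, by = c("strain", "phenotype")) %>%
      dplyr::mutate(excluded_group = g)
  })
  dplyr::bind_rows(rows) %>%
    dplyr::mutate(
      ratio = dplyr::case_when(
        is.na(.data$R_all) | is.na(.data$R_excluding) ~ NA_real_,
        .data$R_all == 0 ~ NA_real_,
        TRUE ~ .data$R_excluding / .data$R_all
      ),
      classification = dplyr::case_when(
        is.na(.data$R_all) | is.na(.data$R_excluding) ~ NA_character_,
        .data$R_all == 0 ~ "undefined",
        .data$ratio >= 1 ~ "neutral_or_positive",
        TRUE ~ "negative_impact"
      )
    ) %>%
    dplyr::select("strain", "phenotype", "excluded_group", "ratio",
                  "classification", "R_all", "R_excluding")
}
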