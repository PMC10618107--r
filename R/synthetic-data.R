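# Synthetic cultivation data with known ground truth.
#
# The generator emulates a microtiter robustness screen: a set of strains is
# exposed to a perturbation space (conditions drawn from six groups), each
# phenotype responds multiplicatively to the condition, and triplicate
# measurements carry multiplicative lognormal noise. All randomness is driven
# by explicit seeds so every downstream stage can be tested against closed-form
# ground truth.

.GROUP_CHEMICALS <- list(
  acids     = c("lactic_acid", "levulinic_acid", "acetic_acid", "formic_acid"),
  pentoses  = c("xylose", "arabinose"),
  hexoses   = c("galactose", "glucose", "mannose"),
  aldehydes = c("vanillin", "hmf", "furfural"),
  NaCl      = "nacl",
  ethanol   = "ethanol"
)

# plausible g/L ranges for each group in lignocellulosic-hydrolysate screens
.GROUP_CONC_RANGE <- list(
  acids     = c(1, 10),
  pentoses  = c(10, 60),
  hexoses   = c(20, 60),
  aldehydes = c(0.5, 5),
  NaCl      = c(10, 40),
  ethanol   = c(20, 80)
)

#' Generate a perturbation space
#'
#' Draws `n_conditions` single-component growth conditions from the six
#' perturbation groups (see [perturbation_groups()]). Counts per group are
#' allocated from `group_weights` by largest remainder, every group with
#' positive weight is represented whenever `n_conditions` allows, and
#' concentrations are sampled on a 0.5 g/L grid within group-typical ranges so
#' that condition names are unique.
#'
#' @param n_conditions Number of conditions to generate (>= 1). The reference
#'   screen size emulated by the package defaults is 29.
#' @param group_weights Named numeric vector of proportions over the six group
#'   labels; must sum to 1 (tolerance 1e-9). Default: equal weight on all six.
#' @param seed Integer seed; the same seed and arguments reproduce the space
#'   exactly.
#' @param include_control If `TRUE` (default) and hexoses receive at least one
#'   condition, the first hexose condition is pinned to 20 g/L glucose, the
#'   unperturbed comparator medium.
#'
#' @return A tibble with columns `name`, `group`, `concentration_g_l`.
#' @export
#' @examples
#' make_perturbation_space(29, seed = 1)
make_perturbation_space <- function(n_conditions,
                                    group_weights = NULL,
                                    seed = 1,
                                    include_control = TRUE) {
  if (!is.numeric(n_conditions) || length(n_conditions) != 1 ||
      n_conditions < 1 || n_conditions != round(n_conditions)) {
    abort("`n_conditions` must be a positive integer")
  }
  n_conditions <- as.integer(n_conditions)
  if (is.null(group_weights)) {
    group_weights <- stats::setNames(rep(1 / 6, 6), .GROUPS)
  }
  bad <- setdiff(names(group_weights), .GROUPS)
  if (length(bad) > 0) {
    abort(paste0("unknown perturbation group label(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (is.null(names(group_weights)) || any(!nzchar(names(group_weights)))) {
    abort("`group_weights` must be named by perturbation group")
  }
  if (any(group_weights < 0)) abort("group weights must be non-negative")
  if (abs(sum(group_weights) - 1) > 1e-9) {
    abort("group weights must sum to 1 (tolerance 1e-9)")
  }
  group_weights <- group_weights[group_weights > 0]

  # largest-remainder allocation of conditions to groups
  raw <- group_weights * n_conditions
  counts <- floor(raw)
  left <- n_conditions - sum(counts)
  if (left > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(left)]
    counts[extra] <- counts[extra] + 1
  }
  # every positively weighted group represented when there is room
  if (n_conditions >= length(group_weights)) {
    while (any(counts == 0)) {
      donor <- which.max(counts)
      counts[which(counts == 0)[1]] <- 1L
      counts[donor] <- counts[donor] - 1L
    }
  }

  set.seed(as.integer(seed))
  rows <- lapply(names(counts)[counts > 0], function(g) {
    k <- counts[[g]]
    chems <- rep_len(.GROUP_CHEMICALS[[g]], k)
    grid <- seq(.GROUP_CONC_RANGE[[g]][1], .GROUP_CONC_RANGE[[g]][2], by = 0.5)
    conc <- sample(grid, k, replace = k > length(grid))
    tibble::tibble(
      name = paste0(chems, "_", format(conc, trim = TRUE)),
      group = g,
      concentration_g_l = conc
    )
  })
  out <- dplyr::bind_rows(rows)
  if (include_control && "hexoses" %in% out$group) {
    i <- which(out$group == "hexoses")[1]
    out$name[i] <- "glucose_20"
    out$concentration_g_l[i] <- 20
  }
  # names are keys: de-duplicate deterministically if sampling ever collides
  while (anyDuplicated(out$name) > 0) {
    i <- which(duplicated(out$name))[1]
    out$concentration_g_l[i] <- out$concentration_g_l[i] + 0.5
    out$name[i] <- sub("_[^_]*$", paste0("_", format(out$concentration_g_l[i],
                                                     trim = TRUE)),
                       out$name[i])
  }
  out
}

#' Construct an effect model for the phenotype simulator
#'
#' An effect model holds the ground-truth structure behind a simulated
#' phenotype table: per-strain baseline means for each phenotype, optional
#' multiplicative per-condition effect factors shared by all strains, optional
#' per-strain across-condition response spreads (which create the
#' between-condition variance that the robustness statistic measures), and
#' replicate-level measurement noise expressed as a coefficient of variation.
#'
#' @param strains Character vector of strain labels.
#' @param baseline Matrix (strains x phenotypes) of baseline means, or a named
#'   vector of per-phenotype means recycled over strains. All entries must be
#'   positive.
#' @param condition_factors Optional positive numeric vector of multiplicative
#'   condition effects; length must match the condition set handed to
#'   [simulate_phenotype_table()]. `NULL` means all factors are 1.
#' @param strain_sd Matrix (strains x phenotypes) of across-condition response
#'   standard deviations relative to the strain mean, or a named per-phenotype
#'   vector, or `NULL` for none. Values must be non-negative.
#' @param noise_cv Named per-phenotype coefficient of variation of the
#'   multiplicative lognormal replicate noise (>= 0). A single unnamed value is
#'   recycled.
#' @param phenotypes Phenotypes to simulate (default all five).
#' @param seed Integer seed driving every random draw of the simulator.
#'
#' @return An object of class `effect_model`.
#' @export
effect_model <- function(strains,
                         baseline,
                         condition_factors = NULL,
                         strain_sd = NULL,
                         noise_cv = 0.1,
                         phenotypes = phenotype_names(),
                         seed = 1) {
  if (length(strains) < 1) abort("at least one strain is required")
  if (anyDuplicated(strains) > 0) abort("strain labels must be unique")
  bad <- setdiff(phenotypes, .PHENOTYPES)
  if (length(bad) > 0) {
    abort(paste0("unknown phenotype(s): ", paste(bad, collapse = ", ")))
  }
  n_s <- length(strains)
  n_p <- length(phenotypes)

  expand <- function(x, what, allow_zero = FALSE) {
    if (is.matrix(x)) {
      if (nrow(x) != n_s || ncol(x) != n_p) {
        abort(paste0("`", what, "` matrix must be strains x phenotypes"))
      }
      m <- x
    } else {
      if (!is.null(names(x))) x <- x[phenotypes]
      m <- matrix(rep(as.numeric(x), each = n_s), nrow = n_s, ncol = n_p)
    }
    dimnames(m) <- list(strains, phenotypes)
    if (anyNA(m)) abort(paste0("`", what, "` has missing entries"))
    if (allow_zero) {
      if (any(m < 0)) abort(paste0("`", what, "` must be non-negative"))
    } else if (any(m <= 0)) {
      abort(paste0("`", what, "` must be strictly positive"))
    }
    m
  }

  baseline <- expand(baseline, "baseline")
  if (!is.null(strain_sd)) strain_sd <- expand(strain_sd, "strain_sd",
                                               allow_zero = TRUE)
  if (!is.null(condition_factors)) {
    if (any(condition_factors <= 0)) {
      abort("`condition_factors` must be strictly positive")
    }
  }
  if (any(noise_cv < 0)) abort("`noise_cv` must be non-negative")
  if (is.null(names(noise_cv))) {
    noise_cv <- stats::setNames(rep_len(noise_cv, n_p), phenotypes)
  } else {
    noise_cv <- noise_cv[phenotypes]
    if (anyNA(noise_cv)) abort("`noise_cv` must cover every phenotype")
  }

  structure(
    list(
      strains = as.character(strains),
      phenotypes = phenotypes,
      baseline = baseline,
      condition_factors = condition_factors,
      strain_sd = strain_sd,
      noise_cv = noise_cv,
      seed = as.integer(seed)
    ),
    class = "effect_model"
  )
}

#' @export
print.effect_model <- function(x, ...) {
  cat("<effect_model>\n")
  cat("  strains:    ", length(x$strains), "\n")
  cat("  phenotypes: ", paste(x$phenotypes, collapse = ", "), "\n")
  cat("  factors:    ",
      if (is.null(x$condition_factors)) "none (all 1)" else
        paste0("per-condition (n = ", length(x$condition_factors), ")"), "\n")
  cat("  strain_sd:  ", if (is.null(x$strain_sd)) "none" else "per-strain", "\n")
  cat("  noise_cv:   ", paste(signif(x$noise_cv, 3), collapse = ", "), "\n")
  cat("  seed:       ", x$seed, "\n")
  invisible(x)
}

# typical phenotype magnitudes for a yeast microtiter screen
.PHENO_TYPICAL <- c(
  mu_max = 0.30, lag = 3.0, cdw = 4.5,
  biomass_yield = 0.25, ethanol_yield = 0.40
)

#' Default effect model for a synthetic robustness screen
#'
#' Baselines are drawn per strain around field-typical magnitudes (lognormal,
#' 25% spread across strains), condition effect factors are lognormal with 30%
#' spread, per-strain response spreads are lognormal around 0.2, and replicate
#' noise defaults to a 10% CV — the order of magnitude of triplicate scatter in
#' plate cultivations.
#'
#' @param strains Character vector of strain labels.
#' @param n_conditions Number of conditions the model will be paired with.
#' @param noise_cv Replicate noise CV (recycled per phenotype).
#' @param seed Integer seed.
#' @return An `effect_model`.
#' @export
default_effect_model <- function(strains, n_conditions, noise_cv = 0.1,
                                 seed = 1) {
  set.seed(derive_seed(seed, 1))
  n_s <- length(strains)
  n_p <- length(.PHENOTYPES)
  baseline <- matrix(
    stats::qlnorm(stats::runif(n_s * n_p),
                  meanlog = rep(log(.PHENO_TYPICAL), each = n_s),
                  sdlog = 0.25),
    nrow = n_s, ncol = n_p, dimnames = list(strains, .PHENOTYPES)
  )
  factors <- stats::rlnorm(n_conditions, meanlog = 0, sdlog = 0.3)
  strain_sd <- matrix(
    stats::rlnorm(n_s * n_p, meanlog = log(0.2), sdlog = 0.3),
    nrow = n_s, ncol = n_p, dimnames = list(strains, .PHENOTYPES)
  )
  effect_model(strains, baseline,
               condition_factors = factors,
               strain_sd = strain_sd,
               noise_cv = noise_cv,
               seed = derive_seed(seed, 2))
}

#' Specify a performance-robustness trade-off to embed
#'
#' @param phenotype Target phenotype name.
#' @param rho Target population Spearman correlation in \[-1, 1\] between
#'   per-strain mean performance and robustness of the target phenotype.
#' @param seed Integer seed.
#' @param robustness_scale Median magnitude of the analytic robustness values
#'   drawn for the strains (dimensionless, > 0).
#' @param robustness_sdlog Log-scale spread of the robustness magnitudes.
#' @return An object of class `tradeoff_spec`.
#' @export
tradeoff_spec <- function(phenotype, rho, seed = 1,
                          robustness_scale = 0.12, robustness_sdlog = 0.5) {
  if (!phenotype %in% .PHENOTYPES) {
    abort(paste0("unknown phenotype: ", phenotype))
  }
  if (!is.numeric(rho) || length(rho) != 1 || abs(rho) > 1) {
    abort("`rho` must be a single value in [-1, 1]")
  }
  if (robustness_scale <= 0) abort("`robustness_scale` must be positive")
  structure(
    list(phenotype = phenotype, rho = rho, seed = as.integer(seed),
         robustness_scale = robustness_scale,
         robustness_sdlog = robustness_sdlog),
    class = "tradeoff_spec"
  )
}

#' Embed a performance-robustness trade-off in an effect model
#'
#' Constructs an [effect_model()] whose per-strain (mean performance,
#' across-condition variance) pairs for the target phenotype follow a Gaussian
#' copula on ranks, so that the population Spearman correlation between mean
#' performance and the analytic robustness \eqn{-(\sigma^2/\bar{x})(1/m)}
#' equals `rho`. At `rho = -1` the construction is exactly anti-monotone: the
#' best-performing strain has the most negative robustness. Sampling noise in
#' a finite simulated table attenuates the realized correlation, so recovery
#' tests use tolerance bands rather than equality.
#'
#' @param strains Character vector of at least 5 strain labels.
#' @param spec A [tradeoff_spec()].
#' @param noise_cv Replicate noise CV handed to the model.
#' @return An `effect_model` with attribute `"tradeoff"` carrying the drawn
#'   per-strain baselines and analytic robustness targets.
#' @export
embed_tradeoff <- function(strains, spec, noise_cv = 0.1) {
  if (!inherits(spec, "tradeoff_spec")) abort("`spec` must be a tradeoff_spec")
  n_s <- length(strains)
  if (n_s < 5) {
    abort("at least 5 strains are required to realize a rank correlation")
  }
  set.seed(derive_seed(spec$seed, 3))
  # Gaussian copula: Pearson rho_g gives population Spearman 6/pi*asin(rho_g/2)
  rho_g <- 2 * sin(pi * (-spec$rho) / 6)
  z1 <- stats::rnorm(n_s)
  zq <- rho_g * z1 + sqrt(max(0, 1 - rho_g^2)) * stats::rnorm(n_s)

  pheno <- spec$phenotype
  b <- stats::qlnorm(stats::pnorm(z1),
                     meanlog = log(.PHENO_TYPICAL[[pheno]]), sdlog = 0.25)
  q <- stats::qlnorm(stats::pnorm(zq),
                     meanlog = log(spec$robustness_scale),
                     sdlog = spec$robustness_sdlog)
  # R_s = -b_s * sd_s^2 / m  with m = mean(b); choose sd so that R_s = -q_s
  sd_target <- sqrt(q * mean(b) / b)

  n_p <- length(.PHENOTYPES)
  baseline <- matrix(
    stats::rlnorm(n_s * n_p, meanlog = rep(log(.PHENO_TYPICAL), each = n_s),
                  sdlog = 0.25),
    nrow = n_s, ncol = n_p, dimnames = list(strains, .PHENOTYPES)
  )
  strain_sd <- matrix(
    stats::rlnorm(n_s * n_p, meanlog = log(0.2), sdlog = 0.3),
    nrow = n_s, ncol = n_p, dimnames = list(strains, .PHENOTYPES)
  )
  baseline[, pheno] <- b
  strain_sd[, pheno] <- sd_target

  model <- effect_model(strains, baseline,
                        condition_factors = NULL,
                        strain_sd = strain_sd,
                        noise_cv = noise_cv,
                        seed = derive_seed(spec$seed, 4))
  attr(model, "tradeoff") <- list(
    phenotype = pheno, rho = spec$rho,
    performance = stats::setNames(b, strains),
    analytic_R = stats::setNames(-q, strains)
  )
  model
}

#' Simulate a long-format phenotype table with known ground truth
#'
#' Each value is drawn as `baseline x condition factor x (1 + strain-specific
#' condition deviation) x replicate noise`, truncated at zero. Strain-specific
#' deviations are standardized within each strain to have exactly zero sample
#' mean and the model's target standard deviation across conditions, and are
#' rescaled (jointly, preserving ranks) if needed to keep all noiseless values
#' positive; the noiseless per-strain mean, across-condition sample variance
#' and analytic robustness are therefore available in closed form and attached
#' as the `"ground_truth"` attribute (see [ground_truth()]).
#'
#' @param strains Character vector of strain labels; must match the model's.
#' @param conditions Tibble from [make_perturbation_space()] (columns `name`,
#'   `group`, `concentration_g_l`).
#' @param n_replicates Number of replicate measurements per well (>= 1).
#' @param model An [effect_model()].
#'
#' @return A tibble with columns `strain, condition, group, replicate,
#'   phenotype, value, units, qc_flags` and attribute `ground_truth`.
#' @export
simulate_phenotype_table <- function(strains, conditions, n_replicates,
                                     model) {
  if (!inherits(model, "effect_model")) abort("`model` must be an effect_model")
  if (!identical(as.character(strains), model$strains)) {
    abort("`strains` must match the strains of the effect model")
  }
  if (!is.data.frame(conditions) ||
      !all(c("name", "group") %in% names(conditions)) ||
      nrow(conditions) < 1) {
    abort("`conditions` must be a non-empty tibble with `name` and `group`")
  }
  if (n_replicates < 1) abort("`n_replicates` must be >= 1")
  n_s <- length(model$strains)
  n_c <- nrow(conditions)
  n_r <- as.integer(n_replicates)
  phenos <- model$phenotypes

  factors <- model$condition_factors
  if (is.null(factors)) {
    factors <- rep(1, n_c)
  } else if (length(factors) != n_c) {
    abort("`condition_factors` length must equal the number of conditions")
  }

  set.seed(model$seed)
  truth <- list()
  values <- array(
    NA_real_, dim = c(n_s, n_c, n_r, length(phenos)),
    dimnames = list(model$strains, conditions$name, NULL, phenos)
  )
  for (p in phenos) {
    b <- model$baseline[, p]
    # strain x condition deviations, standardized to exact sample moments
    if (!is.null(model$strain_sd) && any(model$strain_sd[, p] > 0) && n_c > 1) {
      e <- matrix(stats::rnorm(n_s * n_c), nrow = n_s)
      e <- (e - rowMeans(e)) / apply(e, 1, stats::sd)
      w <- model$strain_sd[, p]
      # joint rescale keeps 1 + w*e positive without reordering variances
      low <- apply(e, 1, min) * w
      if (any(low <= -1)) w <- w * (0.995 / max(-low))
      dev <- 1 + e * w
    } else {
      w <- rep(0, n_s)
      dev <- matrix(1, n_s, n_c)
    }
    v0 <- (b %o% factors) * dev  # noiseless strains x conditions

    cv <- model$noise_cv[[p]]
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      eta <- matrix(stats::rlnorm(n_s * n_c * n_r,
                                  meanlog = -sdlog^2 / 2, sdlog = sdlog),
                    nrow = n_s * n_c)
    } else {
      eta <- matrix(1, n_s * n_c, n_r)
    }
    values[, , , p] <- pmax(rep(as.vector(v0), n_r) * as.vector(eta), 0)

    m_p <- mean(v0)
    truth[[p]] <- tibble::tibble(
      strain = model$strains,
      phenotype = p,
      true_mean = unname(rowMeans(v0)),
      true_var = unname(apply(v0, 1, stats::var)),
      strain_sd_effective = unname(w),
      m = m_p,
      analytic_R = unname(-(apply(v0, 1, stats::var) / rowMeans(v0)) / m_p)
    )
  }

  grid <- expand.grid(
    strain = model$strains, condition = conditions$name,
    replicate = seq_len(n_r), phenotype = phenos,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  out <- tibble::as_tibble(grid)
  out$value <- as.vector(values)
  out$group <- conditions$group[match(out$condition, conditions$name)]
  out$replicate <- as.integer(out$replicate)
  out$units <- unname(.PHENOTYPE_UNITS[out$phenotype])
  out$qc_flags <- ""
  out <- out[, .PHENO_COLS]
  attr(out, "ground_truth") <- dplyr::bind_rows(truth)
  out
}

#' Ground truth attached to a simulated phenotype table
#'
#' @param table A table produced by [simulate_phenotype_table()].
#' @return Tibble with per strain x phenotype noiseless mean, across-condition
#'   sample variance, grand mean `m` and analytic robustness.
#' @export
ground_truth <- function(table) {
  gt <- attr(table, "ground_truth")
  if (is.null(gt)) abort("`table` carries no ground-truth attribute")
  gt
}

#' Zwietering-Gompertz growth curve in natural-log space
#'
#' Returns \eqn{\ln(N_t/N_0)} of the modified Gompertz model parameterized
#' directly by the maximum specific growth rate `mu` (1/h), lag time `lam` (h)
#' and ln-scale asymptote `a_ln` \eqn{= \ln(A/N_0)}. The analytic maximum
#' derivative equals `mu` and the tangent at the inflection crosses zero at
#' `t = lam`.
#'
#' @param t Time vector (h).
#' @param mu Maximum specific growth rate (1/h); `mu = 0` gives a flat curve.
#' @param lam Lag time (h).
#' @param a_ln Total ln-scale signal increase (> 0).
#' @return Numeric vector of ln-fold changes.
#' @export
zwietering_ln <- function(t, mu, lam, a_ln) {
  if (a_ln <= 0) abort("`a_ln` must be positive")
  if (mu < 0 || lam < 0) abort("`mu` and `lam` must be non-negative")
  if (mu == 0) return(rep(0, length(t)))
  a_ln * exp(-exp(mu * exp(1) * (lam - t) / a_ln + 1))
}

#' Simulate plate-reader growth curves
#'
#' Generates modified-Gompertz (Zwietering) curves in ln-signal space on a
#' regular time grid, one well per row of `params`, optionally replicated with
#' additive Gaussian reader noise. Noiseless curves have analytic maximum
#' specific slope `mu` and tangent-intercept lag `lam`.
#'
#' @param params Tibble with one row per strain x condition and columns
#'   `strain`, `condition`, `A` (carrying capacity, signal units), `mu` (1/h),
#'   `lam` (h), `baseline` (initial signal, > 0); optional `group`,
#'   `concentration_g_l`, `replicate`.
#' @param dt Sampling interval (h, > 0).
#' @param t_end Cultivation length (h, > dt).
#' @param n_replicates Replicate curves per row when `params` has no
#'   `replicate` column.
#' @param noise_sd Additive reader noise SD (signal units).
#' @param seed Integer seed; fixed seed gives a bit-identical realization.
#' @return Long tibble `strain, condition, group, concentration_g_l,
#'   replicate, time_h, signal`.
#' @export
simulate_growth_curves <- function(params, dt = 0.25, t_end = 48,
                                   n_replicates = 1, noise_sd = 0, seed = 1) {
  need <- c("strain", "condition", "A", "mu", "lam", "baseline")
  missing <- setdiff(need, names(params))
  if (length(missing) > 0) {
    abort(paste0("`params` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (dt <= 0) abort("`dt` must be positive")
  if (t_end <= dt) abort("`t_end` must exceed `dt`")
  if (any(params$baseline <= 0)) abort("`baseline` must be positive (log undefined)")
  if (any(params$A <= params$baseline)) abort("`A` must exceed `baseline`")
  if (any(params$mu < 0) || any(params$lam < 0)) {
    abort("`mu` and `lam` must be non-negative")
  }
  if (!"group" %in% names(params)) params$group <- NA_character_
  if (!"concentration_g_l" %in% names(params)) {
    params$concentration_g_l <- NA_real_
  }
  if (!"replicate" %in% names(params)) {
    params <- tidyr::crossing(params, replicate = seq_len(n_replicates))
  }

  times <- seq(0, t_end, by = dt)
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    g <- zwietering_ln(times, p$mu, p$lam, log(p$A / p$baseline))
    signal <- p$baseline * exp(g)
    if (noise_sd > 0) {
      signal <- signal + stats::rnorm(length(times), sd = noise_sd)
    }
    tibble::tibble(
      strain = p$strain, condition = p$condition, group = p$group,
      concentration_g_l = p$concentration_g_l,
      replicate = as.integer(p$replicate),
      time_h = times, signal = pmax(signal, 1e-6)
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-strain OD-to-CDW calibration table
#'
#' @param strains Strain labels.
#' @param slope g/L of cell dry weight per OD unit (> 0), recycled.
#' @param intercept g/L offset, recycled.
#' @return Tibble `strain, slope, intercept`.
#' @export
make_calibrations <- function(strains, slope = 0.5, intercept = 0) {
  if (any(slope <= 0)) abort("calibration `slope` must be positive")
  tibble::tibble(
    strain = as.character(strains),
    slope = rep_len(slope, length(strains)),
    intercept = rep_len(intercept, length(strains))
  )
}

#' Simulate endpoint assays consistent with target phenotype values
#'
#' Builds an endpoint assay table (consumed sugars, ethanol, initial/final OD)
#' whose yields, computed through [compute_yields()], reproduce the supplied
#' `cdw`, `biomass_yield` and `ethanol_yield` exactly in the absence of noise.
#'
#' @param wells Tibble with columns `strain, condition, group, replicate, cdw,
#'   biomass_yield, ethanol_yield` (one row per well).
#' @param calibrations Calibration table from [make_calibrations()].
#' @param od_initial Inoculation OD (default 0.02, a typical screen inoculum).
#' @param residual_fraction Fraction of the initial sugar left unconsumed
#'   (default 0.2) — fixes the initial sugar level given the consumed amount.
#' @return Tibble `strain, condition, group, replicate, sugar_initial_g_l,
#'   sugar_residual_g_l, ethanol_g_l, od_initial, od_final`.
#' @export
simulate_assays <- function(wells, calibrations, od_initial = 0.02,
                            residual_fraction = 0.2) {
  need <- c("strain", "condition", "replicate", "cdw", "biomass_yield",
            "ethanol_yield")
  missing <- setdiff(need, names(wells))
  if (length(missing) > 0) {
    abort(paste0("`wells` is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (!"group" %in% names(wells)) wells$group <- NA_character_
  cal <- calibrations[match(wells$strain, calibrations$strain), ]
  if (anyNA(cal$slope)) {
    abort(paste0("no calibration for strain(s): ",
                 paste(unique(wells$strain[is.na(cal$slope)]), collapse = ", ")))
  }
  cdw0 <- pmax(cal$slope * od_initial + cal$intercept, 0)
  consumed <- (wells$cdw - cdw0) / wells$biomass_yield
  if (any(consumed <= 0)) {
    abort("target `cdw` must exceed the inoculum CDW for every well")
  }
  initial <- consumed / (1 - residual_fraction)
  tibble::tibble(
    strain = wells$strain, condition = wells$condition, group = wells$group,
    replicate = as.integer(wells$replicate),
    sugar_initial_g_l = initial,
    sugar_residual_g_l = initial - consumed,
    ethanol_g_l = wells$ethanol_yield * consumed,
    od_initial = od_initial,
    od_final = (wells$cdw - cal$intercept) / cal$slope
  )
}
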