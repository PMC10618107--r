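# Growth-curve and endpoint phenotyping.
#
# mu_max and lag come from the reader curves (sliding-window log-linear
# regression and the tangent-intercept construction); cdw and the two yields
# come from the endpoint assays through the per-strain OD-to-CDW calibration.

# internal: validate one growth-curve series
assert_curve <- function(times, signal) {
  if (length(times) < 4) abort("a growth curve needs at least 4 time points")
  if (length(signal) != length(times)) {
    abort("`times` and `signal` must have equal length")
  }
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing")
  if (any(signal <= 0)) abort("all signals must be positive")
  invisible(NULL)
}

#' Maximum specific growth rate from a growth curve
#'
#' Fits ordinary least squares of `ln(signal - blank)` against time over every
#' contiguous window of `window` points and returns the maximum positive slope
#' among windows whose fit has `r^2 >= r2_min`. If no window qualifies (flat or
#' erratic curve) the estimate is 0 with the `no_growth` flag. The log-slope is
#' invariant to multiplying the whole signal series by a positive constant.
#'
#' @param times Time vector (h), strictly increasing, length >= 4.
#' @param signal Reader signal vector (> 0).
#' @param window Window length in points (>= 3, <= series length).
#' @param r2_min Minimum within-window r-squared for a window to qualify.
#' @param blank Signal blank subtracted before the log transform (default 0;
#'   the reader signal is assumed already blank-corrected). Values at or below
#'   `blank` are floored at `floor` before taking logs.
#' @param floor Positivity floor applied after blank subtraction.
#'
#' @return List with `mu_max` (1/h), `window_start` (h), `r2`, `intercept`
#'   (the ln-scale intercept of the winning window fit, used by
#'   [estimate_lag()]) and `qc_flags` (character, possibly empty).
#' @export
#' @examples
#' t <- seq(0, 10, by = 0.25)
#' fit_mu_max(t, 0.02 * exp(0.4 * t))$mu_max
fit_mu_max <- function(times, signal, window = 5L, r2_min = 0.98,
                       blank = 0, floor = 1e-6) {
  assert_curve(times, signal)
  window <- as.integer(window)
  if (window < 3) abort("`window` must be at least 3 points")
  n <- length(times)
  if (window > n) abort("`window` is larger than the series length")

  y <- log(pmax(signal - blank, floor))
  # rolling windowed sums via cumulative sums: S[i] over points i..(i+k-1)
  k <- window
  roll <- function(x) {
    c0 <- c(0, cumsum(x))
    c0[(k + 1):(n + 1)] - c0[1:(n - k + 1)]
  }
  st <- roll(times); sy <- roll(y)
  stt <- roll(times^2); syy <- roll(y^2); sty <- roll(times * y)
  sxx <- stt - st^2 / k
  sxy <- sty - st * sy / k
  syy_c <- syy - sy^2 / k
  slope <- sxy / sxx
  r2 <- ifelse(syy_c > 0, sxy^2 / (sxx * syy_c), NA_real_)
  ok <- !is.na(slope) & slope > 0 & !is.na(r2) & r2 >= r2_min

  if (!any(ok)) {
    return(list(mu_max = 0, window_start = NA_real_, r2 = NA_real_,
                intercept = NA_real_, qc_flags = "no_growth"))
  }
  best <- which(ok)[which.max(slope[ok])]
  mu <- slope[best]
  intercept <- (sy[best] - mu * st[best]) / k
  list(
    mu_max = mu,
    window_start = times[best],
    r2 = r2[best],
    intercept = intercept,
    qc_flags = ""
  )
}

#' Lag phase from the tangent-intercept construction
#'
#' The tangent line of the winning maximum-slope window (in ln-signal space)
#' is extended back to the initial ln-signal baseline, taken as the minimum of
#' the first three ln-signal values; the crossing time, floored at 0, is the
#' lag. If the curve showed no growth the lag is the total cultivation time,
#' flagged `no_growth`.
#'
#' @inheritParams fit_mu_max
#' @param fit Result of [fit_mu_max()] on the same curve.
#' @return List with `lag` (h) and `qc_flags`.
#' @export
estimate_lag <- function(times, signal, fit, blank = 0, floor = 1e-6) {
  assert_curve(times, signal)
  if (fit$mu_max <= 0) {
    return(list(lag = max(times), qc_flags = "no_growth"))
  }
  y0 <- min(log(pmax(signal[1:3] - blank, floor)))
  lag <- (y0 - fit$intercept) / fit$mu_max
  list(lag = max(lag, 0), qc_flags = "")
}

#' Convert optical density to cell dry weight
#'
#' @param od Optical density (>= 0), vectorized.
#' @param cal A single calibration: list or one-row tibble with `slope` (g/L
#'   per OD unit, > 0) and `intercept` (g/L).
#' @return Cell dry weight in g/L, floored at 0.
#' @export
od_to_cdw <- function(od, cal) {
  if (any(od < 0)) abort("`od` must be non-negative")
  if (is.data.frame(cal)) cal <- as.list(cal[1, ])
  if (is.null(cal$slope) || cal$slope <= 0) {
    abort("calibration `slope` must be positive")
  }
  pmax(cal$slope * od + cal$intercept, 0)
}

#' Biomass and ethanol yields from an endpoint assay
#'
#' The yield denominator is the total consumed substrate summed over all
#' sugars present (media may contain sugar mixes). The biomass-yield numerator
#' is the CDW produced during cultivation (final minus initial), while the
#' `cdw` phenotype itself reports the final CDW.
#'
#' @param assay List or one-row tibble with numeric `initial_sugars` and
#'   `residual_sugars` (g/L, one entry per sugar), `ethanol_g_l`, `od_initial`
#'   and `od_final`.
#' @param cal Calibration for the strain, as in [od_to_cdw()].
#' @param clamp_tol Residuals exceeding the initial concentration by at most
#'   this fraction (assay noise) are clamped to the initial value; larger
#'   excesses are an error.
#' @return List with `biomass_yield` (g/g), `ethanol_yield` (g/g), `consumed`
#'   (g/L) and `qc_flags`. When nothing was consumed both yields are `NA` with
#'   the `no_consumption` flag.
#' @export
compute_yields <- function(assay, cal, clamp_tol = 0.05) {
  if (is.data.frame(assay)) assay <- as.list(assay[1, ])
  ini <- assay$initial_sugars
  res <- assay$residual_sugars
  if (length(ini) != length(res)) {
    abort("initial and residual sugar vectors must have equal length")
  }
  if (any(ini < 0) || any(res < 0)) abort("sugar concentrations must be >= 0")
  over <- res > ini * (1 + clamp_tol)
  if (any(over)) {
    abort("residual sugar exceeds the initial concentration beyond assay tolerance")
  }
  res <- pmin(res, ini)
  consumed <- sum(ini - res)
  if (consumed <= 0) {
    return(list(biomass_yield = NA_real_, ethanol_yield = NA_real_,
                consumed = 0, qc_flags = "no_consumption"))
  }
  delta_cdw <- od_to_cdw(assay$od_final, cal) - od_to_cdw(assay$od_initial, cal)
  list(
    biomass_yield = delta_cdw / consumed,
    ethanol_yield = assay$ethanol_g_l / consumed,
    consumed = consumed,
    qc_flags = ""
  )
}

#' Extract the five phenotypes from curves and endpoint assays
#'
#' Produces one long-format record per well and phenotype: `mu_max` and `lag`
#' from the growth curves, `cdw` from the final OD through the strain's
#' calibration, and the two yields from the endpoint assay. Wells present only
#' in the curves are allowed when `allow_curve_only = TRUE` (their endpoint
#' phenotypes are absent). QC flags raised during fitting are propagated.
#'
#' @param curves Long tibble as written by [simulate_growth_curves()]:
#'   `strain, condition, group, replicate, time_h, signal` (one row per time
#'   point).
#' @param assays Endpoint tibble as written by [simulate_assays()], or `NULL`
#'   for curve-only extraction.
#' @param calibrations Calibration table (`strain, slope, intercept`);
#'   required when `assays` is given.
#' @param window,r2_min,blank Passed to [fit_mu_max()].
#' @param allow_curve_only Permit wells without a matching assay record.
#' @return A phenotype table (`strain, condition, group, replicate, phenotype,
#'   value, units, qc_flags`).
#' @export
extract_phenotypes <- function(curves, assays = NULL, calibrations = NULL,
                               window = 5L, r2_min = 0.98, blank = 0,
                               allow_curve_only = is.null(assays)) {
  if ((is.null(curves) || nrow(curves) == 0) &&
      (is.null(assays) || nrow(assays) == 0)) {
    return(empty_phenotype_table())
  }
  records <- list()

  if (!is.null(curves) && nrow(curves) > 0) {
    need <- c("strain", "condition", "replicate", "time_h", "signal")
    missing <- setdiff(need, names(curves))
    if (length(missing) > 0) {
      abort(paste0("`curves` is missing column(s): ",
                   paste(missing, collapse = ", ")))
    }
    if (!"group" %in% names(curves)) curves$group <- NA_character_
    dup <- curves %>%
      dplyr::count(.data$strain, .data$condition, .data$replicate,
                   .data$time_h) %>%
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0) {
      abort(paste0(
        "duplicate curve key tuples (strain, condition, replicate, time_h): ",
        paste(utils::head(paste(dup$strain, dup$condition, dup$replicate,
                                dup$time_h, sep = "/"), 10), collapse = "; ")
      ))
    }
    curve_fits <- curves %>%
      dplyr::arrange(.data$strain, .data$condition, .data$replicate,
                     .data$time_h) %>%
      dplyr::group_by(.data$strain, .data$condition, .data$group,
                      .data$replicate) %>%
      dplyr::group_modify(function(d, key) {
        fit <- fit_mu_max(d$time_h, d$signal, window = window,
                          r2_min = r2_min, blank = blank)
        lag <- estimate_lag(d$time_h, d$signal, fit, blank = blank)
        tibble::tibble(
          phenotype = c("mu_max", "lag"),
          value = c(fit$mu_max, lag$lag),
          qc_flags = c(fit$qc_flags, lag$qc_flags)
        )
      }) %>%
      dplyr::ungroup()
    records$curves <- curve_fits
  }

  if (!is.null(assays) && nrow(assays) > 0) {
    need <- c("strain", "condition", "replicate", "sugar_initial_g_l",
              "sugar_residual_g_l", "ethanol_g_l", "od_initial", "od_final")
    missing <- setdiff(need, names(assays))
    if (length(missing) > 0) {
      abort(paste0("`assays` is missing column(s): ",
                   paste(missing, collapse = ", ")))
    }
    if (!"group" %in% names(assays)) assays$group <- NA_character_
    dup <- assays %>%
      dplyr::count(.data$strain, .data$condition, .data$replicate) %>%
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0) {
      abort(paste0(
        "duplicate assay key tuples (strain, condition, replicate): ",
        paste(utils::head(paste(dup$strain, dup$condition, dup$replicate,
                                sep = "/"), 10), collapse = "; ")
      ))
    }
    if (is.null(calibrations)) {
      abort("`calibrations` is required when endpoint assays are given")
    }
    nocal <- setdiff(unique(assays$strain), calibrations$strain)
    if (length(nocal) > 0) {
      abort(paste0("no calibration for strain(s): ",
                   paste(nocal, collapse = ", ")))
    }
    endpoint <- lapply(seq_len(nrow(assays)), function(i) {
      a <- assays[i, ]
      cal <- calibrations[calibrations$strain == a$strain, ][1, ]
      yields <- compute_yields(
        list(initial_sugars = a$sugar_initial_g_l,
             residual_sugars = a$sugar_residual_g_l,
             ethanol_g_l = a$ethanol_g_l,
             od_initial = a$od_initial, od_final = a$od_final),
        cal
      )
      tibble::tibble(
        strain = a$strain, condition = a$condition, group = a$group,
        replicate = as.integer(a$replicate),
        phenotype = c("cdw", "biomass_yield", "ethanol_yield"),
        value = c(od_to_cdw(a$od_final, cal),
                  yields$biomass_yield, yields$ethanol_yield),
        qc_flags = c("", yields$qc_flags, yields$qc_flags)
      )
    })
    records$assays <- dplyr::bind_rows(endpoint)
  } else if (!allow_curve_only) {
    abort("endpoint assays are required unless `allow_curve_only = TRUE`")
  }

  out <- dplyr::bind_rows(records)
  out$units <- unname(.PHENOTYPE_UNITS[out$phenotype])
  out$replicate <- as.integer(out$replicate)
  out <- out[, .PHENO_COLS]
  dplyr::arrange(out, .data$strain, .data$condition, .data$replicate,
                 match(.data$phenotype, .PHENOTYPES))
}
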