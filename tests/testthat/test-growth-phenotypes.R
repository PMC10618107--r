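test_that("a pure exponential recovers its rate exactly in log space", {
  t <- seq(0, 10, by = 0.25)
  fit <- fit_mu_max(t, 0.02 * exp(0.4 * t))
  expect_equal(fit$mu_max, 0.4, tolerance = 1e-6)
  expect_equal(fit$qc_flags, "")
  # no lag: the tangent passes through the initial baseline at t = 0
  lag <- estimate_lag(t, 0.02 * exp(0.4 * t), fit)
  expect_equal(lag$lag, 0, tolerance = 1e-9)
})

test_that("mu_max is invariant to rescaling the signal", {
  t <- seq(0, 30, by = 0.25)
  signal <- 0.05 * exp(gompertz_oracle(t, 0.3, 2, 2.3))
  f1 <- fit_mu_max(t, signal)
  f2 <- fit_mu_max(t, signal * 37.5)
  expect_equal(f1$mu_max, f2$mu_max, tolerance = 1e-12)
})

test_that("flat and erratic curves are flagged as no growth", {
  t <- 0:10
  fit <- fit_mu_max(t, rep(1, 11))
  expect_equal(fit$mu_max, 0)
  expect_equal(fit$qc_flags, "no_growth")
  lag <- estimate_lag(t, rep(1, 11), fit)
  expect_equal(lag$lag, 10)
  expect_equal(lag$qc_flags, "no_growth")
})

test_that("curve preconditions are enforced", {
  expect_error(fit_mu_max(0:10, rep(1, 11), window = 12), "larger than")
  expect_error(fit_mu_max(0:2, 1:3), "at least 4")
  expect_error(fit_mu_max(c(0, 1, 1, 2), 1:4), "strictly increasing")
  expect_error(fit_mu_max(0:3, c(1, -1, 1, 1)), "positive")
  expect_error(fit_mu_max(0:4, exp(0:4), window = 2), "at least 3")
})

test_that("Gompertz curves recover mu and lag within stated tolerances", {
  t <- seq(0, 48, by = 0.1)
  signal <- 0.05 * exp(gompertz_oracle(t, 0.35, 3, 2.3))
  fit <- fit_mu_max(t, signal)
  expect_lt(abs(fit$mu_max - 0.35) / 0.35, 0.05)
  lag <- estimate_lag(t, signal, fit)
  expect_lt(abs(lag$lag - 3), 0.5)
})

test_that("lag plus ln-rise over mu approximates the time to plateau", {
  t <- seq(0, 48, by = 0.1)
  a_ln <- 2.3
  signal <- 0.05 * exp(gompertz_oracle(t, 0.4, 6, a_ln))
  fit <- fit_mu_max(t, signal)
  lag <- estimate_lag(t, signal, fit)
  t_plateau_pred <- lag$lag + a_ln / fit$mu_max
  # plateau = the curve reaching 90% of its total ln-rise
  t_plateau_obs <- t[which(signal >= 0.05 * exp(a_ln * 0.9))[1]]
  expect_lt(abs(t_plateau_pred - t_plateau_obs) / t_plateau_obs, 0.10)
})

test_that("OD converts to CDW linearly with a floor at zero", {
  expect_equal(od_to_cdw(0, list(slope = 0.5, intercept = 0)), 0)
  expect_equal(od_to_cdw(10, list(slope = 0.5, intercept = 0)), 5)
  expect_equal(od_to_cdw(0.1, list(slope = 0.5, intercept = -0.2)), 0)
  expect_error(od_to_cdw(-1, list(slope = 0.5, intercept = 0)),
               "non-negative")
  expect_error(od_to_cdw(1, list(slope = 0, intercept = 0)), "slope")
})

test_that("yields follow consumed-substrate arithmetic", {
  cal <- list(slope = 0.5, intercept = 0)
  y <- compute_yields(
    list(initial_sugars = 20, residual_sugars = 0, ethanol_g_l = 9.2,
         od_initial = 0, od_final = 0), cal
  )
  expect_equal(y$ethanol_yield, 0.46)

  y2 <- compute_yields(
    list(initial_sugars = 20, residual_sugars = 10, ethanol_g_l = 0,
         od_initial = 0, od_final = 4), cal  # delta CDW = 2 g/L
  )
  expect_equal(y2$biomass_yield, 0.2)

  y3 <- compute_yields(
    list(initial_sugars = 20, residual_sugars = 20, ethanol_g_l = 0,
         od_initial = 0, od_final = 1), cal
  )
  expect_true(is.na(y3$biomass_yield) && is.na(y3$ethanol_yield))
  expect_equal(y3$qc_flags, "no_consumption")

  # mixed sugars are summed in the denominator
  y4 <- compute_yields(
    list(initial_sugars = c(5, 30), residual_sugars = c(0, 15),
         ethanol_g_l = 8, od_initial = 0, od_final = 0), cal
  )
  expect_equal(y4$consumed, 20)
  expect_equal(y4$ethanol_yield, 0.4)

  expect_error(
    compute_yields(
      list(initial_sugars = 10, residual_sugars = 12, ethanol_g_l = 0,
           od_initial = 0, od_final = 0), cal
    ),
    "exceeds"
  )
})

test_that("extraction produces one record per well and phenotype", {
  strains <- c("s1", "s2")
  conds <- data.frame(condition = c("c1", "c2"),
                      group = c("hexoses", "acids"))
  params <- merge(
    expand.grid(strain = strains, condition = conds$condition,
                replicate = 1:2, stringsAsFactors = FALSE),
    conds
  )
  params$A <- 0.5; params$mu <- 0.3; params$lam <- 2; params$baseline <- 0.05
  curves <- simulate_growth_curves(params, dt = 0.25, t_end = 30)
  cal <- make_calibrations(strains)
  wells <- params[, c("strain", "condition", "group", "replicate")]
  wells$cdw <- 4; wells$biomass_yield <- 0.2; wells$ethanol_yield <- 0.4
  assays <- simulate_assays(wells, cal)

  tab <- extract_phenotypes(curves, assays, cal)
  expect_equal(nrow(tab), 2 * 2 * 2 * 5)
  expect_setequal(unique(tab$phenotype), phenotype_names())
  expect_identical(tab, extract_phenotypes(curves, assays, cal))

  # zero-noise values match the generator targets
  expect_equal(unique(tab$value[tab$phenotype == "cdw"]), 4)
  expect_equal(unique(tab$value[tab$phenotype == "biomass_yield"]), 0.2,
               tolerance = 1e-9)
  expect_lt(max(abs(tab$value[tab$phenotype == "mu_max"] - 0.3)) / 0.3, 0.05)
  expect_lt(max(abs(tab$value[tab$phenotype == "lag"] - 2)), 0.5)
})

test_that("extraction rejects duplicates and unknown strains", {
  t <- seq(0, 5, by = 0.5)
  curves <- data.frame(strain = "s1", condition = "c1", group = "hexoses",
                       replicate = 1L, time_h = t, signal = exp(0.3 * t))
  expect_error(extract_phenotypes(rbind(curves, curves)), "duplicate")

  cal <- make_calibrations("other")
  wells <- data.frame(strain = "s1", condition = "c1", group = "hexoses",
                      replicate = 1L, cdw = 4, biomass_yield = 0.2,
                      ethanol_yield = 0.4)
  assays <- simulate_assays(wells, make_calibrations("s1"))
  expect_error(extract_phenotypes(curves, assays, cal), "s1")
})

test_that("curve-only extraction and empty input are supported", {
  t <- seq(0, 10, by = 0.25)
  curves <- data.frame(strain = "s1", condition = "c1", group = "hexoses",
                       replicate = 1L, time_h = t,
                       signal = 0.02 * exp(0.4 * t))
  tab <- extract_phenotypes(curves)
  expect_setequal(unique(tab$phenotype), c("mu_max", "lag"))

  empty <- extract_phenotypes(curves[0, ])
  expect_equal(nrow(empty), 0)
  expect_named(empty, c("strain", "condition", "group", "replicate",
                        "phenotype", "value", "units", "qc_flags"))
})
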