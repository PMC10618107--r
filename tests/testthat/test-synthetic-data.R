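test_that("perturbation space covers the requested groups and is deterministic", {
  cs <- make_perturbation_space(29, seed = 1)
  expect_equal(nrow(cs), 29)
  expect_setequal(unique(cs$group), perturbation_groups())
  expect_false(anyDuplicated(cs$name) > 0)
  expect_true(all(cs$concentration_g_l >= 0))

  cs2 <- make_perturbation_space(29, seed = 1)
  expect_identical(cs, cs2)

  one <- make_perturbation_space(1, group_weights = c(hexoses = 1), seed = 2)
  expect_equal(nrow(one), 1)
  expect_equal(one$group, "hexoses")

  same7a <- make_perturbation_space(12, seed = 7)
  same7b <- make_perturbation_space(12, seed = 7)
  expect_identical(same7a, same7b)
})

test_that("perturbation space rejects invalid weights", {
  expect_error(make_perturbation_space(10, c(sugars = 1)), "sugars")
  expect_error(make_perturbation_space(10, c(hexoses = 0.5, acids = 0.4)),
               "sum to 1")
  expect_error(make_perturbation_space(0), "positive integer")
})

test_that("the control condition flag pins 20 g/L glucose", {
  with_ctl <- make_perturbation_space(12, seed = 3, include_control = TRUE)
  expect_true("glucose_20" %in% with_ctl$name)
  no_ctl <- make_perturbation_space(
    12, group_weights = c(acids = 0.5, ethanol = 0.5), seed = 3
  )
  expect_false("glucose_20" %in% no_ctl$name)
})

test_that("simulated tables have exact record counts and determinism", {
  strains <- sprintf("s%02d", 1:24)
  cs <- make_perturbation_space(29, seed = 1)
  model <- default_effect_model(strains, 29, seed = 2)
  tab <- simulate_phenotype_table(strains, cs, 3, model)
  expect_equal(nrow(tab), 24 * 29 * 3 * 5)  # 10,440 pre-QC records
  expect_identical(tab, simulate_phenotype_table(strains, cs, 3, model))
  expect_true(all(tab$value >= 0))
})

test_that("zero noise and unit factors reproduce the baseline exactly", {
  cs <- make_perturbation_space(1, c(hexoses = 1), seed = 1)
  model <- effect_model(
    "s1",
    baseline = c(mu_max = 0.3, lag = 3, cdw = 4, biomass_yield = 0.2,
                 ethanol_yield = 0.4),
    condition_factors = 2, noise_cv = 0, seed = 1
  )
  tab <- simulate_phenotype_table("s1", cs, 1, model)
  expect_equal(tab$value[tab$phenotype == "mu_max"], 0.3 * 2)
  expect_equal(tab$value[tab$phenotype == "ethanol_yield"], 0.4 * 2)
})

test_that("lognormal replicate noise gives the analytic Fano factor", {
  # CV = 0.3 on unit mean: population variance/mean = 0.09
  cs <- make_perturbation_space(29, seed = 4)
  strains <- sprintf("s%03d", 1:200)
  model <- effect_model(
    strains,
    baseline = c(mu_max = 1, lag = 1, cdw = 1, biomass_yield = 1,
                 ethanol_yield = 1),
    noise_cv = 0.3, phenotypes = "mu_max", seed = 9
  )
  tab <- simulate_phenotype_table(strains, cs, 1, model)
  fano <- vapply(split(tab$value, tab$strain),
                 function(v) var(v) / mean(v), numeric(1))
  # Monte-Carlo error of the mean over 200 strain series
  se <- sd(fano) / sqrt(length(fano))
  expect_lt(abs(mean(fano) - 0.09), 3 * se + 0.002)
})

test_that("negative noise CV is rejected", {
  expect_error(
    effect_model("s1", baseline = c(mu_max = 1, lag = 1, cdw = 1,
                                    biomass_yield = 1, ethanol_yield = 1),
                 noise_cv = -0.1),
    "non-negative"
  )
})

test_that("growth curves are Gompertz in ln space with analytic slope", {
  p <- data.frame(strain = "s", condition = "c", A = 0.5, mu = 0.4,
                  lam = 2, baseline = 0.05)
  cur <- simulate_growth_curves(p, dt = 0.25, t_end = 30)
  expect_equal(cur$signal,
               0.05 * exp(gompertz_oracle(cur$time_h, 0.4, 2, log(10))),
               tolerance = 1e-12)
  fit <- fit_mu_max(cur$time_h, cur$signal)
  expect_lt(abs(fit$mu_max - 0.4) / 0.4, 0.05)

  flat <- simulate_growth_curves(
    data.frame(strain = "s", condition = "c", A = 0.5, mu = 0,
               lam = 0, baseline = 0.05), dt = 1, t_end = 10
  )
  expect_true(all(flat$signal == 0.05))

  n1 <- simulate_growth_curves(p, noise_sd = 0.01, seed = 11)
  n2 <- simulate_growth_curves(p, noise_sd = 0.01, seed = 11)
  expect_identical(n1, n2)
})

test_that("growth-curve preconditions are enforced", {
  p <- data.frame(strain = "s", condition = "c", A = 0.5, mu = 0.4,
                  lam = 2, baseline = 0.05)
  expect_error(simulate_growth_curves(p, dt = 0), "positive")
  expect_error(simulate_growth_curves(p, dt = 1, t_end = 0.5), "exceed")
  p$baseline <- 0
  expect_error(simulate_growth_curves(p), "log undefined")
})

test_that("embedded rho = -1 is exactly anti-monotone", {
  strains <- sprintf("s%02d", 1:24)
  model <- embed_tradeoff(strains, tradeoff_spec("mu_max", -1, seed = 5),
                          noise_cv = 0)
  info <- attr(model, "tradeoff")
  expect_equal(which.max(info$performance), which.min(info$analytic_R))
  expect_equal(cor(info$performance, info$analytic_R, method = "spearman"), -1)

  cs <- make_perturbation_space(29, seed = 3)
  tab <- simulate_phenotype_table(strains, cs, 1, model)
  rv <- robustness_table(tab)
  perf <- strain_performance(tab)
  d <- merge(perf[perf$phenotype == "mu_max", ],
             rv[rv$phenotype == "mu_max", ], by = "strain")
  expect_equal(cor(d$performance, d$R, method = "spearman"), -1)
})

test_that("embedded rho = 0 yields a centred estimated correlation", {
  strains <- sprintf("s%02d", 1:24)
  cs <- make_perturbation_space(20, seed = 8)
  rs <- vapply(1:200, function(seed) {
    model <- embed_tradeoff(strains, tradeoff_spec("mu_max", 0, seed = seed),
                            noise_cv = 0)
    tab <- simulate_phenotype_table(strains, cs, 1, model)
    info <- attr(model, "tradeoff")
    rv <- robustness_table(tab)
    d <- merge(
      data.frame(strain = strains, performance = info$performance),
      rv[rv$phenotype == "mu_max", ], by = "strain"
    )
    cor(d$performance, d$R, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)) + 0.02)
})

test_that("too few strains cannot carry a rank correlation", {
  expect_error(embed_tradeoff(c("a", "b", "c"),
                              tradeoff_spec("mu_max", -0.5)),
               "at least 5")
})

test_that("noiseless ground truth matches a direct recomputation", {
  strains <- sprintf("s%d", 1:6)
  cs <- make_perturbation_space(8, seed = 2)
  model <- embed_tradeoff(strains, tradeoff_spec("cdw", -0.5, seed = 3),
                          noise_cv = 0)
  tab <- simulate_phenotype_table(strains, cs, 1, model)
  gt <- ground_truth(tab)
  for (p in unique(tab$phenotype)) {
    sub <- tab[tab$phenotype == p, ]
    m <- mean(sub$value)
    for (s in strains) {
      v <- sub$value[sub$strain == s]
      row <- gt[gt$strain == s & gt$phenotype == p, ]
      expect_equal(row$true_mean, mean(v), tolerance = 1e-12)
      expect_equal(row$true_var, var(v), tolerance = 1e-12)
      expect_equal(row$analytic_R, -(var(v) / mean(v)) / m, tolerance = 1e-12)
    }
  }
})

test_that("assay simulation inverts yield computation exactly", {
  cal <- make_calibrations(c("s1", "s2"), slope = c(0.5, 0.6),
                           intercept = c(0, -0.01))
  wells <- data.frame(
    strain = c("s1", "s2"), condition = "c1", group = "hexoses",
    replicate = 1L, cdw = c(4.5, 3.8),
    biomass_yield = c(0.25, 0.2), ethanol_yield = c(0.40, 0.35)
  )
  assays <- simulate_assays(wells, cal)
  for (i in 1:2) {
    y <- compute_yields(
      list(initial_sugars = assays$sugar_initial_g_l[i],
           residual_sugars = assays$sugar_residual_g_l[i],
           ethanol_g_l = assays$ethanol_g_l[i],
           od_initial = assays$od_initial[i],
           od_final = assays$od_final[i]),
      cal[cal$strain == assays$strain[i], ]
    )
    expect_equal(y$biomass_yield, wells$biomass_yield[i], tolerance = 1e-9)
    expect_equal(y$ethanol_yield, wells$ethanol_yield[i], tolerance = 1e-9)
  }
})
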