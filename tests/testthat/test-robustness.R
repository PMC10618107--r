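test_that("the robustness statistic follows its defining arithmetic", {
  expect_equal(robustness(c(2, 2, 2), m = 5), 0)
  expect_equal(robustness(c(1, 2, 3), m = 2), -0.25)
  # scale invariance: data and m scaled by the same constant
  expect_equal(robustness(c(10, 20, 30), m = 20), -0.25)
  expect_lte(robustness(rlnorm(10), m = 1), 0)
})

test_that("robustness preconditions are enforced", {
  expect_error(robustness(c(1), m = 1), "at least 2")
  expect_error(robustness(c(1, 2), m = 0), "positive")
  expect_error(robustness(c(-3, 1), m = 1), "mean across perturbations")
  expect_error(robustness(c(1, 2, NA), m = NA), "positive")
})

test_that("normalization constants are grand means per phenotype", {
  tab <- tibble::tibble(
    strain = rep(c("a", "b"), each = 2), condition = rep(c("c1", "c2"), 2),
    group = "hexoses", replicate = 1L, phenotype = "mu_max",
    value = c(0.5, 1.5, 2.5, 3.5), units = "1/h", qc_flags = ""
  )
  norms <- normalization_constants(tab)
  expect_equal(norms$m[norms$phenotype == "mu_max"], 2.0)

  single <- tab[1, ]; single$value <- 5
  expect_equal(normalization_constants(single)$m, 5)

  tab$value <- NA_real_
  expect_warning(out <- normalization_constants(tab), "no values")
  expect_equal(nrow(out), 0)
})

test_that("robustness_table equals brute force on random tables", {
  set.seed(11)
  for (i in 1:25) {
    tab <- random_phenotype_table(
      n_strains = sample(2:5, 1), n_conditions = sample(3:8, 1),
      n_replicates = sample(1:3, 1)
    )
    got <- robustness_table(tab)
    want <- brute_force_robustness(tab)
    merged <- merge(got, want, by = c("strain", "phenotype"),
                    suffixes = c("_got", "_want"))
    expect_equal(nrow(merged), nrow(want))
    expect_equal(merged$R_got, merged$R_want, tolerance = 1e-12)
    expect_equal(merged$sem_got, merged$sem_want, tolerance = 1e-12)
  }
})

test_that("replicate aggregation gives mean and SEM across replicates", {
  # three replicates engineered to give R = -0.2, -0.3, -0.4
  vals <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  # R_rep = -(s2/xbar)/m: with s2 = 1, xbar = 2 -> R = -1/(2 m)
  # choose per-replicate scalings: scaling values by c scales R by c
  tab <- dplyr::bind_rows(lapply(1:3, function(r) {
    c_r <- c(0.4, 0.6, 0.8)[r] # R_rep = -c_r * 1/(2m'), see below
    tibble::tibble(
      strain = "s", condition = c("c1", "c2", "c3"), group = "hexoses",
      replicate = as.integer(r), phenotype = "mu_max",
      value = c_r * c(1, 2, 3), units = "1/h", qc_flags = ""
    )
  }))
  m <- mean(tab$value)
  rv <- robustness_table(tab, norms = tibble::tibble(phenotype = "mu_max",
                                                     m = m))
  r_reps <- -c(0.4, 0.6, 0.8) * 0.5 / m
  expect_equal(rv$R, mean(r_reps), tolerance = 1e-12)
  expect_equal(rv$sem, sd(r_reps) / sqrt(3), tolerance = 1e-12)

  # identical replicates: SEM = 0
  tab2 <- tab; tab2$value <- rep(c(1, 2, 3), 3)
  rv2 <- robustness_table(tab2)
  expect_equal(rv2$sem, 0)
})

test_that("noiseless simulation matches the closed form to 1e-12", {
  strains <- sprintf("s%d", 1:8)
  cs <- make_perturbation_space(12, seed = 4)
  model <- effect_model(
    strains,
    baseline = c(mu_max = 0.3, lag = 3, cdw = 4, biomass_yield = 0.2,
                 ethanol_yield = 0.4),
    condition_factors = rlnorm(12, 0, 0.25),
    noise_cv = 0, seed = 5
  )
  tab <- simulate_phenotype_table(strains, cs, 2, model)
  gt <- ground_truth(tab)
  rv <- robustness_table(tab)
  merged <- merge(rv, gt, by = c("strain", "phenotype"))
  expect_equal(merged$R, merged$analytic_R, tolerance = 1e-12)
  expect_equal(merged$sem, rep(0, nrow(merged)), tolerance = 1e-12)
})

test_that("insufficient data is reported, not fatal", {
  tab <- tibble::tibble(
    strain = "s", condition = "c1", group = "hexoses", replicate = 1L,
    phenotype = "mu_max", value = 0.3, units = "1/h", qc_flags = ""
  )
  rv <- robustness_table(tab)
  expect_true(is.na(rv$R))
  expect_match(rv$reason, "insufficient")
})

test_that("mean robustness averages phenotypes per strain", {
  rvals <- tibble::tibble(
    strain = "s1", phenotype = phenotype_names(),
    R = c(-0.2, -0.3, -0.9, -0.9, -0.9), sem = 0, n_replicates = 3L,
    n_conditions_used = 10L, reason = NA_character_
  )
  expect_equal(mean_robustness(rvals, "s1"), -0.64)
  expect_equal(mean_robustness(rvals[1, ], "s1"), -0.2)
  rvals$R <- 0
  expect_equal(mean_robustness(rvals, "s1"), 0)
  expect_true(is.na(mean_robustness(rvals, "missing_strain")))
})

test_that("a variance-carrying group drives the influence ratio to zero", {
  tab <- tibble::tibble(
    strain = "s", condition = c("c1", "c2", "c3", "c4"),
    group = c("hexoses", "hexoses", "hexoses", "aldehydes"),
    replicate = 1L, phenotype = "mu_max",
    value = c(1, 1, 1, 3), units = "1/h", qc_flags = ""
  )
  infl <- group_influence(tab, groups = "aldehydes", min_conditions = 2)
  # m = 1.5; R_all = -(1 / 1.5) / 1.5; R_excluding = 0
  expect_equal(infl$R_all, -(1 / 1.5) / 1.5, tolerance = 1e-12)
  expect_equal(infl$R_excluding, 0)
  expect_equal(infl$ratio, 0)
  expect_equal(infl$classification, "negative_impact")
})

test_that("excluding an absent group leaves robustness unchanged", {
  set.seed(21)
  tab <- random_phenotype_table()
  tab$group <- "hexoses"
  infl <- group_influence(tab, groups = "NaCl")
  expect_true(all(infl$ratio == 1))
  expect_true(all(infl$classification == "neutral_or_positive"))
})

test_that("constant series give undefined influence classification", {
  tab <- tibble::tibble(
    strain = "s", condition = c("c1", "c2", "c3", "c4"),
    group = c("hexoses", "hexoses", "acids", "acids"),
    replicate = 1L, phenotype = "mu_max",
    value = 2, units = "1/h", qc_flags = ""
  )
  infl <- group_influence(tab, groups = "acids")
  expect_equal(infl$classification, "undefined")
  expect_true(is.na(infl$ratio))
})

test_that("robustness is invariant to rescaling a phenotype everywhere", {
  set.seed(31)
  for (i in 1:10) {
    tab <- random_phenotype_table()
    c_scale <- runif(1, 0.01, 100)
    tab2 <- tab
    tab2$value[tab2$phenotype == "mu_max"] <-
      tab2$value[tab2$phenotype == "mu_max"] * c_scale
    r1 <- robustness_table(tab)
    r2 <- robustness_table(tab2)
    expect_equal(r1$R, r2$R, tolerance = 1e-12)
  }
})
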