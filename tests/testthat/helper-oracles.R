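# Independent oracles used across the suite.

# brute-force robustness recomputation from raw values: explicit loops,
# no shared code with robustness_table()
brute_force_robustness <- function(table, min_conditions = 2) {
  out <- list()
  for (p in unique(table$phenotype)) {
    vals_p <- table$value[table$phenotype == p & !is.na(table$value)]
    m <- mean(vals_p)
    for (s in unique(table$strain)) {
      r_reps <- c()
      n_c <- c()
      reps <- unique(table$replicate[table$strain == s &
                                       table$phenotype == p])
      for (r in reps) {
        v <- table$value[table$strain == s & table$phenotype == p &
                           table$replicate == r]
        v <- v[!is.na(v)]
        if (length(v) >= min_conditions && mean(v) > 0) {
          xbar <- sum(v) / length(v)
          s2 <- sum((v - xbar)^2) / (length(v) - 1)
          r_reps <- c(r_reps, -(s2 / xbar) / m)
          n_c <- c(n_c, length(v))
        }
      }
      if (length(r_reps) > 0) {
        out[[paste(s, p)]] <- data.frame(
          strain = s, phenotype = p,
          R = mean(r_reps),
          sem = if (length(r_reps) > 1) {
            sd(r_reps) / sqrt(length(r_reps))
          } else 0,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

# random small phenotype table for property tests
random_phenotype_table <- function(n_strains = 4, n_conditions = 6,
                                   n_replicates = 2,
                                   phenotypes = c("mu_max", "cdw")) {
  grid <- expand.grid(
    strain = sprintf("s%d", seq_len(n_strains)),
    condition = sprintf("c%d", seq_len(n_conditions)),
    replicate = seq_len(n_replicates),
    phenotype = phenotypes,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  tibble::tibble(
    strain = grid$strain,
    condition = grid$condition,
    group = sample(perturbation_groups(), nrow(grid), replace = TRUE),
    replicate = as.integer(grid$replicate),
    phenotype = grid$phenotype,
    value = stats::rlnorm(nrow(grid), meanlog = 0, sdlog = 0.5),
    units = unname(phenotype_units()[grid$phenotype]),
    qc_flags = ""
  )
}

# closed-form Zwietering-Gompertz ln-curve, written out independently
gompertz_oracle <- function(t, mu, lam, a_ln) {
  a_ln * exp(-exp((mu * exp(1) / a_ln) * (lam - t) + 1))
}

# tangent-intercept lag of the observed noiseless curve: the tangent at the
# inflection crosses the initial observed ln-level f(0) at lam + f(0)/mu
geometric_lag <- function(mu, lam, a_ln) {
  lam + gompertz_oracle(0, mu, lam, a_ln) / mu
}
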