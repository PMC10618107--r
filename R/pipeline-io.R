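# End-to-end orchestration and the CSV exchange format.
#
# All stage outputs are RFC 4180 CSV (UTF-8, LF, "." decimal separator) with a
# single leading comment line carrying the package version and a hash of the
# configuration, so every file is traceable to the run that wrote it.

#' Assemble and validate a pipeline configuration
#'
#' Exactly one of `simulation` or `inputs` must be provided. A simulation spec
#' describes a synthetic screen (strain/condition/replicate counts, noise, an
#' optional embedded trade-off and an optional simulated second cultivation);
#' an input spec points at a phenotype-table CSV in the package's dialect.
#'
#' @param simulation Optional list with elements `n_strains`, `n_conditions`,
#'   `n_replicates` (defaults 24, 29, 3), `noise_cv` (default 0.1), `tradeoff`
#'   (optional list with `phenotype` and `rho`), `transfer` (logical, default
#'   `TRUE`: simulate a second cultivation of mu_max) and `include_control`.
#' @param inputs Optional list with element `phenotypes` (path to a CSV
#'   readable by [read_phenotype_csv()]).
#' @param bounds Trimming bounds (default [default_trim_bounds()]).
#' @param out_dir Output directory (created if missing).
#' @param seed Root integer seed; all stage seeds are derived from it.
#' @param alpha Significance level for correlation labels.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL,
                            bounds = default_trim_bounds(),
                            out_dir = tempfile("robustpheno_run_"),
                            seed = 1, alpha = 0.05) {
  if (is.null(simulation) == is.null(inputs)) {
    abort("provide exactly one of `simulation` or `inputs`")
  }
  if (!is.null(simulation)) {
    defaults <- list(n_strains = 24, n_conditions = 29, n_replicates = 3,
                     noise_cv = 0.1, tradeoff = NULL, transfer = TRUE,
                     include_control = TRUE)
    unknown <- setdiff(names(simulation), names(defaults))
    if (length(unknown) > 0) {
      abort(paste0("unknown simulation field(s): ",
                   paste(unknown, collapse = ", ")))
    }
    simulation <- utils::modifyList(defaults, simulation)
  }
  if (!is.null(inputs)) {
    if (is.null(inputs$phenotypes)) {
      abort("`inputs` must name a `phenotypes` CSV path")
    }
    if (!file.exists(inputs$phenotypes)) {
      abort(paste0("input file not found: ", inputs$phenotypes))
    }
  }
  structure(
    list(simulation = simulation, inputs = inputs, bounds = bounds,
         out_dir = out_dir, seed = as.integer(seed), alpha = alpha),
    class = "pipeline_config"
  )
}

# internal: version + config-hash comment line for output files
output_comment <- function(config) {
  paste0("# robustpheno ",
         as.character(utils::packageVersion("robustpheno")),
         "; config_hash=", rlang::hash(config[c("simulation", "inputs",
                                                "seed", "alpha")]))
}

write_stage_csv <- function(x, path, comment) {
  readr::write_lines(comment, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE)
}

#' Read a phenotype table CSV
#'
#' The file must carry exactly the header
#' `strain,condition,group,replicate,phenotype,value,units,qc_flags` (leading
#' `#` comment lines are ignored). Unknown phenotype labels and duplicated key
#' tuples are rejected with the offending rows named (up to 10).
#'
#' @param path Path to the CSV.
#' @return A phenotype tibble.
#' @export
read_phenotype_csv <- function(path) {
  header_line <- readr::read_lines(path, n_max = 50)
  header_line <- header_line[!startsWith(header_line, "#")][1]
  header <- strsplit(header_line, ",", fixed = TRUE)[[1]]
  missing <- setdiff(.PHENO_COLS, header)
  if (length(missing) > 0) {
    abort(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (!identical(header, .PHENO_COLS)) {
    abort(paste0("header must be exactly: ", paste(.PHENO_COLS, collapse = ",")))
  }
  table <- readr::read_csv(
    path, comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      strain = readr::col_character(), condition = readr::col_character(),
      group = readr::col_character(), replicate = readr::col_integer(),
      phenotype = readr::col_character(), value = readr::col_double(),
      units = readr::col_character(), qc_flags = readr::col_character()
    )
  )
  bad <- which(!table$phenotype %in% .PHENOTYPES)
  if (length(bad) > 0) {
    abort(paste0(
      "unknown phenotype label(s) at row(s): ",
      paste(utils::head(bad, 10), collapse = ", ")
    ))
  }
  dup <- table %>%
    dplyr::count(.data$strain, .data$condition, .data$replicate,
                 .data$phenotype) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0(
      "duplicated key tuple(s): ",
      paste(utils::head(paste(dup$strain, dup$condition, dup$replicate,
                              dup$phenotype, sep = "/"), 10), collapse = "; ")
    ))
  }
  table$qc_flags[is.na(table$qc_flags)] <- ""
  table
}

#' Write a phenotype table CSV
#'
#' Writes the canonical 8-column dialect (UTF-8, LF, "." decimal separator),
#' optionally preceded by a version comment line. `read_phenotype_csv()`
#' round-trips the content exactly.
#'
#' @param table A phenotype table.
#' @param path Output path.
#' @param comment Optional comment line (written verbatim; pass `NULL` for a
#'   plain file).
#' @return `path`, invisibly.
#' @export
write_phenotype_csv <- function(table, path, comment = NULL) {
  assert_phenotype_table(table, need_flags = TRUE)
  table <- table[, .PHENO_COLS]
  if (is.null(comment)) {
    readr::write_csv(table, path, progress = FALSE)
  } else {
    write_stage_csv(table, path, comment)
  }
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate or ingest the phenotype table; QC (trim,
#' ethanol-yield exclusion, outlier flagging, normality check); robustness per
#' strain x phenotype; per-group influence ratios; performance-robustness
#' trade-offs, cross-phenotype correlations and group-vs-hexoses tests; and,
#' when second-cultivation data are simulated, the transfer analysis. Every
#' stage writes its table to `config$out_dir` and logs input/output counts.
#' The run is deterministic given the configuration seed.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return A `run_report` list: record counts at every stage, the QC report,
#'   skipped entries with reasons, package version, config echo and
#'   timestamps. Stage outputs are in `$tables`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config")
  }
  t_start <- Sys.time()
  log_msg <- function(...) if (!quiet) message("[robustpheno] ", ...)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  comment <- output_comment(config)
  counts <- list()
  skips <- list()

  # --- stage 1: simulate or ingest -------------------------------------
  transfer_second <- NULL
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    strains <- sprintf("strain_%02d", seq_len(sim$n_strains))
    conditions <- make_perturbation_space(
      sim$n_conditions, seed = derive_seed(config$seed, 11),
      include_control = isTRUE(sim$include_control)
    )
    if (!is.null(sim$tradeoff)) {
      spec <- tradeoff_spec(sim$tradeoff$phenotype, sim$tradeoff$rho,
                            seed = derive_seed(config$seed, 12))
      model <- embed_tradeoff(strains, spec, noise_cv = sim$noise_cv)
    } else {
      model <- default_effect_model(strains, nrow(conditions),
                                    noise_cv = sim$noise_cv,
                                    seed = derive_seed(config$seed, 12))
    }
    table <- simulate_phenotype_table(strains, conditions,
                                      sim$n_replicates, model)
    if (isTRUE(sim$transfer)) {
      # second cultivation: per-well improvement factor plus replicate noise
      mu1 <- table[table$phenotype == "mu_max", ]
      set.seed(derive_seed(config$seed, 13))
      well <- unique(mu1[, c("strain", "condition")])
      well$factor <- stats::runif(nrow(well), 0.9, 1.8)
      mu2 <- dplyr::left_join(mu1, well, by = c("strain", "condition"))
      mu2$value <- mu2$value * mu2$factor *
        stats::rlnorm(nrow(mu2), sdlog = 0.05)
      mu2$factor <- NULL
      transfer_second <- mu2
    }
  } else {
    table <- read_phenotype_csv(config$inputs$phenotypes)
    log_msg("ingested ", nrow(table), " records from ",
            config$inputs$phenotypes)
  }
  counts$input <- nrow(table)
  log_msg("stage phenotypes: ", nrow(table), " records")
  write_phenotype_csv(table, file.path(config$out_dir, "phenotypes_raw.csv"),
                      comment = comment)

  # --- stage 2: QC ------------------------------------------------------
  qc <- qc_phenotype_table(table, bounds = config$bounds)
  counts$qc_retained <- nrow(qc$table)
  log_msg("stage qc: ", counts$input, " -> ", counts$qc_retained,
          " (trimmed ", qc$report$n_trimmed,
          ", excluded ", qc$report$n_excluded,
          ", flagged ", qc$report$n_outliers_flagged, ")")
  write_phenotype_csv(qc$table, file.path(config$out_dir, "phenotypes_qc.csv"),
                      comment = comment)
  jsonlite::write_json(
    qc$report[c("n_input", "n_trimmed", "n_excluded", "n_retained",
                "n_outliers_flagged", "by_rule")],
    file.path(config$out_dir, "qc_report.json"),
    auto_unbox = TRUE, pretty = TRUE
  )

  # --- stage 3: robustness ---------------------------------------------
  rvals <- robustness_table(qc$table)
  n_missing <- sum(is.na(rvals$R))
  if (n_missing > 0) {
    skips$robustness <- rvals[is.na(rvals$R),
                              c("strain", "phenotype", "reason")]
    log_msg("stage robustness: ", n_missing, " strain x phenotype entries ",
            "skipped (insufficient data)")
  }
  counts$robustness <- sum(!is.na(rvals$R))
  log_msg("stage robustness: ", counts$robustness, " entries")
  write_stage_csv(rvals, file.path(config$out_dir, "robustness.csv"), comment)

  # --- stage 4: group influence ----------------------------------------
  infl <- group_influence(qc$table)
  counts$influence <- nrow(infl)
  log_msg("stage influence: ", nrow(infl), " ratios")
  write_stage_csv(infl, file.path(config$out_dir, "influence.csv"), comment)

  # --- stage 5: trade-offs ---------------------------------------------
  tradeoffs <- performance_robustness_tradeoffs(qc$table, rvals)
  cross <- cross_phenotype_correlations(qc$table)
  group_tests <- list()
  for (p in unique(qc$table$phenotype)) {
    for (g in setdiff(unique(stats::na.omit(qc$table$group)), "hexoses")) {
      res <- tryCatch(
        group_vs_reference_test(qc$table, p, g, alpha = config$alpha),
        error = function(e) NULL
      )
      if (!is.null(res)) group_tests[[paste(p, g)]] <- res
    }
  }
  group_tests <- dplyr::bind_rows(group_tests)
  counts$tradeoffs <- sum(!is.na(tradeoffs$spearman_r))
  log_msg("stage tradeoffs: ", counts$tradeoffs, " correlations")
  write_stage_csv(tradeoffs, file.path(config$out_dir, "tradeoffs.csv"),
                  comment)
  write_stage_csv(cross, file.path(config$out_dir, "cross_correlations.csv"),
                  comment)
  if (nrow(group_tests) > 0) {
    write_stage_csv(group_tests, file.path(config$out_dir, "group_tests.csv"),
                    comment)
  }

  # --- stage 6: transfer (optional) ------------------------------------
  transfer <- NULL
  if (!is.null(transfer_second)) {
    records <- transfer_records(table, transfer_second)
    records <- resolve_infinities(records)
    transfer <- transfer_summary(records)
    transfer$vs_robustness <- improvement_robustness_correlation(records, rvals)
    counts$transfer_records <- nrow(records)
    log_msg("stage transfer: ", nrow(records), " records, ",
            nrow(transfer$strains), " strains")
    write_stage_csv(records, file.path(config$out_dir, "transfer.csv"),
                    comment)
    write_stage_csv(transfer$strains,
                    file.path(config$out_dir, "transfer_summary_strains.csv"),
                    comment)
    write_stage_csv(transfer$groups,
                    file.path(config$out_dir, "transfer_summary_groups.csv"),
                    comment)
  }

  report <- structure(
    list(
      counts = counts,
      qc_report = qc$report,
      skips = skips,
      version = as.character(utils::packageVersion("robustpheno")),
      config = config,
      started = t_start,
      finished = Sys.time(),
      tables = list(
        phenotypes = table, phenotypes_qc = qc$table, robustness = rvals,
        influence = infl, tradeoffs = tradeoffs,
        cross_correlations = cross, group_tests = group_tests,
        transfer = transfer
      )
    ),
    class = "run_report"
  )
  jsonlite::write_json(
    list(counts = counts, version = report$version,
         started = format(t_start), finished = format(report$finished)),
    file.path(config$out_dir, "run_report.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  log_msg("done: outputs in ", config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<robustpheno run_report>\n")
  cat("  version:", x$version, "\n")
  for (n in names(x$counts)) cat("  ", n, ":", x$counts[[n]], "\n")
  invisible(x)
}
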