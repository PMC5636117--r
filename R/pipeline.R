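# End-to-end driver: QC -> forward search over several pattern sizes ->
# permutation test of the top candidates -> inverse analysis -> reports.

#' Pipeline configuration
#'
#' @param genotypes Path to a genotype table in the package TSV dialect, or
#'   `NULL` to simulate input with `sim`.
#' @param sim A [simulation_config()] used when `genotypes` is `NULL`.
#' @param r_values Pattern sizes to search; default `c(3, 4, 5)`.
#' @param prevalence Disease prevalence; default 0.0047.
#' @param maf_min,hwe_control_min,hwe_case_min QC thresholds; defaults 0.05,
#'   0.01, 1e-4.
#' @param min_carriers Minimum case carriers per candidate; default 8.
#' @param lower_mult,upper_mult Frequency-band multipliers; defaults 0.01, 0.2.
#' @param n_permutations,subsample_size Permutation settings; defaults 1000,
#'   1000 (capped at the case-cohort size).
#' @param run_inverse Run the label-swapped analysis too; default `TRUE`.
#' @param inverse_prevalence Healthy-phenotype prevalence; default 0.9953.
#' @param seed Integer seed governing simulation and permutation.
#' @param out_dir Output directory (created if absent).
#' @param allow_heavy Permit searches whose estimated work
#'   `choose(n, r) * (n_cases + n_controls)` exceeds `heavy_limit`.
#' @param heavy_limit Work guard; default 5e8.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(genotypes = NULL, sim = simulation_config(),
                            r_values = c(3L, 4L, 5L), prevalence = 0.0047,
                            maf_min = 0.05, hwe_control_min = 0.01,
                            hwe_case_min = 1e-4, min_carriers = 8L,
                            lower_mult = 0.01, upper_mult = 0.2,
                            n_permutations = 1000L, subsample_size = 1000L,
                            run_inverse = TRUE, inverse_prevalence = 0.9953,
                            seed = 1L, out_dir = tempfile("cgcp_run_"),
                            allow_heavy = FALSE, heavy_limit = 5e8) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the optional
#' `sim:` block mirrors [simulation_config()] (its `planted_patterns` as a
#' list of `{r, n_carriers}` maps).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) {
    if (!is.null(y$sim$planted_patterns))
      y$sim$planted_patterns <- lapply(y$sim$planted_patterns, function(pp)
        do.call(planted_pattern, pp))
    if (!is.null(y$sim$maf_range)) y$sim$maf_range <- as.numeric(y$sim$maf_range)
    y$sim <- do.call(simulation_config, y$sim)
  }
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Stages: input (read or simulate) -> QC filter -> per-r forward search
#' with candidate tables -> top candidate per r (maximum carrier count, ties
#' broken by rsID-lexicographic SNP tuple then genotype tuple) -> permutation
#' test of each top candidate -> inverse analysis per r -> manifest.
#'
#' Output files under `out_dir`: `qc_report.tsv`, `candidates_r{r}.tsv`,
#' `top_candidates.tsv`, `permutation_r{r}.tsv`, `inverse_r{r}.tsv`,
#' `manifest.json`.
#'
#' @param config A [pipeline_config()].
#' @return The run manifest, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(...) file.path(config$out_dir, paste0(...))
  manifest <- list(package_version = as.character(utils::packageVersion("cgcp")),
                   parameters = config[setdiff(names(config), c("sim", "genotypes"))],
                   stages = list())
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    res
  }

  data <- stage("input", {
    if (!is.null(config$genotypes)) {
      manifest$input <- list(kind = "file", path = config$genotypes,
                              sha = unname(tools::md5sum(config$genotypes)))
      read_genotype_table(config$genotypes)
    } else {
      sim <- config$sim
      sim$seed <- config$seed
      manifest$input <- list(kind = "simulated", n_snps = sim$n_snps,
                              n_cases = sim$n_cases, n_controls = sim$n_controls,
                              seed = config$seed)
      simulate_cohort(sim)
    }
  })

  qc <- stage("qc", {
    res <- qc_filter(data$snps, config$maf_min, config$hwe_control_min,
                     config$hwe_case_min)
    utils::write.table(res$report, outfile("qc_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    res
  })
  keep <- match(qc$pass$rsid, data$snps$rsid)
  cases <- data$cases[, keep, drop = FALSE]
  controls <- data$controls[, keep, drop = FALSE]
  attr(cases, "snps") <- qc$pass
  attr(controls, "snps") <- qc$pass
  manifest$qc <- list(n_snps_in = nrow(data$snps), n_snps_pass = nrow(qc$pass))

  model <- prevalence_model(config$prevalence, config$lower_mult, config$upper_mult)
  freqs <- genotype_frequencies(cases, controls)
  work <- function(r) choose(ncol(cases), r) * (nrow(cases) + nrow(controls))
  heavy <- config$r_values[vapply(config$r_values, work, numeric(1)) > config$heavy_limit]
  if (length(heavy) && !config$allow_heavy)
    stop("search at r = ", paste(heavy, collapse = ","),
         " exceeds the work guard (", config$heavy_limit,
         "); rerun with allow_heavy = TRUE")

  results <- list()
  tops <- list()
  for (r in config$r_values) {
    cand <- stage(paste0("search_r", r), {
      cfg <- search_config(r = r, min_carriers = config$min_carriers, model = model)
      out <- search_cgcp(cases, controls, cfg, freqs = freqs)
      write_candidate_table(out, r, outfile("candidates_r", r, ".tsv"))
      out
    })
    results[[as.character(r)]] <- cand
    manifest$search[[as.character(r)]] <- list(n_candidates = nrow(cand))
    if (nrow(cand)) tops[[as.character(r)]] <- cand[1L, , drop = FALSE]
  }

  top_df <- if (length(tops)) {
    data.frame(r = as.integer(names(tops)),
               rsids = vapply(tops, function(x) x$rsids, character(1)),
               genotype_string = vapply(tops, function(x) x$genotype, character(1)),
               n_case_carriers = vapply(tops, function(x) x$n_case_carriers, integer(1)),
               product_frequency = vapply(tops, function(x) x$product_frequency, numeric(1)),
               row.names = NULL)
  } else {
    data.frame(r = integer(), rsids = character(), genotype_string = character(),
               n_case_carriers = integer(), product_frequency = numeric())
  }
  utils::write.table(top_df, outfile("top_candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  for (r in names(tops)) {
    stage(paste0("permutation_r", r), {
      top <- tops[[r]]
      pat <- genotype_pattern(top$snp_index[[1L]], top$codes[[1L]])
      pc <- permutation_config(config$n_permutations,
                               min(config$subsample_size, nrow(cases)),
                               seed = config$seed + as.integer(r))
      counts <- permuted_carrier_counts(cases, pat, pc)
      utils::write.table(data.frame(replicate = seq_along(counts), count = counts),
                         outfile("permutation_r", r, ".tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      s <- distribution_summary(counts, observed = top$n_case_carriers)
      manifest$permutation[[r]] <- list(mean = s$mean, sd = s$sd,
                                         observed = s$observed,
                                         quantile = s$quantile,
                                         subsample_size = pc$subsample_size,
                                         seed = pc$seed)
    })
  }

  if (config$run_inverse) {
    for (r in config$r_values) {
      stage(paste0("inverse_r", r), {
        icfg <- inverse_config(r = r, prevalence = config$inverse_prevalence)
        inv <- inverse_search(cases, controls, icfg)
        write_candidate_table(inv, r, outfile("inverse_r", r, ".tsv"))
        manifest$inverse[[as.character(r)]] <-
          list(n_candidates = nrow(inv),
               max_carriers = if (nrow(inv)) max(inv$n_case_carriers) else 0L)
      })
    }
  }

  manifest$complete <- TRUE
  jsonlite::write_json(manifest, outfile("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
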