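# Seeded synthetic case-control genotype generator: Hardy-Weinberg background
# genotypes at sampled minor-allele frequencies, optional missingness, and
# planted case-exclusive genotype combination patterns with known carriers.

#' Specify a pattern to plant
#'
#' @param r Number of SNPs in the pattern.
#' @param n_carriers Number of case carriers to write the pattern into.
#' @param band Numeric pair: the absolute product-frequency interval the
#'   planted pattern's realized product frequency must fall in; `NULL`
#'   (default) means the forward acceptance band `(0.01 p, 0.2 p)` at the
#'   simulation's prevalence.
#' @return A list describing the request.
#' @export
planted_pattern <- function(r, n_carriers, band = NULL) {
  stopifnot(r >= 1L, n_carriers >= 1L,
            is.null(band) || (length(band) == 2L && band[1L] < band[2L]))
  list(r = as.integer(r), n_carriers = as.integer(n_carriers), band = band)
}

#' Simulation configuration
#'
#' Defaults give the quick fixture scale (20 SNPs, 500 + 500 samples); the
#' study-scale cohort shape is 51 SNPs, 8372 cases and 8510 controls (see
#' `n_snps`, `n_cases`, `n_controls`).
#'
#' @param n_snps Number of biallelic SNPs.
#' @param n_cases,n_controls Cohort sizes.
#' @param maf_range Interval the per-SNP minor allele frequency is drawn
#'   from, within `[0.05, 0.5]`.
#' @param missing_rate Per-call missingness probability, in `[0, 0.1]`.
#' @param planted_patterns List of [planted_pattern()] requests.
#' @param prevalence Disease prevalence used for planted-band defaults and
#'   truth bookkeeping; default 0.0047.
#' @param allow_overlap Allow planted patterns to share SNP columns
#'   (default `FALSE`).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_snps = 20L, n_cases = 500L, n_controls = 500L,
                              maf_range = c(0.05, 0.5), missing_rate = 0.005,
                              planted_patterns = list(), prevalence = 0.0047,
                              allow_overlap = FALSE, seed = NULL) {
  stopifnot(n_snps >= 1L, n_cases >= 1L, n_controls >= 1L,
            length(maf_range) == 2L, maf_range[1L] >= 0.05 - 1e-12,
            maf_range[2L] <= 0.5, maf_range[1L] <= maf_range[2L],
            missing_rate >= 0, missing_rate <= 0.1)
  for (pp in planted_patterns) {
    if (pp$n_carriers > n_cases)
      stop("planted n_carriers exceeds the number of cases")
    if (pp$r > n_snps) stop("planted pattern r exceeds n_snps")
  }
  if (!allow_overlap && length(planted_patterns) &&
      sum(vapply(planted_patterns, `[[`, integer(1), "r")) > n_snps)
    stop("planted SNP sets exceed n_snps; set allow_overlap = TRUE or reduce patterns")
  structure(list(n_snps = as.integer(n_snps), n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls), maf_range = maf_range,
                 missing_rate = missing_rate, planted_patterns = planted_patterns,
                 prevalence = prevalence, allow_overlap = allow_overlap,
                 seed = seed),
            class = "simulation_config")
}

#' Simulate a case-control genotype cohort
#'
#' Background genotypes are drawn independently per SNP from Hardy-Weinberg
#' proportions at a minor allele frequency sampled from `maf_range` (shared
#' by cases and controls; no association, no linkage disequilibrium). Any
#' requested patterns are then planted into randomly chosen cases (see
#' [plant_patterns()]); missingness is applied last, uniformly at random,
#' but never at a planted carrier's pattern SNPs.
#'
#' @param config A [simulation_config()].
#' @return A list with `cases` and `controls` (integer genotype matrices
#'   with the SNP table attached as attribute `"snps"`), `snps` (the per-SNP
#'   record data.frame) and `truth` (per planted pattern: rsIDs, column
#'   indices, genotype codes and string, planted carrier IDs, realized
#'   product frequency, and the total case-carrier count including
#'   coincidental carriers).
#' @export
simulate_cohort <- function(config) {
  with_seed(config$seed, {
    n_snp <- config$n_snps
    rsids <- sprintf("rs%04d", seq_len(n_snp))
    pairs <- t(vapply(seq_len(n_snp), function(i)
      sort(sample(c("A", "C", "G", "T"), 2L)), character(2)))
    maf <- stats::runif(n_snp, config$maf_range[1L], config$maf_range[2L])
    snps <- data.frame(rsid = rsids, allele_a = pairs[, 1L], allele_b = pairs[, 2L],
                       maf = maf, stringsAsFactors = FALSE)

    draw <- function(n, prefix) {
      m <- matrix(NA_integer_, nrow = n, ncol = n_snp,
                  dimnames = list(sprintf("%s%05d", prefix, seq_len(n)), rsids))
      for (j in seq_len(n_snp)) {
        q <- maf[j]   # allele_b is the minor allele
        m[, j] <- sample(0:2, n, replace = TRUE,
                         prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
      }
      m
    }
    cases <- draw(config$n_cases, "case_")
    controls <- draw(config$n_controls, "ctrl_")

    planted <- plant_patterns(cases, controls, config,
                              model = prevalence_model(p = config$prevalence))
    cases <- planted$cases; controls <- planted$controls

    # missingness, protecting planted carriers' pattern SNPs
    if (config$missing_rate > 0) {
      protect <- matrix(FALSE, nrow(cases), ncol(cases))
      for (tr in planted$truth)
        protect[match(tr$carriers, rownames(cases)), tr$snp_index] <- TRUE
      drop_case <- matrix(stats::runif(length(cases)) < config$missing_rate,
                          nrow(cases)) & !protect
      cases[drop_case] <- NA_integer_
      drop_ctrl <- matrix(stats::runif(length(controls)) < config$missing_rate,
                          nrow(controls))
      controls[drop_ctrl] <- NA_integer_
    }

    # refresh realized truth quantities on the final (post-missingness) matrices
    truth <- planted$truth
    if (length(truth)) {
      freqs <- genotype_frequencies(cases, controls)
      model <- prevalence_model(p = config$prevalence)
      for (k in seq_along(truth)) {
        pat <- genotype_pattern(truth[[k]]$snp_index, truth[[k]]$codes)
        truth[[k]]$product_frequency <- pattern_product_frequency(pat, freqs, model)
        truth[[k]]$n_case_carriers_total <- sum(pattern_carriers(cases, pat))
      }
    }

    snps_out <- snp_records(cases, controls, snps)
    attr(cases, "snps") <- snps_out
    attr(controls, "snps") <- snps_out
    list(cases = cases, controls = controls, snps = snps_out, truth = truth)
  })
}

#' Plant case-exclusive genotype patterns
#'
#' For each request, repeatedly proposes an r-SNP subset and a genotype tuple
#' whose product frequency (recomputed after planting) lies inside the
#' requested band, overwrites the genotypes of `n_carriers` randomly chosen
#' cases with the tuple, and rewrites any control that coincidentally carries
#' a planted tuple by flipping one of its pattern genotypes to a different
#' code, iterating until no control carries any planted tuple. A proposal
#' whose realized product frequency drifts outside the band (collision fixes
#' shift the control frequencies slightly) is rolled back and replaced.
#'
#' Consumes the current RNG stream; call under a seed (as [simulate_cohort()]
#' does) for reproducibility.
#'
#' @param cases,controls Background integer genotype matrices.
#' @param config A [simulation_config()] carrying `planted_patterns`.
#' @param model [prevalence_model()] used for the product-frequency bands.
#' @param max_attempts Proposals tried per pattern before giving up.
#' @param band_margin Relative margin the proposal band is shrunk by on both
#'   sides (default 0.05), so that later small frequency perturbations
#'   (collision fixes for subsequent patterns, missingness) cannot push a
#'   planted pattern outside its requested band.
#' @return A list with the modified `cases` and `controls` matrices and
#'   `truth`, the per-pattern ground-truth records.
#' @export
plant_patterns <- function(cases, controls, config, model = prevalence_model(),
                           max_attempts = 200L, band_margin = 0.05) {
  truth <- list()
  if (!length(config$planted_patterns))
    return(list(cases = cases, controls = controls, truth = truth))
  used_snps <- integer(0)
  used_carriers <- character(0)
  all_tuples <- list()   # planted tuples so far, for collision rescans

  for (k in seq_along(config$planted_patterns)) {
    req <- config$planted_patterns[[k]]
    band <- if (is.null(req$band)) c(model$lower_mult, model$upper_mult) * model$p else req$band
    band <- c(band[1L] * (1 + band_margin), band[2L] * (1 - band_margin))
    avail <- if (config$allow_overlap) seq_len(ncol(cases))
             else setdiff(seq_len(ncol(cases)), used_snps)
    if (length(avail) < req$r)
      stop("not enough unused SNPs to plant pattern ", k,
           "; set allow_overlap = TRUE")
    free_cases <- setdiff(rownames(cases), used_carriers)
    if (length(free_cases) < req$n_carriers)
      stop("not enough unused cases to plant pattern ", k)

    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      idx <- sort(sample(avail, req$r))
      # pre-screen genotype tuples by product frequency at current cohort freqs
      freqs <- genotype_frequencies(cases, controls)
      fmat <- population_frequency_matrix(freqs, model)
      grid <- as.matrix(expand.grid(rep(list(0:2), req$r)))
      pf <- apply(grid, 1L, function(codes)
        prod(fmat[cbind(codes + 1L, idx)]))
      ok <- which(pf > band[1L] & pf < band[2L])
      if (!length(ok)) next
      codes <- as.integer(grid[sample(ok, 1L), ])
      carriers <- sample(free_cases, req$n_carriers)

      cases_try <- cases; controls_try <- controls
      cases_try[match(carriers, rownames(cases_try)), idx] <-
        matrix(codes, nrow = req$n_carriers, ncol = req$r, byrow = TRUE)
      tuples_try <- c(all_tuples, list(list(snp_index = idx, codes = codes)))
      controls_try <- scrub_control_carriers(controls_try, tuples_try)
      if (is.null(controls_try)) next   # collision fixing did not converge

      # verify the realized product frequency after all edits
      pf_real <- pattern_product_frequency(
        genotype_pattern(idx, codes),
        genotype_frequencies(cases_try, controls_try), model)
      if (!(pf_real > band[1L] && pf_real < band[2L])) next

      cases <- cases_try; controls <- controls_try
      all_tuples <- tuples_try
      used_snps <- union(used_snps, idx)
      used_carriers <- c(used_carriers, carriers)
      n_total <- sum(pattern_carriers(cases, list(snp_index = idx, codes = codes)))
      truth[[k]] <- list(snp_index = idx, rsids = colnames(cases)[idx],
                         codes = codes, carriers = sort(carriers),
                         product_frequency = pf_real,
                         n_case_carriers_total = n_total)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("no genotype tuple achievable in the frequency band [",
           band[1L], ", ", band[2L], "] for pattern ", k,
           " after ", max_attempts, " proposals")
  }
  list(cases = cases, controls = controls, truth = truth)
}

# flip one genotype of every control that carries any planted tuple, looping
# until no control carries any of them; NULL if not converged
scrub_control_carriers <- function(controls, tuples, max_iter = 100L) {
  for (iter in seq_len(max_iter)) {
    dirty <- FALSE
    for (tp in tuples) {
      hit <- which(pattern_carriers(controls, tp))
      if (!length(hit)) next
      dirty <- TRUE
      for (i in hit) {
        j <- sample(seq_along(tp$snp_index), 1L)
        old <- tp$codes[j]
        controls[i, tp$snp_index[j]] <- sample(setdiff(0:2, old), 1L)
      }
    }
    if (!dirty) return(controls)
  }
  NULL
}
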