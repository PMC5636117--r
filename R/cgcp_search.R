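# Exhaustive search for case-exclusive r-SNP genotype combination patterns
# (CGCPs) with a prevalence-weighted product-frequency boundary filter.

#' Prevalence model for population-frequency weighting
#'
#' Bundles the disease prevalence p, the derived weighting constant
#' lambda = (1 - p)/p, and the multipliers defining the product-frequency
#' acceptance band (lower_mult * p, upper_mult * p). lambda arises from
#' rescaling the control cohort so that cases make up a fraction p of the
#' combined population, which turns the population frequency of a genotype
#' into the mixture (alpha + lambda * beta) / (1 + lambda).
#'
#' @param p Disease prevalence, in (0, 1). Default 0.0047 (4.7 per mille).
#' @param lower_mult,upper_mult Band multipliers applied to p; defaults 0.01
#'   and 0.2, i.e. a pattern is kept when its product frequency lies strictly
#'   between 0.01 p and 0.2 p (each affected individual is assumed to carry
#'   between 5 and 100 causal patterns).
#' @return An object of class `prevalence_model`.
#' @export
prevalence_model <- function(p = 0.0047, lower_mult = 0.01, upper_mult = 0.2) {
  stopifnot(is.numeric(p), length(p) == 1L, p > 0, p < 1,
            lower_mult > 0, lower_mult < upper_mult, upper_mult <= 1)
  structure(list(p = p, lambda = (1 - p) / p,
                 lower_mult = lower_mult, upper_mult = upper_mult),
            class = "prevalence_model")
}

#' Size of the pattern space
#'
#' Number of distinct r-SNP genotype combination patterns over n SNPs:
#' `3^r * choose(n, r)` (three genotypes per SNP, any r-subset of SNPs).
#' Computed by the exact binomial recurrence so every intermediate is an
#' integer; errors out rather than return a value above 2^53, where doubles
#' stop being exact.
#'
#' @param n Total number of SNPs.
#' @param r SNPs per pattern, `0 <= r <= n`.
#' @return The exact count as a numeric scalar.
#' @export
count_pattern_space <- function(n, r) {
  stopifnot(length(n) == 1L, length(r) == 1L, n == floor(n), r == floor(r), n >= 0)
  if (r < 0 || r > n) stop("r must satisfy 0 <= r <= n (got r = ", r, ", n = ", n, ")")
  limit <- 2^53
  acc <- 1
  for (k in seq_len(r)) {
    acc <- acc * (n - k + 1) / k      # C(n, k): integer at every step
    acc <- acc * 3                    # fold in the genotype factor
    if (acc > limit) stop("pattern space exceeds 2^53; count not exactly representable")
  }
  acc
}

#' Prevalence-weighted population frequency of a genotype
#'
#' Estimates the frequency of a genotype in the general population from its
#' case-cohort frequency alpha and control-cohort frequency beta:
#' `F = (alpha + lambda * beta) / (1 + lambda)` with `lambda = (1 - p)/p`.
#' Vectorized over alpha and beta.
#'
#' @param alpha Genotype frequency among cases, in `[0, 1]`.
#' @param beta Genotype frequency among controls, in `[0, 1]`.
#' @param model A [prevalence_model()].
#' @return Population frequency estimate(s) in `[0, 1]`.
#' @export
population_frequency <- function(alpha, beta, model) {
  if (any(alpha < 0 | alpha > 1, na.rm = TRUE) ||
      any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("alpha and beta must lie in [0, 1]")
  (alpha + model$lambda * beta) / (1 + model$lambda)
}

# 3 x n_SNP matrix of population frequencies for all genotypes
population_frequency_matrix <- function(freqs, model) {
  population_frequency(freqs$alpha, freqs$beta, model)
}

#' Construct a genotype pattern
#'
#' A pattern assigns one genotype code to each SNP of a strictly increasing
#' tuple of column indices (the canonical form used throughout the search).
#'
#' @param snp_index Strictly increasing integer vector of SNP column indices.
#' @param codes Integer vector of genotype codes (0/1/2), same length.
#' @return An object of class `genotype_pattern`.
#' @export
genotype_pattern <- function(snp_index, codes) {
  snp_index <- as.integer(snp_index); codes <- as.integer(codes)
  stopifnot(length(snp_index) >= 1L, length(snp_index) == length(codes),
            all(diff(snp_index) > 0L), all(codes %in% 0:2))
  structure(list(snp_index = snp_index, codes = codes), class = "genotype_pattern")
}

#' Product frequency of a pattern
#'
#' The pattern's estimated population frequency under the independence
#' approximation: the product over its SNPs of the prevalence-weighted
#' population frequency of the pattern's genotype at that SNP.
#'
#' @param pattern A [genotype_pattern()].
#' @param freqs A [genotype_frequencies()] object.
#' @param model A [prevalence_model()].
#' @return The product frequency, a fraction in `[0, 1]`.
#' @export
pattern_product_frequency <- function(pattern, freqs, model) {
  fmat <- population_frequency_matrix(freqs, model)
  prod(fmat[cbind(pattern$codes + 1L, pattern$snp_index)])
}

#' Search configuration
#'
#' @param r Number of SNPs per pattern (>= 1).
#' @param min_carriers Minimum number of case carriers for a candidate;
#'   default 8.
#' @param model A [prevalence_model()]; supplies the frequency band
#'   `(lower_mult * p, upper_mult * p)` unless `bounds` overrides it.
#' @param snp_subset Optional integer vector restricting the searched columns.
#' @param bounds Either `NULL` (band from `model`), `FALSE` (disable the
#'   frequency filter), or a numeric pair `c(lower, upper)` of absolute
#'   product-frequency bounds (both strict).
#' @return An object of class `search_config`.
#' @export
search_config <- function(r, min_carriers = 8L, model = prevalence_model(),
                          snp_subset = NULL, bounds = NULL) {
  stopifnot(r >= 1L, r == floor(r), min_carriers >= 1L)
  if (is.numeric(bounds)) {
    stopifnot(length(bounds) == 2L, bounds[1L] < bounds[2L])
  } else if (!is.null(bounds) && !identical(bounds, FALSE)) {
    stop("bounds must be NULL, FALSE, or a numeric pair")
  }
  structure(list(r = as.integer(r), min_carriers = as.integer(min_carriers),
                 model = model, snp_subset = snp_subset, bounds = bounds),
            class = "search_config")
}

config_bounds <- function(config) {
  if (identical(config$bounds, FALSE)) return(NULL)
  if (is.numeric(config$bounds)) return(config$bounds)
  m <- config$model
  c(m$lower_mult * m$p, m$upper_mult * m$p)
}

# base-3 encoding of the genotype tuple at the given columns; NA if any
# member call is missing
encode_tuples <- function(m, idx) {
  key <- m[, idx[1L]]
  for (j in idx[-1L]) key <- key * 3L + m[, j]
  key
}

decode_tuple <- function(key, r) {
  codes <- integer(r)
  for (j in r:1) { codes[j] <- key %% 3L; key <- key %/% 3L }
  codes
}

#' Observed genotype tuples at a SNP subset
#'
#' Records, for every sample with no missing call among the chosen SNPs, its
#' genotype tuple, and returns the map from tuple to carrier sample IDs.
#' Samples with a missing call at any of the SNPs contribute nothing.
#'
#' @param m Integer genotype matrix.
#' @param snp_index Integer vector of column indices.
#' @return A named list: names are the tuples rendered as `"c1,c2,..."`,
#'   values are character vectors of carrier sample IDs.
#' @export
enumerate_observed_patterns <- function(m, snp_index) {
  stopifnot(all(snp_index >= 1L), all(snp_index <= ncol(m)))
  key <- encode_tuples(m, snp_index)
  ok <- !is.na(key)
  ids <- rownames(m)[ok]
  split_keys <- split(ids, key[ok])
  names(split_keys) <- vapply(as.integer(names(split_keys)), function(k)
    paste(decode_tuple(k, length(snp_index)), collapse = ","), character(1))
  split_keys
}

empty_candidates <- function() {
  data.frame(rsids = character(), genotype = character(),
             n_case_carriers = integer(), product_frequency = numeric(),
             snp_index = I(list()), codes = I(list()), carriers = I(list()),
             stringsAsFactors = FALSE)
}

#' Exhaustive search for case-exclusive genotype combination patterns
#'
#' For every r-subset of SNP columns, collects the genotype tuples observed
#' in cases, eliminates every tuple observed in even a single control, and
#' retains the case-exclusive tuples carried by at least `min_carriers` cases
#' whose product frequency lies strictly inside the configured band. A case
#' or control with a missing call at any SNP of a subset neither carries nor
#' refutes a tuple there.
#'
#' Rather than materializing all `3^r * choose(n, r)` abstract patterns, the
#' search hashes the tuples actually observed per subset, which yields the
#' identical candidate set (see [brute_force_search()], the oracle used to
#' prove the equivalence in the test suite).
#'
#' @param cases,controls Integer genotype matrices (same SNP columns, QC'd).
#' @param config A [search_config()].
#' @param freqs Optional precomputed [genotype_frequencies()] (alpha from
#'   `cases`, beta from `controls`); computed if missing.
#' @return A data.frame of candidates sorted by descending carrier count,
#'   then rsID-lexicographic SNP tuple, then genotype tuple. Columns:
#'   `rsids` (comma-joined), `genotype` (rendered allele string when SNP
#'   allele metadata is attached, else code string), `n_case_carriers`,
#'   `product_frequency`, and list-columns `snp_index`, `codes`, `carriers`.
#' @export
search_cgcp <- function(cases, controls, config, freqs = NULL) {
  validate_search_input(cases, controls, config)
  if (is.null(freqs)) freqs <- genotype_frequencies(cases, controls)
  fmat <- population_frequency_matrix(freqs, config$model)
  bounds <- config_bounds(config)
  cols <- if (is.null(config$snp_subset)) seq_len(ncol(cases)) else as.integer(config$snp_subset)
  r <- config$r
  subsets <- utils::combn(cols, r)
  rows <- vector("list", 64L); nrows <- 0L
  for (s in seq_len(ncol(subsets))) {
    idx <- subsets[, s]
    ck <- encode_tuples(cases, idx)
    ok <- !is.na(ck)
    if (!any(ok)) next
    kk <- ck[ok]
    ctrl <- encode_tuples(controls, idx)
    ctrl <- unique(ctrl[!is.na(ctrl)])
    excl <- !(kk %in% ctrl)
    if (!any(excl)) next
    kx <- kk[excl]
    u <- sort(unique(kx))
    cnt <- tabulate(match(kx, u))
    keep <- cnt >= config$min_carriers
    if (!any(keep)) next
    ids <- rownames(cases)[ok][excl]
    for (t in which(keep)) {
      codes <- decode_tuple(u[t], r)
      pf <- prod(fmat[cbind(codes + 1L, idx)])
      if (!is.null(bounds) && !(pf > bounds[1L] && pf < bounds[2L])) next
      nrows <- nrows + 1L
      if (nrows > length(rows)) rows <- c(rows, vector("list", length(rows)))
      rows[[nrows]] <- list(idx = idx, codes = codes, pf = pf,
                            carriers = ids[kx == u[t]])
    }
  }
  build_candidate_frame(rows[seq_len(nrows)], cases)
}

validate_search_input <- function(cases, controls, config) {
  if (nrow(cases) == 0L || nrow(controls) == 0L)
    stop("both cohorts must be non-empty")
  if (ncol(cases) != ncol(controls))
    stop("case and control matrices must share the same SNP columns")
  n_avail <- if (is.null(config$snp_subset)) ncol(cases) else length(config$snp_subset)
  if (config$r > n_avail)
    stop("r (", config$r, ") exceeds the number of searchable SNPs (", n_avail, ")")
}

build_candidate_frame <- function(rows, cases) {
  if (length(rows) == 0L) return(empty_candidates())
  rsid_of <- colnames(cases)
  if (is.null(rsid_of)) rsid_of <- paste0("snp", seq_len(ncol(cases)))
  snps_meta <- attr(cases, "snps")
  render <- function(idx, codes) {
    if (!is.null(snps_meta)) {
      paste(vapply(seq_along(idx), function(i)
        genotype_code_string(codes[i], snps_meta$allele_a[idx[i]],
                             snps_meta$allele_b[idx[i]]), character(1)),
        collapse = "")
    } else paste(codes, collapse = "")
  }
  df <- data.frame(
    rsids = vapply(rows, function(x) paste(rsid_of[x$idx], collapse = ","), character(1)),
    genotype = vapply(rows, function(x) render(x$idx, x$codes), character(1)),
    n_case_carriers = vapply(rows, function(x) length(x$carriers), integer(1)),
    product_frequency = vapply(rows, function(x) x$pf, numeric(1)),
    stringsAsFactors = FALSE)
  df$snp_index <- I(lapply(rows, function(x) x$idx))
  df$codes <- I(lapply(rows, function(x) x$codes))
  df$carriers <- I(lapply(rows, function(x) sort(x$carriers)))
  gt_key <- vapply(rows, function(x) paste(x$codes, collapse = ","), character(1))
  ord <- order(-df$n_case_carriers, df$rsids, gt_key, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Brute-force pattern search (testing oracle)
#'
#' Literally enumerates every one of the `3^r * choose(n, r)` abstract
#' patterns, scans each sample for carriage, and applies the same
#' case-exclusivity, carrier-count and frequency-band filters as
#' [search_cgcp()]. Intended for small instances only; refuses to run when
#' the pattern space exceeds `guard`.
#'
#' @inheritParams search_cgcp
#' @param guard Maximum admissible pattern space (default 1e6).
#' @return Same shape as [search_cgcp()].
#' @export
brute_force_search <- function(cases, controls, config, freqs = NULL, guard = 1e6) {
  validate_search_input(cases, controls, config)
  cols <- if (is.null(config$snp_subset)) seq_len(ncol(cases)) else as.integer(config$snp_subset)
  space <- count_pattern_space(length(cols), config$r)
  if (space > guard)
    stop("pattern space ", space, " exceeds the brute-force guard of ", guard)
  if (is.null(freqs)) freqs <- genotype_frequencies(cases, controls)
  fmat <- population_frequency_matrix(freqs, config$model)
  bounds <- config_bounds(config)
  r <- config$r
  subsets <- utils::combn(cols, r)
  all_codes <- as.matrix(expand.grid(rep(list(0:2), r)))[, r:1, drop = FALSE]
  rows <- list(); nrows <- 0L
  carriers_of <- function(m, idx, codes) {
    hit <- rep(TRUE, nrow(m))
    for (i in seq_along(idx)) {
      x <- m[, idx[i]]
      hit <- hit & !is.na(x) & x == codes[i]
    }
    hit
  }
  for (s in seq_len(ncol(subsets))) {
    idx <- subsets[, s]
    for (g in seq_len(nrow(all_codes))) {
      codes <- as.integer(all_codes[g, ])
      if (any(carriers_of(controls, idx, codes))) next
      hits <- carriers_of(cases, idx, codes)
      if (sum(hits) < config$min_carriers) next
      pf <- prod(fmat[cbind(codes + 1L, idx)])
      if (!is.null(bounds) && !(pf > bounds[1L] && pf < bounds[2L])) next
      nrows <- nrows + 1L
      rows[[nrows]] <- list(idx = idx, codes = codes, pf = pf,
                            carriers = rownames(cases)[hits])
    }
  }
  build_candidate_frame(rows, cases)
}

#' Descriptive statistics of candidate product frequencies
#'
#' @param candidates Candidate data.frame from [search_cgcp()].
#' @return A one-row data.frame with `n`, `mean`, `sd`, `min`, `max` of the
#'   product frequencies; for an empty candidate list, `n = 0` and the
#'   statistics are `NA` (the empty-summary sentinel).
#' @export
summarize_frequency_distribution <- function(candidates) {
  f <- candidates$product_frequency
  if (length(f) == 0L)
    return(data.frame(n = 0L, mean = NA_real_, sd = NA_real_,
                      min = NA_real_, max = NA_real_))
  data.frame(n = length(f), mean = mean(f),
             sd = if (length(f) > 1L) stats::sd(f) else 0,
             min = min(f), max = max(f))
}

#' Write a candidate table as TSV
#'
#' One rsID column per SNP of the pattern, the concatenated genotype string,
#' the case-carrier count and the product frequency.
#'
#' @param candidates Candidate data.frame from [search_cgcp()].
#' @param r Pattern size (needed to lay out the rsID columns when the table
#'   is empty).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, r, path) {
  rs <- if (nrow(candidates)) {
    do.call(rbind, strsplit(candidates$rsids, ",", fixed = TRUE))
  } else matrix(character(), ncol = r)
  out <- data.frame(rs, stringsAsFactors = FALSE)
  names(out) <- paste0("rsid_", seq_len(r))
  out$genotype_string <- candidates$genotype
  out$n_case_carriers <- candidates$n_case_carriers
  out$product_frequency <- candidates$product_frequency
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
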