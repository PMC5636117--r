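# Subsampling permutation test: distribution of a pattern's carrier count
# across random case subsamples.

#' Permutation test configuration
#'
#' @param n_permutations Number of replicates (default 1000).
#' @param subsample_size Cases drawn per replicate, without replacement
#'   (default 1000).
#' @param seed Integer seed for reproducibility, or `NULL` to use the current
#'   RNG state.
#' @return An object of class `permutation_config`.
#' @export
permutation_config <- function(n_permutations = 1000L, subsample_size = 1000L,
                               seed = NULL) {
  stopifnot(n_permutations >= 1L, subsample_size >= 1L)
  structure(list(n_permutations = as.integer(n_permutations),
                 subsample_size = as.integer(subsample_size), seed = seed),
            class = "permutation_config")
}

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

# logical carrier indicator for one pattern over a genotype matrix
pattern_carriers <- function(m, pattern) {
  hit <- rep(TRUE, nrow(m))
  for (i in seq_along(pattern$snp_index)) {
    x <- m[, pattern$snp_index[i]]
    hit <- hit & !is.na(x) & x == pattern$codes[i]
  }
  hit
}

#' Carrier counts of a pattern across random case subsamples
#'
#' Each replicate draws `subsample_size` cases without replacement from the
#' full case cohort and counts how many of them carry the pattern. The
#' resulting counts follow the hypergeometric distribution with population
#' size the number of cases, success count the number of carriers, and draw
#' size the subsample size.
#'
#' @param cases Integer genotype matrix of the case cohort.
#' @param pattern A [genotype_pattern()].
#' @param config A [permutation_config()].
#' @return Integer vector of length `n_permutations`.
#' @export
permuted_carrier_counts <- function(cases, pattern, config) {
  if (config$subsample_size > nrow(cases))
    stop("subsample_size (", config$subsample_size,
         ") exceeds the number of cases (", nrow(cases), ")")
  carrier <- pattern_carriers(cases, pattern)
  n <- nrow(cases)
  with_seed(config$seed, {
    vapply(seq_len(config$n_permutations), function(i)
      sum(carrier[sample.int(n, config$subsample_size)]), integer(1))
  })
}

#' Summary of a permuted carrier-count distribution
#'
#' @param counts Integer vector of replicate carrier counts.
#' @param observed The observed carrier count to locate in the distribution.
#' @return A list with `histogram` (data.frame `count`, `n_replicates`),
#'   `mean`, `sd`, `observed`, and `quantile`, the empirical quantile of the
#'   observed count under the `<=`-rank convention
#'   (`mean(counts <= observed)`).
#' @export
distribution_summary <- function(counts, observed) {
  stopifnot(length(counts) >= 1L)
  tab <- table(counts)
  hist <- data.frame(count = as.integer(names(tab)),
                     n_replicates = as.integer(tab))
  list(histogram = hist, mean = mean(counts),
       sd = if (length(counts) > 1L) stats::sd(counts) else 0,
       observed = observed, quantile = mean(counts <= observed))
}
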