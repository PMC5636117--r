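# Shared fixture builders. All randomness is driven by explicit seeds so the
# suite is deterministic.

# small random cohort with independent uniform genotype codes (no structure)
random_cohort <- function(n_snps, n_cases, n_controls, missing_rate = 0,
                          seed = NULL) {
  build <- function() {
    rsids <- sprintf("rs%04d", seq_len(n_snps))
    draw <- function(n, prefix) {
      m <- matrix(sample(0:2, n * n_snps, replace = TRUE), nrow = n,
                  dimnames = list(sprintf("%s%04d", prefix, seq_len(n)), rsids))
      if (missing_rate > 0)
        m[matrix(runif(length(m)) < missing_rate, nrow = n)] <- NA_integer_
      m
    }
    list(cases = draw(n_cases, "case_"), controls = draw(n_controls, "ctrl_"))
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# genotype matrix from a plain integer matrix with default names
gt_matrix <- function(codes, prefix = "s") {
  m <- matrix(as.integer(codes), nrow = nrow(codes))
  dimnames(m) <- list(sprintf("%s%03d", prefix, seq_len(nrow(m))),
                      sprintf("rs%04d", seq_len(ncol(m))))
  m
}

# write a small genotype TSV from explicit genotype strings
write_fixture_tsv <- function(path, rsids, rows) {
  writeLines(c(paste(c("sample_id", "phenotype", rsids), collapse = "\t"),
               vapply(rows, paste, character(1), collapse = "\t")), path)
}

# chi-square goodness-of-fit p-value of permuted carrier counts against the
# exact hypergeometric pmf (population N, carriers K, draws n), pooling the
# tails so every bin has expected count >= 5
hyper_gof_pvalue <- function(counts, K, N, n) {
  support <- 0:min(n, K)
  pmf <- dhyper(support, K, N - K, n)
  expctd <- pmf * length(counts)
  core <- which(expctd >= 5)
  lo <- support[min(core)]; hi <- support[max(core)]
  probs <- c(sum(pmf[support <= lo]),
             pmf[support > lo & support < hi],
             sum(pmf[support >= hi]))
  grp <- pmin(pmax(counts, lo), hi)
  obs <- tabulate(grp - lo + 1L, nbins = hi - lo + 1L)
  stopifnot(length(obs) == length(probs))
  chi2 <- sum((obs - length(counts) * probs)^2 / (length(counts) * probs))
  pchisq(chi2, df = length(probs) - 1, lower.tail = FALSE)
}

# strip carrier identities down to a comparable candidate signature
candidate_signature <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  paste(df$rsids, df$genotype,
        df$n_case_carriers, signif(df$product_frequency, 12), sep = "|")
}
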