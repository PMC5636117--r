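# Label-swapped ("inverse") search: healthy individuals are treated as the
# patient cohort with prevalence 1 - p_disease, and the frequency band is
# applied as absolute bounds because the swapped prevalence is close to 1.

#' Configuration for the inverse (label-swapped) search
#'
#' @param r Number of SNPs per pattern.
#' @param prevalence Prevalence of the "healthy patient" phenotype; default
#'   0.9953 (one minus the 4.7 per mille disease prevalence).
#' @param lower,upper Absolute product-frequency bounds; defaults 0.01 and
#'   0.2. With prevalence near 1 these agree with the forward
#'   parameterization's `lower_mult * p` and `upper_mult * p` to within half
#'   a percent.
#' @param min_carriers Minimum number of carriers in the healthy cohort;
#'   default 1 (no carrier cut).
#' @param snp_subset Optional restriction of searched columns.
#' @return A [search_config()] with the swapped prevalence model and
#'   absolute bounds.
#' @export
inverse_config <- function(r, prevalence = 0.9953, lower = 0.01, upper = 0.2,
                           min_carriers = 1L, snp_subset = NULL) {
  stopifnot(prevalence > 0.5, prevalence < 1)
  model <- prevalence_model(p = prevalence,
                            lower_mult = lower / prevalence,
                            upper_mult = upper / prevalence)
  search_config(r = r, min_carriers = min_carriers, model = model,
                snp_subset = snp_subset, bounds = c(lower, upper))
}

#' Inverse genotype combination search
#'
#' Runs the forward engine with the cohort roles swapped: genotype tuples
#' observed among healthy controls are kept only if absent from every case,
#' the mixture weights take alpha from the controls and beta from the cases,
#' and the prevalence model is that of the healthy phenotype. The output is
#' a candidate table over the control cohort (its `carriers` are control
#' sample IDs).
#'
#' @param cases,controls Integer genotype matrices (same SNP columns).
#' @param config An [inverse_config()].
#' @return Same shape as [search_cgcp()].
#' @export
inverse_search <- function(cases, controls, config) {
  search_cgcp(controls, cases, config)
}

#' Per-r frequency summary of candidate sets
#'
#' @param results Named list of candidate data.frames, one per pattern size;
#'   names are the r values.
#' @return A data.frame with one row per r: `r`, `n_candidates`, `mean`,
#'   `min`, `max` product frequency. On cohorts where every level is
#'   non-empty the mean is non-increasing in r, since each additional SNP
#'   multiplies the product by a frequency below one.
#' @export
frequency_by_r_report <- function(results) {
  stopifnot(length(results) >= 1L, !is.null(names(results)))
  out <- do.call(rbind, lapply(names(results), function(r) {
    s <- summarize_frequency_distribution(results[[r]])
    data.frame(r = as.integer(r), n_candidates = s$n,
               mean = s$mean, min = s$min, max = s$max)
  }))
  out[order(out$r), , drop = FALSE]
}
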