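# cgcp — exhaustive case-exclusive genotype combination search

`cgcp` mines case-control SNP genotype data for **causal genotype combination
patterns (CGCPs)**: assignments of one genotype (AA/AB/BB) to each SNP of an
r-SNP subset that are carried by at least a minimum number of cases and by
**zero** controls, and whose estimated population frequency is compatible with
the disease prevalence. The approach treats a complex disease the way a
Mendelian disease treats its causal genotype — looking for multi-locus genotype
states that co-segregate perfectly with the affected phenotype in a large
case-control cohort — and is aimed at statistical geneticists exploring
deterministic multi-locus models on panels of a few dozen susceptibility SNPs.

## The model

With `n` qualified SNPs and patterns of `r` SNPs, the search space holds

```
3^r * C(n, r)
```

patterns (three genotypes per SNP, any r-subset of SNPs). For a genotype `g_i`
of SNP `i` with frequency `alpha_i` among cases and `beta_i` among controls,
its frequency in the general population is estimated by the prevalence-weighted
mixture

```
F(g_i) = (alpha_i + lambda * beta_i) / (1 + lambda),    lambda = (1 - p) / p
```

where `p` is the disease prevalence (default 4.7 per mille, appropriate for
psoriasis in a Chinese population). A pattern's population frequency is
approximated by the product `prod_i F(g_i)` over its SNPs, and a candidate is
retained when

```
0.01 * P  <  prod_i F(g_i)  <  0.2 * P        (P = p)
```

i.e. assuming each affected individual carries on the order of 5-100 causal
patterns. Upstream, SNPs must pass MAF > 0.05 in both cohorts, Hardy-Weinberg
equilibrium p > 0.01 in controls and p > 1e-4 in cases (1-df chi-square test).
The package also provides the subsampling permutation test (carrier counts of a
candidate across random 1000-case subsamples) and the inverse, label-swapped
analysis (healthy individuals as "patients", prevalence 0.9953, absolute
frequency band 0.01-0.2).

## Worked example

```r
library(cgcp)

# synthetic cohort: 20 SNPs in HWE, 2000 cases + 2000 controls, one planted
# case-exclusive 3-SNP pattern with 16 carriers inside the frequency band
sim <- simulate_cohort(simulation_config(
  n_snps = 20, n_cases = 2000, n_controls = 2000,
  planted_patterns = list(planted_pattern(3, 16)), seed = 7))

qc <- qc_filter(sim$snps)                      # MAF + HWE filters
keep <- match(qc$pass$rsid, sim$snps$rsid)
cases <- sim$cases[, keep]; controls <- sim$controls[, keep]
attr(cases, "snps") <- qc$pass; attr(controls, "snps") <- qc$pass

res <- search_cgcp(cases, controls, search_config(r = 3, min_carriers = 8))
head(res[, c("rsids", "genotype", "n_case_carriers", "product_frequency")], 5)
#>                  rsids genotype n_case_carriers product_frequency
#> 1 rs0007,rs0008,rs0013   GGGGTT              17      0.0003253641
#> 2 rs0008,rs0010,rs0013   GGGGTT              16      0.0006763840
#> 3 rs0008,rs0009,rs0013   GGCCTT              15      0.0006877189
#> 4 rs0002,rs0008,rs0013   GTGGTT              11      0.0004612818
#> 5 rs0006,rs0008,rs0013   CTGGTT              11      0.0004133700
```

The top row is the planted pattern (`rs0007,rs0008,rs0013`, genotype string
`GGGGTT`): its 16 planted carriers plus one coincidental case carrier, zero
control carriers, and a product frequency of 3.3e-4 — inside the band
(4.7e-5, 9.4e-4). A permutation test of its carrier count across 1000 random
subsamples of 1000 cases:

```r
top <- res[1, ]
pat <- genotype_pattern(top$snp_index[[1]], top$codes[[1]])
counts <- permuted_carrier_counts(cases, pat,
                                  permutation_config(1000, 1000, seed = 8))
distribution_summary(counts, observed = top$n_case_carriers)[c("mean", "sd", "observed")]
#> $mean   [1] 8.452
#> $sd     [1] 2.025
#> $observed [1] 17
```

The mean of ~8.5 carriers per 1000-case subsample matches the hypergeometric
expectation `17 * 1000 / 2000 = 8.5`.

## Genotype TSV dialect

Header `sample_id<TAB>phenotype<TAB><rsid1><TAB>...`; one row per sample;
`phenotype` is `case` or `control`; genotypes are two-character allele strings
(`CG` == `GC`); `NN`, `--` or an empty field mean missing. A minimal biallelic
VCF reader (`dialect = "vcf"` plus a sample sheet) is available when `vcfR` is
installed.

## Command line

A thin wrapper over the package functions ships in `inst/scripts/cgcp`:

```sh
Rscript inst/scripts/cgcp simulate --n-snps 20 --n-cases 500 --n-controls 500 --seed 1 --out cohort.tsv
Rscript inst/scripts/cgcp search   --genotypes cohort.tsv --r 3 --prevalence 0.0047 --min-carriers 8 --out out/
Rscript inst/scripts/cgcp permute  --genotypes cohort.tsv --pattern "rs0001:CC,rs0002:AG" --seed 1 --out out/
Rscript inst/scripts/cgcp inverse  --genotypes cohort.tsv --r 3 --out out/
Rscript inst/scripts/cgcp run      --config pipeline.yaml
```

`run_pipeline()` drives QC, per-r searches, top-candidate selection,
permutation and inverse analysis from one (YAML-configurable) object and
writes `qc_report.tsv`, `candidates_r{r}.tsv`, `top_candidates.tsv`,
`permutation_r{r}.tsv`, `inverse_r{r}.tsv` and `manifest.json`.

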