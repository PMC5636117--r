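---
title: "Methods: exhaustive case-exclusive genotype combination search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exhaustive case-exclusive genotype combination search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgcp)
```

## The model and its assumptions

Complex-disease association studies usually compare single-SNP allele
frequencies between cases and controls; any individual variant is shared by
many healthy carriers. `cgcp` asks a different, deterministic question,
borrowed from the Mendelian setting: is there a *combination* of genotypes at
several SNPs that appears in affected individuals and in no unaffected one?

Formally, a pattern assigns one of the three genotypes (AA, AB, BB) to each
SNP in an r-subset of the n qualified SNPs, so the space of patterns has size
$3^r \binom{n}{r}$. A pattern is a candidate when

1. at least `min_carriers` cases carry it at all r SNPs,
2. **no** control carries it (a single control occurrence eliminates it), and
3. its estimated population frequency is compatible with the disease
   prevalence (below).

The population frequency of a genotype $g_i$ is estimated from its case
frequency $\alpha_i$ and control frequency $\beta_i$ by rescaling the control
cohort so cases make up exactly the prevalence $p$ of the combined
population. If there are $m$ cases and the controls are magnified $x$-fold to
$nx$ individuals with $m/(m+nx) = p$, the mixture weight reduces to
$\lambda = (1-p)/p$, independent of the cohort sizes, giving

$$F(g_i) = \frac{\alpha_i + \lambda \beta_i}{1 + \lambda}.$$

A pattern's population frequency is approximated by the product
$\prod_{i=1}^{r} F(g_i)$, i.e. under *independence of the member SNPs*. The
acceptance band

$$0.01\,P < \prod_i F(g_i) < 0.2\,P$$

encodes the assumption that an affected individual carries on the order of 5
to 100 causal patterns, so a single pattern accounts for between 1% and 20%
of the prevalence $P$. The upper bound also implies the weaker preliminary
condition that a candidate's frequency is below the prevalence itself, which
the search therefore does not apply separately.

Key modelling assumptions, then: deterministic causality (zero control
carriage, not low control frequency); independence across the pattern's SNPs
when converting per-genotype frequencies into a pattern frequency; and a
known external prevalence.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `p` (prevalence) | 0.0047 | population fraction affected; 4.7 per mille is the psoriasis prevalence the default targets |
| `lower_mult`, `upper_mult` | 0.01, 0.2 | band multipliers on `p`; see above |
| `min_carriers` | 8 | minimum case carriers for a candidate |
| `maf_min` | 0.05 | minor-allele-frequency floor, both cohorts |
| `hwe_control_min` | 0.01 | HWE p-value floor in controls |
| `hwe_case_min` | 1e-4 | HWE p-value floor in cases — deliberately lenient, since true disease association distorts case genotype proportions |
| `n_permutations`, `subsample_size` | 1000, 1000 | permutation test replicates and cases per replicate |
| inverse `prevalence` | 0.9953 | 1 − 0.0047, the "healthy patient" prevalence |
| inverse bounds | 0.01, 0.2 | absolute, since with prevalence ≈ 1 the multiplicative and absolute forms coincide to < 0.5% |

`min_carriers = 8` is stated for three-SNP patterns; whether the same cut
applies at r = 4, 5 is not specified anywhere we know of, so the package
keeps it a single knob applied at every r rather than hard-coding per-r
rules. Similarly the inverse analysis specifies no carrier cut, so its
default is `min_carriers = 1`.

## The search algorithm

Enumerating all $3^r \binom{n}{r}$ abstract patterns and testing every sample
against each is wasteful: per SNP subset, only tuples actually observed in a
case can ever become candidates. `search_cgcp()` therefore, per r-subset,
base-3-encodes each sample's genotype tuple, removes every tuple observed in
any control by a hash lookup, and tabulates carriers of the survivors —
$O\!\left(\binom{n}{r}(m_\text{case}+m_\text{control})\right)$ instead of
$O\!\left(3^r\binom{n}{r} \cdot \text{samples}\right)$. `brute_force_search()`
implements the literal enumeration (guarded to small instances) and the test
suite proves the two return identical candidate sets on randomized fixtures;
this dual-route check is the package's core correctness argument.

Numerical and procedural choices:

* **Exact counting.** `count_pattern_space()` uses the exact binomial
  recurrence (every intermediate is an integer) and refuses to return values
  above $2^{53}$, where doubles lose exactness. Floating point is used only
  for frequencies.
* **Missing calls.** A sample with a missing call at any SNP of a subset
  neither carries nor refutes a tuple there: only affirmative observations
  count, for exclusivity as well as carriage. Frequencies use non-missing
  denominators.
* **HWE test.** 1-df chi-square goodness-of-fit against expectations from the
  estimated allele frequency; monomorphic SNPs get p = 1 by convention (they
  cannot depart from HWE, and the MAF filter removes them anyway). An exact
  test would differ only at small counts, below the cohort sizes this
  package targets.
* **Ordering and ties.** Output is sorted by descending carrier count, then
  rsID-lexicographic SNP tuple, then genotype tuple — a total order, so
  results are byte-identical across runs and independent of any internal
  chunking. "Top" candidates are defined by this order.
* **Genotype coding.** Code 0/2 are the homozygotes of the alphabetically
  first/second allele; heterozygotes are order-normalized on input (`GC` ≡
  `CG`). Display strings render homozygotes doubled and heterozygotes in
  allele_a+allele_b order.

## Permutation test

The test subsamples `subsample_size` cases *without replacement* from the
case cohort (the phrase "1000 cases" is read as 1000 distinct individuals)
and counts pattern carriers per replicate, so the counts are exactly
hypergeometric with population size the case-cohort size, success count the
number of carriers, and draw size the subsample size — the suite verifies
this against the closed-form pmf by a chi-square goodness-of-fit at
α = 0.001 on 10,000 replicates. Note this is a *subsampling stability check
within cases*, not a case/control label permutation: it characterizes how
often the pattern would be seen in a 1000-case study, and its expectation is
simply `carriers × subsample/cases`. Interpretation beyond that is left to
the user.

## Inverse analysis

`inverse_search()` is a thin parameterization of the forward engine with the
cohort roles swapped: α from controls, β from cases, exclusivity against
cases, prevalence 0.9953, absolute band 0.01–0.2. The frequency measure is
the same product $\prod F(g_i)$ as in the forward direction (the "same
criteria" reading); a raw joint-frequency variant would be a different
statistic and is not implemented. Because the engine is shared, the test
suite asserts `inverse_search(a, b, cfg)` ≡ `search_cgcp(b, a, swapped cfg)`
on random fixtures.

## The synthetic generator

`simulate_cohort()` produces what the analysis assumes about its input:
biallelic SNPs with minor allele frequency drawn from `maf_range`
(default [0.05, 0.5]), genotypes sampled per SNP from Hardy-Weinberg
proportions $q^2, 2q(1-q), (1-q)^2$, identical distributions in cases and
controls (no marginal association), optional uniform missingness (default
0.5%, a typical array-genotyping rate), and planted case-exclusive patterns.
The quick fixture scale is 20 SNPs and 500 + 500 samples; the study-scale
shape is 51 SNPs, 8372 cases and 8510 controls.

Planting overwrites the genotypes of randomly chosen cases with a tuple
whose product frequency falls in the requested band, then flips one genotype
of any control that coincidentally carries a planted tuple (minimal edit),
iterating until no control carries any planted tuple — exact case-exclusivity
is guaranteed by construction, which the CGCP definition requires. Proposals
are screened against a band shrunk by 5% on both sides so that later
perturbations (collision flips, missingness) cannot push the realized
frequency outside the requested band; the realized frequency is re-measured
on the final matrices and stored in the truth record. Planting slightly
perturbs HWE and case frequencies at the planted SNPs; with tens of carriers
in cohorts of hundreds the perturbation can trip the case HWE filter, which
is why pipeline-level fixtures use cohorts of 1000+ — at study scale (16
carriers in 8372 cases) the perturbation is negligible.

What the generator does **not** emulate: linkage disequilibrium between
SNPs, population structure, genotyping batch effects, and probabilistic
penetrance. The absence of LD matters for interpreting results: with
independent SNPs the product $\prod F(g_i)$ is also (approximately) the joint
carrier frequency, so an inverse-analysis candidate — product frequency above
0.01 yet absent from every case — is essentially impossible in simulated
cohorts of thousands, and the package's synthetic inverse runs typically
return zero candidates. In real panels of susceptibility SNPs, LD and
structure make the product overestimate the joint frequency, which is what
lets label-swapped candidates through. Passing tests on synthetic data
therefore validate the machinery (filters, exclusivity, determinism,
distributional correctness), not the biological yield on real genotypes.

## Problem sizes in the test suite

The suite runs the oracle-equivalence check on 50 random fixtures of up to
10 SNPs and 100 + 100 samples at r ≤ 3; planted-recovery on 20 cohorts of
20 SNPs and 500 + 500 samples with three planted 3-SNP patterns each
(10–20 carriers); the permutation law on 10,000 replicates over a
study-shaped 8372-case cohort; and the monotone-frequency property on an
18-SNP fixture searched at r = 3, 4, 5. That last fixture plants its three
3-SNP patterns in the upper part of the band (0.1 P – 0.2 P) with 20
carriers each, by design: every extension of a case-exclusive pattern by an
extra SNP is itself case-exclusive with a strictly smaller product
frequency, so planting high leaves the r = 4 and r = 5 extensions above the
0.01 P lower bound and with enough of the 20 carriers to pass
`min_carriers = 8`, guaranteeing non-empty candidate sets at every level
without further tuning.

## Known limitations

* The exhaustive search is exponential-ish in r; r = 5 over ~50 SNPs with
  study-sized cohorts is hours of single-threaded work. `run_pipeline()`
  refuses such configurations unless `allow_heavy = TRUE`.
* No multiple-testing control is applied across candidates (the method
  defines candidacy by exclusivity and the frequency band, not by per-pattern
  p-values).
* Case-exclusivity is brittle to genotyping error: a single miscalled
  control can delete a true pattern, and the package takes calls at face
  value.
* SNPs are identified by rsID only — no coordinates, strand, or X/Y
  handling.
* The qualified-SNP count of a real panel depends on the QC thresholds; the
  pipeline reports whatever its filters yield rather than a fixed number.
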