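# Genotype calls are stored as an integer matrix (samples x SNPs):
#   0 = homozygous allele_a, 1 = heterozygous, 2 = homozygous allele_b, NA = missing.
# allele_a is the alphabetically first allele of the pair, so a heterozygote is
# coded identically whether the input text reads "TC" or "CT".

GT_MISSING <- c("NN", "--", "", "..", "00")

#' Read a case-control genotype table
#'
#' Reads the package's genotype TSV dialect (or a minimal biallelic VCF) into
#' one integer genotype matrix per cohort plus a per-SNP record table.
#'
#' The TSV dialect has a header line
#' `sample_id<TAB>phenotype<TAB><rsid1><TAB>...` followed by one row per
#' sample. `phenotype` is `case` or `control`; genotypes are two-character
#' allele strings (e.g. `CG`, order irrelevant); `NN`, `--` or an empty field
#' mean missing. Alleles are taken from the observed genotype characters
#' (at most two per SNP), with `allele_a` the alphabetically first.
#'
#' @param path Path to the genotype file.
#' @param dialect `"tsv"` (default) or `"vcf"`. The VCF reader needs the
#'   `vcfR` package and a `sample_sheet` mapping samples to phenotypes.
#' @param sample_sheet For `dialect = "vcf"`: path to a two-column TSV
#'   (`sample_id`, `phenotype`) assigning each VCF sample to a cohort.
#' @return A list with elements `cases` and `controls` (integer genotype
#'   matrices with sample IDs as rownames and rsIDs as colnames) and `snps`,
#'   a data.frame of per-SNP records (see [snp_records()]).
#' @export
read_genotype_table <- function(path, dialect = c("tsv", "vcf"), sample_sheet = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (dialect == "vcf") return(read_genotype_vcf(path, sample_sheet))

  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("genotype table needs a header and at least one sample row")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 3L || header[1L] != "sample_id" || header[2L] != "phenotype")
    stop("header must start with 'sample_id<TAB>phenotype' followed by rsIDs")
  rsids <- header[-(1:2)]
  if (anyDuplicated(rsids)) stop("duplicated rsIDs in header")

  n_snp <- length(rsids)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != n_snp + 2L)
  if (length(bad))
    stop("malformed row at line ", bad[1L] + 1L, ": expected ",
         n_snp + 2L, " fields, got ", length(rows[[bad[1L]]]))

  tab <- do.call(rbind, rows)
  sample_ids <- tab[, 1L]
  if (anyDuplicated(sample_ids)) stop("duplicated sample IDs")
  phen <- tab[, 2L]
  if (!all(phen %in% c("case", "control")))
    stop("phenotype must be 'case' or 'control'; offending sample: ",
         sample_ids[which(!phen %in% c("case", "control"))[1L]])
  gts <- tab[, -(1:2), drop = FALSE]
  gts[gts %in% GT_MISSING] <- NA_character_

  # infer the allele pair per SNP from the observed characters
  allele_a <- allele_b <- character(n_snp)
  calls <- matrix(NA_integer_, nrow = length(sample_ids), ncol = n_snp,
                  dimnames = list(sample_ids, rsids))
  for (j in seq_len(n_snp)) {
    g <- gts[, j]
    obs <- g[!is.na(g)]
    if (length(obs) && any(nchar(obs) != 2L))
      stop("SNP ", rsids[j], ": genotype strings must be two characters")
    al <- sort(unique(unlist(strsplit(obs, "", fixed = TRUE))))
    if (length(al) > 2L)
      stop("SNP ", rsids[j], ": more than two alleles observed (",
           paste(al, collapse = ","), ")")
    if (length(al) && !all(al %in% c("A", "C", "G", "T")))
      stop("SNP ", rsids[j], ": allele not in {A,C,G,T}: ",
           paste(setdiff(al, c("A", "C", "G", "T")), collapse = ","))
    allele_a[j] <- if (length(al) >= 1L) al[1L] else NA_character_
    allele_b[j] <- if (length(al) == 2L) al[2L] else NA_character_
    calls[, j] <- encode_genotype_strings(g, allele_a[j], allele_b[j],
                                          rsids[j], sample_ids)
  }

  cases <- calls[phen == "case", , drop = FALSE]
  controls <- calls[phen == "control", , drop = FALSE]
  snps <- data.frame(rsid = rsids, allele_a = allele_a, allele_b = allele_b,
                     stringsAsFactors = FALSE)
  list(cases = cases, controls = controls,
       snps = snp_records(cases, controls, snps))
}

# map two-character allele strings to codes 0/1/2 for one SNP
encode_genotype_strings <- function(g, a, b, rsid, sample_ids) {
  out <- rep(NA_integer_, length(g))
  ok <- !is.na(g)
  if (!any(ok)) return(out)
  c1 <- substr(g[ok], 1L, 1L)
  c2 <- substr(g[ok], 2L, 2L)
  known <- c(a, b)
  bad <- !(c1 %in% known) | !(c2 %in% known)
  if (any(bad))
    stop("SNP ", rsid, ", sample ", sample_ids[ok][which(bad)[1L]],
         ": genotype contains an allele outside {", a, ",", b, "}")
  code <- (c1 == b) + (c2 == b)   # heterozygote order-normalized by counting
  out[ok] <- as.integer(code)
  out
}

read_genotype_vcf <- function(path, sample_sheet) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  if (is.null(sample_sheet))
    stop("dialect 'vcf' requires a sample_sheet mapping sample_id to phenotype")
  sheet <- utils::read.table(sample_sheet, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  if (!all(c("sample_id", "phenotype") %in% names(sheet)))
    stop("sample sheet must have columns sample_id and phenotype")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  if (any(nchar(ref) != 1L | nchar(alt) != 1L | grepl(",", alt, fixed = TRUE)))
    stop("only biallelic SNP records are supported")
  rsids <- fix[, "ID"]
  gt <- vcfR::extract.gt(v, element = "GT")
  # dosage of ALT allele; phased or unphased separators both accepted
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), rsids))
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  for (i in seq_len(nrow(gt))) dos[, i] <- unname(map[gt[i, ]])
  # orient codes so code 0 is the alphabetically first allele
  allele_a <- pmin(ref, alt); allele_b <- pmax(ref, alt)
  flip <- ref != allele_a
  dos[, flip] <- 2L - dos[, flip, drop = FALSE]
  idx <- match(rownames(dos), sheet$sample_id)
  if (anyNA(idx)) stop("VCF sample missing from sample sheet: ",
                       rownames(dos)[which(is.na(idx))[1L]])
  phen <- sheet$phenotype[idx]
  snps <- data.frame(rsid = rsids, allele_a = allele_a, allele_b = allele_b,
                     stringsAsFactors = FALSE)
  cases <- dos[phen == "case", , drop = FALSE]
  controls <- dos[phen == "control", , drop = FALSE]
  list(cases = cases, controls = controls,
       snps = snp_records(cases, controls, snps))
}

#' Write a genotype table in the package TSV dialect
#'
#' Inverse of [read_genotype_table()]: cases are written first, then controls;
#' missing calls are written as `NN`.
#'
#' @param cases,controls Integer genotype matrices (codes 0/1/2, NA missing).
#' @param snps Data.frame with at least `rsid`, `allele_a`, `allele_b`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(cases, controls, snps, path) {
  stopifnot(ncol(cases) == nrow(snps), ncol(controls) == nrow(snps))
  render_row <- function(calls) {
    out <- character(length(calls))
    for (j in seq_along(calls)) {
      out[j] <- if (is.na(calls[j])) "NN"
        else genotype_code_string(calls[j], snps$allele_a[j], snps$allele_b[j])
    }
    out
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", "phenotype", snps$rsid), collapse = "\t"), con)
  for (i in seq_len(nrow(cases)))
    writeLines(paste(c(rownames(cases)[i], "case", render_row(cases[i, ])),
                     collapse = "\t"), con)
  for (i in seq_len(nrow(controls)))
    writeLines(paste(c(rownames(controls)[i], "control", render_row(controls[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

# two-character display string for one genotype code
genotype_code_string <- function(code, a, b) {
  switch(as.character(code),
         "0" = paste0(a, a),
         "1" = paste0(a, b),
         "2" = paste0(b, b),
         stop("invalid genotype code: ", code))
}

#' Per-SNP genotype count records
#'
#' Tallies genotype and missing-call counts per SNP and cohort, yielding one
#' record per SNP with the inputs needed for MAF and HWE quality control.
#'
#' @param cases,controls Integer genotype matrices (codes 0/1/2, NA missing).
#' @param snps Data.frame with `rsid`, `allele_a`, `allele_b` (one row per
#'   matrix column, same order).
#' @return `snps` extended with columns `case_AA`, `case_AB`, `case_BB`,
#'   `control_AA`, `control_AB`, `control_BB`, `n_missing_case`,
#'   `n_missing_control`.
#' @export
snp_records <- function(cases, controls, snps) {
  stopifnot(ncol(cases) == nrow(snps), ncol(controls) == nrow(snps))
  tally <- function(m) {
    t(vapply(seq_len(ncol(m)), function(j) {
      x <- m[, j]
      c(sum(x == 0L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
        sum(x == 2L, na.rm = TRUE), sum(is.na(x)))
    }, numeric(4)))
  }
  ca <- tally(cases); co <- tally(controls)
  snps$case_AA <- ca[, 1]; snps$case_AB <- ca[, 2]; snps$case_BB <- ca[, 3]
  snps$control_AA <- co[, 1]; snps$control_AB <- co[, 2]; snps$control_BB <- co[, 3]
  snps$n_missing_case <- ca[, 4]; snps$n_missing_control <- co[, 4]
  snps
}

#' Minor allele frequency from a genotype count triple
#'
#' @param counts Numeric triple `(n_AA, n_AB, n_BB)` of genotype counts.
#' @return The minor allele frequency `min(f, 1 - f)` with
#'   `f = (2 n_AA + n_AB) / (2 N)`, in `[0, 0.5]`.
#' @export
compute_maf <- function(counts) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("undefined frequency: all calls missing")
  f <- (2 * counts[1L] + counts[2L]) / (2 * n)
  unname(min(f, 1 - f))
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts against
#' the Hardy-Weinberg expectations computed from the estimated allele
#' frequency. Monomorphic counts return p = 1 by convention (no departure is
#' testable).
#'
#' @param counts Numeric triple `(n_AA, n_AB, n_BB)`.
#' @return The chi-square p-value in `[0, 1]`.
#' @export
hwe_test <- function(counts) {
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n == 0) stop("undefined HWE test: all calls missing")
  q <- (2 * counts[1L] + counts[2L]) / (2 * n)   # frequency of allele a
  if (q == 0 || q == 1) return(1)
  expected <- n * c(q^2, 2 * q * (1 - q), (1 - q)^2)
  chi2 <- sum((counts - expected)^2 / expected)
  unname(stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Quality-control filter for SNP records
#'
#' Retains SNPs with minor allele frequency above `maf_min` in both cohorts,
#' HWE p-value above `hwe_control_min` in controls, and HWE p-value above
#' `hwe_case_min` in cases; everything else is excluded with a named reason.
#'
#' @param records SNP record data.frame from [snp_records()].
#' @param maf_min MAF threshold (exclusive), default 0.05.
#' @param hwe_control_min Control HWE p-value threshold (exclusive), default 0.01.
#' @param hwe_case_min Case HWE p-value threshold (exclusive), default 1e-4.
#' @return A list with `pass` (the retained records) and `report`, a per-SNP
#'   data.frame with columns `rsid`, `maf_case`, `maf_control`, `hwe_p_case`,
#'   `hwe_p_control`, `status` (`pass`/`fail`) and `reason` (failing rules,
#'   `;`-separated).
#' @export
qc_filter <- function(records, maf_min = 0.05, hwe_control_min = 0.01,
                      hwe_case_min = 1e-4) {
  n <- nrow(records)
  maf_case <- maf_control <- hwe_case <- hwe_control <- numeric(n)
  for (i in seq_len(n)) {
    cc <- as.numeric(records[i, c("case_AA", "case_AB", "case_BB")])
    oc <- as.numeric(records[i, c("control_AA", "control_AB", "control_BB")])
    maf_case[i] <- compute_maf(cc)
    maf_control[i] <- compute_maf(oc)
    hwe_case[i] <- hwe_test(cc)
    hwe_control[i] <- hwe_test(oc)
  }
  reasons <- character(n)
  fail <- function(cond, tag) ifelse(cond, tag, NA_character_)
  rs <- cbind(fail(maf_case <= maf_min, "MAF(case)"),
              fail(maf_control <= maf_min, "MAF(control)"),
              fail(hwe_control <= hwe_control_min, "HWE(control)"),
              fail(hwe_case <= hwe_case_min, "HWE(case)"))
  for (i in seq_len(n))
    reasons[i] <- paste(stats::na.omit(rs[i, ]), collapse = ";")
  status <- ifelse(nzchar(reasons), "fail", "pass")
  report <- data.frame(rsid = records$rsid, maf_case = maf_case,
                       maf_control = maf_control, hwe_p_case = hwe_case,
                       hwe_p_control = hwe_control, status = status,
                       reason = reasons, stringsAsFactors = FALSE)
  list(pass = records[status == "pass", , drop = FALSE], report = report)
}

#' Per-genotype cohort frequencies
#'
#' Computes, for every SNP and genotype code, the genotype frequency in the
#' case cohort (alpha) and in the control cohort (beta) over non-missing
#' calls. These are the ingredients of the prevalence-weighted population
#' frequency estimator.
#'
#' @param cases,controls Integer genotype matrices sharing the same SNP columns.
#' @return An object of class `genotype_frequencies`: a list with 3 x n_SNP
#'   matrices `alpha` and `beta` (rows = genotype codes 0..2, columns = rsIDs).
#' @export
genotype_frequencies <- function(cases, controls) {
  if (ncol(cases) != ncol(controls))
    stop("case and control matrices must share the same SNP columns")
  freq1 <- function(m, cohort) {
    f <- vapply(seq_len(ncol(m)), function(j) {
      x <- m[, j]
      n <- sum(!is.na(x))
      if (n == 0)
        stop("SNP ", colnames(m)[j], ": zero non-missing calls in ", cohort)
      c(sum(x == 0L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
        sum(x == 2L, na.rm = TRUE)) / n
    }, numeric(3))
    dimnames(f) <- list(c("0", "1", "2"), colnames(m))
    f
  }
  structure(list(alpha = freq1(cases, "cases"), beta = freq1(controls, "controls")),
            class = "genotype_frequencies")
}
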