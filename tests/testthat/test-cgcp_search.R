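test_that("count_pattern_space matches explicit enumeration for small n, r", {
  # independent oracle: literally generate every (subset, genotype tuple)
  enumerate <- function(n, r) {
    if (r == 0) return(1L)
    subsets <- utils::combn(n, r)
    ncol(subsets) * nrow(expand.grid(rep(list(0:2), r)))
  }
  for (n in 0:6) for (r in 0:n)
    expect_equal(count_pattern_space(n, r), enumerate(n, r))
  expect_equal(count_pattern_space(2, 1), 6)
  expect_equal(count_pattern_space(3, 2), 27)
  expect_equal(count_pattern_space(51, 3), 27 * choose(51, 3))  # 562275
  expect_equal(count_pattern_space(51, 3), 562275)
  expect_error(count_pattern_space(3, 4), "0 <= r <= n")
  expect_error(count_pattern_space(200, 100), "2\\^53")
})

test_that("population_frequency implements the prevalence-weighted mixture", {
  m <- prevalence_model(p = 0.0047)
  expect_equal(m$lambda, (1 - 0.0047) / 0.0047, tolerance = 1e-15)
  # fixed point when the cohorts agree
  expect_equal(population_frequency(0.2, 0.2, m), 0.2, tolerance = 1e-12)
  # arithmetic mean at lambda = 1
  expect_equal(population_frequency(0.3, 0.1, prevalence_model(p = 0.5)), 0.2,
               tolerance = 1e-12)
  # hand evaluation at lambda = 0.9953/0.0047 = 211.7659...
  lam <- 0.9953 / 0.0047
  expect_equal(population_frequency(0.5, 0.1, m), (0.5 + lam * 0.1) / (1 + lam),
               tolerance = 1e-12)
  expect_equal(population_frequency(0.5, 0.1, m), 0.10188, tolerance = 1e-4)
  expect_error(population_frequency(1.2, 0.1, m), "\\[0, 1\\]")
  # bounded by the two cohort frequencies, monotone in both
  withr::with_seed(2, {
    a <- runif(50); b <- runif(50); p <- runif(50, 0.001, 0.999)
    for (i in 1:50) {
      f <- population_frequency(a[i], b[i], prevalence_model(p = p[i]))
      expect_gte(f, min(a[i], b[i]))
      expect_lte(f, max(a[i], b[i]))
    }
  })
})

test_that("pattern_product_frequency multiplies per-SNP population frequencies", {
  cases <- gt_matrix(matrix(c(0, 1, 2, 0, 1, 2, 0, 0, 1, 2, 1, 0), nrow = 4))
  controls <- gt_matrix(matrix(c(1, 1, 0, 2, 2, 0, 1, 0, 0, 1, 2, 2), nrow = 4))
  fr <- genotype_frequencies(cases, controls)
  m <- prevalence_model(p = 0.0047)
  # r = 1 reduces to population_frequency of the single genotype
  p1 <- genotype_pattern(2L, 1L)
  expect_equal(pattern_product_frequency(p1, fr, m),
               population_frequency(fr$alpha["1", 2], fr$beta["1", 2], m))
  # spreadsheet-style hand product over three SNPs
  p3 <- genotype_pattern(1:3, c(0L, 1L, 2L))
  hand <- prod(vapply(1:3, function(i)
    population_frequency(fr$alpha[c(0, 1, 2)[i] + 1, i],
                         fr$beta[c(0, 1, 2)[i] + 1, i], m), numeric(1)))
  expect_equal(pattern_product_frequency(p3, fr, m), hand, tolerance = 1e-15)
})

test_that("enumerate_observed_patterns maps tuples to carriers, skipping missing", {
  m <- gt_matrix(matrix(c(0, 0, 1, NA,
                          2, 2, 1, 0), nrow = 4))
  m[3, 2] <- NA
  out <- enumerate_observed_patterns(m, c(1L, 2L))
  expect_named(out, c("0,2"), ignore.order = TRUE)
  expect_identical(out[["0,2"]], c("s001", "s002"))
  # hand enumeration of an 8-sample fixture
  m8 <- gt_matrix(matrix(c(0, 0, 1, 1, 2, 2, 0, 1,
                           1, 1, 0, 0, 2, 2, 1, 0), nrow = 8))
  out8 <- enumerate_observed_patterns(m8, c(1L, 2L))
  expect_identical(out8[["0,1"]], c("s001", "s002", "s007"))
  expect_identical(out8[["1,0"]], c("s003", "s004", "s008"))
  expect_identical(out8[["2,2"]], c("s005", "s006"))
})

test_that("a single control occurrence eliminates a pattern", {
  cases <- gt_matrix(matrix(rep(c(0L, 2L), each = 10), nrow = 10))
  controls <- gt_matrix(matrix(c(0L, rep(1L, 9), rep(1L, 10)), nrow = 10))
  controls[1, ] <- c(0L, 2L)  # one control carries the case tuple
  cfg <- search_config(r = 2, min_carriers = 1, bounds = FALSE)
  res <- search_cgcp(cases, controls, cfg)
  expect_false("rs0001,rs0002" %in% res$rsids[res$genotype == "02"])
  # re-scanning the controls finds zero carriers for every reported candidate
  for (i in seq_len(nrow(res))) {
    pat <- list(snp_index = res$snp_index[[i]], codes = res$codes[[i]])
    expect_identical(sum(cgcp:::pattern_carriers(controls, pat)), 0L)
  }
})

test_that("search matches the brute-force oracle on random fixtures", {
  withr::with_seed(17, {
    for (i in 1:10) {
      co <- random_cohort(n_snps = sample(3:7, 1), n_cases = 40,
                          n_controls = 40, missing_rate = 0.05)
      r <- sample(1:2, 1)
      cfg <- search_config(r = r, min_carriers = sample(1:3, 1), bounds = FALSE)
      expect_identical(search_cgcp(co$cases, co$controls, cfg),
                       brute_force_search(co$cases, co$controls, cfg))
    }
  })
})

test_that("brute force refuses oversized pattern spaces", {
  co <- random_cohort(20, 5, 5, seed = 1)
  cfg <- search_config(r = 5, min_carriers = 1)
  expect_error(brute_force_search(co$cases, co$controls, cfg, guard = 1e6),
               "guard")
})

test_that("planted case-only patterns are recovered exactly", {
  cfg <- simulation_config(n_snps = 15, n_cases = 400, n_controls = 400,
                           planted_patterns = list(planted_pattern(3, 10)),
                           missing_rate = 0, seed = 42)
  sim <- simulate_cohort(cfg)
  tr <- sim$truth[[1]]
  res <- search_cgcp(sim$cases, sim$controls, search_config(r = 3, min_carriers = 8))
  key <- paste(tr$rsids, collapse = ",")
  hit <- res[res$rsids == key &
               vapply(res$codes, function(x) identical(x, tr$codes), logical(1)), ]
  expect_equal(nrow(hit), 1L)
  expect_true(all(tr$carriers %in% hit$carriers[[1]]))
  expect_equal(hit$product_frequency, tr$product_frequency, tolerance = 1e-12)
})

test_that("raising min_carriers never adds candidates", {
  sim <- simulate_cohort(simulation_config(
    n_snps = 12, n_cases = 300, n_controls = 300,
    planted_patterns = list(planted_pattern(2, 15), planted_pattern(3, 10)),
    seed = 9))
  sets <- lapply(c(1, 5, 10, 20), function(mc)
    candidate_signature(search_cgcp(sim$cases, sim$controls,
                                    search_config(r = 2, min_carriers = mc,
                                                  bounds = FALSE))))
  for (i in 2:length(sets)) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("every reported product frequency lies strictly inside the band", {
  sim <- simulate_cohort(simulation_config(
    n_snps = 15, n_cases = 400, n_controls = 400,
    planted_patterns = list(planted_pattern(3, 12), planted_pattern(3, 18)),
    seed = 31))
  model <- prevalence_model(0.0047)
  res <- search_cgcp(sim$cases, sim$controls,
                     search_config(r = 3, min_carriers = 8, model = model))
  expect_gt(nrow(res), 0)
  expect_true(all(res$product_frequency > model$lower_mult * model$p))
  expect_true(all(res$product_frequency < model$upper_mult * model$p))
  # the preliminary filter (below disease prevalence) is implied by the band
  expect_true(all(res$product_frequency < model$p))
})

test_that("search output is deterministic and sorted", {
  sim <- simulate_cohort(simulation_config(
    n_snps = 12, n_cases = 300, n_controls = 300,
    planted_patterns = list(planted_pattern(3, 10), planted_pattern(3, 14)),
    seed = 12))
  cfg <- search_config(r = 3, min_carriers = 8)
  r1 <- search_cgcp(sim$cases, sim$controls, cfg)
  r2 <- search_cgcp(sim$cases, sim$controls, cfg)
  expect_identical(r1, r2)
  expect_true(all(diff(r1$n_case_carriers) <= 0))
})

test_that("summarize_frequency_distribution handles edge cases", {
  one <- data.frame(product_frequency = 3e-4)
  s <- summarize_frequency_distribution(one)
  expect_equal(s[c("mean", "min", "max")],
               data.frame(mean = 3e-4, min = 3e-4, max = 3e-4))
  expect_equal(s$sd, 0)
  two <- data.frame(product_frequency = c(1e-4, 3e-4))
  expect_equal(summarize_frequency_distribution(two)$mean, 2e-4)
  empty <- summarize_frequency_distribution(data.frame(product_frequency = numeric()))
  expect_identical(empty$n, 0L)
  expect_true(is.na(empty$mean))
})

test_that("search errors on invalid inputs", {
  co <- random_cohort(4, 10, 10, seed = 2)
  expect_error(search_cgcp(co$cases, co$controls,
                           search_config(r = 5, min_carriers = 1)),
               "exceeds the number of searchable SNPs")
  expect_error(search_cgcp(co$cases[0, ], co$controls,
                           search_config(r = 2, min_carriers = 1)),
               "non-empty")
})
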