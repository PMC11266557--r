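chrlen <- c(chrA = 20e6, chrB = 12e6)

test_that("midpoint window assignment uses half-open boundaries", {
  calls <- tibble::tibble(
    sample_id = "s1", chrom = "chrA",
    start = c(4999000, 1, 9e6), end = c(5001000, 1000, 16e6)
  )
  wc <- assign_windows(calls, chrlen)
  # midpoint 5,000,000 lands in the SECOND window (index 1)
  hit <- wc$counts[, "s1"] > 0
  idx <- wc$windows$window_index[hit & wc$windows$chrom == "chrA"]
  expect_setequal(idx, c(0, 1, 2))
  # record spanning several windows counted once, in its midpoint window
  expect_equal(sum(wc$counts), 3)
})

test_that("window assignment errors on out-of-range records", {
  expect_error(
    assign_windows(tibble::tibble(sample_id = "s1", chrom = "chrA",
                                  start = 19e6, end = 21e6), chrlen),
    "coordinate error.*chrA:19000000-21000000"
  )
  expect_error(
    assign_windows(tibble::tibble(sample_id = "s1", chrom = "chrZ",
                                  start = 1, end = 10), chrlen),
    "unknown chromosome"
  )
})

test_that("window counts conserve per-sample totals", {
  cfg <- sim_config(n_cases = 25, n_controls = 25, seed = 17)
  sim <- simulate_terminal_burden(cfg)
  wc <- assign_windows(sim$cnv_calls, cfg$chrom_lengths,
                       sample_ids = sim$samples$sample_id)
  per_sample <- table(factor(sim$cnv_calls$sample_id,
                             levels = sim$samples$sample_id))
  expect_equal(unname(colSums(wc$counts)), as.vector(per_sample))
})

test_that("identical count distributions give p near one half", {
  set.seed(41)
  counts <- matrix(rpois(40 * 60, 2), 40, 60,
                   dimnames = list(paste("chrA", 0:39),
                                   sprintf("s%02d", 1:60)))
  wc <- structure(list(
    counts = counts,
    windows = tibble::tibble(chrom = "chrA", window_index = 0:39,
                             wstart = (0:39) * 5e5, wend = (1:40) * 5e5),
    window_size = 5e5
  ), class = "window_counts")
  samples <- toy_samples(30, 30)
  res <- window_tests(wc, samples)
  expect_true(abs(median(res$p_one_sided, na.rm = TRUE) - 0.5) < 0.15)
})

test_that("the one-sided rank test matches exact enumeration at small n", {
  set.seed(42)
  # tie-free data: the exact path reproduces full enumeration
  for (i in 1:40) {
    n1 <- sample(4:8, 1); n2 <- sample(4:8, 1)
    x <- runif(n1); y <- runif(n2)
    p_exact_pkg <- svbk:::rank_test_greater(x, y, exact = TRUE)
    p_enum <- oracle_exact_ranksum_p(x, y)
    expect_equal(p_exact_pkg, p_enum, tolerance = 1e-12)
  }
  # tied count data: the normal approximation tracks enumeration closely
  for (i in 1:40) {
    n1 <- sample(5:8, 1); n2 <- sample(5:8, 1)
    x <- rpois(n1, 3); y <- rpois(n2, 3)
    if (sd(c(x, y)) == 0) next
    p_norm <- svbk:::rank_test_greater(x, y)
    p_enum <- oracle_exact_ranksum_p(x, y)
    expect_lt(abs(p_norm - p_enum), 0.1)
  }
  # strictly greater cases at n = 20/20: near the exact permutation tail
  x <- 21:40; y <- 1:20
  p_norm <- svbk:::rank_test_greater(x, y)
  expect_lt(p_norm, 1e-4)
})

test_that("planted terminal enrichment is detected where it was planted", {
  cfg <- sim_config(n_cases = 200, n_controls = 200, seed = 19,
                    terminal_burden_delta = 2)
  sim <- simulate_terminal_burden(cfg)
  wc <- assign_windows(sim$cnv_calls, cfg$chrom_lengths,
                       sample_ids = sim$samples$sample_id)
  tb <- terminal_burden(wc, sim$samples)
  expect_equal(nrow(tb), 10)
  expect_lt(tb$p_one_sided[1], 1e-3)
  expect_true(all(tb$p_one_sided[3:10] > 0.01))
  expect_gt(tb$mean_cases[1], tb$mean_controls[1])

  wt <- window_tests(wc, sim$samples)
  nw <- table(wt$chrom)
  is_term <- wt$window_index == 0 |
    wt$window_index == as.integer(nw[wt$chrom]) - 1L
  expect_lt(median(wt$p_one_sided[is_term], na.rm = TRUE),
            median(wt$p_one_sided[!is_term], na.rm = TRUE))
})

test_that("terminal bins skip chromosomes shorter than the bin reach", {
  short <- c(chrA = 200e6, chrB = 30e6) # chrB has 6 windows
  calls <- tibble::tibble(sample_id = rep(sprintf("s%02d", 1:10), 2),
                          chrom = "chrA", start = 1e6, end = 1e6 + 2000)
  wc <- assign_windows(calls, short,
                       sample_ids = sprintf("s%02d", 1:10))
  tb <- terminal_burden(wc, toy_samples(5, 5), n_bins = 10)
  expect_true(all(tb$n_chrom_skipped[4:10] >= 1))
})

test_that("empty burden yields NA tests", {
  wc <- assign_windows(
    tibble::tibble(sample_id = character(), chrom = character(),
                   start = integer(), end = integer()),
    chrlen, sample_ids = toy_samples()$sample_id
  )
  tb <- terminal_burden(wc, toy_samples())
  expect_true(all(is.na(tb$p_one_sided)))
  expect_true(all(tb$mean_cases == 0))
})

test_that("age trend recovers a planted slope and nulls a constant", {
  set.seed(43)
  ages <- runif(500, 55, 85)
  grp_truth <- as.integer(cut(ages, quantile(ages, seq(0, 1, 0.25)),
                              include.lowest = TRUE))
  counts <- rpois(500, 2 + 0.5 * grp_truth)
  res <- age_trend(counts, ages)
  expect_lt(res$p_trend, 0.01)
  expect_gt(res$slope, 0)

  const <- age_trend(rep(3, 500), ages)
  expect_equal(const$slope, 0)

  jt <- age_trend(counts, ages, method = "jonckheere")
  expect_lt(jt$p_trend, 0.01)

  expect_error(age_trend(1:3, c(60, 60, 60)), "binning error")
})

test_that("age-trend p values are calibrated under the null", {
  set.seed(44)
  ps <- replicate(200, {
    ages <- runif(120, 55, 85)
    age_trend(rpois(120, 3), ages)$p_trend
  })
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})
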