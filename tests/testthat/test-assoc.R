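test_that("odds ratios from frequencies match hand arithmetic", {
  expect_equal(round(or_from_freqs(0.288, 0.450), 2), 0.49)
  expect_equal(or_from_freqs(0.5, 0.5), 1)
  expect_equal(or_from_freqs(0.2, 0.1), 2.25)
  expect_error(or_from_freqs(0, 0.5), "infinite-odds")
  expect_error(or_from_freqs(0.5, 1), "infinite-odds")
})

test_that("frequency -> odds-ratio -> frequency round-trips", {
  set.seed(51)
  for (i in 1:50) {
    f0 <- runif(1, 0.05, 0.95)
    or <- exp(runif(1, -1.5, 1.5))
    f1 <- svbk:::case_freq_from_or(f0, or)
    expect_equal(or_from_freqs(f1, f0), or, tolerance = 1e-10)
  }
})

test_that("meta-analysis closed forms hold", {
  one <- meta_combine(tibble::tibble(p = 0.05, n = 500, delta = 1))
  expect_equal(one$meta_p, 0.05)
  # self-combination identity for arbitrary p
  for (p in c(1e-8, 0.001, 0.3, 1)) {
    expect_equal(
      meta_combine(tibble::tibble(p = p, n = 123, delta = -1))$meta_p, p
    )
  }

  two <- meta_combine(tibble::tibble(p = c(0.05, 0.05), n = c(500, 500),
                                     delta = c(1, 1)))
  z <- qnorm(0.025) # -1.959964
  expect_equal(two$meta_p, 2 * pnorm(-abs(z) * sqrt(2)), tolerance = 1e-12)
  expect_equal(round(two$meta_p, 5), 0.00557)

  cancel <- meta_combine(tibble::tibble(p = c(0.05, 0.05), n = c(500, 500),
                                        delta = c(1, -1)))
  expect_equal(cancel$meta_z, 0)
  expect_equal(cancel$meta_p, 1)
})

test_that("meta-analysis is permutation-invariant and validates p", {
  d <- tibble::tibble(p = c(0.01, 0.2, 0.7), n = c(300, 500, 200),
                      delta = c(1, 1, -1))
  expect_equal(meta_combine(d), meta_combine(d[c(3, 1, 2), ]))
  expect_error(meta_combine(tibble::tibble(p = 0, n = 10, delta = 1)),
               "domain error")
  expect_error(meta_combine(tibble::tibble(p = 1.2, n = 10, delta = 1)),
               "domain error")
  # literal upper-tail form exceeds 1 (audit only)
  lit <- meta_combine(tibble::tibble(p = 0.05, n = 100, delta = 1),
                      literal_tail = TRUE)
  expect_gt(lit$meta_p, 1)
})

test_that("significance flags use the stated thresholds exactly", {
  gw <- meta_combine(tibble::tibble(p = 4e-8, n = 1000, delta = 1))
  expect_true(gw$passes_gw)
  not_gw <- meta_combine(tibble::tibble(p = 6e-8, n = 1000, delta = 1))
  expect_false(not_gw$passes_gw)
  rep_ok <- meta_combine(tibble::tibble(p = 0.004, n = 1000, delta = 1))
  expect_true(rep_ok$passes_replication)
  rep_no <- meta_combine(tibble::tibble(p = 0.0046, n = 1000, delta = 1))
  expect_false(rep_no$passes_replication)
})

test_that("stratified association recovers a planted protective SV", {
  cfg <- sim_config(
    n_cases = 1000, n_controls = 1000, n_background_variants = 6, seed = 61,
    planted_effects = tibble::tibble(vclass = "SV_DEL", maf_controls = 0.45,
                                     odds_ratio = 0.49)
  )
  cs <- simulate_cohort(cfg)
  id <- attr(cs, "truth")$variant_id
  st <- assoc_variant(cs, id)
  expect_equal(nrow(st), 2)
  expect_true(all(st$delta == -1))
  or_hat <- exp(sum(st$effect * st$n) / sum(st$n))
  expect_lt(abs(or_hat - 0.49), 0.12)
  meta <- meta_combine(st)
  expect_lt(meta$meta_p, 1e-6)
})

test_that("the scan tests SVs, CNVs and STRs and flags the planted hits", {
  cfg <- sim_config(
    n_cases = 600, n_controls = 600, n_background_variants = 5, seed = 62,
    planted_effects = tibble::tibble(
      vclass = c("SV_DEL", "CNV_DEL", "kSTR"),
      maf_controls = c(0.45, 0.3, 0.45),
      odds_ratio = c(0.4, 2.2, 0.45)
    )
  )
  cs <- simulate_cohort(cfg)
  sc <- assoc_scan(cs)
  expect_s3_class(sc, "svbk_assoc")
  planted <- dplyr::filter(sc, grepl("planted", variant_id))
  expect_equal(nrow(planted), 3)
  expect_true(all(planted$meta_p < 1e-4))
  expect_gt(min(dplyr::filter(sc, !grepl("planted", variant_id))$meta_p),
            min(planted$meta_p))
  expect_true(all(c("variant_id", "stratum", "p") %in% names(tidy(sc))))
  expect_s3_class(autoplot(sc), "ggplot")
  expect_equal(glance(sc)$n_tested, nrow(sc))
})

test_that("monomorphic variants are skipped with NA and separation flagged", {
  samples <- toy_samples(30, 30)
  v <- tibble::tibble(variant_id = c("mono", "sep"), chrom = "chr1",
                      start = 1000, end = 1999, vclass = "SV_DEL")
  g <- rbind(mono = rep(0L, 60),
             sep = c(rep(1L, 30), rep(0L, 30))) # perfectly separates
  colnames(g) <- samples$sample_id
  cs <- cohort_callset(samples, v, genotypes = g)
  mono <- assoc_variant(cs, "mono", covariates = "sex", strata = NULL)
  expect_true(is.na(mono$p))
  sep <- assoc_variant(cs, "sep", covariates = "sex", strata = NULL)
  expect_true(sep$firth)
  expect_true(is.finite(sep$effect))
  expect_lt(sep$p, 0.001)
})

test_that("LD statistics match hand evaluation of standard formulas", {
  perfect <- ld_stats(c(AB = 50, Ab = 0, aB = 0, ab = 50))
  expect_equal(perfect$d_prime, 1)
  expect_equal(perfect$r2, 1)

  indep <- ld_stats(c(AB = 16, Ab = 24, aB = 24, ab = 36)) # products
  expect_equal(indep$D, 0)
  expect_equal(indep$r2, 0)

  # a rare allele perfectly nested within a common one: D' = 1, tiny r2
  nested <- ld_stats(c(AB = 10, Ab = 0, aB = 490, ab = 500))
  expect_equal(nested$d_prime, 1)
  expect_equal(round(nested$r2, 2), 0.01)

  # and hand evaluation for an asymmetric nesting
  other <- ld_stats(c(AB = 10, Ab = 0, aB = 90, ab = 900))
  expect_equal(other$d_prime, 1)
  expect_equal(other$r2, 0.009^2 / (0.01 * 0.99 * 0.1 * 0.9))

  mono <- ld_stats(c(AB = 10, Ab = 10, aB = 0, ab = 0))
  expect_true(is.na(mono$r2))
})

test_that("penetrance modification is recovered from a planted interaction", {
  ic <- simulate_interaction_cohort(n = 6000, or_interaction = 0.4, seed = 71)
  pm <- penetrance_modifier(ic, "primary", "modifier")
  car <- dplyr::filter(pm$strata, stratum == "carrier",
                       modifier_genotype > 0, n > 0)
  expect_true(all(car$or_vs_wt < 1, na.rm = TRUE))
  non <- dplyr::filter(pm$strata, stratum == "non_carrier",
                       modifier_genotype == 1)
  expect_lt(abs(non$or_vs_wt - 1), 0.35)
  expect_lt(pm$interaction$interaction_p, 0.01)
  expect_equal(nrow(pm$control_cocarriage), 2)
})

test_that("a null interaction leaves both strata flat", {
  ic <- simulate_interaction_cohort(n = 4000, or_interaction = 1,
                                    or_primary = 1.5, seed = 72)
  pm <- penetrance_modifier(ic, "primary", "modifier")
  expect_gt(pm$interaction$interaction_p, 0.05)
})

test_that("degenerate penetrance tables are flagged, not dropped", {
  samples <- toy_samples(6, 6)
  v <- tibble::tibble(variant_id = c("pri", "mod"), chrom = "chr1",
                      start = 1000, end = 1999, vclass = "SV_DEL")
  # all modifier carriers among primary carriers are cases
  g <- rbind(pri = c(rep(1L, 8), rep(0L, 4)),
             mod = c(rep(1L, 4), rep(0L, 8)))
  colnames(g) <- samples$sample_id
  cs <- cohort_callset(samples, v, genotypes = g)
  pm <- penetrance_modifier(cs, "pri", "mod")
  car <- dplyr::filter(pm$strata, stratum == "carrier",
                       modifier_genotype == 1)
  expect_true(car$degenerate)
  expect_equal(car$or_vs_wt, Inf)
  expect_false(is.na(car$p_exact))
})

test_that("two-sample power matches its closed form and stays monotone", {
  a <- 0.05 / 100000
  p <- power_two_sample(466, 513, a, 0.325)
  expect_equal(p, 0.5208, tolerance = 1e-3)
  # two-sided size at zero effect
  expect_equal(power_two_sample(100, 100, 0.05, 0), 0.05, tolerance = 1e-10)
  grid <- vapply(seq(0, 0.6, by = 0.05), function(d) {
    power_two_sample(466, 513, a, d)
  }, numeric(1))
  expect_true(all(diff(grid) > 0))
  # Monte-Carlo mode agrees with the normal approximation
  mc <- power_two_sample(466, 513, a, 0.325, method = "montecarlo",
                         n_sim = 4000, seed = 9)
  expect_lt(abs(mc - p), 0.03)
})

test_that("allele-frequency power behaves at its limits", {
  null_curve <- power_allele(466, 513, 0.05, genotype_rr = 1)
  expect_true(all(abs(null_curve$power - 0.05) < 1e-10))
  curve <- power_allele(466, 513, 0.05 / 100000,
                        maf_grid = seq(0.02, 0.9, by = 0.02),
                        genotype_rr = 1.6)
  peak <- which.max(curve$power)
  expect_gt(peak, 1)
  expect_lt(peak, nrow(curve))
  expect_lt(curve$power[1], 0.05)
})
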