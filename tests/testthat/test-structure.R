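test_that("MuAF follows the class-specific carrier definitions", {
  cs <- toy_callset()
  mf <- muaf(cs)
  # SV: mutant alleles / non-missing alleles = (1+2+1+1)/20
  expect_equal(mf$muaf[mf$variant_id == "sv1"], 0.25)
  # CNV: carrier fraction 3/10
  expect_equal(mf$muaf[mf$variant_id == "cnv1"], 0.3)
  # kSTR: samples with any allele differing from ref repeat 6: 3/10
  expect_equal(mf$muaf[mf$variant_id == "kstr1"], 0.3)
  # dSTR: samples with any supporting read: 2/10
  expect_equal(mf$muaf[mf$variant_id == "dstr1"], 0.2)
})

test_that("MuAF hits the degenerate ends and ignores sample order", {
  cs <- toy_callset()
  cs$cnv_sizes["cnv1", ] <- 5000 # every sample carries
  expect_equal(muaf(cs, "cnv1")$muaf, 1)
  cs$cnv_sizes["cnv1", ] <- 0
  expect_equal(muaf(cs, "cnv1")$muaf, 0)

  cs2 <- toy_callset()
  perm <- sample(ncol(cs2$genotypes))
  cs2$samples <- cs2$samples[perm, ]
  cs2$genotypes <- cs2$genotypes[, perm]
  cs2$cnv_sizes <- cs2$cnv_sizes[, perm]
  cs2$repeats$a1 <- cs2$repeats$a1[, perm]
  cs2$repeats$a2 <- cs2$repeats$a2[, perm]
  expect_equal(muaf(cs2)$muaf, muaf(toy_callset())$muaf)
})

test_that("PCA frequency windows are class-specific and inclusive", {
  samples <- toy_samples(100, 100)
  n <- 200
  v <- tibble::tibble(
    variant_id = c("sv_hi", "sv_in", "cnv_all", "kstr_low", "dstr_in"),
    chrom = "chr1", start = 1000, end = 1999,
    vclass = c("SV_DEL", "SV_DEL", "CNV_DEL", "kSTR", "dSTR"),
    ref_repeat = c(NA, NA, NA, 6, NA)
  )
  g <- matrix(NA_integer_, 5, n, dimnames = list(v$variant_id, NULL))
  g["sv_hi", ] <- c(rep(2L, 199), 1L) # muaf 0.9975 > 0.99: excluded
  g["sv_in", ] <- rep(c(0L, 1L), 100)
  sz <- matrix(0, 5, n, dimnames = dimnames(g))
  sz["cnv_all", ] <- 1000 # muaf 1: retained for CNV
  a1 <- matrix(NA_real_, 5, n, dimnames = dimnames(g))
  a2 <- a1
  a1["kstr_low", ] <- c(rep(5, 6), rep(6, 194)) # carrier 0.03 < 0.05 floor
  a2["kstr_low", ] <- 6
  a1["dstr_in", ] <- c(rep(17, 20), rep(0, 180))
  a2["dstr_in", ] <- 0
  cs <- cohort_callset(samples, v, genotypes = g, cnv_sizes = sz,
                       repeats = list(a1 = a1, a2 = a2))
  sel <- select_for_pca(cs)
  expect_setequal(sel$variant_id, c("sv_in", "cnv_all", "dstr_in"))
})

test_that("PCA separates planted subpopulations on PC1", {
  set.seed(31)
  n_per <- 60; n_var <- 40
  # two subpopulations with divergent allele frequencies
  f_a <- runif(n_var, 0.1, 0.4)
  f_b <- pmin(f_a + 0.35, 0.95)
  g <- cbind(
    matrix(rbinom(n_var * n_per, 2, f_a), n_var, n_per),
    matrix(rbinom(n_var * n_per, 2, f_b), n_var, n_per)
  )
  grp <- rep(c("g1", "g2"), each = n_per)
  res <- pca_check(t(g), sample_groups = tibble::tibble(region = grp))
  p1 <- res$separation$p[res$separation$group == "region" &
                           res$separation$component == "PC1"]
  expect_lt(p1, 0.01)
})

test_that("sex-linked dosage separates sexes until those variants go", {
  set.seed(32)
  samples <- toy_samples(50, 50)
  n <- 100
  male <- samples$sex == "male"
  v <- tibble::tibble(
    variant_id = sprintf("v%02d", 1:20),
    chrom = c(rep("chrX", 6), rep("chr1", 14)),
    start = 1000, end = 1999, vclass = "SV_DEL"
  )
  g <- matrix(rbinom(20 * n, 2, 0.3), 20, n,
              dimnames = list(v$variant_id, samples$sample_id))
  g[1:6, male] <- rbinom(6 * sum(male), 1, 0.05) # hemizygous-like shift
  cs <- cohort_callset(samples, v, genotypes = g)

  with_sex <- pca_check(cs, "SV", apply_muaf_window = FALSE)
  p_sex <- min(with_sex$separation$p[with_sex$separation$group == "sex"])
  expect_lt(p_sex, 0.01)

  no_sex <- pca_check(cs, "SV", apply_muaf_window = FALSE,
                      exclude_chroms = "chrX")
  p_after <- min(no_sex$separation$p[no_sex$separation$group == "sex"])
  expect_gt(p_after, 0.05)
})

test_that("constant matrices are rejected, near-constant ones reported", {
  m <- matrix(1, 30, 8)
  expect_error(pca_check(m), "no variable columns")
  m2 <- cbind(m, rnorm(30))
  res <- pca_check(m2, n_components = 2)
  expect_equal(res$n_dropped, 8)
  expect_equal(sum(res$var_explained), 1, tolerance = 1e-8)
})

test_that("tidiers and autoplot work on PCA results", {
  cfg <- sim_config(n_cases = 40, n_controls = 40,
                    n_background_variants = 10, seed = 13)
  cs <- simulate_cohort(cfg)
  res <- pca_check(cs, "SV")
  expect_true(all(c("PC1", "PC2", "phenotype") %in% names(tidy(res))))
  expect_s3_class(glance(res), "tbl_df")
  expect_s3_class(autoplot(res), "ggplot")
})
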