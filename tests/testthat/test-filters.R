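make_sv_callset <- function(variants, genotypes) {
  cohort_callset(toy_samples(), variants, genotypes = genotypes)
}

test_that("cross-sample SV filter applies size, rate and MAF rules", {
  v <- tibble::tibble(
    variant_id = paste0("v", 1:6), chrom = "chr1",
    start = c(1000, 1000, 1000, 1000, 1000, 1000),
    end = c(1149, 1098, 1299, 1199, 1099, 1999),
    vclass = "SV_DEL"
  ) # sizes: 150, 99, 300, 200, 100, 1000
  g <- rbind(
    v1 = c(1L, 1L, 0L, 1L, 0L, 1L, 1L, 1L, 0L, 0L),
    v2 = c(1L, 1L, 0L, 1L, 0L, 1L, 1L, 1L, 0L, 0L), # size 99: removed
    v3 = c(1L, 1L, 0L, 1L, 0L, 1L, 0L, 1L, NA, NA), # rate 0.8: removed
    v4 = c(0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L, 0L, 0L),
    v5 = c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, NA), # boundary rate 0.9, maf 1/18
    v6 = c(2L, 1L, 0L, 1L, 0L, 1L, 1L, 1L, 0L, 0L)
  )
  out <- filter_sv(make_sv_callset(v, g))
  expect_setequal(out$variants$variant_id, c("v1", "v4", "v5", "v6"))
  # boundary values pass: exclusion inequalities are strict
  expect_true("v5" %in% out$variants$variant_id)
})

test_that("a 99 bp SV and a rate-0.89 SV are excluded", {
  n <- 100
  samples <- toy_samples(50, 50)
  v <- tibble::tibble(
    variant_id = c("small", "low_rate"), chrom = "chr1",
    start = c(1000, 5000), end = c(1098, 5149), vclass = "SV_DEL"
  )
  g <- rbind(small = rep(c(0L, 1L), 50), low_rate = rep(c(0L, 1L), 50))
  g["low_rate", 1:11] <- NA # rate 0.89
  colnames(g) <- samples$sample_id
  out <- filter_sv(cohort_callset(samples, v, genotypes = g))
  expect_equal(nrow(out$variants), 0)
})

test_that("inversions need quality or split/paired evidence support", {
  v <- tibble::tibble(
    variant_id = c("inv_lowq", "inv_msq", "inv_ev"), chrom = "chr1",
    start = 1000, end = 1999, vclass = "SV_INV",
    qc = list(
      list(mean_sample_quality = 140, ev_sr = 2, ev_pe = 3, ev_total = 100),
      list(mean_sample_quality = 150, ev_sr = 0, ev_pe = 0, ev_total = 100),
      list(mean_sample_quality = 10, ev_sr = 6, ev_pe = 5, ev_total = 100)
    )
  )
  g <- matrix(rep(c(0L, 1L), 15), 3, 10, byrow = TRUE,
              dimnames = list(v$variant_id, NULL))
  out <- filter_sv(make_sv_callset(v, g))
  expect_setequal(out$variants$variant_id, c("inv_msq", "inv_ev"))

  v_bad <- dplyr::mutate(v[1, ], qc = list(list(ev_sr = 1)))
  expect_error(
    filter_sv(make_sv_callset(v_bad, g[1, , drop = FALSE])),
    "configuration error.*mean_sample_quality"
  )
})

test_that("CNV filter combines qc attribute and size rules", {
  qc_ok <- list(p_value = 5e-5, mq0_frac = 0.1, n_frac = 0, gap_dist = 2000)
  calls <- tibble::tibble(
    chrom = "chr1",
    start = c(1e6, 2e6, 3e6, 4e6, 5e6),
    end = c(1e6 + 499, 2e6 + 7599, 3e6 + 149999, 4e6 + 999, 5e6 + 7599),
    sample_id = "s01",
    qc = list(qc_ok, qc_ok, qc_ok, qc_ok,
              list(p_value = 2e-4, mq0_frac = 0.1, n_frac = 0,
                   gap_dist = 2000))
  )
  out <- filter_cnv(calls)
  # 500 bp below floor; 150,000 bp above ceiling; 1000 bp exactly at the
  # inclusive floor passes; high p fails
  expect_equal(out$start, c(2e6, 4e6))
  expect_error(
    filter_cnv(dplyr::mutate(calls[1, ], qc = list(list(p_value = 1e-6)))),
    "configuration error.*mq0_frac"
  )
})

test_that("STR filters use strict inequalities on call attributes", {
  v <- tibble::tibble(
    variant_id = c("k_keep", "k_boundary", "d_keep", "d_irr"),
    chrom = "chr1", start = 100, end = 135,
    vclass = c("kSTR", "kSTR", "dSTR", "dSTR"),
    ref_repeat = c(6, 6, NA, NA),
    qc = list(
      list(quality = 31, depth = 11),
      list(quality = 30, depth = 11),
      list(anchor_mapq = 60, irr_mapq = 20, depth_obs = 5, depth_norm = 5),
      list(anchor_mapq = 60, irr_mapq = 40, depth_obs = 5, depth_norm = 5)
    )
  )
  a <- matrix(6, 4, 10, dimnames = list(v$variant_id, NULL))
  cs <- cohort_callset(toy_samples(), v, repeats = list(a1 = a, a2 = a))
  out <- filter_str(cs)
  expect_setequal(out$variants$variant_id, c("k_keep", "d_keep"))
})

test_that("all three filters are idempotent", {
  cfg <- sim_config(n_cases = 30, n_controls = 30,
                    n_background_variants = 8, seed = 42)
  cs <- simulate_cohort(cfg)
  once <- filter_str(filter_cnv(filter_sv(cs)))
  twice <- filter_str(filter_cnv(filter_sv(once)))
  expect_identical(once$variants, twice$variants)
  expect_identical(once$genotypes, twice$genotypes)
})

test_that("CNV interval merging unions overlapping spans only", {
  shared <- merge_cnv_intervals(
    tibble::tibble(chrom = "chr1", start = c(100, 200), end = c(200, 300))
  )
  expect_equal(nrow(shared$regions), 1)
  expect_equal(c(shared$regions$start, shared$regions$end), c(100, 300))

  gap <- merge_cnv_intervals(
    tibble::tibble(chrom = "chr1", start = c(100, 202), end = c(200, 300))
  )
  expect_equal(nrow(gap$regions), 2)

  # touching (201 after 200) shares no base: stays apart
  touch <- merge_cnv_intervals(
    tibble::tibble(chrom = "chr1", start = c(100, 201), end = c(200, 300))
  )
  expect_equal(nrow(touch$regions), 2)

  tri <- merge_cnv_intervals(tibble::tibble(
    chrom = "chr1", start = c(100, 150, 400), end = c(200, 250, 500),
    sample_id = c("a", "b", "c")
  ))
  expect_equal(tri$regions$start, c(100, 400))
  expect_equal(tri$regions$end, c(250, 500))
  expect_equal(tri$sizes["cnvr_chr1_100_250", c("a", "b")],
               c(a = 101, b = 101))

  empty <- merge_cnv_intervals(
    tibble::tibble(chrom = character(), start = integer(), end = integer())
  )
  expect_equal(nrow(empty$regions), 0)
})

test_that("merged intervals are disjoint and conserve covered bases", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    start <- sample.int(1000, n, replace = TRUE)
    len <- sample.int(50, n, replace = TRUE)
    rec <- tibble::tibble(chrom = sample(c("chrA", "chrB"), n, TRUE),
                          start = start, end = start + len)
    out <- merge_cnv_intervals(rec)$regions
    for (ch in unique(out$chrom)) {
      o <- dplyr::arrange(dplyr::filter(out, chrom == ch), start)
      if (nrow(o) > 1) {
        expect_true(all(o$start[-1] > o$end[-nrow(o)]))
      }
      covered <- unique(unlist(Map(seq, o$start, o$end)))
      input_cov <- unique(unlist(Map(
        seq, rec$start[rec$chrom == ch], rec$end[rec$chrom == ch]
      )))
      expect_setequal(covered, input_cov)
    }
  }
})
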