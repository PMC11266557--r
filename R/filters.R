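#' Cross-sample SV filter
#'
#' Applies the cross-sample quality rules for structural variants: records
#' smaller than `min_size` bp are excluded, as are records with a sample
#' genotyping rate below `min_genotype_rate` or a minor allele frequency
#' below `min_maf` (both computed over non-missing genotypes). Inversions
#' must additionally show a mean sample quality of at least 150 or
#' split-read plus paired-end evidence exceeding 10% of total evidence
#' (qc keys `mean_sample_quality`, `ev_sr`, `ev_pe`, `ev_total`).
#'
#' Exclusion thresholds are strict as stated, so boundary values
#' (size exactly 100 bp, rate exactly 0.90, MAF exactly 0.01) pass.
#'
#' @param callset A [cohort_callset()] with a genotype matrix.
#' @param min_size Minimum record size in bp.
#' @param min_genotype_rate Minimum fraction of samples with a non-missing
#'   genotype.
#' @param min_maf Minimum minor allele frequency over non-missing alleles.
#' @return The callset with failing SV-class variants removed; variants of
#'   other classes are untouched.
#' @export
filter_sv <- function(callset, min_size = 100, min_genotype_rate = 0.90,
                      min_maf = 0.01) {
  stopifnot(inherits(callset, "cohort_callset"))
  v <- callset$variants
  is_sv <- v$vclass %in% c("SV_DEL", "SV_DUP", "SV_INV", "SV_MEI")
  if (!any(is_sv)) return(callset)
  if (is.null(callset$genotypes)) abort("filter_sv requires a genotype matrix")

  size <- v$end - v$start + 1
  g <- callset$genotypes
  rate <- sv_genotype_rate(g)
  maf <- sv_maf(g)

  keep <- !is_sv |
    (!(size < min_size) & !(rate < min_genotype_rate) &
       !(maf < min_maf) & !is.na(maf))

  inv <- which(is_sv & v$vclass == "SV_INV" & keep)
  for (i in inv) {
    qc <- v$qc[[i]]
    msq <- qc_value(qc, "mean_sample_quality", v$variant_id[i])
    sr <- qc_value(qc, "ev_sr", v$variant_id[i])
    pe <- qc_value(qc, "ev_pe", v$variant_id[i])
    tot <- qc_value(qc, "ev_total", v$variant_id[i])
    keep[i] <- msq >= 150 || (tot > 0 && (sr + pe) / tot > 0.10)
  }
  subset_variants(callset, v$variant_id[keep])
}

#' CNV call filter
#'
#' Keeps CNV records whose caller attributes satisfy: P value below `p_max`,
#' MQ0 read fraction below `mq0_max`, N-base fraction below `nfrac_max`,
#' distance from the nearest large gap segment above `gap_min` bp, and size
#' within `[size_min, size_max]` bp. Attributes are read from the `qc`
#' list column (keys `p_value`, `mq0_frac`, `n_frac`, `gap_dist`); a missing
#' key is a configuration error.
#'
#' @param x Either a [cohort_callset()] (CNV-class variants are filtered) or
#'   a tibble of raw per-sample CNV calls with columns `chrom`, `start`,
#'   `end`, and `qc`.
#' @param p_max,mq0_max,nfrac_max,gap_min,size_min,size_max Filter
#'   thresholds; strict inequalities except the inclusive size bounds.
#' @return Object of the same kind as `x` with failing CNV records removed.
#' @export
filter_cnv <- function(x, p_max = 1e-4, mq0_max = 0.5, nfrac_max = 0.1,
                       gap_min = 1000, size_min = 1000, size_max = 100000) {
  pass_row <- function(qc, size, id) {
    qc_value(qc, "p_value", id) < p_max &&
      qc_value(qc, "mq0_frac", id) < mq0_max &&
      qc_value(qc, "n_frac", id) < nfrac_max &&
      qc_value(qc, "gap_dist", id) > gap_min &&
      size >= size_min && size <= size_max
  }
  if (inherits(x, "cohort_callset")) {
    v <- x$variants
    is_cnv <- v$vclass %in% c("CNV_DEL", "CNV_DUP")
    size <- v$end - v$start + 1
    keep <- !is_cnv
    for (i in which(is_cnv)) {
      keep[i] <- pass_row(v$qc[[i]], size[i], v$variant_id[i])
    }
    return(subset_variants(x, v$variant_id[keep]))
  }
  x <- as_tibble(x)
  if (!"qc" %in% names(x)) abort("configuration error: CNV calls need a qc column")
  size <- x$end - x$start + 1
  id <- if ("variant_id" %in% names(x)) x$variant_id else as.character(seq_len(nrow(x)))
  keep <- vapply(seq_len(nrow(x)),
                 function(i) pass_row(x$qc[[i]], size[i], id[i]), logical(1))
  x[keep, , drop = FALSE]
}

#' STR call filter
#'
#' Catalogued STRs (kSTR) are kept when call quality exceeds
#' `kstr_min_quality` and coverage depth exceeds `kstr_min_depth`
#' (qc keys `quality`, `depth`). De novo STRs (dSTR) are kept when the
#' anchor-read MAPQ exceeds `dstr_anchor_mapq`, the in-repeat-read MAPQ is
#' below `dstr_irr_mapq`, and both observed and normalized read depths
#' exceed `dstr_min_depth` (qc keys `anchor_mapq`, `irr_mapq`, `depth_obs`,
#' `depth_norm`). All inequalities are strict: boundary values fail.
#'
#' @param callset A [cohort_callset()].
#' @param kstr_min_quality,kstr_min_depth,dstr_anchor_mapq,dstr_irr_mapq,dstr_min_depth
#'   Filter thresholds.
#' @return The callset with failing STR-class variants removed.
#' @export
filter_str <- function(callset, kstr_min_quality = 30, kstr_min_depth = 10,
                       dstr_anchor_mapq = 50, dstr_irr_mapq = 40,
                       dstr_min_depth = 4) {
  stopifnot(inherits(callset, "cohort_callset"))
  v <- callset$variants
  keep <- rep(TRUE, nrow(v))
  for (i in seq_len(nrow(v))) {
    id <- v$variant_id[i]
    qc <- v$qc[[i]]
    if (v$vclass[i] == "kSTR") {
      keep[i] <- qc_value(qc, "quality", id) > kstr_min_quality &&
        qc_value(qc, "depth", id) > kstr_min_depth
    } else if (v$vclass[i] == "dSTR") {
      keep[i] <- qc_value(qc, "anchor_mapq", id) > dstr_anchor_mapq &&
        qc_value(qc, "irr_mapq", id) < dstr_irr_mapq &&
        qc_value(qc, "depth_obs", id) > dstr_min_depth &&
        qc_value(qc, "depth_norm", id) > dstr_min_depth
    }
  }
  subset_variants(callset, v$variant_id[keep])
}

#' Merge overlapping CNV intervals across samples
#'
#' Builds maximal unions of CNV intervals that share at least 1 bp
#' (1-based inclusive coordinates, so [100, 200] and [200, 300] merge but
#' [100, 200] and [201, 300] do not), and tabulates the total CNV base
#' pairs each sample contributes inside each merged region.
#'
#' @param records Tibble of per-sample CNV calls: columns `chrom`, `start`,
#'   `end`, and optionally `sample_id`.
#' @return A list with `regions` (tibble: `region_id`, `chrom`, `start`,
#'   `end`, `n_records`) and, when `sample_id` is present, `sizes`, a
#'   region-by-sample matrix of summed per-sample CNV bp.
#' @export
merge_cnv_intervals <- function(records) {
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    return(list(regions = tibble(region_id = character(), chrom = character(),
                                 start = integer(), end = integer(),
                                 n_records = integer()),
                sizes = NULL))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = records$chrom,
    ranges = IRanges::IRanges(start = records$start, end = records$end)
  )
  # min.gapwidth = 0: only intervals sharing >= 1 bp coalesce; touching
  # intervals (gap 0) stay apart.
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  red <- GenomicRanges::sort(red)
  hits <- GenomicRanges::findOverlaps(gr, red)
  region_of <- S4Vectors_to_int(hits)
  regions <- tibble(
    region_id = sprintf("cnvr_%s_%d_%d",
                        as.character(GenomicRanges::seqnames(red)),
                        GenomicRanges::start(red), GenomicRanges::end(red)),
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red),
    end = GenomicRanges::end(red),
    n_records = as.integer(tabulate(region_of, nbins = length(red)))
  )
  sizes <- NULL
  if ("sample_id" %in% names(records)) {
    samples <- unique(records$sample_id)
    sizes <- matrix(0, nrow(regions), length(samples),
                    dimnames = list(regions$region_id, samples))
    bp <- records$end - records$start + 1
    for (k in seq_along(region_of)) {
      sizes[region_of[k], records$sample_id[k]] <-
        sizes[region_of[k], records$sample_id[k]] + bp[k]
    }
  }
  list(regions = regions, sizes = sizes)
}

# Each input record falls in exactly one reduced region.
S4Vectors_to_int <- function(hits) {
  out <- integer(S4Vectors::queryLength(hits))
  out[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  out
}
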