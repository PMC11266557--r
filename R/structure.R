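#' Mutated allele frequency (MuAF) per variant
#'
#' Class-specific carrier/allele frequencies:
#' * SV: mutant-allele frequency from dosages, mutant alleles over
#'   non-missing alleles;
#' * CNV: carrier fraction, 1 minus the fraction of samples with no CNV
#'   base pairs in the region;
#' * dSTR: carrier fraction, a carrier being a sample with any supporting
#'   read (any allele repeat count > 0);
#' * kSTR: carrier fraction, a carrier being a sample whose repeat number
#'   differs from the locus reference repeat on either allele.
#'
#' Samples with missing values at a locus are excluded from both numerator
#' and denominator.
#'
#' @param callset A [cohort_callset()].
#' @param variant_ids Variants to summarise (default: all).
#' @return Tibble: `variant_id`, `vclass`, `muaf`, `n_samples`.
#' @export
muaf <- function(callset, variant_ids = NULL) {
  stopifnot(inherits(callset, "cohort_callset"))
  v <- callset$variants
  if (!is.null(variant_ids)) {
    missing_ids <- setdiff(variant_ids, v$variant_id)
    if (length(missing_ids)) {
      abort(paste0("unknown variant(s): ", paste(missing_ids, collapse = ", ")))
    }
    v <- v[match(variant_ids, v$variant_id), ]
  }
  one <- function(id, vclass) {
    if (vclass %in% c("SV_DEL", "SV_DUP", "SV_INV", "SV_MEI")) {
      g <- callset$genotypes[id, ]
      ok <- !is.na(g)
      c(if (any(ok)) sum(g[ok]) / (2 * sum(ok)) else NA_real_, sum(ok))
    } else if (vclass %in% c("CNV_DEL", "CNV_DUP")) {
      s <- callset$cnv_sizes[id, ]
      ok <- !is.na(s)
      c(mean(s[ok] > 0), sum(ok))
    } else if (vclass == "dSTR") {
      a1 <- callset$repeats$a1[id, ]; a2 <- callset$repeats$a2[id, ]
      ok <- !(is.na(a1) & is.na(a2))
      carrier <- (!is.na(a1) & a1 > 0) | (!is.na(a2) & a2 > 0)
      c(mean(carrier[ok]), sum(ok))
    } else if (vclass == "kSTR") {
      a1 <- callset$repeats$a1[id, ]; a2 <- callset$repeats$a2[id, ]
      ref <- callset$variants$ref_repeat[callset$variants$variant_id == id]
      if (is.na(ref)) {
        abort(paste0("kSTR variant ", id, " has no ref_repeat"))
      }
      ok <- !is.na(a1) & !is.na(a2)
      carrier <- a1 != ref | a2 != ref
      c(mean(carrier[ok]), sum(ok))
    } else {
      abort(paste0("unknown vclass for MuAF: ", vclass))
    }
  }
  res <- map2(v$variant_id, v$vclass, one)
  tibble(
    variant_id = v$variant_id, vclass = v$vclass,
    muaf = map_dbl(res, 1), n_samples = map_dbl(res, 2)
  )
}

#' Select variants inside the per-class MuAF windows
#'
#' Retains SVs with MuAF in `[0.01, 0.99]`, CNVs in `[0.01, 1]`, kSTRs in
#' `[0.05, 1]`, and dSTRs in `[0.01, 1]` (inclusive bounds), the frequency
#' windows used before PCA.
#'
#' @param callset A [cohort_callset()].
#' @return Tibble of retained variants: `variant_id`, `vclass`, `muaf`.
#' @export
select_for_pca <- function(callset) {
  mf <- muaf(callset)
  lo <- c(SV = 0.01, CNV = 0.01, kSTR = 0.05, dSTR = 0.01)
  hi <- c(SV = 0.99, CNV = 1, kSTR = 1, dSTR = 1)
  grp <- dplyr::case_when(
    mf$vclass %in% c("SV_DEL", "SV_DUP", "SV_INV", "SV_MEI") ~ "SV",
    mf$vclass %in% c("CNV_DEL", "CNV_DUP") ~ "CNV",
    TRUE ~ mf$vclass
  )
  keep <- !is.na(mf$muaf) & mf$muaf >= lo[grp] & mf$muaf <= hi[grp]
  mf[keep, c("variant_id", "vclass", "muaf")]
}

# Internal: sample x variant numeric matrix for one variant class.
class_matrix <- function(callset, class_group, variant_ids = NULL) {
  v <- callset$variants
  cls <- switch(class_group,
    SV = c("SV_DEL", "SV_DUP", "SV_INV", "SV_MEI"),
    CNV = c("CNV_DEL", "CNV_DUP"),
    kSTR = "kSTR", dSTR = "dSTR",
    abort(paste0("unknown class group: ", class_group)))
  ids <- v$variant_id[v$vclass %in% cls]
  if (!is.null(variant_ids)) ids <- intersect(ids, variant_ids)
  if (!length(ids)) abort(paste0("no ", class_group, " variants to analyse"))
  m <- switch(class_group,
    SV = callset$genotypes[ids, , drop = FALSE],
    CNV = callset$cnv_sizes[ids, , drop = FALSE],
    kSTR = , dSTR = callset$repeats$a1[ids, , drop = FALSE] +
      callset$repeats$a2[ids, , drop = FALSE])
  t(m) # samples x variants
}

#' PCA stratification check
#'
#' Runs principal component analysis on a sample-by-variant matrix
#' (columns mean-imputed where missing, centered, not scaled) and tests
#' whether the leading component scores separate sample groups: phenotype,
#' region, sex, and median splits of age and sequencing depth, each by a
#' two-sided rank-sum test on PC1 and PC2 scores. Zero-variance columns
#' are dropped (count reported).
#'
#' @param x A [cohort_callset()] or a numeric sample-by-variant matrix.
#' @param class_group For a callset: which matrix to analyse, one of
#'   `"SV"`, `"CNV"`, `"kSTR"`, `"dSTR"`.
#' @param sample_groups For a matrix input: data frame of grouping columns
#'   aligned with the matrix rows (for a callset the sample table is used).
#' @param apply_muaf_window Restrict to variants inside the per-class MuAF
#'   window ([select_for_pca()]); callset input only.
#' @param exclude_chroms Chromosomes whose variants are excluded (e.g. sex
#'   chromosomes); callset input only.
#' @param n_components Number of components to keep.
#' @return Object of class `svbk_pca` with `scores`, `var_explained`,
#'   `separation` (tibble: `group`, `component`, `p`), `n_dropped`,
#'   `n_imputed`. [tidy()] returns scores, [glance()] variance explained,
#'   [autoplot()] a PC1/PC2 scatter.
#' @export
pca_check <- function(x, class_group = "SV", sample_groups = NULL,
                      apply_muaf_window = TRUE, exclude_chroms = NULL,
                      n_components = 2) {
  if (inherits(x, "cohort_callset")) {
    ids <- NULL
    if (apply_muaf_window) ids <- select_for_pca(x)$variant_id
    if (!is.null(exclude_chroms)) {
      keep <- x$variants$variant_id[!x$variants$chrom %in% exclude_chroms]
      ids <- if (is.null(ids)) keep else intersect(ids, keep)
    }
    m <- class_matrix(x, class_group, ids)
    sg <- x$samples
  } else {
    m <- as.matrix(x)
    sg <- as_tibble(sample_groups %||%
                      tibble(.rows = nrow(m)))
  }

  n_imputed <- sum(is.na(m))
  if (n_imputed > 0) {
    for (j in seq_len(ncol(m))) {
      mis <- is.na(m[, j])
      if (any(mis)) m[mis, j] <- mean(m[, j], na.rm = TRUE)
    }
    m[is.na(m)] <- 0
  }
  v <- apply(m, 2, stats::var)
  n_dropped <- sum(v == 0)
  m <- m[, v > 0, drop = FALSE]
  if (ncol(m) == 0) abort("no variable columns left for PCA")

  k <- min(n_components, ncol(m), nrow(m) - 1)
  pc <- prcomp(m, center = TRUE, scale. = FALSE, rank. = k)
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  if (!is.null(rownames(m))) scores <- mutate(scores, sample_id = rownames(m),
                                              .before = 1)
  scores <- dplyr::bind_cols(scores,
                             sg[setdiff(names(sg), names(scores))])

  grp_defs <- list()
  if ("phenotype" %in% names(sg)) grp_defs$phenotype <- sg$phenotype
  if ("region" %in% names(sg)) grp_defs$region <- sg$region
  if ("sex" %in% names(sg)) grp_defs$sex <- sg$sex
  if ("age" %in% names(sg)) {
    grp_defs$age_median_split <-
      ifelse(sg$age > stats::median(sg$age), "high", "low")
  }
  if ("mean_depth" %in% names(sg)) {
    grp_defs$depth_median_split <-
      ifelse(sg$mean_depth > stats::median(sg$mean_depth), "high", "low")
  }
  sep <- purrr::imap(grp_defs, function(g, nm) {
    lev <- unique(g)
    if (length(lev) != 2) return(NULL)
    bind_rows(lapply(seq_len(k), function(j) {
      p <- tryCatch(
        wilcox.test(pc$x[g == lev[1], j], pc$x[g == lev[2], j],
                    exact = FALSE)$p.value,
        error = function(e) NA_real_)
      tibble(group = nm, component = paste0("PC", j), p = p)
    }))
  })
  structure(list(
    scores = scores,
    sdev = pc$sdev,
    var_explained = pc$sdev[seq_len(k)]^2 / sum(pc$sdev^2),
    separation = bind_rows(sep),
    n_dropped = n_dropped, n_imputed = n_imputed,
    centered = TRUE, scaled = FALSE
  ), class = "svbk_pca")
}

#' @export
print.svbk_pca <- function(x, ...) {
  cat("<svbk_pca> ", nrow(x$scores), " samples; variance explained: ",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "),
      "\n", sep = "")
  if (x$n_dropped) cat("  dropped", x$n_dropped, "zero-variance columns\n")
  if (x$n_imputed) cat("  mean-imputed", x$n_imputed, "missing entries\n")
  print(x$separation)
  invisible(x)
}

#' @method tidy svbk_pca
#' @export
tidy.svbk_pca <- function(x, ...) x$scores

#' @method glance svbk_pca
#' @export
glance.svbk_pca <- function(x, ...) {
  tibble(n_components = length(x$var_explained),
         var_explained_pc1 = x$var_explained[1],
         n_dropped = x$n_dropped, n_imputed = x$n_imputed)
}

#' @method autoplot svbk_pca
#' @export
autoplot.svbk_pca <- function(object, colour = "phenotype", ...) {
  df <- object$scores
  stopifnot(all(c("PC1", "PC2") %in% names(df)))
  aes_col <- if (colour %in% names(df)) df[[colour]] else NULL
  ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    (if (is.null(aes_col)) ggplot2::geom_point() else
      ggplot2::geom_point(ggplot2::aes(colour = aes_col))) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2]),
      colour = colour
    ) +
    ggplot2::theme_minimal()
}
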