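# Internal: normalise expression input to list(counts, cell_types).
as_expr <- function(x, cell_types = NULL) {
  if (inherits(x, "expr_matrix")) return(x)
  m <- as.matrix(x)
  if (is.null(cell_types)) abort("cell_types required for a plain matrix")
  stopifnot(length(cell_types) == ncol(m))
  if (is.null(colnames(m))) {
    colnames(m) <- names(cell_types) %||% paste0("cell", seq_len(ncol(m)))
  }
  if (is.null(names(cell_types))) {
    cell_types <- setNames(cell_types, colnames(m))
  }
  structure(list(counts = m, cell_types = cell_types[colnames(m)]),
            class = "expr_matrix")
}

#' Cell-type specificity of gene expression
#'
#' For each gene, the mean expression within each cell type divided by the
#' sum of those means over all types, so rows sum to 1 for any expressed
#' gene. A gene expressed in a single type has specificity 1 there and 0
#' elsewhere.
#'
#' @param expr An `expr_matrix` (e.g. from [simulate_expression()]) or a
#'   gene-by-cell matrix.
#' @param cell_types For a plain matrix: cell-type label per column.
#' @return Tibble: `gene`, one column per cell type; genes with zero total
#'   expression get `NA` rows (their count is reported via a message).
#' @export
specificity <- function(expr, cell_types = NULL) {
  e <- as_expr(expr, cell_types)
  types <- unique(e$cell_types)
  if (length(types) < 2) abort("need at least 2 cell types")
  means <- vapply(types, function(tp) {
    rowMeans(e$counts[, e$cell_types == tp, drop = FALSE])
  }, numeric(nrow(e$counts)))
  tot <- rowSums(means)
  zero <- tot == 0
  if (any(zero)) {
    message(sum(zero), " gene(s) with zero expression everywhere: NA rows")
  }
  spec <- means / tot
  spec[zero, ] <- NA_real_
  dplyr::bind_cols(tibble(gene = rownames(e$counts)), as_tibble(spec))
}

#' Bootstrap cell-type enrichment of a gene set
#'
#' Tests whether a target gene set's mean cell-type specificity exceeds
#' that of random gene sets of the same size: `n_boot` sets are drawn
#' uniformly from all expressed genes, and per cell type the p value is
#' `(1 + #{bootstrap mean >= target mean}) / (1 + n_boot)` (the add-one
#' estimator, never exactly zero). Deterministic given `seed`.
#'
#' @param expr An `expr_matrix` or gene-by-cell matrix.
#' @param target_genes Character vector of genes to test (intersected with
#'   the matrix rows; an empty intersection is an error).
#' @param n_boot Number of bootstrap gene sets (> 0).
#' @param seed Integer seed.
#' @param cell_types For a plain matrix input.
#' @return Tibble: `cell_type`, `target_mean_specificity`, `p`, `n_target`,
#'   `n_boot`.
#' @export
ewce_bootstrap <- function(expr, target_genes, n_boot = 10000, seed = 1,
                           cell_types = NULL) {
  if (n_boot <= 0) abort("n_boot must be positive")
  e <- as_expr(expr, cell_types)
  spec <- specificity(e)
  smat <- as.matrix(spec[, -1])
  rownames(smat) <- spec$gene
  expressed <- rownames(smat)[!is.na(smat[, 1])]
  smat <- smat[expressed, , drop = FALSE]
  target <- intersect(target_genes, expressed)
  if (length(target) == 0) {
    abort("input error: no target genes present in the expression matrix")
  }
  set.seed(as.integer(seed))
  tmean <- colMeans(smat[target, , drop = FALSE])
  k <- length(target)
  boot <- matrix(NA_real_, n_boot, ncol(smat))
  for (b in seq_len(n_boot)) {
    boot[b, ] <- colMeans(smat[sample(nrow(smat), k), , drop = FALSE])
  }
  p <- vapply(seq_len(ncol(smat)), function(j) {
    (1 + sum(boot[, j] >= tmean[j])) / (1 + n_boot)
  }, numeric(1))
  tibble(cell_type = colnames(smat),
         target_mean_specificity = unname(tmean),
         p = p, n_target = k, n_boot = n_boot)
}

#' Fold-change standard deviation of a gene across cells
#'
#' Fold-change in cell i is the gene's expression in that cell divided by
#' its mean expression over the chosen cells; the statistic is the sample
#' standard deviation (n - 1 denominator) of those fold-changes. It is
#' invariant to rescaling the gene's expression vector, and 0 exactly when
#' expression is constant. Dosage-sensitive genes are expected to show low
#' values, loss-of-function-tolerant genes high values.
#'
#' @param expr An `expr_matrix` or gene-by-cell matrix.
#' @param genes Genes to score (default: all).
#' @param cell_subset Cells (or a cell-type name) to restrict to; the
#'   subset is an explicit argument because the comparison is usually run
#'   within one cell type.
#' @param cell_types For a plain matrix input.
#' @return Tibble: `gene`, `n_cells`, `sd` (`NA` when the gene's mean
#'   expression over the subset is 0).
#' @export
fold_change_sd <- function(expr, genes = NULL, cell_subset = NULL,
                           cell_types = NULL) {
  e <- as_expr(expr, cell_types)
  cols <- colnames(e$counts)
  if (!is.null(cell_subset)) {
    if (length(cell_subset) == 1 && cell_subset %in% e$cell_types) {
      cols <- names(e$cell_types)[e$cell_types == cell_subset]
    } else {
      cols <- intersect(cell_subset, cols)
    }
    if (!length(cols)) abort("cell_subset matches no cells")
  }
  genes <- genes %||% rownames(e$counts)
  genes <- intersect(genes, rownames(e$counts))
  if (!length(genes)) abort("input error: no requested genes in the matrix")
  m <- e$counts[genes, cols, drop = FALSE]
  mu <- rowMeans(m)
  sds <- rep(NA_real_, length(genes))
  pos <- mu > 0
  if (any(pos)) {
    fc <- m[pos, , drop = FALSE] / mu[pos]
    sds[pos] <- apply(fc, 1, sd)
  }
  tibble(gene = genes, n_cells = length(cols), sd = sds)
}

#' Compare fold-change SDs of a target gene set with reference sets
#'
#' One-sided rank-sum test of the target genes' fold-change SDs being
#' lower than those of the loss-of-function-tolerant (LofT) set, and a
#' two-sided comparison against the known dosage-sensitive set, within an
#' explicit cell subset.
#'
#' @param expr An `expr_matrix` or gene-by-cell matrix.
#' @param target_genes,sensitive_set,loft_set Gene sets (intersected with
#'   matrix rows; empty intersections are an error).
#' @param cell_subset Cells or one cell-type name (required focus of the
#'   comparison).
#' @param cell_types For a plain matrix input.
#' @return Tibble with one row per comparison: `comparison`, `alternative`,
#'   `n_target`, `n_reference`, `median_target`, `median_reference`, `p`.
#' @export
compare_sd <- function(expr, target_genes, sensitive_set, loft_set,
                       cell_subset, cell_types = NULL) {
  e <- as_expr(expr, cell_types)
  sd_of <- function(genes, label) {
    g <- intersect(genes, rownames(e$counts))
    if (!length(g)) abort(paste0("input error: empty ", label, " gene set"))
    na.omit(fold_change_sd(e, g, cell_subset)$sd)
  }
  s_t <- sd_of(target_genes, "target")
  s_s <- sd_of(sensitive_set, "sensitive")
  s_l <- sd_of(loft_set, "LofT")
  p_loft <- suppressWarnings(
    wilcox.test(s_t, s_l, alternative = "less", exact = FALSE)$p.value)
  p_sens <- suppressWarnings(
    wilcox.test(s_t, s_s, alternative = "two.sided", exact = FALSE)$p.value)
  tibble(
    comparison = c("target_vs_loft", "target_vs_sensitive"),
    alternative = c("less", "two.sided"),
    n_target = length(s_t), n_reference = c(length(s_l), length(s_s)),
    median_target = stats::median(s_t),
    median_reference = c(stats::median(s_l), stats::median(s_s)),
    p = c(p_loft, p_sens)
  )
}
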