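#' Assign CNV calls to fixed genomic windows by midpoint
#'
#' Each record is assigned to exactly one window via the physical position
#' of its midpoint, `floor((start + end) / 2)`. Windows are half-open
#' `[k * window_size, (k + 1) * window_size)` in 0-based space, so a
#' midpoint falling exactly on a boundary lands in the right-hand window;
#' the last window of a chromosome may be short.
#'
#' @param cnv_calls Tibble of per-sample CNV records: `sample_id`, `chrom`,
#'   `start`, `end`.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param window_size Window width in bp.
#' @param sample_ids Optional full roster of samples (so samples with zero
#'   CNVs keep a column of zeros).
#' @return Object of class `window_counts`: list with `counts` (window by
#'   sample matrix) and `windows` (tibble: `chrom`, `window_index`,
#'   `wstart`, `wend`).
#' @export
assign_windows <- function(cnv_calls, chrom_lengths, window_size = 5e6,
                           sample_ids = NULL) {
  cnv_calls <- as_tibble(cnv_calls)
  bad_chrom <- setdiff(unique(cnv_calls$chrom), names(chrom_lengths))
  if (length(bad_chrom)) {
    abort(paste0("coordinate error: unknown chromosome(s) ",
                 paste(bad_chrom, collapse = ", ")))
  }
  over <- cnv_calls$end > chrom_lengths[cnv_calls$chrom]
  if (any(over)) {
    i <- which(over)[1]
    abort(paste0("coordinate error: record ", cnv_calls$chrom[i], ":",
                 format(cnv_calls$start[i], scientific = FALSE), "-",
                 format(cnv_calls$end[i], scientific = FALSE),
                 " extends beyond its chromosome"))
  }

  windows <- bind_rows(imap(as.list(chrom_lengths), function(L, ch) {
    nw <- ceiling(L / window_size)
    tibble(chrom = ch, window_index = seq_len(nw) - 1L,
           wstart = (seq_len(nw) - 1) * window_size,
           wend = pmin(seq_len(nw) * window_size, L))
  }))
  wkey <- paste(windows$chrom, windows$window_index)

  samples <- sample_ids %||% sort(unique(cnv_calls$sample_id))
  counts <- matrix(0L, nrow(windows), length(samples),
                   dimnames = list(wkey, samples))
  if (nrow(cnv_calls)) {
    mid <- floor((cnv_calls$start + cnv_calls$end) / 2)
    widx <- pmin(mid %/% window_size,
                 ceiling(chrom_lengths[cnv_calls$chrom] / window_size) - 1)
    key <- paste(cnv_calls$chrom, widx)
    tab <- table(key, factor(cnv_calls$sample_id, levels = samples))
    counts[rownames(tab), ] <- counts[rownames(tab), , drop = FALSE] +
      as.matrix(unclass(tab))
  }
  structure(list(counts = counts, windows = windows,
                 window_size = window_size),
            class = "window_counts")
}

# Internal: one-sided rank-sum p (cases > controls), normal approximation
# with tie correction, or an exact variant for small groups.
rank_test_greater <- function(x_case, x_control, exact = FALSE) {
  if (length(x_case) < 2 || length(x_control) < 2) {
    abort("undefined test: each group needs at least 2 samples")
  }
  if (all(c(x_case, x_control) == c(x_case, x_control)[1])) return(NA_real_)
  suppressWarnings(
    wilcox.test(x_case, x_control, alternative = "greater",
                exact = exact, correct = TRUE)$p.value
  )
}

#' Per-window case-control CNV count tests
#'
#' One-sided rank-sum test (alternative: cases carry more CNVs than
#' controls) on per-sample counts in every window.
#'
#' @param window_counts A `window_counts` object from [assign_windows()].
#' @param samples Sample table with `sample_id` and `phenotype`.
#' @return Tibble of class `svbk_burden`: window coordinates, per-group
#'   mean counts, and `p_one_sided` (NA for windows with all-equal counts).
#' @export
window_tests <- function(window_counts, samples) {
  stopifnot(inherits(window_counts, "window_counts"))
  samples <- as_tibble(samples)
  idx <- match(colnames(window_counts$counts), samples$sample_id)
  stopifnot(!anyNA(idx))
  pheno <- samples$phenotype[idx]
  if (!all(table(pheno) >= 2) || length(unique(pheno)) < 2) {
    abort("undefined test: need at least 2 cases and 2 controls")
  }
  ca <- pheno == "case"
  m <- window_counts$counts
  res <- window_counts$windows
  res$mean_cases <- rowMeans(m[, ca, drop = FALSE])
  res$mean_controls <- rowMeans(m[, !ca, drop = FALSE])
  res$p_one_sided <- vapply(seq_len(nrow(m)), function(i) {
    rank_test_greater(m[i, ca], m[i, !ca])
  }, numeric(1))
  class(res) <- c("svbk_burden", class(res))
  res
}

#' Chromosome-terminal CNV burden by distance bin
#'
#' Aggregates each sample's window counts into distance-from-chromosome-end
#' bins (0-5 Mb, 5-10 Mb, ..., by default out to 50 Mb), summing over the
#' corresponding windows at both ends of every autosome (p- and q-terminal;
#' restrict with `ends`). Chromosome/bin combinations that would reach past
#' the chromosome midpoint are skipped (their count is reported). Each bin
#' is tested with the one-sided rank-sum test (cases > controls).
#'
#' @param window_counts A `window_counts` object from [assign_windows()].
#' @param samples Sample table with `sample_id` and `phenotype`.
#' @param n_bins Number of distance bins.
#' @param ends `"both"`, `"left"`, or `"right"` chromosome ends.
#' @return Tibble of class `svbk_terminal`: `bin`, `dist_lo`, `dist_hi`
#'   (Mb), per-group means and SDs, `p_one_sided`, `n_windows`,
#'   `n_chrom_skipped`.
#' @export
terminal_burden <- function(window_counts, samples, n_bins = 10,
                            ends = c("both", "left", "right")) {
  stopifnot(inherits(window_counts, "window_counts"))
  ends <- match.arg(ends)
  samples <- as_tibble(samples)
  pheno <- samples$phenotype[match(colnames(window_counts$counts),
                                   samples$sample_id)]
  ca <- pheno == "case"
  w <- window_counts$windows
  ws <- window_counts$window_size
  nw_by_chrom <- table(w$chrom)

  out <- vector("list", n_bins)
  for (d in seq_len(n_bins)) {
    rows <- integer(0)
    skipped <- 0L
    for (ch in names(nw_by_chrom)) {
      nw <- as.integer(nw_by_chrom[[ch]])
      if ((d - 1) >= nw / 2) { skipped <- skipped + 1L; next }
      left <- which(w$chrom == ch & w$window_index == d - 1L)
      right <- which(w$chrom == ch & w$window_index == nw - d)
      rows <- c(rows,
                switch(ends, both = unique(c(left, right)),
                       left = left, right = right))
    }
    tot <- if (length(rows)) {
      colSums(window_counts$counts[rows, , drop = FALSE])
    } else rep(0, ncol(window_counts$counts))
    p <- if (all(tot == 0)) NA_real_ else rank_test_greater(tot[ca], tot[!ca])
    out[[d]] <- tibble(
      bin = d, dist_lo = (d - 1) * ws / 1e6, dist_hi = d * ws / 1e6,
      mean_cases = mean(tot[ca]), sd_cases = sd(tot[ca]),
      mean_controls = mean(tot[!ca]), sd_controls = sd(tot[!ca]),
      p_one_sided = p, n_windows = length(rows), n_chrom_skipped = skipped
    )
  }
  res <- bind_rows(out)
  class(res) <- c("svbk_terminal", class(res))
  res
}

#' Terminal-burden trend across age groups
#'
#' Bins samples (intended: controls) into ordered age groups by
#' equal-frequency quantiles and tests for a monotone trend in their
#' terminal CNV counts: either a least-squares regression of count on
#' group rank (default) or a Jonckheere-Terpstra rank test (normal
#' approximation).
#'
#' @param counts Per-sample terminal CNV counts.
#' @param ages Ages (years), aligned with `counts`.
#' @param n_groups Number of ordered age groups.
#' @param method `"lm"` or `"jonckheere"`.
#' @return One-row tibble: `method`, `n_groups`, `slope` (lm only),
#'   `statistic`, `p_trend`; attribute `group_means` holds per-group mean
#'   counts.
#' @export
age_trend <- function(counts, ages, n_groups = 4,
                      method = c("lm", "jonckheere")) {
  method <- match.arg(method)
  stopifnot(length(counts) == length(ages))
  if (length(unique(ages)) < n_groups) {
    abort("binning error: fewer distinct ages than age groups")
  }
  brks <- quantile(ages, probs = seq(0, 1, length.out = n_groups + 1))
  if (anyDuplicated(brks)) {
    abort("binning error: age quantiles are not distinct")
  }
  grp <- as.integer(cut(ages, brks, include.lowest = TRUE))

  gm <- tibble(group = sort(unique(grp))) |>
    mutate(mean_count = map_dbl(.data$group, ~ mean(counts[grp == .x])),
           n = map_dbl(.data$group, ~ sum(grp == .x)))

  if (method == "lm") {
    if (sd(counts) == 0) {
      res <- tibble(method = method, n_groups = n_groups, slope = 0,
                    statistic = NA_real_, p_trend = NA_real_)
    } else {
      fit <- lm(counts ~ grp)
      sm <- summary(fit)$coefficients
      res <- tibble(method = method, n_groups = n_groups,
                    slope = sm[2, 1], statistic = sm[2, 3],
                    p_trend = sm[2, 4])
    }
  } else {
    res <- tibble(method = method, n_groups = n_groups, slope = NA_real_)
    jt <- jonckheere_stat(counts, grp)
    res$statistic <- jt["z"]
    res$p_trend <- 2 * pnorm(-abs(jt["z"]))
  }
  attr(res, "group_means") <- gm
  res
}

# Jonckheere-Terpstra statistic, normal approximation (no tie correction
# in the variance; ties contribute 1/2 to U).
jonckheere_stat <- function(x, grp) {
  lev <- sort(unique(grp))
  U <- 0
  for (i in seq_along(lev)) {
    for (j in seq_along(lev)) {
      if (i < j) {
        xi <- x[grp == lev[i]]; xj <- x[grp == lev[j]]
        U <- U + sum(outer(xi, xj, "<")) + 0.5 * sum(outer(xi, xj, "=="))
      }
    }
  }
  n <- length(x)
  ni <- table(grp)
  mu <- (n^2 - sum(ni^2)) / 4
  v <- (n^2 * (2 * n + 3) - sum(ni^2 * (2 * ni + 3))) / 72
  c(U = U, z = (U - mu) / sqrt(v))
}

#' @method autoplot svbk_burden
#' @export
autoplot.svbk_burden <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(chrom = factor(.data$chrom, levels = unique(.data$chrom)),
           neglog10p = -log10(.data$p_one_sided))
  ggplot2::ggplot(df, ggplot2::aes(.data$wstart / 1e6, .data$neglog10p)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "window start (Mb)",
                  y = expression(-log[10] ~ p ~ "(cases > controls)")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing = ggplot2::unit(0.1, "lines"),
                   axis.text.x = ggplot2::element_blank())
}

#' @method autoplot svbk_terminal
#' @export
autoplot.svbk_terminal <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("mean_cases", "mean_controls"),
                        names_to = "group", values_to = "mean_count") |>
    mutate(group = sub("mean_", "", .data$group))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$bin), .data$mean_count,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "distance bin from chromosome end (5 Mb each)",
                  y = "mean CNV count per sample", fill = NULL) +
    ggplot2::theme_minimal()
}
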