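#' Odds ratio from two proportions
#'
#' `(f_case / (1 - f_case)) / (f_control / (1 - f_control))`. Works
#' identically whether the proportions are allele frequencies or carrier
#' frequencies.
#'
#' @param f_case,f_control Proportions strictly inside (0, 1).
#' @return Odds ratio (vectorised).
#' @export
#' @examples
#' or_from_freqs(0.288, 0.450) # ~0.49
or_from_freqs <- function(f_case, f_control) {
  if (any(f_case <= 0 | f_case >= 1 | f_control <= 0 | f_control >= 1)) {
    abort("infinite-odds error: frequencies must lie strictly in (0, 1)")
  }
  (f_case / (1 - f_case)) / (f_control / (1 - f_control))
}

# Firth-penalized logistic regression (Jeffreys-prior score correction);
# used as fallback when the ML fit separates.
firth_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    W <- p * (1 - p)
    XWX <- crossprod(X, X * W)
    XWXinv <- tryCatch(solve(XWX), error = function(e) NULL)
    if (is.null(XWXinv)) break
    H <- (X * sqrt(W)) %*% XWXinv %*% t(X * sqrt(W))
    h <- diag(H)
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- drop(XWXinv %*% U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  W <- plogis(eta) * (1 - plogis(eta))
  se <- sqrt(diag(solve(crossprod(X, X * W))))
  list(coef = beta, se = se)
}

# Internal: logistic association of phenotype on one predictor with
# covariates; Wald p; Firth fallback on separation.
logistic_assoc <- function(y, x, covar) {
  X <- cbind(`(Intercept)` = 1, x = x, covar)
  keep <- complete.cases(X) & !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  # drop constant covariate columns (can happen in small strata)
  const <- apply(X[, -1, drop = FALSE], 2, function(v) sd(v) == 0)
  X <- X[, c(TRUE, !const), drop = FALSE]

  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  separated <- !fit$converged || any(abs(fit$coefficients) > 15) ||
    any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  if (separated) {
    ff <- firth_logistic(X, y)
    est <- ff$coef[2]; se <- ff$se[2]
  } else {
    p_fit <- fit$fitted.values
    W <- p_fit * (1 - p_fit)
    cov_mat <- tryCatch(solve(crossprod(X, X * W)), error = function(e) NULL)
    if (is.null(cov_mat)) {
      ff <- firth_logistic(X, y)
      est <- ff$coef[2]; se <- ff$se[2]
      separated <- TRUE
    } else {
      est <- fit$coefficients[2]; se <- sqrt(diag(cov_mat))[2]
    }
  }
  z <- est / se
  list(effect = unname(est), p = 2 * pnorm(-abs(z)),
       delta = sign(unname(est)), n = length(y), firth = separated)
}

#' Stratified per-variant association test
#'
#' Runs the class-appropriate case-control test separately within each
#' regional stratum:
#' * SV: logistic regression of phenotype on allele dosage (additive
#'   0/1/2 coding) with covariates, Wald test;
#' * CNV: logistic regression on per-sample affected kilobases;
#' * STR: one-sided rank-sum test on per-sample total repeat numbers, the
#'   alternative being fixed by the effect direction in the first
#'   (discovery) stratum.
#'
#' Default covariates are sex, age, and the top two principal components
#' of the stratum's SV dosage matrix. Complete separation triggers a
#' Firth-penalized refit, flagged in the output. Monomorphic variants are
#' reported with `NA` p.
#'
#' @param callset A [cohort_callset()].
#' @param variant_id Variant to test.
#' @param covariates Subset of `c("sex", "age", "PC1", "PC2")`.
#' @param strata Sample column defining strata (default `"region"`), or
#'   `NULL` for a single unstratified analysis.
#' @return Tibble, one row per stratum: `variant_id`, `stratum`, `n`,
#'   `effect`, `delta`, `p`, `method`, `firth`.
#' @export
assoc_variant <- function(callset, variant_id,
                          covariates = c("sex", "age", "PC1", "PC2"),
                          strata = "region") {
  stopifnot(inherits(callset, "cohort_callset"))
  v <- callset$variants
  i <- match(variant_id, v$variant_id)
  if (is.na(i)) abort(paste0("unknown variant: ", variant_id))
  vclass <- v$vclass[i]
  smp <- callset$samples
  strat_vals <- if (is.null(strata)) rep("all", nrow(smp)) else smp[[strata]]
  strata_levels <- unique(strat_vals)

  want_pcs <- any(c("PC1", "PC2") %in% covariates)
  alternative <- NULL
  out <- vector("list", length(strata_levels))
  for (si in seq_along(strata_levels)) {
    sl <- strata_levels[si]
    in_s <- strat_vals == sl
    y <- as.integer(smp$phenotype[in_s] == "case")
    n_s <- sum(in_s)

    covar <- NULL
    if ("sex" %in% covariates) {
      covar <- cbind(covar, sex = as.integer(smp$sex[in_s] == "male"))
    }
    if ("age" %in% covariates) covar <- cbind(covar, age = smp$age[in_s])
    if (want_pcs && !is.null(callset$genotypes)) {
      sv_ids <- v$variant_id[v$vclass %in%
                               c("SV_DEL", "SV_DUP", "SV_INV", "SV_MEI")]
      sv_ids <- setdiff(sv_ids, variant_id)
      if (length(sv_ids) >= 3) {
        m <- t(callset$genotypes[sv_ids, in_s, drop = FALSE])
        for (j in seq_len(ncol(m))) {
          mis <- is.na(m[, j])
          if (any(mis)) m[mis, j] <- mean(m[, j], na.rm = TRUE)
        }
        m[is.na(m)] <- 0
        m <- m[, apply(m, 2, sd) > 0, drop = FALSE]
        if (ncol(m) >= 2) {
          pcs <- prcomp(m, center = TRUE, rank. = 2)$x
          for (pc in intersect(c("PC1", "PC2"), covariates)) {
            if (pc %in% colnames(pcs)) {
              covar <- cbind(covar, pcs[, pc, drop = FALSE])
            }
          }
        }
      }
    }

    if (vclass %in% c("SV_DEL", "SV_DUP", "SV_INV", "SV_MEI")) {
      x <- callset$genotypes[variant_id, in_s]
      method <- "logistic_dosage"
    } else if (vclass %in% c("CNV_DEL", "CNV_DUP")) {
      x <- callset$cnv_sizes[variant_id, in_s] / 1000
      method <- "logistic_size"
    } else {
      x <- callset$repeats$a1[variant_id, in_s] +
        callset$repeats$a2[variant_id, in_s]
      method <- "ranksum_repeats"
    }

    if (sd(x, na.rm = TRUE) == 0 || all(is.na(x))) {
      out[[si]] <- tibble(variant_id = variant_id, stratum = sl, n = n_s,
                          effect = NA_real_, delta = NA_real_, p = NA_real_,
                          method = method, firth = FALSE)
      next
    }

    if (method == "ranksum_repeats") {
      xc <- x[y == 1]; xn <- x[y == 0]
      shift <- mean(rank(x)[y == 1]) - mean(rank(x)[y == 0])
      if (is.null(alternative)) {
        alternative <- if (shift >= 0) "greater" else "less"
      }
      p <- suppressWarnings(
        wilcox.test(xc, xn, alternative = alternative,
                    exact = FALSE)$p.value)
      out[[si]] <- tibble(variant_id = variant_id, stratum = sl, n = n_s,
                          effect = shift, delta = sign(shift), p = p,
                          method = paste0(method, "_", alternative),
                          firth = FALSE)
    } else {
      la <- logistic_assoc(y, x, covar)
      out[[si]] <- tibble(variant_id = variant_id, stratum = sl, n = la$n,
                          effect = la$effect, delta = la$delta, p = la$p,
                          method = method, firth = la$firth)
    }
  }
  bind_rows(out)
}

#' Sample-size-weighted Stouffer Z meta-analysis
#'
#' Each stratum's p value is transformed to a direction-signed Z score,
#' `Z_i = qnorm(P_i / 2) * sign(delta_i)` (note `qnorm(P/2)` is negative,
#' so a positive-direction effect yields a negative `Z_i`; the combined
#' statistic is used through its absolute value, which makes the meta p
#' invariant to this global sign convention). Weights are `W_i =
#' sqrt(N_i)` and the combined statistic is
#' `z = sum(Z_i W_i) / sqrt(sum(W_i^2))`. The two-sided meta p is
#' `2 * pnorm(-|z|)`; a single stratum therefore returns its own p
#' unchanged. Setting `literal_tail = TRUE` reproduces the upper-tail
#' variant `2 * pnorm(|z|)` for audit; it exceeds 1 and is not used
#' anywhere in the package.
#'
#' @param stratum_results Tibble with columns `p`, `n`, `delta` (rows with
#'   `NA` p are dropped), e.g. from [assoc_variant()].
#' @param gw_threshold Genome-wide significance threshold on the meta p.
#' @param replication_threshold Bonferroni replication threshold.
#' @param literal_tail Use the upper tail instead of the lower (audit only).
#' @return One-row tibble: `meta_z`, `meta_p`, `n_total`, `n_strata`,
#'   `passes_gw`, `passes_replication`.
#' @export
#' @examples
#' meta_combine(tibble::tibble(p = c(0.05, 0.05), n = c(500, 500),
#'                             delta = c(1, 1)))
meta_combine <- function(stratum_results, gw_threshold = 5e-8,
                         replication_threshold = 0.05 / 11,
                         literal_tail = FALSE) {
  d <- filter(as_tibble(stratum_results), !is.na(.data$p))
  if (nrow(d) == 0) {
    return(tibble(meta_z = NA_real_, meta_p = NA_real_, n_total = 0L,
                  n_strata = 0L, passes_gw = FALSE,
                  passes_replication = FALSE))
  }
  if (any(d$p <= 0 | d$p > 1)) {
    abort("domain error: p values must lie in (0, 1]")
  }
  zi <- qnorm(d$p / 2) * sign(d$delta)
  wi <- sqrt(d$n)
  z <- sum(zi * wi) / sqrt(sum(wi^2))
  meta_p <- if (literal_tail) 2 * pnorm(abs(z)) else 2 * pnorm(-abs(z))
  tibble(
    meta_z = z, meta_p = meta_p,
    n_total = sum(d$n), n_strata = nrow(d),
    passes_gw = !is.na(meta_p) && meta_p < gw_threshold,
    passes_replication = !is.na(meta_p) && meta_p < replication_threshold
  )
}

#' Genome-wide stratified association scan with meta-analysis
#'
#' Applies the MuAF > `min_freq` inclusion rule, tests every retained
#' variant with [assoc_variant()] in each regional stratum, and combines
#' strata with [meta_combine()].
#'
#' @param callset A [cohort_callset()].
#' @param min_freq Minimum mutated-allele/carrier frequency for inclusion
#'   (strict).
#' @param covariates,strata Passed to [assoc_variant()].
#' @return Tibble of class `svbk_assoc`, one row per tested variant:
#'   coordinates, meta statistics, significance flags, and a `strata`
#'   list column of per-stratum results. [tidy()] unnests the stratum
#'   rows; [glance()] counts significant hits; [autoplot()] draws a
#'   Manhattan plot.
#' @export
assoc_scan <- function(callset, min_freq = 0.01,
                       covariates = c("sex", "age", "PC1", "PC2"),
                       strata = "region") {
  stopifnot(inherits(callset, "cohort_callset"))
  mf <- muaf(callset)
  keep <- mf$variant_id[!is.na(mf$muaf) & mf$muaf > min_freq &
                          (!startsWith(mf$vclass, "SV") | mf$muaf < 1)]
  res <- map(keep, function(id) {
    st <- assoc_variant(callset, id, covariates = covariates,
                        strata = strata)
    meta <- meta_combine(st)
    mutate(meta, variant_id = id, strata = list(st), .before = 1)
  })
  res <- bind_rows(res)
  res <- left_join(res,
                   select(callset$variants, "variant_id", "chrom",
                          "start", "end", "vclass"),
                   by = "variant_id") |>
    select("variant_id", "chrom", "start", "end", "vclass",
           dplyr::everything())
  class(res) <- c("svbk_assoc", class(res))
  res
}

#' @method tidy svbk_assoc
#' @export
tidy.svbk_assoc <- function(x, ...) {
  d <- as_tibble(x)[, c("vclass", "strata")]
  tidyr::unnest(d, "strata") |>
    select("variant_id", "vclass", dplyr::everything())
}

#' @method glance svbk_assoc
#' @export
glance.svbk_assoc <- function(x, ...) {
  tibble(n_tested = nrow(x),
         n_genome_wide = sum(x$passes_gw, na.rm = TRUE),
         n_replication = sum(x$passes_replication, na.rm = TRUE),
         min_meta_p = suppressWarnings(min(x$meta_p, na.rm = TRUE)))
}

#' @method autoplot svbk_assoc
#' @export
autoplot.svbk_assoc <- function(object, gw_threshold = 5e-8, ...) {
  df <- as_tibble(object) |>
    mutate(chrom = factor(.data$chrom, levels = unique(.data$chrom)),
           neglog10p = -log10(.data$meta_p))
  ggplot2::ggplot(df, ggplot2::aes(.data$start / 1e6, .data$neglog10p,
                                   colour = .data$vclass)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::geom_hline(yintercept = -log10(gw_threshold),
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_grid(~chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10] ~ meta ~ p),
                  colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing = ggplot2::unit(0.1, "lines"),
                   axis.text.x = ggplot2::element_blank())
}
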