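#' Power of a two-sided two-sample location test
#'
#' Normal-approximation power for detecting a standardized mean difference
#' `delta_sd` between groups of size `n1` and `n2` at two-sided level
#' `alpha`:
#' `power = pnorm(ncp - qnorm(1 - alpha / 2)) +
#'          pnorm(-ncp - qnorm(1 - alpha / 2))`
#' with `ncp = delta_sd * sqrt(n1 * n2 / (n1 + n2))`; the second
#' (opposite-tail) term keeps the size exact at `delta_sd = 0` and is
#' negligible for real effects. A Monte-Carlo mode
#' simulates normal samples and applies the two-sided Welch t test.
#'
#' @param n1,n2 Group sizes.
#' @param alpha Two-sided type-I error.
#' @param delta_sd Standardized mean difference between group means.
#' @param method `"normal"` (closed form) or `"montecarlo"`.
#' @param n_sim Monte-Carlo replicates.
#' @param seed Seed for the Monte-Carlo mode.
#' @return Power in `[0, 1]`.
#' @export
#' @examples
#' power_two_sample(466, 513, alpha = 0.05 / 100000, delta_sd = 0.325)
power_two_sample <- function(n1, n2, alpha, delta_sd,
                             method = c("normal", "montecarlo"),
                             n_sim = 20000, seed = 1) {
  stopifnot(n1 > 1, n2 > 1, alpha > 0, alpha < 1, delta_sd >= 0)
  method <- match.arg(method)
  if (method == "normal") {
    ncp <- delta_sd * sqrt(n1 * n2 / (n1 + n2))
    zcrit <- qnorm(1 - alpha / 2)
    return(pnorm(ncp - zcrit) + pnorm(-ncp - zcrit))
  }
  set.seed(as.integer(seed))
  crit <- qnorm(1 - alpha / 2)
  hits <- 0L
  for (b in seq_len(n_sim)) {
    x <- rnorm(n1, mean = delta_sd)
    y <- rnorm(n2)
    z <- (mean(x) - mean(y)) /
      sqrt(stats::var(x) / n1 + stats::var(y) / n2)
    if (abs(z) >= crit) hits <- hits + 1L
  }
  hits / n_sim
}

#' Power curve of a two-proportion allele test over allele frequencies
#'
#' For each control minor-allele frequency on `maf_grid`, derives the case
#' allele frequency implied by the supplied genotype relative risk
#' (`p1 = rr * p0 / (1 + (rr - 1) * p0)`) and evaluates the power of the
#' two-sided two-proportion z test on allele counts (`2 * n` alleles per
#' group).
#'
#' @param n_case,n_control Numbers of individuals per group.
#' @param alpha Two-sided type-I error.
#' @param maf_grid Control allele frequencies to evaluate.
#' @param genotype_rr Per-allele relative risk (must be supplied; the
#'   effect size is a modelling choice, not an estimate).
#' @return Tibble: `maf`, `f_case`, `power`.
#' @export
power_allele <- function(n_case, n_control, alpha,
                         maf_grid = seq(0.05, 0.6, by = 0.05),
                         genotype_rr) {
  stopifnot(n_case > 1, n_control > 1, alpha > 0, alpha < 1,
            genotype_rr > 0, all(maf_grid > 0), all(maf_grid < 1))
  p0 <- maf_grid
  p1 <- genotype_rr * p0 / (1 + (genotype_rr - 1) * p0)
  m1 <- 2 * n_case
  m0 <- 2 * n_control
  se <- sqrt(p1 * (1 - p1) / m1 + p0 * (1 - p0) / m0)
  zcrit <- qnorm(1 - alpha / 2)
  ncp <- abs(p1 - p0) / se
  tibble(maf = p0, f_case = p1,
         power = pnorm(ncp - zcrit) + pnorm(-ncp - zcrit))
}
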