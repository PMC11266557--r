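# x * log(p) with the 0 * log(0) = 0 limit, so epsilon = 0 is exact.
xlogp <- function(x, p) ifelse(x == 0, 0, x * log(p))

#' Binomial genotype likelihoods for a biallelic STR
#'
#' At a locus with a short (5-repeat) and a long (6-repeat) allele, given
#' `n` informative reads of which `k` support the long allele and a
#' per-read error rate `epsilon`, the three genotype likelihoods are
#' `L(5|5) = C(n,k) (1-e)^(n-k) e^k`, `L(5|6) = C(n,k) (1/2)^n`,
#' `L(6|6) = C(n,k) (1-e)^k e^(n-k)`. Computed in log space.
#'
#' @param n,k Total informative reads and long-allele-supporting reads
#'   (vectorised; `0 <= k <= n`).
#' @param epsilon Per-read error probability in `[0, 0.5)`.
#' @return Tibble: `n`, `k`, `loglik_55`, `loglik_56`, `loglik_66`,
#'   `lik_55`, `lik_56`, `lik_66`. Rows with `n = 0` carry `NA`
#'   likelihoods (no-call).
#' @export
#' @examples
#' genotype_likelihoods(10, 0)$lik_55 # 0.95^10
genotype_likelihoods <- function(n, k, epsilon = 0.05) {
  if (epsilon < 0 || epsilon >= 0.5) {
    abort("configuration error: epsilon must lie in [0, 0.5)")
  }
  stopifnot(all(k >= 0), all(k <= n), all(n >= 0))
  lc <- lchoose(n, k)
  l55 <- lc + xlogp(n - k, 1 - epsilon) + xlogp(k, epsilon)
  l56 <- lc + n * log(0.5)
  l66 <- lc + xlogp(k, 1 - epsilon) + xlogp(n - k, epsilon)
  out <- tibble(n = as.integer(n), k = as.integer(k),
                loglik_55 = l55, loglik_56 = l56, loglik_66 = l66,
                lik_55 = exp(l55), lik_56 = exp(l56), lik_66 = exp(l66))
  nocall <- out$n == 0
  out[nocall, c("loglik_55", "loglik_56", "loglik_66",
                "lik_55", "lik_56", "lik_66")] <- NA_real_
  out
}

#' Maximum-likelihood genotype call from STR read support
#'
#' Picks the genotype maximising the binomial likelihoods of
#' [genotype_likelihoods()]. Samples with fewer than `min_depth`
#' informative reads, and exact likelihood ties (possible at `k = n/2`),
#' return `"no-call"` rather than an arbitrary pick.
#'
#' @param support Tibble with columns `n` and `k` (e.g. from
#'   [simulate_str_reads()]); other columns are carried through.
#' @param epsilon Per-read error probability.
#' @param min_depth Minimum informative reads for a call.
#' @return The input tibble with `genotype` (one of `"5|5"`, `"5|6"`,
#'   `"6|6"`, `"no-call"`) and the three log-likelihood columns.
#' @export
call_genotype <- function(support, epsilon = 0.05, min_depth = 2) {
  support <- as_tibble(support)
  ll <- genotype_likelihoods(support$n, support$k, epsilon)
  lmat <- as.matrix(ll[, c("loglik_55", "loglik_56", "loglik_66")])
  gts <- c("5|5", "5|6", "6|6")
  call_one <- function(i) {
    if (support$n[i] < min_depth) return("no-call")
    li <- lmat[i, ]
    top <- max(li)
    best <- which(li > top - 1e-12)
    if (length(best) > 1) "no-call" else gts[best]
  }
  support$genotype <- vapply(seq_len(nrow(support)), call_one, character(1))
  dplyr::bind_cols(support,
                   ll[, c("loglik_55", "loglik_56", "loglik_66")])
}

#' Genotype concordance from a confusion matrix
#'
#' Fraction of individuals whose test genotype matches the truth genotype:
#' the diagonal sum of the 3x3 truth-by-test table over its total.
#'
#' @param table 3x3 matrix of counts, truth genotypes in rows, test
#'   genotypes in columns, homozygous-reference / heterozygous /
#'   homozygous-alternate order on both axes.
#' @return One-row tibble: `n`, `n_concordant`, `accuracy`.
#' @export
#' @examples
#' concordance(diag(c(10, 10, 10)))$accuracy # 1
concordance <- function(table) {
  m <- as.matrix(table)
  stopifnot(nrow(m) == 3, ncol(m) == 3, all(m >= 0))
  N <- sum(m)
  if (N == 0) abort("undefined: confusion table is empty")
  tibble(n = N, n_concordant = sum(diag(m)), accuracy = sum(diag(m)) / N)
}

#' Bundled cross-platform genotype validation tables
#'
#' Reads the example 3x3 genotype confusion matrices shipped with the
#' package: validations of a 1.6-kb deletion SV (vs Sanger sequencing and
#' vs long-read sequencing) and of a biallelic GGGAAA-repeat STR locus
#' (vs a second short-read caller and vs long-read sequencing). Rows are
#' truth-platform genotypes, columns the short-read WGS genotypes.
#'
#' @return Named list of four 3x3 matrices: `sv_sanger`, `sv_longread`,
#'   `str_hipstr`, `str_longread`.
#' @export
validation_confusion_tables <- function() {
  dir <- system.file("extdata", package = "svbk")
  read_one <- function(f) {
    d <- as.data.frame(readr::read_tsv(file.path(dir, f),
                                       show_col_types = FALSE))
    m <- as.matrix(d[, -1])
    rownames(m) <- d[[1]]
    m
  }
  list(sv_sanger = read_one("confusion_sv_sanger.tsv"),
       sv_longread = read_one("confusion_sv_longread.tsv"),
       str_hipstr = read_one("confusion_str_hipstr.tsv"),
       str_longread = read_one("confusion_str_longread.tsv"))
}
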