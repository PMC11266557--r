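# Shared fixtures and independent oracles, all built in code.

toy_samples <- function(n_case = 5, n_control = 5) {
  n <- n_case + n_control
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)),
    phenotype = rep(c("case", "control"), c(n_case, n_control)),
    sex = rep(c("male", "female"), length.out = n),
    age = seq(60, 80, length.out = n),
    region = rep(c("north", "south"), length.out = n),
    mean_depth = rep(44, n)
  )
}

# A ten-sample callset with one variant of each matrix-backed class.
toy_callset <- function() {
  samples <- toy_samples()
  variants <- tibble::tibble(
    variant_id = c("sv1", "cnv1", "kstr1", "dstr1"),
    chrom = c("chr1", "chr2", "chr3", "chr4"),
    start = c(1000L, 5000L, 200L, 300L),
    end = c(2999L, 14999L, 235L, 605L),
    vclass = c("SV_DEL", "CNV_DEL", "kSTR", "dSTR"),
    motif = c("", "", "AC", "AGG"),
    ref_repeat = c(NA, NA, 6, NA)
  )
  g <- matrix(NA_integer_, 4, 10,
              dimnames = list(variants$variant_id, samples$sample_id))
  g["sv1", ] <- c(0L, 1L, 2L, 0L, 1L, 0L, 0L, 1L, 0L, 0L)
  sz <- matrix(0, 4, 10, dimnames = dimnames(g))
  sz["cnv1", ] <- c(10000, 10000, 0, 0, 0, 10000, 0, 0, 0, 0)
  a1 <- matrix(NA_real_, 4, 10, dimnames = dimnames(g))
  a2 <- a1
  a1["kstr1", ] <- c(5, 6, 6, 6, 6, 5, 6, 6, 6, 6)
  a2["kstr1", ] <- c(6, 6, 6, 6, 5, 6, 6, 6, 6, 6)
  a1["dstr1", ] <- c(17, 0, 0, 0, 17, 0, 0, 0, 0, 0)
  a2["dstr1", ] <- c(0, 0, 0, 0, 17, 0, 0, 0, 0, 0)
  cohort_callset(samples, variants, genotypes = g, cnv_sizes = sz,
                 repeats = list(a1 = a1, a2 = a2))
}

# Brute-force argmax of the squared reciprocal-overlap score, written
# independently of the package implementation.
oracle_best_overlap <- function(q, cand) {
  score <- function(s0, e0, si, ei) {
    num <- min(e0, ei) - max(s0, si)
    if (num < 0) return(0)
    num^2 / ((e0 - s0) * (ei - si))
  }
  p <- vapply(seq_len(nrow(cand)), function(i) {
    score(q$start, q$end, cand$start[i], cand$end[i])
  }, numeric(1))
  size_q <- q$end - q$start + 1
  size_c <- cand$end - cand$start + 1
  ord <- order(-p, abs(size_c - size_q), cand$start)
  list(best = cand$variant_id[ord[1]], p = p[ord[1]], all_p = p)
}

# Exact one-sided permutation p (cases > controls) for the rank-sum
# statistic with midranks, by full enumeration of group assignments.
oracle_exact_ranksum_p <- function(x_case, x_control) {
  pooled <- c(x_case, x_control)
  r <- rank(pooled)
  n1 <- length(x_case)
  obs <- sum(r[seq_len(n1)])
  idx <- utils::combn(length(pooled), n1)
  sums <- colSums(matrix(r[idx], nrow = n1))
  mean(sums >= obs)
}

# Closed-form log-likelihoods for the STR caller, independent arithmetic.
oracle_str_loglik <- function(n, k, eps) {
  c(l55 = lchoose(n, k) + (n - k) * log(1 - eps) + k * log(eps),
    l56 = lchoose(n, k) + n * log(0.5),
    l66 = lchoose(n, k) + k * log(1 - eps) + (n - k) * log(eps))
}
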