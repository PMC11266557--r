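#' Linkage disequilibrium from phased two-locus haplotype counts
#'
#' Standard gametic disequilibrium: with haplotype frequencies from the
#' counts, `D = p_AB - p_A * p_B`, `D' = D / Dmax` where `Dmax` is
#' `min(p_A * p_b, p_a * p_B)` for positive `D` and
#' `min(p_A * p_B, p_a * p_b)` for negative `D`, and
#' `r^2 = D^2 / (p_A * p_a * p_B * p_b)`.
#'
#' @param hap Counts of the four phased haplotypes, in order
#'   `AB, Ab, aB, ab` (A/a alleles of the first locus, B/b of the second).
#' @return One-row tibble: `p_A`, `p_B`, `D`, `d_prime`, `r2`; all-`NA`
#'   disequilibrium when either locus is monomorphic.
#' @export
#' @examples
#' ld_stats(c(AB = 10, Ab = 0, aB = 490, ab = 500)) # D' = 1, r2 ~ 0.01
ld_stats <- function(hap) {
  stopifnot(length(hap) == 4, all(hap >= 0))
  N <- sum(hap)
  if (N == 0) abort("haplotype counts sum to zero")
  f <- hap / N
  p_A <- f[1] + f[2]
  p_B <- f[1] + f[3]
  if (p_A %in% c(0, 1) || p_B %in% c(0, 1)) {
    return(tibble(p_A = unname(p_A), p_B = unname(p_B), D = NA_real_,
                  d_prime = NA_real_, r2 = NA_real_))
  }
  D <- f[1] - p_A * p_B
  dmax <- if (D >= 0) min(p_A * (1 - p_B), (1 - p_A) * p_B)
          else min(p_A * p_B, (1 - p_A) * (1 - p_B))
  tibble(
    p_A = unname(p_A), p_B = unname(p_B), D = unname(D),
    d_prime = unname(if (dmax == 0) NA_real_ else abs(D) / dmax),
    r2 = unname(D^2 / (p_A * (1 - p_A) * p_B * (1 - p_B)))
  )
}
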