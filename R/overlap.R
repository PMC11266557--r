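#' Squared reciprocal-overlap score between two intervals
#'
#' For intervals `(start0, end0)` and `(start_i, end_i)` on the same
#' chromosome the identity score is
#' `(min(end0, end_i) - max(start0, start_i))^2 /
#'  ((end0 - start0) * (end_i - start_i))`.
#' The score is 1 exactly when the intervals coincide and decays with both
#' the unshared span of the query and of the candidate. Non-overlapping
#' pairs would square a negative difference into a spurious positive score,
#' so the score is defined as 0 whenever the pair shares no base.
#' Coordinate differences are used as printed (no `+ 1`), which differs
#' deliberately from the inclusive size convention of [variant_size()].
#'
#' @param start0,end0 Query interval (vectorised).
#' @param start_i,end_i Candidate interval (vectorised).
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
#' @examples
#' overlap_proportion(0, 100, 50, 150) # 0.25
#' overlap_proportion(0, 100, 25, 75) # 0.5
overlap_proportion <- function(start0, end0, start_i, end_i) {
  if (any(end0 == start0) || any(end_i == start_i)) {
    abort("degenerate interval: end equals start (zero-length span)")
  }
  if (any(end0 < start0) || any(end_i < start_i)) {
    abort("coordinate error: end < start")
  }
  num <- pmin(end0, end_i) - pmax(start0, start_i)
  p <- ifelse(num < 0, 0, num^2 / ((end0 - start0) * (end_i - start_i)))
  pmin(p, 1)
}

#' Best-matching SV among overlap candidates
#'
#' Scores every candidate with [overlap_proportion()] and returns the
#' argmax. Ties are broken by the smallest absolute size difference, then
#' by the lowest candidate start, so the result is deterministic. A match
#' with score above 0.8 (strict) is classed `high`, any other overlapping
#' match `low`, and an empty candidate list `none`.
#'
#' @param query One-row data frame with `variant_id`, `start`, `end`.
#' @param candidates Data frame of candidate records (same chromosome and
#'   SV type as the query, each sharing at least 1 bp with it).
#' @return One-row tibble: `query_id`, `best_id`, `p_overlap`,
#'   `identity_class`.
#' @export
best_match <- function(query, candidates) {
  if (is.null(candidates) || nrow(candidates) == 0) {
    return(tibble(query_id = query$variant_id, best_id = NA_character_,
                  p_overlap = NA_real_, identity_class = "none"))
  }
  p <- overlap_proportion(query$start, query$end,
                          candidates$start, candidates$end)
  size_q <- query$end - query$start + 1
  size_c <- candidates$end - candidates$start + 1
  ord <- order(-p, abs(size_c - size_q), candidates$start)
  i <- ord[1]
  tibble(
    query_id = query$variant_id,
    best_id = candidates$variant_id[i],
    p_overlap = p[i],
    identity_class = if (p[i] > 0.8) "high" else "low"
  )
}

#' Match one SV call set against a reference call set
#'
#' Every query SV is compared to reference SVs of the same chromosome and
#' SV type that share at least 1 bp; the best match is scored with the
#' squared reciprocal-overlap identity. Queries with a score above 0.8 are
#' `high`-identity, overlapped-but-divergent queries `low`, and queries
#' with no overlapping reference SV `novel`. Results are summarised within
#' minor-allele-frequency bins (<0.01, 0.01-0.05, >0.05) when the query
#' call set carries genotypes.
#'
#' @param query_set,reference_set [cohort_callset()] objects or variant
#'   tibbles (`variant_id`, `chrom`, `start`, `end`, `vclass`).
#' @return List with `matches` (per-query tibble: `query_id`, `best_id`,
#'   `p_overlap`, `identity_class`, `maf`, `maf_bin`) and `by_maf`
#'   (per-bin fractions of high/low/novel).
#' @export
match_callsets <- function(query_set, reference_set) {
  qv <- if (inherits(query_set, "cohort_callset")) query_set$variants else as_tibble(query_set)
  rv <- if (inherits(reference_set, "cohort_callset")) reference_set$variants else as_tibble(reference_set)
  sv_classes <- c("SV_DEL", "SV_DUP", "SV_INV", "SV_MEI")
  qv <- filter(qv, .data$vclass %in% sv_classes)
  rv <- filter(rv, .data$vclass %in% sv_classes)

  maf <- rep(NA_real_, nrow(qv))
  if (inherits(query_set, "cohort_callset") && !is.null(query_set$genotypes)) {
    maf <- sv_maf(query_set$genotypes)[match(qv$variant_id,
                                             rownames(query_set$genotypes))]
  }

  matches <- map(seq_len(nrow(qv)), function(i) {
    q <- qv[i, ]
    cand <- filter(rv, .data$chrom == q$chrom, .data$vclass == q$vclass,
                   pmin(.data$end, q$end) - pmax(.data$start, q$start) >= 0)
    best_match(q, cand)
  })
  matches <- bind_rows(matches)
  matches$identity_class[matches$identity_class == "none"] <- "novel"
  matches$maf <- maf
  matches$maf_bin <- cut(maf, breaks = c(-Inf, 0.01, 0.05, Inf),
                         labels = c("<0.01", "0.01-0.05", ">0.05"),
                         right = FALSE)

  by_maf <- matches |>
    mutate(maf_bin = ifelse(is.na(.data$maf_bin), "all",
                            as.character(.data$maf_bin))) |>
    count(.data$maf_bin, .data$identity_class) |>
    group_by(.data$maf_bin) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup()

  list(matches = matches, by_maf = by_maf)
}
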