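#' Assemble a cohort call set
#'
#' Bundles sample metadata, a variant table, and the per-sample value
#' matrices used downstream: allele-dosage genotypes for SVs, total affected
#' base pairs for CNV regions, and allele repeat counts for STRs. All
#' analysis functions in the package take this container (or plain tibbles
#' derived from it) and return tibbles.
#'
#' @param samples Data frame with columns `sample_id`, `phenotype`
#'   (`"case"`/`"control"`), `sex` (`"male"`/`"female"`), `age` (years, > 0),
#'   `region` (`"north"`/`"south"`), `mean_depth` (fold coverage).
#' @param variants Data frame with columns `variant_id`, `chrom`, `start`,
#'   `end` (1-based inclusive), `vclass` (one of `SV_DEL`, `SV_DUP`, `SV_INV`,
#'   `SV_MEI`, `CNV_DEL`, `CNV_DUP`, `kSTR`, `dSTR`); optional `motif`
#'   (repeat unit, STRs), `ref_repeat` (catalog repeat number, kSTRs), and
#'   `qc` (list column of named caller attributes).
#' @param genotypes Variant-by-sample integer matrix of allele dosages
#'   (0/1/2, `NA` for missing); rows named by `variant_id`, columns by
#'   `sample_id`. Only SV-class rows are interpreted.
#' @param cnv_sizes Variant-by-sample numeric matrix of total CNV base pairs
#'   per sample within each (merged) CNV region; 0 means no CNV.
#' @param repeats List with matrices `a1` and `a2` of per-allele repeat
#'   counts for STR loci (`NA` for missing).
#'
#' @return An object of class `cohort_callset`.
#' @export
#' @examples
#' cs <- cohort_callset(
#'   samples = tibble::tibble(
#'     sample_id = c("s1", "s2"), phenotype = c("case", "control"),
#'     sex = c("male", "female"), age = c(63, 70),
#'     region = c("north", "south"), mean_depth = c(44, 41)
#'   ),
#'   variants = tibble::tibble(
#'     variant_id = "sv1", chrom = "chr12",
#'     start = 40488206, end = 40489818, vclass = "SV_DEL"
#'   ),
#'   genotypes = matrix(c(1L, 0L), 1, 2,
#'     dimnames = list("sv1", c("s1", "s2"))
#'   )
#' )
#' cs
cohort_callset <- function(samples, variants, genotypes = NULL,
                           cnv_sizes = NULL, repeats = NULL) {
  samples <- as_tibble(samples)
  variants <- as_tibble(variants)
  req_s <- c("sample_id", "phenotype", "sex", "age", "region", "mean_depth")
  if (!all(req_s %in% names(samples))) {
    abort(paste0("samples is missing column(s): ",
                 paste(setdiff(req_s, names(samples)), collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) {
    abort("sample_id values must be unique within a cohort")
  }
  if (any(samples$age <= 0, na.rm = TRUE)) abort("sample ages must be > 0")
  stopifnot(all(samples$phenotype %in% c("case", "control")),
            all(samples$sex %in% c("male", "female")),
            all(samples$region %in% c("north", "south")))

  req_v <- c("variant_id", "chrom", "start", "end", "vclass")
  if (!all(req_v %in% names(variants))) {
    abort(paste0("variants is missing column(s): ",
                 paste(setdiff(req_v, names(variants)), collapse = ", ")))
  }
  if (anyDuplicated(variants$variant_id)) abort("variant_id values must be unique")
  bad <- variants$end < variants$start
  if (any(bad)) {
    abort(paste0("coordinate error: end < start for variant(s) ",
                 paste(variants$variant_id[bad], collapse = ", ")))
  }
  known <- c("SV_DEL", "SV_DUP", "SV_INV", "SV_MEI",
             "CNV_DEL", "CNV_DUP", "kSTR", "dSTR")
  if (!all(variants$vclass %in% known)) {
    abort(paste0("unknown vclass: ",
                 paste(setdiff(variants$vclass, known), collapse = ", ")))
  }
  if (!"motif" %in% names(variants)) variants$motif <- ""
  if (!"ref_repeat" %in% names(variants)) variants$ref_repeat <- NA_real_
  if (!"qc" %in% names(variants)) {
    variants$qc <- rep(list(list()), nrow(variants))
  }

  check_mat <- function(m, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (nrow(m) != nrow(variants) || ncol(m) != nrow(samples)) {
      abort(paste0(what, " must be a ", nrow(variants), " x ", nrow(samples),
                   " (variant x sample) matrix"))
    }
    rownames(m) <- variants$variant_id
    colnames(m) <- samples$sample_id
    m
  }
  genotypes <- check_mat(genotypes, "genotypes")
  if (!is.null(genotypes) &&
      !all(genotypes %in% c(0L, 1L, 2L) | is.na(genotypes))) {
    abort("genotype dosages must be 0, 1, 2, or NA")
  }
  cnv_sizes <- check_mat(cnv_sizes, "cnv_sizes")
  if (!is.null(cnv_sizes) && any(cnv_sizes < 0, na.rm = TRUE)) {
    abort("cnv_sizes must be non-negative")
  }
  if (!is.null(repeats)) {
    stopifnot(is.list(repeats), all(c("a1", "a2") %in% names(repeats)))
    repeats$a1 <- check_mat(repeats$a1, "repeats$a1")
    repeats$a2 <- check_mat(repeats$a2, "repeats$a2")
  }

  structure(
    list(samples = samples, variants = variants, genotypes = genotypes,
         cnv_sizes = cnv_sizes, repeats = repeats),
    class = "cohort_callset"
  )
}

#' @export
print.cohort_callset <- function(x, ...) {
  cls <- table(x$variants$vclass)
  cat("<cohort_callset> ", nrow(x$samples), " samples (",
      sum(x$samples$phenotype == "case"), " cases / ",
      sum(x$samples$phenotype == "control"), " controls), ",
      nrow(x$variants), " variants\n", sep = "")
  if (length(cls)) {
    cat("  ", paste0(names(cls), ": ", as.integer(cls), collapse = ", "), "\n",
        sep = "")
  }
  cat("  matrices:",
      paste(c("genotypes", "cnv_sizes", "repeats")[
        !vapply(x[c("genotypes", "cnv_sizes", "repeats")], is.null, logical(1))],
        collapse = ", "), "\n")
  invisible(x)
}

#' Variant sizes under the 1-based inclusive convention
#'
#' Size of a record spanning `start..end` is `end - start + 1` base pairs,
#' so a single-base record has size 1.
#'
#' @param variants A variants data frame (columns `start`, `end`, and
#'   optionally `variant_id`) or a `cohort_callset`.
#' @return The input variant table as a tibble with a `size` column (bp).
#' @export
#' @examples
#' variant_size(tibble::tibble(
#'   variant_id = "muc19_del", chrom = "chr12",
#'   start = 40488206, end = 40489818
#' ))$size # 1613
variant_size <- function(variants) {
  if (inherits(variants, "cohort_callset")) variants <- variants$variants
  variants <- as_tibble(variants)
  bad <- variants$end < variants$start
  if (any(bad)) {
    ids <- if ("variant_id" %in% names(variants)) {
      paste(variants$variant_id[bad], collapse = ", ")
    } else paste(which(bad), collapse = ", ")
    abort(paste0("coordinate error: end < start for variant(s) ", ids))
  }
  mutate(variants, size = .data$end - .data$start + 1)
}

# Internal: subset a callset to a set of variant ids (order preserved).
subset_variants <- function(cs, keep_ids) {
  idx <- match(keep_ids, cs$variants$variant_id)
  stopifnot(!anyNA(idx))
  cs$variants <- cs$variants[idx, , drop = FALSE]
  for (m in c("genotypes", "cnv_sizes")) {
    if (!is.null(cs[[m]])) cs[[m]] <- cs[[m]][idx, , drop = FALSE]
  }
  if (!is.null(cs$repeats)) {
    cs$repeats$a1 <- cs$repeats$a1[idx, , drop = FALSE]
    cs$repeats$a2 <- cs$repeats$a2[idx, , drop = FALSE]
  }
  cs
}

# Internal: fetch a qc attribute, failing loudly when a filter needs a key
# the caller did not provide.
qc_value <- function(qc, key, variant_id) {
  if (is.null(qc[[key]])) {
    abort(paste0("configuration error: qc key '", key,
                 "' is required but absent for variant ", variant_id))
  }
  qc[[key]]
}

# Internal: per-row genotype summaries over non-missing entries.
sv_genotype_rate <- function(g) rowMeans(!is.na(g))

sv_allele_freq <- function(g) {
  alt <- rowSums(g, na.rm = TRUE)
  tot <- 2 * rowSums(!is.na(g))
  ifelse(tot > 0, alt / tot, NA_real_)
}

sv_maf <- function(g) {
  f <- sv_allele_freq(g)
  pmin(f, 1 - f)
}
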