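sv_vclass_to_type <- c(SV_DEL = "DEL", SV_DUP = "DUP",
                       SV_INV = "INV", SV_MEI = "MEI")

#' Write SV genotypes to a VCF file
#'
#' Minimal VCF 4.2 with `SVTYPE` and `END` INFO keys and a per-sample `GT`
#' field; dosage 0/1/2 maps to `0/0`, `0/1`, `1/1` and missing to `./.`.
#'
#' @param callset A [cohort_callset()]; only SV-class variants are written.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(callset, path) {
  stopifnot(inherits(callset, "cohort_callset"))
  v <- callset$variants
  sv <- v$vclass %in% names(sv_vclass_to_type)
  v <- v[sv, ]
  g <- callset$genotypes[v$variant_id, , drop = FALSE]
  gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow(g), ncol(g))
  gt[is.na(g)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV class\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", callset$samples$sample_id), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$start[i], v$variant_id[i], "N",
            paste0("<", sv_vclass_to_type[[v$vclass[i]]], ">"), ".", "PASS",
            paste0("SVTYPE=", sv_vclass_to_type[[v$vclass[i]]],
                   ";END=", v$end[i]),
            "GT", gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read SV genotypes from a VCF file
#'
#' Parses a VCF with `SVTYPE`/`END` INFO keys and per-sample `GT` into a
#' variants tibble and an allele-dosage matrix.
#'
#' @param path VCF file.
#' @return List with `variants` (tibble) and `genotypes` (variant-by-sample
#'   dosage matrix).
#' @export
read_sv_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  svtype <- sub(".*SVTYPE=([^;]+).*", "\\1", fx$INFO)
  endpos <- as.integer(sub(".*END=([0-9]+).*", "\\1", fx$INFO))
  type_map <- setNames(names(sv_vclass_to_type), sv_vclass_to_type)
  variants <- tibble(
    variant_id = fx$ID, chrom = fx$CHROM, start = as.integer(fx$POS),
    end = endpos, vclass = unname(type_map[svtype])
  )
  gtc <- vcfR::extract.gt(vcf, element = "GT")
  dose <- matrix(NA_integer_, nrow(gtc), ncol(gtc), dimnames = dimnames(gtc))
  clean <- gsub("\\|", "/", gtc)
  dose[clean == "0/0"] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean == "1/1"] <- 2L
  rownames(dose) <- variants$variant_id
  list(variants = variants, genotypes = dose)
}

#' Write/read per-sample CNV calls as BED-like TSV
#'
#' Columns: `chrom`, `start`, `end`, `sample_id`, `size`, and `qc` (caller
#' attributes serialised as one JSON object per row).
#'
#' @param calls Tibble of CNV calls (`chrom`, `start`, `end`, `sample_id`,
#'   optional `qc` list column).
#' @param path File path.
#' @return `write_cnv_calls()`: `path`, invisibly. `read_cnv_calls()`: the
#'   calls tibble with a `qc` list column.
#' @export
write_cnv_calls <- function(calls, path) {
  calls <- as_tibble(calls)
  qc <- if ("qc" %in% names(calls)) calls$qc else rep(list(list()), nrow(calls))
  out <- tibble(
    chrom = calls$chrom, start = calls$start, end = calls$end,
    sample_id = if ("sample_id" %in% names(calls)) calls$sample_id else NA_character_,
    size = calls$end - calls$start + 1,
    qc = map_chr(qc, function(q) {
      as.character(jsonlite::toJSON(q, auto_unbox = TRUE))
    })
  )
  readr::write_tsv(out, path, quote = "none", escape = "none")
  invisible(path)
}

#' @rdname write_cnv_calls
#' @export
read_cnv_calls <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(qc = readr::col_character()))
  d$qc <- map(d$qc, function(s) {
    if (is.na(s)) list() else jsonlite::fromJSON(s, simplifyVector = TRUE)
  })
  d
}

#' Write/read sample metadata as TSV
#'
#' @param samples Sample tibble (`sample_id`, `phenotype`, `sex`, `age`,
#'   `region`, `mean_depth`).
#' @param path File path.
#' @return `write_samples()`: `path`, invisibly. `read_samples()`: tibble.
#' @export
write_samples <- function(samples, path) {
  readr::write_tsv(as_tibble(samples), path)
  invisible(path)
}

#' @rdname write_samples
#' @export
read_samples <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write/read STR allele-pair repeat calls as TSV
#'
#' Long format: one row per locus and sample with the two allele repeat
#' counts (`NA` for missing).
#'
#' @param callset A [cohort_callset()] with a `repeats` pair of matrices.
#' @param path File path.
#' @return `write_str_repeats()`: `path`, invisibly. `read_str_repeats()`:
#'   tibble `variant_id`, `sample_id`, `allele1`, `allele2`.
#' @export
write_str_repeats <- function(callset, path) {
  stopifnot(inherits(callset, "cohort_callset"), !is.null(callset$repeats))
  v <- callset$variants
  str_ids <- v$variant_id[v$vclass %in% c("kSTR", "dSTR")]
  a1 <- callset$repeats$a1[str_ids, , drop = FALSE]
  a2 <- callset$repeats$a2[str_ids, , drop = FALSE]
  long <- tibble(
    variant_id = rep(rownames(a1), ncol(a1)),
    sample_id = rep(colnames(a1), each = nrow(a1)),
    allele1 = as.vector(a1), allele2 = as.vector(a2)
  )
  readr::write_tsv(long, path)
  invisible(path)
}

#' @rdname write_str_repeats
#' @export
read_str_repeats <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write/read long-read STR support counts as TSV
#'
#' Columns `sample_id`, `n` (informative reads), `k` (reads supporting the
#' long allele).
#'
#' @param support Tibble with `n` and `k` (e.g. [simulate_str_reads()]).
#' @param path File path.
#' @return `write_str_support()`: `path`, invisibly.
#'   `read_str_support()`: tibble.
#' @export
write_str_support <- function(support, path) {
  readr::write_tsv(as_tibble(support), path)
  invisible(path)
}

#' @rdname write_str_support
#' @export
read_str_support <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
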