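#' Simulation configuration for synthetic cohorts
#'
#' Collects every knob of the synthetic-data generators. Defaults mirror a
#' two-region case-control whole-genome study: 466 cases and 513 controls,
#' a 22-autosome toy genome (60-250 Mb chromosomes, so chromosome-terminal
#' windows exist without reference files), Hardy-Weinberg background
#' variants with phenotype-independent frequencies, a deletion planted at
#' control allele frequency 0.45 with odds ratio 0.49 plus an STR allele at
#' 0.45 with odds ratio 0.47 (protective signals of the size the method is
#' meant to detect), an extra 0.6 terminal CNV deletions per case spread
#' over terminal 5 Mb windows, and long-read STR support at sequencing
#' error rate 0.05.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param seed Integer seed; every generator is deterministic given it.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param n_background_variants Background variants per class
#'   (`SV_DEL`, `CNV_DEL`, `kSTR`, `dSTR`).
#' @param planted_effects Tibble with columns `vclass`, `maf_controls`,
#'   `odds_ratio`; one variant is planted per row.
#' @param terminal_burden_delta Extra mean terminal CNV deletions per case
#'   (total across terminal windows).
#' @param cnv_window_rate Baseline mean CNV deletions per sample per 5 Mb
#'   window in the burden generator.
#' @param age_range Length-2 numeric, years.
#' @param region_mix Fraction of samples from the northern region.
#' @param str_error_rate Long-read sequencing error rate `epsilon`
#'   in `[0, 0.5)`.
#' @param read_depth_dist Mean long-read depth per STR locus.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 466, n_controls = 513, seed = 1,
                       chrom_lengths = toy_genome(),
                       n_background_variants = 40,
                       planted_effects = tibble(
                         vclass = c("SV_DEL", "kSTR"),
                         maf_controls = c(0.45, 0.45),
                         odds_ratio = c(0.49, 0.47)
                       ),
                       terminal_burden_delta = 0.6,
                       cnv_window_rate = 0.05,
                       age_range = c(55, 85), region_mix = 0.5,
                       str_error_rate = 0.05, read_depth_dist = 20) {
  stopifnot(n_cases > 0, n_controls > 0, n_background_variants > 0,
            length(age_range) == 2, age_range[1] > 0,
            age_range[2] > age_range[1],
            region_mix >= 0, region_mix <= 1, read_depth_dist > 0,
            cnv_window_rate >= 0)
  if (str_error_rate < 0 || str_error_rate >= 0.5) {
    abort("configuration error: str_error_rate must lie in [0, 0.5)")
  }
  if (terminal_burden_delta < 0) {
    abort("configuration error: terminal_burden_delta must be >= 0")
  }
  planted_effects <- as_tibble(planted_effects)
  if (nrow(planted_effects)) {
    stopifnot(all(planted_effects$maf_controls > 0),
              all(planted_effects$maf_controls < 1))
    if (any(planted_effects$odds_ratio <= 0)) {
      abort("configuration error: odds_ratio must be > 0")
    }
  }
  structure(list(
    n_cases = n_cases, n_controls = n_controls, seed = as.integer(seed),
    chrom_lengths = chrom_lengths,
    n_background_variants = n_background_variants,
    planted_effects = planted_effects,
    terminal_burden_delta = terminal_burden_delta,
    cnv_window_rate = cnv_window_rate,
    age_range = age_range, region_mix = region_mix,
    str_error_rate = str_error_rate, read_depth_dist = read_depth_dist
  ), class = "sim_config")
}

#' Toy autosome lengths
#'
#' 22 autosomes spanning 250 Mb down to 60 Mb in even steps, rounded to
#' whole megabases. Long enough that 5 Mb terminal windows and 50 Mb
#' terminal bins are well defined.
#'
#' @return Named numeric vector of chromosome lengths in bp.
#' @export
toy_genome <- function() {
  len <- round(seq(250, 60, length.out = 22)) * 1e6
  setNames(len, paste0("chr", 1:22))
}

# Case allele frequency implied by a per-allele odds ratio.
case_freq_from_or <- function(f0, or) {
  odds <- or * f0 / (1 - f0)
  f1 <- odds / (1 + odds)
  if (any(f1 <= 0) || any(f1 >= 1) || any(!is.finite(f1))) {
    abort("configuration error: implied case allele frequency outside (0, 1)")
  }
  f1
}

#' Simulate a case-control cohort call set
#'
#' Background variants of each class draw Hardy-Weinberg genotypes from a
#' single allele frequency shared by cases and controls; each planted
#' effect draws case genotypes at the allele frequency implied by its odds
#' ratio on the allele scale. Covariates (sex, age, region, depth) are
#' drawn independently of phenotype. SV loci fill the dosage matrix, CNV
#' loci the per-sample affected-bp matrix (dosage times locus size), and
#' STR loci the two allele-repeat matrices (kSTR: reference repeat vs a
#' one-unit contraction; dSTR: expansion repeat length vs 0). All simulated
#' records carry passing qc attributes, so the cross-sample filters are
#' no-ops unless perturbed.
#'
#' @param config A [sim_config()].
#' @return A [cohort_callset()] with a `truth` attribute (tibble of planted
#'   variant ids, class, control/case allele frequencies, odds ratio).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  samples <- tibble(
    sample_id = sprintf("s%04d", seq_len(n)),
    phenotype = rep(c("case", "control"), c(config$n_cases, config$n_controls)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = round(runif(n, config$age_range[1], config$age_range[2]), 1),
    region = sample(c("north", "south"), n, replace = TRUE,
                    prob = c(config$region_mix, 1 - config$region_mix)),
    mean_depth = round(pmax(10, rnorm(n, 44.3, 4)), 1)
  )
  is_case <- samples$phenotype == "case"

  chroms <- names(config$chrom_lengths)
  rand_locus <- function(size) {
    chrom <- sample(chroms, length(size), replace = TRUE)
    maxs <- config$chrom_lengths[chrom] - size
    start <- floor(runif(length(size), 1, pmax(maxs, 2)))
    tibble(chrom = chrom, start = start, end = start + size - 1)
  }
  default_qc <- function(vclass) {
    switch(vclass,
      CNV_DEL = , CNV_DUP = list(p_value = 1e-6, mq0_frac = 0.05,
                                 n_frac = 0.01, gap_dist = 5e4),
      kSTR = list(quality = 50, depth = 30),
      dSTR = list(anchor_mapq = 60, irr_mapq = 20,
                  depth_obs = 10, depth_norm = 10),
      list()
    )
  }
  class_sizes <- function(vclass, k) {
    switch(vclass,
      SV_DEL = , SV_DUP = , SV_MEI = , SV_INV =
        round(pmin(pmax(exp(rnorm(k, log(2000), 1)), 100), 1e5)),
      CNV_DEL = , CNV_DUP =
        round(pmin(pmax(exp(rnorm(k, log(8000), 0.8)), 1000), 1e5)),
      kSTR = 6 * 6, dSTR = 17 * 18
    )
  }

  bg_classes <- c("SV_DEL", "CNV_DEL", "kSTR", "dSTR")
  plan <- bind_rows(
    tibble(vclass = rep(bg_classes, each = config$n_background_variants),
           maf_controls = NA_real_, odds_ratio = 1, planted = FALSE),
    mutate(config$planted_effects, planted = TRUE)
  )
  nv <- nrow(plan)
  plan$maf_controls[is.na(plan$maf_controls)] <- runif(sum(is.na(plan$maf_controls)),
                                                       0.02, 0.5)
  plan$f_case <- case_freq_from_or(plan$maf_controls, plan$odds_ratio)

  sizes <- unlist(map2(plan$vclass, seq_len(nv),
                       function(vc, i) class_sizes(vc, 1)))
  loci <- rand_locus(sizes)
  variants <- tibble(
    variant_id = sprintf("%s_%03d%s", tolower(plan$vclass), seq_len(nv),
                         ifelse(plan$planted, "_planted", "")),
    chrom = loci$chrom, start = loci$start, end = loci$end,
    vclass = plan$vclass,
    motif = ifelse(plan$vclass == "kSTR", "GGGAAA",
                   ifelse(plan$vclass == "dSTR", "AGCGCGGGAGGCGCAGGC", "")),
    ref_repeat = ifelse(plan$vclass == "kSTR", 6, NA_real_),
    qc = map(plan$vclass, default_qc)
  )

  genotypes <- matrix(NA_integer_, nv, n,
                      dimnames = list(variants$variant_id, samples$sample_id))
  cnv_sizes <- matrix(0, nv, n,
                      dimnames = dimnames(genotypes))
  a1 <- matrix(NA_real_, nv, n, dimnames = dimnames(genotypes))
  a2 <- a1

  for (i in seq_len(nv)) {
    f <- ifelse(is_case, plan$f_case[i], plan$maf_controls[i])
    dose <- rbinom(n, 2, f)
    vc <- plan$vclass[i]
    if (vc %in% c("SV_DEL", "SV_DUP", "SV_INV", "SV_MEI")) {
      genotypes[i, ] <- as.integer(dose)
    } else if (vc %in% c("CNV_DEL", "CNV_DUP")) {
      cnv_sizes[i, ] <- dose * (variants$end[i] - variants$start[i] + 1)
    } else if (vc == "kSTR") {
      # alt allele is a one-unit contraction of the catalog repeat
      a1[i, ] <- ifelse(dose >= 1, 5, 6)
      a2[i, ] <- ifelse(dose == 2, 5, 6)
    } else if (vc == "dSTR") {
      a1[i, ] <- ifelse(dose >= 1, 17, 0)
      a2[i, ] <- ifelse(dose == 2, 17, 0)
    }
  }

  cs <- cohort_callset(samples, variants, genotypes = genotypes,
                       cnv_sizes = cnv_sizes,
                       repeats = list(a1 = a1, a2 = a2))
  attr(cs, "truth") <- tibble(
    variant_id = variants$variant_id[plan$planted],
    vclass = plan$vclass[plan$planted],
    maf_controls = plan$maf_controls[plan$planted],
    maf_cases = plan$f_case[plan$planted],
    odds_ratio = plan$odds_ratio[plan$planted]
  )
  cs
}

#' Simulate per-sample CNV deletion calls with a terminal excess in cases
#'
#' Per-sample deletion counts are Poisson within each 5 Mb window. Controls
#' share one genome-wide rate (`cnv_window_rate`); cases get an extra
#' `terminal_burden_delta` expected deletions in total, spread evenly over
#' the terminal 5 Mb windows (both ends of each autosome). Record midpoints
#' are placed uniformly within their window.
#'
#' @param config A [sim_config()].
#' @param window_size Window width in bp.
#' @return List with `samples` (tibble as in [simulate_cohort()]) and
#'   `cnv_calls` (tibble: `sample_id`, `chrom`, `start`, `end`, `vclass`).
#' @export
simulate_terminal_burden <- function(config, window_size = 5e6) {
  stopifnot(inherits(config, "sim_config"))
  if (config$terminal_burden_delta < 0) {
    abort("configuration error: terminal_burden_delta must be >= 0")
  }
  set.seed(config$seed + 1L)
  n <- config$n_cases + config$n_controls
  samples <- tibble(
    sample_id = sprintf("s%04d", seq_len(n)),
    phenotype = rep(c("case", "control"), c(config$n_cases, config$n_controls)),
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = round(runif(n, config$age_range[1], config$age_range[2]), 1),
    region = sample(c("north", "south"), n, replace = TRUE,
                    prob = c(config$region_mix, 1 - config$region_mix)),
    mean_depth = round(pmax(10, rnorm(n, 44.3, 4)), 1)
  )

  lens <- config$chrom_lengths
  win <- bind_rows(imap(as.list(lens), function(L, ch) {
    nw <- ceiling(L / window_size)
    tibble(chrom = ch, window_index = seq_len(nw) - 1L,
           wstart = (seq_len(nw) - 1L) * window_size,
           wend = pmin(seq_len(nw) * window_size, L),
           terminal = seq_len(nw) %in% c(1L, nw))
  }))
  n_term <- sum(win$terminal)
  extra <- config$terminal_burden_delta / n_term

  nw <- nrow(win)
  is_case <- samples$phenotype == "case"
  lam <- matrix(config$cnv_window_rate, nw, n)
  lam[win$terminal, is_case] <- config$cnv_window_rate + extra
  k <- matrix(rpois(nw * n, lam), nw, n)
  tot <- sum(k)
  if (tot == 0) {
    return(list(samples = samples,
                cnv_calls = tibble(sample_id = character(),
                                   chrom = character(), start = integer(),
                                   end = integer(), vclass = character())))
  }
  rows <- rep(rep(seq_len(nw), n), as.vector(k))
  samp <- rep(rep(seq_len(n), each = nw), as.vector(k))
  size <- round(runif(tot, 1000, 5000))
  # keep whole records inside the chromosome: wend of the last window is
  # the chromosome length
  chrom_len <- lens[win$chrom[rows]]
  mid <- floor(runif(tot,
                     pmax(win$wstart[rows], size) + 1,
                     pmin(win$wend[rows], chrom_len - size)))
  calls <- tibble(
    sample_id = samples$sample_id[samp],
    chrom = win$chrom[rows],
    start = pmax(mid - size %/% 2, 1),
    end = mid + ceiling(size / 2) - 1,
    vclass = "CNV_DEL"
  )
  list(samples = samples, cnv_calls = calls)
}

#' Simulate long-read allele support at a biallelic STR
#'
#' Given a truth genotype, the number of reads supporting the longer
#' (6-repeat) allele is Binomial(n, p) with p = `epsilon`, 1/2, or
#' `1 - epsilon` for genotypes `5|5`, `5|6`, `6|6`.
#'
#' @param truth_genotype Character vector of `"5|5"`, `"5|6"`, `"6|6"`.
#' @param n_reads Integer vector (recycled) of total informative reads.
#' @param epsilon Sequencing error rate in `[0, 0.5)`.
#' @return Tibble: `truth`, `n`, `k`, `epsilon`.
#' @export
simulate_str_reads <- function(truth_genotype, n_reads, epsilon = 0.05) {
  if (epsilon < 0 || epsilon >= 0.5) {
    abort("configuration error: epsilon must lie in [0, 0.5)")
  }
  stopifnot(all(truth_genotype %in% c("5|5", "5|6", "6|6")), all(n_reads >= 0))
  n_reads <- rep_len(n_reads, length(truth_genotype))
  p <- c("5|5" = epsilon, "5|6" = 0.5, "6|6" = 1 - epsilon)[truth_genotype]
  tibble(truth = truth_genotype, n = as.integer(n_reads),
         k = rbinom(length(n_reads), n_reads, p), epsilon = epsilon)
}

#' Simulate a cell-type-structured expression matrix
#'
#' Expression is Gamma-distributed per gene and cell with a gene-specific
#' shape, so the standard deviation of per-cell fold-change is about
#' `1/sqrt(shape)`: dosage-sensitive genes get a large shape (low
#' fold-change SD), loss-of-function-tolerant (LofT) genes a small shape
#' (high SD), background genes an intermediate one. One marker gene per
#' cell type is expressed in that type only. Genes outside the marker set
#' have no cell-type structure, so their fold-change SD is governed purely
#' by the planted dispersion.
#'
#' @param n_genes Total number of genes (markers and set genes included).
#' @param n_cells Total number of cells, split evenly across types.
#' @param cell_types Character vector of cell-type names.
#' @param dosage_sensitive_set,loft_set Disjoint character vectors of gene
#'   names to plant as low- and high-dispersion genes.
#' @param seed Integer seed.
#' @return List of class `expr_matrix`: `counts` (gene x cell matrix),
#'   `cell_types` (named character vector cell -> type).
#' @export
simulate_expression <- function(n_genes = 500, n_cells = 1000,
                                cell_types = c("DA", "nonDA", "AST", "MIC"),
                                dosage_sensitive_set = sprintf("ds_%02d", 1:49),
                                loft_set = sprintf("loft_%03d", 1:330),
                                seed = 1) {
  if (length(intersect(dosage_sensitive_set, loft_set))) {
    abort("configuration error: gene sets must be disjoint")
  }
  set.seed(as.integer(seed))
  markers <- paste0("marker_", cell_types)
  n_named <- length(markers) + length(dosage_sensitive_set) + length(loft_set)
  stopifnot(n_genes >= n_named)
  genes <- c(markers, dosage_sensitive_set, loft_set,
             sprintf("bg_%04d", seq_len(n_genes - n_named)))
  cells <- sprintf("c%05d", seq_len(n_cells))
  type_of <- setNames(rep_len(cell_types, n_cells), cells)

  shape <- setNames(rep(5, length(genes)), genes)
  shape[dosage_sensitive_set] <- 25
  shape[loft_set] <- 1
  mu <- setNames(exp(rnorm(length(genes), log(5), 0.5)), genes)

  counts <- matrix(0, length(genes), n_cells,
                   dimnames = list(genes, cells))
  for (g in genes) {
    counts[g, ] <- rgamma(n_cells, shape = shape[g], rate = shape[g] / mu[g])
  }
  for (i in seq_along(cell_types)) {
    m <- markers[i]
    off <- type_of != cell_types[i]
    counts[m, off] <- 0
  }
  structure(list(counts = counts, cell_types = type_of),
            class = "expr_matrix")
}

#' Simulate a two-variant cohort with a penetrance-modifying interaction
#'
#' Draws Hardy-Weinberg dosages for a primary risk variant and a candidate
#' modifier, then assigns phenotype by a logistic model with main effects
#' and a dosage-by-dosage interaction. Used to test recovery of
#' penetrance modification.
#'
#' @param n Number of samples.
#' @param maf_primary,maf_modifier Allele frequencies.
#' @param or_primary,or_modifier,or_interaction Per-allele odds ratios of
#'   the logistic model (interaction multiplies the primary-carrier odds
#'   per modifier allele).
#' @param base_rate Baseline case probability for double non-carriers.
#' @param seed Integer seed.
#' @return A [cohort_callset()] with variants `primary` and `modifier`.
#' @export
simulate_interaction_cohort <- function(n = 2000, maf_primary = 0.05,
                                        maf_modifier = 0.3,
                                        or_primary = 2.5, or_modifier = 1,
                                        or_interaction = 0.5,
                                        base_rate = 0.3, seed = 1) {
  set.seed(as.integer(seed))
  g1 <- rbinom(n, 2, maf_primary)
  g2 <- rbinom(n, 2, maf_modifier)
  eta <- qlogis(base_rate) + log(or_primary) * g1 + log(or_modifier) * g2 +
    log(or_interaction) * g1 * g2
  pheno <- ifelse(runif(n) < plogis(eta), "case", "control")
  samples <- tibble(
    sample_id = sprintf("s%04d", seq_len(n)), phenotype = pheno,
    sex = sample(c("male", "female"), n, replace = TRUE),
    age = round(runif(n, 55, 85), 1),
    region = sample(c("north", "south"), n, replace = TRUE),
    mean_depth = 44.3
  )
  variants <- tibble(
    variant_id = c("primary", "modifier"),
    chrom = c("chr12", "chr12"),
    start = c(40310434, 40488206), end = c(40310434, 40489818),
    vclass = c("SV_MEI", "SV_DEL")
  )
  genotypes <- rbind(primary = as.integer(g1), modifier = as.integer(g2))
  colnames(genotypes) <- samples$sample_id
  cohort_callset(samples, variants, genotypes = genotypes)
}
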