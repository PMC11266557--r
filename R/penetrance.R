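#' Penetrance modification of a risk variant by a second variant
#'
#' Within carriers and non-carriers of the primary risk variant, compares
#' the case fraction across the modifier's genotype classes (0/1/2): a
#' logistic fit of phenotype on modifier dosage, an exact test on the
#' phenotype-by-genotype table, and per-class odds ratios against the
#' modifier wild type. Also fits the dosage-by-dosage interaction across
#' the whole cohort, and reports, among control carriers and non-carriers
#' of the primary variant, the fraction co-carrying the modifier.
#'
#' @param callset A [cohort_callset()] whose genotype matrix contains both
#'   variants.
#' @param primary_variant Variant whose penetrance is examined (e.g. a
#'   known risk allele).
#' @param modifier_variant Candidate modifier variant.
#' @return List of class `svbk_penetrance`:
#'   * `strata`: tibble per primary-carrier stratum and modifier genotype
#'     class with sample counts, case fraction, odds ratio vs class 0
#'     (`Inf`/`NA` flagged via `degenerate`), and the stratum's logistic
#'     and exact p;
#'   * `interaction`: one-row tibble with the interaction log-odds and p;
#'   * `control_cocarriage`: tibble of modifier co-carriage fractions among
#'     control carriers/non-carriers of the primary variant.
#' @export
penetrance_modifier <- function(callset, primary_variant, modifier_variant) {
  stopifnot(inherits(callset, "cohort_callset"))
  g1 <- callset$genotypes[primary_variant, ]
  g2 <- callset$genotypes[modifier_variant, ]
  y <- as.integer(callset$samples$phenotype == "case")

  strata <- vector("list", 2)
  for (si in 1:2) {
    carrier <- if (si == 1) !is.na(g1) & g1 > 0 else !is.na(g1) & g1 == 0
    lab <- if (si == 1) "carrier" else "non_carrier"
    ys <- y[carrier]; g2s <- g2[carrier]
    ok <- !is.na(g2s)
    ys <- ys[ok]; g2s <- g2s[ok]
    if (length(ys) == 0 || length(unique(ys)) < 2 ||
        length(unique(g2s)) < 2) {
      strata[[si]] <- tibble(stratum = lab, modifier_genotype = NA_integer_,
                             n = length(ys), n_cases = sum(ys),
                             case_fraction = NA_real_, or_vs_wt = NA_real_,
                             degenerate = TRUE,
                             p_logistic = NA_real_, p_exact = NA_real_)
      next
    }
    tab <- table(factor(ys, levels = 0:1), factor(g2s, levels = 0:2))
    p_exact <- fisher.test(tab[, colSums(tab) > 0, drop = FALSE])$p.value
    la <- logistic_assoc(ys, g2s, NULL)
    per_gt <- map(0:2, function(k) {
      nk <- sum(g2s == k); ck <- sum(ys[g2s == k])
      or <- NA_real_; degen <- FALSE
      if (k > 0 && nk > 0 && sum(g2s == 0) > 0) {
        a <- ck; b <- nk - ck
        c0 <- sum(ys[g2s == 0]); d0 <- sum(g2s == 0) - c0
        if (b == 0 || c0 == 0) {
          or <- Inf; degen <- TRUE # all carriers cases (or no wt cases)
        } else if (a == 0 || d0 == 0) {
          or <- 0; degen <- TRUE
        } else {
          or <- (a * d0) / (b * c0)
        }
      }
      tibble(stratum = lab, modifier_genotype = k, n = nk, n_cases = ck,
             case_fraction = if (nk > 0) ck / nk else NA_real_,
             or_vs_wt = or, degenerate = degen,
             p_logistic = la$p, p_exact = p_exact)
    })
    strata[[si]] <- bind_rows(per_gt)
  }

  ok <- !is.na(g1) & !is.na(g2)
  inter <- tryCatch({
    fit <- suppressWarnings(
      glm(y[ok] ~ g1[ok] * g2[ok], family = binomial()))
    sm <- summary(fit)$coefficients
    row <- grep(":", rownames(sm))
    tibble(interaction_logor = sm[row, 1], interaction_p = sm[row, 4])
  }, error = function(e) {
    tibble(interaction_logor = NA_real_, interaction_p = NA_real_)
  })

  ctrl <- callset$samples$phenotype == "control" & ok
  cocc <- tibble(
    primary_status = c("carrier", "non_carrier"),
    n_controls = c(sum(ctrl & g1 > 0), sum(ctrl & g1 == 0)),
    modifier_cocarriage = c(
      mean(g2[ctrl & g1 > 0] > 0),
      mean(g2[ctrl & g1 == 0] > 0)
    )
  )

  structure(list(strata = bind_rows(strata), interaction = inter,
                 control_cocarriage = cocc,
                 primary_variant = primary_variant,
                 modifier_variant = modifier_variant),
            class = "svbk_penetrance")
}

#' @export
print.svbk_penetrance <- function(x, ...) {
  cat("<svbk_penetrance> primary:", x$primary_variant,
      " modifier:", x$modifier_variant, "\n")
  print(x$strata)
  cat("interaction p:", format(x$interaction$interaction_p, digits = 3), "\n")
  print(x$control_cocarriage)
  invisible(x)
}

#' @method tidy svbk_penetrance
#' @export
tidy.svbk_penetrance <- function(x, ...) x$strata

#' @method glance svbk_penetrance
#' @export
glance.svbk_penetrance <- function(x, ...) {
  dplyr::bind_cols(x$interaction,
                   tibble(p_exact_carrier =
                            x$strata$p_exact[x$strata$stratum == "carrier"][1]))
}
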