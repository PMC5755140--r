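# Single-marker case-control association statistics: genotype/allele count
# structures, allelic and genotypic odds ratios with Woolf (log-scale)
# confidence intervals and Haldane-Anscombe correction, chi-squared /
# Fisher association tests with Bonferroni adjustment, plus depth
# filtering and the tumor-vs-normal de novo variant screen.

#' Genotype counts for a biallelic marker
#'
#' Counts are stored in the order commonly printed for a G>C style
#' marker: hom-alt / het / hom-ref (e.g. GG/CG/CC).
#'
#' @param hom_alt,het,hom_ref Non-negative integer counts.
#' @return An object of class `genotype_counts` with an `n_individuals`
#'   field (the sum).
#' @examples
#' genotype_counts(hom_alt = 0, het = 7, hom_ref = 202)
#' @export
genotype_counts <- function(hom_alt, het, hom_ref) {
  hom_alt <- check_count(hom_alt, "hom_alt")
  het <- check_count(het, "het")
  hom_ref <- check_count(hom_ref, "hom_ref")
  structure(list(hom_alt = hom_alt, het = het, hom_ref = hom_ref,
                 n_individuals = hom_alt + het + hom_ref),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("genotype counts (hom_alt/het/hom_ref): %d/%d/%d (n = %d)\n",
              x$hom_alt, x$het, x$hom_ref, x$n_individuals))
  invisible(x)
}

#' Allele counts for a biallelic marker
#'
#' Either converts [genotype_counts()] (`alt = 2*hom_alt + het`,
#' `ref = 2*hom_ref + het`) or constructs counts directly from alt and
#' ref allele totals.
#'
#' @param x A `genotype_counts` object, or the alt allele count.
#' @param ref Ref allele count (only when `x` is the alt count).
#' @param ... Unused.
#' @return An object of class `allele_counts` with fields `alt`, `ref`
#'   and `frequency` (`alt / (alt + ref)`).
#' @examples
#' allele_counts(genotype_counts(6, 519, 32827))$frequency  # 0.00796
#' allele_counts(5, 1001)
#' @export
allele_counts <- function(x, ...) UseMethod("allele_counts")

#' @rdname allele_counts
#' @export
allele_counts.genotype_counts <- function(x, ...) {
  allele_counts(2L * x$hom_alt + x$het, 2L * x$hom_ref + x$het)
}

#' @rdname allele_counts
#' @export
allele_counts.default <- function(x, ref, ...) {
  alt <- check_count(x, "alt")
  ref <- check_count(ref, "ref")
  if (alt + ref == 0L) {
    stop_invalid("allele frequency undefined: zero total allele count")
  }
  structure(list(alt = alt, ref = ref, frequency = alt / (alt + ref)),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("allele counts: alt = %d, ref = %d (frequency %.5g)\n",
              x$alt, x$ref, x$frequency))
  invisible(x)
}

#' Reconstruct genotype counts from allele counts
#'
#' Reference panels sometimes publish only allele counts.  Under the
#' assumption of no hom-alt carriers (reasonable for rare variants and
#' required to make the reconstruction unique) the solution of
#' `2*hom_alt + het = alt`, `het + 2*hom_ref = ref` is `het = alt`,
#' `hom_alt = 0`, `hom_ref = (ref - alt) / 2`.
#'
#' @param a An [allele_counts()] object.
#' @param assume_no_hom_alt Must be `TRUE`; without the assumption the
#'   genotype distribution is not identifiable from allele counts.
#' @return A [genotype_counts()] object.
#' @examples
#' genotypes_from_alleles(allele_counts(5, 1001), assume_no_hom_alt = TRUE)
#' @export
genotypes_from_alleles <- function(a, assume_no_hom_alt = FALSE) {
  if (!inherits(a, "allele_counts")) {
    stop_invalid("`a` must be an allele_counts object")
  }
  if (!isTRUE(assume_no_hom_alt)) {
    stop_invalid(paste("genotype reconstruction from allele counts requires",
                       "assume_no_hom_alt = TRUE (otherwise not identifiable)"))
  }
  if (a$alt > (a$alt + a$ref) / 2) {
    stop_invalid("infeasible: alt (%d) exceeds half the allele total under no hom-alt",
                 a$alt)
  }
  if ((a$ref - a$alt) %% 2L != 0L) {
    stop_invalid("infeasible: ref - het = %d is odd, cannot form hom-ref pairs",
                 a$ref - a$alt)
  }
  genotype_counts(hom_alt = 0L, het = a$alt,
                  hom_ref = (a$ref - a$alt) %/% 2L)
}

#' Allele counts from a published frequency
#'
#' Converts a reference-population allele frequency into integer counts
#' at a stated allele total, rounding half away from zero.
#'
#' @param freq Allele frequency in \[0, 1\].
#' @param n_alleles Total number of alleles (>= 1); e.g. 1006 for 503
#'   European diploid samples.
#' @return An [allele_counts()] object.
#' @examples
#' counts_from_frequency(0.004, 1006)  # alt = 4, ref = 1002
#' @export
counts_from_frequency <- function(freq, n_alleles) {
  check_scalar_number(freq, "freq", min = 0, max = 1)
  n_alleles <- check_count(n_alleles, "n_alleles", min = 1)
  alt <- as.integer(floor(freq * n_alleles + 0.5))
  allele_counts(alt, n_alleles - alt)
}

#' A 2x2 case-control contingency table
#'
#' @param a,b Case exposed / unexposed counts.
#' @param c,d Control exposed / unexposed counts.
#' @return A 2x2 integer matrix (rows = case/control, columns =
#'   exposed/unexposed).
#' @export
contingency_2x2 <- function(a, b, c, d) {
  vals <- c(check_count(a, "a"), check_count(b, "b"),
            check_count(c, "c"), check_count(d, "d"))
  matrix(vals, nrow = 2, byrow = TRUE,
         dimnames = list(c("case", "control"), c("exposed", "unexposed")))
}

check_2x2 <- function(tab) {
  if (is.data.frame(tab)) tab <- as.matrix(tab)
  if (!is.matrix(tab) || !all(dim(tab) == c(2L, 2L)) || !is.numeric(tab) ||
      any(tab < 0) || any(tab != round(tab))) {
    stop_invalid("expected a 2x2 matrix of non-negative counts")
  }
  tab
}

#' Odds ratio with Woolf (log-scale) confidence interval
#'
#' `OR = (a*d) / (b*c)` with the Woolf interval
#' `exp(ln OR +/- z * SE)`, `SE = sqrt(1/a + 1/b + 1/c + 1/d)`, and a
#' two-sided Wald p-value from `ln(OR) / SE`.  If any cell is zero, the
#' Haldane-Anscombe correction (0.5 added to every cell) is applied first
#' and flagged.
#'
#' @param tab A 2x2 matrix from [contingency_2x2()] (rows case/control,
#'   columns exposed/unexposed).
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `odds_ratio`, `ci_low`, `ci_high`, `p_value`,
#'   `conf_level` and `corrected` (whether Haldane-Anscombe was applied).
#' @examples
#' odds_ratio_ci(contingency_2x2(7, 411, 531, 66173))
#' @export
odds_ratio_ci <- function(tab, conf_level = 0.95) {
  tab <- check_2x2(tab)
  check_scalar_number(conf_level, "conf_level", min = 0, max = 1)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_invalid("odds ratio undefined: empty table margin")
  }
  corrected <- any(tab == 0)
  w <- if (corrected) tab + 0.5 else tab
  or <- (w[1, 1] * w[2, 2]) / (w[1, 2] * w[2, 1])
  se <- sqrt(sum(1 / w))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(odds_ratio = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       p_value = 2 * stats::pnorm(-abs(log(or) / se)),
       conf_level = conf_level,
       corrected = corrected)
}

#' Association p-value for a 2x2 table
#'
#' Pearson chi-squared (df = 1, no continuity correction) or two-sided
#' Fisher's exact test (sum of hypergeometric probabilities of all tables
#' with fixed margins whose probability does not exceed the observed
#' table's, within a small relative tolerance).  `method = "auto"`
#' selects Fisher when any expected cell count is below 5, chi-squared
#' otherwise.
#'
#' @param tab A 2x2 count matrix.
#' @param method `"auto"`, `"chi2"` or `"fisher"`.
#' @return A list with `p_value` and `method` (the test actually used).
#' @export
association_pvalue <- function(tab, method = c("auto", "chi2", "fisher")) {
  method <- match.arg(method)
  tab <- check_2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop_invalid("association test undefined: empty table margin")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (method == "auto") {
    method <- if (any(expected < 5)) "fisher" else "chi2"
  }
  p <- if (method == "chi2") {
    suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  } else {
    stats::fisher.test(tab)$p.value
  }
  list(p_value = p, method = method)
}

#' Bonferroni multiple-testing adjustment
#'
#' `adjusted_i = min(1, m * p_i)` with `m` the number of tests.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values of the same length.
#' @export
bonferroni_adjust <- function(p_values) {
  if (!is.numeric(p_values) || any(!is.finite(p_values)) ||
      any(p_values < 0) || any(p_values > 1)) {
    stop_invalid("p-values must be numbers in [0, 1]")
  }
  stats::p.adjust(p_values, method = "bonferroni")
}

resolve_reference <- function(reference, assume_no_hom_alt) {
  if (inherits(reference, "genotype_counts")) {
    list(alleles = allele_counts(reference), genotypes = reference)
  } else if (inherits(reference, "allele_counts")) {
    geno <- if (isTRUE(assume_no_hom_alt)) {
      genotypes_from_alleles(reference, assume_no_hom_alt = TRUE)
    }
    list(alleles = reference, genotypes = geno)
  } else if (is.numeric(reference) &&
             all(c("frequency", "n_alleles") %in% names(reference))) {
    al <- counts_from_frequency(reference[["frequency"]],
                                reference[["n_alleles"]])
    geno <- if (isTRUE(assume_no_hom_alt)) {
      genotypes_from_alleles(al, assume_no_hom_alt = TRUE)
    }
    list(alleles = al, genotypes = geno)
  } else {
    stop_invalid(paste("`reference` must be genotype_counts, allele_counts,",
                       "or c(frequency = ..., n_alleles = ...)"))
  }
}

#' Single-marker association of a cohort against a reference population
#'
#' Builds the allelic 2x2 table (cohort alt/ref alleles vs reference
#' alt/ref alleles) and the genotypic carrier table (het vs hom-ref,
#' cohort vs reference), computes [odds_ratio_ci()] for both, and an
#' [association_pvalue()] on the allelic table.
#'
#' @param cohort [genotype_counts()] of the patient cohort.
#' @param reference Reference population: a [genotype_counts()], an
#'   [allele_counts()] (set `assume_no_hom_alt = TRUE` to enable the
#'   genotypic OR), or `c(frequency = ..., n_alleles = ...)`.
#' @param snp_id Marker identifier carried through to the result.
#' @param conf_level Confidence level for both ORs.
#' @param method Test selection for the association p-value
#'   (see [association_pvalue()]).
#' @param assume_no_hom_alt Assume the reference has no hom-alt carriers
#'   when only allele counts/frequencies are available.
#' @param genotypic Compute the genotypic (het vs hom-ref) OR; errors if
#'   the reference cannot be resolved to genotype counts.
#' @param m_tests Bonferroni family size applied to the association
#'   p-value (default 1, i.e. no adjustment).
#' @return An object of class `association_result`: `snp_id`, `af_obs`,
#'   `af_ref`, `allelic` and `genotypic` OR blocks, `test_method`,
#'   `p_association`, `p_bonferroni`.
#' @examples
#' single_marker_association(
#'   cohort = genotype_counts(0, 7, 202),
#'   reference = genotype_counts(6, 519, 32827),
#'   snp_id = "rs141193530"
#' )
#' @export
single_marker_association <- function(cohort, reference, snp_id = "snp",
                                      conf_level = 0.95, method = "auto",
                                      assume_no_hom_alt = FALSE,
                                      genotypic = TRUE, m_tests = 1) {
  if (!inherits(cohort, "genotype_counts")) {
    stop_invalid("`cohort` must be a genotype_counts object")
  }
  if (cohort$n_individuals == 0L) stop_invalid("empty cohort")
  m_tests <- check_count(m_tests, "m_tests", min = 1)

  co_al <- allele_counts(cohort)
  ref <- resolve_reference(reference, assume_no_hom_alt)

  allelic_tab <- contingency_2x2(co_al$alt, co_al$ref,
                                 ref$alleles$alt, ref$alleles$ref)
  allelic <- odds_ratio_ci(allelic_tab, conf_level)
  assoc <- association_pvalue(allelic_tab, method)

  genotypic_res <- NULL
  if (isTRUE(genotypic)) {
    if (is.null(ref$genotypes)) {
      stop_invalid(paste("genotypic OR unsupported: reference has allele",
                         "counts only and assume_no_hom_alt is FALSE"))
    }
    geno_tab <- contingency_2x2(cohort$het, cohort$hom_ref,
                                ref$genotypes$het, ref$genotypes$hom_ref)
    genotypic_res <- odds_ratio_ci(geno_tab, conf_level)
  }

  structure(list(snp_id = snp_id,
                 af_obs = co_al$frequency,
                 af_ref = ref$alleles$frequency,
                 allelic = allelic,
                 genotypic = genotypic_res,
                 test_method = assoc$method,
                 p_association = assoc$p_value,
                 p_bonferroni = min(1, m_tests * assoc$p_value)),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s: AF_OBS %.5g vs AF_REF %.5g\n", x$snp_id, x$af_obs,
              x$af_ref))
  cat(sprintf("  allelic  OR %.4g (%.4g-%.4g), Wald p %.4g\n",
              x$allelic$odds_ratio, x$allelic$ci_low, x$allelic$ci_high,
              x$allelic$p_value))
  if (!is.null(x$genotypic)) {
    cat(sprintf("  genotypic OR %.4g (%.4g-%.4g), Wald p %.4g\n",
                x$genotypic$odds_ratio, x$genotypic$ci_low,
                x$genotypic$ci_high, x$genotypic$p_value))
  }
  cat(sprintf("  association p %.4g (%s), Bonferroni %.4g\n",
              x$p_association, x$test_method, x$p_bonferroni))
  invisible(x)
}

#' Filter variant records by read depth
#'
#' Keeps records with `depth >= min_depth` (inclusive), preserving order.
#'
#' @param variants Data frame of variant records with a `depth` column.
#' @param min_depth Minimum depth (default 20, the usual coverage cutoff
#'   for targeted resequencing).
#' @return The filtered data frame.
#' @export
filter_by_depth <- function(variants, min_depth = 20) {
  min_depth <- check_count(min_depth, "min_depth")
  if (!is.data.frame(variants) || !"depth" %in% names(variants)) {
    stop_invalid("`variants` must be a data frame with a `depth` column")
  }
  out <- variants[variants$depth >= min_depth, , drop = FALSE]
  rownames(out) <- NULL
  out
}

variant_key <- function(v) {
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

#' De novo (somatic) variant candidates
#'
#' Returns the tumor records whose key (chrom, pos, ref, alt) is absent
#' from the matched normal sample of the same individual — i.e. variants
#' present in the tumor but not in healthy control tissue.
#'
#' @param tumor,normal Data frames of variant records with columns
#'   `chrom`, `pos`, `ref`, `alt`.
#' @return The subset of `tumor` absent from `normal`.
#' @export
somatic_candidates <- function(tumor, normal) {
  need <- c("chrom", "pos", "ref", "alt")
  for (v in list(tumor, normal)) {
    if (!is.data.frame(v) || !all(need %in% names(v))) {
      stop_invalid("variant tables need columns %s", paste(need, collapse = ", "))
    }
  }
  out <- tumor[!variant_key(tumor) %in% variant_key(normal), , drop = FALSE]
  rownames(out) <- NULL
  out
}
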