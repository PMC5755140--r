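# Count structures, odds ratios with Woolf CIs, association tests, and
# the de novo variant screen.

test_that("depth filtering keeps records at the inclusive cutoff", {
  v <- data.frame(chrom = "chr1", pos = 1:3, ref = "A", alt = "C",
                  depth = c(19, 20, 21))
  expect_identical(filter_by_depth(v)$depth, c(20, 21))
  expect_identical(nrow(filter_by_depth(v[0, ])), 0L)
  expect_identical(filter_by_depth(v, min_depth = 0), v)
})

test_that("somatic candidates are the tumor-only variant keys", {
  norm <- data.frame(chrom = "chr1", pos = c(10, 20), ref = c("A", "G"),
                     alt = c("T", "C"), stringsAsFactors = FALSE)
  expect_identical(nrow(somatic_candidates(norm, norm)), 0L)

  tum <- rbind(norm, data.frame(chrom = "chr1", pos = 30, ref = "C",
                                alt = "G"))
  expect_identical(somatic_candidates(tum, norm)$pos, 30)

  # same locus, different alt allele counts as de novo
  tum2 <- norm; tum2$alt[1] <- "G"
  expect_identical(somatic_candidates(tum2, norm)$pos, 10)
})

test_that("genotype counts convert to allele counts and back", {
  a <- allele_counts(genotype_counts(0, 7, 202))
  expect_identical(c(a$alt, a$ref), c(7L, 411L))

  exac <- allele_counts(genotype_counts(6, 519, 32827))
  expect_identical(c(exac$alt, exac$ref), c(531L, 66173L))
  expect_equal(signif(exac$frequency, 3), 0.00796)

  z <- allele_counts(genotype_counts(0, 0, 12))
  expect_identical(c(z$alt, z$ref), c(0L, 24L))
  expect_error(allele_counts(0, 0), "undefined")

  g <- genotypes_from_alleles(allele_counts(5, 1001), assume_no_hom_alt = TRUE)
  expect_identical(c(g$hom_alt, g$het, g$hom_ref), c(0L, 5L, 498L))
  g2 <- genotypes_from_alleles(allele_counts(2, 8), assume_no_hom_alt = TRUE)
  expect_identical(c(g2$hom_alt, g2$het, g2$hom_ref), c(0L, 2L, 3L))
  expect_identical(genotypes_from_alleles(allele_counts(0, 24),
                                          assume_no_hom_alt = TRUE)$hom_ref,
                   12L)
  expect_error(genotypes_from_alleles(allele_counts(2, 7),
                                      assume_no_hom_alt = TRUE), "odd")
  expect_error(genotypes_from_alleles(allele_counts(5, 1001)),
               "assume_no_hom_alt")
})

test_that("frequencies convert to counts with half-away-from-zero rounding", {
  a <- counts_from_frequency(0.004, 1006)
  expect_identical(c(a$alt, a$ref), c(4L, 1002L))
  expect_identical(counts_from_frequency(0.5, 10)$alt, 5L)
  expect_identical(counts_from_frequency(0, 100)$ref, 100L)
  expect_error(counts_from_frequency(1.5, 100), "freq")
})

test_that("odds ratio uses the Woolf interval and Haldane correction", {
  sym <- odds_ratio_ci(contingency_2x2(1, 1, 1, 1))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_value, 1)
  expect_false(sym$corrected)

  hald <- odds_ratio_ci(contingency_2x2(0, 10, 5, 85))
  expect_true(hald$corrected)
  expect_equal(hald$odds_ratio, (0.5 * 85.5) / (10.5 * 5.5))

  expect_error(odds_ratio_ci(contingency_2x2(0, 0, 5, 85)), "margin")

  set.seed(23)
  for (i in 1:25) {
    tab <- random_2x2(200)
    r <- odds_ratio_ci(tab)
    # CI symmetric about log(OR)
    expect_equal(log(r$ci_high) - log(r$odds_ratio),
                 log(r$odds_ratio) - log(r$ci_low), tolerance = 1e-12)
    expect_true(r$ci_low <= r$odds_ratio && r$odds_ratio <= r$ci_high)
    # swapping case and control rows inverts the OR and mirrors the CI
    s <- odds_ratio_ci(tab[2:1, ])
    expect_equal(s$odds_ratio, 1 / r$odds_ratio)
    expect_equal(s$ci_low, 1 / r$ci_high)
    expect_equal(s$ci_high, 1 / r$ci_low)
    expect_equal(s$p_value, r$p_value)
  }
})

test_that("association p-values follow the chi2/Fisher selection rule", {
  eq <- association_pvalue(contingency_2x2(5, 5, 50, 50))
  expect_equal(eq$p_value, 1)
  expect_identical(eq$method, "chi2")

  f <- association_pvalue(contingency_2x2(1, 9, 9, 1), method = "fisher")
  expect_equal(f$p_value, fisher_enumeration_p(contingency_2x2(1, 9, 9, 1)))
  expect_equal(f$p_value, 0.00109, tolerance = 5e-3)

  auto <- association_pvalue(contingency_2x2(2, 3, 4, 5))
  expect_identical(auto$method, "fisher")

  expect_error(association_pvalue(contingency_2x2(0, 0, 5, 5)), "margin")

  set.seed(77)
  for (i in 1:40) {
    tab <- random_2x2(40)
    expect_equal(association_pvalue(tab, "fisher")$p_value,
                 fisher_enumeration_p(tab), tolerance = 1e-9)
  }
})

test_that("Bonferroni adjustment is capped, monotone and order-preserving", {
  expect_equal(bonferroni_adjust(rep(0.008, 6)), rep(0.048, 6))
  expect_equal(bonferroni_adjust(0.3), 0.3)
  expect_equal(bonferroni_adjust(c(0.5, 0.2, 0.9)), c(1, 0.6, 1))
  expect_error(bonferroni_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(3)
  p <- sort(runif(10))
  adj <- bonferroni_adjust(p)
  expect_true(all(diff(adj) >= 0))
  expect_true(all(adj >= p))
})

test_that("single-marker association reproduces the published worked example", {
  res <- single_marker_association(table2_cohort(), table2_exac(),
                                   snp_id = "rs141193530")
  expect_equal(res$allelic$odds_ratio, 2.12, tolerance = 5e-3)
  expect_equal(res$genotypic$odds_ratio, 2.19, tolerance = 5e-3)
  expect_equal(res$af_ref, 0.00796, tolerance = 1e-3)
  expect_true(res$p_bonferroni >= res$p_association)

  kgp <- single_marker_association(table2_cohort(), table2_kgp(),
                                   assume_no_hom_alt = TRUE)
  expect_equal(kgp$allelic$odds_ratio, 3.41, tolerance = 5e-3)
  expect_equal(kgp$genotypic$odds_ratio, 3.45, tolerance = 5e-3)

  # a zero-carrier cohort triggers the flagged Haldane correction
  zero <- single_marker_association(genotype_counts(0, 0, 100),
                                    table2_exac())
  expect_true(zero$allelic$corrected)

  expect_error(
    single_marker_association(table2_cohort(),
                              c(frequency = 0.005, n_alleles = 1006)),
    "unsupported|assume_no_hom_alt")
})
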