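# Synthetic-data generators: determinism, boundary behaviour, and
# agreement of sample statistics with the stated generative models.

test_that("all simulators are pure functions of (spec, seed)", {
  spec <- expression_sim_spec(
    n_pairs = 5,
    genes = data.frame(gene = c("G1", "G3"), delta = c(1, 2),
                       loading = c(1, 0.5)),
    seed = 11)
  expect_identical(simulate_paired_ct(spec), simulate_paired_ct(spec))

  gspec <- genotype_sim_spec(100, maf = 0.3, seed = 5)
  expect_identical(simulate_genotypes(gspec), simulate_genotypes(gspec))

  expect_identical(simulate_variant_pair(4, 2, c(20, 60), seed = 9),
                   simulate_variant_pair(4, 2, c(20, 60), seed = 9))

  pwm <- pwm_model(matrix(c(9, 1, 0, 0, 0, 0, 8, 2, 1, 1, 1, 7), nrow = 4))
  expect_identical(generate_motif_sequence(pwm, 10, 1, "A", seed = 3),
                   generate_motif_sequence(pwm, 10, 1, "A", seed = 3))

  # the global RNG stream is untouched
  set.seed(42); before <- rnorm(1)
  set.seed(42); invisible(simulate_paired_ct(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("paired Ct simulation honours boundary cases and validation", {
  genes <- data.frame(gene = "G1", delta = 1, loading = 0)
  empty <- simulate_paired_ct(expression_sim_spec(0, genes, seed = 1))
  expect_identical(nrow(empty), 0L)
  expect_named(empty, c("sample", "gene", "tissue", "replicate", "ct"))

  expect_error(expression_sim_spec(-1, genes, seed = 1), "n_pairs")
  expect_error(expression_sim_spec(5, genes, noise_sd = -0.1, seed = 1),
               "noise_sd")
  expect_error(
    expression_sim_spec(
      5, data.frame(gene = "HPRT1", delta = 2, loading = 0), seed = 1),
    "housekeeping")
})

test_that("mean per-pair ddCt matches the simulated shift (law of large numbers)", {
  spec <- expression_sim_spec(
    n_pairs = 2000,
    genes = data.frame(gene = "G1", delta = 2, loading = 0),
    noise_sd = 0.1, seed = 77)
  tab <- simulate_paired_ct(spec)
  res <- run_expression_analysis(tab, "G1")
  expect_lt(abs(mean(res$per_pair$ddct) - 2), 0.05)
})

test_that("genotype simulation follows Hardy-Weinberg proportions", {
  g0 <- simulate_genotypes(genotype_sim_spec(50, maf = 0, seed = 1))
  expect_identical(c(g0$hom_ref, g0$het, g0$hom_alt), c(50L, 0L, 0L))
  g1 <- simulate_genotypes(genotype_sim_spec(50, maf = 1, seed = 1))
  expect_identical(c(g1$hom_ref, g1$het, g1$hom_alt), c(0L, 0L, 50L))
  expect_error(genotype_sim_spec(50, maf = 1.2, seed = 1), "maf")

  g <- simulate_genotypes(genotype_sim_spec(10000, maf = 0.3, seed = 4))
  expect_identical(g$n_individuals, 10000L)
  expect_lt(abs(g$het / g$n_individuals - 0.42), 0.02)
})

test_that("mean simulated allele frequency is unbiased over replicates", {
  afs <- vapply(1:1000, function(i) {
    g <- simulate_genotypes(genotype_sim_spec(100, maf = 0.1, seed = i))
    allele_counts(g)$frequency
  }, 1)
  expect_lt(abs(mean(afs) - 0.1), 0.01)
})

test_that("variant-pair simulation spikes an unambiguous somatic truth set", {
  vp0 <- simulate_variant_pair(5, 0, c(20, 60), seed = 2)
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt)
  expect_setequal(key(vp0$tumor), key(vp0$normal))
  expect_identical(nrow(somatic_candidates(vp0$tumor, vp0$normal)), 0L)

  vp <- simulate_variant_pair(5, 3, c(20, 60), seed = 2)
  som <- somatic_candidates(vp$tumor, vp$normal)
  expect_identical(nrow(som), 3L)
  expect_setequal(key(som), setdiff(key(vp$tumor), key(vp$normal)))

  depths <- c(vp$tumor$depth, vp$normal$depth)
  expect_true(all(depths >= 20 & depths <= 60))
  expect_identical(filter_by_depth(vp$tumor, min_depth = 20), vp$tumor)

  expect_error(simulate_variant_pair(1, 1, c(30, 20), seed = 1), "depth")
})

test_that("planted motif sequences carry the consensus and the SNP", {
  pwm <- pwm_model(matrix(c(9, 1, 0, 0,
                            0, 0, 8, 2,
                            1, 1, 1, 7,
                            8, 0, 1, 1), nrow = 4))
  gen0 <- generate_motif_sequence(pwm, 0, 0, "C", seed = 1)
  expect_identical(nchar(gen0$sequence), ncol(pwm$matrix))

  gen <- generate_motif_sequence(pwm, 25, 2, "A", seed = 8)
  expect_identical(gen$planted_start, 25L)
  expect_identical(gen$snp$pos, 27L)
  expect_identical(substr(gen$sequence, gen$snp$pos + 1, gen$snp$pos + 1),
                   gen$snp$ref)

  hits <- scan_sequence(pfm_to_log_odds(pwm), gen$sequence)
  expect_identical(hits$start[which.max(hits$score)], gen$planted_start)

  # alt base must differ from the planted consensus base
  consensus2 <- c("A", "C", "G", "T")[which.max(pwm$matrix[, 3])]
  expect_error(generate_motif_sequence(pwm, 5, 2, consensus2, seed = 1),
               "alt_base")
})
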