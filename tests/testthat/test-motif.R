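# PWM log-odds scoring: matrix construction, sequence scanning against a
# naive oracle, and SNP disruption deltas including the -Inf rule.

test_that("log-odds entries follow the pseudocount-regularised formula", {
  uni <- pwm_model(matrix(2, nrow = 4, ncol = 3))
  expect_true(all(pfm_to_log_odds(uni) == 0))

  col <- matrix(c(4, 0, 0, 0), nrow = 4)
  lo0 <- pfm_to_log_odds(pwm_model(col, pseudocount = 0))
  expect_equal(unname(lo0["A", 1]), 2)
  expect_true(all(is.infinite(lo0[c("C", "G", "T"), 1]) &
                    lo0[c("C", "G", "T"), 1] < 0))

  lo1 <- pfm_to_log_odds(pwm_model(col, pseudocount = 1))
  expect_equal(unname(lo1["A", 1]), log2(3.4))
  expect_true(all(is.finite(lo1)))

  expect_error(pwm_model(matrix(-1, 4, 2)), "non-negative")
})

test_that("scanning matches an exhaustive window-rescoring oracle", {
  set.seed(55)
  for (i in 1:25) {
    pwm <- random_pwm()
    pwm$pseudocount <- sample(c(0, 0.5, 1), 1)
    lo <- pfm_to_log_odds(pwm)
    seq <- random_dna(ncol(lo) + sample(0:40, 1) + 10)
    got <- scan_sequence(lo, seq, threshold = -Inf)
    want <- naive_scan(lo, seq)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score)
  }
})

test_that("scan respects strand symmetry, thresholds and short sequences", {
  set.seed(66)
  pwm <- random_pwm(len = 5)
  lo <- pfm_to_log_odds(pwm)
  seq <- random_dna(60)

  fwd <- scan_sequence(lo, seq)
  rev <- scan_sequence(lo, reverse_complement(seq))
  expect_equal(sort(fwd$score), sort(rev$score))

  # threshold -Inf reports every window on both strands
  expect_identical(nrow(fwd), 2L * (60L - 5L + 1L))
  expect_identical(nrow(scan_sequence(lo, seq, strands = "plus")),
                   60L - 5L + 1L)
  expect_identical(nrow(scan_sequence(lo, "ACG")), 0L)

  # N contributes the background-weighted column mean
  lo_fin <- pfm_to_log_odds(pwm_model(pwm$matrix, pseudocount = 1))
  tail_seq <- random_dna(4)
  bases <- c("A", "C", "G", "T")
  sN <- scan_sequence(lo_fin, paste0("N", tail_seq), strands = "plus")
  tail_codes <- match(strsplit(tail_seq, "")[[1]], bases)
  expected <- sum(0.25 * lo_fin[, 1]) +
    sum(lo_fin[cbind(tail_codes, 2:5)])
  expect_equal(sN$score[1], expected)
})

test_that("SNP deltas are additive per column and obey the -Inf rule", {
  counts <- matrix(c(8, 0, 1, 1,
                     0, 9, 0, 1,
                     1, 0, 8, 1), nrow = 4)
  pwm <- pwm_model(counts, name = "toy")
  lo <- pfm_to_log_odds(pwm)
  seq <- paste0("TT", paste(c("A", "C", "G")[1:3], collapse = ""), "TT")

  # alt = ref leaves every delta at zero
  d0 <- snp_motif_delta(lo, seq, list(pos = 3, ref = "C", alt = "C"),
                        threshold = -Inf)
  expect_true(all(d0$delta[is.finite(d0$ref_score)] == 0))

  # same window for ref and alt: delta is the single-column entry change
  d <- snp_motif_delta(lo, seq, list(pos = 3, ref = "C", alt = "T"),
                       threshold = NULL, strands = "plus")
  top <- d[d$start == 2, ]
  expect_equal(top$delta, unname(lo["T", 2] - lo["C", 2]))

  # alt base hitting a zero-probability column scores -Inf
  dinf <- snp_motif_delta(lo, seq, list(pos = 3, ref = "C", alt = "G"),
                          strands = "plus")
  expect_true(all(dinf$delta == -Inf))

  # a SNP outside every reported window yields an empty result
  far <- snp_motif_delta(lo, paste0(seq, "AAAA"),
                         list(pos = 10, ref = "A", alt = "C"))
  expect_identical(nrow(far), 0L)

  expect_error(snp_motif_delta(lo, seq, list(pos = 3, ref = "G", alt = "T")),
               "offset 3")
})

test_that("positive pseudocounts keep every delta finite", {
  set.seed(99)
  for (i in 1:10) {
    pwm <- random_pwm(len = 4)
    pwm$pseudocount <- runif(1, 0.1, 2)
    lo <- pfm_to_log_odds(pwm)
    expect_true(all(is.finite(lo)))
    seq <- random_dna(30)
    pos <- sample(0:29, 1)
    ref <- substr(seq, pos + 1, pos + 1)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    d <- snp_motif_delta(lo, seq, list(pos = pos, ref = ref, alt = alt),
                         threshold = -Inf)
    expect_true(all(is.finite(d$delta)))
  }
})

test_that("JASPAR motifs round-trip through both text dialects", {
  pwm <- pwm_model(matrix(c(4, 19, 0, 3,
                            16, 0, 20, 2,
                            0, 1, 0, 14,
                            0, 0, 0, 1), nrow = 4, byrow = TRUE),
                   name = "MA0001.1 TEST")
  path <- withr::local_tempfile(fileext = ".jaspar")
  write_jaspar(pwm, path)
  back <- read_jaspar(path)
  expect_identical(names(back), "MA0001.1 TEST")
  expect_equal(unname(back[[1]]$matrix), unname(pwm$matrix))

  # bare matrix dialect: header line then four unlabelled rows
  path2 <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">MA0002.1 OTHER",
               "4 19 0 3", "16 0 20 2", "0 1 0 14", "0 0 0 1"), path2)
  back2 <- read_jaspar(path2)
  expect_equal(unname(back2[[1]]$matrix), unname(pwm$matrix))
})
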