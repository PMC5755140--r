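# Independent oracles used across the suite.  Each reimplements the
# quantity it checks from first principles (enumeration or naive loops),
# never through the package's own code path.

# Two-sided Fisher p by full hypergeometric enumeration over all tables
# with the observed margins.
fisher_enumeration_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_min <- max(0L, r1 + c1 - n); a_max <- min(r1, c1)
  a_all <- a_min:a_max
  probs <- stats::dhyper(a_all, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Two-sided Mann-Whitney p by enumeration of all assignments of the
# pooled values to group A, using the pairwise-comparison definition of
# U (count of a > b pairs plus half the ties) rather than rank sums.
mw_permutation_p <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  u_of <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(a, b)
  idx <- utils::combn(length(pool), na)
  us <- apply(idx, 2, function(i) u_of(pool[i], pool[-i]))
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# Naive per-window motif scorer: explicit loops, explicit reverse
# complement, no vectorised shortcuts.
naive_scan <- function(log_odds, seq, strands = "both") {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  m <- ncol(log_odds)
  chars <- strsplit(seq, "")[[1]]
  lseq <- length(chars)
  out <- list()
  for (start0 in 0:(lseq - m)) {
    win <- chars[(start0 + 1):(start0 + m)]
    s_plus <- 0
    for (j in seq_len(m)) s_plus <- s_plus + log_odds[match(win[j], bases), j]
    out[[length(out) + 1L]] <- data.frame(start = start0, strand = "+",
                                          score = s_plus)
    if (strands == "both") {
      rcwin <- rev(unname(comp[win]))
      s_minus <- 0
      for (j in seq_len(m)) {
        s_minus <- s_minus + log_odds[match(rcwin[j], bases), j]
      }
      out[[length(out) + 1L]] <- data.frame(start = start0, strand = "-",
                                            score = s_minus)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$strand), ]
}

# Random 2x2 table with total N <= n_max and no empty margin.
random_2x2 <- function(n_max = 40) {
  repeat {
    n <- sample(4:n_max, 1)
    cells <- as.vector(stats::rmultinom(1, n, prob = stats::runif(4, 0.05, 1)))
    tab <- matrix(cells, 2, 2)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) return(tab)
  }
}

# Random count PWM with strict per-column consensus.
random_pwm <- function(len = sample(4:8, 1), total = 20) {
  counts <- sapply(seq_len(len), function(j) {
    x <- as.vector(stats::rmultinom(1, total, prob = stats::runif(4)))
    # force a unique maximum so the consensus is well defined
    i <- which.max(x)
    x[i] <- x[i] + 2L
    x
  })
  pwm_model(counts, name = "rand")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

table2_cohort <- function() genotype_counts(0, 7, 202)
table2_exac <- function() genotype_counts(6, 519, 32827)
table2_kgp <- function() allele_counts(5, 1001)
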