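# PWM log-odds motif scoring and SNP motif-disruption deltas.
#
# A motif match is scored as the sum over columns of
# log2(p_b / background_b), where p_b is the (pseudocount-regularised)
# probability of the observed base.  With pseudocount 0 a base absent
# from a column has probability 0, odds 0, and scores -Inf; the
# difference between alt and ref log-odds is then -Inf as well,
# interpreted as complete loss of the motif match.

#' Construct a position weight/frequency matrix model
#'
#' @param counts Numeric matrix of per-position base counts or
#'   probabilities, either 4 x L with rows A, C, G, T or L x 4 (detected
#'   from dimnames or shape).
#' @param background Background base probabilities (A, C, G, T); must sum
#'   to 1.  Default uniform.
#' @param pseudocount Non-negative regulariser added as
#'   `pseudocount * background_b` to each count (default 0, which
#'   preserves -Inf scores for zero-probability bases).
#' @param name Motif name.
#' @return An object of class `pwm_model` with a 4 x L `matrix` slot.
#' @examples
#' pwm_model(matrix(c(4, 0, 0, 0, 0, 4, 0, 0), nrow = 4), name = "toy")
#' @export
pwm_model <- function(counts, background = c(A = 0.25, C = 0.25,
                                             G = 0.25, T = 0.25),
                      pseudocount = 0, name = "motif") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop_invalid("`counts` must be a numeric matrix")
  }
  if (nrow(counts) != 4L && ncol(counts) == 4L) counts <- t(counts)
  if (nrow(counts) != 4L) {
    stop_invalid("`counts` must have 4 rows (A, C, G, T) or 4 columns")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop_invalid("counts must be non-negative finite numbers")
  }
  if (ncol(counts) < 1L) stop_invalid("motif must have at least 1 position")
  if (any(colSums(counts) == 0)) {
    stop_invalid("every motif position needs a positive column total")
  }
  rownames(counts) <- DNA_BASES
  if (length(background) != 4L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-9) {
    stop_invalid("`background` must be 4 probabilities summing to 1")
  }
  background <- stats::setNames(as.numeric(background), DNA_BASES)
  check_scalar_number(pseudocount, "pseudocount", min = 0)
  structure(list(name = name, matrix = counts, background = background,
                 pseudocount = pseudocount),
            class = "pwm_model")
}

#' Convert a PWM/PFM to a log2-odds scoring matrix
#'
#' Per position and base: `log2(((count + pseudocount * background_b) /
#' (column_total + pseudocount)) / background_b)`.  Entries where the
#' regularised probability is 0 (possible only at pseudocount 0) are
#' `-Inf`.
#'
#' @param pwm A [pwm_model()].
#' @return A 4 x L numeric matrix (rows A, C, G, T) of class
#'   `log_odds_matrix` carrying the background and motif name as
#'   attributes.
#' @examples
#' m <- pwm_model(matrix(c(4, 0, 0, 0), nrow = 4), pseudocount = 1)
#' pfm_to_log_odds(m)[1, 1]  # log2(3.4)
#' @export
pfm_to_log_odds <- function(pwm) {
  if (!inherits(pwm, "pwm_model")) {
    stop_invalid("`pwm` must be created with pwm_model()")
  }
  totals <- colSums(pwm$matrix)
  probs <- sweep(pwm$matrix + pwm$pseudocount * pwm$background, 2,
                 totals + pwm$pseudocount, "/")
  lo <- log2(sweep(probs, 1, pwm$background, "/"))
  structure(lo, class = c("log_odds_matrix", "matrix"),
            background = pwm$background, motif = pwm$name)
}

check_log_odds <- function(log_odds) {
  if (!is.matrix(log_odds) || nrow(log_odds) != 4L) {
    stop_invalid("`log_odds` must be a 4-row matrix (use pfm_to_log_odds())")
  }
  log_odds
}

# Score all windows of `codes` (integer base codes, NA for N) on one
# strand.  N positions take the background-weighted mean of the column's
# entries (-Inf with pseudocount 0 whenever the column has a zero base).
score_windows <- function(log_odds, codes, background) {
  m <- ncol(log_odds)
  lseq <- length(codes)
  nw <- lseq - m + 1L
  if (nw < 1L) return(numeric(0))
  nscore <- colSums(log_odds * background)
  scores <- numeric(nw)
  for (j in seq_len(m)) {
    cj <- codes[j:(j + nw - 1L)]
    col <- unname(log_odds[, j])[cj]
    col[is.na(cj)] <- nscore[j]
    scores <- scores + col
  }
  unname(scores)
}

seq_codes <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  codes <- match(chars, DNA_BASES)  # N and other ambiguity codes -> NA
  codes
}

#' Scan a sequence for motif matches
#'
#' Scores every window of the sequence against a log-odds matrix; on the
#' minus strand the reverse complement of the window is scored and the
#' hit is reported in plus-strand coordinates.
#'
#' @param log_odds Matrix from [pfm_to_log_odds()].
#' @param seq Nucleotide string over A, C, G, T, N.  An N contributes the
#'   background-weighted mean of its column's entries.
#' @param threshold Minimum score to report (default `-Inf`, i.e. all
#'   windows).
#' @param strands `"both"` or `"plus"`.
#' @return A data frame of hits: `start` (0-based, plus-strand
#'   coordinates), `strand`, `score`.
#' @export
scan_sequence <- function(log_odds, seq, threshold = -Inf,
                          strands = c("both", "plus")) {
  strands <- match.arg(strands)
  log_odds <- check_log_odds(log_odds)
  seq <- clean_dna(seq, "seq", alphabet = c(DNA_BASES, "N"))
  background <- attr(log_odds, "background") %||%
    stats::setNames(rep(0.25, 4), DNA_BASES)
  m <- ncol(log_odds)
  lseq <- nchar(seq)
  empty <- data.frame(start = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (lseq < m) return(empty)

  plus <- score_windows(log_odds, seq_codes(seq), background)
  hits <- data.frame(start = seq_along(plus) - 1L, strand = "+",
                     score = plus, stringsAsFactors = FALSE)
  if (strands == "both") {
    minus <- score_windows(log_odds, seq_codes(reverse_complement(seq)),
                           background)
    # window starting at s (0-based) on the revcomp corresponds to the
    # plus-strand window starting at lseq - s - m
    hits_m <- data.frame(start = lseq - (seq_along(minus) - 1L) - m,
                         strand = "-", score = minus,
                         stringsAsFactors = FALSE)
    hits <- rbind(hits, hits_m)
  }
  hits <- hits[hits$score >= threshold, , drop = FALSE]
  hits <- hits[order(hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Default motif-match reporting threshold
#'
#' 80th percentile of the score range: `min + 0.8 * (max - min)`, with
#' the per-column minima/maxima taken over finite entries (so a
#' pseudocount-0 matrix with -Inf entries still yields a finite
#' threshold).
#'
#' @param log_odds Matrix from [pfm_to_log_odds()].
#' @return A scalar score threshold.
#' @export
default_scan_threshold <- function(log_odds) {
  log_odds <- check_log_odds(log_odds)
  finite_min <- apply(log_odds, 2, function(col) min(col[is.finite(col)]))
  smin <- sum(finite_min)
  smax <- sum(apply(log_odds, 2, max))
  smin + 0.8 * (smax - smin)
}

substitute_base <- function(seq, pos0, base) {
  paste0(substr(seq, 1L, pos0), base,
         substr(seq, pos0 + 2L, nchar(seq)))
}

#' Score the effect of a SNP on motif matches
#'
#' For every motif window (on the requested strands) that overlaps the
#' SNP and whose reference-sequence score reaches `threshold`, the window
#' is rescored on the singly-substituted sequence.  `delta = alt_score -
#' ref_score`; if the alternate base hits a zero-probability column
#' (pseudocount 0) the alt odds are 0 and `delta` is `-Inf`, interpreted
#' as complete loss of binding.
#'
#' @param log_odds Matrix from [pfm_to_log_odds()].
#' @param ref_seq Reference nucleotide sequence.
#' @param snp A list or vector with `pos` (0-based offset into
#'   `ref_seq`), `ref` and `alt` bases; `ref` must match the sequence.
#' @param threshold Minimum reference-window score to report; defaults to
#'   [default_scan_threshold()].
#' @param strands `"both"` or `"plus"`.
#' @return A data frame with `motif`, `start`, `strand`, `ref_score`,
#'   `alt_score`, `delta`.
#' @export
snp_motif_delta <- function(log_odds, ref_seq, snp, threshold = NULL,
                            strands = c("both", "plus")) {
  strands <- match.arg(strands)
  log_odds <- check_log_odds(log_odds)
  ref_seq <- clean_dna(ref_seq, "ref_seq", alphabet = c(DNA_BASES, "N"))
  pos0 <- check_count(snp[["pos"]], "snp$pos")
  ref_base <- toupper(snp[["ref"]]); alt_base <- toupper(snp[["alt"]])
  if (pos0 >= nchar(ref_seq)) {
    stop_invalid("SNP offset %d beyond sequence length %d", pos0,
                 nchar(ref_seq))
  }
  actual <- substr(ref_seq, pos0 + 1L, pos0 + 1L)
  if (actual != ref_base) {
    stop_invalid("reference base mismatch at offset %d: sequence has %s, SNP says %s",
                 pos0, actual, ref_base)
  }
  if (is.null(threshold)) threshold <- default_scan_threshold(log_odds)

  m <- ncol(log_odds)
  ref_hits <- scan_sequence(log_odds, ref_seq, threshold = threshold,
                            strands = strands)
  overlap <- ref_hits$start <= pos0 & pos0 < ref_hits$start + m
  ref_hits <- ref_hits[overlap, , drop = FALSE]
  motif_name <- attr(log_odds, "motif") %||% "motif"
  if (nrow(ref_hits) == 0L) {
    return(data.frame(motif = character(), start = integer(),
                      strand = character(), ref_score = numeric(),
                      alt_score = numeric(), delta = numeric(),
                      stringsAsFactors = FALSE))
  }

  alt_seq <- substitute_base(ref_seq, pos0, alt_base)
  alt_all <- scan_sequence(log_odds, alt_seq, threshold = -Inf,
                           strands = strands)
  key <- function(d) paste(d$start, d$strand)
  alt_score <- alt_all$score[match(key(ref_hits), key(alt_all))]
  delta <- alt_score - ref_hits$score
  # -Inf - -Inf is NaN; by convention delta is -Inf exactly when the alt
  # odds are 0, which cannot co-occur with a reported (>= threshold)
  # finite ref score unless threshold = -Inf.
  delta[is.infinite(alt_score) & alt_score < 0] <- -Inf
  data.frame(motif = motif_name, start = ref_hits$start,
             strand = ref_hits$strand, ref_score = ref_hits$score,
             alt_score = alt_score, delta = delta,
             stringsAsFactors = FALSE)
}
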