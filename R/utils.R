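# Shared internal helpers: validation, RNG scoping, nucleotide utilities.

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC degenerate nucleotide alphabet; values are the base sets each
# code stands for.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (finite && !is.finite(x))) {
    stop_invalid("`%s` must be a single finite number", name)
  }
  if (x < min || x > max) {
    stop_invalid("`%s` must be in [%s, %s], got %s", name,
                 format(min), format(max), format(x))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  check_scalar_number(x, name, min = min)
  if (x != as.integer(x)) {
    stop_invalid("`%s` must be a whole number", name)
  }
  invisible(as.integer(x))
}

check_seed <- function(seed) {
  if (missing(seed) || is.null(seed)) {
    stop_invalid("a `seed` is required; simulators keep no global RNG state")
  }
  check_count(seed, "seed")
}

# Runs `code` under a locally seeded RNG without disturbing global state.
with_rng <- function(seed, code) {
  withr::with_seed(seed, code)
}

clean_dna <- function(x, name = "sequence", alphabet = DNA_BASES) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop_invalid("`%s` must be a single character string", name)
  }
  x <- chartr("U", "T", toupper(x))
  bad <- setdiff(unique(strsplit(x, "")[[1]]), alphabet)
  if (length(bad)) {
    stop_invalid("`%s` contains non-nucleotide characters: %s", name,
                 paste(bad, collapse = ", "))
  }
  x
}

#' Reverse complement of a nucleotide string
#'
#' Supports the full IUPAC degenerate alphabet, so it can be applied both
#' to plain sequences and to degenerate restriction-site patterns such as
#' `GRCGYC`.
#'
#' @param x A single character string over the IUPAC alphabet.
#' @return The reverse complement as a character string.
#' @examples
#' reverse_complement("GRCGYC")  # its own reverse complement
#' @export
reverse_complement <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop_invalid("`x` must be a single character string")
  }
  comp <- chartr("ACGTURYSWKMBDHVNacgturyswkmbdhvn",
                 "TGCAAYRSWMKVHDBNtgcaayrswmkvhdbn", x)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}
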