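# Sequence-site utilities: variant-to-region overlap, IUPAC degenerate
# restriction sites, in-silico RFLP digestion, and canonical miRNA seed
# matches.

#' Map variants to genomic regions by interval overlap
#'
#' A variant at 1-based position `pos` overlaps a 0-based half-open
#' region `[start, end)` iff `start <= pos - 1 < end`.  Overlap is
#' computed with `GenomicRanges::findOverlaps()`.
#'
#' @param variants Data frame with columns `chrom`, `pos` (1-based).
#' @param regions Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open, BED convention).
#' @return A data frame with `variant_index`, `region_index` and the
#'   coordinates of each overlapping pair.
#' @export
map_variants_to_regions <- function(variants, regions) {
  if (!is.data.frame(variants) || !all(c("chrom", "pos") %in% names(variants))) {
    stop_invalid("`variants` must have columns chrom, pos")
  }
  if (!is.data.frame(regions) ||
      !all(c("chrom", "start", "end") %in% names(regions))) {
    stop_invalid("`regions` must have columns chrom, start, end")
  }
  if (nrow(regions) && any(regions$start >= regions$end)) {
    stop_invalid("malformed region: start must be < end (0-based half-open)")
  }
  empty <- data.frame(variant_index = integer(), region_index = integer(),
                      chrom = character(), pos = integer(),
                      region_start = integer(), region_end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(variants) == 0L || nrow(regions) == 0L) return(empty)

  vr <- GenomicRanges::GRanges(variants$chrom,
                               IRanges::IRanges(variants$pos, variants$pos))
  rr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L,
                                                regions$end))
  ov <- GenomicRanges::findOverlaps(vr, rr)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  data.frame(variant_index = qi, region_index = si,
             chrom = variants$chrom[qi], pos = variants$pos[qi],
             region_start = regions$start[si], region_end = regions$end[si],
             stringsAsFactors = FALSE)
}

iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad)) {
    stop_invalid("invalid IUPAC code(s) in pattern: %s",
                 paste(unique(bad), collapse = ", "))
  }
  paste(vapply(chars, function(ch) {
    s <- IUPAC_SETS[[ch]]
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, ""), collapse = "")
}

#' Find degenerate (IUPAC) pattern sites in a sequence
#'
#' Reports every 0-based start (overlaps allowed) where each pattern
#' position's base set contains the sequence base.  Minus-strand sites
#' are occurrences of the pattern's reverse complement, reported at
#' their plus-strand start.
#'
#' @param seq Nucleotide string (A, C, G, T).
#' @param pattern IUPAC degenerate pattern, e.g. `"GRCGYC"` (BsaHI).
#' @param strands `"both"` or `"plus"`.
#' @return A data frame with `start` (0-based) and `strand`.
#' @examples
#' find_degenerate_sites("GGGTGGCGTCTCC", "GRCGYC")  # start 4
#' @export
find_degenerate_sites <- function(seq, pattern,
                                  strands = c("both", "plus")) {
  strands <- match.arg(strands)
  seq <- clean_dna(seq, "seq")
  starts_of <- function(pat) {
    rx <- paste0("(?=", iupac_regex(pat), ")")
    m <- gregexpr(rx, seq, perl = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m) - 1L
  }
  plus_starts <- starts_of(pattern)
  out <- data.frame(start = plus_starts,
                    strand = rep("+", length(plus_starts)),
                    stringsAsFactors = FALSE)
  if (strands == "both") {
    minus_starts <- starts_of(reverse_complement(pattern))
    out <- rbind(out,
                 data.frame(start = minus_starts,
                            strand = rep("-", length(minus_starts)),
                            stringsAsFactors = FALSE))
  }
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

apply_substitutions <- function(seq, subs) {
  if (is.null(subs) || length(subs) == 0L) return(seq)
  offs <- as.integer(names(subs))
  if (any(is.na(offs)) || any(offs < 0) || any(offs >= nchar(seq))) {
    stop_invalid("substitution offsets must be 0-based positions within the amplicon")
  }
  chars <- strsplit(seq, "")[[1]]
  chars[offs + 1L] <- toupper(unname(unlist(subs)))
  paste(chars, collapse = "")
}

#' In-silico RFLP digestion of an amplicon
#'
#' For each allele (a set of base substitutions applied to the
#' amplicon), locates recognition sites of a degenerate pattern and
#' reports whether the enzyme cuts and the resulting fragment lengths.
#' The classic assay logic: a variant destroying the recognition site
#' leaves the product undigested (one full-length band), while the
#' reference allele is cut; a heterozygote shows the union of both
#' alleles' bands.
#'
#' @param amplicon Nucleotide string of the PCR product.
#' @param alleles Named list of alleles; each element is `NULL` (no
#'   change) or a named character vector of substitutions with 0-based
#'   offsets as names, e.g. `list(ref = NULL, var = c("5" = "C"))`.
#' @param pattern IUPAC recognition pattern (default `"GRCGYC"`, BsaHI).
#' @param cut_offset 0-based offset of the cut within the site; default
#'   half the site length.  BsaHI cuts GR^CGYC, i.e. offset 2.
#' @return A list with `per_allele` (for each allele: `sites`, `cut`,
#'   `fragments`) and `het_bands`, the sorted union of all alleles'
#'   fragment lengths.
#' @export
predict_rflp <- function(amplicon, alleles = list(ref = NULL),
                         pattern = "GRCGYC", cut_offset = NULL) {
  amplicon <- clean_dna(amplicon, "amplicon")
  if (!is.list(alleles) || is.null(names(alleles)) ||
      any(names(alleles) == "")) {
    stop_invalid("`alleles` must be a named list of substitution vectors")
  }
  if (is.null(cut_offset)) cut_offset <- nchar(pattern) %/% 2L
  cut_offset <- check_count(cut_offset, "cut_offset")
  len <- nchar(amplicon)

  per_allele <- lapply(alleles, function(subs) {
    seq_a <- apply_substitutions(amplicon, subs)
    sites <- find_degenerate_sites(seq_a, pattern, strands = "plus")
    cuts <- sort(unique(sites$start + cut_offset))
    cuts <- cuts[cuts > 0 & cuts < len]
    fragments <- diff(c(0L, cuts, len))
    list(sites = sites, cut = length(cuts) > 0L, fragments = fragments)
  })
  het_bands <- sort(unique(unlist(lapply(per_allele, `[[`, "fragments"))))
  list(per_allele = per_allele, het_bands = het_bands)
}

#' Canonical miRNA seed matches in a 3'UTR
#'
#' Detects sites where the UTR is Watson-Crick complementary to the
#' miRNA seed (positions 2-7 of the mature miRNA, 5'->3') and classifies
#' them: `6mer` (positions 2-7), `7mer-m8` (2-8), `7mer-A1` (2-7 plus an
#' A in the UTR opposite miRNA position 1), `8mer` (2-8 plus that A).
#' U and T are treated equivalently.
#'
#' @param utr 3'UTR sequence (DNA or RNA alphabet), 5'->3'.
#' @param mirna Mature miRNA sequence, 5'->3', length >= 8.
#' @return A data frame with `site_type` and `utr_start` (0-based start
#'   of the full site, whose length matches the type).
#' @export
mirna_seed_matches <- function(utr, mirna) {
  utr <- clean_dna(utr, "utr")
  mirna <- clean_dna(mirna, "mirna")
  if (nchar(mirna) < 8L) stop_invalid("`mirna` must be at least 8 nt")
  mchars <- strsplit(mirna, "")[[1]]
  seed6 <- paste(mchars[2:7], collapse = "")
  core <- reverse_complement(seed6)           # matches UTR 5'->3'
  m8_base <- reverse_complement(mchars[8])    # UTR base pairing miRNA pos 8

  starts <- gregexpr(paste0("(?=", core, ")"), utr, perl = TRUE)[[1]]
  if (starts[1] == -1L) {
    return(data.frame(site_type = character(), utr_start = integer(),
                      stringsAsFactors = FALSE))
  }
  starts <- as.integer(starts) - 1L  # 0-based start of the 6mer core
  len <- nchar(utr)
  res <- lapply(starts, function(i) {
    has_m8 <- i >= 1L && substr(utr, i, i) == m8_base
    has_a1 <- i + 6L < len && substr(utr, i + 7L, i + 7L) == "A"
    if (has_m8 && has_a1) {
      data.frame(site_type = "8mer", utr_start = i - 1L)
    } else if (has_m8) {
      data.frame(site_type = "7mer-m8", utr_start = i - 1L)
    } else if (has_a1) {
      data.frame(site_type = "7mer-A1", utr_start = i)
    } else {
      data.frame(site_type = "6mer", utr_start = i)
    }
  })
  out <- do.call(rbind, res)
  out$site_type <- as.character(out$site_type)
  rownames(out) <- NULL
  out
}
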