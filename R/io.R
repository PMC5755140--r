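# Readers and writers for the plain-text formats the pipeline consumes:
# long-format Ct CSV, genotype/reference-count TSV, minimal VCF, BED,
# FASTA and JASPAR PFM motif files.

#' Read / write a long-format Ct table
#'
#' Columns: `sample`, `gene`, `tissue` (`tumor`/`normal`), `replicate`,
#' `ct`.
#'
#' @param path File path.
#' @param table Data frame to write.
#' @return `read_ct_table()` returns the data frame;
#'   `write_ct_table()` returns `path` invisibly.
#' @export
read_ct_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "tissue", "replicate", "ct")
  if (!all(need %in% names(tab))) {
    stop_invalid("Ct table %s lacks columns: %s", path,
                 paste(setdiff(need, names(tab)), collapse = ", "))
  }
  tab
}

#' @rdname read_ct_table
#' @export
write_ct_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write genotype-count tables
#'
#' TSV with columns `snp_id`, `population`, `hom_alt`, `het`, `hom_ref`.
#'
#' @param path File path.
#' @param counts Data frame (or a single [genotype_counts()] plus
#'   `snp_id`/`population`) to write.
#' @param snp_id,population Identifiers used when `counts` is a
#'   `genotype_counts` object.
#' @return `read_genotype_counts()` returns the data frame.
#' @export
read_genotype_counts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "population", "hom_alt", "het", "hom_ref")
  if (!all(need %in% names(tab))) {
    stop_invalid("genotype table %s lacks columns: %s", path,
                 paste(setdiff(need, names(tab)), collapse = ", "))
  }
  tab
}

#' @rdname read_genotype_counts
#' @export
write_genotype_counts <- function(counts, path, snp_id = "snp",
                                  population = "cohort") {
  if (inherits(counts, "genotype_counts")) {
    counts <- data.frame(snp_id = snp_id, population = population,
                         hom_alt = counts$hom_alt, het = counts$het,
                         hom_ref = counts$hom_ref)
  }
  utils::write.table(counts, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write variant records as a minimal VCF
#'
#' Emits a VCFv4.2 file with CHROM, POS, ID, REF, ALT, QUAL, FILTER and
#' an INFO `DP` field holding the read depth.
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `depth`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  need <- c("chrom", "pos", "ref", "alt", "depth")
  if (!is.data.frame(variants) || !all(need %in% names(variants))) {
    stop_invalid("`variants` must have columns %s", paste(need, collapse = ", "))
  }
  header <- c("##fileformat=VCFv4.2",
              "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(variants)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d", variants$chrom,
            as.integer(variants$pos), variants$ref, variants$alt,
            as.integer(variants$depth))
  } else {
    character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read variant records from a VCF
#'
#' Parses CHROM/POS/REF/ALT via `vcfR` and takes the read depth from the
#' INFO `DP` field (NA when absent).
#'
#' @param path VCF file path.
#' @param sample_role Optional role label (`"tumor"`/`"normal"`) attached
#'   to every record.
#' @return A data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `depth`, `sample_role`.
#' @export
read_variants_vcf <- function(path, sample_role = NA_character_) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single record comes back as a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      depth = integer(), sample_role = character(),
                      stringsAsFactors = FALSE))
  }
  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
             alt = fix$ALT, depth = dp,
             sample_role = rep(sample_role, nrow(fix)),
             stringsAsFactors = FALSE)
}

#' Read a BED file of regions
#'
#' First three columns are `chrom`, `start`, `end` in the BED 0-based
#' half-open convention; a fourth column, when present, is kept as
#' `name`.
#'
#' @param path BED file path.
#' @return A data frame with `chrom`, `start`, `end` (and `name`).
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 3L) stop_invalid("BED file %s needs at least 3 columns", path)
  names(tab)[1:3] <- c("chrom", "start", "end")
  if (ncol(tab) >= 4L) names(tab)[4] <- "name"
  tab[, seq_len(min(ncol(tab), 4L)), drop = FALSE]
}

#' Write a BED file of regions
#'
#' @param regions Data frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(regions))
  utils::write.table(regions[, cols, drop = FALSE], path, sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return A named character vector of sequences.
#' @export
read_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(seqs), names(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

parse_jaspar_numbers <- function(x) {
  as.numeric(strsplit(trimws(gsub("[][]", " ", x)), "[[:space:]]+")[[1]])
}

#' Read motifs from a JASPAR PFM text file
#'
#' Accepts both common dialects: four labelled rows (`A [ 4 19 0 ]` ...),
#' with or without a `>ID name` header, and the bare four-row matrix
#' following a header line.
#'
#' @param path JASPAR-format file path.
#' @param background,pseudocount Passed to [pwm_model()].
#' @return A named list of [pwm_model()] objects.
#' @export
read_jaspar <- function(path, background = c(A = 0.25, C = 0.25,
                                             G = 0.25, T = 0.25),
                        pseudocount = 0) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_invalid("empty motif file: %s", path)

  motifs <- list()
  i <- 1L
  while (i <= length(lines)) {
    name <- sprintf("motif%d", length(motifs) + 1L)
    if (startsWith(lines[i], ">")) {
      name <- trimws(sub("^>", "", lines[i]))
      i <- i + 1L
    }
    if (i + 3L > length(lines)) {
      stop_invalid("truncated motif entry in %s", path)
    }
    block <- lines[i:(i + 3L)]
    i <- i + 4L
    rows <- lapply(block, function(ln) {
      ln2 <- sub("^[ACGT][[:space:]:|]*", "", ln)
      parse_jaspar_numbers(ln2)
    })
    base_order <- if (all(grepl("^[ACGT]\\b", block))) {
      substr(block, 1, 1)
    } else {
      DNA_BASES
    }
    if (length(unique(lengths(rows))) != 1L) {
      stop_invalid("ragged motif matrix in %s", path)
    }
    mat <- do.call(rbind, rows)
    rownames(mat) <- base_order
    mat <- mat[DNA_BASES, , drop = FALSE]
    motifs[[name]] <- pwm_model(mat, background = background,
                                pseudocount = pseudocount, name = name)
  }
  motifs
}

#' Write a motif in JASPAR PFM format
#'
#' @param pwm A [pwm_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pwm, path) {
  if (!inherits(pwm, "pwm_model")) {
    stop_invalid("`pwm` must be created with pwm_model()")
  }
  rows <- vapply(DNA_BASES, function(b) {
    sprintf("%s [ %s ]", b,
            paste(format(pwm$matrix[b, ], trim = TRUE), collapse = " "))
  }, "")
  writeLines(c(paste0(">", pwm$name), rows), path)
  invisible(path)
}
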