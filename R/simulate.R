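# Synthetic-data generators.  These emulate the statistical structure of a
# paired tumor/normal candidate-gene study: correlated tumor downregulation
# of target genes on the qPCR cycle (Ct) scale, Hardy-Weinberg genotype
# draws for cohort and reference populations, paired tumor/normal variant
# tables with optional spiked somatic variants, and sequences with a
# planted transcription-factor motif overlapped by a SNP.
#
# All generators are pure functions of (spec, seed): the seed is a required
# argument and the global RNG state is left untouched.

#' Specification for a paired tumor/normal Ct simulation
#'
#' Describes the generative model for replicate qPCR quantification-cycle
#' (Ct) measurements in a paired tumor/normal design.  For pair `i` and
#' gene `g`, normal-tissue Ct is `baseline_g + noise` and tumor Ct is
#' `baseline_g + delta_g + loading_g * Z_i + noise`, where `Z_i ~
#' N(0, shared_sd)` is a per-sample latent factor shared by all genes.
#' Genes with positive loadings therefore show correlated tumor shifts,
#' the structure behind coordinated downregulation of co-regulated genes.
#' The housekeeping gene always has `delta = 0` and `loading = 0`.
#'
#' @param n_pairs Number of tumor/normal sample pairs (>= 0).
#' @param genes Data frame with columns `gene`, `delta` (tumor Ct shift in
#'   cycles; positive = downregulated) and `loading` (coefficient on the
#'   shared latent factor).
#' @param shared_sd Standard deviation (cycles) of the per-sample latent
#'   factor.
#' @param noise_sd Replicate measurement noise SD (cycles).
#' @param hk_gene Housekeeping (reference) gene name; forced to zero
#'   effect parameters.
#' @param baseline_ct Named numeric vector of mean normal-tissue Ct per
#'   gene; genes absent from the vector default to 24 cycles (target
#'   genes) and 20 cycles (housekeeping gene).
#' @param n_replicates Technical qPCR replicates per (sample, gene,
#'   tissue); default 3.
#' @param seed Integer RNG seed (required).
#' @return An object of class `expression_sim_spec`.
#' @seealso [simulate_paired_ct()]
#' @export
expression_sim_spec <- function(n_pairs, genes, shared_sd = 1,
                                noise_sd = 0.5, hk_gene = "HPRT1",
                                baseline_ct = NULL, n_replicates = 3,
                                seed) {
  n_pairs <- check_count(n_pairs, "n_pairs")
  if (!is.data.frame(genes) ||
      !all(c("gene", "delta", "loading") %in% names(genes))) {
    stop_invalid("`genes` must be a data frame with columns gene, delta, loading")
  }
  check_scalar_number(shared_sd, "shared_sd", min = 0)
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  n_replicates <- check_count(n_replicates, "n_replicates", min = 1)
  seed <- check_seed(seed)

  genes <- genes[, c("gene", "delta", "loading")]
  genes$gene <- as.character(genes$gene)
  if (anyDuplicated(genes$gene)) stop_invalid("duplicated gene names")
  if (hk_gene %in% genes$gene) {
    hk <- genes$gene == hk_gene
    if (any(genes$delta[hk] != 0) || any(genes$loading[hk] != 0)) {
      stop_invalid("housekeeping gene `%s` must have zero delta and loading",
                   hk_gene)
    }
  } else {
    genes <- rbind(genes,
                   data.frame(gene = hk_gene, delta = 0, loading = 0))
  }

  base <- ifelse(genes$gene == hk_gene, 20, 24)
  names(base) <- genes$gene
  if (!is.null(baseline_ct)) {
    if (is.null(names(baseline_ct))) {
      stop_invalid("`baseline_ct` must be a named numeric vector")
    }
    keep <- intersect(names(baseline_ct), genes$gene)
    base[keep] <- baseline_ct[keep]
  }
  if (any(!is.finite(base)) || any(base <= 0)) {
    stop_invalid("baseline Ct values must be finite and positive")
  }

  structure(list(n_pairs = n_pairs, genes = genes, shared_sd = shared_sd,
                 noise_sd = noise_sd, hk_gene = hk_gene,
                 baseline_ct = base, n_replicates = n_replicates,
                 seed = seed),
            class = "expression_sim_spec")
}

#' Simulate a paired tumor/normal Ct table
#'
#' Draws replicate Ct measurements from the generative model described in
#' [expression_sim_spec()].  Deterministic given the spec's seed.
#'
#' @param spec An [expression_sim_spec()].
#' @return A long-format data frame with columns `sample`, `gene`,
#'   `tissue` (`"tumor"` or `"normal"`), `replicate` and `ct`.
#' @examples
#' spec <- expression_sim_spec(
#'   n_pairs = 4,
#'   genes = data.frame(gene = c("GRHL1", "GRHL3"), delta = c(1.5, 1.5),
#'                      loading = c(1, 1)),
#'   seed = 7
#' )
#' head(simulate_paired_ct(spec))
#' @export
simulate_paired_ct <- function(spec) {
  if (!inherits(spec, "expression_sim_spec")) {
    stop_invalid("`spec` must be created with expression_sim_spec()")
  }
  empty <- data.frame(sample = character(), gene = character(),
                      tissue = character(), replicate = integer(),
                      ct = numeric(), stringsAsFactors = FALSE)
  if (spec$n_pairs == 0L || nrow(spec$genes) == 0L) return(empty)

  samples <- sprintf("S%03d", seq_len(spec$n_pairs))
  grid <- expand.grid(replicate = seq_len(spec$n_replicates),
                      tissue = c("normal", "tumor"),
                      gene = spec$genes$gene,
                      sample = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("sample", "gene", "tissue", "replicate")]

  idx <- match(grid$gene, spec$genes$gene)
  pair <- match(grid$sample, samples)
  tumor <- grid$tissue == "tumor"

  with_rng(spec$seed, {
    z <- stats::rnorm(spec$n_pairs, 0, spec$shared_sd)
    eps <- stats::rnorm(nrow(grid), 0, spec$noise_sd)
    grid$ct <- spec$baseline_ct[idx] +
      ifelse(tumor, spec$genes$delta[idx] +
               spec$genes$loading[idx] * z[pair], 0) + eps
  })
  rownames(grid) <- NULL
  grid
}

#' Specification for Hardy-Weinberg genotype simulation
#'
#' @param n_individuals Cohort size (>= 0).
#' @param maf Minor (alternate) allele frequency in \[0, 1\].
#' @param seed Integer RNG seed (required).
#' @return An object of class `genotype_sim_spec`.
#' @seealso [simulate_genotypes()]
#' @export
genotype_sim_spec <- function(n_individuals, maf, seed) {
  n_individuals <- check_count(n_individuals, "n_individuals")
  check_scalar_number(maf, "maf", min = 0, max = 1)
  seed <- check_seed(seed)
  structure(list(n_individuals = n_individuals, maf = maf, seed = seed),
            class = "genotype_sim_spec")
}

#' Simulate cohort genotype counts under Hardy-Weinberg equilibrium
#'
#' Each individual's genotype is drawn with probabilities
#' `((1-maf)^2, 2*maf*(1-maf), maf^2)` for (hom-ref, het, hom-alt).
#'
#' @param spec A [genotype_sim_spec()].
#' @return A [genotype_counts()] object; counts sum to `n_individuals`.
#' @examples
#' simulate_genotypes(genotype_sim_spec(209, maf = 0.008, seed = 1))
#' @export
simulate_genotypes <- function(spec) {
  if (!inherits(spec, "genotype_sim_spec")) {
    stop_invalid("`spec` must be created with genotype_sim_spec()")
  }
  p <- spec$maf
  probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  counts <- with_rng(spec$seed, {
    if (spec$n_individuals == 0L) c(0L, 0L, 0L) else {
      g <- sample.int(3L, spec$n_individuals, replace = TRUE, prob = probs)
      tabulate(g, nbins = 3L)
    }
  })
  genotype_counts(hom_alt = counts[3], het = counts[2], hom_ref = counts[1])
}

#' Simulate a matched tumor/normal variant-table pair
#'
#' Produces a normal-tissue variant list and a tumor list containing the
#' same shared (germline) variants plus `n_somatic` spiked tumor-only
#' variants at loci guaranteed distinct from the shared set, giving an
#' unambiguous truth set for the de novo (somatic) screen.
#'
#' @param n_shared Number of variants shared by tumor and normal (>= 0).
#' @param n_somatic Number of tumor-only spiked variants (>= 0).
#' @param depth_range Length-2 integer vector `(min, max)` of read depths.
#' @param seed Integer RNG seed (required).
#' @param chrom Chromosome name for all simulated loci.
#' @return A list with data frames `tumor` and `normal`, each with columns
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `depth`, `sample_role`.
#' @examples
#' vp <- simulate_variant_pair(5, 3, depth_range = c(20, 60), seed = 42)
#' somatic_candidates(vp$tumor, vp$normal)
#' @export
simulate_variant_pair <- function(n_shared, n_somatic,
                                  depth_range = c(20, 60), seed,
                                  chrom = "chr1") {
  n_shared <- check_count(n_shared, "n_shared")
  n_somatic <- check_count(n_somatic, "n_somatic")
  if (length(depth_range) != 2L || !is.numeric(depth_range)) {
    stop_invalid("`depth_range` must be a length-2 numeric vector")
  }
  if (depth_range[1] > depth_range[2]) {
    stop_invalid("depth_range min (%s) exceeds max (%s)",
                 depth_range[1], depth_range[2])
  }
  check_count(depth_range[1], "depth_range[1]")
  check_count(depth_range[2], "depth_range[2]")
  seed <- check_seed(seed)

  n <- n_shared + n_somatic
  make_records <- function(pos, ref, alt, depth, role) {
    data.frame(chrom = rep(chrom, length(pos)), pos = pos, ref = ref,
               alt = alt, depth = depth, sample_role = rep(role, length(pos)),
               stringsAsFactors = FALSE)
  }
  if (n == 0L) {
    empty <- make_records(integer(), character(), character(), integer(),
                          character())
    return(list(tumor = empty, normal = empty))
  }

  with_rng(seed, {
    pos <- sort(sample.int(max(1000L, 10L * n), n))
    ref <- sample(DNA_BASES, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    rdepth <- function(k) {
      sample(seq.int(depth_range[1], depth_range[2]), k, replace = TRUE)
    }
    shared <- seq_len(n_shared)
    normal <- make_records(pos[shared], ref[shared], alt[shared],
                           rdepth(n_shared), "normal")
    tumor <- make_records(pos, ref, alt, rdepth(n), "tumor")
    list(tumor = tumor, normal = normal)
  })
}

#' Generate a sequence with a planted motif consensus and overlapping SNP
#'
#' Builds `random flank + PWM consensus + random flank` and a SNP inside
#' the planted motif, for exercising motif scanning and SNP impact
#' scoring on a sequence whose best-scoring window is known by
#' construction (the consensus maximises every column).
#'
#' @param pwm A [pwm_model()].
#' @param flank_len Length of each random flank (>= 0).
#' @param snp_offset 0-based offset of the SNP within the motif.
#' @param alt_base Alternate base; must differ from the consensus base at
#'   `snp_offset`.
#' @param seed Integer RNG seed (required).
#' @return A list with `sequence`, `planted_start` (0-based start of the
#'   motif) and `snp` (list with 0-based `pos`, `ref`, `alt`).
#' @export
generate_motif_sequence <- function(pwm, flank_len, snp_offset, alt_base,
                                    seed) {
  if (!inherits(pwm, "pwm_model")) {
    stop_invalid("`pwm` must be created with pwm_model()")
  }
  flank_len <- check_count(flank_len, "flank_len")
  m <- ncol(pwm$matrix)
  snp_offset <- check_count(snp_offset, "snp_offset")
  if (snp_offset >= m) {
    stop_invalid("snp_offset (%d) must be < motif length (%d)", snp_offset, m)
  }
  seed <- check_seed(seed)
  consensus <- DNA_BASES[apply(pwm$matrix, 2, which.max)]
  ref_base <- consensus[snp_offset + 1L]
  alt_base <- toupper(alt_base)
  if (!alt_base %in% DNA_BASES) stop_invalid("`alt_base` must be A, C, G or T")
  if (alt_base == ref_base) {
    stop_invalid("alt_base equals the planted reference base (%s) at offset %d",
                 ref_base, snp_offset)
  }
  seq <- with_rng(seed, {
    left <- paste(sample(DNA_BASES, flank_len, replace = TRUE), collapse = "")
    right <- paste(sample(DNA_BASES, flank_len, replace = TRUE), collapse = "")
    paste0(left, paste(consensus, collapse = ""), right)
  })
  list(sequence = seq, planted_start = flank_len,
       snp = list(pos = flank_len + snp_offset, ref = ref_base,
                  alt = alt_base))
}
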