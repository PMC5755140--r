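# Pipeline orchestration: a single validated configuration drives the
# expression, association and regulatory-impact stages, with optional
# synthetic-fixture generation, per-stage TSV/JSON outputs and a combined
# machine-readable summary.

stage_names <- c("expression", "association", "regulatory")

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop_invalid("unknown %s key(s): %s", where,
                 paste(unknown, collapse = ", "))
  }
}

#' Build and validate a pipeline configuration
#'
#' @param stages Character vector of stages to run, a subset of
#'   `"expression"`, `"association"`, `"regulatory"` (default: none).
#' @param expression Stage options: `ct_csv` (path), `target_genes`,
#'   `ref_gene` (default `"HPRT1"`), `comparison`, `method`.
#' @param association Stage options: `cohort_tsv`, `reference_tsv`
#'   (paths), `conf_level` (default 0.95), `method` (default `"auto"`),
#'   `assume_no_hom_alt`, `bonferroni` (logical; family size = number of
#'   (snp, reference) comparisons in the run).
#' @param regulatory Stage options: `fasta`, `vcf`, `pfm` (paths), `bed`
#'   (optional path), `pseudocount` (default 0), `threshold` (optional),
#'   `min_depth` (default 20).
#' @param seed Integer seed used by synthetic-fixture generation.
#' @param out_dir Output directory.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = character(0), expression = list(),
                            association = list(), regulatory = list(),
                            seed = 1, out_dir = tempfile("candgene_run_")) {
  if (!all(stages %in% stage_names)) {
    stop_invalid("unknown stage(s): %s",
                 paste(setdiff(stages, stage_names), collapse = ", "))
  }
  check_keys(expression, c("ct_csv", "target_genes", "ref_gene",
                           "comparison", "method"), "expression")
  check_keys(association, c("cohort_tsv", "reference_tsv", "conf_level",
                            "method", "assume_no_hom_alt", "bonferroni"),
             "association")
  check_keys(regulatory, c("fasta", "vcf", "pfm", "bed", "pseudocount",
                           "threshold", "min_depth"), "regulatory")
  seed <- check_seed(seed)
  structure(list(stages = stages, expression = expression,
                 association = association, regulatory = regulatory,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

require_input <- function(path, what, stage) {
  if (is.null(path)) {
    stop_invalid("config error: stage '%s' enabled but %s not set", stage,
                 what)
  }
  if (!file.exists(path)) {
    stop_invalid("config error: stage '%s' input %s not found: %s", stage,
                 what, path)
  }
  path
}

# Replace non-finite numbers by JSON-safe string markers ("-inf", "inf",
# "nan") so that -Inf motif deltas survive serialization.
json_sanitize <- function(x) {
  if (is.list(x)) return(lapply(x, json_sanitize))
  if (is.data.frame(x)) return(as.data.frame(lapply(x, json_sanitize)))
  if (is.numeric(x) && any(!is.finite(x) & !is.na(x))) {
    y <- as.list(x)
    y[!is.na(x) & x == -Inf] <- "-inf"
    y[!is.na(x) & x == Inf] <- "inf"
    y[is.nan(x)] <- "nan"
    return(if (length(y) == 1L) y[[1]] else y)
  }
  x
}

write_stage_json <- function(x, path) {
  jsonlite::write_json(json_sanitize(x), path, auto_unbox = TRUE,
                       digits = 10, na = "null", pretty = TRUE)
  invisible(path)
}

write_tsv <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(col) {
    ifelse(is.finite(col) | is.na(col), format(col, digits = 10,
                                               trim = TRUE),
           ifelse(col == -Inf, "-inf", ifelse(col == Inf, "inf", "nan")))
  })
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_reference_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_id", "population", "kind")
  if (!all(need %in% names(tab))) {
    stop_invalid("reference table %s lacks columns: %s", path,
                 paste(setdiff(need, names(tab)), collapse = ", "))
  }
  tab
}

reference_from_row <- function(row) {
  switch(row$kind,
         genotype = genotype_counts(row$hom_alt, row$het, row$hom_ref),
         allele = allele_counts(row$alt, row$ref),
         frequency = c(frequency = row$frequency,
                       n_alleles = row$n_alleles),
         stop_invalid("unknown reference kind '%s' (use genotype, allele or frequency)",
                      row$kind))
}

run_expression_stage <- function(cfg, out_dir) {
  opts <- cfg$expression
  path <- require_input(opts$ct_csv, "ct_csv", "expression")
  tab <- read_ct_table(path)
  target_genes <- opts$target_genes %||%
    setdiff(unique(tab$gene), opts$ref_gene %||% "HPRT1")
  res <- run_expression_analysis(tab, target_genes = target_genes,
                                 ref_gene = opts$ref_gene %||% "HPRT1",
                                 comparison = opts$comparison %||% "groups",
                                 method = opts$method %||% "mann_whitney")
  write_tsv(res$per_pair, file.path(out_dir, "expression_per_pair.tsv"))
  summary <- list(per_gene = res$per_gene, correlations = res$correlations)
  write_stage_json(summary, file.path(out_dir, "expression_summary.json"))
  summary
}

run_association_stage <- function(cfg, out_dir) {
  opts <- cfg$association
  cohort_tab <- read_genotype_counts(
    require_input(opts$cohort_tsv, "cohort_tsv", "association"))
  ref_tab <- read_reference_table(
    require_input(opts$reference_tsv, "reference_tsv", "association"))

  rows <- list()
  for (i in seq_len(nrow(ref_tab))) {
    rr <- ref_tab[i, ]
    ci <- cohort_tab[cohort_tab$snp_id == rr$snp_id, ]
    if (nrow(ci) == 0L) next
    cohort <- genotype_counts(ci$hom_alt[1], ci$het[1], ci$hom_ref[1])
    no_hom_alt <- isTRUE(opts$assume_no_hom_alt) ||
      isTRUE(rr$assume_no_hom_alt)
    res <- single_marker_association(
      cohort, reference_from_row(rr), snp_id = rr$snp_id,
      conf_level = opts$conf_level %||% 0.95,
      method = opts$method %||% "auto",
      assume_no_hom_alt = no_hom_alt,
      genotypic = rr$kind == "genotype" || no_hom_alt)
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = res$snp_id, population = rr$population,
      af_obs = res$af_obs, af_ref = res$af_ref,
      allelic_or = res$allelic$odds_ratio,
      allelic_ci_low = res$allelic$ci_low,
      allelic_ci_high = res$allelic$ci_high,
      allelic_p = res$allelic$p_value,
      genotypic_or = res$genotypic$odds_ratio %||% NA_real_,
      genotypic_ci_low = res$genotypic$ci_low %||% NA_real_,
      genotypic_ci_high = res$genotypic$ci_high %||% NA_real_,
      genotypic_p = res$genotypic$p_value %||% NA_real_,
      test_method = res$test_method,
      p_association = res$p_association,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    stop_invalid("association stage: no snp_id shared between cohort and reference tables")
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- if (isTRUE(opts$bonferroni %||% TRUE)) {
    bonferroni_adjust(out$p_association)
  } else {
    out$p_association
  }
  write_tsv(out, file.path(out_dir, "association_results.tsv"))
  write_stage_json(out, file.path(out_dir, "association_results.json"))
  out
}

run_regulatory_stage <- function(cfg, out_dir) {
  opts <- cfg$regulatory
  seqs <- read_fasta(require_input(opts$fasta, "fasta", "regulatory"))
  variants <- read_variants_vcf(require_input(opts$vcf, "vcf", "regulatory"))
  motifs <- read_jaspar(require_input(opts$pfm, "pfm", "regulatory"),
                        pseudocount = opts$pseudocount %||% 0)
  min_depth <- opts$min_depth %||% 20
  variants <- filter_by_depth(
    transform(variants, depth = ifelse(is.na(depth), min_depth, depth)),
    min_depth = min_depth)

  region_map <- NULL
  if (!is.null(opts$bed)) {
    regions <- read_bed(require_input(opts$bed, "bed", "regulatory"))
    region_map <- map_variants_to_regions(variants, regions)
    variants <- variants[unique(region_map$variant_index), , drop = FALSE]
  }

  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (!v$chrom %in% names(seqs)) next
    for (pwm in motifs) {
      lo <- pfm_to_log_odds(pwm)
      hits <- snp_motif_delta(lo, seqs[[v$chrom]],
                              snp = list(pos = v$pos - 1L, ref = v$ref,
                                         alt = v$alt),
                              threshold = opts$threshold)
      if (nrow(hits)) {
        hits <- cbind(snp = sprintf("%s:%d:%s>%s", v$chrom, v$pos, v$ref,
                                    v$alt),
                      hits, stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- hits
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp = character(), motif = character(), start = integer(),
               strand = character(), ref_score = numeric(),
               alt_score = numeric(), delta = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  write_tsv(out, file.path(out_dir, "motif_impact.tsv"))
  write_stage_json(list(n_variants = nrow(variants),
                        n_hits = nrow(out), hits = out,
                        regions = region_map),
                   file.path(out_dir, "motif_impact.json"))
  out
}

# Default demonstration PWM used by the synthetic pipeline mode: a sharp
# 8-position motif with one fully degenerate flank-like column.
default_demo_pwm <- function() {
  counts <- matrix(c(
    12,  0,  0,  0,  4,  0, 12,  3,
     0, 12,  0,  0,  4,  0,  0,  3,
     0,  0, 12,  0,  2, 12,  0,  3,
     0,  0,  0, 12,  2,  0,  0,  3), nrow = 4, byrow = TRUE)
  pwm_model(counts, name = "DEMO_MOTIF")
}

generate_synthetic_inputs <- function(cfg) {
  in_dir <- file.path(cfg$out_dir, "inputs")
  dir.create(in_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed

  # expression: 27 pairs, two co-downregulated genes sharing a latent
  # factor and one unaffected gene
  spec <- expression_sim_spec(
    n_pairs = 27,
    genes = data.frame(gene = c("GRHL1", "GRHL2", "GRHL3"),
                       delta = c(1.5, 0, 1.5), loading = c(1, 0, 1)),
    seed = seed)
  ct_csv <- file.path(in_dir, "ct_long.csv")
  write_ct_table(simulate_paired_ct(spec), ct_csv)

  # association: cohort of 209 and a large reference drawn at the same
  # allele frequency
  cohort <- simulate_genotypes(genotype_sim_spec(209, maf = 0.05,
                                                 seed = seed + 1L))
  reference <- simulate_genotypes(genotype_sim_spec(10000, maf = 0.05,
                                                    seed = seed + 2L))
  cohort_tsv <- file.path(in_dir, "cohort_counts.tsv")
  write_genotype_counts(cohort, cohort_tsv, snp_id = "sim_snp",
                        population = "cohort")
  reference_tsv <- file.path(in_dir, "reference_counts.tsv")
  write_tsv(data.frame(snp_id = "sim_snp", population = "simulated_ref",
                       kind = "genotype", hom_alt = reference$hom_alt,
                       het = reference$het, hom_ref = reference$hom_ref),
            reference_tsv)

  # regulatory: planted motif with an overlapping SNP
  pwm <- default_demo_pwm()
  planted <- generate_motif_sequence(pwm, flank_len = 30, snp_offset = 2,
                                     alt_base = "A", seed = seed + 3L)
  fasta <- file.path(in_dir, "region.fa")
  write_fasta(c(seq1 = planted$sequence), fasta)
  vcf <- file.path(in_dir, "snps.vcf")
  write_vcf(data.frame(chrom = "seq1", pos = planted$snp$pos + 1L,
                       ref = planted$snp$ref, alt = planted$snp$alt,
                       depth = 50), vcf)
  pfm <- file.path(in_dir, "motifs.jaspar")
  write_jaspar(pwm, pfm)
  bed <- file.path(in_dir, "regions.bed")
  write_bed(data.frame(chrom = "seq1", start = 0,
                       end = nchar(planted$sequence), name = "demo_region"),
            bed)

  list(expression = list(ct_csv = ct_csv,
                         target_genes = c("GRHL1", "GRHL2", "GRHL3")),
       association = list(cohort_tsv = cohort_tsv,
                          reference_tsv = reference_tsv),
       regulatory = list(fasta = fasta, vcf = vcf, pfm = pfm, bed = bed))
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages (expression, association, regulatory
#' impact) from a validated configuration, writing per-stage TSV/JSON
#' files and a combined `summary.json` to the output directory.  With
#' `synthetic = TRUE`, fixture inputs are first generated with the
#' synthetic-data module (deterministically from the config seed) and
#' wired into the enabled stages.
#'
#' Stage failures do not abort the run: partial outputs are retained and
#' the failure is recorded in the summary, whose `ok` field is `FALSE`.
#'
#' @param config A [pipeline_config()], a list of its arguments, or the
#'   path to a YAML file holding them.
#' @param synthetic Generate synthetic inputs before running.
#' @return The summary list, invisibly: `seed`, `stages` (per-stage
#'   `status` and `result`), `ok`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(stages = "association", seed = 1)
#' run_pipeline(cfg, synthetic = TRUE)
#' }
#' @export
run_pipeline <- function(config, synthetic = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (isTRUE(synthetic)) {
    gen <- generate_synthetic_inputs(config)
    for (s in stage_names) {
      config[[s]] <- utils::modifyList(gen[[s]], config[[s]])
    }
  }

  # all enabled stages must have their inputs before anything runs
  required_inputs <- list(
    expression = "ct_csv",
    association = c("cohort_tsv", "reference_tsv"),
    regulatory = c("fasta", "vcf", "pfm"))
  for (s in config$stages) {
    for (key in required_inputs[[s]]) {
      require_input(config[[s]][[key]], key, s)
    }
  }

  runners <- list(expression = run_expression_stage,
                  association = run_association_stage,
                  regulatory = run_regulatory_stage)
  stages <- list()
  for (s in config$stages) {
    stages[[s]] <- tryCatch(
      list(status = "ok", result = runners[[s]](config, config$out_dir)),
      error = function(e) list(status = "failed",
                               error = conditionMessage(e)))
  }
  summary <- list(seed = config$seed, stages = stages,
                  ok = all(vapply(stages, function(x) x$status == "ok",
                                  TRUE)))
  write_stage_json(summary, file.path(config$out_dir, "summary.json"))
  invisible(summary)
}
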