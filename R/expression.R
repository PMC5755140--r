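# Relative expression (2^-ddCt) analysis for paired tumor/normal qPCR
# designs: per-pair fold changes, Mann-Whitney group comparisons, Spearman
# inter-gene correlation, and dual-luciferase reporter normalization.

#' Livak relative expression (2^-ddCt)
#'
#' Computes the double-difference normalisation of quantification cycles:
#' `ddCt = (Ct_target,case - Ct_ref,case) - (Ct_target,control -
#' Ct_ref,control)` and the fold change `2^-ddCt`.  Vectorised over its
#' arguments.
#'
#' @param ct_target_case,ct_ref_case Target- and reference-gene Ct in the
#'   case (e.g. tumor) sample.
#' @param ct_target_control,ct_ref_control The same in the matched
#'   control (e.g. normal) sample.
#' @return A data frame with `dct_case`, `dct_control`, `ddct` and
#'   `value` (`2^-ddct`).
#' @examples
#' relative_expression(25, 20, 24, 21)$value  # 0.25
#' @export
relative_expression <- function(ct_target_case, ct_ref_case,
                                ct_target_control, ct_ref_control) {
  args <- list(ct_target_case, ct_ref_case, ct_target_control,
               ct_ref_control)
  if (!all(vapply(args, is.numeric, TRUE)) ||
      !all(vapply(args, function(x) all(is.finite(x)), TRUE))) {
    stop_invalid("all Ct values must be finite numbers")
  }
  dct_case <- ct_target_case - ct_ref_case
  dct_control <- ct_target_control - ct_ref_control
  ddct <- dct_case - dct_control
  data.frame(dct_case = dct_case, dct_control = dct_control, ddct = ddct,
             value = 2^(-ddct))
}

# Two-sided Mann-Whitney p-value.  Exact for combined n <= 20 (Wilcoxon
# distribution when tie-free, full enumeration of group assignments with
# midranks otherwise); normal approximation with tie and continuity
# correction for larger samples.  The two-sided p is 2 * min(P(U <= u),
# P(U >= u)) capped at 1, the convention the exact branch and the normal
# branch share.
mann_whitney_p <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0L

  if (n <= 20L) {
    if (!has_ties) {
      p <- 2 * min(stats::pwilcox(u, na, nb),
                   1 - stats::pwilcox(u - 1, na, nb))
      return(min(1, p))
    }
    comb <- utils::combn(n, na)
    us <- colSums(matrix(r[comb], nrow = na)) - na * (na + 1) / 2
    eps <- 1e-9
    p <- 2 * min(mean(us <= u + eps), mean(us >= u - eps))
    return(min(1, p))
  }

  mu <- na * nb / 2
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Compare two groups of relative expressions
#'
#' Two-sided Mann-Whitney U test (default) or Student t-test.  The
#' Mann-Whitney p is exact for combined n <= 20 and uses the normal
#' approximation with tie and continuity correction otherwise.
#'
#' @param values_a,values_b Numeric vectors (each non-empty; the t-test
#'   requires at least 2 values per group).
#' @param method `"mann_whitney"` or `"t_test"`.
#' @return A list with `p_value` (two-sided) and `method`.
#' @examples
#' compare_groups(1:5, 6:10)$p_value  # 2/252
#' @export
compare_groups <- function(values_a, values_b,
                           method = c("mann_whitney", "t_test")) {
  method <- match.arg(method)
  for (v in list(values_a, values_b)) {
    if (!is.numeric(v) || length(v) == 0L || !all(is.finite(v))) {
      stop_invalid("both groups must be non-empty finite numeric vectors")
    }
  }
  p <- if (method == "t_test") {
    if (length(values_a) < 2L || length(values_b) < 2L) {
      stop_invalid("t_test requires at least 2 values per group")
    }
    stats::t.test(values_a, values_b, var.equal = TRUE)$p.value
  } else {
    mann_whitney_p(values_a, values_b)
  }
  list(p_value = p, method = method)
}

#' Spearman correlation between two genes' expression values
#'
#' Rank (Spearman) correlation with average ranks for ties, its square,
#' and a two-sided p-value.  Reporting both `rho` and `rho^2` covers the
#' common ambiguity of figure legends that label Spearman's coefficient
#' "R^2".
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list with `rho`, `r_squared` (`rho^2`) and `p_value`.
#' @examples
#' correlate_genes(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho  # 0.6
#' @export
correlate_genes <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y) ||
      length(x) < 3L || !all(is.finite(c(x, y)))) {
    stop_invalid("`x` and `y` must be finite numeric vectors of equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_invalid("correlation undefined for a constant vector")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  rho <- unname(ct$estimate)
  list(rho = rho, r_squared = rho^2, p_value = ct$p.value)
}

#' Dual-luciferase reporter activity
#'
#' Per-replicate firefly/Renilla ratios, normalised to the mean control
#' ratio, with a two-tailed Student t-test of test ratios against control
#' ratios.
#'
#' @param firefly,renilla Numeric vectors of equal length >= 1; Renilla
#'   values must be positive.
#' @param control_ratios Firefly/Renilla ratios of the control
#'   transfection.
#' @return A list with `relative_activity`, `sd` (of the normalised test
#'   ratios), `p_value` (NA unless both groups have >= 2 replicates) and
#'   `n_replicates`.
#' @export
reporter_activity <- function(firefly, renilla, control_ratios) {
  if (!is.numeric(firefly) || !is.numeric(renilla) ||
      length(firefly) != length(renilla) || length(firefly) < 1L) {
    stop_invalid("`firefly` and `renilla` must be numeric vectors of equal length >= 1")
  }
  if (any(!is.finite(renilla)) || any(renilla <= 0)) {
    stop_invalid("Renilla values must be positive (normalisation denominator)")
  }
  if (!is.numeric(control_ratios) || length(control_ratios) < 1L ||
      !all(is.finite(control_ratios))) {
    stop_invalid("`control_ratios` must be a non-empty finite numeric vector")
  }
  ratios <- firefly / renilla
  ctrl_mean <- mean(control_ratios)
  if (ctrl_mean <= 0) stop_invalid("mean control ratio must be positive")
  p <- if (length(ratios) >= 2L && length(control_ratios) >= 2L) {
    # essentially-constant data (e.g. all ratios identical) carries no
    # usable variance for a t statistic
    tryCatch(stats::t.test(ratios, control_ratios,
                           var.equal = TRUE)$p.value,
             error = function(e) NA_real_)
  } else {
    NA_real_
  }
  list(relative_activity = mean(ratios) / ctrl_mean,
       sd = stats::sd(ratios / ctrl_mean),
       p_value = p,
       n_replicates = length(ratios))
}

#' Run the full paired-expression analysis
#'
#' From a long-format table of replicate Ct values: averages replicates on
#' the cycle scale per (sample, gene, tissue), computes per-sample
#' `dCt = Ct_gene - Ct_ref`, per-pair `2^-ddCt` (tumor vs the matched
#' normal), a per-gene Mann-Whitney comparison, and Spearman correlations
#' between all target-gene pairs over the per-pair tumor fold changes.
#'
#' Two readings of the group comparison are provided:
#' * `comparison = "groups"` (default): tumor and normal relative
#'   expressions, each computed against the cohort mean normal dCt, are
#'   compared (equivalent in rank terms to an unpaired comparison of
#'   tumor vs normal dCt values).
#' * `comparison = "paired_vs_unit"`: per-pair `2^-ddCt` values are
#'   compared against a same-sized group of 1s (each normal relative to
#'   itself).
#'
#' Samples missing either tissue for a gene or the reference gene are
#' dropped from that gene's analysis with a warning.
#'
#' @param table Data frame with columns `sample`, `gene`, `tissue`
#'   (`"tumor"`/`"normal"`), `replicate`, `ct`.
#' @param target_genes Character vector of target gene names.
#' @param ref_gene Housekeeping gene used for normalisation (default
#'   `"HPRT1"`).
#' @param comparison `"groups"` or `"paired_vs_unit"` (see Details).
#' @param method Test passed to [compare_groups()].
#' @return A list with `per_pair` (sample, gene, dct_tumor, dct_normal,
#'   ddct, rel_expr), `per_gene` (gene, n_pairs, median_rel_expr,
#'   p_value) and `correlations` (gene_a, gene_b, rho, r_squared,
#'   p_value).
#' @export
run_expression_analysis <- function(table, target_genes,
                                    ref_gene = "HPRT1",
                                    comparison = c("groups",
                                                   "paired_vs_unit"),
                                    method = "mann_whitney") {
  comparison <- match.arg(comparison)
  need <- c("sample", "gene", "tissue", "replicate", "ct")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    stop_invalid("`table` must have columns %s", paste(need, collapse = ", "))
  }
  if (!all(table$tissue %in% c("tumor", "normal"))) {
    stop_invalid("`tissue` must be 'tumor' or 'normal'")
  }
  if (!all(is.finite(table$ct)) || any(table$ct <= 0)) {
    stop_invalid("Ct values must be finite and positive")
  }
  genes_needed <- unique(c(target_genes, ref_gene))
  missing_genes <- setdiff(genes_needed, table$gene)
  if (length(missing_genes)) {
    stop_invalid("genes absent from the table: %s",
                 paste(missing_genes, collapse = ", "))
  }

  # replicate means on the Ct scale
  agg <- stats::aggregate(ct ~ sample + gene + tissue,
                          data = table[table$gene %in% genes_needed, ],
                          FUN = mean)

  ref <- agg[agg$gene == ref_gene, c("sample", "tissue", "ct")]
  names(ref)[3] <- "ct_ref"
  dat <- merge(agg[agg$gene %in% target_genes, ], ref,
               by = c("sample", "tissue"))
  dat$dct <- dat$ct - dat$ct_ref

  per_pair_list <- list()
  per_gene_list <- list()
  for (g in target_genes) {
    dg <- dat[dat$gene == g, ]
    tum <- dg[dg$tissue == "tumor", c("sample", "dct")]
    nor <- dg[dg$tissue == "normal", c("sample", "dct")]
    names(tum)[2] <- "dct_tumor"; names(nor)[2] <- "dct_normal"
    pairs <- merge(tum, nor, by = "sample")
    dropped <- setdiff(unique(dg$sample), pairs$sample)
    if (length(dropped)) {
      warning(sprintf("gene %s: dropping samples without a complete pair: %s",
                      g, paste(dropped, collapse = ", ")), call. = FALSE)
    }
    if (nrow(pairs) == 0L) {
      stop_invalid("gene %s: no complete tumor/normal pairs", g)
    }
    pairs$ddct <- pairs$dct_tumor - pairs$dct_normal
    pairs$rel_expr <- 2^(-pairs$ddct)
    pairs <- cbind(gene = g, pairs, stringsAsFactors = FALSE)

    if (comparison == "groups") {
      baseline <- mean(pairs$dct_normal)
      rel_tumor <- 2^(-(pairs$dct_tumor - baseline))
      rel_normal <- 2^(-(pairs$dct_normal - baseline))
      p <- compare_groups(rel_tumor, rel_normal, method = method)$p_value
    } else {
      p <- compare_groups(pairs$rel_expr, rep(1, nrow(pairs)),
                          method = method)$p_value
    }
    per_pair_list[[g]] <- pairs
    per_gene_list[[g]] <- data.frame(gene = g, n_pairs = nrow(pairs),
                                     median_rel_expr = stats::median(pairs$rel_expr),
                                     p_value = p, stringsAsFactors = FALSE)
  }
  per_pair <- do.call(rbind, per_pair_list)
  rownames(per_pair) <- NULL
  per_gene <- do.call(rbind, per_gene_list)
  rownames(per_gene) <- NULL

  correlations <- NULL
  if (length(target_genes) >= 2L) {
    combos <- utils::combn(target_genes, 2)
    correlations <- do.call(rbind, lapply(seq_len(ncol(combos)), function(k) {
      ga <- combos[1, k]; gb <- combos[2, k]
      a <- per_pair[per_pair$gene == ga, c("sample", "rel_expr")]
      b <- per_pair[per_pair$gene == gb, c("sample", "rel_expr")]
      ab <- merge(a, b, by = "sample")
      # fewer than 3 shared pairs (or a constant vector) leaves the
      # correlation undefined; report NA rather than fail the run
      cr <- tryCatch(correlate_genes(ab$rel_expr.x, ab$rel_expr.y),
                     error = function(e) list(rho = NA_real_,
                                              r_squared = NA_real_,
                                              p_value = NA_real_))
      data.frame(gene_a = ga, gene_b = gb, rho = cr$rho,
                 r_squared = cr$r_squared, p_value = cr$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(per_pair = per_pair, per_gene = per_gene, correlations = correlations)
}
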