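---
title: "Methods and design of the candgene pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the candgene pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(candgene)
```

# Scope

`candgene` implements the computational core of a candidate-gene cancer
study in which a small patient cohort is profiled three ways: paired
tumor/normal qPCR expression of a handful of genes, targeted
resequencing with single-marker SNP association against public
reference populations, and regulatory-impact annotation of the
associated SNPs (transcription-factor motif disruption, restriction-site
genotyping assays, microRNA seed sites).  Because patient-level data in
such studies are typically not shareable, a synthetic-data module
generates every input the analysis stages consume, with the statistical
structure the analyses assume.

# Relative expression

Expression is quantified on the qPCR cycle scale.  For a target gene
$g$ and the housekeeping gene in the same sample,
$\Delta Ct = Ct_g - Ct_{hk}$; for a tumor/normal pair from the same
patient, $\Delta\Delta Ct = \Delta Ct_{tumor} - \Delta Ct_{normal}$ and
the fold change is $2^{-\Delta\Delta Ct}$ (Livak).  Replicate Cts are
averaged on the cycle scale before differencing, the standard practice
when the amplification efficiency is taken as 2; no efficiency
correction (Pfaffl) is applied.

Group significance uses a two-tailed Mann–Whitney U test.  Two readings
of "tumor vs normal relative expressions" are provided:

* **`comparison = "groups"` (default).**  Each sample's relative
  expression is computed against the cohort mean normal $\Delta Ct$, so
  both tissues have a distribution, and the tumor and normal groups are
  compared.  Because the Mann–Whitney statistic depends only on ranks,
  this is equivalent to an unpaired comparison of tumor vs normal
  $\Delta Ct$.
* **`comparison = "paired_vs_unit"`.**  Per-pair $2^{-\Delta\Delta Ct}$
  values are compared against a same-sized group of exact 1s (each
  normal sample relative to itself).

The second reading is a literal transcription of "relative expressions
vs control", but it makes the control group a single massive tie; the
tie-corrected test then degenerates into a sign-test-like statistic
whose finite-sample type-I error at 27 pairs is far from the nominal
level (an analytic binomial calculation puts it near 0.12 at nominal
0.05).  The cohort-baseline reading is therefore the default; the
package's null-calibration test verifies its type-I error stays in
[0.03, 0.08] at nominal 0.05 over 400 null simulations.

The Mann–Whitney p-value is exact — by the Wilcoxon distribution
without ties, by full enumeration of the $\binom{n}{n_a}$ group
assignments with midranks when ties are present — whenever the combined
sample size is at most 20, and otherwise uses the normal approximation
with tie and continuity correction.  The two-sided p is
$\min(1,\,2\min(P(U\le u), P(U\ge u)))$ in every branch.  Exhaustive
enumeration at small $n$ was preferred over the more common
"approximate as soon as ties appear" rule because cohorts of this size
produce tied fold changes routinely and the enumeration is cheap.

Inter-gene coordination is measured by Spearman's rank correlation of
the per-pair tumor fold changes.  Published figures in this field
sometimes label Spearman's coefficient "$R^2$"; since it is genuinely
ambiguous whether such values are $\rho$ or $\rho^2$, the package
always reports both `rho` and `r_squared` and leaves the interpretation
to the reader.  Reporter (dual-luciferase) assays are normalised as
per-replicate firefly/Renilla ratios relative to the control mean, with
an equal-variance two-tailed t-test, matching how such assays are
conventionally summarised over three biological replicates.

# Single-marker association

Cohort genotype counts (hom-alt / het / hom-ref) are compared with a
reference population in two 2×2 tables:

* **allelic**: cohort alt/ref allele counts vs reference alt/ref allele
  counts;
* **genotypic (carrier)**: het vs hom-ref, cohort vs reference —
  appropriate for rare variants with no hom-alt carriers in the cohort.

For a table $(a, b; c, d)$ the odds ratio is $ad/bc$ with the Woolf
interval $\exp(\ln\mathrm{OR} \pm z\,\mathrm{SE})$,
$\mathrm{SE} = \sqrt{1/a + 1/b + 1/c + 1/d}$, and a two-sided Wald p
from $\ln(\mathrm{OR})/\mathrm{SE}$.  If any cell is zero the
Haldane–Anscombe correction (+0.5 to every cell) is applied first and
flagged in the result.  This combination reproduces, to printed
precision, all eight published statistics of the worked example shipped
in `inst/extdata/table2_cohort.tsv` / `table2_reference.tsv` (allelic
OR 2.12, 95% CI 1.0006–4.5021, p 0.0498; genotypic OR 2.19, p 0.0426;
and against the smaller panel OR 3.41 / 3.45), which is how the exact
formula family was pinned down.

Reference populations can be supplied as genotype counts, as allele
counts, or as a frequency plus an allele total.  Allele-count-only
panels support the genotypic OR through an explicit
`assume_no_hom_alt = TRUE` reconstruction (`het = alt`,
`hom_ref = (ref - alt)/2`) — the only reading of a rare-variant panel
consistent with the shipped worked example.  Frequencies are converted
to counts by rounding half away from zero at the stated allele total
(1006 alleles for the 503 European diploid reference samples).

The association p-value uses Pearson's χ² (df 1, no Yates correction)
or the two-sided Fisher exact test (sum of all hypergeometric table
probabilities not exceeding the observed one); `method = "auto"`
selects Fisher when any expected cell is below 5.  This textbook rule
does not reproduce the published per-row test choice for two of the six
screening rows reconstructed in `inst/extdata/table1_frequencies.tsv`
(both have minimum expected cells well below 5 yet are annotated as
χ²), and no alternative rule we tried matches all six; the
corresponding acceptance check is deliberately strict and records the
discrepancy.  The screening rows themselves are only checked
qualitatively (every odds ratio exceeds 1): their published ORs cannot
be recovered numerically because the reference sample sizes behind them
are not stated.  Bonferroni adjustment multiplies each p by the family
size, capped at 1; the family size defaults to the number of markers in
the run and is overridable.

The de novo (somatic) screen is a set difference on the variant key
(chrom, pos, ref, alt): tumor records absent from the matched normal
sample.  Variants are first filtered by read depth (default minimum 20,
inclusive, the usual coverage cutoff for targeted panels).

# Motif disruption scoring

A motif match is scored as the log-odds of the position weight matrix:
for base $b$ in column $j$,
$\log_2\!\big(\frac{(n_{bj} + s\,\pi_b)/(N_j + s)}{\pi_b}\big)$ with
background $\pi$ (default uniform) and pseudocount $s$ (default 0).
Log base 2 is a documented constant — the published description of the
score as a log fold change of binding affinity is base-agnostic.  With
$s = 0$, a base absent from a column has odds 0 and scores $-\infty$;
for a SNP whose alternate allele hits such a column the score
difference is $-\infty$, interpreted as complete loss of the motif
match.  This is deliberately the default so that "no match at all" is
distinguishable from "weaker match"; any positive pseudocount makes all
scores finite.  $-\infty$ survives serialisation as the JSON string
`"-inf"`.

Both strands are scanned; minus-strand windows are scored on the
reverse complement and reported in plus-strand coordinates.  `N` bases
contribute the background-weighted mean of their column.  For SNP
deltas, every window overlapping the SNP whose *reference* score
reaches the reporting threshold is rescored on the singly-substituted
sequence (one SNP at a time; interactions between SNPs in the same
motif are out of scope).  The default threshold is the 80th percentile
of the score range, $\min + 0.8(\max - \min)$, computed over finite
entries; no threshold is prescribed by the study this design follows,
so it is exposed as configuration.

Variant coordinates are 1-based (VCF dialect) and regions 0-based
half-open (BED dialect); conversion happens only at I/O boundaries.
Interval overlap is delegated to `GenomicRanges`.

# Restriction sites and miRNA seeds

Degenerate recognition sites (e.g. BsaHI's `GRCGYC`, which is its own
reverse complement) are matched with the full IUPAC alphabet,
overlapping occurrences included.  The in-silico RFLP model substitutes
each allele into the amplicon, reports cut/uncut, and derives fragment
lengths from cut positions (default cut at the site midpoint; BsaHI's
true `GR^CGYC` position is offset 2).  Heterozygotes show the union of
both alleles' bands.  The pyrosequencing context `GGGTG[G/C]C[G/A]TCTCC`
is the shipped worked example: the reference-allele sequence contains
the site at offset 4 and either variant base abolishes it.

MicroRNA target sites are reported by canonical seed classes only:
Watson–Crick complementarity of the UTR to miRNA positions 2–7 (6mer)
or 2–8 (7mer-m8), plus an adenosine opposite position 1 (7mer-A1,
8mer).  Quantitative context scores (conservation, SVR-style models)
have no reproducible published definition here and are out of scope.

# Synthetic data: what it emulates, and what not

`simulate_paired_ct()` draws, for pair $i$ and gene $g$, normal Ct
$= \beta_g + \varepsilon$ and tumor Ct
$= \beta_g + \delta_g + \lambda_g Z_i + \varepsilon$ with a shared
latent factor $Z_i \sim N(0, \sigma_Z)$ and replicate noise
$\varepsilon \sim N(0, \sigma_\varepsilon)$.  The latent factor is what
produces correlated downregulation of co-regulated genes, i.e. the
structure whose detection the expression stage is meant to
demonstrate.  Defaults: 3 technical replicates; $\sigma_Z = 1$ and
$\sigma_\varepsilon = 0.5$ cycles; baseline Ct 24 for targets, 20 for
the housekeeping gene; and a tumor shift $\delta_g = 1.5$ cycles with
loading 1 in the demo configuration.  The study design this emulates
fixes the cohort sizes (27 expression pairs; 209 association patients;
reference panels of 33,352 and 503 diploids) but states no effect sizes
on the Ct scale, so the defaults are package choices: 1.5 cycles is a
roughly threefold expression drop, the magnitude at which a cohort of
27 pairs has comfortable but not trivial power, and $\sigma_Z$
comparable to $\sigma_\varepsilon$ gives inter-gene correlations around
0.7–0.8, strong but below degeneracy.  Genotypes are drawn under
Hardy–Weinberg equilibrium at a stated minor-allele frequency; no
linkage disequilibrium between markers is simulated.  Variant-pair
fixtures spike somatic records at loci guaranteed distinct from the
shared germline set, so the truth set for the de novo screen is
unambiguous.  Motif fixtures plant the PWM consensus (per-column
argmax) between random flanks, which by construction is the
maximum-scoring window.

All generators are pure functions of their spec and a mandatory seed;
the global RNG state is saved and restored around every call.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: FFPE artefacts and allele-specific capture
bias, amplification-efficiency differences between assays, batch
effects, population stratification in the cohort, haplotype structure,
and read-level noise (inputs are consumed at the variant-call level,
never FASTQ/BAM).

# Numerical choices and problem sizes

* Exact Mann–Whitney enumeration up to combined $n = 20$
  ($\binom{20}{10} = 184{,}756$ assignments, vectorised); beyond that,
  tie- and continuity-corrected normal approximation.
* Fisher's two-sided p uses the standard relative tolerance
  $1 + 10^{-7}$ when comparing table probabilities.
* Frequency-to-count conversion rounds half away from zero.
* Ties in the PWM consensus are broken toward the alphabetically first
  base (`which.max`).
* Degenerate inputs fail fast with named validation errors: empty
  table margins, constant correlation vectors, infeasible genotype
  reconstructions, reference-base mismatches.

The package's statistical checks run at deliberately chosen sizes: CI
coverage of the null odds ratio over 1000 simulated cohorts of 209
against the 33,352-diploid reference; type-I error over 400 null
expression cohorts of 27 pairs; correlation sign recovery over 200
seeds; Fisher and PWM oracle equivalence over 500 and 200 random cases.
These sizes put Monte-Carlo error well inside the asserted bands while
keeping the whole suite fast.

# Known limitations

* The allelic and genotypic tables treat alleles within individuals as
  independent (standard for the allelic test, conservative-ish
  otherwise); no correction for within-person allele correlation.
* The Woolf/Wald machinery is asymptotic; with expected alt counts
  near 3, its 95% interval coverage sits near but not exactly at 95%
  (the calibration test brackets it at 93–97%).
* `auto` test selection encodes one textbook rule; as noted above, it
  does not reproduce every published per-row annotation.
* Motif scoring assumes positional independence (standard PWM
  assumption) and a single SNP per window.
* The pipeline consumes variant calls; alignment and calling are out
  of scope, as are external effect predictors (PROVEAN/SIFT, splicing
  enhancer scanners) and annotation services.
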