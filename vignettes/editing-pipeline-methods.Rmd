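---
title: "Methods: A-to-I editome discovery, quantification, and target prioritization"
author: "editome maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: A-to-I editome discovery, quantification, and target prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# Overview

`editome` implements a complete analysis of adenosine-to-inosine (A-to-I)
RNA editing in a two-group cohort — case samples (patient-derived
glioblastoma stem-cell cultures) against control neural stem cells. Because
inosine base-pairs like guanosine, A-to-I edits appear as A>G mismatches
between RNA reads and the genome (T>C on the genomic minus strand), and the
analysis starts from per-sample RNA variant calls and per-site read-count
pileups rather than raw reads. Alignment and variant calling are upstream of
this package; it consumes their outputs.

The pipeline has four analysis stages, each exposed as ordinary functions
and driven end-to-end by the numbered scripts under `analysis/`:

1. **Site discovery** (`run_discovery()`): a filter cascade from raw variant
   calls to high-confidence, informative editing sites.
2. **Quantification** (`build_editing_matrix()`, `gene_editing_matrix()`):
   editing levels at site, gene and sample resolution, with genomic-context
   summaries.
3. **Group specificity** (`classify_specificity()`, `compare_groups()`):
   which genes are edited group-specifically, and whether editing is
   globally elevated in cases.
4. **Target prioritization** (`prioritize_targets()`): a three-criterion
   funnel over an editing-enzyme (ADAR1-style) knockdown experiment and a
   patient survival table, ranked by editing-expression correlation.

A fifth component, the synthetic-cohort generator (`generate_cohort()` and
friends), defines the study conditions under which every stage is validated.

# The discovery cascade

A candidate site enters as a variant record carrying per-site aggregate
metrics: mismatch read count, mean Phred base quality of the mismatched
reads, mean mapping quality, and total coverage. The cascade applies four
pure set predicates, in order:

1. **Quality**: keep records with ≥ 1 mismatched read, base quality ≥ 25,
   mapping quality ≥ 20, and coverage ≥ 10. Every comparison is inclusive
   (≥), matching how such thresholds are conventionally printed. The
   thresholds act on the per-site aggregates carried by the record, not on
   individual reads; read-level filtering belongs to the upstream caller.
2. **DNA-variant subtraction**: remove any record whose
   (chrom, pos, ref, alt) key appears in an exome call set or a public SNP
   catalog. Keys include ref *and* alt deliberately: a T>C germline
   polymorphism must not mask an A>G edit at the same position. Position-only
   matching would be more aggressive; we prefer the stricter key and document
   it.
3. **Editing-catalog restriction**: keep only keys present in a curated
   editing-position whitelist (a RADAR-style database). This is the main
   guard against residual false positives.
4. **Informative-sample rule**: a site must have coverage ≥ 10 in at least
   10 samples, counted over all samples regardless of group. A per-group
   minimum would be a stricter alternative; we implement the total-sample
   rule and expose the count as a threshold (`min_informative_samples`).

Because all four stages are set predicates, the surviving site set is
invariant to record order and catalog order; only the per-stage attrition
report depends on the stage order above, which follows the natural
narrative (technical quality first, genetics second, curation third, power
last). The unit tests assert this order-invariance and check the whole
cascade against an independently coded plain-set-arithmetic oracle.

Surviving sites are annotated with strand, gene, transcript region and
repeat family against the supplied gene model. Strand comes from the
overlapping gene; where genes on both strands overlap, the strand whose
orientation reads A>G wins if exactly one does, otherwise the site is
reported as strand-unknown in genomic orientation. Region labels resolve
overlaps by a fixed priority — 3'UTR > 5'UTR > CDS > ncRNA > intron —
chosen so that the compartment most relevant to 3'UTR-biased editing wins;
plain `exon` features map to CDS.

# Editing levels

The site editing level in one sample is simply

$$\mathrm{level} = \frac{\text{edited reads}}{\text{total reads covering the site}},$$

treated as missing when coverage is below 10 so that poorly covered cells
never contaminate downstream means. Gene-level and sample-level values
**pool read counts** rather than averaging ratios:
$\sum_s e_s / \sum_s t_s$ over the gene's (or sample's) sites. Pooling is
the coverage-weighted mean of the site ratios — an algebraic identity the
tests assert — and is the natural estimator when per-site depths vary by an
order of magnitude. "The gene's sites" means the sites surviving discovery,
so all downstream statistics refer to one consistent site universe.

Missing cells are excluded, never zero-imputed, from every downstream mean;
zero-imputation would bias group comparisons toward the better-covered
group. A group mean additionally requires at least 2 non-missing samples
(configurable) to be considered evaluable.

# Group specificity

For each gene (or site), the specificity score is

$$S = \frac{\bar{x}_{\mathrm{case}}}{\bar{x}_{\mathrm{case}} + \bar{x}_{\mathrm{ctrl}}} \in [0, 1],$$

undefined when both means are zero. A gene is **case-specific** when
$S \ge 0.75$ (inclusive) and **control-specific** by the mirrored rule
$1 - S \ge 0.75$; everything else with a defined score is shared. The
mirrored rule makes relabeling the groups swap the two specific sets
exactly, which the tests assert. Classification defaults to gene-level
pooled means; site-level means are available through the same functions.

One numerical subtlety: scores are reported at 12-decimal precision.
Ratios of decimal fractions are generally not representable in binary
floating point — means of 0.6 and 0.2 give `0.6/0.8` one ulp *below* 0.75 —
and an inclusive decimal threshold should behave as printed at its own
boundary. Rounding to 12 decimals (far below any biological signal, far
above accumulated double-precision error) achieves that without a
tolerance parameter in the classification rule itself.

The global case-versus-control comparison uses Wilcoxon's signed-rank test
on per-unit paired group means (pairing case mean with control mean within
each gene makes the pairing well defined for unequal group sizes such as
31 vs 5). Zero differences are dropped before ranking; with ≤ 25 remaining
pairs and no tied absolute differences the exact null distribution is used,
otherwise the normal approximation with continuity and tie corrections.
With no non-zero differences the p-value is reported as 1 and flagged.
When several groupings are tested (e.g. transcriptional subtypes against
control), p-values are Bonferroni-adjusted across groupings.

# Target prioritization

Candidate editing targets must satisfy three criteria simultaneously:

- **Downregulated upon enzyme knockdown**: fold change strictly greater
  than 2 downward and adjusted P strictly below 0.05 in a supplied
  differential-expression table. The DE model itself (e.g. a
  negative-binomial fit) is out of scope; the funnel consumes its output.
- **Reduced editing**: the gene's pooled editing level drops by strictly
  more than δ between the reference and knockdown pileups. δ defaults to 0
  (any strict decrease) because no principled nonzero default exists; it is
  exposed as a parameter.
- **Adverse survival**: patients split at the median of the gene's
  expression; the high stratum must have a two-sided log-rank p < 0.05
  *and* the worse outcome. Direction comes from a univariate
  proportional-hazards fit on the high/low indicator (used only for its
  sign, so monotone-likelihood non-convergence is irrelevant); significance
  comes from the log-rank test. Patients at exactly the median go to the
  low stratum. Genes with constant expression are unevaluable.

The intersection is ranked by two product-moment correlations across
samples — enzyme expression vs the gene's editing level, and the gene's own
expression vs its editing level — combined as the sum of descending ranks,
ties broken lexicographically by gene id. Candidates with undefined
correlations (constant vectors, or fewer than 3 complete samples) are
flagged and ranked last. The funnel is monotone: relaxing any threshold can
only grow the candidate set.

# The synthetic cohort generator

The generator defines the conditions under which the pipeline is validated.
Its defaults mirror the reference study design: 31 case and 5 control
samples, 5,000 candidate sites over 1,000 genes, and a realistic mismatch
background. Per site $s$ and sample $j$:

$$c_{sj} \sim \mathrm{NegBin}(\mu = 60,\ \mathrm{size} = 5), \qquad
  e_{sj} \sim \mathrm{Binomial}(c_{sj},\ p_{sj}),$$

with $\operatorname{logit} p_{sj} = \operatorname{logit} p_s + \Delta_j$,
where $p_s \sim \mathrm{Beta}(2, 8)$ across sites (mean editing rate 0.2,
right-skewed, overdispersed — the beta-binomial shape seen in real
editomes) and $\Delta_j$ collects the group effects. Acting on the logit
scale keeps rates in $(0,1)$ and lets planted group differences be set
through the two group means. Default choices a practitioner should know:

- **Global case elevation** of 0.4 logits, reflecting globally higher
  editing in the case group; set it to 0 for null cohorts.
- **Germline SNP contamination**: 15% of candidate positions are SNPs, not
  edits. Each sample draws a genotype from the site's allele frequency
  (uniform on 0.2–0.8), so per-sample mismatch fractions sit near 0, 0.5 or
  1 with small noise. SNPs look exactly like strong edits to the quality
  filters — only catalog subtraction can remove them, which is what makes
  that stage testable. The generated exome/SNP catalogs contain exactly the
  SNP keys (with an optional miss rate), and the editing catalog includes
  the SNP keys as decoys, mirroring the fact that curated editing databases
  contain positions polymorphic in some genomes.
- **Error mismatches**: a matched number of non-candidate positions emit
  mismatches at a per-base error rate of 0.002, with substitution types
  uniform over the 12 possibilities; this yields an A-to-G-dominant but not
  A-to-G-pure variant spectrum (roughly 100-fold enrichment at the
  defaults).
- **Context**: repeat families are drawn per site (AluS-heavy:
  45% AluS, 15% AluY, 15% AluJ, 5% other repeats, 20% non-repetitive) and
  regions from a 3'UTR/intron-heavy mix (35% 3'UTR, 30% intron, 12%
  intergenic, 10% CDS, 8% ncRNA, 5% 5'UTR). Genes are laid out on four
  chromosomes in fixed 20-kb blocks with a coding-gene feature layout and
  ~10% dedicated ncRNA genes; repeat annotations are width-1 intervals at
  the repetitive sites. Context labels are assigned, not derived from
  sequence content.
- **Planted specific genes**: a planted gene's shift $d$ is applied as
  $+d/2$ to case and $-d/2$ to control. Because the score saturates when
  base rates are high (a rate cannot exceed 1, so $p_{\mathrm{case}} \ge
  4\,p_{\mathrm{ctrl}}$ is impossible above $p = 0.25$), planted genes draw
  their base rates from the same Beta prior truncated at 0.25. The
  generator records each planted gene's implied true score in the ground
  truth; with $d = 3$ these sit near 0.9.
- **Planted target**: one gene can carry the full three-signal profile —
  a deterministic knockdown log2 fold change of $-\log_2(2 \times 1.5)$
  with small adjusted P, a logit drop of 2.5 in the knockdown pileup, and
  an exponential survival model with log-hazard $\log 3$ per SD of its
  expression over 200 patients with 30% independent censoring (a censored
  patient's observed time is uniform on $(0, t)$, and a censoring rate of 1
  yields a legitimately degenerate all-censored table). Its expression, and
  the enzyme's expression, track the realized editing levels with noise SD
  0.3, giving correlations near 0.9 against a null background near 0.

Determinism: all randomness derives from the master seed through a fixed
rule — `set.seed(seed)` then `sample.int(2^31 - 2, 8)` yields one stream
seed per generator stage — so identical configurations reproduce
byte-identical output bundles, and any sub-stream (catalogs, knockdown,
survival) can be regenerated independently of the others.

## What the generator does and does not emulate

It reproduces the statistical structure the pipeline relies on:
overdispersed beta-binomial editing, negative-binomial coverage,
A-to-G-dominant mismatch spectra, catalog-removable germline contamination,
Alu- and 3'UTR-enriched context, group effects spanning the specificity
threshold, and planted knockdown/survival signal. It does **not** simulate
reads, alignment or splicing artifacts, hyper-editing clusters, correlated
editing along transcripts, realistic Alu sequence content, or
subtype-structured case heterogeneity. Passing tests therefore demonstrate
that the pipeline's arithmetic, set logic and statistics are correct under
the stated model — not that the upstream variant calling or the model
itself matches any particular real data set.

# Validation strategy and problem sizes

Every operation is tested against an independent oracle: brute-force
predicate loops and plain set arithmetic for the cascade, explicit
summation for pooled levels, a linear interval scan for annotation,
enumeration of all $2^n$ sign assignments for the signed-rank test, and the
hand-computed risk-table formula for the log-rank statistic. The
acceptance-style tests use cohorts of 2,000 sites × 36 samples for the
cascade oracle, the default 5,000-site cohort for rate recovery, 2,000
single-site genes for null calibration of the specificity classification
(against a direct Monte-Carlo re-simulation), 2,000 replicates of 50 null
pairs for signed-rank size, a 520-gene cohort for planted-specificity
recovery, and 100 seeds of a 50-gene cohort for end-to-end funnel recovery
of the planted target. These sizes keep the full suite under a minute of
compute per heavy block while leaving Monte-Carlo standard errors small
enough for 2·SE acceptance bands.

# Known limitations

- Quality thresholds act on per-site aggregate metrics; pipelines whose
  callers emit per-read qualities must aggregate before import.
- The informative-sample rule has no per-group minimum, so a site covered
  only in cases can be informative yet unevaluable for group contrasts
  (such units are flagged, not dropped silently).
- The signed-rank pairing operates on per-unit group means; it is a
  paired-by-unit design, not a paired-by-sample design.
- The survival screen is expression-based with a median split; per-site
  editing-level survival screens and covariate-adjusted hazard models are
  out of scope.
- Editing catalogs are treated as ground-truth whitelists; sites absent
  from the catalog are unrecoverable by design.
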