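# editome

Analysis of adenosine-to-inosine (A-to-I) RNA editing in a two-group
transcriptome cohort: discovery of high-confidence editing sites from RNA
variant calls, quantification of editing levels, classification of
group-specific editing, and prioritization of candidate editing targets.

A-to-I editing, catalyzed by ADAR enzymes on double-stranded RNA (typically
inverted Alu repeats), reads out as A>G mismatches against the genome (T>C
on the minus strand). Separating genuine edits from germline variation and
sequencing error, quantifying how edited each site/gene/sample is, and
deciding which edited genes matter functionally is the problem this package
addresses — for example, comparing patient-derived glioblastoma stem-cell
cultures (cases) against neural stem cells (controls) and nominating the
editing target whose loss tracks enzyme knockdown and patient survival.

## The method

**Discovery.** Variant records pass a four-stage cascade, all thresholds
inclusive: (1) ≥ 1 mismatched read, base quality ≥ 25, mapping quality
≥ 20, coverage ≥ 10; (2) removal of known DNA variants (exome calls and SNP
catalogs, keyed by chrom/pos/ref/alt); (3) restriction to a curated
editing-position catalog; (4) an informative-sample rule (coverage ≥ 10 in
≥ 10 samples). Survivors are annotated with strand, gene, transcript region
and repeat family.

**Quantification.** Site editing level = edited reads / total reads
(missing below 10× coverage). Gene and sample levels pool read counts:
Σe/Σt over the relevant sites — the coverage-weighted mean of site levels,
not the mean of ratios.

**Specificity.** With group means x̄_case and x̄_ctrl per gene, the score
S = x̄_case / (x̄_case + x̄_ctrl) classifies genes as case-specific
(S ≥ 0.75, inclusive), control-specific (1 − S ≥ 0.75), or shared. Global
group differences are tested with Wilcoxon's signed-rank test on per-gene
paired group means, Bonferroni-adjusted across groupings.

**Prioritization.** Candidate targets must be (a) downregulated upon
editing-enzyme knockdown (fold change > 2, adjusted P < 0.05), (b) reduced
in pooled editing level, and (c) adversely prognostic (median-split
expression, log-rank p < 0.05 with the high stratum worse). Candidates are
ranked by correlation of their editing with enzyme expression and with
their own expression.

**Synthetic cohorts.** `generate_cohort()` produces seeded, byte-reproducible
cohorts with beta-binomial editing (Beta(2, 8) rates, negative-binomial
coverage, mean 60), germline-SNP contamination removable only by catalog
subtraction, an A-to-G-dominant mismatch spectrum, Alu/3'UTR-enriched
context, and planted group-specific genes and a three-signal target — with
full ground truth for validation.

## Worked example

The numbered scripts under `analysis/` run the whole study on a synthetic
cohort (seed 1): `01_simulate.R` writes the input bundle (pileup TSV,
per-sample VCFs, GFF3/BED annotation, catalogs, knockdown DE table and
pileup, survival table) under `results/cohort/`; the later steps read those
files back through the package's parsers. Running them in order prints:

```
$ Rscript analysis/02_discover.R
filter cascade attrition (unique sites):
                 stage  n_in n_kept n_removed
1:             quality  9928   9853        75
2:     dna-subtraction  9853   9107       746
3:     editing-catalog  9107   4254      4853
4: informative-samples  4254   4254         0
A-to-G records are 102x the mean of the other 11 types
4254 high-confidence informative editing sites

$ Rscript analysis/03_quantify.R
editing matrix: 4254 sites x 36 samples (0.3% missing)
sample-pooled editing: case mean 0.268, control mean 0.197
Alu share of sites: 75.2% (AluS 44.8%); 3'UTR share: 35.6%

$ Rscript analysis/04_specificity.R
997/999 evaluable genes are case-enriched (mean_case > mean_ctrl)
signed-rank case vs control (n = 999 gene pairs): V = 499477, p = 5.2e-165
specificity classes at tau = 0.75 (inclusive):
   case-specific control-specific           shared      unevaluable
              20                0              979                0

$ Rscript analysis/05_prioritize.R
criterion gene sets: 4 downregulated, 508 editing-reduced, 14 adverse-survival
three-way intersection: 1 candidate(s): g0007
top-ranked target: g0007 (r editing~enzyme = 0.28, r editing~expression = 0.94)
```

Reading these numbers: the cascade removes all 746 germline-SNP positions
at the DNA-subtraction stage and all error-only positions at the
catalog-restriction stage, leaving exactly the simulated true editing
sites; case samples are globally more edited than controls (0.268 vs 0.197
pooled level, an overwhelming paired signed-rank signal); the 20 genes
planted with case-biased editing are exactly the 20 called case-specific;
and the one gene planted with all three target signals is the unique funnel
candidate, ranked first with the expected strong editing–expression
correlation.

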