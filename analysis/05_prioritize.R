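#!/usr/bin/env Rscript
## Step 5 — three-criterion target prioritization.
##
## Intersects (a) genes downregulated upon editing-enzyme knockdown
## (fold change > 2, adjusted P < 0.05), (b) genes with reduced pooled
## editing in the knockdown pileup, and (c) genes whose high expression
## predicts worse survival (median split, log-rank p < 0.05, hazard
## ratio > 1), then ranks the surviving candidates by correlation of their
## editing with enzyme and own-gene expression.

suppressMessages({library(editome); library(data.table)})

in_dir <- "results/cohort"
dir.create("results/prioritization", showWarnings = FALSE, recursive = TRUE)

sheet <- read_sample_sheet(file.path(in_dir, "samples.tsv"))
obs <- read_observations(file.path(in_dir, "pileup.tsv"))
obs_kd <- read_observations(file.path(in_dir, "pileup_kd.tsv"))
de <- read_de_table(file.path(in_dir, "de.tsv"))
surv <- read_survival_table(file.path(in_dir, "survival.tsv"))
sites <- fread("results/discovery/sites.tsv")
glev <- read_matrix_tsv("results/quantification/gene_editing_matrix.tsv")
expr <- read_matrix_tsv(file.path(in_dir, "expression.tsv"))
enzyme <- {e <- fread(file.path(in_dir, "enzyme_expression.tsv"))
           setNames(e$enzyme_expression, e$sample)}

case_sheet <- sheet[group == "case"]
ref_lvl <- rowMeans(gene_editing_matrix(obs, sites, case_sheet)$levels, na.rm = TRUE)
kd_lvl <- rowMeans(gene_editing_matrix(obs_kd, sites, case_sheet)$levels, na.rm = TRUE)

funnel <- prioritize_targets(de, ref_lvl, kd_lvl, surv, enzyme, glev, expr)
fwrite(data.table(gene_id = funnel$candidates), "results/prioritization/candidates.tsv",
       sep = "\t")
fwrite(funnel$ranking, "results/prioritization/ranking.tsv", sep = "\t")
fwrite(funnel$survival_table, "results/prioritization/survival_screen.tsv",
       sep = "\t")

cat(sprintf("criterion gene sets: %d downregulated, %d editing-reduced, %d adverse-survival\n",
            length(funnel$downregulated), length(funnel$editing_reduced),
            length(funnel$adverse_survival)))
cat(sprintf("three-way intersection: %d candidate(s): %s\n",
            length(funnel$candidates), paste(funnel$candidates, collapse = ", ")))
if (nrow(funnel$ranking)) {
  top <- funnel$ranking[1]
  cat(sprintf("top-ranked target: %s (r editing~enzyme = %.2f, r editing~expression = %.2f)\n",
              top$gene_id, top$r_enzyme_vs_editing, top$r_expr_vs_editing))
}
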