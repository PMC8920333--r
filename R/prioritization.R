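## Three-criterion target funnel (knockdown downregulation ∩ editing
## reduction ∩ adverse survival) and the correlation ranking that nominates
## the top editing target.

#' Genes downregulated upon enzyme knockdown
#'
#' Keeps genes with fold change greater than `fc_threshold` downward and
#' adjusted P below `p_threshold` — both strict, so a gene at exactly
#' 2-fold (log2FC = -1) is excluded at the default thresholds.
#'
#' @param de DE table (`gene_id`, `log2_fold_change`, `adjusted_p`;
#'   knockdown vs control).
#' @param fc_threshold linear fold-change threshold (default 2).
#' @param p_threshold adjusted-P threshold (default 0.05).
#' @return sorted character vector of gene ids.
#' @export
filter_downregulated <- function(de, fc_threshold = 2, p_threshold = 0.05) {
  de <- as.data.table(de)
  keep <- !is.na(de$log2_fold_change) & !is.na(de$adjusted_p) &
    de$log2_fold_change < -log2(fc_threshold) & de$adjusted_p < p_threshold
  sort(de$gene_id[keep])
}

#' Genes with reduced editing between two conditions
#'
#' Compares pooled gene-level editing between a reference condition (e.g.
#' untreated cells) and a perturbed one (e.g. enzyme knockdown); a gene
#' qualifies iff its pooled level drops by strictly more than `delta` and
#' is evaluable in both conditions.
#'
#' @param levels_ref,levels_alt named numeric vectors (or 1-column
#'   matrices) of pooled gene editing levels per condition; names are gene
#'   ids and must share a universe.
#' @param delta minimum drop (default 0: any strict decrease).
#' @return sorted character vector of gene ids.
#' @export
editing_reduction_genes <- function(levels_ref, levels_alt, delta = 0) {
  ref <- if (is.matrix(levels_ref)) rowMeans(levels_ref, na.rm = TRUE) else levels_ref
  alt <- if (is.matrix(levels_alt)) rowMeans(levels_alt, na.rm = TRUE) else levels_alt
  genes <- intersect(names(ref), names(alt))
  ref <- ref[genes]; alt <- alt[genes]
  ok <- !is.na(ref) & !is.nan(ref) & !is.na(alt) & !is.nan(alt)
  sort(genes[ok & (ref - alt) > delta])
}

#' Median-split survival screen
#'
#' For each gene: patients are dichotomized at the median of its
#' expression, the two strata compared with a two-sided log-rank test, and
#' the hazard direction taken from a univariate proportional-hazards fit on
#' the high/low indicator. A gene passes iff log-rank p < `alpha` and the
#' high-expression stratum has the worse outcome (hazard ratio > 1).
#' Patients at exactly the median go to the low stratum. Genes with
#' constant expression, or with fewer than 2 patients per stratum, are
#' unevaluable.
#'
#' @param surv survival table (`patient_id`, `time`, `event`, one column
#'   per gene).
#' @param genes gene ids to screen (default: all expression columns).
#' @param alpha significance level (default 0.05).
#' @return `data.table` with `gene_id`, `statistic` (log-rank chi-square),
#'   `p_value`, `hazard_ratio` (high vs low), `passes`, `evaluable`.
#' @export
survival_screen <- function(surv, genes = NULL, alpha = 0.05) {
  surv <- as.data.table(surv)
  meta <- c("patient_id", "time", "event")
  if (is.null(genes)) genes <- setdiff(names(surv), meta)
  miss <- setdiff(genes, names(surv))
  if (length(miss)) stopf("gene(s) absent from survival table: %s", miss[1L])
  if (any(surv$time <= 0)) stopf("survival times must be positive")
  if (sum(surv$event) == 0L) stopf("survival table contains no events; screen is unevaluable")

  rows <- lapply(genes, function(g) {
    expr <- surv[[g]]
    high <- expr > median(expr)
    if (length(unique(expr)) < 2L || sum(high) < 2L || sum(!high) < 2L) {
      return(data.table(gene_id = g, statistic = NA_real_, p_value = NA_real_,
                        hazard_ratio = NA_real_, passes = FALSE,
                        evaluable = FALSE))
    }
    sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ high)
    p <- pchisq(sd$chisq, df = 1L, lower.tail = FALSE)
    ## direction of effect only; monotone-likelihood warnings are irrelevant
    cx <- suppressWarnings(survival::coxph(survival::Surv(surv$time, surv$event) ~ high))
    hr <- unname(exp(stats::coef(cx)))
    data.table(gene_id = g, statistic = sd$chisq, p_value = p,
               hazard_ratio = hr,
               passes = is.finite(p) && p < alpha && is.finite(hr) && hr > 1,
               evaluable = TRUE)
  })
  rbindlist(rows)
}

#' Intersect the three prioritization criteria
#'
#' Exact three-way intersection of the downregulated, editing-reduced and
#' adverse-survival gene sets; order- and duplication-invariant,
#' deterministically sorted.
#'
#' @param downregulated,editing_reduced,adverse_survival character vectors
#'   of gene ids.
#' @return sorted character vector of candidate gene ids.
#' @export
intersect_candidates <- function(downregulated, editing_reduced, adverse_survival) {
  sort(intersect(intersect(unique(downregulated), unique(editing_reduced)),
                 unique(adverse_survival)))
}

#' Rank candidate targets by editing-expression correlation
#'
#' For each candidate gene, computes product-moment correlations across
#' samples between (a) editing-enzyme expression and the gene's pooled
#' editing level and (b) the gene's own expression and its editing level.
#' Candidates are ordered by the sum of the descending ranks of the two
#' correlations (smaller rank-sum = stronger on both axes); ties break
#' lexicographically by gene id. Candidates with undefined correlations
#' (constant editing or expression, or fewer than `min_samples` complete
#' samples) are flagged degenerate and ranked last.
#'
#' @param candidates character vector of gene ids.
#' @param enzyme_expression named numeric vector: editing-enzyme (e.g.
#'   ADAR1) expression per sample.
#' @param editing_levels gene x sample matrix of pooled editing levels.
#' @param expression gene x sample matrix of gene expression.
#' @param min_samples minimum complete samples per correlation (default 3).
#' @return `data.table` with `gene_id`, `r_enzyme_vs_editing`,
#'   `r_expr_vs_editing`, `combined_rank`, `degenerate`, sorted by
#'   `combined_rank`.
#' @export
rank_candidates <- function(candidates, enzyme_expression, editing_levels,
                            expression, min_samples = 3L) {
  if (length(candidates) == 0L) {
    return(data.table(gene_id = character(), r_enzyme_vs_editing = numeric(),
                      r_expr_vs_editing = numeric(), combined_rank = numeric(),
                      degenerate = logical()))
  }
  samples <- intersect(colnames(editing_levels), names(enzyme_expression))
  samples <- intersect(samples, colnames(expression))
  safe_cor <- function(a, b) {
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < min_samples) return(NA_real_)
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
    cor(a[ok], b[ok])
  }
  rows <- lapply(candidates, function(g) {
    ed <- if (g %in% rownames(editing_levels)) editing_levels[g, samples] else rep(NA_real_, length(samples))
    ex <- if (g %in% rownames(expression)) expression[g, samples] else rep(NA_real_, length(samples))
    data.table(gene_id = g,
               r_enzyme_vs_editing = safe_cor(enzyme_expression[samples], ed),
               r_expr_vs_editing = safe_cor(ex, ed))
  })
  out <- rbindlist(rows)
  out[, degenerate := is.na(r_enzyme_vs_editing) | is.na(r_expr_vs_editing)]
  ## descending ranks; NA (degenerate) sink to the bottom
  rk <- function(x) rank(-x, ties.method = "average", na.last = "keep")
  out[, combined_rank := rk(r_enzyme_vs_editing) + rk(r_expr_vs_editing)]
  out[degenerate == TRUE, combined_rank := Inf]
  setorder(out, combined_rank, gene_id)
  out[]
}

#' Run the full target-prioritization funnel
#'
#' Composition of [filter_downregulated()], [editing_reduction_genes()],
#' [survival_screen()], [intersect_candidates()] and [rank_candidates()].
#' Relaxing any threshold never shrinks the candidate set.
#'
#' @param de DE table.
#' @param levels_ref,levels_alt pooled gene editing levels per condition
#'   (named vectors or gene x sample matrices).
#' @param surv survival table.
#' @param enzyme_expression named per-sample enzyme expression.
#' @param editing_levels,expression gene x sample matrices for the
#'   correlation ranking.
#' @param fc_threshold,p_threshold,delta,alpha stage thresholds.
#' @return list with the three per-criterion gene sets, `candidates`, and
#'   the `ranking` table.
#' @export
prioritize_targets <- function(de, levels_ref, levels_alt, surv,
                               enzyme_expression, editing_levels, expression,
                               fc_threshold = 2, p_threshold = 0.05,
                               delta = 0, alpha = 0.05) {
  down <- filter_downregulated(de, fc_threshold, p_threshold)
  reduced <- editing_reduction_genes(levels_ref, levels_alt, delta)
  screen <- survival_screen(surv, genes = intersect(union(down, reduced),
                                                    setdiff(names(surv), c("patient_id", "time", "event"))),
                            alpha = alpha)
  adverse <- sort(screen$gene_id[screen$passes])
  candidates <- intersect_candidates(down, reduced, adverse)
  ranking <- rank_candidates(candidates, enzyme_expression, editing_levels, expression)
  list(downregulated = down, editing_reduced = reduced,
       adverse_survival = adverse, survival_table = screen,
       candidates = candidates, ranking = ranking)
}
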