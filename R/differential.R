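## Group comparison of editing levels, case-enriched site calls, and the
## specificity score/classification separating case-specific from
## control-specific editing.

#' Per-unit group means of editing levels
#'
#' Arithmetic mean over non-missing cells per group for every unit (site
#' row of a site-level matrix, or gene row of a gene-level matrix).
#' Missing cells are excluded, never zero-imputed; a unit needs at least
#' `min_samples` non-missing values in each group to be evaluable.
#'
#' @param levels numeric unit x sample matrix (site- or gene-level).
#' @param sheet sample sheet matching the columns.
#' @param min_samples minimum non-missing samples per group for an
#'   evaluable mean (default 2).
#' @return `data.table` with `unit`, `mean_case`, `mean_ctrl`, `n_case`,
#'   `n_ctrl`; unevaluable group means are `NA`.
#' @export
group_mean_editing <- function(levels, sheet, min_samples = 2L) {
  validate_sample_sheet(sheet)
  if (!all(colnames(levels) %in% sheet$sample_id)) {
    stopf("matrix has sample(s) absent from sheet")
  }
  grp <- sheet$group[match(colnames(levels), sheet$sample_id)]
  masked_mean <- function(m, min_n) {
    n <- rowSums(!is.na(m))
    mu <- rowMeans(m, na.rm = TRUE)
    mu[n < min_n] <- NA_real_
    mu[is.nan(mu)] <- NA_real_
    list(mu = mu, n = n)
  }
  ca <- masked_mean(levels[, grp == "case", drop = FALSE], min_samples)
  co <- masked_mean(levels[, grp == "control", drop = FALSE], min_samples)
  data.table(unit = rownames(levels),
             mean_case = ca$mu, mean_ctrl = co$mu,
             n_case = ca$n, n_ctrl = co$n)
}

#' Case-enriched units
#'
#' Units (sites or genes) whose mean editing level is strictly higher in
#' the case group than in controls; ties and unevaluable units are
#' excluded.
#'
#' @param means output of [group_mean_editing()].
#' @return sorted character vector of unit keys.
#' @export
enriched_sites <- function(means) {
  ok <- !is.na(means$mean_case) & !is.na(means$mean_ctrl)
  sort(means$unit[ok & means$mean_case > means$mean_ctrl])
}

#' Group-specificity score
#'
#' `score = mean_case / (mean_case + mean_ctrl)`, in `[0, 1]`; `NA` when
#' both means are zero or either is missing. Satisfies
#' `score(a, b) + score(b, a) == 1` whenever defined. Scores are reported
#' at 12-decimal precision so that decimal-specified thresholds behave as
#' printed: means of 0.6 and 0.2 give a score of exactly 0.75, on the
#' inclusive boundary of the default classification rule, rather than one
#' binary ulp below it.
#'
#' @param mean_case,mean_ctrl non-negative group means (vectors recycle).
#' @return numeric score vector.
#' @export
specificity_score <- function(mean_case, mean_ctrl) {
  if (any(mean_case < 0, na.rm = TRUE) || any(mean_ctrl < 0, na.rm = TRUE)) {
    stopf("group means must be non-negative")
  }
  tot <- mean_case + mean_ctrl
  out <- round(mean_case / tot, 12)
  out[!is.na(tot) & tot == 0] <- NA_real_
  out
}

#' Classify units by group specificity
#'
#' A unit is case-specific iff `score >= tau` (inclusive, so a score of
#' exactly 0.75 is case-specific at the default threshold) and
#' control-specific iff `1 - score >= tau` — the mirrored rule. Everything
#' else with a defined score is shared; units without a score are
#' unevaluable.
#'
#' @param means output of [group_mean_editing()] (site- or gene-level).
#' @param tau specificity threshold in `(0.5, 1]`; default 0.75.
#' @return list with `table` (per-unit `data.table` adding `score` and
#'   `class`) and `counts` (named integer vector over the four classes).
#' @export
classify_specificity <- function(means, tau = 0.75) {
  if (!(tau > 0.5 && tau <= 1)) stopf("tau must lie in (0.5, 1]")
  tab <- as.data.table(means)
  tab[, score := specificity_score(mean_case, mean_ctrl)]
  tab[, class := fifelse(is.na(score), "unevaluable",
                  fifelse(score >= tau, "case-specific",
                   fifelse(1 - score >= tau, "control-specific", "shared")))]
  lev <- c("case-specific", "control-specific", "shared", "unevaluable")
  counts <- table(factor(tab$class, levels = lev))
  list(table = tab[], counts = setNames(as.integer(counts), lev))
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Two-sided signed-rank test. Zero differences are dropped before
#' ranking. With `n <= 25` remaining pairs and no tied absolute
#' differences the exact null distribution is used; otherwise the normal
#' approximation with continuity correction and tie correction. With no
#' non-zero differences the p-value is reported as 1 with `degenerate =
#' TRUE`.
#'
#' @param x,y paired numeric vectors of equal length (or `y = NULL` to
#'   test differences `x` against zero).
#' @return list with `statistic` (V, sum of positive ranks), `p_value`,
#'   `n_used`, `degenerate`, `exact`.
#' @export
signed_rank_test <- function(x, y = NULL) {
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stopf("paired vectors must have equal length")
    x - y
  }
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n < 1L) {
    return(list(statistic = 0, p_value = 1, n_used = 0L,
                degenerate = TRUE, exact = TRUE))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (n <= 25L && !ties) {
    ## exact two-sided p from the signed-rank null distribution
    p <- if (V > n * (n + 1) / 4) {
      2 * (1 - psignrank(V - 1, n))
    } else {
      2 * psignrank(V, n)
    }
    p <- min(p, 1)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- V - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
    p <- min(2 * pnorm(-abs(z)), 1)
    exact <- FALSE
  }
  list(statistic = V, p_value = p, n_used = n, degenerate = FALSE, exact = exact)
}

#' Compare groups across one or more pairings, with Bonferroni adjustment
#'
#' Applies the paired signed-rank test to each supplied grouping: the two
#' groups of the cohort are compared by pairing per-unit case means with
#' per-unit control means (which makes the pairing well defined for
#' unequal group sizes). P-values are adjusted with the Bonferroni method
#' across the groupings.
#'
#' @param pairings named list; each element is a list or data.frame with
#'   elements/columns `case` and `ctrl` — paired per-unit values.
#' @return `data.table` with `label`, `statistic`, `p_value`,
#'   `adjusted_p`, `n_units`, `degenerate`.
#' @export
compare_groups <- function(pairings) {
  if (is.null(names(pairings)) || any(!nzchar(names(pairings)))) {
    stopf("pairings must be a named list")
  }
  rows <- lapply(names(pairings), function(lab) {
    pr <- pairings[[lab]]
    res <- signed_rank_test(pr$case, pr$ctrl)
    data.table(label = lab, statistic = res$statistic, p_value = res$p_value,
               n_units = res$n_used, degenerate = res$degenerate)
  })
  out <- rbindlist(rows)
  out[, adjusted_p := p.adjust(p_value, method = "bonferroni")]
  setcolorder(out, c("label", "statistic", "p_value", "adjusted_p",
                     "n_units", "degenerate"))
  out[]
}
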