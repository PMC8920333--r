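## Editing-level statistics at site, gene and sample resolution, plus
## Alu-subfamily and transcript-region context summaries.

REGION_LEVELS <- c("5UTR", "CDS", "3UTR", "intron", "ncRNA", "intergenic")
REPEAT_LEVELS <- c("AluY", "AluS", "AluJ", "other-repeat", "nonrepetitive")
## region from the highest-priority overlapping feature
REGION_PRIORITY <- c("3UTR", "5UTR", "CDS", "ncRNA", "intron")

#' Editing level at one site in one sample
#'
#' Editing level = edited reads / total reads covering the site; `NA`
#' (missing) where coverage is below `min_coverage`, so under-covered cells
#' never enter downstream means.
#'
#' @param edited_reads,total_reads non-negative integer vectors.
#' @param min_coverage minimum coverage for a defined level (default 10).
#' @return numeric vector in `[0, 1]` with `NA` for under-covered cells.
#' @export
site_editing_level <- function(edited_reads, total_reads, min_coverage = 10L) {
  if (any(edited_reads < 0) || any(total_reads < 0)) stopf("negative read count")
  if (any(edited_reads > total_reads)) stopf("edited_reads exceeds total_reads")
  lev <- ifelse(total_reads > 0L, edited_reads / total_reads, NA_real_)
  lev[total_reads < min_coverage] <- NA_real_
  lev
}

#' Pooled editing level over a gene's sites
#'
#' The overall gene editing level pools read counts — the sum of edited
#' reads at the gene's known editing positions divided by the sum of all
#' reads covering those positions. This coverage-weighted pooling is not
#' the mean of per-site ratios: sites with (2, 10) and (30, 40) reads give
#' 32/50 = 0.64, not 0.475.
#'
#' @param edited_reads,total_reads counts at the gene's sites (one sample,
#'   or pooled across samples).
#' @return pooled level, or `NA` if no reads cover any site.
#' @export
gene_editing_level <- function(edited_reads, total_reads) {
  if (any(edited_reads < 0) || any(total_reads < 0)) stopf("negative read count")
  if (any(edited_reads > total_reads)) stopf("edited_reads exceeds total_reads")
  tot <- sum(total_reads)
  if (tot == 0L) return(NA_real_)
  sum(edited_reads) / tot
}

#' Pooled editing level over all sites in one sample
#'
#' The sample overall editing level: reads supporting all editing sites in
#' the sample divided by all reads mapped to those sites. Same pooling rule
#' as [gene_editing_level()], applied over every site of the sample.
#'
#' @inheritParams gene_editing_level
#' @return pooled level, or `NA` with no covered sites.
#' @export
sample_editing_level <- function(edited_reads, total_reads) {
  gene_editing_level(edited_reads, total_reads)
}

#' Build the site x sample editing matrix
#'
#' Cell-wise [site_editing_level()] with missingness where coverage is
#' below threshold; rows and columns in deterministic sorted order.
#'
#' @param observations pileup table.
#' @param sites discovery site table (or character vector of site keys);
#'   observations at other sites are an error.
#' @param sheet sample sheet; observations for unknown samples are an
#'   error.
#' @param thresholds a [filter_thresholds()] object (supplies
#'   `min_coverage`).
#' @return object of class `editing_matrix`: list with `levels` and
#'   `coverage` matrices (site key x sample id), `sheet`, and
#'   `site_gene` (named vector mapping site key to gene id, filled by
#'   [annotate_site_context()]-annotated site tables; `NA` otherwise).
#' @export
build_editing_matrix <- function(observations, sites, sheet,
                                 thresholds = filter_thresholds()) {
  obs <- as.data.table(observations)
  if (!"site" %in% names(obs)) obs[, site := site_key(chrom, pos, ref, alt)]
  validate_sample_sheet(sheet)
  keys <- if (is.character(sites)) sites else sites$site
  obs <- obs[site %in% keys]
  extra <- setdiff(unique(observations$sample %||% character()),
                   sheet$sample_id)
  if (length(extra)) stopf("observation for unknown sample: %s", extra[1L])

  rn <- sort(unique(keys))
  cn <- sort(sheet$sample_id)
  lev <- matrix(NA_real_, length(rn), length(cn), dimnames = list(rn, cn))
  cov <- matrix(0L, length(rn), length(cn), dimnames = list(rn, cn))
  if (nrow(obs)) {
    ij <- cbind(match(obs$site, rn), match(obs$sample, cn))
    cov[ij] <- obs$total_reads
    lev[ij] <- site_editing_level(obs$edited_reads, obs$total_reads,
                                  thresholds$min_coverage)
  }
  site_gene <- setNames(rep(NA_character_, length(rn)), rn)
  if (!is.character(sites) && "gene_id" %in% names(sites)) {
    site_gene[sites$site] <- sites$gene_id
  }
  structure(list(levels = lev, coverage = cov, sheet = as.data.table(sheet),
                 site_gene = site_gene),
            class = "editing_matrix")
}

#' @exportS3Method base::print
print.editing_matrix <- function(x, ...) {
  cat(sprintf("<editing_matrix: %d sites x %d samples, %.1f%% missing>\n",
              nrow(x$levels), ncol(x$levels),
              100 * mean(is.na(x$levels))))
  invisible(x)
}

#' Pool an editing matrix's observations to gene level
#'
#' For each gene and sample, sums edited and total reads over the gene's
#' sites and applies the pooled-level rule; cells with pooled coverage
#' below `min_coverage` are missing.
#'
#' @param observations pileup table restricted to discovered sites.
#' @param sites annotated site table (needs `site` and `gene_id`).
#' @param sheet sample sheet.
#' @param thresholds a [filter_thresholds()] object.
#' @return list with `levels` (gene x sample matrix) and `counts`
#'   (long `data.table` of pooled edited/total per gene and sample).
#' @export
gene_editing_matrix <- function(observations, sites, sheet,
                                thresholds = filter_thresholds()) {
  obs <- as.data.table(observations)
  if (!"site" %in% names(obs)) obs[, site := site_key(chrom, pos, ref, alt)]
  validate_sample_sheet(sheet)
  obs <- obs[sample %in% sheet$sample_id]
  map <- sites[!is.na(gene_id), .(site, gene_id)]
  obs <- merge(obs, map, by = "site")
  pooled <- obs[, .(edited = sum(edited_reads), total = sum(total_reads)),
                by = .(gene_id, sample)]
  rn <- sort(unique(pooled$gene_id))
  cn <- sort(sheet$sample_id)
  lev <- matrix(NA_real_, length(rn), length(cn), dimnames = list(rn, cn))
  if (nrow(pooled)) {
    val <- ifelse(pooled$total >= thresholds$min_coverage,
                  pooled$edited / pooled$total, NA_real_)
    lev[cbind(match(pooled$gene_id, rn), match(pooled$sample, cn))] <- val
  }
  list(levels = lev, counts = pooled[])
}

#' Annotate sites with strand, gene, transcript region and repeat family
#'
#' Region comes from the highest-priority overlapping gene feature
#' (3UTR > 5UTR > CDS > ncRNA > intron); sites overlapping nothing are
#' `"intergenic"`. Repeat family comes from the overlapping repeat interval
#' (`"nonrepetitive"` if none). Strand follows [assign_site_strand()].
#'
#' @param sites site table with `chrom`, `pos`, `ref_base`, `alt_base`.
#' @param model a `gene_model`.
#' @return the site table with `strand`, `gene_id`, `region`,
#'   `repeat_family` columns filled.
#' @export
annotate_site_context <- function(sites, model) {
  sites <- as.data.table(sites)
  n <- nrow(sites)
  sites[, strand := if (n) assign_site_strand(sites, model) else character()]
  sites[, gene_id := NA_character_]
  sites[, region := rep("intergenic", n)]
  sites[, repeat_family := rep("nonrepetitive", n)]
  if (n == 0L) return(sites[])

  q <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(sites$pos, sites$pos))
  g <- model$genes
  if (length(g)) {
    hits <- GenomicRanges::findOverlaps(q, g, ignore.strand = TRUE)
    if (length(hits)) {
      hdt <- data.table(
        row = S4Vectors::queryHits(hits),
        gene_id = g$gene_id[S4Vectors::subjectHits(hits)],
        feature = g$feature[S4Vectors::subjectHits(hits)]
      )
      hdt[, rank := match(feature, REGION_PRIORITY)]
      best <- hdt[order(rank, gene_id), .SD[1L], by = row]
      sites$region[best$row] <- best$feature
      sites$gene_id[best$row] <- best$gene_id
    }
  }
  r <- model$repeats
  if (length(r)) {
    rhits <- GenomicRanges::findOverlaps(q, r, ignore.strand = TRUE)
    if (length(rhits)) {
      rdt <- data.table(row = S4Vectors::queryHits(rhits),
                        family = r$family[S4Vectors::subjectHits(rhits)])
      rbest <- rdt[, .SD[1L], by = row]
      sites$repeat_family[rbest$row] <- rbest$family
    }
  }
  sites[]
}

#' Summarize region and repeat context of site sets
#'
#' Counts and proportions of sites per transcript-region class and per
#' repeat family, within each label of a site-set partition (e.g.
#' case-enriched vs control-enriched sites).
#'
#' @param sites annotated site table.
#' @param labels character vector (length `nrow(sites)`) partitioning the
#'   sites; a single label is recycled.
#' @return list with `region` and `repeat_family` `data.table`s (`label`,
#'   class, `n`, `proportion`); proportions sum to 1 within each label.
#' @export
summarize_context <- function(sites, labels = "all") {
  sites <- as.data.table(sites)
  labels <- rep_len(labels, nrow(sites))
  one <- function(col, lev) {
    if (nrow(sites) == 0L) {
      return(data.table(label = character(), class = character(),
                        n = integer(), proportion = numeric()))
    }
    dt <- data.table(label = labels, class = factor(sites[[col]], levels = lev))
    out <- dt[, .N, by = .(label, class)][, .(class, n = N, proportion = N / sum(N)),
                                          by = label]
    setnames(out, "class", col)
    out[]
  }
  list(region = one("region", REGION_LEVELS),
       repeat_family = one("repeat_family", REPEAT_LEVELS))
}
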