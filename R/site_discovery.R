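## Filter cascade from raw RNA variant calls to high-confidence, informative
## A-to-I editing sites, plus the 12-type variant spectrum.
##
## All cascade stages are pure set predicates, so the surviving site set is
## invariant to input order and to the order of catalogs; only the per-stage
## attrition report depends on stage order.

#' Filter thresholds for editing-site discovery
#'
#' Defaults follow the standard editome filter: at least one mismatched
#' read, Phred base quality >= 25, mapping quality >= 20, site coverage
#' >= 10, and coverage >= `min_coverage` in at least 10 samples for the
#' informative-site rule. All comparisons are inclusive (>=).
#'
#' @param min_alt_reads minimum mismatched reads supporting the variant.
#' @param min_base_quality minimum Phred base quality.
#' @param min_mapping_quality minimum Phred mapping quality.
#' @param min_coverage minimum read depth at the site.
#' @param min_informative_samples minimum number of samples with coverage
#'   >= `min_coverage` for a site to be informative.
#' @return an object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_alt_reads = 1L, min_base_quality = 25,
                              min_mapping_quality = 20, min_coverage = 10L,
                              min_informative_samples = 10L) {
  th <- list(
    min_alt_reads = as.integer(min_alt_reads),
    min_base_quality = as.numeric(min_base_quality),
    min_mapping_quality = as.numeric(min_mapping_quality),
    min_coverage = as.integer(min_coverage),
    min_informative_samples = as.integer(min_informative_samples)
  )
  if (any(unlist(th) < 0)) stopf("filter thresholds must be non-negative")
  structure(th, class = "filter_thresholds")
}

#' Classify a substitution into one of the 12 variant types
#'
#' Substitutions are labeled in transcript orientation: on the minus strand
#' both bases are complemented before labeling, so a genomic T>C on `-`
#' becomes `"A-to-G"` — the A-to-I signature. Unknown strand labels in
#' genomic orientation.
#'
#' @param ref_base,alt_base genomic plus-strand bases (vectors recycle).
#' @param strand `"+"`, `"-"` or `"unknown"`.
#' @return character vector of labels `"X-to-Y"`; entries classified under
#'   unknown strand carry the attribute-free genomic orientation (flagged in
#'   [tabulate_variant_types()] output via the strand column there).
#' @export
classify_variant_type <- function(ref_base, alt_base, strand = "+") {
  n <- max(length(ref_base), length(alt_base), length(strand))
  ref_base <- rep_len(as.character(ref_base), n)
  alt_base <- rep_len(as.character(alt_base), n)
  strand <- rep_len(as.character(strand), n)
  if (!all(ref_base %in% BASES) || !all(alt_base %in% BASES)) {
    stopf("non-ACGT base in substitution")
  }
  if (any(ref_base == alt_base)) stopf("ref_base equals alt_base")
  if (!all(strand %in% c("+", "-", "unknown"))) {
    stopf("strand must be '+', '-' or 'unknown'")
  }
  minus <- strand == "-"
  ref <- ifelse(minus, complement_base(ref_base), ref_base)
  alt <- ifelse(minus, complement_base(alt_base), alt_base)
  paste0(ref, "-to-", alt)
}

#' All 12 substitution-type labels, in fixed display order
#' @return character vector of length 12.
#' @export
variant_type_levels <- function() {
  out <- character()
  for (r in BASES) for (a in setdiff(BASES, r)) out <- c(out, paste0(r, "-to-", a))
  out
}

#' Tabulate the 12-type variant spectrum per sample and per group
#'
#' Each record is counted exactly once, labeled in transcript orientation
#' using the strand of the gene it overlaps (sites overlapping no gene, or
#' genes on both strands with no unique A-to-G-yielding orientation, count
#' in genomic orientation with strand `"unknown"`).
#'
#' @param records variant table (any number of samples).
#' @param model a `gene_model` used for strand assignment.
#' @param sheet sample sheet covering every sample in `records`.
#' @return list with `per_sample` (sample x 12-type count table, one row
#'   per sample in the sheet) and `group_means` (group x 12-type mean
#'   counts).
#' @export
tabulate_variant_types <- function(records, model, sheet) {
  validate_variant_records(records)
  validate_sample_sheet(sheet)
  extra <- setdiff(unique(records$sample_id), sheet$sample_id)
  if (length(extra)) stopf("sample(s) in records absent from sheet: %s",
                           paste(extra, collapse = ", "))
  lev <- variant_type_levels()
  per_sample <- matrix(0L, nrow = nrow(sheet), ncol = length(lev),
                       dimnames = list(sheet$sample_id, lev))
  if (nrow(records) > 0L) {
    strand <- assign_site_strand(records, model)
    type <- classify_variant_type(records$ref_base, records$alt_base, strand)
    tab <- data.table(sample_id = records$sample_id, type = type)[
      , .N, by = .(sample_id, type)]
    per_sample[cbind(match(tab$sample_id, rownames(per_sample)),
                     match(tab$type, lev))] <- tab$N
  }
  grp <- sheet$group[match(rownames(per_sample), sheet$sample_id)]
  group_means <- rowsum(per_sample, grp) / as.vector(table(grp)[sort(unique(grp))])
  list(per_sample = per_sample, group_means = group_means)
}

#' Assign transcript strand to variant positions from the gene model
#'
#' A position takes the strand of its overlapping gene. Positions
#' overlapping genes on both strands take the strand under which the
#' substitution reads A-to-G, if exactly one orientation does; otherwise
#' `"unknown"`. Intergenic positions are `"unknown"`.
#'
#' @param records variant table (or any table with `chrom`, `pos`,
#'   `ref_base`, `alt_base`).
#' @param model a `gene_model`.
#' @return character vector of `"+"`, `"-"`, `"unknown"` per row.
#' @export
assign_site_strand <- function(records, model) {
  n <- nrow(records)
  if (n == 0L) return(character())
  out <- rep("unknown", n)
  g <- model$genes
  if (length(g) == 0L) return(out)
  q <- GenomicRanges::GRanges(records$chrom, IRanges::IRanges(records$pos, records$pos))
  hits <- GenomicRanges::findOverlaps(q, g, ignore.strand = TRUE)
  if (length(hits) == 0L) return(out)
  hdt <- data.table(row = S4Vectors::queryHits(hits),
                    strand = as.character(GenomicRanges::strand(g))[S4Vectors::subjectHits(hits)])
  st <- hdt[, .(plus = any(strand == "+"), minus = any(strand == "-")), by = row]
  both <- st$plus & st$minus
  out[st$row[st$plus & !st$minus]] <- "+"
  out[st$row[st$minus & !st$plus]] <- "-"
  if (any(both)) {
    rows <- st$row[both]
    ag_plus <- records$ref_base[rows] == "A" & records$alt_base[rows] == "G"
    ag_minus <- records$ref_base[rows] == "T" & records$alt_base[rows] == "C"
    out[rows[ag_plus & !ag_minus]] <- "+"
    out[rows[ag_minus & !ag_plus]] <- "-"
  }
  out
}

#' Apply read-support and quality filters to variant records
#'
#' A record survives iff `n_alt_reads >= min_alt_reads`, `base_quality >=
#' min_base_quality`, `mapping_quality >= min_mapping_quality` and
#' `coverage >= min_coverage` — all boundaries inclusive.
#'
#' @param records variant table.
#' @param thresholds a [filter_thresholds()] object.
#' @return the surviving subset, same columns.
#' @export
apply_quality_filters <- function(records, thresholds = filter_thresholds()) {
  validate_variant_records(records)
  keep <- records$n_alt_reads >= thresholds$min_alt_reads &
    records$base_quality >= thresholds$min_base_quality &
    records$mapping_quality >= thresholds$min_mapping_quality &
    records$coverage >= thresholds$min_coverage
  records[keep]
}

#' Remove records matching known DNA variants
#'
#' A record is removed iff its (chrom, pos, ref, alt) key appears in the
#' union of the supplied catalogs (exome calls, public SNP databases, ...).
#' Removal counts are reported per catalog source; a record matching several
#' catalogs counts once per matching source.
#'
#' @param records variant table.
#' @param catalogs list of `catalog` objects (may be empty).
#' @return surviving records, with attribute `removed_by_source` (named
#'   integer vector).
#' @export
subtract_known_dna_variants <- function(records, catalogs = list()) {
  validate_variant_records(records)
  keys <- site_key(records$chrom, records$pos, records$ref_base, records$alt_base)
  removed_by <- integer(0)
  hit <- rep(FALSE, nrow(records))
  for (cat in catalogs) {
    m <- keys %in% cat$keys
    prev <- if (cat$source_label %in% names(removed_by)) removed_by[[cat$source_label]] else 0L
    removed_by[cat$source_label] <- prev + sum(m)
    hit <- hit | m
  }
  out <- records[!hit]
  setattr(out, "removed_by_source", removed_by)
  out[]
}

#' Restrict records to a curated editing catalog
#'
#' Keeps only records whose key appears in the editing catalog — the
#' inclusion whitelist of curated editing positions (a RADAR-style
#' database). Warns if the catalog is empty.
#'
#' @param records variant table.
#' @param editing_catalog a `catalog`.
#' @return surviving records.
#' @export
restrict_to_editing_catalog <- function(records, editing_catalog) {
  validate_variant_records(records)
  if (length(editing_catalog$keys) == 0L) {
    warnf("editing catalog '%s' is empty; no sites will survive restriction",
          editing_catalog$source_label)
  }
  keys <- site_key(records$chrom, records$pos, records$ref_base, records$alt_base)
  records[keys %in% editing_catalog$keys]
}

#' Select informative sites from pileup observations
#'
#' A site is informative iff the number of samples in which its coverage is
#' at least `min_coverage` reaches `min_informative_samples`. The count is
#' over all samples regardless of group.
#'
#' @param observations pileup table from [read_observations()].
#' @param thresholds a [filter_thresholds()] object.
#' @return character vector of informative site keys.
#' @export
select_informative_sites <- function(observations, thresholds = filter_thresholds()) {
  obs <- as.data.table(observations)
  if (!"site" %in% names(obs)) obs[, site := site_key(chrom, pos, ref, alt)]
  cov <- obs[total_reads >= thresholds$min_coverage,
             .(n_covered = uniqueN(sample)), by = site]
  sort(cov[n_covered >= thresholds$min_informative_samples, site])
}

#' Run the full editing-site discovery cascade
#'
#' Stages, in order: (1) read-support/quality filters per record;
#' (2) subtraction of known DNA variants (exome + SNP catalogs);
#' (3) restriction to the curated editing catalog; (4) the
#' informative-sample rule on pileup coverage. Sites surviving all stages
#' are annotated with strand, gene, transcript region and repeat family.
#' The final set is order-invariant (all stages are set predicates); the
#' per-stage report depends on the stage order above.
#'
#' @param records variant table pooled over samples (a list of per-sample
#'   tables is also accepted and row-bound).
#' @param catalogs list of DNA-variant `catalog`s (stage 2).
#' @param editing_catalog curated editing `catalog` (stage 3).
#' @param model a `gene_model` for annotation.
#' @param observations pileup table for the informative-sample rule
#'   (stage 4).
#' @param thresholds a [filter_thresholds()] object.
#' @return list with `sites` (annotated site table: chrom, pos, ref_base,
#'   alt_base, site, strand, gene_id, region, repeat_family) and `report`
#'   (a `data.table` of per-stage entering/kept/removed counts over unique
#'   site keys; counts are non-increasing down the cascade).
#' @export
run_discovery <- function(records, catalogs, editing_catalog, model,
                          observations, thresholds = filter_thresholds()) {
  if (is.list(records) && !is.data.frame(records)) records <- rbindlist(records)
  validate_variant_records(records)

  n_sites <- function(r) uniqueN(site_key(r$chrom, r$pos, r$ref_base, r$alt_base))
  stages <- character(); entering <- integer(); kept <- integer()

  s0 <- n_sites(records)
  r1 <- apply_quality_filters(records, thresholds)
  stages <- c(stages, "quality"); entering <- c(entering, s0); kept <- c(kept, n_sites(r1))

  r2 <- subtract_known_dna_variants(r1, catalogs)
  stages <- c(stages, "dna-subtraction")
  entering <- c(entering, n_sites(r1)); kept <- c(kept, n_sites(r2))

  r3 <- restrict_to_editing_catalog(r2, editing_catalog)
  stages <- c(stages, "editing-catalog")
  entering <- c(entering, n_sites(r2)); kept <- c(kept, n_sites(r3))

  informative <- select_informative_sites(observations, thresholds)
  k3 <- unique(site_key(r3$chrom, r3$pos, r3$ref_base, r3$alt_base))
  final_keys <- sort(intersect(k3, informative))
  stages <- c(stages, "informative-samples")
  entering <- c(entering, length(k3)); kept <- c(kept, length(final_keys))

  report <- data.table(stage = stages, n_in = entering, n_kept = kept,
                       n_removed = entering - kept)

  sites <- parse_site_key(final_keys)
  sites[, site := final_keys]
  sites <- annotate_site_context(sites, model)
  list(sites = sites[], report = report)
}
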