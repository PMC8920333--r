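## Readers/writers for every external format the pipeline touches.
##
## Coordinate conventions: VCF, GFF3 and the internal model are 1-based
## inclusive; BED is 0-based half-open and converted at the boundary
## (rtracklayer does this on import/export).

# ---------------------------------------------------------------------------
# Variant records (VCF)
# ---------------------------------------------------------------------------

#' Read per-sample RNA variant records from a VCF file
#'
#' Parses biallelic SNV records from a VCF v4.x file into a variant table.
#' Multiallelic lines are split into one record per alternate allele before
#' any filtering; indels (REF or ALT longer than one base, or symbolic
#' alleles) are skipped and counted. Per-record depth and quality annotations
#' are read from the INFO field: `DP` (total read depth at the site), `AD`
#' (comma-separated read depth per alternate allele), `BQ` (mean Phred base
#' quality of mismatched reads) and `MQ` (mean Phred mapping quality).
#'
#' @param path path to a VCF file.
#' @param sample_id sample identifier attached to every record.
#' @return a `data.table` with columns `chrom`, `pos`, `ref_base`,
#'   `alt_base`, `n_alt_reads`, `base_quality`, `mapping_quality`,
#'   `coverage`, `sample_id`; attribute `n_skipped_indels` carries the
#'   number of indel/symbolic alleles skipped.
#' @seealso [write_variant_vcf()] for the inverse operation.
#' @export
read_variant_records <- function(path, sample_id) {
  if (!file.exists(path)) stopf("VCF file not found: %s", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) {
    out <- empty_variant_table()
    setattr(out, "n_skipped_indels", 0L)
    return(out)
  }

  n_skipped <- 0L
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    info <- parse_info(fix[i, "INFO"], i)
    for (f in c("DP", "BQ", "MQ")) {
      if (is.na(info[[f]] %||% NA)) {
        stopf("malformed VCF record at data line %d: missing INFO/%s", i, f)
      }
    }
    ad <- strsplit(info[["AD"]] %||% "", ",", fixed = TRUE)[[1L]]
    if (length(ad) != length(alts)) {
      stopf("malformed VCF record at data line %d: INFO/AD has %d values for %d ALT alleles",
            i, length(ad), length(alts))
    }
    keep <- logical(length(alts))
    for (k in seq_along(alts)) {
      snv <- nchar(ref) == 1L && nchar(alts[k]) == 1L &&
        ref %in% BASES && alts[k] %in% BASES
      if (!snv) n_skipped <- n_skipped + 1L
      keep[k] <- snv
    }
    if (!any(keep)) next
    rows[[i]] <- data.table(
      chrom = fix[i, "CHROM"],
      pos = as.integer(fix[i, "POS"]),
      ref_base = ref,
      alt_base = alts[keep],
      n_alt_reads = as.integer(ad[keep]),
      base_quality = as.numeric(info[["BQ"]]),
      mapping_quality = as.numeric(info[["MQ"]]),
      coverage = as.integer(info[["DP"]]),
      sample_id = sample_id
    )
  }
  out <- rbindlist(rows)
  if (nrow(out) == 0L) out <- empty_variant_table()
  validate_variant_records(out)
  if (n_skipped > 0L) {
    message(sprintf("read_variant_records: skipped %d indel/symbolic allele(s) in %s",
                    n_skipped, basename(path)))
  }
  setattr(out, "n_skipped_indels", n_skipped)
  out[]
}

empty_variant_table <- function() {
  data.table(
    chrom = character(), pos = integer(), ref_base = character(),
    alt_base = character(), n_alt_reads = integer(),
    base_quality = numeric(), mapping_quality = numeric(),
    coverage = integer(), sample_id = character()
  )
}

parse_info <- function(info, line) {
  if (is.na(info) || info == "." || info == "") {
    stopf("malformed VCF record at data line %d: empty INFO field", line)
  }
  kv <- strsplit(strsplit(info, ";", fixed = TRUE)[[1L]], "=", fixed = TRUE)
  vals <- lapply(kv, function(x) if (length(x) == 2L) x[2L] else TRUE)
  names(vals) <- vapply(kv, `[`, "", 1L)
  vals
}

#' Validate a variant table against its type invariants
#'
#' Checks `ref_base != alt_base`, bases in `{A,C,G,T}`, `pos >= 1`,
#' `0 <= n_alt_reads <= coverage` and non-negative qualities.
#'
#' @param records a variant `data.table` as returned by
#'   [read_variant_records()].
#' @return `records`, invisibly; errors on the first violation.
#' @export
validate_variant_records <- function(records) {
  req <- c("chrom", "pos", "ref_base", "alt_base", "n_alt_reads",
           "base_quality", "mapping_quality", "coverage", "sample_id")
  miss <- setdiff(req, names(records))
  if (length(miss)) stopf("variant table missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(records) == 0L) return(invisible(records))
  if (!all(records$ref_base %in% BASES) || !all(records$alt_base %in% BASES)) {
    stopf("variant table contains non-ACGT bases")
  }
  if (any(records$ref_base == records$alt_base)) stopf("ref_base equals alt_base")
  if (any(records$pos < 1L)) stopf("positions must be 1-based (pos >= 1)")
  if (any(records$n_alt_reads < 0L) || any(records$coverage < 0L)) {
    stopf("read counts must be non-negative")
  }
  if (any(records$n_alt_reads > records$coverage)) {
    stopf("n_alt_reads exceeds coverage")
  }
  invisible(records)
}

#' Write variant records as a VCF v4.2 file
#'
#' One biallelic record per row; depth/quality metrics go to the INFO
#' column (`DP`, `AD`, `BQ`, `MQ`) in the encoding [read_variant_records()]
#' expects. Records are written sorted by (chrom, pos, ref, alt).
#'
#' @param records a validated variant table (single sample).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(records, path) {
  validate_variant_records(records)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth at the site\">",
    "##INFO=<ID=AD,Number=A,Type=Integer,Description=\"Read depth per ALT allele\">",
    "##INFO=<ID=BQ,Number=1,Type=Float,Description=\"Mean Phred base quality of mismatched reads\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mean Phred mapping quality\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  r <- as.data.table(records)
  setorder(r, chrom, pos, ref_base, alt_base)
  body <- if (nrow(r)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tDP=%d;AD=%d;BQ=%s;MQ=%s",
            r$chrom, r$pos, r$ref_base, r$alt_base,
            r$coverage, r$n_alt_reads,
            format(r$base_quality, trim = TRUE, scientific = FALSE),
            format(r$mapping_quality, trim = TRUE, scientific = FALSE))
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Variant catalogs (known DNA variants, curated editing positions)
# ---------------------------------------------------------------------------

#' Read a variant catalog (VCF or TSV)
#'
#' A catalog is a set of unique (chrom, pos, ref, alt) keys, e.g. a stand-in
#' for an exome-sequencing call set, a public SNP database, or a curated
#' editing-position database. Keying includes ref and alt — deliberately
#' stricter than position-only matching — so a T>C germline SNP does not
#' mask an A>G edit at the same locus. Duplicate entries collapse to one.
#'
#' Format is detected from the content: files whose first line starts with
#' `##fileformat=VCF` are parsed as VCF, anything else as a TSV with columns
#' `chrom`, `pos`, `ref`, `alt` (header required).
#'
#' @param path path to the catalog file.
#' @param source_label short label used in per-source removal counts
#'   (e.g. `"wes"`, `"snp-db"`, `"editing-db"`).
#' @return an object of class `catalog`: list with `keys` (character set)
#'   and `source_label`.
#' @export
read_catalog <- function(path, source_label) {
  if (!file.exists(path)) stopf("catalog file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) {
    warnf("catalog %s (%s) is empty", basename(path), source_label)
    return(new_catalog(character(), source_label))
  }
  if (startsWith(first, "##fileformat=VCF")) {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
    if (nrow(fix) == 0L) {
      warnf("catalog %s (%s) has no records", basename(path), source_label)
      return(new_catalog(character(), source_label))
    }
    ## split multiallelic ALT into one key per allele
    alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
    n <- lengths(alts)
    keys <- site_key(rep(fix[, "CHROM"], n), rep(as.integer(fix[, "POS"]), n),
                     rep(fix[, "REF"], n), unlist(alts))
  } else {
    tab <- fread(path, colClasses = list(character = "chrom"))
    req <- c("chrom", "pos", "ref", "alt")
    miss <- setdiff(req, names(tab))
    if (length(miss)) stopf("catalog TSV missing column(s): %s", paste(miss, collapse = ", "))
    if (nrow(tab) == 0L) {
      warnf("catalog %s (%s) has no records", basename(path), source_label)
      return(new_catalog(character(), source_label))
    }
    if (any(tab$pos < 1L)) stopf("catalog positions must be 1-based")
    keys <- site_key(tab$chrom, tab$pos, tab$ref, tab$alt)
  }
  new_catalog(keys, source_label)
}

#' Construct a catalog from site keys
#'
#' @param keys character vector of `"chrom:pos:ref>alt"` keys; duplicates
#'   collapse.
#' @param source_label short source label.
#' @return a `catalog` object.
#' @export
new_catalog <- function(keys, source_label) {
  structure(list(keys = unique(as.character(keys)), source_label = source_label),
            class = "catalog")
}

#' @exportS3Method base::print
print.catalog <- function(x, ...) {
  cat(sprintf("<catalog '%s': %d entries>\n", x$source_label, length(x$keys)))
  invisible(x)
}

#' Write a catalog as TSV or VCF
#'
#' @param catalog a `catalog` object.
#' @param path output path.
#' @param format `"tsv"` (columns chrom, pos, ref, alt) or `"vcf"`.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  tab <- parse_site_key(catalog$keys)
  setorder(tab, chrom, pos, ref_base, alt_base)
  if (format == "tsv") {
    setnames(tab, c("ref_base", "alt_base"), c("ref", "alt"))
    fwrite(tab, path, sep = "\t")
  } else {
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##source=%s", catalog$source_label),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- if (nrow(tab)) {
      sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
              tab$chrom, tab$pos, tab$ref_base, tab$alt_base)
    } else character()
    writeLines(c(hdr, body), path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Site observations (pileup TSV)
# ---------------------------------------------------------------------------

#' Read per-site, per-sample read-count observations
#'
#' The pileup table holds, for each candidate editing site and sample, the
#' number of reads carrying the edited base and the total reads covering the
#' site. Rows are preserved in file order.
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`, `sample`,
#'   `edited_reads`, `total_reads`.
#' @return a `data.table` with those columns plus a `site` key column.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stopf("pileup file not found: %s", path)
  obs <- fread(path, colClasses = list(character = c("chrom", "ref", "alt", "sample")))
  req <- c("chrom", "pos", "ref", "alt", "sample", "edited_reads", "total_reads")
  miss <- setdiff(req, names(obs))
  if (length(miss)) stopf("pileup missing column(s): %s", paste(miss, collapse = ", "))
  validate_observations(obs)
  obs[, site := site_key(chrom, pos, ref, alt)]
  obs[]
}

validate_observations <- function(obs) {
  if (nrow(obs) == 0L) return(invisible(obs))
  neg <- which(obs$edited_reads < 0L | obs$total_reads < 0L)
  if (length(neg)) stopf("negative read count at pileup row %d", neg[1L])
  bad <- which(obs$edited_reads > obs$total_reads)
  if (length(bad)) {
    stopf("edited_reads (%d) exceeds total_reads (%d) at pileup row %d",
          obs$edited_reads[bad[1L]], obs$total_reads[bad[1L]], bad[1L])
  }
  invisible(obs)
}

#' Write a pileup observation table
#'
#' @param obs observation `data.table` (the `site` key column, if present,
#'   is dropped on write and rebuilt on read).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  keep <- c("chrom", "pos", "ref", "alt", "sample", "edited_reads", "total_reads")
  validate_observations(obs)
  fwrite(as.data.table(obs)[, keep, with = FALSE], path, sep = "\t")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Sample sheet
# ---------------------------------------------------------------------------

#' Read the cohort sample sheet
#'
#' @param path TSV with columns `sample_id`, `group` (`case` or `control`)
#'   and optional `subtype`.
#' @return a `data.table`; errors on duplicate sample ids or unknown groups.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stopf("sample sheet not found: %s", path)
  sheet <- fread(path, colClasses = list(character = "sample_id"))
  req <- c("sample_id", "group")
  miss <- setdiff(req, names(sheet))
  if (length(miss)) stopf("sample sheet missing column(s): %s", paste(miss, collapse = ", "))
  validate_sample_sheet(sheet)
  sheet[]
}

validate_sample_sheet <- function(sheet) {
  if (anyDuplicated(sheet$sample_id)) stopf("duplicate sample_id in sample sheet")
  if (!all(sheet$group %in% c("case", "control"))) {
    stopf("sample sheet group must be 'case' or 'control'")
  }
  invisible(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet a sample-sheet `data.table`.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  fwrite(sheet, path, sep = "\t")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene model (GFF3) and repeat annotation (BED6)
# ---------------------------------------------------------------------------

#' Read the gene model and repeat annotation
#'
#' Gene features come from a GFF3 file whose records carry a `gene_id`
#' attribute and whose `type` is one of `five_prime_UTR`, `CDS`,
#' `three_prime_UTR`, `intron`, `ncRNA` (plain `exon` maps to `CDS`).
#' Repeat intervals come from a BED6 file whose name column is the repeat
#' family (`AluY`, `AluS`, `AluJ`, or `other-repeat`). BED 0-based
#' half-open coordinates are converted to 1-based inclusive on import.
#'
#' @param gff_path GFF3 gene-feature file.
#' @param repeats_path BED6 repeat file (optional; `NULL` for none).
#' @return an object of class `gene_model`: list with `genes` (a `GRanges`
#'   with `gene_id` and `feature` metadata) and `repeats` (a `GRanges` with
#'   `family`, possibly empty).
#' @export
read_gene_model <- function(gff_path, repeats_path = NULL) {
  if (!file.exists(gff_path)) stopf("gene model file not found: %s", gff_path)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  if (length(gr) == 0L) {
    repeats <- GenomicRanges::GRanges()
    return(structure(list(genes = GenomicRanges::GRanges(), repeats = repeats),
                     class = "gene_model"))
  }
  feat <- as.character(gr$type)
  map <- c(five_prime_UTR = "5UTR", CDS = "CDS", three_prime_UTR = "3UTR",
           intron = "intron", ncRNA = "ncRNA", exon = "CDS")
  unknown <- setdiff(unique(feat), names(map))
  if (length(unknown)) stopf("unsupported GFF3 feature type(s): %s", paste(unknown, collapse = ", "))
  genes <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::ranges(gr),
    strand = GenomicRanges::strand(gr),
    gene_id = as.character(gr$gene_id),
    feature = unname(map[feat])
  )
  repeats <- GenomicRanges::GRanges()
  if (!is.null(repeats_path) && file.size(repeats_path) > 0) {
    if (!file.exists(repeats_path)) stopf("repeat file not found: %s", repeats_path)
    rb <- rtracklayer::import(repeats_path, format = "bed")
    repeats <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(rb),
      ranges = IRanges::ranges(rb),
      family = as.character(rb$name)
    )
  }
  validate_gene_model(structure(list(genes = genes, repeats = repeats),
                                class = "gene_model"))
}

validate_gene_model <- function(model) {
  g <- model$genes
  if (length(g)) {
    if (any(!as.character(GenomicRanges::strand(g)) %in% c("+", "-"))) {
      stopf("gene intervals must be stranded (+/-)")
    }
    ## intervals of one gene share chrom and strand
    dt <- data.table(gene_id = g$gene_id,
                     chrom = as.character(GenomicRanges::seqnames(g)),
                     strand = as.character(GenomicRanges::strand(g)))
    bad <- dt[, .(n = uniqueN(paste(chrom, strand))), by = gene_id][n > 1L]
    if (nrow(bad)) stopf("gene %s spans multiple chromosomes or strands", bad$gene_id[1L])
  }
  model
}

#' @exportS3Method base::print
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model: %d gene intervals (%d genes), %d repeat intervals>\n",
              length(x$genes), length(unique(x$genes$gene_id)), length(x$repeats)))
  invisible(x)
}

#' Write a gene model to GFF3 (+ BED6 repeats)
#'
#' @param model a `gene_model`.
#' @param gff_path output GFF3 path.
#' @param repeats_path output BED6 path (skipped if `NULL`).
#' @return `gff_path`, invisibly.
#' @export
write_gene_model <- function(model, gff_path, repeats_path = NULL) {
  g <- model$genes
  if (length(g) == 0L) {
    writeLines("##gff-version 3", gff_path)
    if (!is.null(repeats_path)) writeLines(character(), repeats_path)
    return(invisible(gff_path))
  }
  inv <- c(`5UTR` = "five_prime_UTR", CDS = "CDS", `3UTR` = "three_prime_UTR",
           intron = "intron", ncRNA = "ncRNA")
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(g),
    ranges = IRanges::ranges(g),
    strand = GenomicRanges::strand(g)
  )
  out$source <- rep("editome", length(g))
  out$type <- unname(inv[g$feature])
  out$gene_id <- g$gene_id
  out$ID <- if (length(g)) paste0(g$gene_id, ":", seq_along(g)) else character()
  out$phase <- ifelse(out$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(out, gff_path, format = "gff3")
  if (!is.null(repeats_path)) {
    r <- model$repeats
    if (length(r) == 0L) {
      writeLines(character(), repeats_path)
      return(invisible(gff_path))
    }
    rb <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(r),
      ranges = IRanges::ranges(r)
    )
    rb$name <- r$family
    rb$score <- rep(0L, length(r))
    rtracklayer::export(rb, repeats_path, format = "bed")
  }
  invisible(gff_path)
}

# ---------------------------------------------------------------------------
# Editing matrix, DE table, survival table
# ---------------------------------------------------------------------------

#' Write / read an editing-level matrix as TSV
#'
#' Rows are site (or gene) keys, columns are samples; missing cells are
#' written as `NA`.
#'
#' @param mat numeric matrix with row and column names.
#' @param path file path.
#' @return `write_matrix_tsv`: `path` invisibly; `read_matrix_tsv`: the
#'   matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  dt <- data.table(key_ = rownames(mat))
  dt <- cbind(dt, as.data.table(mat))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  dt <- fread(path, colClasses = list(character = "key_"))
  m <- as.matrix(dt[, -1L])
  rownames(m) <- dt$key_
  m
}

#' Read a differential-expression table
#'
#' @param path TSV with columns `gene_id`, `log2_fold_change`, `adjusted_p`
#'   (knockdown vs control contrast).
#' @return a validated `data.table`.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stopf("DE table not found: %s", path)
  de <- fread(path, colClasses = list(character = "gene_id"))
  req <- c("gene_id", "log2_fold_change", "adjusted_p")
  miss <- setdiff(req, names(de))
  if (length(miss)) stopf("DE table missing column(s): %s", paste(miss, collapse = ", "))
  if (any(de$adjusted_p < 0 | de$adjusted_p > 1, na.rm = TRUE)) {
    stopf("adjusted_p outside [0, 1]")
  }
  de[]
}

#' Read a patient survival table
#'
#' @param path TSV with columns `patient_id`, `time` (> 0), `event` (0/1)
#'   and one expression column per gene.
#' @return a validated `data.table`.
#' @export
read_survival_table <- function(path) {
  if (!file.exists(path)) stopf("survival table not found: %s", path)
  surv <- fread(path, colClasses = list(character = "patient_id"))
  req <- c("patient_id", "time", "event")
  miss <- setdiff(req, names(surv))
  if (length(miss)) stopf("survival table missing column(s): %s", paste(miss, collapse = ", "))
  if (any(surv$time <= 0)) stopf("survival times must be positive")
  if (!all(surv$event %in% c(0L, 1L))) stopf("event must be 0 or 1")
  surv[]
}
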