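## Seeded generator of complete synthetic editing cohorts with ground truth.
##
## Generative model, per candidate site s and sample j:
##   coverage_sj ~ NegBin(mean, dispersion)
##   edited_sj   ~ Binomial(coverage_sj, rate_sj)
## with logit(rate_sj) = logit(base rate) + group/planted effects for true
## editing sites (base rates Beta-distributed across sites), and
## rate_sj ≈ genotype/2 (0, 0.5 or 1, plus small noise) for germline SNP
## contaminant sites — so quality filters alone cannot remove SNPs; only
## catalog subtraction can. Sequencing-error mismatches appear at separate
## error positions at a per-base error rate, uniformly across the 12
## substitution types, so the variant spectrum is A-to-G dominant but not
## A-to-G pure.

#' Configuration of a synthetic editing cohort
#'
#' Defaults emulate the reference study design: 31 case (tumor stem cell)
#' and 5 control (neural stem cell) samples, 5,000 candidate sites
#' (1,000 genes x 5 sites on average), Beta(2, 8) per-site editing rates,
#' negative-binomial coverage with mean 60, per-base error rate 0.002,
#' 15% germline-SNP contamination, Alu-dominant (AluS-heavy) repeat
#' context and 3'UTR/intron-heavy region context, and a mild global
#' elevation of editing in cases.
#'
#' @param seed integer master seed; all randomness derives from it through
#'   a fixed per-stream rule (see [derive_stream_seeds()]).
#' @param n_case,n_ctrl group sample counts.
#' @param n_genes number of genes; ~10% are ncRNA genes.
#' @param sites_per_gene average candidate sites per gene; total candidate
#'   sites = `n_genes * sites_per_gene`, allocated across regions.
#' @param rate_alpha,rate_beta Beta prior for per-site base editing rates.
#' @param coverage_mean,coverage_dispersion negative-binomial coverage
#'   (mean, size).
#' @param error_rate per-base probability of a non-edit mismatch at error
#'   positions.
#' @param snp_fraction fraction of candidate positions that are germline
#'   SNPs rather than true edits.
#' @param case_logit_shift global logit shift of case editing rates
#'   (0 = no group effect).
#' @param alu_fractions named proportions over
#'   `AluY, AluS, AluJ, other-repeat, nonrepetitive` (sum 1).
#' @param region_fractions named proportions over
#'   `5UTR, CDS, 3UTR, intron, ncRNA, intergenic` (sum 1).
#' @param planted_specific named numeric vector: gene id -> logit shift
#'   `d`, applied as +d/2 to case and -d/2 to control rates of that gene's
#'   sites. Planted genes draw base rates truncated at
#'   `specific_rate_cap` so the implied true specificity score is high
#'   regardless of where the Beta prior lands.
#' @param specific_rate_cap base-rate cap for planted-specific genes.
#' @param planted_target gene id receiving the knockdown-downregulation,
#'   editing-reduction, and survival-hazard signals (or `NULL`).
#' @param kd_log2fc_margin fold-change margin of the planted target in the
#'   knockdown DE table: log2FC = -log2(2 * margin).
#' @param kd_logit_drop logit drop of the planted target's editing rates in
#'   the knockdown pileup.
#' @param null_log2fc_sd SD of null-gene log2 fold changes.
#' @param n_patients,survival_beta,baseline_hazard,censor_rate survival
#'   generator: exponential baseline, per-gene log-hazard
#'   `survival_beta` (planted target only), independent censoring with the
#'   given probability.
#' @param n_error_sites number of error-only positions (default: same as
#'   the candidate-site count).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_case = 31L, n_ctrl = 5L,
                       n_genes = 1000L, sites_per_gene = 5L,
                       rate_alpha = 2, rate_beta = 8,
                       coverage_mean = 60, coverage_dispersion = 5,
                       error_rate = 0.002,
                       snp_fraction = 0.15,
                       case_logit_shift = 0.4,
                       alu_fractions = c(AluY = 0.15, AluS = 0.45, AluJ = 0.15,
                                         `other-repeat` = 0.05,
                                         nonrepetitive = 0.20),
                       region_fractions = c(`5UTR` = 0.05, CDS = 0.10,
                                            `3UTR` = 0.35, intron = 0.30,
                                            ncRNA = 0.08, intergenic = 0.12),
                       planted_specific = NULL,
                       specific_rate_cap = 0.25,
                       planted_target = NULL,
                       kd_log2fc_margin = 1.5,
                       kd_logit_drop = -2.5,
                       null_log2fc_sd = 0.5,
                       n_patients = 200L,
                       survival_beta = log(3),
                       baseline_hazard = 0.1,
                       censor_rate = 0.3,
                       n_error_sites = NULL) {
  cfg <- list(
    seed = as.integer(seed), n_case = as.integer(n_case),
    n_ctrl = as.integer(n_ctrl), n_genes = as.integer(n_genes),
    sites_per_gene = as.integer(sites_per_gene),
    rate_alpha = rate_alpha, rate_beta = rate_beta,
    coverage_mean = coverage_mean, coverage_dispersion = coverage_dispersion,
    error_rate = error_rate, snp_fraction = snp_fraction,
    case_logit_shift = case_logit_shift,
    alu_fractions = alu_fractions, region_fractions = region_fractions,
    planted_specific = planted_specific,
    specific_rate_cap = specific_rate_cap,
    planted_target = planted_target,
    kd_log2fc_margin = kd_log2fc_margin, kd_logit_drop = kd_logit_drop,
    null_log2fc_sd = null_log2fc_sd,
    n_patients = as.integer(n_patients), survival_beta = survival_beta,
    baseline_hazard = baseline_hazard, censor_rate = censor_rate,
    n_error_sites = n_error_sites
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_case < 1L || cfg$n_ctrl < 1L) stopf("need at least one sample per group")
  if (cfg$n_genes < 0L || cfg$sites_per_gene < 0L) stopf("negative size parameter")
  probs <- c(cfg$error_rate, cfg$snp_fraction, cfg$censor_rate)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  for (nm in c("alu_fractions", "region_fractions")) {
    f <- cfg[[nm]]
    if (any(f < 0) || abs(sum(f) - 1) > 1e-8) stopf("%s must be non-negative and sum to 1", nm)
  }
  if (cfg$rate_alpha <= 0 || cfg$rate_beta <= 0) stopf("Beta prior parameters must be positive")
  if (cfg$coverage_mean < 0 || cfg$coverage_dispersion <= 0) stopf("invalid coverage model")
  invisible(cfg)
}

#' Derive per-stream seeds from the master seed
#'
#' All generator stages draw from independent, reproducible streams:
#' `set.seed(master)` followed by `sample.int(2^31 - 2, 8)` yields the
#' stream seeds, in fixed order: (1) cohort structure, (2) true rates,
#' (3) read counts, (4) error mismatches, (5) catalogs, (6) knockdown,
#' (7) survival, (8) expression. Modules can therefore regenerate any
#' sub-stream independently.
#'
#' @param seed master integer seed.
#' @param n number of streams.
#' @return integer vector of stream seeds.
#' @export
derive_stream_seeds <- function(seed, n = 8L) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  sample.int(2147483646L, n)
}

GENE_BLOCK <- 20000L   # bp allocated per gene (gene body + gap)
GENE_BODY <- 10000L

## deterministic multinomial: largest-remainder apportionment of n over probs
apportion <- function(n, probs) {
  raw <- n * probs / sum(probs)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic editing cohort
#'
#' Builds the gene model, candidate sites (true edits + SNP contaminants),
#' per-sample coverage/edited-read counts, per-sample variant records
#' (including error mismatches at non-candidate positions), sample sheet,
#' per-sample enzyme/gene expression for correlation ranking, and the full
#' ground truth. Identical configs (including seed) reproduce identical
#' outputs.
#'
#' @param config a [sim_config()].
#' @return an object of class `editome_cohort`: list with `observations`
#'   (pileup `data.table`), `records` (variant table over all samples),
#'   `sheet`, `model` (a `gene_model`), `expression` (gene x sample
#'   matrix), `enzyme_expression` (named per-sample vector), and `truth`
#'   (list with `sites` table carrying per-group true rates and SNP
#'   status, `snp_keys`, `edit_keys`, `error_keys`, `planted_specific`
#'   with true specificity scores, `planted_target`, `config`).
#' @export
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  streams <- derive_stream_seeds(config$seed)

  ## ---- stream 1: cohort structure (genes, sites, context) ----
  set.seed(streams[1L])
  n_sites <- config$n_genes * config$sites_per_gene
  chroms <- paste0("chr", 1:4)

  gene_ids <- if (config$n_genes) sprintf("g%04d", seq_len(config$n_genes)) else character()
  n_nc <- if (config$n_genes) max(round(config$n_genes * 0.1), as.integer(config$region_fractions[["ncRNA"]] > 0)) else 0L
  is_nc_gene <- seq_len(config$n_genes) > (config$n_genes - n_nc)
  gene_chrom <- chroms[((seq_len(config$n_genes) - 1L) %% length(chroms)) + 1L]
  block_idx <- (seq_len(config$n_genes) - 1L) %/% length(chroms)
  gene_start <- 1L + block_idx * GENE_BLOCK
  gene_strand <- ifelse(seq_len(config$n_genes) %% 2L == 0L, "-", "+")

  model <- build_sim_gene_model(gene_ids, gene_chrom, gene_start, gene_strand, is_nc_gene)

  sites <- allocate_sites(config, n_sites, gene_ids, gene_chrom, gene_start,
                          gene_strand, is_nc_gene)

  ## ---- stream 2: true rates ----
  set.seed(streams[2L])
  sites <- assign_true_rates(sites, config)

  sheet <- data.table(
    sample_id = c(sprintf("case%02d", seq_len(config$n_case)),
                  sprintf("ctrl%02d", seq_len(config$n_ctrl))),
    group = c(rep("case", config$n_case), rep("control", config$n_ctrl)),
    subtype = c(rep(c("proneural", "classical", "mesenchymal"),
                    length.out = config$n_case),
                rep(NA_character_, config$n_ctrl))
  )

  ## ---- stream 3: read counts + pileup + edit/SNP variant records ----
  set.seed(streams[3L])
  counts <- draw_counts(sites, sheet, config)

  ## ---- stream 4: error mismatch records ----
  set.seed(streams[4L])
  n_err <- config$n_error_sites %||% n_sites
  err <- draw_error_records(config, sheet, gene_chrom, gene_start, n_err)

  records <- rbindlist(list(counts$records, err$records))
  setorder(records, sample_id, chrom, pos, ref_base, alt_base)

  ## ---- stream 8: expression for correlation ranking ----
  set.seed(streams[8L])
  expr <- draw_expression(sites, counts$observations, sheet, config)

  truth <- list(
    sites = sites,
    snp_keys = sites[is_snp == TRUE, site],
    edit_keys = sites[is_snp == FALSE, site],
    error_keys = err$keys,
    planted_specific = planted_specific_truth(sites, config),
    planted_target = config$planted_target,
    config = config
  )
  structure(list(observations = counts$observations, records = records,
                 sheet = sheet, model = model,
                 expression = expr$expression,
                 enzyme_expression = expr$enzyme,
                 truth = truth),
            class = "editome_cohort")
}

#' @exportS3Method base::print
print.editome_cohort <- function(x, ...) {
  cat(sprintf("<editome_cohort: %d sites x %d samples (%d case / %d control), %d variant records>\n",
              nrow(x$truth$sites), nrow(x$sheet),
              sum(x$sheet$group == "case"), sum(x$sheet$group == "control"),
              nrow(x$records)))
  invisible(x)
}

build_sim_gene_model <- function(gene_ids, gene_chrom, gene_start, gene_strand,
                                 is_nc_gene) {
  n <- length(gene_ids)
  if (n == 0L) {
    return(structure(list(genes = GenomicRanges::GRanges(),
                          repeats = GenomicRanges::GRanges()),
                     class = "gene_model"))
  }
  ## coding layout within the 10 kb body: 5UTR 0.5k | CDS 2k | intron 3.5k | 3UTR 4k
  feats <- list(`5UTR` = c(0L, 499L), CDS = c(500L, 2499L),
                intron = c(2500L, 5999L), `3UTR` = c(6000L, 9999L))
  rows <- list()
  for (i in seq_len(n)) {
    if (is_nc_gene[i]) {
      rows[[i]] <- data.table(chrom = gene_chrom[i], start = gene_start[i],
                              end = gene_start[i] + GENE_BODY - 1L,
                              strand = gene_strand[i], gene_id = gene_ids[i],
                              feature = "ncRNA")
    } else {
      rows[[i]] <- data.table(chrom = gene_chrom[i],
                              start = gene_start[i] + vapply(feats, `[`, 0L, 1L),
                              end = gene_start[i] + vapply(feats, `[`, 0L, 2L),
                              strand = gene_strand[i], gene_id = gene_ids[i],
                              feature = names(feats))
    }
  }
  tab <- rbindlist(rows)
  genes <- GenomicRanges::GRanges(tab$chrom,
                                  IRanges::IRanges(tab$start, tab$end),
                                  strand = tab$strand,
                                  gene_id = tab$gene_id, feature = tab$feature)
  structure(list(genes = genes, repeats = GenomicRanges::GRanges()),
            class = "gene_model")
}

## Allocate candidate sites to regions/genes, assign positions, strand,
## ref/alt orientation, repeat family, and SNP status. Repeat intervals are
## added to the model afterwards (width-1 at each site).
allocate_sites <- function(config, n_sites, gene_ids, gene_chrom, gene_start,
                           gene_strand, is_nc_gene) {
  if (n_sites == 0L) {
    return(data.table(site = character(), chrom = character(), pos = integer(),
                      ref_base = character(), alt_base = character(),
                      strand = character(), gene_id = character(),
                      region = character(), repeat_family = character(),
                      is_snp = logical(), snp_af = numeric()))
  }
  region_offsets <- list(`5UTR` = c(0L, 499L), CDS = c(500L, 2499L),
                         intron = c(2500L, 5999L), `3UTR` = c(6000L, 9999L),
                         ncRNA = c(0L, GENE_BODY - 1L),
                         intergenic = c(12000L, 18999L))
  n_per_region <- apportion(n_sites, config$region_fractions)
  names(n_per_region) <- names(config$region_fractions)
  coding <- which(!is_nc_gene); nc <- which(is_nc_gene)
  if (length(nc) == 0L) {  # no ncRNA genes: fold ncRNA quota into introns
    n_per_region[["intron"]] <- n_per_region[["intron"]] + n_per_region[["ncRNA"]]
    n_per_region[["ncRNA"]] <- 0L
  }

  rows <- list()
  for (reg in names(n_per_region)) {
    k <- n_per_region[[reg]]
    if (k == 0L) next
    host <- switch(reg, ncRNA = nc, intergenic = seq_along(gene_ids), coding)
    g <- host[(seq_len(k) - 1L) %% length(host) + 1L]
    off <- region_offsets[[reg]]
    ## distinct positions within each host interval
    dt <- data.table(gidx = g, region = reg)
    dt[, pos := gene_start[gidx] + sample.int(off[2L] - off[1L] + 1L, .N) + off[1L] - 1L,
       by = gidx]
    dt[, chrom := gene_chrom[gidx]]
    dt[, gene_id := if (reg == "intergenic") NA_character_ else gene_ids[gidx]]
    dt[, strand := if (reg == "intergenic") "unknown" else gene_strand[gidx]]
    rows[[reg]] <- dt[, .(chrom, pos, gene_id, strand, region)]
  }
  sites <- rbindlist(rows)
  ## transcript-oriented A>G: genomic A>G on + / unknown, T>C on -
  sites[, ref_base := fifelse(strand == "-", "T", "A")]
  sites[, alt_base := fifelse(strand == "-", "C", "G")]
  sites[, repeat_family := sample(names(config$alu_fractions), .N, replace = TRUE,
                                  prob = config$alu_fractions)]
  sites[, is_snp := runif(.N) < config$snp_fraction]
  sites[, snp_af := fifelse(is_snp, runif(.N, 0.2, 0.8), NA_real_)]
  sites[, site := site_key(chrom, pos, ref_base, alt_base)]
  setorder(sites, chrom, pos)
  setcolorder(sites, c("site", "chrom", "pos", "ref_base", "alt_base", "strand",
                       "gene_id", "region", "repeat_family", "is_snp", "snp_af"))
  sites
}

## Add width-1 repeat intervals at each repetitive site to the model.
add_repeat_intervals <- function(model, sites) {
  rep_sites <- sites[repeat_family != "nonrepetitive"]
  repeats <- if (nrow(rep_sites)) {
    GenomicRanges::GRanges(rep_sites$chrom,
                           IRanges::IRanges(rep_sites$pos, rep_sites$pos),
                           family = rep_sites$repeat_family)
  } else GenomicRanges::GRanges()
  model$repeats <- repeats
  model
}

assign_true_rates <- function(sites, config) {
  n <- nrow(sites)
  if (n == 0L) {
    sites[, `:=`(rate_case = numeric(), rate_ctrl = numeric())]
    return(sites)
  }
  base <- rbeta(n, config$rate_alpha, config$rate_beta)
  shifts <- rep(0, n)
  if (!is.null(config$planted_specific) && length(config$planted_specific)) {
    planted <- names(config$planted_specific)
    idx <- which(sites$gene_id %in% planted)
    if (length(idx)) {
      ## planted genes: truncate base rates so the implied score is high
      redraw <- idx[base[idx] > config$specific_rate_cap]
      while (length(redraw)) {
        base[redraw] <- rbeta(length(redraw), config$rate_alpha, config$rate_beta)
        redraw <- redraw[base[redraw] > config$specific_rate_cap]
      }
      shifts[idx] <- config$planted_specific[sites$gene_id[idx]]
    }
  }
  lg <- qlogis(base)
  sites[, rate_ctrl := plogis(lg - shifts / 2)]
  sites[, rate_case := plogis(lg + shifts / 2 + config$case_logit_shift)]
  sites[is_snp == TRUE, `:=`(rate_case = NA_real_, rate_ctrl = NA_real_)]
  sites[]
}

planted_specific_truth <- function(sites, config) {
  if (is.null(config$planted_specific) || !length(config$planted_specific)) {
    return(data.table(gene_id = character(), logit_shift = numeric(),
                      true_score = numeric()))
  }
  g <- sites[gene_id %in% names(config$planted_specific) & is_snp == FALSE,
             .(mc = mean(rate_case), mn = mean(rate_ctrl)), by = gene_id]
  data.table(gene_id = g$gene_id,
             logit_shift = unname(config$planted_specific[g$gene_id]),
             true_score = g$mc / (g$mc + g$mn))
}

## Per-sample coverage and edited-read draws -> pileup + variant records.
draw_counts <- function(sites, sheet, config, rate_cols = c("rate_case", "rate_ctrl"),
                        extra_logit = NULL) {
  n <- nrow(sites)
  obs_list <- vector("list", nrow(sheet))
  rec_list <- vector("list", nrow(sheet))
  for (j in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[j]
    grp <- sheet$group[j]
    cov <- rnbinom(n, size = config$coverage_dispersion, mu = config$coverage_mean)
    rate <- if (grp == "case") sites[[rate_cols[1L]]] else sites[[rate_cols[2L]]]
    if (!is.null(extra_logit)) {
      shift <- extra_logit[sites$gene_id]
      shift[is.na(shift)] <- 0
      rate <- plogis(qlogis(pmin(pmax(rate, 1e-6), 1 - 1e-6)) + shift)
    }
    if (n && any(sites$is_snp)) {
      snp_idx <- which(sites$is_snp)
      gt <- rbinom(length(snp_idx), 2L, sites$snp_af[snp_idx]) / 2
      frac <- pmin(pmax(gt + rnorm(length(snp_idx), 0, 0.01), 0), 1)
      rate[snp_idx] <- frac
    }
    edited <- if (n) rbinom(n, cov, rate) else integer()
    obs_list[[j]] <- data.table(chrom = sites$chrom, pos = sites$pos,
                                ref = sites$ref_base, alt = sites$alt_base,
                                sample = sid,
                                edited_reads = edited, total_reads = cov)
    has <- which(edited >= 1L)
    rec_list[[j]] <- data.table(
      chrom = sites$chrom[has], pos = sites$pos[has],
      ref_base = sites$ref_base[has], alt_base = sites$alt_base[has],
      n_alt_reads = edited[has],
      base_quality = round(pmax(rnorm(length(has), 34, 4), 2), 1),
      mapping_quality = round(pmax(rnorm(length(has), 42, 9), 1), 1),
      coverage = cov[has], sample_id = sid
    )
  }
  obs <- rbindlist(obs_list)
  if (nrow(obs)) obs[, site := site_key(chrom, pos, ref, alt)]
  else obs[, site := character()]
  list(observations = obs[], records = rbindlist(rec_list))
}

## Error positions live in the inter-gene gaps; substitution type is fixed
## per position, drawn uniformly over the 12 types.
draw_error_records <- function(config, sheet, gene_chrom, gene_start, n_err) {
  if (n_err == 0L || length(gene_start) == 0L || config$error_rate == 0) {
    return(list(records = empty_variant_table(), keys = character()))
  }
  host <- (seq_len(n_err) - 1L) %% length(gene_start) + 1L
  dt <- data.table(gidx = host)
  dt[, pos := gene_start[gidx] + 10000L + sample.int(1500L, .N), by = gidx]
  ref <- sample(BASES, n_err, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), "")
  err_sites <- data.table(chrom = gene_chrom[dt$gidx], pos = dt$pos,
                          ref_base = ref, alt_base = unname(alt))
  rec_list <- vector("list", nrow(sheet))
  for (j in seq_len(nrow(sheet))) {
    cov <- rnbinom(n_err, size = config$coverage_dispersion, mu = config$coverage_mean)
    nerr <- rbinom(n_err, cov, config$error_rate)
    has <- which(nerr >= 1L)
    rec_list[[j]] <- data.table(
      chrom = err_sites$chrom[has], pos = err_sites$pos[has],
      ref_base = err_sites$ref_base[has], alt_base = err_sites$alt_base[has],
      n_alt_reads = nerr[has],
      base_quality = round(pmax(rnorm(length(has), 30, 5), 2), 1),
      mapping_quality = round(pmax(rnorm(length(has), 40, 10), 1), 1),
      coverage = cov[has], sample_id = sheet$sample_id[j]
    )
  }
  list(records = rbindlist(rec_list),
       keys = site_key(err_sites$chrom, err_sites$pos, err_sites$ref_base,
                       err_sites$alt_base))
}

## Enzyme expression tracks each sample's overall editing level; the
## planted target's own expression tracks its gene editing level. Null
## genes are independent noise.
draw_expression <- function(sites, observations, sheet, config) {
  samples <- sheet$sample_id
  genes <- sort(unique(stats::na.omit(sites$gene_id)))
  expr <- matrix(rnorm(length(genes) * length(samples)),
                 nrow = length(genes), ncol = length(samples),
                 dimnames = list(genes, samples))
  ## editing tracked at true edit sites only: germline SNP fractions are not
  ## editing and would dilute the planted expression-editing correlations
  edit_keys <- sites[is_snp == FALSE, site]
  observations <- observations[site %in% edit_keys]
  if (nrow(observations)) {
    overall <- observations[, .(lvl = sum(edited_reads) / pmax(sum(total_reads), 1L)),
                            by = sample]
    z <- scale(overall$lvl[match(samples, overall$sample)])[, 1L]
    z[is.na(z)] <- 0
    enzyme <- z + rnorm(length(samples), 0, 0.3)
  } else {
    enzyme <- rnorm(length(samples))
  }
  names(enzyme) <- samples
  tgt <- config$planted_target
  if (!is.null(tgt) && tgt %in% genes && nrow(observations)) {
    map <- sites[!is.na(gene_id) & gene_id == tgt & is_snp == FALSE, site]
    gl <- observations[site %in% map,
                       .(lvl = sum(edited_reads) / pmax(sum(total_reads), 1L)),
                       by = sample]
    zg <- scale(gl$lvl[match(samples, gl$sample)])[, 1L]
    zg[is.na(zg)] <- 0
    expr[tgt, ] <- zg + rnorm(length(samples), 0, 0.3)
  }
  list(expression = expr, enzyme = enzyme)
}

#' Generate stand-in variant catalogs from cohort ground truth
#'
#' The exome (`wes`) and public SNP (`snp-db`) catalogs contain exactly the
#' germline SNP keys of the cohort (each subject to an independent miss
#' rate); the curated editing catalog (`editing-db`) contains all true
#' editing-site keys, plus decoy positions never observed in the cohort,
#' plus (by default) the SNP keys — mirroring the fact that curated editing
#' databases contain positions that are polymorphic in some genomes, which
#' is what makes DNA-variant subtraction a necessary stage.
#'
#' @param config the cohort's [sim_config()].
#' @param truth `truth` element of [generate_cohort()] output.
#' @param miss_rate per-key probability that a SNP key is absent from each
#'   DNA catalog (default 0).
#' @param n_decoys number of decoy editing-catalog keys.
#' @param decoy_snps include the SNP keys in the editing catalog
#'   (default `TRUE`).
#' @return list of three `catalog`s: `wes`, `snp_db`, `editing_db`.
#' @export
generate_catalogs <- function(config, truth, miss_rate = 0, n_decoys = 200L,
                              decoy_snps = TRUE) {
  streams <- derive_stream_seeds(config$seed)
  set.seed(streams[5L])
  keep <- function(keys) keys[runif(length(keys)) >= miss_rate]
  wes <- new_catalog(keep(truth$snp_keys), "wes")
  snp_db <- new_catalog(keep(truth$snp_keys), "snp-db")
  decoys <- if (n_decoys > 0L) {
    site_key("chrD", seq_len(n_decoys) * 10L, "A", "G")
  } else character()
  ed_keys <- c(truth$edit_keys, decoys, if (decoy_snps) truth$snp_keys)
  list(wes = wes, snp_db = snp_db,
       editing_db = new_catalog(ed_keys, "editing-db"))
}

#' Generate the knockdown experiment: DE table and knockdown pileup
#'
#' The planted target gene receives `log2FC = -log2(2 * margin)` with a
#' small adjusted P in the DE table, and a drop of `kd_logit_drop` on the
#' logit of its sites' editing rates in a freshly drawn knockdown pileup
#' (case samples only, matching a knockdown performed in the case cells).
#' Null genes receive `log2FC ~ Normal(0, sd)` and `adjusted_p ~ Uniform`.
#'
#' @param config the cohort's [sim_config()] (with `planted_target` set,
#'   or `NULL` for a fully null experiment).
#' @param truth cohort ground truth.
#' @return list with `de` (DE `data.table`) and `observations_kd`
#'   (knockdown pileup for the case samples).
#' @export
generate_knockdown <- function(config, truth) {
  streams <- derive_stream_seeds(config$seed)
  set.seed(streams[6L])
  genes <- sort(unique(stats::na.omit(truth$sites$gene_id)))
  de <- data.table(
    gene_id = genes,
    log2_fold_change = rnorm(length(genes), 0, config$null_log2fc_sd),
    adjusted_p = runif(length(genes))
  )
  tgt <- config$planted_target
  drop_map <- setNames(numeric(0), character(0))
  if (!is.null(tgt)) {
    if (!tgt %in% genes) stopf("planted target '%s' is not a gene of the cohort", tgt)
    de[gene_id == tgt,
       `:=`(log2_fold_change = -log2(2 * config$kd_log2fc_margin),
            adjusted_p = 0.001)]
    drop_map <- setNames(config$kd_logit_drop, tgt)
  }
  case_sheet <- data.table(sample_id = sprintf("case%02d", seq_len(config$n_case)),
                           group = rep("case", config$n_case))
  counts <- draw_counts(truth$sites, case_sheet, config,
                        extra_logit = if (length(drop_map)) drop_map else NULL)
  list(de = de[], observations_kd = counts$observations)
}

#' Generate a patient expression-survival table
#'
#' `n_patients` patients with one standard-normal expression value per
#' gene; survival times are exponential with log-hazard
#' `survival_beta * expression` for the planted target and 0 for every
#' other gene; censoring is independent with probability `censor_rate`
#' (a censored patient's observed time is uniform on (0, t)).
#'
#' @param config the cohort's [sim_config()].
#' @param truth cohort ground truth.
#' @param genes gene ids to include (default: all cohort genes).
#' @return a survival `data.table` (`patient_id`, `time`, `event`, one
#'   column per gene).
#' @export
generate_survival <- function(config, truth, genes = NULL) {
  streams <- derive_stream_seeds(config$seed)
  set.seed(streams[7L])
  if (is.null(genes)) genes <- sort(unique(stats::na.omit(truth$sites$gene_id)))
  n <- config$n_patients
  expr <- matrix(rnorm(n * length(genes)), nrow = n,
                 dimnames = list(NULL, genes))
  loghaz <- rep(0, n)
  tgt <- config$planted_target
  if (!is.null(tgt) && tgt %in% genes) {
    loghaz <- config$survival_beta * expr[, tgt]
  }
  t_event <- rexp(n, rate = config$baseline_hazard * exp(loghaz))
  censored <- runif(n) < config$censor_rate
  obs_time <- ifelse(censored, t_event * runif(n), t_event)
  obs_time <- pmax(obs_time, 1e-6)
  out <- data.table(patient_id = sprintf("pt%03d", seq_len(n)),
                    time = obs_time, event = as.integer(!censored))
  cbind(out, as.data.table(expr))
}

#' Write a cohort bundle to disk
#'
#' Emits `pileup.tsv`, `samples.tsv`, `genes.gff3`, `repeats.bed`, one VCF
#' per sample under `vcf/`, and `truth.json`. Together with the catalog,
#' knockdown and survival writers this is the full input bundle for every
#' downstream analysis step. Identical cohorts produce byte-identical
#' bundles.
#'
#' @param cohort an `editome_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "vcf"), showWarnings = FALSE)
  write_observations(cohort$observations, file.path(dir, "pileup.tsv"))
  write_sample_sheet(cohort$sheet, file.path(dir, "samples.tsv"))
  model <- add_repeat_intervals(cohort$model, cohort$truth$sites)
  write_gene_model(model, file.path(dir, "genes.gff3"),
                   file.path(dir, "repeats.bed"))
  for (sid in cohort$sheet$sample_id) {
    write_variant_vcf(cohort$records[sample_id == sid],
                      file.path(dir, "vcf", paste0(sid, ".vcf")))
  }
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Annotated gene model of a cohort (gene features + site repeat intervals)
#'
#' @param cohort an `editome_cohort`.
#' @return a `gene_model` whose repeat track covers the cohort's
#'   repetitive sites.
#' @export
cohort_gene_model <- function(cohort) {
  add_repeat_intervals(cohort$model, cohort$truth$sites)
}
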