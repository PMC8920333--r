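## Independent brute-force oracles used by the unit and acceptance tests.
## Deliberately written in plain base R, without calling the package's own
## cascade/statistics code paths.

## Full discovery cascade by plain set arithmetic on (chrom,pos,ref,alt) keys.
## A site key survives the quality stage if ANY of its records passes the
## per-record predicate.
oracle_discovery <- function(records, catalogs, editing_catalog, observations,
                             min_alt = 1, min_bq = 25, min_mq = 20,
                             min_cov = 10, min_samples = 10) {
  key <- paste0(records$chrom, ":", records$pos, ":",
                records$ref_base, ">", records$alt_base)
  pass <- records$n_alt_reads >= min_alt &
    records$base_quality >= min_bq &
    records$mapping_quality >= min_mq &
    records$coverage >= min_cov
  k1 <- unique(key[pass])
  dna <- unique(unlist(lapply(catalogs, function(cat) cat$keys)))
  k2 <- setdiff(k1, dna)
  k3 <- intersect(k2, editing_catalog$keys)
  okey <- paste0(observations$chrom, ":", observations$pos, ":",
                 observations$ref, ">", observations$alt)
  covered <- observations$total_reads >= min_cov
  n_per_site <- tapply(observations$sample[covered], okey[covered],
                       function(s) length(unique(s)))
  informative <- names(n_per_site)[n_per_site >= min_samples]
  sort(intersect(k3, informative))
}

## Exact two-sided signed-rank p by enumeration of all 2^n sign assignments.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p_le <- mean(vs <= v_obs)
  p_ge <- mean(vs >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

## Log-rank chi-square from the 2x2 risk tables at each death time.
oracle_logrank_chisq <- function(time, event, group1) {
  dt <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in dt) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & group1)
    d_t <- sum(time == t & event == 1)
    o1_t <- sum(time == t & event == 1 & group1)
    e1_t <- d_t * n1_t / n_t
    o_minus_e <- o_minus_e + (o1_t - e1_t)
    if (n_t > 1) {
      v <- v + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  if (v == 0) return(0)
  o_minus_e^2 / v
}

## Masked group means by explicit per-row loops.
oracle_group_means <- function(levels, groups, min_samples = 2) {
  t(apply(levels, 1, function(row) {
    out <- c(NA_real_, NA_real_)
    for (g in 1:2) {
      vals <- row[groups == c("case", "control")[g]]
      vals <- vals[!is.na(vals)]
      if (length(vals) >= min_samples) out[g] <- mean(vals)
    }
    out
  }))
}

## Interval annotation by linear scan (region priority 3UTR > 5UTR > CDS >
## ncRNA > intron; intergenic if nothing overlaps).
oracle_annotate <- function(chrom, pos, feat_tab, rep_tab = NULL) {
  prio <- c("3UTR", "5UTR", "CDS", "ncRNA", "intron")
  n <- length(pos)
  region <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  fam <- rep("nonrepetitive", n)
  for (i in seq_len(n)) {
    hits <- which(feat_tab$chrom == chrom[i] & feat_tab$start <= pos[i] &
                    feat_tab$end >= pos[i])
    if (length(hits)) {
      ord <- hits[order(match(feat_tab$feature[hits], prio), feat_tab$gene_id[hits])]
      region[i] <- feat_tab$feature[ord[1]]
      gene[i] <- feat_tab$gene_id[ord[1]]
    }
    if (!is.null(rep_tab)) {
      rh <- which(rep_tab$chrom == chrom[i] & rep_tab$start <= pos[i] &
                    rep_tab$end >= pos[i])
      if (length(rh)) fam[i] <- rep_tab$family[rh[1]]
    }
  }
  data.frame(region = region, gene_id = gene, repeat_family = fam,
             stringsAsFactors = FALSE)
}

## Random variant-record table for fuzz tests.
random_records <- function(n, seed = 1) {
  set.seed(seed)
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  cov <- sample(0:40, n, replace = TRUE)
  data.table::data.table(
    chrom = sample(paste0("chr", 1:3), n, replace = TRUE),
    pos = sample.int(1e6, n),
    ref_base = ref, alt_base = unname(alt),
    n_alt_reads = pmin(sample(0:15, n, replace = TRUE), cov),
    base_quality = round(runif(n, 10, 40), 1),
    mapping_quality = round(runif(n, 5, 60), 1),
    coverage = cov,
    sample_id = sample(sprintf("s%02d", 1:12), n, replace = TRUE)
  )
}

## Small deterministic two-gene model used across tests.
toy_gene_model <- function() {
  tmp_gff <- tempfile(fileext = ".gff3")
  tmp_bed <- tempfile(fileext = ".bed")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tfive_prime_UTR\t100\t199\t.\t+\t.\tID=gA:1;gene_id=gA",
    "chr1\ttest\tCDS\t200\t499\t.\t+\t.\tID=gA:2;gene_id=gA",
    "chr1\ttest\tintron\t500\t799\t.\t+\t.\tID=gA:3;gene_id=gA",
    "chr1\ttest\tthree_prime_UTR\t800\t999\t.\t+\t.\tID=gA:4;gene_id=gA",
    "chr1\ttest\tncRNA\t2000\t2499\t.\t-\t.\tID=gB:1;gene_id=gB"
  ), tmp_gff)
  ## BED is 0-based half-open: covers 1-based [301, 400] and [2101, 2200]
  writeLines(c("chr1\t300\t400\tAluS\t0\t+",
               "chr1\t2100\t2200\tAluJ\t0\t-"), tmp_bed)
  read_gene_model(tmp_gff, tmp_bed)
}
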