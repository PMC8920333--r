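test_that("substitution types are labeled in transcript orientation", {
  expect_equal(classify_variant_type("A", "G", "+"), "A-to-G")
  expect_equal(classify_variant_type("T", "C", "-"), "A-to-G")
  expect_equal(classify_variant_type("C", "T", "+"), "C-to-T")
  expect_equal(classify_variant_type("G", "A", "-"), "C-to-T")
  expect_equal(classify_variant_type("T", "C", "unknown"), "T-to-C")
  expect_error(classify_variant_type("N", "G", "+"), "non-ACGT")
  expect_error(classify_variant_type("A", "A", "+"), "equals")
  expect_length(variant_type_levels(), 12L)
})

test_that("variant spectrum counts every record once, in transcript orientation", {
  model <- toy_gene_model()
  sheet <- data.table::data.table(sample_id = c("s1", "s2"),
                                  group = c("case", "control"))
  ## 10 A>G records inside gene gA (+ strand)
  rec <- data.table::data.table(
    chrom = "chr1", pos = 200:209, ref_base = "A", alt_base = "G",
    n_alt_reads = 2L, base_quality = 30, mapping_quality = 40,
    coverage = 20L, sample_id = rep(c("s1", "s2"), 5)
  )
  tab <- tabulate_variant_types(rec, model, sheet)
  expect_equal(sum(tab$per_sample), 10)
  expect_equal(unname(tab$per_sample["s1", "A-to-G"]), 5)
  expect_equal(sum(tab$per_sample[, setdiff(colnames(tab$per_sample), "A-to-G")]), 0)

  ## T>C inside gB (- strand) also reads A-to-G
  rec2 <- data.table::data.table(
    chrom = "chr1", pos = 2100L, ref_base = "T", alt_base = "C",
    n_alt_reads = 1L, base_quality = 30, mapping_quality = 40,
    coverage = 15L, sample_id = "s1"
  )
  tab2 <- tabulate_variant_types(rec2, model, sheet)
  expect_equal(unname(tab2$per_sample["s1", "A-to-G"]), 1)

  ## rows sum to per-sample record counts
  expect_equal(rowSums(tab$per_sample), c(s1 = 5, s2 = 5))

  ## empty record list -> all-zero table
  tab0 <- tabulate_variant_types(rec[0], model, sheet)
  expect_true(all(tab0$per_sample == 0))

  ## sample absent from sheet -> error
  rec3 <- data.table::copy(rec2)[, sample_id := "ghost"]
  expect_error(tabulate_variant_types(rec3, model, sheet), "absent")
})

test_that("quality filter boundaries are inclusive and match brute force", {
  base <- data.table::data.table(
    chrom = "chr1", pos = 1L, ref_base = "A", alt_base = "G",
    n_alt_reads = 5L, base_quality = 30, mapping_quality = 40,
    coverage = 20L, sample_id = "s1"
  )
  low_cov <- data.table::copy(base)[, coverage := 9L]
  expect_equal(nrow(apply_quality_filters(low_cov)), 0L)
  at_cov <- data.table::copy(base)[, coverage := 10L]
  expect_equal(nrow(apply_quality_filters(at_cov)), 1L)
  at_bq <- data.table::copy(base)[, base_quality := 25]
  expect_equal(nrow(apply_quality_filters(at_bq)), 1L)
  below_bq <- data.table::copy(base)[, base_quality := 24.9]
  expect_equal(nrow(apply_quality_filters(below_bq)), 0L)
  at_mq <- data.table::copy(base)[, mapping_quality := 20]
  expect_equal(nrow(apply_quality_filters(at_mq)), 1L)
  no_alt <- data.table::copy(base)[, n_alt_reads := 0L]
  expect_equal(nrow(apply_quality_filters(no_alt)), 0L)

  ## 200 fuzzed records vs explicit per-record predicate loop
  rec <- random_records(200, seed = 21)
  th <- filter_thresholds()
  got <- apply_quality_filters(rec, th)
  keep <- vapply(seq_len(nrow(rec)), function(i) {
    rec$n_alt_reads[i] >= 1 && rec$base_quality[i] >= 25 &&
      rec$mapping_quality[i] >= 20 && rec$coverage[i] >= 10
  }, logical(1))
  expect_equal(as.data.frame(got), as.data.frame(rec[keep]))
})

test_that("DNA-variant subtraction removes by full key and reports per source", {
  rec <- data.table::data.table(
    chrom = "chr1", pos = c(10L, 10L, 20L), ref_base = c("A", "T", "A"),
    alt_base = c("G", "C", "G"), n_alt_reads = 3L, base_quality = 30,
    mapping_quality = 40, coverage = 20L, sample_id = "s1"
  )
  wes <- new_catalog("chr1:10:A>G", "wes")
  out <- subtract_known_dna_variants(rec, list(wes))
  ## same position, different substitution survives: keying includes ref/alt
  expect_equal(nrow(out), 2L)
  expect_true("chr1:10:T>C" %in% site_key(out$chrom, out$pos, out$ref_base, out$alt_base))
  expect_equal(attr(out, "removed_by_source"), c(wes = 1L))

  ## 500 fuzzed records vs 3 catalogs equals brute-force set difference
  rec2 <- random_records(500, seed = 31)
  keys <- site_key(rec2$chrom, rec2$pos, rec2$ref_base, rec2$alt_base)
  cats <- list(new_catalog(sample(keys, 80), "wes"),
               new_catalog(sample(keys, 50), "snp-db"),
               new_catalog(site_key("chrX", 1:20, "A", "G"), "clinvar"))
  out2 <- subtract_known_dna_variants(rec2, cats)
  union_keys <- unique(c(cats[[1]]$keys, cats[[2]]$keys, cats[[3]]$keys))
  expect_setequal(site_key(out2$chrom, out2$pos, out2$ref_base, out2$alt_base),
                  setdiff(keys, union_keys))
  ## empty catalog list is the identity
  expect_equal(nrow(subtract_known_dna_variants(rec2, list())), nrow(rec2))
})

test_that("editing-catalog restriction keeps only whitelisted keys", {
  rec <- random_records(100, seed = 41)
  keys <- unique(site_key(rec$chrom, rec$pos, rec$ref_base, rec$alt_base))
  cat_in <- new_catalog(keys[1:30], "editing-db")
  out <- restrict_to_editing_catalog(rec, cat_in)
  expect_setequal(site_key(out$chrom, out$pos, out$ref_base, out$alt_base),
                  intersect(keys, cat_in$keys))
  expect_warning(restrict_to_editing_catalog(rec, new_catalog(character(), "editing-db")),
                 "empty")
})

test_that("informative-site rule counts covered samples with inclusive boundary", {
  mk_obs <- function(n_samples, cov) data.table::data.table(
    chrom = "chr1", pos = 5L, ref = "A", alt = "G",
    sample = sprintf("s%02d", seq_len(n_samples)),
    edited_reads = 0L, total_reads = cov
  )
  expect_length(select_informative_sites(mk_obs(9, 10L)), 0L)   # 9 samples: excluded
  expect_length(select_informative_sites(mk_obs(10, 10L)), 1L)  # 10 samples: included
  expect_length(select_informative_sites(mk_obs(12, 9L)), 0L)   # covered below depth

  ## random coverage matrix vs brute-force per-site count
  set.seed(51)
  obs <- data.table::data.table(
    chrom = "chr1", pos = rep(1:40, each = 15), ref = "A", alt = "G",
    sample = rep(sprintf("s%02d", 1:15), 40),
    edited_reads = 0L, total_reads = sample(0:30, 600, replace = TRUE)
  )
  got <- select_informative_sites(obs, filter_thresholds(min_informative_samples = 8L))
  key <- site_key(obs$chrom, obs$pos, obs$ref, obs$alt)
  expected <- sort(unique(key[ave(obs$total_reads >= 10, key, FUN = sum)[
    seq_along(key)] >= 8]))
  expect_equal(got, expected)
})

test_that("full cascade equals the set-arithmetic oracle and is order-invariant", {
  cfg <- sim_config(seed = 99, n_genes = 80, sites_per_gene = 4, n_case = 12L,
                    n_ctrl = 6L)
  co <- generate_cohort(cfg)
  cats <- generate_catalogs(cfg, co$truth, n_decoys = 50)
  model <- cohort_gene_model(co)
  th <- filter_thresholds()

  disc <- run_discovery(co$records, list(cats$wes, cats$snp_db),
                        cats$editing_db, model, co$observations, th)
  oracle <- oracle_discovery(co$records, list(cats$wes, cats$snp_db),
                             cats$editing_db, co$observations)
  expect_equal(disc$sites$site, oracle)

  ## report is a conserved, non-increasing cascade over unique sites
  expect_true(all(diff(disc$report$n_kept) <= 0 |
                    disc$report$n_in[-1] == disc$report$n_kept[-nrow(disc$report)]))
  expect_equal(disc$report$n_in - disc$report$n_removed, disc$report$n_kept)
  expect_equal(disc$report$n_in[-1], disc$report$n_kept[-nrow(disc$report)])

  ## permuting record order and catalog order leaves the site set unchanged
  set.seed(1)
  perm <- co$records[sample(.N)]
  disc2 <- run_discovery(perm, list(cats$snp_db, cats$wes),
                         cats$editing_db, model, co$observations, th)
  expect_equal(disc2$sites$site, disc$sites$site)

  ## degenerate fixtures: everything fails coverage -> attrition at stage 1
  rec_low <- data.table::copy(co$records)[, coverage := 5L][, n_alt_reads := pmin(n_alt_reads, 5L)]
  d0 <- run_discovery(rec_low, list(), cats$editing_db, model, co$observations, th)
  expect_equal(nrow(d0$sites), 0L)
  expect_equal(d0$report$n_kept[1], 0L)

  ## no DNA catalogs: subtraction stage is the identity
  d1 <- run_discovery(co$records, list(), cats$editing_db, model,
                      co$observations, th)
  expect_equal(d1$report$n_removed[2], 0L)
})
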