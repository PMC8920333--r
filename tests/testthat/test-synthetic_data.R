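test_that("config validation rejects impossible parameterizations", {
  expect_error(sim_config(n_case = 0), "at least one sample")
  expect_error(sim_config(snp_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(alu_fractions = c(AluY = 0.5, AluS = 0.2, AluJ = 0.1,
                                            `other-repeat` = 0.1,
                                            nonrepetitive = 0.3)), "sum to 1")
  expect_error(sim_config(rate_alpha = -1), "positive")
})

test_that("a pure-editing generator emits only transcript-oriented A-to-G mismatches", {
  cfg <- sim_config(seed = 5, n_genes = 40, sites_per_gene = 4,
                    error_rate = 0, snp_fraction = 0, n_case = 6L, n_ctrl = 3L)
  co <- generate_cohort(cfg)
  strand <- assign_site_strand(co$records, cohort_gene_model(co))
  types <- classify_variant_type(co$records$ref_base, co$records$alt_base, strand)
  genic <- strand != "unknown"
  expect_true(all(types[genic] == "A-to-G"))
  ## intergenic sites are emitted as genomic A>G by convention
  expect_true(all(co$records$ref_base[!genic] == "A" &
                    co$records$alt_base[!genic] == "G"))
})

test_that("an empty cohort still produces valid, readable output files", {
  cfg <- sim_config(seed = 2, n_genes = 0, sites_per_gene = 0)
  co <- generate_cohort(cfg)
  expect_equal(nrow(co$observations), 0L)
  dir <- file.path(tempdir(), "empty_cohort")
  write_cohort(co, dir)
  obs <- read_observations(file.path(dir, "pileup.tsv"))
  expect_equal(nrow(obs), 0L)
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  expect_equal(nrow(sheet), 36L)
})

test_that("identical seeds give byte-identical bundles; different seeds differ", {
  cfg <- sim_config(seed = 42, n_genes = 30, sites_per_gene = 3, n_case = 5L,
                    n_ctrl = 3L)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  d3 <- file.path(tempdir(), "det3")
  unlink(c(d1, d2, d3), recursive = TRUE)
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  write_cohort(generate_cohort(sim_config(seed = 43, n_genes = 30,
                                          sites_per_gene = 3, n_case = 5L,
                                          n_ctrl = 3L)), d3)
  hash_dir <- function(d) {
    files <- sort(list.files(d, recursive = TRUE, full.names = TRUE))
    unname(tools::md5sum(files))
  }
  expect_equal(hash_dir(d1), hash_dir(d2))
  expect_false(isTRUE(all.equal(hash_dir(d1), hash_dir(d3))))
})

test_that("generated files pass every reader and type invariant", {
  cfg <- sim_config(seed = 8, n_genes = 25, sites_per_gene = 4, n_case = 6L,
                    n_ctrl = 3L)
  co <- generate_cohort(cfg)
  dir <- file.path(tempdir(), "readers_cohort")
  unlink(dir, recursive = TRUE)
  write_cohort(co, dir)

  obs <- read_observations(file.path(dir, "pileup.tsv"))
  expect_true(all(obs$edited_reads <= obs$total_reads))
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  expect_equal(sort(sheet$sample_id), sort(co$sheet$sample_id))
  model <- read_gene_model(file.path(dir, "genes.gff3"),
                           file.path(dir, "repeats.bed"))
  expect_s3_class(model, "gene_model")
  vcfs <- list.files(file.path(dir, "vcf"), full.names = TRUE)
  expect_length(vcfs, 9L)
  rec <- read_variant_records(vcfs[1], tools::file_path_sans_ext(basename(vcfs[1])))
  expect_gt(nrow(rec), 0L)
  back <- co$records[sample_id == tools::file_path_sans_ext(basename(vcfs[1]))]
  expect_equal(nrow(rec), nrow(back))
  expect_setequal(site_key(rec$chrom, rec$pos, rec$ref_base, rec$alt_base),
                  site_key(back$chrom, back$pos, back$ref_base, back$alt_base))
})

test_that("catalogs reflect ground truth: SNP removal and whitelist subsetting", {
  cfg <- sim_config(seed = 17, n_genes = 60, sites_per_gene = 4, n_case = 12L,
                    n_ctrl = 6L)
  co <- generate_cohort(cfg)
  cats <- generate_catalogs(cfg, co$truth, n_decoys = 30)
  expect_setequal(cats$wes$keys, co$truth$snp_keys)
  model <- cohort_gene_model(co)

  ## with a complete WES catalog the cascade removes every SNP site
  disc <- run_discovery(co$records, list(cats$wes, cats$snp_db), cats$editing_db,
                        model, co$observations)
  expect_length(intersect(disc$sites$site, co$truth$snp_keys), 0L)
  ## and survivors are a subset of true edit sites
  expect_true(all(disc$sites$site %in% co$truth$edit_keys))

  ## decoy-only editing catalog -> zero survivors
  decoys_only <- new_catalog(setdiff(cats$editing_db$keys,
                                     c(co$truth$edit_keys, co$truth$snp_keys)),
                             "editing-db")
  d0 <- run_discovery(co$records, list(cats$wes), decoys_only, model,
                      co$observations)
  expect_equal(nrow(d0$sites), 0L)
})

test_that("empirical editing levels track true rates (model calibration)", {
  cfg <- sim_config(seed = 23, n_genes = 150, sites_per_gene = 4,
                    snp_fraction = 0, case_logit_shift = 0, n_case = 10L,
                    n_ctrl = 5L)
  co <- generate_cohort(cfg)
  truth <- co$truth$sites
  obs <- co$observations
  obs <- obs[total_reads >= 10]
  obs[, level := edited_reads / total_reads]
  per_site <- obs[, .(emp = mean(level)), by = site]
  per_site[, true_rate := truth$rate_ctrl[match(site, truth$site)]]
  fit <- stats::lm(emp ~ true_rate, data = per_site)
  expect_lt(abs(unname(stats::coef(fit)[2]) - 1), 0.05)
  expect_gt(summary(fit)$r.squared, 0.9)

  ## A-to-G share of mismatch records dominates at the configured mix
  strand <- assign_site_strand(co$records, cohort_gene_model(co))
  types <- classify_variant_type(co$records$ref_base, co$records$alt_base, strand)
  expect_equal(names(which.max(table(types))), "A-to-G")
  expect_gt(mean(types == "A-to-G"), 0.8)
})

test_that("knockdown generator plants the DE and editing-reduction signals", {
  cfg <- sim_config(seed = 29, n_genes = 40, sites_per_gene = 4,
                    planted_target = "g0005", n_case = 8L, n_ctrl = 4L)
  co <- generate_cohort(cfg)
  kd <- generate_knockdown(cfg, co$truth)
  ## planted target passes the DE filter at margin 1.5
  expect_true("g0005" %in% filter_downregulated(kd$de))
  expect_equal(kd$de[gene_id == "g0005", log2_fold_change], -log2(3))
  ## planted drop shows in pooled editing of the case samples
  case_sheet <- co$sheet[group == "case"]
  edit_sites <- co$truth$sites[is_snp == FALSE]
  ref_lvl <- rowMeans(gene_editing_matrix(co$observations, edit_sites,
                                          case_sheet)$levels, na.rm = TRUE)
  kd_lvl <- rowMeans(gene_editing_matrix(kd$observations_kd, edit_sites,
                                         case_sheet)$levels, na.rm = TRUE)
  expect_true("g0005" %in% editing_reduction_genes(ref_lvl, kd_lvl))
  expect_gt(ref_lvl["g0005"] - kd_lvl["g0005"], 0.1)

  ## unplanted generator leaves no deterministic target signal
  cfg0 <- sim_config(seed = 29, n_genes = 40, sites_per_gene = 4,
                     n_case = 8L, n_ctrl = 4L)
  kd0 <- generate_knockdown(cfg0, generate_cohort(cfg0)$truth)
  expect_false(isTRUE(all.equal(kd0$de[gene_id == "g0005", log2_fold_change],
                                -log2(3))))
})

test_that("survival generator degenerates cleanly and plants hazard", {
  cfg <- sim_config(seed = 31, n_genes = 20, sites_per_gene = 2,
                    planted_target = "g0002", censor_rate = 1)
  co <- generate_cohort(cfg)
  sv_all_censored <- generate_survival(cfg, co$truth)
  expect_true(all(sv_all_censored$event == 0L))
  expect_error(survival_screen(sv_all_censored, "g0002"), "event")

  cfg2 <- sim_config(seed = 31, n_genes = 20, sites_per_gene = 2,
                     planted_target = "g0002", censor_rate = 0.2,
                     n_patients = 250L)
  sv <- generate_survival(cfg2, generate_cohort(cfg2)$truth)
  res <- survival_screen(sv, c("g0002", "g0001"))
  expect_true(res[res$gene_id == "g0002", ]$passes)
})
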