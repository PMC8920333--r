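test_that("DE filter applies strict fold-change and P boundaries", {
  de <- data.table::data.table(
    gene_id = c("a", "b", "c", "d", "e"),
    log2_fold_change = c(-1.0, -1.1, -3, 1.5, -2),
    adjusted_p = c(0.04, 0.04, 0.05, 0.01, 0.049)
  )
  got <- filter_downregulated(de)
  expect_false("a" %in% got)  # |FC| = 2 exactly is not > 2
  expect_true("b" %in% got)
  expect_false("c" %in% got)  # p = 0.05 exactly is not < 0.05
  expect_false("d" %in% got)  # upregulated
  expect_equal(got, c("b", "e"))

  ## random table vs brute-force predicate scan
  set.seed(141)
  rnd <- data.table::data.table(
    gene_id = sprintf("g%03d", 1:300),
    log2_fold_change = rnorm(300, 0, 1.5),
    adjusted_p = runif(300)
  )
  keep <- vapply(seq_len(300), function(i) {
    rnd$log2_fold_change[i] < -1 && rnd$adjusted_p[i] < 0.05
  }, logical(1))
  expect_equal(filter_downregulated(rnd), sort(rnd$gene_id[keep]))
})

test_that("editing reduction requires a strict drop and shared evaluability", {
  ref <- c(g1 = 0.30, g2 = 0.30, g3 = 0.10, g4 = NA, g5 = 0.2)
  alt <- c(g1 = 0.10, g2 = 0.30, g3 = 0.15, g4 = 0.1, g5 = NaN)
  expect_equal(editing_reduction_genes(ref, alt), "g1")
  expect_equal(editing_reduction_genes(ref, alt, delta = 0.25), character(0))
  ## matrices are averaged per gene first
  m_ref <- cbind(s1 = c(g1 = 0.4, g2 = 0.2), s2 = c(0.2, 0.2))
  m_alt <- cbind(s1 = c(g1 = 0.1, g2 = 0.2), s2 = c(0.1, 0.2))
  expect_equal(editing_reduction_genes(m_ref, m_alt), "g1")
})

test_that("survival screen matches hand-computed log-rank on the 4-patient toy", {
  ## patients 1..4: times 1,2,3,4, all events; high expression = patients 1,2
  surv <- data.table::data.table(
    patient_id = sprintf("p%d", 1:4),
    time = c(1, 2, 3, 4), event = 1L,
    gX = c(2, 2, 1, 1)
  )
  got <- survival_screen(surv, "gX")
  hand <- oracle_logrank_chisq(surv$time, surv$event, surv$gX > median(surv$gX))
  expect_equal(got$statistic, hand, tolerance = 1e-10)
  expect_true(got$hazard_ratio > 1)  # high-expression stratum dies first

  ## identical curves (same death times in both strata): statistic 0, p = 1
  surv2 <- data.table::data.table(
    patient_id = sprintf("p%d", 1:8),
    time = rep(c(1, 2, 3, 4), each = 2), event = 1L,
    gY = rep(c(2, 1), 4)
  )
  got2 <- survival_screen(surv2, "gY")
  expect_equal(got2$statistic, 0, tolerance = 1e-10)
  expect_equal(got2$p_value, 1, tolerance = 1e-10)
  expect_false(got2$passes)

  ## constant expression is unevaluable
  surv2$gZ <- 1
  got3 <- survival_screen(surv2, "gZ")
  expect_false(got3$evaluable)

  ## no events at all is a clean error
  surv3 <- data.table::copy(surv)[, event := 0L]
  expect_error(survival_screen(surv3, "gX"), "event")
})

test_that("survival screen has power against a planted hazard and correct direction", {
  set.seed(151)
  n <- 200
  hits <- 0L
  for (r in 1:20) {
    expr <- rnorm(n)
    t_ev <- rexp(n, rate = 0.1 * exp(log(3) * expr))
    surv <- data.table::data.table(patient_id = sprintf("p%d", 1:n),
                                   time = t_ev, event = 1L, g = expr)
    res <- survival_screen(surv, "g")
    hits <- hits + res$passes
  }
  expect_gte(hits, 19L)  # >= 95% power at HR ~ 3 per median split
})

test_that("candidate intersection is exact, sorted, and duplication-invariant", {
  expect_equal(intersect_candidates(c("A", "B", "C"), c("B", "C", "D"), c("C", "E")),
               "C")
  expect_equal(intersect_candidates(character(), c("B"), c("B")), character(0))
  expect_equal(intersect_candidates(c("B", "A", "A"), c("A", "B", "B"), c("B", "A")),
               c("A", "B"))
})

test_that("candidate ranking orders by joint correlation and flags degenerates", {
  samples <- sprintf("s%02d", 1:10)
  set.seed(161)
  ed <- rbind(gT = seq(0.1, 0.5, length.out = 10),
              gN = runif(10), gC = rep(0.3, 10))
  colnames(ed) <- samples
  expr <- rbind(gT = ed["gT", ] * 2 + 1, gN = rnorm(10), gC = rnorm(10))
  colnames(expr) <- samples
  enzyme <- ed["gT", ] + rnorm(10, 0, 0.01)
  names(enzyme) <- samples

  rk <- rank_candidates(c("gT", "gN", "gC"), enzyme, ed, expr)
  expect_equal(rk$gene_id[1], "gT")
  expect_equal(rk$r_expr_vs_editing[1], 1)          # editing identical to expression
  expect_true(rk$degenerate[rk$gene_id == "gC"])    # constant editing
  expect_equal(rk$gene_id[3], "gC")                 # degenerate ranked last
  expect_true(all(abs(stats::na.omit(c(rk$r_enzyme_vs_editing, rk$r_expr_vs_editing))) <= 1))
})

test_that("the funnel is monotone under threshold relaxation", {
  cfg <- sim_config(seed = 33, n_genes = 40, sites_per_gene = 4, n_case = 10L,
                    n_ctrl = 5L, planted_target = "g0001", n_patients = 120L)
  co <- generate_cohort(cfg)
  kd <- generate_knockdown(cfg, co$truth)
  sv <- generate_survival(cfg, co$truth)
  case_sheet <- co$sheet[group == "case"]
  edit_sites <- co$truth$sites[is_snp == FALSE]
  ref_lvl <- rowMeans(gene_editing_matrix(co$observations, edit_sites, case_sheet)$levels,
                      na.rm = TRUE)
  kd_lvl <- rowMeans(gene_editing_matrix(kd$observations_kd, edit_sites, case_sheet)$levels,
                     na.rm = TRUE)
  gm <- gene_editing_matrix(co$observations, edit_sites, co$sheet)
  strict <- prioritize_targets(kd$de, ref_lvl, kd_lvl, sv, co$enzyme_expression,
                               gm$levels, co$expression)
  relaxed <- prioritize_targets(kd$de, ref_lvl, kd_lvl, sv, co$enzyme_expression,
                                gm$levels, co$expression,
                                fc_threshold = 1.5, p_threshold = 0.2, alpha = 0.2)
  expect_true(all(strict$candidates %in% relaxed$candidates))
  expect_true("g0001" %in% strict$candidates)
})
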