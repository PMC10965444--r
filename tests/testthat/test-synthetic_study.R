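test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_genes = 100, n_pan = 5, n_lineage = 5, n_sl = 5,
                    n_um_high = 10, n_um_low = 5, seed = 7)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$panels$avana$scores, b$panels$avana$scores)
  expect_identical(a$expression$tpm, b$expression$tpm)
  expect_identical(a$truth$genes, b$truth$genes)
})

test_that("no planted depletion gives centered gene logFCs", {
  cfg <- sim_config(n_genes = 250, n_pan = 0, n_lineage = 0, n_sl = 0,
                    n_um_high = 0, n_um_low = 0,
                    screen_cell_lines = "UM1", seed = 3)
  sc <- simulate_screen_counts(cfg)
  lfc <- log2_fold_change(sc$counts, tmm_factors(sc$counts))
  g <- summarize_gene_logfc(lfc)
  expect_gt(nrow(g), 200)
  expect_lt(abs(mean(g$gene_logfc)), 0.05)
})

test_that("planted depletion matches the analytic expectation", {
  # one fully efficient pan-essential gene at d = 0.15/day: day 21 vs 4
  # gives a latent change of -0.15 * 17 = -2.55 log2 units
  cfg <- sim_config(n_genes = 500, n_pan = 1, n_lineage = 0, n_sl = 0,
                    n_um_high = 0, n_um_low = 0, efficacy_fixed = 1,
                    screen_cell_lines = "UM1", seed = 1)
  study <- simulate_screen_counts(cfg)
  pan <- study$truth$genes$gene[
    study$truth$genes$dependency_class == "pan_essential"]
  lfc <- log2_fold_change(study$counts, tmm_factors(study$counts))
  g <- summarize_gene_logfc(lfc)
  got <- g$gene_logfc[g$gene == pan & g$day == 21]
  expect_lt(abs(got - (-2.55)), 0.4)
})

test_that("dependency panel scores center on the planted classes", {
  cfg <- sim_config(n_genes = 200, n_pan = 20, n_lineage = 10, n_sl = 20,
                    n_um_high = 0, n_um_low = 0, seed = 11)
  dep <- simulate_dependency_panels(cfg)
  truth <- simulate_truth(cfg)
  sc <- dep$panels$avana$scores
  ann <- dep$panels$avana$annotations
  med <- apply(sc, 1, median)
  cls <- truth$genes$dependency_class
  expect_true(all(med[cls == "pan_essential"] > -1.15 &
                    med[cls == "pan_essential"] < -0.85))
  expect_true(all(abs(med[cls == "neutral"]) < 0.15))
  # SL genes are inert in wild-type lines
  wt <- ann$genotype == "wildtype"
  med_wt <- apply(sc[, wt, drop = FALSE], 1, median)
  expect_true(all(abs(med_wt[cls == "sl_mutant_specific"]) < 0.15))
  # scalar scores exceed the 0.4 cutoff only for pan-essentials (centers
  # 0.6 vs 0.05 with sd 0.1)
  s <- dep$scalar_scores
  expect_gt(mean(s$priority_score[cls == "pan_essential"]), 0.5)
  expect_gt(mean(s$priority_score[cls == "pan_essential"] > 0.4), 0.9)
  expect_gt(mean(s$priority_score[cls != "pan_essential"] <= 0.4), 0.98)
})

test_that("planted expression shifts appear on the log2 scale", {
  cfg <- sim_config(n_genes = 400, n_pan = 0, n_lineage = 0, n_sl = 0,
                    n_um_high = 40, n_um_low = 0, frac_high_shared = 0,
                    seed = 5)
  panel <- simulate_expression_panel(cfg)
  truth <- simulate_truth(cfg)
  hi <- truth$genes$expression_class == "um_high"
  um <- panel$sample_type == "UM"
  cm <- panel$sample_type == "CM"
  l2 <- log2(panel$tpm + 1)
  diff <- apply(l2[hi, um, drop = FALSE], 1, median) -
    apply(l2[hi, cm, drop = FALSE], 1, median)
  expect_true(all(abs(diff - 3) < 0.6 * 3))
  expect_lt(abs(mean(diff) - 3), 0.6)
})

test_that("expected total reads are conserved at the target depth", {
  cfg <- sim_config(n_genes = 300, n_pan = 10, n_lineage = 0, n_sl = 0,
                    n_um_high = 0, n_um_low = 0,
                    screen_cell_lines = "UM1", seed = 9)
  sc <- simulate_screen_counts(cfg)
  expected <- cfg$depth * nrow(sc$counts$counts)
  # NB sampling error on the column total is far below 5%
  expect_true(all(abs(sc$counts$library_sizes / expected - 1) < 0.05))
})

test_that("stronger depletion gives stochastically lower day-21 logFC", {
  day21_pan_mean <- function(d, seed) {
    cfg <- sim_config(n_genes = 200, n_pan = 20, n_lineage = 0, n_sl = 0,
                      n_um_high = 0, n_um_low = 0, d_pan = d,
                      screen_cell_lines = "UM1", seed = seed)
    study <- simulate_screen_counts(cfg)
    pan <- study$truth$genes$gene[
      study$truth$genes$dependency_class == "pan_essential"]
    g <- summarize_gene_logfc(
      log2_fold_change(study$counts, tmm_factors(study$counts)))
    mean(g$gene_logfc[g$gene %in% pan & g$day == 21])
  }
  for (seed in 1:3)
    expect_lt(day21_pan_mean(0.2, seed), day21_pan_mean(0.1, seed))
})

test_that("truth labels alone suffice to score recovery", {
  cfg <- sim_config(n_genes = 120, n_pan = 6, n_lineage = 4, n_sl = 4,
                    n_um_high = 6, n_um_low = 4, seed = 2)
  st <- simulate_study(cfg)
  res <- suppressWarnings(run_pipeline(st, pipeline_config(seed = 2)))
  sc <- score_against_truth(res$hits, st$truth)
  expect_true(all(c("sl_sensitivity", "fdr") %in% names(sc)))
  expect_true(sc$fdr >= 0 && sc$fdr <= 1)
  # every library gene is labeled exactly once per axis
  expect_equal(nrow(st$truth$genes), cfg$n_genes)
  expect_false(anyNA(st$truth$genes$dependency_class))
  expect_false(anyNA(st$truth$genes$expression_class))
})

test_that("a written study round-trips through the file formats", {
  cfg <- sim_config(n_genes = 60, n_pan = 4, n_lineage = 2, n_sl = 2,
                    n_um_high = 4, n_um_low = 2, seed = 4)
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_study(st, dir)
  counts <- read_screen_counts(file.path(dir, "screen_counts.tsv"),
                               file.path(dir, "sample_meta.csv"))
  expect_equal(counts$counts, st$counts$counts)
  ann <- read_cell_line_annotations(
    file.path(dir, "cell_line_annotations.csv"))
  panel <- read_gene_panel(file.path(dir, "panel_avana.csv"), "dependency",
                           annotations = ann)
  expect_equal(panel$scores, st$panels$avana$scores, tolerance = 1e-12)
})
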