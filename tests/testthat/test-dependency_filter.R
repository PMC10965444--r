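test_that("screen hit calls use an inclusive logFC and strict p cutoff", {
  stats <- data.frame(gene = c("a", "b", "c", "d"),
                      cell_line = "UM1", day = 21,
                      gene_logfc = c(-1.2, -0.5, -1.2, -0.49),
                      adj_p = c(0.001, 0.001, 0.01, 0.001))
  h <- screen_hit_call(stats)
  expect_equal(h$hit, c(TRUE,   # clear hit
                        TRUE,   # boundary logFC is included
                        FALSE,  # p exactly at the cutoff is excluded
                        FALSE)) # logFC above the cutoff
  expect_error(screen_hit_call(data.frame(gene = "a", cell_line = "x",
                                          day = 21, gene_logfc = NA,
                                          adj_p = 0.5)), "missing")
})

test_that("pan-essential exclusion uses OR semantics across panels", {
  mk <- function(v) toy_panel(matrix(v, 1, 8, dimnames = list("g1", NULL)))
  strong <- mk(rep(-0.8, 8)); inert <- mk(rep(0, 8))
  e <- pan_essential_exclusion(list(strong, inert, inert))
  expect_equal(e$gene, "g1")
  # all medians exactly at -0.39 are retained (strict < -0.4)
  weak <- mk(rep(-0.39, 8))
  expect_equal(nrow(pan_essential_exclusion(list(weak, weak, weak))), 0L)
  # absence from one panel does not protect a gene another panel flags
  other <- toy_panel(matrix(-0.5, 1, 8, dimnames = list("g2", NULL)),
                     dataset = "drive")
  e2 <- pan_essential_exclusion(list(inert, other))
  expect_equal(e2$gene, "g2")
  expect_equal(e2$panel, "drive")
})

test_that("missing dependency values are dropped from the aggregate", {
  m <- matrix(c(-0.9, -0.9, -0.9, NA, NA, NA, NA, NA), 1, 8,
              dimnames = list("g1", NULL))
  e <- pan_essential_exclusion(list(toy_panel(m)))
  expect_equal(e$gene, "g1")   # median over present values only
})

test_that("published scalar scores exclude on either field", {
  s <- gene_scalar_scores(c("a", "b", "c", "d"),
                          priority_score = c(0.6, 0.4, NA, NA),
                          cellline_dependency_score = c(0.1, 0.4, 0.5, NA))
  e <- score_project_exclusion(s)
  expect_setequal(e$gene, c("a", "c"))  # b: exactly 0.4 retained (strict >)
  expect_false("d" %in% e$gene)         # both missing: retained
})

test_that("lineage exclusion flags CM medians and wt-UM controls", {
  base <- matrix(0, 3, 8, dimnames = list(c("g1", "g2", "g3"), NULL))
  base[1, 1:3] <- -0.7            # CM median -0.7
  base[2, 5] <- -0.6              # one wt-UM control below -0.5
  base[3, 1:3] <- -0.5            # exactly at the cutoff: retained
  base[3, 5:6] <- -0.5
  e <- lineage_exclusion(toy_panel(base))
  expect_setequal(e$gene, c("g1", "g2"))
  expect_equal(e$panel[e$gene == "g1"], "cm_lineage")
  expect_equal(e$panel[e$gene == "g2"], "wt_um_control")

  no_ctl <- cell_line_annotations(paste0("L", 1:2),
                                  rep("cutaneous_melanoma", 2),
                                  rep("wildtype", 2),
                                  is_cm_panel_member = TRUE)
  panel <- DependencyPanel(matrix(0, 1, 2, dimnames =
                                    list("g1", paste0("L", 1:2))), no_ctl)
  expect_error(lineage_exclusion(panel), "control")
})

test_that("final hits intersect screens and respect the two timepoints", {
  hits <- expand.grid(gene = c("g1", "g2", "g3", "g4"),
                      cell_line = c("UM1", "UM2", "UM3"),
                      day = c(14, 21), stringsAsFactors = FALSE)
  hits$gene_logfc <- -1; hits$adj_p <- 1e-4
  hits$hit <- TRUE
  hits$hit[hits$gene == "g2" & hits$cell_line == "UM3"] <- FALSE  # 2/3
  hits$hit[hits$gene == "g3" & hits$day == 14] <- FALSE           # late only
  excl <- list(pan_essential = data.frame(gene = "g4", panel = "avana",
                                          value = -0.9))
  out <- final_hits(hits, excl)
  cls <- setNames(out$final_class, out$gene)
  expect_equal(unname(cls[c("g1", "g2", "g3", "g4")]),
               c("robust_hit", "non_hit", "late_hit", "non_hit"))
  expect_equal(out$excluded_by[out$gene == "g4"], "pan_essential")
  # exclusion tags are recorded even though g4 scored in every screen
  expect_equal(out$n_screens_hit_t2[out$gene == "g4"], 3L)
})

test_that("relaxing thresholds never shrinks the final hit set", {
  cfg <- sim_config(n_genes = 150, n_pan = 8, n_lineage = 5, n_sl = 8,
                    n_um_high = 0, n_um_low = 0, seed = 12)
  st <- simulate_study(cfg)
  run_with <- function(filter) {
    # small library: the adjustment falls back to plain BH, which is fine
    # for a threshold-monotonicity check
    res <- suppressWarnings(
      run_pipeline(st, pipeline_config(filter = filter, seed = 1)))
    res$hits$gene[res$hits$final_class != "non_hit"]
  }
  strict <- run_with(filter_config())
  relaxed <- run_with(filter_config(screen_lfc = -0.3, screen_p = 0.05,
                                    panessential = -0.6, cm_lineage = -0.8,
                                    wt_um = -0.8, score_priority = 0.2))
  expect_true(all(strict %in% relaxed))
})

test_that("every library gene carries a provenance record", {
  cfg <- sim_config(n_genes = 120, n_pan = 8, n_lineage = 4, n_sl = 6,
                    n_um_high = 0, n_um_low = 0, seed = 14)
  st <- simulate_study(cfg)
  res <- suppressWarnings(run_pipeline(st, pipeline_config(seed = 1)))
  expect_setequal(res$hits$gene, unique(st$counts$library$gene))
  expect_true(all(res$hits$final_class %in%
                    c("robust_hit", "late_hit", "non_hit")))
  # a robust hit is never simultaneously excluded
  robust <- res$hits$final_class == "robust_hit"
  expect_true(all(res$hits$excluded_by[robust] == ""))
})
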