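## Synthetic study generator. Every artifact (screen counts, dependency
## panels, scalar scores, expression panel) is drawn from its own RNG stream
## derived from the master seed by a fixed offset, so components are
## individually reproducible and mutually independent.

.SEED_TRUTH <- 0L
.SEED_COUNTS <- 1L
.SEED_PANELS <- 2L
.SEED_EXPR <- 3L

#' Configuration of the synthetic study
#'
#' Defaults emulate a genome-scale dropout screen in three GNAQ/11-mutant
#' uveal melanoma (UM) lines sampled at days 4/14/21 at representation-scale
#' coverage, plus matching dependency panels and a pan-cancer TPM panel.
#' Planted gene classes: pan-essential (depletes everywhere),
#' melanocyte-lineage-essential (depletes in melanoma lines of either
#' subtype), and synthetic-lethal (SL; depletes only in GNAQ/11-mutant
#' lines). Expression classes (UM-high / UM-low, with an optional fraction of
#' UM-high genes shared with the cutaneous comparator) are drawn
#' independently and may overlap the dependency classes.
#'
#' @param n_genes number of genes in the library.
#' @param sgrnas_per_gene constructs per gene.
#' @param n_pan,n_lineage,n_sl planted class sizes (remainder neutral).
#' @param n_um_high,n_um_low planted expression class sizes.
#' @param frac_high_shared fraction of UM-high genes also shifted in the
#'   comparator lineage (exercises the lineage z exclusion).
#' @param screen_cell_lines names of the screened mutant-UM lines.
#' @param days sampled days post-selection; the earliest is the baseline.
#' @param n_replicates replicates per (cell line, day).
#' @param depth mean reads per sgRNA (coverage scale).
#' @param nb_dispersion negative-binomial dispersion of counts.
#' @param d_pan,d_lineage,d_sl depletion rates in log2 units per day for the
#'   planted classes (SL applies in mutant lines only).
#' @param efficacy_shape Beta shape parameters of per-sgRNA efficacy.
#' @param efficacy_fixed if non-NULL, a constant efficacy overriding the Beta
#'   draw (used for analytic checks).
#' @param panel_n_cm,panel_n_um_mut,panel_n_um_wt,panel_n_other cell-line
#'   counts per lineage in the dependency panels; the wild-type UM lines are
#'   flagged as controls, the cutaneous lines as CM panel members.
#' @param dep_score_scale scale k of dependency scores, `score = -k * d +
#'   noise`; the default `1/d_pan` centers pan-essential genes at -1.0.
#' @param dep_noise_sd dependency-score noise standard deviation.
#' @param scalar_center_pan,scalar_center_other,scalar_sd centers and sd of
#'   the per-gene scalar scores (pan-essentials sit above the 0.4 cutoff).
#' @param expr_shift planted expression shift on the log2(TPM+1) scale.
#' @param expr_sd per-sample expression noise sd on the log2 scale.
#' @param expr_n_target,expr_n_comparator,expr_n_other_types,expr_n_per_type
#'   expression panel design: samples of the target type, of the comparator,
#'   and number/size of additional tumor types.
#' @param seed master seed (mandatory).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, sgrnas_per_gene = 5L,
                       n_pan = 60L, n_lineage = 40L, n_sl = 40L,
                       n_um_high = 100L, n_um_low = 50L,
                       frac_high_shared = 0.25,
                       screen_cell_lines = c("UM1", "UM2", "UM3"),
                       days = c(4L, 14L, 21L), n_replicates = 1L,
                       depth = 500, nb_dispersion = 0.05,
                       d_pan = 0.15, d_lineage = 0.12, d_sl = 0.12,
                       efficacy_shape = c(5, 1), efficacy_fixed = NULL,
                       panel_n_cm = 8L, panel_n_um_mut = 3L,
                       panel_n_um_wt = 2L, panel_n_other = 25L,
                       dep_score_scale = 1 / d_pan, dep_noise_sd = 0.05,
                       scalar_center_pan = 0.6, scalar_center_other = 0.05,
                       scalar_sd = 0.1,
                       expr_shift = 3, expr_sd = 0.5,
                       expr_n_target = 10L, expr_n_comparator = 10L,
                       expr_n_other_types = 6L, expr_n_per_type = 10L,
                       seed) {
  if (missing(seed) || !is.finite(seed)) stop("seed is mandatory")
  if (n_pan + n_lineage + n_sl > n_genes)
    stop("planted dependency classes exceed n_genes")
  if (any(c(d_pan, d_lineage, d_sl) < 0)) stop("depletion rates must be >= 0")
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

## depletion rate of gene class g in a cell line described by
## (lineage, genotype); melanocyte lineage = cutaneous or uveal melanoma
.depletion_rate <- function(class, lineage, genotype, config) {
  melanocyte <- lineage %in% c("cutaneous_melanoma", "uveal_melanoma")
  mutant <- genotype == "gnaq11_mutant"
  switch(class,
         pan_essential = config$d_pan,
         lineage_essential = if (melanocyte) config$d_lineage else 0,
         sl_mutant_specific = if (mutant) config$d_sl else 0,
         0)
}

#' Planted truth labels of a synthetic study
#'
#' Assigns each gene one dependency class and one expression class (the two
#' axes are independent and may overlap). Deterministic given the config
#' seed.
#'
#' @param config a [sim_config].
#' @return A list of class `TruthLabels` with a per-gene data.frame `genes`
#'   (`gene`, `dependency_class`, `expression_class`).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + .SEED_TRUTH, {
    genes <- sprintf("g%04d", seq_len(config$n_genes))
    dep <- rep("neutral", config$n_genes)
    idx <- sample.int(config$n_genes,
                      config$n_pan + config$n_lineage + config$n_sl)
    dep[idx[seq_len(config$n_pan)]] <- "pan_essential"
    dep[idx[config$n_pan + seq_len(config$n_lineage)]] <- "lineage_essential"
    dep[idx[config$n_pan + config$n_lineage + seq_len(config$n_sl)]] <-
      "sl_mutant_specific"
    expr <- rep("none", config$n_genes)
    eidx <- sample.int(config$n_genes, config$n_um_high + config$n_um_low)
    hi <- eidx[seq_len(config$n_um_high)]
    n_shared <- round(config$frac_high_shared * config$n_um_high)
    expr[hi] <- "um_high"
    if (n_shared > 0) expr[hi[seq_len(n_shared)]] <- "um_high_shared"
    expr[eidx[config$n_um_high + seq_len(config$n_um_low)]] <- "um_low"
    structure(list(genes = data.frame(gene = genes, dependency_class = dep,
                                      expression_class = expr,
                                      stringsAsFactors = FALSE)),
              class = "TruthLabels")
  })
}

#' Simulate pooled screen counts with planted depletion
#'
#' Each sgRNA `s` of gene `g` carries a latent abundance
#' `a_s * 2^(-u_s * d_g * (day - day0))` with `a_s` log-normal(0, 1) and
#' efficacy `u_s ~ Beta(shape)` fixed per sgRNA; abundances are renormalized
#' within each sample (the sequenced pool is compositional), scaled to the
#' target depth and counts drawn negative-binomially. Deterministic given
#' the config seed.
#'
#' @param config a [sim_config].
#' @param truth optional [simulate_truth] result (generated if missing).
#' @return A list with elements `counts` (a [ScreenCounts] covering all
#'   screen cell lines) and `truth`.
#' @export
simulate_screen_counts <- function(config, truth = simulate_truth(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "TruthLabels"))
  g <- truth$genes
  n_sg <- config$n_genes * config$sgrnas_per_gene
  gene_of <- rep(g$gene, each = config$sgrnas_per_gene)
  class_of <- rep(g$dependency_class, each = config$sgrnas_per_gene)
  sgrna <- paste0(gene_of, "_sg", seq_len(config$sgrnas_per_gene))
  day0 <- min(config$days)
  withr::with_seed(config$seed + .SEED_COUNTS, {
    a <- exp(stats::rnorm(n_sg))
    u <- if (!is.null(config$efficacy_fixed))
      rep(config$efficacy_fixed, n_sg)
    else stats::rbeta(n_sg, config$efficacy_shape[[1]],
                      config$efficacy_shape[[2]])
    samples <- expand.grid(replicate = seq_len(config$n_replicates),
                           day = config$days,
                           cell_line = config$screen_cell_lines,
                           stringsAsFactors = FALSE)
    samples <- data.frame(
      sample_id = paste0(samples$cell_line, "_d", samples$day, "_r",
                         samples$replicate),
      cell_line = samples$cell_line, day = samples$day,
      replicate = samples$replicate, stringsAsFactors = FALSE)
    counts <- matrix(0, n_sg, nrow(samples))
    d_by_class <- vapply(class_of, .depletion_rate,
                         numeric(1), lineage = "uveal_melanoma",
                         genotype = "gnaq11_mutant", config = config)
    for (j in seq_len(nrow(samples))) {
      w <- a * 2^(-u * d_by_class * (samples$day[[j]] - day0))
      mu <- config$depth * n_sg * (w / sum(w))
      counts[, j] <- stats::rnbinom(n_sg, mu = mu,
                                    size = 1 / config$nb_dispersion)
    }
    list(counts = ScreenCounts(counts,
                               library = data.frame(sgrna = sgrna,
                                                    gene = gene_of),
                               samples = samples),
         truth = truth)
  })
}

.panel_annotations <- function(config) {
  cell_line_annotations(
    cell_line = c(sprintf("CM%02d", seq_len(config$panel_n_cm)),
                  sprintf("UMmut%02d", seq_len(config$panel_n_um_mut)),
                  sprintf("UMwt%02d", seq_len(config$panel_n_um_wt)),
                  sprintf("OTH%02d", seq_len(config$panel_n_other))),
    lineage = c(rep("cutaneous_melanoma", config$panel_n_cm),
                rep("uveal_melanoma",
                    config$panel_n_um_mut + config$panel_n_um_wt),
                rep("other", config$panel_n_other)),
    genotype = c(rep("wildtype", config$panel_n_cm),
                 rep("gnaq11_mutant", config$panel_n_um_mut),
                 rep("wildtype", config$panel_n_um_wt),
                 rep("wildtype", config$panel_n_other)),
    is_cm_panel_member = c(rep(TRUE, config$panel_n_cm),
                           rep(FALSE, config$panel_n_um_mut +
                                 config$panel_n_um_wt + config$panel_n_other)),
    is_wt_um_control = c(rep(FALSE, config$panel_n_cm +
                               config$panel_n_um_mut),
                         rep(TRUE, config$panel_n_um_wt),
                         rep(FALSE, config$panel_n_other)))
}

#' Simulate dependency panels and scalar scores matching the planted truth
#'
#' Dependency scores follow `score = -k * d + Normal(0, sd)` with `d` the
#' class- and line-specific depletion rate, so pan-essential genes center at
#' `-k * d_pan` (-1.0 by default) in every line, lineage-essentials only in
#' melanoma lines and SL genes only in mutant lines. Scalar priority and
#' dependency scores center above the 0.4 exclusion cutoff only for
#' pan-essential genes.
#'
#' @inheritParams simulate_screen_counts
#' @return A list with `panels` (named list of three [DependencyPanel]s:
#'   avana, drive, achilles), `scalar_scores` and `annotations`.
#' @export
simulate_dependency_panels <- function(config,
                                       truth = simulate_truth(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "TruthLabels"))
  ann <- .panel_annotations(config)
  g <- truth$genes
  d <- matrix(0, nrow(g), nrow(ann),
              dimnames = list(g$gene, ann$cell_line))
  for (j in seq_len(nrow(ann)))
    d[, j] <- vapply(g$dependency_class, .depletion_rate, numeric(1),
                     lineage = ann$lineage[[j]],
                     genotype = ann$genotype[[j]], config = config)
  withr::with_seed(config$seed + .SEED_PANELS, {
    panels <- lapply(c(avana = "avana", drive = "drive",
                       achilles = "achilles"), function(tag) {
      noise <- matrix(stats::rnorm(length(d), sd = config$dep_noise_sd),
                      nrow(d), ncol(d))
      DependencyPanel(-config$dep_score_scale * d + noise, ann, dataset = tag)
    })
    pan <- g$dependency_class == "pan_essential"
    center <- ifelse(pan, config$scalar_center_pan,
                     config$scalar_center_other)
    scalar <- gene_scalar_scores(
      g$gene,
      priority_score = stats::rnorm(nrow(g), center, config$scalar_sd),
      cellline_dependency_score = stats::rnorm(nrow(g), center,
                                               config$scalar_sd))
    list(panels = panels, scalar_scores = scalar, annotations = ann)
  })
}

#' Simulate a pan-cancer expression panel with planted signature genes
#'
#' Per sample, `log2(TPM+1) ~ Normal(m_g, expr_sd)` around a gene-specific
#' baseline; planted UM-high genes are shifted by `+expr_shift` in
#' target-type samples (shared genes also in the comparator lineage), UM-low
#' genes by `-expr_shift`.
#'
#' @inheritParams simulate_screen_counts
#' @return An [ExpressionPanel].
#' @export
simulate_expression_panel <- function(config,
                                      truth = simulate_truth(config)) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "TruthLabels"))
  g <- truth$genes
  types <- c(rep(config$screen_lineage_label %||% "UM", config$expr_n_target),
             rep("CM", config$expr_n_comparator),
             rep(sprintf("T%02d", seq_len(config$expr_n_other_types)),
                 each = config$expr_n_per_type))
  withr::with_seed(config$seed + .SEED_EXPR, {
    m <- stats::runif(nrow(g), 1, 8)
    shift <- matrix(0, nrow(g), length(types))
    hi <- g$expression_class %in% c("um_high", "um_high_shared")
    lo <- g$expression_class == "um_low"
    shared <- g$expression_class == "um_high_shared"
    shift[hi, types == "UM"] <- config$expr_shift
    shift[shared, types == "CM"] <- config$expr_shift
    shift[lo, types == "UM"] <- -config$expr_shift
    x <- matrix(stats::rnorm(nrow(g) * length(types), sd = config$expr_sd),
                nrow(g), length(types)) + m + shift
    tpm <- pmax(2^x - 1, 0)
    dimnames(tpm) <- list(g$gene, paste0(types, "_s", seq_along(types)))
    ExpressionPanel(tpm, types, target_type = "UM", comparator_type = "CM")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a complete synthetic study
#'
#' Convenience wrapper generating the shared truth labels plus all study
#' artifacts from one config.
#'
#' @param config a [sim_config].
#' @return A list of class `synthetic_study` with elements `truth`, `counts`,
#'   `panels`, `scalar_scores`, `annotations` and `expression`.
#' @export
simulate_study <- function(config) {
  truth <- simulate_truth(config)
  sc <- simulate_screen_counts(config, truth)
  dep <- simulate_dependency_panels(config, truth)
  expr <- simulate_expression_panel(config, truth)
  structure(list(truth = truth, counts = sc$counts, panels = dep$panels,
                 scalar_scores = dep$scalar_scores,
                 annotations = dep$annotations, expression = expr,
                 config = config),
            class = "synthetic_study")
}

#' Write a synthetic study to disk in the pipeline's file formats
#'
#' Emits the screen counts TSV + metadata CSV, one CSV per dependency panel,
#' the scalar score CSV, the cell-line annotation CSV, the expression TSV
#' and `truth_labels.tsv`.
#'
#' @param study a [simulate_study] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_screen_counts(study$counts, file.path(dir, "screen_counts.tsv"),
                      file.path(dir, "sample_meta.csv"))
  utils::write.csv(study$annotations,
                   file.path(dir, "cell_line_annotations.csv"),
                   quote = FALSE, row.names = FALSE)
  for (nm in names(study$panels))
    utils::write.csv(data.frame(gene = rownames(study$panels[[nm]]$scores),
                                study$panels[[nm]]$scores,
                                check.names = FALSE),
                     file.path(dir, paste0("panel_", nm, ".csv")),
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(study$scalar_scores, file.path(dir, "scalar_scores.csv"),
                   quote = FALSE, row.names = FALSE)
  expr <- data.frame(gene = rownames(study$expression$tpm),
                     study$expression$tpm, check.names = FALSE)
  utils::write.table(expr, file.path(dir, "expression_tpm.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth$genes, file.path(dir, "truth_labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
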