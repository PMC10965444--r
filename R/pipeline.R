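## End-to-end orchestration: normalize -> score -> adjust -> filter ->
## signature -> prioritize, with every intermediate written as plain TSV and
## a JSON run summary so any stage can be rerun or audited in isolation.

#' Pipeline configuration
#'
#' One serializable list holding every tunable of the pipeline. All
#' randomness (the cross-fitting fold assignment) flows from `seed`.
#'
#' @param baseline_day baseline timepoint (NULL = earliest sampled day).
#' @param pseudocount pseudocount of the CPM transform.
#' @param gene_summary `"median"` or `"mean"` gene-summary statistic.
#' @param ihw_covariate covariate for the weighted adjustment; the default
#'   `"baseline_cpm"` is the per-gene mean baseline log2 CPM of its
#'   constructs (abundance is informative about power and independent of
#'   the p-value under the null).
#' @param ihw_bins,ihw_folds bins and folds of [ihw_adjust()].
#' @param filter a [filter_config].
#' @param signature_probs percentile band of [percentile_calls()].
#' @param signature_pool `"samples"` or `"type_medians"`.
#' @param signature_min_z minimum lineage z difference.
#' @param seed master seed.
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(baseline_day = NULL, pseudocount = 0.5,
                            gene_summary = "median",
                            ihw_covariate = "baseline_cpm",
                            ihw_bins = 5L, ihw_folds = 5L,
                            filter = filter_config(),
                            signature_probs = c(0.05, 0.95),
                            signature_pool = "samples",
                            signature_min_z = 0.5, seed = 1L) {
  structure(list(baseline_day = baseline_day, pseudocount = pseudocount,
                 gene_summary = gene_summary,
                 ihw_covariate = ihw_covariate, ihw_bins = ihw_bins,
                 ihw_folds = ihw_folds, filter = filter,
                 signature_probs = signature_probs,
                 signature_pool = signature_pool,
                 signature_min_z = signature_min_z,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Serialize / restore a pipeline configuration as YAML
#'
#' Unknown keys in the document are rejected.
#'
#' @param config a [pipeline_config].
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns the restored [pipeline_config].
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$filter <- unclass(x$filter)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) stop("unknown config key: ", unknown[[1]])
  if (!is.null(x$filter)) {
    fknown <- names(formals(filter_config))
    funk <- setdiff(names(x$filter), fknown)
    if (length(funk)) stop("unknown filter config key: ", funk[[1]])
    x$filter <- do.call(filter_config, x$filter)
  }
  do.call(pipeline_config, x)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

## per-gene mean baseline log2 CPM across the gene's sgRNAs, the default
## weighting covariate
.baseline_cpm_covariate <- function(counts, factors, baseline_day,
                                    pseudocount) {
  s <- counts$samples
  base_j <- which(s$day == baseline_day)
  eff <- factors$effective_size[match(s$sample_id[base_j],
                                      factors$sample_id)]
  lcpm <- vapply(seq_along(base_j), function(jj)
    .log2_cpm(counts$counts[, base_j[jj]], eff[jj], pseudocount),
    numeric(nrow(counts$counts)))
  sg_mean <- rowMeans(lcpm)
  tapply(sg_mean, counts$library$gene, mean)
}

#' Run the full hit-calling pipeline
#'
#' Executes normalization, fold-change scoring, RSA, covariate-weighted
#' adjustment, the exclusion cascade, cross-screen intersection and (when
#' an expression panel is present) the expression-signature prioritization.
#' When `outdir` is given every intermediate is written as TSV plus a JSON
#' run summary; reruns with the same inputs and config are byte-identical.
#'
#' @param study a list with elements `counts` ([ScreenCounts]), `panels`
#'   (named list of [DependencyPanel]s; the first is used for the lineage
#'   step), `scalar_scores`, and optional `expression` — e.g. a
#'   [simulate_study()] result or loaded files.
#' @param config a [pipeline_config].
#' @param outdir optional output directory.
#' @return A list of class `pipeline_result`: `norm_factors`, `gene_stats`
#'   (gene x screen x day logFC, RSA p, weight, adjusted p), `hit_calls`,
#'   `exclusions`, `hits` (prioritized [final_hits] table), `signature`
#'   (or NULL), `summary`.
#' @export
run_pipeline <- function(study, config = pipeline_config(), outdir = NULL) {
  counts <- study$counts
  validate_study(counts, panels = study$panels,
                 scalar_scores = study$scalar_scores,
                 expression = study$expression,
                 baseline_day = config$baseline_day)
  baseline_day <- config$baseline_day %||% min(counts$samples$day)

  factors <- tmm_factors(counts)
  sg_lfc <- log2_fold_change(counts, factors, baseline_day,
                             config$pseudocount)
  gene_lfc <- summarize_gene_logfc(sg_lfc, config$gene_summary)

  covariate <- .baseline_cpm_covariate(counts, factors, baseline_day,
                                       config$pseudocount)
  strata <- unique(gene_lfc[, c("cell_line", "day")])
  stats_list <- lapply(seq_len(nrow(strata)), function(k) {
    cl <- strata$cell_line[[k]]; d <- strata$day[[k]]
    ranked <- rank_constructs(sg_lfc, cell_line = cl, day = d)
    rsa <- rsa_pvalues(ranked)
    p <- rsa$rsa_p
    names(p) <- rsa$gene
    adj <- ihw_adjust(p, covariate = unname(covariate[rsa$gene]),
                      G = config$ihw_bins, K = config$ihw_folds,
                      seed = config$seed,
                      covariate_name = config$ihw_covariate)
    glfc <- gene_lfc[gene_lfc$cell_line == cl & gene_lfc$day == d, ]
    merged <- merge(glfc, adj$table,
                    by.x = "gene", by.y = "gene", sort = TRUE)
    data.frame(gene = merged$gene, cell_line = cl, day = d,
               gene_logfc = merged$gene_logfc, rsa_p = merged$raw_p,
               weight = merged$weight, adj_p = merged$adj_p,
               covariate = unname(covariate[merged$gene]),
               stringsAsFactors = FALSE)
  })
  gene_stats <- do.call(rbind, stats_list)

  hit_calls <- screen_hit_call(gene_stats, config$filter)
  exclusions <- list(
    pan_essential = pan_essential_exclusion(study$panels, config$filter),
    score_project = score_project_exclusion(study$scalar_scores,
                                            config$filter),
    lineage = lineage_exclusion(study$panels[[1]], config$filter))
  hits <- final_hits(hit_calls, exclusions, config$filter)

  signature <- NULL
  if (!is.null(study$expression)) {
    prelim <- percentile_calls(study$expression, config$signature_probs,
                               config$signature_pool)
    signature <- lineage_z_exclusion(study$expression, prelim,
                                     config$signature_min_z)
    hits <- prioritize_hits(hits, signature)
  }

  excl_flat <- do.call(rbind, lapply(names(exclusions), function(nm) {
    e <- exclusions[[nm]]
    if (!nrow(e)) return(NULL)
    data.frame(filter = nm, e, stringsAsFactors = FALSE)
  }))
  if (is.null(excl_flat))
    excl_flat <- data.frame(filter = character(), gene = character(),
                            panel = character(), value = numeric())

  summary <- list(
    n_sgrnas = nrow(counts$counts),
    n_genes = length(unique(counts$library$gene)),
    n_screens = length(unique(counts$samples$cell_line)),
    baseline_day = baseline_day,
    thresholds = unclass(config$filter),
    seed = config$seed,
    stage_counts = list(
      screen_hit_calls = sum(hit_calls$hit),
      excluded_genes = length(unique(excl_flat$gene)),
      robust_hits = sum(hits$final_class == "robust_hit"),
      late_hits = sum(hits$final_class == "late_hit"),
      signature_genes = if (is.null(signature)) NA_integer_ else
        sum(signature$call != "none")))

  result <- structure(list(norm_factors = factors, gene_stats = gene_stats,
                           hit_calls = hit_calls, exclusions = exclusions,
                           hits = hits, signature = signature,
                           summary = summary),
                      class = "pipeline_result")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(factors, file.path(outdir, "norm_factors.tsv"))
    .write_tsv(sg_lfc, file.path(outdir, "sgrna_logfc.tsv"))
    .write_tsv(gene_lfc, file.path(outdir, "gene_logfc.tsv"))
    .write_tsv(gene_stats, file.path(outdir, "gene_stats.tsv"))
    .write_tsv(hits, file.path(outdir, "hits.tsv"))
    .write_tsv(excl_flat, file.path(outdir, "exclusions.tsv"))
    if (!is.null(signature))
      .write_tsv(signature, file.path(outdir, "signature.tsv"))
    jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  sc <- x$summary$stage_counts
  cat("Pipeline result:", x$summary$n_genes, "genes,",
      x$summary$n_screens, "screens\n",
      " robust hits:", sc$robust_hits, "| late hits:", sc$late_hits,
      "| excluded genes:", sc$excluded_genes, "\n")
  invisible(x)
}

#' Score pipeline hits against planted truth
#'
#' @param hits a [final_hits] table.
#' @param truth a [simulate_truth] result.
#' @return One-row data.frame: SL sensitivity, counts of pan-essential and
#'   lineage-essential contamination among final hits, empirical FDR of
#'   final hits against the planted SL class, and hit counts.
#' @export
score_against_truth <- function(hits, truth) {
  final <- hits$gene[hits$final_class %in% c("robust_hit", "late_hit")]
  cls <- truth$genes$dependency_class[match(final, truth$genes$gene)]
  sl_genes <- truth$genes$gene[truth$genes$dependency_class ==
                                 "sl_mutant_specific"]
  data.frame(
    sl_sensitivity = if (length(sl_genes))
      mean(sl_genes %in% final) else NA_real_,
    pan_contamination = sum(cls == "pan_essential"),
    lineage_contamination = sum(cls == "lineage_essential"),
    fdr = if (length(final)) mean(cls != "sl_mutant_specific") else 0,
    n_robust = sum(hits$final_class == "robust_hit"),
    n_late = sum(hits$final_class == "late_hit"))
}

#' Replicated parameter-recovery study
#'
#' Simulates `n_reps` complete studies, runs the full pipeline on each and
#' scores the final hits against the planted truth labels.
#'
#' @param sim a [sim_config] (its seed is re-derived per replicate).
#' @param config a [pipeline_config].
#' @param n_reps number of replicate simulations.
#' @param seed master seed; replicate r uses `seed + 1000 * r`.
#' @return A list of class `RecoveryMetrics`: `per_rep` (one scored row per
#'   replicate) and `summary` (mean and sd of each metric).
#' @export
run_recovery_study <- function(sim, config = pipeline_config(),
                               n_reps = 5L, seed = 1L) {
  stopifnot(n_reps >= 1L)
  rows <- lapply(seq_len(n_reps), function(r) {
    sim_r <- sim
    sim_r$seed <- as.integer(seed + 1000L * r)
    study <- simulate_study(sim_r)
    res <- run_pipeline(study, config)
    cbind(rep = r, score_against_truth(res$hits, study$truth))
  })
  per_rep <- do.call(rbind, rows)
  metrics <- setdiff(names(per_rep), "rep")
  summary <- data.frame(metric = metrics,
                        mean = vapply(per_rep[metrics], mean, numeric(1)),
                        sd = vapply(per_rep[metrics], stats::sd, numeric(1)),
                        row.names = NULL)
  structure(list(per_rep = per_rep, summary = summary),
            class = "RecoveryMetrics")
}

#' @export
print.RecoveryMetrics <- function(x, ...) {
  cat("Recovery over", nrow(x$per_rep), "replicate simulations:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a human-readable run report
#'
#' Renders a markdown summary with the per-stage attrition table plus
#' diagnostic plots (gene logFC distributions per day, raw p-value
#' histograms, covariate-versus-weight, attrition waterfall) into a
#' self-contained directory.
#'
#' @param result a [run_pipeline] result.
#' @param dir report directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gs <- result$gene_stats
  grDevices::png(file.path(dir, "logfc_by_day.png"), 900, 500)
  graphics::boxplot(gene_logfc ~ interaction(cell_line, day), data = gs,
                    las = 2, ylab = "gene-summary logFC", xlab = "",
                    main = "Gene logFC by screen and day")
  grDevices::dev.off()
  grDevices::png(file.path(dir, "pvalue_hist.png"), 700, 500)
  graphics::hist(gs$rsa_p, breaks = 40, main = "RSA p-values",
                 xlab = "p")
  grDevices::dev.off()
  grDevices::png(file.path(dir, "covariate_vs_weight.png"), 700, 500)
  graphics::plot(gs$covariate, gs$weight, pch = 16,
                 cex = 0.4, xlab = "baseline log2 CPM covariate",
                 ylab = "hypothesis weight",
                 main = "Covariate vs learned weight")
  grDevices::dev.off()

  excl_counts <- vapply(result$exclusions,
                        function(e) length(unique(e$gene)), integer(1))
  attrition <- data.frame(
    stage = c("library genes", "screen hits (all screens, later day)",
              paste0("excluded: ", names(excl_counts)),
              "robust hits", "late hits"),
    genes = c(result$summary$n_genes,
              sum(result$hits$n_screens_hit_t2 ==
                    result$summary$n_screens),
              unname(excl_counts),
              result$summary$stage_counts$robust_hits,
              result$summary$stage_counts$late_hits))
  grDevices::png(file.path(dir, "attrition.png"), 800, 500)
  op <- graphics::par(mar = c(12, 4, 2, 1))
  graphics::barplot(attrition$genes, names.arg = attrition$stage, las = 2,
                    ylab = "genes", main = "Gene attrition")
  graphics::par(op)
  grDevices::dev.off()

  n_hits <- result$summary$stage_counts$robust_hits +
    result$summary$stage_counts$late_hits
  md <- c("# Screen analysis report", "",
          sprintf("- Genes: %d, screens: %d, baseline day: %d",
                  result$summary$n_genes, result$summary$n_screens,
                  result$summary$baseline_day),
          sprintf("- Final hits: %d (%d robust, %d late)", n_hits,
                  result$summary$stage_counts$robust_hits,
                  result$summary$stage_counts$late_hits),
          if (is.null(result$signature))
            "- Expression signature: skipped (no expression input)"
          else sprintf("- Expression signature: %d genes",
                       result$summary$stage_counts$signature_genes),
          "", "## Attrition", "",
          knitr_kable_fallback(attrition), "",
          "## Diagnostics", "",
          "![](logfc_by_day.png)", "![](pvalue_hist.png)",
          "![](covariate_vs_weight.png)", "![](attrition.png)")
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

## minimal pipe-table renderer so reports need no extra packages
knitr_kable_fallback <- function(df) {
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1L, function(r)
    paste0("| ", paste(trimws(r), collapse = " | "), " |"))
  c(header, sep, rows)
}
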