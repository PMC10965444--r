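## The stepwise exclusion-and-intersection cascade: per-screen hit calling,
## pan-essential / published-score / lineage exclusions against external
## dependency panels, then cross-screen intersection at two timepoints.

#' Thresholds of the hit-calling and exclusion cascade
#'
#' Defaults are the published cutoffs: screen hits need gene-summary
#' logFC <= -0.5 (boundary inclusive) with adjusted P < 0.01 (strict);
#' pan-essentials are excluded at a panel median dependency score < -0.4;
#' published priority / cell-line dependency scores exclude at > 0.4;
#' lineage exclusion removes genes with median CM dependency < -0.5 or any
#' wild-type UM control line < -0.5; final hits must score at both day 14
#' and day 21 (robust) or day 21 only (late).
#'
#' @param screen_lfc,screen_p screen hit thresholds.
#' @param panessential pan-essential exclusion threshold.
#' @param score_priority published scalar-score exclusion threshold.
#' @param cm_lineage,wt_um lineage exclusion thresholds.
#' @param timepoints the two days defining robust vs late hits.
#' @param pan_aggregate aggregator over panel cell lines for the
#'   pan-essential step (`median`, `mean`, or `fraction_below`, the share of
#'   lines below the threshold with exclusion when it exceeds 0.5).
#' @return A list of class `FilterConfig`.
#' @export
filter_config <- function(screen_lfc = -0.5, screen_p = 0.01,
                          panessential = -0.4, score_priority = 0.4,
                          cm_lineage = -0.5, wt_um = -0.5,
                          timepoints = c(14L, 21L),
                          pan_aggregate = c("median", "mean",
                                            "fraction_below")) {
  stopifnot(length(timepoints) == 2L, all(is.finite(c(
    screen_lfc, screen_p, panessential, score_priority, cm_lineage, wt_um))))
  structure(list(screen_lfc = screen_lfc, screen_p = screen_p,
                 panessential = panessential,
                 score_priority = score_priority,
                 cm_lineage = cm_lineage, wt_um = wt_um,
                 timepoints = sort(as.integer(timepoints)),
                 pan_aggregate = match.arg(pan_aggregate)),
            class = "FilterConfig")
}

#' Per-screen, per-day hit calls
#'
#' A gene is a hit in one screen at one day iff its gene-summary logFC is
#' at most the fold-change cutoff (inclusive) and its adjusted p-value is
#' strictly below the significance cutoff.
#'
#' @param stats data.frame with columns `gene`, `cell_line`, `day`,
#'   `gene_logfc` (or `median_logfc`) and `adj_p`.
#' @param config a [filter_config].
#' @return `stats` with a logical `hit` column appended.
#' @export
screen_hit_call <- function(stats, config = filter_config()) {
  lfc <- stats$gene_logfc %||% stats$median_logfc
  if (is.null(lfc) || is.null(stats$adj_p))
    stop("stats needs gene_logfc (or median_logfc) and adj_p columns")
  if (anyNA(lfc) || anyNA(stats$adj_p))
    stop("missing statistics for some library genes")
  stats$hit <- lfc <= config$screen_lfc & stats$adj_p < config$screen_p
  stats
}

.pan_aggregate <- function(x, config) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  switch(config$pan_aggregate,
         median = stats::median(x),
         mean = mean(x),
         fraction_below = {
           # map the fraction-below rule onto the same "< threshold" test:
           # report the threshold itself minus margin when > 50% of lines
           # are below it
           if (mean(x < config$panessential) > 0.5)
             config$panessential - 1 else 0
         })
}

#' Pan-essential exclusion against dependency panels
#'
#' A gene is excluded iff its aggregated dependency score across all
#' annotated cell lines is strictly below the cutoff in any of the panels
#' ("or" semantics). Missing values are dropped from the aggregate; a gene
#' absent from a panel cannot be excluded by that panel.
#'
#' @param panels list of [DependencyPanel] objects.
#' @param config a [filter_config].
#' @return A data.frame `gene`, `panel`, `value` of class
#'   `exclusion_table`, one row per (gene, flagging panel).
#' @export
pan_essential_exclusion <- function(panels, config = filter_config()) {
  rows <- list()
  for (p in panels) {
    med <- apply(p$scores, 1L, .pan_aggregate, config = config)
    flag <- !is.na(med) & med < config$panessential
    if (any(flag))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = rownames(p$scores)[flag], panel = p$dataset,
        value = unname(med[flag]), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), panel = character(), value = numeric())
  class(out) <- c("exclusion_table", "data.frame")
  out
}

#' Exclusion by published per-gene scalar scores
#'
#' Excluded iff `priority_score > cutoff` or
#' `cellline_dependency_score > cutoff` (strict). A missing field falls
#' through to the other; a gene with both missing is retained.
#'
#' @param scores a [gene_scalar_scores] table.
#' @param config a [filter_config].
#' @return An `exclusion_table` data.frame (`gene`, `panel`, `value`).
#' @export
score_project_exclusion <- function(scores, config = filter_config()) {
  pri <- !is.na(scores$priority_score) &
    scores$priority_score > config$score_priority
  dep <- !is.na(scores$cellline_dependency_score) &
    scores$cellline_dependency_score > config$score_priority
  flag <- pri | dep
  out <- data.frame(gene = scores$gene[flag],
                    panel = rep("score_project", sum(flag)),
                    value = pmax(scores$priority_score[flag],
                                 scores$cellline_dependency_score[flag],
                                 na.rm = TRUE),
                    stringsAsFactors = FALSE)
  class(out) <- c("exclusion_table", "data.frame")
  out
}

#' Melanocyte-lineage exclusion
#'
#' Removes genes essential in the melanocyte lineage regardless of
#' genotype: excluded iff the median dependency score over
#' cutaneous-melanoma panel lines is strictly below the CM cutoff, or any
#' wild-type UM control line scores strictly below the control cutoff.
#'
#' @param panel the [DependencyPanel] carrying the lineage annotations
#'   (the CRISPR panel by default in the pipeline).
#' @param config a [filter_config].
#' @return An `exclusion_table` data.frame (`gene`, `panel`, `value`).
#' @export
lineage_exclusion <- function(panel, config = filter_config()) {
  ann <- panel$annotations
  cm <- which(ann$is_cm_panel_member)
  wt <- which(ann$is_wt_um_control)
  if (!length(cm)) stop("no CM panel members annotated")
  if (!length(wt)) stop("no wild-type UM control lines annotated")
  cm_med <- apply(panel$scores[, cm, drop = FALSE], 1L, stats::median,
                  na.rm = TRUE)
  wt_min <- suppressWarnings(
    apply(panel$scores[, wt, drop = FALSE], 1L, min, na.rm = TRUE))
  flag_cm <- !is.na(cm_med) & cm_med < config$cm_lineage
  flag_wt <- is.finite(wt_min) & wt_min < config$wt_um
  flag <- flag_cm | flag_wt
  out <- data.frame(gene = rownames(panel$scores)[flag],
                    panel = as.character(ifelse(flag_cm[flag], "cm_lineage",
                                                "wt_um_control")),
                    value = as.numeric(ifelse(flag_cm[flag], cm_med[flag],
                                              wt_min[flag])),
                    stringsAsFactors = FALSE)
  class(out) <- c("exclusion_table", "data.frame")
  out
}

#' Final cross-screen hit table
#'
#' Candidates at a day are the genes called hit in every screen at that day
#' minus the union of exclusions. Robust hits are candidates at both
#' timepoints, late hits at the later timepoint only; everything else is a
#' non-hit. `excluded_by` records every filter tag that flagged the gene,
#' computed for all steps regardless of order.
#'
#' @param hit_calls a [screen_hit_call] result covering all screens.
#' @param exclusions list of `exclusion_table` data.frames, named by filter
#'   tag (e.g. `pan_essential`, `score_project`, `lineage`).
#' @param config a [filter_config].
#' @return A data.frame of class `HitTable`: `gene`, per-day screen-hit
#'   counts, `excluded_by` (comma-joined tags), `final_class`
#'   (`robust_hit`/`late_hit`/`non_hit`), `best_adj_p`, `in_signature`
#'   (NA until [prioritize_hits()]).
#' @export
final_hits <- function(hit_calls, exclusions = list(),
                       config = filter_config()) {
  genes <- sort(unique(hit_calls$gene))
  n_screens <- length(unique(hit_calls$cell_line))
  t1 <- config$timepoints[[1]]; t2 <- config$timepoints[[2]]
  n_hit <- function(d) {
    sub <- hit_calls[hit_calls$day == d, , drop = FALSE]
    counts <- tapply(sub$hit, sub$gene, sum)
    out <- integer(length(genes)); names(out) <- genes
    out[names(counts)] <- as.integer(counts)
    out
  }
  hits1 <- n_hit(t1); hits2 <- n_hit(t2)
  tags <- lapply(exclusions, function(e) unique(e$gene))
  excluded_by <- vapply(genes, function(g)
    paste(names(tags)[vapply(tags, function(x) g %in% x, logical(1))],
          collapse = ","), character(1))
  excluded <- excluded_by != ""
  cand1 <- hits1 == n_screens & !excluded
  cand2 <- hits2 == n_screens & !excluded
  final_class <- ifelse(cand1 & cand2, "robust_hit",
                        ifelse(cand2, "late_hit", "non_hit"))
  adj <- hit_calls[hit_calls$day %in% c(t1, t2), , drop = FALSE]
  best <- tapply(adj$adj_p, adj$gene, min)
  out <- data.frame(gene = genes,
                    n_screens_hit_t1 = unname(hits1),
                    n_screens_hit_t2 = unname(hits2),
                    excluded_by = unname(excluded_by),
                    final_class = unname(final_class),
                    best_adj_p = unname(best[genes]),
                    in_signature = NA,
                    stringsAsFactors = FALSE)
  attr(out, "timepoints") <- c(t1, t2)
  attr(out, "n_screens") <- n_screens
  class(out) <- c("HitTable", "data.frame")
  out
}
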