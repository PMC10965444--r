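## Pan-cancer percentile expression signature with melanocyte-lineage
## z-score exclusion, used to prioritize screen hits by tumor-type-specific
## expression.

#' Preliminary percentile expression calls
#'
#' Per gene, the 5th and 95th percentiles (linear-interpolation quantiles)
#' of TPM over all pooled non-target samples are compared with the
#' target-type median: strictly above the 95th percentile calls the gene
#' `high`, strictly below the 5th percentile calls it `low`, otherwise
#' `none`. An alternative mode takes the percentiles over per-tumor-type
#' median TPM instead of pooled samples.
#'
#' @param panel an [ExpressionPanel].
#' @param probs lower/upper percentile probabilities.
#' @param pool `"samples"` (default, percentiles over all pooled non-target
#'   samples) or `"type_medians"` (over per-type medians).
#' @return A data.frame with columns `gene`, `call`, `um_median`, `q05`,
#'   `q95`.
#' @export
percentile_calls <- function(panel, probs = c(0.05, 0.95),
                             pool = c("samples", "type_medians")) {
  stopifnot(inherits(panel, "ExpressionPanel"))
  pool <- match.arg(pool)
  is_target <- panel$sample_type == panel$target_type
  if (sum(!is_target) < 20L)
    warning("fewer than 20 non-target samples; percentiles will be coarse")
  target_med <- apply(panel$tpm[, is_target, drop = FALSE], 1L,
                      stats::median)
  ref <- if (pool == "samples") {
    panel$tpm[, !is_target, drop = FALSE]
  } else {
    types <- setdiff(unique(panel$sample_type), panel$target_type)
    vapply(types, function(ty)
      apply(panel$tpm[, panel$sample_type == ty, drop = FALSE], 1L,
            stats::median), numeric(nrow(panel$tpm)))
  }
  q <- t(apply(ref, 1L, stats::quantile, probs = probs, names = FALSE))
  call <- ifelse(target_med > q[, 2L], "high",
                 ifelse(target_med < q[, 1L], "low", "none"))
  data.frame(gene = rownames(panel$tpm), call = call,
             um_median = unname(target_med), q05 = q[, 1L], q95 = q[, 2L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Lineage z-score exclusion of percentile calls
#'
#' Per gene, lineage medians of `log2(TPM+1)` are z-scored across tumor
#' types; a `high` call survives only if the target z exceeds the
#' comparator z by at least `min_diff` (signed difference; a `low` call
#' needs the comparator to exceed the target). This removes genes whose
#' expression pattern is shared across the melanocyte lineage rather than
#' specific to the target type. Genes with zero variance across lineage
#' medians lose their call with tag `zero_lineage_variance`.
#'
#' @param panel an [ExpressionPanel] (needs >= 3 tumor types).
#' @param calls a [percentile_calls] result.
#' @param min_diff minimum signed z difference (default 0.5).
#' @param absolute use the absolute z difference instead of the signed one.
#' @return A data.frame of class `SignatureResult`: `gene`, `call` (final),
#'   `prelim_call`, `um_median`, `q05`, `q95`, `z_target`, `z_comparator`,
#'   `excluded_reason`.
#' @export
lineage_z_exclusion <- function(panel, calls, min_diff = 0.5,
                                absolute = FALSE) {
  stopifnot(inherits(panel, "ExpressionPanel"))
  types <- unique(panel$sample_type)
  if (length(types) < 3L) stop("z-scores need >= 3 tumor types")
  med <- matrix(NA_real_, nrow(panel$tpm), length(types),
                dimnames = list(rownames(panel$tpm), types))
  for (ty in types)
    med[, ty] <- apply(
      log2(panel$tpm[, panel$sample_type == ty, drop = FALSE] + 1), 1L,
      stats::median)
  mu <- rowMeans(med)
  sd <- apply(med, 1L, stats::sd)
  z <- (med - mu) / sd
  zt <- z[, panel$target_type]
  zc <- z[, panel$comparator_type]
  calls <- calls[match(rownames(panel$tpm), calls$gene), , drop = FALSE]
  diff <- if (absolute) abs(zt - zc) else
    ifelse(calls$call == "low", zc - zt, zt - zc)
  final <- calls$call
  reason <- rep("", nrow(calls))
  has_call <- calls$call != "none"
  degenerate <- has_call & (sd == 0 | !is.finite(diff))
  final[degenerate] <- "none"
  reason[degenerate] <- "zero_lineage_variance"
  fails <- has_call & !degenerate & diff < min_diff
  final[fails] <- "none"
  reason[fails] <- "lineage_z"
  out <- data.frame(gene = calls$gene, call = final,
                    prelim_call = calls$call, um_median = calls$um_median,
                    q05 = calls$q05, q95 = calls$q95,
                    z_target = unname(zt), z_comparator = unname(zc),
                    excluded_reason = reason, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("SignatureResult", "data.frame")
  out
}

#' Flag and order screen hits by the expression signature
#'
#' Sets `in_signature` on every hit and orders the table: robust hits
#' before late hits before non-hits, signature members first within class,
#' then ascending best adjusted p-value.
#'
#' @param hits a [final_hits] table.
#' @param signature a [lineage_z_exclusion] result.
#' @return The reordered `HitTable` with `in_signature` filled in.
#' @export
prioritize_hits <- function(hits, signature) {
  sig_genes <- signature$gene[signature$call != "none"]
  hits$in_signature <- hits$gene %in% sig_genes
  class_rank <- match(hits$final_class,
                      c("robust_hit", "late_hit", "non_hit"))
  ord <- order(class_rank, !hits$in_signature, hits$best_adj_p, hits$gene)
  out <- hits[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
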