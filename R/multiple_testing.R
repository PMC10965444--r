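## Multiple-testing adjustment: plain Benjamini-Hochberg, weighted BH, and a
## cross-fitted covariate-weighted procedure ("IHW-lite"). Weights are
## learned per covariate bin on held-out folds as plug-in estimates of the
## non-null fraction, which keeps the held-out p-values independent of their
## weights and preserves the usual BH FDR argument.

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment via [stats::p.adjust()]; input order is preserved.
#'
#' @param p p-values in `[0, 1]`.
#' @return Adjusted p-values, clipped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Weighted Benjamini-Hochberg
#'
#' Applies BH to `p / w`. A zero weight maps its hypothesis to an effective
#' p-value of infinity (adjusted value 1). The weight budget `mean(w) = 1`
#' is enforced so weighting cannot buy extra rejections overall.
#'
#' @param p p-values in `[0, 1]`.
#' @param w non-negative weights with mean 1 (within 1e-9).
#' @return Adjusted p-values; rejections at level `alpha` are those `<= alpha`.
#' @export
weighted_bh <- function(p, w) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (length(w) != length(p)) stop("p and w lengths differ")
  if (any(w < 0)) stop("weights must be >= 0")
  if (abs(mean(w) - 1) > 1e-9) stop("weights must have mean 1")
  eff <- ifelse(w > 0, p / w, Inf)
  # BH is pure arithmetic on the sorted values, so effective p-values above 1
  # pass through and are clipped at 1 by the step-up rule
  stats::p.adjust(eff, method = "BH")
}

#' Plug-in estimate of the null proportion
#'
#' `min(1, #\{p > lambda\} / ((1 - lambda) m))`, the standard tail-census
#' estimator of the fraction of true nulls.
#'
#' @param p p-values.
#' @param lambda censoring point in `(0, 1)`.
#' @return Estimated null proportion in `[0, 1]`.
#' @export
estimate_pi0 <- function(p, lambda = 0.5) {
  if (!length(p)) stop("empty p-value vector")
  stopifnot(lambda > 0, lambda < 1)
  min(1, sum(p > lambda) / ((1 - lambda) * length(p)))
}

#' Cross-fitted covariate-weighted BH adjustment
#'
#' Hypotheses are grouped into `G` covariate quantile bins and split into
#' `K` folds stratified by bin. For each fold, per-bin weights are learned
#' on the other folds as `w_g` proportional to `max(1 - pi0_g, 0.05)`
#' (via [estimate_pi0()] within the bin) and normalized to mean 1 over the
#' held-out fold; [weighted_bh()] is then applied with the cross-fitted
#' weights. With a constant covariate all bins coincide and the result
#' reduces to [bh_adjust()]. Falls back to unweighted BH (with a warning)
#' when there are fewer than `10 * G * K` hypotheses.
#'
#' When `p` is named, fold assignment is keyed by the sorted names so the
#' result is invariant to input order; unnamed input uses input order.
#'
#' @param p p-values in `[0, 1]`, optionally named by gene.
#' @param covariate finite numeric vector, independent of `p` under the
#'   null but informative about power (e.g. baseline read abundance).
#' @param G number of covariate bins.
#' @param K number of cross-fitting folds.
#' @param seed integer seed for the stratified fold assignment.
#' @param lambda censoring point passed to [estimate_pi0()].
#' @param covariate_name label stored in the result metadata.
#' @return A list of class `AdjustmentResult`: `table` (data.frame with
#'   `gene`, `raw_p`, `weight`, `adj_p`) and `meta` (covariate name, `G`,
#'   `K`, `lambda`, `seed`, `fallback`).
#' @export
ihw_adjust <- function(p, covariate, G = 5L, K = 5L, seed = 1L,
                       lambda = 0.5, covariate_name = "covariate") {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(!is.finite(covariate))) stop("covariate must be finite")
  if (length(covariate) != length(p)) stop("p and covariate lengths differ")
  m <- length(p)
  gene <- names(p) %||% as.character(seq_len(m))
  meta <- list(covariate = covariate_name, G = G, K = K, lambda = lambda,
               seed = seed, fallback = FALSE)
  if (m < 10L * G * K) {
    warning("fewer than ", 10L * G * K,
            " hypotheses; falling back to unweighted BH")
    meta$fallback <- TRUE
    out <- data.frame(gene = gene, raw_p = unname(p), weight = 1,
                      adj_p = bh_adjust(unname(p)), stringsAsFactors = FALSE)
    return(structure(list(table = out, meta = meta),
                     class = "AdjustmentResult"))
  }
  breaks <- unique(stats::quantile(covariate, probs = seq(0, 1, length.out
                                                          = G + 1)))
  bin <- if (length(breaks) < 3L) rep(1L, m) else
    as.integer(cut(covariate, breaks, include.lowest = TRUE))
  # stable stratified folds: order within bin by name (or input position),
  # then assign a seeded permutation of cyclic fold labels
  fold <- integer(m)
  for (b in sort(unique(bin))) {
    idx <- which(bin == b)
    idx <- idx[order(gene[idx])]
    labs <- rep_len(seq_len(K), length(idx))
    labs <- withr::with_seed(seed + b, sample(labs))
    fold[idx] <- labs
  }
  w <- numeric(m)
  for (k in seq_len(K)) {
    held <- fold == k
    raw_w <- vapply(sort(unique(bin)), function(b) {
      train <- !held & bin == b
      if (!any(train)) return(0.05)
      max(1 - estimate_pi0(p[train], lambda), 0.05)
    }, numeric(1))
    wk <- raw_w[match(bin[held], sort(unique(bin)))]
    w[held] <- wk / mean(wk)
  }
  w <- w / mean(w)
  out <- data.frame(gene = gene, raw_p = unname(p), weight = w,
                    adj_p = weighted_bh(unname(p), w),
                    stringsAsFactors = FALSE)
  structure(list(table = out, meta = meta), class = "AdjustmentResult")
}

#' @export
print.AdjustmentResult <- function(x, ...) {
  cat("AdjustmentResult:", nrow(x$table), "hypotheses; covariate",
      x$meta$covariate, if (x$meta$fallback) "(BH fallback)" else
        sprintf("(G=%d, K=%d)", x$meta$G, x$meta$K), "\n")
  invisible(x)
}
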