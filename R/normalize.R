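## Count normalization and fold-change scoring.
##
## TMM here follows the published trimmed-mean-of-M-values recipe: pick the
## reference sample by 75th-percentile count fraction, form M (log-ratio),
## A (log-abundance) and the binomial asymptotic variance over sgRNAs nonzero
## in both samples, doubly trim (30% each tail by M, 5% each tail by A), and
## take the precision-weighted mean of the surviving M values.

#' TMM normalization factors for a pooled screen
#'
#' Computes one trimmed-mean-of-M-values factor per sample. All-zero sgRNA
#' rows are removed before computation. Factors are rescaled so their
#' geometric mean is exactly 1; effective library size is
#' `library_size * tmm_factor`.
#'
#' @param counts a [ScreenCounts] object or a bare count matrix.
#' @param logratio_trim,abundance_trim two-sided trim fractions on the M and
#'   A ranks (published defaults 0.30 and 0.05).
#' @return A data.frame of class `NormFactors` with columns `sample_id`,
#'   `library_size`, `tmm_factor`, `effective_size`.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, abundance_trim = 0.05) {
  m <- if (inherits(counts, "ScreenCounts")) counts$counts else as.matrix(counts)
  if (ncol(m) < 2L) stop("TMM needs >= 2 samples")
  m <- m[rowSums(m) > 0, , drop = FALSE]
  N <- colSums(m)
  if (any(N <= 0)) stop("every sample must have positive library size")
  f75 <- apply(m, 2L, function(y) stats::quantile(y / sum(y), 0.75,
                                                  names = FALSE))
  ref <- which.min(abs(f75 - mean(f75)))
  log2f <- vapply(seq_len(ncol(m)), function(k) {
    if (k == ref) return(0)
    yk <- m[, k]; yr <- m[, ref]
    keep <- yk > 0 & yr > 0
    yk <- yk[keep]; yr <- yr[keep]
    M <- log2((yk / N[k]) / (yr / N[ref]))
    if (all(abs(M) < 1e-9)) return(0)  # scaled copy of the reference
    A <- 0.5 * log2((yk / N[k]) * (yr / N[ref]))
    v <- (N[k] - yk) / (N[k] * yk) + (N[ref] - yr) / (N[ref] * yr)
    n <- length(M)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abundance_trim) + 1; hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "first")
    rA <- rank(A, ties.method = "first")
    keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    # degenerate-trim guard: 10 survivors for real libraries, the nominal
    # post-trim retention for toy-sized ones
    min_kept <- min(10L, floor(n * (1 - 2 * logratio_trim)))
    if (sum(keep2) < min_kept) {
      warning("too few sgRNAs survive TMM trimming for sample ",
              colnames(m)[k] %||% k, "; factor set to 1")
      return(0)
    }
    sum(M[keep2] / v[keep2]) / sum(1 / v[keep2])
  }, numeric(1))
  f <- 2^log2f
  f <- f / exp(mean(log(f)))
  sample_id <- colnames(m) %||% as.character(seq_len(ncol(m)))
  out <- data.frame(sample_id = sample_id, library_size = unname(N),
                    tmm_factor = f, effective_size = unname(N) * f,
                    stringsAsFactors = FALSE)
  class(out) <- c("NormFactors", "data.frame")
  out
}

## log2 CPM with the pseudocount applied on the CPM scale (0.5 CPM by
## default): keeps zero-count sgRNAs finite and makes fold changes exactly
## invariant to rescaling a sample's counts. At an effective size of 1e6
## this is identical to adding half a count.
.log2_cpm <- function(y, effective_size, pseudocount = 0.5) {
  log2(1e6 * y / effective_size + pseudocount)
}

#' sgRNA-level log2 fold changes against the baseline day
#'
#' For every (cell line, day) beyond the baseline, computes
#' `log2(cpm_t) - log2(cpm_0)` per sgRNA on TMM-effective library sizes with
#' a pseudocount. Replicates are averaged at the log fold-change level: each
#' day-t replicate is compared against the mean baseline log2 CPM of its
#' cell line, then replicate logFCs are averaged arithmetically.
#'
#' @param counts a [ScreenCounts] object.
#' @param factors a [tmm_factors] result covering every sample.
#' @param baseline_day baseline timepoint; defaults to the earliest day.
#' @param pseudocount offset added on the CPM scale before taking logs
#'   (must be > 0); 0.5 CPM equals half a count at a 1e6 effective size.
#' @return A data.frame of class `LogFcTable` with columns `sgrna`, `gene`,
#'   `cell_line`, `day`, `logfc`.
#' @export
log2_fold_change <- function(counts, factors, baseline_day = NULL,
                             pseudocount = 0.5) {
  stopifnot(inherits(counts, "ScreenCounts"), pseudocount > 0)
  s <- counts$samples
  if (is.null(baseline_day)) baseline_day <- min(s$day)
  eff <- factors$effective_size[match(s$sample_id, factors$sample_id)]
  if (anyNA(eff)) stop("normalization factors missing for some samples")
  lcpm <- matrix(NA_real_, nrow(counts$counts), ncol(counts$counts))
  for (j in seq_len(ncol(counts$counts)))
    lcpm[, j] <- .log2_cpm(counts$counts[, j], eff[j], pseudocount)
  out <- list()
  for (cl in unique(s$cell_line)) {
    base_j <- which(s$cell_line == cl & s$day == baseline_day)
    if (!length(base_j)) stop("no baseline (day ", baseline_day,
                              ") sample for cell line ", cl)
    base <- rowMeans(lcpm[, base_j, drop = FALSE])
    for (d in setdiff(sort(unique(s$day[s$cell_line == cl])), baseline_day)) {
      jj <- which(s$cell_line == cl & s$day == d)
      lfc <- rowMeans(lcpm[, jj, drop = FALSE] - base)
      out[[length(out) + 1L]] <- data.frame(
        sgrna = counts$library$sgrna, gene = counts$library$gene,
        cell_line = cl, day = d, logfc = lfc, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("LogFcTable", "data.frame")
  out
}

#' Gene-summary log fold changes
#'
#' Collapses replicate-averaged sgRNA logFCs to one value per (gene,
#' cell line, day) using the median (robust to single inefficient
#' constructs) or, optionally, the mean.
#'
#' @param table an sgRNA-level [log2_fold_change] result.
#' @param summary `"median"` (default) or `"mean"`.
#' @return A data.frame with columns `gene`, `cell_line`, `day`,
#'   `gene_logfc`.
#' @export
summarize_gene_logfc <- function(table, summary = c("median", "mean")) {
  summary <- match.arg(summary)
  fn <- if (summary == "median") stats::median else mean
  agg <- stats::aggregate(logfc ~ gene + cell_line + day, data = table,
                          FUN = fn)
  names(agg)[names(agg) == "logfc"] <- "gene_logfc"
  agg <- agg[order(agg$cell_line, agg$day, agg$gene), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
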