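## RSA depletion statistic: a gene's p-value is the minimum over iterated
## hypergeometric upper tails of its construct ranks in the genome-wide
## depletion ordering. One-sided for dropout only: rank 1 is the most
## depleted construct.

#' Rank constructs by depletion
#'
#' Ascending sort of sgRNA logFCs for one (cell line, day): the most
#' negative logFC gets rank 1. Tied constructs all receive the worst
#' (maximum) rank of the tied block, so ties cannot borrow significance.
#'
#' @param table an sgRNA-level [log2_fold_change] result (or any data.frame
#'   with `sgrna`, `gene`, `logfc` and optional `cell_line`/`day` columns).
#' @param cell_line,day optional filters selecting one stratum of `table`.
#' @return A data.frame of class `RankedConstructs` with columns `sgrna`,
#'   `gene`, `rank`; attribute `N` is the total number of constructs ranked.
#' @export
rank_constructs <- function(table, cell_line = NULL, day = NULL) {
  if (!is.null(cell_line)) table <- table[table$cell_line == cell_line, ]
  if (!is.null(day)) table <- table[table$day == day, ]
  if (!all(is.finite(table$logfc))) stop("all logFC values must be finite")
  out <- data.frame(sgrna = table$sgrna, gene = table$gene,
                    rank = as.integer(rank(table$logfc, ties.method = "max")),
                    stringsAsFactors = FALSE)
  attr(out, "N") <- nrow(out)
  class(out) <- c("RankedConstructs", "data.frame")
  out
}

#' Hypergeometric upper tail, log-space
#'
#' `P(X >= i)` for `X` hypergeometric with population `N`, `n` marked
#' elements and `r` draws:
#' `sum_{j=i}^{min(n,r)} C(r,j) C(N-r, n-j) / C(N,n)`.
#' Binomial coefficients are evaluated as log-gamma differences so the tail
#' is stable for libraries beyond 1e5 constructs. Vectorized over `n`, `r`
#' and `i` (with recycling); `N` is scalar.
#'
#' @param N population size.
#' @param n number of marked elements (a gene's constructs).
#' @param r number of draws (a construct's rank).
#' @param i threshold count.
#' @return `P(X >= i)` in `[0, 1]`.
#' @export
hypergeom_upper_tail <- function(N, n, r, i) {
  stopifnot(length(N) == 1L, N == round(N), N >= 0)
  len <- max(length(n), length(r), length(i))
  n <- rep_len(as.numeric(n), len)
  r <- rep_len(as.numeric(r), len)
  i <- rep_len(as.numeric(i), len)
  if (any(i < 0 | i > n | n > N | r < 0 | r > N))
    stop("require 0 <= i <= n <= N and 0 <= r <= N")
  denom <- lchoose(N, n)
  p <- numeric(len)
  # term_j = C(r, j) C(N-r, n-j) / C(N, n); lchoose returns -Inf outside the
  # support, so masking by j is only needed against the i threshold
  for (j in seq(0, max(n))) {
    term <- exp(lchoose(r, j) + lchoose(N - r, n - j) - denom)
    active <- j >= i & j <= n
    p[active] <- p[active] + term[active]
  }
  pmin(pmax(p, 0), 1)
}

#' RSA p-values from ranked constructs
#'
#' For a gene with sorted ranks `r_1 <= ... <= r_n` among `N` constructs,
#' `p = min_i P(X >= i)` with `X` hypergeometric(N, n, r_i): the best
#' achievable tail over all prefixes of the gene's constructs. The minimum
#' is taken as-is (the statistic's standard definition); multiplicity across
#' genes is handled downstream.
#'
#' @param ranked a [rank_constructs] result.
#' @return A data.frame with columns `gene`, `rsa_p` (in `(0, 1]`), sorted
#'   by gene.
#' @export
rsa_pvalues <- function(ranked) {
  N <- attr(ranked, "N")
  ord <- order(ranked$gene, ranked$rank)
  gene <- ranked$gene[ord]
  r <- ranked$rank[ord]
  n_per <- table(gene)[unique(gene)]
  n <- rep(as.integer(n_per), as.integer(n_per))
  i <- sequence(as.integer(n_per))
  tails <- hypergeom_upper_tail(N, n, r, i)
  p <- vapply(split(tails, gene), min, numeric(1))
  out <- data.frame(gene = names(p), rsa_p = unname(p),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
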