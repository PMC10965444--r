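# Independent oracles and small fixture builders shared across tests.

# Exhaustive-enumeration oracle for the hypergeometric upper tail: counts,
# over all C(N, n) placements of n construct ranks among N, how many have at
# least i ranks <= r. Returns the N x n matrix of counts; tail probability
# is counts[r, i] / choose(N, n). Independent of the log-gamma code path.
enum_tail_counts <- function(N, n) {
  subsets <- utils::combn(N, n)
  counts <- matrix(0, N, n)
  for (col in seq_len(ncol(subsets))) {
    s <- sort(subsets[, col])
    for (i in seq_len(n)) {
      # the subset has >= i elements <= r exactly when r >= i-th smallest
      counts[s[i]:N, i] <- counts[s[i]:N, i] + 1
    }
  }
  counts
}

# RSA p-value of one rank configuration by enumeration: the minimum tail
# over thresholds, each tail taken from the enumeration table.
enum_rsa_p <- function(ranks, N, counts = enum_tail_counts(N, length(ranks))) {
  ranks <- sort(ranks)
  min(vapply(seq_along(ranks), function(i)
    counts[ranks[i], i] / choose(N, length(ranks)), numeric(1)))
}

# Straight-line hand evaluation of one TMM factor (sample k against
# reference r), written as flat arithmetic so it cannot share a defect with
# the package implementation.
tmm_oracle_log2_factor <- function(yk, yr, logratio_trim = 0.30,
                                   abundance_trim = 0.05) {
  Nk <- sum(yk); Nr <- sum(yr)
  keep <- yk > 0 & yr > 0
  yk <- yk[keep]; yr <- yr[keep]
  M <- log2((yk / Nk) / (yr / Nr))
  A <- 0.5 * log2((yk / Nk) * (yr / Nr))
  v <- (Nk - yk) / (Nk * yk) + (Nr - yr) / (Nr * yr)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abundance_trim) + 1; hiA <- n + 1 - loA
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  sum(M[keep2] / v[keep2]) / sum(1 / v[keep2])
}

# Two-sgRNA, two-sample toy screen used by the loader tests.
toy_counts_files <- function(dir = withr::local_tempdir(.local_envir =
                                                          parent.frame())) {
  counts <- file.path(dir, "counts.tsv")
  meta <- file.path(dir, "meta.csv")
  writeLines(c("sgrna\tgene\ts1\ts2",
               "sgA_1\tgA\t10\t5",
               "sgB_1\tgB\t0\t3"), counts)
  writeLines(c("sample_id,cell_line,day,replicate",
               "s1,UM1,4,1", "s2,UM1,14,1"), meta)
  list(counts = counts, meta = meta)
}

# Minimal ScreenCounts with explicit values: one cell line, two days.
toy_screen_counts <- function() {
  ScreenCounts(matrix(c(100, 64, 200, 25, 0, 400), nrow = 3,
                      dimnames = list(NULL, c("s1", "s2"))),
               library = data.frame(sgrna = c("a_1", "b_1", "c_1"),
                                    gene = c("A", "B", "C")),
               samples = data.frame(sample_id = c("s1", "s2"),
                                    cell_line = "UM1", day = c(4, 14),
                                    replicate = 1))
}

# Dependency panel fixture: named score rows over an annotated line set.
toy_panel <- function(scores, dataset = "avana") {
  ann <- cell_line_annotations(
    cell_line = c("CM1", "CM2", "CM3", "UMm1", "UMw1", "UMw2", "O1", "O2"),
    lineage = c("cutaneous_melanoma", "cutaneous_melanoma",
                "cutaneous_melanoma", "uveal_melanoma", "uveal_melanoma",
                "uveal_melanoma", "other", "other"),
    genotype = c("wildtype", "wildtype", "wildtype", "gnaq11_mutant",
                 "wildtype", "wildtype", "wildtype", "wildtype"),
    is_cm_panel_member = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                           FALSE),
    is_wt_um_control = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE,
                         FALSE))
  colnames(scores) <- ann$cell_line
  DependencyPanel(scores, ann, dataset = dataset)
}
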