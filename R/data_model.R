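#' @keywords internal
"_PACKAGE"

## Canonical orientation everywhere: genes (or sgRNAs) in rows, cell lines or
## samples in columns. Gene symbols are matched case-sensitively after
## whitespace stripping; there is no alias resolution.

.strip <- function(x) trimws(as.character(x))

#' Pooled screen count container
#'
#' Bundles an sgRNA library, per-sample metadata and the raw integer count
#' matrix of a pooled CRISPR dropout screen. Rows of `counts` follow the
#' library order; columns follow the order of `samples`.
#'
#' @param counts integer matrix, sgRNAs in rows, samples in columns.
#' @param library data.frame with columns `sgrna` and `gene`; every sgRNA maps
#'   to exactly one gene and ids are unique.
#' @param samples data.frame with columns `sample_id`, `cell_line`, `day`
#'   (days post-selection) and `replicate` (integer >= 1);
#'   `(cell_line, day, replicate)` must be unique.
#' @return An object of class `ScreenCounts` with elements `counts`, `library`,
#'   `samples` and derived `library_sizes` (per-sample column sums).
#' @export
ScreenCounts <- function(counts, library, samples) {
  library <- data.frame(sgrna = .strip(library$sgrna),
                        gene = .strip(library$gene),
                        stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = .strip(samples$sample_id),
                        cell_line = .strip(samples$cell_line),
                        day = as.integer(samples$day),
                        replicate = as.integer(samples$replicate),
                        stringsAsFactors = FALSE)
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(library))
    stop("counts has ", nrow(counts), " rows but library has ",
         nrow(library), " sgRNAs")
  if (ncol(counts) != nrow(samples))
    stop("counts has ", ncol(counts), " columns but metadata describes ",
         nrow(samples), " samples")
  dup <- library$sgrna[duplicated(library$sgrna)]
  if (length(dup)) stop("duplicate sgRNA id '", dup[[1]], "'")
  if (anyNA(library$gene) || any(library$gene == ""))
    stop("every sgRNA must map to exactly one gene")
  if (any(samples$replicate < 1)) stop("replicate must be >= 1")
  key <- paste(samples$cell_line, samples$day, samples$replicate)
  if (anyDuplicated(key))
    stop("duplicate (cell_line, day, replicate) combination: ",
         key[duplicated(key)][[1]])
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stop("non-integer or negative count for sgRNA '",
         library$sgrna[bad[1, 1]], "' in sample '",
         samples$sample_id[bad[1, 2]], "'")
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(library$sgrna, samples$sample_id)
  structure(list(counts = counts, library = library, samples = samples,
                 library_sizes = colSums(counts)),
            class = "ScreenCounts")
}

#' @export
print.ScreenCounts <- function(x, ...) {
  cat("ScreenCounts:", nrow(x$counts), "sgRNAs x", ncol(x$counts),
      "samples;", length(unique(x$library$gene)), "genes;",
      "cell lines:", paste(unique(x$samples$cell_line), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.ScreenCounts <- function(x) dim(x$counts)

#' Read pooled screen counts from TSV plus sample metadata CSV
#'
#' The counts file is a UTF-8 TSV with header
#' `sgrna<TAB>gene<TAB><sample_id>...`; the metadata file is a CSV with
#' columns `sample_id,cell_line,day,replicate`. Sample column order in the
#' counts file is preserved.
#'
#' @param path path to the counts TSV.
#' @param meta_path path to the sample metadata CSV.
#' @return A [ScreenCounts] object.
#' @export
read_screen_counts <- function(path, meta_path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0L || ncol(tab) < 3L)
    stop("empty counts file: ", path)
  if (!identical(names(tab)[1:2], c("sgrna", "gene")))
    stop("counts file must start with columns 'sgrna' and 'gene'")
  meta <- utils::read.csv(meta_path, colClasses = "character")
  need <- c("sample_id", "cell_line", "day", "replicate")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns ", paste(need, collapse = ", "))
  sample_ids <- names(tab)[-(1:2)]
  missing <- setdiff(sample_ids, .strip(meta$sample_id))
  if (length(missing)) stop("unannotated sample ", missing[[1]])
  meta <- meta[match(sample_ids, .strip(meta$sample_id)), , drop = FALSE]
  raw <- tab[, -(1:2), drop = FALSE]
  counts <- matrix(NA_real_, nrow(raw), ncol(raw))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop("non-integer or negative count for sgRNA '",
           .strip(tab$sgrna)[bad[[1]]], "' in sample '", sample_ids[[j]], "'")
    counts[, j] <- v
  }
  ScreenCounts(counts,
               library = data.frame(sgrna = tab$sgrna, gene = tab$gene),
               samples = meta)
}

#' Write pooled screen counts to TSV plus sample metadata CSV
#'
#' Inverse of [read_screen_counts()]: the written files round-trip to an
#' identical object.
#'
#' @param x a [ScreenCounts] object.
#' @inheritParams read_screen_counts
#' @return `x`, invisibly.
#' @export
write_screen_counts <- function(x, path, meta_path) {
  stopifnot(inherits(x, "ScreenCounts"))
  out <- data.frame(sgrna = x$library$sgrna, gene = x$library$gene,
                    x$counts, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(x$samples, meta_path, quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Cell-line annotation table
#'
#' @param cell_line,lineage,genotype,is_cm_panel_member,is_wt_um_control
#'   parallel vectors; `lineage` is free-form (e.g. `cutaneous_melanoma`,
#'   `uveal_melanoma`, `other`), `genotype` is `gnaq11_mutant` or `wildtype`.
#'   Flags mark cutaneous-melanoma panel membership and wild-type uveal
#'   melanoma control lines used by the lineage exclusion filter.
#' @return A validated data.frame of class `CellLineAnnotation`.
#' @export
cell_line_annotations <- function(cell_line, lineage, genotype,
                                  is_cm_panel_member = FALSE,
                                  is_wt_um_control = FALSE) {
  ann <- data.frame(cell_line = .strip(cell_line), lineage = .strip(lineage),
                    genotype = .strip(genotype),
                    is_cm_panel_member = as.logical(is_cm_panel_member),
                    is_wt_um_control = as.logical(is_wt_um_control),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(ann$cell_line))
    stop("duplicate cell line '", ann$cell_line[duplicated(ann$cell_line)][[1]], "'")
  bad <- ann$is_wt_um_control &
    !(ann$lineage == "uveal_melanoma" & ann$genotype == "wildtype")
  if (any(bad))
    stop("wt-UM control must be uveal_melanoma/wildtype: ",
         ann$cell_line[bad][[1]])
  class(ann) <- c("CellLineAnnotation", "data.frame")
  ann
}

#' Read a cell-line annotation CSV
#'
#' Columns: `cell_line,lineage,genotype,is_cm_panel_member,is_wt_um_control`.
#'
#' @param path path to the CSV.
#' @return A [cell_line_annotations] table.
#' @export
read_cell_line_annotations <- function(path) {
  a <- utils::read.csv(path, colClasses = "character")
  cell_line_annotations(a$cell_line, a$lineage, a$genotype,
                        as.logical(a$is_cm_panel_member),
                        as.logical(a$is_wt_um_control))
}

#' Gene x cell-line dependency score panel
#'
#' Continuous essentiality scores (more negative = more essential) from a
#' genome-wide perturbation dataset, with per-column cell-line annotations.
#' Missing values are permitted and are never imputed.
#'
#' @param scores numeric matrix, genes in rows (rownames = gene symbols),
#'   cell lines in columns.
#' @param annotations a [cell_line_annotations] table covering every column.
#' @param dataset dataset tag, e.g. `"avana"`, `"drive"`, `"achilles"`.
#' @return An object of class `DependencyPanel`.
#' @export
DependencyPanel <- function(scores, annotations, dataset = "avana") {
  scores <- as.matrix(scores)
  rownames(scores) <- .strip(rownames(scores))
  if (anyDuplicated(rownames(scores)))
    stop("duplicate gene '",
         rownames(scores)[duplicated(rownames(scores))][[1]], "'")
  missing <- setdiff(colnames(scores), annotations$cell_line)
  if (length(missing)) stop("cell line without annotation: ", missing[[1]])
  if (any(is.infinite(scores)))
    stop("dependency scores must be finite where present")
  ann <- annotations[match(colnames(scores), annotations$cell_line), ,
                     drop = FALSE]
  rownames(ann) <- NULL
  structure(list(dataset = dataset, scores = scores, annotations = ann),
            class = "DependencyPanel")
}

#' @export
print.DependencyPanel <- function(x, ...) {
  cat("DependencyPanel [", x$dataset, "]: ", nrow(x$scores), " genes x ",
      ncol(x$scores), " cell lines\n", sep = "")
  invisible(x)
}

#' Gene x sample TPM expression panel with tumor-type labels
#'
#' @param tpm non-negative numeric matrix, genes in rows, samples in columns.
#' @param sample_type character vector of tumor-type labels per column.
#' @param target_type the tumor type whose signature is sought (default
#'   `"UM"`, uveal melanoma).
#' @param comparator_type the lineage-matched comparator type (default
#'   `"CM"`, cutaneous melanoma).
#' @return An object of class `ExpressionPanel`.
#' @export
ExpressionPanel <- function(tpm, sample_type, target_type = "UM",
                            comparator_type = "CM") {
  tpm <- as.matrix(tpm)
  rownames(tpm) <- .strip(rownames(tpm))
  if (anyDuplicated(rownames(tpm)))
    stop("duplicate gene '", rownames(tpm)[duplicated(rownames(tpm))][[1]], "'")
  if (any(tpm < 0, na.rm = TRUE)) stop("negative TPM")
  sample_type <- .strip(sample_type)
  if (length(sample_type) != ncol(tpm))
    stop("sample_type must label every column")
  for (ty in c(target_type, comparator_type))
    if (sum(sample_type == ty) < 2L)
      stop("need >= 2 samples of type '", ty, "'")
  structure(list(tpm = tpm, sample_type = sample_type,
                 target_type = target_type,
                 comparator_type = comparator_type),
            class = "ExpressionPanel")
}

#' @export
print.ExpressionPanel <- function(x, ...) {
  cat("ExpressionPanel:", nrow(x$tpm), "genes x", ncol(x$tpm), "samples (",
      paste(names(table(x$sample_type)), table(x$sample_type),
            sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' Per-gene scalar essentiality scores
#'
#' Holds the per-gene `priority_score` and `cellline_dependency_score`
#' published alongside genome-wide fitness screens; either may be missing.
#'
#' @param gene gene symbols (unique).
#' @param priority_score,cellline_dependency_score numeric vectors (NA where
#'   missing).
#' @return A data.frame of class `GeneScalarScores`.
#' @export
gene_scalar_scores <- function(gene, priority_score = NA_real_,
                               cellline_dependency_score = NA_real_) {
  gene <- .strip(gene)
  if (anyDuplicated(gene))
    stop("duplicate gene '", gene[duplicated(gene)][[1]], "'")
  out <- data.frame(gene = gene,
                    priority_score = as.numeric(priority_score),
                    cellline_dependency_score =
                      as.numeric(cellline_dependency_score),
                    stringsAsFactors = FALSE)
  class(out) <- c("GeneScalarScores", "data.frame")
  out
}

#' Read a gene panel from CSV
#'
#' One reader for the three external-panel flavors. All files are CSV with
#' genes in rows and the first column named `gene` (blank cell = missing).
#' DepMap-style line x gene files can be read with `transpose = TRUE`.
#'
#' @param path path to the CSV.
#' @param kind `"dependency"`, `"expression"` or `"scalar"`.
#' @param annotations required for `kind = "dependency"`: a
#'   [cell_line_annotations] table.
#' @param dataset dataset tag for dependency panels.
#' @param sample_type,target_type,comparator_type for `kind = "expression"`:
#'   per-column tumor-type labels and the target/comparator types.
#' @param transpose set `TRUE` if rows are cell lines and columns genes.
#' @return A [DependencyPanel], [ExpressionPanel] or [gene_scalar_scores]
#'   object according to `kind`.
#' @export
read_gene_panel <- function(path, kind = c("dependency", "expression",
                                           "scalar"),
                            annotations = NULL, dataset = "avana",
                            sample_type = NULL, target_type = "UM",
                            comparator_type = "CM", transpose = FALSE) {
  kind <- match.arg(kind)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (names(tab)[[1]] != "gene" && !transpose)
    stop("first column must be 'gene'")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- .strip(tab[[1]])
  if (transpose) m <- t(m)
  storage.mode(m) <- "double"
  switch(kind,
    dependency = {
      if (is.null(annotations)) stop("dependency panels need annotations")
      DependencyPanel(m, annotations, dataset = dataset)
    },
    expression = {
      if (is.null(sample_type)) sample_type <- colnames(m)
      if (any(m < 0, na.rm = TRUE)) stop("negative TPM")
      ExpressionPanel(m, sample_type, target_type, comparator_type)
    },
    scalar = gene_scalar_scores(rownames(m),
                                priority_score = m[, "priority_score"],
                                cellline_dependency_score =
                                  m[, "cellline_dependency_score"])
  )
}

#' Cross-check a loaded study before running the pipeline
#'
#' Reports, without failing, the genes of the screen library that are absent
#' from each external panel (such genes bypass the corresponding exclusion
#' filter), the availability of the baseline day per screen cell line, and
#' replicate counts. A missing baseline-day sample for any screen cell line
#' is a fatal error.
#'
#' @param counts a [ScreenCounts] object.
#' @param panels optional named list of [DependencyPanel] objects.
#' @param scalar_scores optional [gene_scalar_scores] table.
#' @param expression optional [ExpressionPanel].
#' @param baseline_day baseline timepoint; defaults to the earliest sampled
#'   day.
#' @return A list of class `study_validation` with elements `warnings`
#'   (character), `missing_genes` (named list per panel), `baseline_day`, and
#'   `replicates` (per cell line x day counts).
#' @export
validate_study <- function(counts, panels = list(), scalar_scores = NULL,
                           expression = NULL, baseline_day = NULL) {
  stopifnot(inherits(counts, "ScreenCounts"))
  genes <- unique(counts$library$gene)
  if (is.null(baseline_day)) baseline_day <- min(counts$samples$day)
  lines <- unique(counts$samples$cell_line)
  no_base <- lines[!vapply(lines, function(cl)
    any(counts$samples$cell_line == cl & counts$samples$day == baseline_day),
    logical(1))]
  if (length(no_base))
    stop("no baseline (day ", baseline_day, ") sample for cell line ",
         no_base[[1]])
  warnings <- character()
  missing_genes <- list()
  for (nm in names(panels)) {
    absent <- setdiff(genes, rownames(panels[[nm]]$scores))
    missing_genes[[nm]] <- absent
    if (length(absent))
      warnings <- c(warnings, paste0(length(absent),
        " library gene(s) absent from panel '", nm,
        "'; these bypass its filter"))
  }
  if (!is.null(scalar_scores)) {
    absent <- setdiff(genes, scalar_scores$gene)
    missing_genes[["scalar"]] <- absent
    if (length(absent))
      warnings <- c(warnings, paste0(length(absent),
        " library gene(s) absent from the scalar score table"))
  }
  if (!is.null(expression)) {
    absent <- setdiff(genes, rownames(expression$tpm))
    missing_genes[["expression"]] <- absent
    if (length(absent))
      warnings <- c(warnings, paste0(length(absent),
        " library gene(s) absent from the expression panel"))
  }
  reps <- as.data.frame(table(cell_line = counts$samples$cell_line,
                              day = counts$samples$day),
                        responseName = "n_replicates")
  structure(list(warnings = warnings, missing_genes = missing_genes,
                 baseline_day = baseline_day, replicates = reps),
            class = "study_validation")
}

#' @export
print.study_validation <- function(x, ...) {
  cat("Study validation (baseline day ", x$baseline_day, ")\n", sep = "")
  if (length(x$warnings)) cat(paste0(" - ", x$warnings, collapse = "\n"), "\n")
  else cat(" - no warnings\n")
  invisible(x)
}
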