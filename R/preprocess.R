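#' Read a raw count matrix with sample labels
#'
#' The count TSV mirrors the immunome layout (header of sample names, first
#' column `gene`, non-negative integer counts); the label TSV has columns
#' `sample` and `cell_type`, one row per sample.
#'
#' @param counts_path,labels_path File paths.
#' @return A list of class `"count_matrix"` with elements `counts` (integer
#'   matrix, genes x samples) and `sample_to_celltype` (named character
#'   vector, names are samples).
#' @export
read_counts <- function(counts_path, labels_path) {
  df <- readr::read_tsv(counts_path, col_types = readr::cols(
    .default = readr::col_double(), gene = readr::col_character()),
    progress = FALSE)
  if (!"gene" %in% names(df))
    abort("count TSV must have a 'gene' first column",
          class = "dime_format_error")
  m <- as.matrix(df[setdiff(names(df), "gene")])
  rownames(m) <- df$gene
  lab <- readr::read_tsv(labels_path,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("sample", "cell_type") %in% names(lab)))
    abort("label TSV must have columns 'sample' and 'cell_type'",
          class = "dime_format_error")
  count_matrix(m, setNames(lab$cell_type, lab$sample))
}

#' Construct a labelled count matrix
#'
#' @param counts Non-negative integer matrix, genes x samples, with dimnames.
#' @param sample_to_celltype Named character vector mapping every sample
#'   (column) to its cell-type label.
#' @return A list of class `"count_matrix"`.
#' @export
count_matrix <- function(counts, sample_to_celltype) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("counts need gene row names and sample column names",
          class = "dime_format_error")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    abort("counts must be non-negative integers", class = "dime_format_error")
  unl <- setdiff(colnames(counts), names(sample_to_celltype))
  if (length(unl) > 0)
    abort(paste0("unlabelled sample(s): ", paste(unl, collapse = ", ")),
          class = "dime_format_error")
  structure(list(counts = counts,
                 sample_to_celltype =
                   sample_to_celltype[colnames(counts)]),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples, %d cell types\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$sample_to_celltype))))
  invisible(x)
}

#' Remove genes with low counts in almost all samples
#'
#' A gene is removed iff its count is below `min_count` in at least
#' `sample_fraction` of the samples (default: fewer than 20 reads in 95% of
#' samples). All other genes are retained in their original order.
#'
#' @param cm A [count_matrix()].
#' @param min_count Count threshold (reads), default 20.
#' @param sample_fraction Fraction of samples that must be below `min_count`
#'   for removal, default 0.95.
#' @return The filtered `count_matrix`.
#' @export
filter_low_count_genes <- function(cm, min_count = 20, sample_fraction = 0.95) {
  stopifnot(inherits(cm, "count_matrix"),
            sample_fraction > 0, sample_fraction <= 1, min_count >= 0)
  frac_low <- rowMeans(cm$counts < min_count)
  keep <- frac_low < sample_fraction
  if (!any(keep))
    abort("no gene passes the low-count filter; lower min_count or sample_fraction")
  count_matrix(cm$counts[keep, , drop = FALSE], cm$sample_to_celltype)
}

#' Library-size normalise and log-transform counts
#'
#' Computes `log2(CPM + 1)` per entry, where CPM is counts per million reads
#' of the sample: `value(g, s) = log2(counts(g, s) / libsize(s) * 1e6 + 1)`.
#'
#' @param cm A [count_matrix()].
#' @return Numeric matrix, genes x samples, non-negative.
#' @export
cpm_log_transform <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  libsize <- colSums(cm$counts)
  zero <- which(libsize == 0)
  if (length(zero) > 0)
    abort(paste0("zero library size for sample(s): ",
                 paste(colnames(cm$counts)[zero], collapse = ", ")))
  log2(sweep(cm$counts, 2, libsize, "/") * 1e6 + 1)
}

#' Collapse samples to cell-type medians
#'
#' One column per cell type, each entry the median of the gene's expression
#' over that cell type's samples (even sample numbers use the midpoint of the
#' two central order statistics). Cell types appear in order of first
#' occurrence among the samples.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param sample_to_celltype Named character vector mapping samples to cell
#'   types.
#' @return An [immunome()].
#' @export
aggregate_median_by_celltype <- function(expr, sample_to_celltype) {
  unl <- setdiff(colnames(expr), names(sample_to_celltype))
  if (length(unl) > 0)
    abort(paste0("unlabelled sample(s): ", paste(unl, collapse = ", ")))
  labels <- sample_to_celltype[colnames(expr)]
  types <- unique(labels)
  med <- vapply(types, function(ct) {
    cols <- which(labels == ct)
    apply(expr[, cols, drop = FALSE], 1, median)
  }, numeric(nrow(expr)))
  immunome(matrix(med, nrow = nrow(expr),
                  dimnames = list(rownames(expr), types)))
}

#' Counts to immunome in one call
#'
#' Convenience chain: [filter_low_count_genes()], [cpm_log_transform()],
#' [aggregate_median_by_celltype()].
#'
#' @inheritParams filter_low_count_genes
#' @return An [immunome()].
#' @export
preprocess_counts <- function(cm, min_count = 20, sample_fraction = 0.95) {
  cm <- filter_low_count_genes(cm, min_count, sample_fraction)
  aggregate_median_by_celltype(cpm_log_transform(cm), cm$sample_to_celltype)
}
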