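#' Construct an immunome matrix
#'
#' The immunome is the reference expression context every disease is mapped
#' onto: a dense non-negative matrix of genes by immune cell types, on the
#' log2(CPM + 1) scale, typically one column per cell type obtained as the
#' median over that cell type's samples.
#'
#' @param values Numeric matrix, genes in rows, cell types in columns.
#' @param gene_ids,cell_ids Optional character vectors overriding
#'   `rownames(values)` / `colnames(values)`.
#' @return A numeric matrix of class `"immunome"` with gene symbols as row
#'   names and cell-type names as column names.
#' @examples
#' m <- matrix(runif(6), 3, 2, dimnames = list(c("TNF", "IL6", "CD4"),
#'                                             c("NK", "Monocyte")))
#' imm <- immunome(m)
#' @export
immunome <- function(values, gene_ids = rownames(values),
                     cell_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  colnames(values) <- cell_ids
  validate_immunome(values)
  structure(values, class = c("immunome", "matrix", "array"))
}

validate_immunome <- function(values) {
  genes <- rownames(values)
  cells <- colnames(values)
  if (is.null(genes) || is.null(cells))
    abort("immunome requires gene row names and cell-type column names",
          class = "dime_format_error")
  if (nrow(values) < 2L || ncol(values) < 2L)
    abort("immunome must have at least 2 genes and 2 cell types",
          class = "dime_format_error")
  if (anyNA(values))
    abort("immunome contains missing values", class = "dime_format_error")
  if (any(genes == "") || anyDuplicated(genes)) {
    dup <- genes[duplicated(genes)][1]
    abort(paste0("duplicate or empty gene symbol: '", dup, "'"),
          class = "dime_format_error")
  }
  if (anyDuplicated(cells))
    abort(paste0("duplicate cell-type name: '",
                 cells[duplicated(cells)][1], "'"),
          class = "dime_format_error")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    abort(sprintf("negative expression value at (%s, %s)",
                  genes[neg[1, 1]], cells[neg[1, 2]]),
          class = "dime_format_error")
  invisible(values)
}

#' @export
print.immunome <- function(x, ...) {
  cat(sprintf("<immunome> %d genes x %d cell types, range [%.3g, %.3g]\n",
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Read or write an immunome expression matrix
#'
#' Plain UTF-8 TSV: header row of cell-type names, first column `gene`
#' holding gene symbols, remaining cells non-negative reals. Row and column
#' order are preserved, and `read_immunome(write_immunome(x))` is the
#' identity.
#'
#' @param path File path.
#' @param fmt Only `"tsv"` is supported.
#' @return `read_immunome()` returns an [immunome()]; `write_immunome()`
#'   returns `path` invisibly.
#' @export
read_immunome <- function(path, fmt = "tsv") {
  fmt <- match.arg(fmt, "tsv")
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_double(),
    gene = readr::col_character()
  ), progress = FALSE)
  if (!"gene" %in% names(df))
    abort("immunome TSV must have a 'gene' first column",
          class = "dime_format_error")
  if (ncol(df) < 2L)
    abort("immunome TSV has no cell-type columns", class = "dime_format_error")
  m <- as.matrix(df[setdiff(names(df), "gene")])
  if (anyNA(m))
    abort("immunome TSV contains non-numeric or missing expression values",
          class = "dime_format_error")
  rownames(m) <- df$gene
  immunome(m)
}

#' @rdname read_immunome
#' @param imm An [immunome()].
#' @export
write_immunome <- function(imm, path) {
  df <- tibble::as_tibble(unclass(imm), .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble(gene = rownames(imm)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
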