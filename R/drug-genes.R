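#' Read a drug-gene interaction table
#'
#' TSV with columns `gene`, `drug`, `source` and `approved` (`true`/`false`,
#' case-insensitive; `TRUE`/`FALSE`, `1`/`0` also accepted). `source` records
#' provenance (e.g. `DGIdb`, `CLUE`, `hPDI`, `custom`); `approved` marks
#' interactions whose drug has regulatory approval, so repurposing reports can
#' be restricted to approved compounds.
#'
#' @param path File path.
#' @return A tibble of class `"drug_gene_tbl"` with columns `gene`, `drug`,
#'   `source`, `approved`; one row per unique (gene, drug, source) record.
#' @export
read_drug_gene_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  needed <- c("gene", "drug", "source", "approved")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    abort(paste0("missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "dime_format_error")
  appr <- parse_flag(df$approved)
  if (anyNA(appr))
    abort(paste0("unparseable 'approved' flag: '",
                 df$approved[which(is.na(appr))[1]], "'"),
          class = "dime_format_error")
  if (nrow(df) > 0 && any(!nzchar(df$drug)))
    abort("empty drug name", class = "dime_format_error")
  out <- tibble(gene = df$gene, drug = df$drug, source = df$source,
                approved = appr)
  as_drug_gene_tbl(dplyr::distinct(out))
}

parse_flag <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(lx))
  out[lx %in% c("true", "t", "1", "yes")] <- TRUE
  out[lx %in% c("false", "f", "0", "no")] <- FALSE
  as.logical(out)
}

as_drug_gene_tbl <- function(x) {
  x <- as_tibble(x)
  stopifnot(all(c("gene", "drug", "source", "approved") %in% names(x)))
  class(x) <- unique(c("drug_gene_tbl", class(x)))
  x
}

#' Merge drug-gene tables from several sources
#'
#' Rows are unioned; duplicate (gene, drug) pairs coming from different
#' sources are kept as one record per pair with the sources concatenated
#' (`;`-separated, sorted) and `approved` true if any source marks the drug
#' approved.
#'
#' @param ... Drug-gene tibbles (or a single list of them).
#' @return A merged `"drug_gene_tbl"` tibble.
#' @export
merge_drug_sources <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1 && is.list(tabs[[1]]) && !is.data.frame(tabs[[1]]))
    tabs <- tabs[[1]]
  if (length(tabs) == 0)
    return(as_drug_gene_tbl(tibble(gene = character(), drug = character(),
                                   source = character(), approved = logical())))
  all <- dplyr::bind_rows(tabs)
  out <- all |>
    dplyr::group_by(.data$gene, .data$drug) |>
    dplyr::summarise(
      source = paste(sort(unique(.data$source)), collapse = ";"),
      approved = any(.data$approved),
      .groups = "drop")
  as_drug_gene_tbl(out)
}
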