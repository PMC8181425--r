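#' Read a disease-gene association table
#'
#' Builds the disease-gene network: one row per (disease, gene) association,
#' deduplicated. Three dialects are understood:
#'
#' * `"disgenet_curated"` — any TSV containing at least the columns
#'   `geneSymbol`, `diseaseId` (a UMLS CUI such as `"C0010346"`) and
#'   `diseaseName`, in any order; extra columns are ignored. If a `score`
#'   column is present it is carried along as the association weight.
#' * `"two_column"` — headered TSV with columns `disease_id` and `gene`.
#' * `"gene_list"` — one gene symbol per line (no header) for a single
#'   disease named via `disease_name`.
#'
#' Gene symbols are treated as opaque case-sensitive identifiers; no alias
#' mapping is attempted.
#'
#' @param path File path.
#' @param dialect One of `"disgenet_curated"`, `"two_column"`, `"gene_list"`.
#' @param disease_filter Optional character vector of disease ids (CUIs); only
#'   those diseases are retained.
#' @param disease_id,disease_name Identifier and display name used by the
#'   `gene_list` dialect.
#' @return A tibble of class `"disease_gene_tbl"` with columns `disease_id`,
#'   `disease_name`, `gene` and optionally `score`, one row per unique
#'   association.
#' @export
read_disease_gene_table <- function(path,
                                    dialect = c("disgenet_curated",
                                                "two_column", "gene_list"),
                                    disease_filter = NULL,
                                    disease_id = "custom",
                                    disease_name = disease_id) {
  dialect <- rlang::arg_match(dialect)
  if (dialect == "gene_list") {
    genes <- readr::read_lines(path, progress = FALSE)
    genes <- genes[nzchar(trimws(genes))]
    out <- tibble(disease_id = disease_id, disease_name = disease_name,
                  gene = trimws(genes))
  } else {
    df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE)
    needed <- switch(dialect,
      disgenet_curated = c("geneSymbol", "diseaseId", "diseaseName"),
      two_column = c("disease_id", "gene"))
    missing <- setdiff(needed, names(df))
    if (length(missing) > 0)
      abort(paste0("missing required column(s): ",
                   paste(missing, collapse = ", "),
                   " (expected ", paste(needed, collapse = ", "), ")"),
            class = "dime_format_error")
    out <- if (dialect == "disgenet_curated") {
      res <- tibble(disease_id = df$diseaseId,
                    disease_name = df$diseaseName,
                    gene = df$geneSymbol)
      if ("score" %in% names(df)) res$score <- as.numeric(df$score)
      res
    } else {
      tibble(disease_id = df$disease_id, disease_name = df$disease_id,
             gene = df$gene)
    }
  }
  out <- dplyr::distinct(out, .data$disease_id, .data$gene, .keep_all = TRUE)
  if (!is.null(disease_filter))
    out <- dplyr::filter(out, .data$disease_id %in% disease_filter)
  as_disease_gene_tbl(out)
}

as_disease_gene_tbl <- function(x) {
  x <- as_tibble(x)
  stopifnot(all(c("disease_id", "disease_name", "gene") %in% names(x)))
  class(x) <- unique(c("disease_gene_tbl", class(x)))
  x
}

#' Gene set of one disease
#'
#' @param net A disease-gene tibble (see [read_disease_gene_table()]).
#' @param disease_id Disease identifier (CUI).
#' @return Character vector of unique gene symbols.
#' @export
disease_genes <- function(net, disease_id) {
  if (!disease_id %in% net$disease_id)
    abort(paste0("unknown disease id: ", disease_id))
  unique(net$gene[net$disease_id == disease_id])
}

#' Remove HLA genes from a disease-gene network
#'
#' HLA genes are removed before mapping diseases onto the immunome to avoid
#' biasing results towards the myeloid and B cells that constitutively express
#' them. A gene is removed iff its symbol starts with the prefix `"HLA-"`
#' (case-insensitive); symbols such as `HHLA2` are untouched. An explicit
#' `extra` exclusion list can supplement the prefix rule.
#'
#' @param net A disease-gene tibble.
#' @param extra Optional character vector of additional symbols to drop.
#' @return The filtered tibble; the number of removed rows is attached as
#'   attribute `"n_removed"`.
#' @export
remove_hla_genes <- function(net, extra = character()) {
  drop <- startsWith(toupper(net$gene), "HLA-") | net$gene %in% extra
  out <- net[!drop, , drop = FALSE]
  attr(out, "n_removed") <- sum(drop)
  as_disease_gene_tbl(out)
}

#' Restrict a disease-gene network to immunome genes
#'
#' Associations whose gene is absent from the immunome are dropped (exact
#' symbol intersection); diseases left with no genes are removed with a
#' warning. The number of dropped associations is attached as attribute
#' `"n_dropped"`.
#'
#' @param net A disease-gene tibble.
#' @param imm An [immunome()].
#' @return The restricted tibble.
#' @export
restrict_to_immunome <- function(net, imm) {
  keep <- net$gene %in% rownames(imm)
  out <- net[keep, , drop = FALSE]
  lost <- setdiff(unique(net$disease_id), unique(out$disease_id))
  if (length(lost) > 0)
    warn(paste0("disease(s) dropped with no immunome genes: ",
                paste(lost, collapse = ", ")))
  if (nrow(out) == 0)
    abort("no disease retains any immunome gene", class = "dime_format_error")
  attr(out, "n_dropped") <- sum(!keep)
  as_disease_gene_tbl(out)
}
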