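#' Annotate network genes with drug-gene interactions
#'
#' Pure decoration: every edge whose gene has at least one record in the
#' drug-gene table (optionally restricted to approved drugs) gets
#' `druggable = TRUE` and the `;`-separated sorted drug list; edge sets and
#' scores are unchanged.
#'
#' @param nw A [build_dime_network()] tibble or a
#'   [common_cell_gene_network()] result.
#' @param dgn A drug-gene tibble ([read_drug_gene_table()]).
#' @param approved_only Keep only approved-drug records, default `FALSE`.
#' @return The same object with `druggable` and `drugs` filled in.
#' @export
annotate_druggable <- function(nw, dgn, approved_only = FALSE) {
  if (inherits(nw, "common_network")) {
    nw$edges <- annotate_edges(nw$edges, dgn, approved_only)
    return(nw)
  }
  out <- annotate_edges(nw, dgn, approved_only)
  as_dime_network(out, disease_id = attr(nw, "disease_id"),
                  cells = attr(nw, "cells"))
}

annotate_edges <- function(edges, dgn, approved_only) {
  if (approved_only) dgn <- dgn[dgn$approved, , drop = FALSE]
  by_gene <- dgn |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(drugs = paste(sort(unique(.data$drug)), collapse = ";"),
                     .groups = "drop")
  edges$drugs <- by_gene$drugs[match(edges$gene, by_gene$gene)]
  edges$drugs[is.na(edges$drugs)] <- ""
  edges$druggable <- nzchar(edges$drugs)
  edges
}

#' Drug repurposing candidates from significant common networks
#'
#' Implements the repurposing logic: restrict to disease pairs whose common
#' cell-gene network overlap is significant (Fisher p <= `alpha`), collect
#' every druggable gene that is an endpoint of a common edge in such a pair,
#' and report, per gene, the diseases involved, its drugs/sources, and
#' whether the gene is a top gene of the top (rank 1) cluster in every
#' listed disease's network ("top-cluster target", the strictest criterion).
#' Rows are sorted by number of diseases (descending), then gene symbol.
#'
#' @param cmp A [pairwise_comparison()] result over networks
#'   (`item_kind = "cell_gene_pairs"`).
#' @param results Named list of [run_dime()] results keyed by disease id
#'   (used for the top-cluster flag).
#' @param dgn A drug-gene tibble.
#' @param alpha Significance threshold on the Fisher p-value, default 0.05.
#' @param approved_only Restrict to approved drugs, default `TRUE`.
#' @return Tibble with columns `gene`, `diseases`, `n_diseases`, `drugs`,
#'   `sources`, `top_cluster_target`.
#' @export
repurposing_candidates <- function(cmp, results, dgn, alpha = 0.05,
                                   approved_only = TRUE) {
  stopifnot(inherits(cmp, "dime_comparison"),
            cmp$item_kind == "cell_gene_pairs")
  if (approved_only) dgn <- dgn[dgn$approved, , drop = FALSE]
  empty <- tibble(gene = character(), diseases = character(),
                  n_diseases = integer(), drugs = character(),
                  sources = character(), top_cluster_target = logical())
  sig <- cmp$pairs[cmp$pairs$fisher_p <= alpha, , drop = FALSE]
  if (nrow(sig) == 0) {
    warn("no significant common cell-gene network at this alpha")
    return(empty)
  }
  hits <- purrr::pmap(sig, function(disease_a, disease_b, ...) {
    cn <- cmp$common[[paste(disease_a, disease_b, sep = "|")]]
    genes <- intersect(unique(cn$edges$gene), unique(dgn$gene))
    if (length(genes) == 0) return(NULL)
    tibble(gene = genes, disease = list(c(disease_a, disease_b)))
  })
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0) return(empty)

  top_dags_of <- function(id) {
    res <- results[[id]]
    if (is.null(res)) return(character())
    res$clusters$top_dags[[which(res$clusters$rank == 1L)]]
  }
  drug_info <- dgn |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(drugs = paste(sort(unique(.data$drug)), collapse = ";"),
                     sources = paste(sort(unique(unlist(
                       strsplit(.data$source, ";", fixed = TRUE)))),
                       collapse = ";"),
                     .groups = "drop")
  hits |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(disease_set = list(sort(unique(unlist(.data$disease)))),
                     .groups = "drop") |>
    dplyr::mutate(
      diseases = purrr::map_chr(.data$disease_set, paste, collapse = ";"),
      n_diseases = purrr::map_int(.data$disease_set, length),
      top_cluster_target = purrr::map2_lgl(
        .data$gene, .data$disease_set,
        function(g, ds) all(purrr::map_lgl(ds, function(d)
          g %in% top_dags_of(d))))) |>
    dplyr::left_join(drug_info, by = "gene") |>
    dplyr::arrange(dplyr::desc(.data$n_diseases), .data$gene) |>
    dplyr::select("gene", "diseases", "n_diseases", "drugs", "sources",
                  "top_cluster_target")
}
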