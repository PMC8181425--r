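#' Write a cell-gene network to disk
#'
#' Three formats:
#' * `edge_tsv` — columns `cell`, `gene`, `cluster_rank`, `dac_score`,
#'   `dag_score`, `median_expression`, `druggable`, `drugs`; lossless, reads
#'   back with [read_network()].
#' * `graphml` — bipartite graph (node attribute `type`: `"cell"`/`"gene"`)
#'   with scores and drug annotations as node/edge attributes (via igraph;
#'   export only).
#' * `json` — edge list plus attributes as one JSON object.
#'
#' Common networks ([common_cell_gene_network()]) are written through the
#' same interface; their edge columns are `cell`, `gene`, `rank_a`, `rank_b`,
#' `druggable`, `drugs`.
#'
#' @param nw A `dime_network` tibble or `common_network` object.
#' @param path Output file path.
#' @param fmt `"edge_tsv"`, `"graphml"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(nw, path, fmt = c("edge_tsv", "graphml", "json")) {
  fmt <- rlang::arg_match(fmt)
  edges <- if (inherits(nw, "common_network")) nw$edges else nw
  switch(fmt,
    edge_tsv = readr::write_tsv(as_tibble(edges), path, progress = FALSE),
    json = jsonlite::write_json(
      list(disease_id = attr(nw, "disease_id"),
           edges = as_tibble(edges)),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE),
    graphml = {
      g <- network_igraph(edges)
      igraph::write_graph(g, path, format = "graphml")
    })
  invisible(path)
}

network_igraph <- function(edges) {
  cells <- unique(edges$cell)
  genes <- unique(edges$gene)
  nodes <- tibble(
    name = c(paste0("cell:", cells), paste0("gene:", genes)),
    label = c(cells, genes),
    type = c(rep("cell", length(cells)), rep("gene", length(genes))))
  if ("druggable" %in% names(edges)) {
    dg <- edges |>
      dplyr::distinct(.data$gene, .data$druggable, .data$drugs)
    nodes$druggable <- c(rep(FALSE, length(cells)),
                         dg$druggable[match(genes, dg$gene)])
    nodes$drugs <- c(rep("", length(cells)),
                     dg$drugs[match(genes, dg$gene)])
  }
  el <- edges
  el$from <- paste0("cell:", el$cell)
  el$to <- paste0("gene:", el$gene)
  igraph::graph_from_data_frame(
    el[, c("from", "to",
           setdiff(names(el), c("from", "to", "cell", "gene")))],
    directed = FALSE, vertices = nodes)
}

#' Read an edge-list network written by [write_network()]
#'
#' @param path An `edge_tsv` file.
#' @return A `dime_network` tibble (with an empty `disease_id` attribute; the
#'   edge set round-trips losslessly).
#' @export
read_network <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    cell = "c", gene = "c", cluster_rank = "i", dac_score = "d",
    dag_score = "d", median_expression = "d", druggable = "l",
    drugs = "c"), progress = FALSE)
  df$drugs[is.na(df$drugs)] <- ""
  as_dime_network(df)
}

#' Write a disease-gene or drug-gene table
#'
#' Plain TSV mirrors of the reader dialects, for round-tripping generated
#' data.
#'
#' @param x The tibble to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_disease_gene_table <- function(x, path) {
  readr::write_tsv(tibble(geneSymbol = x$gene, diseaseId = x$disease_id,
                          diseaseName = x$disease_name),
                   path, progress = FALSE)
  invisible(path)
}

#' @rdname write_disease_gene_table
#' @export
write_drug_gene_table <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}
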