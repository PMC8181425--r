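#' Default analysis configuration
#'
#' Central knobs of the pipeline with their defaults: top-quartile membership
#' (`percentile = 0.75`), 30 NMF restarts, candidate cluster numbers 2..7
#' (capped by the matrix shape), at least 15 mappable disease genes to
#' attempt a factorization, the NMF stopping rule, and the jackknife and
#' comparison settings.
#'
#' @param percentile Score quantile above which a cell/gene is a top member.
#' @param n_runs NMF restarts used for consensus and best-of-restart scoring.
#' @param k_max Largest candidate cluster number.
#' @param min_genes Minimum mappable disease genes required.
#' @param max_iter,tol NMF stopping rule.
#' @param n_sim,frac Jackknife simulations and subsample fraction.
#' @param alpha Significance level for overlap tests.
#' @param ... Overrides stored verbatim.
#' @return A named list of class `"dime_config"`.
#' @export
dime_config <- function(percentile = 0.75, n_runs = 30L, k_max = 7L,
                        min_genes = 15L, max_iter = 2000L, tol = 1e-6,
                        n_sim = 1000L, frac = 0.70, alpha = 0.05, ...) {
  structure(list(percentile = percentile, n_runs = as.integer(n_runs),
                 k_max = as.integer(k_max), min_genes = as.integer(min_genes),
                 max_iter = as.integer(max_iter), tol = tol,
                 n_sim = as.integer(n_sim), frac = frac, alpha = alpha, ...),
            class = "dime_config")
}

#' Extract a disease's expression submatrix from the immunome
#'
#' Rows are the disease's genes that are present in the immunome (immunome
#' row order preserved), columns all immunome cell types. The number of
#' unmappable disease genes is attached as attribute `"n_dropped"`.
#'
#' @param imm An [immunome()].
#' @param net A disease-gene tibble.
#' @param disease_id Disease identifier.
#' @param min_genes Minimum mappable genes (default 15); fewer is an error.
#' @return Numeric matrix (genes x cells) with attributes `disease_id` and
#'   `n_dropped`.
#' @export
extract_disease_matrix <- function(imm, net, disease_id, min_genes = 15L) {
  dag <- disease_genes(net, disease_id)
  keep <- rownames(imm)[rownames(imm) %in% dag]
  n_dropped <- length(dag) - length(keep)
  if (length(keep) < min_genes)
    abort(sprintf(
      "too few mappable disease genes for %s: %d present (min %d), %d dropped",
      disease_id, length(keep), min_genes, n_dropped))
  X <- unclass(imm)[keep, , drop = FALSE]
  attr(X, "disease_id") <- disease_id
  attr(X, "n_dropped") <- n_dropped
  X
}

#' Scale a non-negative score vector to \[0, 1\]
#'
#' Division by the maximum: zeros stay zero and the largest entry maps to 1,
#' so "no weight" keeps meaning "no contribution" (unlike min-max scaling).
#'
#' @param v Non-negative numeric vector with `max(v) > 0`.
#' @return `v / max(v)`.
#' @export
scale_scores <- function(v) {
  if (length(v) == 0 || anyNA(v) || any(v < 0))
    abort("scores must be non-negative and non-missing")
  m <- max(v)
  if (m <= 0) abort("all-zero score vector: cluster carries no weight")
  v / m
}

#' Select ids in the top percentile range of their scores
#'
#' An id is selected iff its score is at or above the `q`-quantile of the
#' score multiset, computed with linear interpolation between order
#' statistics (R's default type-7 quantile, `h = q (n - 1)`). The maximum
#' always qualifies, so the selection is never empty.
#'
#' @param scores Named numeric vector in `[0, 1]`.
#' @param q Quantile, default 0.75 (the "top 25th percentile" rule).
#' @return Character vector of selected names, in score order (descending).
#' @export
top_percentile_select <- function(scores, q = 0.75) {
  if (length(scores) == 0) abort("empty score vector")
  if (q <= 0 || q >= 1) abort("q must be in (0, 1)")
  thr <- quantile(scores, probs = q, type = 7, names = FALSE)
  sel <- scores[scores >= thr]
  names(sort(sel, decreasing = TRUE))
}

#' Rank NMF clusters by the Frobenius norm of their rank-one parts
#'
#' Each cluster i contributes the rank-one component `w_i h_i^T` of the
#' factorization; its weight is `||w_i h_i^T||_F = ||w_i||_2 ||h_i||_2`. The
#' cluster with the largest weight is the top (rank 1) cluster. Ties keep the
#' lower cluster index first.
#'
#' @param fit An [nmf_kl()] fit.
#' @return Tibble with columns `cluster` (original index), `rank`,
#'   `frobenius_weight`, ordered by rank.
#' @export
rank_clusters <- function(fit) {
  stopifnot(inherits(fit, "nmf_fit"))
  w <- vapply(seq_len(fit$k), function(i)
    sqrt(sum(fit$W[, i]^2)) * sqrt(sum(fit$H[i, ]^2)), numeric(1))
  ord <- order(-w, seq_along(w))
  tibble(cluster = as.integer(ord), rank = seq_along(ord),
         frobenius_weight = w[ord])
}

#' Run the disease-to-immune-cell mapping for one disease
#'
#' The full per-disease procedure: extract the disease expression submatrix
#' `X_D`, choose `k` by the cophenetic criterion (unless given), keep the
#' restart with the lowest final KL divergence, scale each cluster's cell
#' coefficients (`H` row) and gene weights (`W` column) to \[0, 1\] as DAC
#' and DAG scores, select top members by the top-quartile rule, and rank
#' clusters by Frobenius weight. Deterministic given `(seed, config)`.
#'
#' @param imm An [immunome()].
#' @param net A disease-gene tibble.
#' @param disease_id Disease identifier present in `net`.
#' @param k Number of clusters; `NULL` (default) selects it with [select_k()].
#' @param seed Integer seed.
#' @param config A [dime_config()].
#' @return An object of class `"dime_result"`: list with `disease_id`,
#'   `disease_name`, `k`, `k_table` (cophenetic selection table or `NULL`),
#'   `clusters` (tibble: `rank`, `cluster`, `frobenius_weight`, list-columns
#'   `dac_scores`, `dag_scores`, `top_dacs`, `top_dags`), `fit`, `seed`,
#'   `percentile`, `n_genes_dropped`.
#' @export
run_dime <- function(imm, net, disease_id, k = NULL, seed = 1L,
                     config = dime_config()) {
  X <- extract_disease_matrix(imm, net, disease_id,
                              min_genes = config$min_genes)
  k_table <- NULL
  if (is.null(k)) {
    kmax <- min(config$k_max, min(dim(X)) - 1L)
    sel <- select_k(X, k_range = seq(2L, kmax), n_runs = config$n_runs,
                    base_seed = seed, max_iter = config$max_iter,
                    tol = config$tol)
    k <- sel$k
    k_table <- sel$table
    # consensus restarts stop on assignment stability; re-fit the chosen k
    # under the divergence rule and keep the best of the restarts
    fit <- best_of_restarts(X, k, n_runs = config$n_runs, base_seed = seed,
                            max_iter = config$max_iter, tol = config$tol)
  } else if (k == 1L) {
    fit <- nmf_kl(X, 1L, seed = seed, max_iter = config$max_iter,
                  tol = config$tol)
  } else {
    fit <- best_of_restarts(X, k, n_runs = config$n_runs, base_seed = seed,
                            max_iter = config$max_iter, tol = config$tol)
  }
  ranking <- rank_clusters(fit)
  clusters <- ranking
  clusters$dac_scores <- lapply(ranking$cluster, function(i)
    scale_scores(fit$H[i, ]))
  clusters$dag_scores <- lapply(ranking$cluster, function(i)
    scale_scores(fit$W[, i]))
  clusters$top_dacs <- lapply(clusters$dac_scores, top_percentile_select,
                              q = config$percentile)
  clusters$top_dags <- lapply(clusters$dag_scores, top_percentile_select,
                              q = config$percentile)
  clusters <- clusters[, c("rank", "cluster", "frobenius_weight",
                           "dac_scores", "dag_scores", "top_dacs",
                           "top_dags")]
  name <- unique(net$disease_name[net$disease_id == disease_id])[1]
  structure(list(disease_id = disease_id, disease_name = name,
                 k = as.integer(k), k_table = k_table, clusters = clusters,
                 fit = fit, seed = as.integer(seed),
                 percentile = config$percentile,
                 n_genes_dropped = attr(X, "n_dropped")),
            class = "dime_result")
}

best_of_restarts <- function(X, k, n_runs, base_seed, ...) {
  best <- NULL
  for (r in seq_len(n_runs) - 1L) {
    fit <- nmf_kl(X, k, seed = derive_seed(base_seed, r), ...)
    if (is.null(best) || final_divergence(fit) < final_divergence(best))
      best <- fit
  }
  best
}

#' @export
print.dime_result <- function(x, ...) {
  cat(sprintf("<dime_result> %s (%s): k = %d clusters over %d genes x %d cells\n",
              x$disease_id, x$disease_name %||% "", x$k,
              nrow(x$fit$W), ncol(x$fit$H)))
  top <- x$clusters[1, ]
  cat(sprintf("top cluster (rank 1): %d top cells, %d top genes, |w h|_F = %.4g\n",
              length(top$top_dacs[[1]]), length(top$top_dags[[1]]),
              top$frobenius_weight))
  invisible(x)
}

#' Build the bipartite disease cell-gene network
#'
#' For every cluster the edge set is the complete bipartite product of its
#' top cells and top genes, tagged with the cluster rank. Each edge carries
#' the member scores and the gene's median expression across the cluster's
#' top cells (the quantity used for display pruning).
#'
#' @param res A [run_dime()] result.
#' @param imm The [immunome()] the result was computed from.
#' @return A tibble of class `"dime_network"` with columns `cell`, `gene`,
#'   `cluster_rank`, `dac_score`, `dag_score`, `median_expression`,
#'   `druggable`, `drugs`; attributes `disease_id` and `cells` (the immunome
#'   cell universe).
#' @export
build_dime_network <- function(res, imm) {
  stopifnot(inherits(res, "dime_result"))
  rows <- purrr::pmap(res$clusters, function(rank, cluster, frobenius_weight,
                                             dac_scores, dag_scores,
                                             top_dacs, top_dags) {
    med <- apply(unclass(imm)[top_dags, top_dacs, drop = FALSE], 1, median)
    tidyr::expand_grid(cell = top_dacs, gene = top_dags) |>
      dplyr::mutate(cluster_rank = as.integer(rank),
                    dac_score = unname(dac_scores[.data$cell]),
                    dag_score = unname(dag_scores[.data$gene]),
                    median_expression = unname(med[.data$gene]))
  })
  edges <- dplyr::bind_rows(rows)
  edges$druggable <- FALSE
  edges$drugs <- ""
  as_dime_network(edges, disease_id = res$disease_id,
                  cells = colnames(imm))
}

as_dime_network <- function(edges, disease_id = NA_character_, cells = NULL) {
  edges <- as_tibble(edges)
  needed <- c("cell", "gene", "cluster_rank", "dac_score", "dag_score",
              "median_expression", "druggable", "drugs")
  stopifnot(all(needed %in% names(edges)))
  attr(edges, "disease_id") <- disease_id
  attr(edges, "cells") <- cells
  class(edges) <- unique(c("dime_network", class(edges)))
  edges
}

#' Prune a network for display
#'
#' Per cluster: keep at most `max_dags` genes by descending gene score, then
#' drop genes whose median expression across the cluster's top cells is at or
#' below `min_expression`. Cells are untouched.
#'
#' @param nw A [build_dime_network()] tibble.
#' @param max_dags Gene cap per cluster, default 50.
#' @param min_expression Median log2(CPM + 1) a gene must exceed, default 5.
#' @return The pruned network tibble.
#' @export
prune_for_display <- function(nw, max_dags = 50L, min_expression = 5.0) {
  stopifnot(inherits(nw, "dime_network"))
  pruned <- nw |>
    dplyr::group_by(.data$cluster_rank) |>
    dplyr::group_modify(function(df, key) {
      keep <- df |>
        dplyr::distinct(.data$gene, .data$dag_score, .data$median_expression) |>
        dplyr::arrange(dplyr::desc(.data$dag_score), .data$gene) |>
        dplyr::slice_head(n = max_dags) |>
        dplyr::filter(.data$median_expression > min_expression)
      dplyr::filter(df, .data$gene %in% keep$gene)
    }) |>
    dplyr::ungroup() |>
    dplyr::relocate("cell", "gene", "cluster_rank")
  as_dime_network(pruned, disease_id = attr(nw, "disease_id"),
                  cells = attr(nw, "cells"))
}
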