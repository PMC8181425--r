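#' @describeIn run_dime Tidy the per-item scores: one row per (cluster rank,
#'   item), columns `rank`, `kind` (`"cell"`/`"gene"`), `item`, `score`,
#'   `top`.
#' @param x A `dime_result`.
#' @param ... Unused.
#' @export
tidy.dime_result <- function(x, ...) {
  purrr::pmap(x$clusters, function(rank, cluster, frobenius_weight,
                                   dac_scores, dag_scores, top_dacs,
                                   top_dags) {
    dplyr::bind_rows(
      tibble(rank = as.integer(rank), kind = "cell",
             item = names(dac_scores), score = unname(dac_scores),
             top = names(dac_scores) %in% top_dacs),
      tibble(rank = as.integer(rank), kind = "gene",
             item = names(dag_scores), score = unname(dag_scores),
             top = names(dag_scores) %in% top_dags))
  }) |> dplyr::bind_rows()
}

#' @describeIn run_dime One row per cluster: `rank`, `cluster`,
#'   `frobenius_weight`, `n_top_cells`, `n_top_genes`, plus the run metadata.
#' @export
glance.dime_result <- function(x, ...) {
  x$clusters |>
    dplyr::transmute(disease_id = x$disease_id, k = x$k,
                     rank = .data$rank, cluster = .data$cluster,
                     frobenius_weight = .data$frobenius_weight,
                     n_top_cells = lengths(.data$top_dacs),
                     n_top_genes = lengths(.data$top_dags),
                     final_divergence = final_divergence(x$fit),
                     converged = x$fit$converged)
}

#' @describeIn jackknife_run Occurrence table as a tidy tibble.
#' @param x A `jackknife_result`.
#' @param ... Unused.
#' @export
tidy.jackknife_result <- function(x, ...) {
  dplyr::mutate(x$occurrence, disease_id = x$disease_id, mode = x$mode,
                frequency = .data$count / x$n_effective,
                .before = 1)
}

#' @describeIn jackknife_run One-row summary: r, p, verdict, sizes.
#' @export
glance.jackknife_result <- function(x, ...) {
  tibble(disease_id = x$disease_id, mode = x$mode, n_sim = x$n_sim,
         n_effective = x$n_effective, frac = x$frac,
         pearson_r = x$pearson_r, pearson_p = x$pearson_p,
         significant = x$significant)
}

#' @describeIn pairwise_comparison Long-form pair table.
#' @param x A `dime_comparison`.
#' @param ... Unused.
#' @export
tidy.dime_comparison <- function(x, ...) x$pairs

#' Heatmap of per-cluster scores for one disease
#'
#' Cells and genes (top members only, to keep the panel readable) against
#' cluster rank, tile fill = score.
#'
#' @param object A [run_dime()] result.
#' @param kind `"cell"` or `"gene"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dime_result <- function(object, kind = c("cell", "gene"), ...) {
  kind <- rlang::arg_match(kind)
  df <- tidy(object)
  df <- df[df$kind == kind & df$top, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$rank),
    y = stats::reorder(.data$item, .data$score),
    fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "cluster rank", y = NULL, fill = "score",
                  title = paste0(object$disease_id, ": top ",
                                 kind, "s by cluster")) +
    ggplot2::theme_minimal()
}

#' Overlap heatmap for an all-pairs disease comparison
#'
#' Jaccard index as fill, significance stars printed on each tile.
#'
#' @param object A [pairwise_comparison()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dime_comparison <- function(object, ...) {
  df <- object$pairs
  sym <- dplyr::bind_rows(
    df,
    dplyr::rename(df, disease_a = "disease_b", disease_b = "disease_a"))
  ggplot2::ggplot(sym, ggplot2::aes(.data$disease_a, .data$disease_b,
                                    fill = .data$jaccard)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$significance)) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Jaccard") +
    ggplot2::theme_minimal()
}

#' Jackknife occurrence against original score
#'
#' One point per tracked item; stable analyses put the original top members
#' in the upper-right corner.
#'
#' @param object A [jackknife_run()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.jackknife_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$original_score, .data$frequency,
                                   colour = .data$original_top)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "original top-cluster score", y = "occurrence frequency",
      colour = "top in original",
      title = sprintf("%s (%s): r = %.3f, p = %.2g", object$disease_id,
                      object$mode, object$pearson_r %||% NA_real_,
                      object$pearson_p %||% NA_real_)) +
    ggplot2::theme_minimal()
}
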