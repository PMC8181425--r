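#' Jackknife stability analysis of a disease's top members
#'
#' Repeatedly re-runs the whole per-disease procedure on random subsamples
#' and counts how often each item returns as a top member of the top
#' (rank 1) cluster:
#'
#' * `mode = "subsample_genes"` draws `floor(frac * n_genes)` of the
#'   disease's mappable genes per simulation and counts the top cluster's top
#'   cells (testing DAC stability);
#' * `mode = "subsample_cells"` draws `floor(frac * n_cells)` cell types and
#'   counts, among the original run's top-10 genes by score, how often each
#'   returns as a top gene of the top cluster (testing DAG stability).
#'
#' `k` is re-selected inside every simulation. Simulations whose gene
#' subsample falls below `config$min_genes` are skipped (logged; the
#' effective denominator `n_effective` is reported). Fully deterministic:
#' simulation `s` uses seed `base_seed + s`.
#'
#' The stability verdict is the Pearson correlation between the original
#' run's top-cluster scores and the occurrence counts ([consistency_test()]).
#'
#' @param imm An [immunome()].
#' @param net A disease-gene tibble.
#' @param disease_id Disease identifier.
#' @param mode `"subsample_genes"` or `"subsample_cells"`.
#' @param n_sim Number of simulations (default from `config`, 1000).
#' @param frac Subsample fraction, default 0.70.
#' @param base_seed Integer seed.
#' @param config A [dime_config()].
#' @param original Optional precomputed [run_dime()] result for the full
#'   data (must have been run with `base_seed` and `config`); avoids
#'   recomputation.
#' @return An object of class `"jackknife_result"`: list with `disease_id`,
#'   `mode`, `n_sim`, `n_effective`, `frac`, `occurrence` (tibble `item`,
#'   `count`, `original_score`, `original_top`), `pearson_r`, `pearson_p`,
#'   `significant`, `original`.
#' @export
jackknife_run <- function(imm, net, disease_id,
                          mode = c("subsample_genes", "subsample_cells"),
                          n_sim = NULL, frac = NULL, base_seed = 1L,
                          config = dime_config(), original = NULL) {
  mode <- rlang::arg_match(mode)
  n_sim <- as.integer(n_sim %||% config$n_sim)
  frac <- frac %||% config$frac
  stopifnot(frac > 0, frac <= 1, n_sim >= 1)

  original <- original %||%
    run_dime(imm, net, disease_id, seed = base_seed, config = config)
  top <- original$clusters[original$clusters$rank == 1L, ]

  if (mode == "subsample_genes") {
    items <- colnames(imm)
    scores <- top$dac_scores[[1]][items]
  } else {
    dag_scores <- sort(top$dag_scores[[1]], decreasing = TRUE)
    items <- names(head(dag_scores, 10L))
    scores <- dag_scores[items]
  }

  genes <- disease_genes(net, disease_id)
  genes <- genes[genes %in% rownames(imm)]
  cells <- colnames(imm)
  counts <- setNames(rep(0L, length(items)), items)
  n_skipped <- 0L

  for (s in seq_len(n_sim)) {
    sim_seed <- derive_seed(base_seed, s)
    set.seed(sim_seed)
    if (mode == "subsample_genes") {
      sub_genes <- sample(genes, floor(frac * length(genes)))
      sub_net <- tibble(disease_id = disease_id,
                        disease_name = original$disease_name,
                        gene = sub_genes)
      sub_imm <- imm
    } else {
      sub_cells <- sample(cells, floor(frac * length(cells)))
      sub_net <- net[net$disease_id == disease_id, ]
      sub_imm <- immunome(unclass(imm)[, sort(match(sub_cells, cells)),
                                       drop = FALSE])
    }
    if (mode == "subsample_genes" &&
        length(sub_genes) < config$min_genes) {
      n_skipped <- n_skipped + 1L
      next
    }
    complete <- if (mode == "subsample_genes")
      length(sub_genes) == length(genes) else length(sub_cells) == length(cells)
    res <- tryCatch(
      run_dime(sub_imm, as_disease_gene_tbl(sub_net), disease_id,
               # a complete subsample (frac = 1) reproduces the original run
               seed = if (complete) base_seed else sim_seed, config = config),
      error = function(e) NULL)
    if (is.null(res)) {
      n_skipped <- n_skipped + 1L
      next
    }
    sim_top <- res$clusters[res$clusters$rank == 1L, ]
    hits <- if (mode == "subsample_genes") sim_top$top_dacs[[1]]
            else sim_top$top_dags[[1]]
    hits <- intersect(hits, items)
    counts[hits] <- counts[hits] + 1L
  }
  n_eff <- n_sim - n_skipped
  if (n_skipped > 0)
    inform(sprintf("%d of %d simulations skipped (subsample below minimum)",
                   n_skipped, n_sim))

  occurrence <- tibble(item = items, count = unname(counts[items]),
                       original_score = unname(scores),
                       original_top = items %in%
                         (if (mode == "subsample_genes") top$top_dacs[[1]]
                          else top$top_dags[[1]]))
  ct <- consistency_test(occurrence$original_score, occurrence$count)
  structure(list(disease_id = disease_id, mode = mode, n_sim = n_sim,
                 n_effective = n_eff, frac = frac, occurrence = occurrence,
                 pearson_r = ct$r, pearson_p = ct$p,
                 significant = ct$significant, original = original),
            class = "jackknife_result")
}

#' Pearson consistency test between original scores and jackknife counts
#'
#' Two-sided Pearson correlation test (t distribution, n - 2 df) between the
#' original top-cluster scores and the number of simulations in which each
#' item returned as a top member. Items never returning keep count 0 and are
#' included. Zero variance in either vector leaves the correlation undefined
#' and the result non-significant (with a warning).
#'
#' @param scores Numeric vector of original scores.
#' @param counts Integer vector of occurrence counts, same length.
#' @param alpha Significance level, default 0.05.
#' @return List with `r`, `p`, `significant`.
#' @export
consistency_test <- function(scores, counts, alpha = 0.05) {
  if (length(scores) != length(counts)) abort("length mismatch")
  if (length(scores) < 3) abort("need at least 3 items")
  if (stats::sd(scores) == 0 || stats::sd(counts) == 0) {
    warn("zero variance: correlation undefined, reported non-significant")
    return(list(r = NA_real_, p = NA_real_, significant = FALSE))
  }
  ct <- cor.test(scores, counts, method = "pearson",
                 alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value,
       significant = ct$p.value <= alpha)
}

#' @export
print.jackknife_result <- function(x, ...) {
  cat(sprintf(
    "<jackknife_result> %s, %s: %d/%d simulations, r = %.3f, p = %.3g (%s)\n",
    x$disease_id, x$mode, x$n_effective, x$n_sim,
    x$pearson_r %||% NA, x$pearson_p %||% NA,
    if (isTRUE(x$significant)) "significant" else "not significant"))
  invisible(x)
}
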