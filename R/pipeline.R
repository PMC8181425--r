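#' Run the whole analysis end to end
#'
#' Orchestrates: optional count preprocessing, disease-gene filtering (HLA
#' removal, immunome restriction), per-disease factorization and network
#' construction, all-pairs comparison of the networks, optional jackknife
#' stability runs, and the drug-gene overlay with repurposing candidates.
#' Every artifact lands under `out_dir`:
#'
#' * `manifest.json` — tool version, configuration, config hash, all seeds;
#' * `immunome.tsv` — the (possibly preprocessed) expression matrix;
#' * `dime_<id>.json`, `network_<id>.tsv` / `.graphml` — per disease;
#' * `comparison_long.tsv`, `comparison_matrix.tsv` — all-pairs overlap;
#' * `common_<a>__<b>.tsv` — each pair's common network;
#' * `candidates.tsv` — repurposing candidates (when a drug table is given);
#' * `jackknife_<id>.json` + `.tsv` — when `jackknife = TRUE`.
#'
#' Identical `config` + `seed` produce byte-identical artifacts.
#'
#' @param immunome_path Immunome TSV (or `NULL` when counts are given).
#' @param disease_path Disease-gene table path.
#' @param dialect Dialect for [read_disease_gene_table()].
#' @param out_dir Output directory (created if missing).
#' @param seed Integer master seed.
#' @param counts_path,labels_path Optional raw counts + sample labels; when
#'   given they are preprocessed into the immunome.
#' @param drug_path Optional drug-gene TSV.
#' @param disease_filter Optional CUIs to keep.
#' @param jackknife Run jackknife stability per disease (default `FALSE`).
#' @param config A [dime_config()].
#' @return Invisibly, a list with the in-memory results (`immunome`, `net`,
#'   `results`, `networks`, `comparison`, `candidates`, `jackknife`) and
#'   `out_dir`.
#' @export
run_end_to_end <- function(immunome_path = NULL, disease_path,
                           dialect = "disgenet_curated", out_dir,
                           seed = 1L, counts_path = NULL, labels_path = NULL,
                           drug_path = NULL, disease_filter = NULL,
                           jackknife = FALSE, config = dime_config()) {
  if (is.null(immunome_path) && is.null(counts_path))
    abort("either immunome_path or counts_path is required",
          class = "dime_usage_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  imm <- if (!is.null(counts_path)) {
    preprocess_counts(read_counts(counts_path, labels_path))
  } else read_immunome(immunome_path)

  net <- read_disease_gene_table(disease_path, dialect = dialect,
                                 disease_filter = disease_filter)
  net <- remove_hla_genes(net)
  net <- restrict_to_immunome(net, imm)
  dgn <- if (!is.null(drug_path)) read_drug_gene_table(drug_path) else NULL

  ids <- unique(net$disease_id)
  results <- list()
  networks <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    res <- run_dime(imm, net, id, seed = derive_seed(seed, 10000L * i),
                    config = config)
    nw <- build_dime_network(res, imm)
    if (!is.null(dgn)) nw <- annotate_druggable(nw, dgn)
    results[[id]] <- res
    networks[[id]] <- nw
  }

  comparison <- NULL
  candidates <- NULL
  if (length(ids) >= 2) {
    universe <- ncol(imm) * length(unique(net$gene))
    comparison <- pairwise_comparison(networks, universe_size = universe,
                                      item_kind = "cell_gene_pairs")
    if (!is.null(dgn))
      candidates <- repurposing_candidates(comparison, results, dgn,
                                           alpha = config$alpha)
  }

  jk <- NULL
  if (isTRUE(jackknife)) {
    jk <- lapply(seq_along(ids), function(i)
      jackknife_run(imm, net, ids[i], mode = "subsample_genes",
                    base_seed = derive_seed(seed, 10000L * i),
                    config = config,
                    original = results[[ids[i]]]))
    names(jk) <- ids
  }

  write_run_artifacts(out_dir, imm, net, results, networks, comparison,
                      candidates, jk, seed, config)
  invisible(list(immunome = imm, net = net, results = results,
                 networks = networks, comparison = comparison,
                 candidates = candidates, jackknife = jk,
                 out_dir = out_dir))
}

write_run_artifacts <- function(out_dir, imm, net, results, networks,
                                comparison, candidates, jk, seed, config) {
  p <- function(...) file.path(out_dir, ...)
  write_immunome(imm, p("immunome.tsv"))
  for (id in names(results)) {
    res <- results[[id]]
    safe <- gsub("[^A-Za-z0-9_.-]", "_", id)
    jsonlite::write_json(dime_result_json(res), p(paste0("dime_", safe,
                                                         ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_network(networks[[id]], p(paste0("network_", safe, ".tsv")),
                  fmt = "edge_tsv")
    write_network(networks[[id]], p(paste0("network_", safe, ".graphml")),
                  fmt = "graphml")
  }
  if (!is.null(comparison)) {
    readr::write_tsv(comparison$pairs, p("comparison_long.tsv"),
                     progress = FALSE)
    cm <- comparison_matrix(comparison)
    readr::write_tsv(dplyr::bind_cols(tibble(disease = rownames(cm)),
                                      as_tibble(cm)),
                     p("comparison_matrix.tsv"), progress = FALSE)
    for (key in names(comparison$common)) {
      safe <- gsub("[^A-Za-z0-9_.-]", "_", gsub("\\|", "__", key))
      readr::write_tsv(comparison$common[[key]]$edges,
                       p(paste0("common_", safe, ".tsv")), progress = FALSE)
    }
  }
  if (!is.null(candidates))
    readr::write_tsv(candidates, p("candidates.tsv"), progress = FALSE)
  if (!is.null(jk)) {
    for (id in names(jk)) {
      safe <- gsub("[^A-Za-z0-9_.-]", "_", id)
      jsonlite::write_json(glance(jk[[id]]), p(paste0("jackknife_", safe,
                                                      ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      readr::write_tsv(tidy(jk[[id]]), p(paste0("jackknife_", safe, ".tsv")),
                       progress = FALSE)
    }
  }
  manifest <- list(
    tool = "dime",
    version = as.character(utils::packageVersion("dime")),
    seed = seed,
    config = unclass(config),
    config_hash = rlang::hash(list(seed = seed, config = unclass(config))),
    diseases = lapply(results, function(r)
      list(disease_id = r$disease_id, seed = r$seed, k = r$k,
           k_table = r$k_table, n_genes_dropped = r$n_genes_dropped)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

dime_result_json <- function(res) {
  list(disease_id = res$disease_id, disease_name = res$disease_name,
       k = res$k, seed = res$seed, percentile = res$percentile,
       k_table = res$k_table,
       n_genes_dropped = res$n_genes_dropped,
       final_divergence = final_divergence(res$fit),
       converged = res$fit$converged,
       clusters = purrr::pmap(res$clusters, function(rank, cluster,
                                                     frobenius_weight,
                                                     dac_scores, dag_scores,
                                                     top_dacs, top_dags) {
         list(rank = rank, cluster = cluster,
              frobenius_weight = frobenius_weight,
              dac_scores = as.list(dac_scores),
              dag_scores = as.list(dag_scores),
              top_dacs = top_dacs, top_dags = top_dags)
       }))
}

#' Write a synthetic study to disk
#'
#' Generates the planted immunome, disease networks and drug table and
#' writes them in the TSV formats the readers consume; the planted truth is
#' written alongside for downstream evaluation.
#'
#' @param out_dir Output directory.
#' @param spec A [planted_spec()].
#' @param assignments Disease-to-module map as in
#'   [generate_disease_networks()]; the default plants two diseases sharing
#'   module 1, one of them also carrying module 2.
#' @param n_background_genes Background genes per disease, default 75.
#' @param druggable_fraction Fraction of module genes flagged druggable.
#' @param seed Integer seed (also used for the spec when it has none).
#' @return Invisibly, the list of written paths.
#' @export
simulate_run <- function(out_dir, spec = NULL,
                         assignments = list(DIS_A = 1L,
                                            DIS_B = c(1L, 2L)),
                         n_background_genes = 75L,
                         druggable_fraction = 0.2, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- spec %||% planted_spec(seed = seed)
  sim <- generate_immunome(spec)
  net <- generate_disease_networks(
    sim$truth, assignments, n_background_genes = n_background_genes,
    all_genes = rownames(sim$immunome), seed = derive_seed(seed, 1L))
  dgn <- generate_drug_table(sim$truth, druggable_fraction,
                             seed = derive_seed(seed, 2L))
  paths <- list(
    immunome = file.path(out_dir, "immunome.tsv"),
    diseases = file.path(out_dir, "disease_genes.tsv"),
    drugs = file.path(out_dir, "drug_genes.tsv"),
    truth = file.path(out_dir, "truth.tsv"))
  write_immunome(sim$immunome, paths$immunome)
  write_disease_gene_table(net, paths$diseases)
  write_drug_gene_table(dgn, paths$drugs)
  readr::write_tsv(sim$truth, paths$truth, progress = FALSE)
  invisible(paths)
}
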