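#' Specification of a planted-module synthetic immunome
#'
#' The generator emulates a reference immune-cell expression matrix on the
#' log2(CPM + 1) scale: 40 cell types, a few hundred genes, and
#' cell-type-specific gene modules planted on a flat low-expression
#' background. Each module is a block of genes highly expressed by a small
#' set of "primary" cell types and, optionally, at an intermediate level by
#' "secondary" cell types (related lineages sharing the programme at lower
#' level). Everything else sits at `low_mean`. Values are
#' `max(0, Normal(mean, sd))` draws, deterministic under `seed`.
#'
#' Defaults plant two disjoint modules of 75 genes: module 1 with primary
#' cells 1-10 at mean 7 and secondary cells 21-30 at mean 3; module 2 with
#' primary cells 11-20 at mean 6 and secondary cells 31-40 at mean 2.5;
#' background mean 1, sd 0.5. With 300 genes and 40 cells each module's genes
#' are 25% of the genes and its primary cells 25% of the cell types, matching
#' the top-quartile membership rule, and the mean gap between the top module
#' and background is 6 at noise sd 0.5.
#'
#' @param n_genes,n_cells Matrix dimensions (defaults 300 and 40).
#' @param modules List of module descriptions: `genes` and `cells` (integer
#'   indices or names), `high_mean`, and optional `secondary_cells`,
#'   `secondary_mean`. `NULL` gives the two-module default above.
#' @param low_mean,sd Background mean and shared noise sd.
#' @param seed Integer seed.
#' @return A list of class `"planted_spec"`.
#' @export
planted_spec <- function(n_genes = 300L, n_cells = 40L, modules = NULL,
                         low_mean = 1, sd = 0.5, seed = 1L) {
  modules <- modules %||% list(
    list(genes = 1:75, cells = 1:10, high_mean = 7,
         secondary_cells = 21:30, secondary_mean = 3),
    list(genes = 76:150, cells = 11:20, high_mean = 6,
         secondary_cells = 31:40, secondary_mean = 2.5))
  for (m in modules) {
    stopifnot(m$high_mean > low_mean, m$high_mean >= 0)
    stopifnot(max(m$genes) <= n_genes, max(m$cells) <= n_cells)
  }
  all_genes <- unlist(lapply(modules, `[[`, "genes"))
  if (anyDuplicated(all_genes))
    abort("module gene sets must be disjoint")
  structure(list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
                 modules = modules, low_mean = low_mean, sd = sd,
                 seed = as.integer(seed)),
            class = "planted_spec")
}

synthetic_gene_names <- function(n) sprintf("G%04d", seq_len(n))
synthetic_cell_names <- function(n) sprintf("cell_%02d", seq_len(n))

#' Generate a synthetic immunome with planted modules
#'
#' @param spec A [planted_spec()].
#' @return A list with `immunome` (an [immunome()]) and `truth`, a tibble of
#'   planted memberships: columns `module`, `kind` (`"gene"`/`"cell"`/
#'   `"secondary_cell"`), `item`.
#' @export
generate_immunome <- function(spec = planted_spec()) {
  stopifnot(inherits(spec, "planted_spec"))
  set.seed(spec$seed)
  genes <- synthetic_gene_names(spec$n_genes)
  cells <- synthetic_cell_names(spec$n_cells)
  mean_mat <- matrix(spec$low_mean, spec$n_genes, spec$n_cells,
                     dimnames = list(genes, cells))
  truth <- list()
  for (i in seq_along(spec$modules)) {
    m <- spec$modules[[i]]
    mean_mat[m$genes, m$cells] <- m$high_mean
    truth[[length(truth) + 1]] <-
      tibble(module = i, kind = "gene", item = genes[m$genes])
    truth[[length(truth) + 1]] <-
      tibble(module = i, kind = "cell", item = cells[m$cells])
    if (!is.null(m$secondary_cells)) {
      mean_mat[m$genes, m$secondary_cells] <- m$secondary_mean
      truth[[length(truth) + 1]] <-
        tibble(module = i, kind = "secondary_cell",
               item = cells[m$secondary_cells])
    }
  }
  values <- pmax(mean_mat + matrix(stats::rnorm(length(mean_mat), 0, spec$sd),
                                   nrow(mean_mat)), 0)
  list(immunome = immunome(values), truth = dplyr::bind_rows(truth))
}

#' Generate disease-gene networks over planted modules
#'
#' Each disease's gene set is the union of its assigned planted modules'
#' genes plus `n_background_genes` random non-module genes, so shared module
#' assignments induce a known overlap structure between diseases.
#'
#' @param truth The `truth` tibble from [generate_immunome()].
#' @param assignments Named list mapping disease id to an integer vector of
#'   module indices (may be empty for a background-only disease).
#' @param n_background_genes Background genes per disease (drawn without
#'   replacement from non-module genes).
#' @param all_genes Character vector of all immunome genes (to draw
#'   background from).
#' @param seed Integer seed.
#' @param disjoint_background If `TRUE` (default) diseases get disjoint
#'   background gene sets, so gene overlap between diseases is exactly their
#'   shared modules.
#' @return A `"disease_gene_tbl"` tibble.
#' @export
generate_disease_networks <- function(truth, assignments,
                                      n_background_genes = 0L,
                                      all_genes, seed = 1L,
                                      disjoint_background = TRUE) {
  set.seed(seed)
  module_genes <- split(truth$item[truth$kind == "gene"],
                        truth$module[truth$kind == "gene"])
  bad <- setdiff(unlist(assignments), as.integer(names(module_genes)))
  if (length(bad) > 0)
    abort(paste0("unknown module(s): ", paste(bad, collapse = ", ")))
  background_pool <- sample(setdiff(all_genes, unlist(module_genes)))
  rows <- purrr::imap(assignments, function(mods, id) {
    genes <- unlist(module_genes[as.character(mods)], use.names = FALSE)
    if (n_background_genes > 0) {
      if (length(background_pool) < n_background_genes)
        abort("not enough background genes left")
      bg <- background_pool[seq_len(n_background_genes)]
      if (disjoint_background)
        background_pool <<- setdiff(background_pool, bg)
      genes <- c(genes, bg)
    }
    tibble(disease_id = id, disease_name = id, gene = genes)
  })
  as_disease_gene_tbl(dplyr::bind_rows(rows))
}

#' Generate a synthetic drug-gene interaction table
#'
#' Flags a seeded random fraction of the planted module genes as druggable,
#' with synthetic drug names (`drug_<gene>`), source `"custom"` and
#' `approved = TRUE`.
#'
#' @param truth The `truth` tibble from [generate_immunome()].
#' @param druggable_fraction Fraction of module genes to flag, in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `"drug_gene_tbl"` tibble.
#' @export
generate_drug_table <- function(truth, druggable_fraction = 0.2, seed = 1L) {
  stopifnot(druggable_fraction >= 0, druggable_fraction <= 1)
  set.seed(seed)
  genes <- unique(truth$item[truth$kind == "gene"])
  n <- round(druggable_fraction * length(genes))
  pick <- if (n > 0) sort(sample(genes, n)) else character()
  as_drug_gene_tbl(tibble(gene = pick,
                          drug = paste0("drug_", tolower(pick)),
                          source = "custom", approved = TRUE))
}

#' Generate a synthetic count matrix for the preprocessing path
#'
#' Count-level twin of [generate_immunome()]: for each cell type,
#' `n_samples_per_celltype` samples are drawn with
#' `counts ~ Poisson(library_size * p_g)` where the per-gene rates `p_g` are
#' proportional to `2^mu - 1` for that cell type's planted mean expression
#' `mu` (so that CPM + log2 preprocessing approximately recovers the planted
#' pattern).
#'
#' @param spec A [planted_spec()].
#' @param n_samples_per_celltype Samples per cell type, default 3.
#' @param library_size Expected reads per sample, default 1e6.
#' @return A [count_matrix()].
#' @export
generate_counts <- function(spec = planted_spec(),
                            n_samples_per_celltype = 3L,
                            library_size = 1e6) {
  stopifnot(inherits(spec, "planted_spec"))
  set.seed(derive_seed(spec$seed, 777L))
  genes <- synthetic_gene_names(spec$n_genes)
  cells <- synthetic_cell_names(spec$n_cells)
  mean_mat <- matrix(spec$low_mean, spec$n_genes, spec$n_cells,
                     dimnames = list(genes, cells))
  for (m in spec$modules) {
    mean_mat[m$genes, m$cells] <- m$high_mean
    if (!is.null(m$secondary_cells))
      mean_mat[m$genes, m$secondary_cells] <- m$secondary_mean
  }
  rel <- 2^mean_mat - 1
  rel <- sweep(rel, 2, colSums(rel), "/")
  samples <- character(0)
  labels <- character(0)
  counts <- matrix(0L, spec$n_genes,
                   spec$n_cells * n_samples_per_celltype,
                   dimnames = list(genes, NULL))
  col <- 0L
  for (j in seq_len(spec$n_cells)) {
    for (s in seq_len(n_samples_per_celltype)) {
      col <- col + 1L
      counts[, col] <- stats::rpois(spec$n_genes, library_size * rel[, j])
      samples <- c(samples, sprintf("%s_s%d", cells[j], s))
      labels <- c(labels, cells[j])
    }
  }
  colnames(counts) <- samples
  count_matrix(counts, setNames(labels, samples))
}
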