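#' Jaccard index of two finite sets
#'
#' `|A intersect B| / |A union B|`; both sets empty is an error.
#'
#' @param A,B Vectors treated as sets.
#' @return A number in `[0, 1]`.
#' @export
jaccard_index <- function(A, B) {
  A <- unique(A); B <- unique(B)
  u <- length(union(A, B))
  if (u == 0) abort("Jaccard index undefined for two empty sets")
  length(intersect(A, B)) / u
}

#' One-sided Fisher's exact test for set overlap
#'
#' Tests over-representation of the observed overlap between two sets drawn
#' from a common universe of `universe_size` items: the p-value is the upper
#' hypergeometric tail `P(X >= |A intersect B|)` with
#' `X ~ Hypergeom(N = universe_size, K = |A|, n = |B|)`.
#'
#' @param A,B Vectors treated as sets (subsets of the universe).
#' @param universe_size Number of items in the universe.
#' @return A p-value in `(0, 1]`.
#' @export
fisher_overlap_test <- function(A, B, universe_size) {
  A <- unique(A); B <- unique(B)
  K <- length(A); n <- length(B); m <- length(intersect(A, B))
  if (K > universe_size || n > universe_size)
    abort("set larger than the universe")
  phyper(m - 1, K, universe_size - K, n, lower.tail = FALSE)
}

significance_label <- function(p) {
  dplyr::case_when(p <= 0.001 ~ "***", p <= 0.01 ~ "**",
                   p <= 0.05 ~ "*", .default = "")
}

overlap_result <- function(disease_a, disease_b, A, B, universe_size,
                           item_kind) {
  inter <- intersect(A, B)
  p <- fisher_overlap_test(A, B, universe_size)
  tibble(disease_a = disease_a, disease_b = disease_b,
         item_kind = item_kind,
         n_a = length(unique(A)), n_b = length(unique(B)),
         n_common = length(inter),
         jaccard = jaccard_index(A, B),
         fisher_p = p, universe_size = as.integer(universe_size),
         significance = significance_label(p))
}

edge_keys <- function(nw) {
  unique(paste(nw$cell, nw$gene, sep = "\r"))
}

#' Common cell-gene network of two diseases
#'
#' Intersects the `(cell, gene)` edge sets of two disease networks (cluster
#' rank ignored for membership), annotating every common edge with its rank
#' in each disease, and summarises the overlap with the Jaccard index and the
#' one-sided Fisher test.
#'
#' @param nwA,nwB [build_dime_network()] tibbles built on the same immunome
#'   cell set.
#' @param universe_size Universe for the Fisher test; conventionally
#'   `|cells| * |union of disease genes across the loaded diseases|`.
#' @return A list of class `"common_network"`: `edges` (tibble `cell`,
#'   `gene`, `rank_a`, `rank_b`, `druggable`, `drugs`) and `overlap` (one-row
#'   tibble as in [pairwise_comparison()]).
#' @export
common_cell_gene_network <- function(nwA, nwB, universe_size) {
  cellsA <- attr(nwA, "cells"); cellsB <- attr(nwB, "cells")
  if (!is.null(cellsA) && !is.null(cellsB) && !setequal(cellsA, cellsB))
    abort("networks were built on different immunome cell sets")
  a <- nwA |>
    dplyr::group_by(.data$cell, .data$gene) |>
    dplyr::summarise(rank_a = min(.data$cluster_rank), .groups = "drop")
  b <- nwB |>
    dplyr::group_by(.data$cell, .data$gene) |>
    dplyr::summarise(rank_b = min(.data$cluster_rank), .groups = "drop")
  edges <- dplyr::inner_join(a, b, by = c("cell", "gene"))
  edges$druggable <- FALSE
  edges$drugs <- ""
  overlap <- overlap_result(attr(nwA, "disease_id"), attr(nwB, "disease_id"),
                            edge_keys(nwA), edge_keys(nwB), universe_size,
                            "cell_gene_pairs")
  structure(list(edges = edges, overlap = overlap),
            class = "common_network")
}

#' @export
print.common_network <- function(x, ...) {
  o <- x$overlap
  cat(sprintf("<common_network> %s vs %s: %d common edges, JI = %.3g, FET p = %.3g%s\n",
              o$disease_a, o$disease_b, o$n_common, o$jaccard, o$fisher_p,
              if (nzchar(o$significance)) paste0(" ", o$significance) else ""))
  invisible(x)
}

#' All-pairs disease overlap comparison
#'
#' Computes the Jaccard index and one-sided Fisher's exact test for every
#' unordered pair of diseases, over either plain gene sets or the
#' `(cell, gene)` edge sets of their networks. No multiple-testing correction
#' is applied; the long-form table carries raw p-values. Significance stars:
#' `***` for p <= 0.001, `**` <= 0.01, `*` <= 0.05.
#'
#' @param items Named list: per disease either a character vector of genes
#'   (`item_kind = "genes"`) or a `dime_network` tibble
#'   (`item_kind = "cell_gene_pairs"`).
#' @param universe_size Universe for the Fisher test. For gene sets a natural
#'   choice is the number of genes in the loaded, filtered disease-gene
#'   network; for edge sets, `|immunome cells| * |union of disease genes|`.
#' @param item_kind `"genes"` or `"cell_gene_pairs"`.
#' @return An object of class `"dime_comparison"`: list with `pairs`
#'   (long-form tibble of all unordered pairs), `common` (named list of
#'   [common_cell_gene_network()] results when comparing networks),
#'   `item_kind`, `universe_size`.
#' @export
pairwise_comparison <- function(items, universe_size,
                                item_kind = c("genes", "cell_gene_pairs")) {
  item_kind <- rlang::arg_match(item_kind)
  ids <- names(items)
  if (length(ids) < 2) abort("need at least two diseases to compare")
  pairs <- utils::combn(ids, 2, simplify = FALSE)
  common <- list()
  rows <- purrr::map(pairs, function(pr) {
    if (item_kind == "genes") {
      overlap_result(pr[1], pr[2], items[[pr[1]]], items[[pr[2]]],
                     universe_size, item_kind)
    } else {
      cn <- common_cell_gene_network(items[[pr[1]]], items[[pr[2]]],
                                     universe_size)
      cn$overlap$disease_a <- pr[1]
      cn$overlap$disease_b <- pr[2]
      common[[paste(pr, collapse = "|")]] <<- cn
      cn$overlap
    }
  })
  structure(list(pairs = dplyr::bind_rows(rows), common = common,
                 item_kind = item_kind,
                 universe_size = as.integer(universe_size)),
            class = "dime_comparison")
}

#' @export
print.dime_comparison <- function(x, ...) {
  cat(sprintf("<dime_comparison> %s, universe %d\n", x$item_kind,
              x$universe_size))
  print(x$pairs)
  invisible(x)
}

#' Square matrix view of a pairwise comparison
#'
#' Jaccard indices below the diagonal, significance stars above, 1 on the
#' diagonal (a disease compared with itself).
#'
#' @param cmp A [pairwise_comparison()] result.
#' @return Character matrix with disease ids as dimnames.
#' @export
comparison_matrix <- function(cmp) {
  ids <- sort(unique(c(cmp$pairs$disease_a, cmp$pairs$disease_b)))
  m <- matrix("", length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- "1"
  for (r in seq_len(nrow(cmp$pairs))) {
    row <- cmp$pairs[r, ]
    i <- match(row$disease_a, ids); j <- match(row$disease_b, ids)
    lo <- max(i, j); hi <- min(i, j)
    m[lo, hi] <- formatC(row$jaccard, digits = 4, format = "g")
    m[hi, lo] <- row$significance
  }
  m
}
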