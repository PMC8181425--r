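#' Generalized Kullback-Leibler divergence between a matrix and its model
#'
#' `D(X || WH) = sum_ij [ X_ij log(X_ij / (WH)_ij) - X_ij + (WH)_ij ]` with
#' the convention `0 * log 0 = 0`. This is the objective minimised by the
#' multiplicative-update factorization in [nmf_kl()]; it is zero iff
#' `X == WH` elementwise and positive otherwise. `WH` is floored at
#' `eps = 1e-12` before logs are taken.
#'
#' @param X Non-negative numeric matrix.
#' @param WH Model matrix of the same shape (typically `W %*% H`).
#' @param eps Positive floor applied to `WH`.
#' @return A single non-negative number.
#' @examples
#' kl_divergence(matrix(1), matrix(2)) # 1 - log(2)
#' @export
kl_divergence <- function(X, WH, eps = 1e-12) {
  X <- as.matrix(X); WH <- as.matrix(WH)
  if (!all(dim(X) == dim(WH)))
    abort("X and WH have different shapes")
  WH <- pmax(WH, eps)
  pos <- X > 0
  sum(X[pos] * log(X[pos] / WH[pos])) - sum(X) + sum(WH)
}

nmf_init <- function(X, k, seed) {
  set.seed(seed)
  s <- sqrt(mean(X))
  list(W = matrix(runif(nrow(X) * k), nrow(X), k) * s,
       H = matrix(runif(k * ncol(X)), k, ncol(X)) * s)
}

check_nmf_input <- function(X, k) {
  if (anyNA(X) || any(X < 0)) abort("X must be non-negative with no NAs")
  if (k < 1 || k > min(dim(X)))
    abort(sprintf("k = %d out of range 1..%d", k, min(dim(X))))
  zr <- which(rowSums(X) == 0)
  if (length(zr) > 0)
    abort(paste0("all-zero row(s): ",
                 paste(head(rownames(X)[zr] %||% zr, 5), collapse = ", ")))
  zc <- which(colSums(X) == 0)
  if (length(zc) > 0)
    abort(paste0("all-zero column(s): ",
                 paste(head(colnames(X)[zc] %||% zc, 5), collapse = ", ")))
  invisible(TRUE)
}

#' KL-divergence non-negative matrix factorization (multiplicative updates)
#'
#' Factorises a non-negative matrix `X` (genes x cells) into `W` (genes x k,
#' the basis whose columns carry gene weights per cluster) and `H` (k x
#' cells, whose rows carry cell weights per cluster) by the classic
#' multiplicative update rules that monotonically decrease the generalized
#' KL divergence:
#' \deqn{H_{aj} \leftarrow H_{aj} \frac{\sum_i W_{ia} X_{ij}/(WH)_{ij}}
#'   {\sum_i W_{ia}}, \qquad
#'   W_{ia} \leftarrow W_{ia} \frac{\sum_j H_{aj} X_{ij}/(WH)_{ij}}
#'   {\sum_j H_{aj}}.}
#'
#' `W` and `H` are initialised `Uniform(0, 1)` scaled by `sqrt(mean(X))`
#' under `seed`, and floored at `eps` throughout. Iteration stops when the
#' divergence decrease over a 10-iteration window falls below `tol` relative
#' to its starting value, or at `max_iter`.
#'
#' @param X Non-negative matrix with no all-zero row or column.
#' @param k Number of clusters, `1 <= k <= min(dim(X))`.
#' @param seed Integer seed for the random initialisation.
#' @param max_iter,tol Stopping rule (defaults 2000 and 1e-6).
#' @param eps Non-negativity floor, default 1e-12.
#' @param stop_connectivity If positive, additionally stop once the cluster
#'   assignment (per-column argmax of `H`) has been unchanged for this many
#'   consecutive iterations — the classical stopping rule of consensus NMF
#'   clustering, used by [consensus_cophenetic()] where only the assignments
#'   matter. 0 (the default) disables it.
#' @return An object of class `"nmf_fit"`: list with `W`, `H`, `k`, `seed`,
#'   `divergence_trace` (length `n_iter + 1`, non-increasing), `n_iter`,
#'   `converged`.
#' @export
nmf_kl <- function(X, k, seed = 1L, max_iter = 2000L, tol = 1e-6,
                   eps = 1e-12, stop_connectivity = 0L) {
  X <- as.matrix(X)
  check_nmf_input(X, k)
  init <- nmf_init(X, k, seed)
  res <- nmf_kl_cpp(X, init$W, init$H, as.integer(max_iter), tol, eps, 10L,
                    as.integer(stop_connectivity))
  rownames(res$W) <- rownames(X)
  colnames(res$H) <- colnames(X)
  structure(list(W = res$W, H = res$H, k = as.integer(k),
                 seed = as.integer(seed),
                 divergence_trace = res$divergence_trace,
                 n_iter = res$n_iter, converged = res$converged),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("<nmf_fit> %d x %d, k = %d, %d iterations%s, divergence %.6g\n",
              nrow(x$W), ncol(x$H), x$k, x$n_iter,
              if (x$converged) " (converged)" else "",
              final_divergence(x)))
  invisible(x)
}

final_divergence <- function(fit) {
  fit$divergence_trace[[length(fit$divergence_trace)]]
}

#' Connectivity matrix of a factorization
#'
#' Assigns each cell to the cluster with the largest coefficient in its `H`
#' column (ties to the lowest cluster index) and returns the binary cells x
#' cells matrix with 1 where two cells share a cluster.
#'
#' @param fit An [nmf_kl()] fit with `k >= 2`.
#' @return Symmetric binary matrix with unit diagonal.
#' @export
connectivity_matrix <- function(fit) {
  stopifnot(inherits(fit, "nmf_fit"))
  if (fit$k < 2) abort("connectivity requires k >= 2")
  assign <- cluster_assignment(fit$H)
  C <- outer(assign, assign, "==") * 1
  dimnames(C) <- list(colnames(fit$H), colnames(fit$H))
  C
}

cluster_assignment <- function(H) {
  apply(H, 2, which.max) # which.max breaks ties at the lowest index
}

#' Consensus clustering and cophenetic correlation over NMF restarts
#'
#' Runs `n_runs` seeded restarts of [nmf_kl()] at a fixed `k`, averages their
#' connectivity matrices into a consensus matrix, and measures the stability
#' of the induced clustering as the Pearson correlation between the
#' consensus distances `1 - consensus` and the cophenetic distances of
#' average-linkage hierarchical clustering on those same distances. A value
#' near 1 means cells co-cluster identically across restarts; when the
#' distance vector is constant (perfect consensus) the coefficient is defined
#' as 1.
#'
#' @param X Non-negative matrix.
#' @param k Number of clusters, `k >= 2`.
#' @param n_runs Number of restarts, default 30.
#' @param base_seed Seed; run `r` uses `base_seed + r - 1`.
#' @param ... Passed to [nmf_kl()].
#' @return An object of class `"nmf_consensus"`: list with `k`, `consensus`,
#'   `cophenetic`, `n_runs`, `seeds`, and `best_fit` (the restart with the
#'   lowest final divergence).
#' @export
consensus_cophenetic <- function(X, k, n_runs = 30L, base_seed = 1L, ...) {
  if (k < 2) abort("consensus requires k >= 2")
  if (n_runs < 2) abort("need n_runs >= 2")
  seeds <- vapply(seq_len(n_runs) - 1L, function(r) derive_seed(base_seed, r),
                  integer(1))
  consensus <- matrix(0, ncol(X), ncol(X))
  best_fit <- NULL
  for (s in seeds) {
    fit <- nmf_kl(X, k, seed = s, stop_connectivity = 40L, ...)
    consensus <- consensus + connectivity_matrix(fit)
    if (is.null(best_fit) ||
        final_divergence(fit) < final_divergence(best_fit))
      best_fit <- fit
  }
  consensus <- consensus / n_runs
  dimnames(consensus) <- list(colnames(X), colnames(X))
  structure(list(k = as.integer(k), consensus = consensus,
                 cophenetic = cophenetic_coefficient(consensus),
                 n_runs = as.integer(n_runs), seeds = seeds,
                 best_fit = best_fit),
            class = "nmf_consensus")
}

cophenetic_coefficient <- function(consensus) {
  d <- as.dist(1 - consensus)
  dv <- as.vector(d)
  cd <- as.vector(cophenetic(hclust(d, method = "average")))
  if (stats::sd(dv) == 0 || stats::sd(cd) == 0) return(1)
  cor(dv, cd)
}

#' Choose the number of clusters by the cophenetic criterion
#'
#' Computes [consensus_cophenetic()] for every `k` in `k_range` and returns
#' the smallest `k` attaining the maximum cophenetic coefficient, together
#' with the full selection table.
#'
#' @param X Non-negative matrix.
#' @param k_range Candidate cluster numbers; default `2:min(7, min(dim(X)) - 1)`.
#' @param n_runs Restarts per `k`, default 30.
#' @param base_seed Seed; candidate `k` uses seed block `base_seed + 1000 * k`.
#' @param ... Passed to [nmf_kl()].
#' @return An object of class `"k_selection"`: list with `k` (the choice),
#'   `table` (tibble of k, cophenetic), and `consensus` (list of
#'   `"nmf_consensus"` objects keyed by k).
#' @export
select_k <- function(X, k_range = NULL, n_runs = 30L, base_seed = 1L, ...) {
  kmax <- min(7L, min(dim(X)) - 1L)
  k_range <- k_range %||% seq(2L, kmax)
  if (length(k_range) == 0 || any(k_range < 2) ||
      any(k_range > min(dim(X))))
    abort(sprintf("infeasible k_range for a %d x %d matrix",
                  nrow(X), ncol(X)))
  cons <- lapply(k_range, function(k)
    consensus_cophenetic(X, k, n_runs = n_runs,
                         base_seed = derive_seed(base_seed, 1000L * k), ...))
  names(cons) <- as.character(k_range)
  coph <- vapply(cons, function(cc) cc$cophenetic, numeric(1))
  best <- k_range[which.max(coph)] # which.max: smallest k on ties
  structure(list(k = as.integer(best),
                 table = tibble(k = as.integer(k_range), cophenetic = coph),
                 consensus = cons),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("<k_selection> chose k = %d\n", x$k))
  print(x$table)
  invisible(x)
}
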