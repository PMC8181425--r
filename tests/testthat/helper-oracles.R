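# Independent oracles, kept deliberately naive: plain-R reimplementations and
# brute-force formulas the package code never calls.

# KL divergence straight from the definition, elementwise loop
oracle_kl <- function(X, WH, eps = 1e-12) {
  d <- 0
  for (i in seq_len(nrow(X))) {
    for (j in seq_len(ncol(X))) {
      x <- X[i, j]
      p <- max(WH[i, j], eps)
      d <- d + (if (x > 0) x * log(x / p) else 0) - x + p
    }
  }
  d
}

# reference multiplicative-update NMF in plain R (fixed iteration count)
oracle_nmf_kl <- function(X, k, seed, iters = 1000, eps = 1e-12) {
  set.seed(seed)
  s <- sqrt(mean(X))
  W <- matrix(runif(nrow(X) * k), nrow(X), k) * s
  H <- matrix(runif(k * ncol(X)), k, ncol(X)) * s
  for (it in seq_len(iters)) {
    WH <- pmax(W %*% H, eps)
    H <- pmax(H * (t(W) %*% (X / WH)) / colSums(W), eps)
    WH <- pmax(W %*% H, eps)
    W <- pmax(W * ((X / WH) %*% t(H)) / rep(rowSums(H), each = nrow(W)), eps)
  }
  list(W = W, H = H, divergence = oracle_kl(X, W %*% H, eps))
}

# Frobenius norm of the materialised outer product, elementwise
oracle_frobenius_rank1 <- function(w, h) {
  sqrt(sum((w %*% t(h))^2))
}

# hypergeometric upper-tail by explicit combinatorial sum
oracle_hyper_tail <- function(m, K, n, N) {
  i <- seq(m, min(K, n))
  if (length(i) == 0 || m > min(K, n)) return(if (m <= 0) 1 else 0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Pearson r and two-sided p from the defining formulas
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    (stats::sd(x) * stats::sd(y) * (n - 1))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# precision/recall of a recovered set against a planted set
precision_recall <- function(recovered, planted) {
  c(precision = mean(recovered %in% planted),
    recall = mean(planted %in% recovered))
}

# match each module to the cluster rank whose top genes overlap it most
match_cluster_to_module <- function(res, truth, module) {
  genes <- truth$item[truth$kind == "gene" & truth$module == module]
  ov <- vapply(res$clusters$top_dags,
               function(gs) length(intersect(gs, genes)), integer(1))
  res$clusters$rank[which.max(ov)]
}
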