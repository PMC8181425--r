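test_that("disease matrix extraction preserves order and reports drops", {
  imm <- tiny_imm()
  net <- dime:::as_disease_gene_tbl(tibble::tibble(
    disease_id = "D1", disease_name = "d",
    gene = c("CD4", "TNF", "missing_gene")))
  X <- extract_disease_matrix(imm, net, "D1", min_genes = 2L)
  expect_identical(rownames(X), c("TNF", "CD4")) # immunome order
  expect_identical(attr(X, "n_dropped"), 1L)
  expect_error(extract_disease_matrix(imm, net, "D1", min_genes = 15L),
               "too few mappable")
})

test_that("score scaling is division by the maximum", {
  expect_equal(scale_scores(c(2, 4, 8)), c(0.25, 0.5, 1))
  expect_equal(scale_scores(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(scale_scores(c(0, 0, 5)), c(0, 0, 1))
  expect_error(scale_scores(c(0, 0)), "all-zero")
})

test_that("top-percentile selection interpolates order statistics", {
  scores <- c(a = 0.1, b = 0.4, c = 0.7, d = 1.0)
  # h = 0.75 * 3 = 2.25 -> threshold 0.7 + 0.25 * 0.3 = 0.775 -> only d
  expect_identical(top_percentile_select(scores), "d")
  expect_setequal(top_percentile_select(c(x = 0.5, y = 0.5, z = 0.5)),
                  c("x", "y", "z"))
  expect_identical(top_percentile_select(c(only = 0.3)), "only")
  # never empty over random score vectors
  set.seed(8)
  for (i in 1:20) {
    s <- setNames(runif(sample(2:30, 1)), NULL)
    names(s) <- paste0("i", seq_along(s))
    expect_gte(length(top_percentile_select(s, q = runif(1, 0.05, 0.95))), 1)
  }
})

test_that("cluster ranking matches the rank-1 Frobenius identity and oracle", {
  f <- structure(list(W = cbind(c(3, 4)), H = rbind(c(1, 2)), k = 1L),
                 class = "nmf_fit")
  expect_equal(rank_clusters(f)$frobenius_weight, 5 * sqrt(5),
               tolerance = 1e-12)

  set.seed(12)
  for (i in 1:50) {
    m <- sample(3:12, 1); n <- sample(3:8, 1); k <- sample(2:4, 1)
    fit <- structure(list(W = matrix(rexp(m * k), m, k),
                          H = matrix(rexp(k * n), k, n), k = k),
                     class = "nmf_fit")
    rc <- rank_clusters(fit)
    brute <- vapply(seq_len(k), function(a)
      oracle_frobenius_rank1(fit$W[, a, drop = FALSE], fit$H[a, ]),
      numeric(1))
    expect_equal(rc$frobenius_weight, brute[rc$cluster], tolerance = 1e-10)
    expect_identical(rc$cluster, order(-brute, seq_len(k)))
  }

  # ties keep original index order
  ftie <- structure(list(W = cbind(c(1, 0), c(0, 1)),
                         H = rbind(c(1, 0), c(0, 1)), k = 2L),
                    class = "nmf_fit")
  expect_identical(rank_clusters(ftie)$cluster, c(1L, 2L))
})

test_that("rank-one components sum exactly to the factorization product", {
  X <- unclass(small_sim$immunome)[1:30, ]
  f <- nmf_kl(X, 3, seed = 9, max_iter = 300)
  recomposed <- Reduce(`+`, lapply(1:3, function(i)
    f$W[, i, drop = FALSE] %*% f$H[i, , drop = FALSE]))
  expect_equal(recomposed, f$W %*% f$H, tolerance = 1e-10)
})

test_that("run_dime recovers planted modules and is deterministic", {
  res <- run_dime(small_sim$immunome, small_net, "D1", seed = 21L)
  expect_identical(res$k, 2L)
  for (mod in 1:2) {
    r <- match_cluster_to_module(res, small_sim$truth, mod)
    cl <- res$clusters[res$clusters$rank == r, ]
    pr_c <- precision_recall(
      cl$top_dacs[[1]],
      small_sim$truth$item[small_sim$truth$kind == "cell" &
                             small_sim$truth$module == mod])
    pr_g <- precision_recall(
      cl$top_dags[[1]],
      small_sim$truth$item[small_sim$truth$kind == "gene" &
                             small_sim$truth$module == mod])
    expect_gte(min(pr_c), 0.75)
    expect_gte(min(pr_g), 0.9)
  }
  again <- run_dime(small_sim$immunome, small_net, "D1", seed = 21L)
  expect_identical(tidy(again), tidy(res))
  expect_identical(again$clusters$frobenius_weight,
                   res$clusters$frobenius_weight)
})

test_that("forcing k = 1 yields a single max-scaled cluster", {
  res <- run_dime(small_sim$immunome, small_net, "D1", k = 1L, seed = 2L)
  expect_identical(res$k, 1L)
  expect_identical(res$clusters$rank, 1L)
  expect_equal(max(res$clusters$dac_scores[[1]]), 1)
  expect_equal(max(res$clusters$dag_scores[[1]]), 1)
})

test_that("dime result is invariant to cluster relabeling", {
  res <- run_dime(small_sim$immunome, small_net, "D1", k = 2L, seed = 13L)
  perm <- res
  perm$fit$W <- perm$fit$W[, c(2, 1)]
  perm$fit$H <- perm$fit$H[c(2, 1), ]
  rc <- rank_clusters(perm$fit)
  expect_setequal(rc$frobenius_weight,
                  res$clusters$frobenius_weight)
  top_perm <- scale_scores(perm$fit$H[rc$cluster[rc$rank == 1], ])
  expect_equal(sort(top_percentile_select(top_perm)),
               sort(res$clusters$top_dacs[[1]]))
})

test_that("network construction is complete bipartite per cluster", {
  res <- run_dime(small_sim$immunome, small_net, "D1", k = 2L, seed = 3L)
  nw <- build_dime_network(res, small_sim$immunome)
  for (r in 1:2) {
    cl <- res$clusters[res$clusters$rank == r, ]
    sub <- nw[nw$cluster_rank == r, ]
    expect_identical(nrow(sub),
                     as.integer(length(cl$top_dacs[[1]]) *
                                  length(cl$top_dags[[1]])))
    expect_setequal(unique(sub$cell), cl$top_dacs[[1]])
    expect_setequal(unique(sub$gene), cl$top_dags[[1]])
  }
  expect_gte(min(table(nw$cluster_rank)), 1)
})

test_that("display pruning caps genes and drops weakly expressed ones", {
  res <- run_dime(small_sim$immunome, small_net, "D1", k = 2L, seed = 3L)
  nw <- build_dime_network(res, small_sim$immunome)
  capped <- prune_for_display(nw, max_dags = 5L, min_expression = 0)
  genes_per <- tapply(capped$gene, capped$cluster_rank,
                      function(g) length(unique(g)))
  expect_true(all(genes_per <= 5))

  strict <- prune_for_display(nw, max_dags = 50L, min_expression = 5.0)
  expect_true(all(strict$median_expression > 5.0))
  # the top module sits near mean 7, so its genes survive
  expect_gt(nrow(strict[strict$cluster_rank == 1, ]), 0)

  loose <- prune_for_display(nw, max_dags = 1000L, min_expression = -1)
  expect_identical(dplyr::arrange(as.data.frame(loose), cluster_rank, cell,
                                  gene),
                   dplyr::arrange(as.data.frame(nw), cluster_rank, cell,
                                  gene))
})
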