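test_that("Jaccard index basics", {
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_identical(jaccard_index(letters[1:4], letters[1:4]), 1)
  expect_identical(jaccard_index("a", "b"), 0)
  expect_error(jaccard_index(character(), character()), "empty")
})

test_that("Fisher overlap test matches exact combinatorics", {
  # N=10, |A|=|B|=5, full overlap: p = 1 / C(10,5)
  A <- letters[1:5]
  expect_equal(fisher_overlap_test(A, A, 10), 1 / choose(10, 5),
               tolerance = 1e-12)
  # zero overlap: the tail from 0 is everything
  expect_identical(fisher_overlap_test(letters[1:3], letters[10:12], 26), 1)
  expect_error(fisher_overlap_test(letters[1:5], letters[1:2], 3), "universe")
})

test_that("hypergeometric tail equals the brute-force sum and is monotone", {
  set.seed(33)
  for (i in 1:200) {
    N <- sample(2:40, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    ms <- max(0, K + n - N):min(K, n)
    p_impl <- vapply(ms, function(m) {
      A <- seq_len(K)
      B <- seq(K - m + 1, length.out = n)
      fisher_overlap_test(A, B, N)
    }, numeric(1))
    p_brute <- vapply(ms, oracle_hyper_tail, numeric(1), K = K, n = n, N = N)
    expect_lt(max(abs(p_impl - p_brute)), 1e-10)
    expect_true(all(diff(p_impl) <= 1e-12)) # monotone in overlap
  }
})

test_that("common cell-gene network is the rank-annotated edge intersection", {
  nwA <- dime:::as_dime_network(tibble::tibble(
    cell = c("c1", "c1"), gene = c("g1", "g2"),
    cluster_rank = c(1L, 2L), dac_score = 1, dag_score = 1,
    median_expression = 1, druggable = FALSE, drugs = ""),
    disease_id = "A", cells = c("c1", "c2"))
  nwB <- dime:::as_dime_network(tibble::tibble(
    cell = c("c1", "c2"), gene = c("g1", "g2"),
    cluster_rank = c(2L, 1L), dac_score = 1, dag_score = 1,
    median_expression = 1, druggable = FALSE, drugs = ""),
    disease_id = "B", cells = c("c1", "c2"))
  cn <- common_cell_gene_network(nwA, nwB, universe_size = 20)
  expect_identical(nrow(cn$edges), 1L)
  expect_identical(cn$edges$cell, "c1")
  expect_identical(cn$edges$rank_a, 1L)
  expect_identical(cn$edges$rank_b, 2L)
  expect_equal(cn$overlap$jaccard, 1 / 3)

  same <- common_cell_gene_network(nwA, nwA, universe_size = 20)
  expect_identical(same$overlap$jaccard, 1)
  expect_lt(same$overlap$fisher_p,
            fisher_overlap_test("x", "x", 20) + 1e-12)

  nwC <- nwB
  nwC$gene <- c("g8", "g9")
  cn0 <- common_cell_gene_network(nwA, dime:::as_dime_network(
    nwC, disease_id = "C", cells = c("c1", "c2")), universe_size = 20)
  expect_identical(nrow(cn0$edges), 0L)
  expect_identical(cn0$overlap$jaccard, 0)
  expect_identical(cn0$overlap$fisher_p, 1)
})

significance_label_of <- function(cmp, a, b) {
  row <- cmp$pairs[(cmp$pairs$disease_a == a & cmp$pairs$disease_b == b) |
                     (cmp$pairs$disease_a == b & cmp$pairs$disease_b == a), ]
  row$significance
}

test_that("pairwise comparison covers all unordered pairs symmetrically", {
  sets <- list(D1 = letters[1:6], D2 = letters[4:9], D3 = letters[10:12])
  cmp <- pairwise_comparison(sets, universe_size = 26, item_kind = "genes")
  expect_identical(nrow(cmp$pairs), 3L) # C(3, 2) unordered pairs
  ji_ab <- cmp$pairs$jaccard[cmp$pairs$disease_a == "D1" &
                               cmp$pairs$disease_b == "D2"]
  expect_equal(ji_ab, jaccard_index(sets$D1, sets$D2)) # symmetric by def
  expect_equal(ji_ab, jaccard_index(sets$D2, sets$D1))

  m <- comparison_matrix(cmp)
  expect_identical(diag(m), setNames(rep("1", 3), c("D1", "D2", "D3")))
  expect_identical(m["D1", "D3"], significance_label_of(cmp, "D1", "D3"))
})

test_that("significance stars follow the 0.05/0.01/0.001 thresholds", {
  expect_identical(dime:::significance_label(c(0.2, 0.05, 0.01, 0.0005)),
                   c("", "*", "**", "***"))
})
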