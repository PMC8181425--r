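test_that("kl_divergence matches closed forms and conventions", {
  X <- matrix(runif(12, 0.1, 2), 3, 4)
  expect_identical(kl_divergence(X, X), 0)
  expect_equal(kl_divergence(matrix(1), matrix(2)), 1 - log(2),
               tolerance = 1e-12)
  expect_equal(kl_divergence(matrix(0), matrix(0.5)), 0.5) # 0 log 0 = 0
  expect_error(kl_divergence(matrix(1), matrix(1, 2, 2)), "shape")
  # against the elementwise oracle
  WH <- matrix(runif(12, 0.1, 2), 3, 4)
  expect_equal(kl_divergence(X, WH), oracle_kl(X, WH), tolerance = 1e-12)
})

test_that("factorization recovers exact rank-1 matrices", {
  set.seed(11)
  for (s in 1:5) {
    w <- runif(8, 0.2, 2); h <- runif(5, 0.2, 2)
    X <- w %*% t(h)
    f <- nmf_kl(X, 1, seed = s)
    expect_lt(dime:::final_divergence(f), 1e-6)
    expect_lt(norm(X - f$W %*% f$H, "F") / norm(X, "F"), 1e-3)
  }
  # constant positive matrix is rank 1
  Xc <- matrix(3, 6, 4)
  fc <- nmf_kl(Xc, 1, seed = 2)
  expect_equal(fc$W %*% fc$H, Xc, ignore_attr = TRUE, tolerance = 1e-4)
})

test_that("divergence trace is non-increasing and factors stay non-negative", {
  set.seed(5)
  for (s in 1:10) {
    X <- matrix(rexp(30 * 12), 30, 12)
    f <- nmf_kl(X, sample(2:3, 1), seed = s)
    expect_true(all(diff(f$divergence_trace) <= 1e-9))
    expect_length(f$divergence_trace, f$n_iter + 1)
    expect_true(all(f$W >= 0) && all(f$H >= 0))
  }
})

test_that("input validation names offending rows/columns", {
  X <- matrix(1, 4, 3, dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
  expect_error(nmf_kl(X, 5, seed = 1), "out of range")
  Xz <- X; Xz["g2", ] <- 0
  expect_error(nmf_kl(Xz, 2, seed = 1), "g2")
  Xc <- X; Xc[, "c3"] <- 0
  expect_error(nmf_kl(Xc, 2, seed = 1), "c3")
})

test_that("final divergence agrees with an independent reference NMF", {
  set.seed(21)
  for (s in 1:10) {
    X <- matrix(rexp(20 * 10) + 0.05, 20, 10)
    mine <- nmf_kl(X, 3, seed = s)
    ref <- oracle_nmf_kl(X, 3, seed = s, iters = 1000)
    expect_lt(abs(dime:::final_divergence(mine) - ref$divergence) /
                ref$divergence, 0.05)
  }
})

test_that("scale indeterminacy: rescaled factors give the same model", {
  set.seed(3)
  X <- matrix(rexp(18 * 8) + 0.1, 18, 8)
  f <- nmf_kl(X, 3, seed = 4)
  S <- diag(c(2, 0.5, 7))
  g <- f
  g$W <- f$W %*% S
  g$H <- solve(S) %*% f$H
  colnames(g$H) <- colnames(f$H)
  expect_equal(g$W %*% g$H, f$W %*% f$H, tolerance = 1e-12)
  # cluster weights ||w_i||*||h_i|| are invariant under the rescaling
  expect_equal(rank_clusters(g)$frobenius_weight,
               rank_clusters(f)$frobenius_weight, tolerance = 1e-10)
  expect_identical(rank_clusters(g)$cluster, rank_clusters(f)$cluster)
})

test_that("connectivity matrix follows argmax assignment with low-index ties", {
  f <- structure(list(W = diag(2), H = matrix(c(1, 0, 0, 1), 2, 2),
                      k = 2L), class = "nmf_fit")
  expect_equal(connectivity_matrix(f), diag(2), ignore_attr = TRUE)

  f$H <- matrix(c(1, 0.2, 1, 0.3, 1, 0.1), 2, 3)
  expect_true(all(connectivity_matrix(f) == 1))

  f$H <- matrix(c(0.5, 0.5, 1, 0), 2, 2) # tie in column 1 -> cluster 1
  C <- connectivity_matrix(f)
  expect_true(all(C == 1))
})

test_that("consensus is binary under identical restarts, cophenetic degenerate = 1", {
  X <- unclass(small_sim$immunome)[1:40, ]
  cc <- consensus_cophenetic(X, 2, n_runs = 2, base_seed = 5,
                             max_iter = 300)
  expect_true(all(cc$consensus %in% c(0, 1) |
                    (cc$consensus >= 0 & cc$consensus <= 1)))
  expect_true(isSymmetric(cc$consensus))
  expect_true(all(diag(cc$consensus) == 1))

  # a perfectly block-structured consensus has cophenetic exactly 1
  cons <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(dime:::cophenetic_coefficient(cons), 1, tolerance = 1e-12)
  # constant-distance consensus: defined as 1
  expect_identical(dime:::cophenetic_coefficient(matrix(1, 3, 3)), 1)
})

test_that("cophenetic criterion prefers the planted number of blocks", {
  X <- unclass(small_sim$immunome)
  c2 <- consensus_cophenetic(X, 2, n_runs = 10, base_seed = 31)
  c4 <- consensus_cophenetic(X, 4, n_runs = 10, base_seed = 31)
  expect_gt(c2$cophenetic, c4$cophenetic)
})

test_that("select_k returns the smallest maximiser and validates the range", {
  X <- unclass(small_sim$immunome)
  sel <- select_k(X, k_range = 2:4, n_runs = 8, base_seed = 17)
  expect_identical(sel$k, 2L)
  expect_identical(nrow(sel$table), 3L)
  expect_error(select_k(X[1:3, 1:3], k_range = 5:6), "infeasible")
})
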