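make_cm <- function(counts) {
  n <- ncol(counts)
  count_matrix(counts, setNames(rep("T", n), colnames(counts)))
}

test_that("low-count filter removes genes at and above the fraction boundary", {
  counts <- rbind(
    all19 = rep(19, 20),                    # below 20 in 20/20 = 1.00 >= .95
    two25 = c(rep(25, 2), rep(0, 18)),      # below 20 in 18/20 = 0.90 < .95
    high = rep(100, 20))
  colnames(counts) <- sprintf("s%02d", 1:20)
  cm <- make_cm(counts)
  kept <- filter_low_count_genes(cm)
  expect_identical(rownames(kept$counts), c("two25", "high"))

  # min_count = 0: no count is < 0, nothing removed
  expect_identical(rownames(filter_low_count_genes(cm, min_count = 0)$counts),
                   rownames(counts))
  # everything removed is an error
  expect_error(filter_low_count_genes(cm, min_count = 1000), "filter")
})

test_that("low-count filter is monotone in min_count", {
  set.seed(42)
  counts <- matrix(rpois(50 * 10, 15), 50, 10,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   sprintf("s%02d", 1:10)))
  cm <- make_cm(counts)
  kept <- lapply(c(5, 10, 20, 40), function(mc)
    tryCatch(rownames(filter_low_count_genes(cm, min_count = mc)$counts),
             error = function(e) character()))
  for (i in seq_len(length(kept) - 1))
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
})

test_that("log2(CPM + 1) matches direct arithmetic", {
  counts <- matrix(c(10, 90), 2, 1,
                   dimnames = list(c("g1", "g2"), "s1"))
  v <- cpm_log_transform(make_cm(counts))
  expect_equal(v[, 1], c(g1 = log2(1e5 + 1), g2 = log2(9e5 + 1)),
               tolerance = 1e-12)
  expect_equal(unname(v["g1", 1]), 16.6096, tolerance = 1e-4)
  expect_equal(unname(v["g2", 1]), 19.7797, tolerance = 1e-4)

  # zero count -> log2(1) = 0; single expressed gene -> CPM = 1e6
  counts2 <- matrix(c(0, 7), 2, 1, dimnames = list(c("a", "b"), "s1"))
  v2 <- cpm_log_transform(make_cm(counts2))
  expect_identical(unname(v2["a", 1]), 0)
  expect_equal(unname(v2["b", 1]), log2(1e6 + 1))

  zero <- matrix(c(1, 0), 1, 2, dimnames = list("g", c("ok", "empty")))
  expect_error(cpm_log_transform(make_cm(zero)), "empty")
})

test_that("CPM mass is conserved per sample", {
  set.seed(9)
  counts <- matrix(rpois(30 * 4, 40), 30, 4,
                   dimnames = list(sprintf("g%02d", 1:30),
                                   sprintf("s%d", 1:4)))
  v <- cpm_log_transform(make_cm(counts))
  expect_equal(colSums(2^v - 1), rep(1e6, 4), ignore_attr = TRUE,
               tolerance = 1e-6)
})

test_that("median aggregation uses midpoint convention and keeps order", {
  expr <- matrix(c(1, 2, 9, 4, 6,
                   1, 3, 5, 1, 3), 2, 5, byrow = TRUE,
                 dimnames = list(c("g1", "g2"),
                                 c("a1", "a2", "a3", "b1", "b2")))
  lab <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B")
  agg <- aggregate_median_by_celltype(expr, lab)
  expect_equal(unname(unclass(agg)[, "A"]), c(2, 3)) # odd n
  expect_equal(unname(unclass(agg)[, "B"]), c(5, 2)) # even n: midpoint

  # one sample per cell type: relabeled identity
  expr3 <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  agg3 <- aggregate_median_by_celltype(expr3, c(s1 = "NK", s2 = "Mono"))
  expect_identical(colnames(agg3), c("NK", "Mono"))
  expect_equal(unclass(agg3), expr3, ignore_attr = TRUE)
})

test_that("HLA prefix rule removes exactly HLA- symbols", {
  net <- dime:::as_disease_gene_tbl(tibble::tibble(
    disease_id = "D", disease_name = "d",
    gene = c("HLA-B", "TNF", "HHLA2", "hla-DRB1")))
  out <- remove_hla_genes(net)
  expect_setequal(out$gene, c("TNF", "HHLA2"))
  expect_identical(attr(out, "n_removed"), 2L)
  empty <- remove_hla_genes(net[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("immunome restriction intersects on exact symbols", {
  imm <- tiny_imm() # TNF, IL6, CD4
  net <- dime:::as_disease_gene_tbl(tibble::tibble(
    disease_id = c("D1", "D1", "D1", "D2"),
    disease_name = "d",
    gene = c("TNF", "IL6", "gX", "gY")))
  expect_warning(out <- restrict_to_immunome(net, imm), "D2")
  expect_setequal(disease_genes(out, "D1"), c("TNF", "IL6"))
  expect_identical(attr(out, "n_dropped"), 2L)
  expect_false("D2" %in% out$disease_id)

  all_in <- net[net$gene %in% rownames(imm), ]
  expect_identical(nrow(restrict_to_immunome(all_in, imm)), nrow(all_in))
  expect_error(suppressWarnings(
    restrict_to_immunome(net[net$gene == "gY", ], imm)),
    class = "dime_format_error")
})

test_that("count-mode generator feeds the preprocessing chain", {
  cm <- generate_counts(small_spec(seed = 5L), n_samples_per_celltype = 2L,
                        library_size = 2e5)
  expect_identical(ncol(cm$counts), 32L)
  imm <- preprocess_counts(cm, min_count = 1, sample_fraction = 0.99)
  expect_s3_class(imm, "immunome")
  expect_identical(ncol(imm), 16L)
  # planted module pattern survives preprocessing: module-1 genes higher in
  # primary cells than in background cells
  m1 <- intersect(rownames(imm), sprintf("G%04d", 1:20))
  expect_gt(mean(unclass(imm)[m1, 1:4]), mean(unclass(imm)[m1, 9:12]))
})
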