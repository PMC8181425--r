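# Small fixtures shared across test files. Everything is generated in code;
# the "small" planted spec keeps the module/cell proportions of the default
# study conditions (module genes = 25% of genes, primary cells = 25% of cell
# types, secondary tier at intermediate mean) at a quarter of the size, so
# unit tests stay fast.

small_spec <- function(seed = 1L) {
  planted_spec(
    n_genes = 80L, n_cells = 16L,
    modules = list(
      list(genes = 1:20, cells = 1:4, high_mean = 7,
           secondary_cells = 9:12, secondary_mean = 3),
      list(genes = 21:40, cells = 5:8, high_mean = 6,
           secondary_cells = 13:16, secondary_mean = 2.5)),
    seed = seed)
}

small_sim <- generate_immunome(small_spec(seed = 7L))

small_net <- generate_disease_networks(
  small_sim$truth, list(D1 = c(1L, 2L)), n_background_genes = 40L,
  all_genes = rownames(small_sim$immunome), seed = 8L)

tiny_imm <- function() {
  immunome(matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
                  dimnames = list(c("TNF", "IL6", "CD4"),
                                  c("NK", "Mono"))))
}

tiny_net <- function() {
  as_tibble_net <- tibble::tibble(
    disease_id = c("D1", "D1", "D2"),
    disease_name = c("one", "one", "two"),
    gene = c("TNF", "IL6", "CD4"))
  dime:::as_disease_gene_tbl(as_tibble_net)
}

write_tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# random valid immunome for round-trip properties
random_immunome <- function(seed, n_genes = 5, n_cells = 3) {
  set.seed(seed)
  immunome(matrix(round(runif(n_genes * n_cells, 0, 12), 6),
                  n_genes, n_cells,
                  dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                  sprintf("c%02d", seq_len(n_cells)))))
}
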