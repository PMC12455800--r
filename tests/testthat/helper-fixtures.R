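# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except files the helpers write themselves
# into tempdirs.

# Write a tiny MatrixMarket triplet directory: 3 spots x 2 genes with counts
# [[1,0],[0,2],[3,0]] in spot order of the barcode file.
new_test_dir <- function() {
  d <- tempfile("stgem_fixture_")
  dir.create(d)
  d
}

write_tiny_mtx_dir <- function(dir = new_test_dir(), drop_barcode = FALSE) {
  m <- Matrix::sparseMatrix(i = c(1, 2, 1), j = c(1, 2, 3), x = c(1, 2, 3),
                            dims = c(2, 3))   # genes x spots (10x layout)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(c("ENSG01\tGENEA\tGene Expression",
               "ENSG02\tGENEB\tGene Expression"),
             file.path(dir, "features.tsv"))
  writeLines(c("BC-1", "BC-2", "BC-3"), file.path(dir, "barcodes.tsv"))
  pos <- data.frame(barcode = c("BC-1", "BC-2", "BC-3"),
                    in_tissue = 1, array_row = c(0, 0, 1),
                    array_col = c(0, 1, 0), pxl_row = c(10, 10, 20),
                    pxl_col = c(10, 20, 10))
  if (drop_barcode) pos <- pos[-2, ]
  utils::write.table(pos, file.path(dir, "tissue_positions_list.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  dir
}

write_tiny_csv_dir <- function(dir = new_test_dir()) {
  counts <- data.frame(spot_id = c("BC-1", "BC-2", "BC-3"),
                       GENEA = c(1, 0, 3), GENEB = c(0, 2, 0))
  utils::write.csv(counts, file.path(dir, "counts.csv"), row.names = FALSE)
  pos <- data.frame(barcode = c("BC-1", "BC-2", "BC-3"),
                    array_row = c(0, 0, 1), array_col = c(0, 1, 0))
  utils::write.csv(pos, file.path(dir, "positions.csv"), row.names = FALSE)
  dir
}

# Small raw dataset built directly in memory: deterministic counts on a grid.
make_raw_dataset <- function(n_side = 8, n_genes = 12, seed = 42,
                             gene_ids = NULL) {
  n <- n_side^2
  counts <- withr::with_seed(seed,
    matrix(rnbinom(n * n_genes, mu = 5, size = 2), n, n_genes))
  gr <- expand.grid(array_row = seq_len(n_side), array_col = seq_len(n_side))
  ids <- gene_ids %||% sprintf("G%03d", seq_len(n_genes))
  spatial_dataset(counts,
                  data.frame(spot_id = sprintf("S%03d", seq_len(n)),
                             array_row = gr$array_row,
                             array_col = gr$array_col,
                             x = NA_real_, y = NA_real_),
                  ids, sprintf("S%03d", seq_len(n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw from a multivariate t: mu + chol(Sigma)' e / sqrt(g/v)
rmvt_fix <- function(n, mu, Sigma, v) {
  D <- length(mu)
  Zc <- matrix(rnorm(n * D), n, D) %*% chol(Sigma)
  g <- rchisq(n, v)
  sweep(Zc / sqrt(g / v), 2, mu, "+")
}

# Tiny MAE configuration used for gradient checks and fast smoke tests.
tiny_mae_cfg <- function(seed = 1) {
  mae_config(patch_size = 4, mask_ratio = 0.5, encoder_blocks = 1,
             attention_heads = 2, token_dim = 8, embed_dim = 4,
             mlp_ratio = 2, decoder_channels = c(4, 3, 2), seed = seed)
}
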