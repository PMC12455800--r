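
# Reading, quality control and rasterization of spot-level spatial
# transcriptomics data. Counts are held spots x genes in a sparse Matrix;
# normalization is library-size scaling to the median library followed by
# log1p, mirroring the conventional scanpy-style ST preprocessing stream.

#' Construct a spatial dataset
#'
#' Container for spot-level spatial transcriptomics counts: a spots x genes
#' count matrix, per-spot grid coordinates and identifiers. Normalization
#' state is tracked by monotone flags; [preprocess()] refuses already
#' normalized input.
#'
#' @param counts spots x genes non-negative matrix (dense or sparse).
#' @param spot_coords data.frame with columns `spot_id`, `array_row`,
#'   `array_col` and optionally continuous `x`, `y`.
#' @param gene_ids Unique gene symbols, one per column of `counts`.
#' @param spot_ids Unique spot barcodes, one per row of `counts`.
#' @return An object of class `spatial_dataset`.
#' @export
spatial_dataset <- function(counts, spot_coords, gene_ids, spot_ids) {
  counts <- as_sparse(counts)
  dimnames(counts) <- list(as.character(spot_ids), as.character(gene_ids))
  ds <- structure(list(
    counts = counts,
    spot_coords = spot_coords,
    gene_ids = as.character(gene_ids),
    spot_ids = as.character(spot_ids),
    normalized = FALSE,
    log_transformed = FALSE
  ), class = "spatial_dataset")
  validate_spatial_dataset(ds)
  ds
}

validate_spatial_dataset <- function(ds) {
  if (nrow(ds$counts) != length(ds$spot_ids))
    stopf("counts has %d rows but %d spot ids", nrow(ds$counts), length(ds$spot_ids))
  if (ncol(ds$counts) != length(ds$gene_ids))
    stopf("counts has %d columns but %d gene ids", ncol(ds$counts), length(ds$gene_ids))
  if (anyDuplicated(ds$gene_ids)) stopf("gene ids are not unique")
  if (nrow(ds$spot_coords) != length(ds$spot_ids))
    stopf("spot_coords must have one row per spot")
  if (any(ds$counts@x < 0)) stopf("counts must be non-negative")
  invisible(ds)
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat(sprintf("<spatial_dataset> %d spots x %d genes | normalized=%s log=%s\n",
              nrow(x$counts), ncol(x$counts), x$normalized, x$log_transformed))
  invisible(x)
}

read_positions_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  pos <- utils::read.csv(path, header = has_header, stringsAsFactors = FALSE)
  if (!has_header) {
    nm <- c("barcode", "in_tissue", "array_row", "array_col", "pxl_row", "pxl_col")
    names(pos) <- nm[seq_len(ncol(pos))]
  } else {
    names(pos)[1] <- "barcode"
    names(pos) <- sub("pxl_row_in_fullres", "pxl_row", names(pos))
    names(pos) <- sub("pxl_col_in_fullres", "pxl_col", names(pos))
  }
  pos
}

find_component <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stopf("missing input file: none of {%s} found in %s",
        paste(candidates, collapse = ", "), dir)
}

#' Load spatial transcriptomics data
#'
#' Reads a 10x-Visium-style MatrixMarket triplet directory (matrix +
#' features + barcodes + tissue positions table, with or without header) or
#' a plain CSV pair. No filtering is applied; counts come back raw with
#' coordinates aligned to the barcode order of the count matrix.
#'
#' @param path Directory containing the components.
#' @param format One of `"mtx_dir"`, `"csv"`. (`"h5"` is recognised but not
#'   supported by this build; convert to one of the text formats.)
#' @return A [spatial_dataset()].
#' @export
load_spatial_dataset <- function(path, format = c("mtx_dir", "csv", "h5")) {
  format <- match.arg(format)
  if (format == "h5")
    stopf("format 'h5' is not supported by this build; export the data as an mtx_dir or csv directory")
  if (!dir.exists(path)) stopf("missing input: directory '%s' does not exist", path)

  if (format == "mtx_dir") {
    mtx <- find_component(path, c("matrix.mtx", "matrix.mtx.gz"))
    fts <- find_component(path, c("features.tsv", "genes.tsv"))
    bcs <- find_component(path, c("barcodes.tsv"))
    pst <- find_component(path, c("tissue_positions_list.csv", "tissue_positions.csv",
                                  "positions.csv"))
    m <- Matrix::readMM(mtx)                   # genes x barcodes (10x layout)
    feat <- utils::read.delim(fts, header = FALSE, stringsAsFactors = FALSE)
    gene_ids <- if (ncol(feat) >= 2) feat[[2]] else feat[[1]]
    gene_ids <- make.unique(as.character(gene_ids))
    barcodes <- readLines(bcs)
    if (nrow(m) != length(gene_ids) || ncol(m) != length(barcodes))
      stopf("matrix dimensions (%d x %d) disagree with features/barcodes (%d/%d)",
            nrow(m), ncol(m), length(gene_ids), length(barcodes))
    counts <- Matrix::t(m)
    pos <- read_positions_table(pst)
  } else {
    cts <- find_component(path, c("counts.csv"))
    pst <- find_component(path, c("positions.csv"))
    tab <- utils::read.csv(cts, check.names = FALSE, stringsAsFactors = FALSE)
    barcodes <- as.character(tab[[1]])
    counts <- as_sparse(as.matrix(tab[, -1, drop = FALSE]))
    gene_ids <- colnames(tab)[-1]
    pos <- read_positions_table(pst)
  }

  missing <- setdiff(barcodes, pos$barcode)
  if (length(missing) > 0)
    stopf("positions table lacks %d barcode(s) present in counts; first offender: %s",
          length(missing), missing[1])
  pos <- pos[match(barcodes, pos$barcode), , drop = FALSE]
  spot_coords <- data.frame(
    spot_id = barcodes,
    array_row = as.integer(pos$array_row),
    array_col = as.integer(pos$array_col),
    x = if ("pxl_col" %in% names(pos)) as.numeric(pos$pxl_col) else NA_real_,
    y = if ("pxl_row" %in% names(pos)) as.numeric(pos$pxl_row) else NA_real_,
    stringsAsFactors = FALSE
  )
  spatial_dataset(counts, spot_coords, gene_ids, barcodes)
}

#' Quality-control and normalize a spatial dataset
#'
#' Removes mitochondrial (`MT-`/`mt-`) and ERCC spike-in genes and genes
#' detected (count > 0) in fewer than `min_spots` spots. Spots are never
#' filtered, preserving the spatial integrity of the section. Counts are then
#' scaled per spot to the median library size and log1p-transformed.
#'
#' The raw (filtered) counts, per-spot scale factors and the normalization
#' target are retained on the returned object so simulators can estimate
#' count-model parameters downstream.
#'
#' @param ds A raw [spatial_dataset()].
#' @param min_spots Minimum number of spots a gene must be detected in.
#' @return The normalized `spatial_dataset` (flags set).
#' @export
preprocess <- function(ds, min_spots = 10) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (isTRUE(ds$normalized))
    stopf("dataset is already normalized; preprocess() expects raw counts")

  drop <- grepl("^(MT-|ERCC-)", ds$gene_ids, ignore.case = TRUE)
  detected <- Matrix::colSums(ds$counts > 0)
  keep <- !drop & detected >= min_spots
  if (!any(keep)) stopf("all genes removed by quality control")

  counts <- ds$counts[, keep, drop = FALSE]
  lib <- Matrix::rowSums(counts)
  target <- stats::median(lib)
  sf <- ifelse(lib > 0, target / lib, 0)
  norm <- Matrix::Diagonal(x = sf) %*% counts
  norm <- as_sparse(norm)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(counts)

  ds$raw_counts <- counts
  ds$counts <- norm
  ds$gene_ids <- ds$gene_ids[keep]
  ds$size_factors <- sf
  ds$norm_target <- target
  ds$normalized <- TRUE
  ds$log_transformed <- TRUE
  ds
}

# Per-spot pixel assignment shared by rasterize() and by downstream code
# that must map fresh count vectors through the identical geometry.
spot_pixel_map <- function(ds, height, width) {
  sc <- ds$spot_coords
  if (!all(is.finite(sc$array_row)) || !all(is.finite(sc$array_col))) {
    rr <- sc$y; cc <- sc$x
  } else {
    rr <- sc$array_row; cc <- sc$array_col
  }
  span <- function(v, n) {
    if (max(v) == min(v)) rep(1L, length(v))
    else 1L + as.integer(round((v - min(v)) / (max(v) - min(v)) * (n - 1)))
  }
  pr <- span(rr, height)
  pc <- span(cc, width)
  pix <- (pc - 1L) * height + pr       # column-major linear pixel index
  list(pix = pix, height = height, width = width)
}

#' Rasterize per-gene expression into gray-scale images
#'
#' Maps each spot's array coordinates affinely onto an `height` x `width`
#' pixel grid (spots sharing a pixel are averaged) and min-max scales each
#' gene's map to `[0, 1]`. Pixels not covered by any spot form the off-tissue
#' region and are zero for every gene. A gene constant across several pixels
#' degenerates to an all-zero map; with a single covered pixel the map anchors
#' at zero so a positive value maps to one.
#'
#' @param ds A preprocessed (log-transformed) [spatial_dataset()].
#' @param height,width Image dimensions; must be divisible by `patch_size`.
#' @param patch_size Patch size the downstream masked autoencoder will use.
#' @return An object of class `gene_image_stack` with fields `images`
#'   (N x H x W array), `valid_mask`, `gene_ids` and per-gene `scaling`.
#' @export
rasterize <- function(ds, height = 48, width = 48, patch_size = 4) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (!isTRUE(ds$log_transformed))
    stopf("rasterize() expects log-transformed data; run preprocess() first")
  if (height %% patch_size != 0 || width %% patch_size != 0)
    stopf("image dimensions (%d x %d) must be divisible by patch size %d",
          height, width, patch_size)
  if (ncol(ds$counts) == 0 || nrow(ds$counts) == 0) stopf("empty dataset")

  map <- spot_pixel_map(ds, height, width)
  pix <- map$pix
  used <- sort(unique(pix))
  grp <- match(pix, used)
  cnt <- tabulate(grp, nbins = length(used))
  # averaging operator: pixels x spots
  A <- Matrix::sparseMatrix(i = grp, j = seq_along(pix),
                            x = 1 / cnt[grp],
                            dims = c(length(used), length(pix)))
  P <- as.matrix(A %*% ds$counts)      # used-pixels x genes

  n_genes <- ncol(P)
  smin <- apply(P, 2, min)
  smax <- apply(P, 2, max)
  if (length(used) == 1L) smin <- rep(0, n_genes)   # single-pixel convention
  rng <- smax - smin
  Pn <- sweep(P, 2, smin, "-")
  pos <- rng > 0
  Pn[, pos] <- sweep(Pn[, pos, drop = FALSE], 2, rng[pos], "/")
  Pn[, !pos] <- 0

  images <- array(0, dim = c(n_genes, height, width))
  flat <- matrix(0, height * width, n_genes)
  flat[used, ] <- Pn
  for (g in seq_len(n_genes)) images[g, , ] <- matrix(flat[, g], height, width)

  valid_mask <- matrix(FALSE, height, width)
  valid_mask[used] <- TRUE

  structure(list(
    images = images,
    valid_mask = valid_mask,
    gene_ids = ds$gene_ids,
    scaling = cbind(min = smin, max = smax),
    pixel_map = map
  ), class = "gene_image_stack")
}

#' @export
print.gene_image_stack <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<gene_image_stack> %d genes, %d x %d pixels (%d on-tissue)\n",
              d[1], d[2], d[3], sum(x$valid_mask)))
  invisible(x)
}

# Rasterize an arbitrary per-spot value vector through a stack's geometry,
# optionally reusing a recorded (min, max) scaling. Values are clipped to
# [0, 1] when a foreign scaling is imposed.
rasterize_values <- function(stack, values, scaling = NULL) {
  map <- stack$pixel_map
  used <- which(as.vector(stack$valid_mask))
  grp <- match(map$pix, used)
  agg <- rowsum(values, grp)
  cnt <- tabulate(grp, nbins = length(used))
  v <- as.vector(agg) / cnt
  if (is.null(scaling)) {
    smin <- min(v); smax <- max(v)
    if (length(v) == 1L) smin <- 0
  } else {
    smin <- scaling[1]; smax <- scaling[2]
  }
  img <- matrix(0, map$height, map$width)
  if (smax > smin) img[used] <- clamp((v - smin) / (smax - smin), 0, 1)
  img
}

#' Write / read a gene image stack as plain text
#'
#' Serializes images, mask, gene ids and scaling into a directory of TSV and
#' JSON files so stacks can be exchanged without binary formats.
#'
#' @param stack A `gene_image_stack`.
#' @param dir Output directory (created if needed).
#' @export
write_gene_images <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(stack$images)
  flat <- matrix(stack$images, nrow = d[1])
  utils::write.table(flat, file.path(dir, "images.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(stack$scaling, file.path(dir, "scaling.tsv"), sep = "\t",
                     row.names = FALSE, col.names = TRUE)
  writeLines(stack$gene_ids, file.path(dir, "gene_ids.txt"))
  utils::write.table(stack$valid_mask * 1L, file.path(dir, "valid_mask.tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- sprintf('{"height": %d, "width": %d, "n_genes": %d}', d[2], d[3], d[1])
  writeLines(meta, file.path(dir, "meta.json"))
  invisible(dir)
}

#' @rdname write_gene_images
#' @export
read_gene_images <- function(dir) {
  flat <- as.matrix(utils::read.delim(file.path(dir, "images.tsv"), header = FALSE))
  mask <- as.matrix(utils::read.delim(file.path(dir, "valid_mask.tsv"), header = FALSE)) > 0
  sc <- as.matrix(utils::read.delim(file.path(dir, "scaling.tsv"), header = TRUE))
  ids <- readLines(file.path(dir, "gene_ids.txt"))
  hw <- dim(mask)
  structure(list(
    images = array(flat, dim = c(nrow(flat), hw[1], hw[2])),
    valid_mask = unname(mask), gene_ids = ids, scaling = sc,
    pixel_map = NULL
  ), class = "gene_image_stack")
}
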