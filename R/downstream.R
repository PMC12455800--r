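
# Embedding-based downstream analyses: spatial-variability scoring against
# simulated homogeneous counterparts, retrieval of genes matching a
# designated spatial pattern, redundancy-aware feature selection via
# normalized-cut spectral grouping, and gene-crosstalk correlation shifts.

# Map a raw count vector through the dataset's normalization and the model's
# raster geometry, optionally imposing a recorded per-gene scaling.
counts_to_image <- function(model, ds, counts_vec, scaling = NULL) {
  sf <- ds$size_factors %||% rep(1, length(counts_vec))
  vals <- log1p(counts_vec * sf)
  rasterize_values(model$stack, vals, scaling = scaling)
}

embed_images <- function(model, imgs_flat) {
  fw <- mae_encode(imgs_flat_as_array(imgs_flat, model), model$mae,
                   mask_ratio = 0)
  fw$Z
}

imgs_flat_as_array <- function(M, model) {
  array(M, c(nrow(M), model$mae$height, model$mae$width))
}

#' Spatial-variability scores from embeddings
#'
#' For each gene, `m` spatially homogeneous counterparts are simulated from
#' its fitted NB/ZINB marginal ([simulate_homogeneous()]), pushed through
#' the identical normalization, raster geometry and per-gene intensity
#' scaling, and embedded. The score is the mean scaled cosine dissimilarity
#' between the gene's embedding and its counterparts': genes whose spatial
#' arrangement carries information beyond their marginal count distribution
#' score high.
#'
#' @param model A fitted [fit_stgem()] model.
#' @param ds The preprocessed dataset the model was trained on.
#' @param m Replicates per gene.
#' @param seed Integer seed.
#' @return data.frame `gene_id, score, rank, m` (rank 1 = most variable).
#' @export
svg_scores <- function(model, ds, m = 10, seed = 1) {
  stopifnot(inherits(model, "stgem_model"))
  if (!identical(model$gene_ids, ds$gene_ids))
    stopf("dataset genes do not match the trained model")
  N <- length(model$gene_ids)
  HW <- model$mae$height * model$mae$width
  scores <- numeric(N)
  # embed counterparts in chunks to bound memory
  chunk <- max(1, floor(4096 / m))
  for (start in seq(1, N, by = chunk)) {
    idx <- start:min(start + chunk - 1, N)
    imgs <- matrix(0, length(idx) * m, HW)
    row <- 1
    for (g in idx) {
      sims <- simulate_homogeneous(ds, g, n_replicates = m,
                                   seed = seed + (g - 1L) * m)
      for (r in seq_len(m)) {
        imgs[row, ] <- as.vector(counts_to_image(model, ds, sims[, r],
                                                 scaling = model$stack$scaling[g, ]))
        row <- row + 1
      }
    }
    Zs <- embed_images(model, imgs)
    for (j in seq_along(idx)) {
      g <- idx[j]
      zr <- model$Z[g, ]
      zh <- Zs[((j - 1) * m + 1):(j * m), , drop = FALSE]
      scores[g] <- mean(scaled_cosine_dissim_rows(zh, zr))
    }
  }
  data.frame(gene_id = model$gene_ids, score = scores,
             rank = rank(-scores, ties.method = "first"), m = m)
}

#' Rank genes against an embedded query map
#'
#' Embeds a per-spot count vector through the model and ranks all real
#' genes by scaled cosine similarity of their embeddings to the query's.
#'
#' @param model A fitted model.
#' @param ds The matching preprocessed dataset.
#' @param counts_vec Raw counts per spot (the query).
#' @return data.frame `gene_id, similarity, rank` sorted by rank.
#' @export
match_counts <- function(model, ds, counts_vec) {
  if (length(counts_vec) != length(ds$spot_ids))
    stopf("query has %d values for %d spots", length(counts_vec),
          length(ds$spot_ids))
  img <- counts_to_image(model, ds, counts_vec)
  zq <- as.vector(embed_images(model, matrix(as.vector(img), 1)))
  sim <- 1 - scaled_cosine_dissim_rows(model$Z, zq)
  ord <- order(sim, decreasing = TRUE)
  data.frame(gene_id = model$gene_ids[ord], similarity = sim[ord],
             rank = seq_along(ord))
}

#' Find genes matching a designated spatial pattern
#'
#' Simulates a pseudo-gene realizing the pattern ([sps_simulate()]), embeds
#' it, and ranks all real genes by scaled cosine similarity to the
#' pseudo-gene's embedding. The conventional level percentiles are
#' high/medium/low = 95/75/35.
#'
#' @param model A fitted model.
#' @param ds The matching preprocessed dataset.
#' @param pattern A [designated_pattern()] covering every spot.
#' @param seed Seed for the pseudo-gene simulation.
#' @return data.frame `gene_id, similarity, rank`.
#' @export
match_pattern <- function(model, ds, pattern, seed = 1) {
  if (length(pattern$region_labels) != length(ds$spot_ids))
    stopf("pattern does not cover the dataset's spots")
  pseudo <- sps_simulate(ds, pattern, seed = seed)
  match_counts(model, ds, pseudo)
}

# Shi-Malik normalized-cut spectral clustering of a non-negative adjacency.
# Sign ambiguity resolved by making each eigenvector's largest-magnitude
# entry positive; kmeans seeded for determinism.
shi_malik_groups <- function(A, n_groups, seed = 1) {
  d <- rowSums(A)
  if (any(d <= 0)) stopf("isolated node in the adjacency graph")
  dm <- 1 / sqrt(d)
  Lsym <- diag(nrow(A)) - dm * sweep(A, 2, dm, "*")
  eg <- eigen(Lsym, symmetric = TRUE)
  n <- ncol(eg$vectors)
  U <- eg$vectors[, n - seq_len(n_groups) + 1, drop = FALSE]  # smallest eigenvalues
  for (j in seq_len(ncol(U))) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  rn <- sqrt(rowSums(U^2)); rn[rn == 0] <- 1
  U <- U / rn
  # duplicate rows (collapsed embeddings) can keep Hartigan-Wong cycling;
  # the partition it returns is still valid
  with_seed(seed, suppressWarnings(
    stats::kmeans(U, centers = n_groups, nstart = 10, iter.max = 200)$cluster))
}

#' Redundancy-aware feature selection
#'
#' Groups genes into `n_groups` functionally coherent clusters by
#' normalized-cut spectral clustering of a kNN cosine-similarity graph over
#' the embeddings, then retains the top `ceil((1 - redundancy) * N)` genes
#' by spatial-variability score, guaranteeing at least one gene per group.
#'
#' @param sgr N x D embedding matrix with gene-id rownames.
#' @param svg SVG table from [svg_scores()], aligned to `sgr`'s genes.
#' @param n_groups Number of spectral groups.
#' @param redundancy Fraction of genes to discard, in `[0, 1)`.
#' @param k Neighbours in the similarity graph.
#' @param seed Seed for the spectral k-means.
#' @return List with `selected` (gene ids) and `groups` (data.frame
#'   `gene_id, group, score, selected`).
#' @export
isc_select <- function(sgr, svg, n_groups, redundancy = 0.5, k = 10, seed = 1) {
  if (redundancy < 0 || redundancy >= 1) stopf("redundancy must lie in [0, 1)")
  N <- nrow(sgr)
  ids <- rownames(sgr) %||% as.character(seq_len(N))
  sc <- svg$score[match(ids, svg$gene_id)]
  if (anyNA(sc)) stopf("svg table does not cover all embedding genes")

  C <- cosine_cols(t(sgr))
  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    o <- order(C[i, -i], decreasing = TRUE)
    nb <- setdiff(seq_len(N), i)[o[seq_len(min(k, N - 1))]]
    A[i, nb] <- pmax(C[i, nb], 0)
  }
  A <- pmax(A, t(A))
  diag(A) <- 1e-8   # keep every node connected
  grp <- shi_malik_groups(A, n_groups, seed = seed)

  quota <- ceiling((1 - redundancy) * N)
  if (quota < n_groups)
    stopf("redundancy %.2f leaves %d slots for %d groups", redundancy, quota,
          n_groups)
  sel <- logical(N)
  for (g in seq_len(n_groups)) {      # one guaranteed gene per group
    member <- which(grp == g)
    sel[member[which.max(sc[member])]] <- TRUE
  }
  remaining <- order(sc, decreasing = TRUE)
  for (i in remaining) {
    if (sum(sel) >= quota) break
    sel[i] <- TRUE
  }
  list(selected = ids[sel],
       groups = data.frame(gene_id = ids, group = grp, score = sc,
                           selected = sel))
}

#' Gene-crosstalk correlation shift between two datasets
#'
#' Pearson correlations between gene pairs are computed across embedding
#' dimensions within each dataset; the shift matrix is the absolute
#' difference. Pairs involving genes whose interactions changed between
#' conditions show large shifts.
#'
#' @param sgr_a,sgr_b Embedding matrices with gene-id rownames.
#' @param gene_ids Genes to compare (must be present in both).
#' @return List of class `correlation_shift`: `rho_a`, `rho_b`,
#'   `delta` (= |rho_a - rho_b|), `gene_ids`.
#' @export
crosstalk_shift <- function(sgr_a, sgr_b, gene_ids = NULL) {
  gene_ids <- gene_ids %||% intersect(rownames(sgr_a), rownames(sgr_b))
  ia <- match(gene_ids, rownames(sgr_a))
  ib <- match(gene_ids, rownames(sgr_b))
  if (anyNA(ia) || anyNA(ib)) stopf("gene ids missing from one of the matrices")
  Za <- sgr_a[ia, , drop = FALSE]
  Zb <- sgr_b[ib, , drop = FALSE]
  if (any(apply(Za, 1, stats::sd) == 0) || any(apply(Zb, 1, stats::sd) == 0))
    stopf("constant embedding row: correlation undefined")
  rho_a <- stats::cor(t(Za))
  rho_b <- stats::cor(t(Zb))
  structure(list(rho_a = rho_a, rho_b = rho_b,
                 delta = abs(rho_a - rho_b), gene_ids = gene_ids),
            class = "correlation_shift")
}
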