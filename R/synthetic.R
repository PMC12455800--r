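
# Synthetic spatial transcriptomics with planted structure, and the two
# count simulators used by the downstream analyses: a designated-pattern
# pseudo-gene simulator (negative binomial with a mean-dispersion trend and
# rank re-assignment against the tissue's smoothed expression template) and
# a spatially homogeneous gene simulator (NB/ZINB, i.i.d. across spots).
#
# Dispersion convention throughout: Var(x) = mu + phi * mu^2, i.e. phi is
# the NB overdispersion and rnbinom's size = 1/phi.

DISPERSION_FLOOR <- 1e-3
DISPERSION_CAP <- 1e3

#' Designated spatial expression pattern
#'
#' Assigns every spot a region id and every region an expression percentile
#' in `[0, 100]` (e.g. high = 95, medium = 75, low = 35): the target mean of a
#' region is that percentile of the per-gene average expression distribution.
#'
#' @param region_labels Integer region id per spot.
#' @param region_levels Named numeric vector mapping region id to percentile.
#' @return An object of class `designated_pattern`.
#' @export
designated_pattern <- function(region_labels, region_levels) {
  region_labels <- as.integer(region_labels)
  lv <- unlist(region_levels)
  if (any(lv < 0 | lv > 100)) stopf("region levels must be percentiles in [0, 100]")
  miss <- setdiff(unique(region_labels), as.integer(names(lv)))
  if (length(miss) > 0)
    stopf("region id(s) without a level: %s", paste(miss, collapse = ", "))
  structure(list(region_labels = region_labels,
                 region_levels = lv), class = "designated_pattern")
}

#' Read a designated pattern from CSV + YAML
#'
#' @param csv Path to a CSV with columns `spot_id`, `region_id`.
#' @param yaml_path Path to a YAML map from region id to percentile.
#' @param spot_ids Spot ordering to align the labels to.
#' @export
read_designated_pattern <- function(csv, yaml_path, spot_ids) {
  tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
  lv <- unlist(yaml::read_yaml(yaml_path))
  idx <- match(spot_ids, tab$spot_id)
  if (anyNA(idx)) stopf("pattern CSV lacks spot '%s'", spot_ids[which(is.na(idx))[1]])
  designated_pattern(tab$region_id[idx], lv)
}

#' Generate a synthetic spatial dataset with planted structure
#'
#' Spots sit on a square grid; tissue domains are contiguous Voronoi cells of
#' random centers. Genes are split into planted spatially co-expressed
#' clusters: each cluster is "on" in its own subset of domains, where the
#' gene's baseline mean is multiplied by `effect_size`. A fraction of genes
#' is spatially homogeneous (domain-constant mean). Counts are negative
#' binomial around mean x spot size factor.
#'
#' @param n_spots_side Side length of the square spot grid.
#' @param n_genes Number of genes.
#' @param n_gene_clusters Number of planted spatial gene clusters.
#' @param n_domains Number of tissue domains.
#' @param effect_size Fold change of "on" domains relative to baseline
#'   (`1` = no spatial effect anywhere).
#' @param dispersion NB overdispersion phi (Var = mu + phi mu^2).
#' @param frac_homogeneous Fraction of genes with spatially constant mean.
#' @param seed Integer seed; the generator is a pure function of its inputs.
#' @param size_factor_sd Log-normal sd of per-spot size factors (mean 1).
#' @return `list(dataset = spatial_dataset, truth = synthetic_truth)` where
#'   the truth carries `gene_cluster_labels` (0 for homogeneous genes),
#'   `domain_labels`, `svg_flags` and the per-gene NB parameters.
#' @export
generate_synthetic_st <- function(n_spots_side, n_genes, n_gene_clusters,
                                  n_domains, effect_size = 6, dispersion = 0.5,
                                  frac_homogeneous = 0, seed = 1,
                                  size_factor_sd = 0.1) {
  if (n_genes < n_gene_clusters) stopf("need n_genes >= n_gene_clusters")
  if (n_spots_side^2 < n_domains) stopf("need n_spots_side^2 >= n_domains")
  if (frac_homogeneous < 0 || frac_homogeneous > 1)
    stopf("frac_homogeneous must lie in [0, 1]")
  if (effect_size <= 0 || dispersion <= 0) stopf("effect size and dispersion must be positive")

  with_seed(seed, {
    n_spots <- n_spots_side^2
    gr <- expand.grid(array_row = seq_len(n_spots_side),
                      array_col = seq_len(n_spots_side))
    # farthest-point placement of domain centers: random anchor, then each
    # center maximizes its distance to the chosen ones. Voronoi cells of
    # uniformly random centers can degenerate into slivers of a handful of
    # spots, which are not meaningful tissue domains.
    ci <- sample.int(n_spots, 1)
    d2min <- (gr$array_row - gr$array_row[ci])^2 +
             (gr$array_col - gr$array_col[ci])^2
    for (k in seq_len(n_domains - 1)) {
      nxt <- which.max(d2min)
      ci <- c(ci, nxt)
      d2min <- pmin(d2min, (gr$array_row - gr$array_row[nxt])^2 +
                           (gr$array_col - gr$array_col[nxt])^2)
    }
    centers <- gr[ci, , drop = FALSE]
    d2 <- outer(gr$array_row, centers$array_row, "-")^2 +
          outer(gr$array_col, centers$array_col, "-")^2
    domain <- max.col(-d2, ties.method = "first")

    n_homo <- round(frac_homogeneous * n_genes)
    homo <- rep(FALSE, n_genes)
    if (n_homo > 0) homo[sample.int(n_genes, n_homo)] <- TRUE
    clu <- integer(n_genes)
    clu[!homo] <- rep_len(seq_len(n_gene_clusters), sum(!homo))

    # each cluster is "on" in a distinct single domain (wrapping if there are
    # more clusters than domains, in which case a second domain is added to
    # keep profiles distinct)
    on_domains <- lapply(seq_len(n_gene_clusters), function(j) {
      d1 <- (j - 1L) %% n_domains + 1L
      if (j > n_domains) sort(unique(c(d1, j %% n_domains + 1L))) else d1
    })

    baseline <- exp(stats::runif(n_genes, log(1), log(8)))
    sf <- exp(stats::rnorm(n_spots, 0, size_factor_sd))
    sf <- sf / mean(sf)

    mu <- matrix(0, n_spots, n_genes)
    for (g in seq_len(n_genes)) {
      fold <- rep(1, n_spots)
      if (!homo[g] && effect_size != 1)
        fold[domain %in% on_domains[[clu[g]]]] <- effect_size
      mu[, g] <- baseline[g] * fold * sf
    }
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = 1 / dispersion),
                     n_spots, n_genes)

    spot_ids <- sprintf("spot_%04d", seq_len(n_spots))
    gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
    ds <- spatial_dataset(
      counts,
      data.frame(spot_id = spot_ids, array_row = gr$array_row,
                 array_col = gr$array_col, x = NA_real_, y = NA_real_),
      gene_ids, spot_ids)

    truth <- structure(list(
      gene_cluster_labels = clu,
      domain_labels = domain,
      svg_flags = !homo & effect_size != 1,
      nb_params = data.frame(gene_id = gene_ids, mean = baseline,
                             dispersion = dispersion),
      on_domains = on_domains,
      seed = seed
    ), class = "synthetic_truth")
    list(dataset = ds, truth = truth)
  })
}

# Method-of-moments NB dispersion phi = (var - mean) / mean^2, clipped.
mom_dispersion <- function(m, v) {
  phi <- (v - m) / m^2
  clamp(ifelse(is.finite(phi), phi, DISPERSION_FLOOR),
        DISPERSION_FLOOR, DISPERSION_CAP)
}

raw_counts_of <- function(ds) {
  if (!is.null(ds$raw_counts)) return(ds$raw_counts)
  if (isTRUE(ds$normalized))
    stopf("dataset is normalized and carries no raw counts; rerun preprocess() on raw data")
  ds$counts
}

# 3x3 mean filter of a per-spot field over the array grid.
smooth_field <- function(ds, values) {
  r <- ds$spot_coords$array_row; c <- ds$spot_coords$array_col
  rr <- r - min(r) + 1L; cc <- c - min(c) + 1L
  H <- max(rr); W <- max(cc)
  grid <- matrix(NA_real_, H, W)
  grid[cbind(rr, cc)] <- values
  sm <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    block <- grid[max(1, i - 1):min(H, i + 1), max(1, j - 1):min(W, j + 1)]
    sm[i, j] <- mean(block, na.rm = TRUE)
  }
  sm[cbind(rr, cc)]
}

#' Simulate a pseudo-gene with a designated spatial pattern
#'
#' Negative-binomial simulation of one gene whose regional mean expression
#' follows the pattern's percentile targets: per-gene average expressions
#' define the percentile scale, a log-log regression of method-of-moments
#' dispersions on means supplies the dispersion at each target, counts are
#' drawn per spot (optionally scaled by spot library-size factors), and
#' within each region the draws are re-assigned by rank against a smoothed
#' (3x3 mean filter) template so the simulated gene shows tissue-like local
#' coherence rather than salt-and-pepper noise.
#'
#' The default template (`"self"`) smooths the pseudo-gene's own draws,
#' creating spatial autocorrelation without importing any other gene's
#' pattern into designated-off regions. `template = "total"` instead matches
#' ranks to the smoothed total-expression field, letting the pseudo-gene
#' inherit the tissue's global intensity structure; with strongly
#' domain-organized data this bleeds unrelated expression domains into
#' regions designated as low.
#'
#' @param ds A [spatial_dataset()]; raw counts are used for estimation
#'   (retained by [preprocess()]).
#' @param pattern A [designated_pattern()].
#' @param seed Integer seed.
#' @param use_size_factors Scale spot means by library-size factors.
#' @param template Rank-reassignment template, `"self"` or `"total"`.
#' @return Integer vector of simulated counts, one per spot.
#' @export
sps_simulate <- function(ds, pattern, seed = 1, use_size_factors = TRUE,
                         template = c("self", "total")) {
  template <- match.arg(template)
  stopifnot(inherits(ds, "spatial_dataset"), inherits(pattern, "designated_pattern"))
  counts <- raw_counts_of(ds)
  if (length(pattern$region_labels) != nrow(counts))
    stopf("pattern labels one region per spot; got %d labels for %d spots",
          length(pattern$region_labels), nrow(counts))
  regions <- as.integer(names(pattern$region_levels))
  n_per <- table(factor(pattern$region_labels, levels = regions))
  if (any(n_per == 0))
    stopf("region %s contains zero spots", names(n_per)[which(n_per == 0)[1]])

  gm <- Matrix::colMeans(counts)
  gv <- apply(counts, 2, function(col) stats::var(as.numeric(col)))
  ok <- gm > 0 & gv > 0
  if (sum(ok) < 10) stopf("fewer than 10 usable genes for the dispersion trend")
  phi <- mom_dispersion(gm[ok], gv[ok])
  trend <- stats::lm(log(phi) ~ log(gm[ok]))
  if (anyNA(stats::coef(trend))) stopf("dispersion trend fit is degenerate")

  target_mean <- stats::quantile(gm, pattern$region_levels / 100, names = FALSE)
  names(target_mean) <- names(pattern$region_levels)
  target_phi <- clamp(exp(stats::coef(trend)[1] + stats::coef(trend)[2] * log(target_mean)),
                      DISPERSION_FLOOR, DISPERSION_CAP)

  lib <- Matrix::rowSums(counts)
  sf <- if (use_size_factors) {
    md <- stats::median(lib)
    ifelse(lib > 0, lib / md, 1)
  } else rep(1, nrow(counts))

  total_field <- if (template == "total")
    smooth_field(ds, Matrix::rowSums(counts)) else NULL

  with_seed(seed, {
    region_of <- match(pattern$region_labels, regions)
    mu <- target_mean[region_of] * sf
    phi_spot <- target_phi[region_of]
    x <- stats::rnbinom(length(mu), mu = mu, size = 1 / phi_spot)
    tmpl <- total_field %||% smooth_field(ds, x)
    # impose the template's spatial rank order within each region
    for (rgn in seq_along(regions)) {
      idx <- which(region_of == rgn)
      ord <- order(rank(tmpl[idx], ties.method = "first"))
      x[idx[ord]] <- sort(x[idx])
    }
    as.integer(x)
  })
}

#' Simulate spatially homogeneous counterparts of a gene
#'
#' Fits a negative binomial to the gene's observed counts by the method of
#' moments; if the observed zero fraction exceeds the NB-implied zero
#' probability by more than 0.05, a moment-matched zero-inflated NB is used.
#' Replicates are drawn i.i.d. across spots, destroying all spatial
#' structure while preserving the marginal count distribution; replicate `r`
#' uses `seed + r`.
#'
#' @param ds A [spatial_dataset()] (raw counts used).
#' @param gene_index Column index or gene id of the gene to homogenize.
#' @param n_replicates Number of replicates.
#' @param seed Integer seed.
#' @return Matrix of simulated counts, spots x replicates.
#' @export
simulate_homogeneous <- function(ds, gene_index, n_replicates = 10, seed = 1) {
  counts <- raw_counts_of(ds)
  if (nrow(counts) < 30) stopf("need at least 30 spots to estimate count moments")
  if (is.character(gene_index)) gene_index <- match(gene_index, ds$gene_ids)
  if (is.na(gene_index) || gene_index < 1 || gene_index > ncol(counts))
    stopf("gene not found")
  x <- as.numeric(counts[, gene_index])
  if (all(x == 0)) stopf("gene is all-zero; a homogeneous counterpart is undefined")

  m <- mean(x); v <- stats::var(x)
  phi <- mom_dispersion(m, v)
  size <- 1 / phi
  p0_nb <- (size / (size + m))^size
  z <- mean(x == 0)

  use_zinb <- (z - p0_nb) > 0.05
  if (use_zinb) {
    # fixed point: the NB component's own zero probability shifts as the
    # inflation weight rescales its mean/variance, so iterate
    # z = w + (1 - w) * p0(w) to self-consistency
    w <- (z - p0_nb) / (1 - p0_nb)
    for (it in 1:25) {
      w <- clamp(w, 0, 0.95)
      m_nb <- m / (1 - w)
      v_nb <- (v + m^2) / (1 - w) - m_nb^2
      phi_nb <- mom_dispersion(m_nb, max(v_nb, m_nb * 1.0001))
      size_nb <- 1 / phi_nb
      p0 <- (size_nb / (size_nb + m_nb))^size_nb
      w_new <- clamp((z - p0) / (1 - p0), 0, 0.95)
      if (abs(w_new - w) < 1e-8) { w <- w_new; break }
      w <- w_new
    }
    m_nb <- m / (1 - w)
    v_nb <- (v + m^2) / (1 - w) - m_nb^2
    phi_nb <- mom_dispersion(m_nb, max(v_nb, m_nb * 1.0001))
    size_nb <- 1 / phi_nb
  }

  n <- length(x)
  out <- matrix(0L, n, n_replicates)
  for (r in seq_len(n_replicates)) {
    out[, r] <- with_seed(seed + r, {
      if (use_zinb) {
        drop0 <- stats::rbinom(n, 1, w) == 1
        y <- stats::rnbinom(n, mu = m_nb, size = size_nb)
        y[drop0] <- 0L
        y
      } else {
        stats::rnbinom(n, mu = m, size = size)
      }
    })
  }
  out
}
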