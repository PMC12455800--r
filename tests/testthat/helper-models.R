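# A small trained model shared across downstream tests; trained once per
# test session and memoized. 150 genes on a 16 x 16 grid, 5 planted
# clusters, 40% spatially homogeneous genes.
.model_cache <- new.env(parent = emptyenv())

# The full-size planted-cluster study: 600 genes on a 24 x 24 grid, six
# spatially co-expressed clusters at effect size 6, reduced model (32 x 32
# rasters, D = 32, K = 6).
get_planted_model <- function() {
  if (!is.null(.model_cache$planted)) return(.model_cache$planted)
  sim <- generate_synthetic_st(24, 600, 6, 6, effect_size = 6,
                               dispersion = 0.5, frac_homogeneous = 0,
                               seed = 1)
  ds <- preprocess(sim$dataset, min_spots = 1)
  pr <- stgem_reduced_preset(K = 6, seed = 1, max_epochs = 12)
  m <- suppressMessages(fit_stgem(ds, pr$cfg, pr$mae_cfg,
                                  height = 32, width = 32))
  .model_cache$planted <- list(model = m, ds = ds, sim = sim)
  .model_cache$planted
}

# The spatial-variability study: 100 planted SVGs against 400 spatially
# homogeneous genes on the same grid. Patch size 4: several planted
# clusters occupy well under 10% of the section, and 8 x 8-pixel patches
# cannot resolve them. The model is stopped early because prolonged
# training memorizes the noise textures of homogeneous genes and blurs the
# contrast with their simulated counterparts.
get_svg_model <- function() {
  if (!is.null(.model_cache$svg)) return(.model_cache$svg)
  sim <- generate_synthetic_st(24, 500, 5, 6, effect_size = 6,
                               dispersion = 0.5, frac_homogeneous = 0.8,
                               seed = 2)
  ds <- preprocess(sim$dataset, min_spots = 10)
  cfg <- stgem_config(K = 6, max_epochs = 2, warmup_steps = 600,
                      batch_size = 128, lr_mae = 1e-4, seed = 2)
  mc <- mae_config(patch_size = 4, encoder_blocks = 2, attention_heads = 4,
                   token_dim = 48, embed_dim = 32,
                   decoder_channels = c(32, 16, 8))
  m <- suppressMessages(fit_stgem(ds, cfg, mc, height = 32, width = 32))
  .model_cache$svg <- list(model = m, ds = ds, sim = sim)
  .model_cache$svg
}

get_small_model <- function() {
  if (!is.null(.model_cache$small)) return(.model_cache$small)
  sim <- generate_synthetic_st(20, 150, 5, 5, effect_size = 6,
                               dispersion = 0.5, frac_homogeneous = 0.4,
                               seed = 101)
  ds <- preprocess(sim$dataset, min_spots = 1)
  cfg <- stgem_config(K = 5, max_epochs = 4, warmup_steps = 1000,
                      batch_size = 75, lr_mae = 1e-4, seed = 3)
  mc <- mae_config(patch_size = 4, mask_ratio = 0.8, encoder_blocks = 2,
                   attention_heads = 4, token_dim = 32, embed_dim = 16,
                   decoder_channels = c(16, 8, 4))
  m <- suppressMessages(fit_stgem(ds, cfg, mc, height = 16, width = 16))
  .model_cache$small <- list(model = m, ds = ds, sim = sim)
  .model_cache$small
}
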