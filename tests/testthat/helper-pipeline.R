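# end-to-end pipeline driver shared by the acceptance tests:
# scene -> calibration -> mean spectra -> SG+SNV -> SPA -> key-band cube ->
# 5x5 blocks -> stride-10 split -> standardize -> multiscale 3DCNN ->
# majority vote.
run_viability_pipeline <- function(train_spec, extra_eval_specs = list(),
                                   k_bands = 12L, block_size = 5L,
                                   stride = 10L, epochs = 70L,
                                   model_seed = 7L) {
  sc <- generate_seed_scene(train_spec)
  cube <- calibrate_cube(sc$calibration)
  tab <- mean_spectra(cube, sc$mask)
  X <- snv_transform(savitzky_golay_smooth(tab$spectra, 11L, 2L))
  bands <- sort(spa_select(X, 1L, k_bands)$indices)
  key <- hyper_cube(cube$data[, , bands, drop = FALSE],
                    cube$wavelengths[bands])
  bs <- suppressWarnings(extract_blocks(key, sc$mask, block_size,
                                        sc$classes))
  spl <- systematic_split(train_spec$n_seeds, stride)
  std <- standardize_blocks(subset_blocks(bs, spl$train),
                            subset_blocks(bs, spl$test))
  cfg <- model_config("multiscale",
                      input_shape = c(block_size, block_size, k_bands),
                      epochs = epochs, seed = model_seed)
  fit <- train_model(build_model(cfg), std$train)
  collect <- function(blocks, classes) {
    if (length(blocks$blocks) == 0L)
      return(list(voted = integer(0), truth = integer(0)))
    preds <- predict_seeds(fit$model, blocks)
    ids <- vapply(preds, `[[`, 0L, "seed_id")
    list(voted = vapply(preds, `[[`, 0L, "voted_class"),
         truth = classes[ids])
  }
  held_out <- collect(std$other, sc$classes)
  extra <- list(voted = integer(0), truth = integer(0))
  for (es in extra_eval_specs) {
    sce <- generate_seed_scene(es)
    cubee <- calibrate_cube(sce$calibration)
    keye <- hyper_cube(cubee$data[, , bands, drop = FALSE],
                       cubee$wavelengths[bands])
    bse <- suppressWarnings(extract_blocks(keye, sce$mask, block_size,
                                           sce$classes))
    res <- collect(apply_block_standardization(bse, std$stats), sce$classes)
    extra$voted <- c(extra$voted, res$voted)
    extra$truth <- c(extra$truth, res$truth)
  }
  list(bands = bands,
       n_train_blocks = length(std$train$blocks),
       history = fit$history,
       held_out = held_out,
       extra = extra,
       held_out_accuracy = mean(held_out$voted == held_out$truth),
       pooled_accuracy = mean(c(held_out$voted, extra$voted) ==
                              c(held_out$truth, extra$truth)))
}

# the desk-scale scene used by the end-to-end acceptance criterion:
# 40 seeds keep two 70-epoch trainings inside the stated 10-minute budget
acceptance_scene <- function(class_offset, seed) {
  scene_spec(n_seeds = 40L, image_size = c(170L, 260L), n_bands = 64L,
             seed_axes_px = c(7, 5.5), noise_sd = 0.01,
             class_offset = class_offset, seed = seed)
}
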