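# End-to-end worked example on a 12-seed synthetic scene (see README.md)
library(seedhsi)

sp <- scene_spec(n_seeds = 12, image_size = c(120, 160), n_bands = 16,
                 seed_axes_px = c(8, 6), class_offset = 0.05,
                 noise_sd = 0.01, seed = 42)
scene <- generate_seed_scene(sp)

cube <- calibrate_cube(scene$calibration)   # reflectance in [0, 1]
mask <- segment_seeds(cube, band_nm = 801)  # Otsu cutoff at the mask band
print(mask)

tab <- mean_spectra(cube, mask, scene$classes)
prep <- snv_transform(savitzky_golay_smooth(tab$spectra, window = 7))
bands <- spa_select(prep, start_band = 1, k = 4)
print(bands)

key <- subset_wavelengths(cube, 420, 1000)
key$data <- key$data[, , sort(bands$indices), drop = FALSE]
key$wavelengths <- key$wavelengths[sort(bands$indices)]

blocks <- extract_blocks(key, scene$mask, block_size = 5,
                         labels = scene$classes)
print(blocks)

split <- systematic_split(sp$n_seeds, stride = 10)
std <- standardize_blocks(subset_blocks(blocks, split$train),
                          subset_blocks(blocks, split$test))

cfg <- model_config("multiscale", input_shape = c(5, 5, 4),
                    epochs = 30, seed = 7)
fit <- train_model(build_model(cfg), std$train)
print(round(tail(fit$history, 2), 3))

preds <- predict_seeds(fit$model, std$other)
print(seed_level_accuracy(preds, setNames(scene$classes, seq_len(sp$n_seeds))))

bud <- generate_bud_mask(bud_spec(length_px = 100, width_px = 5,
                                  curvature = 0.8, n_spurs = 2, seed = 1))
print(measure_bud_length(bud$mask))
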