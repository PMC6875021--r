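# Shared fixtures, built in code.

# A small, fast model configuration used throughout the tests: deep enough
# to segment the phantoms well, small enough to train on one CPU in
# minutes.
small_model_config <- function(seed, epochs = 10, batch_size = 4) {
  model_config(
    depth = 3, base_channels = 4, residual_blocks_per_level = 1,
    epochs = epochs, batch_size = batch_size, learning_rate = 2e-3,
    seed = seed
  )
}

no_augmentation <- function() {
  augmentation_config(
    rotation_max = 0, flip_horizontal = FALSE, flip_vertical = FALSE,
    intensity_shift_sd = 0, translation_max = 0
  )
}

# The end-to-end study: train both resolution models on 200 phantoms,
# evaluate on 50 held-out phantoms. Trained once per test run and cached,
# because several properties (recovery accuracy, determinism, reports) are
# checked against the same trained pipeline.
.pipeline_cache <- new.env(parent = emptyenv())

get_trained_pipeline <- function() {
  if (!is.null(.pipeline_cache$pipeline)) {
    return(.pipeline_cache$pipeline)
  }
  n_train <- 200
  n_test <- 50
  cohort <- generate_cohort(n_train + n_test, seed = 42)
  preps <- lapply(cohort$samples, function(s) {
    prepare_sample(s$plane, s$truth_contour)
  })
  tr <- seq_len(n_train)
  te <- n_train + seq_len(n_test)
  mk <- function(res) {
    lapply(preps, function(p) list(plane = p[[res]]$plane, mask = p[[res]]$mask))
  }
  model_coarse <- train_model(build_model(small_model_config(seed = 1)),
                              mk("r1")[tr], mk("r1")[te])
  model_fine <- train_model(build_model(small_model_config(seed = 2)),
                            mk("r0.5")[tr], mk("r0.5")[te])
  detections <- lapply(te, function(i) {
    tryCatch(detect(cohort$samples[[i]]$plane, model_coarse, model_fine),
             error = identity)
  })
  .pipeline_cache$pipeline <- list(
    cohort = cohort, test_idx = te,
    model_coarse = model_coarse, model_fine = model_fine,
    detections = detections
  )
  .pipeline_cache$pipeline
}

# One quickly-trained tiny pipeline for interface-level tests.
get_tiny_models <- function() {
  if (!is.null(.pipeline_cache$tiny)) {
    return(.pipeline_cache$tiny)
  }
  cohort <- generate_cohort(6, seed = 7)
  preps <- lapply(cohort$samples, function(s) prepare_sample(s$plane, s$truth_contour))
  mk <- function(res) {
    lapply(preps, function(p) list(plane = p[[res]]$plane, mask = p[[res]]$mask))
  }
  cfg <- small_model_config(seed = 5, epochs = 2)
  .pipeline_cache$tiny <- list(
    cohort = cohort,
    model_coarse = train_model(build_model(cfg), mk("r1")[1:5], mk("r1")[6]),
    model_fine = train_model(build_model(cfg), mk("r0.5")[1:5], mk("r0.5")[6])
  )
  .pipeline_cache$tiny
}

# A crisp synthetic probability map: binary disc(s) on a grid centred at 0.
disc_prob_map <- function(radii, centers, spacing = 0.5, size = 128) {
  origin <- -(size - 1) / 2 * spacing * c(1, 1)
  xs <- origin[1] + (seq_len(size) - 1) * spacing
  X <- matrix(xs, size, size, byrow = TRUE)
  Y <- matrix(xs, size, size)
  v <- matrix(0, size, size)
  for (q in seq_along(radii)) {
    v[(X - centers[[q]][1])^2 + (Y - centers[[q]][2])^2 <= radii[q]^2] <- 1
  }
  probability_map(v, spacing, origin)
}
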