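test_that("configuration invariants are enforced", {
  expect_error(model_config(depth = 0), "depth")
  expect_error(model_config(depth = 5, input_size = 48), "divisible")
  expect_error(model_config(base_channels = 0), "base_channels")
  expect_error(model_config(epochs = 0), "epochs")
  expect_error(model_config(residual_blocks_per_level = 0),
               "residual_blocks_per_level")
  expect_error(augmentation_config(rotation_max = -1), ">= 0")
})

test_that("graph shapes follow the encoder-decoder contract", {
  cfg <- model_config(depth = 4, base_channels = 2,
                      residual_blocks_per_level = 1, input_size = 128)
  g <- unet_graph(cfg)
  hs <- vapply(g$ops, `[[`, 0, "h")
  # bottleneck spatial size is input_size / 2^depth
  expect_equal(min(hs), 128 / 2^4)
  # final op is the sigmoid head at full resolution
  last <- g$ops[[length(g$ops)]]
  expect_equal(last$type, 7L)
  expect_equal(last$h, 128)
  # head convolution is 1x1 down to one channel
  convs <- Filter(function(o) o$type == 1L, g$ops)
  head <- convs[[length(convs)]]
  expect_equal(head$k, 1L)
  expect_equal(head$cout, 1L)
})

test_that("the untrained forward pass is sigmoid-bounded and seed-deterministic", {
  cfg <- small_model_config(seed = 3)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(small_model_config(seed = 4))
  expect_false(identical(m1$params, m3$params))

  x <- matrix(rnorm(128 * 128), 128, 128)
  p1 <- forward_prob(m1, x)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, forward_prob(m2, x))
  # head bias -2 pushes the initial output towards the background prior
  expect_lt(mean(p1), 0.5)
})

test_that("analytic gradients match central finite differences", {
  cfg <- model_config(depth = 2, base_channels = 2,
                      residual_blocks_per_level = 1, input_size = 8,
                      seed = 21)
  m <- build_model(cfg)
  # jitter every parameter so no ReLU pre-activation sits exactly at the
  # kink (identity-initialized residual convs are all-zero otherwise,
  # where the derivative is not defined and finite differences disagree)
  m$params <- m$params + with_seed(4, rnorm(length(m$params), 0, 0.05))
  x <- as.numeric(with_seed(1, matrix(rnorm(64, 0, 0.5), 8, 8)))
  y <- as.numeric(with_seed(2, matrix(rbinom(64, 1, 0.3), 8, 8)))
  g <- cpp_unet_loss_grad(m$graph, m$params, x, y, 1, 1)
  idx <- with_seed(3, sample.int(length(m$params), 40))
  eps <- 1e-5
  for (i in idx) {
    pp <- m$params; pp[i] <- pp[i] + eps
    pm <- m$params; pm[i] <- pm[i] - eps
    fd <- (cpp_unet_loss_grad(m$graph, pp, x, y, 1, 1)$loss -
             cpp_unet_loss_grad(m$graph, pm, x, y, 1, 1)$loss) / (2 * eps)
    expect_equal(g$grad[i], fd, tolerance = 1e-4)
  }
})

test_that("loss variants change the objective as configured", {
  cfg_b <- model_config(depth = 2, base_channels = 2,
                        residual_blocks_per_level = 1, input_size = 8,
                        loss = "bce", seed = 21)
  cfg_d <- model_config(depth = 2, base_channels = 2,
                        residual_blocks_per_level = 1, input_size = 8,
                        loss = "dice", seed = 21)
  m <- build_model(cfg_b)
  x <- as.numeric(with_seed(1, matrix(rnorm(64, 0, 0.5), 8, 8)))
  y <- as.numeric(with_seed(2, matrix(rbinom(64, 1, 0.3), 8, 8)))
  wb <- loss_weights(cfg_b$loss)
  wd <- loss_weights(cfg_d$loss)
  lb <- cpp_unet_loss_grad(m$graph, m$params, x, y, wb[["bce"]], wb[["dice"]])
  ld <- cpp_unet_loss_grad(m$graph, m$params, x, y, wd[["bce"]], wd[["dice"]])
  lboth <- cpp_unet_loss_grad(m$graph, m$params, x, y, 1, 1)
  expect_equal(lb$loss + ld$loss, lboth$loss, tolerance = 1e-10)
  expect_false(isTRUE(all.equal(lb$grad, ld$grad)))
})

test_that("the network can overfit a single sample to near-perfect Dice", {
  s <- generate_phantom(phantom_spec(noise_sd = 15), seed = 8)
  prep <- prepare_sample(s$plane, s$truth_contour)$r1
  # one sample per epoch: 50 optimizer steps, enough for convergence
  cfg <- small_model_config(seed = 6, epochs = 50, batch_size = 1)
  cfg$augmentation <- no_augmentation()
  trained <- train_model(build_model(cfg), list(prep), list(prep))
  expect_gt(max(trained$history$val_dice), 0.95)
  expect_equal(trained$resolution, 1.0)
  expect_equal(nrow(trained$history), 50)
})

test_that("training rejects malformed or mismatched sample sets", {
  s <- generate_phantom(phantom_spec(), seed = 8)
  prep <- prepare_sample(s$plane, s$truth_contour)
  m <- build_model(small_model_config(seed = 1, epochs = 1))
  expect_error(train_model(m, list(prep$r1), list()), "at least one")
  expect_error(train_model(m, list(prep$r1), list(prep$r0.5)),
               "different resolutions")
  expect_error(train_model(m, list(prep$r1, prep$r0.5), list(prep$r1)),
               "mixed resolutions")
  no_mask <- list(plane = prep$r1$plane, mask = NULL)
  expect_error(train_model(m, list(no_mask), list(prep$r1)), "mask")
})

test_that("training is bit-deterministic under a fixed seed", {
  cohort <- generate_cohort(4, seed = 31)
  preps <- lapply(cohort$samples, function(s) {
    prepare_sample(s$plane, s$truth_contour)$r1
  })
  cfg <- small_model_config(seed = 9, epochs = 2)
  t1 <- train_model(build_model(cfg), preps[1:3], preps[4])
  t2 <- train_model(build_model(cfg), preps[1:3], preps[4])
  expect_identical(t1$params, t2$params)
  expect_identical(t1$history, t2$history)
})

test_that("checkpoints round-trip bit-exactly and histories export", {
  tiny <- get_tiny_models()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(tiny$model_coarse, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, tiny$model_coarse$params)
  expect_identical(back$history, tiny$model_coarse$history)
  x <- tiny$cohort$samples[[1]]$plane
  prep <- prepare_sample(x)
  expect_identical(predict_map(back, prep$r1$plane)$values,
                   predict_map(tiny$model_coarse, prep$r1$plane)$values)

  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1), bad)
  expect_error(load_checkpoint(bad), "not an annulus_model")

  csv <- withr::local_tempfile(fileext = ".csv")
  write_history_csv(tiny$model_coarse, csv)
  h <- read.csv(csv)
  expect_named(h, c("epoch", "train_loss", "val_loss", "val_dice"))
  expect_equal(nrow(h), nrow(tiny$model_coarse$history))
  expect_error(write_history_csv(build_model(small_model_config(1)),
                                 withr::local_tempfile()),
               "no training history")
})

test_that("prediction validates its inputs and preserves the grid", {
  tiny <- get_tiny_models()
  prep <- prepare_sample(tiny$cohort$samples[[2]]$plane)
  pm <- predict_map(tiny$model_fine, prep$r0.5$plane)
  expect_s3_class(pm, "probability_map")
  expect_equal(pm$spacing, prep$r0.5$plane$spacing)
  expect_equal(pm$origin, prep$r0.5$plane$origin)
  expect_true(all(pm$values >= 0 & pm$values <= 1))

  expect_error(predict_map(tiny$model_fine, prep$r1$plane),
               "does not match the model resolution")
  untrained <- build_model(small_model_config(seed = 1))
  expect_error(predict_map(untrained, prep$r1$plane), "untrained")
  expect_error(predict_map(tiny$model_coarse,
                           annular_plane(matrix(0, 64, 64), 1.0)),
               "128")
})

test_that("augmentation preserves geometry pairing and mask binarity", {
  s <- generate_phantom(phantom_spec(noise_sd = 0), seed = 2)
  prep <- prepare_sample(s$plane, s$truth_contour)$r1
  cfg <- augmentation_config(rotation_max = 25, intensity_shift_sd = 20,
                             translation_max = 4)
  a <- with_seed(10, augment_sample(prep$plane$values, prep$mask$values, cfg))
  expect_equal(dim(a$values), dim(prep$plane$values))
  expect_true(all(a$mask %in% c(FALSE, TRUE)))
  # foreground count is approximately preserved by rigid transforms
  expect_equal(sum(a$mask), sum(prep$mask$values), tolerance = 0.1)
  # identity augmentation is a no-op
  id <- augment_sample(prep$plane$values, prep$mask$values, no_augmentation())
  expect_identical(id$values, prep$plane$values)
  expect_identical(id$mask, prep$mask$values)
})
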