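#' Augmentation configuration
#'
#' On-the-fly training-data augmentation: random rotation, flips, integer
#' translation and a global intensity shift. Geometric transforms are
#' applied identically to plane and mask; intensity shifts only to the
#' plane (in HU, before standardization).
#'
#' @param rotation_max Maximum absolute rotation, degrees.
#' @param flip_horizontal,flip_vertical Enable random flips.
#' @param intensity_shift_sd SD of the additive global HU shift.
#' @param translation_max Maximum absolute translation, pixels (integer
#'   shifts).
#' @return Object of class `augmentation_config`.
#' @export
augmentation_config <- function(rotation_max = 30,
                                flip_horizontal = TRUE,
                                flip_vertical = TRUE,
                                intensity_shift_sd = 25,
                                translation_max = 5) {
  if (rotation_max < 0 || intensity_shift_sd < 0 || translation_max < 0) {
    stop_invariant("augmentation magnitudes must be >= 0")
  }
  structure(
    list(
      rotation_max = rotation_max,
      flip_horizontal = isTRUE(flip_horizontal),
      flip_vertical = isTRUE(flip_vertical),
      intensity_shift_sd = intensity_shift_sd,
      translation_max = as.integer(translation_max)
    ),
    class = "augmentation_config"
  )
}

#' Segmentation model configuration
#'
#' Architecture and training hyperparameters of the encoder-decoder
#' residual segmentation network. The encoder halves the spatial size at
#' each of `depth` levels (channels doubling from `base_channels`); the
#' decoder mirrors it with skip connections; a final 1x1 convolution with
#' sigmoid yields per-pixel probabilities.
#'
#' @param depth Number of down/up levels (>= 1); `input_size` must be
#'   divisible by `2^depth`.
#' @param base_channels Channels at the first level.
#' @param residual_blocks_per_level Residual blocks per level.
#' @param input_size Input width/height in pixels.
#' @param loss One of `"dice+bce"`, `"dice"`, `"bce"`.
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs (>= 1).
#' @param batch_size Mini-batch size.
#' @param augmentation An [augmentation_config()].
#' @param seed Integer seed for weight initialization, shuffling and
#'   augmentation.
#' @return Object of class `model_config`.
#' @export
model_config <- function(depth = 4,
                         base_channels = 16,
                         residual_blocks_per_level = 2,
                         input_size = 128L,
                         loss = c("dice+bce", "dice", "bce"),
                         learning_rate = 1e-3,
                         epochs = 30,
                         batch_size = 8,
                         augmentation = augmentation_config(),
                         seed = 1L) {
  loss <- match.arg(loss)
  if (!is_count(depth) || depth < 1) stop_invariant("`depth` must be >= 1")
  if (!is_count(epochs) || epochs < 1) stop_invariant("`epochs` must be >= 1")
  if (!is_count(input_size) || input_size %% 2^depth != 0) {
    stop_invariant("`input_size` must be divisible by 2^depth")
  }
  if (!is_count(base_channels) || base_channels < 1) {
    stop_invariant("`base_channels` must be >= 1")
  }
  if (!is_count(residual_blocks_per_level) || residual_blocks_per_level < 1) {
    stop_invariant("`residual_blocks_per_level` must be >= 1")
  }
  structure(
    list(
      depth = depth, base_channels = base_channels,
      residual_blocks_per_level = residual_blocks_per_level,
      input_size = as.integer(input_size), loss = loss,
      learning_rate = learning_rate, epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), augmentation = augmentation,
      seed = as.integer(seed)
    ),
    class = "model_config"
  )
}

loss_weights <- function(loss) {
  switch(loss,
    "dice+bce" = c(bce = 1, dice = 1),
    "dice" = c(bce = 0, dice = 1),
    "bce" = c(bce = 1, dice = 0)
  )
}

# Build the op tape for the network. Tensor 0 is the input; op i produces
# tensor i + 1. Returns the graph list consumed by the C++ kernels plus
# the total parameter count.
unet_graph <- function(config) {
  ops <- list()
  poff <- 0L
  last <- 0L  # last produced tensor id
  push <- function(op) {
    ops[[length(ops) + 1L]] <<- op
    last <<- length(ops)
    invisible(last)
  }
  conv <- function(in1, k, cin, cout, h, w, zero_init = FALSE) {
    op <- list(type = 1L, in1 = in1, k = as.integer(k), cin = as.integer(cin),
               cout = as.integer(cout), h = as.integer(h), w = as.integer(w),
               poff = as.integer(poff), zero_init = isTRUE(zero_init))
    poff <<- poff + k * k * cin * cout + cout
    push(op)
  }
  relu <- function(in1, h, w) push(list(type = 2L, in1 = in1, h = h, w = w))
  addt <- function(in1, in2, h, w) {
    push(list(type = 3L, in1 = in1, in2 = in2, h = h, w = w))
  }
  pool <- function(in1, h, w) push(list(type = 4L, in1 = in1, h = h, w = w))
  upsm <- function(in1, h, w) push(list(type = 5L, in1 = in1, h = h, w = w))
  conc <- function(in1, in2, h, w) {
    push(list(type = 6L, in1 = in1, in2 = in2, h = h, w = w))
  }
  res_block <- function(x, ch, h, w) {
    t1 <- conv(x, 3, ch, ch, h, w)
    t1 <- relu(t1, h, w)
    # zero-init so the block starts as the identity (Fixup-style); without
    # normalization layers this makes trainability independent of the
    # weight-initialization seed
    t1 <- conv(t1, 3, ch, ch, h, w, zero_init = TRUE)
    t1 <- addt(t1, x, h, w)
    relu(t1, h, w)
  }

  d <- config$depth
  nb <- config$residual_blocks_per_level
  ch <- config$base_channels * 2^(0:d)
  sz <- config$input_size / 2^(0:d)

  x <- 0L
  skips <- integer(d)
  cin <- 1L
  for (l in seq_len(d)) {
    h <- sz[l]
    x <- conv(x, 3, cin, ch[l], h, h)
    x <- relu(x, h, h)
    for (b in seq_len(nb)) x <- res_block(x, ch[l], h, h)
    skips[l] <- x
    x <- pool(x, h / 2, h / 2)
    cin <- ch[l]
  }
  h <- sz[d + 1]
  x <- conv(x, 3, ch[d], ch[d + 1], h, h)
  x <- relu(x, h, h)
  for (b in seq_len(nb)) x <- res_block(x, ch[d + 1], h, h)
  for (l in rev(seq_len(d))) {
    h <- sz[l]
    x <- upsm(x, h, h)
    x <- conv(x, 3, ch[l + 1], ch[l], h, h)
    x <- relu(x, h, h)
    x <- conc(x, skips[l], h, h)
    x <- conv(x, 3, 2 * ch[l], ch[l], h, h)
    x <- relu(x, h, h)
    for (b in seq_len(nb)) x <- res_block(x, ch[l], h, h)
  }
  x <- conv(x, 1, ch[1], 1, config$input_size, config$input_size)
  push(list(type = 7L, in1 = x, h = config$input_size, w = config$input_size))

  list(
    ops = ops,
    in_h = config$input_size, in_w = config$input_size, in_c = 1L,
    n_params = poff
  )
}

# He-normal weight initialization, seeded; the second convolution of each
# residual block stays at zero (identity block at the start); the head
# bias starts at -2 so the initial output reflects the
# background-dominant class prior.
init_params <- function(graph, seed) {
  params <- numeric(graph$n_params)
  convs <- Filter(function(o) o$type == 1L, graph$ops)
  with_seed(seed, {
    for (o in convs) {
      if (isTRUE(o$zero_init)) next
      nw <- o$k^2 * o$cin * o$cout
      params[o$poff + seq_len(nw)] <- rnorm(nw, 0, sqrt(2 / (o$k^2 * o$cin)))
    }
  })
  head <- convs[[length(convs)]]
  stopifnot(head$cout == 1L)
  params[head$poff + head$k^2 * head$cin * head$cout + 1L] <- -2
  params
}

#' Build an untrained segmentation model
#'
#' Constructs the network graph and seeded initial weights for the given
#' configuration. Two builds with the same configuration (including seed)
#' have identical initial weights.
#'
#' @param config A [model_config()].
#' @return Object of class `annulus_model` (untrained: `resolution` is
#'   `NA`, `history` is `NULL`).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  graph <- unet_graph(config)
  structure(
    list(
      graph = graph,
      params = init_params(graph, config$seed),
      config = config,
      resolution = NA_real_,
      history = NULL
    ),
    class = "annulus_model"
  )
}

#' @export
print.annulus_model <- function(x, ...) {
  cat(sprintf(
    "<annulus_model> depth %d, base %d ch, %s params, resolution %s mm%s\n",
    x$config$depth, x$config$base_channels,
    format(length(x$params), big.mark = ","),
    ifelse(is.na(x$resolution), "<untrained>", format(x$resolution)),
    if (!is.null(x$history)) sprintf(", best val Dice %.3f",
                                     max(x$history$val_dice)) else ""
  ))
  invisible(x)
}

check_sample_list <- function(samples, input_size, what) {
  if (length(samples) < 1) stop_invariant("need at least one ", what, " sample")
  sp <- vapply(samples, function(s) s$plane$spacing[1], 0)
  if (max(sp) - min(sp) > 1e-9) {
    stop_invariant(what, " samples have mixed resolutions")
  }
  for (s in samples) {
    if (!all(dim(s$plane$values) == input_size)) {
      stop_invariant(what, " sample is not ", input_size, " x ", input_size)
    }
    if (is.null(s$mask) || !all(dim(s$mask$values) == input_size)) {
      stop_invariant(what, " sample is missing an aligned mask")
    }
  }
  sp[1]
}

forward_prob <- function(model, values_std) {
  p <- cpp_unet_forward(model$graph, model$params, as.numeric(values_std))
  matrix(p, nrow(values_std), ncol(values_std))
}

hard_dice <- function(p, mask, threshold = 0.5) {
  a <- p >= threshold
  b <- mask
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}

#' Train a segmentation model
#'
#' Optimizes the configured loss with Adam, applying augmentation
#' on-the-fly to training samples only. Per-epoch training and validation
#' loss and hard Dice (threshold 0.5) are recorded, and the returned
#' weights are those of the epoch with the best validation Dice. HU inputs
#' are standardized by [standardize_hu()] before entering the network.
#' Fully deterministic under the configuration seed.
#'
#' @param model An `annulus_model` from [build_model()].
#' @param samples Training samples: list of lists with elements `plane`
#'   (a clipped [annular_plane()] at the training resolution) and `mask`
#'   (the matching [binary_mask()]).
#' @param val_samples Validation samples, same format (>= 1).
#' @param verbose Print per-epoch progress.
#' @return The trained `annulus_model` with `resolution` and `history`
#'   filled in.
#' @export
train_model <- function(model, samples, val_samples, verbose = FALSE) {
  stopifnot(inherits(model, "annulus_model"))
  cfg <- model$config
  res <- check_sample_list(samples, cfg$input_size, "training")
  vres <- check_sample_list(val_samples, cfg$input_size, "validation")
  if (abs(res - vres) > 1e-9) {
    stop_invariant("training and validation samples are at different resolutions")
  }
  w <- loss_weights(cfg$loss)
  val_x <- lapply(val_samples, function(s) standardize_hu(s$plane$values))
  val_m <- lapply(val_samples, function(s) s$mask$values)

  params <- model$params
  m <- numeric(length(params))
  v <- numeric(length(params))
  t_step <- 0L
  best <- list(dice = -Inf, params = params)
  hist <- vector("list", cfg$epochs)

  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(samples))
      ep_loss <- 0
      ep_dice <- 0
      nb <- 0L
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        xs <- vector("list", length(idx))
        ys <- vector("list", length(idx))
        for (q in seq_along(idx)) {
          s <- samples[[idx[q]]]
          aug <- augment_sample(s$plane$values, s$mask$values, cfg$augmentation)
          xs[[q]] <- as.numeric(standardize_hu(aug$values))
          ys[[q]] <- as.numeric(aug$mask)
        }
        t_step <- t_step + 1L
        r <- cpp_unet_train_batch(
          model$graph, params, m, v, t_step, xs, ys,
          cfg$learning_rate, 0.9, 0.999, 1e-8, w[["bce"]], w[["dice"]]
        )
        params <- r$params
        m <- r$m
        v <- r$v
        ep_loss <- ep_loss + r$loss
        ep_dice <- ep_dice + r$dice
        nb <- nb + 1L
      }
      # validation (no augmentation)
      val_loss <- 0
      val_dice <- 0
      tmp_model <- list(graph = model$graph, params = params)
      for (q in seq_along(val_x)) {
        p <- forward_prob(tmp_model, val_x[[q]])
        pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
        q_mask <- val_m[[q]]
        bce <- -mean(q_mask * log(pc) + (1 - q_mask) * log(1 - pc))
        dl <- 1 - (2 * sum(pc * q_mask) + 1) / (sum(pc) + sum(q_mask) + 1)
        val_loss <- val_loss + (w[["bce"]] * bce + w[["dice"]] * dl)
        val_dice <- val_dice + hard_dice(p, q_mask)
      }
      val_loss <- val_loss / length(val_x)
      val_dice <- val_dice / length(val_x)
      hist[[ep]] <- data.frame(
        epoch = ep, train_loss = ep_loss / nb, train_dice = ep_dice / nb,
        val_loss = val_loss, val_dice = val_dice
      )
      if (val_dice > best$dice) {
        best <- list(dice = val_dice, params = params)
      }
      if (verbose) {
        message(sprintf(
          "epoch %3d  train loss %.4f dice %.3f | val loss %.4f dice %.3f",
          ep, ep_loss / nb, ep_dice / nb, val_loss, val_dice
        ))
      }
    }
  })

  model$params <- best$params
  model$resolution <- res
  model$history <- do.call(rbind, hist)
  model
}

#' Per-pixel probability map
#'
#' @param values Numeric matrix with all entries in `[0, 1]`.
#' @param spacing,origin Grid geometry as in [annular_plane()].
#' @return Object of class `probability_map`.
#' @export
probability_map <- function(values, spacing, origin = c(0, 0)) {
  if (!is.matrix(values) || any(values < 0) || any(values > 1) ||
      any(!is.finite(values))) {
    stop_invariant("probability map values must lie in [0, 1]")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- c(spacing, spacing)
  structure(
    list(values = values, spacing = spacing, origin = as.numeric(origin)),
    class = "probability_map"
  )
}

#' Predict the annulus probability map for one plane
#'
#' Runs the trained network (no augmentation) on a prepared plane. The
#' output map shares the plane's grid. Deterministic given fixed weights.
#'
#' @param model A trained `annulus_model`.
#' @param plane A clipped [annular_plane()] at the model's resolution and
#'   input size.
#' @return A [probability_map()].
#' @export
predict_map <- function(model, plane) {
  stopifnot(inherits(model, "annulus_model"), inherits(plane, "annular_plane"))
  if (is.na(model$resolution)) {
    stop_invariant("model is untrained (no resolution tag)")
  }
  if (!all(dim(plane$values) == model$config$input_size)) {
    stop_invariant("plane is not ", model$config$input_size, " px square")
  }
  if (abs(plane$spacing[1] - model$resolution) > 1e-9 || !is_isotropic(plane)) {
    stop_invariant("plane spacing does not match the model resolution")
  }
  p <- forward_prob(model, standardize_hu(plane$values))
  p <- pmin(pmax(p, 0), 1)
  probability_map(p, plane$spacing, plane$origin)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores weights, full configuration, resolution tag and
#' training history. Round-tripping is bit-exact.
#'
#' @param model An `annulus_model`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored `annulus_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "annulus_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "annulus_model")) {
    stop_invariant("not an annulus_model checkpoint: ", path)
  }
  model
}

#' Write a per-epoch training history CSV
#'
#' @param model A trained `annulus_model`.
#' @param path Output CSV path (`epoch,train_loss,val_loss,val_dice`).
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(model, path) {
  if (is.null(model$history)) stop_invariant("model has no training history")
  write.csv(
    model$history[, c("epoch", "train_loss", "val_loss", "val_dice")],
    path, row.names = FALSE
  )
  invisible(path)
}
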