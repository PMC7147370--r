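# Synthetic fixtures: texture-classification images, ellipse segmentation
# images with exact ground-truth masks, a tiny CNN with named activation
# slots, and the desk-scale benchmark comparing a stochastic ensemble with
# the all-ReLU baseline.  The fixtures emulate the *shape* of the two task
# types (multi-class image classification, two-class skin-like
# segmentation); they do not imitate any particular dataset.

#' Generate a synthetic texture-classification dataset
#'
#' Each class is a sinusoidal grating at a class-specific spatial
#' frequency and orientation; each image gets a random phase, a fixed
#' class frequency and additive Gaussian pixel noise, clipped to \[0, 1\].
#' Classes are separable by construction (a frequency-domain
#' nearest-centroid rule is perfect at `noise_sd = 0`); raising `noise_sd`
#' makes the task harder.
#'
#' @param n_classes Number of classes (>= 2).
#' @param n_per_class Images per class.
#' @param image_size `c(H, W, 3)`.
#' @param texture_freqs Cycles per image per class (default `2 * class`).
#' @param noise_sd Gaussian noise standard deviation (default 0.15).
#' @param seed Integer seed; the dataset is a pure function of the spec.
#' @return List with `x` (`H x W x 3 x N` array in \[0, 1\]), `y` (integer
#'   labels `1..n_classes`) and the generating parameters.
#' @export
gen_classification <- function(n_classes = 3L, n_per_class = 60L,
                               image_size = c(32L, 32L, 3L),
                               texture_freqs = 2 * seq_len(n_classes),
                               noise_sd = 0.15, seed = 1L) {
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("`n_classes` must be >= 2")
  if (length(image_size) != 3L || any(image_size < 1L))
    stop("`image_size` must be a valid (H, W, C) triple")
  if (length(texture_freqs) != n_classes)
    stop("`texture_freqs` needs one frequency per class")
  H <- image_size[1]; W <- image_size[2]; C <- image_size[3]
  N <- n_classes * n_per_class
  y <- rep(seq_len(n_classes), each = n_per_class)
  theta <- (seq_len(n_classes) - 1L) * pi / n_classes  # class orientations
  rowg <- matrix(seq_len(H) / H, H, W)
  colg <- matrix(rep(seq_len(W) / W, each = H), H, W)
  x <- array(0, c(H, W, C, N))
  .with_seed(seed, {
    for (i in seq_len(N)) {
      g <- y[i]
      phase <- stats::runif(1, 0, 2 * pi)
      u <- cos(theta[g]) * colg + sin(theta[g]) * rowg
      base <- 0.5 + 0.5 * sin(2 * pi * texture_freqs[g] * u + phase)
      for (ch in seq_len(C)) {
        img <- base + stats::rnorm(H * W, sd = noise_sd)
        x[, , ch, i] <- pmin(pmax(img, 0), 1)
      }
    }
  })
  list(x = x, y = y, n_classes = n_classes, texture_freqs = texture_freqs,
       noise_sd = noise_sd, seed = seed)
}

#' Generate a synthetic two-class segmentation dataset
#'
#' Random filled ellipses ("skin" foreground) painted on noisy background
#' canvases, with per-channel Gaussian color clusters for foreground and
#' background.  The ground-truth mask equals the painted pixels exactly.
#'
#' @param n_images Number of images (>= 1).
#' @param image_size `c(H, W, 3)`.
#' @param fg_color_mean,fg_color_sd Foreground color cluster (per channel);
#'   the default is a skin-like warm tone.
#' @param bg_color_mean,bg_color_sd Background cluster.
#' @param seed Integer seed.
#' @return List with `x` (`H x W x 3 x N` array in \[0, 1\]) and `masks`
#'   (list of `H x W` integer matrices; 2 = foreground, 1 = background).
#' @export
gen_segmentation <- function(n_images = 40L, image_size = c(32L, 32L, 3L),
                             fg_color_mean = c(0.80, 0.55, 0.45),
                             fg_color_sd = c(0.08, 0.08, 0.08),
                             bg_color_mean = c(0.30, 0.40, 0.55),
                             bg_color_sd = c(0.08, 0.08, 0.08),
                             seed = 1L) {
  n_images <- as.integer(n_images)
  if (n_images < 1L) stop("`n_images` must be >= 1")
  H <- image_size[1]; W <- image_size[2]; C <- image_size[3]
  if (H < 8L || W < 8L) stop("canvas too small for a foreground ellipse")
  x <- array(0, c(H, W, C, n_images))
  masks <- vector("list", n_images)
  rowi <- matrix(seq_len(H), H, W)
  coli <- matrix(rep(seq_len(W), each = H), H, W)
  .with_seed(seed, {
    for (i in seq_len(n_images)) {
      cy <- stats::runif(1, 0.3 * H, 0.7 * H)
      cx <- stats::runif(1, 0.3 * W, 0.7 * W)
      ry <- stats::runif(1, 0.15 * H, 0.3 * H)
      rx <- stats::runif(1, 0.15 * W, 0.3 * W)
      ang <- stats::runif(1, 0, pi)
      dy <- rowi - cy; dx <- coli - cx
      u <- cos(ang) * dx + sin(ang) * dy
      v <- -sin(ang) * dx + cos(ang) * dy
      inside <- (u / rx)^2 + (v / ry)^2 <= 1
      m <- matrix(1L, H, W); m[inside] <- 2L
      for (ch in seq_len(C)) {
        img <- matrix(stats::rnorm(H * W, bg_color_mean[ch], bg_color_sd[ch]),
                      H, W)
        img[inside] <- stats::rnorm(sum(inside), fg_color_mean[ch],
                                    fg_color_sd[ch])
        x[, , ch, i] <- pmin(pmax(img, 0), 1)
      }
      masks[[i]] <- m
    }
  })
  list(x = x, masks = masks, seed = seed)
}

#' Build a tiny CNN with named activation slots
#'
#' A small conv/activation/pool stack ending in a dense softmax head
#' (classification) or a mirrored encoder-decoder with a per-pixel softmax
#' (segmentation), with exactly `n_act_layers` activation slots (ReLU by
#' default).  It is the desk-scale stand-in backbone: small enough to
#' train in seconds on the synthetic tasks, while exposing the same
#' replaceable activation slots a full-scale backbone would.
#'
#' @param n_classes Number of output classes.
#' @param n_act_layers Number of activation slots (>= 1).
#' @param seed Integer seed for the weight initialization (He normal).
#' @param input_size `c(H, W, C)` of the inputs.
#' @param n_filters Convolution width (filters per conv layer).
#' @param task `"classify"` or `"segment"`.
#' @return A [model_graph()].
#' @export
tiny_cnn <- function(n_classes, n_act_layers = 2L, seed = 1L,
                     input_size = c(32L, 32L, 3L), n_filters = 8L,
                     task = c("classify", "segment")) {
  task <- match.arg(task)
  n_act_layers <- as.integer(n_act_layers)
  if (n_act_layers < 1L) stop("`n_act_layers` must be >= 1")
  H <- input_size[1]; W <- input_size[2]; C <- input_size[3]
  relu <- activation_spec("ReLU")
  .with_seed(seed, {
    layers <- list()
    cin <- C; h <- H; w <- W
    if (task == "classify") {
      for (i in seq_len(n_act_layers)) {
        layers <- c(layers, list(.layer_conv(3L, 3L, cin, n_filters)))
        layers <- c(layers, list(.layer_act(relu, n_filters)))
        cin <- n_filters
        if (h %% 2L == 0L && w %% 2L == 0L && min(h, w) >= 8L) {
          layers <- c(layers, list(list(kind = "pool")))
          h <- h %/% 2L; w <- w %/% 2L
        }
      }
      layers <- c(layers,
                  list(list(kind = "flatten")),
                  list(.layer_dense(h * w * cin, n_classes)),
                  list(list(kind = "softmax")))
    } else {
      pooled <- FALSE
      for (i in seq_len(n_act_layers)) {
        layers <- c(layers, list(.layer_conv(3L, 3L, cin, n_filters)))
        layers <- c(layers, list(.layer_act(relu, n_filters)))
        cin <- n_filters
        if (!pooled && n_act_layers > 1L && h %% 2L == 0L && w %% 2L == 0L) {
          layers <- c(layers, list(list(kind = "pool")))
          h <- h %/% 2L; w <- w %/% 2L; pooled <- TRUE
        }
      }
      if (pooled) layers <- c(layers, list(list(kind = "upsample")))
      layers <- c(layers,
                  list(.layer_conv(1L, 1L, cin, n_classes, pad = 0L)),
                  list(list(kind = "pixel_softmax")))
    }
    model_graph(layers, input_size, n_classes, task)
  })
}

#' Run the desk-scale benchmark once
#'
#' The toy-scale analogue of the full comparison: generate the synthetic
#' classification task, train a single all-ReLU [tiny_cnn()] and an
#' ensemble of `n_members` stochastically replaced variants of the same
#' base (each member fine-tuned identically), fuse the ensemble by the sum
#' rule, and report test accuracy for both.  The default problem size
#' (3 classes x 60 images at 32 x 32 x 3, 2:1 stratified train/test split,
#' 5 members, 6 epochs of SGD at rate 0.05) keeps one run under a minute
#' on one CPU.  The default noise level 0.35 places the single baseline
#' clearly below ceiling while leaving the task learnable, so the
#' single-vs-ensemble comparison is informative rather than a tie at 100%.
#'
#' @param seed Integer seed driving data generation, splits, member
#'   assignment and training shuffles.
#' @param n_classes,n_per_class,image_size,noise_sd Passed to
#'   [gen_classification()].
#' @param n_members Ensemble size.
#' @param epochs,learning_rate,batch_size Training overrides for the tiny
#'   network.
#' @param pool Activation pool (default [default_pool()]).
#' @return List with `acc_single` (all-ReLU model), `acc_ensemble`
#'   (sum-rule fusion), `acc_members` (individual member accuracies) and
#'   the manifests of the ensemble members.
#' @export
desk_bench <- function(seed = 1L, n_classes = 3L, n_per_class = 60L,
                       image_size = c(32L, 32L, 3L), noise_sd = 0.35,
                       n_members = 5L, epochs = 6L, learning_rate = 0.05,
                       batch_size = 32L, pool = default_pool()) {
  ds <- gen_classification(n_classes, n_per_class, image_size,
                           noise_sd = noise_sd, seed = seed)
  N <- length(ds$y)
  test_idx <- .with_seed(seed + 1L, {
    unlist(lapply(split(seq_len(N), ds$y), function(idx)
      sample(idx, max(1L, round(length(idx) / 3)))))
  })
  tr <- list(x = ds$x[, , , -test_idx, drop = FALSE], y = ds$y[-test_idx])
  te <- list(x = ds$x[, , , test_idx, drop = FALSE], y = ds$y[test_idx])

  cfg <- train_config("classify", batch_size = batch_size,
                      learning_rate = learning_rate, max_epochs = epochs,
                      augmentation = FALSE)
  base <- tiny_cnn(n_classes, n_act_layers = 2L, seed = seed,
                   input_size = image_size)
  trainer <- function(model, sd) train_model(model, tr, cfg, seed = sd)

  single <- trainer(base, seed + 2L)
  acc_single <- accuracy(predict_classes(single, te$x)$decision, te$y)

  ens <- create_ensemble(base, pool, n_members, seed + 3L, trainer)
  fused <- predict_ensemble(ens, te$x, "classify")
  acc_ensemble <- accuracy(fused$decision, te$y)
  acc_members <- vapply(ens$members, function(m)
    accuracy(predict_classes(m, te$x)$decision, te$y), numeric(1))

  list(acc_single = acc_single, acc_ensemble = acc_ensemble,
       acc_members = acc_members, manifests = ens$manifests,
       n_train = length(tr$y), n_test = length(te$y))
}

#' Write a synthetic dataset to disk
#'
#' Writes a classification set as one PNG directory per class plus a
#' `labels.csv`, or a segmentation set as parallel `images/` and `masks/`
#' directories with matching filenames (masks as single-channel label
#' PNGs), the layouts the command-line interface consumes.
#'
#' @param dataset Result of [gen_classification()] or
#'   [gen_segmentation()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  N <- dim(dataset$x)[4]
  if (!is.null(dataset$y)) {
    for (g in unique(dataset$y))
      dir.create(file.path(dir, paste0("class", g)), showWarnings = FALSE)
    files <- character(N)
    for (i in seq_len(N)) {
      files[i] <- file.path(paste0("class", dataset$y[i]),
                            sprintf("img%04d.png", i))
      png::writePNG(aperm(dataset$x[, , , i], c(1, 2, 3)),
                    file.path(dir, files[i]))
    }
    utils::write.csv(data.frame(file = files, label = dataset$y),
                     file.path(dir, "labels.csv"), row.names = FALSE)
  } else {
    dir.create(file.path(dir, "images"), showWarnings = FALSE)
    dir.create(file.path(dir, "masks"), showWarnings = FALSE)
    for (i in seq_len(N)) {
      fn <- sprintf("img%04d.png", i)
      png::writePNG(dataset$x[, , , i], file.path(dir, "images", fn))
      png::writePNG((dataset$masks[[i]] - 1L) / 255,
                    file.path(dir, "masks", fn))
    }
  }
  invisible(dir)
}
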