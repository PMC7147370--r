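# Training contract, augmentation recipe and resize conventions.

#' Training configuration
#'
#' Defaults reproduce the published fine-tuning settings: batch size 32 for
#' both tasks; learning rate 1e-4 (classification) or 1e-3 (segmentation);
#' 30 epochs (classification) or 50 (segmentation, with augmentation active
#' for the first 30); augmentation on; class weighting for segmentation;
#' 224 x 224 network input.  The optimizer is stochastic gradient descent
#' with momentum 0.9 and the loss is (pixel-wise, class-weighted)
#' cross-entropy; neither is pinned down by the published table, so both
#' are configurable.  Every field can be overridden, which the desk-scale
#' experiments do (small random-initialized networks want a larger rate and
#' far fewer epochs than a 224 x 224 fine-tuning run).
#'
#' @param task `"classify"` or `"segment"`.
#' @param batch_size Minibatch size.
#' @param learning_rate SGD learning rate.
#' @param max_epochs Training epochs.
#' @param momentum SGD momentum.
#' @param augmentation Apply [augment()] to each training batch.
#' @param augment_epochs Number of initial epochs with augmentation active
#'   (defaults to 30 for segmentation, all epochs for classification).
#' @param class_weighting Inverse-frequency class weights in the pixel-wise
#'   loss (segmentation only).
#' @param grad_clip Clip the global gradient norm of each minibatch to this
#'   value before the update (default 5).  Learnable activation parameters
#'   are shared across all pixels of a channel, so their raw gradients can
#'   be orders of magnitude larger than weight gradients; clipping keeps a
#'   single learning rate workable for every member of a stochastic pool.
#'   Set to `Inf` to disable.
#' @param input_size Spatial input size of the full-scale models.
#' @return A list of class `train_config`.
#' @export
train_config <- function(task = c("classify", "segment"),
                         batch_size = 32L,
                         learning_rate = if (task == "classify") 1e-4 else 1e-3,
                         max_epochs = if (task == "classify") 30L else 50L,
                         momentum = 0.9,
                         augmentation = TRUE,
                         augment_epochs = if (task == "classify") max_epochs
                                          else 30L,
                         class_weighting = task == "segment",
                         grad_clip = 5,
                         input_size = c(224L, 224L)) {
  task <- match.arg(task)
  structure(list(task = task, batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), momentum = momentum,
                 augmentation = isTRUE(augmentation),
                 augment_epochs = as.integer(augment_epochs),
                 class_weighting = isTRUE(class_weighting),
                 grad_clip = grad_clip,
                 input_size = as.integer(input_size)),
            class = "train_config")
}

# ---- resizing ---------------------------------------------------------------

.resize_bilinear <- function(x, h, w) {
  d <- dim(x)
  if (d[1] == h && d[2] == w) return(x)
  # EBImage indexes (x, y) = (dim1, dim2); our arrays are H x W (x C)
  unclass(EBImage::resize(x, w = h, h = w, filter = "bilinear"))
}

.resize_nearest <- function(x, h, w) {
  d <- dim(x)
  if (is.null(d)) stop("mask must be a matrix")
  if (d[1] == h && d[2] == w) return(x)
  y <- unclass(EBImage::resize(x, w = h, h = w, filter = "none"))
  if (is.integer(x)) storage.mode(y) <- "integer"
  y
}

#' Resize an image to the model input size
#'
#' Bilinear resize to `size` (default 224 x 224, the convention all
#' full-scale models share); an input already at the target size is
#' returned unchanged.  Masks travel the other way with
#' `resize_mask_back()`, nearest-neighbor so labels stay integral; on an
#' already-matching size it is the identity.
#'
#' @param image `H x W (x C)` numeric array.
#' @param size Target `c(H, W)`.
#' @return The resized image.
#' @export
resize_for_model <- function(image, size = c(224L, 224L)) {
  if (any(size < 1L)) stop("target size must be positive")
  d <- dim(image)
  if (is.null(d) || length(image) == 0L) stop("image must be a nonempty array")
  .resize_bilinear(image, size[1], size[2])
}

#' @rdname resize_for_model
#' @param mask Integer label matrix.
#' @param original_size Target `c(H, W)` (the pre-resize image size).
#' @export
resize_mask_back <- function(mask, original_size) {
  if (any(original_size < 1L)) stop("target size must be positive")
  .resize_nearest(mask, original_size[1], original_size[2])
}

# ---- augmentation -----------------------------------------------------------

#' Augment a training image (and optionally its mask)
#'
#' The augmentation recipe: reflect horizontally with probability 1/2,
#' reflect vertically with probability 1/2, then rescale the two axes by
#' independent factors drawn uniformly from \[1, 2\] (bilinear for the
#' image) and center-crop back to the original shape.  A mask passed
#' alongside receives the identical draws, with nearest-neighbor
#' interpolation so its labels stay integral and pixel-aligned with the
#' image.  Draws come from the current RNG, so results are deterministic
#' under `set.seed()`; the draws can also be pinned via the explicit
#' arguments (e.g. `sx = sy = 1` with no flips is the identity).
#'
#' @param image `H x W x C` numeric array (nonempty).
#' @param mask Optional integer label matrix `H x W`.
#' @param hflip,vflip Logical; flip draws (default: random).
#' @param sx,sy Axis rescale factors in \[1, 2\] (default: random).
#' @return The augmented image, or `list(image, mask)` when a mask is
#'   given; shapes equal the input shapes.
#' @export
augment <- function(image, mask = NULL, hflip = NULL, vflip = NULL,
                    sx = NULL, sy = NULL) {
  d <- dim(image)
  if (is.null(d) || length(image) == 0L) stop("image must be a nonempty array")
  if (length(d) == 2L) { dim(image) <- c(d, 1L); d <- dim(image) }
  if (is.null(hflip)) hflip <- stats::runif(1) < 0.5
  if (is.null(vflip)) vflip <- stats::runif(1) < 0.5
  if (is.null(sx)) sx <- stats::runif(1, 1, 2)
  if (is.null(sy)) sy <- stats::runif(1, 1, 2)

  if (hflip) image <- image[, rev(seq_len(d[2])), , drop = FALSE]
  if (vflip) image <- image[rev(seq_len(d[1])), , , drop = FALSE]
  nh <- max(d[1], round(d[1] * sy)); nw <- max(d[2], round(d[2] * sx))
  out <- .resize_bilinear(image, nh, nw)
  r0 <- (nh - d[1]) %/% 2L; c0 <- (nw - d[2]) %/% 2L
  out <- out[r0 + seq_len(d[1]), c0 + seq_len(d[2]), , drop = FALSE]

  if (is.null(mask)) return(out)
  if (hflip) mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  if (vflip) mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
  mk <- .resize_nearest(mask, nh, nw)
  mk <- mk[r0 + seq_len(d[1]), c0 + seq_len(d[2]), drop = FALSE]
  list(image = out, mask = mk)
}

# ---- training ---------------------------------------------------------------

# Trainable parameter names per layer kind.
.layer_params <- function(layer) {
  switch(layer$kind,
    conv = , dense = list(holder = layer, names = c("W", "b")),
    act = list(holder = layer$state, names = names(layer$state)),
    list(holder = NULL, names = character())
  )
}

.get_param <- function(model, i, nm) {
  if (model$layers[[i]]$kind == "act") model$layers[[i]]$state[[nm]]
  else model$layers[[i]][[nm]]
}

.set_param <- function(model, i, nm, value) {
  if (model$layers[[i]]$kind == "act") model$layers[[i]]$state[[nm]] <- value
  else model$layers[[i]][[nm]] <- value
  model
}

#' Train a model by minibatch gradient descent
#'
#' Stochastic gradient descent with momentum on the (class-weighted,
#' pixel-wise for segmentation) cross-entropy loss.  Learnable activation
#' parameters train alongside the weights; when an APLU layer is present
#' its `l2_penalty * sum(a^2)` term joins the loss.  With
#' `config$augmentation` the recipe of [augment()] is applied to every
#' training image during the configured epochs.  Training is deterministic
#' for a fixed `(data, config, seed)`.
#'
#' @param model A [model_graph()].
#' @param data For classification, `list(x = H x W x C x N array,
#'   y = integer labels in 1..n_classes)`; for segmentation,
#'   `list(x = array, masks = list of H x W integer matrices in
#'   1..n_classes)`.
#' @param config A [train_config()].
#' @param seed Integer seed controlling shuffling and augmentation draws.
#' @return The trained `model_graph`, with a numeric `loss_history`
#'   attribute (mean loss per epoch).
#' @export
train_model <- function(model, data, config, seed = 1L) {
  stopifnot(inherits(model, "model_graph"), inherits(config, "train_config"))
  x <- .as_batch(data$x)
  N <- dim(x)[4]
  if (N == 0L) stop("dataset is empty")
  seg <- model$task == "segment"
  if (seg) {
    if (is.null(data$masks) || length(data$masks) != N)
      stop("segmentation data needs one mask per image")
    labs <- unlist(lapply(data$masks, as.vector))
  } else {
    if (is.null(data$y) || length(data$y) != N)
      stop("classification data needs one label per image")
    labs <- data$y
  }
  if (any(labs < 1L) || any(labs > model$n_classes))
    stop("labels out of range 1..", model$n_classes)
  if (config$max_epochs == 0L) return(model)

  cw <- rep(1, model$n_classes)
  if (seg && config$class_weighting) {
    freq <- tabulate(labs, model$n_classes)
    cw <- ifelse(freq > 0, sum(freq) / (model$n_classes * freq), 0)
  }

  vel <- lapply(model$layers, function(ly) {
    p <- .layer_params(ly)
    stats::setNames(lapply(p$names, function(nm) {
      v <- p$holder[[nm]]; v[] <- 0; v
    }), p$names)
  })

  history <- numeric(config$max_epochs)
  .with_seed(seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(N)
      ep_loss <- 0; n_batches <- 0L
      for (start in seq(1L, N, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, N)]
        xb <- x[, , , idx, drop = FALSE]
        mb <- if (seg) data$masks[idx] else NULL
        yb <- if (!seg) data$y[idx] else NULL
        if (config$augmentation && epoch <= config$augment_epochs) {
          for (j in seq_along(idx)) {
            if (seg) {
              am <- augment(xb[, , , j], mb[[j]])
              xb[, , , j] <- am$image; mb[[j]] <- am$mask
            } else xb[, , , j] <- augment(xb[, , , j])
          }
        }
        fw <- .model_forward(model, xb, cache = TRUE)
        if (seg) {
          lt <- .seg_loss_grad(fw$y, mb, cw)
        } else {
          lt <- .cls_loss_grad(fw$y, yb)
        }
        grads <- .model_backward(model, fw$caches, lt$grad)
        loss <- lt$loss
        # APLU penalty, then global-norm clipping, then the update
        sqsum <- 0
        for (i in seq_along(model$layers)) {
          g <- grads[[i]]
          if (is.null(g) || !length(g)) next
          ly <- model$layers[[i]]
          if (ly$kind == "act" && ly$spec$name == "APLU") {
            pen <- ly$spec$l2_penalty
            g$a <- g$a + 2 * pen * ly$state$a
            loss <- loss + pen * sum(ly$state$a^2)
            grads[[i]] <- g
          }
          for (nm in names(g)) sqsum <- sqsum + sum(g[[nm]]^2)
        }
        scale <- if (is.finite(config$grad_clip) &&
                     sqrt(sqsum) > config$grad_clip)
          config$grad_clip / sqrt(sqsum) else 1
        for (i in seq_along(model$layers)) {
          g <- grads[[i]]
          if (is.null(g) || !length(g)) next
          for (nm in names(g)) {
            g[[nm]] <- g[[nm]] * scale
            v <- config$momentum * vel[[i]][[nm]] - config$learning_rate * g[[nm]]
            vel[[i]][[nm]] <- v
            model <- .set_param(model, i, nm, .get_param(model, i, nm) + v)
          }
        }
        ep_loss <- ep_loss + loss; n_batches <- n_batches + 1L
      }
      history[epoch] <- ep_loss / n_batches
    }
  })
  attr(model, "loss_history") <- history
  model
}

# Cross-entropy loss and softmax-input gradient for classification.
# p: K x N post-softmax matrix, y: labels 1..K.
.cls_loss_grad <- function(p, y) {
  N <- ncol(p)
  picked <- p[cbind(y, seq_len(N))]
  one <- matrix(0, nrow(p), N)
  one[cbind(y, seq_len(N))] <- 1
  list(loss = -mean(log(pmax(picked, 1e-12))), grad = (p - one) / N)
}

# Weighted pixel-wise cross-entropy for segmentation.
# p: H x W x K x N post-softmax array, masks: list of H x W label matrices.
.seg_loss_grad <- function(p, masks, cw) {
  d <- dim(p)
  grad <- array(0, d)
  loss <- 0; denom <- d[1] * d[2] * d[4]
  for (n in seq_len(d[4])) {
    m <- masks[[n]]
    one <- array(0, d[1:3])
    idx <- cbind(as.vector(row(m)), as.vector(col(m)), as.vector(m))
    one[idx] <- 1
    w <- matrix(cw[m], d[1], d[2])
    pn <- p[, , , n, drop = TRUE]
    if (length(d[1:3]) == 3L) dim(pn) <- d[1:3]
    picked <- pn[idx]
    loss <- loss - sum(w * log(pmax(picked, 1e-12)))
    warr <- array(rep(w, d[3]), d[1:3])
    grad[, , , n] <- warr * (pn - one)
  }
  list(loss = loss / denom, grad = grad / denom)
}
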