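# A minimal convolutional-network container with explicit forward and
# backward passes, sized for desk-scale experiments.  Layers are plain
# lists; activation layers carry an activation_spec plus an
# activation_state and are the replaceable slots the surgery module
# operates on.  Batches are H x W x C x N arrays (single images are
# promoted to N = 1).

.as_batch <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("images must be arrays")
  if (length(d) == 3L) { dim(x) <- c(d, 1L); d <- dim(x) }
  if (length(d) != 4L) stop("expected an H x W x C (x N) array")
  x
}

.layer_conv <- function(kh, kw, cin, cout, pad = 1L) {
  fan_in <- kh * kw * cin
  W <- array(stats::rnorm(fan_in * cout, sd = sqrt(2 / fan_in)),
             dim = c(kh, kw, cin, cout))
  list(kind = "conv", W = W, b = numeric(cout), pad = as.integer(pad))
}

.layer_act <- function(spec, channels) {
  list(kind = "act", spec = spec,
       state = activation_state(spec, channels), channels = channels)
}

.layer_dense <- function(n_in, n_out) {
  list(kind = "dense",
       W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_out, n_in),
       b = numeric(n_out))
}

#' Construct a model graph
#'
#' Wraps an ordered layer list into a `model_graph`.  Users normally build
#' models with [tiny_cnn()]; this constructor is exposed for custom
#' architectures and for attaching externally defined backbones expressed
#' in the same layer vocabulary (`conv`, `act`, `pool`, `upsample`,
#' `flatten`, `dense`, `softmax`, `pixel_softmax`).
#'
#' @param layers List of layer descriptors.
#' @param input_size Integer `c(H, W, C)` the model expects.
#' @param n_classes Number of output classes.
#' @param task `"classify"` (softmax over a dense head) or `"segment"`
#'   (per-pixel softmax over a 1x1 conv head).
#' @return An object of class `model_graph`.
#' @export
model_graph <- function(layers, input_size, n_classes,
                        task = c("classify", "segment")) {
  task <- match.arg(task)
  structure(list(layers = layers, input_size = as.integer(input_size),
                 n_classes = as.integer(n_classes), task = task),
            class = "model_graph")
}

#' @export
print.model_graph <- function(x, ...) {
  kinds <- vapply(x$layers, `[[`, "", "kind")
  acts <- which(kinds == "act")
  cat("<model_graph> task =", x$task, " input =",
      paste(x$input_size, collapse = "x"),
      " classes =", x$n_classes, "\n  layers:",
      paste(kinds, collapse = " -> "), "\n")
  if (length(acts)) {
    nm <- vapply(acts, function(i) x$layers[[i]]$spec$name, "")
    cat("  activation slots:", paste0(acts, ":", nm, collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- conv via im2col --------------------------------------------------------

# Index matrix mapping each (output position, kernel element) pair to an
# offset into the zero-padded image, column order matching the flattened
# kernel array (kh fastest, then kw, then input channel).
.im2col_idx <- function(H, W, C, kh, kw, pad) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- Hp - kh + 1L; Wo <- Wp - kw + 1L
  oi <- rep(seq_len(Ho), times = Wo)           # output row, fastest
  oj <- rep(seq_len(Wo), each = Ho)
  base <- oi + (oj - 1L) * Hp                  # top-left of each patch
  koff <- as.vector(outer(seq_len(kh) - 1L, (seq_len(kw) - 1L) * Hp, `+`))
  koff <- as.vector(outer(koff, (seq_len(C) - 1L) * Hp * Wp, `+`))
  list(idx = outer(base, koff, `+`), Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
}

.pad_batch <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3], d[4]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), , ] <- x
  xp
}

.conv_forward <- function(layer, x) {
  d <- dim(x); kd <- dim(layer$W)
  if (d[3] != kd[3]) stop("conv layer expects ", kd[3], " input channels")
  ii <- .im2col_idx(d[1], d[2], d[3], kd[1], kd[2], layer$pad)
  xp <- .pad_batch(x, layer$pad)
  S <- ii$Hp * ii$Wp * d[3]
  P <- nrow(ii$idx); K <- ncol(ii$idx); N <- d[4]
  cols <- matrix(0, P * N, K)
  xpf <- as.vector(xp)
  for (n in seq_len(N))
    cols[(n - 1L) * P + seq_len(P), ] <-
      matrix(xpf[ii$idx + (n - 1L) * S], P, K)
  Wm <- matrix(layer$W, K, kd[4])
  out <- cols %*% Wm
  out <- sweep(out, 2L, layer$b, `+`)
  y <- array(aperm(array(out, c(P, N, kd[4])), c(1L, 3L, 2L)),
             c(ii$Ho, ii$Wo, kd[4], N))
  list(y = y, cache = list(cols = cols, ii = ii, dims = d, S = S))
}

.conv_backward <- function(layer, cache, dy) {
  kd <- dim(layer$W); d <- cache$dims; ii <- cache$ii
  P <- nrow(ii$idx); K <- ncol(ii$idx); N <- d[4]
  dout <- matrix(aperm(array(dy, c(P, kd[4], N)), c(1L, 3L, 2L)),
                 P * N, kd[4])
  dW <- array(crossprod(cache$cols, dout), dim = kd)
  db <- colSums(dout)
  dcols <- tcrossprod(dout, matrix(layer$W, K, kd[4]))
  dxp <- matrix(0, cache$S, N)
  gidx <- as.vector(ii$idx)
  for (n in seq_len(N)) {
    g <- rowsum(as.vector(dcols[(n - 1L) * P + seq_len(P), ]), gidx)
    dxp[as.integer(rownames(g)), n] <- g
  }
  dim(dxp) <- c(ii$Hp, ii$Wp, d[3], N)
  pad <- layer$pad
  dx <- dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

# ---- pooling / upsampling ---------------------------------------------------

.pool_forward <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L || d[2] %% 2L) stop("2x2 max pool requires even spatial dims")
  i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
  a <- x[i1, j1, , , drop = FALSE]; b <- x[i2, j1, , , drop = FALSE]
  cc <- x[i1, j2, , , drop = FALSE]; dd <- x[i2, j2, , , drop = FALSE]
  y <- pmax(a, b, cc, dd)
  m1 <- a == y; m2 <- (b == y) & !m1
  m3 <- (cc == y) & !(m1 | m2); m4 <- !(m1 | m2 | m3)
  list(y = y, cache = list(m = list(m1, m2, m3, m4), d = d))
}

.pool_backward <- function(cache, dy) {
  d <- cache$d
  dx <- array(0, d)
  i1 <- seq(1L, d[1], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[2], 2L); j2 <- j1 + 1L
  m <- cache$m
  dx[i1, j1, , ] <- dy * m[[1]]
  dx[i2, j1, , ] <- dy * m[[2]]
  dx[i1, j2, , ] <- dy * m[[3]]
  dx[i2, j2, , ] <- dy * m[[4]]
  dx
}

.upsample_forward <- function(x) {
  d <- dim(x)
  y <- x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
         drop = FALSE]
  list(y = y, cache = d)
}

.upsample_backward <- function(d, dy) {
  i1 <- seq(1L, 2L * d[1], 2L); j1 <- seq(1L, 2L * d[2], 2L)
  dy[i1, j1, , , drop = FALSE] + dy[i1 + 1L, j1, , , drop = FALSE] +
    dy[i1, j1 + 1L, , , drop = FALSE] + dy[i1 + 1L, j1 + 1L, , , drop = FALSE]
}

# ---- softmax heads ----------------------------------------------------------

# Column-wise softmax of a K x N matrix.
.softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), `/`)
}

# Per-pixel softmax over the channel dimension of an H x W x K x N array.
.pixel_softmax <- function(x) {
  d <- dim(x)
  z <- array(x, c(d[1] * d[2], d[3], d[4]))
  mx <- z[, 1L, , drop = FALSE]
  for (k in seq_len(d[3])[-1]) mx <- pmax(mx, z[, k, , drop = FALSE])
  for (k in seq_len(d[3])) z[, k, ] <- exp(z[, k, ] - mx[, 1L, ])
  s <- z[, 1L, ]
  if (d[3] > 1L) for (k in seq_len(d[3])[-1]) s <- s + z[, k, ]
  for (k in seq_len(d[3])) z[, k, ] <- z[, k, ] / s
  array(z, d)
}

# ---- full passes ------------------------------------------------------------

# Forward pass; with cache = TRUE also returns everything backward needs.
.model_forward <- function(model, x, cache = FALSE) {
  x <- .as_batch(x)
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    r <- switch(ly$kind,
      conv = .conv_forward(ly, x),
      act  = list(y = act_forward(ly$spec, ly$state, x), cache = x),
      pool = .pool_forward(x),
      upsample = .upsample_forward(x),
      flatten = list(y = matrix(x, prod(dim(x)[1:3]), dim(x)[4]),
                     cache = dim(x)),
      dense = list(y = sweep(ly$W %*% x, 1L, ly$b, `+`), cache = x),
      softmax = list(y = .softmax_cols(x), cache = NULL),
      pixel_softmax = list(y = .pixel_softmax(x), cache = NULL),
      stop("unknown layer kind: ", ly$kind)
    )
    x <- r$y
    if (cache) caches[[i]] <- r$cache
  }
  if (cache) list(y = x, caches = caches) else x
}

# Backward pass from the gradient at the softmax *input* (cross-entropy
# grads are computed jointly with softmax, so the softmax layer itself is
# skipped).  Returns per-layer parameter gradients.
.model_backward <- function(model, caches, dtop) {
  n <- length(model$layers)
  grads <- vector("list", n)
  dy <- dtop
  for (i in rev(seq_len(n))) {
    ly <- model$layers[[i]]
    if (ly$kind %in% c("softmax", "pixel_softmax")) next
    r <- switch(ly$kind,
      conv = .conv_backward(ly, caches[[i]], dy),
      act  = {
        bk <- act_backward(ly$spec, ly$state, caches[[i]], dy)
        list(dx = bk$d_input, grads = bk$d_params)
      },
      pool = list(dx = .pool_backward(caches[[i]], dy), grads = NULL),
      upsample = list(dx = .upsample_backward(caches[[i]], dy), grads = NULL),
      flatten = { d <- caches[[i]]; dim(dy) <- d; list(dx = dy, grads = NULL) },
      dense = list(dx = crossprod(ly$W, dy),
                   grads = list(W = tcrossprod(dy, caches[[i]]),
                                b = rowSums(dy)))
    )
    grads[i] <- list(r$grads)
    dy <- r$dx
  }
  grads
}

#' Predict class scores or masks from a model
#'
#' `predict_classes()` returns the post-softmax score matrix (one row per
#' sample, columns summing to 1) and the argmax decision.
#' `predict_masks()` returns per-pixel score arrays, one per image.
#'
#' @param model A `model_graph` (task `"classify"` / `"segment"`).
#' @param x Image batch `H x W x C x N` (or a single `H x W x C` array).
#' @return `predict_classes()`: list with `scores` (`N x K` matrix) and
#'   `decision` (integer labels in `1..K`).  `predict_masks()`: list of
#'   `H x W x K` score arrays.
#' @export
predict_classes <- function(model, x) {
  stopifnot(inherits(model, "model_graph"), model$task == "classify")
  p <- t(.model_forward(model, x))
  list(scores = p, decision = max.col(p, ties.method = "first"))
}

#' @rdname predict_classes
#' @export
predict_masks <- function(model, x) {
  stopifnot(inherits(model, "model_graph"), model$task == "segment")
  y <- .model_forward(model, x)
  lapply(seq_len(dim(y)[4]), function(n) y[, , , n, drop = TRUE])
}

#' Save or load a model
#'
#' Models are stored via R serialization (a versioned list of layers,
#' weights and activation assignments); the round trip is bit-exact.
#'
#' @param model A `model_graph`.
#' @param path File path.
#' @return `load_model()` returns the `model_graph`; `save_model()` its
#'   path, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "model_graph"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "model_graph"))
  m
}
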