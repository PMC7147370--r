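# Activation-function catalogue: forward maps, analytic gradients and
# published initializations for ReLU and its nine variants, including the
# Mexican-hat (MeLU/wMeLU) and Gaussian (GaLU/sGaLU) piecewise-linear
# families.

#' Names of the supported activation functions
#'
#' The catalogue contains one static baseline (ReLU), two static variants
#' (Leaky ReLU, ELU) and seven functions with learnable parameters (PReLU,
#' SReLU, APLU, MeLU, wMeLU, GaLU, sGaLU).
#'
#' @return Character vector of the ten activation names.
#' @export
activation_names <- function() {
  c("ReLU", "LeakyReLU", "ELU", "PReLU", "SReLU", "APLU",
    "MeLU", "wMeLU", "GaLU", "sGaLU")
}

# Fixed basis settings for the Mexican-hat / Gaussian families.  alpha are
# the basis centers and lam the half-widths, both in units of max_input.
.basis_table <- function(name) {
  switch(name,
    MeLU  = list(k = 4L, alpha = c(2, 1, 3),                  lam = c(2, 1, 1)),
    wMeLU = list(k = 8L, alpha = c(2, 1, 3, 0.5, 1.5, 2.5, 3.5),
                 lam = c(2, 1, 1, 0.5, 0.5, 0.5, 0.5)),
    GaLU  = list(k = 4L, alpha = c(1, 0.5, 2.5),              lam = c(1, 0.5, 0.5)),
    sGaLU = list(k = 2L, alpha = 1,                           lam = 1),
    list(k = 0L, alpha = numeric(0), lam = numeric(0))
  )
}

#' Define an activation function
#'
#' Builds an immutable specification of one activation function: its name,
#' fixed hyperparameters and (for the MeLU/GaLU families) the fixed basis
#' centers `alpha` and half-widths `lam` in units of `max_input`.
#'
#' `max_input` is a normalization factor matching the input intensity range
#' (1 for inputs in \[0,1\], 255 for \[0,255\]); all basis centers and widths
#' scale with it.  The Leaky ReLU slope defaults to 0.01; 0.1 is also found
#' in the literature and can be set via `leaky_a`.
#'
#' @param name One of [activation_names()].
#' @param max_input Positive normalization factor (1 or 255 in typical use).
#' @param leaky_a Leaky ReLU negative-side slope (default 0.01).
#' @param elu_a ELU scale (default 1).
#' @param n_hinges Number of APLU hinge functions (default 3).
#' @param l2_penalty L2 penalty weight on the APLU hinge slopes, reported to
#'   the training loop (default 0.001).
#' @return An object of class `activation_spec`.
#' @examples
#' sp <- activation_spec("MeLU", max_input = 1)
#' sp$alpha  # c(2, 1, 3)
#' @export
activation_spec <- function(name, max_input = 1, leaky_a = 0.01, elu_a = 1,
                            n_hinges = 3L, l2_penalty = 0.001) {
  name <- match.arg(name, activation_names())
  if (!is.numeric(max_input) || length(max_input) != 1L ||
      !is.finite(max_input) || max_input <= 0)
    stop("`max_input` must be a single positive finite number")
  if (!is.finite(leaky_a) || !is.finite(elu_a))
    stop("`leaky_a` and `elu_a` must be finite")
  n_hinges <- as.integer(n_hinges)
  if (n_hinges < 1L) stop("`n_hinges` must be a positive integer")
  if (l2_penalty < 0) stop("`l2_penalty` must be nonnegative")
  b <- .basis_table(name)
  spec <- list(name = name, max_input = max_input,
               k = b$k, alpha = b$alpha, lam = b$lam,
               leaky_a = leaky_a, elu_a = elu_a,
               n_hinges = n_hinges, l2_penalty = l2_penalty)
  class(spec) <- "activation_spec"
  spec
}

#' @export
`$<-.activation_spec` <- function(x, name, value)
  stop("activation_spec objects are immutable; build a new one")

#' @export
`[[<-.activation_spec` <- function(x, i, value)
  stop("activation_spec objects are immutable; build a new one")

#' @export
print.activation_spec <- function(x, ...) {
  cat("<activation_spec>", x$name, " max_input =", x$max_input, "\n")
  if (x$k > 0L) {
    cat("  k =", x$k, " alpha = [", paste(x$alpha, collapse = ", "),
        "]  lam = [", paste(x$lam, collapse = ", "), "]\n")
  }
  invisible(x)
}

#' Initialize the learnable parameters of an activation
#'
#' Returns the per-layer learnable state at its published initialization:
#' all coefficients zero (PReLU slope, MeLU/GaLU `c` vector, APLU hinge
#' slopes), SReLU knots `(al, tl, ar, tr) = (0, 0, 1, max_input)`, and APLU
#' hinge positions drawn uniformly on `[0, max_input]` from the current RNG.
#' At this initialization every learnable function in the catalogue equals
#' plain ReLU pointwise.
#'
#' @param spec An [activation_spec()].
#' @param n_channels Number of input channels the layer acts on; learnable
#'   coefficients are per channel (SReLU knots are per layer).
#' @return An object of class `activation_state` (an empty one for the
#'   static functions ReLU, LeakyReLU, ELU).
#' @export
activation_state <- function(spec, n_channels = 1L) {
  stopifnot(inherits(spec, "activation_spec"))
  n_channels <- as.integer(n_channels)
  if (n_channels < 1L) stop("`n_channels` must be >= 1")
  st <- switch(spec$name,
    PReLU = list(a = rep(0, n_channels)),
    SReLU = list(al = 0, tl = 0, ar = 1, tr = spec$max_input),
    APLU  = list(a = matrix(0, n_channels, spec$n_hinges),
                 b = matrix(stats::runif(n_channels * spec$n_hinges,
                                         0, spec$max_input),
                            n_channels, spec$n_hinges)),
    MeLU  = , wMeLU = , GaLU = , sGaLU =
      list(c = matrix(0, n_channels, spec$k)),
    list()
  )
  structure(st, class = "activation_state", n_channels = n_channels,
            name = spec$name)
}

# ---- elementwise helpers ----------------------------------------------------

.check_finite <- function(x, what = "x") {
  if (!is.numeric(x)) stop("`", what, "` must be numeric")
  if (anyNA(x) || any(!is.finite(x)))
    stop("non-finite values in `", what, "`")
  invisible(x)
}

# Expand a per-channel parameter vector to the shape of x.  x may be a plain
# vector (single channel), an H x W x C array, or an H x W x C x N batch.
.expand_chan <- function(p, x) {
  if (length(p) == 1L) return(p)
  d <- dim(x)
  if (is.null(d) || length(d) < 3L || d[3L] != length(p))
    stop("per-channel parameter of length ", length(p),
         " does not match the input's channel dimension")
  n_rest <- length(x) / (d[1L] * d[2L] * d[3L])
  array(rep(rep(p, each = d[1L] * d[2L]), times = n_rest), dim = d)
}

# Sum an elementwise gradient over everything but the channel dimension.
.chan_sum <- function(g, n_channels) {
  if (n_channels == 1L) return(sum(g))
  d <- dim(g)
  hw <- d[1L] * d[2L]
  dim(g) <- c(hw, n_channels, length(g) / (hw * n_channels))
  rowSums(colSums(g))
}

.keepdim <- function(y, x) { dim(y) <- dim(x); y }

# ---- static functions -------------------------------------------------------

#' Rectified linear unit
#'
#' `act_relu(x)` is `max(x, 0)` elementwise; `act_relu_grad(x)` is its
#' derivative, 0 for `x < 0` and 1 for `x >= 0`.
#'
#' @param x Numeric vector or array of pre-activations (finite).
#' @return Same shape as `x`.
#' @examples
#' act_relu(c(-1, 2))       # 0 2
#' act_relu_grad(c(-3, 1))  # 0 1
#' @export
act_relu <- function(x) {
  .check_finite(x)
  .keepdim(pmax(x, 0), x)
}

#' @rdname act_relu
#' @export
act_relu_grad <- function(x) {
  .check_finite(x)
  .keepdim(as.numeric(x >= 0), x)
}

#' Leaky rectified linear unit
#'
#' `a * x` for `x < 0`, `x` otherwise; the gradient is `a` on the negative
#' side and 1 on the nonnegative side, so it is positive everywhere.
#'
#' @inheritParams act_relu
#' @param a Negative-side slope (default 0.01).
#' @return Same shape as `x`.
#' @export
act_leaky_relu <- function(x, a = 0.01) {
  .check_finite(x)
  if (!is.finite(a)) stop("`a` must be finite")
  .keepdim(pmax(x, 0) + a * pmin(x, 0), x)
}

#' @rdname act_leaky_relu
#' @export
act_leaky_relu_grad <- function(x, a = 0.01) {
  .check_finite(x)
  .keepdim((x >= 0) + a * (x < 0), x)
}

#' Exponential linear unit
#'
#' `a * (exp(x) - 1)` for `x < 0`, `x` otherwise; gradient `a * exp(x)` on
#' the negative side, 1 on the nonnegative side.
#'
#' @inheritParams act_relu
#' @param a Scale of the saturating branch (default 1).
#' @return Same shape as `x`.
#' @export
act_elu <- function(x, a = 1) {
  .check_finite(x)
  if (!is.finite(a)) stop("`a` must be finite")
  y <- x
  neg <- x < 0
  y[neg] <- a * (exp(x[neg]) - 1)
  y
}

#' @rdname act_elu
#' @export
act_elu_grad <- function(x, a = 1) {
  .check_finite(x)
  d <- .keepdim(rep(1, length(x)), x)
  neg <- x < 0
  d[neg] <- a * exp(x[neg])
  d
}

# ---- learnable functions ----------------------------------------------------

#' Parametric rectified linear unit
#'
#' `a_c * x` for `x < 0`, `x` otherwise, with one learned slope `a_c` per
#' input channel.  `act_prelu_grad()` returns the elementwise partials:
#' `d_input` (`a_c` on the negative side, 1 otherwise) and `d_a`
#' (`x` on the negative side, 0 otherwise).
#'
#' @inheritParams act_relu
#' @param a_c Learned slope(s): a scalar, or one value per channel when `x`
#'   is an array whose third dimension indexes channels.
#' @return `act_prelu()`: same shape as `x`.  `act_prelu_grad()`: list with
#'   elementwise `d_input` and `d_a`.
#' @export
act_prelu <- function(x, a_c) {
  .check_finite(x)
  A <- .expand_chan(a_c, x)
  .keepdim(pmax(x, 0) + A * pmin(x, 0), x)
}

#' @rdname act_prelu
#' @export
act_prelu_grad <- function(x, a_c) {
  .check_finite(x)
  A <- .expand_chan(a_c, x)
  list(d_input = .keepdim((x >= 0) + A * (x < 0), x),
       d_a     = .keepdim(pmin(x, 0), x))
}

#' S-shaped rectified linear unit
#'
#' Piecewise linear with four learnable knots per layer: below `tl` the line
#' `tl + al (x - tl)`, identity between `tl` and `tr`, above `tr` the line
#' `tr + ar (x - tr)`.  At the published initialization
#' `(al, tl, ar, tr) = (0, 0, 1, max_input)` it equals ReLU.
#'
#' The elementwise parameter partials follow from differentiating the
#' defining lines: `d/d al = x - tl` and `d/d tl = 1 - al` on `x < tl`,
#' mirrored as `d/d ar = x - tr` and `d/d tr = 1 - ar` on `x > tr`, zero
#' elsewhere.
#'
#' @inheritParams act_relu
#' @param knots Numeric `c(al, tl, ar, tr)` (or a list with those names);
#'   requires `tl <= tr`.
#' @return `act_srelu()`: same shape as `x`.  `act_srelu_grad()`: list with
#'   `d_input`, `d_al`, `d_tl`, `d_ar`, `d_tr` (elementwise).
#' @export
act_srelu <- function(x, knots) {
  .check_finite(x)
  kn <- .srelu_knots(knots)
  y <- x
  l <- x < kn$tl; r <- x > kn$tr
  y[l] <- kn$tl + kn$al * (x[l] - kn$tl)
  y[r] <- kn$tr + kn$ar * (x[r] - kn$tr)
  y
}

.srelu_knots <- function(knots) {
  if (is.list(knots)) knots <- unlist(knots[c("al", "tl", "ar", "tr")])
  if (length(knots) != 4L || anyNA(knots))
    stop("`knots` must supply (al, tl, ar, tr)")
  kn <- list(al = knots[[1]], tl = knots[[2]], ar = knots[[3]], tr = knots[[4]])
  if (kn$tl > kn$tr) stop("SReLU requires tl <= tr")
  kn
}

#' @rdname act_srelu
#' @export
act_srelu_grad <- function(x, knots) {
  .check_finite(x)
  kn <- .srelu_knots(knots)
  l <- x < kn$tl; r <- x > kn$tr
  d <- .keepdim(rep(1, length(x)), x)
  d[l] <- kn$al; d[r] <- kn$ar
  z <- .keepdim(rep(0, length(x)), x)
  d_al <- z; d_al[l] <- x[l] - kn$tl
  d_tl <- z; d_tl[l] <- 1 - kn$al
  d_ar <- z; d_ar[r] <- x[r] - kn$tr
  d_tr <- z; d_tr[r] <- 1 - kn$ar
  list(d_input = d, d_al = d_al, d_tl = d_tl, d_ar = d_ar, d_tr = d_tr)
}

#' Adaptive piecewise linear unit
#'
#' `ReLU(x) + sum_c a_c * max(0, -x + b_c)` with learnable hinge slopes
#' `a_c` and positions `b_c`.  The hinge is the max form, the one
#' consistent with the published slope gradient (`d/d a_c = -x + b_c`,
#' active on `x < b_c`) and with the original APLU.  The position partial
#' follows by differentiating that same hinge: `d/d b_c = a_c` on
#' `x < b_c`, zero elsewhere.
#'
#' During training an L2 penalty `l2_penalty * sum(a^2)` is added to the
#' loss; it is not part of the forward value.
#'
#' @inheritParams act_relu
#' @param a,b Hinge slopes and positions.  For a single channel, numeric
#'   vectors of equal length (one entry per hinge); for multi-channel input,
#'   `channels x hinges` matrices.
#' @return `act_aplu()`: same shape as `x`.  `act_aplu_grad()`: list with
#'   `d_input` plus elementwise `d_a` and `d_b`, one slice per hinge.
#' @export
act_aplu <- function(x, a, b) {
  .check_finite(x)
  ab <- .aplu_ab(a, b)
  y <- pmax(x, 0)
  for (h in seq_len(ncol(ab$a))) {
    A <- .expand_chan(ab$a[, h], x)
    B <- .expand_chan(ab$b[, h], x)
    y <- y + A * pmax(0, -x + B)
  }
  .keepdim(y, x)
}

.aplu_ab <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1L)
  if (is.null(dim(b))) b <- matrix(b, nrow = 1L)
  if (!identical(dim(a), dim(b)))
    stop("APLU `a` and `b` must have matching length/shape")
  list(a = a, b = b)
}

#' @rdname act_aplu
#' @export
act_aplu_grad <- function(x, a, b) {
  .check_finite(x)
  ab <- .aplu_ab(a, b)
  nh <- ncol(ab$a)
  d <- .keepdim(as.numeric(x >= 0), x)
  d_a <- vector("list", nh); d_b <- vector("list", nh)
  for (h in seq_len(nh)) {
    A <- .expand_chan(ab$a[, h], x)
    B <- .expand_chan(ab$b[, h], x)
    act <- x < B
    d <- d - A * act
    d_a[[h]] <- .keepdim(pmax(0, -x + B), x)
    d_b[[h]] <- .keepdim(A * act, x)
  }
  list(d_input = d, d_a = d_a, d_b = d_b)
}

# ---- basis functions and their families ------------------------------------

#' Mexican-hat basis function
#'
#' The triangular bump `max(lam * M - |x - a * M|, 0)` with `M = max_input`:
#' continuous, piecewise linear, nonnegative, supported on
#' `[(a - lam) M, (a + lam) M]` with peak value `lam * M` at `a * M`.
#'
#' @inheritParams act_relu
#' @param a Center, in units of `max_input`.
#' @param lam Half-width, in units of `max_input`; must be positive.
#' @param max_input Normalization factor `M > 0`.
#' @return Same shape as `x`; `mexican_hat_grad()` returns the derivative in
#'   `x` (+1 on the rising edge, -1 on the falling edge, 0 outside; at a
#'   kink the right-hand branch is used).
#' @examples
#' mexican_hat(c(0, 2, 5), a = 2, lam = 2, max_input = 1)  # 0 2 0
#' @export
mexican_hat <- function(x, a, lam, max_input = 1) {
  .check_finite(x)
  if (!is.finite(lam) || lam <= 0) stop("`lam` must be positive")
  if (!is.finite(max_input) || max_input <= 0) stop("`max_input` must be positive")
  .keepdim(pmax(lam * max_input - abs(x - a * max_input), 0), x)
}

#' @rdname mexican_hat
#' @export
mexican_hat_grad <- function(x, a, lam, max_input = 1) {
  .check_finite(x)
  if (!is.finite(lam) || lam <= 0) stop("`lam` must be positive")
  ctr <- a * max_input; hw <- lam * max_input
  up   <- (x >= ctr - hw) & (x < ctr)
  down <- (x >= ctr) & (x < ctr + hw)
  .keepdim(as.numeric(up) - as.numeric(down), x)
}

#' Gaussian-type piecewise-linear basis function
#'
#' A bump/dip pair: the Mexican-hat bump centered at `a * M` followed by its
#' mirrored dip `min(|x - a M - 2 lam M| - lam M, 0)` centered at
#' `(a + 2 lam) M`.  Continuous and piecewise linear, ranging over
#' `[-lam M, lam M]`, zero outside `[(a - lam) M, (a + 3 lam) M]`.
#'
#' @inheritParams mexican_hat
#' @return Same shape as `x`.
#' @examples
#' gaussian_basis(c(1, 3, -5), a = 1, lam = 1, max_input = 1)  # 1 -1 0
#' @export
gaussian_basis <- function(x, a, lam, max_input = 1) {
  .check_finite(x)
  if (!is.finite(lam) || lam <= 0) stop("`lam` must be positive")
  if (!is.finite(max_input) || max_input <= 0) stop("`max_input` must be positive")
  M <- max_input
  y <- pmax(lam * M - abs(x - a * M), 0) +
       pmin(abs(x - a * M - 2 * lam * M) - lam * M, 0)
  .keepdim(y, x)
}

#' @rdname gaussian_basis
#' @export
gaussian_basis_grad <- function(x, a, lam, max_input = 1) {
  .check_finite(x)
  if (!is.finite(lam) || lam <= 0) stop("`lam` must be positive")
  M <- max_input
  d <- mexican_hat_grad(x, a, lam, M)
  dip_ctr <- (a + 2 * lam) * M; hw <- lam * M
  dn <- (x >= dip_ctr - hw) & (x < dip_ctr)
  up <- (x >= dip_ctr) & (x < dip_ctr + hw)
  .keepdim(d - as.numeric(dn) + as.numeric(up), x)
}

# Evaluate all k-1 basis functions of a spec at x; returns a list.
.basis_eval <- function(spec, x, grad = FALSE) {
  fn <- if (spec$name %in% c("GaLU", "sGaLU")) {
    if (grad) gaussian_basis_grad else gaussian_basis
  } else {
    if (grad) mexican_hat_grad else mexican_hat
  }
  lapply(seq_along(spec$alpha), function(j)
    fn(x, spec$alpha[j], spec$lam[j], spec$max_input))
}

#' Mexican ReLU (MeLU / wMeLU)
#'
#' `PReLU_{c0}(x) + sum_j c_j * phi_{alpha_j, lam_j}(x)` where `phi` is the
#' Mexican-hat basis ([mexican_hat()]) at the fixed centers/widths of the
#' spec (`k = 4` for MeLU, `k = 8` for wMeLU).  With all coefficients zero —
#' the published initialization — MeLU equals plain ReLU, so ReLU networks
#' can adopt it without changing their function.
#'
#' @inheritParams act_relu
#' @param state An [activation_state()] for the spec, or a bare coefficient
#'   vector of length `k` (`c0` first), or a `channels x k` matrix.
#' @param spec An [activation_spec()] with name `MeLU` or `wMeLU`
#'   (`GaLU`/`sGaLU` for [act_galu()]).
#' @return `act_melu()`: same shape as `x`.  `act_melu_grad()`: list with
#'   `d_input` and `d_c`, a list of `k` elementwise partials (`c0` first).
#' @export
act_melu <- function(x, state, spec) {
  stopifnot(inherits(spec, "activation_spec"))
  if (!spec$name %in% c("MeLU", "wMeLU"))
    stop("`spec` must name MeLU or wMeLU")
  .melu_family(x, state, spec)
}

#' Gaussian ReLU (GaLU / sGaLU)
#'
#' Same construction as [act_melu()] with the Gaussian bump/dip basis
#' ([gaussian_basis()]); `k = 4` for GaLU, `k = 2` for sGaLU.
#'
#' @inheritParams act_melu
#' @return Same shape as `x`; gradients as in [act_melu_grad()].
#' @export
act_galu <- function(x, state, spec) {
  stopifnot(inherits(spec, "activation_spec"))
  if (!spec$name %in% c("GaLU", "sGaLU"))
    stop("`spec` must name GaLU or sGaLU")
  .melu_family(x, state, spec)
}

.coef_matrix <- function(state, spec) {
  cc <- if (inherits(state, "activation_state")) state$c else state
  if (is.null(dim(cc))) cc <- matrix(cc, nrow = 1L)
  if (ncol(cc) != spec$k)
    stop("coefficient vector must have length k = ", spec$k)
  cc
}

.melu_family <- function(x, state, spec) {
  .check_finite(x)
  cc <- .coef_matrix(state, spec)
  y <- act_prelu(x, cc[, 1L])
  phi <- .basis_eval(spec, x)
  for (j in seq_along(phi)) {
    Cj <- .expand_chan(cc[, j + 1L], x)
    y <- y + Cj * phi[[j]]
  }
  .keepdim(y, x)
}

#' @rdname act_melu
#' @export
act_melu_grad <- function(x, state, spec) {
  stopifnot(inherits(spec, "activation_spec"))
  if (!spec$name %in% c("MeLU", "wMeLU", "GaLU", "sGaLU"))
    stop("`spec` must name a MeLU/GaLU-family function")
  .check_finite(x)
  cc <- .coef_matrix(state, spec)
  pg <- act_prelu_grad(x, cc[, 1L])
  d <- pg$d_input
  dphi <- .basis_eval(spec, x, grad = TRUE)
  phi  <- .basis_eval(spec, x)
  for (j in seq_along(dphi)) {
    Cj <- .expand_chan(cc[, j + 1L], x)
    d <- d + Cj * dphi[[j]]
  }
  list(d_input = .keepdim(d, x), d_c = c(list(pg$d_a), phi))
}

#' @rdname act_melu
#' @export
act_galu_grad <- act_melu_grad

# ---- unified layer-facing interface ----------------------------------------

#' Evaluate an activation (generic over the catalogue)
#'
#' `act_forward()` applies the function named by `spec` with the learnable
#' parameters in `state`; `act_backward()` propagates an upstream gradient
#' `dy`, returning the input gradient and the per-parameter gradients summed
#' over all elements sharing a parameter (per channel, or per layer for
#' SReLU).  These are the entry points the network layers use.
#'
#' @param spec An [activation_spec()].
#' @param state An [activation_state()] matching `spec`.
#' @param x Numeric vector or `H x W x C (x N)` array.
#' @param dy Upstream gradient, same shape as `x`.
#' @return `act_forward()`: same shape as `x`.  `act_backward()`: list with
#'   `d_input` and `d_params` (a list shaped like the state's fields; empty
#'   for static functions).
#' @export
act_forward <- function(spec, state, x) {
  switch(spec$name,
    ReLU      = act_relu(x),
    LeakyReLU = act_leaky_relu(x, spec$leaky_a),
    ELU       = act_elu(x, spec$elu_a),
    PReLU     = act_prelu(x, state$a),
    SReLU     = act_srelu(x, state),
    APLU      = act_aplu(x, state$a, state$b),
    .melu_family(x, state, spec)
  )
}

#' @rdname act_forward
#' @export
act_backward <- function(spec, state, x, dy) {
  C <- if (inherits(state, "activation_state")) attr(state, "n_channels") else 1L
  switch(spec$name,
    ReLU = list(d_input = act_relu_grad(x) * dy, d_params = list()),
    LeakyReLU = list(d_input = act_leaky_relu_grad(x, spec$leaky_a) * dy,
                     d_params = list()),
    ELU = list(d_input = act_elu_grad(x, spec$elu_a) * dy, d_params = list()),
    PReLU = {
      g <- act_prelu_grad(x, state$a)
      list(d_input = g$d_input * dy,
           d_params = list(a = .chan_sum(g$d_a * dy, C)))
    },
    SReLU = {
      g <- act_srelu_grad(x, state)
      list(d_input = g$d_input * dy,
           d_params = list(al = sum(g$d_al * dy), tl = sum(g$d_tl * dy),
                           ar = sum(g$d_ar * dy), tr = sum(g$d_tr * dy)))
    },
    APLU = {
      g <- act_aplu_grad(x, state$a, state$b)
      nh <- spec$n_hinges
      da <- matrix(0, C, nh); db <- matrix(0, C, nh)
      for (h in seq_len(nh)) {
        da[, h] <- .chan_sum(g$d_a[[h]] * dy, C)
        db[, h] <- .chan_sum(g$d_b[[h]] * dy, C)
      }
      list(d_input = g$d_input * dy, d_params = list(a = da, b = db))
    },
    { # MeLU / wMeLU / GaLU / sGaLU
      g <- act_melu_grad(x, state, spec)
      dc <- matrix(0, C, spec$k)
      for (j in seq_len(spec$k))
        dc[, j] <- .chan_sum(g$d_c[[j]] * dy, C)
      list(d_input = g$d_input * dy, d_params = list(c = dc))
    }
  )
}

# Breakpoints (kinks) of the forward map, where one-sided derivatives differ.
.act_breakpoints <- function(spec, state) {
  M <- spec$max_input
  bp <- 0
  if (spec$name == "SReLU") bp <- c(state$tl, state$tr)
  if (spec$name == "APLU") bp <- c(0, as.vector(state$b))
  if (spec$name %in% c("MeLU", "wMeLU"))
    bp <- c(0, M * (spec$alpha - spec$lam), M * spec$alpha,
            M * (spec$alpha + spec$lam))
  if (spec$name %in% c("GaLU", "sGaLU"))
    bp <- c(0, M * (spec$alpha - spec$lam), M * spec$alpha,
            M * (spec$alpha + spec$lam), M * (spec$alpha + 2 * spec$lam),
            M * (spec$alpha + 3 * spec$lam))
  sort(unique(bp))
}

#' Check analytic gradients against central finite differences
#'
#' Compares the analytic input gradient and every learnable-parameter
#' gradient of the activation named by `spec` with central finite
#' differences of the forward map, at evaluation points kept away from the
#' function's breakpoints (where one-sided derivatives differ) by at least
#' `10 * step`.
#'
#' @param spec An [activation_spec()].
#' @param state An [activation_state()]; default is a fresh single-channel
#'   initialization.
#' @param points Evaluation points; default 100 points drawn uniformly on
#'   `[-4, 4] * max_input` (current RNG), filtered away from breakpoints.
#' @param tol Relative tolerance (default `1e-4`).
#' @param step Finite-difference step (default `1e-6`).
#' @return List with `ok` (logical), `max_err` (worst relative error) and
#'   `failures` (data frame naming parameter and point for each violation).
#' @export
gradient_check <- function(spec, state = NULL, points = NULL,
                           tol = 1e-4, step = 1e-6) {
  stopifnot(inherits(spec, "activation_spec"))
  if (is.null(state)) state <- activation_state(spec, 1L)
  if (is.null(points))
    points <- stats::runif(100, -4 * spec$max_input, 4 * spec$max_input)
  bp <- .act_breakpoints(spec, state)
  margin <- 10 * step
  keep <- vapply(points, function(p) all(abs(p - bp) >= margin), logical(1))
  points <- points[keep]
  if (!length(points)) stop("no evaluation points left off the breakpoints")

  fwd <- function(st, x) act_forward(spec, st, x)
  rel_err <- function(an, fd) abs(an - fd) / pmax(1, abs(an))

  fails <- list(); max_err <- 0
  record <- function(param, pts, err) {
    bad <- err > tol
    max_err <<- max(max_err, err)
    if (any(bad))
      fails[[length(fails) + 1L]] <<- data.frame(param = param,
                                                 point = pts[bad],
                                                 rel_err = err[bad])
  }

  # input gradient
  an <- act_backward(spec, state, points, rep(1, length(points)))$d_input
  fd <- (fwd(state, points + step) - fwd(state, points - step)) / (2 * step)
  record("input", points, rel_err(an, fd))

  # learnable parameters, one scalar at a time
  for (nm in names(state)) {
    v <- state[[nm]]
    for (i in seq_along(v)) {
      stp <- stm <- state
      stp[[nm]][i] <- v[i] + step
      stm[[nm]][i] <- v[i] - step
      fd <- (fwd(stp, points) - fwd(stm, points)) / (2 * step)
      an_sum <- vapply(points, function(p)
        act_backward(spec, state, p, 1)$d_params[[nm]][i], numeric(1))
      record(paste0(nm, "[", i, "]"), points, rel_err(an_sum, fd))
    }
  }
  list(ok = length(fails) == 0L, max_err = max_err,
       failures = if (length(fails)) do.call(rbind, fails)
                  else data.frame(param = character(), point = numeric(),
                                  rel_err = numeric()))
}
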