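# Forward values, analytic gradients and initialization behaviour of the
# activation catalogue.

test_that("static activations reproduce their defining piecewise values", {
  expect_equal(act_relu(c(-1, 2)), c(0, 2))
  expect_equal(act_relu_grad(c(-3, 4)), c(0, 1))
  expect_equal(act_leaky_relu(c(-1, 5), a = 0.01), c(-0.01, 5))
  expect_equal(act_leaky_relu_grad(-2, a = 0.01), 0.01)
  expect_equal(act_elu(0), 0)
  expect_equal(act_elu(-20, a = 1), exp(-20) - 1)  # ~ -1 limit
  expect_equal(act_elu_grad(-1, a = 1), exp(-1))
  expect_error(act_relu(c(1, NaN)), "non-finite")
  expect_error(act_relu(Inf), "non-finite")
})

test_that("PReLU values and elementwise parameter partials", {
  expect_equal(act_prelu(-5, a_c = 0), 0)          # initialization slope
  expect_equal(act_prelu(-4, a_c = 0.25), -1)
  g <- act_prelu_grad(c(-4, 3), a_c = 0.25)
  expect_equal(g$d_a, c(-4, 0))
  expect_equal(g$d_input, c(0.25, 1))
  # per-channel slopes on an H x W x C array
  x <- array(-1, c(2, 2, 3))
  y <- act_prelu(x, a_c = c(0, 0.5, 1))
  expect_equal(y[1, 1, ], c(0, -0.5, -1))
  expect_error(act_prelu(x, a_c = c(1, 2)), "channel")
})

test_that("SReLU branches, init equivalence and knot validation", {
  expect_equal(act_srelu(-3, c(0.1, -1, 1, 1)), -1 + 0.1 * (-3 + 1))  # -1.2
  expect_equal(act_srelu(0.5, c(0, 0, 1, 1)), 0.5)                    # middle
  x <- seq(-3, 3, length.out = 101)
  expect_equal(act_srelu(x, c(0, 0, 1, 1)), act_relu(x))              # init
  expect_error(act_srelu(1, c(0, 2, 1, 1)), "tl <= tr")
  g <- act_srelu_grad(c(-2, 0.5, 3), c(0.1, -1, 2, 1))
  expect_equal(g$d_input, c(0.1, 1, 2))
  expect_equal(g$d_al, c(-1, 0, 0))
  expect_equal(g$d_tl, c(0.9, 0, 0))
  expect_equal(g$d_ar, c(0, 0, 2))
  expect_equal(g$d_tr, c(0, 0, -1))
})

test_that("APLU hinge form matches its stated slope gradient", {
  x <- seq(-2, 2, length.out = 41)
  expect_equal(act_aplu(x, a = c(0, 0, 0), b = c(0.2, 0.5, 0.9)),
               act_relu(x))                        # zero slopes -> ReLU
  expect_equal(act_aplu(0, a = 0.5, b = 1), 0.5)   # 0.5 * max(0, 1)
  g <- act_aplu_grad(0, a = 0.5, b = 1)
  expect_equal(g$d_a[[1]], 1)                      # -x + b on x < b
  expect_equal(g$d_b[[1]], 0.5)                    # a on x < b
  expect_error(act_aplu(0, a = c(1, 2), b = 1), "matching")
})

test_that("Mexican hat basis: peak, support and zeros", {
  expect_equal(mexican_hat(0, a = 2, lam = 2, max_input = 1), 0)
  expect_equal(mexican_hat(2, a = 2, lam = 2, max_input = 1), 2)
  expect_equal(mexican_hat(5, a = 2, lam = 2, max_input = 1), 0)
  x <- seq(-10, 10, length.out = 2001)
  phi <- mexican_hat(x, 2, 2, 1)
  expect_true(all(phi >= 0))
  expect_true(all(phi[x < 0 | x > 4] == 0))        # compact support
  # the same basis scaled to max_input = 255 peaks at 510
  expect_equal(mexican_hat(510, 2, 2, 255), 510)
})

test_that("Gaussian basis is a bump/dip pair with compact support", {
  expect_equal(gaussian_basis(1, 1, 1, 1), 1)
  expect_equal(gaussian_basis(3, 1, 1, 1), -1)
  expect_equal(gaussian_basis(-5, 1, 1, 1), 0)
  x <- seq(-10, 10, length.out = 2001)
  g <- gaussian_basis(x, 1, 1, 1)
  expect_true(all(g[x < 0 | x > 4] == 0))
  expect_equal(max(g), 1)
  expect_equal(min(g), -1)
})

test_that("MeLU/GaLU combine PReLU with their bases as stated", {
  melu <- activation_spec("MeLU")
  expect_equal(act_melu(1, c(0, 0.5, 0.5, 0.5), melu), 2)
  g <- act_melu_grad(1, c(0, 0, 0, 0), melu)
  expect_equal(g$d_c[[2]], 1)                      # phi_{2,2}(1) = 1
  sg <- activation_spec("sGaLU")
  expect_equal(act_galu(1, c(0, 1), sg), 2)        # 1 + bump(1)
  expect_equal(act_galu(3, c(0, 1), sg), 2)        # 3 + dip(-1)
  expect_error(act_melu(1, c(0, 0), melu), "length k")
  expect_error(act_melu(1, c(0, 0, 0, 0), activation_spec("GaLU")), "MeLU")
})

test_that("Table settings: family sizes and basis parameters", {
  expect_equal(activation_spec("MeLU")$alpha, c(2, 1, 3))
  expect_equal(activation_spec("MeLU")$lam, c(2, 1, 1))
  expect_equal(activation_spec("wMeLU")$k, 8L)
  expect_equal(activation_spec("wMeLU")$alpha, c(2, 1, 3, 0.5, 1.5, 2.5, 3.5))
  expect_equal(activation_spec("GaLU")$alpha, c(1, 0.5, 2.5))
  expect_equal(activation_spec("sGaLU")$k, 2L)
  expect_error(activation_spec("MeLU", max_input = -1), "positive")
})

test_that("activation specs are immutable and states initialize per table", {
  sp <- activation_spec("SReLU", max_input = 255)
  expect_error(sp$max_input <- 1, "immutable")
  st <- activation_state(sp)
  expect_equal(unlist(st[c("al", "tl", "ar", "tr")]),
               c(al = 0, tl = 0, ar = 1, tr = 255))
  ap <- activation_spec("APLU", max_input = 255)
  set.seed(1)
  sta <- activation_state(ap, n_channels = 4L)
  expect_true(all(sta$a == 0))
  expect_true(all(sta$b >= 0 & sta$b <= 255))
  expect_equal(dim(sta$b), c(4L, 3L))
  stm <- activation_state(activation_spec("wMeLU"), n_channels = 2L)
  expect_equal(dim(stm$c), c(2L, 8L))
  expect_true(all(stm$c == 0))
})

test_that("every learnable function equals ReLU at its initialization", {
  x <- seq(-4, 4, length.out = 1001)
  ref <- act_relu(x)
  for (nm in c("PReLU", "SReLU", "APLU", "MeLU", "wMeLU", "GaLU", "sGaLU")) {
    for (M in c(1, 255)) {
      sp <- activation_spec(nm, max_input = M)
      st <- activation_state(sp)
      expect_identical(max(abs(act_forward(sp, st, x * M) - ref * M)), 0,
                       label = paste(nm, "max_input", M))
    }
  }
})

test_that("forward maps are continuous at every breakpoint", {
  eps <- 1e-6
  set.seed(42)
  for (nm in activation_names()) {
    sp <- activation_spec(nm)
    st <- activation_state(sp)
    for (f in names(st)) st[[f]][] <- st[[f]] + rnorm(length(st[[f]]), sd = 0.3)
    if (nm == "SReLU" && st$tl > st$tr) st[c("tl", "tr")] <- st[c("tr", "tl")]
    bps <- stochact:::.act_breakpoints(sp, st)
    jump <- vapply(bps, function(b)
      abs(act_forward(sp, st, b - eps) - act_forward(sp, st, b + eps)),
      numeric(1))
    expect_lt(max(jump), 1e-5, label = nm)
  }
})

test_that("analytic gradients agree with finite differences (all functions)", {
  set.seed(7)
  for (nm in activation_names()) {
    sp <- activation_spec(nm)
    st <- activation_state(sp)
    for (f in names(st)) st[[f]][] <- st[[f]] + rnorm(length(st[[f]]), sd = 0.3)
    if (nm == "SReLU" && st$tl > st$tr) st[c("tl", "tr")] <- st[c("tr", "tl")]
    r <- gradient_check(sp, st, tol = 1e-4)
    expect_true(r$ok, label = paste(nm, "max rel err", r$max_err))
  }
})

test_that("gradient_check screens breakpoints and reports structured results", {
  sp <- activation_spec("PReLU")
  st <- activation_state(sp)
  st$a <- 0.3
  r <- gradient_check(sp, st, points = c(-2, -0.5, 0.5, 2))
  expect_true(r$ok)
  expect_s3_class(r$failures, "data.frame")
  expect_named(r$failures, c("param", "point", "rel_err"))
  # every supplied point sitting on a breakpoint is rejected up front
  expect_error(gradient_check(sp, st, points = c(0, 1e-9)),
               "no evaluation points")
})

test_that("maxInput scaling: MeLU/GaLU families are positively homogeneous", {
  set.seed(5)
  x <- runif(50, -4, 4)
  cc <- rnorm(4, sd = 0.5)
  for (nm in c("MeLU", "GaLU")) {
    f1 <- activation_spec(nm, max_input = 1)
    for (s in c(3, 255)) {
      fs <- activation_spec(nm, max_input = s)
      expect_equal(act_forward(fs, structure(list(c = matrix(cc, 1)),
                                             class = "activation_state",
                                             n_channels = 1L, name = nm),
                               s * x),
                   s * act_forward(f1, structure(list(c = matrix(cc, 1)),
                                                 class = "activation_state",
                                                 n_channels = 1L, name = nm),
                                   x),
                   tolerance = 1e-12, label = paste(nm, "scale", s))
    }
  }
})

test_that("act_backward sums parameter gradients per channel", {
  sp <- activation_spec("PReLU")
  st <- activation_state(sp, n_channels = 2L)
  x <- array(c(-1, -2, 1, -3), c(1, 2, 2, 1))  # channel 1: -1,-2; ch2: 1,-3
  bk <- act_backward(sp, st, x, array(1, dim(x)))
  expect_equal(bk$d_params$a, c(-3, -3))
})
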