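# Training contract, augmentation, resize conventions and the evaluation
# statistics.

test_that("train_config defaults reproduce the published table", {
  cc <- train_config("classify")
  expect_equal(cc$batch_size, 32L)
  expect_equal(cc$learning_rate, 1e-4)
  expect_equal(cc$max_epochs, 30L)
  expect_true(cc$augmentation)
  expect_equal(cc$input_size, c(224L, 224L))
  cs <- train_config("segment")
  expect_equal(cs$learning_rate, 1e-3)
  expect_equal(cs$max_epochs, 50L)
  expect_equal(cs$augment_epochs, 30L)
  expect_true(cs$class_weighting)
})

test_that("accuracy is the fraction of true predictions", {
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(accuracy(c(1, 1), c(2, 2)), 0)
  expect_equal(accuracy(c(1, 2, 3, 1), c(1, 2, 3, 2)), 0.75)
  expect_error(accuracy(integer(0), integer(0)), "nonempty")
  expect_error(accuracy(1:3, 1:4), "equal length")
})

test_that("pixel F1 follows 2tp/(2tp+fn+fp), aggregated over all pixels", {
  gt <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(pixel_f1(gt, gt), 1)
  expect_equal(pixel_f1(matrix(0, 2, 2), gt), 0)
  # tp=2, fp=1, fn=1 -> 4/6
  pred <- matrix(c(1, 1, 1, 0), 2)
  gt2 <- matrix(c(1, 1, 0, 1), 2)
  expect_equal(pixel_f1(pred, gt2), 4 / 6)
  # aggregation across images differs from per-image averaging
  p <- list(matrix(c(1, 0), 1), matrix(c(1, 1), 1))
  g <- list(matrix(c(1, 1), 1), matrix(c(0, 1), 1))
  expect_equal(pixel_f1(p, g), 2 * 2 / (2 * 2 + 1 + 1))
  # empty truth perfectly predicted
  expect_equal(pixel_f1(matrix(0, 3, 3), matrix(0, 3, 3)), 1)
  expect_error(pixel_f1(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("wilcoxon signed-rank: symmetry, degenerate input, exactness", {
  set.seed(21)
  a <- runif(8); b <- runif(8)
  expect_equal(wilcoxon_signed_rank(a, b), wilcoxon_signed_rank(b, a))
  expect_warning(p <- wilcoxon_signed_rank(a, a), "zero")
  expect_equal(p, 1)
  expect_error(wilcoxon_signed_rank(1:3, 2:4), "at least 5")
  # exact agreement with the enumeration oracle, with and without ties
  for (rep in 1:20) {
    n <- sample(5:10, 1)
    x <- round(runif(n), 2)
    y <- round(runif(n), 2)  # rounding induces occasional ties/zeros
    expect_equal(wilcoxon_signed_rank(x, y), brute_wilcoxon(x, y),
                 label = paste("rep", rep))
  }
  # and with stats::wilcox.test on tie-free data (independent route)
  for (rep in 1:10) {
    x <- rnorm(9); y <- rnorm(9)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    expect_equal(wilcoxon_signed_rank(x, y), ref, label = paste("wt", rep))
  }
})

test_that("large-sample wilcoxon approximates the exact tail sensibly", {
  set.seed(4)
  x <- rnorm(30); y <- rnorm(30, mean = 1)
  p <- wilcoxon_signed_rank(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(p, ref, tolerance = 1e-8)
})

test_that("eval_report averages, ranks and compares methods", {
  m <- rbind(A = c(0.9, 0.8, 0.85, 0.9, 0.95),
             B = c(0.7, 0.75, 0.8, 0.7, 0.72))
  r <- eval_report(m)
  expect_equal(unname(r$average), c(0.88, 0.734))
  expect_equal(unname(r$rank), c(1L, 2L))
  expect_true(is.matrix(r$pairwise_p))
  expect_equal(r$pairwise_p["A", "B"], r$pairwise_p["B", "A"])
  expect_error(eval_report(matrix(1.5, 2, 5)), "0, 1")
})

test_that("kfold_split partitions and stratifies", {
  f <- kfold_split(20, 5, seed = 1)
  expect_length(f, 5L)
  expect_setequal(unlist(f), 1:20)
  y <- rep(1:2, each = 10)
  fs <- kfold_split(20, 5, seed = 1, strata = y)
  for (fold in fs) expect_equal(sum(y[fold] == 1), sum(y[fold] == 2))
})

test_that("augmentation: identity draws, shape contract, determinism", {
  img <- array(runif(16 * 12 * 3), c(16, 12, 3))
  expect_identical(augment(img, hflip = FALSE, vflip = FALSE, sx = 1, sy = 1),
                   img)
  set.seed(5)
  a1 <- augment(img)
  expect_equal(dim(a1), dim(img))
  set.seed(5)
  expect_identical(augment(img), a1)
  expect_error(augment(array(0, c(0, 3, 3))), "nonempty")
})

test_that("augmenting image and mask together keeps them pixel-aligned", {
  # paint a block; mask marks the block; identical draws must track it
  img <- array(0, c(20, 20, 3))
  img[4:9, 11:15, ] <- 1
  mask <- matrix(1L, 20, 20); mask[4:9, 11:15] <- 2L
  set.seed(9)
  for (i in 1:5) {
    am <- augment(img, mask)
    lit <- am$image[, , 1] > 0.5
    expect_gt(mean(lit == (am$mask == 2L)), 0.97)
  }
})

test_that("resize conventions: bilinear images, nearest masks, round trips", {
  img224 <- array(runif(224 * 224 * 3), c(224, 224, 3))
  expect_identical(resize_for_model(img224), img224)
  const <- array(0.4, c(448, 448, 3))
  r <- resize_for_model(const)
  expect_equal(dim(r), c(224L, 224L, 3L))
  expect_equal(range(r), c(0.4, 0.4))
  # nearest-neighbor mask round trip on even factors is exact
  m <- matrix(sample(0:1, 100 * 80, TRUE), 100, 80)
  up <- resize_mask_back(m, c(200L, 160L))
  back <- resize_mask_back(up, c(100L, 80L))
  expect_equal(unname(back), unname(m))
  expect_error(resize_for_model(img224, size = c(0, 10)), "positive")
})

test_that("zero-epoch training returns the model unchanged", {
  m <- make_toy_model()
  ds <- gen_classification(2, 4, image_size = c(16L, 16L, 3L), seed = 3)
  cfg <- train_config("classify", max_epochs = 0L)
  expect_identical(serialize(train_model(m, ds[c("x", "y")], cfg), NULL),
                   serialize(m, NULL))
})

test_that("training rejects out-of-range labels before touching weights", {
  m <- make_toy_model(n_classes = 2L)
  ds <- gen_classification(3, 2, image_size = c(16L, 16L, 3L), seed = 3)
  cfg <- train_config("classify", max_epochs = 1L)
  expect_error(train_model(m, list(x = ds$x, y = ds$y), cfg), "out of range")
})

test_that("training decreases the loss and is seed-deterministic", {
  ds <- gen_classification(2, 12, image_size = c(16L, 16L, 3L),
                           noise_sd = 0, seed = 11)
  m <- make_toy_model(n_classes = 2L)
  cfg <- train_config("classify", learning_rate = 0.05, max_epochs = 5L,
                      augmentation = FALSE)
  t1 <- train_model(m, ds[c("x", "y")], cfg, seed = 2L)
  h <- attr(t1, "loss_history")
  expect_lt(h[length(h)], h[1])
  expect_gt(accuracy(predict_classes(t1, ds$x)$decision, ds$y), 0.9)
  t2 <- train_model(m, ds[c("x", "y")], cfg, seed = 2L)
  expect_identical(serialize(unclass(t1), NULL), serialize(unclass(t2), NULL))
})

test_that("segmentation training with class weighting learns the ellipse task", {
  sg <- gen_segmentation(8, seed = 13)
  m <- tiny_cnn(2, 2, seed = 5, task = "segment")
  cfg <- train_config("segment", learning_rate = 0.2, max_epochs = 4L,
                      augmentation = FALSE)
  mt <- train_model(m, list(x = sg$x, masks = sg$masks), cfg, seed = 1L)
  pm <- predict_masks(mt, sg$x)
  hard <- lapply(pm, function(s) s[, , 2] > s[, , 1])
  f1 <- pixel_f1(hard, lapply(sg$masks, function(mm) mm == 2L))
  expect_gt(f1, 0.6)
})
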