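# independent layer-by-layer parameter sum, written against the
# architecture definition rather than the package's closed form
oracle_param_sum <- function(widths, cin = 1, cout = 1) {
  n <- 0
  L <- length(widths)
  prev <- cin
  for (i in seq_len(L)) {
    n <- n + 9 * prev * widths[i] + widths[i]
    n <- n + 9 * widths[i] * widths[i] + widths[i]
    prev <- widths[i]
  }
  for (j in (L - 1):1) {
    n <- n + 4 * widths[j + 1] * widths[j] + widths[j]
    n <- n + 9 * (2 * widths[j]) * widths[j] + widths[j]
    n <- n + 9 * widths[j] * widths[j] + widths[j]
  }
  n + 1 * widths[1] * cout + cout
}

test_that("parameter count matches the independent layer sum for any widths", {
  expect_equal(unet_parameter_count(c(64, 128, 256, 512, 1024)), 31030593)
  expect_equal(oracle_param_sum(c(64, 128, 256, 512, 1024)), 31030593)
  for (w in list(c(8, 16, 32, 64, 128), c(4, 8, 16), c(2, 6))) {
    expect_equal(unet_parameter_count(w), oracle_param_sum(w))
    m <- build_unet(unet_config(n_levels = length(w), widths = w,
                                patch_size = 32))
    expect_equal(m$n_params, oracle_param_sum(w))
    expect_equal(sum(m$layers$params), m$n_params)
  }
})

test_that("a five-level net accepts 128x128 input (8x8 bottleneck) and rejects indivisible sizes", {
  cfg <- unet_config(widths = c(2, 3, 4, 5, 6), patch_size = 128)
  m <- build_unet(cfg)
  x <- array(rnorm(128 * 128), c(128, 128, 1, 1))
  p <- unet_forward(m, x)
  expect_equal(dim(p), c(128, 128, 1, 1))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(unet_forward(m, array(0, c(72, 72, 1, 1))), "divisible")
})

test_that("config invariants are enforced", {
  expect_error(unet_config(n_levels = 1, widths = 8), "n_levels")
  expect_error(unet_config(widths = c(64, 64, 256, 512, 1024)), "increasing")
  expect_error(unet_config(learning_rate = 0), "learning_rate")
  expect_error(unet_config(smooth_eps = 0), "smooth_eps")
  expect_error(unet_config(patch_size = 60), "divisible")
})

test_that("dice loss matches its analytic values", {
  truth <- matrix(0, 8, 8); truth[3:5, 3:5] <- 1
  # perfect binary prediction: loss tends to 0 as eps shrinks
  expect_lt(dice_loss(truth, truth, smooth_eps = 1e-9), 1e-9)
  # both empty: eps/eps == 1, loss exactly 0
  expect_identical(dice_loss(matrix(0, 4, 4), matrix(0, 4, 4), 1.0), 0)
  # complete miss against k foreground pixels: 1 - eps/(k + eps)
  k <- sum(truth)
  for (eps in c(1e-3, 1, 10))
    expect_equal(dice_loss(matrix(0, 8, 8), truth, eps), 1 - eps / (k + eps))
  expect_error(dice_loss(matrix(0, 4, 4), matrix(0, 5, 5)), "shape")
  expect_error(dice_loss(matrix(2, 4, 4), matrix(0, 4, 4)), "\\[0, 1\\]")
})

test_that("dice loss is symmetric for binary inputs and bounded in [0, 1)", {
  set.seed(1)
  for (i in 1:20) {
    a <- matrix(rbinom(64, 1, 0.3), 8, 8)
    b <- matrix(rbinom(64, 1, 0.3), 8, 8)
    la <- dice_loss(a, b)
    expect_equal(la, dice_loss(b, a))
    expect_gte(la, 0); expect_lt(la, 1)
    p <- matrix(runif(64), 8, 8)
    lp <- dice_loss(p, b)
    expect_gte(lp, 0); expect_lt(lp, 1)
  }
})

test_that("binarization is strictly greater-than the threshold", {
  half <- array(0.5, c(4, 4, 2))
  expect_equal(sum(binarize(half)), 0)
  expect_equal(sum(binarize(array(0.51, c(4, 4, 2)))), 32)
  set.seed(2)
  m <- array(runif(200), c(10, 10, 2))
  bin <- binarize(m, 0.5)
  brute <- 0L
  for (i in seq_along(m)) if (m[i] > 0.5) brute <- brute + 1L
  expect_equal(sum(bin), brute)
  expect_true(all(bin %in% c(0L, 1L)))
})

test_that("backpropagated gradients match finite differences", {
  cfg <- unet_config(n_levels = 2, widths = c(2, 4), patch_size = 8,
                     rng_seed = 7)
  m <- build_unet(cfg)
  set.seed(42)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  y <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 1, 2))
  loss_of <- function(mm) {
    fw <- cathrecon:::unet_forward_cache(mm, x, keep = TRUE)
    cathrecon:::dice_batch(fw$prob, y, 1.0)
  }
  fw <- cathrecon:::unet_forward_cache(m, x, keep = TRUE)
  db <- cathrecon:::dice_batch(fw$prob, y, 1.0)
  grads <- cathrecon:::unet_backward(m, fw$cache, db$gprob)
  eps <- 1e-4
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      m2 <- m
      m2$params[[nm]][i] <- p[i] + eps
      l1 <- loss_of(m2)$loss
      m2$params[[nm]][i] <- p[i] - eps
      l0 <- loss_of(m2)$loss
      num <- (l1 - l0) / (2 * eps)
      ana <- grads[[nm]][i]
      # single-precision forward: accept small absolute or relative error
      ok <- abs(num - ana) < 1e-3 ||
        abs(num - ana) / (abs(num) + abs(ana)) < 2e-2
      expect_true(ok, label = sprintf("%s[%d]: num %.3e vs ana %.3e",
                                      nm, i, num, ana))
    }
  }
})

test_that("training is deterministic and reduces the loss on phantom patches", {
  ph <- generate_phantom(small_phantom_config(seed = 14L))
  labels <- rasterize_truth_mask(ph$paths, ph$config$shape, 2)
  patches <- sample_training_patches(normalize_volume(ph$t1w), labels,
                                     n_patches = 48, patch_size = 32,
                                     rng_seed = 5)
  cfg <- tiny_unet_config(epochs = 5L)
  f1 <- train_unet(build_unet(cfg), patches)
  f2 <- train_unet(build_unet(cfg), patches)
  expect_identical(f1$history, f2$history)
  expect_lt(tail(f1$history$train_loss, 1), f1$history$train_loss[1])
  expect_gt(tail(f1$history$train_dice, 1), f1$history$train_dice[1])
})

test_that("training on all-background labels drives predictions to background", {
  ph <- generate_phantom(small_phantom_config(seed = 15L))
  vol <- normalize_volume(ph$t1w)
  empty <- array(0L, dim = ph$config$shape)
  patches <- extract_patches(vol, empty, 32, stride = 32,
                             slices = c(3, 8, 13))
  fit <- train_unet(build_unet(tiny_unet_config(epochs = 4L)), patches)
  pm <- predict_mask_stack(fit$model, vol, patch_size = 32)
  expect_lt(mean(binarize(pm)), 0.01)
})

test_that("empty patch sets are rejected", {
  expect_error(train_unet(build_unet(tiny_unet_config()), list()), "empty")
})

test_that("stitched prediction is conservative: constant model gives constant map", {
  m <- constant_output_model(0.3)
  vol <- image_volume(array(rnorm(48 * 48 * 3), c(48, 48, 3)),
                      c(1, 1, 1), "t1w")
  pm <- predict_mask_stack(m, vol, patch_size = 32, stride = 16)
  expect_equal(dim(pm$data), c(48, 48, 3))
  expect_equal(unname(as.vector(pm$data)), rep(0.3, 48 * 48 * 3),
               tolerance = 1e-6)
})

test_that("zero-overlap tiling of an exact-multiple slice equals per-patch output", {
  cfg <- tiny_unet_config()
  m <- build_unet(cfg)
  vol <- image_volume(array(rnorm(64 * 64 * 2), c(64, 64, 2)),
                      c(1, 1, 1), "t1w")
  pm <- predict_mask_stack(m, vol, patch_size = 32, stride = 32)
  # recompute one tile directly
  x <- array(vol$data[33:64, 1:32, 2], c(32, 32, 1, 1))
  direct <- unet_forward(m, x)[, , 1, 1]
  expect_equal(pm$data[33:64, 1:32, 2], direct, tolerance = 1e-7)
  expect_true(all(pm$data >= 0 & pm$data <= 1))
})

test_that("stitched values stay within the range of contributing windows", {
  cfg <- tiny_unet_config()
  m <- build_unet(cfg)
  vol <- image_volume(array(rnorm(40 * 40 * 1), c(40, 40, 1)),
                      c(1, 1, 1), "t2w")
  pm <- predict_mask_stack(m, vol, patch_size = 32, stride = 8)
  offs <- unique(c(seq(1, 9, by = 8), 9))
  win <- expand.grid(r = offs, c = offs)
  preds <- lapply(seq_len(nrow(win)), function(k) {
    x <- array(vol$data[win$r[k]:(win$r[k] + 31),
                        win$c[k]:(win$c[k] + 31), 1], c(32, 32, 1, 1))
    unet_forward(m, x)[, , 1, 1]
  })
  # pixel (20, 20) is covered by every window
  vals <- vapply(seq_len(nrow(win)), function(k)
    preds[[k]][20 - win$r[k] + 1, 20 - win$c[k] + 1], 0)
  expect_gte(pm$data[20, 20, 1], min(vals) - 1e-9)
  expect_lte(pm$data[20, 20, 1], max(vals) + 1e-9)
})

test_that("models survive a save/load round trip", {
  m <- build_unet(tiny_unet_config(), modality = "t2w")
  f <- tempfile(fileext = ".json")
  save_unet(m, f)
  m2 <- load_unet(f)
  expect_equal(m2$modality, "t2w")
  expect_equal(m2$params, m$params)
  x <- array(rnorm(32 * 32), c(32, 32, 1, 1))
  expect_equal(unet_forward(m2, x), unet_forward(m, x))
})
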