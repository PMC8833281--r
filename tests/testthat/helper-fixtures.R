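# Small fixtures shared across test files. Everything is generated in
# code; sizes are kept small so the default test run stays fast.

# compact phantom: 4 catheters, 20 slices
small_phantom_config <- function(seed = 1L, ...) {
  phantom_config(shape = c(64L, 64L, 20L), n_catheters = 4L,
                 rng_seed = seed, ...)
}

# 3-level network on 32x32 patches: small enough for quick training tests
tiny_unet_config <- function(...) {
  args <- list(n_levels = 3L, widths = c(4L, 8L, 16L), patch_size = 32L,
               learning_rate = 1e-3, epochs = 3L, rng_seed = 3L)
  args[names(list(...))] <- list(...)
  do.call(unet_config, args)
}

# a model whose output is a given constant probability everywhere:
# all weights zero, final bias at the logit
constant_output_model <- function(p, config = tiny_unet_config()) {
  m <- build_unet(config)
  for (nm in names(m$params)) m$params[[nm]][] <- 0
  m$params[["fin_b"]][] <- log(p / (1 - p))
  m
}

# straight-catheter phantom volumes built by hand: k catheters at fixed
# (row, col) across all slices, no noise, uniform background
straight_volumes <- function(seats, shape = c(48L, 48L, 12L),
                             contrast = 50, spacing = c(0.5, 0.5, 1)) {
  t1 <- array(100, dim = shape)
  t2 <- array(100, dim = shape)
  mask <- array(0L, dim = shape)
  for (i in seq_len(nrow(seats))) {
    r <- seats[i, 1]; c0 <- seats[i, 2]
    for (s in seq_len(shape[3])) {
      t1[r, c0, s] <- 100 + contrast
      t2[r, c0, s] <- 100 - contrast
      mask[r, c0, s] <- 1L
    }
  }
  list(t1w = image_volume(t1, spacing, "t1w"),
       t2w = image_volume(t2, spacing, "t2w"),
       mask = mask, spacing = spacing, shape = shape)
}
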