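#' U-net configuration
#'
#' Hyperparameters of the 2D encoder-decoder segmentation network. The
#' default widths mirror the original U-net (64 doubling to 1024 over
#' five levels); desk-scale runs use much narrower networks via
#' `widths`. Each encoder level applies two 3x3 convolutions with ReLU
#' followed by 2x2 max pooling (stride 2); each decoder level applies a
#' 2x2 transposed convolution with ReLU, concatenates the matching
#' encoder feature map, and applies two 3x3 convolutions with ReLU; a
#' final 1x1 convolution with sigmoid yields the per-pixel catheter
#' probability.
#'
#' @param n_levels number of encoder levels including the bottleneck
#'   (>= 2).
#' @param widths channel widths per level, strictly increasing down the
#'   encoder; length must equal `n_levels`.
#' @param in_channels input channels (1: one model per MR contrast).
#' @param learning_rate Adam learning rate (> 0).
#' @param epochs training epochs.
#' @param batch_size training mini-batch size.
#' @param smooth_eps smoothing constant of the Dice loss (> 0); keeps
#'   the loss defined when prediction and truth are both empty.
#' @param patch_size training patch side length; must be divisible by
#'   `2^(n_levels - 1)`.
#' @param init_bias initial value of the final-layer bias, i.e. the
#'   logit of the network's initial foreground prior. Catheter
#'   cross-sections occupy well under 1 percent of a patch, and with a
#'   Dice objective a network that starts at a 50 percent prior spends
#'   most of a short schedule suppressing background; starting near the
#'   true class prior (default -3, about a 5 percent prior) removes
#'   that transient.
#' @param rng_seed seed for He-normal weight initialization and batch
#'   shuffling; training is fully deterministic given the seed.
#' @return A list of class `unet_config`.
#' @export
unet_config <- function(n_levels = 5L,
                        widths = c(64L, 128L, 256L, 512L, 1024L),
                        in_channels = 1L,
                        learning_rate = 1e-5,
                        epochs = 100L,
                        batch_size = 8L,
                        smooth_eps = 1.0,
                        patch_size = 64L,
                        init_bias = -3,
                        rng_seed = 1L) {
  n_levels <- as.integer(n_levels)
  widths <- as.integer(widths)
  if (n_levels < 2L) stop("`n_levels` must be >= 2")
  if (length(widths) != n_levels)
    stop("`widths` must have one entry per level (", n_levels, ")")
  if (any(diff(widths) <= 0))
    stop("`widths` must be strictly increasing down the encoder")
  if (learning_rate <= 0) stop("`learning_rate` must be > 0")
  if (smooth_eps <= 0) stop("`smooth_eps` must be > 0")
  if (patch_size %% 2^(n_levels - 1) != 0)
    stop("`patch_size` must be divisible by 2^(n_levels - 1) = ",
         2^(n_levels - 1))
  structure(list(
    n_levels = n_levels, widths = widths,
    in_channels = as.integer(in_channels),
    learning_rate = learning_rate, epochs = as.integer(epochs),
    batch_size = as.integer(batch_size), smooth_eps = smooth_eps,
    patch_size = as.integer(patch_size), init_bias = init_bias,
    rng_seed = as.integer(rng_seed)
  ), class = "unet_config")
}

#' Closed-form trainable-parameter count of the U-net
#'
#' Sums `k^2 * c_in * c_out + c_out` over every convolution in the
#' architecture (3x3 encoder/decoder convolutions, 2x2 transposed
#' convolutions, final 1x1 convolution). For the canonical widths
#' (64, 128, 256, 512, 1024) with one input and one output channel this
#' evaluates to 31,030,593.
#'
#' @param widths per-level channel widths.
#' @param in_channels,out_channels network input/output channels.
#' @return Integer parameter count (as a double to avoid overflow).
#' @export
unet_parameter_count <- function(widths, in_channels = 1, out_channels = 1) {
  L <- length(widths)
  conv <- function(k, ci, co) k^2 * ci * co + co
  total <- 0
  ci <- in_channels
  for (i in seq_len(L)) {
    total <- total + conv(3, ci, widths[i]) + conv(3, widths[i], widths[i])
    ci <- widths[i]
  }
  for (j in (L - 1):1) {
    total <- total + conv(2, widths[j + 1], widths[j])      # transposed conv
    total <- total + conv(3, 2 * widths[j], widths[j])      # after concat
    total <- total + conv(3, widths[j], widths[j])
  }
  total + conv(1, widths[1], out_channels)
}

he_init <- function(k, ci, co) {
  array(rnorm(k * k * ci * co, sd = sqrt(2 / (k * k * ci))),
        dim = c(k, k, ci, co))
}

#' Build (initialize) a U-net model
#'
#' Allocates He-normal-initialized weights for the configured
#' architecture and returns the model together with a layer-by-layer
#' descriptor and the total trainable-parameter count (which always
#' equals [unet_parameter_count] for the same widths).
#'
#' @param config a [unet_config].
#' @param modality tag recorded on the model (`"t1w"` or `"t2w"`).
#' @return A list of class `unet_model` with elements `config`,
#'   `modality`, `params` (flat named list of weight/bias arrays),
#'   `layers` (data frame: name, type, kernel, in/out channels, params)
#'   and `n_params`.
#' @export
build_unet <- function(config, modality = "t1w") {
  stopifnot(inherits(config, "unet_config"))
  L <- config$n_levels
  w <- config$widths
  params <- list()
  layers <- list()
  add <- function(name, type, k, ci, co) {
    layers[[length(layers) + 1]] <<- data.frame(
      name = name, type = type, kernel = k, in_ch = ci, out_ch = co,
      params = k^2 * ci * co + co
    )
  }
  with_seed(config$rng_seed, {
    ci <- config$in_channels
    for (i in seq_len(L)) {
      params[[paste0("enc", i, "_w1")]] <- he_init(3, ci, w[i])
      params[[paste0("enc", i, "_b1")]] <- numeric(w[i])
      params[[paste0("enc", i, "_w2")]] <- he_init(3, w[i], w[i])
      params[[paste0("enc", i, "_b2")]] <- numeric(w[i])
      add(paste0("enc", i, "_conv1"), "conv3x3+relu", 3, ci, w[i])
      add(paste0("enc", i, "_conv2"), "conv3x3+relu", 3, w[i], w[i])
      ci <- w[i]
    }
    for (j in (L - 1):1) {
      params[[paste0("dec", j, "_wu")]] <- he_init(2, w[j + 1], w[j])
      params[[paste0("dec", j, "_bu")]] <- numeric(w[j])
      params[[paste0("dec", j, "_w1")]] <- he_init(3, 2 * w[j], w[j])
      params[[paste0("dec", j, "_b1")]] <- numeric(w[j])
      params[[paste0("dec", j, "_w2")]] <- he_init(3, w[j], w[j])
      params[[paste0("dec", j, "_b2")]] <- numeric(w[j])
      add(paste0("dec", j, "_upconv"), "upconv2x2+relu", 2, w[j + 1], w[j])
      add(paste0("dec", j, "_conv1"), "conv3x3+relu", 3, 2 * w[j], w[j])
      add(paste0("dec", j, "_conv2"), "conv3x3+relu", 3, w[j], w[j])
    }
    params[["fin_w"]] <- he_init(1, w[1], 1)
    params[["fin_b"]] <- config$init_bias
    add("final", "conv1x1+sigmoid", 1, w[1], 1)
  })
  layers <- do.call(rbind, layers)
  structure(list(
    config = config, modality = modality, params = params,
    layers = layers, n_params = sum(vapply(params, length, 0))
  ), class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model %s> %d levels, widths %s, %s parameters\n",
              x$modality, x$config$n_levels,
              paste(x$config$widths, collapse = "-"),
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

# concatenate two (H,W,C,N) stacks along the channel axis
channel_cat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# forward pass with optional cache for backprop; x is (H,W,Cin,N)
unet_forward_cache <- function(model, x, keep = FALSE) {
  p <- model$params
  L <- model$config$n_levels
  cache <- list(enc = vector("list", L), dec = vector("list", L - 1))
  skips <- vector("list", L - 1)
  cur <- x
  for (i in seq_len(L)) {
    in1 <- cur
    y1 <- conv_fwd_cpp(in1, p[[paste0("enc", i, "_w1")]],
                       p[[paste0("enc", i, "_b1")]], TRUE)
    y2 <- conv_fwd_cpp(y1, p[[paste0("enc", i, "_w2")]],
                       p[[paste0("enc", i, "_b2")]], TRUE)
    if (keep) cache$enc[[i]] <- list(in1 = in1, y1 = y1, y2 = y2)
    if (i < L) {
      skips[[i]] <- y2
      pooled <- pool_fwd_cpp(y2)
      if (keep) cache$enc[[i]]$pool_idx <- pooled$idx
      cur <- pooled$y
    } else cur <- y2
  }
  for (j in (L - 1):1) {
    upin <- cur
    up <- upconv_fwd_cpp(upin, p[[paste0("dec", j, "_wu")]],
                         p[[paste0("dec", j, "_bu")]], TRUE)
    cat_in <- channel_cat(skips[[j]], up)
    y1 <- conv_fwd_cpp(cat_in, p[[paste0("dec", j, "_w1")]],
                       p[[paste0("dec", j, "_b1")]], TRUE)
    y2 <- conv_fwd_cpp(y1, p[[paste0("dec", j, "_w2")]],
                       p[[paste0("dec", j, "_b2")]], TRUE)
    if (keep) cache$dec[[j]] <- list(upin = upin, up = up, cat_in = cat_in,
                                     y1 = y1, y2 = y2)
    cur <- y2
  }
  logits <- conv_fwd_cpp(cur, p[["fin_w"]], p[["fin_b"]], FALSE)
  prob <- 1 / (1 + exp(-logits))
  if (keep) {
    cache$fin <- list(in1 = cur, logits = logits)
    cache$prob <- prob
  }
  list(prob = prob, cache = if (keep) cache else NULL)
}

#' Run the network on a batch of patches
#'
#' @param model a [build_unet] model.
#' @param x array `(H, W, in_channels, N)`; `H` and `W` must be
#'   divisible by `2^(n_levels - 1)`.
#' @return Probability array of the same spatial shape, one channel.
#' @export
unet_forward <- function(model, x) {
  stopifnot(inherits(model, "unet_model"))
  d <- dim(x)
  div <- 2^(model$config$n_levels - 1)
  if (length(d) != 4L || d[1] %% div != 0 || d[2] %% div != 0)
    stop("input spatial dims must be divisible by ", div)
  unet_forward_cache(model, x, keep = FALSE)$prob
}

# backward pass: dloss/dprob -> named list of parameter gradients
unet_backward <- function(model, cache, gprob) {
  p <- model$params
  L <- model$config$n_levels
  grads <- list()
  glogits <- gprob * cache$prob * (1 - cache$prob)
  bw <- conv_bwd_cpp(cache$fin$in1, p[["fin_w"]], cache$fin$logits,
                     glogits, FALSE)
  grads[["fin_w"]] <- bw$gw; grads[["fin_b"]] <- bw$gb
  g <- bw$gx
  gskip <- vector("list", L - 1)
  for (j in seq_len(L - 1)) {        # decoder levels, last applied first
    cc <- cache$dec[[j]]
    b2 <- conv_bwd_cpp(cc$y1, p[[paste0("dec", j, "_w2")]], cc$y2, g, TRUE)
    grads[[paste0("dec", j, "_w2")]] <- b2$gw
    grads[[paste0("dec", j, "_b2")]] <- b2$gb
    b1 <- conv_bwd_cpp(cc$cat_in, p[[paste0("dec", j, "_w1")]], cc$y1,
                       b2$gx, TRUE)
    grads[[paste0("dec", j, "_w1")]] <- b1$gw
    grads[[paste0("dec", j, "_b1")]] <- b1$gb
    cj <- model$config$widths[j]
    gcat <- b1$gx
    gskip[[j]] <- gcat[, , seq_len(cj), , drop = FALSE]
    gup <- gcat[, , cj + seq_len(cj), , drop = FALSE]
    bu <- upconv_bwd_cpp(cc$upin, p[[paste0("dec", j, "_wu")]], cc$up,
                         gup, TRUE)
    grads[[paste0("dec", j, "_wu")]] <- bu$gw
    grads[[paste0("dec", j, "_bu")]] <- bu$gb
    g <- bu$gx
  }
  for (i in L:1) {                   # encoder levels, bottleneck first
    cc <- cache$enc[[i]]
    if (i < L) {
      d2 <- dim(cc$y2)
      g <- pool_bwd_cpp(g, cc$pool_idx, d2[1], d2[2]) + gskip[[i]]
    }
    b2 <- conv_bwd_cpp(cc$y1, p[[paste0("enc", i, "_w2")]], cc$y2, g, TRUE)
    grads[[paste0("enc", i, "_w2")]] <- b2$gw
    grads[[paste0("enc", i, "_b2")]] <- b2$gb
    b1 <- conv_bwd_cpp(cc$in1, p[[paste0("enc", i, "_w1")]], cc$y1,
                       b2$gx, TRUE)
    grads[[paste0("enc", i, "_w1")]] <- b1$gw
    grads[[paste0("enc", i, "_b1")]] <- b1$gb
    g <- b1$gx
  }
  grads
}

#' Smoothed Dice loss
#'
#' `1 - (2 * sum(pred * truth) + eps) / (sum(pred) + sum(truth) + eps)`.
#' The smoothing constant keeps the loss at 0 when prediction and truth
#' are both empty, so all-background patches are handled gracefully.
#' The loss lies in `[0, 1)`.
#'
#' @param pred probability map (values in `[0, 1]`).
#' @param truth binary map of the same shape.
#' @param smooth_eps smoothing constant (> 0).
#' @return Scalar loss.
#' @export
dice_loss <- function(pred, truth, smooth_eps = 1.0) {
  if (!all(dim(pred) == dim(truth)) ||
      length(pred) != length(truth))
    stop("pred and truth shapes differ")
  if (any(pred < 0 | pred > 1)) stop("pred must lie in [0, 1]")
  if (!all(truth %in% c(0, 1))) stop("truth must be binary")
  inter <- sum(pred * truth)
  1 - (2 * inter + smooth_eps) / (sum(pred) + sum(truth) + smooth_eps)
}

# per-sample dice loss and gradient wrt pred for a (H,W,1,N) batch
dice_batch <- function(prob, truth, eps) {
  d <- dim(prob)
  n <- d[4]
  losses <- numeric(n)
  gprob <- array(0, dim = d)
  for (s in seq_len(n)) {
    pk <- prob[, , 1, s]; tk <- truth[, , 1, s]
    inter <- sum(pk * tk)
    denom <- sum(pk) + sum(tk) + eps
    losses[s] <- 1 - (2 * inter + eps) / denom
    gprob[, , 1, s] <- -(2 * tk * denom - (2 * inter + eps)) / denom^2 / n
  }
  list(loss = mean(losses), gprob = gprob)
}

#' Train a U-net on labeled patches
#'
#' Mini-batch Adam optimization of the smoothed Dice loss. Training is
#' deterministic given the config seed: initialization and the epoch
#' shuffles all derive from it.
#'
#' @param model a [build_unet] model.
#' @param patches training patches from [extract_patches] or
#'   [sample_training_patches].
#' @param validation optional held-out patches; per-epoch validation
#'   Dice is logged (no early stopping or model selection).
#' @param epochs,batch_size,learning_rate overrides of the model config.
#' @param clip_norm global gradient-norm ceiling per batch; batches
#'   whose gradient norm exceeds it are rescaled to it. Dice gradients
#'   spike when a prediction collapses toward empty, and clipping keeps
#'   those batches from destabilizing the whole run. `Inf` disables.
#' @param verbose print per-epoch losses.
#' @return A list with `model` (trained) and `history` (data frame:
#'   epoch, train_loss, train_dice, val_dice).
#' @export
train_unet <- function(model, patches, validation = NULL,
                       epochs = NULL, batch_size = NULL,
                       learning_rate = NULL, clip_norm = 5,
                       verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"))
  if (length(patches) == 0) stop("empty patch set")
  cfg <- model$config
  epochs <- if (is.null(epochs)) cfg$epochs else epochs
  batch_size <- if (is.null(batch_size)) cfg$batch_size else batch_size
  lr <- if (is.null(learning_rate)) cfg$learning_rate else learning_rate

  ps <- nrow(patches[[1]]$pixels)
  n <- length(patches)
  X <- array(0, dim = c(ps, ps, 1, n))
  Y <- array(0, dim = c(ps, ps, 1, n))
  for (i in seq_len(n)) {
    X[, , 1, i] <- patches[[i]]$pixels
    Y[, , 1, i] <- patches[[i]]$label
  }
  Xv <- Yv <- NULL
  if (!is.null(validation) && length(validation) > 0) {
    nv <- length(validation)
    Xv <- array(0, dim = c(ps, ps, 1, nv))
    Yv <- array(0, dim = c(ps, ps, 1, nv))
    for (i in seq_len(nv)) {
      Xv[, , 1, i] <- validation[[i]]$pixels
      Yv[, , 1, i] <- validation[[i]]$label
    }
  }

  # Adam state
  mstate <- lapply(model$params, function(x) array(0, dim = dim(x) %||% length(x)))
  vstate <- mstate
  t_step <- 0
  beta1 <- 0.9; beta2 <- 0.999; aeps <- 1e-8

  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     train_dice = numeric(), val_dice = numeric())
  with_seed(cfg$rng_seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      ep_losses <- numeric()
      for (b0 in seq(1, n, by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1, n)]
        xb <- X[, , , idx, drop = FALSE]
        yb <- Y[, , , idx, drop = FALSE]
        fw <- unet_forward_cache(model, xb, keep = TRUE)
        db <- dice_batch(fw$prob, yb, cfg$smooth_eps)
        ep_losses <- c(ep_losses, db$loss)
        grads <- unet_backward(model, fw$cache, db$gprob)
        if (is.finite(clip_norm)) {
          gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
          if (gnorm > clip_norm)
            grads <- lapply(grads, function(g) g * (clip_norm / gnorm))
        }
        t_step <- t_step + 1
        for (nm in names(model$params)) {
          g <- grads[[nm]]
          mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * g
          vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * g^2
          mhat <- mstate[[nm]] / (1 - beta1^t_step)
          vhat <- vstate[[nm]] / (1 - beta2^t_step)
          model$params[[nm]] <- model$params[[nm]] -
            lr * mhat / (sqrt(vhat) + aeps)
        }
      }
      val_dice <- NA_real_
      if (!is.null(Xv)) {
        pv <- unet_forward_cache(model, Xv, keep = FALSE)$prob
        val_dice <- 1 - dice_batch(pv, Yv, cfg$smooth_eps)$loss
      }
      tl <- mean(ep_losses)
      hist <- rbind(hist, data.frame(
        epoch = ep, train_loss = tl, train_dice = 1 - tl, val_dice = val_dice
      ))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val dice %.4f", ep, tl, val_dice))
    }
  })
  list(model = model, history = hist)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict a per-slice probability mask stack for a whole volume
#'
#' Tiles each axial slice with overlapping `patch_size` windows, runs
#' the network on each window, and averages predictions where windows
#' overlap. The stitched output has exactly the slice's in-plane shape.
#'
#' @param model a trained [build_unet] model.
#' @param volume a normalized [image_volume].
#' @param patch_size window side length (must suit the model's depth).
#' @param stride tiling stride; defaults to `patch_size / 2`
#'   (50 percent overlap).
#' @param batch_windows how many windows to push through the network at
#'   once.
#' @return A list of class `prob_mask_stack`: `data` (array in `[0,1]`
#'   of the volume's shape) and `modality`.
#' @export
predict_mask_stack <- function(model, volume, patch_size = NULL,
                               stride = NULL, batch_windows = 16L) {
  stopifnot(inherits(model, "unet_model"), inherits(volume, "image_volume"))
  ps <- as.integer(patch_size %||% model$config$patch_size)
  if (is.null(stride)) stride <- max(1L, ps %/% 2L)
  d <- dim(volume$data)
  if (ps > d[1] || ps > d[2]) stop("patch_size exceeds slice dimensions")
  offs <- function(n) unique(c(seq(1L, n - ps + 1L, by = stride), n - ps + 1L))
  ro <- offs(d[1]); co <- offs(d[2])
  win <- expand.grid(r = ro, c = co)

  acc <- array(0, dim = d)
  cnt <- array(0, dim = d)
  for (s in seq_len(d[3])) {
    for (b0 in seq(1, nrow(win), by = batch_windows)) {
      idx <- b0:min(b0 + batch_windows - 1, nrow(win))
      xb <- array(0, dim = c(ps, ps, 1, length(idx)))
      for (k in seq_along(idx)) {
        r <- win$r[idx[k]]; c0 <- win$c[idx[k]]
        xb[, , 1, k] <- volume$data[r:(r + ps - 1), c0:(c0 + ps - 1), s]
      }
      pb <- unet_forward_cache(model, xb, keep = FALSE)$prob
      for (k in seq_along(idx)) {
        r <- win$r[idx[k]]; c0 <- win$c[idx[k]]
        acc[r:(r + ps - 1), c0:(c0 + ps - 1), s] <-
          acc[r:(r + ps - 1), c0:(c0 + ps - 1), s] + pb[, , 1, k]
        cnt[r:(r + ps - 1), c0:(c0 + ps - 1), s] <-
          cnt[r:(r + ps - 1), c0:(c0 + ps - 1), s] + 1
      }
    }
  }
  structure(list(data = acc / cnt, modality = volume$modality),
            class = "prob_mask_stack")
}

#' Threshold a probability mask stack
#'
#' Pixels with probability strictly greater than the threshold are
#' catheter regions; a pixel at exactly the threshold is background.
#'
#' @param mask a `prob_mask_stack` or a bare numeric array.
#' @param threshold probability cutoff (default 0.5).
#' @return Binary (0/1) integer array of the same shape.
#' @export
binarize <- function(mask, threshold = 0.5) {
  x <- if (inherits(mask, "prob_mask_stack")) mask$data else mask
  array(as.integer(x > threshold), dim = dim(x))
}

#' Save / load a model as plain text (RDS-free)
#'
#' Checkpoints are written as a JSON sidecar (config, modality, layer
#' table) plus a flat binary-free representation of the weights encoded
#' in the JSON itself. Adequate for the small desk-scale networks this
#' package trains.
#'
#' @param model a `unet_model`.
#' @param path output file (JSON).
#' @return `save_unet` returns `path` invisibly; `load_unet` returns
#'   the restored model.
#' @export
save_unet <- function(model, path) {
  obj <- list(
    config = unclass(model$config), modality = model$modality,
    n_params = model$n_params,
    params = lapply(model$params, function(p)
      list(dim = dim(p) %||% length(p), values = as.numeric(p)))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(unet_config, obj$config[c(
    "n_levels", "widths", "in_channels", "learning_rate", "epochs",
    "batch_size", "smooth_eps", "patch_size", "init_bias", "rng_seed"
  )])
  model <- build_unet(cfg, modality = obj$modality)
  for (nm in names(model$params)) {
    p <- obj$params[[nm]]
    model$params[[nm]] <- if (length(p$dim) > 1)
      array(p$values, dim = p$dim) else as.numeric(p$values)
  }
  model
}
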