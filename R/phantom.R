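#' Phantom configuration
#'
#' Parameters of the synthetic dual-contrast MR phantom. Defaults emulate
#' the clinical acquisition the method targets: 0.5327 x 0.5327 mm
#' in-plane pixels with 1 mm slices, marker-filled catheters that are
#' bright on T1W and dark (signal voids) on T2W, tissue-like background
#' texture, and dark air-cavity confounders that mimic the structures a
#' planner can confuse with catheters.
#'
#' @param shape integer length-3: voxels per axis (rows, cols, slices);
#'   all entries must be >= 8.
#' @param spacing_mm voxel size in mm per axis.
#' @param n_catheters number of catheters (>= 1).
#' @param curvature maximum in-plane drift per slice, in voxels. Tracks
#'   are smooth random walks whose per-slice step never exceeds this.
#' @param t1_contrast catheter-to-background intensity offset in T1W;
#'   must be positive (catheters are bright on T1W).
#' @param t2_contrast offset in T2W; must be negative (signal voids).
#' @param noise_sd additive white-noise standard deviation.
#' @param n_cavities number of dark ellipsoidal confounder blobs.
#' @param rng_seed integer seed; the whole phantom is a deterministic
#'   function of the config.
#' @param catheter_radius nominal catheter radius in in-plane voxels,
#'   used for label disks (approximately a 6F catheter at 0.53 mm pixels).
#' @param background_mean mean background tissue intensity.
#' @param texture_sd standard deviation of the smoothed background
#'   texture field.
#' @param total_length_mm physical catheter length (clinical 6F catheters
#'   are 294 mm).
#' @param template_thickness_mm thickness of the perineal template.
#' @param start_slice template plane: the slice index where every
#'   catheter is seeded.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(96L, 96L, 40L),
                           spacing_mm = c(0.5327, 0.5327, 1.0),
                           n_catheters = 10L,
                           curvature = 0.8,
                           t1_contrast = 60,
                           t2_contrast = -60,
                           noise_sd = 8,
                           n_cavities = 3L,
                           rng_seed = 1L,
                           catheter_radius = 2L,
                           background_mean = 100,
                           texture_sd = 12,
                           total_length_mm = 294,
                           template_thickness_mm = 20,
                           start_slice = 2L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("`shape` must be 3 integers, all >= 8")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive values")
  if (n_catheters < 1L) stop("`n_catheters` must be >= 1")
  if (t1_contrast <= 0) stop("`t1_contrast` must be positive (bright in T1W)")
  if (t2_contrast >= 0) stop("`t2_contrast` must be negative (dark in T2W)")
  if (curvature < 0) stop("`curvature` must be >= 0")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (start_slice < 1L || start_slice >= shape[3])
    stop("`start_slice` must lie inside the volume")
  structure(list(
    shape = shape, spacing_mm = as.numeric(spacing_mm),
    n_catheters = as.integer(n_catheters), curvature = curvature,
    t1_contrast = t1_contrast, t2_contrast = t2_contrast,
    noise_sd = noise_sd, n_cavities = as.integer(n_cavities),
    rng_seed = as.integer(rng_seed),
    catheter_radius = as.integer(catheter_radius),
    background_mean = background_mean, texture_sd = texture_sd,
    total_length_mm = total_length_mm,
    template_thickness_mm = template_thickness_mm,
    start_slice = as.integer(start_slice)
  ), class = "phantom_config")
}

# evaluate expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# integer (dr, dc) offsets of a filled disk of the given radius
disk_offsets <- function(radius) {
  r <- as.integer(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

# smooth a (H, W, S) array slice-wise with a 5x5 Gaussian kernel
smooth_slices <- function(arr) {
  d <- dim(arr)
  k1 <- exp(-((-2:2)^2) / (2 * 1.2^2))
  ker <- outer(k1, k1)
  ker <- ker / sum(ker)
  x <- array(arr, dim = c(d[1], d[2], 1L, d[3]))
  w <- array(ker, dim = c(5L, 5L, 1L, 1L))
  y <- conv_fwd_cpp(x, w, 0, FALSE)
  array(y, dim = d)
}

# jittered grid of seed positions in the central region; errors when the
# volume cannot hold that many catheters at workable separation
seed_grid <- function(shape, n, margin) {
  usable <- shape[1:2] - 2 * margin
  ncol_g <- ceiling(sqrt(n))
  nrow_g <- ceiling(n / ncol_g)
  sep <- min(usable / c(nrow_g, ncol_g))
  if (sep < 8)
    stop("sizing error: ", n, " catheters do not fit a ", shape[1], "x",
         shape[2], " field of view at >= 8 voxel separation")
  rows <- margin + (seq_len(nrow_g) - 0.5) * usable[1] / nrow_g
  cols <- margin + (seq_len(ncol_g) - 0.5) * usable[2] / ncol_g
  g <- expand.grid(row = rows, col = cols)[seq_len(n), , drop = FALSE]
  jitter <- matrix(runif(2 * n, -1.5, 1.5), ncol = 2)
  as.matrix(g) + jitter
}

# smooth random-walk in-plane drift: per-slice steps, low-pass filtered,
# rescaled so no step exceeds `curvature` voxels
smooth_walk <- function(n_steps, curvature) {
  if (n_steps == 0) return(numeric(0))
  raw <- rnorm(n_steps + 8, sd = max(curvature, 1e-8) / 2)
  sm <- stats::filter(raw, rep(1 / 5, 5), sides = 2)
  sm <- as.numeric(sm[5:(4 + n_steps)])
  sm[is.na(sm)] <- 0
  m <- max(abs(sm))
  if (m > curvature && m > 0) sm <- sm * curvature / m
  sm
}

#' Generate a paired T1W/T2W phantom with known catheter paths
#'
#' Renders smoothly curving catheter tracks into two co-registered
#' synthetic MR volumes. Catheter cross-sections have a Gaussian radial
#' intensity profile (partial-volume-like falloff) added to the
#' background: positive in T1W, negative in T2W. The background is a
#' tissue-like smoothed noise texture; optional ellipsoidal cavities are
#' dark in both contrasts and are placed away from every catheter track.
#'
#' @param config a [phantom_config].
#' @return A list with elements `t1w`, `t2w` ([image_volume]s), `paths`
#'   (list of ground-truth paths: `catheter_id`, `slices`, `points`
#'   (n x 2 matrix of row/col), `insertion_length_mm`, `free_length_mm`),
#'   and `geometry` (a [template_geometry] matching the truth, usable to
#'   drive reconstruction).
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$rng_seed, {
    shp <- config$shape
    margin <- 10
    m <- config$start_slice
    max_covered <- shp[3] - m

    # sizing: a smoothed walk's expected drift envelope grows like
    # curvature * sqrt(slices); reject setups whose envelope exceeds
    # the seed-to-border distance
    if (config$curvature * sqrt(max_covered) > min(shp[1:2]) / 2 - margin)
      stop("sizing error: curvature ", config$curvature,
           " voxels/slice over ", max_covered,
           " slices exceeds the field of view")

    seeds <- seed_grid(shp, config$n_catheters, margin)

    # insertion depths: deep implants spanning most of the stack, but
    # varying per catheter as clinical depths do
    ins_max <- max_covered * config$spacing_mm[3]
    ins <- runif(config$n_catheters, 0.70 * ins_max, 0.95 * ins_max)
    free_len <- config$total_length_mm - config$template_thickness_mm - ins

    paths <- vector("list", config$n_catheters)
    for (i in seq_len(config$n_catheters)) {
      covered <- floor(ins[i] / config$spacing_mm[3] + 1e-9)
      slices <- m:(m + covered)
      n_steps <- length(slices) - 1L
      dr <- smooth_walk(n_steps, config$curvature)
      dc <- smooth_walk(n_steps, config$curvature)
      rows <- pmin(pmax(seeds[i, 1] + cumsum(c(0, dr)), margin / 2), shp[1] - margin / 2)
      cols <- pmin(pmax(seeds[i, 2] + cumsum(c(0, dc)), margin / 2), shp[2] - margin / 2)
      paths[[i]] <- list(
        catheter_id = i, slices = slices,
        points = cbind(row = rows, col = cols),
        insertion_length_mm = ins[i], free_length_mm = free_len[i]
      )
    }

    # background texture, independent per contrast
    mk_bg <- function() {
      tex <- smooth_slices(array(rnorm(prod(shp)), dim = shp))
      tex <- tex / stats::sd(as.vector(tex)) * config$texture_sd
      config$background_mean + tex
    }
    t1 <- mk_bg()
    t2 <- mk_bg()

    # dark ellipsoidal cavities in both contrasts, kept clear of tracks
    all_pts <- do.call(rbind, lapply(paths, function(p)
      cbind(p$points, slice = p$slices)))
    placed <- 0L
    tries <- 0L
    while (placed < config$n_cavities && tries < 200L) {
      tries <- tries + 1L
      ctr <- c(runif(1, margin, shp[1] - margin),
               runif(1, margin, shp[2] - margin),
               runif(1, 3, shp[3] - 3))
      rad <- c(runif(1, 3, 6), runif(1, 3, 6), runif(1, 2, 5))
      near <- all_pts[abs(all_pts[, 3] - ctr[3]) <= rad[3] + 1, , drop = FALSE]
      if (nrow(near) > 0) {
        d <- sqrt((near[, 1] - ctr[1])^2 + (near[, 2] - ctr[2])^2)
        if (min(d) < max(rad[1:2]) + config$catheter_radius + 2) next
      }
      rr <- max(1, floor(ctr[1] - rad[1])):min(shp[1], ceiling(ctr[1] + rad[1]))
      cc <- max(1, floor(ctr[2] - rad[2])):min(shp[2], ceiling(ctr[2] + rad[2]))
      ss <- max(1, floor(ctr[3] - rad[3])):min(shp[3], ceiling(ctr[3] + rad[3]))
      for (s in ss) for (co in cc) for (ro in rr) {
        u <- ((ro - ctr[1]) / rad[1])^2 + ((co - ctr[2]) / rad[2])^2 +
          ((s - ctr[3]) / rad[3])^2
        if (u <= 1) {
          depth <- 70 * (1 - u)
          t1[ro, co, s] <- t1[ro, co, s] - depth
          t2[ro, co, s] <- t2[ro, co, s] - depth
        }
      }
      placed <- placed + 1L
    }

    # catheter cross-sections: Gaussian radial profile, peak = contrast
    sigma <- config$catheter_radius / 1.6
    win <- config$catheter_radius + 2L
    for (p in paths) {
      for (j in seq_along(p$slices)) {
        s <- p$slices[j]
        r0 <- p$points[j, 1]; c0 <- p$points[j, 2]
        rr <- max(1, floor(r0 - win)):min(shp[1], ceiling(r0 + win))
        cc <- max(1, floor(c0 - win)):min(shp[2], ceiling(c0 + win))
        prof <- exp(-(outer((rr - r0)^2, (cc - c0)^2, `+`)) / (2 * sigma^2))
        t1[rr, cc, s] <- t1[rr, cc, s] + config$t1_contrast * prof
        t2[rr, cc, s] <- t2[rr, cc, s] + config$t2_contrast * prof
      }
    }

    if (config$noise_sd > 0) {
      t1 <- t1 + array(rnorm(prod(shp), sd = config$noise_sd), dim = shp)
      t2 <- t2 + array(rnorm(prod(shp), sd = config$noise_sd), dim = shp)
    }

    geometry <- template_geometry(
      total_length_mm = rep(config$total_length_mm, config$n_catheters),
      free_length_mm = free_len,
      template_thickness_mm = config$template_thickness_mm,
      start_slice = m,
      seeds = do.call(rbind, lapply(paths, function(p) p$points[1, ]))
    )

    list(
      t1w = image_volume(t1, config$spacing_mm, "t1w"),
      t2w = image_volume(t2, config$spacing_mm, "t2w"),
      paths = paths,
      geometry = geometry,
      config = config
    )
  })
}

#' Rasterize ground-truth paths into a binary label mask
#'
#' Draws a filled disk of the given radius at each (rounded) path point,
#' one per covered slice. These are the training labels for the
#' segmentation network and the reference masks for overlap metrics.
#'
#' @param paths list of ground-truth paths (as from [generate_phantom]).
#' @param shape integer length-3 volume shape.
#' @param radius disk radius in in-plane voxels; `0` marks the single
#'   centre voxel.
#' @return A binary (0/1) array of the given shape.
#' @export
rasterize_truth_mask <- function(paths, shape, radius = 2L) {
  shape <- as.integer(shape)
  mask <- array(0L, dim = shape)
  offs <- disk_offsets(radius)
  for (p in paths) {
    for (j in seq_along(p$slices)) {
      s <- p$slices[j]
      r0 <- round(p$points[j, 1]); c0 <- round(p$points[j, 2])
      if (r0 < 1 || r0 > shape[1] || c0 < 1 || c0 > shape[2] ||
          s < 1 || s > shape[3])
        stop("point of catheter ", p$catheter_id, " on slice ", s,
             " lies outside the volume")
      rr <- r0 + offs$dr; cc <- c0 + offs$dc
      keep <- rr >= 1 & rr <= shape[1] & cc >= 1 & cc <= shape[2]
      mask[cbind(rr[keep], cc[keep], s)] <- 1L
    }
  }
  mask
}
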