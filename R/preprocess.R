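#' Extract 2D patches from a volume and its label mask
#'
#' Cuts aligned `patch_size x patch_size` windows from image slices and
#' the corresponding label mask. Windows are always fully inside the
#' slice: requested centers near an edge are shifted inward rather than
#' zero-padded, so every patch contains genuine image content.
#'
#' @param volume an [image_volume].
#' @param labels binary array of the same shape (may be `NULL` for
#'   inference-style extraction; label patches are then all-zero).
#' @param patch_size window side length in voxels.
#' @param centers optional matrix with columns `(slice, row, col)` of
#'   requested window centers. When `NULL`, slices are tiled with the
#'   given stride.
#' @param stride tiling stride when `centers` is `NULL`; defaults to
#'   `patch_size` (non-overlapping tiling). The final window in each
#'   direction is shifted to end exactly at the slice border, so the
#'   whole slice is always covered.
#' @param slices slice indices to tile; defaults to all.
#' @return A list of patches; each is a list with `pixels` and `label`
#'   (`patch_size x patch_size` matrices), `source = c(slice, row_off,
#'   col_off)` (1-based offsets of the window's top-left corner) and
#'   `modality`.
#' @export
extract_patches <- function(volume, labels = NULL, patch_size = 64L,
                            centers = NULL, stride = NULL, slices = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  d <- dim(volume$data)
  ps <- as.integer(patch_size)
  if (ps > d[1] || ps > d[2])
    stop("patch_size ", ps, " exceeds slice dimensions ", d[1], "x", d[2])
  if (!is.null(labels)) {
    stopifnot(all(dim(labels) == d))
    if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  }

  windows <- NULL
  if (!is.null(centers)) {
    centers <- rbind(centers)
    ro <- pmin(pmax(round(centers[, 2]) - ps %/% 2, 1L), d[1] - ps + 1L)
    co <- pmin(pmax(round(centers[, 3]) - ps %/% 2, 1L), d[2] - ps + 1L)
    windows <- cbind(slice = centers[, 1], row_off = ro, col_off = co)
  } else {
    if (is.null(stride)) stride <- ps
    offs <- function(n) unique(c(seq(1L, n - ps + 1L, by = stride), n - ps + 1L))
    if (is.null(slices)) slices <- seq_len(d[3])
    g <- expand.grid(row_off = offs(d[1]), col_off = offs(d[2]), slice = slices)
    windows <- cbind(slice = g$slice, row_off = g$row_off, col_off = g$col_off)
  }

  lapply(seq_len(nrow(windows)), function(i) {
    s <- windows[i, "slice"]; r <- windows[i, "row_off"]; c0 <- windows[i, "col_off"]
    lab <- if (is.null(labels)) matrix(0, ps, ps)
           else labels[r:(r + ps - 1L), c0:(c0 + ps - 1L), s]
    list(
      pixels = volume$data[r:(r + ps - 1L), c0:(c0 + ps - 1L), s],
      label = lab,
      source = c(slice = unname(s), row_off = unname(r), col_off = unname(c0)),
      modality = volume$modality
    )
  })
}

# bilinear sampling of matrix `img` at fractional (row, col) coordinates;
# points outside the matrix sample as `fill`
bilinear_sample <- function(img, rows, cols, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  r0 <- floor(rows); c0 <- floor(cols)
  fr <- rows - r0; fc <- cols - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out <- rep(fill, length(ri))
    out[ok] <- img[cbind(ri[ok], ci[ok])]
    out
  }
  val(r0, c0) * (1 - fr) * (1 - fc) +
    val(r0 + 1, c0) * fr * (1 - fc) +
    val(r0, c0 + 1) * (1 - fr) * fc +
    val(r0 + 1, c0 + 1) * fr * fc
}

#' Geometrically augment a patch
#'
#' Applies the same in-plane rigid+scale transform to the pixel window
#' and its label: rotation and isotropic scaling about the patch centre,
#' then translation. Pixels are resampled bilinearly; the label is
#' resampled bilinearly and re-binarized at 0.5 so it stays strictly
#' binary. Parameters are normalized/clamped to the configured ranges
#' (rotation is first wrapped to (-180, 180]); regions mapped from
#' outside the patch fill with 0.
#'
#' @param patch a patch from [extract_patches].
#' @param translation length-2 `(dr, dc)` shift in voxels.
#' @param scale isotropic scale factor.
#' @param rotation_deg rotation angle, degrees, counter-clockwise.
#' @param rng_seed if given and any parameter is `NULL`, missing
#'   parameters are drawn uniformly from the allowed ranges.
#' @param max_translation,scale_range,max_rotation allowed parameter
#'   ranges; out-of-range requests are clamped, not rejected.
#' @return The transformed patch (same structure as the input).
#' @export
augment_patch <- function(patch, translation = c(0, 0), scale = 1,
                          rotation_deg = 0, rng_seed = NULL,
                          max_translation = 8, scale_range = c(0.9, 1.1),
                          max_rotation = 360) {
  if (!is.null(rng_seed)) {
    drawn <- with_seed(rng_seed, list(
      translation = runif(2, -max_translation, max_translation),
      scale = runif(1, scale_range[1], scale_range[2]),
      rotation = runif(1, -max_rotation, max_rotation)
    ))
    if (is.null(translation)) translation <- drawn$translation
    if (is.null(scale)) scale <- drawn$scale
    if (is.null(rotation_deg)) rotation_deg <- drawn$rotation
  }
  rotation_deg <- ((rotation_deg + 180) %% 360) - 180
  rotation_deg <- max(-max_rotation, min(max_rotation, rotation_deg))
  translation <- pmax(-max_translation, pmin(max_translation, translation))
  scale <- max(scale_range[1], min(scale_range[2], scale))

  ps <- nrow(patch$pixels)
  ctr <- (ps + 1) / 2
  th <- rotation_deg * pi / 180
  # output pixel (r, c) samples input at the inverse transform
  g <- expand.grid(r = seq_len(ps), c = seq_len(ps))
  dr <- g$r - ctr - translation[1]
  dc <- g$c - ctr - translation[2]
  src_r <- ctr + (cos(th) * dr + sin(th) * dc) / scale
  src_c <- ctr + (-sin(th) * dr + cos(th) * dc) / scale

  px <- matrix(bilinear_sample(patch$pixels, src_r, src_c), ps, ps)
  lb <- matrix(as.numeric(bilinear_sample(patch$label, src_r, src_c) > 0.5),
               ps, ps)
  patch$pixels <- px
  patch$label <- lb
  patch
}

#' Sample a balanced training patch set from a phantom
#'
#' Draws half the patches centered on labeled catheter cross-sections
#' (with a small random jitter so the catheter is not always dead
#' centre) and half at background positions, optionally with random
#' geometric augmentation. Class balance prevents the trivial
#' all-background solution on sparse labels.
#'
#' @param volume a normalized [image_volume].
#' @param labels binary label mask of the same shape.
#' @param n_patches total number of patches (half positive, half
#'   background).
#' @param patch_size window side length.
#' @param rng_seed integer seed.
#' @param augment fraction of patches to randomly perturb by
#'   translation/scale/rotation (0 disables).
#' @return List of patches as from [extract_patches].
#' @export
sample_training_patches <- function(volume, labels, n_patches = 1000L,
                                    patch_size = 64L, rng_seed = 1L,
                                    augment = 0.5) {
  d <- dim(volume$data)
  fg <- which(labels != 0, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("label mask has no foreground; cannot balance classes")
  with_seed(rng_seed, {
    n_pos <- n_patches %/% 2
    n_neg <- n_patches - n_pos
    ip <- sample(nrow(fg), n_pos, replace = TRUE)
    jit <- matrix(round(runif(2 * n_pos, -6, 6)), ncol = 2)
    pos_centers <- cbind(fg[ip, 3], fg[ip, 1] + jit[, 1], fg[ip, 2] + jit[, 2])

    neg_centers <- matrix(0, n_neg, 3)
    for (i in seq_len(n_neg)) {
      repeat {
        cand <- c(sample(d[3], 1), sample(d[1], 1), sample(d[2], 1))
        if (labels[cand[2], cand[3], cand[1]] == 0) break
      }
      neg_centers[i, ] <- cand
    }
    patches <- extract_patches(volume, labels, patch_size,
                               centers = rbind(pos_centers, neg_centers))
    if (augment > 0) {
      aug_idx <- which(runif(length(patches)) < augment)
      for (i in aug_idx) {
        patches[[i]] <- augment_patch(
          patches[[i]],
          translation = runif(2, -8, 8),
          scale = runif(1, 0.9, 1.1),
          rotation_deg = runif(1, -15, 15),
          max_rotation = 15
        )
      }
    }
    patches[sample(length(patches))]
  })
}
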