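#' Image volume container
#'
#' A 3D scalar image with per-axis voxel spacing and a modality tag. This
#' is the common currency between the phantom generator, the network and
#' the reconstruction stage. Voxel indices are 1-based `(row, col, slice)`;
#' physical coordinates are `(index - 1) * spacing` mm per axis, so the
#' first voxel centre sits at the origin.
#'
#' @param data 3D numeric array (rows x cols x slices).
#' @param spacing_mm numeric length-3, voxel size in mm per axis
#'   (row, col, slice). All entries must be positive.
#' @param modality `"t1w"`, `"t2w"`, or `"mask"`.
#' @return An object of class `image_volume`: a list with elements
#'   `data`, `spacing_mm` and `modality`.
#' @examples
#' vol <- image_volume(array(0, c(8, 8, 4)), c(0.5327, 0.5327, 1), "t1w")
#' dim(vol$data)
#' @export
image_volume <- function(data, spacing_mm, modality = c("t1w", "t2w", "mask")) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array, got ", length(dim(data)), " dims")
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 positive finite values")
  structure(
    list(data = data, spacing_mm = as.numeric(spacing_mm), modality = modality),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<image_volume %s> %d x %d x %d voxels, spacing %.4f x %.4f x %.4f mm\n",
    x$modality, d[1], d[2], d[3],
    x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]
  ))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Normalize a volume to zero mean and unit variance
#'
#' Intensity standardization applied before patch extraction and
#' inference, so that the network sees the same intensity scale it was
#' trained on regardless of scanner gain.
#'
#' @param volume an [image_volume].
#' @return An [image_volume] with standardized intensities; spacing,
#'   shape and modality are preserved.
#' @export
normalize_volume <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  mu <- mean(volume$data)
  sigma <- sqrt(mean((volume$data - mu)^2))  # population sd
  if (!is.finite(sigma) || sigma == 0)
    stop("cannot normalize a constant volume (sd = 0)")
  volume$data <- (volume$data - mu) / sigma
  volume
}

# world-mm coordinates of 1-based voxel indices; pts is a matrix with
# columns (row, col, slice)
voxel_to_mm <- function(pts, spacing_mm) {
  pts <- rbind(pts)
  sweep(pts - 1, 2, spacing_mm, `*`)
}
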