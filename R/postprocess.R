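#' Template geometry driving the reconstruction stopping rule
#'
#' Physical catheter geometry: the insertion depth of each catheter is
#' `total_length - (free_length + template_thickness)`, where the free
#' length is the part of the catheter outside the patient and the
#' template thickness is the perineal template the catheters pass
#' through. The insertion depth, divided by the slice thickness,
#' determines on which slice each reconstruction stops.
#'
#' @param total_length_mm per-catheter total physical length (clinical
#'   6F catheters are 294 mm).
#' @param free_length_mm per-catheter measured free length.
#' @param template_thickness_mm template thickness (scalar).
#' @param start_slice template plane: slice index `m` where all
#'   catheters are seeded.
#' @param seeds `n x 2` matrix of `(row, col)` seed positions on the
#'   start slice; one per catheter, all distinct.
#' @return A list of class `template_geometry`.
#' @export
template_geometry <- function(total_length_mm, free_length_mm,
                              template_thickness_mm, start_slice, seeds) {
  seeds <- rbind(seeds)
  n <- nrow(seeds)
  total_length_mm <- rep_len(total_length_mm, n)
  free_length_mm <- rep_len(free_length_mm, n)
  if (any(free_length_mm + template_thickness_mm > total_length_mm + 1e-9))
    stop("free length + template thickness exceeds total catheter length")
  if (any(free_length_mm < 0) || template_thickness_mm < 0)
    stop("lengths must be non-negative")
  if (anyDuplicated(round(seeds, 6)))
    stop("seed positions must be distinct")
  structure(list(
    total_length_mm = total_length_mm, free_length_mm = free_length_mm,
    template_thickness_mm = template_thickness_mm,
    start_slice = as.integer(start_slice), seeds = seeds
  ), class = "template_geometry")
}

#' Find candidate catheter cross-sections on a binary slice
#'
#' Labels 8-connected foreground components and returns one candidate
#' per component at the component's centroid (mean voxel position).
#'
#' @param mask_slice binary matrix (one axial slice).
#' @param min_size drop components smaller than this many voxels
#'   (default 1: keep everything).
#' @param modality tag recorded on each candidate.
#' @return Data frame with columns `row`, `col` (centroid), `size`
#'   (component voxels) and `modality`; zero rows for an empty slice.
#' @export
find_candidates <- function(mask_slice, min_size = 1L, modality = NA_character_) {
  m <- matrix(as.integer(mask_slice != 0), nrow(mask_slice), ncol(mask_slice))
  lab <- label_components_cpp(m)
  k <- max(lab)
  if (k == 0)
    return(data.frame(row = numeric(), col = numeric(), size = integer(),
                      modality = character()))
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[idx]
  rows <- tapply(idx[, 1], labs, mean)
  cols <- tapply(idx[, 2], labs, mean)
  sizes <- as.integer(table(labs))
  out <- data.frame(row = as.numeric(rows), col = as.numeric(cols),
                    size = sizes, modality = modality)
  out[out$size >= min_size, , drop = FALSE]
}

#' Refine a candidate position to the intensity extremum in a rectangle
#'
#' Within a rectangle centred on the approximate position (clipped to
#' the slice), returns the location of the intensity maximum for T1W
#' (catheters are hyperintense) or minimum for T2W (signal voids). Ties
#' are broken by smallest Euclidean distance to the approximate
#' position, then by row-major order.
#'
#' @param image_slice numeric matrix (intensity slice, not a mask).
#' @param approx length-2 `(row, col)` approximate position.
#' @param halfsize rectangle half side length in voxels.
#' @param modality `"t1w"` (argmax) or `"t2w"` (argmin).
#' @return Length-2 numeric `(row, col)` of the refined position.
#' @export
refine_in_rectangle <- function(image_slice, approx, halfsize = 5L,
                                modality = c("t1w", "t2w")) {
  modality <- match.arg(modality)
  H <- nrow(image_slice); W <- ncol(image_slice)
  r0 <- round(approx[1]); c0 <- round(approx[2])
  rr <- max(1, r0 - halfsize):min(H, r0 + halfsize)
  cc <- max(1, c0 - halfsize):min(W, c0 + halfsize)
  if (length(rr) == 0 || length(cc) == 0)
    stop("refinement rectangle is empty (approx position outside slice)")
  win <- image_slice[rr, cc, drop = FALSE]
  v <- if (modality == "t1w") win else -win
  best <- max(v)
  hits <- which(v >= best, arr.ind = TRUE)
  pr <- rr[hits[, 1]]; pc <- cc[hits[, 2]]
  d2 <- (pr - approx[1])^2 + (pc - approx[2])^2
  ord <- order(d2, pr, pc)
  c(row = pr[ord[1]], col = pc[ord[1]])
}

#' Link tracked catheters to candidates on the next slice
#'
#' Greedy one-to-one nearest-neighbour assignment: catheter-candidate
#' pairs are considered in ascending Euclidean in-plane distance (ties
#' by catheter id, then candidate index); a pair is accepted when both
#' are still free and the distance is within the neighbourhood radius.
#' Catheters left without a candidate inside the neighbourhood are
#' "jumping catheters"; surplus candidates are discarded as false
#' positives.
#'
#' @param positions `n x 2` matrix of current `(row, col)` per tracked
#'   catheter.
#' @param candidates data frame with `row`, `col` columns (as from
#'   [find_candidates] or [merge_modalities]).
#' @param neighborhood_px assignment radius in voxels (default 8).
#' @return List with `assignment` (candidate index per catheter, `NA`
#'   when jumped) and `jumped` (integer ids of unassigned catheters).
#' @export
link_next_slice <- function(positions, candidates, neighborhood_px = 8) {
  positions <- rbind(positions)
  n <- nrow(positions)
  if (n < 1) stop("at least one tracked catheter is required")
  m <- nrow(candidates)
  assignment <- rep(NA_integer_, n)
  if (m > 0) {
    dmat <- outer(positions[, 1], candidates$row, `-`)^2 +
      outer(positions[, 2], candidates$col, `-`)^2
    pairs <- expand.grid(cath = seq_len(n), cand = seq_len(m))
    pairs$d2 <- dmat[cbind(pairs$cath, pairs$cand)]
    pairs <- pairs[sqrt(pairs$d2) <= neighborhood_px, , drop = FALSE]
    pairs <- pairs[order(pairs$d2, pairs$cath, pairs$cand), , drop = FALSE]
    cand_free <- rep(TRUE, m)
    for (i in seq_len(nrow(pairs))) {
      ca <- pairs$cath[i]; cn <- pairs$cand[i]
      if (is.na(assignment[ca]) && cand_free[cn]) {
        assignment[ca] <- cn
        cand_free[cn] <- FALSE
      }
    }
  }
  list(assignment = assignment, jumped = which(is.na(assignment)))
}

#' Impute jumped catheter positions from the detected ones
#'
#' The correction adds the mean absolute per-axis displacement of the
#' detected catheters to each jumped catheter's previous position:
#' `dx = mean(|x_next - x_prev|)`, `dy = mean(|y_next - y_prev|)`, and
#' the corrected position is `(x + dx, y + dy)`. Note the absolute
#' values: the correction is non-negative along both axes by
#' construction. A signed-mean variant (`signed = TRUE`) is available
#' for sensitivity analyses; it is not the default behaviour.
#'
#' @param prev_detected,next_detected `k x 2` matrices of `(row, col)`
#'   for the catheters detected on both slices (`k >= 1`).
#' @param jumped_prev `j x 2` matrix of previous positions of the
#'   jumped catheters.
#' @param signed use signed mean displacement instead of the
#'   absolute-value form.
#' @return `j x 2` matrix of corrected positions.
#' @export
correct_jumping <- function(prev_detected, next_detected, jumped_prev,
                            signed = FALSE) {
  prev_detected <- rbind(prev_detected)
  next_detected <- rbind(next_detected)
  jumped_prev <- rbind(jumped_prev)
  if (nrow(prev_detected) == 0)
    stop("no detected catheters: jump correction is undefined")
  if (nrow(prev_detected) != nrow(next_detected))
    stop("detected catheter sets differ in size between slices")
  disp <- next_detected - prev_detected
  delta <- if (signed) colMeans(disp) else colMeans(abs(disp))
  sweep(jumped_prev, 2, delta, `+`)
}

#' Stopping slice from physical catheter geometry
#'
#' The insertion depth is `total - (free + template)` mm; divided by
#' the slice thickness (catheters are roughly axial) it gives the
#' number of slices covered beyond the template plane, so
#' `stop = start + floor(insertion / thickness)`.
#'
#' @param geometry a [template_geometry].
#' @param slice_thickness_mm axial voxel size in mm.
#' @return Integer vector of stopping slice indices, one per catheter.
#' @export
compute_stop_slice <- function(geometry, slice_thickness_mm) {
  stopifnot(inherits(geometry, "template_geometry"))
  ins <- geometry$total_length_mm -
    (geometry$free_length_mm + geometry$template_thickness_mm)
  if (any(ins < -1e-9)) stop("negative insertion length")
  geometry$start_slice + as.integer(floor(ins / slice_thickness_mm + 1e-9))
}

#' Fuse candidate lists from the two MR contrasts
#'
#' T1W and T2W candidates within `tolerance_px` of each other (greedy
#' one-to-one, ascending distance) are merged to their coordinate mean
#' and flagged dual-modality; unmatched candidates are kept as
#' single-modality detections.
#'
#' @param t1w,t2w candidate data frames with `row`, `col` columns.
#' @param tolerance_px merge radius in voxels.
#' @return Data frame with `row`, `col`, `modality` (`"dual"`, `"t1w"`
#'   or `"t2w"`).
#' @export
merge_modalities <- function(t1w, t2w, tolerance_px = 2) {
  n1 <- nrow(t1w); n2 <- nrow(t2w)
  used1 <- rep(FALSE, n1); used2 <- rep(FALSE, n2)
  merged <- list()
  if (n1 > 0 && n2 > 0) {
    pairs <- expand.grid(i = seq_len(n1), j = seq_len(n2))
    pairs$d2 <- (t1w$row[pairs$i] - t2w$row[pairs$j])^2 +
      (t1w$col[pairs$i] - t2w$col[pairs$j])^2
    pairs <- pairs[sqrt(pairs$d2) <= tolerance_px, , drop = FALSE]
    pairs <- pairs[order(pairs$d2, pairs$i, pairs$j), , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      if (!used1[i] && !used2[j]) {
        used1[i] <- TRUE; used2[j] <- TRUE
        merged[[length(merged) + 1]] <- data.frame(
          row = (t1w$row[i] + t2w$row[j]) / 2,
          col = (t1w$col[i] + t2w$col[j]) / 2,
          modality = "dual"
        )
      }
    }
  }
  singles1 <- if (any(!used1))
    data.frame(row = t1w$row[!used1], col = t1w$col[!used1], modality = "t1w")
  singles2 <- if (any(!used2))
    data.frame(row = t2w$row[!used2], col = t2w$col[!used2], modality = "t2w")
  out <- do.call(rbind, c(merged, list(singles1), list(singles2)))
  if (is.null(out))
    out <- data.frame(row = numeric(), col = numeric(), modality = character())
  rownames(out) <- NULL
  out
}

#' Reconstruct all catheter paths through the volume
#'
#' Iterates slice by slice from the template plane to each catheter's
#' stopping slice. On every slice the binary masks of both contrasts
#' yield candidates (8-connected components), each refined to the local
#' intensity extremum of its own contrast inside a rectangle; the two
#' candidate sets are fused; tracked catheters link to their nearest
#' fused candidate within the neighbourhood radius; catheters with no
#' candidate in reach ("jumping catheters") are imputed from the mean
#' absolute displacement of the detected ones, or carried over
#' unchanged when nothing at all was detected on the transition. Every
#' seed always yields a complete path from the template plane to its
#' stopping slice.
#'
#' @param t1w,t2w co-registered [image_volume]s (intensities; used for
#'   extremum refinement).
#' @param t1w_mask,t2w_mask binary mask stacks (arrays) from [binarize],
#'   or oracle masks.
#' @param geometry a [template_geometry] with one seed per catheter.
#' @param rect_halfsize refinement rectangle half size (voxels).
#' @param neighborhood_px linking radius (voxels).
#' @param merge_tolerance_px dual-contrast merge radius (voxels).
#' @param min_component_size smallest candidate component kept.
#' @param signed_jump_correction use the signed-mean displacement
#'   variant of the jump correction.
#' @return List of `catheter_path` objects: `catheter_id`, `slices`,
#'   `points` (`n x 2` row/col), `provenance` (`"seed"`, `"linked"` or
#'   `"jump-corrected"` per point) and `spacing_mm`.
#' @export
reconstruct_catheters <- function(t1w, t2w, t1w_mask, t2w_mask, geometry,
                                  rect_halfsize = 5L, neighborhood_px = 8,
                                  merge_tolerance_px = 2,
                                  min_component_size = 1L,
                                  signed_jump_correction = FALSE) {
  stopifnot(inherits(t1w, "image_volume"), inherits(t2w, "image_volume"),
            inherits(geometry, "template_geometry"))
  d <- dim(t1w$data)
  if (!all(dim(t2w$data) == d))
    stop("T1W and T2W volumes differ in shape")
  if (!all(dim(t1w_mask) == d) || !all(dim(t2w_mask) == d))
    stop("mask stacks must match the volume shape")
  n <- nrow(geometry$seeds)
  if (n == 0) stop("no seeds given")
  m <- geometry$start_slice
  stops <- compute_stop_slice(geometry, t1w$spacing_mm[3])
  if (any(stops > d[3]))
    stop("stopping slice ", max(stops), " exceeds the volume (",
         d[3], " slices)")

  pos <- rbind(geometry$seeds)
  paths <- lapply(seq_len(n), function(i) list(
    catheter_id = i, slices = m,
    points = matrix(pos[i, ], 1, 2, dimnames = list(NULL, c("row", "col"))),
    provenance = "seed", spacing_mm = t1w$spacing_mm
  ))

  if (max(stops) > m) for (s in (m + 1):max(stops)) {
    active <- which(stops >= s)
    if (length(active) == 0) break

    cand1 <- find_candidates(t1w_mask[, , s], min_component_size, "t1w")
    cand2 <- find_candidates(t2w_mask[, , s], min_component_size, "t2w")
    if (nrow(cand1) > 0)
      for (k in seq_len(nrow(cand1))) {
        p <- refine_in_rectangle(t1w$data[, , s], c(cand1$row[k], cand1$col[k]),
                                 rect_halfsize, "t1w")
        cand1$row[k] <- p[1]; cand1$col[k] <- p[2]
      }
    if (nrow(cand2) > 0)
      for (k in seq_len(nrow(cand2))) {
        p <- refine_in_rectangle(t2w$data[, , s], c(cand2$row[k], cand2$col[k]),
                                 rect_halfsize, "t2w")
        cand2$row[k] <- p[1]; cand2$col[k] <- p[2]
      }
    fused <- merge_modalities(cand1, cand2, merge_tolerance_px)

    link <- link_next_slice(pos[active, , drop = FALSE], fused, neighborhood_px)
    newpos <- pos
    detected <- active[!is.na(link$assignment)]
    if (length(detected) > 0) {
      ai <- link$assignment[!is.na(link$assignment)]
      newpos[detected, 1] <- fused$row[ai]
      newpos[detected, 2] <- fused$col[ai]
    }
    jumped <- active[is.na(link$assignment)]
    if (length(jumped) > 0) {
      if (length(detected) > 0) {
        corr <- correct_jumping(pos[detected, , drop = FALSE],
                                newpos[detected, , drop = FALSE],
                                pos[jumped, , drop = FALSE],
                                signed = signed_jump_correction)
        # keep imputed positions inside the slice
        corr[, 1] <- pmin(pmax(corr[, 1], 1), d[1])
        corr[, 2] <- pmin(pmax(corr[, 2], 1), d[2])
        newpos[jumped, ] <- corr
      }
      # all-jumped transition: positions carry over unchanged
    }

    for (i in active) {
      paths[[i]]$slices <- c(paths[[i]]$slices, s)
      paths[[i]]$points <- rbind(paths[[i]]$points, newpos[i, ])
      paths[[i]]$provenance <- c(
        paths[[i]]$provenance,
        if (i %in% jumped) "jump-corrected" else "linked"
      )
    }
    pos <- newpos
  }
  lapply(paths, function(p) structure(p, class = "catheter_path"))
}

#' @export
print.catheter_path <- function(x, ...) {
  cat(sprintf("<catheter_path %d> slices %d..%d (%d points, %d jump-corrected)\n",
              x$catheter_id, min(x$slices), max(x$slices), length(x$slices),
              sum(x$provenance == "jump-corrected")))
  invisible(x)
}

#' Flatten reconstructed paths to a data frame
#'
#' @param paths list of `catheter_path` objects.
#' @return Data frame with catheter_id, slice, row, col, x_mm, y_mm,
#'   z_mm and provenance.
#' @export
paths_to_df <- function(paths) {
  do.call(rbind, lapply(paths, function(p) {
    mm <- voxel_to_mm(cbind(p$points, p$slices), p$spacing_mm)
    data.frame(
      catheter_id = p$catheter_id, slice = p$slices,
      row = p$points[, 1], col = p$points[, 2],
      x_mm = mm[, 1], y_mm = mm[, 2], z_mm = mm[, 3],
      provenance = p$provenance
    )
  }))
}
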