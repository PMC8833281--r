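# path (catheter_path or ground-truth path) -> n x 3 matrix of mm coords
path_points_mm <- function(path, voxel_spacing_mm = NULL) {
  sp <- path$spacing_mm %||% voxel_spacing_mm
  if (is.null(sp))
    stop("path carries no spacing; supply `voxel_spacing_mm`")
  voxel_to_mm(cbind(path$points, path$slices), sp)
}

#' Resample a catheter path into dwell positions at fixed arc-length
#'
#' Piecewise-linear arc-length parameterization of the path's 3D world
#' coordinates, sampled at 0, 1, 2, ... times the dwell spacing. The
#' terminal point (catheter tip) is always included even when the last
#' interval is shorter than the spacing, because the tip position is
#' clinically salient.
#'
#' @param path a `catheter_path` (or a phantom ground-truth path, in
#'   which case `voxel_spacing_mm` must be given).
#' @param spacing_mm dwell spacing along the path in mm (default 1).
#' @param voxel_spacing_mm voxel size, for paths that do not carry one.
#' @return A list of class `dwell_set`: `catheter_id`, `points`
#'   (`k x 3` matrix, mm), `arc_length_mm`.
#' @export
sample_dwells <- function(path, spacing_mm = 1.0, voxel_spacing_mm = NULL) {
  pts <- path_points_mm(path, voxel_spacing_mm)
  if (nrow(pts) == 0) stop("empty path")
  if (nrow(pts) == 1) {
    return(structure(list(catheter_id = path$catheter_id, points = pts,
                          arc_length_mm = 0), class = "dwell_set"))
  }
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-nrow(pts), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  targets <- seq(0, total, by = spacing_mm)
  if (total - targets[length(targets)] > 1e-9) targets <- c(targets, total)
  out <- matrix(0, length(targets), 3)
  for (k in seq_along(targets)) {
    tt <- targets[k]
    i <- findInterval(tt, cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), nrow(pts) - 1L)
    f <- if (seg[i] > 0) (tt - cum[i]) / seg[i] else 0
    out[k, ] <- pts[i, ] + f * (pts[i + 1, ] - pts[i, ])
  }
  structure(list(catheter_id = path$catheter_id, points = out,
                 arc_length_mm = total), class = "dwell_set")
}

# min distance from each row of pts (n x 3) to polyline poly (m x 3)
dist_to_polyline <- function(pts, poly) {
  pts <- rbind(pts); poly <- rbind(poly)
  if (nrow(poly) == 1) {
    return(sqrt(rowSums(sweep(pts, 2, poly[1, ])^2)))
  }
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(poly) - 1)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    ab <- b - a
    ab2 <- sum(ab^2)
    ap <- sweep(pts, 2, a)
    tproj <- if (ab2 > 0) pmin(pmax(as.vector(ap %*% ab) / ab2, 0), 1) else 0
    close <- outer(tproj, ab) + matrix(a, nrow(pts), 3, byrow = TRUE)
    d <- sqrt(rowSums((pts - close)^2))
    best <- pmin(best, d)
  }
  best
}

#' Dwell-position deviation between two catheter paths
#'
#' For every dwell in `a`, the Euclidean distance to the nearest point
#' of the polyline through `b`'s dwells (not index-paired: longitudinal
#' offset along the catheter is not counted as error). `paired = TRUE`
#' switches to index pairing for sensitivity analyses.
#'
#' @param a,b `dwell_set` objects for the same catheter.
#' @param paired pair dwells by index instead of nearest-point.
#' @return List: `deviations_mm` (per dwell of `a`), `mean`, `sd`,
#'   `frac_lt_2mm`, `frac_gt_3mm`, `n`.
#' @export
dwell_deviation <- function(a, b, paired = FALSE) {
  if (nrow(a$points) == 0 || nrow(b$points) == 0) stop("empty dwell set")
  dev <- if (paired) {
    k <- min(nrow(a$points), nrow(b$points))
    sqrt(rowSums((a$points[seq_len(k), , drop = FALSE] -
                    b$points[seq_len(k), , drop = FALSE])^2))
  } else {
    dist_to_polyline(a$points, b$points)
  }
  list(
    deviations_mm = dev, mean = mean(dev), sd = stats::sd(dev),
    frac_lt_2mm = mean(dev < 2), frac_gt_3mm = mean(dev > 3),
    n = length(dev)
  )
}

#' Dice similarity coefficient of two binary stacks
#'
#' `2|A and B| / (|A| + |B|)`; defined as 1 when both stacks are empty.
#'
#' @param a,b binary arrays of identical shape.
#' @return Scalar in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("shape mismatch")
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1.0)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

#' Symmetric Hausdorff distance between two dwell sets
#'
#' Point-set Hausdorff on the dwell points: the larger of the two
#' directed max-min distances.
#'
#' @param a,b `dwell_set` objects (or bare `n x 3` matrices).
#' @return Scalar distance in mm.
#' @export
hausdorff_dist <- function(a, b) {
  pa <- if (inherits(a, "dwell_set")) a$points else rbind(a)
  pb <- if (inherits(b, "dwell_set")) b$points else rbind(b)
  if (nrow(pa) == 0 || nrow(pb) == 0) stop("empty point set")
  d2 <- outer(rowSums(pa^2), rep(1, nrow(pb))) +
    outer(rep(1, nrow(pa)), rowSums(pb^2)) - 2 * pa %*% t(pb)
  d <- sqrt(pmax(d2, 0))
  max(max(apply(d, 1, min)), max(apply(d, 2, min)))
}

#' Evaluate a reconstruction against ground truth
#'
#' Samples dwell positions at 1 mm arc-length spacing along each
#' reconstructed and reference path, pools per-dwell deviations
#' (nearest point on the reference polyline) over all catheters, and
#' additionally reports the Dice overlap of the rasterized paths and
#' the mean per-catheter Hausdorff distance.
#'
#' @param pred_paths list of reconstructed `catheter_path`s.
#' @param truth_paths list of reference paths (same catheter ids).
#' @param voxel_spacing_mm voxel size (used for truth paths and
#'   rasterization).
#' @param shape volume shape for path rasterization (`NULL` skips DSC).
#' @param radius disk radius for rasterization.
#' @param dwell_spacing_mm dwell spacing (default 1 mm).
#' @return A list of class `eval_report`: pooled `deviations_mm`,
#'   `mean`, `sd`, `frac_lt_2mm`, `frac_gt_3mm`, `dsc`,
#'   `hausdorff_mean_mm`, `n_dwells` and `per_catheter` (data frame).
#' @export
evaluate_reconstruction <- function(pred_paths, truth_paths, voxel_spacing_mm,
                                    shape = NULL, radius = 2L,
                                    dwell_spacing_mm = 1.0) {
  truth_ids <- vapply(truth_paths, function(p) p$catheter_id, 0)
  devs <- list()
  rows <- list()
  for (p in pred_paths) {
    tp <- truth_paths[[match(p$catheter_id, truth_ids)]]
    da <- sample_dwells(p, dwell_spacing_mm, voxel_spacing_mm)
    db <- sample_dwells(tp, dwell_spacing_mm, voxel_spacing_mm)
    dd <- dwell_deviation(da, db)
    hd <- hausdorff_dist(da, db)
    devs[[length(devs) + 1]] <- dd$deviations_mm
    rows[[length(rows) + 1]] <- data.frame(
      catheter_id = p$catheter_id, n_dwells = dd$n, mean_dev_mm = dd$mean,
      max_dev_mm = max(dd$deviations_mm), hausdorff_mm = hd
    )
  }
  dev <- unlist(devs)
  per_cath <- do.call(rbind, rows)
  dsc_val <- NA_real_
  if (!is.null(shape)) {
    mp <- rasterize_truth_mask(pred_paths, shape, radius)
    mt <- rasterize_truth_mask(truth_paths, shape, radius)
    dsc_val <- dsc(mp, mt)
  }
  structure(list(
    deviations_mm = dev, mean = mean(dev), sd = stats::sd(dev),
    frac_lt_2mm = mean(dev < 2), frac_gt_3mm = mean(dev > 3),
    dsc = dsc_val, hausdorff_mean_mm = mean(per_cath$hausdorff_mm),
    n_dwells = length(dev), per_catheter = per_cath
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %d dwells: %.2f +/- %.2f mm; %.2f%% < 2 mm, %.2f%% > 3 mm\n",
    x$n_dwells, x$mean, x$sd, 100 * x$frac_lt_2mm, 100 * x$frac_gt_3mm))
  if (!is.na(x$dsc))
    cat(sprintf("  path DSC %.3f, mean Hausdorff %.2f mm\n",
                x$dsc, x$hausdorff_mean_mm))
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes a binned deviation histogram as CSV and a JSON summary.
#'
#' @param report an `eval_report`.
#' @param out_dir output directory (created if missing).
#' @param bin_width_mm histogram bin width (default 0.25 mm).
#' @return Invisibly, the paths of the files written.
#' @export
export_report <- function(report, out_dir, bin_width_mm = 0.25) {
  stopifnot(inherits(report, "eval_report"))
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  dev <- report$deviations_mm
  upper <- max(bin_width_mm, ceiling(max(dev) / bin_width_mm) * bin_width_mm)
  breaks <- seq(0, upper + bin_width_mm, by = bin_width_mm)
  counts <- as.integer(table(cut(dev, breaks, right = FALSE,
                                 include.lowest = TRUE)))
  histo <- data.frame(bin_lo_mm = head(breaks, -1),
                      bin_hi_mm = tail(breaks, -1), count = counts)
  hist_path <- file.path(out_dir, "deviation_histogram.csv")
  utils::write.csv(histo, hist_path, row.names = FALSE)
  summary_path <- file.path(out_dir, "evaluation_summary.json")
  jsonlite::write_json(list(
    n_dwells = report$n_dwells, mean_mm = report$mean, sd_mm = report$sd,
    frac_lt_2mm = report$frac_lt_2mm, frac_gt_3mm = report$frac_gt_3mm,
    dsc = report$dsc, hausdorff_mean_mm = report$hausdorff_mean_mm
  ), summary_path, digits = NA, auto_unbox = TRUE)
  invisible(c(histogram = hist_path, summary = summary_path))
}
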