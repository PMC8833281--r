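# Independent brute-force oracles, written directly against the method
# definitions and kept free of package internals.

# exhaustive greedy one-to-one matcher: repeatedly picks the globally
# closest free catheter-candidate pair within the radius
brute_greedy <- function(pos, cand, radius = 8) {
  n <- nrow(pos); m <- nrow(cand)
  assignment <- rep(NA_integer_, n)
  if (m > 0) {
    used <- rep(FALSE, m)
    repeat {
      best <- NULL
      for (i in seq_len(n)) for (j in seq_len(m)) {
        if (!is.na(assignment[i]) || used[j]) next
        d <- sqrt(sum((pos[i, ] - c(cand$row[j], cand$col[j]))^2))
        if (d > radius) next
        if (is.null(best) || d < best$d ||
            (d == best$d && (i < best$i || (i == best$i && j < best$j))))
          best <- list(i = i, j = j, d = d)
      }
      if (is.null(best)) break
      assignment[best$i] <- best$j
      used[best$j] <- TRUE
    }
  }
  assignment
}

# the displacement-imputation equations evaluated term by term
brute_jump_correction <- function(prev_det, next_det, jumped) {
  k <- nrow(prev_det)
  dx <- 0; dy <- 0
  for (i in seq_len(k)) {
    dx <- dx + abs(next_det[i, 1] - prev_det[i, 1])
    dy <- dy + abs(next_det[i, 2] - prev_det[i, 2])
  }
  dx <- dx / k; dy <- dy / k
  out <- jumped
  for (j in seq_len(nrow(jumped))) {
    out[j, 1] <- jumped[j, 1] + dx
    out[j, 2] <- jumped[j, 2] + dy
  }
  out
}

# directed max-min point-set distance via explicit double loop
brute_hausdorff <- function(x, y) {
  dxy <- 0
  for (i in seq_len(nrow(x))) {
    dmin <- Inf
    for (j in seq_len(nrow(y)))
      dmin <- min(dmin, sqrt(sum((x[i, ] - y[j, ])^2)))
    dxy <- max(dxy, dmin)
  }
  dyx <- 0
  for (j in seq_len(nrow(y))) {
    dmin <- Inf
    for (i in seq_len(nrow(x)))
      dmin <- min(dmin, sqrt(sum((y[j, ] - x[i, ])^2)))
    dyx <- max(dyx, dmin)
  }
  max(dxy, dyx)
}

# min distance from points to a densely resampled polyline
brute_polyline_dist <- function(pts, poly, steps = 400) {
  dense <- do.call(rbind, lapply(seq_len(nrow(poly) - 1), function(i) {
    f <- seq(0, 1, length.out = steps)
    outer(1 - f, poly[i, ]) + outer(f, poly[i + 1, ])
  }))
  apply(rbind(pts), 1, function(p0)
    min(sqrt(colSums((t(dense) - p0)^2))))
}
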