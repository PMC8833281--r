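test_that("candidates are 8-connected components with mean-position centroids", {
  sl <- matrix(0, 20, 20)
  sl[9:11, 9:11] <- 1
  cand <- find_candidates(sl)
  expect_equal(nrow(cand), 1)
  expect_equal(c(cand$row, cand$col), c(10, 10))
  expect_equal(cand$size, 9L)

  sl[2, 2] <- 1
  expect_equal(nrow(find_candidates(sl)), 2)

  # diagonal touch joins under 8-connectivity
  dg <- matrix(0, 6, 6)
  dg[2, 2] <- 1; dg[3, 3] <- 1
  expect_equal(nrow(find_candidates(dg)), 1)

  # L-shaped component: centroid equals hand-enumerated voxel mean
  L <- matrix(0, 10, 10)
  vox <- rbind(c(3, 3), c(4, 3), c(5, 3), c(5, 4), c(5, 5))
  L[vox] <- 1
  cl <- find_candidates(L)
  expect_equal(cl$row, mean(vox[, 1]))
  expect_equal(cl$col, mean(vox[, 2]))

  expect_equal(nrow(find_candidates(matrix(0, 5, 5))), 0)
  expect_equal(nrow(find_candidates(L, min_size = 6)), 0)
})

test_that("rectangle refinement finds the modality-appropriate extremum", {
  sl <- matrix(0, 20, 20)
  sl[5, 7] <- 10
  expect_equal(unname(refine_in_rectangle(sl, c(6, 6), 5, "t1w")), c(5, 7))
  # T2W on the negated image lands on the same voxel
  expect_equal(unname(refine_in_rectangle(-sl, c(6, 6), 5, "t2w")), c(5, 7))
  # uniform window: tie-break returns the (rounded) approximate position
  expect_equal(unname(refine_in_rectangle(matrix(3, 20, 20), c(8, 9), 4, "t1w")),
               c(8, 9))
  # window clipped at the slice border still works
  expect_equal(unname(refine_in_rectangle(sl, c(2, 2), 5, "t1w")), c(5, 7))
})

test_that("tie-breaking prefers proximity, then row-major order", {
  sl <- matrix(0, 11, 11)
  sl[3, 6] <- 5   # distance 3 from (6, 6)
  sl[6, 8] <- 5   # distance 2
  expect_equal(unname(refine_in_rectangle(sl, c(6, 6), 5, "t1w")), c(6, 8))
  sl2 <- matrix(0, 11, 11)
  sl2[4, 6] <- 5; sl2[8, 6] <- 5  # equidistant: smaller row wins
  expect_equal(unname(refine_in_rectangle(sl2, c(6, 6), 5, "t1w")), c(4, 6))
})

test_that("linking assigns nearest candidates one-to-one within the neighborhood", {
  pos <- rbind(c(10, 10), c(20, 20))
  cand <- data.frame(row = c(10, 20), col = c(10, 20))
  lk <- link_next_slice(pos, cand)
  expect_equal(lk$assignment, c(1L, 2L))
  expect_length(lk$jumped, 0)

  none <- link_next_slice(pos, cand[0, ])
  expect_equal(none$jumped, c(1L, 2L))
  expect_true(all(is.na(none$assignment)))

  # candidate beyond the 8-pixel radius is out of reach
  far <- link_next_slice(rbind(c(10, 10)), data.frame(row = 10, col = 19))
  expect_equal(far$jumped, 1L)
  near <- link_next_slice(rbind(c(10, 10)), data.frame(row = 10, col = 18))
  expect_equal(near$assignment, 1L)
})

test_that("linking equals brute-force greedy matching on random instances", {
  set.seed(7)
  for (trial in 1:200) {
    n <- sample(1:10, 1); m <- sample(0:20, 1)
    pos <- cbind(runif(n, 0, 30), runif(n, 0, 30))
    cand <- data.frame(row = runif(m, 0, 30), col = runif(m, 0, 30))
    lk <- link_next_slice(pos, cand)
    expect_identical(lk$assignment, brute_greedy(pos, cand))
  }
})

test_that("jump correction applies the mean absolute displacement", {
  prev <- rbind(c(10, 10), c(20, 20))
  nxt <- rbind(c(11, 12), c(21, 22))
  corr <- correct_jumping(prev, nxt, rbind(c(5, 5)))
  expect_equal(unname(corr[1, ]), c(6, 7))

  # stationary detections leave the jumped catheter in place
  still <- correct_jumping(prev, prev, rbind(c(5, 5)))
  expect_equal(unname(still[1, ]), c(5, 5))

  # absolute values: opposite moves do NOT cancel
  opp <- correct_jumping(rbind(c(0, 0), c(0, 0)),
                         rbind(c(1, 0), c(-1, 0)),
                         rbind(c(5, 5)))
  expect_equal(unname(opp[1, ]), c(6, 5))
  # ... unless the signed-mean variant is requested
  sgn <- correct_jumping(rbind(c(0, 0), c(0, 0)),
                         rbind(c(1, 0), c(-1, 0)),
                         rbind(c(5, 5)), signed = TRUE)
  expect_equal(unname(sgn[1, ]), c(5, 5))

  expect_error(correct_jumping(matrix(0, 0, 2), matrix(0, 0, 2),
                               rbind(c(1, 1))), "undefined")
})

test_that("jump correction is translation-consistent for uniform moves", {
  set.seed(11)
  for (trial in 1:50) {
    k <- sample(1:6, 1)
    prev <- matrix(runif(2 * k, 0, 50), k, 2)
    d <- c(runif(1, 0, 3), runif(1, 0, 3))  # non-negative shift
    corr <- correct_jumping(prev, sweep(prev, 2, d, `+`), rbind(c(25, 25)))
    expect_equal(unname(corr[1, ]), c(25, 25) + d, tolerance = 1e-12)
  }
})

test_that("stopping slice follows total - (free + template)", {
  g <- template_geometry(294, 100, 20, start_slice = 3,
                         seeds = rbind(c(10, 10)))
  expect_equal(compute_stop_slice(g, 1), 3 + 174)
  expect_equal(compute_stop_slice(g, 2), 3 + 87)

  # insertion zero: path is the seed slice only
  g0 <- template_geometry(120, 100, 20, start_slice = 5,
                          seeds = rbind(c(10, 10)))
  expect_equal(compute_stop_slice(g0, 1), 5)

  expect_error(template_geometry(100, 90, 20, 1, rbind(c(1, 1))), "exceeds")
})

test_that("stopping arithmetic matches independent integer arithmetic on random geometries", {
  set.seed(13)
  for (trial in 1:200) {
    total <- runif(1, 100, 400)
    template <- runif(1, 5, 30)
    ins <- runif(1, 0, 60)
    thick <- sample(c(0.5, 1, 2, 2.5), 1)
    m <- sample(1:5, 1)
    g <- template_geometry(total, total - template - ins, template, m,
                           rbind(c(4, 4)))
    oracle <- m + floor((total - ((total - template - ins) + template)) /
                          thick + 1e-9)
    expect_equal(compute_stop_slice(g, thick), oracle)
  }
})

test_that("modality fusion merges nearby candidates to their mean", {
  a <- data.frame(row = c(10, 30), col = c(10, 30))
  same <- merge_modalities(a, a, tolerance_px = 2)
  expect_equal(nrow(same), 2)
  expect_true(all(same$modality == "dual"))

  far <- merge_modalities(a, data.frame(row = 50, col = 50), tolerance_px = 2)
  expect_equal(nrow(far), 3)
  expect_setequal(far$modality, c("t1w", "t2w"))

  fused <- merge_modalities(data.frame(row = 10, col = 10),
                            data.frame(row = 11, col = 11), tolerance_px = 2)
  expect_equal(nrow(fused), 1)
  expect_equal(c(fused$row, fused$col), c(10.5, 10.5))
  expect_equal(fused$modality, "dual")

  empty <- merge_modalities(a[0, ], a[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("straight catheters reconstruct as constant paths", {
  seats <- rbind(c(12, 12), c(12, 36), c(36, 24))
  sv <- straight_volumes(seats)
  g <- template_geometry(294, 294 - 20 - 10, 20, start_slice = 2,
                         seeds = seats)
  rec <- reconstruct_catheters(sv$t1w, sv$t2w, sv$mask, sv$mask, g)
  expect_length(rec, 3)
  for (i in 1:3) {
    expect_equal(rec[[i]]$slices, 2:12)
    expect_true(all(rec[[i]]$points[, 1] == seats[i, 1]))
    expect_true(all(rec[[i]]$points[, 2] == seats[i, 2]))
    expect_true(all(rec[[i]]$provenance[-1] == "linked"))
  }
})

test_that("a single-slice dropout yields exactly one jump-corrected point and a complete path", {
  seats <- rbind(c(12, 12), c(12, 36), c(36, 24))
  sv <- straight_volumes(seats)
  mask2 <- sv$mask
  mask2[36, 24, 7] <- 0L   # delete catheter 3's component on slice 7 only
  g <- template_geometry(294, 294 - 20 - 10, 20, start_slice = 2,
                         seeds = seats)
  rec <- reconstruct_catheters(sv$t1w, sv$t2w, mask2, mask2, g)
  p3 <- rec[[3]]
  expect_equal(p3$slices, 2:12)
  expect_equal(sum(p3$provenance == "jump-corrected"), 1)
  expect_equal(p3$provenance[p3$slices == 7], "jump-corrected")
  # detected catheters were stationary, so the imputed position is unchanged
  expect_equal(unname(p3$points[p3$slices == 7, ]), c(36, 24))
  # the two untouched catheters are unaffected
  expect_true(all(rec[[1]]$provenance[-1] == "linked"))
})

test_that("an all-jumped transition carries positions over unchanged", {
  seats <- rbind(c(12, 12), c(36, 36))
  sv <- straight_volumes(seats)
  mask2 <- sv$mask
  mask2[, , 5] <- 0L       # nothing detected on slice 5
  g <- template_geometry(294, 294 - 20 - 8, 20, start_slice = 2,
                         seeds = seats)
  rec <- reconstruct_catheters(sv$t1w, sv$t2w, mask2, mask2, g)
  for (i in 1:2) {
    expect_equal(rec[[i]]$slices, 2:10)
    expect_equal(unname(rec[[i]]$points[rec[[i]]$slices == 5, ]),
                 unname(seats[i, ]))
    expect_equal(rec[[i]]$provenance[rec[[i]]$slices == 5], "jump-corrected")
  }
})

test_that("reconstruction with oracle masks recovers phantom paths to a voxel", {
  ph <- generate_phantom(small_phantom_config(seed = 21L))
  mask <- rasterize_truth_mask(ph$paths, ph$config$shape, 2)
  rec <- reconstruct_catheters(normalize_volume(ph$t1w),
                               normalize_volume(ph$t2w),
                               mask, mask, ph$geometry)
  expect_length(rec, length(ph$paths))
  for (i in seq_along(rec)) {
    expect_equal(rec[[i]]$slices, ph$paths[[i]]$slices)
    err <- sqrt(rowSums((rec[[i]]$points - ph$paths[[i]]$points)^2))
    expect_lt(max(err), 1.5)
  }
})

test_that("reconstruction rejects inconsistent inputs", {
  sv <- straight_volumes(rbind(c(12, 12)))
  g <- template_geometry(294, 294 - 20 - 10, 20, 2, rbind(c(12, 12)))
  expect_error(reconstruct_catheters(sv$t1w, sv$t2w,
                                     sv$mask[, , 1:5], sv$mask, g), "mask")
  g_long <- template_geometry(294, 100, 20, 2, rbind(c(12, 12)))
  expect_error(reconstruct_catheters(sv$t1w, sv$t2w, sv$mask, sv$mask,
                                     g_long), "exceeds")
})
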