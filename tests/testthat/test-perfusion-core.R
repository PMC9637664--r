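test_that("subtraction removes the mean of the first two frames", {
  dat <- array(0, c(2, 2, 1, 3))
  dat[1, 1, 1, ] <- c(100, 102, 150)
  dat[, , , 1][-1] <- 100; dat[, , , 2][-1] <- 100; dat[, , , 3][-1] <- 100
  s <- dce_series(dat, dt = 1, n_precontrast = 2)
  sub <- compute_subtraction(s)
  expect_equal(sub$data[1, 1, 1, ], c(-1, 1, 49))
  expect_equal(sub$baseline_frames_used, 2L)
  # constant series -> identically zero
  s0 <- dce_series(array(7, c(2, 2, 1, 6)), dt = 1, n_precontrast = 2)
  expect_true(all(compute_subtraction(s0)$data == 0))
})

test_that("noiseless phantom subtraction equals the forward-model enhancement", {
  sp <- small_spec(cnr = 1e9, rng_seed = 41L)
  tr <- make_phantom_truth(sp)
  v <- synthesize_visit(sp, tr, 1L)
  sub <- compute_subtraction(v)
  t <- v$frame_times
  aif <- gamma_variate_aif(sp$aif, t)
  vox <- which(tr$lung_mask & !tr$defect_mask & !tr$vessel_mask)[10]
  expected <- conv_oracle(aif, (tr$pbf_truth[vox] / 6000) *
                            exp(-t / tr$mtt_truth[vox]), sp$dt)
  got <- matrix(sub$data, ncol = sp$n_frames)[vox, ]
  expect_equal(got, expected, tolerance = 1e-5)
})

test_that("AIF detection recovers the arterial curve from the phantom", {
  sp <- small_spec(cnr = 50, rng_seed = 43L)
  tr <- make_phantom_truth(sp)
  v <- synthesize_visit(sp, tr, 1L)
  sub <- compute_subtraction(v)
  aif <- detect_aif(sub, tr$artery_mask)
  expect_true(all(tr$artery_mask[aif$source_voxels]))
  truth_curve <- gamma_variate_aif(sp$aif, v$frame_times)
  expect_lt(abs(aif$peak_value - max(truth_curve)) / max(truth_curve), 0.05)
  expect_equal(aif$peak_frame, which.max(truth_curve))
})

test_that("flat series yield no AIF", {
  dat <- array(100, c(6, 6, 2, 12))
  s <- dce_series(dat, dt = 1, n_precontrast = 2)
  expect_error(detect_aif(compute_subtraction(s), array(TRUE, c(6, 6, 2))),
               "insufficient_enhancement")
})

test_that("the earlier of two candidate populations is selected", {
  # two blobs with equal peak height; the early one must win
  nf <- 30
  dat <- array(100, c(10, 10, 2, nf))
  early <- numeric(nf); early[8] <- 50; early[7] <- 40; early[9] <- 40
  late <- numeric(nf); late[16] <- 50; late[15] <- 40; late[17] <- 40
  for (i in 1:5) for (j in 1:5) dat[i, j, 1, ] <- 100 + early
  for (i in 6:10) for (j in 6:10) dat[i, j, 2, ] <- 100 + late
  s <- dce_series(dat, dt = 1, n_precontrast = 2)
  aif <- detect_aif(compute_subtraction(s), array(TRUE, c(10, 10, 2)))
  expect_equal(aif$peak_frame, 8L)
})

test_that("convolution matrix reproduces the direct convolution sum", {
  set.seed(1)
  a <- c(0, 0, runif(10, 0, 5))
  r <- runif(12)
  A <- build_convolution_matrix(a, dt = 1.5)
  expect_equal(as.vector(A %*% r), conv_oracle(a, r, 1.5), tolerance = 1e-12)
  # unit impulse AIF -> dt * identity
  imp <- c(1, rep(0, 7))
  expect_equal(build_convolution_matrix(imp, 2), 2 * diag(8))
  expect_true(all(build_convolution_matrix(rep(0, 6), 1) == 0))
})

test_that("impulse-AIF systems invert to machine precision", {
  nf <- 20
  imp <- c(1, rep(0, nf - 1))
  R <- c(0, 0, exp(-(0:(nf - 3)) / 4))   # residue arrives after the baseline
  C <- as.vector(build_convolution_matrix(imp, 1.5) %*% R)
  dat <- array(100, c(2, 2, 1, nf))
  dat[1, 1, 1, ] <- 100 + C
  s <- dce_series(dat, dt = 1.5, n_precontrast = 2)
  sub <- compute_subtraction(s)
  mask <- array(FALSE, c(2, 2, 1)); mask[1, 1, 1] <- TRUE
  rm <- tsvd_deconvolve(sub, imp, mask, truncation_fraction = 1e-12)
  expect_equal(rm$rt[1, 1, 1, ], R, tolerance = 1e-12)
})

test_that("deconvolution is exactly linear in the tissue signal", {
  sp <- small_spec(cnr = 30, rng_seed = 47L)
  tr <- make_phantom_truth(sp)
  v <- synthesize_visit(sp, tr, 1L)
  sub <- compute_subtraction(v)
  aif <- detect_aif(sub, tr$artery_mask)
  rm1 <- tsvd_deconvolve(sub, aif, tr$lung_mask)
  sub2 <- sub; sub2$data <- 0.8 * sub$data
  rm2 <- tsvd_deconvolve(sub2, aif, tr$lung_mask)
  expect_equal(rm2$rt, 0.8 * rm1$rt, tolerance = 1e-12)
  expect_equal(rm2$tmax_frame, rm1$tmax_frame)
})

test_that("a global scan gain cancels when the AIF is re-detected per scan", {
  sp <- small_spec(cnr = 1e9, visit_scale_error = 0.8, rng_seed = 49L)
  tr <- make_phantom_truth(sp)
  v1 <- synthesize_visit(sp, tr, 1L)
  v2 <- synthesize_visit(sp, tr, 2L)   # 0.8 * noiseless visit 1
  r <- lapply(list(v1, v2), function(v) {
    sub <- compute_subtraction(v)
    tsvd_deconvolve(sub, detect_aif(sub, tr$artery_mask), tr$lung_mask)
  })
  expect_equal(r[[2]]$rt, r[[1]]$rt, tolerance = 1e-6)
  # with the visit-1 AIF held fixed, the residue field scales by the gain
  sub2 <- compute_subtraction(v2)
  aif1 <- detect_aif(compute_subtraction(v1), tr$artery_mask)
  r_fixed <- tsvd_deconvolve(sub2, aif1, tr$lung_mask)
  expect_equal(r_fixed$rt, 0.8 * r[[1]]$rt, tolerance = 1e-6)
})

test_that("per-scan AIF amplitude errors scale the residue field by their inverse", {
  sp <- small_spec(cnr = 1e9, aif_scale_error = c(1, 0.8), rng_seed = 51L)
  tr <- make_phantom_truth(sp)
  v1 <- synthesize_visit(sp, tr, 1L)
  v2 <- synthesize_visit(sp, tr, 2L, noise_seed = sp$rng_seed)
  r <- lapply(list(v1, v2), function(v) {
    sub <- compute_subtraction(v)
    tsvd_deconvolve(sub, detect_aif(sub, tr$artery_mask), tr$lung_mask)
  })
  tissue <- tr$lung_mask & !tr$vessel_mask
  f <- array(tissue, dim = dim(r[[1]]$rt)[1:3])
  sel <- which(f)
  r1 <- matrix(r[[1]]$rt, ncol = sp$n_frames)[sel, ]
  r2 <- matrix(r[[2]]$rt, ncol = sp$n_frames)[sel, ]
  expect_equal(r2, r1 / 0.8, tolerance = 1e-6)
})

test_that("PBF and PBV closed forms hold", {
  # boxcar residue of height h over m frames
  h <- 3; m <- 5; nf <- 12; dt <- 1.5
  rt <- array(0, c(1, 1, 1, nf))
  rt[1, 1, 1, 1:m] <- h
  expect_equal(compute_pbf(rt, scale = 1)[1, 1, 1], h)
  # trapezoid: first sample is an edge sample with half weight
  expect_equal(compute_pbv(rt, dt = dt, scale = 1)[1, 1, 1], dt * (h * m - h / 2))
  # spec-style example evaluated with the trapezoid oracle
  rt2 <- array(0, c(1, 1, 1, 4)); rt2[1, 1, 1, ] <- c(0, 2, 5, 3)
  trap_oracle <- sum(diff(0:3) * (c(0, 2, 5) + c(2, 5, 3)) / 2)
  expect_equal(compute_pbf(rt2, scale = 1)[1, 1, 1], 5)
  expect_equal(compute_pbv(rt2, dt = 1, scale = 1)[1, 1, 1], trap_oracle)
  # all-zero residue
  expect_equal(compute_pbf(array(0, c(2, 2, 1, 5)), scale = 1),
               array(0, c(2, 2, 1)))
  expect_equal(compute_pbv(array(0, c(2, 2, 1, 5)), dt = 1),
               array(0, c(2, 2, 1)))
  # negatives: retained in the integral, floored in the map
  rt3 <- array(c(-1, 2, -1, 2), c(1, 1, 1, 4))
  expect_equal(compute_pbf(rt3, scale = 1)[1, 1, 1], 2)
  expect_equal(compute_pbv(rt3, dt = 1, scale = 1)[1, 1, 1],
               max(0, sum(c(-1, 2, -1, 2)) - (-1 + 2) / 2))
})

test_that("whole-lung summaries are medians with non-finite values excluded", {
  map <- array(seq_len(101), c(101, 1, 1))
  mask <- array(TRUE, c(101, 1, 1))
  expect_equal(as.numeric(summarize_whole_lung(map, mask)), 51)
  map[3] <- NaN
  s <- summarize_whole_lung(map, mask)
  expect_equal(attr(s, "n_nonfinite"), 1L)
  expect_error(summarize_whole_lung(map, array(FALSE, c(101, 1, 1))), "empty")
  cmap <- array(2.5, c(4, 4, 2))
  expect_equal(as.numeric(summarize_whole_lung(cmap, array(TRUE, c(4, 4, 2)))), 2.5)
})

test_that("noiseless phantom recovery: PBF within 15%, PBV within 5% per voxel", {
  sp <- small_spec(cnr = 1e9, rng_seed = 53L)
  tr <- make_phantom_truth(sp)
  v <- synthesize_visit(sp, tr, 1L)
  sub <- compute_subtraction(v)
  aif <- detect_aif(sub, tr$artery_mask)
  rm <- tsvd_deconvolve(sub, aif, tr$lung_mask)
  pbf <- compute_pbf(rm); pbv <- compute_pbv(rm)
  lung <- tr$lung_mask
  expect_lt(max(abs(pbf[lung] - tr$pbf_truth[lung]) / tr$pbf_truth[lung]), 0.15)
  expect_lt(max(abs(pbv[lung] - tr$pbv_truth[lung]) / tr$pbv_truth[lung]), 0.05)
  # whole-lung PBF median lands near the gravity-weighted normal value
  med <- as.numeric(summarize_whole_lung(pbf, lung & !tr$defect_mask &
                                           !tr$vessel_mask))
  expect_lt(abs(med - sp$normal_pbf) / sp$normal_pbf, 0.15)
})

test_that("PBV conservation holds for the recovered residue functions", {
  sp <- small_spec(cnr = 1e9, rng_seed = 57L)
  tr <- make_phantom_truth(sp)
  v <- synthesize_visit(sp, tr, 1L)
  sub <- compute_subtraction(v)
  aif <- detect_aif(sub, tr$artery_mask)
  rm <- tsvd_deconvolve(sub, aif, tr$lung_mask)
  vox <- which(tr$lung_mask & !tr$defect_mask & !tr$vessel_mask)[3]
  nf <- sp$n_frames
  C <- matrix(sub$data, ncol = nf)[vox, ]
  R <- matrix(rm$rt, ncol = nf)[vox, ]
  lhs <- sp$dt * sum(C)
  rhs <- (sp$dt * sum(aif$curve)) * (sp$dt * sum(R))
  expect_lt(abs(lhs - rhs) / lhs, 0.05)
})

test_that("truncation fraction outside (0,1) is rejected", {
  sp <- small_spec(rng_seed = 59L)
  tr <- make_phantom_truth(sp)
  sub <- compute_subtraction(synthesize_visit(sp, tr, 1L))
  aif <- detect_aif(sub, tr$artery_mask)
  expect_error(tsvd_deconvolve(sub, aif, tr$lung_mask, truncation_fraction = 0))
  expect_error(tsvd_deconvolve(sub, aif, tr$lung_mask, truncation_fraction = 1.2))
})
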