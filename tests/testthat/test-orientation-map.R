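noiseless <- scatter_model(noise_sigma = 0)

test_that("average map and profile extraction are elementwise exact", {
  st <- angular_stack(array(rep(1:24, each = 16), c(4, 4, 24)), seq(0, 345, 15))
  expect_true(all(average_intensity_map(st) == mean(1:24)))

  # alternating 0/2 frames average to 1
  st2 <- angular_stack(array(rep(c(0, 2), each = 16, times = 12),
                             c(4, 4, 24)), seq(0, 345, 15))
  expect_true(all(average_intensity_map(st2) == 1))

  # random stack: spot-check against a hand loop
  set.seed(7)
  arr <- array(runif(4 * 5 * 24), c(4, 5, 24))
  st3 <- angular_stack(arr, seq(0, 345, 15))
  avg <- average_intensity_map(st3)
  for (pix in list(c(1, 1), c(2, 5), c(4, 3), c(3, 2), c(4, 5))) {
    s <- 0
    for (k in 1:24) s <- s + arr[pix[1], pix[2], k]
    expect_equal(avg[pix[1], pix[2]], s / 24)
  }
  prof <- extract_profile(st3, 2, 4)
  expect_equal(prof$intensity, arr[2, 4, ])
  expect_length(prof$intensity, 24)
  expect_error(extract_profile(st3, 5, 1), "out of range")
})

test_that("orientation maps recover constant and crossing phantom truth", {
  f <- make_orientation_field("constant", 16, 16, list(theta = 35))
  om <- compute_orientation_map(render_scatter_stack(f, noiseless))
  expect_true(all(om$valid))
  expect_lt(max(circ_err(om$orientations[, , 1], 35)), 1)

  fc <- make_orientation_field("two_region_crossing", 8, 12,
                               list(theta1 = 20, theta2 = 110))
  omc <- compute_orientation_map(render_scatter_stack(fc, noiseless))
  mid <- sort(omc$orientations[4, 6, 1:2])
  expect_lt(max(circ_err(mid, c(20, 110))), 3)
  expect_equal(omc$peak_count[4, 6], 4L)
})

test_that("flat background pixels have zero peaks and are invalid", {
  st <- angular_stack(array(0.2, c(3, 3, 24)), seq(0, 345, 15))
  om <- compute_orientation_map(st)
  expect_true(all(!om$valid))
  expect_true(all(om$peak_count == 0))
  expect_true(all(is.na(om$orientations)))
})

test_that("orientations are equivariant under angle relabeling", {
  f <- make_orientation_field("smooth_gradient", 5, 5,
                              list(theta_from = 10, theta_to = 80))
  st <- render_scatter_stack(f, noiseless)
  om0 <- compute_orientation_map(st)
  for (delta in c(15, 45, 90)) {
    # same intensities, every angle label shifted by +delta
    sh <- angular_stack(st$frames, st$angles + delta)
    omr <- compute_orientation_map(sh)
    expect_lt(max(circ_err(omr$orientations[, , 1],
                           (om0$orientations[, , 1] + delta) %% 180)), 1e-6)
  }
})

test_that("results are invariant to intensity scale and frame order", {
  f <- make_orientation_field("smooth_gradient", 6, 6,
                              list(theta_from = 10, theta_to = 160))
  st <- render_scatter_stack(f, scatter_model(noise_sigma = 0.03), seed = 4)
  om <- compute_orientation_map(st)

  st_scaled <- angular_stack(st$frames * 137.5, st$angles)
  om_s <- compute_orientation_map(st_scaled)
  expect_equal(om_s$orientations, om$orientations, tolerance = 1e-12)
  expect_identical(om_s$valid, om$valid)

  # frames supplied in scrambled order with their labels: same results
  perm <- sample(24)
  st_p <- angular_stack(st$frames[, , perm], st$angles[perm])
  om_p <- compute_orientation_map(st_p)
  expect_identical(om_p$orientations, om$orientations)
})

test_that("noiseless theta sweep recovers orientations within 1 degree", {
  thetas <- seq(0, 175, by = 5)
  errs <- vapply(thetas, function(th) {
    fld <- make_orientation_field("constant", 3, 3, list(theta = th))
    om <- compute_orientation_map(render_scatter_stack(fld, noiseless))
    circ_err(om$orientations[2, 2, 1], th)
  }, numeric(1))
  expect_lt(max(errs), 1)
  # without refinement the error is bounded by half the angular step
  errs_raw <- vapply(thetas, function(th) {
    fld <- make_orientation_field("constant", 3, 3, list(theta = th))
    om <- compute_orientation_map(render_scatter_stack(fld, noiseless),
                                  refine = FALSE)
    circ_err(om$orientations[2, 2, 1], th)
  }, numeric(1))
  expect_lte(max(errs_raw), 7.5 + 1e-9)
})

test_that("FOM colors follow the orientation color wheel", {
  f <- make_orientation_field("constant", 2, 2, list(theta = 0))
  om <- compute_orientation_map(render_scatter_stack(f, noiseless))
  om$orientations[, , 1] <- 0
  fom <- colorize_fom(om)
  expect_equal(as.integer(fom[1, 1, ]), c(255L, 0L, 0L))
  om$orientations[, , 1] <- 90
  expect_equal(as.integer(colorize_fom(om)[1, 1, ]), c(0L, 255L, 255L))
  om$orientations[, , 1] <- 120
  expect_equal(as.integer(colorize_fom(om)[1, 1, ]), c(0L, 0L, 255L))
  # masked pixel is black
  msk <- matrix(FALSE, 2, 2); msk[1, 1] <- TRUE
  expect_equal(as.integer(colorize_fom(om, msk)[1, 1, ]), c(0L, 0L, 0L))
})

test_that("average-intensity masking blacks out the low population", {
  fom <- array(255L, c(10, 10, 3))
  avg <- matrix(c(rep(0.1, 50), rep(0.9, 50)), 10, 10)
  avg <- avg + seq(-0.01, 0.01, length.out = 100)  # jitter the populations
  r <- mask_by_average_intensity(fom, avg, method = "otsu")
  expect_identical(r$mask, avg > 0.5)  # exactly the high population kept
  expect_true(all(r$fom[, , 1][!r$mask] == 0))
  expect_true(all(r$fom[, , 1][r$mask] == 255))
  # oracle: exhaustive between-class variance search lands between the modes
  thr <- oracle_otsu_threshold(c(avg))
  expect_identical(avg >= thr, r$mask)

  # absolute thresholds at the extremes
  all_kept <- mask_by_average_intensity(fom, avg, "absolute", level = 0)
  expect_true(all(all_kept$fom == fom))
  none <- mask_by_average_intensity(fom, avg, "absolute", level = 2)
  expect_true(all(none$fom == 0))
  expect_error(mask_by_average_intensity(fom, avg, "absolute"), "level")
})
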