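angles24 <- seq(0, 345, by = 15)

two_peak_profile <- function(mu1 = 40, mu2 = 220, sigma = 20, baseline = 0.1,
                             amp = 1, angles = angles24) {
  d1 <- ((angles - mu1 + 180) %% 360) - 180
  d2 <- ((angles - mu2 + 180) %% 360) - 180
  baseline + amp * (exp(-d1^2 / (2 * sigma^2)) + exp(-d2^2 / (2 * sigma^2)))
}

test_that("flat and two-peak profiles are detected as specified", {
  expect_equal(nrow(detect_prominent_peaks(rep(2, 24), angles24)), 0)

  p <- detect_prominent_peaks(two_peak_profile(), angles24)
  expect_equal(nrow(p), 2)
  expect_lt(max(abs(p$position - c(40, 220))), 1)
})

test_that("a bump below the prominence threshold is excluded", {
  prof <- two_peak_profile()
  # add a small bump at 130 deg with normalized prominence ~0.04
  rng <- max(prof) - min(prof)
  d <- ((angles24 - 130 + 180) %% 360) - 180
  prof2 <- prof + 0.04 * rng * exp(-d^2 / (2 * 10^2))
  got <- detect_prominent_peaks(prof2, angles24, prominence_threshold = 0.08)
  expect_equal(nrow(got), 2)
  expect_lt(max(abs(got$position - c(40, 220))), 2)
  # lowering the threshold reveals it
  got2 <- detect_prominent_peaks(prof2, angles24, prominence_threshold = 0.02)
  expect_equal(nrow(got2), 3)
})

test_that("detected peak sets match the brute-force prominence oracle", {
  set.seed(101)
  for (rep in 1:300) {
    prof <- random_profile()
    got <- detect_prominent_peaks(prof, angles24, prominence_threshold = 0.08,
                                  refine = FALSE)
    want <- oracle_prominent_peaks(prof, 0.08)
    expect_identical(sort(got$position), sort(angles24[want$bin]))
    expect_equal(sort(got$prominence), sort(want$prominence),
                 tolerance = 1e-12)
  }
})

test_that("antipodal pairing applies the 180 +/- 35 degree rule", {
  pk <- function(pos) data.frame(position = pos,
                                 prominence = rep(1, length(pos)))
  r <- pair_antipodal_peaks(pk(c(40, 220)))
  expect_equal(nrow(r$pairs), 1)
  expect_equal(r$pairs$separation, 180)
  expect_equal(r$pairs$midpoint, 130)

  r2 <- pair_antipodal_peaks(pk(c(0, 150)))   # 150 in [145, 215]
  expect_equal(nrow(r2$pairs), 1)
  expect_equal(length(r2$unpaired), 0)

  r3 <- pair_antipodal_peaks(pk(c(0, 140)))   # 140 < 145: no pair
  expect_equal(nrow(r3$pairs), 0)
  expect_equal(r3$unpaired, c(1, 2))

  # greedy: closest-to-180 pair wins first
  r4 <- pair_antipodal_peaks(pk(c(0, 100, 180, 285)))
  expect_equal(nrow(r4$pairs), 2)
  first <- r4$pairs[which.min(abs(r4$pairs$separation - 180)), ]
  expect_setequal(c(first$i, first$j), c(1, 3))
})

test_that("orientation rules follow the peak-count validity table", {
  pk <- function(pos) data.frame(position = pos,
                                 prominence = rep(1, length(pos)))
  # single peak: orientation at the peak position mod 180
  r1 <- orientations_from_profile(pk(60))
  expect_true(r1$valid)
  expect_equal(r1$orientations, 60)
  expect_equal(orientations_from_profile(pk(200))$orientations, 20)

  # pair midpoint, wrapping across 360
  expect_equal(orientations_from_profile(pk(c(40, 220)))$orientations, 130)
  expect_equal(orientations_from_profile(pk(c(170, 350)))$orientations, 80)

  # 3 and 5 peaks: not evaluated
  expect_false(orientations_from_profile(pk(c(10, 100, 190)))$valid)
  expect_false(orientations_from_profile(pk(c(10, 80, 150, 220, 290)))$valid)

  # 4 paired peaks -> 2 orientations; 6 -> 3; 7 -> invalid
  r4 <- orientations_from_profile(pk(c(20, 110, 200, 290)))
  expect_true(r4$valid)
  expect_setequal(round(r4$orientations), c(110, 20))
  r6 <- orientations_from_profile(pk(c(10, 70, 130, 190, 250, 310)))
  expect_true(r6$valid)
  expect_equal(length(r6$orientations), 3)
  r7 <- orientations_from_profile(pk(seq(0, 324, length.out = 7)))
  expect_false(r7$valid)

  # even count with an unpairable peak: invalid
  r2bad <- orientations_from_profile(pk(c(0, 90)))
  expect_false(r2bad$valid)
  expect_equal(r2bad$peak_count, 2)
})

test_that("parabolic refinement recovers off-grid peak positions", {
  for (mu in c(40, 43.7, 47.5, 51)) {
    prof <- two_peak_profile(mu1 = mu, mu2 = mu + 180)
    p <- detect_prominent_peaks(prof, angles24)
    expect_lt(max(circ_err(p$position, c(mu, mu + 180), 360)), 0.6)
  }
})
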