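circle_boundary <- function(cx, cy, r, n = 128) {
  a <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  boundary_annotation(cbind(cx + r * cos(a), cy - r * sin(a)), closed = TRUE)
}

test_that("annotation invariants are enforced", {
  expect_error(boundary_annotation(cbind(c(0, 1), c(0, 0)), closed = TRUE),
               "3 vertices")
  expect_error(boundary_annotation(cbind(0, 0), closed = FALSE), "2 vertices")
  expect_error(boundary_annotation(cbind(c(0, 0, 1), c(0, 0, 1)),
                                   closed = FALSE), "repeated")
})

test_that("tangents of straight segments and circles are analytic", {
  seg <- boundary_annotation(cbind(c(0, 50), c(10, 10)), closed = FALSE)
  tf <- resample_and_tangents(seg, spacing = 5)
  expect_true(all(tf$tangent_deg == 0))
  # constant spacing within 1%
  d <- sqrt(diff(tf$x)^2 + diff(tf$y)^2)
  expect_lt(max(abs(d - mean(d))) / mean(d), 0.01)

  r <- 60
  circ <- circle_boundary(100, 100, r, n = 720)
  tc <- resample_and_tangents(circ, spacing = r / 20)
  alpha <- (atan2(-(tc$y - 100), tc$x - 100) * 180 / pi) %% 180
  expect_lt(max(circ_err(tc$tangent_deg, (alpha + 90) %% 180)), 1)
  d <- sqrt(diff(tc$x)^2 + diff(tc$y)^2)
  expect_lt(max(abs(d - mean(d))) / mean(d), 0.01)
})

test_that("peritumoral band approximates the annulus area", {
  circ <- circle_boundary(60, 60, 50)
  band <- peritumoral_band(circ, 10, c(121, 121), side = "both")
  expect_lt(abs(sum(band) - pi * (60^2 - 40^2)) / (pi * (60^2 - 40^2)), 0.05)

  outside <- peritumoral_band(circ, 10, c(121, 121), side = "outside")
  expect_lt(abs(sum(outside) - pi * (60^2 - 50^2)) / (pi * (60^2 - 50^2)),
            0.05)
  # outside band contains no interior pixel
  expect_false(outside[61, 61])
  expect_false(outside[61, 95])   # (x, y) = (94, 60), r = 34 inside tumor
  expect_true(outside[61, 115])   # (x, y) = (114, 60), r = 54 in band
  expect_false(outside[2, 2])     # far corner excluded

  # micrometer units require pixel size metadata
  expect_error(peritumoral_band(circ, 100, c(121, 121), units = "um"),
               "pixel_size")
  b_um <- peritumoral_band(circ, 50, c(121, 121), units = "um",
                           pixel_size = 5, side = "both")
  expect_identical(b_um, peritumoral_band(circ, 10, c(121, 121),
                                          side = "both"))
})

test_that("tiny band widths collapse to the rasterized curve", {
  circ <- circle_boundary(20, 20, 10)
  thin <- peritumoral_band(circ, 0.5, c(41, 41), side = "both")
  d <- sqrt((col(thin) - 1 - 20)^2 + (row(thin) - 1 - 20)^2)
  expect_true(all(abs(d[thin] - 10) <= 0.51))
  expect_error(peritumoral_band(circ, 0, c(41, 41)), "positive")
})

test_that("relative angle is the acute difference, symmetric and bounded", {
  expect_equal(relative_angle(30, 30), 0)
  expect_equal(relative_angle(30, 120), 90)
  expect_equal(relative_angle(30, 150), 60)
  expect_error(relative_angle(190, 0), "\\[0, 180\\)")

  set.seed(77)
  a <- runif(500, 0, 180); b <- runif(500, 0, 180)
  d1 <- relative_angle(a, b)
  expect_true(all(d1 >= 0 & d1 <= 90))
  expect_equal(d1, relative_angle(b, a))
  expect_equal(d1, mapply(oracle_relative_angle, a, b))
})

test_that("phantom relative orientations separate tangential from radial", {
  noiseless <- scatter_model(noise_sigma = 0)
  run <- function(arrangement) {
    f <- make_orientation_field("tumor_phantom", 110, 110,
                                list(radius = 30, band_width = 14,
                                     arrangement = arrangement), seed = 1)
    om <- compute_orientation_map(render_scatter_stack(f, noiseless))
    bd <- boundary_annotation(attr(f, "boundary"))
    tg <- resample_and_tangents(bd, spacing = 2)
    band <- peritumoral_band(bd, 14, c(110, 110))
    relative_orientation_map(om, tg, band)
  }
  rel_t <- run("tangential")
  rel_r <- run("radial")
  expect_gt(mean(rel_t$samples < 10), 0.95)
  expect_gt(mean(rel_r$samples > 80), 0.95)

  # collagen mask all false -> zero samples
  f <- make_orientation_field("tumor_phantom", 60, 60,
                              list(radius = 15, band_width = 8))
  om <- compute_orientation_map(render_scatter_stack(f, noiseless))
  bd <- boundary_annotation(attr(f, "boundary"))
  tg <- resample_and_tangents(bd, spacing = 2)
  band <- peritumoral_band(bd, 8, c(60, 60))
  rel0 <- relative_orientation_map(om, tg, band,
                                   collagen = matrix(FALSE, 60, 60))
  expect_length(rel0$samples, 0)
  expect_error(relative_orientation_map(om, tg[0, ], band), "empty")
})

test_that("joint rotation of scene and boundary leaves the distribution alone", {
  noiseless <- scatter_model(noise_sigma = 0)
  n <- 90
  f <- make_orientation_field("tumor_phantom", n, n,
                              list(center = c(38, 50), radius = 22,
                                   band_width = 12, arrangement = "mixed",
                                   mixed_fraction = 0.5), seed = 9)
  st <- render_scatter_stack(f, noiseless)
  bd <- attr(f, "boundary")$curves[[1]]$points

  # rotate the whole scene by 90 deg anti-clockwise on screen: frames rotate
  # spatially ((x, y) -> (y, n-1-x)) and the illumination labels shift by 90
  rot90 <- function(m) t(m)[n:1, , drop = FALSE]
  frames2 <- array(0, dim(st$frames))
  for (k in 1:24) frames2[, , k] <- rot90(st$frames[, , k])
  st2 <- angular_stack(frames2, st$angles + 90)
  bd2 <- cbind(bd[, 2], (n - 1) - bd[, 1])

  run <- function(stack, poly) {
    om <- compute_orientation_map(stack)
    b <- boundary_annotation(poly)
    relative_orientation_map(om, resample_and_tangents(b, 2),
                             peritumoral_band(b, 12, c(n, n)))
  }
  r1 <- run(st, bd)
  r2 <- run(st2, bd2)
  expect_equal(length(r1$samples), length(r2$samples))
  expect_lt(max(abs(quantile(r1$samples, 1:19 / 20) -
                    quantile(r2$samples, 1:19 / 20))), 1)
})

test_that("relative FOM colors run green (parallel) to magenta (perpendicular)", {
  rel <- structure(list(delta = matrix(c(0, 90, 45, NA), 1, 4),
                        multiplicity = matrix(c(1, 1, 1, 0), 1, 4),
                        samples = c(0, 90, 45)),
                   class = "relative_orientation_map")
  img <- colorize_relative_fom(rel)
  expect_equal(as.integer(img[1, 1, ]), c(0L, 255L, 0L))      # parallel
  expect_equal(as.integer(img[1, 2, ]), c(255L, 0L, 255L))    # perpendicular
  mid <- t(grDevices::col2rgb(grDevices::hsv(210 / 360, 1, 1)))
  expect_equal(as.integer(img[1, 3, ]), as.integer(mid))      # arc midpoint
  expect_equal(as.integer(img[1, 4, ]), c(0L, 0L, 0L))        # out of band
})
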