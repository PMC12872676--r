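test_that("printed equation constants evaluate exactly", {
  expect_equal(axialLengthFromRx(0), 23.757, tolerance = 1e-12)
  expect_equal(axialLengthFromRx(-6), 26.229, tolerance = 1e-12)
  expect_equal(axialLengthFromRx(6), 21.285, tolerance = 1e-12)
  expect_warning(axialLengthFromRx(-12), "extrapolat")

  expect_equal(verticalAxis(1, 0), 0.9921, tolerance = 1e-12)
  expect_equal(verticalAxis(10, -6) / 10, 0.9921 + 0.004072 * 6,
               tolerance = 1e-12)

  expect_equal(correctThickness(0, 0), -0.07437, tolerance = 1e-12)
  expect_equal(correctThickness(50, 0.1), 49.94643, tolerance = 1e-12)

  expect_equal(correctLateralResolution(0.010, 24.385), 0.010,
               tolerance = 1e-12)
  expect_equal(round(correctLateralResolution(0.010, 26), 6), 0.010662)
  expect_equal(round(correctLateralResolution(0.010, 22), 6), 0.009022)
})

test_that("tilt correction is strictly dominated for every real tilt", {
  tilts <- c(seq(0, 1.5, by = 0.01), 1.611 / (2 * 14.03))
  corr <- correctThickness(100, tilts)
  expect_true(all(corr < 100))
  # the quadratic's maximum (at the vertex) stays below -0.028 um
  expect_lt(max(corr - 100), -0.028)
  # sign convention: magnitude of tilt
  expect_equal(correctThickness(40, -0.2), correctThickness(40, 0.2))
})

test_that("lateral-resolution correction scales with axial length", {
  al <- seq(20, 28, by = 0.5)
  res <- correctLateralResolution(0.0309, al)
  expect_true(all(diff(res) > 0))
  expect_error(correctLateralResolution(0.01, -1), "positive")
})

test_that("ellipse fit recovers exact ellipses and flags degenerate profiles", {
  x <- seq(-7000, 7000, length.out = 201)
  a <- 10000; b <- 8000; c0 <- 40
  z <- c0 + b * (1 - sqrt(1 - (x / a)^2))
  fit <- fitFovealEllipse(x, z)
  expect_true(fit$ok)
  expect_equal(fit$axisHoriz, a, tolerance = 1e-6)
  expect_equal(fit$axisZ, b, tolerance = 1e-6)
  # a constant z offset only moves the centre, never the axes
  fit2 <- fitFovealEllipse(x, z + 1234.5)
  expect_equal(fit2$axisHoriz, fit$axisHoriz, tolerance = 1e-6)
  # degenerate profiles signal exclusion, not a silent default
  expect_false(fitFovealEllipse(x, rep(5, length(x)))$ok)
  expect_false(fitFovealEllipse(x[1:4], z[1:4])$ok)
})

test_that("curvature translation is even-symmetric and has an identity limit", {
  vol <- makeFlatVolume()
  y <- (5 - seq_len(9)) * 500
  out <- reconstructVerticalCurvature(vol, NULL, 0, y, axisVertUm = 11000)
  g <- out@meta$curvatureTranslationUm
  expect_equal(g, rev(g))              # symmetric ellipse, symmetric arcs
  expect_equal(g[5], 0)                # foveal B-scan fixed
  expect_true(all(diff(g[5:9]) > 0))   # grows with eccentricity
  # thickness preserved under rigid translation
  expect_equal(axialThickness(out), axialThickness(vol))
  idty <- reconstructVerticalCurvature(vol, NULL, 0, y, axisVertUm = Inf)
  expect_equal(idty@iplInlZ, vol@iplInlZ)
})

test_that("nodal-point de-warp satisfies the sphere oracle and its limits", {
  vol <- makeFlatVolume(nB = 11L, nA = 21L)
  x <- (seq_len(21) - 11) * 500
  y <- (6 - seq_len(11)) * 500
  # flat-field limit: infinite nodal distance is the identity
  idty <- dewarpToNodalPoint(vol, x, y, 24, nodalDistMm = Inf)
  expect_equal(idty@iplInlZ, vol@iplInlZ)
  # a constant raw depth is the image of a sphere centred at the nodal point
  rho0 <- 17000
  dw <- dewarpToNodalPoint(vol, x, y, 24, nodalDistMm = rho0 / 1000)
  scale <- vol@meta$axialScaleUmPerPx
  zRef <- vol@iplInlZ[6, 11] * scale
  z <- dw@iplInlZ * scale - zRef
  r2 <- outer(y^2, rep(1, 21)) + outer(rep(1, 11), x^2)
  dist <- sqrt(r2 + (z + rho0)^2)
  expect_lt(max(abs(dist - rho0)), 0.5 * scale)
  # the on-axis A-scan is fixed
  expect_equal(dw@iplInlZ[6, 11], vol@iplInlZ[6, 11])
})

test_that("axial thickness follows the boundary separation", {
  vol <- makeFlatVolume(sep = 10, scale = 3.87)
  expect_equal(axialThickness(vol)[1, 1], 38.7)
  expect_true(all(axialThickness(makeFlatVolume(sep = 0)) == 0))
  vol@exclusionMask[2, 3] <- TRUE
  expect_true(is.na(axialThickness(vol)[2, 3]))
  bad <- makeFlatVolume()
  bad@exclusionMask[] <- FALSE
  bad@rnflGclZ[4, 4] <- bad@iplInlZ[4, 4] + 5
  expect_error(axialThickness(bad), "negative")
})

test_that("tilt field matches closed forms for plane and sphere", {
  x <- seq(-5000, 5000, length.out = 41)
  y <- seq(4000, -4000, length.out = 33)
  flat <- matrix(0, 33, 41)
  expect_true(all(tiltField(flat, x, y) == 0))
  plane <- outer(rep(0, 33), 0.1 * x, "+")
  expect_equal(max(abs(tiltField(plane, x, y) - atan(0.1))), 0,
               tolerance = 1e-9)
  r <- 12000
  sph <- outer(r - sqrt(r^2 - y^2), rep(1, 41)) +
    outer(rep(1, 33), r - sqrt(r^2 - x^2))
  tl <- tiltField(sph, x, y)
  mid <- 17  # row of y = 0
  expect_true(all(diff(tl[mid, 21:41]) > 0))  # grows with eccentricity
  expect_lt(tl[mid, 21], 0.01)                # near zero at the fovea
})

test_that("exclusion interpolation fills bounded runs only", {
  m <- matrix(c(40, NA, NA, NA, 48,
                NA, NA, 30, 30, 30,
                10, 12, 14, 16, 18), 3, 5, byrow = TRUE)
  out <- interpolateExclusions(m)
  expect_equal(out[1, ], c(40, 42, 44, 46, 48))
  expect_true(all(is.na(out[2, 1:2])))        # run touches the scan edge
  expect_equal(out[3, ], m[3, ])              # no exclusions: identity
  prot <- matrix(FALSE, 3, 5); prot[1, 3] <- TRUE
  out2 <- interpolateExclusions(m, prot)
  expect_true(is.na(out2[1, 3]))              # protected zones never filled
  expect_equal(out2[1, c(2, 4)], c(42, 46))
})

test_that("fovea-disc tilt has the documented sign convention", {
  f <- list(row = 10, col = 10)
  expect_equal(foveaDiscTilt(f, list(row = 10, col = 20), 100, 100), 0)
  expect_equal(foveaDiscTilt(f, list(row = 5, col = 15), 100, 100), 45)
  expect_error(foveaDiscTilt(f, f, 100, 100), "coincide")
  # mirroring an OS eye restores the OD sign
  od <- foveaDiscTilt(f, list(row = 7, col = 16), 100, 100, "OD")
  os <- foveaDiscTilt(f, list(row = 7, col = 4), 100, 100, "OS")
  expect_equal(od, os)
})

test_that("grid averaging covers sampled squares and flags the rest", {
  nA <- 200L; nB <- 61L
  x <- (seq_len(nA) - 100) * 40
  y <- (31 - seq_len(nB)) * 120
  g <- gridAverage(matrix(50, nB, nA), x, y, tiltDeg = 0, nGrid = 160L)
  v <- gridValues(g)
  expect_true(all(v[is.finite(v)] == 50))
  expect_true(any(is.na(v)))                       # footprint < grid area
  ctr <- v[78:83, 78:83]
  expect_true(all(is.finite(ctr)))                 # fovea fully covered
  expect_error(gridAverage(matrix(50, nB, nA), x + 1e6, y), "fovea")
})

test_that("mirroring a volume and flipping laterality leaves the grid unchanged", {
  rt <- oneEyeRoundTrip()
  res2 <- processVolume(mirrorVolume(rt$vol), matchingOptions(rt$cfg))
  expect_equal(gridValues(res2$grid), gridValues(rt$res$grid))
})

test_that("the correction cascade inverts the generator distortions", {
  rt <- oneEyeRoundTrip()
  g <- gridValues(rt$res$grid)
  tv <- gridValues(rt$truth)
  ok <- is.finite(g)
  expect_gt(sum(ok), 10000)
  expect_lt(mean(abs(g[ok] - tv[ok])), 3.87)
  # the fovea-disc tilt fed to the generator is recovered exactly
  expect_equal(rt$res$tiltDeg, rt$eye$fovea_disc_tilt, tolerance = 1e-9)
  # corrected never exceeds uncorrected where both are defined
  m <- rt$res$map
  both <- is.finite(m@uncorrected) & is.finite(m@corrected)
  expect_true(all(m@corrected[both] < m@uncorrected[both]))
})
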