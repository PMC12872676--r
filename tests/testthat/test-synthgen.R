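test_that("cohort generation honours bracket structure and determinism", {
  co <- generateCohort(generatorConfig(seed = 1L))
  expect_equal(nrow(co), 470L)
  expect_equal(sum(co$age >= 20 & co$age < 30), 70L)
  expect_equal(unname(table(co$bracket)), c(70L, 73L, 70L, 80L, 102L, 75L),
               ignore_attr = TRUE)
  expect_true(all(co$age >= 20))
  expect_true(all(co$refraction >= -6 & co$refraction <= 6))
  expect_true(all(co$axial_length > 0))
  expect_true(all(co$sex %in% 0:1))
  # determinism contract
  expect_identical(co, generateCohort(generatorConfig(seed = 1L)))
  expect_false(identical(co$age, generateCohort(generatorConfig(seed = 2L))$age))
  # configuration errors
  expect_error(generatorConfig(bracketCounts = rep(0L, 6)), "configuration")
  expect_error(generatorConfig(nEyes = 100L), "configuration")
})

test_that("cohort moments match the study demographics", {
  co <- generateCohort(generatorConfig(seed = 11L))
  n <- nrow(co)
  expect_lt(abs(mean(co$axial_length) - 23.97), 3 * 1.12 / sqrt(n))
  expect_lt(abs(sd(co$axial_length) - 1.12), 3 * 1.12 / sqrt(2 * (n - 1)))
  expect_lt(abs(mean(co$fovea_disc_tilt) - 7.14), 3 * 3.87 / sqrt(n))
  # refraction-biometry coupling is strongly negative
  expect_lt(cor(co$refraction, co$axial_length), -0.5)
  expect_equal(mean(is.na(co$axial_length_observed)), 0.3, tolerance = 0.1)
})

test_that("truth maps evaluate the cluster model with demographic effects", {
  model <- defaultClusterModel()
  eye <- list(eye_id = "t", age = 50, axial_length = 23.97, sex = 0.5)
  tm <- truthMap(eye, model, eyeNoiseSd = 0, squareNoiseSd = 0)
  v <- gridValues(tm)
  # innermost cluster: 106.6 - 0.19 * 50 = 97.1 um
  expect_equal(unique(v[model$template == 9L]), 97.1, tolerance = 1e-9)
  expect_equal(unique(v[model$template == 1L]), 32.89 - 0.04 * 50,
               tolerance = 1e-9)
  # identical demographics, no noise -> identical grids
  tm2 <- truthMap(eye, model, eyeNoiseSd = 0, squareNoiseSd = 0, seed = 99L)
  expect_identical(gridValues(tm2), v)
  # demographic effects shift every square additively
  eye2 <- list(eye_id = "t2", age = 50, axial_length = 24.97, sex = 0.5)
  tm3 <- truthMap(eye2, model, eyeNoiseSd = 0, squareNoiseSd = 0)
  expect_true(all(abs((gridValues(tm3) - v) + 0.436) < 1e-9))
})

test_that("noisy truth maps converge to the model value in the mean", {
  model <- defaultClusterModel(stride = 8L)
  eye <- list(eye_id = "t", age = 40, axial_length = 23.97, sex = 0.5)
  sq <- which(model$template == 5L)[1]
  vals <- vapply(1:60, function(s)
    gridValues(truthMap(eye, model, seed = s))[sq], 0)
  expected <- 75.23 - 0.19 * 40
  expect_lt(abs(mean(vals) - expected),
            3 * sqrt(5^2 + 3^2) / sqrt(60))
})

test_that("the cluster template is concentric and complete", {
  for (stride in c(1L, 4L)) {
    tpl <- defaultClusterModel(stride = stride)$template
    expect_setequal(unique(as.vector(tpl)), 1:9)
    # cluster index increases toward the fovea: mean eccentricity decreases
    n <- nrow(tpl)
    ctr <- (n + 1) / 2
    ecc <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
    meanEcc <- vapply(1:9, function(c) mean(ecc[tpl == c]), 0)
    expect_true(all(diff(meanEcc) < 0))
  }
})

test_that("identity distortion round-trips through the cascade", {
  cfg <- generatorConfig(nEyes = 1L, bracketCounts = c(0L, 1L, 0L, 0L, 0L, 0L),
                         seed = 21L, missingAlFraction = 0,
                         distortions = list(warpage = FALSE, tilt = FALSE,
                                            magnification = FALSE,
                                            rotation = FALSE,
                                            vesselMask = FALSE))
  eye <- generateCohort(cfg)[1, ]
  tm <- truthMap(eye, eyeNoiseSd = 0, squareNoiseSd = 0)
  vol <- distortToRaw(tm, eye, cfg)
  res <- processVolume(vol, matchingOptions(cfg))
  g <- gridValues(res$grid); tv <- gridValues(tm)
  ok <- is.finite(g)
  expect_lt(mean(abs(g[ok] - tv[ok])), 0.5)
})

test_that("tilt distortion inflates axial thickness everywhere", {
  cfg <- generatorConfig(nEyes = 1L, bracketCounts = c(0L, 1L, 0L, 0L, 0L, 0L),
                         seed = 22L, missingAlFraction = 0,
                         distortions = list(warpage = FALSE, tilt = TRUE,
                                            magnification = FALSE,
                                            rotation = FALSE,
                                            vesselMask = FALSE))
  eye <- generateCohort(cfg)[1, ]
  tm <- truthMap(eye, eyeNoiseSd = 0, squareNoiseSd = 0)
  vol <- distortToRaw(tm, eye, cfg)
  res <- processVolume(vol, matchingOptions(cfg))
  m <- res$map
  both <- is.finite(m@uncorrected) & is.finite(m@corrected)
  expect_true(all(m@uncorrected[both] > m@corrected[both]))
  expect_gt(max(m@tilt), 0.3)   # widefield eccentricity reaches steep tilt
  g <- gridValues(res$grid); tv <- gridValues(tm)
  ok <- is.finite(g)
  expect_lt(mean(abs(g[ok] - tv[ok])), 3.87)
})

test_that("vessel masking stays within the configured coverage range", {
  rt <- oneEyeRoundTrip()
  frac <- mean(rt$vol@exclusionMask)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.25)
  # same seed, same volume
  vol2 <- distortToRaw(rt$truth, rt$eye, rt$cfg, seed = 9L)
  expect_identical(vol2@exclusionMask, rt$vol@exclusionMask)
  expect_identical(vol2@iplInlZ, rt$vol@iplInlZ)
})

test_that("cluster tables evaluate the per-cluster lines", {
  model <- defaultClusterModel()
  tab <- clusterTable(model, nPerBracket = 2L, residualSd = 0, seed = 4L)
  one <- tab[tab$cluster == 1L, ]
  expect_equal(one$value, 32.89 - 0.04 * one$age, tolerance = 1e-9)
  # noiseless recovery of slope and intercept by OLS
  f <- lm(value ~ age, data = one)
  expect_equal(unname(coef(f)), c(32.89, -0.04), tolerance = 1e-9)
  # log10 scale evaluates the log lines
  tl <- clusterTable(model, nPerBracket = 2L, residualSd = 0, seed = 4L,
                     scale = "log10")
  nine <- tl[tl$cluster == 9L, ]
  expect_equal(nine$log10_value, 2.04 - 0.001 * nine$age, tolerance = 1e-9)
})
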