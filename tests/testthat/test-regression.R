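test_that("global regression recovers noiseless coefficients exactly", {
  d <- simulateGlobalCohort(200, noiseSd = 0, seed = 2L)
  fit <- suppressWarnings(globalRegression(d))
  est <- fit$coefficients$estimate
  names(est) <- fit$coefficients$term
  expect_equal(unname(est[c("age", "axial_length", "sex")]),
               c(-0.053, -0.436, -0.646), tolerance = 1e-9)
  # collinear designs fail loudly, naming the aliased term
  d$age2 <- 2 * d$age
  expect_error(globalRegression(d, thickness ~ age + age2 + sex), "age2")
})

test_that("fitting age alone shifts its coefficient by the omitted-variable bias", {
  d <- simulateGlobalCohort(300, noiseSd = 0, seed = 6L)
  ageOnly <- coef(lm(thickness ~ age, data = d))[2]
  gAL <- coef(lm(axial_length ~ age, data = d))[2]
  gSex <- coef(lm(sex ~ age, data = d))[2]
  expect_equal(unname(ageOnly), -0.053 + (-0.436) * unname(gAL) +
                 (-0.646) * unname(gSex), tolerance = 1e-9)
})

test_that("the elimination arithmetic reproduces the reported change", {
  expect_equal(round(coefficientChangePct(-0.053, -0.050), 2), 5.66)
})

test_that("backward elimination drops only innocuous terms", {
  set.seed(5)
  n <- 300
  x1 <- rnorm(n)
  x2 <- x1 + rnorm(n, 0, 0.4)            # correlated pair: removal shifts x1
  junk <- rnorm(n)                       # orthogonal irrelevant term
  y <- 2 * x1 + 1.5 * x2 + rnorm(n, 0, 0.5)
  d <- data.frame(y, x1, x2, junk)
  el <- backwardElimination(y ~ x1 + x2 + junk, d)
  # the orthogonal term goes with negligible coefficient changes,
  # the correlated confounder is restored by the 10% rule
  expect_false("junk" %in% el$retained)
  expect_setequal(el$retained, c("x1", "x2"))
  expect_lt(max(el$steps[[1]]$pctChange), 2)
  expect_equal(el$steps[[length(el$steps)]]$decision, "restored")
  # idempotence: rerunning on the retained model changes nothing
  el2 <- backwardElimination(reformulate(el$retained, response = "y"), d)
  expect_setequal(el2$retained, el$retained)
  expect_error(backwardElimination(y ~ x1, d), "2 candidate")
})

test_that("the repeatability coefficient follows the printed formula", {
  expect_equal(repeatabilityCoefficient(c(1, 2, 3), c(1, 2, 3))$cR, 0)
  expect_equal(repeatabilityCoefficient(c(1, 2), c(0, 3))$cR, 1.96)
  r <- repeatabilityCoefficient(c(0, 3), c(1, 0))
  expect_equal(r$cR, 1.96 * sqrt(2), tolerance = 1e-12)
  expect_equal(r$n, 2L)
  # homogeneity: scaling all differences by c scales C_R by sqrt(c)
  m <- c(10, 14, 9); cl <- c(11, 12, 10)
  r1 <- repeatabilityCoefficient(m, cl)$cR
  r4 <- repeatabilityCoefficient(cl + 4 * (m - cl), cl)$cR
  expect_equal(r4, 2 * r1, tolerance = 1e-12)
  # conventional Bland-Altman form
  expect_equal(repeatabilityCoefficient(m, cl, "classic")$cR,
               1.96 * sd(m - cl), tolerance = 1e-12)
  expect_error(repeatabilityCoefficient(NA, 1), "overlapping")
})

test_that("sliding windows tile the age range per offset", {
  d <- data.frame(age = rep(seq(21, 79, by = 2), each = 2),
                  value = 50, cluster = rep(1:2, 30))
  sw <- slidingWindow(d)
  expect_true(all(sw$meanValue == 50))
  expect_setequal(unique(sw$offset), 0:9)
  # linear truth: window means lie exactly on the line
  d2 <- data.frame(age = seq(20, 79.5, by = 0.5),
                   value = 100 - 0.2 * seq(20, 79.5, by = 0.5))
  sw2 <- slidingWindow(d2)
  expect_equal(sw2$meanValue, 100 - 0.2 * sw2$meanAge, tolerance = 1e-9)
  expect_error(slidingWindow(data.frame(age = c(21, 24), value = 1:2)),
               "span")
})

test_that("linear-vs-quadratic comparison detects curvature only when present", {
  x <- seq(20, 80, by = 2)
  lin <- compareLinearQuadratic(x, 100 - 0.2 * x + rnorm(length(x), 0, 1e-8))
  expect_lt(lin$fStatistic, 1)
  expect_lte(lin$adjR2Complex, lin$adjR2Simple + 1e-6)
  quad <- compareLinearQuadratic(x, 100 - 0.2 * x + 0.01 * (x - 50)^2 +
                                   rnorm(length(x), 0, 0.01))
  expect_lt(quad$pValue, 1e-6)
  expect_error(compareLinearQuadratic(rep(1, 10), rnorm(10)), "degenerate")
  expect_error(compareLinearQuadratic(1:3, 1:3), "at least 4")
})

test_that("mixed-effects slopes reduce to per-cluster OLS without eye effects", {
  tab <- clusterTable(nPerBracket = 6L, seed = 31L)
  tab$eye <- tab$eye_id
  mx <- suppressMessages(mixedEffectsByCluster(tab))
  ols <- perClusterLinearFit(tab)
  expect_equal(mx$slopes$slope, ols$slope, tolerance = 1e-6)
  # marginal means evaluated over the bracket grid
  expect_equal(sort(unique(mx$emm$age)), seq(25, 75, by = 10))
  bad <- tab; bad$value[3] <- -1
  expect_error(mixedEffectsByCluster(bad, logScale = TRUE), "positive")
})

test_that("the eye random intercept absorbs between-eye variance", {
  tab <- clusterTable(nPerBracket = 12L, residualSd = 2, eyeSd = 6,
                      seed = 32L)
  tab$eye <- tab$eye_id
  mx <- suppressMessages(mixedEffectsByCluster(tab))
  expect_lt(max(abs(mx$slopes$slope - defaultClusterModel()$slope)), 0.15)
  # eye effects cancel in slope contrasts: the mixed-model contrast SE is
  # far below the naive pooled-OLS interaction SE
  st <- suppressMessages(sharedSlopeTests(tab))
  olsContrastSe <- summary(
    lm(value ~ age * factor(cluster), data = tab))$coefficients[
      "age:factor(cluster)2", 2]
  expect_lt(st$tukey$SE[1], 0.6 * olsContrastSe)
})

test_that("per-cluster fits recover the generating lines exactly without noise", {
  tab <- clusterTable(nPerBracket = 2L, residualSd = 0, seed = 33L)
  fits <- suppressWarnings(perClusterLinearFit(tab))
  expect_equal(fits$slope,
               c(-0.04, -0.04, -0.12, -0.12, rep(-0.19, 5)), tolerance = 1e-9)
  expect_equal(fits$intercept,
               c(32.89, 38.53, 52.06, 62.57, 75.23, 83.76, 91.97, 99.68,
                 106.6), tolerance = 1e-9)
  expect_equal(fits$rmse, rep(0, 9), tolerance = 1e-7)
  # constant response: zero slope, zero R2
  flat <- data.frame(value = 5, age = c(20, 40, 60, 80), cluster = 1L)
  ff <- suppressWarnings(perClusterLinearFit(flat))
  expect_equal(ff$slope, 0)
  expect_equal(ff$r2, 0)
  # log fits linearise a noiseless exponential decline
  ages <- seq(20, 80, by = 5)
  expo <- data.frame(value = 10^(1.8 - 0.002 * ages), age = ages,
                     cluster = 1L)
  fl <- suppressWarnings(perClusterLinearFit(expo, logScale = TRUE))
  expect_equal(fl$slope, -0.002, tolerance = 1e-9)
})

test_that("shared-slope tests separate only truly different slopes", {
  # two clusters generated identically: contrast estimate ~ 0
  model <- defaultClusterModel()
  model$slope[2] <- model$slope[1]
  tab <- clusterTable(model, nPerBracket = 12L,
                      residualSd = sqrt(5.5^2 - 4^2), eyeSd = 4, seed = 41L)
  tab <- tab[tab$cluster %in% 1:2, ]
  tab$eye <- tab$eye_id
  st <- suppressMessages(sharedSlopeTests(tab))
  expect_lt(abs(st$tukey$estimate[1]), 0.05)
  expect_error(
    suppressMessages(sharedSlopeTests(tab, groupings = list(c(1, 7)))),
    "unknown")
})

test_that("pooled-OLS F and mixed-model LR agree, with calibrated size", {
  flat <- defaultClusterModel()
  flat$slope <- rep(-0.12, 9)           # null: one shared slope
  agree <- 0L; nullNonSig <- 0L
  reps <- 10L
  for (r in seq_len(reps)) {
    tab <- clusterTable(flat, nPerBracket = 10L,
                        residualSd = 4, eyeSd = 4, seed = 500L + r)
    tab$eye <- tab$eye_id
    st <- suppressMessages(sharedSlopeTests(tab))
    dLR <- st$lr$p < 0.05
    dF <- st$olsF$p < 0.05
    if (dLR == dF) agree <- agree + 1L
    if (!dLR) nullNonSig <- nullNonSig + 1L
  }
  expect_gte(agree, 8L)
  expect_gte(nullNonSig, 8L)
})
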