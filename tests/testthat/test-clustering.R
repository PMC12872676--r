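test_that("covariate adjustment centres at the cohort means", {
  g1 <- matrix(50, 4, 4); g2 <- matrix(60, 4, 4)
  cohort <- data.frame(eye_id = c("a", "b"), sex = c(0, 1),
                       refraction = c(0, 0),
                       axial_length_observed = c(23, 25))
  grids <- list(a = g1, b = g2)
  # zero effects: identity
  adj0 <- adjustForCovariates(grids, cohort, betaAL = 0, betaSex = 0)
  expect_equal(adj0$a, g1)
  # an eye at the cohort-mean covariates is unchanged
  cohort2 <- data.frame(eye_id = c("a", "b"), sex = c(0.5, 0.5),
                        refraction = c(0, 0),
                        axial_length_observed = c(24, 24))
  adj <- adjustForCovariates(grids, cohort2)
  expect_equal(adj$a, g1)
  expect_equal(adj$b, g2)
})

test_that("adjustment removes the generating covariate association", {
  set.seed(8)
  n <- 60
  al <- rnorm(n, 23.97, 1.12)
  sex <- rbinom(n, 1, 0.5)
  base <- 70
  grids <- lapply(seq_len(n), function(i)
    matrix(base - 0.436 * (al[i] - 23.97) - 0.646 * (sex[i] - 0.5) +
             rnorm(1, 0, 0.1), 3, 3))
  names(grids) <- sprintf("e%02d", seq_len(n))
  cohort <- data.frame(eye_id = names(grids), sex = sex, refraction = 0,
                       axial_length_observed = al)
  adj <- adjustForCovariates(grids, cohort)
  vals <- vapply(adj, function(m) m[1, 1], 0)
  expect_lt(abs(cor(vals, al)), 0.2)
  raw <- vapply(grids, function(m) m[1, 1], 0)
  expect_lt(cor(raw, al), -0.7)
})

test_that("bracket pooling averages per square and drops incomplete squares", {
  ages <- c(25, 35, 45, 55, 65, 75)
  mats <- lapply(ages, function(a) matrix(a, 4, 4))
  st <- poolByBracket(mats, ages)
  expect_equal(nrow(stackProfile(st)), 16L)
  expect_true(all(stackProfile(st) ==
                    matrix(ages, 16, 6, byrow = TRUE)))
  # a square missing in one eye uses the remaining eyes of the bracket
  mats2 <- c(mats, list(matrix(99, 4, 4)))
  mats2[[7]] <- matrix(31, 4, 4); mats2[[7]][1, 1] <- NA
  st2 <- poolByBracket(c(mats, list(mats2[[7]])), c(ages, 30))
  prof <- stackProfile(st2)
  i11 <- which(st2@squareIndex$row == 1 & st2@squareIndex$col == 1)
  iOther <- which(st2@squareIndex$row == 2 & st2@squareIndex$col == 2)
  expect_equal(prof[i11, 2], 35)            # bracket mean from remaining eye
  expect_equal(prof[iOther, 2], (35 + 31) / 2)
  # a square missing in a whole bracket is dropped
  mats3 <- mats; mats3[[2]][2, 2] <- NA
  st3 <- poolByBracket(mats3, ages)
  expect_equal(nrow(stackProfile(st3)), 15L)
  expect_error(poolByBracket(mats[1:5], ages[1:5]), "70\\+")
})

test_that("noiseless pooling reproduces the cluster-model bracket values", {
  model <- defaultClusterModel(stride = 8L)
  ages <- c(25, 35, 45, 55, 65, 75)
  grids <- lapply(ages, function(a) {
    eye <- list(eye_id = "x", age = a, axial_length = 23.97, sex = 0.5)
    gridValues(truthMap(eye, model, eyeNoiseSd = 0, squareNoiseSd = 0))
  })
  st <- poolByBracket(grids, ages)
  lab <- model$template[cbind(st@squareIndex$row, st@squareIndex$col)]
  pred <- outer(model$intercept[lab], rep(1, 6)) +
    outer(model$slope[lab], ages)
  expect_equal(stackProfile(st), pred, ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("within-groups agglomeration matches the exhaustive oracle", {
  X <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  st <- new("AgeBracketStack", profile = cbind(X, X, X, X, X, X),
            counts = rep(1L, 6), bracketAges = c(25, 35, 45, 55, 65, 75),
            brackets = rbind(c(20, 30, 40, 50, 60, 70),
                             c(30, 40, 50, 60, 70, Inf)),
            squareIndex = data.frame(row = 1:4, col = rep(1L, 4)),
            gridDim = 4L)
  sol <- hierarchicalCluster(st, 2L)
  expect_same_partition(clusterLabels(sol), c(1, 1, 2, 2))
  oracle <- bestPartitionWG(st@profile, 2L)
  expect_same_partition(clusterLabels(sol), oracle$labels)
  # k = number of points: singletons
  solN <- hierarchicalCluster(st, 4L)
  expect_equal(length(unique(clusterLabels(solN))), 4L)
  expect_error(hierarchicalCluster(st, 5L), "distinct")
})

test_that("hierarchical clustering recovers the generating template", {
  st <- smallStack()
  sol <- hierarchicalCluster(st, 9L)
  tpl <- smallTemplate()
  lab <- clusterMap(sol)
  idx <- lab > 0
  expect_equal(mean(lab[idx] == tpl[idx]), 1)
  # ordering invariants
  expect_true(all(diff(sol@clusterMeans) > 0))
  adj <- sol@pairwiseDPrime[cbind(1:8, 2:9)]
  expect_true(all(adj >= 1))
})

test_that("two-step clustering agrees with hierarchical on separable data", {
  st <- smallStack()
  hh <- hierarchicalCluster(st, 9L)
  tt <- twostepCluster(st, 9L)
  expect_same_partition(clusterLabels(hh), clusterLabels(tt))
  # k = 1: everything in one cluster
  expect_equal(unique(clusterLabels(twostepCluster(st, 1L))), 1L)
  # permuting the input order leaves the partition unchanged
  set.seed(2)
  perm <- sample(nrow(st@profile))
  stP <- st
  stP@profile <- st@profile[perm, , drop = FALSE]
  stP@squareIndex <- st@squareIndex[perm, ]
  ttP <- twostepCluster(stP, 9L)
  expect_same_partition(clusterLabels(ttP), clusterLabels(tt)[perm])
})

test_that("silhouette matches the hand-computed fixture and the reference", {
  X <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  lab <- c(1L, 1L, 2L, 2L)
  expect_equal(silhouetteCoefficient(X, lab), 0.99, tolerance = 1e-4)
  # coincident points split across clusters: a = b = 0 -> 0 by convention
  expect_equal(silhouetteCoefficient(matrix(rep(1, 4), ncol = 1),
                                     c(1L, 1L, 2L, 2L)), 0)
  expect_error(silhouetteCoefficient(X, rep(1L, 4)), "2 clusters")
  # cross-check against the independent reference implementation
  skip_if_not_installed("cluster")
  set.seed(3)
  Y <- matrix(rnorm(90), ncol = 3)
  labY <- sample(1:3, 30, replace = TRUE)
  ref <- mean(cluster::silhouette(labY, dist(Y))[, "sil_width"])
  expect_equal(silhouetteCoefficient(Y, labY), ref, tolerance = 1e-9)
  # bounds hold for arbitrary labelings
  expect_true(abs(silhouetteCoefficient(Y, labY)) <= 1)
})

test_that("d-prime follows its definition", {
  expect_equal(dPrime(10, 2, 10, 3), 0)
  expect_equal(dPrime(10, 2, 12, 2), 1)
  expect_equal(dPrime(10, 2, 12, 2), dPrime(12, 2, 10, 2))
  expect_equal(dPrime(110, 2, 112, 2), dPrime(10, 2, 12, 2))
  expect_error(dPrime(5, 0, 5, 0), "undefined")
  expect_equal(dPrime(5, 0, 6, 0), Inf)
})

test_that("cluster-count selection applies both separability gates", {
  st <- smallStack()
  sol <- selectK(st, kMax = 12L, algorithm = "hierarchical")
  expect_equal(sol@k, 9L)
  expect_gte(sol@meanSilhouette, 0.5)
  expect_true(all(sol@pairwiseDPrime[cbind(1:8, 2:9)] >= 1))
  d <- sol@diagnostics
  expect_true(all(d$pass[d$k <= 9]))
  expect_false(any(d$pass[d$k > 9]))
  # heavily overlapping data: sentinel k = 1 with diagnostics
  set.seed(7)
  ov <- st
  ov@profile <- matrix(rnorm(nrow(st@profile) * 6, 50, 5),
                       nrow(st@profile), 6)
  sent <- selectK(ov, kMax = 6L, algorithm = "hierarchical")
  expect_equal(sent@k, 1L)
  expect_false(any(sent@diagnostics$pass))
})

test_that("raising the residual noise never increases the selected k", {
  ks <- vapply(c(5.5, 30, 120), function(sd)
    selectK(smallStack(residualSd = sd, seed = 13L), kMax = 10L,
            algorithm = "hierarchical")@k, 0L)
  expect_true(all(diff(ks) <= 0))
  expect_equal(ks[1], 9L)
})
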