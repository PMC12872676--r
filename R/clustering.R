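#' Remove non-age demographic effects from thickness grids
#'
#' Before pooling by age bracket, grid-square thicknesses are corrected for
#' the demographic factors other than age identified by the multiple
#' regression model: adjusted = value - betaAL (AL - mean AL) -
#' betaSex (sex - mean sex), with cohort-mean centring (centring only shifts
#' intercepts, never slopes). Eyes with missing demographics are skipped with
#' a message; an eye without measured axial length uses the refraction
#' fallback \code{\link{axialLengthFromRx}}.
#'
#' @param grids named list of \linkS4class{ThicknessGrid} (names = eye ids),
#'   or a list of numeric matrices.
#' @param cohort data.frame with \code{eye_id}, \code{axial_length_observed}
#'   (or \code{axial_length}), \code{refraction}, \code{sex}.
#' @param betaAL,betaSex effect sizes (defaults: full-model estimates).
#' @return the list of adjusted grids (same classes), dropping skipped eyes.
#' @export
adjustForCovariates <- function(grids, cohort, betaAL = -0.436,
                                betaSex = -0.646) {
  ids <- names(grids) %||% cohort$eye_id[seq_along(grids)]
  m <- match(ids, cohort$eye_id)
  alObs <- cohort$axial_length_observed %||% cohort$axial_length
  al <- ifelse(is.finite(alObs), alObs, axialLengthFromRx(cohort$refraction))
  keep <- !is.na(m) & is.finite(al[m]) & is.finite(cohort$sex[m])
  if (any(!keep))
    message("skipping ", sum(!keep), " eye(s) with missing demographics: ",
            paste(ids[!keep], collapse = ", "))
  al <- al[m[keep]]; sex <- cohort$sex[m[keep]]
  alBar <- mean(al); sexBar <- mean(sex)
  out <- grids[keep]
  for (i in seq_along(out)) {
    shift <- betaAL * (al[i] - alBar) + betaSex * (sex[i] - sexBar)
    if (is(out[[i]], "ThicknessGrid"))
      out[[i]]@values <- out[[i]]@values - shift
    else out[[i]] <- out[[i]] - shift
  }
  out
}

#' Pool adjusted grids into an age-bracket stack
#'
#' Averages corresponding grid squares across the eyes of each decade age
#' bracket (20-<30 up to 70+). A square missing for some eyes uses the
#' remaining eyes of the bracket; squares undefined in any bracket are
#' dropped from the stack (clustering needs a complete profile).
#'
#' @param grids list of \linkS4class{ThicknessGrid} or matrices (adjusted).
#' @param ages numeric, one age per grid.
#' @param stride use every stride-th grid square (tractability control for
#'   the O(n^2) clustering; default 1).
#' @return an \linkS4class{AgeBracketStack}; bracket age values are the mean
#'   ages of the contributing eyes.
#' @export
poolByBracket <- function(grids, ages, stride = 1L) {
  stopifnot(length(grids) == length(ages))
  mats <- lapply(grids, function(g)
    if (is(g, "ThicknessGrid")) gridValues(g) else g)
  nGrid <- nrow(mats[[1]])
  keep <- seq(1L, nGrid, by = stride)
  br <- bracketOf(ages)
  counts <- tabulate(br, 6L)
  if (any(counts == 0))
    stop("empty age bracket(s): ",
         paste(c("20-<30", "30-<40", "40-<50", "50-<60", "60-<70", "70+")
               [counts == 0], collapse = ", "))
  arr <- vapply(mats, function(m) m[keep, keep], matrix(0, length(keep),
                                                        length(keep)))
  prof <- matrix(NA_real_, length(keep)^2, 6L)
  for (b in 1:6) {
    sub <- arr[, , br == b, drop = FALSE]
    prof[, b] <- as.vector(apply(sub, c(1, 2), function(v)
      if (any(is.finite(v))) mean(v[is.finite(v)]) else NA_real_))
  }
  complete <- rowSums(is.finite(prof)) == 6L
  rc <- expand.grid(row = keep, col = keep)
  new("AgeBracketStack", profile = prof[complete, , drop = FALSE],
      counts = as.integer(counts),
      bracketAges = vapply(1:6, function(b) mean(ages[br == b]), 0),
      brackets = rbind(BRACKET_EDGES[-7], BRACKET_EDGES[-1]),
      squareIndex = rc[complete, ], gridDim = as.integer(nGrid))
}

# Within-groups average linkage agglomeration on squared Euclidean distance.
# At each step the pair whose merged cluster has the smallest mean
# within-cluster squared pairwise distance is merged; ties break at the
# lowest column-major index. Returns the merge sequence (representative ids).
wgHclust <- function(X) {
  n <- nrow(X)
  if (n < 2) stop("need at least 2 profiles")
  D2 <- as.matrix(stats::dist(X))^2
  S <- D2                      # between-cluster sums of pairwise d^2
  W <- numeric(n)              # within-cluster sums
  sz <- rep(1L, n)
  active <- rep(TRUE, n)
  pairs <- function(m) m * (m - 1) / 2
  C <- S / 1                   # merged pair criterion for singletons
  diag(C) <- Inf
  merges <- matrix(0L, n - 1L, 2L)
  for (s in seq_len(n - 1L)) {
    idx <- which.min(C)
    j <- (idx - 1L) %/% n + 1L
    i <- idx - (j - 1L) * n
    merges[s, ] <- c(min(i, j), max(i, j))
    a <- min(i, j); b <- max(i, j)
    W[a] <- W[a] + W[b] + S[a, b]
    sz[a] <- sz[a] + sz[b]
    active[b] <- FALSE
    S[a, ] <- S[a, ] + S[b, ]
    S[, a] <- S[a, ]
    C[b, ] <- Inf; C[, b] <- Inf
    upd <- which(active); upd <- upd[upd != a]
    if (length(upd)) {
      cr <- (W[a] + W[upd] + S[a, upd]) / pairs(sz[a] + sz[upd])
      C[a, upd] <- cr; C[upd, a] <- cr
    }
    C[a, a] <- Inf
  }
  list(merges = merges, n = n)
}

cutWg <- function(h, k) {
  lab <- seq_len(h$n)
  nm <- h$n - k
  if (nm > 0) for (s in seq_len(nm))
    lab[lab == h$merges[s, 2]] <- h$merges[s, 1]
  match(lab, sort(unique(lab)))
}

# Order clusters by ascending mean thickness and compute diagnostics.
makeClusterSolution <- function(stack, labels, algorithm,
                                diagnostics = data.frame()) {
  k <- length(unique(labels))
  prof <- stack@profile
  means <- vapply(seq_len(k), function(c)
    mean(prof[labels == c, , drop = FALSE]), 0)
  ord <- order(means)
  relab <- match(labels, ord)
  means <- means[ord]
  sds <- vapply(seq_len(k), function(c)
    stats::sd(as.vector(prof[relab == c, , drop = FALSE])), 0)
  dp <- matrix(NA_real_, k, k)
  if (k > 1) {
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      dp[a, b] <- dp[b, a] <- dPrime(means[a], sds[a], means[b], sds[b])
    }
    # undefined (all-singleton) silhouettes are reported as NA here; the
    # direct silhouetteCoefficient() call still errors
    sil <- tryCatch(silhouetteCoefficient(prof, relab),
                    error = function(e) NA_real_)
  } else sil <- NA_real_
  new("ClusterSolution", labels = as.integer(relab), k = as.integer(k),
      clusterMeans = means, clusterSds = sds, meanSilhouette = sil,
      pairwiseDPrime = dp, squareIndex = stack@squareIndex,
      gridDim = stack@gridDim, algorithm = algorithm,
      diagnostics = diagnostics)
}

#' Hierarchical clustering of age-bracket profiles
#'
#' Agglomerative clustering of the 6-dimensional bracket profiles using
#' squared Euclidean distance and within-groups linkage (each merge minimises
#' the merged cluster's mean within-cluster squared pairwise distance), cut
#' at \code{k} clusters. Deterministic given input order; ties break at the
#' lowest column-major pair index.
#'
#' @param stack an \linkS4class{AgeBracketStack}.
#' @param k number of clusters (2 <= k <= number of distinct profiles).
#' @return a \linkS4class{ClusterSolution}, clusters ordered by ascending
#'   mean thickness.
#' @export
hierarchicalCluster <- function(stack, k) {
  prof <- stack@profile
  nd <- nrow(unique(prof))
  if (k < 1 || k > nd)
    stop("k must lie in 1..", nd, " (number of distinct profiles)")
  if (k == 1)
    return(makeClusterSolution(stack, rep(1L, nrow(prof)), "hierarchical"))
  h <- wgHclust(prof)
  makeClusterSolution(stack, cutWg(h, k), "hierarchical")
}

# Stage-1 coarse pre-clustering: k-means over lexicographically sorted
# profiles, initialised from evenly spaced rows of the sorted unique
# profiles. Fully deterministic and invariant to input order (the seed
# argument is accepted for interface stability; no randomness is consumed).
twostepStage1 <- function(X, nSub, seed) {
  U <- unique(X)
  U <- U[do.call(order, as.data.frame(U)), , drop = FALSE]
  if (nrow(U) <= nSub) {
    sub <- match(asplit(X, 1), asplit(U, 1))
    return(list(sub = sub, nSub = nrow(U)))
  }
  ord <- do.call(order, as.data.frame(X))
  pick <- unique(round(seq(1, nrow(U), length.out = nSub)))
  init <- U[pick, , drop = FALSE]
  km <- stats::kmeans(X[ord, , drop = FALSE], centers = init, iter.max = 100)
  sub <- integer(nrow(X))
  sub[ord] <- km$cluster
  list(sub = sub, nSub = nrow(init))
}

# Stage-2 log-likelihood-distance agglomeration of sub-clusters (continuous
# variables): zeta(v) = -N_v * sum_f 0.5 log(sigma_f^2 + s_vf^2), merge the
# pair minimising zeta(a) + zeta(b) - zeta(ab).
twostepStage2 <- function(X, sub, k) {
  nSub <- max(sub)
  f <- ncol(X)
  N <- tabulate(sub, nSub)
  Sm <- rowsum(X, sub)
  Sq <- rowsum(X^2, sub)
  sigma2 <- apply(X, 2, function(v) mean((v - mean(v))^2)) + 1e-12
  zeta <- function(n, s, q) {
    vr <- q / n - (s / n)^2
    -n * sum(0.5 * log(sigma2 + pmax(vr, 0)))
  }
  act <- rep(TRUE, nSub)
  z <- vapply(seq_len(nSub), function(v) zeta(N[v], Sm[v, ], Sq[v, ]), 0)
  grp <- seq_len(nSub)
  while (sum(act) > k) {
    ids <- which(act)
    best <- c(Inf, 0L, 0L)
    for (ai in seq_along(ids)) for (bi in seq_len(ai - 1L)) {
      a <- ids[bi]; b <- ids[ai]   # lowest-index-first tie-break
      dz <- z[a] + z[b] -
        zeta(N[a] + N[b], Sm[a, ] + Sm[b, ], Sq[a, ] + Sq[b, ])
      if (dz < best[1]) best <- c(dz, a, b)
    }
    a <- best[2]; b <- best[3]
    N[a] <- N[a] + N[b]; Sm[a, ] <- Sm[a, ] + Sm[b, ]
    Sq[a, ] <- Sq[a, ] + Sq[b, ]
    z[a] <- zeta(N[a], Sm[a, ], Sq[a, ])
    act[b] <- FALSE
    grp[grp == b] <- a
  }
  match(grp, sort(unique(grp)))[sub]
}

#' Two-step clustering of age-bracket profiles
#'
#' Stage 1 coarsely pre-clusters the profiles into many sub-clusters on
#' Euclidean distance (seeded k-means over lexicographically sorted input,
#' so the partition is order-invariant); stage 2 agglomerates the
#' sub-clusters to \code{k} final clusters with a probabilistic
#' log-likelihood distance. Deterministic under a fixed seed.
#'
#' @param stack an \linkS4class{AgeBracketStack}.
#' @param k final number of clusters.
#' @param nSub stage-1 granularity (default 64 sub-clusters).
#' @param seed RNG seed for stage 1.
#' @return a \linkS4class{ClusterSolution}.
#' @export
twostepCluster <- function(stack, k, nSub = 64L, seed = 1L) {
  prof <- stack@profile
  nd <- nrow(unique(prof))
  if (k < 1 || k > nd)
    stop("k must lie in 1..", nd, " (number of distinct profiles)")
  if (k == 1)
    return(makeClusterSolution(stack, rep(1L, nrow(prof)), "twostep"))
  s1 <- twostepStage1(prof, nSub, seed)
  if (s1$nSub < k) stop("stage-1 produced fewer sub-clusters than k")
  makeClusterSolution(stack, twostepStage2(prof, s1$sub, k), "twostep")
}

#' Mean silhouette coefficient
#'
#' For each point, a = mean distance to the other members of its cluster
#' (0 for singletons), b = mean distance to the points of the nearest other
#' cluster, s = (b - a) / max(a, b); the coefficient is the mean of s
#' (Euclidean metric). When a = b = 0 (coincident points split across
#' clusters) s is defined as 0.
#'
#' @param X numeric matrix of profiles (rows = points), or ignored when
#'   \code{D} is given.
#' @param labels integer cluster labels.
#' @param D optional precomputed distance matrix.
#' @return mean silhouette in [-1, 1].
#' @export
silhouetteCoefficient <- function(X, labels, D = NULL) {
  if (is.null(D)) D <- as.matrix(stats::dist(X))
  k <- length(unique(labels))
  if (k < 2) stop("silhouette undefined for fewer than 2 clusters")
  n <- length(labels)
  if (all(tabulate(labels, k) == 1L))
    stop("silhouette undefined when every cluster is a singleton")
  sizes <- tabulate(labels, k)
  # mean distance from each point to each cluster
  M <- sapply(seq_len(k), function(c)
    rowSums(D[, labels == c, drop = FALSE]) / sizes[c])
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- labels[i]
    a <- if (sizes[ci] > 1) M[i, ci] * sizes[ci] / (sizes[ci] - 1) else 0
    b <- min(M[i, -ci])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' d-prime cluster separability
#'
#' \deqn{d' = |x_1 - x_2| / \sqrt{0.5 (\sigma_1^2 + \sigma_2^2)}}
#' A d-prime of 1 indicates cluster means separated by at least one (pooled)
#' standard deviation. Symmetric and translation-invariant.
#'
#' @param m1,m2 cluster means.
#' @param s1,s2 cluster standard deviations (>= 0, not both 0 unless the
#'   means differ, in which case Inf is returned).
#' @return the separability index.
#' @export
dPrime <- function(m1, s1, m2, s2) {
  stopifnot(s1 >= 0, s2 >= 0)
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2) stop("d-prime undefined: zero variance and equal means")
    return(Inf)
  }
  abs(m1 - m2) / sqrt(0.5 * (s1^2 + s2^2))
}

#' Select the number of clusters by silhouette and d-prime gates
#'
#' Tests k = 2..kMax and returns the solution at the largest k whose mean
#' silhouette is at least \code{minSilhouette} (0.5) and whose cluster-pair
#' d-prime separability is at least \code{minDPrime} (1). By default the
#' d-prime gate is applied to adjacent pairs after thickness-ordering (with
#' nine ordered concentric clusters, all-pairs separability between the
#' extremes is automatic when adjacent pairs separate; \code{pairs = "all"}
#' applies the stricter rule). If no k passes, a k = 1 sentinel is returned.
#' The per-k diagnostics are attached to the returned solution.
#'
#' @param stack an \linkS4class{AgeBracketStack}.
#' @param kMax largest k to test (default 12).
#' @param algorithm "hierarchical" or "twostep".
#' @param minSilhouette,minDPrime the gate thresholds.
#' @param pairs "adjacent" or "all" cluster pairs for the d-prime gate.
#' @param seed seed for the two-step stage 1.
#' @param nSub two-step stage-1 granularity.
#' @return the selected \linkS4class{ClusterSolution} with a
#'   \code{diagnostics} data.frame (k, meanSilhouette, minDPrime, pass).
#' @export
selectK <- function(stack, kMax = 12L,
                    algorithm = c("hierarchical", "twostep"),
                    minSilhouette = 0.5, minDPrime = 1,
                    pairs = c("adjacent", "all"), seed = 1L, nSub = 64L) {
  algorithm <- match.arg(algorithm)
  pairs <- match.arg(pairs)
  prof <- stack@profile
  kMax <- min(kMax, nrow(unique(prof)))
  h <- if (algorithm == "hierarchical") wgHclust(prof) else NULL
  sols <- vector("list", kMax)
  diag <- data.frame(k = 2:kMax, meanSilhouette = NA_real_,
                     minDPrime = NA_real_, pass = FALSE)
  for (k in 2:kMax) {
    sol <- if (algorithm == "hierarchical")
      makeClusterSolution(stack, cutWg(h, k), algorithm)
    else twostepCluster(stack, k, nSub = nSub, seed = seed)
    sols[[k]] <- sol
    dp <- sol@pairwiseDPrime
    gate <- if (pairs == "adjacent")
      dp[cbind(1:(k - 1), 2:k)] else dp[upper.tri(dp)]
    i <- k - 1L
    diag$meanSilhouette[i] <- sol@meanSilhouette
    diag$minDPrime[i] <- min(gate)
    diag$pass[i] <- sol@meanSilhouette >= minSilhouette &&
      min(gate) >= minDPrime
  }
  if (any(diag$pass)) {
    kSel <- max(diag$k[diag$pass])
    sol <- sols[[kSel]]
  } else {
    sol <- makeClusterSolution(stack, rep(1L, nrow(prof)), algorithm)
  }
  sol@diagnostics <- diag
  sol
}

# Exhaustive-search oracle: the partition of <= ~10 points into k non-empty
# blocks minimising the total mean within-cluster squared pairwise distance.
# Used only for testing the greedy within-groups agglomeration.
bestPartitionWG <- function(X, k) {
  n <- nrow(X)
  stopifnot(n <= 10)
  D2 <- as.matrix(stats::dist(X))^2
  best <- list(obj = Inf, labels = NULL)
  assign <- integer(n)
  recurse <- function(i, used) {
    if (i > n) {
      if (used != k) return()
      obj <- 0
      for (c in seq_len(k)) {
        m <- which(assign == c)
        if (length(m) > 1)
          obj <- obj + sum(D2[m, m]) / 2 / choose(length(m), 2)
      }
      if (obj < best$obj) best <<- list(obj = obj, labels = assign)
      return()
    }
    for (c in seq_len(min(used + 1L, k))) {
      assign[i] <<- c
      recurse(i + 1L, max(used, c))
    }
  }
  recurse(1L, 0L)
  best
}

# Per-cluster centroid profiles of a solution.
clusterCentroids <- function(stack, solution) {
  rowsum(stack@profile, solution@labels) /
    as.vector(table(solution@labels))
}

# Broadcast a (possibly stride-decimated) cluster solution to another stack
# by nearest-centroid assignment of every complete profile square.
assignToClusters <- function(profile, centroids) {
  d <- sapply(seq_len(nrow(centroids)), function(c)
    rowSums((profile - matrix(centroids[c, ], nrow(profile), ncol(profile),
                              byrow = TRUE))^2))
  max.col(-d, ties.method = "first")
}
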