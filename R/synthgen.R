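#' Nine-cluster concentric model of GCIPL ageing
#'
#' The spatial ageing model: nine concentric, nasally displaced clusters of
#' grid squares, each with a linear decline of mean thickness with age.
#' Default coefficients are the study estimates (absolute scale, um):
#' slopes -0.04 (clusters 1-2), -0.12 (3-4), -0.19 (5-9) with intercepts
#' rising monotonically from 32.89 to 106.6 um toward the fovea, residual SD
#' about 5.5 um; a log10 companion model carries slopes -0.0005 (1-2) and
#' -0.0010 (3-9).
#'
#' @param nGrid template side length (default 160).
#' @param squareUm grid square edge (um).
#' @param stride template decimation factor: the template labels every
#'   \code{stride}-th square (stride 4 gives a 40 x 40 working grid).
#' @return a list of class \code{clusterModel}: \code{nClusters},
#'   \code{slope}, \code{intercept}, \code{residualSd}, \code{logSlope},
#'   \code{logIntercept}, \code{logResidualSd}, \code{template} (integer
#'   matrix of labels), \code{nGrid}, \code{squareUm}, \code{stride}.
#' @export
defaultClusterModel <- function(nGrid = 160L, squareUm = 100, stride = 1L) {
  model <- list(
    nClusters = 9L,
    slope = c(-0.04, -0.04, -0.12, -0.12, -0.19, -0.19, -0.19, -0.19, -0.19),
    intercept = c(32.89, 38.53, 52.06, 62.57, 75.23, 83.76, 91.97, 99.68,
                  106.6),
    residualSd = c(5.46, 5.46, 5.47, 5.48, 5.50, 5.49, 5.50, 5.48, 5.48),
    logSlope = c(-5e-04, -5e-04, -0.001, -0.001, -0.001, -0.001, -0.001,
                 -0.001, -0.001),
    logIntercept = c(1.51, 1.59, 1.71, 1.80, 1.87, 1.92, 1.97, 2.00, 2.04),
    logResidualSd = 0.036,
    template = clusterTemplate(nGrid = nGrid, squareUm = squareUm,
                               stride = stride),
    nGrid = as.integer(nGrid), squareUm = squareUm, stride = as.integer(stride))
  stopifnot(all(diff(model$intercept) > 0), all(model$residualSd > 0))
  class(model) <- "clusterModel"
  model
}

#' Concentric cluster template
#'
#' Maps grid squares to cluster labels 1..9: nested ellipses centred on the
#' fovea, vertically compressed (ratio 0.8), displaced nasally outside the
#' central retina so the pattern forms the characteristic nasally-shifted
#' horseshoe; cluster index increases toward the fovea (thicker tissue).
#' Ring semi-axes are free parameters chosen so cluster areas grow with
#' eccentricity.
#'
#' @param nGrid,squareUm grid geometry.
#' @param radiiMm outer semi-major axes (mm) of the boundaries enclosing
#'   clusters 2..9, in decreasing order.
#' @param vertRatio vertical-to-horizontal semi-axis ratio.
#' @param nasalShiftPerMm nasal centre displacement (mm per mm of radius
#'   beyond 3.6 mm).
#' @param stride decimate to every stride-th square.
#' @return integer matrix of labels (1..9).
#' @export
clusterTemplate <- function(nGrid = 160L, squareUm = 100,
                            radiiMm = c(7.3, 5.9, 4.7, 3.7, 2.9, 2.2, 1.6, 1.0),
                            vertRatio = 0.8, nasalShiftPerMm = 0.15,
                            stride = 1L) {
  ctr <- gridCellCenters(nGrid = nGrid, squareUm = squareUm)
  keep <- seq(1L, nGrid, by = stride)
  x <- ctr$x[keep] / 1000  # mm
  y <- ctr$y[keep] / 1000
  n <- length(keep)
  lab <- matrix(1L, n, n)
  for (r in radiiMm) {
    x0 <- if (r > 3.6) nasalShiftPerMm * (r - 3.6) else 0
    inside <- outer(y^2 / (vertRatio * r)^2, rep(1, n)) +
      outer(rep(1, n), (x - x0)^2) / r^2 <= 1
    lab[inside] <- lab[inside] + 1L
  }
  lab
}

#' Generator configuration
#'
#' Defines the synthetic study conditions: cohort size and per-decade bracket
#' counts, demographic effect sizes, noise levels, scan geometry and the five
#' acquisition-distortion toggles. Defaults reproduce the study cohort
#' structure (470 eyes, brackets 70/73/70/80/102/75; axial length
#' 23.97 +/- 1.12 mm; fovea-disc tilt 7.14 +/- 3.87 degrees) and the
#' full-model demographic effects (-0.436 um/mm axial length, -0.646 um for
#' female sex).
#'
#' @param nEyes cohort size.
#' @param bracketCounts eyes per decade bracket (20-<30 ... 70+); must sum to
#'   \code{nEyes}.
#' @param seed RNG seed.
#' @param betaAL,betaSex demographic effects (um per mm, um per unit sex).
#' @param eyeNoiseSd between-eye thickness SD (um, shared across squares).
#' @param squareNoiseSd independent per-square noise SD (um).
#' @param missingAlFraction fraction of eyes whose measured axial length is
#'   withheld (exercising the refraction fallback).
#' @param distortions named logical list: \code{warpage}, \code{tilt},
#'   \code{magnification}, \code{rotation}, \code{vesselMask}.
#' @param nAscan,nBscan,lateralResMm,bscanSpacingMm,axialScaleUmPerPx scan
#'   geometry (defaults: 512 A-scans at ~0.031 mm/px over 55 degrees, 109
#'   B-scans 120 um apart, 3.87 um/px axial).
#' @param vesselRate expected vessel-shadow crossings per B-scan.
#' @return a validated list of class \code{generatorConfig}.
#' @export
generatorConfig <- function(nEyes = 470L,
                            bracketCounts = c(70L, 73L, 70L, 80L, 102L, 75L),
                            seed = 1L,
                            betaAL = -0.436, betaSex = -0.646,
                            eyeNoiseSd = 5, squareNoiseSd = 3,
                            missingAlFraction = 0.3,
                            distortions = list(warpage = TRUE, tilt = TRUE,
                                               magnification = TRUE,
                                               rotation = TRUE,
                                               vesselMask = TRUE),
                            nAscan = 512L, nBscan = 109L,
                            lateralResMm = 0.0309, bscanSpacingMm = 0.120,
                            axialScaleUmPerPx = 3.87,
                            vesselRate = 4) {
  cfg <- as.list(environment())
  if (any(bracketCounts < 0) || sum(bracketCounts) == 0)
    stop("configuration error: bracket counts must be non-negative and sum > 0")
  if (sum(bracketCounts) != nEyes)
    stop("configuration error: bracket counts sum to ", sum(bracketCounts),
         ", not nEyes = ", nEyes)
  if (eyeNoiseSd < 0 || squareNoiseSd < 0) stop("noise SDs must be >= 0")
  cfg$distortions <- mergeOptions(
    list(warpage = TRUE, tilt = TRUE, magnification = TRUE, rotation = TRUE,
         vesselMask = TRUE), distortions, "distortion")
  class(cfg) <- "generatorConfig"
  cfg
}

BRACKET_EDGES <- c(20, 30, 40, 50, 60, 70, Inf)
BRACKET_MEAN_AGES <- c(24.93, 35.07, 45.32, 55.34, 65.05, 74.21)

bracketOf <- function(age) findInterval(age, BRACKET_EDGES[-7])

#' Generate a synthetic cohort of eye records
#'
#' Samples demographics with the study cohort's structure: ages uniform
#' within each decade bracket at the configured per-bracket counts, axial
#' length Normal(23.97, 1.12) mm truncated to [20, 28], refraction coupled to
#' axial length by inverting the biometry regression
#' (rx = (23.757 - AL)/0.412) plus Normal(0, 1) D scatter (clipped to the
#' +/- 6 D inclusion range), sex Bernoulli(262/470 female), laterality
#' Bernoulli(247/470 right), fovea-disc tilt Normal(7.14, 3.87) degrees and
#' IOP Normal(14.64, 3.00) mmHg (carried, unused). A configured fraction of
#' eyes has the measured axial length withheld.
#'
#' @param config a \code{\link{generatorConfig}}.
#' @return data.frame with one row per eye: \code{eye_id}, \code{age},
#'   \code{sex} (0 male / 1 female), \code{refraction},
#'   \code{axial_length} (true), \code{axial_length_observed} (NA when
#'   withheld), \code{laterality}, \code{fovea_disc_tilt}, \code{iop},
#'   \code{bracket}.
#' @export
generateCohort <- function(config = generatorConfig()) {
  stopifnot(inherits(config, "generatorConfig"))
  set.seed(config$seed)
  counts <- config$bracketCounts
  n <- sum(counts)
  lower <- BRACKET_EDGES[-7]
  upper <- pmin(BRACKET_EDGES[-1], 80)
  age <- unlist(lapply(seq_along(counts), function(b)
    stats::runif(counts[b], lower[b], upper[b])))
  al <- stats::rnorm(n, 23.97, 1.12)
  while (any(bad <- al < 20 | al > 28))
    al[bad] <- stats::rnorm(sum(bad), 23.97, 1.12)
  rx <- (23.757 - al) / 0.412 + stats::rnorm(n, 0, 1)
  rx <- pmin(6, pmax(-6, rx))
  sex <- stats::rbinom(n, 1, 262 / 470)
  lat <- ifelse(stats::runif(n) < 247 / 470, "OD", "OS")
  tilt <- stats::rnorm(n, 7.14, 3.87)
  iop <- stats::rnorm(n, 14.64, 3.00)
  withheld <- stats::runif(n) < config$missingAlFraction
  data.frame(
    eye_id = sprintf("eye%04d", seq_len(n)),
    age = age, sex = sex, refraction = rx,
    axial_length = al,
    axial_length_observed = ifelse(withheld, NA_real_, al),
    laterality = lat, fovea_disc_tilt = tilt, iop = iop,
    bracket = bracketOf(age),
    stringsAsFactors = FALSE)
}

#' Ground-truth GCIPL grid for one synthetic eye
#'
#' Each grid square's expected value is
#' cluster intercept + cluster slope x age + betaAL x (AL - 23.97) +
#' betaSex x (sex - 0.5), plus an eye-level Normal(0, eyeNoiseSd) offset
#' shared across squares and independent Normal(0, squareNoiseSd) per-square
#' noise; values are floored at \code{floorUm} (1 um) to keep deep-peripheral
#' squares physical.
#'
#' @param eye one row of a \code{\link{generateCohort}} data.frame (or any
#'   list with \code{age}, \code{axial_length}, \code{sex}, \code{eye_id}).
#' @param model a \code{\link{defaultClusterModel}}.
#' @param betaAL,betaSex demographic effects.
#' @param eyeNoiseSd,squareNoiseSd noise SDs (um); set both to 0 for the
#'   deterministic expectation.
#' @param seed RNG seed for this eye's noise.
#' @param floorUm clip floor (um).
#' @return a \linkS4class{ThicknessGrid} at the model's template resolution.
#' @export
truthMap <- function(eye, model = defaultClusterModel(),
                     betaAL = -0.436, betaSex = -0.646,
                     eyeNoiseSd = 5, squareNoiseSd = 3, seed = 1L,
                     floorUm = 1) {
  tpl <- model$template
  vals <- model$intercept[tpl] + model$slope[tpl] * eye$age +
    betaAL * (eye$axial_length - 23.97) + betaSex * (eye$sex - 0.5)
  if (eyeNoiseSd > 0 || squareNoiseSd > 0) {
    set.seed(seed)
    vals <- vals + stats::rnorm(1, 0, eyeNoiseSd) +
      stats::rnorm(length(vals), 0, squareNoiseSd)
  }
  vals <- pmax(matrix(vals, nrow(tpl), ncol(tpl)), floorUm)
  new("ThicknessGrid", values = vals,
      squareUm = model$squareUm * model$stride, alignmentTilt = 0,
      eyeId = as.character(eye$eye_id %||% "truth"),
      origin = gridOriginString())
}

FOVEA_DISC_DISTANCE_UM <- 4500

#' Distort a truth grid into a raw boundary volume
#'
#' Emits the B-scan boundary volume an instrument would record for the given
#' truth grid, applying (per toggle) the inverse of every correction the
#' geometry cascade performs: posterior-globe curvature giving an
#' eccentricity-dependent tilt field with axial thickness inflation (inverse
#' of the tilt-perpendicular correction), nodal-point warpage plus removal of
#' vertical curvature (flattened export; the flattening offsets are computed
#' with the same ellipse-fit code the cascade uses, so reconstruction is the
#' exact inverse), axial-length lateral scaling, rotation by the eye's
#' fovea-disc tilt (left eyes mirrored), and vessel-shadow exclusion runs.
#'
#' @param truth a \linkS4class{ThicknessGrid} from \code{\link{truthMap}}
#'   (template stride 1).
#' @param eye the matching cohort row.
#' @param config a \code{\link{generatorConfig}} (scan geometry + toggles).
#' @param seed RNG seed for the vessel mask.
#' @return a \linkS4class{BoundaryVolume} whose metadata records the observed
#'   (possibly withheld) axial length and the applied distortions.
#' @export
distortToRaw <- function(truth, eye, config = generatorConfig(), seed = 1L) {
  tg <- config$distortions
  al <- eye$axial_length
  rx <- eye$refraction
  mag <- if (tg$magnification) al / REFERENCE_AXIAL_LENGTH_MM else 1
  dX <- config$lateralResMm * 1000 * mag
  dY <- config$bscanSpacingMm * 1000 * mag
  nA <- config$nAscan; nB <- config$nBscan
  fovRow <- (nB + 1) / 2; fovCol <- floor(nA / 2)
  xUm <- (seq_len(nA) - fovCol) * dX
  yUm <- (fovRow - seq_len(nB)) * dY
  theta <- if (tg$rotation) eye$fovea_disc_tilt else 0
  isOS <- identical(eye$laterality, "OS")

  # disc placed on the nasal side of the aligned frame, elevation theta
  dAligned <- rotateXY(FOVEA_DISC_DISTANCE_UM, 0, theta)
  dxScan <- if (isOS) -dAligned$x else dAligned$x
  discPx <- list(row = fovRow - dAligned$y / dY, col = fovCol + dxScan / dX)

  # truth lookup: scan coords -> aligned frame -> containing square
  xs <- rep(xUm, each = nB)
  ys <- rep(yUm, times = nA)
  xm <- if (isOS) -xs else xs
  rot <- rotateXY(xm, ys, -theta)
  nGrid <- nrow(truth@values)
  cell <- gridCell(rot$x, rot$y, nGrid = nGrid, squareUm = truth@squareUm)
  tcor <- rep(NA_real_, nB * nA)
  ok <- cell$ok
  tcor[ok] <- truth@values[cbind(cell$row[ok], cell$col[ok])]
  outside <- !is.finite(tcor)
  tcor[outside] <- 70  # placeholder under excluded positions
  tcor <- matrix(tcor, nB, nA)
  outside <- matrix(outside, nB, nA)
  badRow <- rowMeans(outside) > 0.5
  if (any(badRow))
    stop("generation error: >50% of B-scan(s) ",
         paste(which(badRow), collapse = ", "), " undefined after resampling")

  # posterior-globe surface (um depth, apex at the fovea)
  if (tg$tilt) {
    rH <- al / 2 * 1000
    rV <- verticalAxis(rH, rx)
    zIpl <- outer(rV - sqrt(rV^2 - yUm^2), rep(1, nA)) +
      outer(rep(1, nB), rH - sqrt(rH^2 - xUm^2))
  } else {
    zIpl <- matrix(0, nB, nA)
  }
  tiltRad <- tiltField(zIpl, xUm, yUm)
  # inverse of the tilt-perpendicular correction: inflate axial thickness
  rawAx <- tcor + 14.03 * tiltRad^2 - 1.611 * tiltRad + 0.07437
  zRnfl <- zIpl - rawAx

  if (tg$warpage) {
    rho0 <- nodalDistanceUm(al)
    zIpl <- warpFromNodalPoint(zIpl, xUm, yUm, rho0)
    zRnfl <- warpFromNodalPoint(zRnfl, xUm, yUm, rho0)
    # flattened export: subtract the vertical-curvature translation the
    # cascade will re-impose, derived from the emitted foveal B-scan itself
    fit <- fitFovealEllipse(xUm, zIpl[round(fovRow), ])
    if (!fit$ok)
      stop("generation error: foveal profile not elliptical (", fit$reason, ")")
    g <- curvatureTranslationUm(verticalAxis(fit$axisHoriz, rx), yUm)
    zIpl <- zIpl - g
    zRnfl <- zRnfl - g
  }

  scale <- config$axialScaleUmPerPx
  zOffsetPx <- 150
  mask <- outside
  # optic disc region carries no GCIPL
  ddx <- (seq_len(nA) - discPx$col) * dX
  ddy <- (discPx$row - seq_len(nB)) * dY
  d2 <- outer(ddy^2, rep(1, nA)) + outer(rep(1, nB), ddx^2)
  mask[d2 <= 900^2] <- TRUE
  if (tg$vesselMask) {
    set.seed(seed)
    for (i in seq_len(nB)) {
      nv <- stats::rpois(1, config$vesselRate)
      if (nv == 0) next
      ctrs <- sample.int(nA, nv)
      for (c0 in ctrs) {
        w <- sample(2:6, 1)
        mask[i, max(1, c0 - w):min(nA, c0 + w)] <- TRUE
      }
    }
  }

  meta <- list(
    lateralResolutionMmPerPx = config$lateralResMm,
    bscanSpacingMm = config$bscanSpacingMm,
    axialScaleUmPerPx = scale,
    refraction = rx,
    axialLengthMm = eye$axial_length_observed %||% al,
    foveaPx = list(row = fovRow, col = fovCol),
    discPx = discPx,
    laterality = eye$laterality,
    eyeId = as.character(eye$eye_id %||% "eye"),
    seed = seed,
    distortions = tg)
  new("BoundaryVolume",
      rnflGclZ = zRnfl / scale + zOffsetPx,
      iplInlZ = zIpl / scale + zOffsetPx,
      exclusionMask = mask, meta = meta)
}

#' Processing options matching a generator configuration
#'
#' The correction cascade should invert exactly the distortions a synthetic
#' volume carries; this helper maps the generator's toggles to
#' \code{\link{processingOptions}} (warpage -> curvature reconstruction and
#' de-warping, magnification -> lateral-resolution correction, rotation ->
#' fovea-disc alignment).
#'
#' @param config a \code{\link{generatorConfig}}.
#' @param ... further arguments passed to \code{\link{processingOptions}}.
#' @return a \code{\link{processingOptions}} list.
#' @export
matchingOptions <- function(config, ...) {
  tg <- config$distortions
  processingOptions(correctCurvature = tg$warpage, dewarp = tg$warpage,
                    correctMagnification = tg$magnification,
                    rotateToAxis = TRUE, ...)
}

#' Per-eye, per-cluster mean thickness table
#'
#' Shortcut generator feeding the regression stage without the geometry
#' stack: one row per eye per cluster, value = cluster line at the eye's age
#' plus Normal(0, residualSd) noise (on the absolute or log10 scale).
#'
#' @param model a \code{\link{defaultClusterModel}}.
#' @param nPerBracket eyes per decade bracket (scalar or length 6).
#' @param residualSd residual SD; scalar or per cluster. Defaults to the
#'   model's per-cluster values (absolute) or its log residual SD (log10).
#' @param eyeSd SD of an additional eye-level offset shared across an eye's
#'   clusters (default 0: purely independent noise). Use it to emulate the
#'   within-eye correlation the mixed-effects analysis accounts for.
#' @param seed RNG seed.
#' @param scale "absolute" (um) or "log10" (value generated on the log10
#'   scale and back-transformed; column \code{log10_value} also returned).
#' @return data.frame: \code{eye_id}, \code{age}, \code{bracket},
#'   \code{cluster}, \code{value} (and \code{log10_value} for log10 scale).
#' @export
clusterTable <- function(model = defaultClusterModel(),
                         nPerBracket = c(70L, 73L, 70L, 80L, 102L, 75L),
                         residualSd = NULL, eyeSd = 0, seed = 1L,
                         scale = c("absolute", "log10")) {
  scale <- match.arg(scale)
  if (length(nPerBracket) == 1L) nPerBracket <- rep(nPerBracket, 6L)
  stopifnot(length(nPerBracket) == 6L, all(nPerBracket > 0), eyeSd >= 0)
  k <- model$nClusters
  if (is.null(residualSd))
    residualSd <- if (scale == "absolute") model$residualSd else
      rep(model$logResidualSd, k)
  if (length(residualSd) == 1L) residualSd <- rep(residualSd, k)
  set.seed(seed)
  lower <- BRACKET_EDGES[-7]; upper <- pmin(BRACKET_EDGES[-1], 80)
  age <- unlist(lapply(1:6, function(b)
    stats::runif(nPerBracket[b], lower[b], upper[b])))
  n <- length(age)
  eyeEff <- stats::rnorm(n, 0, eyeSd)
  d <- data.frame(
    eye_id = rep(sprintf("eye%04d", seq_len(n)), times = k),
    age = rep(age, times = k),
    bracket = rep(bracketOf(age), times = k),
    cluster = rep(seq_len(k), each = n))
  eps <- stats::rnorm(nrow(d), 0, residualSd[d$cluster]) +
    rep(eyeEff, times = k)
  if (scale == "absolute") {
    d$value <- model$intercept[d$cluster] + model$slope[d$cluster] * d$age + eps
  } else {
    d$log10_value <- model$logIntercept[d$cluster] +
      model$logSlope[d$cluster] * d$age + eps
    d$value <- 10^d$log10_value
  }
  d
}

#' Synthetic age-bracket stack from the cluster model
#'
#' Builds the clustering feature space directly at study scale: for every
#' template square the per-bracket mean adjusted thickness, i.e. the cluster
#' line evaluated at the bracket mean age plus the sampling noise of a
#' bracket mean (Normal with SD residualSd / sqrt(n_bracket)).
#'
#' @param model a \code{\link{defaultClusterModel}} (use \code{stride} > 1
#'   for a tractable working grid).
#' @param counts eyes per bracket.
#' @param residualSd per-eye residual SD (um), scalar.
#' @param seed RNG seed.
#' @return an \linkS4class{AgeBracketStack}.
#' @export
syntheticBracketStack <- function(model = defaultClusterModel(stride = 4L),
                                  counts = c(70L, 73L, 70L, 80L, 102L, 75L),
                                  residualSd = 5.5, seed = 1L) {
  tpl <- model$template
  idx <- which(!is.na(tpl), arr.ind = TRUE)
  lab <- tpl[idx]
  set.seed(seed)
  prof <- sapply(1:6, function(b)
    model$intercept[lab] + model$slope[lab] * BRACKET_MEAN_AGES[b] +
      stats::rnorm(length(lab), 0, residualSd / sqrt(counts[b])))
  new("AgeBracketStack", profile = prof, counts = as.integer(counts),
      bracketAges = BRACKET_MEAN_AGES,
      brackets = rbind(BRACKET_EDGES[-7], BRACKET_EDGES[-1]),
      squareIndex = data.frame(row = idx[, 1], col = idx[, 2]),
      gridDim = nrow(tpl))
}

#' Synthetic cohort with global mean thickness from the demographic model
#'
#' For demographic-regression recovery studies: global (grid-mean) GCIPL
#' thickness generated from the full-model linear predictor
#' intercept + betaAge x age + betaAL x AL + betaSex x sex plus Normal(0,
#' noiseSd) residuals, with age uniform over [20, 80], axial length
#' Normal(23.97, 1.12) and sex Bernoulli(0.56).
#'
#' @param n cohort size.
#' @param beta named vector: \code{intercept}, \code{age}, \code{al},
#'   \code{sex}. The default age/AL/sex effects are the study's full-model
#'   estimates; the intercept (88 um) only locates the mean near the observed
#'   global thickness.
#' @param noiseSd residual SD (um).
#' @param seed RNG seed.
#' @return data.frame: \code{age}, \code{axial_length}, \code{sex},
#'   \code{thickness}.
#' @export
simulateGlobalCohort <- function(n = 470L,
                                 beta = c(intercept = 88, age = -0.053,
                                          al = -0.436, sex = -0.646),
                                 noiseSd = 2, seed = 1L) {
  set.seed(seed)
  age <- stats::runif(n, 20, 80)
  al <- stats::rnorm(n, 23.97, 1.12)
  sex <- stats::rbinom(n, 1, 0.56)
  mu <- beta["intercept"] + beta["age"] * age + beta["al"] * al +
    beta["sex"] * sex
  data.frame(age = age, axial_length = al, sex = sex,
             thickness = mu + stats::rnorm(n, 0, noiseSd))
}
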