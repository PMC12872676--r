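# Shared fixtures, built in code and memoised across test files.

fixtureCache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = fixtureCache)) assign(name, expr, fixtureCache)
  get(name, envir = fixtureCache)
}

# Minimal flat boundary volume for unit-level geometry checks.
makeFlatVolume <- function(nB = 9L, nA = 15L, sep = 18, zIpl = 120,
                           scale = 3.87, latRes = 0.5, spacing = 0.5) {
  new("BoundaryVolume",
      rnflGclZ = matrix(zIpl - sep, nB, nA),
      iplInlZ = matrix(zIpl, nB, nA),
      exclusionMask = matrix(FALSE, nB, nA),
      meta = list(lateralResolutionMmPerPx = latRes, bscanSpacingMm = spacing,
                  axialScaleUmPerPx = scale, refraction = 0,
                  axialLengthMm = 24, keratometryMm = 7.7,
                  foveaPx = list(row = (nB + 1) / 2, col = (nA + 1) / 2),
                  discPx = NULL, laterality = "OD", eyeId = "flat"))
}

# One noiseless eye pushed through distortToRaw and the full cascade.
oneEyeRoundTrip <- function() cached("rt1", {
  cfg <- generatorConfig(nEyes = 1L, bracketCounts = c(0L, 0L, 1L, 0L, 0L, 0L),
                         seed = 3L, missingAlFraction = 0)
  eye <- generateCohort(cfg)[1, ]
  truth <- truthMap(eye, eyeNoiseSd = 0, squareNoiseSd = 0)
  vol <- distortToRaw(truth, eye, cfg, seed = 9L)
  res <- processVolume(vol, matchingOptions(cfg))
  list(cfg = cfg, eye = eye, truth = truth, vol = vol, res = res)
})

# Study-scale nine-cluster bracket stack on a 20 x 20 working grid.
smallStack <- function(residualSd = 5.5, seed = 5L) {
  syntheticBracketStack(defaultClusterModel(stride = 8L),
                        residualSd = residualSd, seed = seed)
}

smallTemplate <- function() defaultClusterModel(stride = 8L)$template

# Canonical form of a partition: labels by order of first appearance.
canonicalPartition <- function(labels) match(labels, unique(labels))

expect_same_partition <- function(a, b) {
  expect_identical(canonicalPartition(a), canonicalPartition(b))
}
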