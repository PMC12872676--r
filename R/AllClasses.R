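#' @import methods
NULL

#' Paired layer-boundary surfaces from one widefield OCT volume
#'
#' Holds the two segmented boundary surfaces delimiting the ganglion
#' cell-inner plexiform layer (GCIPL): the RNFL-GCL boundary above and the
#' IPL-INL boundary below, as axial (z) pixel positions per A-scan (column)
#' per B-scan (row), together with an exclusion mask (vessel shadows, disc,
#' uncorrectable segmentation) and scan metadata.
#'
#' Metadata fields used by the processing cascade:
#' \code{lateralResolutionMmPerPx}, \code{bscanSpacingMm},
#' \code{axialScaleUmPerPx} (default 3.87), \code{refraction} (spherical
#' equivalent, D), \code{axialLengthMm} (NA when not measured),
#' \code{foveaPx}/\code{discPx} (lists with \code{row}, \code{col}),
#' \code{laterality} ("OD"/"OS") and \code{eyeId}.
#'
#' @slot rnflGclZ numeric matrix, z position (pixels) of the RNFL-GCL boundary.
#' @slot iplInlZ numeric matrix, z position (pixels) of the IPL-INL boundary.
#' @slot exclusionMask logical matrix, TRUE where segmentation is unusable.
#' @slot meta list of scan metadata (see Details).
#' @export
setClass("BoundaryVolume",
  representation(rnflGclZ = "matrix", iplInlZ = "matrix",
                 exclusionMask = "matrix", meta = "list"))

setValidity("BoundaryVolume", function(object) {
  msg <- NULL
  if (!identical(dim(object@rnflGclZ), dim(object@iplInlZ)))
    msg <- c(msg, "boundary surfaces must share dimensions")
  if (!identical(dim(object@rnflGclZ), dim(object@exclusionMask)))
    msg <- c(msg, "exclusion mask must share the boundary dimensions")
  ok <- !object@exclusionMask & is.finite(object@iplInlZ) &
    is.finite(object@rnflGclZ)
  if (any(ok) && any(object@iplInlZ[ok] < object@rnflGclZ[ok] - 1e-6))
    msg <- c(msg, "IPL-INL boundary must lie at or below RNFL-GCL where usable")
  need <- c("lateralResolutionMmPerPx", "bscanSpacingMm", "axialScaleUmPerPx",
            "refraction", "foveaPx", "laterality")
  miss <- setdiff(need, names(object@meta))
  if (length(miss))
    msg <- c(msg, paste("missing meta field(s):", paste(miss, collapse = ", ")))
  if (is.null(msg)) TRUE else msg
})

#' Per-position GCIPL thickness across a widefield scan
#'
#' Intermediate product of the correction cascade: axial (uncorrected) and
#' tilt-perpendicular (corrected) GCIPL thickness in microns per A-scan per
#' B-scan, the retinal tilt field (radians, magnitude relative to the
#' instrument horizontal through the foveal centre) and physical sample
#' coordinates.
#'
#' @slot uncorrected numeric matrix, axial thickness (um); NA where excluded.
#' @slot corrected numeric matrix, tilt-corrected thickness (um).
#' @slot tilt numeric matrix, retinal tilt (radians, >= 0).
#' @slot xUm,yUm numeric, physical coordinate (um, fovea-centred) per
#'   column / per row; x positive nasal (pre-mirroring), y positive superior.
#' @slot meta list carried over from the source volume.
#' @export
setClass("ThicknessMap",
  representation(uncorrected = "matrix", corrected = "matrix",
                 tilt = "matrix", xUm = "numeric", yUm = "numeric",
                 meta = "list"))

setValidity("ThicknessMap", function(object) {
  d <- dim(object@uncorrected)
  if (!identical(d, dim(object@corrected)) || !identical(d, dim(object@tilt)))
    return("thickness and tilt matrices must share dimensions")
  if (length(object@xUm) != d[2] || length(object@yUm) != d[1])
    return("coordinate vectors must match matrix dimensions")
  TRUE
})

#' Fovea-centred GCIPL thickness grid
#'
#' The comparable end product: mean GCIPL thickness (um) over 100 x 100 um
#' squares on a 160 x 160 fovea-centred lattice whose axes were aligned to the
#' individual fovea-disc axis and rotated to zero tilt; left eyes are mirrored
#' to right-eye orientation first. NA marks squares with insufficient coverage.
#'
#' @slot values numeric matrix (nGrid x nGrid) of thickness (um), NA = missing.
#' @slot squareUm numeric, square edge length in um (100).
#' @slot alignmentTilt numeric, fovea-disc tilt (degrees) removed at gridding.
#' @slot eyeId character identifier.
#' @slot origin character, orientation/origin convention descriptor.
#' @export
setClass("ThicknessGrid",
  representation(values = "matrix", squareUm = "numeric",
                 alignmentTilt = "numeric", eyeId = "character",
                 origin = "character"))

gridOriginString <- function() {
  paste("fovea at shared corner of the four central squares;",
        "rows superior->inferior, cols temporal->nasal, right-eye orientation")
}

setValidity("ThicknessGrid", function(object) {
  msg <- NULL
  v <- object@values
  if (nrow(v) != ncol(v)) msg <- c(msg, "grid must be square")
  if (any(is.finite(v) & v < 0)) msg <- c(msg, "defined values must be >= 0")
  if (length(object@squareUm) != 1 || object@squareUm <= 0)
    msg <- c(msg, "squareUm must be a positive scalar")
  if (is.null(msg)) TRUE else msg
})

#' Age-bracket mean-thickness profiles per grid square
#'
#' Clustering feature space: for every retained grid square, the mean
#' covariate-adjusted GCIPL thickness per decade age bracket (20-<30 up to
#' 70+). Squares missing in any bracket are dropped.
#'
#' @slot profile numeric matrix, squares x brackets (um).
#' @slot counts integer, contributing eyes per bracket.
#' @slot bracketAges numeric, mean (or midpoint) age per bracket used as the
#'   bracket's age value.
#' @slot brackets numeric matrix, 2 x nBracket lower/upper edges (upper Inf).
#' @slot squareIndex data.frame with grid \code{row}, \code{col} per profile row.
#' @slot gridDim integer, the side length of the source grid.
#' @export
setClass("AgeBracketStack",
  representation(profile = "matrix", counts = "integer",
                 bracketAges = "numeric", brackets = "matrix",
                 squareIndex = "data.frame", gridDim = "integer"))

setValidity("AgeBracketStack", function(object) {
  msg <- NULL
  if (ncol(object@profile) != length(object@bracketAges))
    msg <- c(msg, "profile columns must match bracket count")
  if (nrow(object@profile) != nrow(object@squareIndex))
    msg <- c(msg, "squareIndex must have one row per profile row")
  if (any(!is.finite(object@profile)))
    msg <- c(msg, "profiles must be fully defined (drop incomplete squares)")
  if (is.null(msg)) TRUE else msg
})

#' Spatial cluster solution over grid squares
#'
#' Cluster labels per retained grid square plus the separability diagnostics
#' used for model selection: per-cluster mean and SD over all member-square
#' bracket values, mean silhouette coefficient and the pairwise d-prime
#' matrix. Clusters are relabelled in ascending mean thickness, so label k
#' (the largest) is the thickest, most central cluster.
#'
#' @slot labels integer, cluster id (1..k) per stack square.
#' @slot k integer, number of clusters (1 = sentinel: no separable solution).
#' @slot clusterMeans,clusterSds numeric per cluster (um).
#' @slot meanSilhouette numeric in [-1, 1] (NA for k = 1).
#' @slot pairwiseDPrime numeric k x k matrix of d-prime separability.
#' @slot squareIndex data.frame grid row/col per label.
#' @slot gridDim integer side length of the source grid.
#' @slot algorithm character, "hierarchical" or "twostep".
#' @slot diagnostics data.frame of per-k gating diagnostics (may be empty).
#' @export
setClass("ClusterSolution",
  representation(labels = "integer", k = "integer",
                 clusterMeans = "numeric", clusterSds = "numeric",
                 meanSilhouette = "numeric", pairwiseDPrime = "matrix",
                 squareIndex = "data.frame", gridDim = "integer",
                 algorithm = "character", diagnostics = "data.frame"))

setValidity("ClusterSolution", function(object) {
  msg <- NULL
  k <- object@k
  if (length(object@labels) && (min(object@labels) < 1 || max(object@labels) > k))
    msg <- c(msg, "labels must lie in 1..k")
  if (k > 1 && any(diff(object@clusterMeans) <= 0))
    msg <- c(msg, "cluster means must be strictly increasing after ordering")
  if (is.finite(object@meanSilhouette) &&
      (object@meanSilhouette < -1 || object@meanSilhouette > 1))
    msg <- c(msg, "mean silhouette must lie in [-1, 1]")
  if (is.null(msg)) TRUE else msg
})
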