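#' Accessors for the widefieldGCIPL containers
#'
#' Slot access for user code goes through these accessors.
#'
#' @param object a package container object.
#' @return \code{gridValues}: the numeric value matrix. \code{missingMask}:
#'   logical matrix, TRUE where the grid square is undefined.
#'   \code{clusterLabels}: integer labels per stack square.
#'   \code{clusterMap}: integer matrix at grid resolution, 0 = unclustered.
#'   \code{stackProfile}: squares x brackets feature matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("gridValues", function(object) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setMethod("gridValues", "ThicknessGrid", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("missingMask", function(object) standardGeneric("missingMask"))
#' @rdname accessors
#' @export
setMethod("missingMask", "ThicknessGrid", function(object) is.na(object@values))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setMethod("clusterLabels", "ClusterSolution", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("clusterMap", function(object) standardGeneric("clusterMap"))
#' @rdname accessors
#' @export
setMethod("clusterMap", "ClusterSolution", function(object) {
  n <- object@gridDim
  m <- matrix(0L, n, n)
  idx <- cbind(object@squareIndex$row, object@squareIndex$col)
  m[idx] <- object@labels
  m
})

#' @rdname accessors
#' @export
setGeneric("stackProfile", function(object) standardGeneric("stackProfile"))
#' @rdname accessors
#' @export
setMethod("stackProfile", "AgeBracketStack", function(object) object@profile)

setMethod("show", "BoundaryVolume", function(object) {
  d <- dim(object@iplInlZ)
  cat("BoundaryVolume:", d[1], "B-scans x", d[2], "A-scans\n")
  cat("  eye:", object@meta$eyeId %||% "<unnamed>",
      " laterality:", object@meta$laterality, "\n")
  cat(sprintf("  excluded positions: %.1f%%\n",
              100 * mean(object@exclusionMask)))
})

setMethod("show", "ThicknessMap", function(object) {
  d <- dim(object@corrected)
  cat("ThicknessMap:", d[1], "x", d[2], "positions;",
      sprintf("%.1f%% defined\n", 100 * mean(is.finite(object@corrected))))
})

setMethod("show", "ThicknessGrid", function(object) {
  v <- object@values
  cat("ThicknessGrid:", nrow(v), "x", ncol(v), "squares of",
      object@squareUm, "um\n")
  cat(sprintf("  defined: %d (%.1f%%), mean %.1f um\n",
              sum(is.finite(v)), 100 * mean(is.finite(v)),
              mean(v, na.rm = TRUE)))
  cat(sprintf("  alignment tilt removed: %.2f deg; eye: %s\n",
              object@alignmentTilt, object@eyeId))
})

setMethod("show", "AgeBracketStack", function(object) {
  cat("AgeBracketStack:", nrow(object@profile), "grid squares x",
      ncol(object@profile), "age brackets\n")
  cat("  eyes per bracket:", paste(object@counts, collapse = ", "), "\n")
})

setMethod("show", "ClusterSolution", function(object) {
  cat("ClusterSolution (", object@algorithm, "): k = ", object@k, "\n", sep = "")
  if (object@k > 1) {
    cat(sprintf("  mean silhouette: %.3f\n", object@meanSilhouette))
    cat("  cluster means (um):",
        paste(sprintf("%.1f", object@clusterMeans), collapse = ", "), "\n")
    adj <- object@pairwiseDPrime[cbind(1:(object@k - 1), 2:object@k)]
    cat("  adjacent d':",
        paste(sprintf("%.2f", adj), collapse = ", "), "\n")
  } else {
    cat("  sentinel: no clustering satisfied the separability gates\n")
  }
})
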