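#' Axial length predicted from spherical equivalent refraction
#'
#' Linear regression relating axial length (mm) to spherical equivalent
#' refraction (D), used when biometry was not acquired:
#' \deqn{AL = -0.412 \times rx + 23.757.}
#'
#' @param rx spherical equivalent refraction in dioptres.
#' @return axial length in mm.
#' @examples
#' axialLengthFromRx(0)    # 23.757
#' axialLengthFromRx(-6)   # 26.229
#' @export
axialLengthFromRx <- function(rx) {
  stopifnot(is.numeric(rx), all(is.finite(rx)))
  if (any(rx < -10 | rx > 10))
    warning("refraction outside [-10, +10] D: extrapolating beyond the ",
            "range the regression was derived over")
  -0.412 * rx + 23.757
}

#' Vertical ellipse long axis from the horizontal axis and refraction
#'
#' The vertical-meridian curvature of the posterior globe is reconstructed
#' from the foveal B-scan's fitted long-axis parameter:
#' \deqn{axis_{vert} = (-0.004072 \times rx + 0.9921) \times axis_{horiz}.}
#'
#' @param axisHoriz long-axis parameter of the ellipse fitted to the foveal
#'   B-scan (same length unit as the return value).
#' @param rx spherical equivalent refraction (D).
#' @return vertical long-axis parameter.
#' @export
verticalAxis <- function(axisHoriz, rx) {
  stopifnot(axisHoriz > 0)
  (-0.004072 * rx + 0.9921) * axisHoriz
}

#' Tilt-perpendicular GCIPL thickness correction
#'
#' Axial thickness overestimates true (boundary-perpendicular) thickness as
#' retinal tilt grows. The corrected thickness is
#' \deqn{GCIPL_{corr} = GCIPL_{uncorr} - 14.03\,tilt^2 + 1.611\,tilt - 0.07437}
#' with thickness in microns and tilt in radians. Tilt enters as a magnitude
#' (the quadratic's maximum, at tilt \eqn{\approx} 0.0574 rad, is -0.0281 um,
#' so the correction is negative for every real tilt).
#'
#' @param uncorrected axial GCIPL thickness (um); NA propagates.
#' @param tiltRad retinal tilt in radians; the absolute value is used.
#' @return corrected thickness (um).
#' @export
correctThickness <- function(uncorrected, tiltRad) {
  t <- abs(tiltRad)
  uncorrected - 14.03 * t^2 + 1.611 * t - 0.07437
}

#' Axial-length correction of lateral resolution
#'
#' Transverse magnification scales with axial length; lateral resolution is
#' rescaled to the 24.385 mm reference eye:
#' \deqn{res_{corr} = res \times AL / 24.385.}
#'
#' @param resolution original lateral resolution (mm/pixel), > 0.
#' @param axialLengthMm axial length in mm, > 0.
#' @return corrected lateral resolution (mm/pixel).
#' @export
correctLateralResolution <- function(resolution, axialLengthMm) {
  stopifnot(all(resolution > 0))
  if (any(!is.finite(axialLengthMm)) || any(axialLengthMm <= 0))
    stop("axial length must be positive and finite")
  resolution * axialLengthMm / 24.385
}

REFERENCE_AXIAL_LENGTH_MM <- 24.385

#' Fit an axis-aligned ellipse to a foveal B-scan boundary profile
#'
#' Algebraic least-squares fit of the conic
#' \eqn{x^2 + C z^2 + D x + E z + F = 0} (linear in C, D, E, F) to the
#' IPL-INL z profile of the manually selected foveal B-scan. The long-axis
#' parameter along x is \code{axisHoriz}. A degenerate or non-elliptical fit
#' (rank deficiency, C <= 0, imaginary axes or residual above
#' \code{maxRmsUm}) signals an atypical macular profile: \code{ok} is FALSE
#' and the eye should be excluded rather than silently defaulted.
#'
#' When the unconstrained conic is not an ellipse (raw exports are often
#' locally near-parabolic), a constrained fovea-centred ellipse arc
#' \eqn{z = c + b (1 - \sqrt{1 - (x/a)^2})} is fitted by Nelder-Mead least
#' squares instead, initialised from the profile's apex curvature.
#'
#' @param xUm lateral position (um) per A-scan, fovea-centred.
#' @param zUm boundary z position (um) per A-scan (any constant offset is
#'   absorbed by the fit).
#' @param maxRmsUm residual threshold (um) above which the profile is flagged
#'   atypical.
#' @return a list of class \code{ellipseFit}: \code{ok}, \code{axisHoriz},
#'   \code{axisZ}, \code{centerX}, \code{centerZ}, \code{rmsResidual},
#'   \code{reason} (when not ok).
#' @export
fitFovealEllipse <- function(xUm, zUm, maxRmsUm = 200) {
  keep <- is.finite(xUm) & is.finite(zUm)
  x <- xUm[keep]; z <- zUm[keep]
  fail <- function(reason) structure(
    list(ok = FALSE, reason = reason, axisHoriz = NA_real_, axisZ = NA_real_,
         centerX = NA_real_, centerZ = NA_real_, rmsResidual = NA_real_),
    class = "ellipseFit")
  if (length(x) < 5) return(fail("fewer than 5 defined points"))
  conic <- conicEllipseFit(x, z)
  fit <- if (!is.null(conic)) conic else arcEllipseFit(x, z)
  if (is.character(fit)) return(fail(fit))
  if (fit$rmsResidual > maxRmsUm)
    return(fail("atypical macular profile (poor ellipse fit)"))
  structure(c(fit, list(ok = TRUE, reason = NULL)), class = "ellipseFit")
}

# Algebraic axis-aligned conic fit x^2 + C z^2 + D x + E z + F = 0.
# Returns NULL when the best-fit conic is not a real ellipse.
conicEllipseFit <- function(x, z) {
  X <- cbind(z^2, x, z, 1)
  qrX <- qr(X)
  if (qrX$rank < 4) return(NULL)
  cf <- qr.coef(qrX, -x^2)
  C <- -cf[1]; D <- -cf[2]; E <- -cf[3]; Fc <- -cf[4]
  if (!is.finite(C) || C <= 1e-12) return(NULL)
  G <- D^2 / 4 + E^2 / (4 * C) - Fc
  if (!is.finite(G) || G <= 0) return(NULL)
  axisHoriz <- sqrt(G); axisZ <- sqrt(G / C)
  centerX <- -D / 2; centerZ <- -E / (2 * C)
  u <- 1 - ((x - centerX) / axisHoriz)^2
  u[u < 0] <- 0
  zArc <- axisZ * sqrt(u)
  res <- pmin(abs(z - (centerZ + zArc)), abs(z - (centerZ - zArc)))
  list(axisHoriz = unname(axisHoriz), axisZ = unname(axisZ),
       centerX = unname(centerX), centerZ = unname(centerZ),
       rmsResidual = unname(sqrt(mean(res^2))))
}

# Constrained fovea-centred ellipse arc z = c + b (1 - sqrt(1 - (x/a)^2)),
# a > max|x|; Nelder-Mead on (log(a/max|x| - 1), log b, c). Translation of z
# by a constant shifts only c, so the fitted axes are offset-invariant.
arcEllipseFit <- function(x, z) {
  xm <- max(abs(x))
  if (xm <= 0) return("degenerate profile (no lateral extent)")
  q <- stats::lm(z ~ I(x^2))
  qc <- unname(stats::coef(q)[2])
  if (!is.finite(qc) || qc <= 1e-12)
    return("degenerate profile (flat or inverted)")
  r0 <- 1 / (2 * qc)                  # apex radius of curvature
  a0 <- max(r0, 1.2 * xm)
  b0 <- 2 * qc * a0^2
  obj <- function(p) {
    a <- xm * (1 + exp(p[1])); b <- exp(p[2]); c <- p[3]
    zi <- c + b * (1 - sqrt(pmax(1 - (x / a)^2, 0)))
    sum((z - zi)^2)
  }
  p0 <- c(log(a0 / xm - 1), log(b0), unname(stats::coef(q)[1]))
  opt <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-14))
  a <- xm * (1 + exp(opt$par[1])); b <- exp(opt$par[2])
  list(axisHoriz = a, axisZ = b, centerX = 0,
       centerZ = opt$par[3] + b, rmsResidual = sqrt(opt$value / length(x)))
}

#' @export
print.ellipseFit <- function(x, ...) {
  if (!x$ok) cat("ellipseFit: FAILED (", x$reason, ")\n", sep = "")
  else cat(sprintf(
    "ellipseFit: axisHoriz %.0f um, axisZ %.0f um, rms %.2f um\n",
    x$axisHoriz, x$axisZ, x$rmsResidual))
  invisible(x)
}

# Per-B-scan z translation (um) imposing the reconstructed vertical
# curvature: a circular arc of radius axisVert through the foveal B-scan.
curvatureTranslationUm <- function(axisVertUm, yUm) {
  if (!is.finite(axisVertUm)) return(rep(0, length(yUm)))  # flat limit
  if (any(abs(yUm) >= axisVertUm))
    stop("vertical scan extent exceeds the reconstructed curvature radius")
  axisVertUm - sqrt(axisVertUm^2 - yUm^2)
}

#' Reconstruct vertical scan curvature
#'
#' B-scans are acquired individually along the horizontal meridian, so the
#' exported volume has lost curvature information along the vertical
#' meridian. Each B-scan is rigidly translated in z so that the foveal-column
#' profile across B-scans follows an arc with the vertical long axis derived
#' from the foveal ellipse fit and refraction (see \code{\link{verticalAxis}}).
#' The translation is zero at the foveal B-scan and even-symmetric about it.
#'
#' @param volume a \linkS4class{BoundaryVolume} (flattened export).
#' @param fit an \code{ellipseFit} from \code{\link{fitFovealEllipse}}.
#' @param rx spherical equivalent refraction (D).
#' @param yUm physical vertical coordinate (um) per B-scan, 0 at the foveal
#'   B-scan.
#' @param axisVertUm optional explicit vertical axis (um); \code{Inf} disables
#'   the translation (identity limit).
#' @return the translated \linkS4class{BoundaryVolume}; the applied
#'   translations (um) are stored in \code{meta$curvatureTranslationUm}.
#' @export
reconstructVerticalCurvature <- function(volume, fit, rx, yUm,
                                         axisVertUm = NULL) {
  if (is.null(axisVertUm)) {
    if (!isTRUE(fit$ok)) stop("cannot reconstruct curvature from a failed fit")
    axisVertUm <- verticalAxis(fit$axisHoriz, rx)
  }
  g <- curvatureTranslationUm(axisVertUm, yUm)
  scale <- volume@meta$axialScaleUmPerPx
  gPx <- g / scale
  volume@rnflGclZ <- volume@rnflGclZ + gPx
  volume@iplInlZ <- volume@iplInlZ + gPx
  volume@meta$curvatureTranslationUm <- g
  volume
}

nodalDistanceUm <- function(axialLengthMm, nodalBehindCorneaMm = 7.1) {
  # reduced schematic eye: nodal point nodalBehindCorneaMm behind the cornea
  # in the reference eye, scaled with axial length
  (axialLengthMm - nodalBehindCorneaMm * axialLengthMm /
     REFERENCE_AXIAL_LENGTH_MM) * 1000
}

#' De-warp boundaries to constant distance from the nodal point
#'
#' OCT acquisition records depth along beams that pivot about the nodal point
#' of the eye, flattening the posterior curvature in the displayed B-scan.
#' Boundary z positions are re-mapped so that each A-scan's boundary lies on
#' an arc of constant distance from the nodal point: with the nodal point a
#' distance \eqn{\rho_0} anterior to the foveal retina, a recorded depth
#' \eqn{z'} at lateral offset \eqn{(x, y)} maps to
#' \eqn{z = \sqrt{(z' + \rho_0)^2 - x^2 - y^2} - \rho_0}. Depths are measured
#' relative to the IPL-INL position at the foveal centre (the on-axis point is
#' fixed). \code{nodalDistMm = Inf} is the planar (flat-field) limit and
#' returns the input unchanged.
#'
#' @param volume a \linkS4class{BoundaryVolume}.
#' @param xUm,yUm physical sample coordinates (um), fovea-centred.
#' @param axialLengthMm axial length (mm), measured or from
#'   \code{\link{axialLengthFromRx}}.
#' @param nodalBehindCorneaMm schematic-eye nodal depth behind the cornea at
#'   the reference axial length (default 7.1 mm), scaled by AL/24.385.
#' @param nodalDistMm optional explicit nodal-point-to-retina distance (mm),
#'   overriding the schematic model.
#' @return the de-warped \linkS4class{BoundaryVolume}.
#' @export
dewarpToNodalPoint <- function(volume, xUm, yUm, axialLengthMm,
                               nodalBehindCorneaMm = 7.1,
                               nodalDistMm = NULL) {
  rho0 <- if (!is.null(nodalDistMm)) nodalDistMm * 1000 else
    nodalDistanceUm(axialLengthMm, nodalBehindCorneaMm)
  if (!is.finite(rho0)) return(volume)  # planar limit
  scale <- volume@meta$axialScaleUmPerPx
  fov <- volume@meta$foveaPx
  zRef <- volume@iplInlZ[round(fov$row), round(fov$col)] * scale
  nr <- nrow(volume@iplInlZ); nc <- ncol(volume@iplInlZ)
  r2 <- outer(yUm^2, rep(1, nc)) + outer(rep(1, nr), xUm^2)
  dewarp1 <- function(zPx) {
    zU <- zPx * scale - zRef
    if (any(zU >= rho0, na.rm = TRUE))
      stop("nodal point lies inside the imaged retina")
    arg <- (zU + rho0)^2 - r2
    if (any(arg <= 0, na.rm = TRUE))
      stop("de-warp is undefined: lateral offset exceeds the nodal arc")
    (sqrt(arg) - rho0 + zRef) / scale
  }
  volume@rnflGclZ <- dewarp1(volume@rnflGclZ)
  volume@iplInlZ <- dewarp1(volume@iplInlZ)
  volume@meta$nodalDistanceUm <- rho0
  volume
}

# forward warp used by the synthetic generator (exact inverse of the above)
warpFromNodalPoint <- function(zUm, xUm, yUm, rho0Um) {
  if (!is.finite(rho0Um)) return(zUm)
  nr <- nrow(zUm); nc <- ncol(zUm)
  r2 <- outer(yUm^2, rep(1, nc)) + outer(rep(1, nr), xUm^2)
  sqrt(r2 + (zUm + rho0Um)^2) - rho0Um
}

#' Axial GCIPL thickness from the boundary pair
#'
#' Thickness is the axial distance between the RNFL-GCL and IPL-INL
#' boundaries times the axial scale; excluded positions are NA.
#'
#' @param volume a \linkS4class{BoundaryVolume} (aligned surfaces).
#' @return numeric matrix of axial thickness (um), NA where excluded.
#' @export
axialThickness <- function(volume) {
  scale <- volume@meta$axialScaleUmPerPx
  unc <- (volume@iplInlZ - volume@rnflGclZ) * scale
  unc[volume@exclusionMask] <- NA_real_
  if (any(unc < -1e-6, na.rm = TRUE))
    stop("negative axial thickness at a defined position: boundary order is ",
         "inconsistent")
  unc[unc < 0] <- 0
  unc
}

#' Retinal tilt field
#'
#' Local inclination of the IPL-INL surface relative to the tangent plane at
#' the foveal centre (the instrument horizontal), from finite-difference
#' surface gradients in physical units:
#' \eqn{tilt = \arctan |\nabla z|} (radians, >= 0).
#'
#' @param surfaceZUm IPL-INL surface as an nB x nA matrix of physical depth
#'   (um); any constant offset is irrelevant.
#' @param xUm,yUm physical coordinates (um) per column / per row.
#' @return matrix of tilt in radians.
#' @export
tiltField <- function(surfaceZUm, xUm, yUm) {
  g <- surfaceGradient(surfaceZUm, xUm, yUm)
  atan(sqrt(g$gx^2 + g$gy^2))
}

#' Interpolate excluded positions along the horizontal meridian
#'
#' Corrected thickness is linearly interpolated along each B-scan row across
#' excluded runs bounded by defined values. Runs touching the scan edges stay
#' undefined, rows that are excluded in whole are skipped, and positions
#' inside protected zones (adjacent to the optic disc, within the macular
#' region, at scan edges) are never filled.
#'
#' @param values numeric matrix with NA at excluded positions.
#' @param protected optional logical matrix: TRUE positions are never filled.
#' @return the matrix with interior runs filled.
#' @export
interpolateExclusions <- function(values, protected = NULL) {
  out <- values
  nc <- ncol(values)
  for (i in seq_len(nrow(values))) {
    v <- values[i, ]
    def <- which(is.finite(v))
    if (length(def) < 2) next
    hole <- which(is.na(v))
    hole <- hole[hole > def[1] & hole < def[length(def)]]
    if (!length(hole)) next
    out[i, hole] <- stats::approx(def, v[def], xout = hole)$y
  }
  if (!is.null(protected)) out[protected & is.na(values)] <- NA_real_
  out
}

#' Fovea-to-optic-disc tilt
#'
#' Angle (degrees) between the fovea-to-disc vector and the horizontal image
#' axis in physical units; a disc above the fovea horizontal gives a positive
#' angle. Left eyes are mirrored to right-eye orientation before the angle is
#' taken so the sign convention is laterality-independent.
#'
#' @param foveaPx,discPx lists with \code{row}, \code{col} image coordinates.
#' @param deltaXUm,deltaYUm physical size (um) of one A-scan step / one
#'   B-scan step (lateral-resolution corrected).
#' @param laterality "OD" or "OS".
#' @return tilt in degrees.
#' @export
foveaDiscTilt <- function(foveaPx, discPx, deltaXUm, deltaYUm,
                          laterality = "OD") {
  dx <- (discPx$col - foveaPx$col) * deltaXUm
  dy <- (foveaPx$row - discPx$row) * deltaYUm  # row grows inferior, y superior
  if (identical(laterality, "OS")) dx <- -dx
  if (abs(dx) < 1e-9 && abs(dy) < 1e-9)
    stop("fovea and disc centres coincide")
  atan2(dy, dx) * 180 / pi
}

#' Average a thickness map onto the fovea-centred grid
#'
#' Samples (including vertically upsampled intermediate rows between adjacent
#' B-scans, standing in for the bicubic resize to SLO dimensions) are mirrored
#' to right-eye orientation for left eyes, rotated so the fovea-disc axis is
#' horizontal (grid tilt 0), then averaged per 100 x 100 um square of a
#' fovea-centred \code{nGrid x nGrid} lattice. A square is missing when it
#' receives no samples or when fewer than \code{minFrac} of its samples are
#' defined. The grid area (16 x 16 mm by default) deliberately exceeds the
#' scan footprint, so edge squares are missing by construction. Defined
#' values are floored at 0 um.
#'
#' @param values corrected thickness matrix (um) with NA at missing positions.
#' @param xUm,yUm physical sample coordinates (um) per column / row.
#' @param tiltDeg fovea-disc tilt (degrees) to remove.
#' @param laterality "OD" or "OS" (OS is mirrored).
#' @param nGrid grid side length (default 160).
#' @param squareUm square edge (default 100 um).
#' @param minFrac minimum defined-sample fraction per square (default 0.5).
#' @param upsample vertical upsampling factor between B-scan rows (default 4).
#' @param eyeId identifier stored on the grid.
#' @return a \linkS4class{ThicknessGrid}.
#' @export
gridAverage <- function(values, xUm, yUm, tiltDeg = 0, laterality = "OD",
                        nGrid = 160L, squareUm = 100, minFrac = 0.5,
                        upsample = 4L, eyeId = "eye") {
  stopifnot(nrow(values) == length(yUm), ncol(values) == length(xUm))
  fovInside <- min(xUm) < 0 && max(xUm) > 0 && min(yUm) < 0 && max(yUm) > 0
  if (!fovInside) stop("fovea lies outside the scan area")
  vals <- list(values); ys <- list(yUm)
  if (upsample > 1L && nrow(values) > 1L) {
    nr <- nrow(values)
    for (f in seq_len(upsample - 1L)) {
      w <- f / upsample
      vals[[f + 1L]] <- (1 - w) * values[-nr, , drop = FALSE] +
        w * values[-1L, , drop = FALSE]
      ys[[f + 1L]] <- (1 - w) * yUm[-nr] + w * yUm[-1L]
    }
  }
  v <- do.call(rbind, vals)
  yAll <- unlist(ys)
  nr <- nrow(v); nc <- ncol(v)
  xs <- rep(xUm, each = nr)
  ysv <- rep(yAll, times = nc)
  if (identical(laterality, "OS")) xs <- -xs
  rot <- rotateXY(xs, ysv, -tiltDeg)
  cell <- gridCell(rot$x, rot$y, nGrid = nGrid, squareUm = squareUm)
  keep <- cell$ok
  lin <- (cell$col[keep] - 1L) * nGrid + cell$row[keep]
  vv <- as.vector(v)[keep]
  nTot <- tabulate(lin, nbins = nGrid * nGrid)
  def <- is.finite(vv)
  nDef <- tabulate(lin[def], nbins = nGrid * nGrid)
  sums <- numeric(nGrid * nGrid)
  if (any(def)) {
    rs <- rowsum(vv[def], group = lin[def])
    sums[as.integer(rownames(rs))] <- rs[, 1]
  }
  g <- sums / nDef
  g[nDef == 0 | nTot == 0 | nDef < minFrac * nTot] <- NA_real_
  g[is.finite(g) & g < 0] <- 0
  new("ThicknessGrid", values = matrix(g, nGrid, nGrid),
      squareUm = squareUm, alignmentTilt = tiltDeg,
      eyeId = as.character(eyeId), origin = gridOriginString())
}

#' Processing options for the geometry cascade
#'
#' @param correctCurvature reconstruct vertical curvature (default TRUE).
#' @param dewarp de-warp to the nodal point (default TRUE).
#' @param correctMagnification apply the axial-length lateral-resolution
#'   correction (default TRUE).
#' @param rotateToAxis align grids to the fovea-disc axis (default TRUE).
#' @param interpolate fill excluded runs along B-scans (default TRUE).
#' @param nodalBehindCorneaMm schematic nodal depth (mm) behind the cornea.
#' @param nodalDistMm explicit nodal distance override (mm) or NULL.
#' @param macularZoneUm protected macular radius about the fovea (um;
#'   default 2300, about 8 degrees).
#' @param discZoneFactor protected radius as a multiple of the disc radius.
#' @param discRadiusUm nominal disc radius (um).
#' @param edgePx protected margin at scan edges (pixels).
#' @param nGrid,squareUm,minFrac,upsample grid-averaging controls, see
#'   \code{\link{gridAverage}}.
#' @param maxRmsUm ellipse-fit residual threshold (um).
#' @return a named list of validated options.
#' @export
processingOptions <- function(correctCurvature = TRUE, dewarp = TRUE,
                              correctMagnification = TRUE,
                              rotateToAxis = TRUE, interpolate = TRUE,
                              nodalBehindCorneaMm = 7.1, nodalDistMm = NULL,
                              macularZoneUm = 2300, discZoneFactor = 1.5,
                              discRadiusUm = 900, edgePx = 2L,
                              nGrid = 160L, squareUm = 100, minFrac = 0.5,
                              upsample = 4L, maxRmsUm = 200) {
  as.list(environment())
}

buildProtectedMask <- function(dim, xUm, yUm, discPx, opts) {
  nr <- dim[1]; nc <- dim[2]
  prot <- matrix(FALSE, nr, nc)
  prot[, c(seq_len(opts$edgePx), nc - seq_len(opts$edgePx) + 1L)] <- TRUE
  prot[c(seq_len(opts$edgePx), nr - seq_len(opts$edgePx) + 1L), ] <- TRUE
  r2 <- outer(yUm^2, rep(1, nc)) + outer(rep(1, nr), xUm^2)
  prot[r2 <= opts$macularZoneUm^2] <- TRUE
  if (!is.null(discPx)) {
    dx <- (seq_len(nc) - discPx$col) * (xUm[2] - xUm[1])
    dy <- (seq_len(nr) - discPx$row) * (yUm[1] - yUm[2])
    d2 <- outer(dy^2, rep(1, nc)) + outer(rep(1, nr), dx^2)
    prot[d2 <= (opts$discZoneFactor * opts$discRadiusUm)^2] <- TRUE
  }
  prot
}

#' Run the full geometry correction cascade on one volume
#'
#' Applies, in order: foveal ellipse fit (eyes with an atypical macular
#' profile raise an error of class \code{atypicalMacularProfile}), vertical
#' curvature reconstruction, nodal-point de-warping, axial thickness,
#' tilt-field computation and tilt-perpendicular correction, exclusion
#' interpolation outside protected zones, and fovea-disc aligned grid
#' averaging with lateral-resolution correction.
#'
#' @param volume a \linkS4class{BoundaryVolume}.
#' @param opts options from \code{\link{processingOptions}}.
#' @return list with \code{grid} (\linkS4class{ThicknessGrid}), \code{map}
#'   (\linkS4class{ThicknessMap}), \code{ellipse} (the fit), and
#'   \code{tiltDeg} (alignment tilt removed).
#' @export
processVolume <- function(volume, opts = processingOptions()) {
  meta <- volume@meta
  rx <- meta$refraction
  al <- meta$axialLengthMm
  if (is.null(al) || !is.finite(al)) al <- axialLengthFromRx(rx)
  mag <- if (opts$correctMagnification) al / REFERENCE_AXIAL_LENGTH_MM else 1
  dX <- meta$lateralResolutionMmPerPx * 1000 * mag
  dY <- meta$bscanSpacingMm * 1000 * mag
  nr <- nrow(volume@iplInlZ); nc <- ncol(volume@iplInlZ)
  fov <- meta$foveaPx
  xUm <- (seq_len(nc) - fov$col) * dX
  yUm <- (fov$row - seq_len(nr)) * dY
  scale <- meta$axialScaleUmPerPx

  fit <- fitFovealEllipse(xUm, volume@iplInlZ[round(fov$row), ] * scale,
                          maxRmsUm = opts$maxRmsUm)
  if (!fit$ok && opts$correctCurvature) {
    cond <- structure(
      class = c("atypicalMacularProfile", "error", "condition"),
      list(message = paste0("eye excluded: ", fit$reason),
           call = sys.call()))
    stop(cond)
  }
  if (opts$correctCurvature)
    volume <- reconstructVerticalCurvature(volume, fit, rx, yUm)
  if (opts$dewarp)
    volume <- dewarpToNodalPoint(volume, xUm, yUm, al,
                                 nodalBehindCorneaMm = opts$nodalBehindCorneaMm,
                                 nodalDistMm = opts$nodalDistMm)
  unc <- axialThickness(volume)
  tilt <- tiltField(volume@iplInlZ * scale, xUm, yUm)
  corr <- correctThickness(unc, tilt)
  if (opts$interpolate) {
    prot <- buildProtectedMask(dim(corr), xUm, yUm, meta$discPx, opts)
    corr <- interpolateExclusions(corr, prot)
  }
  tiltDeg <- if (opts$rotateToAxis && !is.null(meta$discPx)) {
    foveaDiscTilt(fov, meta$discPx, dX, dY, meta$laterality)
  } else 0
  grid <- gridAverage(corr, xUm, yUm, tiltDeg = tiltDeg,
                      laterality = meta$laterality, nGrid = opts$nGrid,
                      squareUm = opts$squareUm, minFrac = opts$minFrac,
                      upsample = opts$upsample,
                      eyeId = meta$eyeId %||% "eye")
  map <- new("ThicknessMap", uncorrected = unc, corrected = corr,
             tilt = tilt, xUm = xUm, yUm = yUm, meta = meta)
  list(grid = grid, map = map, ellipse = fit, tiltDeg = tiltDeg)
}

#' Mirror a boundary volume and flip its laterality
#'
#' Utility for orientation-invariance checks: reverses the A-scan axis of all
#' surfaces and masks, mirrors the fovea/disc column coordinates and flips
#' the laterality flag. Processing a mirrored volume yields an identical
#' \linkS4class{ThicknessGrid}.
#'
#' @param volume a \linkS4class{BoundaryVolume}.
#' @return the mirrored volume.
#' @export
mirrorVolume <- function(volume) {
  nc <- ncol(volume@iplInlZ)
  flip <- function(m) m[, rev(seq_len(nc)), drop = FALSE]
  volume@rnflGclZ <- flip(volume@rnflGclZ)
  volume@iplInlZ <- flip(volume@iplInlZ)
  volume@exclusionMask <- flip(volume@exclusionMask)
  volume@meta$foveaPx$col <- nc + 1 - volume@meta$foveaPx$col
  if (!is.null(volume@meta$discPx))
    volume@meta$discPx$col <- nc + 1 - volume@meta$discPx$col
  volume@meta$laterality <- if (identical(volume@meta$laterality, "OD"))
    "OS" else "OD"
  volume
}
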