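# Plain-text interchange: delimited matrices with JSON sidecars.

writeMatrixTsv <- function(m, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(format(m, digits = 12, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

readMatrixTsv <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path)
  m <- tryCatch(
    as.matrix(utils::read.table(path, sep = "\t", comment.char = "#",
                                na.strings = "NA")),
    error = function(e) stop("corrupt matrix file: ", path, " (",
                             conditionMessage(e), ")", call. = FALSE))
  storage.mode(m) <- "double"
  unname(m)
}

#' Write / read a boundary volume
#'
#' One delimited matrix file per boundary plus the exclusion mask and a JSON
#' metadata sidecar (lateral resolution, refraction, axial length or null,
#' fovea/disc coordinates, laterality, seed, applied distortions).
#'
#' @param volume a \linkS4class{BoundaryVolume}.
#' @param dir output directory (created if needed).
#' @param eyeId file-name stem; defaults to the volume's id.
#' @return \code{writeBoundaryVolume}: the sidecar path, invisibly.
#'   \code{readBoundaryVolume}: the \linkS4class{BoundaryVolume}.
#' @export
writeBoundaryVolume <- function(volume, dir, eyeId = NULL) {
  eyeId <- eyeId %||% volume@meta$eyeId %||% "eye"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeMatrixTsv(volume@rnflGclZ, file.path(dir, paste0(eyeId, "_rnfl_gcl.tsv")))
  writeMatrixTsv(volume@iplInlZ, file.path(dir, paste0(eyeId, "_ipl_inl.tsv")))
  writeMatrixTsv(volume@exclusionMask + 0L,
                 file.path(dir, paste0(eyeId, "_mask.tsv")))
  sidecar <- file.path(dir, paste0(eyeId, "_meta.json"))
  meta <- volume@meta
  meta$axialLengthMm <- if (is.finite(meta$axialLengthMm %||% NA))
    meta$axialLengthMm else NULL
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(sidecar)
}

#' @rdname writeBoundaryVolume
#' @export
readBoundaryVolume <- function(dir, eyeId) {
  meta <- jsonlite::read_json(file.path(dir, paste0(eyeId, "_meta.json")),
                              simplifyVector = TRUE)
  meta$axialLengthMm <- meta$axialLengthMm %||% NA_real_
  meta$foveaPx <- as.list(meta$foveaPx)
  if (!is.null(meta$discPx)) meta$discPx <- as.list(meta$discPx)
  rn <- readMatrixTsv(file.path(dir, paste0(eyeId, "_rnfl_gcl.tsv")))
  ip <- readMatrixTsv(file.path(dir, paste0(eyeId, "_ipl_inl.tsv")))
  mk <- readMatrixTsv(file.path(dir, paste0(eyeId, "_mask.tsv"))) > 0
  if (!identical(dim(rn), dim(ip)) || !identical(dim(rn), dim(mk)))
    stop("corrupt boundary files for eye ", eyeId, ": dimensions disagree")
  new("BoundaryVolume", rnflGclZ = rn, iplInlZ = ip, exclusionMask = mk,
      meta = meta)
}

#' Write / read a thickness grid
#'
#' Delimited 160 x 160 matrix (NA sentinel for missing) with an explicit
#' orientation header line and a JSON provenance sidecar (eye id, alignment
#' tilt, square size, corrections applied).
#'
#' @param grid a \linkS4class{ThicknessGrid}.
#' @param path output path (\code{.tsv}; sidecar written alongside).
#' @param provenance optional named list merged into the sidecar.
#' @return \code{writeThicknessGrid}: \code{path}, invisibly.
#'   \code{readThicknessGrid}: the \linkS4class{ThicknessGrid}.
#' @export
writeThicknessGrid <- function(grid, path, provenance = list()) {
  writeMatrixTsv(gridValues(grid), path, header = grid@origin)
  side <- c(list(eyeId = grid@eyeId, squareUm = grid@squareUm,
                 alignmentTilt = grid@alignmentTilt, origin = grid@origin),
            provenance)
  jsonlite::write_json(side, sub("\\.tsv$", ".json", path),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeThicknessGrid
#' @export
readThicknessGrid <- function(path) {
  side <- jsonlite::read_json(sub("\\.tsv$", ".json", path),
                              simplifyVector = TRUE)
  new("ThicknessGrid", values = readMatrixTsv(path),
      squareUm = side$squareUm, alignmentTilt = side$alignmentTilt,
      eyeId = side$eyeId, origin = side$origin)
}

#' Write / read a cohort table
#'
#' CSV with header \code{eye_id,age,sex,refraction,axial_length,laterality,
#' tilt}; \code{axial_length} is the observed value (empty when withheld).
#' The full generator columns are preserved when present.
#'
#' @param cohort a \code{\link{generateCohort}} data.frame.
#' @param path CSV path.
#' @return \code{writeCohort}: \code{path}, invisibly; \code{readCohort}:
#'   the data.frame.
#' @export
writeCohort <- function(cohort, path) {
  out <- data.frame(eye_id = cohort$eye_id, age = cohort$age,
                    sex = cohort$sex, refraction = cohort$refraction,
                    axial_length = cohort$axial_length_observed %||%
                      cohort$axial_length,
                    laterality = cohort$laterality,
                    tilt = cohort$fovea_disc_tilt %||% cohort$tilt)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname writeCohort
#' @export
readCohort <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("eye_id", "age", "sex", "refraction", "axial_length",
            "laterality", "tilt")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("cohort file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  d$axial_length_observed <- d$axial_length
  d$fovea_disc_tilt <- d$tilt
  d
}
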