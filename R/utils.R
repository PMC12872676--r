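# Internal helpers shared by the geometry and simulation code.

# Counter-clockwise rotation of point coordinates by `deg` degrees.
rotateXY <- function(x, y, deg) {
  th <- deg * pi / 180
  list(x = x * cos(th) - y * sin(th),
       y = x * sin(th) + y * cos(th))
}

# Map fovea-centred physical coordinates (um) to grid row/col indices.
# Convention: the fovea sits at the shared corner of the four central squares;
# columns increase temporal -> nasal (+x), rows increase superior -> inferior
# (row 1 holds the most superior squares, y in [ (n/2-1)*s, n/2*s )).
gridCell <- function(xUm, yUm, nGrid = 160L, squareUm = 100) {
  col <- floor(xUm / squareUm) + nGrid / 2 + 1
  row <- nGrid / 2 - floor(yUm / squareUm)
  ok <- col >= 1 & col <= nGrid & row >= 1 & row <= nGrid &
    is.finite(col) & is.finite(row)
  list(row = as.integer(row), col = as.integer(col), ok = ok)
}

# Physical centres (um) of grid squares under the same convention.
gridCellCenters <- function(nGrid = 160L, squareUm = 100) {
  list(x = ((seq_len(nGrid)) - nGrid / 2 - 1) * squareUm + squareUm / 2,
       y = (nGrid / 2 - seq_len(nGrid)) * squareUm + squareUm / 2)
}

# Deterministic derived seeds, kept inside the 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1e6) * 1009 + 131 * k) %% 2147483647L + 1L
}

# Finite-difference surface gradient in physical units. `z` is nB x nA (um),
# `x` the per-column and `y` the per-row physical coordinate (um).
surfaceGradient <- function(z, x, y) {
  nr <- nrow(z); nc <- ncol(z)
  jm <- c(1L, seq_len(nc - 1L)); jp <- c(seq_len(nc - 1L) + 1L, nc)
  gx <- (z[, jp, drop = FALSE] - z[, jm, drop = FALSE]) /
    rep(x[jp] - x[jm], each = nr)
  im <- c(1L, seq_len(nr - 1L)); ip <- c(seq_len(nr - 1L) + 1L, nr)
  gy <- (z[ip, , drop = FALSE] - z[im, , drop = FALSE]) / (y[ip] - y[im])
  list(gx = gx, gy = gy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shallow-merge a user list over defaults, rejecting unknown keys.
mergeOptions <- function(defaults, user, where = "options") {
  if (is.null(user)) return(defaults)
  stopifnot(is.list(user))
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(user)] <- user
  defaults
}

# MD5 of an in-memory character scalar (via a temp file; no extra deps).
md5string <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(x, tf)
  unname(tools::md5sum(tf))
}
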