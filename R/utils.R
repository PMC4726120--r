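# Internal geometry and numeric helpers.

# Shoelace area of a polygon given vertex coordinates (closed implicitly).
polygonArea <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Solidity of a pixel set: pixel count divided by the area of the convex hull
# of the pixel squares (each pixel contributes its four corners, so a single
# pixel has hull area 1). Clamped to 1 against discretisation round-off.
maskSolidity <- function(pixels) {
  n <- nrow(pixels)
  if (n == 0L) return(NA_real_)
  if (n <= 2L) return(1)
  bd <- boundaryPixels(pixels)
  r <- c(bd[, 1L] - 0.5, bd[, 1L] - 0.5, bd[, 1L] + 0.5, bd[, 1L] + 0.5)
  c_ <- c(bd[, 2L] - 0.5, bd[, 2L] + 0.5, bd[, 2L] - 0.5, bd[, 2L] + 0.5)
  h <- grDevices::chull(c_, r)
  ha <- polygonArea(c_[h], r[h])
  if (ha <= 0) return(1)
  min(1, n / ha)
}

# Pixels of a mask whose 4-neighbourhood is not entirely inside the mask.
boundaryPixels <- function(pixels) {
  r0 <- min(pixels[, 1L]) - 1L
  c0 <- min(pixels[, 2L]) - 1L
  nr <- max(pixels[, 1L]) - r0 + 2L
  nc <- max(pixels[, 2L]) - c0 + 2L
  m <- matrix(FALSE, nr, nc)
  m[cbind(pixels[, 1L] - r0, pixels[, 2L] - c0)] <- TRUE
  core <- m[2:(nr - 1L), 2:(nc - 1L), drop = FALSE]
  interior <- core &
    m[1:(nr - 2L), 2:(nc - 1L), drop = FALSE] &
    m[3:nr,        2:(nc - 1L), drop = FALSE] &
    m[2:(nr - 1L), 1:(nc - 2L), drop = FALSE] &
    m[2:(nr - 1L), 3:nc,        drop = FALSE]
  idx <- which(core & !interior, arr.ind = TRUE)
  cbind(idx[, 1L] + r0, idx[, 2L] + c0)
}

# Logical mask matrix (cropped to bbox with given origin) from pixel coords.
pixelsToMatrix <- function(pixels, nrow, ncol, rowOffset = 0L, colOffset = 0L) {
  m <- matrix(FALSE, nrow, ncol)
  m[cbind(pixels[, 1L] - rowOffset, pixels[, 2L] - colOffset)] <- TRUE
  m
}

# Exact array rotations for multiples of 90 degrees (no interpolation).
# Convention: rotateExact(m, 90) maps a bright row r to a bright column r,
# i.e. horizontal stripes become vertical with preserved coordinates along
# the stripe-normal axis.
rotateExact <- function(m, angleDeg) {
  a <- angleDeg %% 360
  if (a == 0) return(m)
  if (a == 90) { t_ <- t(m); return(t_[, rev(seq_len(ncol(t_))), drop = FALSE]) }
  if (a == 180) return(m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE])
  if (a == 270) { t_ <- t(m); return(t_[rev(seq_len(nrow(t_))), , drop = FALSE]) }
  stop("rotateExact only handles multiples of 90 degrees")
}

# Ordinary-least-squares slope; NA when fewer than 2 points or degenerate x.
olsSlope <- function(t, y) {
  ok <- is.finite(t) & is.finite(y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 2L) return(NA_real_)
  dt <- t - mean(t)
  ss <- sum(dt^2)
  if (ss == 0) return(NA_real_)
  sum(dt * (y - mean(y))) / ss
}

# Evaluate an expression with a locally seeded RNG, restoring the caller's
# RNG state afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
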