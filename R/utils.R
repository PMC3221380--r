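## Geometry and interpolation helpers shared by the MPR and ray-cast paths.

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

#' Map voxel indices to patient-space millimetres
#'
#' @param volume an [ImageVolume-class].
#' @param ijk numeric matrix (n x 3) of 1-based (row, col, slice) indices;
#'   fractional indices are allowed.
#' @return n x 3 matrix of mm positions.
#' @export
voxelToPatient <- function(volume, ijk) {
  ijk <- rbind(ijk)
  R <- volume@orientation
  sp <- volume@spacing
  off <- sweep(ijk - 1, 2, sp, "*")
  sweep(off %*% t(R), 2, volume@origin, "+")
}

#' Map patient-space millimetres to continuous voxel indices
#'
#' @param volume an [ImageVolume-class].
#' @param pts numeric matrix (n x 3) of mm positions.
#' @return n x 3 matrix of continuous 1-based (row, col, slice) indices.
#' @export
patientToVoxel <- function(volume, pts) {
  pts <- rbind(pts)
  R <- volume@orientation
  sp <- volume@spacing
  rel <- sweep(pts, 2, volume@origin, "-") %*% R  # R orthonormal: inverse = t
  sweep(rel, 2, sp, "/") + 1
}

## Trilinear interpolation of the voxel grid at continuous 1-based indices.
## Points outside [1, dim] (beyond a tiny tolerance) return `background`.
.trilinear <- function(vox, idx, background = -1024) {
  d <- dim(vox)
  r <- idx[, 1]; cc <- idx[, 2]; s <- idx[, 3]
  eps <- 1e-7
  inside <- r >= 1 - eps & r <= d[1] + eps &
    cc >= 1 - eps & cc <= d[2] + eps &
    s >= 1 - eps & s <= d[3] + eps
  out <- rep(background, length(r))
  if (!any(inside)) return(out)
  r <- pmin(pmax(r[inside], 1), d[1])
  cc <- pmin(pmax(cc[inside], 1), d[2])
  s <- pmin(pmax(s[inside], 1), d[3])
  r0 <- if (d[1] > 1L) pmin(floor(r), d[1] - 1L) else rep(1, length(r))
  c0 <- if (d[2] > 1L) pmin(floor(cc), d[2] - 1L) else rep(1, length(cc))
  s0 <- if (d[3] > 1L) pmin(floor(s), d[3] - 1L) else rep(1, length(s))
  r1 <- pmin(r0 + 1, d[1]); c1 <- pmin(c0 + 1, d[2]); s1 <- pmin(s0 + 1, d[3])
  fr <- r - r0; fc <- cc - c0; fs <- s - s0
  at <- function(i, j, k) vox[cbind(i, j, k)]
  v000 <- at(r0, c0, s0); v100 <- at(r1, c0, s0)
  v010 <- at(r0, c1, s0); v110 <- at(r1, c1, s0)
  v001 <- at(r0, c0, s1); v101 <- at(r1, c0, s1)
  v011 <- at(r0, c1, s1); v111 <- at(r1, c1, s1)
  v00 <- v000 * (1 - fr) + v100 * fr
  v10 <- v010 * (1 - fr) + v110 * fr
  v01 <- v001 * (1 - fr) + v101 * fr
  v11 <- v011 * (1 - fr) + v111 * fr
  v0 <- v00 * (1 - fc) + v10 * fc
  v1 <- v01 * (1 - fc) + v11 * fc
  out[inside] <- v0 * (1 - fs) + v1 * fs
  out
}

.nearestNeighbour <- function(vox, idx, background = -1024) {
  d <- dim(vox)
  i <- round(idx)
  inside <- i[, 1] >= 1 & i[, 1] <= d[1] &
    i[, 2] >= 1 & i[, 2] <= d[2] &
    i[, 3] >= 1 & i[, 3] <= d[3]
  out <- rep(background, nrow(idx))
  if (any(inside)) out[inside] <- vox[i[inside, , drop = FALSE]]
  out
}

#' Sample a volume at arbitrary patient-space points
#'
#' Trilinear (default) or nearest-neighbour interpolation of the HU grid;
#' points outside the volume return the background HU (air, -1024, by
#' convention).
#'
#' @param volume an [ImageVolume-class].
#' @param pts n x 3 matrix of mm positions.
#' @param background HU value returned outside the grid.
#' @param method "trilinear" or "nearest".
#' @return numeric vector of HU samples.
#' @export
sampleVolume <- function(volume, pts, background = -1024,
                         method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  idx <- patientToVoxel(volume, pts)
  if (method == "trilinear") .trilinear(volume@voxels, idx, background)
  else .nearestNeighbour(volume@voxels, idx, background)
}

## Bilinear interpolation of a 2-D matrix at continuous 1-based (row, col).
.bilinear <- function(img, r, cc, background = 0) {
  d <- dim(img)
  eps <- 1e-7
  inside <- r >= 1 - eps & r <= d[1] + eps & cc >= 1 - eps & cc <= d[2] + eps
  out <- rep(background, length(r))
  if (!any(inside)) return(out)
  r <- pmin(pmax(r[inside], 1), d[1])
  cc <- pmin(pmax(cc[inside], 1), d[2])
  r0 <- if (d[1] > 1L) pmin(floor(r), d[1] - 1L) else rep(1, length(r))
  c0 <- if (d[2] > 1L) pmin(floor(cc), d[2] - 1L) else rep(1, length(cc))
  r1 <- pmin(r0 + 1, d[1]); c1 <- pmin(c0 + 1, d[2])
  fr <- r - r0; fc <- cc - c0
  v00 <- img[cbind(r0, c0)]; v10 <- img[cbind(r1, c0)]
  v01 <- img[cbind(r0, c1)]; v11 <- img[cbind(r1, c1)]
  out[inside] <- (v00 * (1 - fr) + v10 * fr) * (1 - fc) +
    (v01 * (1 - fr) + v11 * fr) * fc
  out
}

## Round half away from zero (display convention for 8-bit output).
.roundHalfUp <- function(x) floor(x + 0.5)

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
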