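## Ray-cast volume rendering: orthographic front-to-back alpha compositing
## with per-step opacity correction, plus a maximum-intensity mode.

#' Construct a transfer function
#'
#' @param hu control-point HU positions, strictly increasing.
#' @param opacity per-point opacity in [0,1].
#' @param gray per-point gray value in [0,1].
#' @param name preset id.
#' @param compositing "alpha" or "mip".
#' @return a [TransferFunction-class].
#' @export
transferFunction <- function(hu, opacity, gray, name = "custom",
                             compositing = "alpha") {
  new("TransferFunction", hu = as.numeric(hu), opacity = as.numeric(opacity),
      gray = as.numeric(gray), name = name, compositing = compositing)
}

## evaluate opacity and gray at arbitrary HU (linear between control points,
## clamped to the end values outside the range)
.tfEval <- function(tf, hu) {
  list(opacity = stats::approx(tf@hu, tf@opacity, hu, rule = 2)$y,
       gray = stats::approx(tf@hu, tf@gray, hu, rule = 2)$y)
}

#' Packaged tissue rendering presets
#'
#' Named opacity/gray presets for 3-D viewing of head CT. The HU anchors are
#' conventional CT values (bone ramp starting near 300 HU, contrast-filled
#' vessels a few hundred HU), packaged as configuration defaults.
#' \code{"mip"} switches compositing to maximum-intensity projection.
#'
#' @param name one of "bone", "soft_tissue", "vessel", "mip".
#' @return a [TransferFunction-class].
#' @export
renderingPreset <- function(name) {
  switch(name,
    bone = transferFunction(
      hu = c(-1024, 150, 300, 1000, 3000),
      opacity = c(0, 0, 0.8, 1, 1),
      gray = c(0, 0.1, 0.7, 1, 1), name = "bone"),
    soft_tissue = transferFunction(
      hu = c(-1024, -150, 0, 40, 90, 300, 3000),
      opacity = c(0, 0, 0.05, 0.45, 0.65, 0, 0),
      gray = c(0, 0.05, 0.3, 0.55, 0.8, 0.9, 1), name = "soft_tissue"),
    vessel = transferFunction(
      hu = c(-1024, 100, 200, 600, 3000),
      opacity = c(0, 0, 0.7, 1, 1),
      gray = c(0, 0.1, 0.8, 1, 1), name = "vessel"),
    mip = transferFunction(
      hu = c(-1024, 3071),
      opacity = c(0, 1),
      gray = c(0, 1), name = "mip", compositing = "mip"),
    stop("unknown preset: ", name))
}

#' Construct an orthographic camera
#'
#' @param eye,lookAt mm positions defining the view direction.
#' @param up up vector (not parallel to the view direction).
#' @param halfExtent orthographic half-extent in mm; length 1 (square) or 2
#'   (half-height, half-width).
#' @param outSize integer(2) output (rows, cols).
#' @return a [Camera-class].
#' @export
camera <- function(eye, lookAt, up = c(0, 0, 1), halfExtent, outSize) {
  if (length(halfExtent) == 1L) halfExtent <- rep(halfExtent, 2L)
  new("Camera", eye = as.numeric(eye), lookAt = as.numeric(lookAt),
      up = as.numeric(up), halfExtent = as.numeric(halfExtent),
      outSize = as.integer(outSize))
}

## A camera looking down the slice axis at the volume centre, framing the
## whole volume. Convenience for sessions and offline rendering.
#' @rdname renderRaycast
#' @param volume an [ImageVolume-class].
#' @param outSize integer(2) output (rows, cols).
#' @export
defaultCamera <- function(volume, outSize = c(256L, 256L)) {
  d <- dim(volume@voxels)
  ctr <- as.numeric(voxelToPatient(volume, (d + 1) / 2))
  n <- volume@orientation[, 3]
  extent <- (d - 1) * volume@spacing
  half <- max(extent[1], extent[2]) / 2 * 1.05
  diag3 <- sqrt(sum(extent^2))
  camera(eye = ctr - n * diag3, lookAt = ctr, up = -volume@orientation[, 1],
         halfExtent = half, outSize = outSize)
}

#' Ray-cast an orthographic 3-D rendering of a volume
#'
#' One ray per output pixel, sampled every \code{stepMm} millimetres by
#' trilinear interpolation. Alpha compositing is front-to-back with early
#' termination once accumulated opacity reaches 0.99; per-sample opacity is
#' corrected for step size as \code{1 - (1 - a)^(stepMm / referenceStepMm)}
#' so renders are comparable across step sizes. The background gray is
#' composited wherever opacity does not saturate. With a MIP transfer
#' function the brightest HU along each ray is mapped through the gray ramp.
#'
#' @param camera a [Camera-class].
#' @param tf a [TransferFunction-class].
#' @param stepMm ray sampling step in mm, > 0.
#' @param background background gray level 0..255.
#' @param referenceStepMm reference step for opacity correction (1 mm).
#' @return integer matrix (camera outSize) with values 0..255.
#' @export
renderRaycast <- function(volume, camera, tf, stepMm = 1, background = 0,
                          referenceStepMm = 1) {
  if (stepMm <= 0) stop("stepMm must be > 0")
  validObject(camera)
  dirv <- .unit(camera@lookAt - camera@eye)
  right <- .unit(.cross3(dirv, camera@up))
  upv <- .cross3(right, dirv)
  nr <- camera@outSize[1]; nc <- camera@outSize[2]
  hh <- camera@halfExtent[1]; hw <- camera@halfExtent[2]
  vOff <- ((rep(seq_len(nr), times = nc) - 0.5) / nr - 0.5) * 2 * hh
  uOff <- ((rep(seq_len(nc), each = nr) - 0.5) / nc - 0.5) * 2 * hw
  origins <- outer(uOff, right) - outer(vOff, upv)
  origins <- sweep(origins, 2, camera@eye, "+")
  ## ray parameter range from the volume's eight corners
  d <- dim(volume@voxels)
  corners <- as.matrix(expand.grid(c(1, d[1]), c(1, d[2]), c(1, d[3])))
  cornerMm <- voxelToPatient(volume, corners)
  tProj <- (cornerMm %*% dirv)
  oProj <- origins %*% dirv
  tMin <- min(tProj) - max(oProj) - stepMm
  tMax <- max(tProj) - min(oProj) + stepMm
  nPix <- nr * nc
  accA <- numeric(nPix)
  accC <- numeric(nPix)
  maxHu <- rep(-Inf, nPix)
  mip <- tf@compositing == "mip"
  active <- rep(TRUE, nPix)
  corr <- stepMm / referenceStepMm
  for (t in seq(tMin, tMax, by = stepMm)) {
    if (!any(active)) break
    idx <- which(active)
    pts <- origins[idx, , drop = FALSE] + matrix(dirv, length(idx), 3,
                                                 byrow = TRUE) * t
    hu <- sampleVolume(volume, pts, background = -1024)
    if (mip) {
      maxHu[idx] <- pmax(maxHu[idx], hu)
    } else {
      m <- .tfEval(tf, hu)
      a <- 1 - (1 - m$opacity)^corr
      w <- (1 - accA[idx]) * a
      accC[idx] <- accC[idx] + w * m$gray
      accA[idx] <- accA[idx] + w
      active[idx] <- accA[idx] < 0.99
    }
  }
  bg <- background / 255
  out <- if (mip) {
    maxHu[!is.finite(maxHu)] <- -1024
    .tfEval(tf, maxHu)$gray
  } else {
    accC + (1 - accA) * bg
  }
  img <- .roundHalfUp(pmin(pmax(out, 0), 1) * 255)
  storage.mode(img) <- "integer"
  matrix(img, nrow = nr, ncol = nc)
}
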