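## Multiplanar reformatting: arbitrary plane extraction with slab averaging,
## plus the in-plane pan/zoom/rotate view transform.

#' Construct a slice plane by hand
#'
#' @param origin mm position of output pixel (1,1).
#' @param rowDir,colDir orthogonal unit vectors spanning the plane.
#' @param pxSpacing numeric(2) mm per output pixel (row, col).
#' @param slabThickness slab thickness in mm (0 = single sample).
#' @param outSize integer(2) output (rows, cols).
#' @return a [SlicePlane-class].
#' @export
slicePlane <- function(origin, rowDir, colDir, pxSpacing,
                       slabThickness = 0, outSize) {
  new("SlicePlane", origin = as.numeric(origin), rowDir = .unit(rowDir),
      colDir = .unit(colDir), pxSpacing = as.numeric(pxSpacing),
      slabThickness = as.numeric(slabThickness),
      outSize = as.integer(outSize))
}

#' Axis-aligned reformation plane through a volume
#'
#' Builds the sampling plane for an axial, sagittal or coronal reformation at
#' a given millimetre offset along the corresponding patient axis (measured
#' from the volume origin). The default output grid covers the volume's
#' projected extent at native spacing, so an axial plane at the offset of a
#' stored slice samples exactly that slice's grid.
#'
#' @param volume an [ImageVolume-class].
#' @param axis "axial", "sagittal" or "coronal".
#' @param indexMm offset along the plane normal, in mm from the volume origin.
#' @param slabThickness slab thickness in mm.
#' @return a [SlicePlane-class].
#' @export
orthogonalPlane <- function(volume, axis = c("axial", "sagittal", "coronal"),
                            indexMm, slabThickness = 0) {
  axis <- match.arg(axis)
  d <- dim(volume@voxels)
  R <- volume@orientation
  sp <- volume@spacing
  extent <- (d - 1) * sp                  # (row, col, slice) extents in mm
  cfg <- switch(axis,
    axial    = list(n = R[, 3], rowDir = R[, 1], colDir = R[, 2],
                    ps = sp[c(1, 2)], size = d[c(1, 2)], ext = extent[3]),
    sagittal = list(n = R[, 2], rowDir = R[, 3], colDir = R[, 1],
                    ps = sp[c(3, 1)], size = d[c(3, 1)], ext = extent[2]),
    coronal  = list(n = R[, 1], rowDir = R[, 3], colDir = R[, 2],
                    ps = sp[c(3, 2)], size = d[c(3, 2)], ext = extent[1]))
  if (indexMm < -1e-6 || indexMm > cfg$ext + 1e-6)
    stop("plane outside volume: ", axis, " offset ", indexMm,
         " mm not in [0, ", round(cfg$ext, 3), "]")
  slicePlane(origin = volume@origin + indexMm * cfg$n,
             rowDir = cfg$rowDir, colDir = cfg$colDir,
             pxSpacing = cfg$ps, slabThickness = slabThickness,
             outSize = cfg$size)
}

#' Extract a reformatted 2-D HU slice
#'
#' Samples the volume by trilinear interpolation at every output pixel. With
#' a positive slab thickness, samples are taken at native slice-spacing steps
#' along the plane normal across the slab and combined by mean
#' (average-intensity) or maximum-intensity projection. Samples outside the
#' volume contribute the background HU.
#'
#' @param volume an [ImageVolume-class].
#' @param plane a [SlicePlane-class].
#' @param projection "mean" (average-intensity, default) or "max".
#' @param background HU outside the volume (default -1024, air).
#' @param interpolation "trilinear" or "nearest".
#' @return numeric matrix (plane outSize) of HU.
#' @examples
#' v <- imageVolume(array(rep(c(10, 20, 30), each = 16), c(4, 4, 3)),
#'                  spacing = c(1, 1, 1))
#' p <- orthogonalPlane(v, "axial", indexMm = 1, slabThickness = 3)
#' unique(as.vector(extractSlice(v, p)))  # slab mean of 10,20,30 -> 20
#' @export
extractSlice <- function(volume, plane, projection = c("mean", "max"),
                         background = -1024,
                         interpolation = c("trilinear", "nearest")) {
  projection <- match.arg(projection)
  interpolation <- match.arg(interpolation)
  nr <- plane@outSize[1]; nc <- plane@outSize[2]
  rIdx <- rep(seq_len(nr) - 1, times = nc)
  cIdx <- rep(seq_len(nc) - 1, each = nr)
  base <- outer(rIdx * plane@pxSpacing[1], plane@rowDir) +
    outer(cIdx * plane@pxSpacing[2], plane@colDir)
  base <- sweep(base, 2, plane@origin, "+")
  normal <- .cross3(plane@rowDir, plane@colDir)
  step <- volume@spacing[3]
  nSamp <- if (plane@slabThickness > 0) max(1L, round(plane@slabThickness / step))
           else 1L
  offsets <- (seq_len(nSamp) - (nSamp + 1) / 2) * step
  acc <- NULL
  for (off in offsets) {
    pts <- sweep(base, 2, off * normal, "+")
    smp <- sampleVolume(volume, pts, background = background,
                        method = if (interpolation == "trilinear") "trilinear"
                                 else "nearest")
    acc <- if (is.null(acc)) smp
           else if (projection == "mean") acc + smp
           else pmax(acc, smp)
  }
  if (projection == "mean") acc <- acc / nSamp
  matrix(acc, nrow = nr, ncol = nc)
}

#' Construct a view transform
#'
#' @param pan numeric(2) (dx, dy) in viewport pixels.
#' @param zoom scale factor > 0.
#' @param rotation in-plane rotation in degrees.
#' @return a [ViewTransform-class].
#' @export
viewTransform <- function(pan = c(0, 0), zoom = 1, rotation = 0) {
  if (zoom <= 0) stop("invalid zoom: must be > 0")
  new("ViewTransform", pan = as.numeric(pan), zoom = as.numeric(zoom),
      rotation = as.numeric(rotation))
}

#' Apply pan/zoom/rotation to a 2-D image for a viewport
#'
#' The source image is centred in the viewport, rotated about the viewport
#' centre, zoomed, then panned, in that fixed order; pixels are resampled
#' bilinearly and the output is exactly viewport-sized. Pixels with no source
#' coverage take the background value.
#'
#' @param image numeric matrix (source).
#' @param transform a [ViewTransform-class].
#' @param viewport integer(2) output (rows, cols).
#' @param background value for uncovered pixels (default 0).
#' @param interpolation "bilinear" or "nearest".
#' @return numeric matrix of size viewport.
#' @export
applyView <- function(image, transform, viewport, background = 0,
                      interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (any(viewport < 1)) stop("viewport must be positive")
  if (transform@zoom <= 0) stop("invalid zoom: must be > 0")
  vr <- viewport[1]; vc <- viewport[2]
  sr <- nrow(image); sc <- ncol(image)
  vCtr <- c((vr + 1) / 2, (vc + 1) / 2)
  sCtr <- c((sr + 1) / 2, (sc + 1) / 2)
  th <- transform@rotation * pi / 180
  ## forward: v = R(th) %*% x * zoom + pan  (x relative to source centre,
  ## v relative to viewport centre); invert for output-driven resampling
  outR <- rep(seq_len(vr), times = vc) - vCtr[1] - transform@pan[1]
  outC <- rep(seq_len(vc), each = vr) - vCtr[2] - transform@pan[2]
  outR <- outR / transform@zoom
  outC <- outC / transform@zoom
  srcR <- cos(th) * outR + sin(th) * outC + sCtr[1]
  srcC <- -sin(th) * outR + cos(th) * outC + sCtr[2]
  vals <- if (interpolation == "bilinear")
    .bilinear(image, srcR, srcC, background)
  else {
    d <- dim(image)
    i <- round(srcR); j <- round(srcC)
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2]
    v <- rep(background, length(i))
    v[ok] <- image[cbind(i[ok], j[ok])]
    v
  }
  matrix(vals, nrow = vr, ncol = vc)
}
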