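## Quantitative operations on calibrated volumes. Everything here works on
## raw HU; 8-bit output exists only at the display end of the pipeline.

#' @rdname accessors
#' @export
setMethod("voxelData", "ImageVolume", function(x, ...) x@voxels)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "ImageVolume", function(x, ...) x@spacing)

#' @rdname accessors
#' @export
setMethod("volumeOrigin", "ImageVolume", function(x, ...) x@origin)

#' @rdname accessors
#' @export
setMethod("volumeOrientation", "ImageVolume", function(x, ...) x@orientation)

#' @rdname accessors
#' @export
setMethod("modality", "ImageVolume", function(x, ...) x@modality)

#' @rdname accessors
#' @export
setMethod("volumeAttributes", "ImageVolume", function(x, ...) x@attributes)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageVolume (%s): %d x %d x %d voxels\n", object@modality,
              d[1], d[2], d[3]))
  cat(sprintf("  spacing (mm): %.4f x %.4f x %.4f\n", object@spacing[1],
              object@spacing[2], object@spacing[3]))
  cat(sprintf("  HU range: [%g, %g]\n", min(object@voxels), max(object@voxels)))
  if (length(object@attributes))
    cat("  attributes:", paste(names(object@attributes), collapse = ", "), "\n")
})

#' Construct an ImageVolume directly
#'
#' @param voxels 3-D HU array, indexed (row, col, slice).
#' @param spacing numeric(3) mm spacing (row, col, slice).
#' @param origin numeric(3) mm position of voxel (1,1,1).
#' @param orientation 3x3 orthonormal direction matrix (columns: row
#'   direction, column direction, slice normal).
#' @param modality "NCCT", "CTA" or "OTHER".
#' @param attributes named list of textual metadata.
#' @return an [ImageVolume-class].
#' @export
imageVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        orientation = diag(3), modality = "OTHER",
                        attributes = list()) {
  new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin), orientation = orientation,
      modality = modality, attributes = attributes)
}

#' Construct a display window
#'
#' @param center window center (level) in HU.
#' @param width window width in HU, >= 1.
#' @return a [WindowLevel-class].
#' @export
windowLevel <- function(center, width) {
  if (width < 1) stop("invalid window: width must be >= 1")
  new("WindowLevel", center = as.numeric(center), width = as.numeric(width))
}

#' Map an HU image to 8-bit grayscale through a window
#'
#' DICOM-convention linear VOI mapping:
#' \deqn{out = clamp(((v - (c - 0.5)) / (w - 1) + 0.5) \times 255, 0, 255)}
#' rounded half-up, so values at or below center - width/2 map to 0 and
#' values at or above center + width/2 map to 255, monotonically. A width of
#' 1 degenerates to binary thresholding at the center.
#'
#' @param image numeric matrix of HU values.
#' @param wl a [WindowLevel-class] (or list with center/width).
#' @return integer matrix of the same shape with values in 0..255.
#' @examples
#' m <- matrix(c(-10, 0, 40, 80, 120), 1)
#' applyWindow(m, windowLevel(40, 80))
#' @export
applyWindow <- function(image, wl) {
  if (!is(wl, "WindowLevel")) wl <- windowLevel(wl$center, wl$width)
  c0 <- wl@center; w <- wl@width
  if (w < 1) stop("invalid window: width must be >= 1")
  num <- image - (c0 - 0.5)
  tt <- if (w == 1) ifelse(num == 0, 0.5, ifelse(num > 0, Inf, -Inf))
        else num / (w - 1) + 0.5
  out <- .roundHalfUp(pmin(pmax(tt * 255, 0), 255))
  storage.mode(out) <- "integer"
  dim(out) <- dim(image)
  out
}

#' Probe Hounsfield units over a rectangle of a stored slice
#'
#' Statistics are computed on the original HU voxels, never on windowed 8-bit
#' display data — the quantitative check recommended for disambiguating a
#' suspected dense vessel from its contralateral counterpart.
#'
#' @param volume an [ImageVolume-class].
#' @param slice stored slice index (1-based).
#' @param rect numeric(4): (rowMin, rowMax, colMin, colMax) in voxel indices;
#'   clipped to the slice extent.
#' @return an [HUProbe-class] with mean, sd, min, max and voxel count.
#' @export
huProbe <- function(volume, slice, rect) {
  d <- dim(volume@voxels)
  if (slice < 1 || slice > d[3]) stop("empty probe region: slice outside volume")
  r0 <- max(1L, ceiling(rect[1])); r1 <- min(d[1], floor(rect[2]))
  c0 <- max(1L, ceiling(rect[3])); c1 <- min(d[2], floor(rect[4]))
  if (r0 > r1 || c0 > c1) stop("empty probe region")
  vals <- volume@voxels[r0:r1, c0:c1, slice]
  new("HUProbe", region = c(r0, r1, c0, c1), slice = slice,
      mean = mean(vals), sd = if (length(vals) > 1L) stats::sd(vals) else 0,
      min = min(vals), max = max(vals), count = length(vals))
}

setMethod("show", "HUProbe", function(object) {
  cat(sprintf(
    "HU probe, slice %d, rows %d-%d cols %d-%d (%d voxels)\n  mean %.1f HU (sd %.1f), range [%g, %g]\n",
    as.integer(object@slice), as.integer(object@region[1]),
    as.integer(object@region[2]), as.integer(object@region[3]),
    as.integer(object@region[4]), as.integer(object@count), object@mean,
    object@sd, object@min, object@max))
})
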