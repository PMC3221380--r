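## S4 classes for the rendering / streaming engine.

.checkUnit <- function(v, tol = 1e-6) abs(sqrt(sum(v^2)) - 1) <= tol

#' ImageVolume: a calibrated 3-D Hounsfield-unit grid
#'
#' The central data object: CT voxels in Hounsfield units (HU) together with
#' the geometry needed to place every voxel in patient space. Voxels are
#' stored as an R array indexed \code{[row, col, slice]} (1-based). The
#' patient-space position of voxel (i, j, k) is
#' \code{origin + (i-1)*sp[1]*R[,1] + (j-1)*sp[2]*R[,2] + (k-1)*sp[3]*R[,3]}
#' where \code{R} is the orientation matrix (columns: row direction, column
#' direction, slice normal; LPS convention) and \code{sp} the spacing in mm.
#'
#' @slot voxels 3-D numeric array of HU values.
#' @slot spacing numeric(3): (row, column, slice) spacing in mm, all > 0.
#' @slot origin numeric(3): patient-space mm position of voxel (1,1,1).
#' @slot orientation 3x3 matrix of orthonormal direction columns.
#' @slot modality one of "NCCT", "CTA", "OTHER".
#' @slot attributes named list of whitelisted textual metadata.
#'
#' @seealso [loadSeries()], [huProbe()], [extractSlice()]
#' @export
setClass("ImageVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric",
                 orientation = "matrix", modality = "character",
                 attributes = "list"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@voxels)) != 3L)
      msg <- c(msg, "voxels must be a 3-D array")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive values (mm)")
    if (length(object@origin) != 3L)
      msg <- c(msg, "origin must be length 3 (mm)")
    R <- object@orientation
    if (!all(dim(R) == c(3L, 3L))) {
      msg <- c(msg, "orientation must be 3x3")
    } else {
      ok <- all(vapply(1:3, function(i) .checkUnit(R[, i]), logical(1))) &&
        abs(sum(R[, 1] * R[, 2])) <= 1e-6 &&
        abs(sum(R[, 1] * R[, 3])) <= 1e-6 &&
        abs(sum(R[, 2] * R[, 3])) <= 1e-6
      if (!ok) msg <- c(msg, "orientation columns must be orthonormal (tol 1e-6)")
    }
    if (!object@modality %in% c("NCCT", "CTA", "OTHER"))
      msg <- c(msg, "modality must be NCCT, CTA or OTHER")
    if (length(msg)) msg else TRUE
  })

#' WindowLevel: an HU display window
#'
#' @slot center window center (level) in HU.
#' @slot width window width in HU, at least 1.
#' @export
setClass("WindowLevel",
  representation(center = "numeric", width = "numeric"),
  validity = function(object) {
    if (length(object@width) != 1L || object@width < 1)
      "invalid window: width must be >= 1" else TRUE
  })

#' HUProbe: summary statistics of a rectangular HU probe
#'
#' Result of probing raw Hounsfield units over a rectangle of a stored slice.
#'
#' @slot region integer(4): (rowMin, rowMax, colMin, colMax) voxel indices.
#' @slot slice stored slice index probed.
#' @slot mean,sd,min,max HU statistics over the region.
#' @slot count number of voxels in the region.
#' @export
setClass("HUProbe",
  representation(region = "numeric", slice = "numeric", mean = "numeric",
                 sd = "numeric", min = "numeric", max = "numeric",
                 count = "numeric"),
  validity = function(object) {
    if (object@count < 1) return("probe must cover at least one voxel")
    if (object@min > object@mean + 1e-9 || object@mean > object@max + 1e-9)
      return("probe statistics inconsistent (min <= mean <= max)")
    TRUE
  })

#' SlicePlane: sampling geometry of one reformatted slice
#'
#' @slot origin mm position of output pixel (1,1).
#' @slot rowDir,colDir orthogonal unit vectors spanning the plane.
#' @slot pxSpacing numeric(2): output pixel spacing (row, col) in mm.
#' @slot slabThickness slab thickness in mm (0 = single sample).
#' @slot outSize integer(2): output (rows, cols).
#' @export
setClass("SlicePlane",
  representation(origin = "numeric", rowDir = "numeric", colDir = "numeric",
                 pxSpacing = "numeric", slabThickness = "numeric",
                 outSize = "integer"),
  validity = function(object) {
    msg <- character()
    if (!.checkUnit(object@rowDir) || !.checkUnit(object@colDir))
      msg <- c(msg, "rowDir/colDir must be unit vectors (tol 1e-6)")
    if (abs(sum(object@rowDir * object@colDir)) > 1e-6)
      msg <- c(msg, "rowDir and colDir must be orthogonal")
    if (any(object@pxSpacing <= 0)) msg <- c(msg, "pxSpacing must be > 0")
    if (object@slabThickness < 0) msg <- c(msg, "slabThickness must be >= 0")
    if (any(object@outSize < 1L)) msg <- c(msg, "outSize must be positive")
    if (length(msg)) msg else TRUE
  })

#' ViewTransform: in-plane pan / zoom / rotation
#'
#' Applied in the fixed order rotate (about the viewport centre), then zoom,
#' then pan, so that recorded event streams replay reproducibly.
#'
#' @slot pan numeric(2): (dx, dy) in viewport pixels.
#' @slot zoom scale factor, > 0.
#' @slot rotation in-plane rotation in degrees.
#' @export
setClass("ViewTransform",
  representation(pan = "numeric", zoom = "numeric", rotation = "numeric"),
  validity = function(object) {
    if (object@zoom <= 0) "invalid zoom: must be > 0" else TRUE
  })

#' TransferFunction: HU to opacity/gray mapping for volume rendering
#'
#' Piecewise-linear control points mapping Hounsfield units to opacity and a
#' gray value. \code{compositing} selects front-to-back alpha blending or
#' maximum-intensity projection.
#'
#' @slot hu control-point HU positions, strictly increasing.
#' @slot opacity per-point opacity in [0,1].
#' @slot gray per-point gray value in [0,1].
#' @slot name preset id.
#' @slot compositing "alpha" or "mip".
#' @export
setClass("TransferFunction",
  representation(hu = "numeric", opacity = "numeric", gray = "numeric",
                 name = "character", compositing = "character"),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(object@hu, strictly = TRUE))
      msg <- c(msg, "control points must be sorted by HU, strictly increasing")
    if (any(object@opacity < 0 | object@opacity > 1))
      msg <- c(msg, "opacity must lie in [0,1]")
    if (length(object@opacity) != length(object@hu) ||
        length(object@gray) != length(object@hu))
      msg <- c(msg, "hu, opacity and gray must have equal length")
    if (!object@compositing %in% c("alpha", "mip"))
      msg <- c(msg, "compositing must be 'alpha' or 'mip'")
    if (length(msg)) msg else TRUE
  })

#' Camera: orthographic camera for ray casting
#'
#' @slot eye,lookAt mm positions; the view direction is lookAt - eye.
#' @slot up up vector, not parallel to the view direction.
#' @slot halfExtent numeric(2): orthographic half-height/half-width in mm.
#' @slot outSize integer(2): output image (rows, cols).
#' @export
setClass("Camera",
  representation(eye = "numeric", lookAt = "numeric", up = "numeric",
                 halfExtent = "numeric", outSize = "integer"),
  validity = function(object) {
    d <- object@lookAt - object@eye
    if (sqrt(sum(d^2)) < 1e-9) return("invalid camera: eye equals lookAt")
    d <- d / sqrt(sum(d^2))
    u <- object@up / sqrt(sum(object@up^2))
    if (sqrt(sum((d - u * sum(d * u))^2)) < 1e-6)
      return("invalid camera: up parallel to view direction")
    if (any(object@halfExtent <= 0)) return("halfExtent must be > 0")
    if (any(object@outSize < 1L)) return("outSize must be positive")
    TRUE
  })

#' EncodedFrame: one viewport update on the wire
#'
#' The unit of frame traffic: the set of 8x8 blocks that changed since the
#' previous frame, each carried as an independent JPEG payload. A keyframe
#' carries every block and resets the client canvas.
#'
#' @slot frameSize integer(2): (rows, cols) of the viewport.
#' @slot keyframe logical flag.
#' @slot quality JPEG quality factor in [1, 100].
#' @slot blocks list of \code{list(row=, col=, payload=raw)} with 1-based
#'   block-grid coordinates.
#' @slot sequenceNumber monotonically increasing frame counter.
#' @export
setClass("EncodedFrame",
  representation(frameSize = "integer", keyframe = "logical",
                 quality = "integer", blocks = "list",
                 sequenceNumber = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@quality < 1L || object@quality > 100L)
      msg <- c(msg, "quality must be in [1,100]")
    nbr <- ceiling(object@frameSize[1] / 8)
    nbc <- ceiling(object@frameSize[2] / 8)
    if (length(object@blocks)) {
      rc <- vapply(object@blocks, function(b) c(b$row, b$col), numeric(2))
      if (any(rc[1, ] < 1 | rc[1, ] > nbr | rc[2, ] < 1 | rc[2, ] > nbc))
        msg <- c(msg, "block coordinates outside the block grid")
      if (anyDuplicated(paste(rc[1, ], rc[2, ])))
        msg <- c(msg, "block coordinates must be unique")
    }
    if (object@keyframe && length(object@blocks) != nbr * nbc)
      msg <- c(msg, "keyframe must cover the full block grid")
    if (length(msg)) msg else TRUE
  })

#' CodecState: server-side state of the block-delta encoder
#'
#' The encoder keeps the last frame it sent, pre-compression, and compares
#' each new frame against it block by block.
#'
#' @slot lastSent last pre-compression 8-bit frame (0x0 matrix before the
#'   first frame).
#' @slot sequenceNumber frames emitted so far.
#' @slot sinceKeyframe frames since the last keyframe.
#' @slot keyframeInterval emit a fresh keyframe every this many frames.
#' @export
setClass("CodecState",
  representation(lastSent = "matrix", sequenceNumber = "integer",
                 sinceKeyframe = "integer", keyframeInterval = "integer"),
  validity = function(object) {
    if (object@keyframeInterval < 1L) "keyframeInterval must be >= 1" else TRUE
  })

#' StateModel: hierarchical view/session state
#'
#' A tree of typed leaves addressed by slash-separated paths (for example
#' \code{"view/wl/center"}). Only diffs of this model ever travel between
#' server and clients.
#'
#' @slot leaves named list: path -> scalar value (number, string or boolean).
#' @slot revision monotonically increasing revision counter.
#' @rdname stateModel
#' @export
setClass("StateModel",
  representation(leaves = "list", revision = "integer"),
  validity = function(object) {
    p <- names(object@leaves)
    if (length(object@leaves)) {
      if (is.null(p) || any(!nzchar(p))) return("all leaves must be named by path")
      if (anyDuplicated(p)) return("paths must be unique")
      for (q in p) if (any(startsWith(p, paste0(q, "/"))))
        return(sprintf("path '%s' is both a leaf and an interior node", q))
      okType <- vapply(object@leaves, function(v)
        length(v) == 1L && (is.numeric(v) || is.character(v) || is.logical(v)),
        logical(1))
      if (!all(okType)) return("leaf values must be scalar number, string or boolean")
    }
    if (object@revision < 0L) return("revision must be >= 0")
    TRUE
  })

#' StateDiff: the difference between two state models
#'
#' @slot upserts named list of paths to set with their new values.
#' @slot deletes character vector of paths to remove.
#' @slot baseRevision revision the diff applies to (NA for a full resync).
#' @slot newRevision revision after application; > baseRevision.
#' @rdname stateModel
#' @export
setClass("StateDiff",
  representation(upserts = "list", deletes = "character",
                 baseRevision = "integer", newRevision = "integer"),
  validity = function(object) {
    if (length(object@upserts) &&
        any(names(object@upserts) %in% object@deletes))
      return("upsert and delete path sets must be disjoint")
    if (!is.na(object@baseRevision) &&
        object@newRevision <= object@baseRevision)
      return("newRevision must exceed baseRevision")
    TRUE
  })

#' InsertSpec: one synthetic lesion or vessel
#'
#' @slot kind one of hemorrhage, ischemia, dense_vessel, vessel,
#'   occlusion_gap, mimic_mass.
#' @slot shape "sphere", "ellipsoid" or "tube".
#' @slot center mm centre (spheres/ellipsoids) or first tube endpoint.
#' @slot size radius (sphere, tube) or semi-axes (ellipsoid), mm.
#' @slot end2 second tube endpoint in mm (tubes only).
#' @slot huValue HU stamped into the volume.
#' @rdname phantomSpec
#' @export
setClass("InsertSpec",
  representation(kind = "character", shape = "character", center = "numeric",
                 size = "numeric", end2 = "numeric", huValue = "numeric"),
  validity = function(object) {
    kinds <- c("hemorrhage", "ischemia", "dense_vessel", "vessel",
               "occlusion_gap", "mimic_mass")
    if (!object@kind %in% kinds) return("unknown insert kind")
    if (!object@shape %in% c("sphere", "ellipsoid", "tube"))
      return("shape must be sphere, ellipsoid or tube")
    if (any(object@size <= 0)) return("insert dimensions must be > 0")
    if (object@shape == "tube" && length(object@end2) != 3L)
      return("tube inserts need two endpoints")
    TRUE
  })

#' PhantomSpec: declarative description of a synthetic head CT
#'
#' Defaults mirror routine acute-stroke acquisitions: 512 x 512 slices over a
#' 220-mm field of view (0.4297 mm in-plane), 5-mm slices for NCCT and
#' 0.6-mm slices for CTA.
#'
#' @slot kind "NCCT" or "CTA".
#' @slot gridSize integer(3): (rows, cols, slices).
#' @slot spacing numeric(3): (row, col, slice) mm.
#' @slot inserts list of [InsertSpec-class] objects.
#' @slot noiseSd additive white Gaussian noise SD in HU, >= 0.
#' @slot seed RNG seed making the phantom reproducible.
#' @rdname phantomSpec
#' @export
setClass("PhantomSpec",
  representation(kind = "character", gridSize = "integer", spacing = "numeric",
                 inserts = "list", noiseSd = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("NCCT", "CTA")) msg <- c(msg, "kind must be NCCT or CTA")
    if (any(object@gridSize < 4L)) msg <- c(msg, "gridSize too small")
    if (any(object@spacing <= 0)) msg <- c(msg, "spacing must be > 0")
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' GroundTruth: exact lesion labels of a phantom
#'
#' @slot masks list of integer vectors: per-insert linear voxel indices.
#' @slot labels named logical: case-level findings (hemorrhage, ischemia,
#'   dense_vessel, occlusion).
#' @slot insertKinds kind of each insert, parallel to \code{masks}.
#' @name groundTruth
#' @export
setClass("GroundTruth",
  representation(masks = "list", labels = "logical", insertKinds = "character"),
  validity = function(object) {
    need <- c("hemorrhage", "ischemia", "dense_vessel", "occlusion")
    if (!all(need %in% names(object@labels)))
      return("labels must include hemorrhage, ischemia, dense_vessel, occlusion")
    if (length(object@masks) != length(object@insertKinds))
      return("one kind per mask required")
    TRUE
  })

#' ContingencyTable: 2x2 diagnostic cross-classification
#'
#' @slot tp,fp,tn,fn non-negative counts.
#' @export
setClass("ContingencyTable",
  representation(tp = "integer", fp = "integer", tn = "integer", fn = "integer"),
  validity = function(object) {
    v <- c(object@tp, object@fp, object@tn, object@fn)
    if (any(v < 0L)) return("counts must be non-negative")
    if (sum(v) == 0L) return("table must contain at least one observation")
    TRUE
  })
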