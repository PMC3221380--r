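## Synthetic head-CT phantoms: geometric primitives (ellipsoid head, skull
## shell, ventricles; sphere/ellipsoid/tube inserts) stamped at configured
## HU, with exact voxel-level ground truth. Emulates the acquisition geometry
## of acute-stroke head CT: 512x512 over a 220-mm field of view, 5-mm NCCT
## slices, 0.6-mm CTA slices.

## HU layer defaults: CT-convention values, packaged configuration, not
## measurements.
.PHANTOM_HU <- c(air = -1000, brain = 35, ventricle = 8, skull = 1000,
                 hemorrhage = 70, ischemia = 27, dense_vessel = 60,
                 vessel = 250, occlusion_gap = 45, mimic_mass = 50)

.INPLANE_MM <- 220 / 512                 # 220-mm field of view, 512 px

#' Describe a synthetic head CT
#'
#' @param kind "NCCT" (5-mm slices) or "CTA" (0.6-mm slices).
#' @param gridSize integer(3) (rows, cols, slices); the default emulates the
#'   acquisition matrix (512 x 512; 30 NCCT / 200 CTA slices).
#' @param spacing numeric(3) mm; defaults from the acquisition geometry.
#' @param inserts list of [InsertSpec-class] (see [sphereInsert()]).
#' @param noiseSd additive white Gaussian noise SD in HU.
#' @param seed RNG seed; the phantom is bit-reproducible given the seed.
#' @return a [PhantomSpec-class].
#' @rdname phantomSpec
#' @export
phantomSpec <- function(kind = c("NCCT", "CTA"), gridSize = NULL,
                        spacing = NULL, inserts = list(), noiseSd = 0,
                        seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(gridSize))
    gridSize <- if (kind == "NCCT") c(512L, 512L, 30L) else c(512L, 512L, 200L)
  if (is.null(spacing))
    spacing <- c(.INPLANE_MM, .INPLANE_MM, if (kind == "NCCT") 5 else 0.6)
  new("PhantomSpec", kind = kind, gridSize = as.integer(gridSize),
      spacing = as.numeric(spacing), inserts = inserts,
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

#' Lesion and vessel insert constructors
#'
#' Positions and dimensions are in phantom millimetres (the origin is voxel
#' (1,1,1)). Default HU per kind: hemorrhage 70, ischemia 27 (parenchyma
#' minus 8), dense vessel 60, contrast vessel 250, occlusion gap 45 (soft
#' tissue), mimic mass 50 — CT-convention defaults, configurable per insert.
#'
#' @param kind insert kind (see [InsertSpec-class]).
#' @param center mm centre.
#' @param radius sphere/tube radius in mm.
#' @param hu stamped HU value.
#' @return an [InsertSpec-class].
#' @rdname inserts
#' @export
sphereInsert <- function(kind, center, radius, hu = .PHANTOM_HU[[kind]]) {
  new("InsertSpec", kind = kind, shape = "sphere", center = as.numeric(center),
      size = as.numeric(radius), end2 = numeric(0), huValue = as.numeric(hu))
}

#' @rdname inserts
#' @param semiAxes numeric(3) mm semi-axes.
#' @export
ellipsoidInsert <- function(kind, center, semiAxes, hu = .PHANTOM_HU[[kind]]) {
  new("InsertSpec", kind = kind, shape = "ellipsoid",
      center = as.numeric(center), size = as.numeric(semiAxes),
      end2 = numeric(0), huValue = as.numeric(hu))
}

#' @rdname inserts
#' @param from,to mm endpoints of the tube axis.
#' @export
tubeInsert <- function(kind, from, to, radius, hu = .PHANTOM_HU[[kind]]) {
  new("InsertSpec", kind = kind, shape = "tube", center = as.numeric(from),
      size = as.numeric(radius), end2 = as.numeric(to),
      huValue = as.numeric(hu))
}

## mm coordinate vectors of the voxel grid
.gridCoords <- function(spec) {
  list(r = (seq_len(spec@gridSize[1]) - 1) * spec@spacing[1],
       c = (seq_len(spec@gridSize[2]) - 1) * spec@spacing[2],
       s = (seq_len(spec@gridSize[3]) - 1) * spec@spacing[3])
}

## normalized squared ellipsoid radius at every voxel of the grid
.ellipsoidRho2 <- function(spec, center, semi) {
  g <- .gridCoords(spec)
  xr <- ((g$r - center[1]) / semi[1])^2
  xc <- ((g$c - center[2]) / semi[2])^2
  xs <- ((g$s - center[3]) / semi[3])^2
  outer(outer(xr, xc, "+"), xs, "+")
}

## logical mask of an insert, evaluated only inside its bounding box
.insertMask <- function(spec, ins) {
  d <- spec@gridSize
  mask <- array(FALSE, d)
  g <- .gridCoords(spec)
  if (ins@shape %in% c("sphere", "ellipsoid")) {
    semi <- if (ins@shape == "sphere") rep(ins@size[1], 3) else ins@size
    rIn <- which(abs(g$r - ins@center[1]) <= semi[1])
    cIn <- which(abs(g$c - ins@center[2]) <= semi[2])
    sIn <- which(abs(g$s - ins@center[3]) <= semi[3])
    if (!length(rIn) || !length(cIn) || !length(sIn)) return(mask)
    xr <- ((g$r[rIn] - ins@center[1]) / semi[1])^2
    xc <- ((g$c[cIn] - ins@center[2]) / semi[2])^2
    xs <- ((g$s[sIn] - ins@center[3]) / semi[3])^2
    sub <- outer(outer(xr, xc, "+"), xs, "+") <= 1
    mask[rIn, cIn, sIn] <- sub
  } else {                               # tube: distance to segment <= radius
    p1 <- ins@center; p2 <- ins@end2; rad <- ins@size[1]
    lo <- pmin(p1, p2) - rad; hi <- pmax(p1, p2) + rad
    rIn <- which(g$r >= lo[1] & g$r <= hi[1])
    cIn <- which(g$c >= lo[2] & g$c <= hi[2])
    sIn <- which(g$s >= lo[3] & g$s <= hi[3])
    if (!length(rIn) || !length(cIn) || !length(sIn)) return(mask)
    pts <- cbind(rep(g$r[rIn], times = length(cIn) * length(sIn)),
                 rep(rep(g$c[cIn], each = length(rIn)), times = length(sIn)),
                 rep(g$s[sIn], each = length(rIn) * length(cIn)))
    ax <- p2 - p1
    len2 <- sum(ax^2)
    rel <- sweep(pts, 2, p1, "-")
    t <- pmin(pmax(as.vector(rel %*% ax) / len2, 0), 1)
    nearest <- outer(t, ax)
    d2 <- rowSums((rel - nearest)^2)
    sub <- array(d2 <= rad^2, c(length(rIn), length(cIn), length(sIn)))
    mask[rIn, cIn, sIn] <- sub
  }
  mask
}

## anatomy background: air, elliptic skull shell, brain parenchyma,
## ventricles. Returns list(voxels, brainMask).
.phantomBackground <- function(spec) {
  d <- spec@gridSize
  extent <- (d - 1) * spec@spacing
  ctr <- extent / 2
  headSemi <- c(0.46 * extent[1], 0.44 * extent[2], 0.75 * extent[3])
  rho2 <- .ellipsoidRho2(spec, ctr, headSemi)
  vox <- array(.PHANTOM_HU[["air"]], d)
  skull <- rho2 <= 1 & rho2 > 0.88^2
  brain <- rho2 <= 0.88^2
  vox[skull] <- .PHANTOM_HU[["skull"]]
  vox[brain] <- .PHANTOM_HU[["brain"]]
  for (side in c(-1, 1)) {
    vc <- ctr + c(0, side * 0.12 * extent[2], 0)
    vent <- .ellipsoidRho2(spec, vc,
                           c(0.10 * extent[1], 0.055 * extent[2],
                             max(0.18 * extent[3], spec@spacing[3]))) <= 1
    vox[vent & brain] <- .PHANTOM_HU[["ventricle"]]
  }
  list(voxels = vox, brainMask = brain)
}

.voxelIndexOfMm <- function(spec, p) {
  pmin(pmax(round(p / spec@spacing) + 1, 1), spec@gridSize)
}

.buildPhantom <- function(spec, cta) {
  bg <- .phantomBackground(spec)
  vox <- bg$voxels
  masks <- list()
  kinds <- character(0)
  vesselMask <- array(FALSE, spec@gridSize)
  ## vessels first so occlusion gaps can carve them
  ord <- order(vapply(spec@inserts, function(i) i@kind == "occlusion_gap",
                      logical(1)))
  for (ins in spec@inserts[ord]) {
    ctrIdx <- .voxelIndexOfMm(spec, if (ins@shape == "tube")
      (ins@center + ins@end2) / 2 else ins@center)
    if (ins@kind == "occlusion_gap") {
      m <- .insertMask(spec, ins)
      if (!any(m & vesselMask))
        stop("invalid occlusion: occlusion_gap does not overlap a vessel")
      m <- m & vesselMask
    } else {
      if (!bg$brainMask[ctrIdx[1], ctrIdx[2], ctrIdx[3]])
        stop("invalid insert: ", ins@kind, " centre outside the brain mask")
      m <- .insertMask(spec, ins)
      if (!any(m)) stop("invalid insert: ", ins@kind, " mask is empty")
    }
    vox[m] <- ins@huValue
    if (ins@kind == "vessel") vesselMask <- vesselMask | m
    if (ins@kind == "occlusion_gap") vesselMask <- vesselMask & !m
    masks <- c(masks, list(which(m)))
    kinds <- c(kinds, ins@kind)
  }
  if (spec@noiseSd > 0) {
    vox <- .withSeed(spec@seed,
                     vox + stats::rnorm(length(vox), 0, spec@noiseSd))
  }
  vox <- round(vox)                      # integer HU: exact DICOM round trips
  labels <- c(hemorrhage = "hemorrhage" %in% kinds,
              ischemia = "ischemia" %in% kinds,
              dense_vessel = "dense_vessel" %in% kinds,
              occlusion = "occlusion_gap" %in% kinds)
  vol <- imageVolume(vox, spacing = spec@spacing,
                     modality = if (cta) "CTA" else "NCCT",
                     attributes = list(
                       SeriesDescription = paste("Phantom",
                                                 if (cta) "CTA" else "NCCT"),
                       Modality = "CT",
                       SliceCount = spec@gridSize[3]))
  list(volume = vol,
       truth = new("GroundTruth", masks = masks, labels = labels,
                   insertKinds = kinds))
}

#' Generate a synthetic NCCT brain phantom
#'
#' Deterministic given the spec's seed: background anatomy layers (air,
#' elliptic skull shell, brain parenchyma, ventricles), inserts stamped at
#' their configured HU, Gaussian noise added last, all HU rounded to
#' integers. Ground-truth masks are exact.
#'
#' @param spec a [PhantomSpec-class].
#' @return \code{list(volume = ImageVolume, truth = GroundTruth)}.
#' @rdname generatePhantom
#' @export
generateNcct <- function(spec) {
  stopifnot(spec@kind == "NCCT")
  bad <- vapply(spec@inserts, function(i)
    i@kind %in% c("vessel", "occlusion_gap"), logical(1))
  if (any(bad)) stop("invalid insert: contrast vessels belong in CTA phantoms")
  .buildPhantom(spec, cta = FALSE)
}

#' Generate a synthetic CTA head phantom
#'
#' As [generateNcct()], plus contrast-opacified vessel tubes; an
#' \code{occlusion_gap} insert replaces the overlapped vessel segment with
#' soft-tissue HU and flags the case-level occlusion label.
#'
#' @rdname generatePhantom
#' @export
generateCta <- function(spec) {
  stopifnot(spec@kind == "CTA")
  .buildPhantom(spec, cta = TRUE)
}

#' @rdname groundTruth
#' @export
setMethod("caseLabels", "GroundTruth", function(x, ...) x@labels)

#' @rdname groundTruth
#' @export
setMethod("lesionMasks", "GroundTruth", function(x, ...) x@masks)

#' Simulate binary reader responses from case truth
#'
#' Each positive case is called positive with probability \code{sens}; each
#' negative case is called positive with probability \code{1 - spec}.
#' Deterministic given the seed.
#'
#' @param truth logical (or 0/1) vector of case-level truth labels.
#' @param sens,spec reader sensitivity and specificity, in [0,1].
#' @param seed RNG seed.
#' @return logical vector of reader calls, same length as \code{truth}.
#' @export
simulateReaderResponses <- function(truth, sens, spec, seed = 1L) {
  if (sens < 0 || sens > 1 || spec < 0 || spec > 1)
    stop("sens and spec must lie in [0,1]")
  truth <- as.logical(truth)
  .withSeed(seed, {
    u <- stats::runif(length(truth))
    ifelse(truth, u < sens, u < 1 - spec)
  })
}
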