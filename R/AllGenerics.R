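#' Accessors for image volumes and derived objects
#'
#' Bioconductor-style accessor generics for the classes in this package.
#' Use these rather than reaching into slots directly.
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @return The slot value (array, numeric vector, matrix, character or list,
#'   depending on the accessor).
#' @name accessors
#' @aliases voxelData voxelSpacing volumeOrigin volumeOrientation modality
#'   volumeAttributes
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x, ...) standardGeneric("voxelData"))

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x, ...) standardGeneric("voxelSpacing"))

#' @rdname accessors
#' @export
setGeneric("volumeOrigin", function(x, ...) standardGeneric("volumeOrigin"))

#' @rdname accessors
#' @export
setGeneric("volumeOrientation", function(x, ...) standardGeneric("volumeOrientation"))

#' @rdname accessors
#' @export
setGeneric("modality", function(x, ...) standardGeneric("modality"))

#' @rdname accessors
#' @export
setGeneric("volumeAttributes", function(x, ...) standardGeneric("volumeAttributes"))

#' @rdname groundTruth
#' @export
setGeneric("caseLabels", function(x, ...) standardGeneric("caseLabels"))

#' @rdname groundTruth
#' @export
setGeneric("lesionMasks", function(x, ...) standardGeneric("lesionMasks"))

#' @rdname stateModel
#' @export
setGeneric("stateRevision", function(x, ...) standardGeneric("stateRevision"))

#' @rdname stateModel
#' @export
setGeneric("stateLeaves", function(x, ...) standardGeneric("stateLeaves"))
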