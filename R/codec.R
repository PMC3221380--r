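## Block-delta frame codec: the streaming core. Each new viewport frame is
## compared 8x8-block-wise against the last frame sent (kept pre-compression
## server-side); only changed blocks are JPEG-compressed and transmitted.
## Quality policy: 25 while the user is interacting, 100 for static frames.

.QUALITY_INTERACTIVE <- 25L
.QUALITY_STATIC <- 100L

#' Create a fresh codec state
#'
#' @param keyframeInterval emit a full keyframe every this many frames to
#'   bound client drift (default 120).
#' @return a [CodecState-class] with no frame history (the first encode is
#'   forced to be a keyframe).
#' @export
newCodecState <- function(keyframeInterval = 120L) {
  new("CodecState", lastSent = matrix(integer(), 0, 0),
      sequenceNumber = 0L, sinceKeyframe = 0L,
      keyframeInterval = as.integer(keyframeInterval))
}

.blockGrid <- function(dims) c(ceiling(dims[1] / 8), ceiling(dims[2] / 8))

## Extract one 8x8 block (1-based block coordinates), zero-padding past the
## image edge.
.getBlock <- function(img, br, bc) {
  r0 <- (br - 1L) * 8L + 1L; c0 <- (bc - 1L) * 8L + 1L
  r1 <- min(r0 + 7L, nrow(img)); c1 <- min(c0 + 7L, ncol(img))
  blk <- matrix(0L, 8L, 8L)
  blk[seq_len(r1 - r0 + 1L), seq_len(c1 - c0 + 1L)] <- img[r0:r1, c0:c1]
  blk
}

## Which blocks differ between two equal-sized 8-bit images (bit-exact)?
.changedBlocks <- function(a, b) {
  nb <- .blockGrid(dim(a))
  padR <- nb[1] * 8L; padC <- nb[2] * 8L
  dm <- matrix(FALSE, padR, padC)
  dm[seq_len(nrow(a)), seq_len(ncol(a))] <- a != b
  dim(dm) <- c(8L, nb[1], 8L, nb[2])
  chg <- apply(dm, c(2, 4), any)
  which(chg, arr.ind = TRUE)
}

#' Encode a viewport frame as changed-block JPEG payloads
#'
#' Compares the new frame against the last frame sent (pre-compression) and
#' emits an [EncodedFrame-class] holding one independent 8x8 JPEG per changed
#' block. The first frame, any frame after a state reset, and every
#' \code{keyframeInterval}-th frame is a keyframe carrying all blocks. The
#' JPEG quality factor is 25 during interactive presentation and 100 for
#' static presentation.
#'
#' @param state a [CodecState-class].
#' @param current integer matrix, 8-bit gray values 0..255.
#' @param interactive TRUE while a drag is in progress.
#' @param forceKeyframe request a keyframe regardless of history.
#' @return \code{list(frame = EncodedFrame, state = CodecState)} — the codec
#'   is purely functional; keep the returned state for the next call.
#' @examples
#' st <- newCodecState()
#' img <- matrix(0L, 64, 64)
#' r1 <- encodeFrame(st, img, interactive = FALSE)   # keyframe, 64 blocks
#' r2 <- encodeFrame(r1$state, img)                  # unchanged: 0 blocks
#' length(r2$frame@blocks)
#' @export
encodeFrame <- function(state, current, interactive = FALSE,
                        forceKeyframe = FALSE) {
  storage.mode(current) <- "integer"
  empty <- length(state@lastSent) == 0L
  if (!empty && !all(dim(state@lastSent) == dim(current)) && !forceKeyframe)
    stop("frame size changed: reset the codec (forceKeyframe) first")
  periodic <- state@sinceKeyframe + 1L >= state@keyframeInterval
  keyframe <- empty || forceKeyframe || periodic ||
    !all(dim(state@lastSent) == dim(current))
  q <- if (interactive) .QUALITY_INTERACTIVE else .QUALITY_STATIC
  nb <- .blockGrid(dim(current))
  coords <- if (keyframe) {
    as.matrix(expand.grid(row = seq_len(nb[1]), col = seq_len(nb[2])))
  } else {
    .changedBlocks(current, state@lastSent)
  }
  blocks <- vector("list", nrow(coords))
  if (nrow(coords)) {
    for (i in seq_len(nrow(coords))) {
      blk <- .getBlock(current, coords[i, 1], coords[i, 2])
      payload <- jpeg::writeJPEG(blk / 255, raw(), quality = q / 100)
      blocks[[i]] <- list(row = as.integer(coords[i, 1]),
                          col = as.integer(coords[i, 2]), payload = payload)
    }
  }
  frame <- new("EncodedFrame", frameSize = dim(current),
               keyframe = keyframe, quality = q, blocks = blocks,
               sequenceNumber = state@sequenceNumber + 1L)
  newState <- new("CodecState", lastSent = current,
                  sequenceNumber = state@sequenceNumber + 1L,
                  sinceKeyframe = if (keyframe) 0L else state@sinceKeyframe + 1L,
                  keyframeInterval = state@keyframeInterval)
  list(frame = frame, state = newState)
}

#' Decode an encoded frame onto a client canvas
#'
#' JPEG-decodes every transmitted block and writes it at its grid position;
#' untouched blocks keep their prior canvas content. A keyframe replaces the
#' whole canvas (and may change its size).
#'
#' @param canvas integer matrix (the client's current canvas), or NULL before
#'   the first keyframe.
#' @param frame an [EncodedFrame-class].
#' @return the updated integer canvas matrix.
#' @export
decodeFrame <- function(canvas, frame) {
  fs <- frame@frameSize
  if (frame@keyframe) {
    canvas <- matrix(0L, fs[1], fs[2])
  } else {
    if (is.null(canvas) || !all(dim(canvas) == fs))
      stop("canvas dimensions do not match frame size (need a keyframe)")
  }
  for (b in frame@blocks) {
    dec <- tryCatch(jpeg::readJPEG(b$payload),
                    error = function(e) stop(sprintf(
                      "decode failure at block (%d,%d): %s", b$row, b$col,
                      conditionMessage(e)), call. = FALSE))
    if (length(dim(dec)) == 3L) dec <- dec[, , 1]
    blk <- .roundHalfUp(dec * 255)
    r0 <- (b$row - 1L) * 8L + 1L; c0 <- (b$col - 1L) * 8L + 1L
    r1 <- min(r0 + 7L, fs[1]); c1 <- min(c0 + 7L, fs[2])
    canvas[r0:r1, c0:c1] <- blk[seq_len(r1 - r0 + 1L), seq_len(c1 - c0 + 1L)]
  }
  storage.mode(canvas) <- "integer"
  canvas
}

#' Payload bytes and compression ratio of an encoded frame
#'
#' The ratio is raw frame bytes divided by total transmitted JPEG payload
#' bytes. For a static (quality 100) full keyframe the ratio is checked
#' against the configurable guideline bound for neurological CT (12:1): a
#' warning is issued when compression exceeds it.
#'
#' @param rawBytes size of the uncompressed frame in bytes, > 0.
#' @param frame an [EncodedFrame-class].
#' @param guidelineBound maximum recommended compression ratio (default 12).
#' @return the compression ratio (a number).
#' @export
compressionRatio <- function(rawBytes, frame, guidelineBound = 12) {
  if (rawBytes <= 0) stop("rawBytes must be > 0")
  payload <- payloadBytes(frame)
  if (payload == 0) stop("no traffic: frame transmitted zero blocks")
  ratio <- rawBytes / payload
  if (frame@keyframe && frame@quality == .QUALITY_STATIC &&
      ratio > guidelineBound)
    warning(sprintf(
      "static frame compression ratio %.1f:1 exceeds the %g:1 guideline",
      ratio, guidelineBound))
  ratio
}

#' @rdname compressionRatio
#' @export
payloadBytes <- function(frame) {
  if (!length(frame@blocks)) return(0L)
  sum(vapply(frame@blocks, function(b) length(b$payload), integer(1)))
}

setMethod("show", "EncodedFrame", function(object) {
  cat(sprintf(
    "EncodedFrame #%d: %dx%d, %s, q=%d, %d block(s), %d payload bytes\n",
    object@sequenceNumber, object@frameSize[1], object@frameSize[2],
    if (object@keyframe) "keyframe" else "delta", object@quality,
    length(object@blocks), payloadBytes(object)))
})

## --- wire format -----------------------------------------------------------
## Length-prefixed big-endian binary:
##   header : uint32 sequenceNumber | uint16 rows | uint16 cols |
##            uint8 quality | uint8 keyframe | uint16 blockCount
##   block  : uint16 blockRow | uint16 blockCol | uint32 payloadLength |
##            payload bytes
## (documented in inst/extdata/wire_format.md)

#' Serialize / deserialize an encoded frame for transmission
#'
#' Implements the package's documented big-endian wire format (see
#' \code{system.file("extdata", "wire_format.md", package = "teleCT")}).
#'
#' @param frame an [EncodedFrame-class].
#' @return \code{packFrame}: a raw vector; \code{unpackFrame}: the
#'   reconstructed [EncodedFrame-class].
#' @export
packFrame <- function(frame) {
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(frame@sequenceNumber, con, size = 4, endian = "big")
  writeBin(frame@frameSize[1], con, size = 2, endian = "big")
  writeBin(frame@frameSize[2], con, size = 2, endian = "big")
  writeBin(frame@quality, con, size = 1)
  writeBin(as.integer(frame@keyframe), con, size = 1)
  writeBin(length(frame@blocks), con, size = 2, endian = "big")
  for (b in frame@blocks) {
    writeBin(b$row, con, size = 2, endian = "big")
    writeBin(b$col, con, size = 2, endian = "big")
    writeBin(length(b$payload), con, size = 4, endian = "big")
    writeBin(b$payload, con)
  }
  rawConnectionValue(con)
}

#' @rdname packFrame
#' @param bytes a raw vector produced by \code{packFrame}.
#' @export
unpackFrame <- function(bytes) {
  con <- rawConnection(bytes, "rb")
  on.exit(close(con))
  seqNum <- readBin(con, integer(), size = 4, endian = "big")
  rows <- readBin(con, integer(), size = 2, endian = "big", signed = FALSE)
  cols <- readBin(con, integer(), size = 2, endian = "big", signed = FALSE)
  quality <- readBin(con, integer(), size = 1, signed = FALSE)
  keyframe <- readBin(con, integer(), size = 1, signed = FALSE) > 0L
  nBlocks <- readBin(con, integer(), size = 2, endian = "big", signed = FALSE)
  if (!length(nBlocks)) stop("parse error: truncated frame header")
  blocks <- vector("list", nBlocks)
  for (i in seq_len(nBlocks)) {
    br <- readBin(con, integer(), size = 2, endian = "big", signed = FALSE)
    bc <- readBin(con, integer(), size = 2, endian = "big", signed = FALSE)
    len <- readBin(con, integer(), size = 4, endian = "big")
    payload <- readBin(con, raw(), len)
    if (length(payload) != len) stop("parse error: truncated block payload")
    blocks[[i]] <- list(row = br, col = bc, payload = payload)
  }
  new("EncodedFrame", frameSize = c(rows, cols), keyframe = keyframe,
      quality = quality, blocks = blocks, sequenceNumber = seqNum)
}
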