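## Minimal DICOM Part-10 I/O for single-frame CT.
##
## Scope: explicit and implicit VR little endian, uncompressed pixel data,
## the CT image module tags needed to reconstruct calibrated volumes.
## Deflated and encapsulated transfer syntaxes are rejected with a clear
## error. This is deliberately not a general DICOM toolkit.

.TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
.TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
.CT_SOP_CLASS <- "1.2.840.10008.5.1.4.1.1.2"

.uint16le <- function(x) as.raw(c(x %% 256, x %/% 256))
.uint32le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

.padEven <- function(v, pad = as.raw(0)) {
  if (length(v) %% 2L == 1L) c(v, pad) else v
}

.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

.dcmElement <- function(group, element, vr, value) {
  value <- .padEven(value, if (vr %in% c("UI", "OB", "OW")) as.raw(0) else as.raw(0x20))
  head <- c(.uint16le(group), .uint16le(element), charToRaw(vr))
  if (vr %in% .LONG_VRS) {
    c(head, as.raw(c(0, 0)), .uint32le(length(value)), value)
  } else {
    if (length(value) > 65534) stop("value too long for short VR form")
    c(head, .uint16le(length(value)), value)
  }
}

.dcmString <- function(group, element, vr, s) {
  .dcmElement(group, element, vr, charToRaw(paste(s, collapse = "\\")))
}

.dcmUS <- function(group, element, x) {
  .dcmElement(group, element, "US", as.raw(unlist(lapply(x, function(v)
    c(v %% 256, v %/% 256)))))
}

.dcmDS <- function(group, element, x) {
  .dcmString(group, element, "DS", format(x, digits = 10, trim = TRUE,
                                          scientific = FALSE))
}

.newUid <- local({
  counter <- 0L
  function() {
    counter <<- counter + 1L
    paste0("1.2.826.0.1.3680043.9777.", as.integer(Sys.time()) %% 100000L,
           ".", sample.int(.Machine$integer.max, 1L) %% 99999L, ".", counter)
  }
})

#' Write an ImageVolume as a single-frame DICOM CT series
#'
#' Emits one Part-10 file per slice (explicit VR little endian, uncompressed,
#' 16-bit unsigned pixels with rescale intercept -1024) so that integer HU
#' values round-trip exactly through [loadSeries()].
#'
#' @param volume an [ImageVolume-class] with integer-valued HU in
#'   [-1024, 64511].
#' @param dir output directory (created if needed).
#' @param seriesDescription textual series description.
#' @param patientName,patientId identifying fields, present so that the
#'   anonymizing loader has something to strip.
#' @param filePrefix prefix of the per-slice file names.
#' @param seriesUid optional SeriesInstanceUID (generated when NULL).
#' @return invisibly, the vector of file paths written.
#' @export
writeDicomSeries <- function(volume, dir,
                             seriesDescription = paste("Phantom", volume@modality),
                             patientName = "Phantom^Head",
                             patientId = "PHANTOM-0001",
                             filePrefix = "slice", seriesUid = NULL) {
  stopifnot(is(volume, "ImageVolume"))
  vox <- volume@voxels
  if (max(abs(vox - round(vox))) > 1e-6)
    stop("writeDicomSeries requires integer-valued HU")
  vox <- round(vox)
  intercept <- -1024
  stored <- vox - intercept
  if (min(stored) < 0 || max(stored) > 65535)
    stop("HU out of the storable range [-1024, 64511]")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(vox)
  if (is.null(seriesUid)) seriesUid <- .newUid()
  studyUid <- .newUid()
  iop <- c(volume@orientation[, 2], volume@orientation[, 1])
  date <- format(Sys.Date(), "%Y%m%d")
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    ipp <- as.numeric(voxelToPatient(volume, c(1, 1, k)))
    sopUid <- .newUid()
    ds <- c(
      .dcmString(0x0008, 0x0016, "UI", .CT_SOP_CLASS),
      .dcmString(0x0008, 0x0018, "UI", sopUid),
      .dcmString(0x0008, 0x0021, "DA", date),
      .dcmString(0x0008, 0x0060, "CS", "CT"),
      .dcmString(0x0008, 0x103E, "LO", seriesDescription),
      .dcmString(0x0010, 0x0010, "PN", patientName),
      .dcmString(0x0010, 0x0020, "LO", patientId),
      .dcmDS(0x0018, 0x0050, volume@spacing[3]),
      .dcmString(0x0020, 0x000D, "UI", studyUid),
      .dcmString(0x0020, 0x000E, "UI", seriesUid),
      .dcmString(0x0020, 0x0013, "IS", as.character(k)),
      .dcmDS(0x0020, 0x0032, ipp),
      .dcmDS(0x0020, 0x0037, iop),
      .dcmUS(0x0028, 0x0002, 1L),
      .dcmString(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .dcmUS(0x0028, 0x0010, d[1]),
      .dcmUS(0x0028, 0x0011, d[2]),
      .dcmDS(0x0028, 0x0030, volume@spacing[1:2]),
      .dcmUS(0x0028, 0x0100, 16L),
      .dcmUS(0x0028, 0x0101, 16L),
      .dcmUS(0x0028, 0x0102, 15L),
      .dcmUS(0x0028, 0x0103, 0L)
    )
    ds <- c(ds,
      .dcmDS(0x0028, 0x1052, intercept),
      .dcmDS(0x0028, 0x1053, 1))
    ## pixel data: row-major uint16 little endian
    sl <- t(stored[, , k])               # row-major order
    px <- as.vector(sl)
    pxRaw <- as.raw(rbind(px %% 256, px %/% 256))
    ds <- c(ds, .dcmElement(0x7FE0, 0x0010, "OW", pxRaw))
    meta <- c(
      .dcmElement(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
      .dcmString(0x0002, 0x0002, "UI", .CT_SOP_CLASS),
      .dcmString(0x0002, 0x0003, "UI", sopUid),
      .dcmString(0x0002, 0x0010, "UI", .TS_EXPLICIT_LE),
      .dcmString(0x0002, 0x0012, "UI", "1.2.826.0.1.3680043.9777.1")
    )
    meta <- c(.dcmElement(0x0002, 0x0000, "UL", .uint32le(length(meta))), meta)
    path <- file.path(dir, sprintf("%s_%04d.dcm", filePrefix, k))
    con <- file(path, "wb")
    writeBin(c(raw(128), charToRaw("DICM"), meta, ds), con)
    close(con)
    paths[k] <- path
  }
  invisible(paths)
}

## --- reading ---------------------------------------------------------------

.TEXT_VRS <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO", "LT", "PN",
               "SH", "ST", "TM", "UI", "UC", "UR", "UT")

.tagKey <- function(group, element) sprintf("%04X,%04X", group, element)

## tag -> implicit-VR hint for the tags this reader interprets
.IMPLICIT_VR <- c(
  "0008,0016" = "UI", "0008,0018" = "UI", "0008,0021" = "DA",
  "0008,0060" = "CS", "0008,103E" = "LO", "0010,0010" = "PN",
  "0010,0020" = "LO", "0018,0050" = "DS", "0020,000D" = "UI",
  "0020,000E" = "UI", "0020,0013" = "IS", "0020,0032" = "DS",
  "0020,0037" = "DS", "0028,0002" = "US", "0028,0004" = "CS",
  "0028,0010" = "US", "0028,0011" = "US", "0028,0030" = "DS",
  "0028,0100" = "US", "0028,0101" = "US", "0028,0102" = "US",
  "0028,0103" = "US", "0028,1052" = "DS", "0028,1053" = "DS",
  "7FE0,0010" = "OW")

.readU16 <- function(bytes, pos) as.integer(bytes[pos]) + 256L * as.integer(bytes[pos + 1L])
.readU32 <- function(bytes, pos) {
  as.numeric(bytes[pos]) + 256 * as.numeric(bytes[pos + 1L]) +
    65536 * as.numeric(bytes[pos + 2L]) + 16777216 * as.numeric(bytes[pos + 3L])
}

## Skip an undefined-length value (sequences): scan for the sequence
## delimitation item (FFFE,E0DD) with zero length. Returns position after it.
.skipUndefined <- function(bytes, pos) {
  n <- length(bytes)
  while (pos + 7L <= n) {
    if (bytes[pos] == as.raw(0xFE) && bytes[pos + 1L] == as.raw(0xFF) &&
        bytes[pos + 2L] == as.raw(0xDD) && bytes[pos + 3L] == as.raw(0xE0))
      return(pos + 8L)
    pos <- pos + 2L
  }
  stop("parse error: unterminated undefined-length value")
}

.parseValue <- function(vr, value, pixelSigned = FALSE) {
  if (vr %in% .TEXT_VRS) {
    s <- rawToChar(value[value != as.raw(0)])
    s <- sub(" +$", "", s)
    if (vr %in% c("DS", "IS")) {
      as.numeric(strsplit(s, "\\\\", fixed = FALSE)[[1]])
    } else if (grepl("\\\\", s)) {
      strsplit(s, "\\\\")[[1]]
    } else s
  } else if (vr == "US") {
    readBin(value, integer(), length(value) %/% 2L, size = 2L,
            signed = FALSE, endian = "little")
  } else if (vr == "UL") {
    readBin(value, integer(), length(value) %/% 4L, size = 4L, endian = "little")
  } else value
}

#' Read one single-frame DICOM CT file
#'
#' Parses the Part-10 header and the CT image module tags. Supports explicit
#' and implicit VR little endian with uncompressed pixel data.
#'
#' @param path file path.
#' @return a named list of parsed elements (Rows, Columns, PixelSpacing,
#'   ImagePositionPatient, ImageOrientationPatient, RescaleSlope/Intercept,
#'   pixel matrix as stored values, ...).
#' @export
readDicomFile <- function(path) {
  bytes <- readBin(path, raw(), file.info(path)$size)
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM Part-10 file: ", path)
  pos <- 133L
  meta <- list()
  ## file meta group is always explicit VR little endian
  while (pos + 7L <= length(bytes)) {
    group <- .readU16(bytes, pos)
    if (group != 0x0002) break
    element <- .readU16(bytes, pos + 2L)
    vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
    if (vr %in% .LONG_VRS) {
      len <- .readU32(bytes, pos + 8L); vstart <- pos + 12L
    } else {
      len <- .readU16(bytes, pos + 6L); vstart <- pos + 8L
    }
    val <- if (len > 0) bytes[vstart:(vstart + len - 1L)] else raw(0)
    meta[[.tagKey(group, element)]] <- .parseValue(vr, val)
    pos <- vstart + len
  }
  ts <- meta[["0002,0010"]]
  if (is.null(ts)) stop("parse error: missing transfer syntax")
  if (!ts %in% c(.TS_EXPLICIT_LE, .TS_IMPLICIT_LE))
    stop("unsupported transfer syntax: ", ts,
         " (only uncompressed little endian is supported)")
  explicit <- ts == .TS_EXPLICIT_LE
  out <- list()
  n <- length(bytes)
  while (pos + 7L <= n) {
    group <- .readU16(bytes, pos)
    element <- .readU16(bytes, pos + 2L)
    key <- .tagKey(group, element)
    if (explicit) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% .LONG_VRS) {
        len <- .readU32(bytes, pos + 8L); vstart <- pos + 12L
      } else {
        len <- .readU16(bytes, pos + 6L); vstart <- pos + 8L
      }
    } else {
      vr <- if (key %in% names(.IMPLICIT_VR)) .IMPLICIT_VR[[key]] else "UN"
      len <- .readU32(bytes, pos + 4L); vstart <- pos + 8L
    }
    if (len == 4294967295) {             # undefined length (sequences)
      pos <- .skipUndefined(bytes, vstart)
      next
    }
    if (vstart + len - 1L > n) stop("parse error: truncated element ", key)
    if (key %in% names(.IMPLICIT_VR) || group == 0x0008 || group == 0x0010) {
      val <- if (len > 0) bytes[vstart:(vstart + len - 1L)] else raw(0)
      if (!explicit && !key %in% names(.IMPLICIT_VR)) {
        ## unknown tag in an identifying group: keep raw so it can be dropped
        out[[key]] <- val
      } else {
        out[[key]] <- .parseValue(vr, val)
      }
    }
    pos <- vstart + len
  }
  if (is.null(out[["0028,0010"]]) || is.null(out[["7FE0,0010"]]))
    stop("parse error: missing image pixel module in ", path)
  rows <- out[["0028,0010"]]; cols <- out[["0028,0011"]]
  signed <- !is.null(out[["0028,0103"]]) && out[["0028,0103"]] == 1L
  px <- readBin(out[["7FE0,0010"]], integer(), rows * cols, size = 2L,
                signed = signed, endian = "little")
  out[["pixels"]] <- matrix(px, nrow = rows, ncol = cols, byrow = TRUE)
  out[["7FE0,0010"]] <- NULL
  out
}

.DICOM_NAMES <- c(
  "0008,0016" = "SOPClassUID", "0008,0018" = "SOPInstanceUID",
  "0008,0021" = "SeriesDate", "0008,0060" = "Modality",
  "0008,103E" = "SeriesDescription", "0010,0010" = "PatientName",
  "0010,0020" = "PatientID", "0018,0050" = "SliceThickness",
  "0020,000D" = "StudyInstanceUID", "0020,000E" = "SeriesInstanceUID",
  "0020,0013" = "InstanceNumber", "0020,0032" = "ImagePositionPatient",
  "0020,0037" = "ImageOrientationPatient", "0028,0030" = "PixelSpacing",
  "0028,1052" = "RescaleIntercept", "0028,1053" = "RescaleSlope")

## Textual attributes that survive anonymization.
.ATTRIBUTE_WHITELIST <- c("SeriesDescription", "Modality", "SeriesDate",
                          "SliceCount", "Rows", "Columns", "PixelSpacing",
                          "SliceThickness")

#' Load a DICOM CT series into a calibrated volume
#'
#' Reads every DICOM file in a directory, selects one series, sorts slices by
#' the projection of their image position onto the slice normal, applies the
#' rescale slope/intercept so voxels are Hounsfield units, and validates the
#' geometry (uniform inter-slice spacing, consistent dimensions).
#'
#' @param dir directory of single-frame CT DICOM files.
#' @param seriesSelector optional SeriesInstanceUID or SeriesDescription; if
#'   the directory holds a single series it may be omitted.
#' @param anonymize drop all metadata except a whitelist of non-identifying
#'   textual attributes (default TRUE).
#' @param spacingTolerance allowed relative deviation of inter-slice steps
#'   from their median (default 0.05).
#' @return an [ImageVolume-class].
#' @examples
#' spec <- phantomSpec("NCCT", gridSize = c(32, 32, 8))
#' ph <- generateNcct(spec)
#' dir <- file.path(tempdir(), "ncct-demo")
#' writeDicomSeries(ph$volume, dir)
#' vol <- loadSeries(dir)
#' stopifnot(identical(dim(voxelData(vol)), c(32L, 32L, 8L)))
#' @export
loadSeries <- function(dir, seriesSelector = NULL, anonymize = TRUE,
                       spacingTolerance = 0.05) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  parsed <- list()
  for (f in files) {
    p <- tryCatch(readDicomFile(f), error = function(e) NULL)
    if (!is.null(p) && identical(p[["0008,0060"]], "CT")) parsed[[f]] <- p
  }
  if (length(parsed) < 2L)
    stop("inconsistent series: need at least 2 CT DICOM slices in ", dir)
  uids <- vapply(parsed, function(p) p[["0020,000E"]] %||% "", character(1))
  descs <- vapply(parsed, function(p) p[["0008,103E"]] %||% "", character(1))
  if (!is.null(seriesSelector)) {
    keep <- uids == seriesSelector | descs == seriesSelector
    if (!any(keep)) stop("series not found: ", seriesSelector)
    parsed <- parsed[keep]; uids <- uids[keep]
  } else if (length(unique(uids)) > 1L) {
    stop("directory holds multiple series; give a seriesSelector")
  }
  rows <- vapply(parsed, function(p) p[["0028,0010"]], integer(1))
  cols <- vapply(parsed, function(p) p[["0028,0011"]], integer(1))
  if (length(unique(rows)) > 1L || length(unique(cols)) > 1L)
    stop("heterogeneous series: mixed image dimensions")
  iop <- parsed[[1]][["0020,0037"]]
  if (is.null(iop) || length(iop) != 6L)
    stop("inconsistent series: missing image orientation")
  colDir <- .unit(iop[1:3]); rowDir <- .unit(iop[4:6])
  normal <- .cross3(rowDir, colDir)
  proj <- vapply(parsed, function(p) {
    ipp <- p[["0020,0032"]]
    if (is.null(ipp) || length(ipp) != 3L)
      stop("inconsistent series: missing image position")
    sum(ipp * normal)
  }, numeric(1))
  ord <- order(proj)
  proj <- proj[ord]; parsed <- parsed[ord]
  steps <- diff(proj)
  if (any(steps < 1e-6))
    stop("inconsistent series: duplicate or missing slice positions")
  med <- stats::median(steps)
  if (any(abs(steps - med) / med > spacingTolerance))
    stop("non-uniform spacing: inter-slice steps deviate beyond tolerance")
  first <- parsed[[1]]
  slope <- (first[["0028,1053"]] %||% 1)
  icept <- (first[["0028,1052"]] %||% 0)
  nR <- unname(rows[1]); nC <- unname(cols[1]); nS <- length(parsed)
  vox <- array(0, dim = c(nR, nC, nS))
  for (k in seq_len(nS)) {
    p <- parsed[[k]]
    vox[, , k] <- p[["pixels"]] * (p[["0028,1053"]] %||% slope) +
      (p[["0028,1052"]] %||% icept)
  }
  pxsp <- first[["0028,0030"]]
  if (is.null(pxsp) || length(pxsp) != 2L) pxsp <- c(1, 1)
  desc <- first[["0008,103E"]] %||% ""
  mod <- if (grepl("CTA", desc, ignore.case = TRUE)) "CTA" else "NCCT"
  attrsAll <- list()
  for (key in names(.DICOM_NAMES)) {
    v <- first[[key]]
    if (!is.null(v)) attrsAll[[.DICOM_NAMES[[key]]]] <- v
  }
  attrsAll$SliceCount <- nS
  attrsAll$Rows <- nR
  attrsAll$Columns <- nC
  attrs <- if (anonymize) attrsAll[names(attrsAll) %in% .ATTRIBUTE_WHITELIST]
           else attrsAll
  new("ImageVolume",
      voxels = vox,
      spacing = c(pxsp[1], pxsp[2], med),
      origin = as.numeric(first[["0020,0032"]]),
      orientation = cbind(rowDir, colDir, .unit(normal)),
      modality = mod,
      attributes = attrs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
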