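## Session engine: lifecycle, series selection, interaction events, frame
## streaming and state broadcast — with an explicit serialized wire layer.
##
## Every byte exchanged between server and clients passes through the wire
## log as one of four message types (catalog text, packed frames, state
## diffs, probe text). DICOM files and raw pixel arrays never appear on the
## wire; `assertConfidential()` checks that over a whole session. Clients
## are in-process reference clients that consume only wire bytes.

.DEFAULT_VIEWPORT <- c(480L, 320L)       # portrait smartphone: 320 x 480 px

#' Default server address used when a client gives none
#' @return a character scalar.
#' @export
defaultServerAddress <- function() "rsp://127.0.0.1:2100"

#' Start an in-process visualization server
#'
#' @param volumes named list of [ImageVolume-class] objects (the series
#'   catalog), or a directory whose subdirectories each hold one DICOM
#'   series.
#' @param token shared authentication token clients must present.
#' @param config list: \code{viewport} (rows, cols; default 480 x 320),
#'   \code{keyframeInterval} (default 120), \code{guidelineRatio} (default
#'   12), \code{background} gray (default 0).
#' @return a \code{TeleServer} object (environment).
#' @export
teleServer <- function(volumes, token = "phantom-token", config = list()) {
  if (is.character(volumes)) {
    dirs <- list.dirs(volumes, recursive = FALSE)
    vols <- lapply(dirs, loadSeries)
    names(vols) <- basename(dirs)
    volumes <- vols
  }
  stopifnot(length(volumes) >= 1L, !is.null(names(volumes)))
  cfg <- utils::modifyList(list(viewport = .DEFAULT_VIEWPORT,
                                keyframeInterval = 120L,
                                guidelineRatio = 12,
                                background = 0L), config)
  srv <- new.env(parent = emptyenv())
  srv$volumes <- volumes
  srv$token <- token
  srv$config <- cfg
  srv$sessions <- list()
  srv$wireLog <- list()
  srv$nextId <- 1L
  class(srv) <- "TeleServer"
  srv
}

.logWire <- function(server, direction, type, payload, sessionId = NA) {
  server$wireLog[[length(server$wireLog) + 1L]] <-
    list(direction = direction, type = type, payload = payload,
         sessionId = sessionId)
  invisible(payload)
}

.whitelistedCatalog <- function(volumes) {
  lapply(names(volumes), function(id) {
    a <- volumes[[id]]@attributes
    a <- a[names(a) %in% .ATTRIBUTE_WHITELIST]
    a <- lapply(a, function(v) if (is.numeric(v)) v else as.character(v))
    c(list(seriesId = id), a)
  })
}

.getSession <- function(server, sessionId, requireOpen = TRUE) {
  s <- server$sessions[[sessionId]]
  if (is.null(s)) stop("unknown session: ", sessionId)
  if (requireOpen && !s$open) stop("session closed: ", sessionId)
  s
}

#' Open a session and fetch the series catalog
#'
#' Authenticates against the server's shared token and returns the catalog:
#' whitelisted textual series attributes only, never patient identifiers.
#'
#' @param server a \code{TeleServer}.
#' @param token the shared token.
#' @param address server address; the packaged default is used when none is
#'   given, so interpretation can start without typing one.
#' @return \code{list(sessionId, address, catalog)}.
#' @export
connectSession <- function(server, token, address = NULL) {
  if (is.null(address)) address <- defaultServerAddress()
  if (!identical(token, server$token))
    stop("connection refused: unauthorized")
  id <- sprintf("s%04d", server$nextId)
  server$nextId <- server$nextId + 1L
  ses <- new.env(parent = emptyenv())
  ses$id <- id
  ses$open <- TRUE
  ses$volume <- NULL
  ses$seriesId <- NULL
  ses$state <- stateModel()
  ses$codec <- NULL
  ses$viewport <- as.integer(server$config$viewport)
  ses$clients <- list()
  server$sessions[[id]] <- ses
  catalog <- .whitelistedCatalog(server$volumes)
  .logWire(server, "server->client", "catalog",
           as.character(jsonlite::toJSON(catalog, auto_unbox = TRUE)), id)
  list(sessionId = id, address = address, catalog = catalog)
}

.defaultWindow <- function(modality) {
  if (modality == "CTA") c(center = 150, width = 600)
  else c(center = 40, width = 80)        # brain window
}

.defaultSessionState <- function(volume) {
  d <- dim(volume@voxels)
  midMm <- (ceiling(d[3] / 2) - 1) * volume@spacing[3]
  wl <- .defaultWindow(volume@modality)
  stateModel(list(
    "view/mode" = "2D",
    "view/plane/axis" = "axial",
    "view/plane/sliceMm" = midMm,
    "view/wl/center" = as.numeric(wl[["center"]]),
    "view/wl/width" = as.numeric(wl[["width"]]),
    "view/transform/panX" = 0,
    "view/transform/panY" = 0,
    "view/transform/zoom" = 1,
    "view/transform/rotation" = 0,
    "view/preset" = "soft_tissue"))
}

## render the current state of a session to an 8-bit viewport image
.renderSession <- function(server, ses) {
  vol <- ses$volume
  st <- ses$state
  vp <- ses$viewport
  tr <- viewTransform(pan = c(getLeaf(st, "view/transform/panX"),
                              getLeaf(st, "view/transform/panY")),
                      zoom = getLeaf(st, "view/transform/zoom"),
                      rotation = getLeaf(st, "view/transform/rotation"))
  mode <- getLeaf(st, "view/mode")
  if (mode == "3D") {
    base <- renderRaycast(vol, defaultCamera(vol, outSize = c(vp[2], vp[2])),
                          renderingPreset(getLeaf(st, "view/preset")),
                          stepMm = max(vol@spacing))
    applyView(base, tr, vp, background = server$config$background)
  } else {
    wl <- windowLevel(getLeaf(st, "view/wl/center"),
                      max(1, getLeaf(st, "view/wl/width")))
    renderOne <- function(sliceMm, viewport) {
      plane <- orthogonalPlane(vol, getLeaf(st, "view/plane/axis"), sliceMm)
      img <- applyWindow(extractSlice(vol, plane), wl)
      applyView(img, tr, viewport, background = server$config$background)
    }
    sliceMm <- getLeaf(st, "view/plane/sliceMm")
    if (mode == "2D-side-by-side") {
      ## two viewports sharing one state tree: current and next slice
      half <- c(vp[1], vp[2] %/% 2L)
      nextMm <- min(sliceMm + vol@spacing[3],
                    (dim(vol@voxels)[3] - 1) * vol@spacing[3])
      out <- matrix(server$config$background, vp[1], vp[2])
      out[, seq_len(half[2])] <- renderOne(sliceMm, half)
      out[, (vp[2] - half[2] + 1L):vp[2]] <- renderOne(nextMm, half)
      out
    } else {
      renderOne(sliceMm, vp)
    }
  }
}

.broadcast <- function(server, ses, type, payload) {
  .logWire(server, "server->client", type, payload, ses$id)
  for (cl in ses$clients) .clientReceive(cl, type, payload)
}

.streamFrame <- function(server, ses, interactive = FALSE,
                         forceKeyframe = FALSE) {
  img <- .renderSession(server, ses)
  res <- encodeFrame(ses$codec, img, interactive = interactive,
                     forceKeyframe = forceKeyframe)
  ses$codec <- res$state
  .broadcast(server, ses, "frame", packFrame(res$frame))
  res$frame
}

#' Select a series into a session
#'
#' Loads the volume server-side, resets the codec, initializes the view
#' state (middle axial slice, modality-default window) and streams the first
#' keyframe plus a full-state resync diff.
#'
#' @param server a \code{TeleServer}.
#' @param sessionId id from [connectSession()].
#' @param seriesId catalog series id.
#' @return \code{list(frame = EncodedFrame, diff = StateDiff)}.
#' @export
selectSeries <- function(server, sessionId, seriesId) {
  ses <- .getSession(server, sessionId)
  vol <- server$volumes[[seriesId]]
  if (is.null(vol)) stop("not found: series ", seriesId)
  ses$volume <- vol
  ses$seriesId <- seriesId
  ses$codec <- newCodecState(server$config$keyframeInterval)
  diff <- fullStateDiff(.defaultSessionState(vol))
  ses$state <- applyDiff(stateModel(), diff)   # adopt the resync revision
  .broadcast(server, ses, "diff", serializeDiff(diff))
  frame <- .streamFrame(server, ses, interactive = FALSE)
  list(frame = frame, diff = diff)
}

.EVENT_KINDS <- c("wl_delta", "pan", "zoom", "rotate", "scroll_slice",
                  "set_mode", "set_preset", "probe")

#' Create an interaction event
#'
#' @param kind one of wl_delta, pan, zoom, rotate, scroll_slice, set_mode,
#'   set_preset, probe.
#' @param payload kind-specific numbers (or strings for set_mode /
#'   set_preset; a rectangle for probe).
#' @param interactive TRUE while a drag is in progress (streams at JPEG
#'   quality 25), FALSE on release (quality 100).
#' @return an interaction event list.
#' @export
interactionEvent <- function(kind, payload = NULL, interactive = FALSE) {
  if (!kind %in% .EVENT_KINDS) stop("bad event: unknown kind '", kind, "'")
  list(kind = kind, payload = payload, interactive = isTRUE(interactive))
}

.checkPayload <- function(e, n) {
  if (length(e$payload) != n || !is.numeric(e$payload))
    stop("bad event: ", e$kind, " expects ", n, " numeric value(s)")
  as.numeric(e$payload)
}

#' Handle a client interaction event
#'
#' Mutates the session state, re-renders server-side and streams the changed
#' blocks (quality 25 while \code{interactive}, 100 otherwise). Probe events
#' leave the frame untouched and return textual HU statistics computed on
#' the original data.
#'
#' @param server a \code{TeleServer}.
#' @param sessionId an open session with a selected series.
#' @param event an [interactionEvent()].
#' @return \code{list(frame, diff, text)}; \code{frame} is NULL for probes.
#' @export
handleEvent <- function(server, sessionId, event) {
  ses <- .getSession(server, sessionId)
  if (is.null(ses$volume)) stop("bad event: no series selected")
  if (is.null(event$kind) || !event$kind %in% .EVENT_KINDS)
    stop("bad event: unknown kind")
  .logWire(server, "client->server", "event",
           as.character(jsonlite::toJSON(event, auto_unbox = TRUE)), ses$id)
  vol <- ses$volume
  st <- ses$state
  if (event$kind == "probe") {
    p <- .checkPayload(event, 4)
    k <- round(getLeaf(st, "view/plane/sliceMm") / vol@spacing[3]) + 1
    pr <- huProbe(vol, k, p)
    text <- as.character(jsonlite::toJSON(list(
      slice = k, mean = pr@mean, sd = pr@sd, min = pr@min, max = pr@max,
      count = pr@count), auto_unbox = TRUE, digits = NA))
    .broadcast(server, ses, "probe_text", text)
    return(list(frame = NULL, diff = NULL, text = text))
  }
  bump <- function(path, delta) setLeaf(st, path, getLeaf(st, path) + delta)
  st <- switch(event$kind,
    wl_delta = {
      p <- .checkPayload(event, 2)
      s1 <- setLeaf(st, "view/wl/center", getLeaf(st, "view/wl/center") + p[1])
      setLeaf(s1, "view/wl/width",
              max(1, getLeaf(s1, "view/wl/width") + p[2]))
    },
    pan = {
      p <- .checkPayload(event, 2)
      s1 <- bump("view/transform/panX", p[1])
      setLeaf(s1, "view/transform/panY",
              getLeaf(s1, "view/transform/panY") + p[2])
    },
    zoom = {
      p <- .checkPayload(event, 1)
      if (p <= 0) stop("invalid zoom")
      setLeaf(st, "view/transform/zoom",
              getLeaf(st, "view/transform/zoom") * p)
    },
    rotate = bump("view/transform/rotation", .checkPayload(event, 1)),
    scroll_slice = {
      p <- .checkPayload(event, 1)
      maxMm <- (dim(vol@voxels)[3] - 1) * vol@spacing[3]
      setLeaf(st, "view/plane/sliceMm",
              min(maxMm, max(0, getLeaf(st, "view/plane/sliceMm") + p)))
    },
    set_mode = {
      if (!event$payload %in% c("2D", "2D-side-by-side", "3D"))
        stop("bad event: unknown mode")
      setLeaf(st, "view/mode", event$payload)
    },
    set_preset = {
      renderingPreset(event$payload)     # validates the name
      setLeaf(st, "view/preset", event$payload)
    })
  diff <- computeDiff(ses$state, st)
  ses$state <- applyDiff(ses$state, diff)
  .broadcast(server, ses, "diff", serializeDiff(diff))
  frame <- .streamFrame(server, ses, interactive = isTRUE(event$interactive))
  list(frame = frame, diff = diff, text = NULL)
}

#' Close a session
#'
#' Releases the server-side volume and codec state and tells attached
#' clients to blank their canvas and purge cached state. Idempotent: a
#' second disconnect is a no-op.
#'
#' @param server a \code{TeleServer}.
#' @param sessionId session to close.
#' @export
disconnectSession <- function(server, sessionId) {
  ses <- server$sessions[[sessionId]]
  if (is.null(ses) || !ses$open) return(invisible(NULL))
  ses$open <- FALSE
  ses$volume <- NULL
  ses$codec <- NULL
  ses$state <- stateModel()
  for (cl in ses$clients) .clientPurge(cl)
  ses$clients <- list()
  invisible(NULL)
}

## --- reference client ------------------------------------------------------

#' A scriptable reference client
#'
#' Connects to an in-process server, then maintains a decoded canvas and a
#' synchronized state tree purely from wire messages. Several clients may
#' attach to one session; all receive identical traffic.
#'
#' @param server a \code{TeleServer}.
#' @param token shared token.
#' @param address optional server address (defaults to the packaged one).
#' @param sessionId attach to an existing session instead of opening a new
#'   one (collaboration).
#' @return a \code{TeleClient} object (environment).
#' @export
referenceClient <- function(server, token, address = NULL, sessionId = NULL) {
  cl <- new.env(parent = emptyenv())
  if (is.null(sessionId)) {
    conn <- connectSession(server, token, address)
    cl$sessionId <- conn$sessionId
    cl$catalog <- conn$catalog
  } else {
    ses0 <- .getSession(server, sessionId)
    cl$sessionId <- sessionId
    cl$catalog <- .whitelistedCatalog(server$volumes)
  }
  cl$canvas <- NULL
  cl$state <- stateModel()
  cl$open <- TRUE
  class(cl) <- "TeleClient"
  ses <- .getSession(server, cl$sessionId)
  ses$clients[[length(ses$clients) + 1L]] <- cl
  if (!is.null(ses$volume)) {
    ## late joiner: full-state resync plus a keyframe for everyone
    resync <- serializeDiff(fullStateDiff(ses$state))
    .logWire(server, "server->client", "diff", resync, ses$id)
    .clientReceive(cl, "diff", resync)
    .streamFrame(server, ses, interactive = FALSE, forceKeyframe = TRUE)
  }
  cl
}

.clientReceive <- function(client, type, payload) {
  if (!client$open) return(invisible(NULL))
  if (type == "frame") {
    frame <- unpackFrame(payload)
    client$canvas <- decodeFrame(client$canvas, frame)
  } else if (type == "diff") {
    diff <- parseDiff(payload)
    client$state <- applyDiff(client$state, diff)
  } else if (type == "probe_text") {
    client$lastProbe <- payload
  }
  invisible(NULL)
}

.clientPurge <- function(client) {
  ## the confidentiality contract on exit: blank image, volatile cache
  ## cleared
  client$canvas <- NULL
  client$state <- stateModel()
  client$catalog <- NULL
  client$lastProbe <- NULL
  client$open <- FALSE
  invisible(NULL)
}

#' Inspect a client's volatile cache
#'
#' @param client a \code{TeleClient}.
#' @return list with the canvas, state leaf count and catalog entry count —
#'   all empty after disconnect.
#' @export
clientCache <- function(client) {
  list(canvas = client$canvas,
       stateLeaves = length(client$state@leaves),
       catalogEntries = length(client$catalog),
       open = client$open)
}

#' Assert the confidentiality contract over a session's wire traffic
#'
#' Checks that every logged wire message is one of the allowed structured
#' types (catalog text, packed encoded frame, state diff, probe text, event
#' text), that frame bytes parse as the documented wire format, that no
#' message embeds a DICOM file (no "DICM" magic), and that textual messages
#' carry no patient-identifying keys.
#'
#' @param server a \code{TeleServer}.
#' @return invisibly TRUE; stops with a message on any violation.
#' @export
assertConfidential <- function(server) {
  allowed <- c("catalog", "frame", "diff", "probe_text", "event")
  forbidden <- c("PatientName", "PatientID", "patient_name", "patient_id")
  for (i in seq_along(server$wireLog)) {
    msg <- server$wireLog[[i]]
    if (!msg$type %in% allowed)
      stop("confidentiality violation: unexpected wire message type '",
           msg$type, "'")
    if (msg$type == "frame") {
      if (!is.raw(msg$payload))
        stop("confidentiality violation: frame message is not binary")
      if (length(grepRaw("DICM", msg$payload, all = FALSE)) > 0)
        stop("confidentiality violation: DICOM payload on the wire (message ",
             i, ")")
      unpackFrame(msg$payload)           # must be a well-formed frame
    } else {
      if (!is.character(msg$payload))
        stop("confidentiality violation: non-frame message must be text")
      if (any(vapply(forbidden, grepl, logical(1), x = msg$payload,
                     fixed = TRUE)))
        stop("confidentiality violation: identifying key in message ", i)
      if (grepl("DICM", msg$payload, fixed = TRUE))
        stop("confidentiality violation: DICOM content in message ", i)
    }
  }
  invisible(TRUE)
}

#' Replay a recorded interaction script against a phantom
#'
#' Builds a fresh server from the phantom spec, connects a reference client,
#' selects the series, applies the events in order and returns the decoded
#' client canvas together with the server for inspection. With fixed seeds
#' and codec settings the decoded canvas is byte-identical across runs.
#'
#' @param spec a [PhantomSpec-class].
#' @param events list of [interactionEvent()]s.
#' @param token shared token (defaults to the demo token).
#' @param config server config overrides.
#' @return \code{list(canvas, client, server)}.
#' @export
replayScript <- function(spec, events, token = "phantom-token",
                         config = list()) {
  ph <- if (spec@kind == "NCCT") generateNcct(spec) else generateCta(spec)
  srv <- teleServer(list(phantom = ph$volume), token = token, config = config)
  cl <- referenceClient(srv, token)
  selectSeries(srv, cl$sessionId, "phantom")
  for (e in events) handleEvent(srv, cl$sessionId, e)
  list(canvas = cl$canvas, client = cl, server = srv)
}
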