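# Session lifecycle, event streaming, multi-client sharing and the
# confidentiality contract.

smallServer <- function(spec = tinyNcctSpec(noiseSd = 2, seed = 4,
                                            gridSize = c(48L, 48L, 8L)),
                        viewport = c(96L, 64L), ...) {
  ph <- if (spec@kind == "NCCT") generateNcct(spec) else generateCta(spec)
  teleServer(list(phantom = ph$volume),
             config = list(viewport = viewport, ...))
}

test_that("connect authenticates and returns an identifier-free catalog", {
  srv <- smallServer()
  expect_error(connectSession(srv, "wrong-token"), "unauthorized")
  conn <- connectSession(srv, "phantom-token")
  expect_equal(conn$address, defaultServerAddress())
  expect_equal(length(conn$catalog), 1L)
  keys <- names(conn$catalog[[1]])
  expect_true("seriesId" %in% keys)
  expect_false(any(grepl("Patient", keys)))

  # two phantom series -> two catalog entries, still clean
  ph2 <- generateCta(tinyCtaSpec(gridSize = c(32L, 32L, 8L)))
  srv2 <- teleServer(list(a = ph2$volume, b = ph2$volume))
  conn2 <- connectSession(srv2, "phantom-token", address = "rsp://example:9")
  expect_equal(conn2$address, "rsp://example:9")
  expect_equal(length(conn2$catalog), 2L)
})

test_that("selecting a series streams a keyframe matching the offline render", {
  srv <- smallServer()
  cl <- referenceClient(srv, "phantom-token")
  res <- selectSeries(srv, cl$sessionId, "phantom")
  expect_true(res$frame@keyframe)
  expect_equal(res$frame@quality, 100L)

  # offline render of the same default view (middle axial slice, brain
  # window, identity transform)
  vol <- srv$volumes$phantom
  d <- dim(voxelData(vol))
  k <- ceiling(d[3] / 2)
  plane <- orthogonalPlane(vol, "axial", (k - 1) * voxelSpacing(vol)[3])
  img <- applyWindow(extractSlice(vol, plane), windowLevel(40, 80))
  expected <- applyView(img, viewTransform(), c(96L, 64L))
  expect_lte(max(abs(cl$canvas - expected)), 2)   # q=100 JPEG tolerance

  expect_error(selectSeries(srv, cl$sessionId, "nope"), "not found")
  # re-selecting resets the codec: a fresh keyframe with sequence 1
  res2 <- selectSeries(srv, cl$sessionId, "phantom")
  expect_true(res2$frame@keyframe)
  expect_equal(res2$frame@sequenceNumber, 1L)

  disconnectSession(srv, cl$sessionId)
  expect_error(selectSeries(srv, cl$sessionId, "phantom"), "session closed")
})

test_that("events honour the interactive quality policy and the no-change rule", {
  srv <- smallServer()
  cl <- referenceClient(srv, "phantom-token")
  selectSeries(srv, cl$sessionId, "phantom")

  drag <- handleEvent(srv, cl$sessionId,
                      interactionEvent("wl_delta", c(5, 0), interactive = TRUE))
  expect_equal(drag$frame@quality, 25L)
  release <- handleEvent(srv, cl$sessionId,
                         interactionEvent("wl_delta", c(0, 0),
                                          interactive = FALSE))
  expect_equal(release$frame@quality, 100L)

  still <- handleEvent(srv, cl$sessionId, interactionEvent("pan", c(0, 0)))
  expect_equal(length(still$frame@blocks), 0L)
  expect_equal(length(still$diff@upserts), 0L)

  expect_error(handleEvent(srv, cl$sessionId,
                           list(kind = "teleport", payload = 1)),
               "bad event")
  expect_error(handleEvent(srv, cl$sessionId,
                           interactionEvent("pan", c(1, 2, 3))), "bad event")
})

test_that("probe events return raw-HU statistics as text, not frames", {
  spec <- tinyNcctSpec()                 # zero noise: exact insert HU
  ph <- generateNcct(spec)
  srv <- teleServer(list(phantom = ph$volume),
                    config = list(viewport = c(96L, 64L)))
  cl <- referenceClient(srv, "phantom-token")
  selectSeries(srv, cl$sessionId, "phantom")

  hem <- arrayInd(lesionMasks(ph$truth)[[1]], dim(voxelData(ph$volume)))
  k <- round(stats::median(hem[, 3]))
  ns <- dim(voxelData(ph$volume))[3]
  handleEvent(srv, cl$sessionId, interactionEvent(
    "scroll_slice", (k - ceiling(ns / 2)) * voxelSpacing(ph$volume)[3]))
  onSlice <- hem[hem[, 3] == k, , drop = FALSE]
  r <- round(mean(onSlice[, 1])); cc <- round(mean(onSlice[, 2]))
  res <- handleEvent(srv, cl$sessionId,
                     interactionEvent("probe", c(r, r, cc, cc)))
  expect_null(res$frame)
  stats <- jsonlite::fromJSON(res$text)
  expect_equal(stats$mean, 70)           # configured hemorrhage HU
  expect_equal(stats$sd, 0)
})

test_that("two clients on one session receive identical frames and state", {
  srv <- smallServer()
  cl1 <- referenceClient(srv, "phantom-token")
  selectSeries(srv, cl1$sessionId, "phantom")
  cl2 <- referenceClient(srv, "phantom-token", sessionId = cl1$sessionId)
  expect_identical(cl2$canvas, cl1$canvas)        # resynced on attach

  for (e in list(interactionEvent("zoom", 2, interactive = TRUE),
                 interactionEvent("scroll_slice", 5),
                 interactionEvent("set_mode", "2D-side-by-side")))
    handleEvent(srv, cl1$sessionId, e)

  expect_identical(cl1$canvas, cl2$canvas)
  expect_identical(stateLeaves(cl1$state), stateLeaves(cl2$state))
  expect_identical(stateLeaves(cl1$state),
                   stateLeaves(srv$sessions[[cl1$sessionId]]$state))
})

test_that("disconnect clears the client cache and rejects further events", {
  srv <- smallServer()
  cl <- referenceClient(srv, "phantom-token")
  selectSeries(srv, cl$sessionId, "phantom")
  handleEvent(srv, cl$sessionId, interactionEvent("zoom", 1.5))
  expect_false(is.null(clientCache(cl)$canvas))

  disconnectSession(srv, cl$sessionId)
  cache <- clientCache(cl)
  expect_null(cache$canvas)              # blank image on exit
  expect_equal(cache$stateLeaves, 0L)    # volatile state purged
  expect_equal(cache$catalogEntries, 0L)
  expect_error(handleEvent(srv, cl$sessionId, interactionEvent("zoom", 2)),
               "session closed")
  expect_silent(disconnectSession(srv, cl$sessionId))   # idempotent
})

test_that("wire traffic carries only structured messages, never DICOM or raw pixels", {
  srv <- smallServer()
  cl <- referenceClient(srv, "phantom-token")
  selectSeries(srv, cl$sessionId, "phantom")
  for (e in demoEventScript()) handleEvent(srv, cl$sessionId, e)
  handleEvent(srv, cl$sessionId, interactionEvent("probe", c(10, 20, 10, 20)))
  expect_true(assertConfidential(srv))
  types <- vapply(srv$wireLog, function(m) m$type, character(1))
  expect_true(all(types %in% c("catalog", "frame", "diff", "probe_text",
                               "event")))
  # probe text exposes summary statistics only
  probeMsgs <- srv$wireLog[types == "probe_text"]
  expect_gt(length(probeMsgs), 0)
  keys <- names(jsonlite::fromJSON(probeMsgs[[1]]$payload))
  expect_true(all(keys %in% c("slice", "mean", "sd", "min", "max", "count")))
})

test_that("a replayed event script yields byte-identical canvases", {
  spec <- tinyNcctSpec(noiseSd = 3, seed = 7, gridSize = c(48L, 48L, 8L))
  run1 <- replayScript(spec, demoEventScript(),
                       config = list(viewport = c(96L, 64L)))
  run2 <- replayScript(spec, demoEventScript(),
                       config = list(viewport = c(96L, 64L)))
  expect_identical(run1$canvas, run2$canvas)
  expect_identical(lapply(run1$server$wireLog, function(m) m$payload),
                   lapply(run2$server$wireLog, function(m) m$payload))
})
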