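# Block-delta frame codec: change detection, quality policy, round trips,
# wire format.

# a smooth synthetic viewport frame (windowed-CT-like content)
smoothFrame <- function(rows = 480, cols = 320, phase = 0) {
  r <- matrix(seq_len(rows), rows, cols)
  cc <- matrix(seq_len(cols), rows, cols, byrow = TRUE)
  img <- 127 + 90 * sin(r / 40 + phase) * cos(cc / 55)
  storage.mode(img) <- "integer"
  img
}

test_that("unchanged frames transmit zero blocks; one pixel means one block", {
  st <- newCodecState()
  img <- smoothFrame()
  r1 <- encodeFrame(st, img, interactive = FALSE)
  expect_true(r1$frame@keyframe)
  expect_equal(length(r1$frame@blocks), 40 * 60)   # 320x480 -> 2400 blocks

  r2 <- encodeFrame(r1$state, img)
  expect_equal(length(r2$frame@blocks), 0L)
  expect_false(r2$frame@keyframe)

  img2 <- img; img2[101, 205] <- img2[101, 205] + 1L
  r3 <- encodeFrame(r2$state, img2)
  expect_equal(length(r3$frame@blocks), 1L)
  expect_equal(r3$frame@blocks[[1]]$row, ceiling(101 / 8))
  expect_equal(r3$frame@blocks[[1]]$col, ceiling(205 / 8))
})

test_that("quality policy: 25 while interactive, 100 when static", {
  st <- newCodecState()
  img <- smoothFrame()
  drag <- encodeFrame(st, img, interactive = TRUE)
  expect_equal(drag$frame@quality, 25L)
  release <- encodeFrame(drag$state, smoothFrame(phase = 1),
                         interactive = FALSE)
  expect_equal(release$frame@quality, 100L)
})

test_that("quality-100 keyframe round trip stays within 2 gray levels", {
  st <- newCodecState()
  img <- smoothFrame(96, 120)
  r <- encodeFrame(st, img, interactive = FALSE)
  canvas <- decodeFrame(NULL, r$frame)
  expect_lte(max(abs(canvas - img)), 2)
})

test_that("payload bytes are monotone in quality for the same frame pair", {
  base <- smoothFrame(96, 120)
  nxt <- smoothFrame(96, 120, phase = 0.7)
  st <- encodeFrame(newCodecState(), base)$state
  q25 <- encodeFrame(st, nxt, interactive = TRUE)$frame
  q100 <- encodeFrame(st, nxt, interactive = FALSE)$frame
  expect_equal(length(q25@blocks), length(q100@blocks))
  expect_lte(payloadBytes(q25), payloadBytes(q100))
})

test_that("delta updates reproduce the encoder input within JPEG tolerance", {
  st <- newCodecState()
  img <- smoothFrame(96, 120)
  r1 <- encodeFrame(st, img)
  canvas <- decodeFrame(NULL, r1$frame)
  img2 <- img
  img2[17:40, 33:56] <- 255L - img2[17:40, 33:56]
  r2 <- encodeFrame(r1$state, img2)
  expect_gt(length(r2$frame@blocks), 0)
  expect_lt(length(r2$frame@blocks), 96 * 120 / 64)
  canvas <- decodeFrame(canvas, r2$frame)
  expect_lte(max(abs(canvas - img2)), 2)

  # zero-block frame leaves the canvas untouched
  r3 <- encodeFrame(r2$state, img2)
  expect_identical(decodeFrame(canvas, r3$frame), canvas)
})

test_that("randomized update sequences keep full canvas coverage and drift bounded", {
  set.seed(99)
  st <- newCodecState(keyframeInterval = 10L)
  img <- smoothFrame(64, 80)
  r <- encodeFrame(st, img)
  st <- r$state
  canvas <- decodeFrame(NULL, r$frame)
  covered <- matrix(TRUE, 64, 80)        # keyframe covers everything
  for (i in 1:25) {
    img <- img
    nEdit <- sample(0:3, 1)
    for (e in seq_len(nEdit)) {
      r0 <- sample(1:56, 1); c0 <- sample(1:72, 1)
      img[r0:(r0 + 7), c0:(c0 + 7)] <-
        sample(0:255, 64, TRUE)
    }
    res <- encodeFrame(st, img, interactive = sample(c(TRUE, FALSE), 1))
    st <- res$state
    canvas <- decodeFrame(canvas, res$frame)
    expect_true(all(dim(canvas) == c(64, 80)))
    if (res$frame@keyframe && res$frame@quality == 100L) {
      # a static keyframe resynchronizes within the q=100 round-trip bound
      expect_lte(max(abs(canvas - img)), 2)
    }
  }
  # force a final static keyframe: exact resynchronization bound
  res <- encodeFrame(st, img, interactive = FALSE, forceKeyframe = TRUE)
  canvas <- decodeFrame(canvas, res$frame)
  expect_lte(max(abs(canvas - img)), 2)
})

test_that("dimension changes require a reset and periodic keyframes fire", {
  st <- encodeFrame(newCodecState(), smoothFrame(32, 32))$state
  expect_error(encodeFrame(st, smoothFrame(40, 40)), "frame size changed")
  ok <- encodeFrame(st, smoothFrame(40, 40), forceKeyframe = TRUE)
  expect_true(ok$frame@keyframe)

  st <- newCodecState(keyframeInterval = 3L)
  img <- smoothFrame(16, 16)
  r1 <- encodeFrame(st, img)                     # keyframe (first)
  r2 <- encodeFrame(r1$state, img)
  r3 <- encodeFrame(r2$state, img)
  r4 <- encodeFrame(r3$state, img)               # every 3rd frame: fresh key
  expect_false(r2$frame@keyframe || r3$frame@keyframe)
  expect_true(r4$frame@keyframe)
  expect_equal(vapply(list(r1, r2, r3, r4), function(x) x$frame@sequenceNumber,
                      integer(1)), 1:4)
})

test_that("corrupt payloads identify the failing block", {
  r <- encodeFrame(newCodecState(), smoothFrame(16, 16))
  bad <- r$frame
  bad@blocks[[2]]$payload <- as.raw(c(1, 2, 3))
  expect_error(decodeFrame(NULL, bad), "decode failure at block")
})

test_that("compression ratio and the 12:1 static guideline check", {
  expect_equal(compressionRatio(1000, structure(
    new("EncodedFrame", frameSize = c(8L, 8L), keyframe = FALSE,
        quality = 25L, sequenceNumber = 1L,
        blocks = list(list(row = 1L, col = 1L, payload = raw(100)))))),
    10)

  # JPEG of constant content compresses far beyond 12:1 as a whole frame
  img <- matrix(80L, 240, 240)
  whole <- jpeg::writeJPEG(img / 255, raw(), quality = 1.0)
  expect_gt(length(img) / length(whole), 12)
  # and a constant block costs far less than a random one even per-block
  constBlk <- jpeg::writeJPEG(matrix(0.3, 8, 8), raw(), quality = 1.0)
  set.seed(1)
  randBlk <- jpeg::writeJPEG(matrix(stats::runif(64), 8, 8), raw(),
                             quality = 1.0)
  expect_lt(length(constBlk), length(randBlk))

  # the static guideline bound warns when compression exceeds 12:1
  r <- encodeFrame(newCodecState(), matrix(80L, 8L, 8L), interactive = FALSE)
  rawBytes <- 50 * payloadBytes(r$frame)
  expect_warning(ratio <- compressionRatio(rawBytes, r$frame),
                 "exceeds the 12:1 guideline")
  expect_gt(ratio, 12)
  expect_silent(r2 <- compressionRatio(2 * payloadBytes(r$frame), r$frame))

  empty <- encodeFrame(r$state, matrix(80L, 8L, 8L))$frame
  expect_error(compressionRatio(1000, empty), "no traffic")
})

test_that("the wire format round-trips frames bit-exactly", {
  st <- encodeFrame(newCodecState(), smoothFrame(50, 44))  # non-multiple of 8
  img2 <- smoothFrame(50, 44, phase = 2)
  r <- encodeFrame(st$state, img2, interactive = TRUE)
  bytes <- packFrame(r$frame)
  back <- unpackFrame(bytes)
  expect_equal(back@sequenceNumber, r$frame@sequenceNumber)
  expect_equal(back@frameSize, r$frame@frameSize)
  expect_equal(back@quality, r$frame@quality)
  expect_equal(back@keyframe, r$frame@keyframe)
  expect_identical(back@blocks, r$frame@blocks)
  # decoded canvases agree whichever side decodes
  expect_identical(decodeFrame(decodeFrame(NULL, st$frame), back),
                   decodeFrame(decodeFrame(NULL, st$frame), r$frame))
})

test_that("edge blocks are padded for encoding and cropped on decode", {
  img <- smoothFrame(13, 11)             # ragged edges
  r <- encodeFrame(newCodecState(), img)
  canvas <- decodeFrame(NULL, r$frame)
  expect_equal(dim(canvas), c(13L, 11L))
  expect_lte(max(abs(canvas - img)), 2)
})
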