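# Synthetic head-CT phantoms and simulated reader responses.

test_that("zero-noise inserts stamp their configured HU exactly", {
  ph <- generateNcct(tinyNcctSpec())
  vox <- voxelData(ph$volume)
  masks <- lesionMasks(ph$truth)
  expect_equal(unique(vox[masks[[1]]]), 70)       # hemorrhage
  expect_equal(unique(vox[masks[[2]]]), 60)       # dense vessel
  labels <- caseLabels(ph$truth)
  expect_true(labels[["hemorrhage"]] && labels[["dense_vessel"]])
  expect_false(labels[["ischemia"]] || labels[["occlusion"]])
})

test_that("ground-truth masks and case labels are mutually consistent", {
  for (spec in list(tinyNcctSpec(), tinyCtaSpec(), tinyCtaSpec(TRUE))) {
    ph <- if (spec@kind == "NCCT") generateNcct(spec) else generateCta(spec)
    masks <- lesionMasks(ph$truth)
    kinds <- ph$truth@insertKinds
    labels <- caseLabels(ph$truth)
    expect_true(all(lengths(masks) > 0))
    expect_equal(labels[["hemorrhage"]], "hemorrhage" %in% kinds)
    expect_equal(labels[["occlusion"]], "occlusion_gap" %in% kinds)
    expect_equal(labels[["dense_vessel"]], "dense_vessel" %in% kinds)
  }
})

test_that("noise level is recovered and generation is deterministic", {
  spec <- tinyNcctSpec(noiseSd = 5, seed = 42)
  ph1 <- generateNcct(spec)
  ph2 <- generateNcct(spec)
  expect_identical(voxelData(ph1$volume), voxelData(ph2$volume))

  other <- generateNcct(tinyNcctSpec(noiseSd = 5, seed = 43))
  expect_false(identical(voxelData(ph1$volume), voxelData(other$volume)))

  # sample SD over a uniform brain region (>= 1000 voxels) within 10% of 5;
  # integer rounding of stored HU adds ~sqrt(1/12) of quantization variance
  clean <- generateNcct(tinyNcctSpec())
  brain <- which(voxelData(clean$volume) == 35)
  expect_gt(length(brain), 1000)
  sdHat <- stats::sd(voxelData(ph1$volume)[brain])
  expect_lt(abs(sdHat - 5) / 5, 0.10)
})

test_that("phantom volumes round-trip through DICOM exactly", {
  ph <- generateCta(tinyCtaSpec(TRUE, noiseSd = 4, seed = 9))
  dir <- withr::local_tempdir()
  writeDicomSeries(ph$volume, dir)
  vol <- loadSeries(dir)
  expect_identical(voxelData(vol), voxelData(ph$volume))
  expect_equal(modality(vol), "CTA")
})

test_that("invalid inserts are rejected", {
  outside <- phantomSpec("NCCT", gridSize = c(32L, 32L, 8L),
                         inserts = list(sphereInsert("hemorrhage",
                                                     center = c(0.5, 0.5, 1),
                                                     radius = 1)))
  expect_error(generateNcct(outside), "invalid insert")

  gapOnly <- phantomSpec("CTA", gridSize = c(32L, 32L, 8L),
                         inserts = list(tubeInsert("occlusion_gap",
                                                   from = c(5, 5, 2),
                                                   to = c(8, 8, 2),
                                                   radius = 1)))
  expect_error(generateCta(gapOnly), "invalid occlusion")

  expect_error(generateNcct(tinyCtaSpec()))      # kind mismatch
})

test_that("patent vessels project one continuous track, occluded ones two", {
  patent <- generateCta(tinyCtaSpec(occluded = FALSE))
  occluded <- generateCta(tinyCtaSpec(occluded = TRUE))

  trackRuns <- function(ph) {
    masks <- lesionMasks(ph$truth)
    kinds <- ph$truth@insertKinds
    d <- dim(voxelData(ph$volume))
    vessel <- array(FALSE, d)
    vessel[masks[[which(kinds == "vessel")]]] <- TRUE
    if ("occlusion_gap" %in% kinds)
      vessel[masks[[which(kinds == "occlusion_gap")]]] <- FALSE
    proj <- apply(vessel, 2, any)        # projection along the track axis
    countRuns(proj)
  }
  expect_equal(trackRuns(patent), 1L)
  expect_equal(trackRuns(occluded), 2L)

  # the same story on the rendered MIP: bright track broken by the gap
  # (restricted to the rows around the vessel so the skull stays out)
  mipTrack <- function(ph) {
    v <- ph$volume
    k <- ceiling(dim(voxelData(v))[3] / 2)
    p <- orthogonalPlane(v, "axial", (k - 1) * voxelSpacing(v)[3],
                         slabThickness = 6 * voxelSpacing(v)[3])
    sl <- extractSlice(v, p, projection = "max")
    vesselRows <- unique(arrayInd(lesionMasks(ph$truth)[[1]],
                                  dim(voxelData(v)))[, 1])
    bright <- apply(sl[vesselRows, , drop = FALSE] > 150, 2, any)
    countRuns(bright)
  }
  expect_equal(mipTrack(patent), 1L)
  expect_equal(mipTrack(occluded), 2L)
})

test_that("occlusion gaps carve soft-tissue HU into the vessel", {
  ph <- generateCta(tinyCtaSpec(TRUE))
  vox <- voxelData(ph$volume)
  kinds <- ph$truth@insertKinds
  gap <- lesionMasks(ph$truth)[[which(kinds == "occlusion_gap")]]
  expect_equal(unique(vox[gap]), 45)
})

test_that("simulated reader responses follow sens/spec and the seed", {
  truth <- c(rep(TRUE, 18), rep(FALSE, 47))
  expect_identical(simulateReaderResponses(truth, 1, 1, seed = 2), truth)
  expect_false(any(simulateReaderResponses(truth, 0, 1, seed = 2)[1:18]))
  expect_identical(simulateReaderResponses(truth, 0.7, 0.9, seed = 8),
                   simulateReaderResponses(truth, 0.7, 0.9, seed = 8))
  expect_error(simulateReaderResponses(truth, 1.2, 1), "\\[0,1\\]")

  # parameter recovery across seeds (the CTA operating point)
  sensHat <- vapply(1:400, function(s) {
    calls <- simulateReaderResponses(truth, 0.944, 1, seed = s)
    sum(calls[1:18]) / 18
  }, numeric(1))
  se <- sqrt(0.944 * (1 - 0.944) / (18 * 400))
  expect_lt(abs(mean(sensHat) - 0.944), 4 * se)
  expect_equal(max(vapply(1:50, function(s)
    sum(simulateReaderResponses(truth, 0.944, 1, seed = s)[19:65]),
    numeric(1))), 0)                     # spec = 1: never a false positive
})
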