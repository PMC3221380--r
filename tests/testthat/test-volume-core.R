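# DICOM ingestion, window/level mapping and HU probing.

test_that("phantom DICOM round trip preserves HU exactly and sorts shuffled slices", {
  ph <- generateNcct(tinyNcctSpec(noiseSd = 3, seed = 11))
  dir <- withr::local_tempdir()
  writeDicomSeries(ph$volume, dir)
  vol <- loadSeries(dir)
  expect_identical(voxelData(vol), voxelData(ph$volume))
  expect_equal(voxelSpacing(vol), voxelSpacing(ph$volume), tolerance = 1e-9)

  # shuffle the on-disk order: the loader sorts by position, not name
  files <- list.files(dir, full.names = TRUE)
  shuffled <- withr::local_tempdir()
  perm <- rev(seq_along(files))
  for (i in seq_along(files))
    file.copy(files[perm[i]], file.path(shuffled, sprintf("x%02d.dcm", i)))
  vol2 <- loadSeries(shuffled)
  expect_identical(voxelData(vol2), voxelData(vol))
})

test_that("in-plane spacing follows the 220-mm field of view at 512 pixels", {
  # 220 / 512 = 0.4297 mm; fixture grids share that spacing
  ph <- generateNcct(tinyNcctSpec())
  dir <- withr::local_tempdir()
  writeDicomSeries(ph$volume, dir)
  vol <- loadSeries(dir)
  expect_equal(voxelSpacing(vol)[1:2], rep(220 / 512, 2), tolerance = 1e-9)
})

test_that("rescale slope/intercept turns stored values into HU", {
  # stored value 1024 with slope 1, intercept -1024 must read back as 0 HU
  v <- imageVolume(array(0, c(8, 8, 3)), spacing = c(1, 1, 2))
  dir <- withr::local_tempdir()
  writeDicomSeries(v, dir)
  parsed <- readDicomFile(list.files(dir, full.names = TRUE)[1])
  expect_equal(unique(as.vector(parsed$pixels)), 1024)
  expect_equal(parsed[["0028,1052"]], -1024)
  vol <- loadSeries(dir)
  expect_equal(unique(as.vector(voxelData(vol))), 0)
})

test_that("pydicom independently reads back the written series", {
  py <- Sys.which("python")
  expect_true(nzchar(py))
  ph <- generateNcct(tinyNcctSpec(noiseSd = 2, seed = 5,
                                  gridSize = c(16L, 16L, 4L)))
  dir <- withr::local_tempdir()
  writeDicomSeries(ph$volume, dir)
  out <- file.path(dir, "hu.txt")
  script <- sprintf(paste0(
    "import glob, pydicom, numpy as np\n",
    "fs = sorted(glob.glob('%s/*.dcm'))\n",
    "v = np.stack([pydicom.dcmread(f).pixel_array for f in fs]).astype(np.int64) - 1024\n",
    "np.savetxt('%s', v.flatten()[None], fmt='%%d')\n"), dir, out)
  sf <- file.path(dir, "read.py"); writeLines(script, sf)
  expect_equal(system2(py, sf), 0L)
  y <- scan(out, quiet = TRUE)
  oracle <- aperm(array(y, dim = c(16, 16, 4)), c(2, 1, 3))
  expect_equal(max(abs(oracle - voxelData(ph$volume))), 0)
})

test_that("malformed series are rejected with specific errors", {
  ph <- generateNcct(tinyNcctSpec(gridSize = c(16L, 16L, 6L)))
  dir <- withr::local_tempdir()
  writeDicomSeries(ph$volume, dir)
  files <- sort(list.files(dir, full.names = TRUE))

  dup <- withr::local_tempdir()              # duplicate slice position
  file.copy(files, dup)
  file.copy(files[2], file.path(dup, "dup.dcm"))
  expect_error(loadSeries(dup), "inconsistent series")

  gap <- withr::local_tempdir()              # missing middle slice
  file.copy(files[-3], gap)
  expect_error(loadSeries(gap), "non-uniform spacing")

  mixed <- withr::local_tempdir()            # mixed dimensions in one series
  uid <- "1.2.826.0.1.3680043.9777.4242"
  writeDicomSeries(ph$volume, mixed, seriesUid = uid)
  other <- generateNcct(tinyNcctSpec(gridSize = c(24L, 24L, 6L)))
  shifted <- imageVolume(voxelData(other$volume),
                         spacing = voxelSpacing(other$volume),
                         origin = c(0, 0, 1000), modality = "NCCT")
  writeDicomSeries(shifted, mixed, filePrefix = "other", seriesUid = uid)
  expect_error(loadSeries(mixed), "heterogeneous series")
})

test_that("anonymized loads expose only whitelisted attributes", {
  ph <- generateNcct(tinyNcctSpec(gridSize = c(16L, 16L, 4L)))
  dir <- withr::local_tempdir()
  writeDicomSeries(ph$volume, dir, patientName = "Doe^Jane",
                   patientId = "SECRET-42")
  anon <- volumeAttributes(loadSeries(dir))
  expect_false(any(c("PatientName", "PatientID") %in% names(anon)))
  expect_true(all(c("SeriesDescription", "Modality", "SliceCount") %in%
                    names(anon)))
  full <- volumeAttributes(loadSeries(dir, anonymize = FALSE))
  expect_equal(full$PatientName, "Doe^Jane")
})

test_that("window mapping follows the DICOM linear ramp", {
  # centre 40, width 80: 0 HU -> 0 and 80 HU -> 255 (ramp endpoints)
  img <- matrix(c(-50, 0, 40, 80, 200), 1)
  out <- applyWindow(img, windowLevel(40, 80))
  expect_equal(out[1, c(1, 2, 4, 5)], c(0L, 0L, 255L, 255L))
  expect_true(abs(out[1, 3] - 127.5) <= 2)   # centre maps to mid-gray

  # constant image at the centre is constant mid-gray
  flat <- applyWindow(matrix(40, 5, 5), windowLevel(40, 400))
  expect_equal(length(unique(as.vector(flat))), 1L)
  expect_true(abs(flat[1, 1] - 127.5) <= 2)

  # width 1 degenerates to a binary threshold at the centre
  bin <- applyWindow(matrix(c(39, 40, 41), 1), windowLevel(40, 1))
  expect_equal(as.vector(bin), c(0L, 255L, 255L))

  expect_error(applyWindow(img, list(center = 40, width = 0)),
               "invalid window")
})

test_that("window mapping is monotone in voxel rank", {
  set.seed(42)
  for (i in 1:20) {
    v <- sort(stats::runif(50, -1200, 2000))
    wl <- windowLevel(stats::runif(1, -100, 300), stats::runif(1, 1, 2000))
    out <- applyWindow(matrix(v, 1), wl)
    expect_true(all(diff(as.vector(out)) >= 0))
  }
})

test_that("HU probes run on raw data, not windowed output", {
  ph <- generateNcct(tinyNcctSpec())              # zero noise
  vol <- ph$volume
  hem <- lesionMasks(ph$truth)[[1]]
  idx <- arrayInd(hem[1], dim(voxelData(vol)))
  pr <- huProbe(vol, idx[3], c(idx[1], idx[1], idx[2], idx[2]))
  expect_equal(pr@mean, 70)                       # configured hemorrhage HU
  expect_equal(pr@sd, 0)
  expect_equal(pr@count, 1)

  # full-slice probe differs from the statistics of the windowed rendering
  win <- applyWindow(voxelData(vol)[, , idx[3]], windowLevel(40, 80))
  full <- huProbe(vol, idx[3], c(1, 48, 1, 48))
  expect_false(isTRUE(all.equal(full@mean, mean(win))))
  expect_true(full@min <= full@mean && full@mean <= full@max)

  expect_error(huProbe(vol, idx[3], c(100, 120, 100, 120)),
               "empty probe region")
  expect_error(huProbe(vol, 99, c(1, 2, 1, 2)), "empty probe region")
})

test_that("contralateral probes on a dense-vessel phantom recover the contrast", {
  spec <- tinyNcctSpec()
  ph <- generateNcct(spec)
  vol <- ph$volume
  vesselIdx <- arrayInd(lesionMasks(ph$truth)[[2]], dim(voxelData(vol)))
  k <- round(stats::median(vesselIdx[, 3]))
  onSlice <- vesselIdx[vesselIdx[, 3] == k, , drop = FALSE]
  r <- round(mean(onSlice[, 1])); c0 <- round(mean(onSlice[, 2]))
  dense <- huProbe(vol, k, c(r, r, c0, c0))
  mirror <- huProbe(vol, k, c(48 + 1 - r, 48 + 1 - r, c0, c0))
  expect_equal(dense@mean, 60)                    # dense vessel HU
  expect_equal(mirror@mean, 35)                   # contralateral parenchyma
  expect_equal(dense@mean - mirror@mean, 25)
})
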