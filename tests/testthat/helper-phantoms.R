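# Shared fixture builders: everything is generated in code at test time.

# Small NCCT phantom with a hemorrhage sphere and a dense-vessel tube.
tinyNcctSpec <- function(noiseSd = 0, seed = 1L, gridSize = c(48L, 48L, 10L)) {
  ext <- (gridSize - 1) * c(220 / 512, 220 / 512, 5)
  ctr <- ext / 2
  ctr[3] <- round(ctr[3] / 5) * 5        # land on a 5-mm slice plane
  zr <- min(5, 0.3 * ext[3])
  phantomSpec("NCCT", gridSize = gridSize, noiseSd = noiseSd, seed = seed,
              inserts = list(
                sphereInsert("hemorrhage",
                             center = ctr - c(0.10 * ext[1], 0.10 * ext[2], 0),
                             radius = max(0.10 * min(ext[1:2]), 0.7)),
                tubeInsert("dense_vessel",
                           from = ctr + c(0.15 * ext[1], 0.10 * ext[2], -zr),
                           to = ctr + c(0.15 * ext[1], 0.10 * ext[2], zr),
                           radius = max(0.05 * min(ext[1:2]), 0.55))))
}

# CTA phantom: one contrast vessel along the column axis, optionally with an
# occlusion gap in its middle third.
tinyCtaSpec <- function(occluded = FALSE, noiseSd = 0, seed = 1L,
                        gridSize = c(48L, 48L, 16L)) {
  ext <- (gridSize - 1) * c(220 / 512, 220 / 512, 0.6)
  ctr <- ext / 2
  ins <- list(tubeInsert("vessel",
                         from = c(ctr[1], ctr[2] - 0.35 * ext[2], ctr[3]),
                         to = c(ctr[1], ctr[2] + 0.35 * ext[2], ctr[3]),
                         radius = 1.0))
  if (occluded)
    ins <- c(ins, list(tubeInsert("occlusion_gap",
                                  from = c(ctr[1], ctr[2] - 0.05 * ext[2], ctr[3]),
                                  to = c(ctr[1], ctr[2] + 0.05 * ext[2], ctr[3]),
                                  radius = 1.4)))
  phantomSpec("CTA", gridSize = gridSize, noiseSd = noiseSd, seed = seed,
              inserts = ins)
}

# The interaction script used by determinism tests and the acceptance run.
demoEventScript <- function() {
  list(interactionEvent("wl_delta", c(10, 20), interactive = TRUE),
       interactionEvent("pan", c(5, -3), interactive = TRUE),
       interactionEvent("zoom", 1.5, interactive = TRUE),
       interactionEvent("zoom", 1, interactive = FALSE),
       interactionEvent("scroll_slice", 5),
       interactionEvent("rotate", 15),
       interactionEvent("set_mode", "2D-side-by-side"),
       interactionEvent("set_mode", "3D"),
       interactionEvent("set_preset", "bone"),
       interactionEvent("set_mode", "2D"))
}

# random state trees for diff/apply property tests
randomStateModel <- function(npaths = 8) {
  paths <- paste0("a/", sample(letters[1:6], npaths, TRUE), "/",
                  sample(1:12, npaths, TRUE))
  paths <- unique(paths)
  leaves <- lapply(seq_along(paths), function(i) {
    switch(sample(3, 1),
           round(stats::runif(1, -100, 100), 3),
           paste0("v", sample(1000, 1)),
           sample(c(TRUE, FALSE), 1))
  })
  names(leaves) <- paths
  stateModel(leaves, revision = sample(0:50, 1))
}

randomStateDiff <- function() {
  n <- sample(0:6, 1)
  up <- lapply(seq_len(n), function(i)
    switch(sample(3, 1),
           stats::runif(1, -1e6, 1e6),
           paste0("éß-", sample(100, 1)),   # unicode strings
           sample(c(TRUE, FALSE), 1)))
  names(up) <- if (n) paste0("p/", seq_len(n), "/", sample(99, n)) else NULL
  dels <- if (sample(c(TRUE, FALSE), 1)) paste0("q/", sample(50, sample(3, 1)))
          else character(0)
  base <- sample(0:100, 1)
  new("StateDiff", upserts = up, deletes = unique(dels),
      baseRevision = as.integer(base),
      newRevision = as.integer(base + sample(1:5, 1)))
}

# order a named list by name (empty lists have NULL names)
sortByName <- function(x) if (length(x)) x[order(names(x))] else x

# count connected runs of TRUE in a logical vector (projection track oracle)
countRuns <- function(x) {
  r <- rle(x)
  sum(r$values)
}
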