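# Independent oracles for the rendering tests: a scalar-loop ray marcher
# sharing no vectorized code with the renderer, and a centred orthographic
# camera looking down +z.

raycastOracle <- function(volume, cam, tf, stepMm, background = 0) {
  dirv <- cam@lookAt - cam@eye
  dirv <- dirv / sqrt(sum(dirv^2))
  right <- c(dirv[2] * cam@up[3] - dirv[3] * cam@up[2],
             dirv[3] * cam@up[1] - dirv[1] * cam@up[3],
             dirv[1] * cam@up[2] - dirv[2] * cam@up[1])
  right <- right / sqrt(sum(right^2))
  upv <- c(right[2] * dirv[3] - right[3] * dirv[2],
           right[3] * dirv[1] - right[1] * dirv[3],
           right[1] * dirv[2] - right[2] * dirv[1])
  nr <- cam@outSize[1]; nc <- cam@outSize[2]
  d <- dim(voxelData(volume))
  corners <- as.matrix(expand.grid(c(1, d[1]), c(1, d[2]), c(1, d[3])))
  cornerMm <- voxelToPatient(volume, corners)
  tRange <- range(cornerMm %*% dirv)
  out <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    vOff <- ((r - 0.5) / nr - 0.5) * 2 * cam@halfExtent[1]
    uOff <- ((cc - 0.5) / nc - 0.5) * 2 * cam@halfExtent[2]
    o <- cam@eye + uOff * right - vOff * upv
    oProj <- sum(o * dirv)
    A <- 0; C <- 0
    for (t in seq(tRange[1] - oProj - stepMm, tRange[2] - oProj + stepMm,
                  by = stepMm)) {
      hu <- sampleVolume(volume, matrix(o + t * dirv, 1))
      op <- stats::approx(tf@hu, tf@opacity, hu, rule = 2)$y
      gr <- stats::approx(tf@hu, tf@gray, hu, rule = 2)$y
      a <- 1 - (1 - op)^(stepMm / 1)
      C <- C + (1 - A) * a * gr
      A <- A + (1 - A) * a
      if (A >= 0.99) break
    }
    out[r, cc] <- floor(min(max(C + (1 - A) * background / 255, 0), 1) * 255 + 0.5)
  }
  out
}

centredCamera <- function(volume, outSize, halfExtent) {
  d <- dim(voxelData(volume))
  ctr <- as.numeric(voxelToPatient(volume, matrix((d + 1) / 2, 1)))
  camera(eye = ctr - c(0, 0, 100), lookAt = ctr, up = c(1, 0, 0),
         halfExtent = halfExtent, outSize = outSize)
}
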