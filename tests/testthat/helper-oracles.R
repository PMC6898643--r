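# Independent brute-force oracles, deliberately written differently from the
# package implementations they check.

# Stack-based scalar flood fill.
bfs_flood_oracle <- function(window, seedXY, connectivity = 8) {
  nr <- nrow(window); nc <- ncol(window)
  out <- matrix(0L, nr, nc)
  sx <- seedXY[1]; sy <- seedXY[2]
  if (window[sy, sx] == 0) return(out)
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  stack <- list(c(sy, sx))
  out[sy, sx] <- 1L
  while (length(stack)) {
    p <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (o in offs) {
      r <- p[1] + o[1]; c <- p[2] + o[2]
      if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
          window[r, c] != 0 && out[r, c] == 0L) {
        out[r, c] <- 1L
        stack[[length(stack) + 1L]] <- c(r, c)
      }
    }
  }
  out
}

# Double-loop pixel confusion counter.
overlay_oracle <- function(pred, ref) {
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j] != 0; r <- ref[i, j] != 0
    if (p && r) tp <- tp + 1
    else if (p && !r) fp <- fp + 1
    else if (!p && r) fn <- fn + 1
  }
  c(tp = tp, fp = fp, fn = fn)
}

# O(n^2) all-pairs Feret diameter (same pixel-extent convention as the
# package: max center distance plus one pixel, times spacing).
feret_oracle <- function(mask, spacingMm) {
  idx <- which(mask != 0, arr.ind = TRUE)
  dmax <- 0
  if (nrow(idx) > 1) {
    for (i in seq_len(nrow(idx) - 1)) for (j in (i + 1):nrow(idx)) {
      d <- sqrt(sum((idx[i, ] - idx[j, ])^2))
      if (d > dmax) dmax <- d
    }
  }
  (dmax + 1) * spacingMm
}

# A small, quick phantom spec (CECT only unless more zones given).
tiny_spec <- function(seed, noiseSd = c(CECT = 0), shift = c(0, 0),
                      rot = 0, irregularity = 0,
                      zones = list(CECT = c(120, 280, 320))) {
  PhantomSpec(rngSeed = seed, gridPx = 64, spacingMm = 0.3,
              coreRadiusMm = 4, coreIrregularity = irregularity,
              ringWidthMm = 1.5, valuesByZone = zones,
              noiseSd = noiseSd, shiftPx = shift, rotationDeg = rot,
              nLandmarks = 3)
}

# Registered (aligned) reference plus image for one phantom case.
align_case <- function(case) {
  tr <- estimateTransform(case@reference, case@truth$imageMarkerXY,
                          case@truth$imageLandmarks)
  applyTransform(case@reference, tr)
}
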