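## necrosis_isolation: binary windowing + seeded region growing.

#' Binary windowing of an image at an upper cutoff
#'
#' A pixel is foreground iff its value lies in the inclusive window
#' \code{[0, upper]}. Marker-sentinel pixels are always excluded (they are
#' rendered far below zero for exactly this reason).
#'
#' @param image an \linkS4class{ImageGrid} or numeric matrix.
#' @param upper upper cutoff in image units.
#' @return integer 0/1 matrix.
#' @export
windowBinary <- function(image, upper) {
  stopifnot(is.finite(upper))
  v <- if (is(image, "ImageGrid")) gridValues(image) else image
  w <- (!is.na(v) & v >= 0 & v <= upper) * 1L
  w[!is.na(v) & v == .MARKER_SENTINEL] <- 0L
  w
}

## Neighbour offsets (dy, dx) for 4- and 8-connectivity.
.conn_offsets <- function(connectivity) {
  if (connectivity == 4) {
    cbind(dy = c(-1L, 1L, 0L, 0L), dx = c(0L, 0L, -1L, 1L))
  } else if (connectivity == 8) {
    cbind(dy = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
          dx = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))
  } else stop("connectivity must be 4 or 8")
}

#' Seeded region growing on a binary window
#'
#' Returns the connected component of the window that contains the seed
#' (empty if the seed pixel itself fails the window). Implemented as a
#' vectorized breadth-first frontier expansion.
#'
#' @param window integer/logical matrix (output of \code{\link{windowBinary}}).
#' @param seedXY seed pixel as (x, y), 1-based.
#' @param connectivity 4 or 8 (default 8).
#' @return integer 0/1 matrix: the grown region.
#' @export
regionGrow <- function(window, seedXY, connectivity = 8) {
  nr <- nrow(window); nc <- ncol(window)
  sx <- as.integer(round(seedXY[1])); sy <- as.integer(round(seedXY[2]))
  if (sx < 1 || sx > nc || sy < 1 || sy > nr)
    stop("seed outside grid bounds")
  out <- matrix(0L, nr, nc)
  if (window[sy, sx] == 0) return(out)
  offs <- .conn_offsets(connectivity)
  win <- window != 0
  visited <- matrix(FALSE, nr, nc)
  frontier <- (sx - 1L) * nr + sy            # linear index, column-major
  visited[frontier] <- TRUE
  while (length(frontier)) {
    rows <- ((frontier - 1L) %% nr) + 1L
    cols <- ((frontier - 1L) %/% nr) + 1L
    nxt <- integer(0)
    for (k in seq_len(nrow(offs))) {
      r2 <- rows + offs[k, 1L]; c2 <- cols + offs[k, 2L]
      ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
      if (!any(ok)) next
      idx <- (c2[ok] - 1L) * nr + r2[ok]
      idx <- idx[win[idx] & !visited[idx]]
      if (length(idx)) {
        visited[idx] <- TRUE
        nxt <- c(nxt, idx)
      }
    }
    frontier <- unique(nxt)
  }
  out[visited] <- 1L
  out
}

#' Isolate the candidate-necrosis region at one threshold
#'
#' Composition of \code{\link{windowBinary}} and \code{\link{regionGrow}}:
#' window the image to \code{[0, upper]}, then keep the connected component
#' containing the seed.
#'
#' @param image an \linkS4class{ImageGrid}.
#' @param upper upper cutoff in image units.
#' @param seedXY seed pixel (x, y); see \code{\link{defaultSeed}}.
#' @param connectivity 4 or 8.
#' @return list with elements \code{mask} (0/1 matrix), \code{threshold},
#'   \code{seed_xy}, \code{n_pixels}.
#' @export
isolateAblation <- function(image, upper, seedXY, connectivity = 8) {
  w <- windowBinary(image, upper)
  m <- regionGrow(w, seedXY, connectivity)
  list(mask = m, threshold = upper, seed_xy = seedXY,
       n_pixels = sum(m))
}

#' Default region-growing seed near the marker
#'
#' The plastic tube sits on the ablation axis, so the necrotic core
#' surrounds the marker. The seed is the lower-quartile-valued pixel of a
#' thin annulus just outside the marker disk (radii 1.2-2.2 mm from the
#' marker centroid): deterministic, inside the core, clearly below any
#' sensible cutoff under noise, yet not so extreme that it falls below the
#' window's zero floor.
#'
#' @param image an \linkS4class{ImageGrid}.
#' @param markerImageXY marker centroid in the image frame, (x, y).
#' @return seed pixel (x, y).
#' @export
defaultSeed <- function(image, markerImageXY) {
  v <- gridValues(image)
  sp <- spacingMm(image)
  nr <- nrow(v); nc <- ncol(v)
  rx <- seq_len(nc); ry <- seq_len(nr)
  dx <- outer(rep(1, nr), rx - markerImageXY[1]) * sp
  dy <- outer(ry - markerImageXY[2], rep(1, nc)) * sp
  rho <- sqrt(dx^2 + dy^2)
  cand <- which(rho > 1.2 & rho <= 2.2 & v != .MARKER_SENTINEL)
  if (!length(cand)) stop("no seed candidates outside the marker disk")
  ord <- cand[order(v[cand])]
  best <- ord[max(1L, ceiling(0.25 * length(ord)))]
  c(((best - 1L) %/% nr) + 1L, ((best - 1L) %% nr) + 1L)
}
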