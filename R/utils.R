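# Internal helpers shared across modules.

#' Shift a matrix by (dr, dc) with edge replication
#'
#' Replicated (reflective at depth 1) padding so border pixels see their own
#' value beyond the frame; this is the convention that makes an all-ones mask
#' produce no outline at the physical border.
#' @noRd
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

#' Rasterize a line segment with Bresenham's algorithm
#'
#' Returns integer (row, col) pixel coordinates, 1-based, inclusive of both
#' endpoints.
#' @noRd
bresenham <- function(r0, c0, r1, c1) {
  r0 <- as.integer(round(r0)); c0 <- as.integer(round(c0))
  r1 <- as.integer(round(r1)); c1 <- as.integer(round(c1))
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  n <- max(dr, dc) + 1L
  rows <- integer(n); cols <- integer(n)
  err <- dr - dc
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    rows[i] <- r; cols[i] <- c
    if (r == r1 && c == c1) {
      rows <- rows[seq_len(i)]; cols <- cols[seq_len(i)]
      break
    }
    e2 <- 2L * err
    if (e2 > -dc) { err <- err - dc; r <- r + sr }
    if (e2 < dr)  { err <- err + dr; c <- c + sc }
  }
  cbind(row = rows, col = cols)
}

#' Draw a closed or open polyline into a binary matrix
#' @noRd
draw_polyline <- function(size, verts, closed = TRUE) {
  m <- matrix(0L, size, size)
  n <- nrow(verts)
  last <- if (closed) n else n - 1L
  for (i in seq_len(last)) {
    j <- if (i == n) 1L else i + 1L
    px <- bresenham(verts[i, 1], verts[i, 2], verts[j, 1], verts[j, 2])
    keep <- px[, 1] >= 1 & px[, 1] <= size & px[, 2] >= 1 & px[, 2] <= size
    m[px[keep, , drop = FALSE]] <- 1L
  }
  m
}

#' Even-odd point-in-polygon test at pixel centers
#'
#' Pixel-centered, 0-based (row, col) frame; the polygon is closed implicitly
#' (last vertex connects to the first). Vectorized ray casting along +col.
#' @noRd
polygon_fill <- function(nrow_px, ncol_px, verts) {
  pr <- rep(seq_len(nrow_px) - 1, times = ncol_px)
  pc <- rep(seq_len(ncol_px) - 1, each = nrow_px)
  vr <- verts[, 1]; vc <- verts[, 2]
  n <- length(vr)
  inside <- rep(FALSE, length(pr))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vr[i] > pr) != (vr[j] > pr))
    if (any(crosses)) {
      xint <- vc[j] + (pr[crosses] - vr[j]) * (vc[i] - vc[j]) / (vr[i] - vr[j])
      flip <- pc[crosses] < xint
      idx <- which(crosses)[flip]
      inside[idx] <- !inside[idx]
    }
    j <- i
  }
  matrix(as.integer(inside), nrow_px, ncol_px)
}

#' Bounding box of a mask's nonzero pixels, padded by `margin`
#'
#' Returns `rows` and `cols` index vectors clipped to the matrix frame.
#' @noRd
roi_bbox <- function(mask, margin = 2L) {
  idx <- which(mask == 1, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - margin)
  r1 <- min(nrow(mask), max(idx[, 1]) + margin)
  c0 <- max(1L, min(idx[, 2]) - margin)
  c1 <- min(ncol(mask), max(idx[, 2]) + margin)
  list(rows = r0:r1, cols = c0:c1)
}

#' Validate a binary mask
#' @noRd
assert_binary_mask <- function(m, arg = "mask") {
  if (!is.matrix(m)) stop(arg, " must be a matrix", call. = FALSE)
  if (!all(m %in% c(0L, 1L))) {
    stop(arg, " must contain only 0/1 values", call. = FALSE)
  }
  invisible(m)
}

#' Dice overlap between two binary masks
#'
#' @param a,b binary 0/1 matrices of equal dimension.
#' @return Scalar in \[0, 1\]; 1 for identical non-empty masks.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sa <- sum(a == 1); sb <- sum(b == 1)
  if (sa + sb == 0) return(1)
  2 * sum(a == 1 & b == 1) / (sa + sb)
}
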