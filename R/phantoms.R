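# Analytic fractal phantoms used as ground-truth substrates for the
# box-counting core: their dimensions are known in closed form, so FD
# recovery can be checked without any imaging data.

#' Sierpinski carpet phantom
#'
#' Generates the level-`level` Sierpinski carpet as a binary mask. A cell is
#' foreground unless any base-3 digit pair of its (row, col) index is (1, 1),
#' so the foreground cell count is exactly `8^level` and the Hausdorff
#' dimension of the limiting set is `log(8)/log(3) ~ 1.8928`.
#'
#' @param level carpet recursion depth (1..7).
#' @param px_per_cell integer pixel width of each carpet cell.
#' @param max_side guard on the output side length in pixels.
#' @return A 0/1 integer matrix of side `3^level * px_per_cell`.
#' @examples
#' m <- phantom_sierpinski(2)
#' sum(m) # 64 = 8^2
#' @export
phantom_sierpinski <- function(level, px_per_cell = 1L, max_side = 8192L) {
  if (length(level) != 1 || level < 1 || level != round(level)) {
    stop("`level` must be a positive integer", call. = FALSE)
  }
  if (level > 7) stop("`level` must be <= 7", call. = FALSE)
  n <- 3L^level
  side <- n * as.integer(px_per_cell)
  if (side > max_side) {
    stop("phantom side ", side, " px exceeds max_side ", max_side,
         call. = FALSE)
  }
  idx <- 0:(n - 1)
  # keep[i] per digit level: TRUE where base-3 digit != 1
  fg <- matrix(TRUE, n, n)
  for (d in seq_len(level)) {
    digit <- (idx %/% 3L^(d - 1L)) %% 3L
    hole <- digit == 1L
    fg <- fg & !outer(hole, hole, `&`)
  }
  m <- matrix(0L, n, n)
  m[fg] <- 1L
  if (px_per_cell > 1L) {
    m <- m[rep(seq_len(n), each = px_per_cell),
           rep(seq_len(n), each = px_per_cell)]
  }
  m
}

# Recursive vertex expansion for the triadic Koch curve: each segment is
# replaced by four, with the middle bump rotated +60 degrees.
koch_vertices <- function(level) {
  pts <- matrix(c(0, 0, 1, 0), ncol = 2, byrow = TRUE) # (x, y)
  for (l in seq_len(level)) {
    n <- nrow(pts) - 1L
    out <- matrix(0, 4L * n + 1L, 2L)
    k <- 1L
    for (i in seq_len(n)) {
      p0 <- pts[i, ]; p1 <- pts[i + 1L, ]
      v <- (p1 - p0) / 3
      a <- p0 + v
      b <- p0 + 2 * v
      # peak: rotate v by +60 degrees about a
      peak <- a + c(v[1] * 0.5 - v[2] * sqrt(3) / 2,
                    v[1] * sqrt(3) / 2 + v[2] * 0.5)
      out[k, ] <- p0
      out[k + 1L, ] <- a
      out[k + 2L, ] <- peak
      out[k + 3L, ] <- b
      k <- k + 4L
    }
    out[4L * n + 1L, ] <- pts[n + 1L, ]
    pts <- out
  }
  pts
}

#' Koch curve phantom
#'
#' Rasterizes the open triadic Koch curve (one edge of the Koch snowflake) at
#' recursion depth `level` with 1-px-wide Bresenham segments. The curve has
#' `4^level` segments and limiting dimension `log(4)/log(3) ~ 1.2619`;
#' `level = 0` is a straight line of dimension 1.
#'
#' @param level recursion depth (0..8).
#' @param size_px side length of the square output mask.
#' @return A 0/1 integer matrix of side `size_px`.
#' @export
phantom_koch <- function(level, size_px = 512L) {
  if (level < 0 || level > 8 || level != round(level)) {
    stop("`level` must be an integer in 0..8", call. = FALSE)
  }
  margin <- max(2L, round(0.02 * size_px))
  width <- size_px - 2L * margin
  if (width / 3^level < 1) {
    stop("size_px too small to resolve level-", level,
         " segments (< 1 px)", call. = FALSE)
  }
  pts <- koch_vertices(level)
  # map x to columns, y upward from a baseline near the bottom
  col <- margin + pts[, 1] * width
  row <- (size_px - margin) - pts[, 2] * width
  draw_polyline(size_px, cbind(row, col), closed = FALSE)
}

#' Rasterized circle phantom
#'
#' 1-px-wide circle drawn by the annulus test `|d - radius| < 0.5` on the
#' pixel-center distance `d` from the grid center. The mask has exact 4-fold
#' rotational symmetry; a smooth closed curve, so its box-count FD is ~ 1.
#'
#' @param radius_px circle radius in pixels (> 0, < size/2 - 2).
#' @param size_px side length of the square mask.
#' @return A 0/1 integer matrix.
#' @export
phantom_circle <- function(radius_px, size_px = 128L) {
  if (radius_px <= 0) stop("`radius_px` must be positive", call. = FALSE)
  if (radius_px >= size_px / 2 - 2) {
    stop("`radius_px` must be < size_px/2 - 2", call. = FALSE)
  }
  ctr <- (size_px + 1) / 2
  d <- sqrt(outer((seq_len(size_px) - ctr)^2,
                  (seq_len(size_px) - ctr)^2, `+`))
  m <- matrix(0L, size_px, size_px)
  m[abs(d - radius_px) < 0.5] <- 1L
  m
}

# Periodic midpoint-displacement profile of length n (a power of 2) with
# Hurst exponent H; returns zero-mean fluctuations with unit initial scale.
midpoint_profile <- function(n, hurst) {
  depth <- as.integer(round(log2(n)))
  stopifnot(2^depth == n)
  z <- c(0, 0) # two anchor points of the periodic profile
  scale <- 1
  while (length(z) < n) {
    m <- length(z)
    mids <- (z + z[c(2:m, 1)]) / 2 + rnorm(m, 0, scale)
    out <- numeric(2 * m)
    out[seq(1, 2 * m, by = 2)] <- z
    out[seq(2, 2 * m, by = 2)] <- mids
    z <- out
    scale <- scale * 2^(-hurst)
  }
  z - mean(z)
}

#' Rough closed-boundary phantom with tunable complexity
#'
#' Builds a closed 1-px boundary whose radial profile r(theta) is a periodic
#' midpoint-displacement fractal with Hurst exponent `roughness_H`. Lower H
#' gives a rougher outline with higher box-count FD (the fractional-Brownian
#' graph-dimension 2 - H intuition); H near 1 approaches a smooth circle.
#' Used as a tunable stand-in for the trabecular/blood-pool interface.
#'
#' @param roughness_H Hurst exponent in (0, 1].
#' @param n_angles number of radial samples; coerced to a power of 2
#'   (a power of 2 plus 1 is accepted and reduced by one).
#' @param size_px side of the square output mask.
#' @param seed integer seed; the mask is a pure function of the arguments.
#' @param base_radius_frac base radius as a fraction of `size_px` (default
#'   0.35); fluctuations are bounded to keep the boundary inside the frame.
#' @param amplitude_frac fluctuation scale as a fraction of the base radius.
#' @return A 0/1 integer matrix containing one closed boundary.
#' @export
phantom_rough_boundary <- function(roughness_H, n_angles = 256L,
                                   size_px = 256L, seed = 1L,
                                   base_radius_frac = 0.35,
                                   amplitude_frac = 0.2) {
  if (roughness_H <= 0 || roughness_H > 1) {
    stop("`roughness_H` must be in (0, 1]", call. = FALSE)
  }
  n <- 2^floor(log2(n_angles))
  r0 <- base_radius_frac * size_px
  prof <- withr::with_seed(seed, midpoint_profile(n, roughness_H))
  r <- rough_radius(prof, r0, amplitude_frac)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  ctr <- (size_px + 1) / 2
  verts <- cbind(ctr + r * sin(theta), ctr + r * cos(theta))
  draw_polyline(size_px, verts, closed = TRUE)
}

# Map zero-mean fluctuations onto a positive radius, clipped so the boundary
# cannot collapse or escape.
rough_radius <- function(prof, r0, amplitude_frac) {
  s <- stats::sd(prof)
  if (s == 0) return(rep(r0, length(prof)))
  r <- r0 * (1 + amplitude_frac * prof / s)
  pmin(pmax(r, 0.3 * r0), 1.35 * r0)
}
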