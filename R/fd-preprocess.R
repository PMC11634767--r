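# Bias-field correction and ROI definition preceding trabecular segmentation.

#' Histogram stretching (bias-field correction)
#'
#' Linearly maps intensities so that the `p_low` percentile goes to 0 and the
#' `p_high` percentile to 1, then clips to \[0, 1\]. Percentiles are computed
#' over `mask` when given (ROI-local stretching), otherwise globally. The
#' ordering of distinct intensities is preserved inside the clip range.
#'
#' @param img a `slice_image` or numeric matrix.
#' @param p_low,p_high percentiles in \[0, 100\], `p_low < p_high`.
#' @param mask optional 0/1 matrix restricting percentile computation.
#' @return A `slice_image` with intensities in \[0, 1\]. A constant image
#'   (zero percentile spread) maps to all zeros with a warning.
#' @export
stretch_histogram <- function(img, p_low = 2, p_high = 98, mask = NULL) {
  if (p_low >= p_high) stop("`p_low` must be < `p_high`", call. = FALSE)
  img <- as_slice_image(img)
  px <- img$pixels
  vals <- if (is.null(mask)) as.vector(px) else px[mask == 1]
  q <- quantile(vals, c(p_low, p_high) / 100, names = FALSE, type = 7)
  if (q[2] - q[1] <= .Machine$double.eps * max(1, abs(q[2]))) {
    warning("constant image: zero percentile spread, returning all zeros")
    img$pixels <- matrix(0, nrow(px), ncol(px))
    return(img)
  }
  out <- (px - q[1]) / (q[2] - q[1])
  img$pixels <- pmin(pmax(out, 0), 1)
  img
}

#' Region of interest for trabecular analysis
#'
#' The ROI is the whole LV cavity (blood-pool label) plus the inner half of
#' the myocardial wall: myocardial pixels strictly closer (4-connected
#' geodesic distance within the wall) to the endocardial edge than to the
#' epicardial edge. Edge detection is applied within the whole cavity, so the
#' ROI is always a superset of the blood pool.
#'
#' @param seg label matrix (0 background, 1 myocardium, 2 blood pool).
#' @return A 0/1 integer matrix; empty (all zero) when the blood pool is
#'   empty so downstream stages can flag `empty_roi`.
#' @export
make_roi <- function(seg) {
  seg <- validate_segmentation(seg)
  myo <- seg == 1L
  pool <- seg == 2L
  if (!any(myo)) stop("geometry error: no myocardium ring in segmentation",
                      call. = FALSE)
  if (!any(pool)) {
    return(matrix(0L, nrow(seg), ncol(seg)))
  }
  d_endo <- geodesic_dist(myo, adjacent_to(myo, pool))
  d_epi <- geodesic_dist(myo, adjacent_to(myo, seg == 0L))
  inner <- myo & (d_endo < d_epi)
  out <- matrix(0L, nrow(seg), ncol(seg))
  out[pool | inner] <- 1L
  out
}

# Myocardial pixels 4-adjacent to `other`.
adjacent_to <- function(myo, other) {
  nb <- shift_mat(other, 1, 0) | shift_mat(other, -1, 0) |
    shift_mat(other, 0, 1) | shift_mat(other, 0, -1)
  myo & nb
}

# Multi-source 4-connected geodesic distance within `domain`, seeded at
# `sources` (distance 0). Iterative min-plus relaxation; the wall is thin so
# few sweeps are needed.
geodesic_dist <- function(domain, sources) {
  d <- matrix(Inf, nrow(domain), ncol(domain))
  d[sources] <- 0
  repeat {
    nb <- pmin(shift_mat(d, 1, 0), shift_mat(d, -1, 0),
               shift_mat(d, 0, 1), shift_mat(d, 0, -1)) + 1
    new <- pmin(d, nb)
    new[!domain & !sources] <- Inf
    new[sources] <- 0
    if (identical(new, d)) break
    d <- new
  }
  d
}
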