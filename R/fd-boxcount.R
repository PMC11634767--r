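# Boundary extraction and box-counting fractal dimension.

#' Extract a mask outline with a Sobel filter
#'
#' Sobel gradient magnitude of the 0/1 mask (replicated borders, so an
#' all-ones mask yields no outline at the physical frame), thresholded at
#' > 0 and intersected with the foreground: a 1-px-thick outline containing
#' every pixel with at least one opposite-valued 4-neighbor.
#'
#' @param mask 0/1 matrix.
#' @return 0/1 integer matrix of outline pixels.
#' @export
sobel_outline <- function(mask) {
  assert_binary_mask(mask)
  m <- mask * 1.0
  gx <- (shift_mat(m, -1, -1) + 2 * shift_mat(m, 0, -1) + shift_mat(m, 1, -1)) -
        (shift_mat(m, -1,  1) + 2 * shift_mat(m, 0,  1) + shift_mat(m, 1,  1))
  gy <- (shift_mat(m, -1, -1) + 2 * shift_mat(m, -1, 0) + shift_mat(m, -1, 1)) -
        (shift_mat(m,  1, -1) + 2 * shift_mat(m,  1, 0) + shift_mat(m,  1, 1))
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[(gx != 0 | gy != 0) & mask == 1] <- 1L
  out
}

#' Box-size schedule
#'
#' Box sizes run from `min_box` (default 2 px) up to
#' `floor(max_fraction * min(rows, cols))` (default 45% of the smaller image
#' dimension). The default `"geometric"` spacing keeps only the integer sizes
#' nearest the ladder `min_box * box_ratio^k`, so each scale octave carries
#' equal weight in the log-log fit; `"all"` uses every integer size and
#' `"log2"` is the ladder at ratio 2.
#'
#' @param shape integer (rows, cols) of the image.
#' @param cfg an [fd_config()].
#' @return Increasing integer vector of box sizes (possibly shorter than the
#'   5 sizes a valid fit needs; callers flag that as `poor_fit`).
#' @export
box_sizes <- function(shape, cfg = fd_config()) {
  smax <- floor(cfg$max_fraction * min(shape))
  if (smax < cfg$min_box) return(integer(0))
  sizes <- seq.int(cfg$min_box, smax)
  if (cfg$box_spacing != "all") {
    ratio <- if (cfg$box_spacing == "log2") 2 else cfg$box_ratio
    k <- ceiling(log(smax / cfg$min_box) / log(ratio))
    ladder <- cfg$min_box * ratio^(0:k)
    sizes <- unique(vapply(ladder[ladder <= smax],
                           function(l) sizes[which.min(abs(sizes - l))],
                           integer(1)))
  }
  sizes
}

#' Count occupied boxes at one box size
#'
#' The grid is anchored at pixel (0, 0) with a single offset; cells in the
#' final row/column may be partial and still count. A cell is occupied when
#' it contains at least one foreground pixel.
#'
#' @param outline 0/1 matrix.
#' @param s integer box size >= 2.
#' @return Integer count of occupied `s` x `s` cells.
#' @export
box_count <- function(outline, s) {
  if (s < 2) stop("box size must be >= 2", call. = FALSE)
  # block-sum rows then columns, then count nonzero cells
  rgrp <- (seq_len(nrow(outline)) - 1L) %/% as.integer(s)
  cgrp <- (seq_len(ncol(outline)) - 1L) %/% as.integer(s)
  rs <- rowsum(outline, rgrp, reorder = TRUE)
  cs <- rowsum(t(rs), cgrp, reorder = TRUE)
  sum(cs > 0)
}

#' Box-count curve over a size schedule
#'
#' @param outline 0/1 matrix.
#' @param sizes increasing integer box sizes (default: the schedule from
#'   [box_sizes()] for this image).
#' @param cfg an [fd_config()].
#' @return A tibble with columns `box_size` and `count`, class
#'   `box_count_curve`.
#' @export
box_count_curve <- function(outline, sizes = NULL, cfg = fd_config()) {
  assert_binary_mask(outline, "outline")
  if (is.null(sizes)) sizes <- box_sizes(dim(outline), cfg)
  counts <- vapply(sizes, function(s) box_count(outline, s), numeric(1))
  structure(
    tibble::tibble(box_size = as.integer(sizes), count = counts),
    class = c("box_count_curve", class(tibble::tibble()))
  )
}

#' Fit the fractal dimension from a box-count curve
#'
#' Ordinary least squares of log(count) on log(box size) over all scheduled
#' sizes; the fractal dimension is the negative slope. Sizes with zero counts
#' are dropped (log undefined) with a warning; fewer than 5 remaining pairs,
#' or fit r-squared below `min_r2`, flags `poor_fit`.
#'
#' @param curve a `box_count_curve` or data frame with `box_size`, `count`.
#' @param min_r2 minimum r-squared for qc = "ok" (default 0.95).
#' @return An `fd_result`: list with `fd`, `r_squared`, `n_boxsizes`, `qc`,
#'   `intercept` and the fitted `curve`.
#' @export
fit_fd <- function(curve, min_r2 = 0.95) {
  df <- as.data.frame(curve)
  stopifnot(all(c("box_size", "count") %in% names(df)))
  if (any(df$count == 0)) {
    warning(sum(df$count == 0), " box size(s) with zero count dropped")
    df <- df[df$count > 0, , drop = FALSE]
  }
  if (nrow(df) < 5) {
    return(new_fd_result(NA_real_, NA_real_, nrow(df), "poor_fit", NA_real_,
                         df))
  }
  lx <- log(df$box_size)
  ly <- log(df$count)
  if (stats::var(ly) == 0) {
    # flat curve: zero slope, no explainable variance
    return(new_fd_result(0, 0, nrow(df), "poor_fit", ly[1], df))
  }
  # closed-form simple OLS (avoids summary.lm's perfect-fit warning)
  slope <- stats::cov(lx, ly) / stats::var(lx)
  intercept <- mean(ly) - slope * mean(lx)
  r2 <- stats::cor(lx, ly)^2
  fd <- -slope
  qc <- if (r2 < min_r2) "poor_fit" else "ok"
  if (qc == "ok" && (fd <= 0.5 || fd >= 2.5)) qc <- "poor_fit"
  new_fd_result(fd, r2, nrow(df), qc, intercept, df)
}

new_fd_result <- function(fd, r2, n, qc, intercept, curve) {
  structure(
    list(fd = fd, r_squared = r2, n_boxsizes = as.integer(n), qc = qc,
         intercept = intercept, curve = tibble::as_tibble(curve)),
    class = "fd_result"
  )
}

#' @export
print.fd_result <- function(x, ...) {
  cat(sprintf("<fd_result> fd = %s, r^2 = %s, %d box sizes, qc = %s\n",
              format(x$fd, digits = 4), format(x$r_squared, digits = 4),
              x$n_boxsizes, x$qc))
  invisible(x)
}

#' Box-counting FD of a binary mask
#'
#' Convenience wrapper: outline extraction (optional) followed by the full
#' box-count curve and log-log fit.
#'
#' @param mask 0/1 matrix.
#' @param cfg an [fd_config()].
#' @param outline if TRUE (default) apply [sobel_outline()] first; set FALSE
#'   when `mask` is already a curve-like set (e.g. an analytic phantom).
#' @return An `fd_result`.
#' @export
mask_fd <- function(mask, cfg = fd_config(), outline = TRUE) {
  m <- if (outline) sobel_outline(mask) else mask
  if (sum(m) == 0) {
    return(new_fd_result(NA_real_, NA_real_, 0L, "degenerate_outline",
                         NA_real_,
                         tibble::tibble(box_size = integer(), count = numeric())))
  }
  fit_fd(box_count_curve(m, cfg = cfg), min_r2 = cfg$min_r2)
}
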