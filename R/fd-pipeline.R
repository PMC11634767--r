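# Per-slice and per-stack orchestration of the FD measurement pipeline:
# stretch -> ROI -> level set -> Sobel outline -> box counting -> OLS fit.

#' Fractal dimension of one short-axis slice
#'
#' Runs the full measurement chain on a slice and its segmentation. The qc
#' flag propagates the worst stage: `empty_roi` when the segmentation has no
#' blood pool, `degenerate_outline` when segmentation or outline is empty,
#' `poor_fit` when the box-size schedule is too short or the log-log fit is
#' below the r-squared gate. Fully deterministic.
#'
#' @param img a `slice_image` or intensity matrix.
#' @param seg label matrix (0 background, 1 myocardium, 2 blood pool).
#' @param cfg an [fd_config()].
#' @return An `fd_result` with `slice_index` and `long_axis_position` fields
#'   added; `fd` is `NA` whenever qc != "ok".
#' @export
slice_fd <- function(img, seg, cfg = fd_config()) {
  img <- as_slice_image(img)
  roi <- make_roi(seg)
  res <- if (sum(roi) == 0) {
    new_fd_result(NA_real_, NA_real_, 0L, "empty_roi", NA_real_,
                  tibble::tibble(box_size = integer(), count = numeric()))
  } else {
    stretched <- stretch_histogram(img, cfg$p_low, cfg$p_high, mask = roi)
    # evolve the level set on the ROI bounding box (plus margin) only; the
    # mask is re-embedded so the box-size schedule still sees the full frame
    bb <- roi_bbox(roi, margin = 2L)
    sub <- stretched$pixels[bb$rows, bb$cols, drop = FALSE]
    seg_out <- levelset_segment(sub, roi[bb$rows, bb$cols, drop = FALSE], cfg)
    if (seg_out$qc != "ok") {
      new_fd_result(NA_real_, NA_real_, 0L, seg_out$qc, NA_real_,
                    tibble::tibble(box_size = integer(), count = numeric()))
    } else {
      full <- matrix(0L, nrow(roi), ncol(roi))
      full[bb$rows, bb$cols] <- seg_out$mask
      mask_fd(full, cfg = cfg, outline = TRUE)
    }
  }
  if (res$qc != "ok") res$fd <- NA_real_
  res$slice_index <- img$slice_index
  res$long_axis_position <- img$long_axis_position
  res
}

#' Fractal dimension of a full slice stack
#'
#' Applies [slice_fd()] to every slice, preserving base-to-apex order.
#'
#' @param stack list of slices; each element a list with `image`
#'   (`slice_image`) and `seg` (label matrix), as produced by
#'   [simulate_lv_stack()] or [read_stack()].
#' @param cfg an [fd_config()].
#' @return A tibble of class `fd_stack` with one row per slice:
#'   `slice_index`, `position`, `fd`, `r_squared`, `n_boxsizes`, `qc`, plus
#'   an `n_valid` attribute (slices with qc == "ok").
#' @export
stack_fd <- function(stack, cfg = fd_config()) {
  rows <- purrr::map(stack, function(sl) {
    r <- slice_fd(sl$image, sl$seg, cfg)
    tibble::tibble(
      slice_index = r$slice_index,
      position = r$long_axis_position,
      fd = r$fd,
      r_squared = r$r_squared,
      n_boxsizes = r$n_boxsizes,
      qc = r$qc
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- dplyr::arrange(out, .data$slice_index)
  new_fd_stack(out)
}

#' Construct an `fd_stack` from per-slice values
#'
#' Mostly useful for building stacks directly from numbers (tests, external
#' FD series). `position` must be non-decreasing base to apex.
#'
#' @param position numeric long-axis positions in \[0, 1\].
#' @param fd numeric FD values (NA for failed slices).
#' @param qc character qc flags; defaults to "ok" where `fd` is finite.
#' @return An `fd_stack` tibble.
#' @export
fd_stack <- function(position, fd, qc = NULL) {
  stopifnot(length(position) == length(fd))
  if (is.null(qc)) qc <- ifelse(is.finite(fd), "ok", "missing")
  new_fd_stack(tibble::tibble(
    slice_index = seq_along(fd),
    position = as.numeric(position),
    fd = as.numeric(fd),
    r_squared = NA_real_,
    n_boxsizes = NA_integer_,
    qc = qc
  ))
}

new_fd_stack <- function(df) {
  structure(df, class = c("fd_stack", class(tibble::tibble())),
            n_valid = sum(df$qc == "ok" & is.finite(df$fd)))
}

#' Number of valid slices in an `fd_stack`
#' @param x an `fd_stack`.
#' @return Integer count of slices with qc "ok" and finite FD.
#' @export
n_valid_slices <- function(x) {
  sum(x$qc == "ok" & is.finite(x$fd))
}
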