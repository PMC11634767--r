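#' Construct a short-axis slice image
#'
#' A grayscale slice with pixel spacing and its normalized long-axis position
#' (0 = base, 1 = apex). FD itself is computed in pixel units (it is a
#' scale-invariant ratio); spacing is carried as metadata.
#'
#' @param pixels numeric matrix of intensities (finite).
#' @param pixel_spacing_mm length-2 positive numeric (row, col) spacing.
#' @param slice_index integer position of the slice in its stack.
#' @param long_axis_position scalar in \[0, 1\], base to apex.
#' @return An object of class `slice_image`.
#' @export
slice_image <- function(pixels, pixel_spacing_mm = c(1, 1),
                        slice_index = 1L, long_axis_position = 0) {
  if (!is.matrix(pixels) || !all(is.finite(pixels))) {
    stop("`pixels` must be a matrix of finite intensities", call. = FALSE)
  }
  if (length(pixel_spacing_mm) == 1) {
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2)
  }
  if (any(pixel_spacing_mm <= 0)) {
    stop("`pixel_spacing_mm` must be positive", call. = FALSE)
  }
  structure(
    list(pixels = pixels,
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         slice_index = as.integer(slice_index),
         long_axis_position = as.numeric(long_axis_position)),
    class = "slice_image"
  )
}

#' @export
print.slice_image <- function(x, ...) {
  cat(sprintf("<slice_image> %d x %d px, spacing %.2f x %.2f mm, slice %d, position %.3f\n",
              nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
              x$slice_index, x$long_axis_position))
  invisible(x)
}

# Coerce matrices to slice_image where convenient.
as_slice_image <- function(x) {
  if (inherits(x, "slice_image")) return(x)
  if (is.matrix(x)) return(slice_image(x))
  stop("cannot coerce to slice_image", call. = FALSE)
}

#' Validate an LV segmentation label grid
#'
#' Labels: 0 background, 1 myocardium, 2 blood pool.
#' @param seg integer matrix.
#' @return The validated matrix, invisibly typed as integer.
#' @export
validate_segmentation <- function(seg) {
  if (!is.matrix(seg)) stop("segmentation must be a matrix", call. = FALSE)
  bad <- setdiff(unique(as.vector(seg)), c(0, 1, 2))
  if (length(bad)) {
    stop("format error: unknown segmentation label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  storage.mode(seg) <- "integer"
  seg
}
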