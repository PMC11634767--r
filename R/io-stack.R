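# Stack readers/writers. NIfTI (image volume + integer label volume) is the
# lossless path; png_json stores 8-bit PNG slices (an interchange format,
# quantized) plus endo/epi contour polygons in JSON (contours are rasterized
# on read with an even-odd pixel-center test unioned with the contour
# pixels themselves).

#' Write an LV stack to disk
#'
#' NIfTI format writes `image.nii.gz` (double intensities), `labels.nii.gz`
#' (integer labels 0 background / 1 myocardium / 2 blood pool) and a
#' `meta.json` sidecar with slice order, positions and pixel spacing.
#' png_json format writes one 8-bit grayscale PNG per slice (intensities are
#' rescaled to the stored `intensity_range` and quantized, so this path is
#' lossy) plus a `contours.json` with closed endo/epi polygons per slice
#' (pixel-centered, 0-based row/col coordinates).
#'
#' @param stack list of slices with `image` (`slice_image`) and `seg`.
#' @param dir output directory (created if needed).
#' @param format "nifti" or "png_json".
#' @return `dir`, invisibly.
#' @export
write_stack <- function(stack, dir, format = c("nifti", "png_json")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(stack)
  meta <- list(
    n_slices = n,
    slice_index = vapply(stack, function(s) s$image$slice_index, integer(1)),
    long_axis_position = vapply(stack, function(s) s$image$long_axis_position,
                                numeric(1)),
    pixel_spacing_mm = stack[[1]]$image$pixel_spacing_mm,
    format = format
  )
  if (format == "nifti") {
    dims <- dim(stack[[1]]$image$pixels)
    vol <- array(0, c(dims, n))
    lab <- array(0L, c(dims, n))
    for (i in seq_len(n)) {
      vol[, , i] <- stack[[i]]$image$pixels
      lab[, , i] <- stack[[i]]$seg
    }
    sp <- meta$pixel_spacing_mm
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = c(sp, 10)),
                       file.path(dir, "image.nii.gz"), datatype = "double")
    RNifti::writeNifti(RNifti::asNifti(lab, pixdim = c(sp, 10)),
                       file.path(dir, "labels.nii.gz"), datatype = "int16")
  } else {
    contours <- vector("list", n)
    for (i in seq_len(n)) {
      px <- stack[[i]]$image$pixels
      rng <- range(px)
      scl <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
      png::writePNG(scl, file.path(dir, sprintf("slice_%03d.png", i)),
                    dpi = NULL)
      contours[[i]] <- list(
        intensity_range = rng,
        endo = trace_contour(stack[[i]]$seg == 2L),
        epi = trace_contour(stack[[i]]$seg == 1L | stack[[i]]$seg == 2L)
      )
    }
    jsonlite::write_json(contours, file.path(dir, "contours.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# Ordered boundary polygon of a (star-shaped) region: boundary pixels sorted
# by angle about the region centroid, in pixel-centered 0-based coordinates.
trace_contour <- function(mask) {
  if (!any(mask)) return(list())
  b <- mask & !(shift_mat(mask, 1, 0) & shift_mat(mask, -1, 0) &
                shift_mat(mask, 0, 1) & shift_mat(mask, 0, -1))
  idx <- which(b, arr.ind = TRUE)
  r <- idx[, 1] - 1; c <- idx[, 2] - 1
  ang <- atan2(r - mean(r), c - mean(c))
  ord <- order(ang)
  list(row = r[ord], col = c[ord])
}

#' Read an LV stack from disk
#'
#' Slices are returned ordered base to apex by `slice_index` regardless of
#' on-disk order, with `long_axis_position` populated from the sidecar.
#' Label volumes are validated (labels outside \{0, 1, 2\} raise a format
#' error naming the slice); missing spacing metadata falls back to 1.0 mm
#' with a warning.
#'
#' @param dir directory written by [write_stack()].
#' @param format "nifti" or "png_json".
#' @return List of slices with `image` and `seg`, ordered by slice index.
#' @export
read_stack <- function(dir, format = c("nifti", "png_json")) {
  format <- match.arg(format)
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) stop("missing meta.json in ", dir,
                                    call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  sp <- meta$pixel_spacing_mm
  if (is.null(sp) || !length(sp)) {
    warning("missing spacing metadata: assuming 1.0 mm")
    sp <- c(1, 1)
  }
  n <- meta$n_slices
  slices <- vector("list", n)
  if (format == "nifti") {
    vol <- as.array(RNifti::readNifti(file.path(dir, "image.nii.gz")))
    lab <- as.array(RNifti::readNifti(file.path(dir, "labels.nii.gz")))
    for (i in seq_len(n)) {
      seg <- matrix(as.integer(lab[, , i]), dim(lab)[1], dim(lab)[2])
      bad <- setdiff(unique(as.vector(seg)), c(0L, 1L, 2L))
      if (length(bad)) {
        stop("format error: slice ", i, " contains unknown label(s): ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      slices[[i]] <- list(
        image = slice_image(vol[, , i], pixel_spacing_mm = sp,
                            slice_index = meta$slice_index[i],
                            long_axis_position = meta$long_axis_position[i]),
        seg = seg
      )
    }
  } else {
    contours <- jsonlite::read_json(file.path(dir, "contours.json"),
                                    simplifyVector = FALSE)
    for (i in seq_len(n)) {
      scl <- png::readPNG(file.path(dir, sprintf("slice_%03d.png", i)))
      ct <- contours[[i]]
      rng <- unlist(ct$intensity_range)
      px <- scl * diff(rng) + rng[1]
      endo <- list(row = unlist(ct$endo$row), col = unlist(ct$endo$col))
      epi <- list(row = unlist(ct$epi$row), col = unlist(ct$epi$col))
      seg <- rasterize_contours(dim(px), endo, epi)
      slices[[i]] <- list(
        image = slice_image(px, pixel_spacing_mm = sp,
                            slice_index = meta$slice_index[i],
                            long_axis_position = meta$long_axis_position[i]),
        seg = seg
      )
    }
  }
  slices[order(meta$slice_index)]
}

# Rebuild the label grid from closed endo/epi polygons: even-odd fill at
# pixel centers, unioned with the contour pixels themselves (they were
# boundary pixels of the original region); epi must enclose endo.
rasterize_contours <- function(shape, endo, epi) {
  seg <- matrix(0L, shape[1], shape[2])
  if (!length(epi) || !length(epi$row)) return(seg)
  region_from_contour <- function(ct) {
    fill <- polygon_fill(shape[1], shape[2], cbind(ct$row, ct$col))
    n <- length(ct$row)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      px <- bresenham(ct$row[i] + 1, ct$col[i] + 1,
                      ct$row[j] + 1, ct$col[j] + 1)
      keep <- px[, 1] >= 1 & px[, 1] <= shape[1] &
        px[, 2] >= 1 & px[, 2] <= shape[2]
      fill[px[keep, , drop = FALSE]] <- 1L
    }
    fill
  }
  epi_fill <- region_from_contour(epi)
  endo_fill <- if (length(endo) && length(endo$row)) {
    region_from_contour(endo)
  } else matrix(0L, shape[1], shape[2])
  if (any(endo_fill == 1 & epi_fill == 0)) {
    stop("geometry error: endocardial contour not enclosed by epicardial",
         call. = FALSE)
  }
  seg[epi_fill == 1] <- 1L
  seg[endo_fill == 1] <- 2L
  seg
}
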