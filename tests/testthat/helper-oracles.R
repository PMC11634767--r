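# Shared oracles and fixture builders for the test suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force box-count oracle: the number of distinct (floor(r/s), floor(c/s))
# cells containing at least one foreground pixel, computed per pixel with no
# shared code with box_count().
oracle_box_count <- function(outline, s) {
  idx <- which(outline == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0L)
  cells <- unique(paste((idx[, 1] - 1) %/% s, (idx[, 2] - 1) %/% s))
  length(cells)
}

# Noiseless two-intensity slice phantom: the simulated LV geometry with the
# image re-rendered at exactly two intensities (tissue 0.35, blood 0.9), plus
# the tissue ground truth restricted to the analysis ROI.
two_intensity_phantom <- function(seed, hurst = 0.5) {
  spec <- lv_stack_spec(n_slices = 1, noise_sd = 0, bias_amplitude = 0,
                        seed = seed, complexity_profile = hurst)
  sl <- simulate_lv_slice(spec, 1)
  roi <- make_roi(sl$seg)
  tissue <- (sl$trabeculae == 1 | sl$seg == 1)
  img <- matrix(0.9, nrow(roi), ncol(roi))
  img[tissue] <- 0.35
  gt <- matrix(0L, nrow(roi), ncol(roi))
  gt[tissue & roi == 1] <- 1L
  list(image = img, seg = sl$seg, roi = roi, truth = gt)
}

# 90-degree counter-clockwise rotation of a matrix.
rot90 <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]

# fd_stack with `k` valid slices out of 9 (the rest flagged missing).
stack_with_k_valid <- function(k, fd_value = 1.3) {
  fd <- rep(NA_real_, 9)
  if (k > 0) fd[seq_len(k)] <- fd_value
  fd_stack(position = (0:8) / 8, fd = fd)
}
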