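# Synthetic short-axis LV stacks with known ground truth: a bright blood
# pool, a dark compact-myocardium annulus, and an intermediate-intensity
# trabecular meshwork rendered as concentric strand layers whose blood-facing
# edges are midpoint-displacement fractals of tunable roughness.

#' Specification of a synthetic LV slice stack
#'
#' Geometry is a cropped LV region: circular cavity inside a myocardial
#' annulus. The trabecular compartment occupies the outer part of the cavity
#' as three concentric strand layers bridged by radial spokes; each layer
#' boundary follows a rough radial profile with the per-slice Hurst exponent
#' from `complexity_profile` (lower H = rougher edges = higher FD).
#'
#' @param n_slices number of slices, base to apex (>= 1).
#' @param image_size_px square image side in pixels.
#' @param cavity_radius_px cavity (endocardial) radius in pixels.
#' @param wall_thickness_px compact wall thickness in pixels;
#'   `cavity_radius_px + wall_thickness_px` must be < `image_size_px / 2`.
#' @param complexity_profile Hurst exponent in (0, 1] per slice.
#' @param noise_sd additive Gaussian intensity noise (intensities are on
#'   \[0, 1\]; the trabecula/pool contrast is 0.55, kept >= 3x the default
#'   noise).
#' @param bias_amplitude peak amplitude of a smooth multiplicative intensity
#'   ramp across the image (emulates residual coil bias).
#' @param seed integer; the stack is a pure function of the spec.
#' @return A list of class `lv_stack_spec`.
#' @export
lv_stack_spec <- function(n_slices = 9L, image_size_px = 192L,
                          cavity_radius_px = 60, wall_thickness_px = 16,
                          complexity_profile = rep(0.5, n_slices),
                          noise_sd = 0.05, bias_amplitude = 0.05,
                          seed = 1L) {
  if (n_slices < 1) stop("`n_slices` must be >= 1", call. = FALSE)
  if (length(complexity_profile) != n_slices) {
    stop("`complexity_profile` must have one entry per slice", call. = FALSE)
  }
  if (any(complexity_profile <= 0 | complexity_profile > 1)) {
    stop("`complexity_profile` entries must be in (0, 1]", call. = FALSE)
  }
  if (cavity_radius_px + wall_thickness_px >= image_size_px / 2) {
    stop("geometry error: cavity_radius + wall_thickness must be < image_size/2",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(
    list(n_slices = as.integer(n_slices),
         image_size_px = as.integer(image_size_px),
         cavity_radius_px = cavity_radius_px,
         wall_thickness_px = wall_thickness_px,
         complexity_profile = complexity_profile,
         noise_sd = noise_sd,
         bias_amplitude = bias_amplitude,
         seed = as.integer(seed)),
    class = "lv_stack_spec"
  )
}

# nominal tissue intensities on [0, 1]
lv_intensities <- c(background = 0.05, myocardium = 0.20,
                    trabeculae = 0.35, pool = 0.90)

#' Simulate one short-axis LV slice
#'
#' @param spec an [lv_stack_spec()].
#' @param slice_index which slice (1..n_slices).
#' @return A list with `image` (a `slice_image`), `seg` (label matrix:
#'   0 background, 1 myocardium, 2 blood pool) and `trabeculae` (0/1
#'   ground-truth mask, always inside the cavity of `seg`).
#' @export
simulate_lv_slice <- function(spec, slice_index = 1L) {
  stopifnot(inherits(spec, "lv_stack_spec"))
  if (slice_index < 1 || slice_index > spec$n_slices) {
    stop("`slice_index` out of range", call. = FALSE)
  }
  n <- spec$image_size_px
  ctr <- (n + 1) / 2
  dr <- outer(seq_len(n) - ctr, rep(1, n))
  dc <- outer(rep(1, n), seq_len(n) - ctr)
  d <- sqrt(dr^2 + dc^2)
  theta <- atan2(dr, dc) %% (2 * pi)

  # apex tapering: radius shrinks modestly toward the apex
  pos <- if (spec$n_slices == 1) 0 else (slice_index - 1) / (spec$n_slices - 1)
  taper <- 1 - 0.25 * pos
  r_cav <- spec$cavity_radius_px * taper
  r_epi <- r_cav + spec$wall_thickness_px

  pool <- d <= r_cav
  myo <- d > r_cav & d <= r_epi
  seg <- matrix(0L, n, n)
  seg[myo] <- 1L
  seg[pool] <- 2L

  slice_seed <- spec$seed + 7919L * as.integer(slice_index)
  hurst <- spec$complexity_profile[slice_index]
  # trabecular meshwork: three concentric strand layers with rough
  # blood-facing edges, bridged by radial spokes and an outer rim on the
  # endocardial border
  n_ang <- 512L
  ang_idx <- pmin(floor(theta / (2 * pi) * n_ang) + 1L, n_ang)
  layer_base <- seq(0.55, 0.88, length.out = 3) * r_cav
  layer_w <- 0.10 * r_cav
  trab <- matrix(FALSE, n, n)
  for (k in 1:3) {
    prof <- withr::with_seed(slice_seed + 131L * k,
                             midpoint_profile(n_ang, hurst))
    rk <- layer_base[k] * (1 + 0.18 * prof / max(stats::sd(prof), 1e-12))
    rk_px <- matrix(rk[ang_idx], n, n)
    trab <- trab | (d > rk_px & d <= rk_px + layer_w)
  }
  n_spokes <- 12L
  spoke_phase <- (theta / (2 * pi) * n_spokes) %% 1
  spokes <- spoke_phase < 0.08 & d > 0.5 * r_cav
  trab <- (trab | spokes | d > 0.94 * r_cav) & pool
  trab_mask <- matrix(0L, n, n)
  trab_mask[trab] <- 1L

  img <- matrix(lv_intensities["background"], n, n)
  img[pool] <- lv_intensities["pool"]
  img[myo] <- lv_intensities["myocardium"]
  img[trab] <- lv_intensities["trabeculae"]

  if (spec$bias_amplitude > 0) {
    ramp <- 1 + spec$bias_amplitude * (dc / n + dr / n)
    img <- img * ramp
  }
  if (spec$noise_sd > 0) {
    img <- img + withr::with_seed(
      slice_seed + 1L, matrix(rnorm(n * n, 0, spec$noise_sd), n, n))
  }

  list(
    image = slice_image(img, pixel_spacing_mm = c(1.8, 1.8),
                        slice_index = slice_index,
                        long_axis_position = pos),
    seg = seg,
    trabeculae = trab_mask
  )
}

#' Simulate a full short-axis LV stack
#'
#' Slices carry normalized long-axis positions 0 (base) to 1 (apex).
#'
#' @param spec an [lv_stack_spec()].
#' @return A list of class `lv_stack` of per-slice triples (see
#'   [simulate_lv_slice()]).
#' @export
simulate_lv_stack <- function(spec) {
  stopifnot(inherits(spec, "lv_stack_spec"))
  out <- lapply(seq_len(spec$n_slices), function(i) simulate_lv_slice(spec, i))
  structure(out, class = "lv_stack", spec = spec)
}
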