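#' Pipeline configuration
#'
#' Assembles the full set of tunable parameters for the per-slice FD pipeline
#' and the downstream profile/classification stages, with validated defaults.
#'
#' @param p_low,p_high histogram-stretch percentiles (0 <= p_low < p_high <= 100).
#' @param levelset_smoothing curvature-smoothing weight for the region-based
#'   level set; internally applied as `round(10 * weight)` morphological
#'   smoothing passes per iteration.
#' @param levelset_max_iter maximum level-set iterations.
#' @param levelset_tol convergence tolerance on the change in the two region
#'   means between iterations.
#' @param blood_bright logical; TRUE when the blood pool is the bright phase
#'   (bright-blood cine convention). The returned trabecular mask is the
#'   phase matching myocardial tissue intensity.
#' @param min_box smallest box size in pixels (>= 2).
#' @param max_fraction largest box size as a fraction of the smaller image
#'   dimension (default 0.45).
#' @param box_spacing "geometric" (default) keeps the integer sizes nearest a
#'   geometric ladder of ratio `box_ratio`, weighting every scale octave
#'   equally in the log-log fit; "all" uses every integer size (which
#'   overweights large, saturating boxes); "log2" is the geometric ladder
#'   fixed at ratio 2.
#' @param box_ratio ladder ratio for `box_spacing = "geometric"` (> 1).
#' @param min_r2 minimum r-squared of the log-log fit for qc = "ok".
#' @param interp_bandwidth Gaussian kernel bandwidth on the normalized
#'   base-to-apex axis for nine-slice interpolation.
#' @param interp_local "constant" (Nadaraya-Watson) or "linear" local fit.
#' @param min_valid_slices minimum number of valid slices for a profile.
#' @param threshold_sd classification threshold in s.d. units.
#' @return A list of class `fd_config`.
#' @export
fd_config <- function(p_low = 2, p_high = 98,
                      levelset_smoothing = 0.1,
                      levelset_max_iter = 200L,
                      levelset_tol = 1e-4,
                      blood_bright = TRUE,
                      min_box = 2L,
                      max_fraction = 0.45,
                      box_spacing = c("geometric", "all", "log2"),
                      box_ratio = sqrt(2),
                      min_r2 = 0.95,
                      interp_bandwidth = 0.15,
                      interp_local = c("constant", "linear"),
                      min_valid_slices = 6L,
                      threshold_sd = 1.5) {
  box_spacing <- match.arg(box_spacing)
  interp_local <- match.arg(interp_local)
  cfg <- list(
    p_low = p_low, p_high = p_high,
    levelset_smoothing = levelset_smoothing,
    levelset_max_iter = as.integer(levelset_max_iter),
    levelset_tol = levelset_tol,
    blood_bright = isTRUE(blood_bright),
    min_box = as.integer(min_box),
    max_fraction = max_fraction,
    box_spacing = box_spacing,
    box_ratio = box_ratio,
    min_r2 = min_r2,
    interp_bandwidth = interp_bandwidth,
    interp_local = interp_local,
    min_valid_slices = as.integer(min_valid_slices),
    threshold_sd = threshold_sd
  )
  validate_config(cfg)
  structure(cfg, class = "fd_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, key, bound) {
    if (!ok) stop("config error: `", key, "` ", bound, call. = FALSE)
  }
  chk(cfg$p_low >= 0 && cfg$p_low < cfg$p_high && cfg$p_high <= 100,
      "p_low/p_high", "must satisfy 0 <= p_low < p_high <= 100")
  chk(cfg$max_fraction > 0 && cfg$max_fraction < 1,
      "max_fraction", "must be in (0, 1)")
  chk(cfg$min_box >= 2, "min_box", "must be >= 2")
  chk(cfg$levelset_max_iter >= 1, "levelset_max_iter", "must be >= 1")
  chk(cfg$levelset_tol > 0, "levelset_tol", "must be > 0")
  chk(cfg$min_r2 >= 0 && cfg$min_r2 <= 1, "min_r2", "must be in [0, 1]")
  chk(cfg$interp_bandwidth > 0, "interp_bandwidth", "must be > 0")
  chk(cfg$min_valid_slices >= 1, "min_valid_slices", "must be >= 1")
  chk(cfg$threshold_sd > 0, "threshold_sd", "must be > 0")
  chk(cfg$box_spacing %in% c("geometric", "all", "log2"), "box_spacing",
      "must be 'geometric', 'all' or 'log2'")
  chk(cfg$box_ratio > 1, "box_ratio", "must be > 1")
  invisible(cfg)
}

#' Load a pipeline configuration from a YAML file
#'
#' Absent keys take the defaults of [fd_config()]; unknown keys are rejected.
#' An empty file yields the full default configuration.
#'
#' @param path YAML file with any subset of the [fd_config()] arguments.
#' @return An `fd_config` list.
#' @export
load_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(fd_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("config error: unknown key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(fd_config, vals)
}

#' @export
print.fd_config <- function(x, ...) {
  cat("<fd_config>\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k, format(x[[k]])))
  invisible(x)
}
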