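# Nine-slice standardization of per-slice FD series and the 25 summary
# traits over the four cardiac levels.

#' Normalize long-axis positions of an FD stack
#'
#' Affinely rescales the positions of valid slices so the first valid slice
#' sits at 0 (base) and the last at 1 (apex). A stack with a single valid
#' slice is flagged degenerate (positions cannot be normalized).
#'
#' @param stack an `fd_stack`.
#' @return The `fd_stack` with rescaled `position`; attribute
#'   `degenerate = TRUE` when fewer than 2 valid slices.
#' @export
normalize_positions <- function(stack) {
  valid <- stack$qc == "ok" & is.finite(stack$fd)
  if (!any(valid)) stop("empty stack: no valid slices", call. = FALSE)
  p <- stack$position[valid]
  if (length(p) < 2 || max(p) == min(p)) {
    attr(stack, "degenerate") <- TRUE
    return(stack)
  }
  stack$position <- (stack$position - min(p)) / (max(p) - min(p))
  stack
}

#' Interpolate an FD series onto the nine-slice template
#'
#' Gaussian-kernel local fit of the valid per-slice FD values, evaluated at
#' the nine template positions t_k = (k-1)/8 on the normalized base-to-apex
#' axis. The default local-constant (Nadaraya-Watson) fit is a kernel-
#' weighted mean, so every template value lies within the range of the
#' contributing slice values; a local-linear variant is available. Stacks
#' with fewer valid slices than `min_valid` (default 6) are rejected.
#'
#' @param stack an `fd_stack` (positions assumed normalized to \[0, 1\];
#'   apply [normalize_positions()] first if needed).
#' @param bandwidth Gaussian kernel bandwidth on the normalized axis.
#' @param min_valid minimal slice cutoff (default 6).
#' @param local "constant" or "linear" local fit.
#' @return A tibble of class `fd_profile` with columns `template_slice`
#'   (1..9), `template_position`, `fd`; attribute `n_valid`. When the stack
#'   fails the cutoff, a zero-row tibble with attribute `qc = "lt_min_slices"`.
#' @export
interp_nine_slice <- function(stack, bandwidth = 0.15, min_valid = 6L,
                              local = c("constant", "linear")) {
  local <- match.arg(local)
  valid <- stack$qc == "ok" & is.finite(stack$fd)
  n_valid <- sum(valid)
  tpos <- (0:8) / 8
  if (n_valid < min_valid) {
    out <- tibble::tibble(template_slice = integer(),
                          template_position = numeric(),
                          fd = numeric())
    return(structure(out, class = c("fd_profile", class(out)),
                     n_valid = n_valid, qc = "lt_min_slices"))
  }
  x <- stack$position[valid]
  y <- stack$fd[valid]
  fd_hat <- vapply(tpos, function(t0) {
    w <- exp(-0.5 * ((x - t0) / bandwidth)^2)
    if (local == "constant" || sum(w > 0) < 3) {
      sum(w * y) / sum(w)
    } else {
      # weighted local-linear fit at t0
      fit <- lm(y ~ I(x - t0), weights = w)
      unname(coef(fit)[1])
    }
  }, numeric(1))
  out <- tibble::tibble(template_slice = 1:9, template_position = tpos,
                        fd = fd_hat)
  structure(out, class = c("fd_profile", class(out)),
            n_valid = n_valid, qc = "ok")
}

#' Names of the 25 trabeculation summary traits
#'
#' Nine template-slice FDs plus minimum, mean, median and maximum over the
#' four cardiac levels: global (slices 1-9), basal (1-3), mid (4-6) and
#' apical (7-9).
#'
#' @return Character vector of length 25 in the fixed report order.
#' @export
fd_trait_names <- function() {
  c(paste0("fd_slice", 1:9),
    as.vector(t(outer(c("global", "basal", "mid", "apical"),
                      c("min", "mean", "median", "max"), paste, sep = "_"))))
}

# template-slice index sets per cardiac level
fd_levels <- list(global = 1:9, basal = 1:3, mid = 4:6, apical = 7:9)

#' Summarize a nine-slice profile into the 25 traits
#'
#' @param profile an `fd_profile` from [interp_nine_slice()].
#' @return A one-row tibble of class `fd_traits` with the 25 named traits
#'   plus `n_valid_input_slices` and `qc`. A rejected profile yields all
#'   traits `NA` with its qc flag.
#' @export
fd_traits <- function(profile) {
  qc <- attr(profile, "qc") %||% "ok"
  nms <- fd_trait_names()
  if (nrow(profile) != 9 || qc != "ok") {
    vals <- as.list(setNames(rep(NA_real_, 25), nms))
    out <- tibble::as_tibble(vals)
    out$n_valid_input_slices <- attr(profile, "n_valid") %||% NA_integer_
    out$qc <- if (qc == "ok") "invalid_profile" else qc
    return(structure(out, class = c("fd_traits", class(out))))
  }
  v <- profile$fd
  vals <- c(as.list(setNames(v, paste0("fd_slice", 1:9))),
            unlist(lapply(names(fd_levels), function(lv) {
              s <- v[fd_levels[[lv]]]
              setNames(list(min(s), mean(s), median(s), max(s)),
                       paste0(lv, "_", c("min", "mean", "median", "max")))
            }), recursive = FALSE))
  out <- tibble::as_tibble(vals[nms])
  out$n_valid_input_slices <- attr(profile, "n_valid")
  out$qc <- "ok"
  structure(out, class = c("fd_traits", class(out)))
}

#' Full per-subject trait extraction from an FD stack
#'
#' Chains [normalize_positions()], [interp_nine_slice()] and [fd_traits()].
#'
#' @param stack an `fd_stack`.
#' @param cfg an [fd_config()]; supplies bandwidth, local-fit mode and the
#'   minimal slice cutoff.
#' @return A one-row `fd_traits` tibble.
#' @export
stack_traits <- function(stack, cfg = fd_config()) {
  valid <- stack$qc == "ok" & is.finite(stack$fd)
  if (!any(valid)) {
    prof <- structure(tibble::tibble(template_slice = integer(),
                                     template_position = numeric(),
                                     fd = numeric()),
                      class = c("fd_profile", class(tibble::tibble())),
                      n_valid = 0L, qc = "lt_min_slices")
    return(fd_traits(prof))
  }
  stack <- normalize_positions(stack)
  prof <- interp_nine_slice(stack, bandwidth = cfg$interp_bandwidth,
                            min_valid = cfg$min_valid_slices,
                            local = cfg$interp_local)
  fd_traits(prof)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
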