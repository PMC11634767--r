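# broom-style tidiers for fitted objects.

#' Tidy a box-count FD fit
#'
#' @param x an `fd_result`.
#' @param ... unused.
#' @return A tibble with one row per box size: `box_size`, `count`,
#'   `log_size`, `log_count` and the `fitted` log-count from the OLS line.
#' @export
tidy.fd_result <- function(x, ...) {
  df <- tibble::as_tibble(x$curve)
  df$log_size <- log(df$box_size)
  df$log_count <- log(df$count)
  df$fitted <- if (is.finite(x$fd)) x$intercept - x$fd * df$log_size
               else NA_real_
  df
}

#' One-row summary of a box-count FD fit
#'
#' @param x an `fd_result`.
#' @param ... unused.
#' @return A tibble: `fd`, `r_squared`, `n_boxsizes`, `qc`.
#' @export
glance.fd_result <- function(x, ...) {
  tibble::tibble(fd = x$fd, r_squared = x$r_squared,
                 n_boxsizes = x$n_boxsizes, qc = x$qc)
}

#' Tidy a covariate adjustment fit
#'
#' @param x a `trab_adjust`.
#' @param ... unused.
#' @return The coefficient table: `term`, `estimate`, `se`, `p`.
#' @export
tidy.trab_adjust <- function(x, ...) {
  x$coefficients
}

#' One-row summary of a covariate adjustment fit
#'
#' @param x a `trab_adjust`.
#' @param ... unused.
#' @return A tibble: `trait`, `n_used`, `n_excluded`, `r_squared`,
#'   `residual_mean`, `residual_sd`.
#' @export
glance.trab_adjust <- function(x, ...) {
  tibble::tibble(trait = x$trait, n_used = x$n_used,
                 n_excluded = x$n_excluded, r_squared = x$r_squared,
                 residual_mean = mean(x$residuals$residual),
                 residual_sd = sd(x$residuals$residual))
}
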