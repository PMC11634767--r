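# FD report writer: one CSV row per participant with the nine interpolated
# slice FDs, the sixteen level summaries and QC columns, in a fixed and
# documented column order.

#' Write the per-participant FD trait report
#'
#' Column order is fixed: `id`, the 25 traits of [fd_trait_names()] (nine
#' template-slice FDs then min/mean/median/max for global, basal, mid and
#' apical levels), `n_valid_input_slices`, `qc`. Participants failing the
#' minimal slice cutoff keep their row with empty trait cells and
#' `qc = "lt_min_slices"`. Numeric cells are written with 6 significant
#' digits so reruns are byte-identical. An empty input yields a header-only
#' file.
#'
#' @param results a data frame with one row per participant: `id` plus the
#'   `fd_traits` columns (as from [stack_traits()]), or a named list of
#'   `fd_traits` rows.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fd_report <- function(results, path) {
  cols <- c("id", fd_trait_names(), "n_valid_input_slices", "qc")
  if (is.list(results) && !is.data.frame(results)) {
    results <- dplyr::bind_rows(
      purrr::imap(results, function(tr, nm) {
        tr <- tibble::as_tibble(tr)
        tr$id <- nm
        tr
      })
    )
  }
  df <- tibble::as_tibble(results)
  if (nrow(df) == 0) {
    empty <- as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                    cols), check.names = FALSE)
    write.csv(empty, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  missing_cols <- setdiff(cols, names(df))
  for (mc in missing_cols) df[[mc]] <- NA
  df <- df[, cols]
  for (v in cols) {
    if (is.numeric(df[[v]]) && v != "n_valid_input_slices") {
      df[[v]] <- ifelse(is.na(df[[v]]), "", sprintf("%.6g", df[[v]]))
    }
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read an FD trait report
#'
#' @param path CSV written by [write_fd_report()].
#' @return A tibble with empty cells as `NA`.
#' @export
read_fd_report <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                             na.strings = c("", "NA")))
}
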