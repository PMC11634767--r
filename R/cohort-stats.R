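# Participant-level statistics: covariate adjustment to standardized
# residuals, extreme-phenotype classification, group comparison, and simple
# post-index event counting.

#' Default covariate set for FD trait adjustment
#'
#' Age at scan, age squared, sex, age:sex interaction, imaging center
#' (categorical), body surface area, systolic blood pressure, vigorous
#' exercise days per week, and ten ancestry principal components.
#'
#' @return Character vector of column names.
#' @export
default_covariates <- function() {
  c("age", "age2", "sex", "age_sex", "center", "bsa", "sbp", "exercise",
    paste0("PC", 1:10))
}

#' Adjust a trait for covariates via multiple linear regression
#'
#' Ordinary least squares of the trait on the covariates, with categorical
#' covariates expanded as indicators (reference = first declared level).
#' Rows with any missing value among the trait or covariates are excluded
#' (complete-case) and counted. Residuals are standardized to mean 0 and
#' s.d. 1 (n - 1 denominator).
#'
#' @param table cohort data frame with an `id` column.
#' @param trait name of the trait column.
#' @param covariates character vector of covariate column names (default
#'   [default_covariates()], intersected with available columns).
#' @return An object of class `trab_adjust`: `residuals` tibble
#'   (`id`, `residual`), `coefficients` tibble (`term`, `estimate`, `se`,
#'   `p`), `n_used`, `n_excluded`, `r_squared`, `trait`. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
adjust_trait <- function(table, trait = "trait",
                         covariates = default_covariates()) {
  if (!trait %in% names(table)) {
    stop("unknown trait column: ", trait, call. = FALSE)
  }
  if (!"id" %in% names(table)) {
    stop("`table` must have an `id` column", call. = FALSE)
  }
  covariates <- intersect(covariates, names(table))
  if (!length(covariates)) stop("no covariate columns found", call. = FALSE)
  df <- as.data.frame(table)[, c("id", trait, covariates)]
  for (v in covariates) {
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  }
  cc <- complete.cases(df)
  n_excluded <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  y <- df[[trait]]
  if (length(unique(y)) < 2) stop("trait is constant", call. = FALSE)
  p_cols <- sum(vapply(covariates, function(v) {
    if (is.factor(df[[v]])) nlevels(df[[v]]) - 1L else 1L
  }, integer(1)))
  if (nrow(df) <= p_cols + 2) {
    stop("too few complete cases for the model", call. = FALSE)
  }
  fml <- stats::reformulate(covariates, response = trait)
  fit <- lm(fml, data = df)
  if (any(is.na(coef(fit)))) {
    warning("rank-deficient design: dropped aliased column(s): ",
            paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  r <- residuals(fit)
  res_std <- (r - mean(r)) / sd(r)
  sm <- summary(fit)$coefficients
  coefs <- tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                          se = sm[, 2], p = sm[, 4])
  structure(
    list(residuals = tibble::tibble(id = df$id, residual = unname(res_std)),
         coefficients = coefs,
         n_used = nrow(df),
         n_excluded = n_excluded,
         r_squared = summary(fit)$r.squared,
         trait = trait),
    class = "trab_adjust"
  )
}

#' @export
print.trab_adjust <- function(x, ...) {
  cat(sprintf("<trab_adjust> trait '%s': n = %d (%d excluded), R^2 = %.3f\n",
              x$trait, x$n_used, x$n_excluded, x$r_squared))
  invisible(x)
}

#' Classify hyper- and hypotrabeculation
#'
#' On standardized residuals: in the s.d. modes, hyper is residual > +k and
#' hypo is residual < -k (k = 1, 1.5 or 2; default 1.5 s.d.). In deciles
#' mode, hypo is the bottom decile and hyper the top decile, with ties
#' broken by midrank.
#'
#' @param adj a `trab_adjust` object, or a numeric vector of standardized
#'   residuals.
#' @param mode one of `"sd_1.5"` (default), `"sd_1"`, `"sd_2"`, `"deciles"`.
#' @param id optional ids when `adj` is numeric.
#' @return A tibble of class `trab_class`: `id`, `residual`, `class`
#'   (factor hypo/normal/hyper; in deciles mode also a `decile` column).
#' @export
classify_trabeculation <- function(adj, mode = c("sd_1.5", "sd_1", "sd_2",
                                                 "deciles"),
                                   id = NULL) {
  mode <- match.arg(mode)
  if (inherits(adj, "trab_adjust")) {
    res <- adj$residuals$residual
    id <- adj$residuals$id
  } else {
    res <- as.numeric(adj)
    if (is.null(id)) id <- as.character(seq_along(res))
  }
  lv <- c("hypo", "normal", "hyper")
  if (mode == "deciles") {
    n <- length(res)
    if (n < 10) stop("deciles mode needs n >= 10", call. = FALSE)
    dec <- pmin(pmax(ceiling(rank(res, ties.method = "average") * 10 / n),
                     1L), 10L)
    cls <- factor(ifelse(dec == 1, "hypo",
                         ifelse(dec == 10, "hyper", "normal")), levels = lv)
    out <- tibble::tibble(id = id, residual = res, decile = as.integer(dec),
                          class = cls)
  } else {
    k <- c(sd_1 = 1, sd_1.5 = 1.5, sd_2 = 2)[[mode]]
    cls <- factor(ifelse(res > k, "hyper",
                         ifelse(res < -k, "hypo", "normal")), levels = lv)
    out <- tibble::tibble(id = id, residual = res, class = cls)
  }
  structure(out, class = c("trab_class", class(out)), mode = mode)
}

#' Compare adjusted traits across groups
#'
#' Two-sided Student's t-tests (pooled variance) of each non-reference group
#' against the reference; effects are differences in means on the
#' standardized-residual scale (s.d. units).
#'
#' @param adj a `trab_adjust`, or numeric residuals.
#' @param groups group labels aligned with the residuals (by `id` order of
#'   the adjusted object).
#' @param reference reference level; default the first level.
#' @return A tibble: `group`, `n`, `diff`, `se`, `statistic`, `p`.
#' @export
compare_groups <- function(adj, groups, reference = NULL) {
  res <- if (inherits(adj, "trab_adjust")) adj$residuals$residual
         else as.numeric(adj)
  groups <- factor(groups)
  stopifnot(length(groups) == length(res))
  if (is.null(reference)) reference <- levels(groups)[1]
  others <- setdiff(levels(groups), reference)
  if (!length(others)) stop("need >= 2 groups", call. = FALSE)
  ref <- res[groups == reference]
  if (length(ref) < 2) stop("reference group needs n >= 2", call. = FALSE)
  rows <- lapply(others, function(g) {
    x <- res[groups == g]
    if (length(x) < 2) stop("group ", g, " needs n >= 2", call. = FALSE)
    if (stats::var(x) == 0 && stats::var(ref) == 0) {
      stop("zero variance in group ", g, " and reference", call. = FALSE)
    }
    tt <- t.test(x, ref, var.equal = TRUE, alternative = "two.sided")
    d <- mean(x) - mean(ref)
    tibble::tibble(group = g, n = length(x), diff = d,
                   se = unname(tt$stderr), statistic = unname(tt$statistic),
                   p = tt$p.value)
  })
  dplyr::bind_rows(rows)
}

#' Count post-index events by trabeculation class
#'
#' Builds the contingency table of class by event occurrence, restricted to
#' events strictly after the index (imaging) date. Participants whose event
#' precedes (or equals) their index date are excluded and counted, matching
#' an incident-disease design.
#'
#' @param classes a `trab_class` tibble (or any tibble with `id`, `class`).
#' @param index_date per-participant index date (Date or coercible).
#' @param event_date per-participant first event date; NA for no event.
#' @param exclude_pre_index drop participants with pre-index events (default
#'   TRUE); if FALSE, any pre-index event is a validation error.
#' @return A list: `table` (tibble class x event with counts), `n_excluded`.
#' @export
incidence_split <- function(classes, index_date, event_date,
                            exclude_pre_index = TRUE) {
  stopifnot(all(c("id", "class") %in% names(classes)))
  idx <- as.Date(index_date)
  evt <- as.Date(event_date)
  stopifnot(length(idx) == nrow(classes), length(evt) == nrow(classes))
  if (any(is.na(idx))) stop("index dates must be parseable", call. = FALSE)
  pre <- !is.na(evt) & evt <= idx
  if (any(pre) && !exclude_pre_index) {
    stop("validation error: ", sum(pre), " event(s) precede the index date",
         call. = FALSE)
  }
  keep <- !pre
  cls <- factor(classes$class[keep], levels = c("hypo", "normal", "hyper"))
  has_event <- !is.na(evt[keep]) & evt[keep] > idx[keep]
  tab <- as.data.frame(table(class = cls, event = has_event))
  tab <- tidyr::pivot_wider(tibble::as_tibble(tab),
                            names_from = "event", values_from = "Freq")
  names(tab) <- c("class", "no_event", "event")[seq_len(ncol(tab))]
  if (!"event" %in% names(tab)) tab$event <- 0L
  if (!"no_event" %in% names(tab)) tab$no_event <- 0L
  list(table = tab[, c("class", "no_event", "event")],
       n_excluded = sum(pre))
}
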