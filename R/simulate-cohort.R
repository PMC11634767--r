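# Simulated cohorts: FD-like traits generated as a linear function of the
# standard covariate set plus Gaussian noise, for validating covariate
# adjustment, classification and group comparison by parameter recovery.

#' Names of the expanded covariate design columns
#'
#' Order of the planted-effect vector `beta`: age, age squared, sex,
#' age:sex, two imaging-center indicators (centers B and C vs A), body
#' surface area, systolic blood pressure, vigorous-exercise days per week,
#' and ten ancestry principal components.
#'
#' @return Character vector of length 19.
#' @export
cohort_beta_names <- function() {
  c("age", "age2", "sex", "age_sex", "centerB", "centerC",
    "bsa", "sbp", "exercise", paste0("PC", 1:10))
}

#' Specification of a simulated cohort
#'
#' Covariate distributions emulate a mid-life imaging cohort: age ~
#' Uniform(45, 80) years; sex ~ Bernoulli(0.5); BSA ~ Normal(1.8, 0.2) m^2;
#' SBP ~ Normal(138, 18) mmHg; vigorous exercise ~ uniform integer 0..7 days
#' per week; three equiprobable imaging centers; PCs ~ Normal(0, 1).
#'
#' @param n participants.
#' @param beta planted effects on the expanded design (length 19, order of
#'   [cohort_beta_names()]); default all zero.
#' @param intercept trait intercept (FD-like scale).
#' @param noise_sd residual s.d. of the trait (> 0).
#' @param seed integer seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n, beta = rep(0, 19), intercept = 1.2,
                        noise_sd = 0.1, seed = 1L) {
  nb <- length(cohort_beta_names())
  if (length(beta) != nb) {
    stop("spec error: `beta` must have length ", nb,
         " (see cohort_beta_names())", call. = FALSE)
  }
  if (noise_sd <= 0) stop("`noise_sd` must be > 0", call. = FALSE)
  structure(list(n = as.integer(n), beta = as.numeric(beta),
                 intercept = intercept, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort table
#'
#' The raw trait is `intercept + beta . X + Normal(0, noise_sd)` on the
#' expanded design (age centered at 60 and age^2 on the centered scale, to
#' keep the planted coefficients interpretable and the design well
#' conditioned).
#'
#' @param spec a [cohort_spec()].
#' @return A tibble with `id`, `trait`, raw covariates (`age`, `sex`,
#'   `center`, `bsa`, `sbp`, `exercise`, `PC1`..`PC10`) and the expanded
#'   columns `age2`, `age_sex`. Reproducible for a fixed seed.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  withr::with_seed(spec$seed, {
    age <- runif(n, 45, 80) - 60
    sex <- rbinom(n, 1, 0.5)
    center <- sample(c("A", "B", "C"), n, replace = TRUE)
    bsa <- rnorm(n, 1.8, 0.2)
    sbp <- rnorm(n, 138, 18)
    exercise <- sample(0:7, n, replace = TRUE)
    pcs <- matrix(rnorm(n * 10), n, 10,
                  dimnames = list(NULL, paste0("PC", 1:10)))
    eps <- rnorm(n, 0, spec$noise_sd)
  })
  X <- cbind(age = age, age2 = age^2, sex = sex, age_sex = age * sex,
             centerB = as.numeric(center == "B"),
             centerC = as.numeric(center == "C"),
             bsa = bsa, sbp = sbp, exercise = exercise, pcs)
  trait <- spec$intercept + drop(X %*% spec$beta) + eps
  out <- tibble::tibble(
    id = sprintf("P%06d", seq_len(n)),
    trait = trait,
    age = age, age2 = age^2, sex = sex, age_sex = age * sex,
    center = center, bsa = bsa, sbp = sbp, exercise = exercise
  )
  dplyr::bind_cols(out, tibble::as_tibble(pcs))
}
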