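#' Stratum table of the emulated osteosarcoma trial
#'
#' Returns the 16 strata formed by crossing the four binary prognostic
#' factors of the emulated randomised osteosarcoma trial (chemotherapy
#' regimen, sex, histological response, surgical excision margin), together
#' with each stratum's population proportion and the mean and standard
#' deviation of age at surgery within the stratum. These published summary
#' statistics are the covariate model of the synthetic-data generator:
#' strata are sampled multinomially by `proportion` and age is drawn from a
#' stratum-conditional normal distribution.
#'
#' Coding: `treatment` 0 = regimen C, 1 = regimen DI; `sex` 0 = female,
#' 1 = male; `histology` 0 = poor, 1 = good response; `margin` 0 =
#' unknown/incomplete, 1 = complete excision.
#'
#' @return A tibble with 16 rows and columns `treatment`, `sex`,
#'   `histology`, `margin` (integer 0/1), `proportion`, `age_mean`,
#'   `age_sd`.
#' @examples
#' trial_strata()
#' sum(trial_strata()$proportion)
#' @export
trial_strata <- function() {
  path <- system.file("extdata", "osteosarcoma_strata.csv",
                      package = "plannsim", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    treatment = readr::col_integer(),
                    sex = readr::col_integer(),
                    histology = readr::col_integer(),
                    margin = readr::col_integer(),
                    .default = readr::col_double()
                  ))
}

covariate_names <- function() c("treatment", "sex", "histology", "margin", "age")

#' Validate a stratum table
#'
#' Checks the structural invariants of a stratum specification: 16 unique
#' binary combinations, non-negative proportions summing to 1 within a
#' rounding tolerance, and strictly positive age standard deviations.
#'
#' @param strata A tibble as returned by [trial_strata()].
#' @param tol Tolerance on `sum(proportion) - 1`; defaults to 0.005 because
#'   published proportions are rounded to two decimals.
#' @return The validated (renormalized) stratum table, invisibly usable
#'   downstream; proportions are rescaled to sum to exactly 1.
#' @export
validate_strata <- function(strata, tol = 0.005) {
  needed <- c("treatment", "sex", "histology", "margin",
              "proportion", "age_mean", "age_sd")
  missing_cols <- setdiff(needed, names(strata))
  if (length(missing_cols) > 0) {
    stop("strata is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(strata$proportion < 0)) {
    stop("stratum proportions must be non-negative", call. = FALSE)
  }
  if (all(strata$proportion == 0)) {
    stop("all stratum proportions are zero", call. = FALSE)
  }
  if (any(strata$age_sd <= 0)) {
    stop("stratum age_sd must be strictly positive", call. = FALSE)
  }
  s <- sum(strata$proportion)
  if (abs(s - 1) > tol) {
    stop(sprintf("stratum proportions sum to %.4f, outside 1 +/- %.3f", s, tol),
         call. = FALSE)
  }
  dplyr::mutate(strata, proportion = .data$proportion / s)
}

#' Sample covariate vectors from a stratum table
#'
#' Draws `n` subjects: the stratum multinomially according to `proportion`,
#' then age from the stratum's normal distribution. Ages below `age_floor`
#' are redrawn (the trial enrols children and young adults, so negative ages
#' from the normal tails are rejected).
#'
#' @param n Number of subjects (>= 1).
#' @param strata Stratum table, see [trial_strata()].
#' @param age_floor Minimum admissible age in years; draws below it are
#'   resampled. Default 0.
#' @param seed Optional integer seed for a reproducible draw.
#' @return A tibble with `n` rows and columns `treatment`, `sex`,
#'   `histology`, `margin`, `age`.
#' @export
sample_covariates <- function(n, strata = trial_strata(), age_floor = 0,
                              seed = NULL) {
  if (length(n) != 1 || is.na(n) || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  strata <- validate_strata(strata)
  draw <- function() {
    idx <- sample.int(nrow(strata), size = n, replace = TRUE,
                      prob = strata$proportion)
    age <- stats::rnorm(n, strata$age_mean[idx], strata$age_sd[idx])
    bad <- which(age < age_floor)
    while (length(bad) > 0) {
      age[bad] <- stats::rnorm(length(bad), strata$age_mean[idx[bad]],
                               strata$age_sd[idx[bad]])
      bad <- bad[age[bad] < age_floor]
    }
    tibble::tibble(
      treatment = strata$treatment[idx],
      sex = strata$sex[idx],
      histology = strata$histology[idx],
      margin = strata$margin[idx],
      age = age
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
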