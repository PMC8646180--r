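#' Simulate latent survival times from the log-normal AFT model
#'
#' Draws \eqn{T = \exp(\mu + \beta' x + \sigma z)}, \eqn{z \sim N(0,1)},
#' one time per row of the covariate table.
#'
#' @param covariates Tibble with columns `treatment`, `sex`, `histology`,
#'   `margin`, `age` (the order of `coef$betas`).
#' @param coef An [aft_coefficients()] object.
#' @param seed Optional integer seed.
#' @return Numeric vector of strictly positive survival times in years.
#' @export
simulate_survival_times <- function(covariates, coef = default_aft_coefficients(),
                                    seed = NULL) {
  miss <- setdiff(covariate_names(), names(covariates))
  if (length(miss) > 0) {
    stop("covariates is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(covariates[, covariate_names()])
  lp <- coef$intercept + as.numeric(X %*% coef$betas)
  draw <- function() exp(lp + coef$sigma * stats::rnorm(nrow(X)))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate Weibull censoring times
#'
#' @param n Number of draws.
#' @param spec A [censoring_spec()].
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` i.i.d. Weibull(shape, scale) times.
#' @export
simulate_censoring <- function(n, spec, seed = NULL) {
  if (!inherits(spec, "censoring_spec")) {
    stop("spec must be a censoring_spec", call. = FALSE)
  }
  draw <- function() stats::rweibull(n, shape = spec$shape, scale = spec$scale)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Assemble an observed dataset from latent survival and censoring times
#'
#' Applies right censoring: observed time is `min(T, C)` and the event
#' indicator is `1` when the death time precedes (or equals) the censoring
#' time. The latent survival time is retained for generator diagnostics
#' only; no model ever sees it.
#'
#' @param covariates Covariate tibble (one row per subject).
#' @param survival_time Latent death times `T`.
#' @param censoring_time Censoring times `C` (may be `Inf`).
#' @param replicate Replicate id recorded on every row.
#' @param scenario Scenario label recorded on every row.
#' @return A trial dataset tibble with columns `id`, the five covariates,
#'   `time`, `event`, `latent_survival_time`, `replicate`, `scenario`.
#' @export
assemble_dataset <- function(covariates, survival_time, censoring_time,
                             replicate = 1L, scenario = "custom") {
  n <- nrow(covariates)
  if (length(survival_time) != n || length(censoring_time) != n) {
    stop("covariates, survival_time and censoring_time must have equal length",
         call. = FALSE)
  }
  if (any(survival_time <= 0) || any(censoring_time <= 0)) {
    stop("internal error: nonpositive survival or censoring time generated",
         call. = FALSE)
  }
  ds <- dplyr::bind_cols(
    tibble::tibble(id = seq_len(n)),
    covariates[, covariate_names()],
    tibble::tibble(
      time = pmin(survival_time, censoring_time),
      event = as.integer(survival_time <= censoring_time),
      latent_survival_time = survival_time,
      replicate = as.integer(replicate),
      scenario = scenario
    )
  )
  cens_frac <- 1 - mean(ds$event)
  if (cens_frac <= 0 || cens_frac >= 1) {
    # all-event or all-censored datasets break stratified splitting and the
    # censoring KM; flag rather than fail so callers can redraw
    attr(ds, "degenerate") <- TRUE
  }
  ds
}

#' Simulate one complete synthetic trial dataset
#'
#' Convenience pipeline: covariates, log-normal survival times, Weibull
#' censoring, assembly.
#'
#' @param n Subjects per dataset.
#' @param coef [aft_coefficients()]; defaults to the calibrated package
#'   defaults.
#' @param censoring A [censoring_spec()]; defaults to the 61% scenario-1
#'   regime (Weibull shape 2.03, scale 5.72).
#' @param strata Stratum table.
#' @param replicate Replicate id.
#' @param seed Optional integer seed governing the full draw.
#' @return A trial dataset tibble, see [assemble_dataset()].
#' @examples
#' ds <- simulate_trial(200, seed = 1)
#' mean(ds$event)
#' @export
simulate_trial <- function(n, coef = default_aft_coefficients(),
                           censoring = default_censoring_specs()[["61-scenario1"]],
                           strata = trial_strata(), replicate = 1L,
                           seed = NULL) {
  draw <- function() {
    covs <- sample_covariates(n, strata)
    tt <- simulate_survival_times(covs, coef)
    cc <- simulate_censoring(n, censoring)
    assemble_dataset(covs, tt, cc, replicate = replicate,
                     scenario = censoring$label)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Apply an adverse training-data scenario
#'
#' Robustness transforms applied to the training half only:
#' `"drop_early_censored"` removes subjects censored before year 2;
#' `"curtail_5y"` administratively censors all follow-up beyond 5 years
#' (time set to 5, event to 0); `"none"` is the identity.
#'
#' @param data A trial dataset tibble (training half).
#' @param mode One of `"none"`, `"drop_early_censored"`, `"curtail_5y"`.
#' @return The transformed tibble.
#' @export
apply_adverse_scenario <- function(data,
                                   mode = c("none", "drop_early_censored",
                                            "curtail_5y")) {
  mode <- match.arg(mode)
  out <- switch(
    mode,
    none = data,
    drop_early_censored = dplyr::filter(data, !(.data$event == 0 & .data$time < 2)),
    curtail_5y = dplyr::mutate(
      data,
      event = ifelse(.data$time > 5, 0L, .data$event),
      time = pmin(.data$time, 5)
    )
  )
  if (nrow(out) == 0 || sum(out$event) == 0) {
    stop("adverse scenario left a training set with no events", call. = FALSE)
  }
  out
}

#' Split a dataset 50/50 stratified on the event indicator
#'
#' Randomly assigns each subject to the training or test half so that both
#' halves have the same event/censoring proportions (up to one subject per
#' stratum when counts are odd; the extra subject goes to the training
#' half).
#'
#' @param data A trial dataset tibble with >= 2 events and >= 2 censored
#'   subjects.
#' @param seed Optional integer seed.
#' @return The tibble with an added `split` column (`"train"` / `"test"`).
#' @export
split_train_test <- function(data, seed = NULL) {
  if (sum(data$event == 1) < 2 || sum(data$event == 0) < 2) {
    stop("need at least 2 events and 2 censored subjects to split",
         call. = FALSE)
  }
  assign_split <- function() {
    split <- character(nrow(data))
    for (ev in c(0L, 1L)) {
      idx <- which(data$event == ev)
      n_train <- ceiling(length(idx) / 2)
      train_idx <- sample(idx, n_train)
      split[train_idx] <- "train"
      split[setdiff(idx, train_idx)] <- "test"
    }
    split
  }
  split <- if (is.null(seed)) assign_split() else withr::with_seed(seed, assign_split())
  dplyr::mutate(data, split = split)
}

#' Counter-based per-replicate seed
#'
#' Derives a reproducible 32-bit seed for replicate `r` from a master seed,
#' so any replicate can be regenerated in isolation.
#'
#' @param master_seed Integer master seed.
#' @param r Replicate counter (>= 0).
#' @return A positive integer below 2^31.
#' @export
replicate_seed <- function(master_seed, r) {
  m <- 2147483629
  as.integer((as.double(master_seed %% m) * 48271 +
                as.double(r) * 69621 + 1) %% m)
}

#' Write / read a trial dataset as CSV
#'
#' Column layout: `id`, `treatment`, `sex`, `histology`, `margin`, `age`,
#' `time`, `event`, `split` (if assigned), `replicate`. The latent survival
#' time is intentionally not serialized: models must never see it.
#'
#' @param data A trial dataset tibble.
#' @param path File path.
#' @return `write_trial` returns `path` invisibly; `read_trial` returns the
#'   tibble.
#' @export
write_trial <- function(data, path) {
  cols <- intersect(c("id", covariate_names(), "time", "event", "split",
                      "replicate"), names(data))
  readr::write_csv(data[, cols], path)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
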