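#' Fit the Cox proportional hazards baseline
#'
#' Main-effects-only Cox model on the five predictors (treatment, sex,
#' histology, margin, age), maximizing the partial likelihood with the
#' Efron tie correction by default, plus a Breslow-type baseline
#' cumulative hazard estimated at the event times. Backed by
#' [survival::coxph()].
#'
#' @param data Training trial dataset tibble with `time`, `event` and the
#'   five covariates; needs at least one event.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return An object of class `trial_cox` wrapping the `coxph` fit and the
#'   baseline cumulative hazard step function.
#' @examples
#' ds <- simulate_trial(300, seed = 11)
#' fit <- fit_cox(ds)
#' tidy(fit)
#' @export
fit_cox <- function(data, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(data$event) < 1) stop("need at least one event to fit", call. = FALSE)
  # drop constant covariates (unidentifiable) rather than fail
  covs <- covariate_names()
  keep <- covs[vapply(covs, function(cc) stats::var(data[[cc]]) > 0, logical(1))]
  if (length(keep) == 0) {
    fml <- survival::Surv(time, event) ~ 1
    fit <- survival::coxph(fml, data = data, ties = ties)
  } else {
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                   paste(keep, collapse = " + ")))
    fit <- survival::coxph(fml, data = data, ties = ties, x = TRUE)
  }
  # Breslow baseline cumulative hazard at covariate value zero
  bh <- survival::basehaz(fit, centered = FALSE)
  cumhaz_fun <- stats::stepfun(bh$time, c(0, bh$hazard), right = FALSE)
  structure(
    list(fit = fit, covariates = keep, ties = ties,
         cumhaz = cumhaz_fun, max_time = max(bh$time),
         converged = fit$info["convergence"] %||% TRUE),
    class = "trial_cox"
  )
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' @export
print.trial_cox <- function(x, ...) {
  cat("Cox proportional hazards baseline (", x$ties, " ties)\n", sep = "")
  print(x$fit)
  invisible(x)
}

#' Linear prognostic index of a Cox fit
#'
#' \eqn{PI = x'\hat\beta} (uncentered). Higher values mean higher hazard
#' and shorter predicted survival, the opposite-ranking convention used
#' by [harrell_c()].
#'
#' @param fit A `trial_cox` object.
#' @param data Trial dataset tibble.
#' @return Numeric vector of scores.
#' @export
linear_pi <- function(fit, data) {
  if (length(fit$covariates) == 0) return(rep(0, nrow(data)))
  X <- as.matrix(data[, fit$covariates])
  as.numeric(X %*% stats::coef(fit$fit))
}

#' @export
predict_survival.trial_cox <- function(object, data, times, ...) {
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  if (any(times > object$max_time)) {
    warning("horizon beyond the last observed time; baseline hazard carried forward",
            call. = FALSE)
  }
  risk <- exp(linear_pi(object, data))
  H0 <- vapply(pmin(times, object$max_time), object$cumhaz, numeric(1))
  out <- exp(-outer(risk, H0))
  dimnames(out) <- list(data$id, paste0("t", times))
  out
}

#' @method tidy trial_cox
#' @export
tidy.trial_cox <- function(x, ...) {
  if (length(x$covariates) == 0) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric(), hazard.ratio = numeric()))
  }
  s <- summary(x$fit)
  tibble::tibble(
    term = rownames(s$coefficients),
    estimate = s$coefficients[, "coef"],
    std.error = s$coefficients[, "se(coef)"],
    hazard.ratio = s$coefficients[, "exp(coef)"]
  )
}

#' @method glance trial_cox
#' @export
glance.trial_cox <- function(x, ...) {
  tibble::tibble(
    n = x$fit$n,
    n_events = x$fit$nevent,
    ties = x$ties,
    loglik = x$fit$loglik[length(x$fit$loglik)],
    concordance = unname(x$fit$concordance["concordance"])
  )
}
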