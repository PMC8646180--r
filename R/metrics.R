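#' Harrell's concordance index
#'
#' Proportion of usable subject pairs whose risk ordering agrees with
#' their survival ordering, under the opposite-ranking convention: a
#' higher prognostic index predicts shorter survival. Usable pairs are
#' those where the shorter observed time is an event, plus tied-time pairs
#' with exactly one event (the censored subject is known to survive
#' longer). Tied-time pairs with two events are unusable; tied risk scores
#' are credited 0.5.
#'
#' @param pi Prognostic index per subject (higher = worse prognosis).
#' @param time Observed follow-up times.
#' @param event Event indicators (1 = death observed).
#' @return Concordance in `[0, 1]`.
#' @export
harrell_c <- function(pi, time, event) {
  n <- length(pi)
  stopifnot(length(time) == n, length(event) == n)
  E <- matrix(event == 1, n, n)                 # row i: d_i
  earlier <- outer(time, time, "<") & E
  tied_time <- outer(time, time, "==") & E & t(!E)
  usable <- earlier | tied_time                 # ordered (i, j): i "dies first"
  diag(usable) <- FALSE
  conc <- usable & outer(pi, pi, ">")
  tied_pi <- usable & outer(pi, pi, "==")
  n_usable <- sum(usable)
  if (n_usable == 0) stop("no usable pairs: concordance undefined",
                          call. = FALSE)
  (sum(conc) + 0.5 * sum(tied_pi)) / n_usable
}

#' Kaplan-Meier estimate of the censoring distribution
#'
#' Reverses the roles of events and censorings and estimates
#' \eqn{\hat C(t) = P(C > t)} by Kaplan-Meier, as required by the
#' inverse-probability-of-censoring weighting of the Brier score. The
#' returned object evaluates both \eqn{\hat C(t)} (right-continuous) and
#' the left limit \eqn{\hat C(t^-)}.
#'
#' @param time Observed follow-up times.
#' @param event Event indicators (1 = death); censorings (`event == 0`)
#'   are the "events" of the reversed fit.
#' @return An object of class `censoring_km` with functions `$G(t)` and
#'   `$G_minus(t)`.
#' @export
censoring_km <- function(time, event) {
  if (all(event == 1)) {
    G <- function(t) rep(1, length(t))
    return(structure(list(G = G, G_minus = G, times = numeric(0)),
                     class = "censoring_km"))
  }
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  right_cont <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  left_cont <- stats::stepfun(fit$time, c(1, fit$surv), right = TRUE)
  structure(list(G = function(t) right_cont(t),
                 G_minus = function(t) left_cont(t),
                 times = fit$time),
            class = "censoring_km")
}

#' IPCW Brier score at a fixed horizon
#'
#' Inverse-probability-of-censoring-weighted squared prediction error
#' (Graf et al. weighting): subjects with an observed event by `t0`
#' contribute \eqn{(0 - \hat S)^2 / \hat C(t_i^-)}, subjects still under
#' observation beyond `t0` contribute \eqn{(1 - \hat S)^2 / \hat C(t_0)},
#' subjects censored before `t0` contribute nothing; the sum is divided by
#' the total number of subjects. Without censoring this reduces to the
#' plain mean squared error of the survival prediction against the status
#' indicator.
#'
#' @param t0 Horizon (years).
#' @param s_hat Predicted survival probability beyond `t0`, per subject.
#' @param time,event Observed follow-up and event indicator.
#' @param cens Optional [censoring_km()] object (recomputed if missing).
#' @return The weighted Brier score (non-negative scalar).
#' @export
brier_ipcw <- function(t0, s_hat, time, event, cens = NULL) {
  n <- length(time)
  stopifnot(length(s_hat) == n, length(event) == n)
  if (any(s_hat < 0 | s_hat > 1)) {
    stop("predicted survival probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(cens)) cens <- censoring_km(time, event)
  died <- time <= t0 & event == 1
  alive <- time > t0
  w <- numeric(n)
  w[died] <- 1 / cens$G_minus(time[died])
  w[alive] <- 1 / cens$G(t0)
  bad <- !is.finite(w)
  if (any(bad & (died | alive))) {
    warning("censoring weight singular for ", sum(bad), " subject(s); excluded",
            call. = FALSE)
    w[bad] <- 0
  }
  contrib <- numeric(n)
  contrib[died] <- (0 - s_hat[died])^2 * w[died]
  contrib[alive] <- (1 - s_hat[alive])^2 * w[alive]
  sum(contrib) / n
}

#' Integrated Brier score
#'
#' Time-normalized integral of the Brier prediction-error curve over
#' `[0, t_hor]`: \eqn{IBS = \int_0^{t_{hor}} Err(t)\,dt / t_{hor}}, so a
#' constant curve integrates to that constant. The prediction-error curve
#' is only observed at the grid times; by default (`"step"`) it is
#' treated as a right-continuous step function (its value on
#' `[t_l, t_{l+1})` is `Err(t_l)`, the convention of standard
#' prediction-error-curve software), which makes the integral the
#' left-rectangle sum. `"trapezoid"` joins the grid points linearly and
#' `"mean"` averages the positive-time grid points; both are provided for
#' sensitivity analysis.
#'
#' @param grid Increasing evaluation times starting at 0, ending at the
#'   horizon (default grid `0:5` years).
#' @param brier Brier score at each grid time.
#' @param method `"step"` (default), `"trapezoid"` or `"mean"`.
#' @return The integrated score.
#' @export
integrated_brier <- function(grid, brier,
                             method = c("step", "trapezoid", "mean")) {
  method <- match.arg(method)
  stopifnot(length(grid) == length(brier))
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  if (method == "mean") return(mean(brier[grid > 0]))
  widths <- diff(grid)
  area <- if (method == "step") {
    sum(widths * utils::head(brier, -1))
  } else {
    sum(widths * (utils::head(brier, -1) + utils::tail(brier, -1)) / 2)
  }
  area / (max(grid) - min(grid))
}

#' Quartile-group miscalibration error
#'
#' Splits subjects into `groups` equal-count groups by their predicted
#' survival probability at `t0` (ties broken by stable subject order),
#' compares each group's Kaplan-Meier survival at `t0` with its mean
#' predicted survival, and returns the mean squared difference over the
#' groups.
#'
#' @param t0 Horizon (years).
#' @param s_hat Predicted survival at `t0` per subject.
#' @param time,event Observed follow-up and event indicator.
#' @param groups Number of quantile groups (default 4).
#' @param min_group_size Minimum subjects per group (default 5).
#' @return The miscalibration mean squared error.
#' @export
miscalibration <- function(t0, s_hat, time, event, groups = 4,
                           min_group_size = 5) {
  n <- length(s_hat)
  if (n < groups * min_group_size) {
    stop(sprintf("need at least %d subjects for %d groups",
                 groups * min_group_size, groups), call. = FALSE)
  }
  grp <- dplyr::ntile(rank(s_hat, ties.method = "first"), groups)
  sq <- vapply(seq_len(groups), function(g) {
    idx <- grp == g
    km <- survival::survfit(survival::Surv(time[idx], event[idx]) ~ 1)
    s_km <- summary(km, times = t0, extend = TRUE)$surv
    (s_km - mean(s_hat[idx]))^2
  }, numeric(1))
  mean(sq)
}

#' All evaluation metrics for one test set
#'
#' Computes the full metric panel of the study for one method on one test
#' half: Harrell's C on the supplied prognostic index, the IPCW Brier
#' score on the yearly grid 0-5, the integrated Brier score at 5 years,
#' and the quartile miscalibration error at 2 and 5 years.
#'
#' @param pi Prognostic index per test subject (higher = worse).
#' @param surv_matrix Predicted survival at the grid times, `n x 6` matrix
#'   for `times = 0:5` (columns in grid order).
#' @param time,event Observed test follow-up and event indicator.
#' @param grid Brier evaluation grid (default `0:5`).
#' @return A tidy tibble with columns `metric` and `value` (rows:
#'   `cindex`, `brier_0` ... `brier_5`, `ibs_5`, `miscal_2`, `miscal_5`).
#' @export
evaluate_predictions <- function(pi, surv_matrix, time, event, grid = 0:5) {
  cens <- censoring_km(time, event)
  briers <- vapply(seq_along(grid), function(k) {
    brier_ipcw(grid[k], surv_matrix[, k], time, event, cens)
  }, numeric(1))
  tibble::tibble(
    metric = c("cindex", paste0("brier_", grid), "ibs_5", "miscal_2",
               "miscal_5"),
    value = c(
      harrell_c(pi, time, event),
      briers,
      integrated_brier(grid, briers),
      miscalibration(2, surv_matrix[, which(grid == 2)], time, event),
      miscalibration(5, surv_matrix[, which(grid == 5)], time, event)
    )
  )
}
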