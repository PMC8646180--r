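#' Discrete-time interval schemes
#'
#' Builds the interval discretization of follow-up used by the partial
#' logistic networks. Intervals are left-open/right-closed,
#' \eqn{A_l = (\tau_{l-1}, \tau_l]} with \eqn{\tau_0 = 0}; the last interval
#' is open-ended and absorbs all longer follow-up. Shipped schemes:
#' `"yearly"` (L = 8, widths 1 year, last interval beyond 7 years),
#' `"six_month"` (L = 16, widths 0.5), `"three_month"` (L = 32, widths
#' 0.25). Midpoints are interval centers; the open last interval's midpoint
#' is the last boundary plus half the preceding width.
#'
#' @param kind `"yearly"`, `"six_month"` or `"three_month"`.
#' @return An `interval_scheme`: list with `L`, `boundaries`
#'   (\eqn{\tau_0, \ldots, \tau_{L-1}}), `upper` (upper boundary per
#'   interval, `Inf` for the last) and `midpoints`.
#' @examples
#' make_scheme("yearly")$midpoints
#' @export
make_scheme <- function(kind = c("yearly", "six_month", "three_month")) {
  kind <- match.arg(kind)
  width <- switch(kind, yearly = 1, six_month = 0.5, three_month = 0.25)
  L <- as.integer(8 / width)
  boundaries <- width * (0:(L - 1))
  upper <- c(boundaries[-1], Inf)
  midpoints <- c((boundaries[-1] + boundaries[-L]) / 2,
                 boundaries[L] + width / 2)
  structure(list(kind = kind, L = L, boundaries = boundaries, upper = upper,
                 midpoints = midpoints),
            class = "interval_scheme")
}

#' Interval index of a follow-up time
#'
#' Returns the smallest `l` with \eqn{t \le \tau_l}; exact boundaries
#' belong to the earlier interval (right-closed convention) and times
#' beyond the last boundary fall in interval `L`.
#'
#' @param t Positive follow-up times (years); vectorized.
#' @param scheme An [make_scheme()] scheme.
#' @return Integer interval indices in `1:L`.
#' @export
interval_of <- function(t, scheme) {
  if (any(t <= 0)) stop("follow-up times must be strictly positive",
                        call. = FALSE)
  findInterval(t, scheme$boundaries, left.open = TRUE)
}

#' Person-period expansion for training
#'
#' Expands each subject into one row per interval at risk: subject `i`
#' with follow-up \eqn{t_i} in interval \eqn{l_i} contributes rows
#' \eqn{l = 1, \ldots, l_i} with binary target \eqn{d_{il} =} `event` in
#' row \eqn{l_i} and 0 before. The interval containing a censoring time is
#' included (with target 0) by default, matching the discrete-hazard
#' likelihood in which a subject contributes every interval they are at
#' risk in; set `include_censoring_interval = FALSE` to drop the partial
#' last interval of censored subjects for sensitivity analysis.
#'
#' @param data A trial dataset tibble with `id`, covariates, `time`,
#'   `event`.
#' @param scheme An interval scheme.
#' @param include_censoring_interval Keep the interval in which a subject
#'   is censored (default `TRUE`).
#' @return A long tibble with columns `id`, `interval`, `midpoint`, the
#'   five covariates and `d_target`; attribute `role = "train"`.
#' @export
to_long_train <- function(data, scheme, include_censoring_interval = TRUE) {
  if (nrow(data) == 0) stop("dataset is empty", call. = FALSE)
  li <- interval_of(data$time, scheme)
  if (!include_censoring_interval) {
    li <- ifelse(data$event == 0, pmax(li - 1L, 0L), li)
  }
  keep <- li > 0
  rows <- rep(which(keep), li[keep])
  interval <- sequence(li[keep])
  out <- dplyr::bind_cols(
    tibble::tibble(
      id = data$id[rows],
      interval = interval,
      midpoint = scheme$midpoints[interval]
    ),
    data[rows, covariate_names()],
    tibble::tibble(
      d_target = as.integer(data$event[rows] == 1 & interval == rep(li[keep], li[keep]))
    )
  )
  attr(out, "role") <- "train"
  attr(out, "scheme") <- scheme
  out
}

#' Person-period expansion for prediction
#'
#' Every subject is repeated for all `L` intervals (subject-major,
#' interval-minor order), so a forward pass yields the full hazard matrix.
#'
#' @inheritParams to_long_train
#' @return A long tibble with `id`, `interval`, `midpoint` and covariates;
#'   attribute `role = "test"`.
#' @export
to_long_test <- function(data, scheme) {
  if (nrow(data) == 0) stop("dataset is empty", call. = FALSE)
  n <- nrow(data)
  rows <- rep(seq_len(n), each = scheme$L)
  interval <- rep(seq_len(scheme$L), times = n)
  out <- dplyr::bind_cols(
    tibble::tibble(
      id = data$id[rows],
      interval = interval,
      midpoint = scheme$midpoints[interval]
    ),
    data[rows, covariate_names()]
  )
  attr(out, "role") <- "test"
  attr(out, "scheme") <- scheme
  out
}
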