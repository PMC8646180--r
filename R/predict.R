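#' Predicted hazard matrix of a fitted network
#'
#' Expands the dataset to the full person-period grid ([to_long_test()]),
#' runs the forward pass, and reshapes the per-row hazards to one row per
#' subject and one column per interval.
#'
#' @param model A fitted `plann` model.
#' @param data A trial dataset tibble (covariates complete).
#' @return An `n x L` matrix of discrete hazards strictly inside (0, 1).
#' @export
predict_hazards <- function(model, data) {
  long <- to_long_test(data, model$scheme)
  X <- switch(model$feature_type,
              original = features_original(long, model$scaler),
              extended = features_extended(long, model$scaler, model$scheme$L))
  h <- plann_forward(model$net, X, model$activation)
  matrix(h, nrow = nrow(data), ncol = model$scheme$L, byrow = TRUE,
         dimnames = list(data$id, paste0("interval_", seq_len(model$scheme$L))))
}

#' Step survival function from a hazard matrix
#'
#' Discrete-time survival: \eqn{S(t_0) = \prod_{l : \tau_l \le t_0} (1 -
#' h_l)}, the product over all intervals whose upper boundary has been
#' passed by `t_0` (so `S(t0) = 1` before the first boundary and `S(0) =
#' 1`).
#'
#' @param hazards `n x L` hazard matrix.
#' @param scheme Interval scheme the hazards refer to.
#' @param times Evaluation times `t0 >= 0` (vectorized).
#' @return An `n x length(times)` matrix of survival probabilities.
#' @export
survival_curve <- function(hazards, scheme, times) {
  if (any(times < 0)) stop("evaluation times must be non-negative",
                           call. = FALSE)
  hazards <- as.matrix(hazards)
  cum <- cbind(0, t(apply(log1p(-hazards), 1, cumsum)))
  # number of completed intervals by each t0 (upper boundary <= t0)
  k <- vapply(times, function(t0) sum(scheme$upper <= t0), integer(1))
  out <- exp(cum[, k + 1, drop = FALSE])
  dimnames(out) <- list(rownames(hazards), paste0("t", times))
  out
}

#' Model-based survival probabilities at fixed horizons
#'
#' @param object A fitted model (`plann` or `trial_cox`).
#' @param data Trial dataset tibble to predict for.
#' @param times Horizon(s) in years.
#' @param ... Unused.
#' @return `n x length(times)` matrix of survival probabilities.
#' @export
predict_survival <- function(object, data, times, ...) {
  UseMethod("predict_survival")
}

#' @export
predict_survival.plann <- function(object, data, times, ...) {
  survival_curve(predict_hazards(object, data), object$scheme, times)
}

#' Nonlinear prognostic index of a partial logistic network
#'
#' The time-dependent index \eqn{\theta_l = \mathrm{logit}(h_l)} (the
#' pre-activation of the output node) averaged over all `L` intervals,
#' giving one scalar score per subject. Higher scores mean larger
#' predicted hazards, hence shorter predicted survival (opposite
#' ranking), which is the convention [harrell_c()] expects.
#'
#' @param model A fitted `plann` model.
#' @param data Trial dataset tibble.
#' @return Numeric vector of scores, one per subject.
#' @export
nonlinear_pi <- function(model, data) {
  h <- predict_hazards(model, data)
  rowMeans(stats::qlogis(clip_hazard(h)))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy plann
#' @export
tidy.plann <- function(x, ...) {
  if (x$net$H > 0) {
    w1 <- tibble::tibble(
      layer = "input_hidden",
      from = rep(rownames_or_idx(x$net$W1), ncol(x$net$W1)),
      to = rep(paste0("hidden_", seq_len(ncol(x$net$W1))), each = nrow(x$net$W1)),
      weight = as.numeric(x$net$W1)
    )
    w2 <- tibble::tibble(
      layer = "hidden_output",
      from = c("bias", paste0("hidden_", seq_len(nrow(x$net$W2) - 1))),
      to = "output",
      weight = as.numeric(x$net$W2)
    )
    dplyr::bind_rows(w1, w2)
  } else {
    tibble::tibble(layer = "input_output",
                   from = rownames_or_idx(x$net$W),
                   to = "output",
                   weight = as.numeric(x$net$W))
  }
}

rownames_or_idx <- function(W) {
  c("bias", paste0("x", seq_len(nrow(W) - 1)))
}

#' @method glance plann
#' @export
glance.plann <- function(x, ...) {
  n_par <- length(pack_weights(x$net))
  tibble::tibble(
    architecture = x$feature_type,
    hidden_nodes = x$net$H,
    hidden_activation = x$activation,
    n_parameters = n_par,
    n_rows = x$n_rows,
    loss = x$loss,
    converged = x$converged
  )
}

#' Survival-curve plot for fitted models
#'
#' Plots step survival curves for (a subset of) subjects as predicted by a
#' fitted network or Cox model.
#'
#' @param model Fitted model accepted by [predict_survival()].
#' @param data Trial dataset tibble.
#' @param ids Subject ids to draw (default: first 10).
#' @param horizon Last evaluation time (years).
#' @return A ggplot object.
#' @export
plot_survival_curves <- function(model, data, ids = utils::head(data$id, 10),
                                 horizon = 8) {
  sub <- dplyr::filter(data, .data$id %in% ids)
  grid <- seq(0, horizon, by = 0.25)
  S <- predict_survival(model, sub, grid)
  df <- tibble::tibble(
    id = factor(rep(sub$id, times = length(grid))),
    time = rep(grid, each = nrow(sub)),
    survival = as.numeric(S)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   group = .data$id, colour = .data$id)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years", y = "Predicted survival probability") +
    ggplot2::theme_minimal()
}
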