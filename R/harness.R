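#' Scenario configuration
#'
#' Bundles the knobs of one Monte-Carlo cell: sample size, number of
#' replicates, censoring regime, adverse training-data transform and
#' master seed.
#'
#' @param n Subjects per dataset (the study uses 250 or 1000).
#' @param B Number of Monte-Carlo replicates.
#' @param censoring A [censoring_spec()].
#' @param adverse `"none"`, `"drop_early_censored"` or `"curtail_5y"`.
#' @param master_seed Integer master seed; per-replicate seeds are derived
#'   with [replicate_seed()].
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(n = 1000, B = 100,
                            censoring = default_censoring_specs()[["61-scenario1"]],
                            adverse = c("none", "drop_early_censored",
                                        "curtail_5y"),
                            master_seed = 1L) {
  adverse <- match.arg(adverse)
  stopifnot(n >= 16, B >= 1)
  structure(list(n = as.integer(n), B = as.integer(B), censoring = censoring,
                 adverse = adverse, master_seed = as.integer(master_seed)),
            class = "scenario_config")
}

#' Default hyperparameter grids
#'
#' Search grids spanning the qualitative tuning landscape of the study:
#' small networks with a range of regularization strengths for the
#' original architecture; node size, dropout, learning rate, momentum,
#' weak-class weight and hidden activation for the extended one.
#'
#' @param method `"plann_original"` or `"plann_extended"`.
#' @return A tibble, one row per hyperparameter combination.
#' @export
default_tuning_grid <- function(method = c("plann_original", "plann_extended")) {
  method <- match.arg(method)
  if (method == "plann_original") {
    tidyr::expand_grid(hidden_size = c(1, 2, 3, 4, 6, 8),
                       decay = c(0, 0.01, 0.05, 0.1, 0.2))
  } else {
    tidyr::expand_grid(nodesize = c(2, 4, 8),
                       dropout = c(0, 0.1, 0.2),
                       learning_rate = c(0.01, 0.05, 0.1),
                       momentum = c(0, 0.5, 0.9),
                       class_weight = c(1, 1.05),
                       hidden_activation = c("logistic", "relu", "tanh"))
  }
}

# stratified k-fold assignment on the event indicator
make_folds <- function(event, k = 5, seed = NULL) {
  assign_folds <- function() {
    fold <- integer(length(event))
    for (ev in unique(event)) {
      idx <- sample(which(event == ev))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  }
  if (is.null(seed)) assign_folds() else withr::with_seed(seed, assign_folds())
}

fit_method <- function(method, train, scheme, spec, seed) {
  long <- to_long_train(train, scheme)
  switch(method,
         plann_original = train_plann_original(long, spec, seed = seed,
                                               scheme = scheme),
         plann_extended = train_plann_extended(long, spec, seed = seed,
                                               scheme = scheme),
         stop("unknown method: ", method, call. = FALSE))
}

spec_from_row <- function(method, row) {
  if (method == "plann_original") {
    plann_original_spec(hidden_size = row$hidden_size, decay = row$decay)
  } else {
    plann_extended_spec(nodesize = row$nodesize, dropout = row$dropout,
                        learning_rate = row$learning_rate,
                        momentum = row$momentum,
                        class_weight = row$class_weight,
                        hidden_activation = row$hidden_activation)
  }
}

#' Cross-validated grid search for the network hyperparameters
#'
#' 5-fold cross-validation on the training half of one tuning dataset:
#' for every grid combination, the network is fitted on four folds and
#' scored on the held-out fold; the criterion is averaged over the five
#' folds. `criterion = "ibs5"` selects the smallest cross-validated
#' integrated Brier score at 5 years, `"cindex"` the largest
#' cross-validated concordance. Folds are stratified on the event
#' indicator and identical for every combination (and across methods for
#' a fixed seed). Ties are resolved toward the least complex combination
#' (fewest hidden nodes, then strongest regularization).
#'
#' @param method `"plann_original"` or `"plann_extended"`.
#' @param grid Hyperparameter grid tibble, see [default_tuning_grid()].
#' @param train Training half of the tuning dataset.
#' @param scheme Interval scheme.
#' @param criterion `"ibs5"` or `"cindex"`.
#' @param k Number of folds.
#' @param seed Seed for fold assignment and network initialization.
#' @return A `tuning_result`: list with `best` (one-row tibble), `cv`
#'   (per-combination CV means) and `folds`.
#' @export
cv_tune <- function(method, grid = default_tuning_grid(method), train,
                    scheme = make_scheme("yearly"),
                    criterion = c("ibs5", "cindex"), k = 5, seed = 1L) {
  method <- match.arg(method, c("plann_original", "plann_extended"))
  criterion <- match.arg(criterion)
  if (nrow(grid) == 0) stop("empty tuning grid", call. = FALSE)
  folds <- make_folds(train$event, k = k, seed = seed)
  grid_time <- 0:5
  score_one <- function(row) {
    vals <- vapply(seq_len(k), function(f) {
      tr <- train[folds != f, ]
      ho <- train[folds == f, ]
      fit <- tryCatch(
        fit_method(method, tr, scheme, spec_from_row(method, row), seed = seed),
        error = function(e) NULL
      )
      if (is.null(fit)) return(NA_real_)
      if (criterion == "ibs5") {
        S <- predict_survival(fit, ho, grid_time)
        cens <- censoring_km(ho$time, ho$event)
        briers <- vapply(seq_along(grid_time), function(j) {
          brier_ipcw(grid_time[j], S[, j], ho$time, ho$event, cens)
        }, numeric(1))
        integrated_brier(grid_time, briers)
      } else {
        harrell_c(nonlinear_pi(fit, ho), ho$time, ho$event)
      }
    }, numeric(1))
    mean(vals)
  }
  cv <- grid
  cv$cv_value <- vapply(seq_len(nrow(grid)), function(i) score_one(grid[i, ]),
                        numeric(1))
  if (all(is.na(cv$cv_value))) stop("tuning failed for every grid point",
                                    call. = FALSE)
  # complexity tie-break: fewest hidden nodes first, then strongest
  # regularization (largest decay / dropout)
  size_col <- if (method == "plann_original") "hidden_size" else "nodesize"
  reg_col <- if (method == "plann_original") "decay" else "dropout"
  ord <- order(
    if (criterion == "ibs5") cv$cv_value else -cv$cv_value,
    cv[[size_col]], -cv[[reg_col]]
  )
  structure(list(method = method, criterion = criterion,
                 best = cv[ord[1], ], cv = cv, folds = folds),
            class = "tuning_result")
}

#' Run one Monte-Carlo replicate
#'
#' Simulates dataset `r` of the scenario, splits it 50/50 stratified on
#' the event indicator, applies the adverse transform to the training half
#' only, fits the Cox baseline and the requested networks on the identical
#' training half, and evaluates every method on the identical test half.
#'
#' @param r Replicate counter.
#' @param scenario A [scenario_config()].
#' @param specs Named list of fitted-model specs, e.g.
#'   `list(plann_original = plann_original_spec())`; the Cox baseline is
#'   always included.
#' @param coef Generator coefficients.
#' @param strata Stratum table.
#' @param scheme Interval scheme for the networks.
#' @return Tidy tibble with columns `replicate`, `method`, `metric`,
#'   `value`.
#' @export
run_replicate <- function(r, scenario, specs = list(),
                          coef = default_aft_coefficients(),
                          strata = trial_strata(),
                          scheme = make_scheme("yearly")) {
  seed <- replicate_seed(scenario$master_seed, r)
  ds <- simulate_trial(scenario$n, coef = coef,
                       censoring = scenario$censoring, strata = strata,
                       replicate = r, seed = seed)
  if (isTRUE(attr(ds, "degenerate"))) {
    stop("degenerate replicate: all events or all censored", call. = FALSE)
  }
  ds <- split_train_test(ds, seed = seed + 1L)
  train <- apply_adverse_scenario(dplyr::filter(ds, .data$split == "train"),
                                  scenario$adverse)
  test <- dplyr::filter(ds, .data$split == "test")
  if (sum(test$event) < 2) {
    stop("degenerate replicate: too few test events", call. = FALSE)
  }
  grid_time <- 0:5
  rows <- list()
  cox <- fit_cox(train)
  rows$cox <- evaluate_predictions(linear_pi(cox, test),
                                   predict_survival(cox, test, grid_time),
                                   test$time, test$event, grid_time)
  for (m in names(specs)) {
    fit <- fit_method(m, train, scheme, specs[[m]], seed = seed + 2L)
    rows[[m]] <- evaluate_predictions(nonlinear_pi(fit, test),
                                      predict_survival(fit, test, grid_time),
                                      test$time, test$event, grid_time)
  }
  dplyr::bind_rows(lapply(names(rows), function(m) {
    dplyr::mutate(rows[[m]], method = m, replicate = r, .before = 1)
  }))
}

#' Run a Monte-Carlo experiment cell
#'
#' Repeats [run_replicate()] `B` times (degenerate replicates are redrawn
#' with fresh counters and logged) and aggregates each metric's mean and
#' standard deviation over replicates.
#'
#' @param scenario A [scenario_config()].
#' @param specs Named list of network specs (see [run_replicate()]).
#' @param coef,strata,scheme Generator and discretization settings.
#' @param progress Print a dot every 10 replicates.
#' @return A `metric_report`: list with `replicates` (tidy per-replicate
#'   values), `summary` (mean and sd per method x metric) and
#'   `skipped` (redrawn replicate counters).
#' @export
run_experiment <- function(scenario, specs = list(),
                           coef = default_aft_coefficients(),
                           strata = trial_strata(),
                           scheme = make_scheme("yearly"),
                           progress = FALSE) {
  out <- vector("list", scenario$B)
  skipped <- integer(0)
  done <- 0
  r <- 0
  max_draws <- ceiling(scenario$B / 0.8)
  while (done < scenario$B && r < max_draws) {
    r <- r + 1
    res <- tryCatch(run_replicate(r, scenario, specs, coef, strata, scheme),
                    error = function(e) e)
    if (inherits(res, "error")) {
      skipped <- c(skipped, r)
      next
    }
    done <- done + 1
    out[[done]] <- res
    if (progress && done %% 10 == 0) cat(".")
  }
  if (done < scenario$B) {
    stop(sprintf("only %d of %d replicates succeeded (>= 80%% required)",
                 done, scenario$B), call. = FALSE)
  }
  replicates <- dplyr::bind_rows(out)
  summary <- replicates |>
    dplyr::group_by(.data$method, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n_replicates = dplyr::n(), .groups = "drop")
  structure(list(scenario = scenario, replicates = replicates,
                 summary = summary, skipped = skipped),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Monte-Carlo metric report: n = %d, B = %d, censoring %s, adverse = %s\n",
              x$scenario$n, x$scenario$B, x$scenario$censoring$label,
              x$scenario$adverse))
  print(x$summary, n = Inf)
  invisible(x)
}

#' @method tidy metric_report
#' @export
tidy.metric_report <- function(x, ...) x$replicates

#' @method glance metric_report
#' @export
glance.metric_report <- function(x, ...) {
  tidyr::pivot_wider(
    dplyr::filter(x$summary,
                  .data$metric %in% c("cindex", "ibs_5", "brier_5",
                                      "miscal_2", "miscal_5")),
    id_cols = "method", names_from = "metric", values_from = "mean"
  )
}

#' Boxplots of per-replicate metric values
#'
#' @param object A `metric_report`.
#' @param metrics Metrics to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot metric_report
#' @export
autoplot.metric_report <- function(object,
                                   metrics = c("cindex", "ibs_5", "brier_5",
                                               "miscal_2", "miscal_5"), ...) {
  df <- dplyr::filter(object$replicates, .data$metric %in% metrics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$value,
                                   fill = .data$method)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Brier prediction-error curves averaged over replicates
#'
#' @param report A `metric_report`.
#' @return A ggplot object showing the mean Brier score per year and
#'   method with one-sd ribbons.
#' @export
plot_brier_curves <- function(report) {
  df <- report$replicates |>
    dplyr::filter(grepl("^brier_", .data$metric)) |>
    dplyr::mutate(year = as.numeric(sub("brier_", "", .data$metric))) |>
    dplyr::group_by(.data$method, .data$year) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$year, y = .data$mean,
                                   colour = .data$method,
                                   fill = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Years", y = "IPCW Brier score") +
    ggplot2::theme_minimal()
}

#' Pinned tuned hyperparameters
#'
#' Returns the frozen hyperparameter combination selected once by
#' cross-validated grid search on a single n = 1000 tuning dataset per
#' censoring scenario (the tune-once-then-freeze protocol), as shipped in
#' the package configuration.
#'
#' @param method `"plann_original"` or `"plann_extended"`.
#' @param criterion `"ibs5"` or `"cindex"`.
#' @return A `plann_original_spec` or `plann_extended_spec`.
#' @export
pinned_spec <- function(method = c("plann_original", "plann_extended"),
                        criterion = c("ibs5", "cindex")) {
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  cfg <- default_config()$tuned[[method]][[criterion]]
  if (method == "plann_original") {
    plann_original_spec(hidden_size = cfg$hidden_size, decay = cfg$decay,
                        maxit = cfg$maxit)
  } else {
    plann_extended_spec(nodesize = cfg$nodesize, dropout = cfg$dropout,
                        learning_rate = cfg$learning_rate,
                        momentum = cfg$momentum,
                        class_weight = cfg$class_weight,
                        hidden_activation = cfg$hidden_activation,
                        epochs = cfg$epochs, batch_size = cfg$batch_size)
  }
}
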