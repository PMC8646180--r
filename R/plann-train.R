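new_plann <- function(subclass, net, spec, scheme, scaler, activation,
                      feature_type, loss, converged, n_rows) {
  structure(
    list(net = net, spec = spec, scheme = scheme, scaler = scaler,
         activation = activation, feature_type = feature_type,
         loss = loss, converged = converged, n_rows = n_rows),
    class = c(subclass, "plann")
  )
}

#' Train the original partial logistic network
#'
#' Full-batch minimisation of the weight-decay-penalized discrete-hazard
#' cross-entropy by BFGS with analytic gradients. Continuous inputs (the
#' interval midpoint and age) are standardized by training mean and
#' standard deviation; the scaler is stored in the fitted model and reused
#' at prediction time. With `hidden_size = 0` the architecture collapses to
#' a logistic regression on the person-period table, which the test suite
#' exploits as an oracle hook.
#'
#' @param long A training person-period expansion from [to_long_train()].
#' @param spec A [plann_original_spec()].
#' @param seed Integer seed for the weight initialization.
#' @param scheme Interval scheme; defaults to the one attached to `long`.
#' @return A fitted model of class `c("plann_original", "plann")`.
#' @examples
#' ds <- simulate_trial(120, seed = 7)
#' long <- to_long_train(ds, make_scheme("yearly"))
#' fit <- train_plann_original(long, plann_original_spec(hidden_size = 2),
#'                             seed = 1)
#' glance(fit)
#' @export
train_plann_original <- function(long, spec = plann_original_spec(),
                                 seed = 1L, scheme = NULL) {
  scheme <- long_scheme(long, scheme)
  if (sum(long$d_target) < 1) {
    stop("training expansion contains no event rows", call. = FALSE)
  }
  scaler <- make_scaler(long, c("midpoint", "age"))
  X <- features_original(long, scaler)
  d <- long$d_target
  H <- spec$hidden_size
  J <- ncol(X)
  n_par <- if (H > 0) (J + 1) * H + (H + 1) else J + 1
  par0 <- withr::with_seed(seed, stats::runif(n_par, -spec$init_range,
                                              spec$init_range))
  opt <- stats::optim(
    par0,
    fn = plann_objective, gr = plann_gradient,
    X = X, d = d, row_weights = 1, decay = spec$decay, H = H,
    activation = "logistic",
    method = "BFGS",
    control = list(maxit = spec$maxit, reltol = spec$reltol)
  )
  converged <- opt$convergence == 0
  if (!converged) {
    warning("BFGS did not converge within maxit; returning best-so-far weights",
            call. = FALSE)
  }
  new_plann("plann_original", unpack_weights(opt$par, J, H), spec, scheme,
            scaler, activation = "logistic", feature_type = "original",
            loss = opt$value, converged = converged, n_rows = nrow(long))
}

#' Train the extended partial logistic network
#'
#' Mini-batch stochastic gradient descent with momentum on the
#' class-weighted discrete-hazard cross-entropy (batch means), with
#' inverted dropout on the hidden layer during training (scaling kept
#' activations by `1/(1 - dropout)` so no rescaling is needed at
#' prediction time, when dropout is disabled). The `L` interval dummies
#' plus the five covariates form the input layer; hidden activation per
#' the spec, output strictly logistic. Weights use Glorot-style uniform
#' initialization.
#'
#' @param long A training person-period expansion.
#' @param spec A [plann_extended_spec()].
#' @param seed Integer seed governing initialization, shuffling and
#'   dropout masks.
#' @param scheme Interval scheme; defaults to the one attached to `long`.
#' @return A fitted model of class `c("plann_extended", "plann")`.
#' @export
train_plann_extended <- function(long, spec = plann_extended_spec(),
                                 seed = 1L, scheme = NULL) {
  scheme <- long_scheme(long, scheme)
  if (sum(long$d_target) < 1) {
    stop("training expansion contains no event rows", call. = FALSE)
  }
  scaler <- make_scaler(long, "age")
  X <- features_extended(long, scaler, scheme$L)
  d <- long$d_target
  w_row <- ifelse(d == 1, spec$class_weight, 1)
  H <- spec$nodesize
  J <- ncol(X)
  act <- spec$hidden_activation
  n <- nrow(X)
  keep <- 1 - spec$dropout

  run <- function() {
    glorot <- function(fan_in, fan_out) {
      lim <- sqrt(6 / (fan_in + fan_out))
      matrix(stats::runif((fan_in + 1) * fan_out, -lim, lim), fan_in + 1, fan_out)
    }
    W1 <- glorot(J, H)
    W2 <- glorot(H, 1)
    V1 <- W1 * 0
    V2 <- W2 * 0
    g <- activation_fun(act)
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = spec$batch_size)
      for (st in starts) {
        idx <- ord[st:min(st + spec$batch_size - 1, n)]
        B <- length(idx)
        X1 <- cbind(1, X[idx, , drop = FALSE])
        A <- X1 %*% W1
        Z <- g(A)
        if (spec$dropout > 0) {
          mask <- matrix(stats::runif(B * H) < keep, B, H) / keep
          Zd <- Z * mask
        } else {
          mask <- NULL
          Zd <- Z
        }
        Z1 <- cbind(1, Zd)
        h <- stats::plogis(Z1 %*% W2)
        delta <- (w_row[idx] * (h - d[idx])) / B
        gW2 <- crossprod(Z1, delta)
        dZ <- delta %*% t(W2[-1, , drop = FALSE])
        if (!is.null(mask)) dZ <- dZ * mask
        dA <- dZ * activation_grad(act, A, Z)
        gW1 <- crossprod(X1, dA)
        V1 <- spec$momentum * V1 - spec$learning_rate * gW1
        V2 <- spec$momentum * V2 - spec$learning_rate * gW2
        W1 <- W1 + V1
        W2 <- W2 + V2
      }
    }
    list(H = H, W1 = W1, W2 = W2)
  }
  net <- withr::with_seed(seed, run())
  h_final <- forward_cache(net, X, act)$h
  loss <- plann_loss(h_final, d, row_weights = w_row)
  new_plann("plann_extended", net, spec, scheme, scaler, activation = act,
            feature_type = "extended", loss = loss, converged = TRUE,
            n_rows = nrow(long))
}

#' @export
print.plann <- function(x, ...) {
  cat(sprintf("Partial logistic network (%s), %d hidden node(s), %s hidden activation\n",
              x$feature_type, x$net$H, x$activation))
  cat(sprintf("  trained on %d person-period rows; loss %.4f; converged: %s\n",
              x$n_rows, x$loss, x$converged))
  invisible(x)
}

#' Serialize a fitted network to a JSON file
#'
#' Stores weights, scaler, hyperparameters and the interval scheme so a
#' fitted model can be reloaded with [read_plann()] and produce identical
#' predictions.
#'
#' @param model A fitted `plann` model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plann <- function(model, path) {
  payload <- list(
    class = class(model)[1],
    feature_type = model$feature_type,
    activation = model$activation,
    H = model$net$H,
    weights = if (model$net$H > 0) {
      list(W1 = model$net$W1, W2 = model$net$W2)
    } else {
      list(W = model$net$W)
    },
    scaler = list(cols = model$scaler$cols,
                  center = as.list(model$scaler$center),
                  scale = as.list(model$scaler$scale)),
    spec = unclass(model$spec),
    scheme = unclass(model$scheme),
    loss = model$loss, converged = model$converged, n_rows = model$n_rows
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plann
#' @export
read_plann <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  net <- if (p$H > 0) {
    list(H = as.integer(p$H), W1 = as.matrix(p$weights$W1),
         W2 = as.matrix(p$weights$W2))
  } else {
    list(H = 0L, W = as.matrix(p$weights$W))
  }
  scheme <- structure(p$scheme, class = "interval_scheme")
  spec_class <- if (p$class == "plann_original") "plann_original_spec" else "plann_extended_spec"
  new_plann(p$class, net = net, scheme = scheme,
            spec = structure(p$spec, class = spec_class),
            scaler = p$scaler, activation = p$activation,
            feature_type = p$feature_type, loss = p$loss,
            converged = p$converged, n_rows = p$n_rows)
}
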