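#' Hyperparameters of the original partial logistic network
#'
#' One hidden layer, logistic activations throughout, the interval
#' midpoint as a single continuous time input next to the five covariates,
#' and a quadratic weight-decay penalty on all weights (biases included).
#' Trained full-batch by BFGS on the penalized discrete-hazard
#' cross-entropy.
#'
#' @param hidden_size Number of hidden nodes `H` (0 gives the
#'   no-hidden-layer testing hook, a plain logistic regression on the
#'   person-period table).
#' @param decay Weight-decay coefficient (>= 0) multiplying the sum of
#'   squared weights added to the loss.
#' @param maxit Maximum BFGS iterations.
#' @param init_range Initial weights drawn uniformly in `+/- init_range`.
#' @param reltol Relative convergence tolerance passed to [stats::optim()].
#' @return A `plann_original_spec` object.
#' @export
plann_original_spec <- function(hidden_size = 3, decay = 0.1, maxit = 300,
                                init_range = 0.5, reltol = 1e-10) {
  stopifnot(hidden_size >= 0, decay >= 0, maxit >= 1, init_range > 0)
  structure(list(hidden_size = as.integer(hidden_size), decay = decay,
                 maxit = as.integer(maxit), init_range = init_range,
                 reltol = reltol),
            class = "plann_original_spec")
}

#' Hyperparameters of the extended partial logistic network
#'
#' The `L` intervals enter as `L` separate 0/1 input features (dummy
#' coding) instead of one midpoint input; the hidden activation is
#' selectable (logistic, ReLU or tanh) while the output activation stays
#' strictly logistic. Trained by mini-batch stochastic gradient descent
#' with momentum, inverted dropout on the hidden layer, and an optional
#' weak-class weight multiplying the loss of event rows (the minority
#' class of the person-period table).
#'
#' @param nodesize Hidden nodes.
#' @param dropout Dropout rate on the hidden layer, in `[0, 1)`.
#' @param learning_rate SGD learning rate (> 0).
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param class_weight Multiplier (>= 1) on the loss of rows with
#'   `d_target = 1`.
#' @param hidden_activation `"logistic"`, `"relu"` or `"tanh"`.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @return A `plann_extended_spec` object.
#' @export
plann_extended_spec <- function(nodesize = 4, dropout = 0.1,
                                learning_rate = 0.05, momentum = 0.9,
                                class_weight = 1,
                                hidden_activation = c("tanh", "logistic", "relu"),
                                epochs = 150, batch_size = 64) {
  hidden_activation <- match.arg(hidden_activation)
  stopifnot(nodesize >= 1, dropout >= 0, dropout < 1, learning_rate > 0,
            momentum >= 0, momentum < 1, class_weight >= 1, epochs >= 1,
            batch_size >= 1)
  structure(list(nodesize = as.integer(nodesize), dropout = dropout,
                 learning_rate = learning_rate, momentum = momentum,
                 class_weight = class_weight,
                 hidden_activation = hidden_activation,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size)),
            class = "plann_extended_spec")
}

hazard_eps <- 1e-7

clip_hazard <- function(h) pmin(pmax(h, hazard_eps), 1 - hazard_eps)

activation_fun <- function(name) {
  switch(name,
         logistic = stats::plogis,
         relu = function(x) pmax(x, 0),
         tanh = base::tanh,
         stop("unknown activation: ", name, call. = FALSE))
}

# derivative of the hidden activation, written in terms of pre-activation A
# and activation Z so each case uses whichever is cheaper
activation_grad <- function(name, A, Z) {
  switch(name,
         logistic = Z * (1 - Z),
         relu = (A > 0) + 0,
         tanh = 1 - Z^2)
}

pack_weights <- function(net) {
  if (net$H > 0) c(as.numeric(net$W1), as.numeric(net$W2)) else as.numeric(net$W)
}

unpack_weights <- function(par, J, H) {
  if (H > 0) {
    n1 <- (J + 1) * H
    list(H = H,
         W1 = matrix(par[seq_len(n1)], J + 1, H),
         W2 = matrix(par[n1 + seq_len(H + 1)], H + 1, 1))
  } else {
    list(H = 0L, W = matrix(par, J + 1, 1))
  }
}

forward_cache <- function(net, X, activation = "logistic") {
  X1 <- cbind(1, X)
  if (net$H > 0) {
    g <- activation_fun(activation)
    A <- X1 %*% net$W1
    Z <- g(A)
    Z1 <- cbind(1, Z)
    eta <- Z1 %*% net$W2
    list(h = stats::plogis(eta), A = A, Z = Z, Z1 = Z1, X1 = X1)
  } else {
    eta <- X1 %*% net$W
    list(h = stats::plogis(eta), X1 = X1)
  }
}

#' Forward pass of a partial logistic network
#'
#' Computes the per-row discrete hazard
#' \eqn{\lambda = f(w'_{0} + \sum_h w'_{h} g(w_{0h} + \sum_j w_{jh} x_j))}
#' with logistic output \eqn{f}. With zero hidden nodes the network reduces
#' to a plain logistic regression on the input features.
#'
#' @param net Network weights: a list with `H` (hidden nodes) and either
#'   `W1` ((J+1) x H input-to-hidden matrix, bias in row 1) and `W2`
#'   ((H+1) x 1 hidden-to-output, bias first) or, for `H = 0`, `W`
#'   ((J+1) x 1).
#' @param x Feature matrix (rows = person-period rows, no intercept
#'   column).
#' @param activation Hidden activation name.
#' @return Numeric vector of hazards, strictly inside (0, 1).
#' @export
plann_forward <- function(net, x, activation = "logistic") {
  x <- as.matrix(x)
  width <- if (net$H > 0) nrow(net$W1) - 1L else nrow(net$W) - 1L
  if (ncol(x) != width) {
    stop(sprintf("feature width %d does not match network input width %d",
                 ncol(x), width), call. = FALSE)
  }
  if (net$H > 0 && (any(!is.finite(net$W1)) || any(!is.finite(net$W2)))) {
    stop("network weights are not finite", call. = FALSE)
  }
  h <- forward_cache(net, x, activation)$h
  as.numeric(clip_hazard(h))
}

#' Discrete-hazard cross-entropy loss
#'
#' The training criterion of both networks: the negative discrete-time
#' log-likelihood
#' \eqn{-\sum_r w_r [d_r \log h_r + (1 - d_r) \log(1 - h_r)]}
#' summed over person-period rows, with optional row weights implementing
#' the weak-class weight, plus `decay` times the sum of squared network
#' weights (biases included) when a network is supplied.
#'
#' @param h Predicted hazards in (0, 1); values at the boundaries are
#'   clipped at `1e-7`.
#' @param d Binary targets.
#' @param row_weights Per-row loss weights (scalar or vector).
#' @param decay Weight-decay coefficient.
#' @param net Optional network whose squared weights feed the penalty.
#' @return Scalar loss.
#' @export
plann_loss <- function(h, d, row_weights = 1, decay = 0, net = NULL) {
  h <- clip_hazard(h)
  ce <- -sum(row_weights * (d * log(h) + (1 - d) * log(1 - h)))
  if (decay > 0 && !is.null(net)) {
    ce <- ce + decay * sum(pack_weights(net)^2)
  }
  ce
}

# summed-loss gradient wrt packed parameters; the engine behind both
# trainers and the finite-difference tests
plann_gradient <- function(par, X, d, row_weights = 1, decay = 0, H,
                           activation = "logistic") {
  J <- ncol(X)
  net <- unpack_weights(par, J, H)
  fc <- forward_cache(net, X, activation)
  delta <- row_weights * (fc$h - d)           # n x 1, dLoss/deta at output
  if (H > 0) {
    gW2 <- crossprod(fc$Z1, delta) + 2 * decay * net$W2
    dZ <- delta %*% t(net$W2[-1, , drop = FALSE])
    dA <- dZ * activation_grad(activation, fc$A, fc$Z)
    gW1 <- crossprod(fc$X1, dA) + 2 * decay * net$W1
    c(as.numeric(gW1), as.numeric(gW2))
  } else {
    as.numeric(crossprod(fc$X1, delta)) + 2 * decay * par
  }
}

plann_objective <- function(par, X, d, row_weights, decay, H, activation) {
  net <- unpack_weights(par, ncol(X), H)
  h <- forward_cache(net, X, activation)$h
  plann_loss(h, d, row_weights = row_weights) + decay * sum(par^2)
}

# standardization of continuous inputs by training statistics
make_scaler <- function(long, cols) {
  list(cols = cols,
       center = vapply(cols, function(cc) mean(long[[cc]]), numeric(1)),
       scale = vapply(cols, function(cc) {
         s <- stats::sd(long[[cc]])
         if (!is.finite(s) || s == 0) 1 else s
       }, numeric(1)))
}

apply_scaler <- function(values, scaler, col) {
  (values - scaler$center[[col]]) / scaler$scale[[col]]
}

# feature matrices of the two architectures
features_original <- function(long, scaler) {
  cbind(midpoint = apply_scaler(long$midpoint, scaler, "midpoint"),
        treatment = long$treatment, sex = long$sex,
        histology = long$histology, margin = long$margin,
        age = apply_scaler(long$age, scaler, "age"))
}

features_extended <- function(long, scaler, L) {
  dummies <- matrix(0, nrow(long), L,
                    dimnames = list(NULL, paste0("interval_", seq_len(L))))
  dummies[cbind(seq_len(nrow(long)), long$interval)] <- 1
  cbind(dummies,
        treatment = long$treatment, sex = long$sex,
        histology = long$histology, margin = long$margin,
        age = apply_scaler(long$age, scaler, "age"))
}

long_scheme <- function(long, scheme) {
  if (is.null(scheme)) scheme <- attr(long, "scheme")
  if (is.null(scheme)) {
    stop("no interval scheme: pass `scheme` or use a to_long_* expansion",
         call. = FALSE)
  }
  scheme
}
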