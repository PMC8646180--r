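# Independent oracles used across the suite. These deliberately re-derive
# quantities with naive loop-based arithmetic so they share no code with
# the package internals they check.

# two-layer forward pass with explicit loops
oracle_forward <- function(net, X, activation = "logistic") {
  g <- switch(activation,
              logistic = function(x) 1 / (1 + exp(-x)),
              relu = function(x) ifelse(x > 0, x, 0),
              tanh = function(x) tanh(x))
  n <- nrow(X)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (net$H > 0) {
      z <- numeric(net$H)
      for (h in seq_len(net$H)) {
        a <- net$W1[1, h]
        for (j in seq_len(ncol(X))) a <- a + net$W1[j + 1, h] * X[i, j]
        z[h] <- g(a)
      }
      eta <- net$W2[1, 1]
      for (h in seq_len(net$H)) eta <- eta + net$W2[h + 1, 1] * z[h]
    } else {
      eta <- net$W[1, 1]
      for (j in seq_len(ncol(X))) eta <- eta + net$W[j + 1, 1] * X[i, j]
    }
    out[i] <- 1 / (1 + exp(-eta))
  }
  out
}

# summed weighted cross-entropy, loop form
oracle_loss <- function(h, d, w = rep(1, length(d))) {
  tot <- 0
  for (i in seq_along(d)) {
    tot <- tot - w[i] * (d[i] * log(h[i]) + (1 - d[i]) * log(1 - h[i]))
  }
  tot
}

# central finite differences of an objective in packed parameters
oracle_num_grad <- function(fn, par, eps = 1e-6) {
  vapply(seq_along(par), function(k) {
    up <- par; up[k] <- up[k] + eps
    dn <- par; dn[k] <- dn[k] - eps
    (fn(up) - fn(dn)) / (2 * eps)
  }, numeric(1))
}

# loop-based analytic gradient of the batch-MEAN class-weighted
# cross-entropy for a one-hidden-layer net (used for the SGD trajectory
# equivalence check); exact, unlike finite differences
oracle_mean_grad <- function(net, X, d, w, activation) {
  g <- switch(activation,
              logistic = function(x) 1 / (1 + exp(-x)),
              relu = function(x) ifelse(x > 0, x, 0),
              tanh = function(x) tanh(x))
  gp <- switch(activation,
               logistic = function(a, z) z * (1 - z),
               relu = function(a, z) as.numeric(a > 0),
               tanh = function(a, z) 1 - z^2)
  n <- nrow(X)
  gW1 <- net$W1 * 0
  gW2 <- net$W2 * 0
  for (i in seq_len(n)) {
    a <- z <- numeric(net$H)
    for (hh in seq_len(net$H)) {
      a[hh] <- net$W1[1, hh] + sum(net$W1[-1, hh] * X[i, ])
      z[hh] <- g(a[hh])
    }
    eta <- net$W2[1, 1] + sum(net$W2[-1, 1] * z)
    hi <- 1 / (1 + exp(-eta))
    delta <- w[i] * (hi - d[i]) / n
    gW2[1, 1] <- gW2[1, 1] + delta
    for (hh in seq_len(net$H)) {
      gW2[hh + 1, 1] <- gW2[hh + 1, 1] + delta * z[hh]
      da <- delta * net$W2[hh + 1, 1] * gp(a[hh], z[hh])
      gW1[1, hh] <- gW1[1, hh] + da
      for (j in seq_len(ncol(X))) {
        gW1[j + 1, hh] <- gW1[j + 1, hh] + da * X[i, j]
      }
    }
  }
  list(W1 = gW1, W2 = gW2)
}

# O(n^2) double-loop Harrell concordance (opposite ranking: higher score
# predicts earlier death)
oracle_harrell <- function(pi, time, event) {
  n <- length(pi)
  usable <- 0; conc <- 0; ties <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ok <- (time[i] < time[j] && event[i] == 1) ||
        (time[i] == time[j] && event[i] == 1 && event[j] == 0)
      if (!ok) next
      usable <- usable + 1
      if (pi[i] > pi[j]) conc <- conc + 1
      else if (pi[i] == pi[j]) ties <- ties + 1
    }
  }
  (conc + 0.5 * ties) / usable
}

# small deterministic trial fixture used by several files
toy_trial <- function(n = 150, seed = 402) {
  simulate_trial(n, seed = seed)
}
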