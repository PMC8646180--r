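make_random_net <- function(J, H, seed = 1, scale = 0.3) {
  withr::with_seed(seed, {
    if (H > 0) {
      list(H = H,
           W1 = matrix(stats::runif((J + 1) * H, -scale, scale), J + 1, H),
           W2 = matrix(stats::runif(H + 1, -scale, scale), H + 1, 1))
    } else {
      list(H = 0L, W = matrix(stats::runif(J + 1, -scale, scale), J + 1, 1))
    }
  })
}

test_that("forward pass matches an independent hand-rolled computation", {
  X <- matrix(c(0.2, -1.1, 0.5,
                1.0, 0.0, -0.3,
                -0.7, 0.4, 2.2), nrow = 3, byrow = TRUE)
  for (act in c("logistic", "relu", "tanh")) {
    net <- make_random_net(3, 4, seed = 42)
    expect_equal(plann_forward(net, X, act), oracle_forward(net, X, act),
                 tolerance = 1e-12)
  }
  # zero weights -> logistic(0) = 0.5 everywhere
  net0 <- list(H = 2L, W1 = matrix(0, 4, 2), W2 = matrix(0, 3, 1))
  expect_equal(plann_forward(net0, X), rep(0.5, 3))
  # large negative output bias saturates towards 0 (clipped at epsilon)
  netneg <- list(H = 1L, W1 = matrix(0, 4, 1),
                 W2 = matrix(c(-50, 0), 2, 1))
  expect_true(all(plann_forward(netneg, X) < 1e-6))
  expect_true(all(plann_forward(netneg, X) > 0))
  expect_error(plann_forward(net0, X[, 1:2]), "width")
})

test_that("cross-entropy loss has its closed-form values", {
  d <- c(1, 0, 1, 0)
  expect_equal(plann_loss(c(1, 0, 1, 0), d), 0, tolerance = 1e-5)
  expect_equal(plann_loss(rep(0.5, 4), d), 4 * log(2))
  h <- c(0.8, 0.3, 0.6, 0.1)
  # class weight 2 adds exactly the event rows' unweighted contribution
  w2 <- ifelse(d == 1, 2, 1)
  event_part <- oracle_loss(h[d == 1], d[d == 1])
  expect_equal(plann_loss(h, d, row_weights = w2),
               plann_loss(h, d) + event_part)
  expect_equal(plann_loss(h, d), oracle_loss(h, d))
  # decay penalty includes biases
  net <- make_random_net(2, 2, seed = 9)
  expect_equal(plann_loss(h, d, decay = 0.1, net = net),
               plann_loss(h, d) + 0.1 * sum(net$W1^2, net$W2^2))
})

test_that("analytic gradients match central finite differences", {
  withr::with_seed(21, {
    X <- matrix(stats::rnorm(10 * 4), 10, 4)
    d <- stats::rbinom(10, 1, 0.4)
  })
  w <- ifelse(d == 1, 1.05, 1)
  for (act in c("logistic", "relu", "tanh")) {
    for (H in c(0L, 3L)) {
      if (H == 0 && act != "logistic") next
      net <- make_random_net(4, H, seed = 5)
      par <- if (H > 0) c(as.numeric(net$W1), as.numeric(net$W2)) else as.numeric(net$W)
      fn <- function(p) plannsim:::plann_objective(p, X, d, w, 0.05, H, act)
      ga <- plannsim:::plann_gradient(par, X, d, w, 0.05, H, act)
      gn <- oracle_num_grad(fn, par)
      expect_lt(max(abs(ga - gn)) / max(1, max(abs(gn))), 1e-6)
    }
  }
})

test_that("no-hidden-layer network reproduces IRLS logistic regression", {
  ds <- toy_trial(200, seed = 55)
  long <- to_long_train(ds, make_scheme("yearly"))
  fit <- train_plann_original(long,
                              plann_original_spec(hidden_size = 0, decay = 0,
                                                  maxit = 2000, reltol = 1e-14),
                              seed = 2)
  X <- plannsim:::features_original(long, fit$scaler)
  glm_fit <- stats::glm.fit(cbind(1, X), long$d_target,
                            family = stats::binomial())
  expect_lt(max(abs(as.numeric(fit$net$W) - glm_fit$coefficients)), 1e-3)
})

test_that("original network training is deterministic and decreases the loss", {
  ds <- toy_trial(120, seed = 56)
  long <- to_long_train(ds, make_scheme("yearly"))
  spec <- plann_original_spec(hidden_size = 2, decay = 0.05)
  f1 <- train_plann_original(long, spec, seed = 10)
  f2 <- train_plann_original(long, spec, seed = 10)
  expect_identical(f1$net, f2$net)
  expect_identical(predict_hazards(f1, ds), predict_hazards(f2, ds))
  # full-batch objective is non-increasing along the BFGS iterate sequence
  losses <- vapply(1:12, function(k) {
    suppressWarnings(
      train_plann_original(long, plann_original_spec(2, 0.05, maxit = k),
                           seed = 10)$loss
    )
  }, numeric(1))
  expect_true(all(diff(losses) <= 1e-8))
})

test_that("hazards are lowest where the data contain no events", {
  # construct a dataset in which nobody dies in year 1 but many die later
  covs <- sample_covariates(120, seed = 66)
  tt <- withr::with_seed(67, stats::runif(120, 1.5, 4.5))
  ds <- assemble_dataset(covs, tt, rep(6, 120))
  long <- to_long_train(ds, make_scheme("yearly"))
  fit <- train_plann_original(long, plann_original_spec(hidden_size = 2,
                                                        decay = 0.01),
                              seed = 3)
  h <- colMeans(predict_hazards(fit, ds))
  expect_equal(unname(which.min(h[1:5])), 1)
})

test_that("extended network with no dropout/momentum equals plain gradient descent", {
  ds <- toy_trial(40, seed = 58)
  long <- to_long_train(ds, make_scheme("yearly"))
  n <- nrow(long)
  spec1 <- plann_extended_spec(nodesize = 2, dropout = 0, learning_rate = 0.1,
                               momentum = 0, class_weight = 1.05,
                               hidden_activation = "logistic", epochs = 1,
                               batch_size = n)
  fits <- lapply(1:5, function(k) {
    sp <- spec1; sp$epochs <- k
    train_plann_extended(long, sp, seed = 12)
  })
  X <- plannsim:::features_extended(long, fits[[1]]$scaler,
                                    make_scheme("yearly")$L)
  d <- long$d_target
  w <- ifelse(d == 1, 1.05, 1)
  # chain independent full-batch GD steps from the 1-epoch weights
  net <- fits[[1]]$net
  for (k in 2:5) {
    gr <- oracle_mean_grad(net, X, d, w, "logistic")
    net$W1 <- net$W1 - 0.1 * gr$W1
    net$W2 <- net$W2 - 0.1 * gr$W2
    expect_lt(max(abs(net$W1 - fits[[k]]$net$W1)), 1e-10)
    expect_lt(max(abs(net$W2 - fits[[k]]$net$W2)), 1e-10)
  }
})

test_that("all three hidden activations train and give valid hazards", {
  ds <- toy_trial(100, seed = 59)
  long <- to_long_train(ds, make_scheme("yearly"))
  for (act in c("logistic", "relu", "tanh")) {
    fit <- train_plann_extended(long,
                                plann_extended_spec(hidden_activation = act,
                                                    epochs = 30),
                                seed = 4)
    h <- predict_hazards(fit, ds)
    expect_true(all(h > 0 & h < 1))
    # determinism
    fit2 <- train_plann_extended(long,
                                 plann_extended_spec(hidden_activation = act,
                                                     epochs = 30),
                                 seed = 4)
    expect_identical(predict_hazards(fit2, ds), h)
  }
})

test_that("weak class weight scales event-row gradients exactly", {
  withr::with_seed(23, {
    X <- matrix(stats::rnorm(8), 2, 4)
    d <- c(1, 0)
  })
  net <- make_random_net(4, 2, seed = 6)
  par <- c(as.numeric(net$W1), as.numeric(net$W2))
  g_event <- plannsim:::plann_gradient(par, X[1, , drop = FALSE], d[1],
                                       1, 0, 2L, "logistic")
  g_event_w <- plannsim:::plann_gradient(par, X[1, , drop = FALSE], d[1],
                                         1.05, 0, 2L, "logistic")
  expect_equal(g_event_w, 1.05 * g_event, tolerance = 1e-12)
})

test_that("hazard predictions reshape correctly and respect covariate identity", {
  ds <- toy_trial(30, seed = 61)
  long <- to_long_train(ds, make_scheme("yearly"))
  fit <- train_plann_original(long, plann_original_spec(hidden_size = 2),
                              seed = 7)
  h <- predict_hazards(fit, ds)
  expect_equal(dim(h), c(30, 8))
  expect_true(all(h > 0 & h < 1))
  # duplicate covariates -> identical hazard rows
  ds2 <- ds
  ds2[2, c("treatment", "sex", "histology", "margin", "age")] <-
    ds[1, c("treatment", "sex", "histology", "margin", "age")]
  h2 <- predict_hazards(fit, ds2)
  expect_equal(unname(h2[2, ]), unname(h2[1, ]))
})

test_that("survival curves follow the discrete product formula", {
  y <- make_scheme("yearly")
  h <- matrix(0.5, 1, 8)
  S <- survival_curve(h, y, c(0, 0.5, 1, 2, 2.5, 8))
  # only intervals with a finite passed upper boundary enter the product,
  # so t0 = 8 accumulates the 7 closed intervals
  expect_equal(as.numeric(S), c(1, 1, 0.5, 0.25, 0.25, 2^-7))
  # t0 = 2.5 uses exactly intervals 1-2
  h2 <- matrix(c(0.1, 0.2, 0.9, 0.9, 0.9, 0.9, 0.9, 0.9), 1)
  expect_equal(as.numeric(survival_curve(h2, y, 2.5)), 0.9 * 0.8)
  # vanishing hazards -> S = 1 everywhere
  expect_true(all(survival_curve(matrix(1e-9, 1, 8), y, 0:8) > 1 - 1e-6))
  # monotone, bounded, S(0) = 1 for a fitted model
  ds <- toy_trial(50, seed = 62)
  long <- to_long_train(ds, y)
  fit <- train_plann_extended(long, plann_extended_spec(epochs = 20), seed = 8)
  S2 <- predict_survival(fit, ds, seq(0, 8, by = 0.5))
  expect_true(all(S2 >= 0 & S2 <= 1))
  expect_equal(unname(S2[, 1]), rep(1, 50))
  expect_true(all(diff(t(S2)) <= 1e-12))
})

test_that("nonlinear prognostic index averages the logit hazards", {
  ds <- toy_trial(20, seed = 63)
  y <- make_scheme("yearly")
  # all hazards 0.5 -> PI = 0
  net0 <- list(H = 1L, W1 = matrix(0, 7, 1), W2 = matrix(0, 2, 1))
  m0 <- plannsim:::new_plann("plann_original", net0, plann_original_spec(1),
                             y, list(cols = c("midpoint", "age"),
                                     center = c(midpoint = 0, age = 0),
                                     scale = c(midpoint = 1, age = 1)),
                             "logistic", "original", 0, TRUE, 0)
  expect_equal(unname(nonlinear_pi(m0, ds)), rep(0, 20))
  # output bias 1 -> hazards logistic(1) -> PI = 1 via logit identity
  net1 <- net0; net1$W2[1, 1] <- 1
  m1 <- m0; m1$net <- net1
  expect_equal(unname(nonlinear_pi(m1, ds)), rep(1, 20), tolerance = 1e-12)
  # when the time input has zero weight the PI ignores the scheme midpoints
  netc <- list(H = 2L,
               W1 = rbind(0.3, 0, matrix(0.25, 5, 2)),
               W2 = matrix(c(-0.5, 0.8, 0.4), 3, 1))
  mc_y <- m0; mc_y$net <- netc; mc_y$spec <- plann_original_spec(2)
  mc_q <- mc_y; mc_q$scheme <- make_scheme("three_month")
  expect_equal(nonlinear_pi(mc_y, ds), nonlinear_pi(mc_q, ds),
               tolerance = 1e-12)
})

test_that("fitted networks serialize to JSON and reload identically", {
  ds <- toy_trial(60, seed = 64)
  long <- to_long_train(ds, make_scheme("yearly"))
  for (fit in list(
    train_plann_original(long, plann_original_spec(hidden_size = 2), seed = 5),
    train_plann_extended(long, plann_extended_spec(epochs = 10), seed = 5)
  )) {
    path <- withr::local_tempfile(fileext = ".json")
    write_plann(fit, path)
    back <- read_plann(path)
    expect_equal(predict_hazards(back, ds), predict_hazards(fit, ds),
                 tolerance = 1e-12)
  }
})

test_that("tidy and glance summarise fitted networks", {
  ds <- toy_trial(60, seed = 65)
  long <- to_long_train(ds, make_scheme("yearly"))
  fit <- train_plann_original(long, plann_original_spec(hidden_size = 2),
                              seed = 5)
  td <- tidy(fit)
  expect_equal(nrow(td), 7 * 2 + 3)
  g <- glance(fit)
  expect_equal(g$n_parameters, 17)
  expect_equal(g$hidden_nodes, 2L)
})
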