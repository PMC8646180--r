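test_that("stratum table has 16 valid combinations whose proportions sum to one", {
  st <- trial_strata()
  expect_equal(nrow(st), 16)
  expect_equal(nrow(dplyr::distinct(st, treatment, sex, histology, margin)), 16)
  expect_lt(abs(sum(st$proportion) - 1), 0.005)
  expect_true(all(st$age_sd > 0))
})

test_that("strata validation rejects malformed tables", {
  st <- trial_strata()
  expect_error(validate_strata(dplyr::mutate(st, proportion = 0)), "zero")
  expect_error(validate_strata(dplyr::mutate(st, proportion = proportion * 2)),
               "sum")
  expect_error(validate_strata(dplyr::select(st, -age_sd)), "missing")
})

test_that("covariate sampling reproduces stratum frequencies and ages", {
  st <- trial_strata()
  n <- 1e5
  covs <- sample_covariates(n, st, seed = 11)
  # chi-square goodness of fit against the stratum proportions
  key <- paste(covs$treatment, covs$sex, covs$histology, covs$margin)
  ref <- paste(st$treatment, st$sex, st$histology, st$margin)
  counts <- table(factor(key, levels = ref))
  gof <- stats::chisq.test(counts, p = st$proportion / sum(st$proportion))
  expect_gt(gof$p.value, 0.01)
  # mixture mean of age matches the analytic mean of the floored mixture
  # (the redraw below age 0 shifts each stratum to its truncated-normal mean)
  a <- st$age_mean / st$age_sd
  trunc_mean <- st$age_mean + st$age_sd * stats::dnorm(a) / stats::pnorm(a)
  expect_lt(abs(mean(covs$age) - sum(st$proportion * trunc_mean)), 0.05)
  # the truncation shift itself is below a tenth of a year
  expect_lt(sum(st$proportion * trunc_mean) - sum(st$proportion * st$age_mean),
            0.1)
  expect_true(all(covs$age >= 0))
})

test_that("degenerate single-stratum mixture collapses as expected", {
  st <- trial_strata()[1, ]
  st$proportion <- 1
  st$age_sd <- 1e-8
  covs <- sample_covariates(500, st, seed = 3)
  expect_true(all(covs$treatment == st$treatment))
  expect_true(all(abs(covs$age - st$age_mean) < 1e-5))
  expect_error(sample_covariates(0, trial_strata()), "positive count")
})

test_that("AFT survival times follow the log-normal model", {
  covs <- sample_covariates(2000, seed = 5)
  # noise-free intercept-only: T = exp(mu) exactly
  coef0 <- aft_coefficients(1.2, rep(0, 5), sigma = 1e-12)
  expect_equal(simulate_survival_times(covs, coef0, seed = 1),
               rep(exp(1.2), nrow(covs)), tolerance = 1e-6)
  # standard-normal log-times
  coef1 <- aft_coefficients(0, rep(0, 5), 1)
  lt <- log(simulate_survival_times(covs[rep(1, 5e4), ], coef1, seed = 2))
  expect_lt(abs(mean(lt)), 0.02)
  expect_lt(abs(stats::sd(lt) - 1), 0.02)
  # conditional median equals exp(mu + beta'x) (log-normal closed form)
  coef2 <- default_aft_coefficients()
  x0 <- covs[rep(7, 1e5), ]
  tt <- simulate_survival_times(x0, coef2, seed = 3)
  med_theory <- exp(coef2$intercept +
                      sum(as.numeric(x0[1, c("treatment", "sex", "histology",
                                             "margin")]) * coef2$betas[1:4]) +
                      x0$age[1] * coef2$betas[5])
  expect_equal(unname(stats::median(tt)), unname(med_theory), tolerance = 0.02)
  expect_error(simulate_survival_times(covs[, 1:3], coef2), "missing")
})

test_that("dataset assembly applies right censoring by definition", {
  covs <- sample_covariates(2, seed = 1)
  ds <- assemble_dataset(covs, c(1, 3), c(2, 2))
  expect_equal(ds$time, c(1, 2))
  expect_equal(ds$event, c(1L, 0L))
  expect_equal(ds$latent_survival_time, c(1, 3))
  # infinite censoring -> all events
  ds2 <- assemble_dataset(covs, c(1, 3), c(Inf, Inf))
  expect_equal(ds2$event, c(1L, 1L))
  expect_error(assemble_dataset(covs, c(1, -1), c(2, 2)), "nonpositive")
})

test_that("calibrated defaults realize the five nominal censoring rates", {
  coef <- default_aft_coefficients()
  specs <- default_censoring_specs()
  expect_equal(length(specs), 5)
  for (sp in specs) {
    p <- plannsim:::censoring_probability(coef, sp)
    expect_lt(abs(p - sp$nominal), 0.02)
  }
  # Monte-Carlo agreement for the scenario-1 spec
  sp1 <- specs[["61-scenario1"]]
  realized <- mean(vapply(1:50, function(r) {
    1 - mean(simulate_trial(1000, coef, sp1, seed = 5000 + r)$event)
  }, numeric(1)))
  expect_lt(abs(realized - 0.61), 0.02)
})

test_that("intercept calibration by bisection hits an arbitrary target", {
  sp <- censoring_spec(2.03, 5.72, nominal = 0.5)
  coef <- calibrate_aft_coefficients(censoring = sp)
  expect_lt(abs(plannsim:::censoring_probability(coef, sp) - 0.5), 1e-4)
  # intercept-only degenerate variant still converges
  coef0 <- calibrate_aft_coefficients(betas = rep(0, 5), censoring = sp)
  expect_lt(abs(plannsim:::censoring_probability(coef0, sp) - 0.5), 1e-4)
  expect_error(calibrate_aft_coefficients(betas = c(0, 0, -1, 0, 0)), "sign")
})

test_that("log-normal AFT regression recovers the generator parameters", {
  coef <- default_aft_coefficients()
  ds <- simulate_trial(1e5, coef, seed = 99)
  fit <- survival::survreg(
    survival::Surv(time, event) ~ treatment + sex + histology + margin + age,
    data = ds, dist = "lognormal"
  )
  est <- c(stats::coef(fit), fit$scale)
  se <- sqrt(diag(fit$var))          # last entry is for log(scale)
  truth <- c(coef$intercept, coef$betas, coef$sigma)
  z <- abs(est[1:6] - truth[1:6]) / se[1:6]
  expect_true(all(z < 2))
  expect_lt(abs(log(fit$scale) - log(coef$sigma)) / se[7], 2)
})

test_that("adverse scenarios transform the training data as specified", {
  covs <- sample_covariates(3, seed = 2)
  ds <- assemble_dataset(covs, c(2, 1.5, 6), c(1.5, 9, 9))
  # subjects: (1.5, censored), (1.5, event), (6, event)
  expect_equal(ds$time, c(1.5, 1.5, 6))
  expect_equal(ds$event, c(0L, 1L, 1L))
  dropped <- apply_adverse_scenario(ds, "drop_early_censored")
  expect_equal(dropped$time, c(1.5, 6))
  expect_equal(dropped$event, c(1L, 1L))
  curtailed <- apply_adverse_scenario(ds, "curtail_5y")
  expect_equal(curtailed$time, c(1.5, 1.5, 5))
  expect_equal(curtailed$event, c(0L, 1L, 0L))
  expect_identical(apply_adverse_scenario(ds, "none"), ds)
  all_censored <- assemble_dataset(covs, rep(10, 3), rep(1, 3))
  expect_error(apply_adverse_scenario(all_censored, "drop_early_censored"),
               "no events")
})

test_that("train/test split is stratified on the event indicator", {
  ds <- toy_trial(100)
  # force exactly 40 events for the exact-stratification check
  ds$event <- rep(c(1L, 0L), c(40, 60))
  sp <- split_train_test(ds, seed = 8)
  tr <- dplyr::filter(sp, split == "train")
  te <- dplyr::filter(sp, split == "test")
  expect_equal(nrow(tr), 50)
  expect_equal(sum(tr$event), 20)
  expect_equal(sum(te$event), 20)
  # odd counts: extra subject goes to training, halves differ by <= 1/stratum
  ds2 <- toy_trial(101)
  sp2 <- split_train_test(ds2, seed = 9)
  n_tr <- sum(sp2$split == "train")
  expect_true((n_tr - (101 - n_tr)) %in% c(0, 1, 2))
  for (ev in 0:1) {
    a <- sum(sp2$split == "train" & sp2$event == ev)
    b <- sum(sp2$split == "test" & sp2$event == ev)
    expect_lte(abs(a - b), 1)
  }
  expect_identical(split_train_test(ds, seed = 8), sp)
  expect_error(split_train_test(dplyr::mutate(ds, event = 1L)), "censored")
})

test_that("same master seed gives byte-identical datasets and derived seeds", {
  expect_identical(simulate_trial(300, seed = 77), simulate_trial(300, seed = 77))
  s1 <- replicate_seed(123, 1:50)
  expect_identical(s1, replicate_seed(123, 1:50))
  expect_equal(length(unique(s1)), 50)
  expect_true(all(s1 > 0 & s1 < 2^31))
})

test_that("trial CSV round-trips through write_trial/read_trial", {
  ds <- split_train_test(toy_trial(60), seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial(ds, path)
  back <- read_trial(path)
  expect_false("latent_survival_time" %in% names(back))
  expect_equal(back$time, ds$time)
  expect_equal(back$split, ds$split)
})
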