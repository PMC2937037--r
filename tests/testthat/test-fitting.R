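test_that("curve log-likelihood matches direct density products", {
  set.seed(8)
  target <- fit_target(
    wide = tibble::tibble(bin = 1:5, r = runif(5), se_r = runif(5, 0.01, 0.1),
                          mu_p_error = rnorm(5, 0, 0.02),
                          se_mu_p_error = runif(5, 0.005, 0.05)),
    narrow = tibble::tibble(bin = 1:5, r = runif(5), se_r = runif(5, 0.01, 0.1),
                            mu_p_error = rnorm(5, 0, 0.02),
                            se_mu_p_error = runif(5, 0.005, 0.05))
  )
  model <- dplyr::mutate(target, r = r + rnorm(10, 0, 0.05),
                         mu_p_error = mu_p_error + rnorm(10, 0, 0.01))
  ll <- curve_loglik(model, target)
  direct <- sum(log(dnorm(target$r, model$r, target$se_r))) +
    sum(log(dnorm(target$mu_p_error, model$mu_p_error, target$se_mu_p_error)))
  expect_equal(ll, direct, tolerance = 1e-12)

  # zero residuals: the maximum, sum of log(1/(SE*sqrt(2*pi)))
  ll_max <- curve_loglik(target, target)
  expect_equal(ll_max,
               sum(-log(c(target$se_r, target$se_mu_p_error) * sqrt(2 * pi))),
               tolerance = 1e-12)

  # doubling all SEs shifts the log-likelihood by a closed-form amount
  target2 <- dplyr::mutate(target, se_r = 2 * se_r,
                           se_mu_p_error = 2 * se_mu_p_error)
  class(target2) <- class(target)
  z2 <- sum(((target$r - model$r) / target$se_r)^2,
            ((target$mu_p_error - model$mu_p_error) / target$se_mu_p_error)^2)
  expect_equal(curve_loglik(model, target2) - ll,
               -20 * log(2) + (3 / 8) * z2, tolerance = 1e-10)

  expect_error(curve_loglik(model[1:5, ], target), "match")
})

test_that("rms error and r-squared agree with their direct formulas", {
  a <- tibble::tibble(bin = 1:6, r = c(0.9, 0.8, 0.6, 0.5, 0.3, 0.25))
  expect_equal(rms_error(a, a), 0)
  b <- dplyr::mutate(a, r = r + 0.07)
  expect_equal(rms_error(b, a), 0.07, tolerance = 1e-12)
  set.seed(12)
  c1 <- dplyr::mutate(a, r = r + rnorm(6, 0, 0.1))
  expect_equal(rms_error(c1, a), sqrt(mean((c1$r - a$r)^2)), tolerance = 1e-12)

  expect_equal(r_squared(a, a), 1)
  mean_model <- dplyr::mutate(a, r = mean(a$r))
  expect_equal(r_squared(mean_model, a), 0, tolerance = 1e-12)
  # three-point case checked by hand: target (1,2,3) model (1,2,4);
  # SS_res = 1, SS_tot = 2 -> R^2 = 0.5
  t3 <- tibble::tibble(bin = 1:3, r = c(1, 2, 3))
  m3 <- tibble::tibble(bin = 1:3, r = c(1, 2, 4))
  expect_equal(r_squared(m3, t3), 0.5)
})

test_that("the Monte-Carlo objective is deterministic under common random numbers", {
  cfg <- session_config("exp1", prior_sd = 0.2)
  c1 <- average_model_curves(cfg, subject_init(), n_runs = 20, seed = 33)
  c2 <- average_model_curves(cfg, subject_init(), n_runs = 20, seed = 33)
  expect_identical(c1, c2)
  target <- synthetic_subject_target(n_runs = 10, seed = 55)
  f1 <- fit_nig_init(target, exp1_configs(), n_runs = 10, seed = 3, restarts = 1)
  f2 <- fit_nig_init(target, exp1_configs(), n_runs = 10, seed = 3, restarts = 1)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(unlist(f1$init), unlist(f2$init))
})

test_that("fitting is structurally restricted to fixed-prior protocols", {
  target <- synthetic_subject_target(n_runs = 10, seed = 56)
  bad <- list(wide = session_config("exp2"), narrow = session_config("exp1"))
  expect_error(fit_nig_init(target, bad, n_runs = 5), "exp1")
  expect_error(fit_lf_params(target, list(wide = 1), n_runs = 5), "wide")
})

test_that("profile objective peaks at the generative hyperparameter", {
  target <- synthetic_subject_target(n_runs = 40, seed = 77)
  cfgs <- exp1_configs()
  seeds <- priorlearn:::with_seed(42, sample.int(1e6, 2))
  stim_w <- priorlearn:::simulate_stimuli_runs(cfgs$wide, 40, seeds[1])
  stim_n <- priorlearn:::simulate_stimuli_runs(cfgs$narrow, 40, seeds[2])
  truth <- subject_init()
  profile <- vapply(c(0.025, 0.05, 0.1, 0.2, 0.4), function(b0) {
    init <- nig_state(mu = truth$mu, lam = truth$lam, alpha = truth$alpha,
                      beta = b0)
    curve_loglik(priorlearn:::model_curves_both(stim_w, stim_n, init), target)
  }, numeric(1))
  expect_equal(which.max(profile), 3L)  # beta0 = 0.1, the generative value
})

test_that("self-fit recovers the generative gain trajectory", {
  fit <- cached_fit("nig")
  expect_s3_class(fit, "prior_fit")
  cfgs <- exp1_configs()
  for (proto in c("wide", "narrow")) {
    truth_curve <- average_model_curves(cfgs[[proto]], subject_init(),
                                        n_runs = 50, seed = 501)
    fit_curve <- average_model_curves(cfgs[[proto]], fit$init,
                                      n_runs = 50, seed = 501)
    expect_lte(rms_error(fit_curve, truth_curve), 0.05)
  }
})

test_that("filter self-fit recovers its parameters and converges both ways", {
  cfgs <- exp1_configs()
  gen <- lf_state(learning_rate = 0.15, var_init = 0.5)
  target <- fit_target(
    wide = average_model_curves(cfgs$wide, gen, n_runs = 40, seed = 91),
    narrow = average_model_curves(cfgs$narrow, gen, n_runs = 40, seed = 92)
  )
  fit <- fit_lf_params(target, cfgs, n_runs = 40, seed = 7, restarts = 2)
  expect_lt(abs(fit$init$learning_rate - 0.15), 0.1)
  expect_true(fit$init$learning_rate >= 0 && fit$init$learning_rate <= 1)
  # fitted filter converges to the new gain by the final bins in BOTH switch
  # directions: the constant-rate diagnostic failure mode
  for (sds in list(c(0.2, 0.05), c(0.05, 0.2))) {
    cfg2 <- session_config("exp2", prior_sd = sds)
    pred <- predict_model_curves(fit, cfg2, n_runs = 40, seed = 17)
    r_final <- mean(pred$r[pred$bin > 45])
    expect_lt(abs(r_final - compute_gain(sds[2], 0.1)), 0.1)
  }
})

test_that("tidy and glance summarise fits in broom style", {
  fit <- cached_fit("nig")
  td <- tidy(fit)
  expect_equal(td$term, c("mu0", "lam0", "alpha0", "beta0"))
  expect_true(all(is.finite(td$estimate)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$model, "nig")
  expect_true(is.finite(gl$logLik))
})
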