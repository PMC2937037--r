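test_that("bin fit recovers exact linear data and flags degeneracy", {
  set.seed(3)
  cue <- runif(10, -0.3, 0.3)
  d <- tibble::tibble(cue = cue, response = 0.2 * 0.1 + 0.8 * cue)
  fit <- fit_bin(d)
  expect_equal(fit$r, 0.8, tolerance = 1e-10)
  expect_equal(fit$mu_p, 0.1, tolerance = 1e-10)
  expect_false(fit$degenerate)
  # response == cue: unit slope, flat-prior sentinel for the mean
  fit1 <- fit_bin(tibble::tibble(cue = cue, response = cue))
  expect_equal(fit1$r, 1)
  expect_true(fit1$degenerate)
  expect_true(is.na(fit1$mu_p))
  expect_error(fit_bin(tibble::tibble(cue = rep(0.1, 10), response = cue)),
               "singular")
  expect_error(fit_bin(d[1:2, ]), "at least 3")
})

test_that("binned estimates are unbiased on noisy oracle logs", {
  fits <- lapply(1:50, function(s) {
    cfg <- session_config("exp1", prior_sd = 0.2, seed = s)
    d <- run_observer(generate_session(cfg),
                      observer_spec("oracle_fixed_prior", motor_noise_sd = 0.02))
    b <- bin_series(d)
    data.frame(r = b$r, err = b$mu_p - d$prior_mean_true[1])
  })
  fits <- do.call(rbind, fits)
  expect_lt(abs(mean(fits$r) - 0.8), 3 * sd(fits$r) / sqrt(nrow(fits)))
  expect_lt(abs(mean(fits$err, na.rm = TRUE)), 0.01)
})

test_that("bin series partitions trials and drops trailing partial bins", {
  cfg <- session_config("exp1", prior_sd = 0.2, seed = 2)
  d <- run_observer(generate_session(cfg), observer_spec("oracle_fixed_prior"))
  b <- bin_series(d)
  expect_equal(nrow(b), 40)
  expect_equal(b$bin, 1:40)
  expect_warning(b2 <- bin_series(d[1:405, ]), "5 trailing")
  expect_equal(nrow(b2), 40)
  expect_error(bin_series(d[1:5, ]), "shorter")
})

test_that("bin estimates are equivariant under shift and scale", {
  cfg <- session_config("exp1", prior_sd = 0.2, seed = 19)
  d <- run_observer(generate_session(cfg),
                    observer_spec("oracle_fixed_prior", motor_noise_sd = 0.02))
  b <- bin_series(d)
  shift <- dplyr::mutate(d, cue = cue + 0.1, response = response + 0.1,
                         prior_mean_true = prior_mean_true + 0.1)
  b_shift <- bin_series(shift)
  expect_equal(b_shift$r, b$r, tolerance = 1e-10)
  expect_equal(b_shift$mu_p, b$mu_p + 0.1, tolerance = 1e-8)
  scaled <- dplyr::mutate(d, cue = cue * 2, response = response * 2,
                          prior_mean_true = prior_mean_true * 2)
  b_scaled <- bin_series(scaled)
  expect_equal(b_scaled$r, b$r, tolerance = 1e-10)
  expect_equal(b_scaled$mu_p, b$mu_p * 2, tolerance = 1e-8)
})

test_that("NIG learner's narrow-prior curve settles near the optimal gain", {
  cfg <- session_config("exp1", prior_sd = 0.05, seed = 37)
  d <- generate_session(cfg)
  d$response <- run_nig_session(d, subject_init(), 0.1)$response
  b <- bin_series(d)
  expect_true(all(abs(b$r[36:40] - 0.2) < 0.1))
})

test_that("switch-aligned inversion recovers the internal mean estimate exactly", {
  d <- generate_session(session_config("exp3", seed = 41))
  run <- run_switch_session(d, switch_model_config())
  # construct noiseless responses from a known internal estimate and gain
  r_known <- 0.5
  d$response <- (1 - r_known) * run$inferred_mean + r_known * d$cue
  curve <- align_to_switches(d, r_hat = r_known, sign_align = FALSE)
  d$mu_hat <- run$inferred_mean
  first_switch <- which(d$trials_since_switch == 1 & d$trial > 1)[1]
  manual <- d[seq(first_switch, nrow(d)), ] |>
    dplyr::filter(trials_since_switch <= 10) |>
    dplyr::group_by(k = trials_since_switch) |>
    dplyr::summarise(m = mean(mu_hat))
  expect_equal(curve$mean_estimate, manual$m, tolerance = 1e-10)
})

test_that("switch-aligned curve needs switch bookkeeping", {
  cfg <- session_config("exp1", prior_sd = 0.2, seed = 4)
  d <- run_observer(generate_session(cfg), observer_spec("oracle_fixed_prior"))
  expect_error(align_to_switches(d), "bookkeeping")
  d3 <- generate_session(session_config("exp3", switch_prob = 0, seed = 4))
  d3$response <- d3$cue * 0.5
  expect_warning(curve <- align_to_switches(d3, r_hat = 0.5), "no switches")
  expect_equal(nrow(curve), 0)
})

test_that("steady-state gain pools the last trials and exposes the removal modes", {
  cfg <- session_config("exp1", prior_sd = 0.2, seed = 6)
  d <- run_observer(generate_session(cfg), observer_spec("oracle_fixed_prior"))
  expect_equal(steady_state_gain(d)$r, 0.8, tolerance = 1e-10)
  expect_error(steady_state_gain(d, last_n = 500), "shorter")
  # change-point observer: cue-driven belief reweighting adds cue dependence,
  # so the raw (mean-not-removed) slope exceeds the mean-removed one
  rs <- vapply(1:8, function(s) {
    d3 <- generate_session(session_config("exp3", seed = s))
    d3$response <- run_switch_session(d3, switch_model_config())$response
    c(steady_state_gain(d3, remove_mean = TRUE)$r,
      steady_state_gain(d3, remove_mean = FALSE)$r)
  }, numeric(2))
  expect_gt(mean(rs[2, ]), mean(rs[1, ]))
})

test_that("prior trajectories round-trip through the oracle observer", {
  cfg <- session_config("exp1", prior_sd = 0.2, seed = 15)
  d <- run_observer(generate_session(cfg),
                    observer_spec("oracle_fixed_prior", motor_noise_sd = 0.02))
  traj <- prior_trajectory(bin_series(d), likelihood_sd = 0.1)
  expect_equal(nrow(traj), 40)
  expect_lt(abs(mean(traj$sd[!traj$flat]) - 0.2), 0.03)
  # degenerate bins map to the flat sentinel
  b <- tibble::tibble(bin = 1:2, r = c(0.8, 0.99), mu_p = c(0, NA),
                      degenerate = c(FALSE, TRUE))
  tr <- prior_trajectory(b, 0.1)
  expect_equal(tr$sd[1], 0.2)
  expect_true(tr$flat[2] && is.infinite(tr$sd[2]))
})

test_that("trial logs round-trip through CSV with 9 significant digits", {
  cfg <- session_config("exp3", seed = 44)
  d <- run_observer(generate_session(cfg), observer_spec("switching"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_log(d, path)
  back <- read_trial_log(path)
  expect_equal(nrow(back), 600)
  expect_equal(back$cue, signif(d$cue, 9))
  expect_identical(back$caught, d$caught)
  expect_identical(back$trials_since_switch, d$trials_since_switch)
  # absent response fields serialise as empty strings
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_trial_log(generate_session(cfg), path2)
  line <- readLines(path2, n = 2)[2]
  expect_match(line, ",,", fixed = TRUE)
})
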