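test_that("propagation follows the refractory hazard exactly", {
  cfg <- switch_model_config()
  # all mass below the refractory dwell just advances
  b <- matrix(0, 2, cfg$d_max); b[1, 5] <- 1
  b2 <- switch_propagate(b, cfg)
  expect_equal(b2[1, 6], 1)
  # at or past the refractory dwell: 0.8 stays, 0.2 flips to (other, 1)
  b <- matrix(0, 2, cfg$d_max); b[1, 12] <- 1
  b2 <- switch_propagate(b, cfg)
  expect_equal(b2[1, 13], 0.8)
  expect_equal(b2[2, 1], 0.2)
  # symmetric beliefs stay symmetric
  b <- matrix(1 / (2 * cfg$d_max), 2, cfg$d_max)
  b2 <- switch_propagate(b, cfg)
  expect_equal(b2[1, ], b2[2, ])
  expect_equal(sum(b2), 1, tolerance = 1e-12)
})

test_that("dwell mass accumulates at the cap without leaking", {
  cfg <- switch_model_config(d_max = 15, switch_prob = 0.2)
  b <- switch_belief_init(cfg)
  for (i in 1:200) b <- switch_propagate(b, cfg)
  expect_equal(sum(b), 1, tolerance = 1e-12)
  expect_gt(b[1, 15] + b[2, 15], 0)
})

test_that("target conditioning has the hand-computable Gaussian posterior odds", {
  cfg <- switch_model_config()  # means -0.05/0.05, prior sd 0.1
  b <- switch_belief_init(cfg)
  b2 <- switch_observe_target(b, 0.05, cfg)
  odds <- rowSums(b2)[2] / rowSums(b2)[1]
  expect_equal(odds, exp(0.5), tolerance = 1e-12)  # = 1.6487...
  # midpoint target: symmetric likelihood, belief unchanged
  b3 <- switch_observe_target(b, 0, cfg)
  expect_equal(b3, b)
})

test_that("net placement collapses correctly and respects symmetry", {
  cfg <- switch_model_config()
  g <- compute_gain(cfg$prior_sd, cfg$likelihood_sd)
  # collapsed belief: identical to the fixed-prior oracle at that mean
  b <- matrix(0, 2, cfg$d_max); b[1, 3] <- 1
  cue <- 0.12
  expect_equal(switch_place_net(b, cue, cfg),
               optimal_estimate(cfg$means[1], cue, g))
  # symmetric belief, cue equidistant from both means: net at the midpoint
  bs <- switch_belief_init(cfg)
  expect_equal(switch_place_net(bs, 0, cfg), 0)
})

test_that("forward recursion equals brute-force enumeration on short sessions", {
  cfg <- switch_model_config(refractory_trials = 2, switch_prob = 0.3,
                             d_max = 20)
  set.seed(5)
  n <- 8
  targets <- rnorm(n, 0.05, cfg$prior_sd)
  cues <- rnorm(n, targets, cfg$likelihood_sd)
  trials <- tibble::tibble(trial = 1:n, cue = cues, target = targets)
  run <- run_switch_session(trials, cfg)
  oracle <- enum_switch_oracle(targets, cues, cfg)
  expect_equal(run$p_mean1, oracle$p1, tolerance = 1e-10)
  expect_equal(run$response, oracle$net, tolerance = 1e-10)
  # under the default 10-trial refractory no switch is admissible in 8
  # trials; the recursion must still agree with enumeration
  cfg10 <- switch_model_config(d_max = 20)
  run10 <- run_switch_session(trials, cfg10)
  oracle10 <- enum_switch_oracle(targets, cues, cfg10)
  expect_equal(run10$p_mean1, oracle10$p1, tolerance = 1e-10)
})

test_that("belief stays normalised along a full session", {
  cfg <- switch_model_config()
  d <- generate_session(session_config("exp3", seed = 2))
  b <- switch_belief_init(cfg)
  for (t in 1:200) {
    b <- switch_observe_target(b, d$target[t], cfg)
    expect_equal(sum(b), 1, tolerance = 1e-12)
    b <- switch_propagate(b, cfg)
    expect_equal(sum(b), 1, tolerance = 1e-12)
  }
})

test_that("label symmetry: swapping means and negating positions mirrors the run", {
  cfg <- switch_model_config(means = c(-0.05, 0.05))
  cfg_swapped <- switch_model_config(means = c(0.05, -0.05))
  d <- generate_session(session_config("exp3", seed = 9, n_trials = 100))
  run <- run_switch_session(d, cfg)
  neg <- d
  neg$cue <- -neg$cue; neg$target <- -neg$target
  run2 <- run_switch_session(neg, cfg_swapped)
  expect_equal(run2$p_mean1, run$p_mean1, tolerance = 1e-12)
  expect_equal(run2$response, -run$response, tolerance = 1e-12)
})

test_that("repeated evidence drives belief to a hazard-limited ceiling below 1", {
  cfg <- switch_model_config()
  b <- switch_belief_init(cfg)
  p1 <- numeric(300)
  for (i in 1:300) {
    b <- switch_observe_target(b, cfg$means[1], cfg)
    p1[i] <- rowSums(b)[1]
    b <- switch_propagate(b, cfg)
  }
  expect_lt(abs(p1[300] - p1[299]), 1e-10)  # fixed point reached
  expect_lt(p1[300], 0.99)                  # strictly below certainty
  expect_gt(p1[300], 0.5)                   # but favouring the evidenced mean
  # the ceiling reflects the hazard floor: lowering the hazard raises it
  cfg_low <- switch_model_config(switch_prob = 0.05)
  b <- switch_belief_init(cfg_low)
  for (i in 1:300) {
    b <- switch_observe_target(b, cfg_low$means[1], cfg_low)
    b <- switch_propagate(b, cfg_low)
  }
  expect_gt(rowSums(b)[1], p1[300])
})

test_that("detection speed grows with mean separation; zero separation learns nothing", {
  p2_after_one <- vapply(c(0.02, 0.1, 0.3), function(sep) {
    cfg <- switch_model_config(means = c(-sep / 2, sep / 2))
    b <- switch_observe_target(switch_belief_init(cfg), sep / 2, cfg)
    rowSums(b)[2]
  }, numeric(1))
  expect_true(all(diff(p2_after_one) > 0))
  cfg0 <- switch_model_config(means = c(-1e-12, 1e-12))
  b <- switch_observe_target(switch_belief_init(cfg0), 0.05, cfg0)
  expect_equal(rowSums(b)[[1]], 0.5, tolerance = 1e-9)
})

test_that("with no switches the belief converges to the true mean and stays", {
  cfg_gen <- session_config("exp3", switch_prob = 0, seed = 12)
  d <- generate_session(cfg_gen)
  cfg <- switch_model_config(switch_prob = 0)
  run <- run_switch_session(d, cfg)
  truth <- d$prior_mean_true[1]
  idx <- if (truth == cfg$means[1]) run$p_mean1 else 1 - run$p_mean1
  expect_gt(min(idx[50:600]), 0.999)
  expect_equal(run$inferred_mean[600], truth, tolerance = 1e-3)
})
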