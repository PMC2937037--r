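#' Configuration of the change-point inference model
#'
#' The two-state-mean protocol's ideal observer: it knows the prior's spread,
#' the two candidate means, and the switching process (refractory period plus
#' constant hazard), and only has to infer which mean is currently active. It
#' has no free parameters. Because the generative hazard is non-constant
#' (switches are impossible during the refractory period), the belief is kept
#' over joint (active mean, dwell time) states; a constant-hazard
#' approximation is available as a flag for comparison.
#'
#' @param means The two candidate prior means (default `c(-0.05, 0.05)`).
#' @param prior_sd Known prior spread (default 0.1).
#' @param likelihood_sd Known cue spread (default 0.1).
#' @param refractory_trials Trials after a switch during which no further
#'   switch can occur (default 10).
#' @param switch_prob Per-trial switch probability past the refractory period
#'   (default 0.2).
#' @param d_max Dwell-time cap; probability mass at dwell `d_max`
#'   accumulates there (default 60, far into the constant-hazard regime, so
#'   the induced error is negligible).
#' @param constant_hazard If `TRUE`, ignore the refractory period and use a
#'   constant per-trial hazard of `switch_prob` (approximation flag).
#' @param placement `"mean"` (posterior-mean placement under the mixture,
#'   default, the minimum-squared-error choice) or `"map"` (place using the
#'   most probable mean only).
#' @return An object of class `switch_model_config`.
#' @export
switch_model_config <- function(means = c(-0.05, 0.05), prior_sd = 0.1,
                                likelihood_sd = 0.1, refractory_trials = 10,
                                switch_prob = 0.2, d_max = 60,
                                constant_hazard = FALSE,
                                placement = c("mean", "map")) {
  if (prior_sd <= 0 || likelihood_sd <= 0) {
    stop("prior_sd and likelihood_sd must be > 0", call. = FALSE)
  }
  if (length(means) != 2 || means[1] == means[2]) {
    stop("means must be two distinct positions", call. = FALSE)
  }
  structure(list(means = as.numeric(means), prior_sd = prior_sd,
                 likelihood_sd = likelihood_sd,
                 refractory_trials = as.integer(refractory_trials),
                 switch_prob = switch_prob, d_max = as.integer(d_max),
                 constant_hazard = isTRUE(constant_hazard),
                 placement = match.arg(placement)),
            class = "switch_model_config")
}

#' Initial belief over (active mean, dwell time) states
#'
#' Probability mass 1/2 on each mean at dwell 1, mirroring the generative
#' process's random initial state.
#'
#' @param config A [switch_model_config()].
#' @return A 2 x `d_max` matrix of state probabilities (rows: mean index).
#' @export
switch_belief_init <- function(config) {
  b <- matrix(0, 2, config$d_max)
  b[, 1] <- 0.5
  b
}

# Per-dwell hazard: 0 during the refractory period, switch_prob after.
hazard_vector <- function(config) {
  d <- seq_len(config$d_max)
  if (config$constant_hazard) {
    rep(config$switch_prob, config$d_max)
  } else {
    ifelse(d < config$refractory_trials, 0, config$switch_prob)
  }
}

#' Advance the switching belief one trial through the transition model
#'
#' Mass at state (mean m, dwell d) moves to (m, d + 1) with probability
#' `1 - h(d)` and to (other mean, dwell 1) with probability `h(d)`, where the
#' hazard `h(d)` is 0 during the refractory period and `switch_prob`
#' afterwards. Dwell mass at the cap accumulates there. The result is
#' renormalised to guard against floating-point drift.
#'
#' @param belief A 2 x `d_max` probability matrix.
#' @param config A [switch_model_config()].
#' @return The propagated belief matrix.
#' @export
switch_propagate <- function(belief, config) {
  h <- hazard_vector(config)
  D <- config$d_max
  out <- matrix(0, 2, D)
  stay <- belief * rep(1 - h, each = 2)
  out[, 2:D] <- stay[, 1:(D - 1)]
  out[, D] <- out[, D] + stay[, D]            # cap bin accumulates
  flipped <- belief * rep(h, each = 2)
  out[1, 1] <- sum(flipped[2, ])
  out[2, 1] <- sum(flipped[1, ])
  out / sum(out)
}

#' Condition the switching belief on a revealed target position
#'
#' Reweights each mean's states by the target likelihood
#' `Normal(target; mean_m, prior_sd^2)` and renormalises. Only the target is
#' used: given the target, the cue carries no further information about which
#' mean is active.
#'
#' @param belief A 2 x `d_max` probability matrix.
#' @param target Revealed target position.
#' @param config A [switch_model_config()].
#' @return The updated belief matrix.
#' @export
switch_observe_target <- function(belief, target, config) {
  lik <- stats::dnorm(target, config$means, config$prior_sd)
  out <- belief * lik
  out / sum(out)
}

#' Net placement from the switching belief and the current cue
#'
#' The belief over means is first reweighted by each mean's marginal cue
#' likelihood `Normal(cue; mean_m, prior_sd^2 + likelihood_sd^2)` (this
#' conditioning is transient: the persistent belief is updated later from the
#' revealed target, so the cue is never double-counted). The net goes to the
#' posterior-mean placement under the resulting two-component mixture,
#' each component contributing its within-state optimal estimate with the
#' known gain `compute_gain(prior_sd, likelihood_sd)`; with
#' `placement = "map"` the most probable mean's estimate is used instead.
#'
#' @param belief A 2 x `d_max` probability matrix.
#' @param cue Observed cue position.
#' @param config A [switch_model_config()].
#' @return The net position (scalar).
#' @export
switch_place_net <- function(belief, cue, config) {
  p_mean <- rowSums(belief)
  w <- p_mean * stats::dnorm(cue, config$means,
                             sqrt(config$prior_sd^2 + config$likelihood_sd^2))
  w <- w / sum(w)
  g <- compute_gain(config$prior_sd, config$likelihood_sd)
  est <- (1 - g) * config$means + g * cue
  if (config$placement == "map") {
    est[which.max(w)]
  } else {
    sum(w * est)
  }
}

#' Run the change-point observer through a session
#'
#' Per trial: respond with [switch_place_net()], then condition the belief on
#' the revealed target, then propagate through the switch dynamics. The
#' recorded probabilities are the post-observation values — the observer's
#' estimate of the active mean after seeing that trial's coins.
#'
#' @param trials Stimulus tibble (columns `cue`, `target`).
#' @param config A [switch_model_config()].
#' @return A tibble with per-trial `p_mean1` (post-observation probability of
#'   the first mean), `inferred_mean` (posterior-mean of the active mean),
#'   and `response`.
#' @export
run_switch_session <- function(trials, config = switch_model_config()) {
  stopifnot(inherits(config, "switch_model_config"))
  n <- nrow(trials)
  b <- switch_belief_init(config)
  p1 <- numeric(n)
  inferred <- numeric(n)
  resp <- numeric(n)
  for (t in seq_len(n)) {
    resp[t] <- switch_place_net(b, trials$cue[t], config)
    b <- switch_observe_target(b, trials$target[t], config)
    p <- rowSums(b)
    p1[t] <- p[1]
    inferred[t] <- sum(p * config$means)
    b <- switch_propagate(b, config)
  }
  tibble::tibble(trial = trials$trial, cue = trials$cue, target = trials$target,
                 p_mean1 = p1, inferred_mean = inferred, response = resp)
}
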