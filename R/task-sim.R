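#' Generate the stimulus stream for one session
#'
#' Draws the per-trial target and cue positions under the configured protocol:
#' targets from the (possibly time-varying) Gaussian prior, cues Gaussian
#' around each target with the likelihood spread. For `exp3` the active prior
#' mean flips between the two candidate locations under the refractory +
#' Bernoulli hazard. Positions are not clipped to the screen unless
#' `truncate_to_screen` is set: the generative model is an untruncated
#' Gaussian and tail draws are part of it.
#'
#' @param config A [session_config()].
#' @return A tibble with one row per trial and columns `trial`,
#'   `prior_mean_true`, `prior_sd_true`, `target`, `cue` and (for `exp3`)
#'   `trials_since_switch` (`NA` otherwise). The configuration is attached as
#'   attribute `"session_config"`. Identical configs (including seed) give
#'   bit-identical streams.
#' @export
generate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  config <- validate_session_config(config)
  n <- config$n_trials
  seeds <- substream_seeds(config$seed)

  sd_true <- schedule_sd(config$prior_sd_schedule, n)

  if (config$prior_mean_mode == "two_state") {
    sw <- with_seed(seeds[["switches"]], simulate_mean_path(
      n, config$two_state_means, config$refractory_trials, config$switch_prob))
    mean_true <- sw$mean
    since <- sw$trials_since_switch
  } else {
    subject_mean <- with_seed(seeds[["subject"]],
                              stats::rnorm(1, 0, config$subject_mean_sd))
    mean_true <- rep(subject_mean, n)
    since <- rep(NA_integer_, n)
  }

  target <- with_seed(seeds[["targets"]], {
    draw_positions(n, mean_true, sd_true, config$truncate_to_screen)
  })
  cue <- with_seed(seeds[["cues"]], {
    draw_positions(n, target, config$likelihood_sd, config$truncate_to_screen)
  })

  out <- tibble::tibble(
    trial = seq_len(n),
    prior_mean_true = mean_true,
    prior_sd_true = sd_true,
    target = target,
    cue = cue,
    trials_since_switch = since
  )
  attr(out, "session_config") <- config
  out
}

# Per-trial prior spread from a piecewise-constant schedule.
schedule_sd <- function(schedule, n_trials) {
  idx <- findInterval(seq_len(n_trials), schedule$start_trial)
  schedule$sd[idx]
}

# Two-state mean path: dwell counter starts at 1 on the first trial governed
# by a mean; a flip is possible once dwell >= refractory, with prob. hazard.
simulate_mean_path <- function(n, means, refractory, hazard) {
  state <- sample.int(2L, 1L)
  u <- stats::runif(n)
  mean_idx <- integer(n)
  since <- integer(n)
  dwell <- 1L
  for (t in seq_len(n)) {
    if (t > 1L) {
      if (dwell >= refractory && u[t] < hazard) {
        state <- 3L - state
        dwell <- 1L
      } else {
        dwell <- dwell + 1L
      }
    }
    mean_idx[t] <- state
    since[t] <- dwell
  }
  list(mean = means[mean_idx], mean_index = mean_idx, trials_since_switch = since)
}

draw_positions <- function(n, mean, sd, truncate) {
  x <- stats::rnorm(n, mean, sd)
  if (truncate) {
    bad <- which(abs(x) > 0.5)
    while (length(bad) > 0) {
      x[bad] <- stats::rnorm(length(bad), mean[bad], if (length(sd) > 1) sd[bad] else sd)
      bad <- bad[abs(x[bad]) > 0.5]
    }
  }
  x
}

#' Did the net catch the target coin?
#'
#' The net is a thin vertical line, so requiring the net and the coin to
#' overlap by at least `overlap_fraction` of the coin's width reduces to a
#' distance rule: the catch succeeds iff
#' `|net - target| <= (1 - overlap_fraction) * coin_width` (boundary
#' inclusive).
#'
#' @param net Net position (screen units).
#' @param target Target coin position.
#' @param coin_width Coin width in screen units (> 0).
#' @param overlap_fraction Required overlap as a fraction of the coin width.
#' @return Logical, vectorised.
#' @export
is_caught <- function(net, target, coin_width = 0.03, overlap_fraction = 0.5) {
  if (any(coin_width <= 0)) stop("coin_width must be > 0", call. = FALSE)
  abs(net - target) <= (1 - overlap_fraction) * coin_width
}

#' Specify a synthetic observer
#'
#' Observers stand in for subjects: they see the cue, place the net, and only
#' then see the target (matching the trial order of the task). Available
#' models:
#' * `oracle_fixed_prior` — knows the true generative prior on every trial and
#'   responds with the Bayes-optimal placement;
#' * `flat_prior_ml` — maximum-likelihood behaviour: the response is the cue;
#' * `nig_learner` — sequential conjugate (Normal-scaled-Inverse-Gamma)
#'   learner of the prior's mean and variance (see [nig_state()]);
#' * `linear_filter` — fixed-learning-rate variance tracker over a 10-trial
#'   window (see [lf_state()]);
#' * `switching` — change-point inference model for the two-state mean
#'   protocol (see [switch_model_config()]).
#'
#' @param model One of the model names above.
#' @param params Model-specific parameter object (`nig_state`, `lf_state`, or
#'   `switch_model_config`); ignored by the two parameter-free models.
#' @param motor_noise_sd Spread of additive Gaussian response jitter
#'   (default 0).
#' @return An `observer_spec` object.
#' @export
observer_spec <- function(model = c("oracle_fixed_prior", "flat_prior_ml",
                                    "nig_learner", "linear_filter", "switching"),
                          params = NULL, motor_noise_sd = 0) {
  model <- match.arg(model)
  if (motor_noise_sd < 0) stop("motor_noise_sd must be >= 0", call. = FALSE)
  structure(list(model = model, params = params,
                 motor_noise_sd = motor_noise_sd),
            class = "observer_spec")
}

#' Run an observer on a stimulus stream
#'
#' Adds `response` and `caught` columns to a generated session. The response
#' on each trial depends only on the cue and on targets from *earlier* trials
#' (models update after responding), never on the current trial's target.
#' Motor noise, if any, is drawn from the session's dedicated motor substream,
#' so the stimulus stream is unchanged by attaching an observer.
#'
#' @param trials A tibble from [generate_session()].
#' @param observer An [observer_spec()].
#' @param likelihood_sd Cue spread assumed by the observer; defaults to the
#'   value in the attached session config.
#' @return The input tibble with `response` and `caught` columns. Model-based
#'   observers attach their state trajectory as attribute `"trajectory"`.
#' @export
run_observer <- function(trials, observer, likelihood_sd = NULL) {
  stopifnot(inherits(observer, "observer_spec"))
  if (nrow(trials) == 0) stop("empty session", call. = FALSE)
  cfg <- attr(trials, "session_config")
  if (is.null(likelihood_sd)) {
    if (is.null(cfg)) stop("supply likelihood_sd or a session with config attached",
                           call. = FALSE)
    likelihood_sd <- cfg$likelihood_sd
  }

  traj <- NULL
  response <- switch(
    observer$model,
    oracle_fixed_prior = {
      g <- compute_gain(trials$prior_sd_true, likelihood_sd)
      optimal_estimate(trials$prior_mean_true, trials$cue, g)
    },
    flat_prior_ml = trials$cue,
    nig_learner = {
      init <- observer$params %||% nig_state()
      run <- run_nig_session(trials, init, likelihood_sd)
      traj <- run
      run$response
    },
    linear_filter = {
      init <- observer$params %||% lf_state()
      run <- run_lf_session(trials, init, likelihood_sd)
      traj <- run
      run$response
    },
    switching = {
      scfg <- observer$params %||% switch_model_config(likelihood_sd = likelihood_sd)
      run <- run_switch_session(trials, scfg)
      traj <- run
      run$response
    }
  )

  if (observer$motor_noise_sd > 0) {
    if (is.null(cfg)) {
      stop("motor noise needs the session config (for its seed substream)",
           call. = FALSE)
    }
    seeds <- substream_seeds(cfg$seed)
    response <- response + with_seed(seeds[["motor"]],
      stats::rnorm(nrow(trials), 0, observer$motor_noise_sd))
  }

  coin_width <- if (!is.null(cfg)) cfg$coin_width else 0.03
  overlap <- if (!is.null(cfg)) cfg$catch_overlap_fraction else 0.5
  out <- dplyr::mutate(trials,
                       response = response,
                       caught = is_caught(response, .data$target, coin_width, overlap))
  attr(out, "session_config") <- cfg
  attr(out, "trajectory") <- traj
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
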