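#' Configure one simulated session of the coin-catching task
#'
#' Builds the full generative specification of a session under one of the
#' three protocols:
#' * `exp1` — fixed Gaussian prior (spread 0.05 or 0.2), 400 trials;
#' * `exp2` — the prior's spread switches once at mid-session (trial 251 of
#'   500) between 0.05 and 0.2;
#' * `exp3` — the prior's mean flips between two locations (-0.05, +0.05,
#'   spread fixed at 0.1) for 600 trials. A flip is possible only after at
#'   least `refractory_trials` trials in the current state, then occurs
#'   independently each trial with probability `switch_prob`.
#'
#' Positions are in normalised screen units (the screen spans \[-0.5, 0.5\]).
#' The cue is drawn Gaussian around the target with spread `likelihood_sd`
#' (0.1 throughout the study design). For `exp1`/`exp2` each session (synthetic
#' subject) gets its own prior mean, drawn from a zero-mean Gaussian with
#' spread `subject_mean_sd`.
#'
#' @param protocol `"exp1"`, `"exp2"` or `"exp3"`.
#' @param prior_sd Prior spread(s). For `exp1` a single value (default 0.2);
#'   for `exp2` a length-2 vector `c(first_half, second_half)` (default
#'   `c(0.2, 0.05)`); for `exp3` a single value (default 0.1). Ignored when
#'   `prior_sd_schedule` is supplied directly.
#' @param n_trials Number of trials (defaults 400 / 500 / 600 by protocol).
#' @param likelihood_sd Cue spread around the target (default 0.1).
#' @param prior_sd_schedule Optional tibble/data frame with columns
#'   `start_trial`, `sd`: piecewise-constant spread schedule. Must cover
#'   trial 1 with strictly increasing `start_trial`.
#' @param prior_mean_mode `"random_subject_specific"` (exp1/exp2 default) or
#'   `"two_state"` (exp3 default).
#' @param subject_mean_sd Spread of the per-session random prior mean
#'   (default 0.1).
#' @param two_state_means The two candidate means for `exp3`
#'   (default `c(-0.05, 0.05)`).
#' @param refractory_trials Minimum dwell before a mean flip is possible
#'   (default 10).
#' @param switch_prob Per-trial flip probability once past the refractory
#'   period (default 0.2).
#' @param coin_width Coin width in screen units used by the catch rule
#'   (default 0.03; the study reports none, so this is a configurable
#'   package default).
#' @param catch_overlap_fraction Minimum net/coin overlap fraction counted as
#'   a catch (default 0.5).
#' @param truncate_to_screen If `TRUE`, redraw targets/cues that fall outside
#'   the screen (sensitivity option; default `FALSE`, Gaussian tails are kept
#'   because the generative model is untruncated).
#' @param seed Integer seed; the session splits it into independent named
#'   substreams (subject mean, switches, targets, cues, motor noise) so that
#'   adding an observer never perturbs the stimulus stream.
#' @return An object of class `session_config`.
#' @export
session_config <- function(protocol = c("exp1", "exp2", "exp3"),
                           prior_sd = NULL,
                           n_trials = NULL,
                           likelihood_sd = 0.1,
                           prior_sd_schedule = NULL,
                           prior_mean_mode = NULL,
                           subject_mean_sd = 0.1,
                           two_state_means = c(-0.05, 0.05),
                           refractory_trials = 10,
                           switch_prob = 0.2,
                           coin_width = 0.03,
                           catch_overlap_fraction = 0.5,
                           truncate_to_screen = FALSE,
                           seed = 1L) {
  protocol <- match.arg(protocol)
  if (is.null(n_trials)) {
    n_trials <- switch(protocol, exp1 = 400L, exp2 = 500L, exp3 = 600L)
  }
  n_trials <- as.integer(n_trials)
  if (is.null(prior_mean_mode)) {
    prior_mean_mode <- if (protocol == "exp3") "two_state" else "random_subject_specific"
  }
  prior_mean_mode <- match.arg(prior_mean_mode,
                               c("random_subject_specific", "two_state"))
  if (is.null(prior_sd_schedule)) {
    if (is.null(prior_sd)) {
      prior_sd <- switch(protocol, exp1 = 0.2, exp2 = c(0.2, 0.05), exp3 = 0.1)
    }
    prior_sd_schedule <- switch(
      protocol,
      exp1 = tibble::tibble(start_trial = 1L, sd = prior_sd[[1]]),
      exp2 = {
        if (length(prior_sd) != 2) {
          stop("exp2 needs two prior spreads (first and second half)", call. = FALSE)
        }
        tibble::tibble(start_trial = c(1L, n_trials %/% 2L + 1L), sd = prior_sd)
      },
      exp3 = tibble::tibble(start_trial = 1L, sd = prior_sd[[1]])
    )
  } else {
    prior_sd_schedule <- tibble::as_tibble(prior_sd_schedule)
  }
  cfg <- structure(
    list(
      protocol = protocol,
      n_trials = n_trials,
      likelihood_sd = likelihood_sd,
      prior_sd_schedule = prior_sd_schedule,
      prior_mean_mode = prior_mean_mode,
      subject_mean_sd = subject_mean_sd,
      two_state_means = as.numeric(two_state_means),
      refractory_trials = as.integer(refractory_trials),
      switch_prob = switch_prob,
      coin_width = coin_width,
      catch_overlap_fraction = catch_overlap_fraction,
      truncate_to_screen = isTRUE(truncate_to_screen),
      seed = as.integer(seed)
    ),
    class = "session_config"
  )
  validate_session_config(cfg)
}

validate_session_config <- function(cfg) {
  sch <- cfg$prior_sd_schedule
  if (!all(c("start_trial", "sd") %in% names(sch))) {
    stop("prior_sd_schedule needs columns start_trial and sd", call. = FALSE)
  }
  if (cfg$n_trials <= 0) stop("n_trials must be positive", call. = FALSE)
  if (cfg$likelihood_sd <= 0) stop("likelihood_sd must be > 0", call. = FALSE)
  if (any(sch$sd <= 0)) stop("all scheduled prior spreads must be > 0", call. = FALSE)
  if (sch$start_trial[1] != 1L) {
    stop("prior_sd_schedule must cover trial 1", call. = FALSE)
  }
  if (is.unsorted(sch$start_trial, strictly = TRUE)) {
    stop("prior_sd_schedule start_trial values must be strictly increasing",
         call. = FALSE)
  }
  if (cfg$switch_prob < 0 || cfg$switch_prob > 1) {
    stop("switch_prob must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$subject_mean_sd < 0) stop("subject_mean_sd must be >= 0", call. = FALSE)
  if (length(cfg$two_state_means) != 2) {
    stop("two_state_means must have length 2", call. = FALSE)
  }
  if (cfg$coin_width <= 0) stop("coin_width must be > 0", call. = FALSE)
  cfg
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>", x$protocol, "-", x$n_trials, "trials, seed", x$seed, "\n")
  cat("  likelihood sd:", x$likelihood_sd, "\n")
  cat("  prior sd schedule:",
      paste(sprintf("trial %d -> %g", x$prior_sd_schedule$start_trial,
                    x$prior_sd_schedule$sd), collapse = ", "), "\n")
  if (x$prior_mean_mode == "two_state") {
    cat("  means:", paste(x$two_state_means, collapse = " / "),
        " refractory:", x$refractory_trials, " switch prob:", x$switch_prob, "\n")
  } else {
    cat("  subject-specific mean ~ Normal(0,", x$subject_mean_sd, ")\n")
  }
  invisible(x)
}

config_field_names <- function() {
  c("protocol", "prior_sd", "n_trials", "likelihood_sd", "prior_sd_schedule",
    "prior_mean_mode", "subject_mean_sd", "two_state_means",
    "refractory_trials", "switch_prob", "coin_width",
    "catch_overlap_fraction", "truncate_to_screen", "seed")
}

#' Read a session configuration from JSON or YAML
#'
#' The file format is inferred from the extension (`.json`, `.yaml`/`.yml`).
#' Unknown keys are rejected, so typos in configuration files fail loudly
#' rather than silently falling back to defaults.
#'
#' @param path Path to a JSON or YAML file whose keys are
#'   [session_config()] arguments.
#' @return A `session_config`.
#' @export
read_session_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format: ", ext, call. = FALSE)
  )
  unknown <- setdiff(names(raw), config_field_names())
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$prior_sd_schedule)) {
    raw$prior_sd_schedule <- tibble::as_tibble(raw$prior_sd_schedule)
  }
  do.call(session_config, raw)
}

#' Write a session configuration to JSON or YAML
#'
#' @param config A `session_config`.
#' @param path Output path ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
write_session_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  out <- unclass(config)
  out$prior_sd_schedule <- as.data.frame(out$prior_sd_schedule)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                                dataframe = "columns"),
    yaml = ,
    yml = yaml::write_yaml(out, path),
    stop("unsupported config format: ", ext, call. = FALSE)
  )
  invisible(path)
}

# Deterministic per-purpose sub-seeds derived from the session seed, so the
# stimulus stream is invariant to which observer (if any) is attached.
substream_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, 5L)
  names(s) <- c("subject", "switches", "targets", "cues", "motor")
  s
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
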