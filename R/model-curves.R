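# Stimulus streams for many independent sessions (synthetic subjects) of one
# protocol, as trial x run matrices. Run seeds derive deterministically from
# `seed`, so the same seed always yields the same ensemble (common random
# numbers for fitting).
simulate_stimuli_runs <- function(config, n_runs, seed) {
  run_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_runs))
  sessions <- lapply(run_seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    generate_session(cfg)
  })
  list(
    targets = vapply(sessions, function(d) d$target, numeric(config$n_trials)),
    cues = vapply(sessions, function(d) d$cue, numeric(config$n_trials)),
    mean_true = vapply(sessions, function(d) d$prior_mean_true,
                       numeric(config$n_trials)),
    config = config,
    run_seeds = run_seeds
  )
}

# Per-bin OLS of response on cue, vectorised across runs.
# Returns n_bins x R matrices of slopes (r) and mean errors (mu_p - truth),
# with the same degeneracy rule as fit_bin (|1 - r| < 0.05 -> NA mean).
binned_ols_matrix <- function(cues, resps, mean_true, bin_size = 10) {
  n <- nrow(cues)
  n_bins <- n %/% bin_size
  R <- ncol(cues)
  r_mat <- matrix(NA_real_, n_bins, R)
  mu_err <- matrix(NA_real_, n_bins, R)
  for (b in seq_len(n_bins)) {
    idx <- ((b - 1L) * bin_size + 1L):(b * bin_size)
    cx <- cues[idx, , drop = FALSE]
    ry <- resps[idx, , drop = FALSE]
    cmx <- colMeans(cx)
    cmy <- colMeans(ry)
    dx <- sweep(cx, 2, cmx)
    slope <- colSums(dx * sweep(ry, 2, cmy)) / colSums(dx^2)
    intercept <- cmy - slope * cmx
    mu_p <- ifelse(abs(1 - slope) < 0.05, NA_real_, intercept / (1 - slope))
    r_mat[b, ] <- slope
    mu_err[b, ] <- mu_p - colMeans(mean_true[idx, , drop = FALSE])
  }
  list(r = r_mat, mu_p_error = mu_err)
}

curves_from_matrices <- function(binned) {
  R <- ncol(binned$r)
  tibble::tibble(
    bin = seq_len(nrow(binned$r)),
    r = rowMeans(binned$r),
    se_r = apply(binned$r, 1, stats::sd) / sqrt(R),
    mu_p_error = rowMeans(binned$mu_p_error, na.rm = TRUE),
    se_mu_p_error = apply(binned$mu_p_error, 1, stats::sd, na.rm = TRUE) /
      sqrt(pmax(rowSums(!is.na(binned$mu_p_error)), 1)),
    n_runs = R
  )
}

run_model_matrix <- function(stim, init, likelihood_sd, variance_mode = "mean") {
  if (inherits(init, "nig_state")) {
    nig_run_matrix(stim$cues, stim$targets, init, likelihood_sd, variance_mode)
  } else if (inherits(init, "lf_state")) {
    lf_run_matrix(stim$cues, stim$targets, init, likelihood_sd)
  } else {
    stop("init must be an nig_state or lf_state", call. = FALSE)
  }
}

#' Average binned learning curves of a model observer
#'
#' Simulates `n_runs` independent sessions of one protocol (each with its own
#' subject-specific prior mean where the protocol has one), runs the model
#' observer on each, applies the binned least-squares analysis per run, and
#' averages bin-wise across runs — the simulated analogue of across-subject
#' average learning curves. Deterministic given `seed`.
#'
#' @param config A [session_config()].
#' @param init An [nig_state()] or [lf_state()]; selects the model.
#' @param n_runs Number of independent sessions (default 100).
#' @param seed Integer seed for the session ensemble.
#' @param bin_size Trials per bin (default 10).
#' @param variance_mode Passed to the NIG learner (see [run_nig_session()]).
#' @return A tibble with per-bin `r`, `se_r`, `mu_p_error`, `se_mu_p_error`
#'   and `n_runs`. With `n_runs = 1` it equals the single run's
#'   [bin_series()] curve.
#' @export
average_model_curves <- function(config, init, n_runs = 100, seed = 1,
                                 bin_size = 10, variance_mode = "mean") {
  stopifnot(n_runs >= 1)
  stim <- simulate_stimuli_runs(config, n_runs, seed)
  resp <- run_model_matrix(stim, init, config$likelihood_sd, variance_mode)
  binned <- binned_ols_matrix(stim$cues, resp, stim$mean_true, bin_size)
  curves_from_matrices(binned)
}

#' Bins needed to reach (and hold) a gain criterion
#'
#' The first bin index at which the binned gain falls within `tol` of the
#' reference gain. Curves that never reach the criterion are right-censored
#' at `length(r) + 1`, so comparisons between convergence speeds remain
#' well-defined.
#'
#' @param r Vector of per-bin gains (one learning curve).
#' @param r_true Reference (generative) gain.
#' @param tol Criterion half-width (default 0.1).
#' @return Integer bin index, censored at `length(r) + 1`.
#' @export
bins_to_criterion <- function(r, r_true, tol = 0.1) {
  hit <- which(abs(r - r_true) < tol)
  if (length(hit) == 0) length(r) + 1L else hit[1]
}
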