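#' Fixed-learning-rate variance filter state
#'
#' The non-Bayesian comparison model: it tracks only the prior's variance,
#' forming a sample-variance observation over a running window of the last
#' `window_size` targets and blending it into its estimate with a constant
#' learning rate. Its two free parameters are `learning_rate` and `var_init`.
#' Its mean estimate (unspecified by the model's definition) defaults to the
#' running mean of all targets seen so far, switchable to the window mean.
#'
#' @param learning_rate Blend weight on the new variance observation, in
#'   \[0, 1\].
#' @param var_init Initial variance estimate (>= 0, screen units squared).
#' @param window_size Window length for the variance observation (default 10).
#' @param mean_mode `"running"` (default; mean of all targets seen) or
#'   `"window"` (mean of the current window).
#' @return An object of class `lf_state`.
#' @export
lf_state <- function(learning_rate = 0.1, var_init = 0.25, window_size = 10,
                     mean_mode = c("running", "window")) {
  if (learning_rate < 0 || learning_rate > 1) {
    stop("learning_rate must lie in [0, 1]", call. = FALSE)
  }
  if (var_init < 0) stop("var_init must be >= 0", call. = FALSE)
  structure(list(learning_rate = learning_rate, var_init = var_init,
                 window_size = as.integer(window_size),
                 mean_mode = match.arg(mean_mode)),
            class = "lf_state")
}

#' Unbiased sample variance of a window of target positions
#'
#' @param window Numeric vector of positions; at least two points are needed
#'   to form a variance observation.
#' @return The divisor-(n-1) sample variance, or `NA` (the no-observation
#'   sentinel: the filter state is left unchanged that trial) when the window
#'   holds fewer than two points.
#' @export
window_variance <- function(window) {
  if (length(window) < 2) return(NA_real_)
  stats::var(window)
}

#' Run the variance filter through a session
#'
#' Same respond-then-update loop as [run_nig_session()]: the response is
#' `optimal_estimate(mean_estimate, cue, gain)` with the gain computed from
#' the current variance estimate, then the revealed target is pushed into the
#' window. The variance estimate only starts moving once the window is full
#' (warm-up: it stays at `var_init` until `window_size` targets have been
#' seen); thereafter
#' `var' = var + learning_rate * (window_variance - var)` every trial.
#'
#' @param trials Stimulus tibble (columns `cue`, `target`).
#' @param init An [lf_state()].
#' @param likelihood_sd Known cue spread.
#' @return A tibble with per-trial `mean_estimate`, `var_estimate`, `gain`
#'   and `response` (pre-update values, as for the NIG learner).
#' @export
run_lf_session <- function(trials, init = lf_state(), likelihood_sd = 0.1) {
  stopifnot(inherits(init, "lf_state"))
  n <- nrow(trials)
  vl <- likelihood_sd^2
  W <- init$window_size
  rate <- init$learning_rate
  v <- init$var_init
  m <- 0
  seen <- 0
  window <- numeric(0)
  out <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("mean_estimate", "var_estimate",
                                        "gain", "response")))
  for (t in seq_len(n)) {
    g <- v / (v + vl)
    mean_est <- if (seen == 0) 0 else m
    resp <- (1 - g) * mean_est + g * trials$cue[t]
    out[t, ] <- c(mean_est, v, g, resp)
    x <- trials$target[t]
    window <- c(window, x)
    if (length(window) > W) window <- window[-1]
    seen <- seen + 1
    m <- if (init$mean_mode == "running") {
      m + (x - m) / seen
    } else {
      mean(window)
    }
    if (length(window) == W) {
      v <- v + rate * (window_variance(window) - v)
    }
  }
  dplyr::bind_cols(
    tibble::tibble(trial = trials$trial, cue = trials$cue, target = trials$target),
    tibble::as_tibble(out)
  )
}

# Vectorised multi-run pass for fitting: T x R stimulus matrices.
lf_run_matrix <- function(cues, targets, init, likelihood_sd) {
  n <- nrow(targets)
  R <- ncol(targets)
  vl <- likelihood_sd^2
  W <- init$window_size
  rate <- init$learning_rate
  v <- rep(init$var_init, R)
  m <- rep(0, R)
  resp <- matrix(NA_real_, n, R)
  for (t in seq_len(n)) {
    g <- v / (v + vl)
    mean_est <- if (t == 1) rep(0, R) else m
    resp[t, ] <- (1 - g) * mean_est + g * cues[t, ]
    x <- targets[t, ]
    m <- m + (x - m) / t
    if (t >= W) {
      win <- targets[(t - W + 1L):t, , drop = FALSE]
      wm <- colMeans(win)
      wv <- colSums(sweep(win, 2, wm)^2) / (W - 1)
      v <- v + rate * (wv - v)
    }
  }
  resp
}
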