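#' Normal-scaled-Inverse-Gamma belief state
#'
#' The joint conjugate belief over a Gaussian prior's unknown mean and
#' variance: `sigma^2 ~ Inv-Gamma(alpha, beta)` and
#' `mu_p | sigma^2 ~ Normal(mu, sigma^2 / lam)`. The four hyperparameters of
#' the *initial* state are the learner's four free parameters. The default
#' initial state encodes a near-flat prior belief (expected variance 0.5,
#' i.e. an initial cue gain of about 0.98) held with little confidence,
#' matching the flat-prior predisposition seen at the start of sessions.
#'
#' @param mu Belief location for the prior's mean.
#' @param lam Effective observation count for the mean (> 0).
#' @param alpha Inverse-gamma shape (> 0; point estimates need `alpha > 1`).
#' @param beta Inverse-gamma scale (> 0, screen units squared).
#' @return An object of class `nig_state`.
#' @export
nig_state <- function(mu = 0, lam = 1, alpha = 1.2, beta = 0.1) {
  if (any(c(lam, alpha, beta) <= 0)) {
    stop("lam, alpha and beta must all be > 0", call. = FALSE)
  }
  structure(list(mu = mu, lam = lam, alpha = alpha, beta = beta),
            class = "nig_state")
}

#' @export
print.nig_state <- function(x, ...) {
  cat(sprintf("<nig_state> mu = %.4g, lam = %.4g, alpha = %.4g, beta = %.4g\n",
              x$mu, x$lam, x$alpha, x$beta))
  invisible(x)
}

#' One conjugate update of an NIG belief
#'
#' Incorporates one direct draw from the prior (the revealed target position).
#' The standard conjugate recursions are
#' \deqn{\mu' = (\lambda\mu + x)/(\lambda + 1),\quad \lambda' = \lambda + 1,}
#' \deqn{\alpha' = \alpha + 1/2,\quad
#'       \beta' = \beta + \lambda (x - \mu)^2 / (2(\lambda + 1)).}
#' Only the target is used for updating: given the target, the cue carries no
#' further information about the prior.
#'
#' @param state An [nig_state()].
#' @param observation The revealed target position (finite).
#' @return The updated `nig_state`.
#' @export
nig_update <- function(state, observation) {
  stopifnot(inherits(state, "nig_state"))
  if (!is.finite(observation)) stop("observation must be finite", call. = FALSE)
  lam <- state$lam
  nig_state(
    mu = (lam * state$mu + observation) / (lam + 1),
    lam = lam + 1,
    alpha = state$alpha + 0.5,
    beta = state$beta + lam * (observation - state$mu)^2 / (2 * (lam + 1))
  )
}

#' Point estimates of the prior's mean and variance from an NIG belief
#'
#' The mean estimate is `mu`; the variance estimate is the posterior mean of
#' `sigma^2`, `beta / (alpha - 1)` (defined for `alpha > 1`), or the posterior
#' mode `beta / (alpha + 1)` when `variance_point = "mode"`.
#'
#' @param state An [nig_state()].
#' @param variance_point `"mean"` (default) or `"mode"`.
#' @return A named list with `prior_mean` and `prior_var`.
#' @export
nig_point_estimates <- function(state, variance_point = c("mean", "mode")) {
  stopifnot(inherits(state, "nig_state"))
  variance_point <- match.arg(variance_point)
  if (variance_point == "mean" && state$alpha <= 1) {
    stop("posterior-mean variance undefined for alpha <= 1", call. = FALSE)
  }
  v <- switch(variance_point,
              mean = state$beta / (state$alpha - 1),
              mode = state$beta / (state$alpha + 1))
  list(prior_mean = state$mu, prior_var = v)
}

#' Cue gain implied by an NIG belief
#'
#' Plugs the belief's variance point estimate into the optimal gain formula:
#' `compute_gain(sqrt(beta/(alpha-1)), likelihood_sd)`.
#'
#' @inheritParams nig_point_estimates
#' @param likelihood_sd Known cue spread.
#' @return Gain in \[0, 1\].
#' @export
nig_gain <- function(state, likelihood_sd, variance_point = c("mean", "mode")) {
  est <- nig_point_estimates(state, variance_point)
  compute_gain(sqrt(est$prior_var), likelihood_sd)
}

# Variance used for the response gain under the three supported modes.
# "predictive" inflates the posterior-mean variance by (1 + 1/lam) to account
# for residual uncertainty in the prior's mean (moment-matched predictive
# spread of the next target).
nig_response_var <- function(mu, lam, alpha, beta,
                             variance_mode = c("mean", "mode", "predictive")) {
  variance_mode <- match.arg(variance_mode)
  switch(variance_mode,
         mean = beta / (alpha - 1),
         mode = beta / (alpha + 1),
         predictive = beta * (1 + 1 / lam) / (alpha - 1))
}

#' Run the NIG learner through a session
#'
#' On each trial the learner responds with
#' `optimal_estimate(mu, cue, gain)` using its *current* belief, and only then
#' updates on the revealed target — responding with information from the
#' current trial's target would be acausal.
#'
#' @param trials A stimulus tibble from [generate_session()] (columns `cue`,
#'   `target`).
#' @param init Initial [nig_state()] (`alpha > 1` unless
#'   `variance_mode = "mode"`).
#' @param likelihood_sd Known cue spread.
#' @param variance_mode Variance point estimate used for the response gain:
#'   posterior `"mean"` (default), posterior `"mode"`, or `"predictive"`
#'   (mean-uncertainty-inflated; sensitivity option).
#' @return A tibble with one row per trial: `trial`, `cue`, `target`,
#'   the pre-response belief (`mu`, `lam`, `alpha`, `beta`), `var_estimate`,
#'   `gain` and `response`.
#' @export
run_nig_session <- function(trials, init = nig_state(), likelihood_sd = 0.1,
                            variance_mode = c("mean", "mode", "predictive")) {
  stopifnot(inherits(init, "nig_state"))
  variance_mode <- match.arg(variance_mode)
  n <- nrow(trials)
  vl <- likelihood_sd^2
  mu <- init$mu; lam <- init$lam; alpha <- init$alpha; beta <- init$beta
  if (variance_mode != "mode" && alpha <= 1) {
    stop("initial alpha must exceed 1 for posterior-mean variance estimates",
         call. = FALSE)
  }
  out <- matrix(NA_real_, n, 7,
                dimnames = list(NULL, c("mu", "lam", "alpha", "beta",
                                        "var_estimate", "gain", "response")))
  for (t in seq_len(n)) {
    v <- nig_response_var(mu, lam, alpha, beta, variance_mode)
    g <- v / (v + vl)
    resp <- (1 - g) * mu + g * trials$cue[t]
    out[t, ] <- c(mu, lam, alpha, beta, v, g, resp)
    x <- trials$target[t]
    beta <- beta + lam * (x - mu)^2 / (2 * (lam + 1))
    mu <- (lam * mu + x) / (lam + 1)
    lam <- lam + 1
    alpha <- alpha + 0.5
  }
  dplyr::bind_cols(
    tibble::tibble(trial = trials$trial, cue = trials$cue, target = trials$target),
    tibble::as_tibble(out)
  )
}

# Vectorised multi-run NIG pass: stimuli as T x R matrices, belief vectors of
# length R. Returns the T x R response matrix (and final states invisibly).
nig_run_matrix <- function(cues, targets, init, likelihood_sd,
                           variance_mode = "mean") {
  n <- nrow(targets)
  R <- ncol(targets)
  vl <- likelihood_sd^2
  mu <- rep(init$mu, R); lam <- rep(init$lam, R)
  alpha <- rep(init$alpha, R); beta <- rep(init$beta, R)
  resp <- matrix(NA_real_, n, R)
  for (t in seq_len(n)) {
    v <- nig_response_var(mu, lam, alpha, beta, variance_mode)
    g <- v / (v + vl)
    resp[t, ] <- (1 - g) * mu + g * cues[t, ]
    x <- targets[t, ]
    beta <- beta + lam * (x - mu)^2 / (2 * (lam + 1))
    mu <- (lam * mu + x) / (lam + 1)
    lam <- lam + 1
    alpha <- alpha + 0.5
  }
  resp
}
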