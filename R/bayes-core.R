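#' Optimal cue weight (gain) for Gaussian prior-likelihood integration
#'
#' For a Gaussian prior over target positions with spread `prior_sd` and a
#' Gaussian likelihood (cue around the target) with spread `likelihood_sd`,
#' the posterior mean of the target is a convex combination of the prior mean
#' and the cue. The weight on the cue is
#' \deqn{r = \sigma_p^2 / (\sigma_p^2 + \sigma_l^2),}
#' an alternate form of the Kalman gain and, empirically, the slope of the
#' regression of responses on cues.
#'
#' @param prior_sd Spread of the prior over target positions (screen units,
#'   where the screen spans \[-0.5, 0.5\]). Must be >= 0.
#' @param likelihood_sd Spread of the cue around the target (same units).
#'   Must be >= 0; `prior_sd` and `likelihood_sd` must not both be zero.
#' @return Gain in \[0, 1\]. Vectorised over both arguments.
#' @examples
#' compute_gain(0.2, 0.1)   # 0.8, the wide-prior optimal slope
#' compute_gain(0.05, 0.1)  # 0.2, the narrow-prior optimal slope
#' @export
compute_gain <- function(prior_sd, likelihood_sd) {
  if (any(prior_sd < 0) || any(likelihood_sd < 0)) {
    stop("spreads must be non-negative", call. = FALSE)
  }
  vp <- prior_sd^2
  vl <- likelihood_sd^2
  if (any(vp + vl == 0)) {
    stop("prior_sd and likelihood_sd must not both be zero (gain is 0/0)",
         call. = FALSE)
  }
  vp / (vp + vl)
}

#' Bayes-optimal placement given a prior mean, a cue, and a gain
#'
#' Returns `(1 - gain) * prior_mean + gain * cue`, the posterior mean of the
#' target position under conjugate Gaussian integration. The result always
#' lies between `prior_mean` and `cue`.
#'
#' @param prior_mean Believed mean of the prior (screen units).
#' @param cue Observed cue position (screen units).
#' @param gain Weight on the cue, in \[0, 1\] (see [compute_gain()]).
#' @return Optimal net position, vectorised.
#' @export
optimal_estimate <- function(prior_mean, cue, gain) {
  if (any(gain < 0 | gain > 1)) stop("gain must lie in [0, 1]", call. = FALSE)
  (1 - gain) * prior_mean + gain * cue
}

#' Reconstruct the implied prior from a fitted gain
#'
#' Inverts the gain formula under a known likelihood spread: a measured gain
#' `r` implies a prior spread `likelihood_sd * sqrt(r / (1 - r))`. This is how
#' an observer's evolving prior is reconstructed from binned regression fits.
#' A gain at or above 1 corresponds to the flat-prior limit (maximum-likelihood
#' behaviour, the response tracking the cue); it is returned as an infinite
#' spread flagged `flat`, not an error, because early-session behaviour
#' routinely sits there.
#'
#' @param gain Fitted gain; values >= 1 yield the flat-prior sentinel.
#' @param prior_mean Fitted prior mean, carried through unchanged.
#' @param likelihood_sd Known likelihood spread (> 0).
#' @return A tibble with columns `mean`, `sd` and `flat` (logical), one row
#'   per input gain.
#' @examples
#' reconstruct_prior(0.8, 0, 0.1)  # sd 0.2
#' reconstruct_prior(0.2, 0, 0.1)  # sd 0.05
#' @export
reconstruct_prior <- function(gain, prior_mean, likelihood_sd) {
  if (any(likelihood_sd <= 0)) stop("likelihood_sd must be > 0", call. = FALSE)
  if (any(gain < 0)) stop("gain must be >= 0", call. = FALSE)
  n <- max(length(gain), length(prior_mean), length(likelihood_sd))
  gain <- rep_len(gain, n)
  prior_mean <- rep_len(prior_mean, n)
  likelihood_sd <- rep_len(likelihood_sd, n)
  flat <- gain >= 1
  sd <- ifelse(flat, Inf, likelihood_sd * sqrt(gain / (1 - gain)))
  tibble::tibble(mean = prior_mean, sd = sd, flat = flat)
}
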