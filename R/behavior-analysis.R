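#' Least-squares fit of gain and prior mean to one bin of trials
#'
#' Under Gaussian integration the response is linear in the cue,
#' `response = (1 - r) * mu_p + r * cue`, so an ordinary least-squares
#' regression of responses on cues within a bin identifies the gain `r`
#' (slope) and the believed prior mean `mu_p = intercept / (1 - r)`. When the
#' fitted slope is within 0.05 of 1 the intercept-to-mean conversion is
#' ill-conditioned; the bin is flagged `degenerate` and `mu_p` is reported as
#' the flat-prior sentinel (`NA`).
#'
#' @param trials A data frame with columns `cue` and `response`; at least 3
#'   trials with non-degenerate cue spread.
#' @return A one-row tibble: `r`, `se_r`, `mu_p`, `residual_rms`,
#'   `degenerate`, `n`.
#' @export
fit_bin <- function(trials) {
  cue <- trials$cue
  resp <- trials$response
  n <- length(cue)
  if (n < 3) stop("need at least 3 trials to fit a bin", call. = FALSE)
  sxx <- sum((cue - mean(cue))^2)
  if (sxx == 0) stop("singular design: all cues in the bin are identical",
                     call. = FALSE)
  slope <- sum((cue - mean(cue)) * (resp - mean(resp))) / sxx
  intercept <- mean(resp) - slope * mean(cue)
  fitted <- intercept + slope * cue
  rss <- sum((resp - fitted)^2)
  se_r <- sqrt(rss / (n - 2) / sxx)
  degenerate <- abs(1 - slope) < 0.05
  mu_p <- if (degenerate) NA_real_ else intercept / (1 - slope)
  tibble::tibble(r = slope, se_r = se_r, mu_p = mu_p,
                 residual_rms = sqrt(rss / n),
                 degenerate = degenerate, n = n)
}

#' Binned learning curves from a trial log
#'
#' Splits the log into consecutive non-overlapping bins (10 trials each by
#' default, the temporal resolution of the learning curves) and fits
#' `(r, mu_p)` per bin with [fit_bin()]. A trailing partial bin is dropped
#' with a warning. When the log carries the generative truth
#' (`prior_mean_true`), the per-bin mean error `mu_p_error = mu_p - truth` is
#' included.
#'
#' @param trials Trial log with columns `cue`, `response` (and optionally
#'   `trial`, `prior_mean_true`).
#' @param bin_size Trials per bin (default 10).
#' @return A tibble of per-bin estimates (class `binned_estimates`):
#'   `bin`, `r`, `se_r`, `mu_p`, `mu_p_error` (if truth available),
#'   `residual_rms`, `degenerate`, `n`.
#' @export
bin_series <- function(trials, bin_size = 10) {
  n <- nrow(trials)
  if (n < bin_size) stop("log shorter than one bin", call. = FALSE)
  n_bins <- n %/% bin_size
  dropped <- n - n_bins * bin_size
  if (dropped > 0) {
    warning(sprintf("dropping %d trailing trial(s) not filling a bin", dropped),
            call. = FALSE)
  }
  idx <- seq_len(n_bins * bin_size)
  df <- trials[idx, , drop = FALSE]
  df$bin <- rep(seq_len(n_bins), each = bin_size)
  out <- df |>
    dplyr::group_by(.data$bin) |>
    dplyr::group_modify(function(d, key) {
      fit <- fit_bin(d)
      if ("prior_mean_true" %in% names(d)) {
        fit$mu_p_error <- fit$mu_p - mean(d$prior_mean_true)
      }
      fit
    }) |>
    dplyr::ungroup()
  class(out) <- c("binned_estimates", class(out))
  out
}

#' Switch-aligned estimate of the prior's mean
#'
#' Re-sorts a two-state-mean trial log by trials-since-switch and recovers,
#' per post-switch trial index `k = 1..k_max`, the observer's implied prior
#' mean. Single-trial joint `(r, mu)` fits are ill-posed, so the gain is held
#' fixed at `r_hat` (by default the steady-state gain of the log, see
#' [steady_state_gain()]) and each trial is inverted algebraically:
#' `mu_hat = (response - r_hat * cue) / (1 - r_hat)`. Estimates are then
#' averaged across all switches; trials before the first switch (the initial
#' block, which no switch precedes) are excluded.
#'
#' Because switches alternate between the two means, raw estimates from
#' opposite switch directions cancel when averaged. With
#' `sign_align = TRUE` (default, requires the `prior_mean_true` column) each
#' estimate is expressed along the direction of the *new* active mean
#' (multiplied by its sign), so the curve runs from negative (still tracking
#' the old mean) through the inter-mean midpoint at 0 towards the new mean's
#' magnitude.
#'
#' @param trials Trial log with `trials_since_switch`, `cue`, `response`.
#' @param r_hat Fixed gain used for the per-trial inversion; default
#'   `steady_state_gain(trials)$r`.
#' @param k_max Post-switch trials to report (default 10).
#' @param sign_align Express estimates along the new mean's direction
#'   (default `TRUE` when generative truth is available).
#' @return A tibble (class `switch_aligned_curve`) with `k`, `mean_estimate`,
#'   `se`, `n_switches`. With no switches in the log an empty curve is
#'   returned with a warning.
#' @export
align_to_switches <- function(trials, r_hat = NULL, k_max = 10,
                              sign_align = "prior_mean_true" %in% names(trials)) {
  if (!"trials_since_switch" %in% names(trials) ||
      all(is.na(trials$trials_since_switch))) {
    stop("log carries no switch bookkeeping (trials_since_switch)", call. = FALSE)
  }
  since <- trials$trials_since_switch
  n_switches <- sum(since == 1L & trials$trial > 1L, na.rm = TRUE)
  if (n_switches == 0) {
    warning("no switches in log; returning empty switch-aligned curve",
            call. = FALSE)
    out <- tibble::tibble(k = integer(), mean_estimate = double(),
                          se = double(), n_switches = integer())
    class(out) <- c("switch_aligned_curve", class(out))
    return(out)
  }
  if (is.null(r_hat)) r_hat <- steady_state_gain(trials)$r
  if (abs(1 - r_hat) < 0.05) {
    stop("r_hat too close to 1 for a stable per-trial inversion", call. = FALSE)
  }
  if (sign_align && !"prior_mean_true" %in% names(trials)) {
    stop("sign_align needs the prior_mean_true column", call. = FALSE)
  }
  first_switch <- which(since == 1L & trials$trial > 1L)[1]
  out <- trials[seq(first_switch, nrow(trials)), , drop = FALSE] |>
    dplyr::filter(.data$trials_since_switch <= k_max) |>
    dplyr::mutate(
      mu_hat = (.data$response - r_hat * .data$cue) / (1 - r_hat),
      mu_hat = if (sign_align) .data$mu_hat * sign(.data$prior_mean_true) else .data$mu_hat
    ) |>
    dplyr::group_by(k = .data$trials_since_switch) |>
    dplyr::summarise(mean_estimate = mean(.data$mu_hat),
                     se = stats::sd(.data$mu_hat) / sqrt(dplyr::n()),
                     n_switches = dplyr::n(), .groups = "drop")
  attr(out, "r_hat") <- r_hat
  class(out) <- c("switch_aligned_curve", class(out))
  out
}

#' Steady-state gain over the final trials of a session
#'
#' Fits a single response-on-cue regression to the last `last_n` trials
#' (200 by default). For two-state-mean logs the known active mean is
#' removed from cue and response per trial before fitting (when
#' `remove_mean = TRUE` and truth columns exist), so that mean switching
#' does not inflate the slope; setting `remove_mean = FALSE` exposes that
#' confound — the measured gain then underestimates the believed one.
#'
#' @param trials Trial log of length >= `last_n`.
#' @param last_n Number of trailing trials to pool (default 200).
#' @param remove_mean Remove the true active mean before fitting
#'   (default `TRUE`; requires `prior_mean_true`).
#' @return A one-row tibble as from [fit_bin()].
#' @export
steady_state_gain <- function(trials, last_n = 200, remove_mean = TRUE) {
  n <- nrow(trials)
  if (n < last_n) stop("log shorter than last_n trials", call. = FALSE)
  tail_df <- trials[(n - last_n + 1L):n, , drop = FALSE]
  if (remove_mean && "prior_mean_true" %in% names(tail_df)) {
    tail_df <- dplyr::mutate(tail_df,
                             cue = .data$cue - .data$prior_mean_true,
                             response = .data$response - .data$prior_mean_true)
  }
  fit_bin(tail_df)
}

#' Reconstruct the prior's trajectory from binned estimates
#'
#' Applies [reconstruct_prior()] bin-wise: each bin's fitted `(r, mu_p)` pair
#' implies a Gaussian prior with spread `likelihood_sd * sqrt(r / (1 - r))`.
#' Degenerate bins yield the flat-prior sentinel.
#'
#' @param binned A [bin_series()] result.
#' @param likelihood_sd Known cue spread.
#' @return A tibble with `bin`, `mean`, `sd`, `flat`.
#' @export
prior_trajectory <- function(binned, likelihood_sd = 0.1) {
  g <- pmax(binned$r, 0)
  rec <- reconstruct_prior(pmin(g, 1), binned$mu_p, likelihood_sd)
  rec$flat <- rec$flat | binned$degenerate
  rec$sd[binned$degenerate] <- Inf
  tibble::tibble(bin = binned$bin, mean = rec$mean, sd = rec$sd, flat = rec$flat)
}

#' Write a trial log as CSV
#'
#' One row per trial with the standard columns (`trial`, `prior_mean_true`,
#' `prior_sd_true`, `target`, `cue`, `response`, `caught`,
#' `trials_since_switch`); absent fields are written as empty strings and
#' positions with 9 significant digits.
#'
#' @param trials Trial log tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(trials, path) {
  cols <- c("trial", "prior_mean_true", "prior_sd_true", "target", "cue",
            "response", "caught", "trials_since_switch")
  for (col in setdiff(cols, names(trials))) trials[[col]] <- NA
  df <- trials[cols]
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 9)
  readr::write_csv(df, path, na = "")
  invisible(path)
}

#' Read a trial log CSV
#'
#' @param path CSV path written by [write_trial_log()] (header required).
#' @return A trial log tibble.
#' @export
read_trial_log <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    trial = readr::col_integer(),
    prior_mean_true = readr::col_double(),
    prior_sd_true = readr::col_double(),
    target = readr::col_double(),
    cue = readr::col_double(),
    response = readr::col_double(),
    caught = readr::col_logical(),
    trials_since_switch = readr::col_integer()
  ))
}
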