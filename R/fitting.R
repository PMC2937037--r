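#' Assemble a fitting target from two fixed-prior learning-curve ensembles
#'
#' A fitting target holds the across-run average binned curves of the
#' wide-prior and narrow-prior fixed-prior sessions — the quantities model
#' hyperparameters are fitted to. Each row carries the observed mean-error
#' and gain observables with their per-bin standard errors.
#'
#' @param wide,narrow [average_model_curves()]-style tibbles (columns `bin`,
#'   `r`, `se_r`, `mu_p_error`, `se_mu_p_error`).
#' @return A tibble (class `fit_target`) with a `protocol` column
#'   (`"wide"`/`"narrow"`).
#' @export
fit_target <- function(wide, narrow) {
  need <- c("bin", "r", "se_r", "mu_p_error", "se_mu_p_error")
  for (d in list(wide, narrow)) {
    if (!all(need %in% names(d))) {
      stop("curves need columns: ", paste(need, collapse = ", "), call. = FALSE)
    }
  }
  if (any(c(wide$se_r, narrow$se_r) <= 0, na.rm = TRUE)) {
    stop("per-bin standard errors must be > 0", call. = FALSE)
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(wide[need], protocol = "wide"),
    dplyr::mutate(narrow[need], protocol = "narrow")
  )
  class(out) <- c("fit_target", class(out))
  out
}

#' Log-likelihood of target curves under model curves
#'
#' Independent-Gaussian error model: each observed per-bin gain and mean
#' error is scored against the model's value with the *target's* per-bin
#' standard error, `sum log Normal(observed; model, SE)`. SE-weighting means
#' precisely estimated bins constrain the fit more. Bins with missing mean
#' errors (degenerate, flat-prior flagged) contribute only their gain term.
#'
#' @param model_curves Tibble with `protocol`, `bin`, `r`, `mu_p_error`
#'   columns (model values).
#' @param target A [fit_target()].
#' @return Scalar log-likelihood.
#' @export
curve_loglik <- function(model_curves, target) {
  joined <- dplyr::inner_join(
    dplyr::select(target, "protocol", "bin",
                  obs_r = "r", "se_r", obs_mu = "mu_p_error",
                  se_mu = "se_mu_p_error"),
    dplyr::select(model_curves, "protocol", "bin", mod_r = "r",
                  mod_mu = "mu_p_error"),
    by = c("protocol", "bin")
  )
  if (nrow(joined) != nrow(target)) {
    stop("model and target bin structures do not match", call. = FALSE)
  }
  ll_r <- stats::dnorm(joined$obs_r, joined$mod_r, joined$se_r, log = TRUE)
  mu_ok <- is.finite(joined$obs_mu) & is.finite(joined$mod_mu) &
    is.finite(joined$se_mu) & joined$se_mu > 0
  ll_mu <- stats::dnorm(joined$obs_mu[mu_ok], joined$mod_mu[mu_ok],
                        joined$se_mu[mu_ok], log = TRUE)
  sum(ll_r) + sum(ll_mu)
}

check_exp1_configs <- function(configs) {
  if (!is.list(configs) || !all(c("wide", "narrow") %in% names(configs))) {
    stop("configs must be a list with elements 'wide' and 'narrow'", call. = FALSE)
  }
  for (cfg in configs[c("wide", "narrow")]) {
    stopifnot(inherits(cfg, "session_config"))
    if (cfg$protocol != "exp1") {
      stop("fitting accepts only fixed-prior (exp1) configurations; ",
           "predict held-out protocols separately", call. = FALSE)
    }
  }
  configs
}

model_curves_both <- function(stim_wide, stim_narrow, init, variance_mode = "mean") {
  cw <- curves_from_matrices(binned_ols_matrix(
    stim_wide$cues,
    run_model_matrix(stim_wide, init, stim_wide$config$likelihood_sd, variance_mode),
    stim_wide$mean_true))
  cn <- curves_from_matrices(binned_ols_matrix(
    stim_narrow$cues,
    run_model_matrix(stim_narrow, init, stim_narrow$config$likelihood_sd, variance_mode),
    stim_narrow$mean_true))
  dplyr::bind_rows(dplyr::mutate(cw, protocol = "wide"),
                   dplyr::mutate(cn, protocol = "narrow"))
}

fit_via_simplex <- function(objective, starts, par_names) {
  best <- NULL
  trace <- list()
  for (i in seq_along(starts)) {
    opt <- stats::optim(starts[[i]], objective, method = "Nelder-Mead",
                        control = list(fnscale = -1, maxit = 500,
                                       reltol = 1e-8))
    trace[[i]] <- tibble::tibble(restart = i, loglik = opt$value,
                                 converged = opt$convergence == 0)
    if (is.null(best) || opt$value > best$value) best <- opt
  }
  names(best$par) <- par_names
  list(par = best$par, loglik = best$value,
       converged = best$convergence == 0,
       trace = dplyr::bind_rows(trace))
}

#' Fit the NIG learner's four initial hyperparameters to fixed-prior curves
#'
#' Maximises [curve_loglik()] of the target's binned curves under the NIG
#' learner's average curves, over the four initial hyperparameters
#' `(mu, lam, alpha, beta)` (positivity enforced by log transforms;
#' `alpha > 1` by construction so the variance point estimate exists from
#' trial one). The objective is Monte-Carlo but deterministic: the session
#' ensembles are generated once from `seed` and reused for every evaluation
#' (common random numbers), so the optimiser sees a fixed function.
#' Derivative-free simplex search with restarts; non-convergence is flagged
#' on the result, not raised.
#'
#' Only fixed-prior (`exp1`) configurations are accepted: held-out protocols
#' are predicted afterwards with [predict_model_curves()], which cannot feed
#' back into the fit.
#'
#' @param target A [fit_target()].
#' @param configs `list(wide = , narrow = )` of exp1 [session_config()]s.
#' @param n_runs Sessions per ensemble per objective evaluation (default 100).
#' @param seed Seed for the common-random-number ensembles.
#' @param restarts Number of simplex restarts (default 5).
#' @param variance_mode Passed to the NIG learner.
#' @return A `prior_fit` object: fitted `init` ([nig_state()]), `loglik`,
#'   `trace`, `converged`, `n_runs`, `seed`.
#' @export
fit_nig_init <- function(target, configs, n_runs = 100, seed = 1,
                         restarts = 5, variance_mode = "mean") {
  stopifnot(inherits(target, "fit_target"))
  configs <- check_exp1_configs(configs)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 3L))
  stim_w <- simulate_stimuli_runs(configs$wide, n_runs, seeds[1])
  stim_n <- simulate_stimuli_runs(configs$narrow, n_runs, seeds[2])

  objective <- function(par) {
    init <- nig_state(mu = par[1], lam = exp(par[2]),
                      alpha = 1 + exp(par[3]), beta = exp(par[4]))
    ll <- curve_loglik(model_curves_both(stim_w, stim_n, init, variance_mode),
                       target)
    if (!is.finite(ll)) -1e10 else ll
  }

  base <- c(0, log(1), log(0.3), log(0.1))
  starts <- with_seed(seeds[3], {
    c(list(base),
      lapply(seq_len(max(restarts - 1, 0)), function(i) {
        base + stats::rnorm(4, 0, 0.7)
      }))
  })
  res <- fit_via_simplex(objective, starts, c("mu", "log_lam", "log_am1", "log_beta"))
  structure(
    list(model = "nig",
         init = nig_state(mu = res$par[[1]], lam = exp(res$par[[2]]),
                          alpha = 1 + exp(res$par[[3]]),
                          beta = exp(res$par[[4]])),
         loglik = res$loglik, converged = res$converged, trace = res$trace,
         n_runs = n_runs, seed = seed, variance_mode = variance_mode),
    class = "prior_fit"
  )
}

#' Fit the variance filter's two parameters to fixed-prior curves
#'
#' Same objective and optimiser as [fit_nig_init()], over the filter's
#' learning rate (logit-transformed into \[0, 1\]) and initial variance
#' (log-transformed positive).
#'
#' @inheritParams fit_nig_init
#' @return A `prior_fit` object with `init` an [lf_state()].
#' @export
fit_lf_params <- function(target, configs, n_runs = 100, seed = 1,
                          restarts = 5) {
  stopifnot(inherits(target, "fit_target"))
  configs <- check_exp1_configs(configs)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 3L))
  stim_w <- simulate_stimuli_runs(configs$wide, n_runs, seeds[1])
  stim_n <- simulate_stimuli_runs(configs$narrow, n_runs, seeds[2])

  objective <- function(par) {
    init <- lf_state(learning_rate = stats::plogis(par[1]),
                     var_init = exp(par[2]))
    ll <- curve_loglik(model_curves_both(stim_w, stim_n, init), target)
    if (!is.finite(ll)) -1e10 else ll
  }

  base <- c(stats::qlogis(0.2), log(0.25))
  starts <- with_seed(seeds[3], {
    c(list(base),
      lapply(seq_len(max(restarts - 1, 0)), function(i) {
        base + stats::rnorm(2, 0, 0.7)
      }))
  })
  res <- fit_via_simplex(objective, starts, c("logit_rate", "log_var_init"))
  structure(
    list(model = "lf",
         init = lf_state(learning_rate = stats::plogis(res$par[[1]]),
                         var_init = exp(res$par[[2]])),
         loglik = res$loglik, converged = res$converged, trace = res$trace,
         n_runs = n_runs, seed = seed),
    class = "prior_fit"
  )
}

#' Predict average learning curves for any protocol from a fitted model
#'
#' Runs the fitted observer (hyperparameters frozen) on fresh ensembles of
#' the given protocol — typically the held-out variance-switch protocol that
#' the fit never saw.
#'
#' @param fit A `prior_fit` from [fit_nig_init()] or [fit_lf_params()].
#' @param config Any [session_config()].
#' @param n_runs Ensemble size (default: the fit's `n_runs`).
#' @param seed Seed for the prediction ensemble.
#' @return An [average_model_curves()] tibble.
#' @export
predict_model_curves <- function(fit, config, n_runs = NULL, seed = 1) {
  stopifnot(inherits(fit, "prior_fit"))
  n_runs <- n_runs %||% fit$n_runs
  variance_mode <- fit$variance_mode %||% "mean"
  average_model_curves(config, fit$init, n_runs = n_runs, seed = seed,
                       variance_mode = variance_mode)
}

#' Root-mean-square difference between two curves
#'
#' Pools bin-wise differences of one observable (the gain by default) across
#' all protocols present in both curves.
#'
#' @param model_curve,target_curve Tibbles with `bin` (and optionally
#'   `protocol`) plus the observable column.
#' @param observable Column to compare (default `"r"`).
#' @return Scalar RMS error.
#' @export
rms_error <- function(model_curve, target_curve, observable = "r") {
  by <- intersect(c("protocol", "bin"), intersect(names(model_curve),
                                                  names(target_curve)))
  joined <- dplyr::inner_join(
    dplyr::select(model_curve, dplyr::all_of(c(by, observable))),
    dplyr::select(target_curve, dplyr::all_of(c(by, observable))),
    by = by, suffix = c("_model", "_target")
  )
  if (nrow(joined) == 0) stop("no matching bins", call. = FALSE)
  d <- joined[[paste0(observable, "_model")]] -
    joined[[paste0(observable, "_target")]]
  sqrt(mean(d^2))
}

#' Coefficient of determination of a target curve against a model curve
#'
#' Standard definition `1 - SS_res / SS_tot`, with residuals of the target
#' observable around the model's values and total sums of squares around the
#' target's mean.
#'
#' @inheritParams rms_error
#' @return Scalar R-squared (can be negative for a model worse than the
#'   target's mean).
#' @export
r_squared <- function(model_curve, target_curve, observable = "r") {
  by <- intersect(c("protocol", "bin"), intersect(names(model_curve),
                                                  names(target_curve)))
  joined <- dplyr::inner_join(
    dplyr::select(model_curve, dplyr::all_of(c(by, observable))),
    dplyr::select(target_curve, dplyr::all_of(c(by, observable))),
    by = by, suffix = c("_model", "_target")
  )
  obs <- joined[[paste0(observable, "_target")]]
  mod <- joined[[paste0(observable, "_model")]]
  1 - sum((obs - mod)^2) / sum((obs - mean(obs))^2)
}

#' @export
print.prior_fit <- function(x, ...) {
  cat("<prior_fit>", x$model, "model, log-likelihood", format(x$loglik), "\n")
  print(x$init)
  if (!x$converged) cat("  (optimizer did not report convergence)\n")
  invisible(x)
}
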