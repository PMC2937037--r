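#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted observer model
#'
#' @param x A `prior_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per fitted parameter (`term`, `estimate`).
#' @method tidy prior_fit
#' @export
tidy.prior_fit <- function(x, ...) {
  if (x$model == "nig") {
    tibble::tibble(
      term = c("mu0", "lam0", "alpha0", "beta0"),
      estimate = c(x$init$mu, x$init$lam, x$init$alpha, x$init$beta)
    )
  } else {
    tibble::tibble(
      term = c("learning_rate", "var_init"),
      estimate = c(x$init$learning_rate, x$init$var_init)
    )
  }
}

#' One-row summary of a fitted observer model
#'
#' @param x A `prior_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `model`, `logLik`, `converged`, `n_runs`,
#'   `seed`, `n_restarts`.
#' @method glance prior_fit
#' @export
glance.prior_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    logLik = x$loglik,
    converged = x$converged,
    n_runs = x$n_runs,
    seed = x$seed,
    n_restarts = nrow(x$trace)
  )
}
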