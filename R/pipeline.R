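#' Run one simulated session end to end and write its trial log
#'
#' Validates the configuration, generates the stimulus stream, runs the
#' observer, and writes the trial-log CSV plus a run manifest into `out_dir`.
#'
#' @param config A [session_config()] or a path to a JSON/YAML config file.
#' @param observer An [observer_spec()] (default: the fixed-prior oracle).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed overriding the config's.
#' @return Invisibly, a list with the written `log` and `manifest` paths.
#' @export
run_simulate <- function(config, observer = observer_spec("oracle_fixed_prior"),
                         out_dir = ".", seed = NULL) {
  if (is.character(config)) config <- read_session_config(config)
  stopifnot(inherits(config, "session_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trials <- run_observer(generate_session(config), observer)
  log_path <- file.path(out_dir, "trial_log.csv")
  write_trial_log(trials, log_path)
  manifest <- write_manifest(out_dir, stage = "simulate", config = config,
                             seed = config$seed, files = log_path,
                             n_trials = nrow(trials))
  invisible(list(log = log_path, manifest = manifest))
}

#' Analyze a trial log into learning-curve CSVs
#'
#' Computes the binned `(r, mu_p)` curves, the reconstructed prior
#' trajectory, and — when the log carries switch bookkeeping with at least
#' one switch — the switch-aligned mean-estimate curve. Each product is
#' written as CSV next to a manifest.
#'
#' @param log A trial-log tibble or a path to a trial-log CSV.
#' @param out_dir Output directory.
#' @param likelihood_sd Known cue spread (default 0.1).
#' @param bin_size Trials per bin (default 10).
#' @return Invisibly, the list of written paths.
#' @export
run_analyze <- function(log, out_dir = ".", likelihood_sd = 0.1, bin_size = 10) {
  if (is.character(log)) log <- read_trial_log(log)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  binned <- bin_series(log, bin_size = bin_size)
  binned_path <- file.path(out_dir, "binned_estimates.csv")
  readr::write_csv(binned, binned_path)
  traj_path <- file.path(out_dir, "prior_trajectory.csv")
  readr::write_csv(prior_trajectory(binned, likelihood_sd), traj_path)
  files <- c(binned_path, traj_path)
  has_switches <- "trials_since_switch" %in% names(log) &&
    any(log$trials_since_switch == 1L & log$trial > 1L, na.rm = TRUE)
  if (has_switches) {
    curve <- align_to_switches(log)
    switch_path <- file.path(out_dir, "switch_curve.csv")
    readr::write_csv(curve, switch_path)
    files <- c(files, switch_path)
  } else {
    warning("no switch bookkeeping in log; switch-aligned curve skipped",
            call. = FALSE)
  }
  manifest <- write_manifest(out_dir, stage = "analyze", config = NULL,
                             seed = NA, files = files, n_trials = nrow(log))
  invisible(list(files = files, manifest = manifest))
}

#' Fit an observer model to target curves and write the result
#'
#' @param target A [fit_target()] or a path to a CSV with columns
#'   `protocol`, `bin`, `r`, `se_r`, `mu_p_error`, `se_mu_p_error`.
#' @param model `"nig"` (four-hyperparameter conjugate learner) or `"lf"`
#'   (two-parameter variance filter).
#' @param out_dir Output directory.
#' @param configs `list(wide =, narrow =)` of exp1 configs; defaults to the
#'   standard wide (sd 0.2) and narrow (sd 0.05) 400-trial protocols.
#' @param n_runs Ensemble size per objective evaluation.
#' @param seed Seed (common random numbers).
#' @param restarts Simplex restarts.
#' @return Invisibly, the `prior_fit` (also serialised to `fit_<model>.json`).
#' @export
run_fit <- function(target, model = c("nig", "lf"), out_dir = ".",
                    configs = NULL, n_runs = 100, seed = 1, restarts = 5) {
  model <- match.arg(model)
  if (is.character(target)) {
    df <- readr::read_csv(target, col_types = readr::cols())
    target <- fit_target(df[df$protocol == "wide", ],
                         df[df$protocol == "narrow", ])
  }
  if (is.null(configs)) {
    configs <- list(
      wide = session_config("exp1", prior_sd = 0.2),
      narrow = session_config("exp1", prior_sd = 0.05)
    )
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fit <- if (model == "nig") {
    fit_nig_init(target, configs, n_runs = n_runs, seed = seed,
                 restarts = restarts)
  } else {
    fit_lf_params(target, configs, n_runs = n_runs, seed = seed,
                  restarts = restarts)
  }
  fit_path <- file.path(out_dir, paste0("fit_", model, ".json"))
  jsonlite::write_json(
    list(parameters = tidy(fit), summary = glance(fit), trace = fit$trace),
    fit_path, dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  write_manifest(out_dir, stage = "fit", config = NULL, seed = seed,
                 files = fit_path, n_trials = NA)
  invisible(fit)
}

#' Regenerate the package's standard figure data from simulated observers
#'
#' Each figure's content is emitted as CSV first; plots are optional
#' side-outputs (`plot = TRUE` additionally writes a PNG). Available figures:
#' * `"fig2-model"` — cue/response scatter of noiseless optimal observers
#'   under the wide and narrow fixed priors (slopes 0.8 and 0.2);
#' * `"fig3-model"` — average binned learning curves of the NIG learner on
#'   both fixed-prior protocols;
#' * `"fig5-model"` — NIG and variance-filter average curves on both
#'   variance-switch orders;
#' * `"fig6-model"` — switch-aligned mean-estimate curve of the change-point
#'   observer on the two-state-mean protocol.
#'
#' @param figure Figure name (see above).
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @param n_runs Ensemble size for averaged curves (default 50).
#' @param plot Also write a PNG (default `FALSE`).
#' @return Invisibly, the list of written paths.
#' @export
run_reproduce <- function(figure = c("fig2-model", "fig3-model", "fig5-model",
                                     "fig6-model"),
                          out_dir = ".", seed = 1, n_runs = 50, plot = FALSE) {
  figure <- match.arg(figure)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 8L))
  files <- character(0)
  gg <- NULL

  if (figure == "fig2-model") {
    scatter <- purrr::map2_dfr(
      c(0.2, 0.05), seeds[1:2],
      function(sd, s) {
        cfg <- session_config("exp1", prior_sd = sd, seed = s)
        d <- run_observer(generate_session(cfg),
                          observer_spec("oracle_fixed_prior"))
        tibble::tibble(condition = ifelse(sd > 0.1, "wide", "narrow"),
                       cue_centered = d$cue - d$prior_mean_true,
                       response_centered = d$response - d$prior_mean_true)
      })
    path <- file.path(out_dir, "fig2_model_scatter.csv")
    readr::write_csv(scatter, path)
    files <- path
    if (plot) {
      gg <- ggplot2::ggplot(scatter,
              ggplot2::aes(.data$cue_centered, .data$response_centered,
                           colour = .data$condition)) +
        ggplot2::geom_point(size = 0.6) +
        ggplot2::geom_abline(linetype = "dashed") +
        ggplot2::theme_minimal()
    }
  } else if (figure == "fig3-model") {
    curves <- purrr::map2_dfr(
      c(0.2, 0.05), seeds[1:2],
      function(sd, s) {
        cfg <- session_config("exp1", prior_sd = sd)
        dplyr::mutate(
          average_model_curves(cfg, nig_state(), n_runs = n_runs, seed = s),
          condition = ifelse(sd > 0.1, "wide", "narrow"),
          r_optimal = compute_gain(sd, cfg$likelihood_sd))
      })
    path <- file.path(out_dir, "fig3_model_curves.csv")
    readr::write_csv(curves, path)
    files <- path
  } else if (figure == "fig5-model") {
    grid <- tidyr::expand_grid(order = c("wide_first", "narrow_first"),
                               model = c("nig", "lf"))
    curves <- purrr::pmap_dfr(
      list(grid$order, grid$model, seeds[seq_len(nrow(grid))]),
      function(order, model, s) {
        sds <- if (order == "wide_first") c(0.2, 0.05) else c(0.05, 0.2)
        cfg <- session_config("exp2", prior_sd = sds)
        init <- if (model == "nig") nig_state() else lf_state()
        dplyr::mutate(
          average_model_curves(cfg, init, n_runs = n_runs, seed = s),
          order = order, model = model)
      })
    path <- file.path(out_dir, "fig5_model_curves.csv")
    readr::write_csv(curves, path)
    files <- path
  } else if (figure == "fig6-model") {
    cfg <- session_config("exp3", seed = seeds[1])
    scfg <- switch_model_config()
    logs <- purrr::map_dfr(seeds[1:5], function(s) {
      cfg$seed <- s
      trials <- generate_session(cfg)
      run <- run_switch_session(trials, scfg)
      dplyr::mutate(trials, response = run$response)
    }, .id = "session")
    logs$trial <- seq_len(nrow(logs))  # keep switch bookkeeping usable per row
    curve <- align_to_switches(logs)
    path <- file.path(out_dir, "fig6_model_switch_curve.csv")
    readr::write_csv(curve, path)
    files <- path
    if (plot) gg <- plot_switch_curve(curve, means = cfg$two_state_means)
  }

  if (plot && !is.null(gg)) {
    png_path <- file.path(out_dir, paste0(gsub("-", "_", figure), ".png"))
    ggplot2::ggsave(png_path, gg, width = 6, height = 4, dpi = 150)
    files <- c(files, png_path)
  }
  write_manifest(out_dir, stage = paste0("reproduce:", figure), config = NULL,
                 seed = seed, files = files, n_trials = NA)
  invisible(list(files = files))
}

# Run manifest: configuration hash, seed, package version, and the hash of
# every written file, so a run can be audited and reproduced bit-identically.
write_manifest <- function(out_dir, stage, config, seed, files, n_trials) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("priorlearn")),
    seed = seed,
    n_trials = n_trials,
    config_hash = if (is.null(config)) NA else digest::digest(unclass(config)),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = lapply(files, function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  path
}
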