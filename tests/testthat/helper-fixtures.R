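# Shared fixtures: canonical configurations, the synthetic-subject observer,
# independent oracles, and memoised model fits reused across test files.

# Synthetic-subject initial belief: near-flat prior (expected variance 0.5,
# initial cue gain ~0.98) held with little confidence.
subject_init <- function() nig_state(mu = 0, lam = 1, alpha = 1.2, beta = 0.1)

exp1_configs <- function() {
  list(wide = session_config("exp1", prior_sd = 0.2),
       narrow = session_config("exp1", prior_sd = 0.05))
}

# Across-run average binned curves of the synthetic subject on both
# fixed-prior protocols: the stand-in for across-subject average data.
synthetic_subject_target <- function(n_runs = 50, seed = 101) {
  cfgs <- exp1_configs()
  fit_target(
    wide = average_model_curves(cfgs$wide, subject_init(),
                                n_runs = n_runs, seed = seed),
    narrow = average_model_curves(cfgs$narrow, subject_init(),
                                  n_runs = n_runs, seed = seed + 1)
  )
}

.fit_cache <- new.env(parent = emptyenv())
cached_fit <- function(model = c("nig", "lf"), n_runs = 200) {
  model <- match.arg(model)
  key <- paste(model, n_runs, sep = "_")
  if (is.null(.fit_cache[[key]])) {
    target <- synthetic_subject_target()
    cfgs <- exp1_configs()
    .fit_cache[[key]] <- if (model == "nig") {
      fit_nig_init(target, cfgs, n_runs = n_runs, seed = 2024, restarts = 3)
    } else {
      fit_lf_params(target, cfgs, n_runs = n_runs, seed = 2024, restarts = 3)
    }
  }
  .fit_cache[[key]]
}

# Brute-force enumeration over all admissible mean sequences, weighted by the
# generative switching process: the independent oracle for the change-point
# observer's forward recursion. Returns the post-observation probability of
# mean 1 and the net position per trial.
enum_switch_oracle <- function(targets, cues, config) {
  Tn <- length(targets)
  means <- config$means
  ps <- config$prior_sd
  refr <- config$refractory_trials
  p <- config$switch_prob
  g <- compute_gain(ps, config$likelihood_sd)
  ml_sd <- sqrt(ps^2 + config$likelihood_sd^2)
  p1_post <- numeric(Tn)
  net <- numeric(Tn)
  for (t in seq_len(Tn)) {
    seqs <- as.matrix(expand.grid(rep(list(1:2), t)))
    w_prior <- numeric(nrow(seqs))
    lik_hist <- numeric(nrow(seqs))
    lik_full <- numeric(nrow(seqs))
    for (i in seq_len(nrow(seqs))) {
      s <- seqs[i, ]
      pr <- 0.5; dwell <- 1; ok <- TRUE
      if (t > 1) {
        for (j in 2:t) {
          h <- if (dwell >= refr) p else 0
          if (s[j] != s[j - 1]) {
            if (h == 0) { ok <- FALSE; break }
            pr <- pr * h; dwell <- 1
          } else {
            pr <- pr * (1 - h); dwell <- dwell + 1
          }
        }
      }
      if (!ok) next
      w_prior[i] <- pr
      lik_hist[i] <- if (t > 1) {
        prod(stats::dnorm(targets[1:(t - 1)], means[s[1:(t - 1)]], ps))
      } else 1
      lik_full[i] <- lik_hist[i] * stats::dnorm(targets[t], means[s[t]], ps)
    }
    w_pred <- w_prior * lik_hist
    pm <- c(sum(w_pred[seqs[, t] == 1]), sum(w_pred[seqs[, t] == 2]))
    pm <- pm / sum(pm)
    wc <- pm * stats::dnorm(cues[t], means, ml_sd)
    wc <- wc / sum(wc)
    net[t] <- sum(wc * ((1 - g) * means + g * cues[t]))
    w_post <- w_prior * lik_full
    p1_post[t] <- sum(w_post[seqs[, t] == 1]) / sum(w_post)
  }
  list(p1 = p1_post, net = net)
}

# Dense-lattice Bayes posterior over (mu, sigma^2) for Gaussian observations
# under an NIG prior: the independent oracle for the conjugate recursions.
grid_posterior_oracle <- function(x, init, mu_lim, v_lim, n_grid = 400) {
  mu_grid <- seq(mu_lim[1], mu_lim[2], length.out = n_grid)
  v_grid <- seq(v_lim[1], v_lim[2], length.out = n_grid)
  log_lik <- sapply(v_grid, function(v) {
    vapply(mu_grid, function(m) sum(stats::dnorm(x, m, sqrt(v), log = TRUE)),
           numeric(1))
  })
  log_prior <- sapply(v_grid, function(v) {
    stats::dnorm(mu_grid, init$mu, sqrt(v / init$lam), log = TRUE) +
      init$alpha * log(init$beta) - lgamma(init$alpha) -
      (init$alpha + 1) * log(v) - init$beta / v
  })
  lp <- log_lik + log_prior
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  list(mean_mu = sum(rowSums(post) * mu_grid),
       mean_var = sum(colSums(post) * v_grid))
}

# Per-run bins-to-criterion on the variance-switch protocol, computed from
# the per-run binned least-squares gain curves. Returns one row per run with
# the pre (from trial 1, first-half truth) and post (after the switch,
# second-half truth) statistics.
exp2_criterion_times <- function(init, n_runs, seed, first_sd, second_sd,
                                 tol = 0.1, n_trials = 500) {
  cfg <- session_config("exp2", prior_sd = c(first_sd, second_sd),
                        n_trials = n_trials)
  stim <- priorlearn:::simulate_stimuli_runs(cfg, n_runs, seed)
  resp <- priorlearn:::run_model_matrix(stim, init, cfg$likelihood_sd)
  binned <- priorlearn:::binned_ols_matrix(stim$cues, resp, stim$mean_true)
  switch_bin <- (n_trials %/% 2L) %/% 10L
  r_pre <- compute_gain(first_sd, cfg$likelihood_sd)
  r_post <- compute_gain(second_sd, cfg$likelihood_sd)
  pre <- apply(binned$r[seq_len(switch_bin), , drop = FALSE], 2,
               bins_to_criterion, r_true = r_pre, tol = tol)
  post <- apply(binned$r[(switch_bin + 1):nrow(binned$r), , drop = FALSE], 2,
                bins_to_criterion, r_true = r_post, tol = tol)
  data.frame(run = seq_len(n_runs), pre = pre, post = post)
}

# Adaptation-speed statistic that is start-point independent for a
# constant-rate filter: bins until the inferred variance (binned r inverted
# through the gain formula) crosses halfway from the segment's first-bin
# value to the new true variance. Censored at segment length + 1.
variance_halfway_times <- function(init, n_runs, seed, first_sd, second_sd,
                                   likelihood_sd = 0.1) {
  cfg <- session_config("exp2", prior_sd = c(first_sd, second_sd))
  stim <- priorlearn:::simulate_stimuli_runs(cfg, n_runs, seed)
  resp <- priorlearn:::run_model_matrix(stim, init, likelihood_sd)
  binned <- priorlearn:::binned_ols_matrix(stim$cues, resp, stim$mean_true)
  vl <- likelihood_sd^2
  to_v <- function(r) { r <- pmin(pmax(r, 0.02), 0.98); r / (1 - r) * vl }
  seg_time <- function(r, true_sd) {
    v <- to_v(r)
    v_true <- true_sd^2
    thr <- abs((v[1] + v_true) / 2 - v_true)
    k <- which(abs(v - v_true) <= thr)
    if (length(k)) k[1] else length(r) + 1L
  }
  n_half <- nrow(binned$r) %/% 2L
  data.frame(
    pre = apply(binned$r[seq_len(n_half), , drop = FALSE], 2, seg_time,
                true_sd = first_sd),
    post = apply(binned$r[(n_half + 1):nrow(binned$r), , drop = FALSE], 2,
                 seg_time, true_sd = second_sd)
  )
}
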