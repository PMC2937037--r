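# priorlearn

Tools for studying how an observer *learns a prior* in a one-dimensional
"coin catching" estimation task, and for measuring that learning from
trial-by-trial behaviour.

## The task and the model

On every trial a target coin is drawn from a Gaussian prior over horizontal
screen positions, `target ~ N(mu_p, sigma_p^2)` (screen normalised to
[-0.5, 0.5]). The observer never sees the target before responding; instead
a cue coin is shown, drawn around the target with a fixed, known spread,
`cue ~ N(target, sigma_l^2)` with `sigma_l = 0.1`. The observer places a
thin vertical net and catches the coin if the net overlaps it by at least
half a coin width. Under Gaussian integration the optimal placement is
linear in the cue:

    net = (1 - r) * mu_p + r * cue,     r = sigma_p^2 / (sigma_p^2 + sigma_l^2)

`r` — an alternate form of the Kalman gain — is also the slope of the
regression of responses on cues, so an observer's evolving belief about the
prior can be read off their behaviour: fit `(r, mu_p)` by least squares over
bins of 10 consecutive trials, and invert `r` to a believed prior spread
`sigma_l * sqrt(r / (1 - r))`.

The package implements the three session protocols (fixed prior, 400
trials; a variance switch at trial 251 of 500; a mean that flips between
-0.05 and +0.05 under a 10-trial refractory period plus Bernoulli(0.2)
hazard, 600 trials), and three learner models that stand in for subjects:

* **NIG learner** — sequential conjugate updating of a joint
  Normal-scaled-Inverse-Gamma belief over `(mu_p, sigma_p^2)`; its four
  initial hyperparameters are its free parameters. Its growing certainty
  reproduces the signature slow-down of variance learning late in a
  session.
* **Variance filter** — a non-Bayesian baseline that tracks only
  `sigma_p^2`, blending a 10-trial sliding-window sample variance into its
  estimate at a constant learning rate (two free parameters). Its constant
  rate is exactly what fails to reproduce the slow-down.
* **Change-point observer** — for the switching-mean protocol: knows both
  candidate means, the true variance and the switch process, and infers
  which mean is active by an exact forward recursion over
  (mean, dwell-time) states. No free parameters.

A fitting layer maximises the likelihood of binned learning curves under a
model's average behaviour (common random numbers make the Monte-Carlo
objective deterministic), with held-out prediction of the variance-switch
protocol for model comparison.

## Worked example

Simulate a narrow-prior session (`sigma_p = 0.05`), let the NIG learner play
it, and recover its evolving prior from behaviour alone:

```r
library(priorlearn)

cfg    <- session_config("exp1", prior_sd = 0.05, seed = 42)
trials <- generate_session(cfg)
learner <- run_nig_session(trials, nig_state(mu = 0, lam = 1,
                                             alpha = 1.2, beta = 0.1),
                           likelihood_sd = 0.1)
trials$response <- learner$response

curves <- bin_series(trials)       # 40 bins of 10 trials
curves[c(1, 5, 20, 40), c("bin", "r", "mu_p")]
#>     bin     r     mu_p
#>   1   1 0.783 -0.0242
#>   2   5 0.422 -0.0131
#>   3  20 0.268 -0.00819
#>   4  40 0.233 -0.00943

steady_state_gain(trials)$r        # last 200 trials pooled
#> [1] 0.245

prior_trajectory(curves, likelihood_sd = 0.1)[c(1, 5, 20, 40), ]
#>     bin     mean     sd flat
#>   1   1 -0.0242  0.190  FALSE
#>   2   5 -0.0131  0.0854 FALSE
#>   3  20 -0.00819 0.0605 FALSE
#>   4  40 -0.00943 0.0551 FALSE
```

The learner starts near the flat-prior limit (bin-1 gain 0.78, believed
spread 0.19), then narrows towards the truth: by the final bin the measured
gain is 0.23 against the optimal 0.2, the believed spread 0.055 against the
true 0.05, and the believed mean has converged on this session's
subject-specific prior mean (-0.0082). `autoplot(curves)` and
`plot_prior_trajectory()` draw the corresponding learning curves.

`average_model_curves()` repeats this over many sessions to produce
across-subject average curves; `fit_nig_init()` / `fit_lf_params()` fit the
models to such curves; `align_to_switches()` produces the switch-locked
mean-estimate curve for the switching-mean protocol. `run_simulate()`,
`run_analyze()`, `run_fit()` and `run_reproduce()` wrap these stages with
CSV/JSON input-output and run manifests (also available from the shell via
`inst/cli/priorlearn`).

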