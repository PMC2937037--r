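---
title: "Measuring how an observer learns a prior: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring how an observer learns a prior: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priorlearn)
```

## The estimation problem

In the coin-catching task an observer estimates, trial after trial, the
position of a hidden target drawn from a Gaussian prior
$x \sim \mathcal{N}(\mu_p, \sigma_p^2)$, after seeing a cue
$c \sim \mathcal{N}(x, \sigma_l^2)$ whose spread $\sigma_l = 0.1$ (in screen
units; the screen spans $[-0.5, 0.5]$) is fixed and assumed known. The
posterior mean — the placement that maximises the catch probability for a
symmetric catch rule — is linear in the cue,
$$\hat{x} = (1 - r)\,\mu_p + r\,c, \qquad
  r = \frac{\sigma_p^2}{\sigma_p^2 + \sigma_l^2},$$
so everything the observer believes about the prior is summarised by the
pair $(r, \mu_p)$, and both are identifiable from behaviour by regressing
responses on cues. That inverse reading — binned least squares giving a
learning curve in $(r, \mu_p)$, and $\sigma_p = \sigma_l\sqrt{r/(1-r)}$
reconstructing the believed prior — is the package's measurement machinery.
At the two operating spreads used throughout, $\sigma_p \in \{0.2, 0.05\}$,
the optimal gains are $0.8$ and $0.2$.

A gain at or above one is reported as a *flat-prior sentinel* (infinite
spread) rather than an error: behaviour early in a session genuinely sits
there, when the observer effectively ignores any prior and plays maximum
likelihood (response = cue).

## What the generator simulates

`generate_session()` implements three protocols:

* **Fixed prior** (400 trials): one spread, and a subject-specific prior
  mean drawn once per session from $\mathcal{N}(0, 0.1^2)$ — every
  simulated "subject" must learn a different mean, as a real cohort would.
* **Variance switch** (500 trials): the spread flips between 0.05 and 0.2
  at trial 251; the mean stays put.
* **Mean switch** (600 trials): the spread is fixed at 0.1 while the mean
  alternates between $-0.05$ and $+0.05$. After each switch the mean must
  stay for a 10-trial refractory period; from the moment the dwell reaches
  10 trials, each subsequent trial switches independently with probability
  0.2. The minimum run is therefore 10 trials and the expected run length
  is $10 - 1 + 1/0.2 = 14$ trials (about 43 runs per session).

Positions are *not* clipped to the screen: the generative model is an
untruncated Gaussian, and truncation would bias every moment downstream. A
`truncate_to_screen` flag (redraw until inside) exists for sensitivity
checks only. The catch rule for a thin vertical net reduces to
$|net - target| \le (1 - f)\,w$ with overlap fraction $f = 0.5$ and coin
width $w = 0.03$ screen units; the coin width is a package default (no
value is prescribed by the task design) and configurable.

Each session derives five named random substreams (subject mean, switches,
targets, cues, motor noise) deterministically from its seed, so attaching
an observer — or changing its motor noise — can never perturb the stimulus
stream, and identical configurations are bit-reproducible.

What the generator does **not** emulate: display timing and psychophysical
rendering, visual acuity limits, lapses and motor biases beyond additive
Gaussian jitter, sequential effects in human motor control, and any
deviation of real subjects from the linear response rule. Tests passing on
synthetic observers therefore validate the *pipeline* — generative process,
inference machinery, and analysis — not claims about human data.

## The observer models

**NIG learner.** The joint conjugate belief over the prior's unknown mean
and variance is Normal-scaled-Inverse-Gamma:
$\sigma^2 \sim \mathrm{Inv\text{-}Gamma}(\alpha, \beta)$,
$\mu \mid \sigma^2 \sim \mathcal{N}(m, \sigma^2/\lambda)$. After observing
a revealed target $x$:
$$m' = \frac{\lambda m + x}{\lambda + 1},\quad \lambda' = \lambda + 1,\quad
  \alpha' = \alpha + \tfrac12,\quad
  \beta' = \beta + \frac{\lambda (x - m)^2}{2(\lambda + 1)}.$$
The four *initial* hyperparameters are the model's free parameters. Design
choices here, each open in principle:

* *Only the target updates the belief.* Given the revealed target, the cue
  carries no further information about the prior; the cue's role is the
  response on that trial.
* *Respond, then update.* The response on trial $t$ uses the belief formed
  from trials $1..t-1$ plus the current cue; updating first would leak the
  current target into the response, which is acausal for the task.
* *Point estimates, not predictive integrals.* The response plugs
  $\hat\mu_p = m$ and $\widehat{\sigma_p^2} = \beta/(\alpha - 1)$ (the
  posterior mean; the mode $\beta/(\alpha+1)$ is switchable) into the
  linear rule. A `variance_mode = "predictive"` option inflates the
  variance by $(1 + 1/\lambda)$ to account for mean uncertainty; the modes
  differ only by Jensen-gap terms that vanish as $\lambda$ grows.
* *No forgetting.* The learner is a pure conjugate accumulator. Its
  growing certainty ($\lambda$ and $\alpha$ increase by 1 and 1/2 every
  trial) is the *explanatory mechanism* for the late-session slow-down of
  variance learning, and must not be "fixed" with a diffusion term.

The default state `nig_state()` encodes a near-flat initial belief
(expected variance 0.5, initial gain ≈ 0.98) held with little confidence
($\lambda = 1$, $\alpha = 1.2$) — the flat-prior predisposition observed at
session start, and the package's canonical synthetic subject.

**Variance filter.** The baseline tracks only the variance: once a 10-trial
window of targets is full, $v' = v + \eta\,(s^2_{10} - v)$ with unbiased
window variance $s^2_{10}$ and constant rate $\eta$; before that the
estimate stays at its initial value $v_0$ (warm-up). $(\eta, v_0)$ are its
two free parameters; the window length is fixed at 10. The model's mean
estimate is unspecified by its definition; the package uses the running
mean of all targets seen (switchable to the window mean), which keeps its
diagnostic failure specific to variance dynamics. Updating is per-trial
over a sliding window; an every-10th-trial variant would only quantise the
same first-order dynamics.

**Change-point observer.** For the switching-mean protocol the observer
knows both means, the true spread and the switch process, and tracks a
belief over joint (active mean, dwell) states because the hazard is
non-constant: $h(d) = 0$ for $d < 10$ and $0.2$ for $d \ge 10$ — the same
rule the generator uses. Dwell is capped at `d_max = 60` with mass
accumulating in the cap bin; since the hazard is constant past trial 10,
states beyond the cap are dynamically identical and the approximation is
exact for the inference (verified against brute-force enumeration). A
`constant_hazard` flag provides the memoryless approximation for
comparison. Placement first conditions the mean belief on the current cue
through its marginal likelihood
$\mathcal{N}(c;\, \mu_m,\, \sigma_p^2 + \sigma_l^2)$ — transiently, so the
cue is never double-counted when the revealed target later updates the
persistent belief — and then takes the posterior-mean placement under the
two-component mixture (a `"map"` mode places on the most probable mean
instead; posterior mean minimises expected squared error, matching the
estimation framing).

## Fitting and model comparison

`fit_nig_init()` and `fit_lf_params()` maximise the log-likelihood of
observed binned curves (gain and mean-error per bin, both protocols of the
fixed-prior experiment) under the model's average curves, with independent
Gaussian errors at the observed per-bin standard errors. SE weighting is a
choice — the error model behind "the likelihood of across-subject averages"
is not uniquely determined — and means precisely estimated bins constrain
the fit most.

The objective is Monte-Carlo (average over simulated sessions) but
*deterministic*: session ensembles are generated once per fit from the seed
and reused for every evaluation (common random numbers), so derivative-free
simplex search (Nelder-Mead, 5 restarts by default, positivity enforced by
log/logit transforms, $\alpha_0 > 1$ by construction) sees a fixed
function. Non-convergence flags the result rather than raising. Held-out
discipline is structural: the fitting functions accept only fixed-prior
configurations, and variance-switch predictions come from a separate
`predict_model_curves()` call that cannot feed back into the fit.

One empirical note: on synthetic-subject curves generated by the NIG
learner, the SE-weighted likelihood genuinely prefers a filter with small
initial variance and a very small rate over a flat-start filter — verified
by an objective grid scan. Least-squares-style fits trade a few terrible
early bins against many moderately bad middle bins; the result is still a
constant-rate filter, which is all the comparison needs.

## Analysis conventions and numerical choices

* Bins are 10 consecutive trials, 1-indexed; trailing partial bins are
  dropped with a warning (all standard session lengths are multiples of
  10).
* A bin whose fitted slope is within 0.05 of 1 has an ill-conditioned
  intercept-to-mean conversion; it is flagged degenerate and its $\mu_p$
  reported as the flat-prior sentinel.
* Mean error is estimate minus truth. Post-switch trial $k = 1$ is the
  first trial governed by the new mean.
* The switch-aligned curve fixes the gain at the steady-state value (last
  200 trials, single pooled regression) and inverts each trial
  algebraically; single-trial joint $(r, \mu)$ fits are ill-posed. Because
  switches alternate, raw estimates from opposite directions cancel, so
  the curve is expressed along the direction of the new mean (sign
  alignment); the inter-mean midpoint maps to zero.
* For the switching-mean protocol the steady-state gain removes the known
  active mean per trial before fitting, so mean switching does not
  contaminate the slope. Both removal modes are exposed: for the ideal
  change-point observer the *raw* slope sits above the mean-removed one,
  because cue-driven belief reweighting adds cue dependence — the
  direction of this confound depends on whether the observer knows the
  true spread, so surfacing both modes matters.
* Adaptation-speed comparisons use bins-to-criterion ($|r - r_\text{true}|
  < 0.1$, right-censored at segment length + 1). For the *filter's*
  invariance check the speed is measured instead as halfway-crossing of
  the inferred variance (binned $r$ inverted through the gain formula,
  clipped to $[0.02, 0.98]$): variance is the coordinate in which a
  constant-rate filter relaxes exponentially, making the statistic
  independent of starting distance; in gain space, unequal pre/post
  starting points would masquerade as a rate change.
* The variance-increase/decrease asymmetry of the conjugate learner is
  measured with an extended 600-trial post-switch window: its post-switch
  convergence takes roughly 310 trials upward and far longer downward, so
  within a 250-trial half both directions censor and the contrast would be
  invisible.

## Problem sizes

The shipped tests and reproduction scripts use ensembles of 50–200
sessions per condition (200 for the fitted-model comparisons), 100 seeds
for parameter-recovery checks, at least 1000 switches for the switch-locked
curve, a $400 \times 400$ lattice for the grid-integration oracle, and
8-trial sessions (with a shortened 2-trial refractory, so that switches are
admissible) for the enumeration oracle. These sizes put Monte-Carlo error
well below every tolerance asserted while keeping a full run at desk scale.

## Limitations

The pipeline validates computational claims on synthetic observers; no
human data ships with the package, and statistics that depend on subject
cohorts (between-group tests, subject-level fit errors) are out of scope.
The NIG learner's conjugacy relies on the likelihood spread being known; a
prior over $\sigma_l$ would break the closed form. The change-point
observer is an upper bound by construction — it is given the means, the
spread and the hazard — and says nothing about how such structure is
acquired. All models respond through the linear Gaussian rule; non-Gaussian
priors or loss functions other than posterior-mean placement are not
modelled.
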