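---
title: "Beta group-based trajectory models: methods and design"
author: "betagbtm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta group-based trajectory models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betagbtm)
```

## The model

Group-based trajectory modeling (GBTM) treats a population of longitudinal
measurements as a finite mixture of $J$ latent trajectory groups. For subject
$i$ with outcome vector $Y_i = (y_{i1}, \dots, y_{iT})$ over a common time
grid,

$$P(Y_i) = \sum_{j=1}^J \pi_j \, P(Y_i \mid j;\ \theta_j),$$

where $\pi_j$ is the probability of membership in group $j$, parameterized as
a multinomial logit with the last group as reference. Within a group, serial
observations are conditionally independent:
$P(Y_i \mid j) = \prod_t p(y_{it} \mid j)$. All the dependence between a
subject's measurements is carried by the latent group label.

This package specializes GBTM to outcomes on $[0,1]$ — proportions such as
an EEG suppression ratio — using the mean–precision parameterization of the
beta distribution. With mean $\mu \in (0,1)$ and precision $\phi > 0$
(shapes $a = \mu\phi$, $b = (1-\mu)\phi$),

$$E(y) = \mu, \qquad \mathrm{Var}(y) = \frac{\mu(1-\mu)}{1+\phi}.$$

The appeal over a censored normal is the shape flexibility: for $\phi < 1$
the density is unbounded at one or both boundaries (J- and U-shapes), which
matches bounded biomedical data whose histograms pile up at 0 and 1 with an
approximately flat middle.

Each group has a polynomial mean trajectory on a link scale,
$g(\mu_{jt}) = \beta_{0j} + \beta_{1j} t + \beta_{2j} t^2 + \dots$, and its
own precision $\phi_j$.

### Link choice

The defining polynomial can be read either as a direct (identity-link) model
for $\mu_{jt}$ or through a logit link. The package defaults to the logit
link: it guarantees $0 < \mu_{jt} < 1$ for every parameter vector and time,
so the optimizer's search space is unconstrained. The identity link is
retained as an option for fidelity to the direct-polynomial formulation, but
any evaluation outside $(0,1)$ is an explicit error, never a silent clamp;
inside the optimizer such a proposal is rejected by a large penalty value.

### Boundary adjustment

Exact 0/1 observations are outside the beta support. Following standard
practice, `boundary_adjust()` moves them inward by half a reciprocal sample
size: $0 \mapsto 0.5/N$ and $1 \mapsto 1 - 0.5/N$, with $N$ the number of
subjects (configurable; subjects rather than observations because subjects
are the independent units). The map is idempotent and leaves interior values
untouched. A zero/one-inflated mixture would avoid the adjustment entirely
and is a known limitation, not implemented here.

### Non-random dropout

When follow-up ends for reasons correlated with the trajectory (death,
awakening), missingness is informative about the latent group. The package
augments each group's conditional likelihood with a discrete-time logistic
hazard on the occasion index: at each occasion $t \ge 2$ at which a subject
is still observed,

$$h_{jt} = \operatorname{logit}^{-1}(\delta_{0j} + \delta_{1j}\, y_{i,t-1}),$$

contributing $\log(1-h)$ for continuation and $\log(h)$ at the dropout
occasion; the first occasion carries no hazard term. The covariate set is the
intercept plus one lagged outcome by default (configurable to two lags);
occasions with a missing lag contribute no hazard term. The hazard has no
time covariate — the minimal lag-based form keeps the sub-model close to the
observation model while still letting the hazard differ by group, which is
what makes dropout informative. With dropout disabled, missing values are
treated as missing at random and the likelihood is the plain mixture over
observed occasions.

## Estimation

The mixture log-likelihood is maximized directly (no EM) by multi-start
BFGS — a quasi-Newton method — with an analytic gradient assembled from the
beta score, the logistic-hazard score and the multinomial-logit score. Key
numerical choices:

- **Log space everywhere.** Per-group conditional log-likelihoods at
  $T \approx 13$ occasions reach large negative values, and $\phi < 1$
  densities are unbounded; all mixing is done with log-sum-exp, and the
  density is never exponentiated inside likelihood code.
- **Unconstrained parameterization.** Precision enters as $\log\phi$ and
  mixing proportions as logits, so the search space is all of
  $\mathbb{R}^k$.
- **Time rescaling.** Times are affinely recoded to $[0,1]$ before
  polynomial evaluation, which conditions the Hessian at cubic orders;
  coefficients are reported on both the internal and the raw time scale
  (exact polynomial rebasing). Wald statistics for the highest-order term
  are invariant to this recoding.
- **Objective scale.** The optimizer minimizes the *per-subject mean*
  negative log-likelihood, making the gradient tolerance (default `1e-4`
  infinity-norm) scale-free; the BFGS relative function tolerance is
  `1e-10`, tight enough that refits during model selection give stable
  BIC comparisons.
- **Starts.** One deterministic start (subjects quantile-sliced by
  time-averaged outcome into $J$ blocks; per-block least-squares curves on
  the link scale and moment estimates $\phi \approx m(1-m)/v - 1$) plus
  randomized perturbations of it. The reported fit is the best local
  optimum; a fit whose optimum is not replicated by any other start is
  flagged, since mixtures with four or more groups are prone to unstable
  optima.
- **Label switching.** The likelihood is invariant to permuting group
  labels. Fits are relabeled canonically by ascending time-averaged fitted
  mean, so "group 1" is always the lowest trajectory.
- **Standard errors.** From the inverse *observed* information — the
  negative Hessian of the log-likelihood by central finite differences of
  the analytic gradient, step scaled per parameter. Observed rather than
  expected information because the dropout extension has no closed-form
  expected information. A non-positive-definite information matrix yields
  `NA` standard errors and a warning, never silent numbers.
- **Seeds.** All randomness flows from one explicit integer seed through a
  deterministic sub-stream scheme (`derive_seed`); no function perturbs the
  caller's RNG state.

Posterior group memberships are Bayes-rule posteriors computed in log space;
rows sum to one by construction.

## Model selection

No test statistic identifies the number of components of a finite mixture,
so `sweep_groups()` fits each candidate $J$ and reports AIC and BIC side by
side, flagging disagreement and non-replicated optima rather than resolving
them silently. BIC uses the number of *subjects* as the sample size
(configurable), since subjects are the independent units.

Polynomial orders are then chosen by backward pruning
(`prune_polynomials()`): all groups start at a maximum order (default 3);
at each step the group whose highest-order coefficient has the largest Wald
p-value above $\alpha = 0.05$ loses one order and the model is refitted, one
term at a time, because each removal changes the remaining coefficients'
significance. Intercepts are never pruned. The full pruning path is logged.

## Diagnostics

- `density_overlay()` compares, at one occasion and group, a
  relative-frequency density histogram (20 equal-width bins on $[0,1]$;
  heights times widths sum to one) against the fitted beta density. Subjects
  are weighted by their posterior probability of the group by default; hard
  modal assignment is available, but soft weights avoid distortion when
  groups overlap.
- `trajectory_table()` reports fitted curves with pointwise delta-method
  bands (normal interval on the link scale mapped through the inverse link)
  and group shares $100\hat\pi_j$.
- `classification_quality()` reports the average posterior probability of
  assignment (APP) and the odds of correct classification
  $\mathrm{OCC}_j = [\mathrm{APP}_j/(1-\mathrm{APP}_j)]\,/\,
  [\hat\pi_j/(1-\hat\pi_j)]$; OCC well above 5 for every group is the usual
  adequacy bar.
- `residuals()` returns randomized-quantile-style residuals from the
  posterior-weighted mixture CDF, approximately standard normal under a
  correct model.

## The synthetic cohort

No clinical data ship with the package. `cohort_preset()` encodes a
three-group configuration chosen once to echo a comatose post-cardiac-arrest
EEG cohort: 396 subjects on a 13-occasion grid (every 4 h over 0–48 h);
mixing weights 0.27/0.41/0.32; a persistently low group
(logit-scale constant $-2.2$, $\phi = 2$: mean $\approx 0.10$, right-skewed
with a spike near 0), an intermediate declining group (logit-scale
$0.4 - 1.8s$ on unit time: mean falling from 0.60 to about 0.20,
$\phi = 5$), and a persistently high group ($2.2$, $\phi = 4$: mean
$\approx 0.90$, left-skewed). The marginal mid-grid histogram is bimodal
with boundary-adjacent spikes, the shape that motivates a beta rather than
a censored normal observation model. With dropout enabled, hazards are
group-dependent: the low group's hazard *falls* with the lagged outcome
(awakening at low suppression), the high group's *rises* with it (death at
high suppression), and the intermediate group rarely drops out. Generator
coefficients are stated constants in the configuration object, on the same
unit-time basis the fitter uses, so truth and estimates are directly
comparable.

What the generator deliberately does **not** emulate: serial correlation
within group beyond the mean trajectory, exact-0/1 boundary atoms
(beta draws are strictly interior, so boundary adjustment is exercised by
dedicated unit tests rather than by the generator), measurement-grid
irregularity across subjects, and any survival process beyond the dropout
hazard. Passing recovery tests on this generator therefore demonstrates
correctness of the estimator under the model's own assumptions — not
robustness to misspecification on real cohorts.

## Problem sizes and tolerances in the test suite

The simulation-based tests run at the cohort scale the preset defines
(N = 396–400 subjects, 13 occasions) with 10 replicate seeds for recovery,
group-number selection, pruning and dropout-bias comparisons, and 200
replicates (N = 150, T = 10) for the Wald size check; density and likelihood
oracles use dense grids (1000+ points) at `1e-10` tolerances. Histogram
self-consistency is checked at N = 400 and N = 4000: a 20-bin histogram of
~130 subjects per group has an intrinsic total-variation sampling floor
around 0.2, so the shrink-with-N property, not a tight absolute bound at
small N, is the meaningful invariant.

## Known limitations

- Exact 0/1 mass is handled by boundary adjustment, not by a zero/one
  inflation component.
- No covariates other than time in the mean trajectories or mixing logits.
- No within-group random effects or autocorrelated errors; conditional
  independence is structural.
- The identity link is numerically fragile for higher-order polynomials and
  is provided for completeness rather than routine use.
- Four-plus-group fits can exhibit non-replicated optima; the instability
  flag reports this, and results for such fits should be treated with care.
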