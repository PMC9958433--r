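---
title: "Predicting patient-specific length-of-stay ranges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting patient-specific length-of-stay ranges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(losrange)
```

## The problem

Hospital length of stay (LOS) is usually predicted either as a point value
(a regression) or as membership in a pre-set band (a classification). Both
throw information away: a point value says nothing about its own
reliability, and pre-set bands give every patient in a band the same range
regardless of how predictable that patient actually is. `losrange` instead
predicts a *patient-specific interval*

$$[\ \mathrm{center}_i - \alpha\,\mathrm{scale}_i,\ \ \mathrm{center}_i + \alpha\,\mathrm{scale}_i\ ]$$

where the per-patient error scale comes from one of six methods, and a
single multiplier $\alpha$ trades interval width against coverage. All
internal computation is in hours; days appear only in display output.

| method | center | scale |
|---|---|---|
| `rmse` | point prediction | global training RMSE (same for everyone) |
| `err_pred` | point prediction | second network's predicted error magnitude |
| `dis_loss1`–`dis_loss3` | $\mu_{pred}$ | $\sigma_{pred} = e^z$ from a two-output network |
| `wgan_gp` | mean of 500 generated samples | SD of those samples |

Two metrics evaluate an interval set: **coverage accuracy**, the fraction of
patients whose true LOS falls inside their interval (closed on both ends),
and the **overall prediction error (OPE)**, the mean unclamped half-width
$\alpha \times \overline{\mathrm{scale}}$ — the width budget spent to reach
that coverage. `calibrate_alpha()` finds the smallest $\alpha$ on a 0.01
grid reaching a target accuracy; because coverage is monotone in $\alpha$,
the order statistics of the per-patient required multipliers give the answer
exactly, without a search.

## The synthetic cohort generator

Real ICU cohorts with these properties sit behind credentialed access, so
the package ships a generator (`generate_cohort()`) that serves as both demo
data and test fixture. Marginally, LOS is log-normal with median 162 h
(6.75 days) and log-scale SD 0.84, back-solved from the published quartiles
of a large ICU cohort (6.75 [3.88–12.07] days): the implied quartiles are
$\exp(\log 162 \pm 0.6745 \cdot 0.84) \approx 92$ and $285$ h. Three
regimes mirror qualitatively different feature sets:

* **Regime A** (27 features): one feature is a discharge-time analog whose
  linear transform equals LOS up to additive Gaussian noise (default SD
  15 h). With the noise at zero the mapping is exact, which pins down the
  optimization quality of the fitting code; with noise it provides a known
  irreducible error floor.
* **Regime B** (27 features): only a `signal_fraction` (default 0.1) of the
  log-LOS variance is explained by the features — the "weak predictors"
  regime.
* **Regime C** (136 features): a rich feature set drives LOS through a
  smooth conditional mean, with *heteroscedastic* additive noise whose SD is
  the stated function $\sigma(x) \propto \exp(0.5\,x_1)$ of the first
  feature (baseline 40 h). The true per-patient SD is returned as a
  `sigma_true` side channel — never a model input — so that recovery tests
  have an oracle.

Two regime-C design details are deliberate. First, the conditional log-mean
saturates at 2.2 SD ($2.2\tanh(u/2.2)$): unbounded exponential means produce
a handful of patients with conditional means in the thousands of hours that
no desk-scale fit can learn, while saturation keeps conditional means in a
clinically plausible range and leaves the marginal median and quartiles
essentially unchanged (within about 2.5%). Second, adding symmetric noise to
a right-skewed outcome drifts the sample median upward by a few percent
(skew convolution), so the generator rescales the cohort to put the sample
median exactly at `los_median_hours`; `sigma_true` is scaled with it and
remains proportional to $\exp(0.5 x_1)$.

What the generator does *not* emulate: real EHR missingness mechanisms
(missingness here is injected at random by tests), correlated and
categorical clinical features, censoring, or multi-admission structure.
Passing tests therefore demonstrate that the estimators recover known
structure at realistic scales and noise levels — not clinical performance.

## The distributional losses

The two-output network (`train_dist_net()`) predicts $(\mu_{pred}, z)$ with
$\sigma_{pred} = e^z$, so $\sigma_{pred} > 0$ by construction. The target is
the degenerate distribution at the observed LOS: $\mu_0 = \mathrm{LOS}$,
$\sigma_0 \to 0$. Three losses are implemented as pure functions with
analytic gradients (finite-difference-checked in the test suite).

**Loss 1** compares probability mass near the target,
$$L_1 = \frac{e^{-z}\,\mathrm{erf}(0.707 e^{-2z}(\mu_{pred}-\mu_0+1)) -
e^{-z}\,\mathrm{erf}(0.707 e^{-2z}(\mu_{pred}-\mu_0-1))}{2e^{-2z}},$$
implemented exactly in this printed form. It does vanish in its stated limit
($\mu_{pred} \to \mu_0$, $z \to -\infty$), which the tests pin numerically.
But as a *training objective* it is degenerate in two ways: it vanishes as
$z \to -\infty$ for **any** $\mu_{pred}$, and at fixed $z$ it is
*maximized* — not minimized — at $\mu_{pred} = \mu_0$ (it is, up to scale,
the predicted mass in the $\mu_0 \pm 1$ window). Gradient descent therefore
collapses $\sigma$ while the mean stalls and then random-walks once the
gradients vanish (adaptive optimizers renormalize vanishing gradients into
noise). This matches the training instability reported for this loss;
gradient clipping (on by default for loss 1 and 2) slows but does not cure
it. The package keeps loss-1 training honest rather than silently fixing
the objective: fits train without error, snapshot their best weights by
*validation mean error* rather than by the loss itself, and record a status
flag. An `e^{-z}`-argument variant (`variant = "sigma_scaled"` in `loss1()`)
is exposed for experimentation; it shares the same degeneracy.

**Loss 2** measures interval overlap between $[\mu_0 \pm \sigma_0]$ and
$[\mu_{pred} \pm \sigma_{pred}]$. The overlap
$O = \min(\mu_0+\sigma_0, \mu_{pred}+\sigma_{pred}) -
\max(\mu_0-\sigma_0, \mu_{pred}-\sigma_{pred})$ is left unclamped
(negative for disjoint intervals) to preserve gradients. The printed
normalizer $2(\mu_0 + \mu_{pred})$ contradicts the loss's own stated limit:
at $\mu_0 = \mu_{pred} = 100$, $\sigma_0 = \sigma_{pred} = 10$ it gives
$1 - 20/400 = 0.95$, not 0. Both variants are implemented;
`loss2_overlap`, normalized by $\sigma_0 + \sigma_{pred}$, satisfies the
limit and is the default, the printed form is selectable for fidelity.
Since the target needs a non-degenerate interval, $\sigma_0$ defaults to
1 h for this loss. Training gradients vanish once the tiny target interval
sits strictly inside the predicted one (only boundary events move $\mu$),
so convergence of the mean is slow — the "gradient disappearance for large
$\sigma$" behaviour — and clipping is kept on.

**Loss 3** is the squared 2-Wasserstein distance between the two normals
plus a coupling penalty:
$$L_3 = (\mu_{pred}-\mu_0)^2 + (\sigma_{pred}-\sigma_0)^2 +
\lambda\,\frac{(\mu_{pred}-\mu_0)^2}{\sigma_{pred}^2+\varepsilon},
\qquad \varepsilon = 10^{-6}.$$
Without the penalty ($\lambda = 0$) the $\sigma$ head collapses to 0 (shown
in a test); with it, a non-zero $\sigma$ pays wherever the mean error is
non-zero. The resting level has a closed form worth knowing: minimizing
$s^2 + \lambda v/(s^2+\varepsilon)$ over $s^2$, where $v$ is the local mean
squared error of the $\mu$ head, gives $\sigma_{pred} = (\lambda v)^{1/4}$.
Two consequences, both exploited by the tests:

* $\sigma_{pred}$ is a *monotone* transform of the local error variance, so
  rank-based recovery of heteroscedastic structure (Spearman correlation
  with the generator's $\sigma(x)$) works at any $\lambda$;
* $\sigma_{pred}$ equals the residual SD itself exactly when $\lambda$
  equals the residual variance (in the standardized training units). The
  package defaults to $\lambda = 1$, the neutral choice when nothing is
  known; a two-stage recipe — fit the point regressor, set
  $\lambda = (\mathrm{RMSE}_{train}/s_y)^2$ — yields calibrated
  $\sigma_{pred}$ whose $\mu \pm 1.96\sigma$ intervals achieve nominal 95%
  Gaussian coverage, as the test suite verifies.

Targets are standardized during training by default (inverted before
reporting), so LOS scales from tens to thousands of hours optimize
identically; note that loss 1's $\pm 1$ mass window and loss 3's $\lambda$
then live on the standardized scale.

## Network engine and training choices

No deep-learning framework is used: the fully connected engine (matrix
forward/backward passes, Adam, global-norm gradient clipping, minibatching,
early stopping on a 10% validation slice) is part of the package, which
keeps every gradient — including the unusual ones — explicit and testable.
Defaults: three hidden layers of 64 ReLU units, Adam at $10^{-3}$ with step
decay (factor 0.3 at 1/3, 2/3, 0.85 and 0.95 of the epoch budget — coarse
fit first, precision polishing later), batch size 256, up to 200 epochs,
patience 10.

Weight decay (default $10^{-3}$) matters more than usual here: the interval
methods use the *training* RMSE as a width scale, and an unregularized
network memorizes noise-feature directions, deflating training RMSE below
the irreducible noise floor and silently widening the calibrated $\alpha$.
With decay, training and test RMSE agree with the generator's noise floor
within a few percent. Experiments on the 136-feature regime C use
$10^{-2}$ — more mostly-noise features, more shrinkage. The error network
(`train_error_net()`) fits $|{\rm LOS} - {\rm LOS}_{pred}|$ through a
softplus output so predicted half-widths are positive (a signed mode is
available behind a flag; Gaussian errors make the absolute error the
natural target, with mean $\sigma\sqrt{2/\pi}$ — the recovery oracle used
in tests).

## The conditional WGAN-GP

The adversarial method (`train_wgan_gp()`) trains a generator
$(x, \mathrm{noise}) \mapsto \mathrm{LOS}$ against a critic scoring
$(x, \mathrm{LOS})$ pairs — the standard conditional reading when only one
observed LOS exists per patient. The critic objective is
$E[D(x,\hat\ell)] - E[D(x,\ell)] + w_{gp}(\|\nabla_\ell D\|-1)^2$ with the
gradient penalty taken along the LOS coordinate at points interpolated
between real and fake values at fixed features (a flag extending it to the
joint input is deliberately not provided: the generated object is the LOS
scalar). The double-backprop this requires is implemented analytically and
finite-difference-checked. Convention hyperparameters are kept
($w_{gp} = 10$, 5 critic steps per generator step, Adam betas $(0, 0.9)$)
with two desk-scale adaptations, both visible in `gan_config()`:

* learning rate $5 \times 10^{-4}$ rather than the conventional $10^{-4}$,
  which assumes budgets of $\sim 10^5$ generator steps; at the package's
  cohort-scale budgets (a few thousand steps) the conventional rate leaves
  the generator far from the data;
* the critic uses softplus hidden units — smooth, as the penalty requires,
  but non-saturating, where tanh starves the generator of gradient.

Adversarial losses oscillate rather than converge, so the returned
generator is the checkpoint whose generated samples best match the real
first two moments on a fixed training slice (scored on the reporting scale,
hours clamped at zero). Per patient, 500 generated samples are summarized
into `mean_pred` and `std_pred`; the population SD (divisor $n$) is used —
at $n = 500$ the distinction from the sample SD is below 0.1%, and a flag
switches it.

## Evaluation conventions and numerical details

* Interval membership is closed on both ends; lower limits clamp at 0 h,
  which never changes coverage because true LOS is non-negative.
* OPE is the mean *unclamped* half-width, $\alpha \times
  \overline{\mathrm{scale}}$ — exactly linear in $\alpha$; this definition
  reproduces the printed width arithmetic of the reference results (e.g.
  $1.99 \times 52.05 = 103.6$).
* $\alpha$ is calibrated on the evaluation set by default (mirroring how
  such results are usually reported); pass a held-out calibration split for
  deployment-honest numbers. The grid step is 0.01, the bound
  $\alpha \le 50$ before a target is declared unreachable (the error then
  reports the best achievable accuracy).
* Method comparison at fixed width budgets (default 48 h and 96 h)
  back-solves $\alpha_b = b / \overline{\mathrm{scale}}$ per method — the
  budget is a mean half-width, consistent with the OPE definition.
* The split convention floors the training side: 38,597 rows at 9:1 give
  exactly (34,737, 3,860).
* `z` is clamped to $[-30, 30]$ inside loss 1 against $e^{-2z}$ overflow;
  $\mathrm{erf}$ is evaluated through the normal CDF
  ($\mathrm{erf}(x) = 2\Phi(x\sqrt2)-1$); saturated $\mathrm{erf}$
  differences underflow to exact 0 for extreme arguments, so the
  positivity of loss 1 is asserted on the representable region.

## Problem sizes used by the test suite

Cohorts of $n = 20{,}000$ (9:1 split, 2,000 test rows) are used for the
calibration and recovery checks — large enough that Monte-Carlo error on a
95% coverage estimate is about $\pm 1$%; the WGAN runs on $n = 2{,}000$
with ~1,400 generator steps; structural tests use a few hundred rows.
Trained fits are built once per run and shared across test files.

## When do per-patient widths actually help?

A point worth making explicit, because it is easy to assume otherwise:
per-patient (heteroscedastic) widths do *not* dominate a constant width at
every width budget. At a matched mean half-width, allocating width
proportionally to the local residual SD is not the coverage-optimal
allocation when the budget is small — wide-σ patients consume budget and
still miss, while a constant width covers all the predictable patients
cheaply. On the regime-C cohort this is true even with the generator's
*oracle* conditional SD as the scale: at a 48 h budget the oracle scales
cover slightly fewer patients than the constant RMSE width, while at 96 h
and above they win. Where per-patient widths pay off clearly is at high
coverage: the width budget needed for 95% coverage (the OPE at target) is
strictly smaller for the error-network and loss-3 methods than for the
constant-width method, because the calibrated $\alpha$ no longer has to
stretch every interval to cover the hardest patients. The test suite
asserts exactly this pattern.

## Known limitations

* Loss 1 is faithful to its printed form and therefore not a usable
  training objective (see above); its fits are exercised and flagged, not
  relied on.
* The WGAN's conditioning at desk scale is coarse: pooled moments match
  well, per-patient correlation with the true conditional mean is weak.
  The method is included as specified, benchmarked by the pooled-moment
  property.
* Calibrating $\alpha$ on the evaluation set overstates deployment
  coverage; use the optional calibration split for honest intervals.
* The generator's regimes are stylized; nothing here validates clinical
  transportability.
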