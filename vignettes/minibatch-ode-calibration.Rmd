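---
title: "Mini-batch optimization for ODE model calibration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mini-batch optimization for ODE model calibration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbode)
```

## The estimation problem

`mbode` calibrates ODE models of cellular signalling against data collected
under many *experimental conditions*. A condition is one initial value
problem: the model

$$\dot x = f(x, \theta, u^e), \qquad x(0) = x_0(\theta, u^e)$$

shares its unknown parameters $\theta$ (rate constants) across conditions,
while the known input vector $u^e$ — stimulus doses, expression scalings,
drug concentrations — distinguishes condition $e$. Observables
$y = h(x, \theta, u)$ are compared with measurements $\bar y_{e,i}$ carrying
known Gaussian noise SDs $\sigma_{e,i}$. The negative log-likelihood is, up
to a $\theta$-independent constant, the weighted least-squares objective

$$J(\theta) = \frac12 \sum_{e=1}^{M} \sum_{i=1}^{N_e}
  \left(\frac{\bar y_{e,i} - y_{e,i}(\theta)}{\sigma_{e,i}}\right)^2
  = \sum_e J_e(\theta).$$

Because $J$ decomposes over conditions, evaluating the full objective costs
$M$ ODE solves — the motivation for mini-batching: each optimization step
evaluates only a random disjoint subset $S_r$ of conditions and uses the
unnormalized sum $\sum_{e \in S_r} \nabla J_e$ as its gradient estimate. One
pass through all conditions is an epoch; within an epoch every condition is
used exactly once. We deliberately keep the gradient estimate an
unnormalized sum rather than a mean: for the adaptive optimizers the
preconditioning removes the scale anyway, and for SGD the consequence (the
effective step grows with the batch size) is documented rather than hidden.

Parameters are estimated on the $\log_{10}$ scale in the box
$[-5, 3]^{n_\theta}$ (linear scale $[10^{-5}, 10^{3}]$); all
optimization-facing gradients are chain-ruled onto that scale
($\partial\theta/\partial\hat\theta = \theta \ln 10$).

## Numerics

**Integration.** All simulations use a variable-order BDF scheme with
adaptive steps (deSolve), relative tolerance $10^{-8}$, absolute tolerance
$10^{-16}$, at most $10^4$ steps per solve. Integration failure — divergence
or step exhaustion — is always reported as a status value, never thrown;
the optimization layer is built around the ability to observe failures.

**Gradients.** Objective gradients come from forward sensitivity analysis:
the variational system $\dot S = f_x S + f_\theta$, $S(0) = \partial
x_0/\partial\theta$ is appended to the state and integrated together with
it. The built-in model families carry analytic Jacobians (in compiled code
for the cascade family); generic models fall back to central finite
differences of the right-hand side inside the variational system, which
keeps the gradient itself accurate to the solver tolerance. At the package's
intended scale (tens of parameters) forward sensitivities are as exact as,
and simpler than, the adjoint method; the gradient contract (same signature,
same $\log_{10}$ scale) leaves room for an adjoint backend.

**Steady states.** Equilibrium readouts integrate to $t = 10^8$ and accept
the end point iff the tolerance-weighted RMS norm of the vector field,
$\sqrt{\mathrm{mean}_i\,(f_i/(10^{-16} + 10^{-8}|x_i|))^2}$, is below 1.
We additionally require the same norm to pass at the half horizon
$t = 5\times10^7$: a state drifting at constant rate grows until the
relative weight drives the end-point norm to exactly 1, so the single
end-point rule would accept a system that never equilibrates, while genuine
equilibria settle long before either checkpoint.

**Analytic scaling factors.** Observables measured only up to a
multiplicative constant are handled hierarchically: for $y = s\,\hat y$ the
optimal scaling $s^* = \sum \bar y \hat y/\sigma^2 \big/ \sum \hat
y^2/\sigma^2$ is computed analytically per observable group and applied
before the residual. Gradients treat $s$ as fixed at $s^*$, which is exact
by the envelope theorem ($\partial J/\partial s = 0$ at $s^*$). By default
scalings are applied both during optimization and in final metrics; a flag
restricts them to final metrics.

## Optimizers, learning rates, robustness

Four stochastic engines share one update contract
$\theta^{(r+1)} = \mathrm{clip}(\theta^{(r)} + s_r\,\eta_r\,\delta_r)$:
plain SGD ($\delta = -g$), SGD with momentum ($\rho = 0.9$), RMSProp
($\rho = 0.9$, $\varepsilon = 10^{-8}$), and Adam with bias correction in
two tunings — *standard* $(\rho_1, \rho_2) = (0.9, 0.999)$ and *balanced*
$(0.9, 0.9)$. Under a persistent gradient Adam's update norm approaches
$\sqrt{n_\theta}$, so a learning rate $\eta$ translates into steps of size
$\eta\sqrt{n_\theta}$; initial step sizes of $\kappa\sqrt{n_\theta}$ with
$\kappa \in [0.01, 0.1]$ are a reasonable first choice
(`suggest_schedule()`). Four schedule presets are built in: geometric
decays $10^0\!\to\!10^{-3}$, $10^{-1}\!\to\!10^{-4}$,
$10^{-2}\!\to\!10^{-5}$, and a constant $10^{-3}$. Bounds are enforced by
element-wise clipping; accumulators are not reset on clipping.

**Rescue interceptor.** When a mini-batch evaluation fails, the interceptor
keeps the batch, reverts to the pre-step point, halves the step-length
multiplier $s_r$, re-applies the previous update and retries — at most ten
times, after which the local run stops (`rescue_exhausted`). After a
successful step the multiplier doubles back toward 1. The reduction and
recovery factors (0.5 and 2) are symmetric trust-region-flavoured choices.
Failure at the initial point has nothing to undo and ends the run
immediately.

**Mini-batch line-search.** Optionally, each proposed step is checked
objective-only on the *same* mini-batch: the full step first, then
quadratic-interpolation backtracking safeguarded to $[0.1, 0.5]\times$ the
previous trial length, at most three trials, accepting on simple decrease.
If no trial improves, the smallest evaluable trial is accepted anyway — in
the stochastic setting the next batch changes the objective anyway, and
always moving avoids stalling; the event count is recorded in the history.
The learning-rate schedule itself is never modified by the line-search.

**Multi-start.** Local runs start from points sampled uniformly in the
$\log_{10}$ box (100 by default). The start sampler is seeded separately
from the batch shuffles, so different optimizer settings can be compared on
identical start sets (paired ranking). A bounded L-BFGS-B run on the full
objective with the same history schema serves as the full-batch reference
comparator.

## The synthetic benchmark generator

The generator emulates calibration problems whose heterogeneity lives in
the condition table. The time-course family is a phosphorylation cascade of
$L$ activation/deactivation cycles,

$$\dot a_i = (k_{b,i} + k_{a,i}\,s_i)\,b_i - k_{d,i}\,a_i,
  \qquad s_1 = \text{dose}, \quad s_i = a_{i-1},$$

with conserved per-layer totals set by condition inputs (expression
scalings, log-uniform in $[0.2, 5]$), rate constants as the estimated
parameters, and active fractions as observables. Conditions alternate
between stimulus onset (system starts at the unstimulated equilibrium) and
washout (pre-equilibrated at the dose, stimulus removed at $t = 0$); doses
come from a log-spaced grid $10^{[-1.5,\,0.5]}$, the time grid is
$t = 1, 3, \dots, 19$. Presets reproduce the benchmark scale contract:
600 conditions $\times$ 10 records (6,000), 1,200 $\times$ 10 (12,000),
1,500 $\times$ 40 (60,000). Measurement noise is Gaussian with SD equal to
5% of each observable's dynamic range.

Several of these choices were driven by an identifiability analysis rather
than taste, and are worth recording:

* **Composite readout.** With a terminal-layer readout, the three rates of
  an upstream layer form an almost exactly flat direction: scaling them
  jointly changes only that layer's relaxation time, and the downstream
  layers low-pass that signature away, so an optimizer can speed an
  upstream layer up by orders of magnitude at negligible objective cost.
  The single-observable presets therefore read out the mean active
  fraction over all layers — a total-phospho-signal — so every layer's
  transient appears in the output directly.
* **Washout arm.** Onset data alone weakly determine deactivation
  timescales; the washout conditions measure them directly.
* **Depth of the smallest preset.** A Fisher-information analysis at the
  truth shows that with one composite observable a third tier's rate-scale
  direction stays an order of magnitude more uncertain than everything
  else under every design variant we tried, while at two layers all
  parameters are comparably well determined. The smallest preset is
  therefore a 2-layer cascade and is fully practically identifiable; the
  deeper presets intentionally retain weakly determined directions, as
  real medium-scale benchmarks do.
* **Noise level.** At 10%-of-range noise even the 2-layer fixture's rate
  scales are determined too loosely for a meaningful recovery check at
  reduced scale; 5% keeps calibration non-trivial while making the reduced
  benchmark satisfy the recovery property the test suite verifies
  (pooled over independent noise realizations, since single realizations
  can displace a layer-scale direction by a few posterior SDs).

The steady-state family (`viability_like`) emulates drug-response
calibration: viability $v$ relaxes to an equilibrium under
$\dot v = k_{\text{grow}}(1 - v) - k_{\text{kill}} E v$ with drug effect
$E = s_c \sum_d e_{\max,d}\,\text{dose}_d/(\text{EC}_{50,d} +
\text{dose}_d)$, one steady-state readout per condition (cell line
$\times$ drug $\times$ dose, plus untreated references). A condition is
*responsive* iff its readout falls below 50% of the untreated readout of
its cell line (strict inequality); ground-truth labels are emitted for ROC
testing.

What the generator does **not** emulate: model misspecification (the
fitted model is the data-generating model), non-Gaussian or
heteroscedastic-beyond-policy noise, correlated measurement errors,
missing data patterns, and the published benchmark models' exact kinetics.
Passing tests therefore demonstrate the estimation machinery, not
robustness to the full messiness of experimental data.

## Benchmark evaluation and uncertainty analysis

* **Ranking.** Paired multi-start finals are ranked per start across
  optimizer settings (ascending, ties averaged, failed runs worst-tied) and
  averaged — the mean rank is the performance proxy.
* **Value-to-reach.** The convergence threshold is the mean plus one sample
  SD (ddof = 1; with ten values the distinction is small) of the ten best
  reference finals. Convergence of mini-batch runs is checked at epoch
  boundaries on the full dataset; cost is counted in condition simulations,
  a hardware-independent proxy, with wall time secondary.
* **ROC.** Thresholds sweep the unique scores; AUC is trapezoidal (equal to
  the normalized Mann-Whitney statistic); the classification threshold is
  the point where the ROC touches a slope-1 line, operationalized for the
  discrete curve as the Youden maximizer of TPR $-$ FPR with ties broken
  toward smaller FPR; thresholds transfer to independent test scores.
* **Ensembles.** Mini-batch histories are smoothed by a centered moving
  average spanning one epoch (half before, half after, truncated at the
  ends). The cutoff is the best smoothed RMSE $\times$ 1.10, where RMSE is
  recovered from the half-sum-of-squares objective as
  $\sqrt{2J/N_{\text{records}}}$ (with heterogeneous $\sigma$ this is the
  weighted residual RMS). Admitted vectors are thinned uniformly to at most
  50 per start and epoch. Whether the cutoff derives from the smoothed or
  raw best trace is ambiguous in principle; we default to the smoothed best
  for robustness and expose a flag. Ensemble predictions report member mean
  and SD; parameter-space structure is characterized by the covariance
  spectrum (PCA) and by the SVD of the stacked output-sensitivity matrix,
  whose numerical rank (threshold $\max(\dim) \cdot \varepsilon \cdot
  \sigma_{\max}$) counts the directions the data inform.

## Problem sizes used in the test suite

The suite runs everything at desk scale, chosen so the full suite completes
in minutes on one core: objective/gradient checks on 3-6 condition
problems; the identifiability check at 60 conditions; the line-search
ablation on a 100-condition cascade (20 paired starts, 5 repetitions); the
recovery experiment at 100 conditions with 20 starts; full-size presets
(600/1,200/1,500 conditions) only for the record-count contract. The
methods themselves carry no scale assumptions beyond memory.

## Known limitations

* Forward sensitivities scale linearly in $n_\theta$; hundreds of
  parameters would want an adjoint backend behind the same contract.
* Analytic scalings cover multiplicative factors only — no offset or
  noise-parameter hierarchy.
* The line-search's "accept the smallest trial" policy trades monotonicity
  for progress; with pathological objectives it can accept mildly worse
  steps (by design, recorded in the history).
* `deSolve`'s BDF prints solver diagnostics to the console on the (intended)
  divergence fixtures; these are cosmetic.
* History-based ensembles inherit the optimizer's sampling bias; they
  characterize exploration, not the posterior.
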