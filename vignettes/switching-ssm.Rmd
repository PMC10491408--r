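---
title: "Switching state-space models: the variational machinery behind switchssm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Switching state-space models: the variational machinery behind switchssm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`switchssm` fits switching linear-Gaussian state-space models: a pool of $M$
candidate models
$$
x_t^{(m)} = F^{(m)} x_{t-1}^{(m)} + w_t^{(m)}, \qquad w_t^{(m)} \sim N(0, Q^{(m)}),
$$
whose hidden states evolve independently and in parallel from
$x_0^{(m)} \sim N(\mu^{(m)}, Q_0^{(m)})$, together with a hidden Markov chain
$s_t \in \{1,\dots,M\}$ (initial distribution $\rho$, transition matrix
$\phi$ with columns indexing the source state). At each time only the selected
candidate emits:
$$
y_t = G^{(s_t)} x_t^{(s_t)} + v_t, \qquad v_t \sim N(0, R),
$$
with the observation noise covariance $R$ shared across candidates. The time
origin convention everywhere is that $x_0$ and $s_0$ carry no observation;
$y_t$ runs over $t = 1,\dots,T$.

The joint posterior of $(\{x_t^{(m)}\}, \{s_t\})$ given $y$ is intractable:
conditioning on the observations couples the discrete chain to every
continuous state, so exact smoothing requires summing over all $M^{T+1}$
switch paths. The package implements the structured variational
approximation: the posterior is approximated by a product
$q(\{s_t\})\, \prod_m q(\{x_t^{(m)}\})$, optimized by maximizing the negative
variational free energy $F(q,\theta) \le \log p(y \mid \theta)$.

Two summary statistics tie the factors together:

* $g_t^{(m)} = -\tfrac12 \langle (y_t - G^{(m)}x_t^{(m)})' R^{-1}
  (y_t - G^{(m)}x_t^{(m)}) \rangle$ acts as the per-time log-evidence of
  candidate $m$; it is an emission weight for the chain. The common
  $\log|2\pi R|$ constant is omitted because it cancels in the chain
  posterior.
* $h_t^{(m)} = q(s_t = m)$, the responsibility of candidate $m$, scales that
  candidate's effective observation noise to $R / h_t^{(m)}$ during
  smoothing. As $h \to 0$ the measurement update is skipped exactly (the
  implementation scales the innovation precision by $h$, so nothing is ever
  divided by zero; below $10^{-12}$ the update is skipped outright).

The E-step iterates a four-step cycle until stable: forward–backward on $g$,
responsibilities from the chain marginals, per-candidate Kalman/RTS smoothing
with noise $R/h_t$, and fresh evidence from the smoothed moments. Each half
of the cycle is an exact block maximization of $F$, so $F$ is non-decreasing
over cycles (verified to $10^{-8}$ in the test suite, alongside the bound
$F \le \log p(y)$ checked against brute-force path enumeration on small
problems).

## The free energy in closed form

The free energy is assembled in closed form from the quantities the cycle
already computes:
$$
F = -\tfrac{T}{2}\log|2\pi R|
  + \sum_m \sum_t c_t^{(m)}
  - \sum_{t,m} h_t^{(m)} g_t^{(m)}
  + \log Z,
$$
where $\log Z$ is the chain's log-normalizer under emissions $g$ and
$c_t^{(m)} = \ell_t^{(m)} + \tfrac12\log|2\pi R| - \tfrac{p}{2}\log h_t^{(m)}$
combines the Kalman log-likelihood increment $\ell_t^{(m)}$ under noise
$R/h_t$ with the responsibility scaling (the combination has a finite limit,
exactly 0, for skipped steps). With $M = 1$ the expression collapses to the
exact Kalman log-likelihood; both properties are enforced by tests.

## Initializing the fixed-point iterations

The free-energy landscape has many local maxima and the cycle polarizes
responsibilities quickly, so initialization decides everything.

**Deterministic annealing** starts from equal responsibilities and divides
both $g$ and $h$ by a temperature that decays as $T_{i+1} = (T_i + 1)/2$ from
$T_0 = 100$ over 12 iterations. While the temperature exceeds 1 the recorded
free-energy trace is diagnostic only (the tempered quantities are not a valid
variational pair).

**Interpolated densities** initialize the evidence with the leave-one-out
predictive log-density $\log p^{(m)}(y_t \mid y_{\setminus t})$ of every
candidate. These are computed in $O(T)$ per candidate by a two-filter
construction: the forward one-step predictive $N(x_t \mid y_{1:t-1})$ is
fused with a backward information-form likelihood message carrying
$y_{t+1:T}$, and the fused state distribution is pushed through the
observation equation. The construction is tested to $10^{-8}$ against dense
joint-Gaussian conditioning; the $t = 1$ and $t = T$ edges fall out naturally
because an empty message is flat.

**Evidence centering.** Leave-one-out densities are normalized densities, so
candidates with different hidden dimensions are not automatically on one
scale. `init_evidence_interpolated()` can subtract each column's time mean;
by default this is done exactly when candidate state dimensions differ. Two
empirical findings from this package's own experiments shaped the defaults
downstream:

* For the two-candidate spindle model, centering is used (the richer
  candidate otherwise absorbs everything).
* For the larger nested oscillator sets, centering *over*-corrects: each
  restricted candidate's column mean is dominated by the periods where it is
  badly mis-specified, so subtracting it hands restricted candidates a large
  bonus and the full model is never selected. The uncentered leave-one-out
  density already carries a cross-validatory parsimony penalty — an inactive
  extra component inflates the predictive variance — and preserving that
  penalty is what lets the interpolated initialization keep its accuracy as
  the candidate set grows to 31, precisely the regime where annealing
  collapses. The oscillator benchmark therefore runs with centering off.
  This is a deliberate design decision in the face of an under-specified
  heuristic; the scaling benchmark asserts the resulting behavior
  directionally. At the smallest candidate set (3 candidates) annealing
  remains slightly ahead of the interpolated initialization in this
  implementation; we report this honestly rather than tuning the heuristic
  per problem size.

## Parameter learning

With the E-step fixed, all parameters have closed-form M-steps driven by the
smoothed second-moment sums $A, B, C$, the h-weighted observation outer
products, and the chain posteriors: $F = BA^{-1}$, the usual $Q$, $\mu$,
$Q_0$ updates, $\rho$ and column-normalized $\phi$ from the pairwise
posteriors, and $R$ pooled across candidates. Observation matrices are
structural and not updated by default. Alternating E- and M-steps is a
generalized EM scheme; because the interpolated initialization re-computes
the evidence at every E-step, the free energy need not be monotone across EM
iterations (a decrease beyond tolerance triggers a warning, not an error).

**Tied parameters.** Two tying mechanisms pool statistics before solving:

* Element-level tying of $F$ (with fixed entries) via the pooled normal
  equations $\sum_m S_m'(A_m \otimes Q_m^{-1}) S_m \theta
  = \sum_m S_m' \mathrm{vec}(Q_m^{-1} B_m)$ restricted to the free elements,
  plus pooled $Q$ groups. This is the stationary point of the summed
  expected complete log-likelihood over the group; singleton groups
  reproduce the untied updates bitwise. The bivariate benchmark shares
  everything across its two candidates except one coupling element.
* Label-based tying of oscillator blocks: blocks are parameterized as
  $a R(\omega)$ with isotropic noise $\sigma^2 I_2$, and the structured
  update $(\omega = \operatorname{atan2}(s, c)$,
  $a = \sqrt{c^2 + s^2}/\mathrm{tr}A$, with
  $c = \mathrm{tr}B$, $s = B_{21} - B_{12})$ is applied to block statistics
  summed over all candidates carrying the same label. The spindle model
  shares its slow block this way.

**MAP updates.** For oscillator models, `map_priors()` adds weakly
informative inverse-gamma priors on $\sigma^2$ and $R$, a Gaussian prior on
$\omega$ anchored at its initialization (default sd 1 Hz), and optionally a
lower bound on the damping $a$. The damping floor matters in the spindle
application: when no sigma-band rhythm exists, an unconstrained second
oscillator degenerates into a broadband noise absorber (damping near 0.5)
and claims spurious segments; keeping $a \ge 0.9$ preserves its identity as
a narrowband component.

## Benchmarks and what the generators do and do not emulate

`run_benchmark()` reproduces the four simulation studies end to end with the
studies' published parameters as defaults:

* `ar1_inference` / `ar1_learning`: two scalar AR(1) candidates
  ($F = 0.99/0.90$, $Q = 1/10$ for inference; $F = 0.90/0.70$, $Q = 2/10$
  for learning; $R = 0.1$; sticky binary chain, diagonal 0.95; 200 sequences
  of 200 points; learning draws each sequence's starting parameters from
  uniform ranges centered on the truth).
* `bivariate` / `bivariate_learning`: a single bivariate AR(1) whose
  coupling element $F_{12}$ switches between 0.5 and 0 — note the deliberate
  model-class mismatch: inference uses two parallel candidates while the
  generator has one state vector.
* `oscillators`: 2–5 damped oscillators ($a = 0.98$, $\sigma^2 = 3$,
  $R = 1$, 1/10/20/30/40 Hz at 100 Hz) evolving continuously, with a
  multinomial chain (diagonal 0.98) selecting which subset is observed;
  candidates are the $2^n - 1$ nonempty subsets. 10 s per sequence; the
  package's scaling study runs 50 repetitions (20 in the automated test
  suite), sufficient for the directional claims it makes.

The sleep-EEG generator (`synthesize_sleep_eeg()`) is a renewal process of
sigma-band bursts (13 Hz oscillator observed only during events of 0.5–3 s,
about 6 per minute) on a continuous 1 Hz slow oscillation with unit
observation noise. It emulates the *switching structure* of spindles, not
real EEG: no 1/f background, no artifacts, no non-stationary slow-wave
morphology, and spindle amplitude statistics far cleaner than scalp
recordings. Passing the synthetic recall/specificity/frequency-recovery
tests therefore demonstrates the pipeline's correctness, not clinical
performance.

## Numerical choices

* All covariance updates are symmetrized; innovation covariances use
  symmetric positive-definite solves, which fail loudly on degenerate
  models rather than silently regularizing.
* Message passing is entirely in the log domain with log-sum-exp; `-Inf`
  evidence is allowed (vetoing a state), and an all-vetoed time point is a
  degenerate-evidence error.
* E-step convergence: `max |Δh| < 1e-6` and relative `ΔF < 1e-8`, or the
  first decrease of $F$, capped at 50 iterations (12 for the benchmark runs
  that mirror the published comparison). EM convergence: relative
  `ΔF < 1e-5`, capped at 50 iterations; in practice the AR(1) learning
  benchmark converges in roughly 5–10.
* Interpolated densities require positive-definite $Q$ and $R$ (the
  backward pass uses their inverses).
* Segmentation labels: 0.5 threshold on the first candidate's posterior for
  $M = 2$, argmax otherwise; a best-permutation scoring mode exists but the
  benchmarks anchor candidate identity by initialization near the truth.
* Baselines that merge states (`static_switching` probability floor 0.01,
  `imm`, `shumway_stoffer_merge`) require a common state dimension; nested
  oscillator candidates are mapped onto the union of blocks, with absent
  blocks evolving unobserved.

## Known limitations

* Missing observations, control inputs, and non-Gaussian emissions are out
  of scope; so is learning the number of candidates $M$.
* The static multiple-model baseline follows the classical fixed-hypothesis
  estimator with a standard probability floor; the floor value (0.01)
  trades adaptivity against stickiness and is exposed as an argument.
* The spindle detector's event gate requires the learned sigma-band
  component to sit inside `spindle_band` (default 11–16 Hz); on recordings
  whose spectrum genuinely lacks a sigma peak the detector reports no
  events by design.
* EDF input is not supported; supply plain CSV (samples plus a sampling
  rate, or time/value pairs).

## A worked example

```{r example}
library(switchssm)

model <- ar1_switching_model()          # the two-AR(1) benchmark model
sim <- simulate_switching(model, 200, seed = 1)

est <- fixed_point_estep(model, sim$y,
                         estep_config("interpolated", max_iter = 12))
segmentation_accuracy(est$h, sim$s)
autoplot(est)

fit <- vbem(model, sim$y, estep_config("interpolated"), em_config())
tidy(fit)
glance(fit)

eeg <- synthesize_sleep_eeg(duration_s = 30, fs = 100, seed = 42)
det <- detect_spindles(eeg$y, fs = 100)
det$events
autoplot(det)
```
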