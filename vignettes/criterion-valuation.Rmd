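---
title: "Valuing decision criteria under signal and payoff uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing decision criteria under signal and payoff uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdtvalue)
```

## The model

`sdtvalue` treats a binary detection decision as the joint product of three
environmental parameters: the perceptual similarity of the two
signal-generating categories, their relative base rate, and the payoffs
attached to the four possible outcomes.

**Signals.** A *target* category emits signals from `N(mu_target,
sigma_target^2)` with probability `base_rate` (alpha); a *foil* category
emits from `N(mu_foil, sigma_foil^2)` otherwise. The signal axis is
one-dimensional and its units are opaque — percent chance of rain, scowl
intensity, a biomarker level. An observer holds a criterion `x` and responds
"target" whenever the signal falls at or beyond it on the target side
(ties, a measure-zero event for continuous signals, count as target
responses). Crossing category with response yields the four outcomes:
correct detection (CD), missed detection (MD), false alarm (FA), correct
rejection (CR), with probabilities given by Gaussian tail integrals
(`outcome_probabilities()`).

**Value of a criterion.** With payoffs `h, m, a, j` for CD, MD, FA, CR, the
long-run average payoff of holding criterion `x` is

    EV(x) = alpha*h*p[CD](x) + alpha*m*p[MD](x) +
            (1-alpha)*a*p[FA](x) + (1-alpha)*j*p[CR](x)

(`ev_at_criterion()`). Its argmax is the optimal criterion
(`optimal_criterion()`). For equal variances the optimum satisfies a
likelihood-ratio condition: the target/foil density ratio at the optimum
equals `beta* = (1-alpha)(j-a) / (alpha(h-m))`, giving the closed form
`x* = (mu_t+mu_f)/2 + sigma^2 log(beta*) / (mu_t-mu_f)`. The grid-based and
closed-form routes are implemented independently and cross-checked in the
test suite; they agree to far better than 0.05 signal units.

**Degenerate limits.** As the category separation grows, misclassification
probabilities vanish and `EV(x)` flattens to the constant
`alpha*h + (1-alpha)*j` (`no_uncertainty_value()`): riskless economic choice
between two distinct options is the zero-perceptual-uncertainty corner of
the same model. Conversely a flat payoff matrix makes every criterion
equally good; `optimal_criterion()` flags this with `tied = TRUE` and
reports the smallest grid optimum.

**Subjective weighting.** Two generalizations replace the objective
quantities with psychologically transformed ones
(`utility_at_criterion()`):

* *value-weighted*: payoffs pass through a prospect-theory value function
  `V`, probabilities stay objective;
* *fully weighted*: additionally a base-rate weight `B` is applied to
  `alpha` and `1-alpha`, and a signal-probability weight `S` to each of the
  four outcome probabilities.

Each of the four probabilities is weighted independently, exactly as the
weighted sum is written: `S(p[CD]) + S(p[MD])` need not equal 1 afterwards,
and `B(alpha) + B(1-alpha)` need not either. We deliberately do not
renormalize — the non-additivity of decision weights is a substantive
feature of prospect-theory weighting, not a numerical defect. A
`complementary = TRUE` flag exists for sensitivity analyses that prefer
complement-consistent weights. An alternative reading would apply `S` to the
observer's representation of the signal *distributions* rather than to the
computed outcome probabilities; we implement the literal probability-level
weighting and leave the distribution-level variant as an extension point.

## Parameters and defaults

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `gain/loss exponent` (γ) | value-function curvature, in (0, 1] | 0.88 | canonical published calibration of the power value function |
| `loss_aversion` (λ) | loss multiplier, > 0 | 2.25 | same source; makes losses loom ~2× larger |
| `reference` (r) | gain/loss reference point | 0 | status-quo framing; configurable per analysis |
| `delta` (δ) | inverse-S weighting curvature, in (0.28, 1] | 0.61 | canonical gain-domain estimate; below ~0.28 the form loses monotonicity, hence the hard bound |
| `base_rate` (α) | target prevalence, in (0, 1) | 0.5 | balanced problems are the natural reference case |
| grid `n` | criterion grid resolution | 2001 | resolves the domain to ~0.01 sigma before refinement |

The theory itself leaves the shapes of `u`, `V`, `B`, and `S` open to
empirical determination; the defaults here are the standard published forms,
fully declared in every serialized configuration so no behavior is silent.
Probability weighting is applied to stated probabilities independently per
outcome (the non-cumulative form); rank-dependent cumulative weighting is
out of scope.

The expected-utility mode (`weighted_valuation(..., mode = "utility")`)
needs a utility function over signed payoffs although classical treatments
only sketch its shape; we adopt power utility with sign preserved,
`u(v) = sign(v)|v|^0.88`, as a declared convention.

## Numerical choices

* Tail probabilities use `pnorm(..., lower.tail = FALSE)` — the
  complementary-error-function path, accurate to ~1e-15 — never quadrature;
  quadrature appears only as the independent oracle in the tests.
* Grid optimization refines the grid argmax with Brent search
  (`stats::optimize`, tol 1e-6) inside the bracketing interval. The
  expected-value function is unimodal for well-posed payoffs (its derivative
  changes sign exactly once, where the likelihood ratio crosses `beta*`), so
  bracketing the grid argmax is sufficient.
* Environments with `mu_target < mu_foil` are handled by flipping the axis
  internally (the response rule becomes "target iff signal <= criterion");
  all reported criteria stay in user coordinates.
* Unequal variances are supported with two declared conventions: `beta` is
  the actual density ratio at the criterion, and `d_prime` standardizes by
  the root-mean-square of the two standard deviations.
* Domain bounds must enclose both means ± 6 standard deviations, so grid
  searches cannot silently truncate an interior optimum (for well-posed
  payoff ratios the closed-form optimum lies within ± 6 sigma of the
  midpoint).
* Count-based estimates default to the log-linear correction (add 0.5 per
  cell, 1 per denominator): finite estimates with small, well-characterized
  bias. The uncorrected path errors loudly at boundary rates rather than
  returning infinities.

## The simulator and what the tests show

`simulate_trials()` draws all category labels first, then all signals, from
one seeded generator per call, so a (environment, payoffs, criterion, n,
seed) tuple reproduces a byte-identical trial CSV on any platform with R's
default generator. The simulated observer is *deterministic* given its
criterion — all response variability comes from signal noise.

`fit_observer()` recovers parameters two ways. The count-based route applies
the corrected-rate closed forms and maps the bias `c` back to signal units.
The trialwise route maximizes the Bernoulli likelihood of responses given
signals under a probit response rule with a criterion-jitter scale `tau`.
Deterministic responders make this likelihood degenerate — any criterion
inside the gap between the largest "foil"-response signal and the smallest
"target"-response signal attains the supremum as `tau -> 0` — so the fit
detects separability and reports the gap midpoint exactly, flagging
convergence; the numeric search (L-BFGS-B, three jittered starts, bounded
`tau`) engages only for genuinely noisy response data, where both the
criterion and `tau` are informative.

The simulation-based tests run at n = 10,000 trials for parameter recovery,
n = 200,000 for mean-payoff convergence, and 100 replicates of n = 2,000
for the bias check — sizes at which binomial standard errors are small
enough to make ±0.1 on `d'` and ±1 signal unit on the criterion meaningful
bands.

What passing these tests shows: the implementation's probabilities, optima,
and estimators are mutually consistent and recover their own generating
process. What it does not show: that real observers behave like this. The
generator emulates a stationary, memoryless, deterministic-criterion
observer with exactly Gaussian signals; real data exhibit criterion drift,
sequential dependencies, lapses, and non-Gaussian signal distributions, none
of which are modeled. `fit_weighting_grid()` is correspondingly labeled
experimental: many weighting-parameter combinations imply the same optimal
criterion, so choice data of this kind identify a compatibility region at
best.

## Design decisions worth knowing

* The value function is concave over gains and convex over losses (with
  exponents below 1), the standard prospect-theory shape; both curvatures
  and the loss-aversion multiplier are user-settable, so other shapes are
  expressible by configuration.
* Payoff matrices tolerate `h = m` or `j = a` at construction so degenerate
  diagnostics (flat payoffs) can be expressed, but the closed-form solver
  rejects them because `beta*` is then undefined.
* The envelope's "mean" curve uses the mean payoff matrix supplied by the
  user (for the commuting example, the equal-weight average false-alarm
  cost); variant weighting beyond min/mean/max is left to the caller.
* Outcome labels ("bike", "drive", ...) are user-facing strings only; the
  model sees categories, responses, and the payoff matrix.

## Limitations

Single perceptual dimension; Gaussian signals only (non-Gaussian families
are an extension point); static criteria (no learning or sequential
updating); non-cumulative probability weighting; no response-time modeling.
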