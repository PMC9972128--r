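---
title: "Methods: adaptive forced-choice testing under the Thurstonian IRT model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive forced-choice testing under the Thurstonian IRT model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fccat)
```

## The measurement problem

Forced-choice (FC) questionnaires ask respondents to choose between
simultaneously presented items rather than to rate each item on its own
scale, which blunts uniform response biases and some deliberate distortion.
Classical scoring of FC blocks yields ipsative scores; IRT modeling of the
comparative judgments restores normative, interpersonally comparable trait
scores. `fccat` implements the pairwise Thurstonian IRT (TIRT) model for
*dominance* items — items whose endorsement propensity is monotone in their
trait — together with everything needed to run and study a computerized
adaptive test (CAT) built on it: information accounting, Bayesian scoring,
constrained item selection, static-optimal assembly, and a simulation
harness.

## Response model

Item $i$ carries a normally distributed latent utility with mean $\mu_i$,
a single signed loading $\lambda_i$ on its trait $s_i$, and uniqueness
$\psi_i^2$. The first item of a cross-trait pair $\{i,k\}$ is preferred
when its utility realization exceeds the other's, giving the probit form

$$P(Y_{ik}=1\mid\eta)=\Phi\!\left(\frac{\mu_i-\mu_k+
(\lambda_i-\lambda_k)^\top\eta}{\sqrt{\psi_i^2+\psi_k^2}}\right).$$

Because every item loads on exactly one trait, $(\lambda_i-\lambda_k)$ has
two nonzero entries; the model is antisymmetric in the pair order and
invariant to a common shift of both utilities, properties the test suite
checks directly. Response simulation clamps $|z|$ at 8 before the Bernoulli
draw so that simulated streams never become exactly deterministic.

## Information and precision

The pair's Fisher information in the trait metric is the rank-one matrix
$F_{ik}(\eta)=\phi(z)^2\,(\lambda_i-\lambda_k)(\lambda_i-\lambda_k)^\top/
[p(1-p)(\psi_i^2+\psi_k^2)]$; test information is the sum over administered
pairs, and adding the prior precision $\Sigma^{-1}$ of the multivariate
normal trait prior yields the posterior information, positive-definite even
before any response. Per-trait precision is reported as the *directional*
SEM $\sqrt{(I_{\mathrm{post}}^{-1})_{ss}}$ — from the inverse's diagonal,
not $1/\sqrt{I_{ss}}$, so cross-trait correlations are respected. The
implementation clamps response probabilities to $[10^{-10},1-10^{-10}]$
inside information and likelihood denominators; the Bernoulli-variance
denominator otherwise degenerates for extreme $z$.

A pair's information (the nonzero eigenvalue of $F$) peaks exactly where
the comparison is an even call, $z=0$, i.e. on the hyperplane
$\mu_i-\mu_k+\lambda_i\eta_{s_i}-\lambda_k\eta_{s_k}=0$
(`information_peak_locus()`). This geometry explains the cost of
desirability balancing: a threshold $T$ on $|\mu_i-\mu_k|$ restricts the
eligible pairs to those whose peak-information band passes near trait
combinations with $|\lambda_i\eta_{s_i}-\lambda_k\eta_{s_k}|\le T$, so
strict thresholds narrow the regions of the trait space that can be
measured efficiently.

## MAP scoring

Scores maximize the log posterior (Bernoulli likelihood plus MVN prior).
The optimizer is damped Newton on the negative log posterior with the
analytic gradient and the Fisher-information-plus-prior-precision matrix as
Hessian surrogate — always positive-definite, so steps are well defined —
with backtracking halving when a step fails to improve the objective.
Defaults: gradient max-norm tolerance $10^{-6}$, 100 iterations, cold start
at the prior mean, warm start at the previous interim estimate inside CAT.
Non-convergence is flagged on the result rather than raised, because an
adaptive session must proceed block to block. The analytic gradient is
validated in the tests against central finite differences, and full MAP
solutions against an exhaustive grid search on two-trait toys
($[-4,4]^2$, step 0.005, agreement within 0.01 per coordinate).

## Adaptive selection and static assembly

At each step the engine enumerates all cross-trait pairs of remaining items
satisfying $|\mu_i-\mu_k|\le T$ and picks the one minimizing the Bayesian
A-optimality criterion
$\mathrm{tr}[(\Sigma^{-1}+I_{\mathrm{test}}+F_{\mathrm{cand}}(\hat\eta))^{-1}]$
at the interim estimate — the total posterior error variance across traits.
Score ties within relative tolerance $10^{-12}$ are broken uniformly at
random from the seeded stream, so sessions are reproducible. Re-estimation
happens after every block, and the accumulated test information is
re-evaluated at the refreshed interim estimate.

Two implementation choices matter for speed and are covered by equivalence
contracts in the tests. First, the eligible pair table is enumerated once
per session and filtered by a liveness mask as items are consumed —
output-identical to re-enumerating from scratch each step. Second,
candidate scores use the Sherman–Morrison rank-one identity
$\mathrm{tr}[(A+guu^\top)^{-1}]=\mathrm{tr}(A^{-1})-g\,u^\top A^{-2}u/(1+g\,u^\top A^{-1}u)$,
with $u$ two-sparse; the tests require agreement with explicit inversion to
$10^{-10}$. A full 120-pair session on the default 279-item bank runs in
well under a second.

Static-optimal forms (`assemble_static_test()`) run the identical greedy
loop with the interim estimate pinned at the origin and no responses: a
fixed test optimized block-by-block for the average member of the
population, which is the natural operational baseline for judging what
adaptivity itself buys.

## The synthetic item bank

No per-item parameters are distributed with the package, so
`synthesize_bank()` builds banks that match the published *summary*
description of a six-scale (HEXACO) adjective pool: 279 items, per-scale
counts between 24 and 81, per-scale absolute discriminations
$|\lambda/\psi|$ with means H 0.49, E 0.52, X 0.68, A 0.61, C 0.61, O 0.49
over the published per-scale ranges, and mean utilities with sample mean
3.61 and SD 1.54 on $[1.22, 5.80]$. Choices made where only summaries are
printed:

* **Per-scale counts** are fixed at H 36, E 45, X 81, A 48, C 45, O 24 —
  summing to 279 and attaining the stated 24–81 range; the true allocation
  is not published.
* **Utilities** are drawn from a scaled Beta on $[1.22, 5.80]$
  moment-matched to mean 3.61 and SD 1.54. A truncated normal on that
  interval cannot reach SD 1.54 (any unimodal-normal truncation is bounded
  by the uniform limit $\approx 1.32$), whereas the moment-matched Beta is
  mildly U-shaped — which is also the psychologically plausible shape:
  trait adjectives tend to be clearly desirable or clearly undesirable,
  rarely neutral.
* **Discriminations** are drawn per scale from a scaled Beta over the
  published $[\min,\max]$ (concentration 6) and shift-corrected until the
  sample mean is within 0.005 of the published mean; loadings and
  uniquenesses then follow the unit-variance standardization
  $\lambda=d/\sqrt{1+d^2}$, $\psi^2=1/(1+d^2)$, matching a calibration that
  fixes trait variances at 1.
* **Keying**: 30% of items per scale are negatively keyed, assigned at
  random and independently of utility. Real banks correlate keying with
  desirability (undesirable adjectives are usually reverse-keyed), so
  synthetic banks are, if anything, slightly *more* permissive for
  desirability-balanced pairing of mixed-keyed items than a real pool
  would be.

What passing tests on these banks show — full-length feasibility under the
strict constraint, the adaptive-over-static and lenient-over-strict
precision ordering — are properties of the engine under a realistic bank
geometry; they do not certify any particular operational item pool.

## Trait population

The published calibration covariances are not available, so
`default_prior()` uses unit trait variances with a fixed, modest
HEXACO-style intercorrelation pattern (absolute correlations 0.1–0.3,
eigenvalues checked positive). Quantitative SEM/COR/RMSE levels depend on
this choice; the simulation harness therefore asserts effect *directions*
and monotone trends, never magnitudes.

## Simulation design

`run_simulation()` crosses adaptive/static selection with desirability
thresholds (strict 0.5, lenient 1.0, none) under **matched seeds**: one
master seed deterministically spawns the simulee draw and one response
stream per simulee, reused across conditions, so condition contrasts are
paired and their Monte-Carlo SEs (leave-one-simulee-out jackknife on the
paired difference) are sharp. Defaults mirror the reference design — 2,000
simulees, 120 pairs, metrics every 10 blocks. The package's own validation
runs use 500 simulees with checkpoints every 12 blocks for the
four-condition comparison, and 50 sessions for the strict-feasibility
check; at those sizes every directional contrast is already resolved at
several jackknife SEs.

## Numerical caveats

* **SEM trajectories.** With information evaluated at a *fixed* trait
  value, posterior information only grows and every SEM coordinate is
  nonincreasing (Loewner ordering) — exactly true for origin-pinned static
  assembly, and asserted exactly in the tests. Along an adaptive session,
  however, the SEM is re-evaluated at the moving interim MAP estimate, so
  individual steps can tick upward by up to about $10^{-2}$ early in a
  session; checkpoint means across simulees move by at most a few
  $10^{-4}$. The tests therefore allow a small estimate-movement slack
  (0.01 per-step within a session, $2\times10^{-3}$ on checkpoint means)
  rather than pretending strict monotonicity holds where it cannot.
* **Degenerate inputs.** Empty response sets score to the prior mean with
  prior SEMs; pairs with identical loading vectors carry zero information
  and leave MAP at the prior mean; unanimous response patterns stay finite
  thanks to the prior; pool exhaustion truncates a session with a flagged
  reason (and exit code 3 at the CLI) instead of failing.
* **Ties.** Cloned items produce bitwise-equal A-optimality scores; the
  seeded uniform tie-break keeps sessions reproducible while avoiding a
  systematic lexicographic bias.

## Limitations

Only pair blocks are supported (triplets/quads, which extract more
information per block, are out of scope), selection relies on interim point
estimates rather than full-posterior criteria, and simulees respond
honestly — socially desirable responding is represented only through the
design constraint, not as a behavioral model. Desirability is proxied by
item mean utility throughout, as is conventional when direct desirability
ratings are unavailable.
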