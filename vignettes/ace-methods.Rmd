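---
title: "Methods: the accumulated copying error model and its analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the accumulated copying error model and its analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acemodel)
```

## The model and its assumptions

The accumulated copying error (ACE) model treats the repeated manual
copying of a quantitative artifact attribute — here size, in cm — as a
multiplicative random walk. Each generation of a transmission chain copies
the previous generation's value and introduces an error it cannot
perceive. Two assumptions fix the functional form:

* **Proportional error (Weber's law).** Perceptual thresholds scale with
  the magnitude of the stimulus, so the error enters as a dimensionless
  *ratio*, multiplying the previous value rather than adding to it.
* **Normal error (central limit).** Each individual's error ratio is the
  aggregate of many small perceptual and motor contributions, so it is
  modelled as normal with mean 1 (no systematic bias) and standard
  deviation `sigma`.

Thus `X_t = X_{t-1} * eps_t` with `eps_t ~ i.i.d. N(1, sigma^2)`, and
because `E[eps] = 1` and `E[eps^2] = 1 + sigma^2`,

$$
\mathrm{E}[X_t] = x_0, \qquad
\mathrm{Var}[X_t] = x_0^2\left[(1+\sigma^2)^t - 1\right].
$$

The mean is conserved for every horizon while the variance grows
exponentially at rate `log(1 + sigma^2)`. For small `sigma` and moderate
`t` the variance is close to the linearised `x0^2 * t * sigma^2` (within
5% for `sigma <= 0.05`, `t <= 10`), which is why alternative published
formulations of the model agree numerically over experimental horizons.
Generation 0 denotes the seed value itself; the first copy is generation 1.

The walk is strongly right-skewed: the log-size drifts at
`t * E[log eps] ≈ -t * sigma^2 / 2`, so the *median* chain shrinks while
the mean is held constant by a minority of chains that grow very large.
This is not a contradiction but the signature of a multiplicative process,
and `simulate_ensemble()` reproduces it (tested at 10,000 chains over 400
generations).

### Negative values and truncation

A normal ratio can in principle be negative. `truncated_error_moments()`
quantifies why this is irrelevant at human copying precision: for
`N(1, sigma^2)` truncated below at 0 the truncation point sits `1/sigma`
standard deviations below the mean — about 29 sd at `sigma = 0.0343` — so
the truncated mean and sd differ from `(1, sigma)` by less than `1e-50`.
The closed-form moments therefore use the untruncated normal. The
*simulator* instead rejects and resamples non-positive draws (rather than
truncating or aborting), logging the count in `resample_count`; over any
realistic run the count is zero, and the log makes a non-zero incidence
visible rather than silent.

## The simulator

`simulate_ensemble(x0, sigma, n_chains, T, seed)` simulates independent
chains with one seeded random stream per ensemble, draws consumed
chain-major (all generations of chain 1, then chain 2, ...). The same
arguments always produce bit-identical ensembles, which the test suite
relies on throughout. Cross-chain summaries use the sample (n−1) variance,
matching how between-chain variance is estimated in experiments.

`pooled_cv()` pools every value produced in generations `1..T` by every
chain and returns sd/mean. The seed generation is excluded by default: the
seed is an experimenter's constant, not a produced artifact (an
`include_seed` flag exists for sensitivity analysis). An internal
cumulative-sum variant returns the pooled CV at *every* horizon up to `T`
from a single pass, which shapes the calibration design below.

## Analysing a transmission-chain experiment

The canonical experiment is two conditions × 10 chains × 10 generations:
each participant resizes an on-screen handaxe image to match the previous
participant's, starting from a 10 cm seed on a 14.4 cm screen. The two
conditions differ only in the initial size of the image the participant
resizes ("larger" = screen-height, "smaller" = a third of it), which should
be irrelevant under the model — making the condition contrast a built-in
probe for bias. Records are stored long-format (condition, chain,
generation, target size, produced size); heights only, since width is a
fixed 7/15 of height. The validator checks the screen bound, the seed size
and chain linkage (each target equals the previous produced size);
linkage uses a relative tolerance of 1e-6 and degrades to warnings for
externally produced files, where rounding can break exact equality.

* **Copying error per event** is the produced/target ratio; under the
  model these are i.i.d. `N(1, sigma^2)`, so `estimate_sigma()` is the
  sample sd of the ratios. An "overall" sigma is ambiguous when conditions
  have different means, so the pooled scope reports both defensible
  summaries — the sd of all ratios about the grand mean and the mean of
  the per-condition sds — rather than guessing silently.
* **Normality** is assessed with the Anderson–Darling test in its
  composite form (mean and variance estimated from the sample, Stephens'
  case 3, with the `A^2 (1 + 0.75/n + 2.25/n^2)` small-sample adjustment).
  Published A statistics are only comparable if the variant is known, so
  the variant label travels with the result. The computation is delegated
  to `nortest::ad.test()`; the test suite verifies the statistic against
  an independently coded brute-force evaluation of the A² order-statistic
  sum to 1e-10.
* **Model fit** is tested on the final-generation cross-chain mean and
  variance via Monte-Carlo empirical p-values: simulate the experiment's
  design under the null many times (default 10,000, fixed documented
  default seed, both overridable) with the condition's own estimated
  sigma, and report the proportion of simulated statistics at least as
  extreme as the observed one, one-sided, ties counting as extreme. The
  reference point is the closed-form prediction (`x0` for the mean,
  `expected_variance()` for the variance).

One statistical subtlety is made explicit in the interface. With
`direction = "auto"` the test direction is chosen from the sign of the
observed deviation; that selection means either tail can trigger a small
p-value, so a true null is rejected at about *twice* the nominal level —
a property of any sign-picked one-sided test, not an implementation
artifact. With the direction fixed in advance (`"above"`/`"below"`) the
p-value is uniform under the null, and that is how the package's
calibration tests assess it (200 null draws at 2,000 simulations each;
the fraction below 0.05 must sit within 0.05 ± 0.04).

## Calibration against assemblage-level variation

Archaeological size variation is summarised by the CV of an artifact
dimension pooled across many sites and ages — 0.30 for length and 0.23
for breadth in a database of 2601 Acheulean handaxes spanning roughly 1.2
million years. The calibration module asks the model two questions, both
through the pooled CV of a simulated ensemble of 100 chains started at
`x0 = 1` (the scale of the published one-line simulation this mirrors; the
pooled CV is scale-free in `x0`):

* `generations_to_cv(sigma, cv_target)`: the smallest horizon at which the
  pooled CV reaches the target.
* `sigma_for_cv(T, cv_target)`: the copying-error sd that makes the pooled
  CV hit the target at a fixed horizon, solved by bisection.

No analytic expression for the pooled CV is attempted — the pooled values
are a mixture over generations of increasingly skewed lognormal-like
variables — so both operations are simulation-based, and three design
choices make them deterministic enough to test:

* **Median over 25 seeded replicates.** A single 100-chain run has
  noticeable seed-to-seed spread in its pooled CV (the replicate range is
  reported in every result). The median over 25 replicates with seeds
  derived from one base seed removes the seed lottery while preserving
  the scale of the underlying procedure. 25 is a compromise: spread
  estimates stabilise while the 60,000-generation bisection stays at a
  few minutes on one CPU.
* **Full scan instead of doubling search.** The pooled CV at every
  horizon up to `max_T` falls out of one cumulative-sum pass per
  replicate, so `generations_to_cv` simply scans all horizons — exact,
  and no more expensive than a search that recomputes per horizon.
* **Common random numbers for bisection.** Replicate seeds are held fixed
  across sigma evaluations, making the median pooled CV a smooth,
  increasing function of sigma (the monotonicity is tested on a sigma
  grid), so bisection is valid. The solver starts from the small-sigma
  approximation `CV ≈ sigma * sqrt((T+1)/2)`, expands to a bracket, and
  stops when the achieved CV is within 2% (relative) of the target; an
  unreachable target is a reported condition, not an exception.

At one generation the pooled values are i.i.d. `N(x0, x0^2 sigma^2)`, so
`CV → sigma`; this analytic anchor is used as a solver test. Generation
counts convert to years at 20 years per generation (the conventional
figure for hominin generations), so 200 generations ≈ 4,000 years and
60,000 generations ≈ 1.2 million years.

## The synthetic experiment generator

`generate_experiment()` emulates the canonical resizing experiment:
produced = target × `r` with `r ~ N(1 + bias[condition], sigma^2)`,
sizes clipped to the screen (0, 14.4] cm with clip events counted. The
default `sigma = 0.0343` is a typical measured human copying-error sd for
this task, close to the canonical 3% Weber fraction for line length; at
that scale clipping never occurs in practice. The per-condition `bias`
shifts the *mean error ratio* additively — the simplest mechanism
consistent with the multiplicative model — producing geometric drift of
the condition mean (`x0 (1+b)^g` after `g` generations). Its default is 0;
the magnitude of any real initial-size bias is an open empirical question,
so no other value is baked in. `generate_biased_pair()` wires the
direction convention (larger condition drifts up, smaller drifts down)
used when testing that the final-mean p-value flags a bias the
final-variance p-value should not.

What the generator deliberately does *not* emulate: participant-level
heterogeneity in copying precision (one global `sigma`), within-chain
correlation of errors (independence is a model assumption, not an
established fact about people), rounding of recorded sizes, and any
device-specific artifacts of the touch-screen task. Tests passing on
synthetic data therefore demonstrate that the pipeline is correct and
well-calibrated *under the model's own assumptions*, not that real
participants satisfy them.

## Numerical and testing choices

* Closed-form moments are evaluated directly, not by series expansion;
  for extreme horizons the variance may overflow, which surfaces as `Inf`
  with a warning rather than silently saturating.
* Degenerate inputs are first-class: `sigma = 0` gives constant chains, a
  zero pooled CV and a "not reached" calibration; single-chain ensembles
  refuse variance summaries (n−1 denominator); all-equal samples refuse
  the normality test.
* Monte-Carlo assertions in the test suite use 3–4 standard-error bands
  around closed-form oracles, with the variance's standard error taken
  from fourth central moments (no normality assumed). Typical problem
  sizes: 10^5 chains for moment checks, 10^4 × 400 generations for the
  skew/conservation properties, 500 replicate datasets for
  sigma-recovery coverage, 200 × 2,000 simulations for p-value
  calibration, and 25 × 100 × 60,000 for the archaeological inversion.
* Every stochastic result object (ensembles, calibrations, p-values)
  carries the seed and parameters needed to regenerate it exactly.

## Limitations

The model assumes unbiased, independent, homoscedastic-in-ratio copying
along isolated chains. Real transmission adds branching and convergence
between lineages, population structure, selective retention, and — as the
biased generator anticipates — systematic pulls from production mode
(additive vs reductive) or task framing. The calibration comparisons
treat archaeological CVs as single printed scalars and ignore their
spatial and temporal substructure; conclusions are correspondingly
assemblage-scale. Within those limits, the package's claim is narrow and
testable: given a measured perceptual copying error, the ACE null fixes
how fast pooled size variation must accumulate, and both directions of
that calculation are reproducible here to stated tolerances.
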