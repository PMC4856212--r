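---
title: "Methods: Bayesian regression discontinuity designs in bayesrd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian regression discontinuity designs in bayesrd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The design

A regression discontinuity (RD) design exploits a guideline that assigns
treatment by whether a continuous score `X` crosses a threshold `x0`.
The running scenario is statin prescription at a 10-year cardiovascular
risk score of 20% (`x0 = 0.2`), with LDL cholesterol (mmol/l) as the
outcome. The threshold indicator is `Z = 1(X >= x0)` — inclusive at the
boundary, because the guideline recommends treatment at the threshold
itself. When prescribers follow the rule exactly the design is *sharp*
and the outcome jump at the threshold is the average treatment effect
(ATE); when adherence is partial the design is *fuzzy* and `Z` is a
binary instrument for treatment `T`, giving the local average treatment
effect

    LATE = [E(Y|Z=1) - E(Y|Z=0)] / [E(T|Z=1) - E(T|Z=0)] = Dbeta / Dpi.

Because `|Dpi| <= 1`, the LATE always has magnitude at least that of the
outcome jump; the two coincide in the sharp limit `Dpi = 1`.

Identification rests on five assumptions. Instrument relevance (`Z`
associated with `T`) is directly testable and
`test_instrument_association()` tests it. Continuity of the conditional
outcome surface is partly testable on *observed* covariates;
`covariate_continuity()` checks for a jump in a covariate at the
threshold. The remaining three — independence of the guideline from
patient characteristics, unconfoundedness (subjects cannot manipulate
their side of the threshold), and monotonicity (no prescriber
systematically inverts the rule) — involve unobserved quantities and
cannot be tested from the data; `assumptions_report()` states this
explicitly rather than inventing tests for them.

## The Bayesian models

**Outcome (numerator).** Within a bandwidth `h` of the threshold, for
sides `l = b` (below) and `l = a` (above):

    y_il ~ Normal(beta0l + beta1l * xc_il, sigma^2),   xc = x - x0,
    beta0a = beta0b + phi.

A single `sigma` is shared across the two sides; the centred regressor
makes the intercepts the expected outcomes at the threshold, so the jump
`phi` *is* the ATE. Every Normal prior is parameterised by mean and
**variance**. Two presets are offered for the jump: weakly informative
`phi ~ N(0, 2)` (*wip*, a sceptical null-centred prior the data can
overwhelm) and strongly informative `phi ~ N(-2, 1)` (*sip*, encoding
the trial consensus of a roughly 2 mmol/l LDL reduction). The remaining
hyperparameters are implementation defaults chosen to keep prior
predictive LDL in a plausible 1–7 mmol/l range: `beta0b ~ N(3.5, 4)`,
slopes `~ N(0, 100)`, and `sigma ~ Uniform(0, 5)` on the standard
deviation scale. All of them are exposed in `prior_spec()`.

**Treatment (denominator).** Counts of treated subjects per side follow
`sum(t) ~ Binomial(n_l, pi_l)`. The *unc* preset places independent
`Beta(1, 1)` priors on each `pi_l`; the *fdp* (flexible difference)
preset places `logit(pi_a) ~ N(2, 1)` and `logit(pi_b) ~ N(-2, 1)`,
concentrating prior mass on a substantial gap without fixing it, while
keeping all of (0, 1) reachable on both sides
(`prior_predictive_denominator()` visualises this).

**Composition.** The outcome and treatment likelihoods share no
parameters, so the joint posterior factorises and the LATE is computed
draw-by-draw, `LATE_i = phi_i / dpi_i`, pairing draw `i` with draw `i`.
This is equivalent to a single joint MCMC run and considerably simpler.
Draws with `|dpi|` below a configurable floor (default 0.01) are
*counted and reported, never removed*: with a weak instrument the ratio
genuinely explodes, and a sanitised posterior would hide precisely the
pathology the analyst needs to see.

**Sampling.** Models run in JAGS through `rjags`, with the `glm` module
loaded for block-conjugate updates of the regression coefficients.
Defaults: 4 chains, 2000 warmup (half adaptation, half burn-in) and
2000 kept iterations per chain. Chain seeds are derived
deterministically from one user seed, so every fit is exactly
reproducible. Convergence is summarised per parameter by a split-chain
potential scale reduction statistic (each chain split in half) and
effective sample size; fits with split R-hat above 1.05 carry an
explicit warning attached to the result.

**Frequentist baseline.** `ols_ate()` fits the same two-segment model
by least squares; the estimate is the intercept difference, the
standard error combines the two independent sides, and the 95% interval
uses the normal multiplier 1.96 (at RD sample sizes the t correction is
negligible, and the choice is stated rather than hidden). An algebraic
identity — the split fit equals the `y ~ z*xc` interacted regression
evaluated at the threshold — is exploited as a test oracle. No
frequentist LATE is provided; the Bayesian ratio is the point of the
package.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure of a UK
primary-care statin extract without requiring any data download:

- `X ~ Beta(2, 6)`: a right-skewed risk score on [0, 1] with mode near
  0.17 and appreciable mass around the 0.2 threshold — plausible for a
  male 50+ primary-prevention population. This distribution is a
  declared stand-in, not an estimate from real records.
- `U ~ N(0, 1)`: one unobserved confounder playing the role of HDL
  cholesterol, predictive of both prescription and outcome.
- `logit P(T=1) = -gz/2 + gz*Z + gu*U + 0.5*(X - x0)` with
  `gz = 4.4` (strong instrument) or `1.2` (weak), and `gu = 0.2`
  (confounding levels 1–2) or `3.5` (levels 3–4). Centring the
  intercept at `-gz/2` makes the two sides symmetric around 0.5, so
  increasing `gu` genuinely erodes the treatment-probability gap. The
  instrument coefficient is constrained non-negative, so monotonicity
  (no defiers) holds by construction, and `Z` never enters the outcome
  equation directly.
- `Y = 3.5 + 2*(X - x0) - tau*T + lambda*U + eps`, `eps ~ N(0, 0.8^2)`.
  `tau` is the magnitude of the *reduction* (study sizes 2, 1.09, 0.5).
  `lambda` is solved by `uniroot` so the realised sample correlation
  `cor(U, Y)` equals its target exactly — 0.18 (baseline) at levels 1
  and 3, 0.5 (adjusted) at levels 2 and 4. The correlation is monotone
  in `lambda` (Cauchy–Schwarz), so the root is unique; an unattainable
  target fails loudly with the achieved range.

These constants were fixed once, by design-time simulation at
`n = 5000`, to deliver the intended structure: an empirical gap around
0.8 for the strong instrument (calibration target at least 0.6), around
0.3 for the weak one (target at most 0.35), and a weak/high-confounding
cell whose gap (~0.15) is small enough to destabilise the LATE ratio.
They live in one table at the top of `R/cohort.R`. Each cohort draws
its variables from named substreams seeded from the config seed, so
adding a variable to the generator would not perturb the others, and
identical configs give bit-identical cohorts.

What the generator does *not* emulate: measurement error in the risk
score, patient non-compliance with a prescription (adherence here is
the prescriber's, and patients are assumed to take what they are
prescribed), heaping or digit preference in recorded scores, multiple
correlated confounders, and any non-linearity of the outcome surface
beyond the logistic treatment curve. Passing tests therefore show that
the estimators behave correctly under the stated structure, not that
they are robust to every idiosyncrasy of real primary-care records.
About 1–2% of generated LDL values fall outside (0, 8) mmol/l — the
price of an additive normal noise model; they are left untruncated
because truncation would break the linearity the outcome model assumes.

## The replicate study harness

`run_study()` crosses confounding levels, instrument strengths, effect
sizes and bandwidths, generates `R` seeded cohorts per scenario
(study default 100; tests and the acceptance script use 20 at
`n = 2000`, sizes chosen so the full suite runs on a laptop in minutes),
fits the requested estimators, and combines per scenario: Rubin's rules
for the frequentist estimator (total variance `W + (1 + 1/R) B`;
with `R = 1` the between-replicate term is undefined and dropped, with
a message), and the arithmetic mean of posterior means and of the 95%
interval limits for the Bayesian ones. Replicate-level failures are
logged and skipped, and a scenario is flagged when more than 20% of
fits of any estimator fail — a weak-instrument study should report its
casualties, not die of them. Scenario seeds derive from the master seed
and scenario index, so scenarios can run in any order and an
interrupted study resumes from per-scenario CSV checkpoints.

Default bandwidths are `{0.05, 0.15, 0.25}` on the risk-score scale.
No automatic bandwidth selector is offered: published selection rules
are somewhat arbitrary, and the honest procedure is a sensitivity sweep
across analyst-chosen bandwidths, which the harness makes cheap.

## Numerical choices

- The bandwidth window is **closed**, `|x - x0| <= h`, with a relative
  tolerance of `1e-9` so that decimal boundaries behave as written in
  binary floating point (0.15 is retained at `x0 = 0.2, h = 0.05`).
- A record exactly at the threshold is "above" (`z = 1`), from the
  indicator definition.
- Bins in `bin_summaries()` are `[low, high)` and anchored so the
  threshold is a bin *edge*; a straddling bin would smear the
  discontinuity that the plot exists to show.
- Posterior quantiles use type-7 linear interpolation (the R default);
  intervals are central 95% intervals everywhere.
- Missing `x`, `t` or `y` drops the record with a logged count;
  non-finite values are an error naming the offending records.
- `rubin_combine()` and `bayes_combine()` are exact arithmetic; the
  only stochastic quantities in the package are MCMC draws and the
  generator's random variables, all seeded.

## Known limitations

- An outcome with *exactly* zero residual variance (a constant `y`)
  breaks the continuous-outcome sampler as `sigma` collapses to its
  boundary; any realistic noise level, however small, is fine.
- The LATE is local: it speaks for guideline-adherent prescribing near
  the threshold, not for the whole risk range.
- The constrained denominator prior (forcing an ordering on the two
  treatment probabilities) is deliberately not implemented; the
  flexible difference prior covers the stabilisation use case.
- Real-data analyses should treat the weak-instrument flag and the
  reported fraction of near-zero denominator draws as first-class
  results: when both fire, no estimator in this package (or any other)
  will rescue the design.
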