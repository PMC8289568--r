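---
title: "Methods: tiered probabilistic risk assessment for sediment contaminants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiered probabilistic risk assessment for sediment contaminants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedrisk)
```

## The assessment model

`sedrisk` follows the tiered structure used in quantitative ecological
risk assessment of aquatic systems. The input is a station-by-element
table of sediment concentrations (dry-weight mass fractions; the
canonical internal unit is mg/kg, with ng/g used at I/O boundaries and in
hazard tables). All distributional work operates on station means — one
pooled composite per station — because that is the sampling unit of such
surveys; per-cell replicate standard deviations are carried as metadata
only.

**Tier 1** compares each measured value with a low and a high guideline
trigger. Exceedance is strict (`value > trigger`): a concentration
exactly at a guideline is deliberately non-alarming, since tie behaviour
is a reporting convention rather than a scientific claim. Guideline
tables are preserved verbatim even when anomalous — the packaged
guideline fixture carries a high trigger equal to its low trigger for Zn,
and the loader warns rather than corrects, because silently "fixing" a
published table would make results irreproducible against their source.

**Tier 2** treats each element's station means as i.i.d. draws from an
exposure distribution and fits two candidate families by maximum
likelihood:

* *log-normal*: `mu` and `sigma` are the mean and the divisor-`n`
  standard deviation of the log concentrations (the exact MLE);
* *Burr Type III*: `F(x) = (1 + (b/x)^c)^(-k)`, scale `b > 0` and shapes
  `c, k > 0`, reducing to the log-logistic at `k = 1`.

Both fits are reported (the conventional paired-curve display), and the
family with the smaller Kolmogorov–Smirnov statistic `D` is selected,
ties going to the log-normal. Note that this selection rule intentionally
measures in-sample fit, not parsimony: with one extra parameter the Burr
III often attains the smaller `D` even on data genuinely drawn from a
log-normal, so the selected family should be read as "best-fitting
curve", not as an inference about the generating family.

The tier-2 verdict mirrors screening practice: an element clears when the
fitted 99th percentile of the selected family lies below the low trigger;
the fitted probability of exceeding the trigger, `1 - F(trigger)`, is
reported alongside.

**Tier 3** fits a species sensitivity distribution (SSD) to per-species
toxicity endpoints with the same machinery (Burr III by default — the
conventional flexible SSD family — log-normal by flag) and derives:

* `HC_n` — the `n/100` quantile of the SSD, the concentration affecting
  n% of species;
* `HC_n;p` — its p% lower confidence limit by nonparametric bootstrap
  over species (below);
* the expected percentage of species affected,
  `100 * E[F_SSD(X)]` with `X` from the exposure distribution;
* the reduction of the median concentration required to reach an
  acceptable percentage affected.

## Numerical choices

**Burr III likelihood maximisation.** The Burr III likelihood surface is
flat along ridges in `(c, k)`, so raw parameter estimates are weakly
identified while quantiles are stable. The optimizer works on
log-parameters (box 1e-3…1e3 enforced by a quadratic penalty),
Nelder–Mead, started from a method-of-moments log-logistic fit (`k = 1`,
for which `log X` is logistic) and a 3×3 grid of `(c, k)` scalings around
it, with a final polish restart; the achieved log-likelihood is never
accepted below the log-logistic starting value. Validation therefore
targets quantile recovery (the fitted 5th percentile within 10% of truth
at n = 2000), not parameter recovery. Bootstrap refits start from the
parent fit's parameters with a single start and a lighter convergence
budget; failed refits are dropped and counted rather than retried, so the
bootstrap sample space stays well defined, and a failure rate above 20%
is an error rather than a number.

**Kolmogorov–Smirnov testing.** `D` is evaluated at every order
statistic using both one-sided gaps, which handles ties correctly.
Because the parameters are estimated from the same sample, the classical
KS null distribution is anti-conservative; p-values therefore come from a
parametric bootstrap (default 999 replicates, seeded): simulate from the
fitted distribution, refit, recompute `D`. The suite checks calibration
empirically: under the null the test rejects at the 5% level in about 5%
of 200 seeded repetitions.

**Convolution.** `E[F_SSD(X)]` is integrated as
`∫ F_SSD(Q_PDD(p)) dp` over `p ∈ (0, 1)` — a bounded smooth integrand
needing no tail truncation — with `stats::integrate` at absolute
tolerance 1e-6. Exposure quantiles that underflow to zero at extreme `p`
are clamped to the smallest normal double, where every SSD CDF is
numerically zero anyway. The identity `E[F(X)] = 0.5` when exposure and
effects share one distribution, and agreement with a 10^5-draw Monte
Carlo oracle, are asserted in the tests.

**Remediation search.** Scaling a concentration distribution by
`s` is a location shift in log space (log-normal: `mu + log s`; Burr III:
`b -> s b`), preserving shape. The required scale solves
`risk(s) <= max_affected` by bisection to 1e-4 on `s`, returning the
feasible side of the final bracket so the returned scale always satisfies
the criterion. At confidence above 50% the replicate fit pairs are drawn
once and reused across the bisection and across protection levels; the
replicate risk curve is evaluated on a fixed 1024-node midpoint grid in
probability space, with exposure quantiles precomputed so each bisection
step costs one vectorised CDF sweep. The point-estimate path uses the
adaptive quadrature directly.

**Bootstrap conventions.** HC confidence limits use the percentile
method on the replicate HC distribution: `HC_n;p` is its `(100 - p)`th
percentile, `HC_n;50` the replicate median, defaults of 2000 replicates
(at least 500 required for a 95% limit). All HC entries of a report table
are computed from one replicate set, which makes the orderings
`HC_5 <= HC_10 <= HC_25` and `HC_n;95 <= HC_n;50` exact properties of
every output, asserted at construction. Every stochastic stage takes an
explicit integer seed; pipeline stages derive their seeds
deterministically from one master seed, and repeated runs are
byte-identical.

## The synthetic toxicity generator

Per-species sediment toxicity endpoints for the elements of a survey are
generally not published, so tier-3 results on real surveys require either
an external dose–response compilation or an emulation. The generators
draw i.i.d. endpoints from an SSD with known parameters (and station
means from a known exposure distribution), each station/species on its
own deterministic substream of the spec seed so that extending a scenario
preserves earlier draws. The survey-like scenarios take their exposure
side from the log-normal fit of the packaged survey columns
(20 stations, within-station replicate CV 7%, 3 replicates — matching the
fixture's structure) and place a Burr III SSD (`c = 1.8`, `k = 1.2`,
moderate shapes typical of fitted SSDs) with its HC5 two orders of
magnitude below the exposure median: a deliberately impacted scenario in
which the remediation machinery has real work to do, with 30 species — a
typical SSD size.

What passing tests on synthetic data do show: the estimators recover
known quantiles, orderings, and convolution values under the stated
distributional assumptions, deterministically per seed. What they do not
show: anything about real species assemblages — generated endpoints have
no interspecies correlation, no acute-to-chronic structure, and no
measurement error; absolute HC or percent-affected values from emulated
scenarios are labelled synthetic in every output and must not be read as
site risk.

## Known limitations

* The percentile-bootstrap lower confidence limit for an extreme SSD
  quantile undercovers at typical SSD sizes: for HC5 with 30 species the
  measured coverage of the nominal 95% limit is about 84–85%, essentially
  independent of the SSD's log-scale parameters. This is a known property
  of the percentile method for tail quantiles at small n; bias-corrected
  (BCa) or basic intervals would improve coverage but are not the
  procedure implemented here, which follows the standard SSD-bootstrap
  convention. Users needing calibrated coverage at n ≈ 30 should treat
  `HC_n;95` as conservative-in-intent rather than exactly 95%.
* KS-based family selection favours the more flexible family in-sample
  (see above); it is a curve-fitting choice, not model inference.
* Censored endpoints ("<LOD"), interspecies correlation, and
  shape-changing remediation strategies are out of scope; scaling-based
  remediation assumes all sources shrink proportionally.

## Problem sizes used in the test suite

The suite validates at sizes chosen to make the statistical checks
informative while keeping the full run quick on one core: parameter
recovery at n = 2000–5000, KS calibration over 200 repetitions × 99
bootstrap replicates, coverage over 200 simulated 30-species datasets ×
500 bootstrap replicates, Monte-Carlo convolution oracles at 10^5 draws,
and two full pipeline runs (6 elements, 500 bootstrap replicates, 199 KS
replicates) for the determinism check.
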