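---
title: "Estimating deaths averted by mobile overdose response services"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating deaths averted by mobile overdose response services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morsaverted)
```

## The estimation problem

Mobile overdose response services (MORS) — hotlines and apps that stay on
the line while someone uses drugs alone and dispatch help if they become
unresponsive — record how many emergency drug-poisoning responses they
initiated, but not how many of those events would otherwise have been
fatal. The quantity of interest is counterfactual: of the $n$ events a
service responded to, how many deaths were averted?

The estimator is deliberately simple. If an unwitnessed drug poisoning is
fatal with probability $r$, then

$$D = n \times r$$

deaths were averted among $n$ responded events. Everything difficult lives
in $r$, the unwitnessed-overdose fatality rate, which is not known: the
literature brackets it between $a = 0.1$ (derived from take-home-naloxone
impact modelling) and $b = 0.8$ (expert Delphi consensus). The package
treats $r$ as $\mathrm{Uniform}(a, b)$ and propagates that uncertainty
three ways:

1. **Endpoint ranges** — $D \in [n a,\, n b]$, with ceiling rounding per
   service (a fraction of a death counts as one more potential death).
2. **Analytic closed form** — because $D$ is a linear function of a single
   uniform variable, its mean is $n(a+b)/2$ and its $q$-quantile is
   $n(a + q(b-a))$. With the defaults, point estimates are $0.45\,n$ and
   the equal-tailed 95% interval is $[0.1175\,n,\ 0.7825\,n]$.
3. **Monte Carlo** — 10,000 draws of $r$, summarised by the rounded mean
   and the equal-tailed 2.5%/97.5% percentile interval.

This is a sensitivity analysis, not inference: the data never update the
distribution of $r$. The synthetic-cohort experiments below make that
property measurable.

## Data model

A `service_table` holds one row per service with its modality, country
scope, observation period and event count. Counts a service could not
report are carried as an explicit *unknown* state: they remain in tables
and reports (marked "unknown") but are excluded from every sum and
estimate. They are never imputed and never coerced to zero — the published
total of 299 events across nine of eleven services is only consistent
under exclusion, and imputation would manufacture information the services
did not provide. Zero-count services are genuine zeros and are included.

The built-in table (`mors_table1()`, also shipped as
`inst/extdata/mors_services.csv`) records the eleven North American
services observed up to mid-2023. "Canada-exclusive" analyses use
`country_scope == "canada"` only: a service operating globally is not
Canada-exclusive, and the published Canadian range (18–133) is only
consistent with that rule.

## Estimator configuration

| Parameter | Default | Meaning |
|---|---|---|
| `n_draws` | 10,000 | Monte Carlo draws per estimate |
| `seed` | 2023 | arbitrary documented constant; user-overridable |
| `draw_mode` | `"shared"` | one rate draw per iteration applied to all services |
| `interval_mass` | 0.95 | equal-tailed credible interval mass |
| `range_rounding` | `"ceiling"` | endpoint ranges round fractional deaths up |
| `mc_rounding` | `"nearest"` | MC outputs round half away from zero |
| `sampler` | `"systematic"` | see below |

**Draw mode.** Nothing in the estimand forces one choice: the published
per-service results and the total are mutually consistent only if every
service shares the same rate draw within an iteration (the total interval
equals $299$ times the rate quantiles, which is the comonotone case), so
`"shared"` is the default. `"independent"` draws one rate per service per
iteration; rate errors then partially cancel in the total, whose interval
is provably never wider than in shared mode.

**Rounding.** The tabulated range column is a ceiling calculation
($33 \times 0.1 = 3.3 \rightarrow 4$; $18 \times 0.8 = 14.4 \rightarrow
15$) while the Monte Carlo column is nearest-rounded
($77 \times 0.45 = 34.65 \rightarrow 35$). The package mirrors that split
and records the policy in every result object. "Nearest" is half away
from zero, not banker's rounding.

**Sampler.** Because $D$ is a monotone deterministic transform of a single
uniform variable, plain iid sampling wastes its 10,000 draws on noise: the
sample mean of $r$ has standard error $\approx 0.002$, enough to flip a
rounded point estimate that sits near a rounding boundary (e.g.
$77 \times 0.45 = 34.65$) from seed to seed. The default sampler is
therefore a seeded random permutation of the equal-probability midpoint
grid $a + (b-a)(i - \tfrac12)/m$, $i = 1,\dots,m$ — one-dimensional
systematic (quasi-random) stratification, a standard variance-reduction
design in probabilistic sensitivity analysis. Every draw lies in the
support, the ensemble is exactly uniform, and the sample mean and
percentiles coincide with the closed form to floating-point precision, so
rounded Monte Carlo outputs are reproducible and match the analytic oracle
for every count (verified for all $n \le 500$ in the test suite).
Jittered-strata (`"stratified"`) and plain (`"iid"`) samplers are kept for
users who want genuine sampling noise.

**Quantiles.** Finite-sample quantiles are midpoint-interpolated order
statistics (`quantile(..., type = 5)`), pinned for determinism; at 10,000
draws the choice among interpolating definitions moves bounds by
$\mathcal{O}(n/m)$, far below integer rounding for tabulated counts, but
type 5 is the definition whose stratified-sample value is exactly the
analytic quantile.

**Numerical guards.** Products like $33 \times 0.1$ are not exact in
binary floating point (3.3000000000000003); raw values are snapped to nine
decimals before ceiling or nearest rounding so results reflect the real
arithmetic, not the representation. Degenerate models with $a = b$ are
allowed: draws all equal $a$ and intervals collapse to the point.

## Derived metrics

*Summed vs pooled ranges.* Summing per-service ceiling ranges gives 33–243
for the nine known counts; pooling first gives $299 \times [0.1, 0.8] =
[29.9, 239.2]$, nearest-rounded 30–239. Ceiling per addend dominates the
pooled calculation, which is why both are exposed and labelled. (Published
prose quotes both a 33–243 and a "30 to 240" total; the latter is the
pooled calculation loosely rounded. The package exposes both and resolves
nothing.)

*Non-fatal:fatal ratios.* $(n - D)/D$ with $D$ the nearest-rounded pooled
averted count at each rate endpoint (30 and 239 for 299 events, giving
8.97:1 and 0.25:1) and the Monte Carlo point in the centre (135, giving
1.21:1). The endpoint denominators must be the nearest-rounded *pooled*
counts — the ceiling-summed 33/243 give different ratios — and the policy
is recorded in the report.

*Cost savings.* The per-death societal value (life lost to society plus
potential productive life years lost) is not printed in the source
material; the package defines it as the exact rational
$3{,}487{,}836{,}040/18$ cents per death ($\approx$ CAD 1,937,686.69),
the constant implied by a saving of \$34,878,360.40 for 18 averted
Canadian deaths. Money arithmetic is exact integer-cent rational
arithmetic (all magnitudes are far below $2^{53}$, so doubles hold them
exactly). The lower Canadian bound is then reproduced to the cent; the
constant implies an upper bound of \$257,712,329.62, which matches the
published \$257,712,330.00 only after rounding to the whole dollar. No
single constant can match both printed totals to the cent, because the
lower total in cents is not divisible by 18; the package keeps the
lower-bound-derived constant and documents the 38-cent discrepancy rather
than hiding it.

## What the synthetic cohorts emulate — and what they do not

`simulate_cohort()` generates the event log a set of services would have
recorded if the estimator's world were true, plus the latent truth no
service can observe:

- per-service true-emergency counts are Poisson at the scenario rates
  (defaults: the seven strictly positive observed counts, summing to 299);
- each true emergency is counterfactually fatal with the scenario's true
  rate, independently — flagged events are the ground-truth deaths averted;
- false-alarm callouts are a configurable expected fraction of the log
  (default 0.2) and are never counterfactually fatal; the RNG is ordered
  so changing this fraction cannot change the ground truth under a fixed
  seed;
- events are assigned to clients sequentially, joining an existing client
  with probability proportional to the client's event count and scaled by
  a dispersion parameter (default 0.5; 0 makes every event a distinct
  client), emulating the qualitative observation that some clients had
  many events.

`coverage_experiment()` re-draws the true rate from the
$\mathrm{Uniform}(0.1, 0.8)$ model each replicate — the only regime in
which the 95% interval has a calibration claim — and measures how often
the interval contains the true count. At observed scale it sits near 0.95:
the interval trims 2.5% of the rate distribution at each end, and Poisson
count noise plus binomial fatality noise blur the edges approximately
symmetrically. The acceptance suite runs 1,000 replicates; the default
suite uses smaller screens (150–200 replicates, fewer draws) to keep
routine test runs fast.

The same harness documents the estimator's central limitation: with the
true rate held *fixed* at any $r$, the point estimate divided by total
events converges to $(a+b)/2 = 0.45$ — never to $r$. The method propagates
assumed uncertainty; it does not learn the fatality rate from data. The
`uniqueness_gap()` statistic ($1 - \text{unique lives}/\text{events
flagged fatal}$) quantifies a second limitation: repeat clients mean
"deaths averted" overstates "unique lives saved".

What the simulator does **not** model: response-time or outcome
differences between EMS and community dispatch, pharmacology, temporal
trends in drug-supply toxicity, or any mechanism by which a response
might fail to prevent a counterfactual death — the generator makes the
same "response = death averted" equivalence the estimator does, so passing
recovery tests validates internal consistency, not that equivalence.

## Problem sizes

Default runs use 10,000 draws per estimate. The calibration experiment in
the acceptance suite uses 1,000 replicates at the observed table scale
(about 300 true events per cohort); the routine test suite uses 150–200
replicate screens with 500–4,000 draws, sizes at which the binomial
uncertainty on empirical coverage (±2% at 1,000 replicates) is already far
tighter than the [0.92, 0.98] acceptance band.

## Reproducing the published table

```{r}
report <- build_report()
report
```

`run_estimate()` wraps this pipeline with file output in CSV, JSON and
Markdown, each embedding the full effective configuration so any number in
any report can be re-derived from the file alone.
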