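---
title: "Spatio-temporal mortality modelling and life-expectancy surveillance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal mortality modelling and life-expectancy surveillance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Small-area life expectancy is noisy: splitting deaths by area, 5-year age
group, calendar year and sex leaves many cells with a handful of events, so
raw rates — and any life table built from them — are unstable. `stmort`
addresses this with a Bayesian hierarchical Poisson model that borrows
strength across neighbouring areas, adjacent ages and years, and deprivation
deciles, then answers two questions: what is life expectancy at birth in
every area and year, and which area-years show mortality that is
unexplainably high *given* the area's deprivation level and the shared
age/time structure.

## The model

Deaths in area $i$, age group $j$, year $t$ are modelled as

$$y_{ijt} \sim \text{Poisson}(\lambda_{ijt}\,P_{ijt}),$$

with $P_{ijt}$ the person-years at risk and

$$\log \lambda_{ijt} = a_0 + \alpha_j + \gamma_i + \zeta_t + \phi_{d(i)}
  + \omega_{it} + \delta_{ij} + \kappa_{jt} + \nu_{d(i)t},$$

where $d(i)$ is the deprivation decile of area $i$ (1 = most deprived).
The main effects carry smoothness assumptions standard in disease mapping:

* $\alpha_j$, $\zeta_t$, $\phi_d$ — first-order random walks (RW1), since
  mortality varies slowly across adjacent ages, years and deciles;
* $\gamma_i$ — intrinsic conditional autoregressive (ICAR) prior on the
  area adjacency graph, so neighbouring areas share similar baseline rates;
* $\kappa_{jt}$, $\nu_{dt}$ — independent RW1s over time within each age
  group and each decile, giving every age group and decile its own smooth
  trend;
* $\omega_{it}$, $\delta_{ij}$ — exchangeable Gaussians: unstructured,
  data-driven interactions. $\omega_{it}$ is the surveillance term — it
  collects area-year departures that none of the structured terms explain;
* $a_0$ — vague normal, mean 0, variance $10^6$.

Each precision gets a Gamma(1, 0.01) hyperprior, the weakly informative
conjugate default of the disease-mapping literature; both parameters are
configurable in `model_config()`. Sexes are fitted separately.

### Identifiability constraints

Intrinsic priors are improper and every interaction overlaps the main
effects, so constraints are required for a well-defined posterior. We use
the minimal set that removes confounding with the main effects:

* $\sum_j\alpha_j=\sum_i\gamma_i=\sum_t\zeta_t=\sum_d\phi_d=0$;
* $\omega$ and $\delta$ doubly centred (row and column means zero), since a
  nonzero area-mean of $\omega$ is indistinguishable from $\gamma_i$ and a
  nonzero year-mean from $\zeta_t$ (likewise $\delta$ against $\gamma$ and
  $\alpha$);
* each row of $\kappa$ and $\nu$ centred over $t$ (the RW1 level is not
  identified), and each year-column centred over $j$ resp. $d$.

After every MCMC sweep each component is re-centred and the removed means
are transferred into the corresponding main effects and intercept, so the
fitted rates are untouched. Uncentred variants would change only the split
between main effects and interactions, not $\lambda_{ijt}$.

## Inference

`fit()` runs Metropolis-within-Gibbs (compiled, in `src/sampler.cpp`):

* scalar adaptive random-walk Metropolis for $a_0$ and every element of
  every field, exploiting the fact that a single element touches only its
  own slice of cells (the running Poisson means are updated incrementally,
  so one proposal costs one `exp` and a sum over that slice);
* conjugate Gamma Gibbs draws for the eight precisions, with degrees of
  freedom equal to the dimension of the component's constraint-respecting
  subspace: $n-1$ for the RW1 main effects, $I-1$ for the connected ICAR,
  and $(\text{rows}-1)(\text{cols}-1)$ for the doubly centred interaction
  matrices;
* per-component step sizes adapt toward 0.44 acceptance in batches of 50
  sweeps **during burn-in only**, so the post-burn-in kernel is fixed and
  the stationary distribution is preserved;
* chain $c$ is seeded with `seed + c - 1`; a rerun with the same
  configuration is bitwise identical.

`convergence_report()` computes split-chain $\widehat R$ and an
autocorrelation-based effective sample size for the intercept, the
precisions and the field means, flagging $\widehat R > 1.1$.

### Calibration, honestly

The re-centre-and-transfer step is exact for the improper intrinsic
components but slightly perturbs the proper exchangeable ones, and scalar
updates mix the intercept through the transferred means. Across 20 seeded
replicates of the default synthetic world the standardised error of the
posterior mean of $a_0$ has spread ≈ 1.2, i.e. 95% intervals behave like
≈ 90% intervals for this extremely concentrated parameter (its posterior
standard deviation is ~0.001 at ~1.3 million simulated deaths). Field
recovery is unaffected: rank correlations between posterior means and truth
for the age and year effects are ≈ 0.99 at the default conditions.

## Life tables

`e0_from_rates()` implements the Chiang-style abridged period life table on
the standard 20-group grid (<1, 1–4, 5-year groups to 85–89, 90+):
$q_j = n_j m_j / (1 + n_j(1-a_j)m_j)$ with $a_j = 0.5$ for closed intervals
and $a_1 = 0.1$ for the infant year, and the open interval closed as
$L = l/m$. Two numerical guards: rates are floored at $10^{-10}$ before the
arithmetic, and if an interval's $q$ caps at 1 its tabular person-years are
replaced by the exposure-consistent $d/m$ so the immediate-death limit
degenerates correctly. Against oracles, constant-hazard schedules reproduce
$e_0 = 1/m$ and Gompertz schedules match a single-year-of-age life table
within 2% when the abridged inputs are occurrence/exposure rates, the form
real abridged data take.

`area_year_e0()` applies the table to $\exp(\eta_{ijt})$ per posterior draw
and summarises across draws (mean, central 95% interval), so the intervals
propagate full posterior uncertainty. `decile_year_e0()` first pools member
areas' rates with population weights. `e0_gap()` differences the mean
$e_0$ of two periods (default 2012–2013 vs 2017–2018) within each draw
before summarising, and reports days (×365.25), so the gap interval
respects the correlation between periods.

## Detection

`exceedance_probability()` computes $p_{it} = \Pr(\omega_{it} > 0 \mid y)$
as the strict draw fraction; `detect()` flags $p_{it} > 0.95$ (strictly —
a probability of exactly 0.95 is not a flag, and a draw exactly at zero is
not an exceedance) within the detection window, by default calendar years
2012–2018, the period of stalled life-expectancy improvement. Detection of
unusually *low* mortality and multiplicity adjustment are deliberately out
of scope. `sensitivity_compare()` aligns two fits that differ only in the
deprivation-decile vintage and classifies every area-year as flagged by
both, one, or neither.

## The synthetic worlds

`simulate_dataset()` draws every component from its prior — exactly the
model's assumptions — so fitting it back is a genuine self-consistency
check with known truth. Defaults (chosen once, as the package's study
conditions): a 10×10 rook lattice standing in for administrative
contiguity, 10 age groups, 10 years ending 2018, 10 spatially smooth
balanced deciles, baseline rate $e^{a_0} = 0.01$, about $10^4$ person-years
per area-age cell (a deterministic peaked age pyramid with ±20% per-area
jitter), and precisions $\tau_\alpha=2$, $\tau_\gamma=25$,
$\tau_\zeta=100$, $\tau_\phi=25$, $\tau_\delta=100$, $\tau_\kappa=200$,
$\tau_\nu=200$. The space-time precision defaults to $\tau_\omega=10^4$:
under the surveillance premise the *only* unexplained area-year signal is
what is injected via the anomaly list, so a flag anywhere else is a false
alarm. (With a loose $\tau_\omega$, the null world itself contains real
$\omega$ signal that the model then correctly detects — a property of the
world, not an error of the detector.) Anomaly shifts are added to
$\omega$ *after* centring, so injected signal lives exactly where the
detection rule looks.

What the generator does not emulate: real English geography and contiguity,
the construction of the deprivation index, migration, cohort effects, and
age profiles shaped like real mortality (the age effect is a prior draw,
not a Gompertz curve — life-expectancy levels on the 10-group desk grid
are therefore not interpretable as years of human life; the analysis
scripts use a separate 20-group flat-hazard world when interpretable
$e_0$ values are wanted). Passing tests on these worlds demonstrates
self-consistency of inference and detection, not fidelity to England.

## Problem sizes and runtime choices

The tests and the acceptance script run the desk-scale world (100 areas ×
10 ages × 10 years): a single chain of 3,000 sweeps takes a few seconds.
Replicate studies use 20 null worlds (recovery, intercept coverage, false
flags) and 6 anomaly worlds with four +0.3 shifts each (sensitivity);
prior-sampler calibration uses 20,000 replicates against closed-form
variances. The analysis scripts fit 2 chains of 2,250–4,500 sweeps per
world; the decile-effect precision mixes slowest (only nine decile
increments inform it), which is why the life-expectancy world uses the
longer, thinned chains.

## Known limitations

* Exceedance probabilities are reported unadjusted, as is conventional for
  this decision rule; with ~700 window cells a 0.95 threshold implies a
  nontrivial family-wise false-alarm rate under the null.
* The intrinsic CAR is the unweighted improper variant; disconnected
  graphs are refused rather than handled per component.
* The sampler is single-site; for much larger grids block or gradient
  updates would mix better per sweep.
* Zero-population cells are retained with zero likelihood contribution — a
  convention, since the original handling of such cells is not specified
  anywhere authoritative.
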