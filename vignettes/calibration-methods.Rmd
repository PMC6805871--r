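---
title: "Calibrating stochastic kinetic models with equivalence-test fitness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating stochastic kinetic models with equivalence-test fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stochcal)
```

## The problem

Stochastic kinetic models — mass-action reaction networks simulated exactly
with Gillespie's stochastic simulation algorithm (SSA) — rarely come with
measured rate constants. Calibration searches the rate space for parameter
vectors whose *simulated ensembles* reproduce *replicated experimental time
series*. Two features make this harder than fitting an ODE model: every
candidate evaluation is an ensemble of noisy simulations rather than one
deterministic curve, and a sensible notion of "fit" must compare two finite
samples (m experimental replicates against n stochastic runs) per observable
and time point, not two numbers.

stochcal couples a genetic algorithm (GA) to two families of fitness
functions evaluated on each (observable, time point) *cell*:

* **Nine algebraic objectives** (`SDA`, `ADA`, `PWSD`, `APWSD`, `NPWSD`,
  `ANPWSD`, `SSQ`, `CHISQ`, `MNSE`): differences of cell means, mean or raw
  pairwise deviations over all `m × n` replicate/run pairs, and normalised
  variants (by `exp_i`, by the replicate standard deviation, by the replicate
  mean). All are non-negative, zero at a perfect fit, and minimised.
* **Three iterative equivalence tests** (`TOST`, `DUT`, `WMWET`): instead of
  asking whether data and simulations *differ*, an equivalence test asks
  whether they provably differ by *less* than a margin. Each cell yields a
  verdict; the *rejection matrix* collects them, and the fitness is the count
  of cells where equivalence was **not** established. A perfect model scores
  0; a completely wrong one scores `V × T`. The score is a discrete fitness
  with known limits.

## The equivalence tests

**TOST (two one-sided t-tests).** The simulated values are shifted left and
right by the margin ε. Equivalence holds when a one-sided Welch t-test finds
`sim − ε` significantly below the data *and* a second finds `sim + ε`
significantly above it, both at level α (default 0.05). Welch (unequal
variance) tests are used; the choice between pooled and Welch is a documented
implementation decision, as the two samples have no reason to share a
variance.

**DUT (double Mann-Whitney U-test).** The nonparametric analogue: the same
two shifted comparisons are made with one-sided Mann-Whitney U-tests. Pair
counts use the ½-per-tie convention, and `U_exp + U_sims = m·n` always. The
null distribution is exact (via the Wilcoxon count distribution) for
tie-free cells with `m·n ≤ 400`, and a normal approximation with tie and
continuity corrections otherwise — the same switch `wilcox.test` applies.

**WMWET (Wellek's Mann-Whitney equivalence test).** Tests whether
`π = P(sim > exp)` lies in a band `(p_lo, p_hi)` around ½ (default
`(0.19, 0.76)`). The U-statistic estimate `π̂` is standardised by a variance
estimate built from the pair and triple concordance probabilities, and
compared with the critical bound from the α-quantile of the noncentral χ²
distribution with 1 df and noncentrality `((p_hi − p_lo)/(2σ̂))²`. The port
is cross-validated in the test suite against an independent loop-level
transcription of the published routine on tie-free vectors.

**Margins.** For TOST and DUT the margin defaults to one standard deviation
(`range = "1sd"`); the SD pool is configurable (`range_scope`): the default
`"cell"` uses the cell's own replicates, `"observable"` pools the
observable's whole trajectory. The per-cell margin is *strict* for small
`m, n`: with `m = n = 10` the margin (≈ 1 SD) barely exceeds
`t_crit × SE ≈ 0.78 SD` of the difference of the two cell means, so even a
model simulated at the true rates fails a substantial fraction of cells, and
minimising the score rewards matching the dataset's *empirical* cell means.
The per-observable pool is far more permissive (a true model typically scores
0) at the price of a plateau in the fitness landscape. This trade-off is
intrinsic to margin-based equivalence fitness at small sample sizes and is
the main caveat when interpreting recovered parameters; see *Known
limitations*.

**Degenerate cells.** Cells that cannot be tested (fewer than 2 replicates or
runs) are recorded untestable and counted as failed, so the score's upper
bound holds. A TOST/DUT cell with ε = 0 can never establish equivalence
(both one-sided tests cannot reject at a zero margin); two identical
constant samples therefore fail at ε = 0 and pass for any ε > 0. A WMWET
cell with σ̂ = 0 is equivalent exactly when π̂ lies strictly inside the band.
No multiple-testing correction is applied across cells — the score
deliberately counts raw per-cell verdicts.

## The genetic algorithm

A population of `P` parameter vectors is drawn from per-parameter sampling
laws (uniform, or log-uniform for rates spanning decades), simulated
(`n_sims` SSA runs each), scored, ranked, and bred:

* **Strategy 1 (elitist, default).** The top `E` individuals carry over
  unchanged *with their cached simulations and fitness* — elite simulations
  are never repeated. Both parents are drawn uniformly from the elite
  (self-recombination allowed), recombined at a single random point, and each
  parameter is redrawn from its sampling law with probability 0.30.
* **Strategy 2 (non-elitist).** Two *distinct* parents are drawn from the
  whole population with inverse-rank probabilities
  `p_i = 1/(r_i · Σ_j 1/r_j)` (for `R = 100`: 19.28% and 9.64% for the top
  two ranks); elitism is off by default but available.
* **Strategy 3.** As strategy 2, with multi-point crossover (each gene from
  either parent with probability ½) and factor mutation: with probability
  0.20 a parameter is multiplied by a uniform factor within ±10% and clipped
  to its bounds.

Mutation probabilities are applied per parameter. Offspring replace the
non-elite `P − E` slots (strategy 1) or the whole population (strategies 2–3
without elitism); parents do not persist outside the elite. Ranking ties are
always broken by individual id, so runs are deterministic. Failed
simulations carry a `+Inf` sentinel and rank last; they never abort a run
unless every candidate fails.

Under elitism with a single objective the running-best fitness is
non-increasing *by construction* (the incumbent's cached fitness cannot
change), and `calibrate()` asserts this on every such run. Under
multi-objective ranking the elite is selected by rank sum, which need not
retain each per-objective minimum, so the assertion is a single-objective
invariant.

**Multi-objective runs** rank each objective separately (ties sharing the
minimum rank) and order by the unweighted rank sum — no Pareto archiving, no
weighting. Because only ranks enter, the ordering is invariant to monotone
transforms of any single objective. `objective_correlation()` (Pearson,
Spearman, Kendall) helps pick non-redundant objective sets;
`objective_bundles()` ships three presets mixing an algebraic error with the
nonparametric equivalence score.

## Reproducibility and parallelism

One root seed derives, via a Lehmer-style mixer (`derive_seed()`), a separate
stream for every component: initialisation, the operator phase of each
iteration, each candidate's simulation ensemble, each SSA run, each
resampling unit. Consequences: changing `n_sims` does not perturb operator
draws; job completion order cannot change results; and `workers = 1` and
`workers = 8` produce bit-identical calibrations (verified in the tests).
The SSA core carries its own splitmix64 generator, so trajectories are
reproducible across platforms and independent of R's RNG state.

## The built-in simulator and the synthetic benchmark

The SSA core implements the direct method (linear propensity scan) for
mass-action networks with falling-factorial propensities — adequate for the
tens-of-reactions scale this package targets at the desk; rule-based or
network-free semantics belong to external simulators via the
`command_backend()` adapter (placeholders `__FREE__<name>` in any text model
format, `{model}/{seed}/{output}` slots in the command, `gdat`/`kasim_csv`/
`tsv` output dialects). A `max_events` cap (default 2·10⁷ per run) guards
calibrations against runaway candidates; a tripped cap fails that candidate,
which then carries the sentinel fitness.

The benchmark generator reproduces the standard parameter-recovery design: a
two-species birth–death cascade (mRNA synthesis `r1_v = 5`, decay
`r2_k1 = 0.03`, translation `r3_k1 = 0.1`, protein decay `r4_k1 = 0.03`;
stationary means 166.67 mRNA and 555.56 protein), simulated at the true
rates to create replicated synthetic data. Unstated design constants were
fixed once: time grid `0, 20, …, 200` (11 points, spanning the transient —
relaxation time `1/0.03 ≈ 33` — and the near-stationary regime, so all four
rates are in principle identifiable), initial counts 0/0, both species
observed, and a log-uniform search space one decade either side of each true
rate. Ensemble means of the simulator are validated against closed-form
linear-ODE solutions (via deSolve) at three-standard-error tolerance.

What the generator does *not* emulate: measurement noise beyond intrinsic
stochasticity, unequal replicate designs, missing cells, or unit
conversions. Passing the recovery benchmark therefore shows the machinery is
correct and self-consistent, not that real assay noise is handled.

## Benchmark problem sizes

The packaged benchmark runs use population 50, elite 10, 30 iterations and
10 simulations per candidate on 10 synthetic replicates, repeated over three
root seeds with the median reported — a desk-scale design the whole suite
can afford while exercising every component end to end (each run evaluates
1 210 candidates ≈ 12 100 SSA trajectories). The jackknife and bootstrap
examples run reduced configurations for the same reason; both record every
sub-run's seed so any estimate can be reproduced independently.

## Parameter uncertainty

`jackknife_calibrations()` repeats the calibration leaving out one unit at a
time — replicates by default (they are the sampling unit inside every
fitness function), time points optionally. `bootstrap_calibrations()` runs
`n_runs` calibrations on datasets whose replicates are resampled with
replacement, plus a baseline run for the point estimate, and reports
percentile intervals; with 20 runs the percentile resolution `1/(n+1)`
caps the usable level at 90%. Percentile (not BCa) intervals are used: with
~20 runs, higher-order corrections are noise. GA noise can place the point
estimate outside the interval; the report does not force containment.

## Known limitations

* **Small-sample equivalence fitness overfits.** With `m = n = 10` and
  per-cell 1-SD margins the score's minimum is achieved by tracking the
  dataset's realised noise, and under elitism the best individual partly
  reflects a retained lucky simulation draw. Recovered parameters can
  therefore sit tens of percent from the truth even when the score is near
  its observed floor; the timescale of the benchmark cascade contributes
  only a handful of informative cells against several cells of verdict
  noise. Treat single-run recovered values as point estimates and use the
  bootstrap module for spread.
* Experimental variability is not modelled; data enter only through their
  replicate values.
* No identifiability analysis, profile likelihood or ABC posterior — the
  uncertainty module is resampling-based by design.
* The built-in simulator is exact but direct-method only: no tau-leaping,
  delays, or rule-based semantics.
* SLURM integration is an interface stub (`slurm_script()`); local
  parallelism uses forked workers.
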