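---
title: "Methods: a Markov cohort cost-effectiveness model for fibromyalgia pharmacotherapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort cost-effectiveness model for fibromyalgia pharmacotherapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmcea)
```

## The decision problem and the model

fmcea compares pharmacologic strategies for moderate-to-severe fibromyalgia
— amitriptyline, four pregabalin doses (150/300/450/600 mg), two duloxetine
doses (60/120 mg), two milnacipran doses (100/200 mg), and no treatment —
by expected lifetime discounted cost and quality-adjusted life-years
(QALYs).

The disease model is a four-state Markov cohort: three alive severity
states defined on the 11-point pain numeric rating scale — mild (0–3),
moderate (4–6), severe (7–10) — plus absorbing death. Cycles are annual.
Each cycle an individual may stay in their severity state, move to a better
or worse one according to a treatment-specific 3×3 transition matrix
(conditional on survival), or die of background causes with an age- and
sex-specific probability taken from a life table. The horizon is lifetime:
the model runs until the alive fraction of the cohort is below an
extinction threshold (default `1e-7`), so that no further life-years or
costs accrue. Treatment effects are assumed constant for life; there are no
discontinuation or adverse-event states and no treatment sequencing.

### Cohort heterogeneity

The modeled population is predominantly female (94.4%) with entry age
distributed normally with mean 48.4 and SD 10.4 years. Only the mean and SD
are available, so the engine discretizes that distribution into integer-age
strata truncated to [18, 90], weights each stratum by its probability
mass, runs each stratum with its own mortality (aging one year per cycle),
and aggregates traces by weight. Sex enters only through the mortality mix
`p = 0.944·qx(age, female) + 0.056·qx(age, male)`. Everyone enters alive;
the split between moderate and severe entry states is not reported by the
underlying cohort sources, so it is configurable with an unbiased default
of (0.5, 0.5). Mortality does not depend on the severity state, matching
the structure in which fibromyalgia is burdensome but not lethal.

### Half-cycle correction, discounting, termination

Transitions can happen at any time within a year, so valuing occupancy at
cycle starts overstates person-time. We use the trapezoidal half-cycle
correction — cycle *t*'s person-year weight for an alive state is the mean
of its start-of-cycle and end-of-cycle occupancy — applied identically to
costs and QALYs. Cycle *t*'s corrected accruals are discounted by the
discrete annual factor `(1 + r)^(-t)` with `r = 0.03` by default; the
discrete factor is the natural partner of annual cycles. With a single
occupied state and constant death probability `q` this yields total
undiscounted person-years `(1 - q/2)/q`, which the tests verify against
direct geometric summation. Ages beyond the life table's last row clamp to
the terminal row, death probability is forced to 1 at a cap age (default
100), and a configuration whose alive fraction cannot reach the extinction
threshold within 200 cycles is an error rather than a silent infinite run.

## The economics layer

Per-state annual values are a utility weight in [0, 1] and three cost
components: direct medical, direct nonmedical, and indirect. The payer
perspective counts direct medical + direct nonmedical + drug acquisition
cost; the societal perspective adds indirect costs (productivity losses,
work absence, unpaid caregiving). Indirect costs arrive in source files as
3-month estimates and are annualized (×4) at ingestion. Drug cost accrues
for every alive person-year — lifetime therapy, since discontinuation is
not modeled.

Comparative statistics follow the standard frontier construction:
strategies are sorted by cost; any strategy weakly worse than another on
both cost and QALYs (with one strict) is strongly dominated; among
survivors, adjacent incremental cost-effectiveness ratios
(`ICER = ΔCost/ΔQALY`) are computed and any strategy whose ICER is not
strictly below the next pair's is removed as extendedly dominated,
repeating until the ICER sequence strictly increases. Incremental net
monetary benefit is `iNMB = WTP·ΔQALY − ΔCost` at thresholds of $50 000,
$100 000 and $150 000 per QALY by default. An independent brute-force
verifier (`frontier_nmb_oracle()`) maximizes `WTP·QALY − Cost` over a
dense WTP grid; the property tests require its optima to be contained in
the frontier on random instances.

Tie-breaks are deterministic: exact cost-and-QALY ties are both retained
(lexicographic order); an equal-cost, lower-QALY strategy is strongly
dominated. Rounding (costs and iNMB to the dollar, QALYs to 2–3 decimals)
applies only in `cea_report()`, never in internal arithmetic. The ICER of
a pair with equal QALYs is an error by design — dominance logic, not
division, must handle it.

## Uncertainty analysis

**One-way (tornado).** Each parameter is varied across a plausible range
holding the rest at base case; the recorded quantity is the iNMB of a
chosen strategy pair at a chosen WTP, and bars sort by width. Plausible
ranges are rarely published, so the default is ±20% of the base value
clipped to the parameter's domain, overridable per parameter via a ranges
file. When a single transition probability is varied, the varied entry is
held exactly at its set value and the rest of its row is rescaled to the
complement — this honours the requested value exactly, at the price of a
mechanics different from the PSA's row resampling.

**Probabilistic (PSA).** Second-order Monte Carlo with all parameters drawn
jointly: beta for transition probabilities, gamma for costs, lognormal for
utilities, each constructed by analytic moment matching from a mean and
standard error (default SE: 20% of the mean when a source reports only a
mean). Two pragmatic choices deserve note. First, transition-matrix rows
are multinomial but the assigned family is beta, so entries are drawn
independently from their betas and the row is renormalized — a documented
approximation to a Dirichlet that preserves the marginal families. Second,
lognormal utility draws can exceed 1 and are capped there post-draw; the
lognormal was chosen for its behaviour near 0 (severe disease, old age),
not near 1. Default draws: 1000, seed recorded in the result and the run
manifest (default 20240101). The cost-effectiveness acceptability curve
reports, at each WTP, the fraction of draws in which each strategy attains
the maximum net monetary benefit, with exact ties splitting the draw's
mass equally — so curves sum to 1 at every threshold.

## The synthetic input generator

The actual transition probabilities (from a network meta-analysis of 36
RCTs), costs and utilities behind the published analysis live in
supplementary tables that are not redistributable, so
`synthetic_scenario()` + `generate_parameter_set()` produce inputs that
emulate their statistical structure rather than their values:

* a baseline (no treatment) matrix with strong state persistence and net
  worsening pressure;
* one improvement gradient `g` per strategy: each row's probability of
  moving to (or staying in) the next-better state gains `g·(1 − p)` while
  the other entries shrink by `(1 − g)`, preserving row sums and `[0, 1]`
  bounds. The default gradients order the strategies as the published
  effectiveness ranking does (duloxetine 120 mg best, no treatment worst);
* severity-ordered utilities (defaults 0.80 / 0.65 / 0.45) and
  severity-increasing cost levels, with indirect costs large relative to
  direct ones so societal totals dominate payer totals;
* a Gompertz life table `qx = min(1, a·s_sex·e^{b·age})` with the female
  scale below the male, as a stand-in for national vital statistics tables;
* mild multiplicative lognormal jitter (SD 5%) on cost and utility levels,
  driven by the scenario seed, with orderings re-enforced afterwards so
  every downstream validator passes unchanged.

What the generator does **not** emulate: the real magnitude of lifetime
totals, correlations between parameters, dose-response structure within a
drug, or state-dependent mortality. Passing tests on synthetic inputs
therefore demonstrate that the machinery is correct and internally
consistent — not that the synthetic numbers reproduce the published
lifetime costs or QALYs, which depend on the unavailable inputs. The
published per-strategy (cost, QALY) pairs themselves are stored verbatim in
`reference_outcomes()` and exercise the economics layer exactly.

## Worked example

```{r, eval = FALSE}
ps <- generate_parameter_set(synthetic_scenario(seed = 20240101))
res <- run_cea(ps$inputs, cohort_spec(), model_config())
cea_report(res)
psa <- run_psa(ps$inputs, cohort_spec(), model_config(), ps$specs,
               n_draws = 1000, seed = 20240101)
head(ceac(psa, seq(0, 150000, by = 5000)))
```

## Numerical choices and problem sizes

* Row-sum tolerance for transition matrices: `1e-9` on input; cycle
  matrices reproduce row sums to `1e-12`.
* The default cohort discretization spans 73 integer-age strata; the engine
  is vectorized across strata (one 73×3 by 3×3 product per cycle), so the
  deterministic 10-strategy run takes well under a second and a full
  1000-draw PSA of all 10 strategies runs in tens of seconds on one core.
  The test suite uses single-stratum cohorts and brisk synthetic mortality
  where stratification is not the property under test.
* Extinction threshold default `1e-7` alive fraction: with the default cap
  age of 100 every stratum is extinct by construction, and the truncation
  error in person-years is below `1e-6`.
* CSV serialization uses `%.17g`, so every write/read round-trip is
  bit-exact; display rounding exists only in `cea_report()`.

## Known limitations

* Cohort (not individual) simulation: no memory of time-in-state, no
  heterogeneity beyond age/sex mixing.
* No adverse events, discontinuation, sequencing, or time-varying effects.
* PSA samples parameters independently (apart from row renormalization);
  no correlation structure, and no EVPI/EVPPI computation.
* Severity states do not feed back into mortality.
* One published figure describes two additional societal-perspective
  strategies as lying on the frontier while also being dominated by the
  cheapest, most effective one; under the strict dominance rules
  implemented here the societal frontier for those inputs is a singleton,
  which the net-benefit oracle confirms at every willingness-to-pay value.
  Similarly, a few published iNMB cells are not exactly consistent with
  their own printed cost/QALY columns (they reflect rounding of unseen
  internals); validation asserts only the self-consistent cells.
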