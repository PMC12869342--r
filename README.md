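# fmcea

Cost-effectiveness analysis of pharmacologic strategies for
moderate-to-severe fibromyalgia, built as a reusable, tested R pipeline for
health economists and methodologists: a Markov cohort state-transition
engine, an ICER / net-monetary-benefit / efficiency-frontier economics
layer, deterministic (tornado) and probabilistic (second-order Monte Carlo)
sensitivity analysis with cost-effectiveness acceptability curves, and a
synthetic input generator.

## The model in brief

Four health states — mild (pain 0–3), moderate (4–6), severe (7–10) on the
11-point pain scale, plus absorbing death — evolve over annual cycles under
a treatment-specific transition matrix layered with age- and sex-specific
background mortality from a life table. The cohort (94.4% female, entry age
normal with mean 48.4, SD 10.4, truncated to [18, 90] and discretized into
integer-age strata) enters in the moderate or severe states and is followed
for a lifetime horizon with trapezoidal half-cycle correction and 3% annual
discounting of both costs and QALYs.

For each strategy *s* the model yields expected lifetime discounted cost
*C_s* and QALYs *Q_s* under a payer or societal perspective. Comparative
statistics are standard:

* **ICER** between adjacent strategies: ΔC / ΔQ;
* **efficiency frontier**: cost-ordered strategies surviving strong
  dominance (another strategy no costlier and no less effective) and
  extended dominance (ICER not strictly below the next pair's), so frontier
  ICERs strictly increase;
* **iNMB** against a reference at willingness-to-pay λ:
  λ·ΔQ − ΔC (defaults λ = $50k, $100k, $150k per QALY);
* **CEAC**: at each λ, the fraction of probabilistic draws in which a
  strategy attains the maximum net monetary benefit λ·Q − C.

PSA distributions are moment-matched: beta for transition probabilities
(rows renormalized after entrywise draws), gamma for costs, lognormal for
utilities (capped at 1). See `vignettes/fmcea-methods.Rmd` for assumptions,
defaults and limitations.

## Worked example

The package ships the published base-case lifetime (cost, QALY) pairs for
the ten strategies (`reference_outcomes()`), which drive the economics
layer directly:

```r
library(fmcea)
res <- run_cea(outcomes = reference_outcomes("payer"),
               config = model_config(reference_strategy = "amitriptyline"))
cea_report(res)
#>            strategy expected_cost expected_qaly icer_or_status inmb_50000 inmb_100000 inmb_150000
#>       amitriptyline        115145         9.994      reference          0           0           0
#>   duloxetine 120 mg        115770        10.401           1536      19725       40075       60425
#>   pregabalin 450 mg        117434        10.233      dominated       9661       21611       33561
#>   ...                     (ten rows in total)
```

Only amitriptyline and duloxetine 120 mg survive to the payer-perspective
frontier; duloxetine 120 mg buys its extra 0.407 QALYs at $1536 per QALY
and delivers an iNMB of $40 075 over amitriptyline at $100 000 per QALY.
All eight other strategies are strongly dominated.

A full synthetic run exercises the whole pipeline (generator → Markov
engine → frontier → PSA → CEAC):

```r
ps  <- generate_parameter_set(synthetic_scenario(seed = 20240101))
res <- run_cea(ps$inputs, cohort_spec(), model_config())
psa <- run_psa(ps$inputs, cohort_spec(), model_config(), ps$specs,
               n_draws = 1000, seed = 20240101)
cc  <- ceac(psa, seq(0, 150000, by = 5000))
```

There is also a thin CLI (`inst/scripts/fmcea`) with `synth`, `run`, `psa`
and `owsa` subcommands over the same functions, reading the CSV formats
documented in `?read_transition_matrices`, `?read_state_economics`,
`?read_life_table`, `?read_drug_costs` and writing plot-ready CSVs plus a
`manifest.json` with input checksums and seeds.

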