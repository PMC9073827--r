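# cptgdm

Group decision support for risky choices with interval-valued judgments,
built on cumulative prospect theory (CPT). The motivating setting is medical
emergency response: several physicians must jointly pick one of a few
response actions (e.g. traditional surgery vs. a new therapy) whose outcomes
are uncertain both in *which* outcome occurs (success/failure probabilities)
and in *how good* each outcome is on each criterion (interval attribute
values). The package is for analysts and methodologists who want a
reproducible implementation of this interval-valued, multi-attribute CPT
workflow — not a bedside tool.

## The model

Each of `H` experts states an interval reference point `E_hk = [lo, hi]` per
criterion `k` — the band separating what the group would experience as a
gain from a loss. Three stages turn these and the alternatives' interval
outcomes into a ranking:

1. **Consensus.** Reference points are min–max normalized per criterion,
   each expert's distance to the group mean interval is
   `d_hk = sqrt(((R_hk^L − R̄_k^L)² + (R_hk^H − R̄_k^H)²)/2)`, similarity is
   `d_h = Σ_k (1 − d_hk)`, and expert weights are `w_h = d_h / Σ d_h`. The
   collective reference point per criterion is the weighted sum of the *raw*
   expert intervals, `r_k = Σ_h w_h E_hk`.
2. **Payoffs.** Every interval attribute value `C` is compared with `r_k`
   under the six possible interval relations (disjoint below/above, partial
   overlap low/high, containing, nested) and converted into a crisp
   gain ≥ 0 and loss ≤ 0. For disjoint intervals the payoff is the expected
   excess over the reference bound under a uniform density on `C`, i.e.
   `0.5(C^L + C^H) − r^L` or `− r^H`; cost criteria mirror the benefit
   formulas with signs flipped.
3. **Prospect values.** Payoffs pass through the value function
   `v(z) = z^α` for gains and `−λ(−z)^β` for losses, are normalized per
   criterion by the largest absolute value, and are weighted by
   rank-dependent decision weights built from the neo-additive probability
   weighting function `w(p) = μp + (1−μ)/2` on (0,1), `w(0)=0`, `w(1)=1`.
   The prospect value of alternative `i` is
   `PV_i = Σ_k w_k (Σ_gains π⁺ ṽ + Σ_losses π⁻ ṽ)`; alternatives are ranked
   by descending `PV`.

Defaults follow the study setting: `α = β = 1`, loss aversion `λ = 2`,
weighting slope `μ = 0.6`.

## Worked example

The packaged problem (`worked_example()`, also shipped as
`inst/extdata/worked_example.json`) has four experts, three benefit
criteria with weights (0.4, 0.35, 0.25), and three surgical response
alternatives that succeed or fail with probabilities 0.75/0.25, 0.8/0.2 and
0.7/0.3.

```r
library(cptgdm)
report <- solve_problem(worked_example())
print(report)
```

```
Group CPT decision report
  experts: E1 = 0.277, E2 = 0.227, E3 = 0.261, E4 = 0.236
  collective reference points:
    C1       [42.738, 49.012]
    C2       [50.068, 54.798]
    C3       [0.495, 0.586]
  net payoffs (alternative x criterion, by outcome):
    outcome succeed:
       C1     C2    C3
A1 15.988 27.702 0.189
A2 23.488 21.202 0.214
A3 35.988 22.702 0.234
    outcome fail:
       C1      C2     C3
A1 -7.738  -7.568 -0.120
A2 -5.738  -3.068 -0.022
A3 -3.369 -12.568 -0.007
  prospect values and ranking:
    A2       PV = 0.431
    A3       PV = 0.422
    A1       PV = 0.257
  best alternative: A2
```

Expert 1 is weighted highest (0.277) because their reference intervals sit
closest to the group mean. Positive payoffs are expected gains over the
collective reference band (alternative A1's success outcome on criterion C1
beats the reference by 15.988 points); negative ones are expected
shortfalls. A2 wins despite A3's stronger successes because A3's failure
outcome on C2 (−12.568) is punished twice over by loss aversion (λ = 2) and
by the overweighting of its 0.3 failure probability (`w(0.3) = 0.38`).

Sensitivity analyses are one call each:

```r
single_criterion_run(worked_example(), "C1")$prospect_values
#    A1    A2    A3
# 0.138 0.342 0.549          # C1 alone would pick the new therapy A3
expert_weight_scenarios(worked_example(), list(only_E2 = c(0, 1, 0, 0)))
```

The same workflow is available from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("exec", "cptgdm", package = "cptgdm"))')
Rscript "$CLI" demo
Rscript "$CLI" generate --seed 7 -o problem.json
Rscript "$CLI" solve problem.json --report report.json --lambda 1 --no-probability-weighting
```

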