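# rnakin

Kinetic analysis of RNA-mediated enzyme inhibition, built around the
characterisation of cytosolic serine hydroxymethyltransferase (SHMT1) as
a moonlighting RNA-binding protein: the 5'UTR of the SHMT2 transcript
binds SHMT1 and selectively inhibits its serine-cleavage reaction. The
package is for enzymologists and quantitative biologists who want to fit
and discriminate these inhibition mechanisms, and to test such pipelines
end to end on simulated data with known truth.

## What it computes

* **Binding isotherms** from EMSA titrations:
  %bound = B<sub>max</sub>[P]/(K<sub>d</sub><sup>app</sup> + [P]), B<sub>max</sub> fixed at 100%.
* **Inhibition curves**: %activity = 100 (1 − I/(I + IC<sub>50</sub>)).
* **Rate laws**: Michaelis–Menten with folate substrate inhibition,
  v = V<sub>max</sub>S/(K<sub>m</sub> + S(1+S/K<sub>i,THF</sub>)), and its extension to
  **hyperbolic (partial) competitive inhibition**, in which the RNA
  multiplies the effective K<sub>m</sub> by (1+I/K<sub>i</sub>)/(1+I/(αK<sub>i</sub>)) — a factor
  that saturates at α, so velocity does not vanish at saturating
  inhibitor. Pure-competitive and pure-mixed variants serve as
  alternative hypotheses.
* **A rapid-equilibrium oracle** (`solve_equilibrium`,
  `oracle_velocity`) that solves the full species balance of the
  binding scheme numerically and validates the closed-form rate law.
* **Global nonlinear least-squares fits** across inhibitor series
  (shared V<sub>max</sub>, K<sub>m</sub>, K<sub>i,THF</sub>; global K<sub>i</sub>, α) with bootstrap
  intervals and AICc/F-test model comparison.
* **Lineweaver–Burk replot diagnostics** (`diagnose_mechanism`):
  substrate-inhibition exclusion at S* = √(K<sub>m</sub>K<sub>i,THF</sub>),
  double-reciprocal lines, slope/intercept replots, and a decision table
  classifying pure competitive vs pure mixed vs hyperbolic competitive.
* **Synthetic-data generators** reproducing the published designs
  (THF 10–488 µM × tRNA 0–1.77 µM; serine 0.156–10 mM at 80 µM THF;
  EMSA 0.3–9.6 µM; RNA 1 nM–10 µM) with constant-CV multiplicative
  noise and seeded determinism.
* **Interaction-score combination**: threshold classification of
  predictor scores and percentile ranking against a length-matched
  background.

## Worked example

Simulate the THF × tRNA velocity matrix at the published design with the
reported constants as truth, then recover the mechanism and constants:

```r
library(rnakin)
truth <- kinetic_params(vmax = 1, km = 50, ki_thf = 200,
                        ki = 0.031, alpha = 18.8)
tab <- generate_velocity_matrix(builtin_design("thf_trna_matrix"),
                                truth, seed = 101)
diagnose_mechanism(tab)
#> Mechanism call: hyperbolic_competitive
#>   slope replot: hyperbolic; intercept replot: flat
#>   limiting/uninhibited velocity at apparent Km: 0.093 (excludes zero)

fit <- fit_global(tab, "eq_hyperbolic")
bootstrap_ci(fit, n_resamples = 1000, seed = 404)
#> Least-squares fit: eq_hyperbolic (144 points, RSS 0.01545, converged)
#>         estimate std.error  ci_lower ci_upper
#> vmax     0.95218  0.031077   0.86581   1.0618
#> km      46.19376  2.683290  39.43432  54.7245
#> ki_thf 213.91972 11.786189 182.73216 251.6570
#> ki       0.02928  0.001182   0.02651   0.0325
#> alpha   18.85123  0.844500  17.29311  20.4848
```

The replot diagnostics identify the inhibition as hyperbolic (partial)
competitive — the slope replot saturates instead of rising linearly and
the limiting velocity at infinite RNA is nonzero — and the global fit
recovers the generating K<sub>i</sub> (0.031 µM) and α (18.8) within their
bootstrap intervals from 5%-CV triplicate data.

## Analysis workflow

The `analysis/` scripts run the full study pipeline on synthetic data
and write their tables under `results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generates the four experimental layouts |
| `02_binding_affinity.R` | EMSA K<sub>d</sub><sup>app</sup> fits (wild type vs weakened mutant) |
| `03_inhibition_potency.R` | forward vs reverse IC<sub>50</sub> (selectivity of inhibition) |
| `04_mechanism.R` | replot diagnostics + global model comparison |
| `05_score_ranking.R` | combined interaction score and percentile rank |

Run them in order with `Rscript analysis/01_simulate.R`, etc.

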