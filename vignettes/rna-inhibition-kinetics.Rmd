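---
title: "Models and methods: kinetics of RNA-mediated SHMT1 inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: kinetics of RNA-mediated SHMT1 inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnakin)
```

# The scientific problem

Cytosolic serine hydroxymethyltransferase (SHMT1) interconverts serine +
tetrahydrofolate (THF) and glycine + 5,10-CH~2~-THF, a central step of
one-carbon metabolism. Beyond catalysis, SHMT1 moonlights as an
RNA-binding protein: it binds the 5'UTR of the SHMT2 transcript, and the
bound RNA selectively inhibits the serine-cleavage (forward) reaction
while leaving the reverse reaction largely untouched. `rnakin` implements
the quantitative layer of that characterisation: the binding and
inhibition models, the rate laws, a rapid-equilibrium mechanism oracle,
the replot-based mechanism classification, synthetic-data generators
reproducing the experimental designs, and a score-combination layer for
interaction predictions.

All concentrations in the package are micromolar; designs quoted in mM
(serine) are converted at the design boundary. Velocities carry arbitrary
absorbance-based units: only velocity ratios and the concentration-valued
constants are scientifically meaningful, so the generating `vmax` is 1 by
convention.

# Models

**Binding isotherm.** EMSA densitometry yields percent RNA bound versus
protein concentration, fitted by the single-site hyperbola
$\%B = B_{max}[P]/(K_d^{app} + [P])$. $B_{max}$ is fixed at 100% by
default — the signal is normalised to total RNA — and estimating it is
opt-in (`fit_bmax = TRUE`).

**Inhibition curve.** Percent activity at fixed substrates versus RNA
concentration follows $\%A = 100\,(1 - I/(I + IC_{50}))$; the curve is
pinned at 100% at zero RNA, so $IC_{50}$ is the only free parameter.

**Rate laws.** The forward assay varies THF at saturating serine. THF
shows classical substrate inhibition (a non-productive second folate
binding event), $v = V_{max}S/(K_m + S(1+S/K_{i,THF}))$, with a velocity
optimum at $S^* = \sqrt{K_m K_{i,THF}}$. RNA inhibition is *hyperbolic
(partial) competitive*: inhibitor and substrate each bind the free
enzyme, each reduces the other's affinity by the same factor $\alpha$
(thermodynamic cycle closure), and the ternary complex still turns over
at the full $k_{cat}$. The effective Michaelis constant is multiplied by
$(1+I/K_i)/(1+I/(\alpha K_i))$, which saturates at $\alpha$, so the
velocity at saturating inhibitor is nonzero
(`limiting_velocity()`) — the kinetic fingerprint that distinguishes
partial from pure competitive inhibition. Pure competitive
($\alpha \to \infty$, represented as an explicit model variant rather
than a numeric infinity) and pure mixed (linear slope and intercept
factors) variants are provided as the alternative hypotheses that the
mechanism discrimination needs.

# The mechanism oracle

`scheme_spec()` / `solve_equilibrium()` solve the full rapid-equilibrium
species balance of the binding scheme: E, E·S, E·R, E·R·S, plus the
dead-end complexes E·S·S *and* E·R·S·S formed by a second substrate
molecule with a shared constant. The second dead-end complex matters:
with E·S·S alone, the scheme's rate law divides the substrate-inhibition
term by $(1+I/(\alpha K_i))$ and deviates from the closed-form law by up
to ~60% on the study grid, so exact equivalence requires the
non-productive site to be available on both productive complexes.

The solver performs damped Newton iteration on the log free-ligand
concentrations (positivity by construction, deterministic initialisation
at the ligand totals) and accepts a state only when every mass balance
holds to better than $10^{-9}$ relative. `oracle_velocity()` returns
$k_{cat}([E{\cdot}S] + [E{\cdot}R{\cdot}S])$. In deep ligand excess
(enzyme total $10^8$-fold below $K_m$ and $K_i$) the oracle matches the
closed-form law to ~$10^{-9}$ relative, which is the package's central
correctness argument for the rate-law algebra. At an enzyme total only
$10^4$-fold below $K_i$ the residual difference (~$10^{-5}$) is
free-ligand depletion, not algebra: the closed form assumes free equals
total. With enzyme comparable to $K_i$ the oracle quantifies how much
the closed form over-predicts inhibition — an assumption the original
assays leave untested.

# Fitting

All fits are unweighted ordinary least squares on velocities (no
weighting scheme is published for these assays; OLS matches common
practice in Prism-style analyses), run through Levenberg–Marquardt
(`minpack.lm::nls.lm`) on *log-transformed* parameters. Log space
enforces positivity of every constant and makes the optimiser
indifferent to the concentration scale (unit-rescaling invariance is a
tested property). Standard errors are delta-method values from a numeric
Jacobian; bootstrap percentile intervals (case resampling stratified by
inhibitor series, mandatory seed, default 1000 resamples) are available
for all fits. Non-convergence and identifiability problems are recorded
in the `fit_result`, never thrown, so batch simulations can tally
failures.

The global fit shares ($V_{max}, K_m, K_{i,THF}$) across inhibitor
series and estimates ($K_i, \alpha$) globally. It requires at least
three inhibitor levels including an uninhibited series. Estimation is a
deterministic multistart: data-driven starts for the saturation
constants crossed with a logarithmic grid over $K_i$ ($10^{-3}$–$10$ µM)
and $\alpha \in \{3, 10, 60\}$, keeping the best final optimum. The
multistart is not decorative: on a few percent of noisy datasets a
single start drifts into a degenerate basin with $\alpha \to \infty$ and
inflated $K_i$ (the pure-competitive impostor) whose RSS is several-fold
worse than the true optimum. Bootstrap refits are warm-started at the
full-data estimates.

Fixing $\alpha = 1$ collapses the hyperbolic law to the uninhibited one;
$K_i$ then has no gradient and is reported as unidentifiable in the fit
warnings rather than silently returned.

**Model comparison** uses AICc plus the extra-sum-of-squares F-test for
nested pairs (nestedness decided by parameter-set inclusion). AICc is
computed with $k$ = the number of mean (regression) parameters. With the
alternative $k$+1-for-variance convention the small-sample correction
$2k(k+1)/(n-k-1)$ degenerates at the replot sizes used here ($n = 6$
inhibitor levels, denominator 1), making the richer shape essentially
unelectable even on clean data; the mean-parameter convention keeps the
criterion informative at these sizes and is applied consistently
everywhere. The preferred model must lead by more than 2 AICc units,
otherwise a tie is reported.

**Bootstrap interval calibration.** On the full study design at 5% CV,
the percentile interval for $K_i$ covers the truth in about 92% of
simulated datasets rather than the nominal 95%: the sampling
distribution of the NLS estimator is slightly heavier-tailed than its
within-dataset bootstrap distribution. Bootstrap-t intervals were
evaluated and do not materially improve this (the excess tail mass is
between datasets, invisible to resampling within one), so the simpler
percentile interval is kept and the shortfall documented here.

# Mechanism diagnostics

The inference chain mirrors the classical Lineweaver–Burk workflow:

1. Fit the substrate-inhibition law to the uninhibited series and drop
   all points above the fitted optimum $S^*=\sqrt{K_m K_{i,THF}}$ (the
   natural changepoint for "the substrate-inhibition portion"); points
   at the optimum are kept, removing more than half the grid is flagged,
   and fewer than three survivors is an error.
2. Average replicates per cell and fit unweighted straight lines to
   $1/v$ versus $1/S$ per inhibitor level. The retained
   $(1+S/K_{i,THF})$ curvature biases every intercept upward by the same
   bounded amount (all series share the retained grid), so the
   *intercept replot stays exactly flat* even though individual
   intercepts overestimate $1/V_{max}$; the classification relies only
   on the flatness.
3. Replot slopes ($K_m^{app}/V_{max}$) and intercepts ($1/V_{max}$)
   against inhibitor concentration and test shapes: slope linear versus
   saturating hyperbola, intercept flat versus linear.
4. Map the shape pair to a mechanism: hyperbolic slope + flat intercept
   → hyperbolic competitive; linear + flat → pure competitive; linear +
   linear → pure mixed; anything else indeterminate.

Each shape call requires the AICc rule ($\Delta > 2$) and the nested
F-test ($p < 0.05$) to *agree*; a split verdict yields an indeterminate
shape. Both statistics are monotone in the same RSS ratio for nested
least-squares fits, so disagreement is confined to a narrow evidence
band — the rule is a guard against noise-driven hyperbolic calls, not a
second independent test.

The shape tests are *precision-weighted*. Reciprocal-space estimates at
high inhibitor come from tiny velocities and are orders of magnitude
noisier than the rest, while sitting at the highest leverage; unweighted
shape tests are driven by those points alone and misclassify 20–45% of
simulated datasets at the study noise level. The reciprocal lines
themselves stay unweighted (step 2 is the classical visual procedure),
but their slope/intercept standard errors — computed from the pooled
replicate coefficient of variation propagated through each line fit by
the delta method, which is far steadier than the 3-point residuals of an
individual line — supply $1/\mathrm{se}^2$ weights for the replot shape
tests. With this, the classifier recovers the generating mechanism in
roughly 95 of 100 simulated datasets per truth at the study design
(5% CV, triplicates).

For a hyperbolic slope replot the asymptotic slope is finite and the
reported `limiting_velocity_ratio` — the ratio of limiting to
uninhibited velocity evaluated at the apparent uninhibited $K_m$, equal
to $2/(1+s_\infty/s_0)$ — is strictly positive; for a linear slope
replot it is zero.

# Synthetic data

The generators reproduce the published designs as built-ins:

* `thf_trna_matrix` — THF varied at 10 mM serine, crossed with tRNA at
  0, 0.11, 0.22, 0.44, 0.88, 1.77 µM; triplicates. Only the 10–488 µM THF range is reported,
  not the level count; the grid is
  concretised as 8 near-two-fold geometric steps (an exact two-fold grid
  cannot hit both endpoints), recorded in the design metadata.
* `serine_trna_matrix` — serine 0.156–10 mM in exact two-fold steps at
  80 µM THF, same tRNA grid. The published protocol quotes the fixed THF as
  "80 mM", an evident unit slip for 80 µM; the design adopts 80 µM and
  says so in its `note`.
* `emsa_titration` — protein at 0.3–9.6 µM in 6 two-fold steps.
* `ic50_curve` — RNA log-spaced over 10 points from 1 nM to 10 µM.

Noise is multiplicative Gaussian with constant CV
($v = v_{model}(1+\mathrm{CV}\,z)$, independent per replicate, truncated
at zero with a logged count), defaulting to 5% and 3 replicates: the
assays are triplicated coupled spectrophotometric measurements, for
which constant CV is the standard error structure. Binding and activity
signals are clipped to their physical ranges. Every stochastic step
requires a seed, and all randomness flows from the user seed through
named substreams (`stage_seed`), so identical configurations produce
byte-identical files.

Where truth values are unreported, the generators' worked
examples use assay-plausible values chosen once: $V_{max}=1$ (arbitrary
units), $K_m^{THF}=50$ µM, $K_{i,THF}=200$ µM (substrate inhibition
clearly visible inside the 10–488 µM window), $K_m^{ser}=1$ mM, and for
the serine-varied mixed-inhibition scenario $K_i=0.5$ µM with
$\alpha=1$ (the noncompetitive limit, giving the linear slope *and*
intercept replots that experiment showed). The reported constants
($K_i=0.031$ µM, $\alpha=18.8$, $K_d^{app}=1.39$ and $3.0$ µM,
$IC_{50}=33$ nM and $4$ µM) are used as generating truths wherever they
exist.

What the generator does *not* emulate: systematic drift between
replicate days, enzyme inactivation over time, coupled-assay lag,
pipetting covariance within a titration, or gel-quantification
saturation in EMSA. Passing recovery tests therefore demonstrates
correctness of the estimators under the declared error model, not
robustness to every artefact of real data.

# Score combination

The interaction layer takes two predictor outputs per sequence — a
binary interaction propensity and a bound-strength (affinity) score in
[0, 1] — as *inputs*; the predictors themselves are external services
and are never re-implemented or fetched. `classify_interactor()` applies
the affinity threshold (0.25) inclusively: the published call of a 0.27
score against a 0.25 threshold does not resolve the boundary, and ≥ is
the documented choice here. `combined_rank()` min–max-normalises each score
over background ∪ target (zero-spread scores map to 0.5), averages them
with configurable weights (equal by default — the published description says only
"linearly combined"), and reports the fraction of the pooled set whose
combined score is at least the target's, so a target dominating an
*n*-sequence background sits at percentile $1/(n+1)$. This pooled-rank
percentile is invariant under order-preserving affine rescaling of both
scores; it is *not* invariant under arbitrary nonlinear monotone
transforms, which can reorder a min–max-normalised mean — a structural
property of any linear combination of normalised scores. The actual
weights behind the published "top 2%" ranking are unstated, so that
number is illustrative, not a benchmark.

# Numerical choices and degenerate inputs

* Optimiser tolerances: `ftol = ptol = 1e-13`, up to 1000 iterations;
  noiseless recovery is at ~$10^{-9}$ relative for every model.
* The equilibrium solver halves Newton steps until the residual norm
  decreases and refuses states above $10^{-9}$ relative residual.
* Flat inhibition curves (range < 5 percentage points), all-zero or
  saturated-only titrations, and global designs with fewer than three
  inhibitor levels raise identifiability errors; weakly determined
  parameters (missing post-optimum points, $\alpha$ fixed at 1) are
  recorded as warnings inside the result.
* Exactly-at-threshold points: the exclusion keeps $S = S^*$; the
  interactor call keeps score = threshold.
* Duplicate inhibitor levels in a replot are merged by averaging with a
  note; non-positive velocities cannot be reciprocal-transformed and are
  dropped with a warning.

# Problem sizes

The shipped tests and drivers use the study's own dimensions: 144-point
velocity matrices (6 × 8 × 3), 6-point titrations, 10-point inhibition
curves; discrimination and coverage properties are assessed over 100
simulated datasets with 200 bootstrap resamples each, sizes at which the
binomial uncertainty of a ~95% per-dataset success rate comfortably
clears the 90/100 acceptance line.

# Known limitations

* The error model is constant-CV by construction; the estimators are OLS
  and make no attempt at robustness to outliers or heteroscedasticity
  beyond the replot weighting described above.
* Percentile bootstrap intervals undercover by ~3 percentage points at
  the study design (see above).
* The oracle treats binding as rapid-equilibrium (identifying $K_s$ with
  $K_m$) and does not simulate time courses, cooperativity between
  tetramer subunits, or the 0.5-folate-per-subunit stoichiometry
  argument, which was only made qualitatively.
* The quinonoid-intermediate reporter assay has no quantitative model
  here (no published equation exists for it), and cell-based readouts are out of
  scope.
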