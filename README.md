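# parpkin

Kinetic modelling of how PARP1 — the first responder to DNA strand
breaks — associates with DNA and is released from it.  Stopped-flow
fluorescence anisotropy shows that association with a model
double-strand break is diffusion-limited (k₁ ≈ 3 nM⁻¹s⁻¹), while
release of a bound DNA is driven by binding of a *second* DNA molecule
through a transient DNA–protein–DNA ternary complex: intersegment
transfer, the "monkey bar" mechanism that lets the protein scan a
nucleus full of DNA it binds tightly.  The WGR domain (residue W589 in
particular) provides the second DNA-binding "hand"; without it, release
collapses to a slow competitor-independent pathway.

The package is aimed at anyone analysing (or teaching the analysis of)
rapid-mixing competition kinetics: it provides the mass-action schemes,
a realistic synthetic trace generator, per-trace and global fitting,
identifiability bounds, and mechanism discrimination.

## The model

Species in nM: free protein `P`, labeled probe `Dstar`, unlabeled
competitor `D` (binding-site units), binary complexes `PDstar`/`PD`,
ternary complex `T`.  Three schemes:

* association: `P + Dstar ⇌ PDstar` (k₁, k₋₁)
* simple competition: release at k₋₁ with irreversible competitor
  capture `P + D → PD` (k₁′ ≈ k₁) — observed rate independent of [D]
* ternary: `PDstar + D ⇌ T` (k₂, k₋₂), `T ⇌ PD + Dstar`
  (release k₃, re-formation k₋₃), plus the first-site binding steps —
  observed rate rises with [D] and saturates at k₃,
  k_obs ≈ k₃k₂[D] / (k₂[D] + k₋₂ + k₃)

The observable is anisotropy, a calibrated linear function of the
bound-probe fraction `(PDstar + T)/Dstar_tot`.  Fits minimise the summed
squared residuals over a whole concentration series at once
(Levenberg–Marquardt in log-parameter space with Latin-hypercube
multistart); mechanisms are compared by AIC plus the k_obs-vs-[D] trend
and residual-randomness diagnostics.

## A worked example

```r
library(parpkin)

# the wild-type dissociation design at the published rate constants:
# 37 nM protein pre-bound to 25 nM probe, six competitor
# concentrations from 50 nM to 4 uM
series <- simulate_preset("WT", "dissociation", seed = 1, n_points = 250)

fit <- global_fit(series, "ternary",
                  fixed = c(k1 = 3.1, k_m1 = 0.5), n_starts = 8, seed = 1)
print(fit)
#> Global ternary fit: chi2 = 0.0235936 over 1500 points, 4 free parameter(s)
#>   k1           3.1  (fixed)
#>   k_m1         0.5  (fixed)
#>   k2       0.04165  (fitted, se 0.00427)
#>   k_m2       97.07  (fitted, se 9.73)
#>   k3         9.628  (fitted, se 0.176)
#>   k_m3     0.01324  (fitted, se 0.00023)
```

The four exchange constants come back at their generating values
(k₂ = 0.043 nM⁻¹s⁻¹, k₋₂ = 102 s⁻¹, k₃ = 9.7 s⁻¹, k₋₃ = 0.013
nM⁻¹s⁻¹): competitor binds the probe-bound protein about 70-fold slower
than the first DNA binds free protein, and once the ternary complex
forms, the *pre-bound* probe leaves it an order of magnitude slower
(k₃) than the newcomer (k₋₂) — the two hands of the monkey bar are not
equivalent.

```r
compare_schemes(series, fixed = c(k1 = 3.1, k_m1 = 0.5), seed = 1,
                n_starts = 4)
#> Mechanism comparison:
#>              scheme       chi2 n_free converged       aic
#>             ternary 0.02359359      4      TRUE -16582.00
#>  simple_competition 1.61293571      1      TRUE -10250.75
#>   Preferred mechanism: ternary (delta-AIC = 6331.3, decisive).
#>   kobs rises with competitor (slope 0.00134 1/(nM s), p = 0.00098): DNA-dependent release.
```

Competitor-independent release is rejected decisively, for the two
reasons the experiments gave: the observed rate climbs with competitor
concentration, and the simpler scheme cannot fit the trace shapes
(`residual_skew_report()` shows its per-trace residuals are grossly
one-sided).

Other entry points: `generate_association_series()` /
`generate_dissociation_series()` for custom designs,
`profile_upper_bound()` for identifiability bounds (e.g. the 25 ms
association window bounds k₋₁ below 10 s⁻¹),
`bootstrap_uncertainty()`, `recover_params()` for full
simulate-and-refit validation, `preset()` for the tabulated constants
of the wild type, domain deletions, W589A and the plasmid competitor,
and `per_site_rescale()` for re-expressing per-site plasmid constants
under a different site-count assumption.  A thin command-line front end
lives at `inst/cli/parpkin.R` (`simulate`, `fit`, `compare`,
`recover`).

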