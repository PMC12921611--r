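# sasri

Modified Guinier analysis of small-angle scattering concentration series:
extracting the radius of interparticle interaction.

## The problem

Classical Guinier analysis of small-angle X-ray or neutron scattering
(SAXS/SANS) fits the low-Q intensity of a dilute particle solution to

    I(Q) ≈ I(0) · exp(−Q² R_g² / 3)

and reads off the radius of gyration R_g. At finite concentration the
structure factor S(Q) is not unity, and the fitted value — call it
R_g,obs — drifts with concentration even in nominally dilute protein
solutions. The low-Q asymptote of the structure factor has the same
exponential form as the Guinier law,

    S(Q) ≈ S(0) · exp(−(1/6) · ((S(0)−1)/S(0)) · Q² R_i²),

where R_i is the **radius of interparticle interaction**: the
root-mean-square distance of the total correlation function
h(r) = g(r) − 1, i.e. how far a typical particle's local environment
deviates from the ideal-gas configuration. Combining the two exponentials
gives the modified Guinier law

    R_g,obs² = R_g,0² + ξ R_i²,   ξ = (S(0) − 1) / (2 S(0)) ≈ −n B22,

so a concentration series yields three physically meaningful parameters
from two weighted straight-line fits:

1. per profile, a classical Guinier fit gives (R_g,obs, I(0));
2. a line fitted to I(0)/n versus number density n gives the second
   osmotic virial coefficient B22 = −a/(2b) (slope over twice the
   intercept), hence S(0) = 1 − 2nB22 at each concentration;
3. a line fitted to R_g,obs² versus −nB22 gives R_i² (slope) and the
   infinite-dilution R_g,0² (intercept).

The package implements this workflow end to end, plus quadrature routines
that compute R_i and B22 directly from isotropic pair potentials
(hard-sphere closed forms serve as exact references: R_i,HS = √(3/5)·σ =
2·R_g,HS), the classical and modified Zimm forms, and a forward simulator
for synthetic concentration series with counting-statistics noise.

It is intended for scattering practitioners analysing reduced 1D
SAXS/SANS profiles of protein or colloidal solutions, and for anyone who
wants a model-independent length scale for interparticle interactions to
compare with simulations.

## Worked example

Simulate a six-point lysozyme-like series (R_g,0 = 13 Å, R_i = 38 Å,
B22 = −3.8×10⁻²⁰ mL, M_W = 14.3 kDa, 1 % counting noise) and analyse it:

```r
library(sasri)
cfg <- simulation_config(noise_frac = 0.01, seed = 7)
series <- simulate_series(cfg)
analyze_series(series)
```

```
<sas_analysis> 6 concentrations, x-axis = nb22
     c         n        i0    i0_err rg_obs rg_obs_err    s0        x
  2.45 1.032e+17 1.041e+17 2.659e+14  13.20     0.1518 1.008 0.003753
  4.91 2.068e+17 2.097e+17 5.367e+14  13.30     0.1510 1.015 0.007520
  7.40 3.116e+17 3.210e+17 8.202e+14  13.89     0.1457 1.023 0.011334
  9.94 4.186e+17 4.315e+17 1.108e+15  13.78     0.1471 1.030 0.015225
 14.21 5.984e+17 6.237e+17 1.608e+15  14.13     0.1444 1.044 0.021765
 18.56 7.816e+17 8.289e+17 2.132e+15  14.61     0.1400 1.057 0.028427
<virial_result> B22 = -3.64e-20 +/- 2.4e-21 mL
  = -2.19e+04 +/- 1.5e+03 mL/mol = -0.000107 +/- 7.1e-06 mol mL/g^2
  I(0)/n fit: slope = 7.287e-20, intercept = 1.002 (weighted)
<interaction_result> Ri^2 = 1534 +/- 2e+02 Ang^2, Rg,0^2 = 168.7 +/- 3.3 Ang^2
  Ri = 39.2 +/- 2.5 Ang, Rg,0 = 12.987 +/- 0.13 Ang, Ri/Rg,0 = 3.02
```

Reading the output: R_g,obs rises from 13.2 to 14.6 Å across the series —
the apparent-size inflation caused by weak net attraction (negative B22,
S(0) slightly above 1). The two-stage fit strips that inflation off,
recovering the true infinite-dilution R_g,0 ≈ 13.0 Å and an interaction
radius R_i ≈ 39 ± 2.5 Å, consistent with the simulation truth of 38 Å.

Computing R_i and B22 from a pair potential instead (a 30 Å square well,
0.5 kT deep, 1.5σ range):

```r
pot <- pair_potential("square_well", sigma = 30, epsilon = 0.5, lambda = 1.5)
ri_from_potential(pot)$ri      # 57.2 Å
b22_from_potential(pot)$b22_mL # -3.06e-20 mL (attraction outweighs the core)
```

Real data enter through `read_profile()` (whitespace/comma-delimited
ASCII Q, I, dI columns), `subtract_background()` (mean over a high-Q
window, default 0.35–0.45 Å⁻¹), `read_manifest()`/`build_series()`.
A thin command-line wrapper covering the same operations
(`simulate`, `analyze`, `fit-guinier`, `fit-b22`, `fit-ri`, `fit-zimm`,
`potential-ri`) lives at `inst/cli/sasri.R`.

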