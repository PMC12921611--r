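---
title: "Modified Guinier analysis: model, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modified Guinier analysis: model, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sasri)
```

## The model

The scattering intensity of a solution of monodisperse particles is
$I(Q) = n\,P(Q)\,S(Q)$, with $n$ the number density, $P(Q)$ the
single-particle form factor and $S(Q)$ the interparticle structure
factor. The classical Guinier law,
$I(Q) \approx I(0)\,e^{-Q^2 R_g^2/3}$, assumes $S(Q) = 1$ and is
therefore strictly an infinite-dilution statement. At finite
concentration the structure factor carries its own low-$Q$ exponential
asymptote,
$$S(Q) \approx S(0)\, \exp\!\Big(-\tfrac16\,\tfrac{S(0)-1}{S(0)}\,Q^2 R_i^2\Big),$$
where $R_i^2 = \int h(r)\,r^2\,d\mathbf r \big/ \int h(r)\,d\mathbf r$
is the mean-square distance of the total correlation function
$h(r) = g(r) - 1$: the *radius of interparticle interaction*. It
measures how far the local particle arrangement deviates from the
ideal-gas configuration. In the dilute limit $h$ reduces to the Mayer
function $e^{-V(r)/k_BT} - 1$, and for weak potentials further to
$-V(r)/k_BT$, so $R_i$ then reports the spatial range of the pair
potential itself.

Multiplying the two exponentials gives the modified Guinier law: the
measured curve is still a single Gaussian in $Q$, but its apparent size
obeys
$$R_{g,\mathrm{obs}}^2 = R_{g,0}^2 + \xi R_i^2,\qquad
  \xi = \tfrac12\,\tfrac{S(0)-1}{S(0)} \approx -nB_{22},$$
with $S(0) = 1 - 2 n B_{22}$ in the dilute virial expansion. Net
attraction ($B_{22} < 0$) inflates the apparent size with concentration;
repulsion deflates it. The same working equations hold for anisotropic
solutes with orientationally averaged correlation functions, so nothing
in the workflow distinguishes the two cases.

## The two-stage estimator

`analyze_series()` chains three fits, each a weighted linear least
squares with the parameter covariance taken as $(X^TWX)^{-1}$ at the
supplied sigmas (counting-statistics uncertainties are trusted, not
rescaled by the reduced chi-square; without sigmas an ordinary
least-squares fit with residual-variance errors is used):

1. **Guinier stage** — $\ln I$ vs $Q^2$ per profile over a window
   (default $0.015$–$0.07\,\mathrm{\AA}^{-1}$, suited to small globular
   proteins), with $\sigma_{\ln I} = \sigma_I / I$ by the delta method.
   In-window points with $I \le 0$ (possible after background
   subtraction) are excluded pointwise and counted. A warning is issued
   when $Q_{\max} R_g > 1.3$, the conventional validity guard.
2. **Virial stage** — $I(0)/n$ vs $n$; $B_{22} = -a/2b$ from slope and
   intercept, with the 1σ error propagated from the full $(a, b)$
   covariance including the correlation term.
3. **Interaction stage** — $R_{g,\mathrm{obs}}^2$ vs $x$; slope
   $= R_i^2$, intercept $= R_{g,0}^2$, with
   $\sigma(R_g^2) = 2 R_g \sigma(R_g)$ carried from stage 1. A 95 %
   confidence band of the line is retained for plotting.

**The abscissa choice.** The default $x = -nB_{22}$ matches the dilute
form of the law. The exact prefactor
$\xi = -nB_{22}/(1 - 2nB_{22})$ is available as `x_axis = "xi"`; at the
default study conditions the two differ by less than 6 %, and the choice
is recorded in the result. Because the forward simulator composes
$S(Q)$ from the exponential asymptote, the identity
$R_{g,\mathrm{obs}}^2 = R_{g,0}^2 + \xi_{\mathrm{exact}} R_i^2$ holds
exactly there, and round-trip tests at zero noise use the `"xi"` axis to
verify recovery to better than $10^{-6}$ relative; the default axis
carries an $O(nB_{22})$ linearisation bias of a few percent at the top
of the concentration range, visible in the tests as a ~3 % shift of
$R_i$.

**Error-weighting policy.** Whether the published style of this analysis
weights its two linear stages is generally ambiguous in practice, so
both modes are provided (`weighted = FALSE` falls back to OLS
throughout); uncertainties of $n$ itself (concentration errors of
order 1 %) are neglected in the fits.

**Negative slopes.** A fitted $R_i^2 \le 0$ is reported with `ri`
flagged undefined and a warning rather than suppressed: diagnosing an
underpowered or inconsistent series is a primary use of the package.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| Guinier window | 0.015–0.07 | Å⁻¹ | keeps $Q_{\max}R_g \lesssim 1$ for $R_g \approx 13$ Å proteins |
| $Q R_g$ guard | 1.3 | — | conventional upper validity bound; warning, not error |
| background window | 0.35–0.45 | Å⁻¹ | flat incoherent tail of a typical SANS profile; subtracted as a scalar mean |
| abscissa | $-nB_{22}$ | — | dilute form; exact $\xi$ optional |
| $N_A$ | 6.02214076×10²³ | mol⁻¹ | SI exact |

## Potential-theory routines

`ri_from_potential()` and `b22_from_potential()` evaluate the radial
integrals $\int w(r)\,r^{2,4}\,dr$ and the virial integral
$-\tfrac12\int w(r)\,4\pi r^2\,dr$ with $w = e^{-V/k_BT}-1$ (or $w = V$
in weak mode) by piecewise adaptive quadrature (`stats::integrate`) with
mandatory subdivision knots at potential discontinuities — hard cores
break global adaptive schemes otherwise. The cutoff $r_{\max}$ starts
past all structure and doubles until the $r^4$-weighted integral of
$|w|$ is stable to $10^{-10}$ relative; per-piece tolerances are
$10^{-9}$. Closed forms anchor the tests: for hard spheres of diameter
$\sigma$, $R_i = \sqrt{3/5}\,\sigma = 2R_g$ and
$B_{22} = (2\pi/3)\sigma^3$, both matched by quadrature to better than
$10^{-6}$ relative.

Weak mode is refused on a domain containing an infinite hard core, and a
normalizing integral within tolerance of zero (e.g. a potential that is
identically zero, or a sign-balanced mixed potential) raises an
ill-conditioned error instead of returning an unstable ratio — the
framework simply does not define $R_i$ there. For the square well the
weak and Mayer weights are both constant over the well region, so the
two modes agree identically there at any depth; the genuine first-order
convergence of the weak approximation is exercised on a Gaussian well,
where the estimates differ at $O(\varepsilon)$ and the gap shrinks
tenfold per tenfold reduction in depth.

A potential of mean force $\omega(r)$ may be fed through the tabulated
pathway; the quadrature is identical and only the interpretation (valid
at any concentration, rather than dilute) changes.
`structure_factor_numeric()` provides the reference radial Fourier
transform $S(Q) = 1 + 4\pi n\int h(r) r^2 \mathrm{sinc}(Qr)\,dr$ against
which the exponential asymptote is validated: for a dilute hard-sphere
$h$ at $n\sigma^3 = 10^{-3}$, a Guinier-style fit of $\ln S$ over
$QR_i < 0.5$ recovers $R_i$ within 1 %.

## The synthetic-data generator

`simulate_series()` emulates a reduced SANS concentration series the
way the analysis assumes it: $I(Q) = n P(Q) S(Q)$ on a log-spaced
$0.007$–$0.85\,\mathrm{\AA}^{-1}$ grid of 120 points (a typical
small-angle instrument range), with $P$ either a pure Guinier
exponential or a uniform-sphere form factor (radius chosen so
$\sqrt{3/5}R = R_{g,0}$) and $S$ the exponential asymptote
parameterized by $(S(0), R_i)$. Defaults mirror a dilute lysozyme
study: six concentrations 2.45–18.56 mg/mL, $M_W = 14.3$ kDa, mass
density 1.46 g/cm³, $R_{g,0} = 13$ Å, $R_i = 38$ Å,
$B_{22} = -3.8\times10^{-20}$ mL.

Noise is zero-mean Gaussian and heteroscedastic,
$\sigma(Q) = f\,\sqrt{I(Q)\,I(0)}$, which reproduces the
$1/\sqrt{N}$ scaling of detector counting statistics on reduced
(continuous) data; the sigmas are recorded in the `di` column exactly as
a reduction pipeline would. A pure-Poisson option is deliberately
omitted — reduced data are not counts. Simulation is deterministic given
the seed.

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: wavelength-spread/resolution smearing,
multiple scattering, structured (non-flat) backgrounds, polydispersity,
irreversible aggregation, and any $S(Q)$ structure beyond the low-$Q$
exponential (an alternative composition through
`structure_factor_numeric()` with a Mayer $h(r)$ is available to probe
that last misspecification).

**A bias worth knowing about.** With the uniform-sphere form the
truncated Guinier fit is biased slightly *upward*:
$\ln P(x) = -x^2/5 - x^4/350 + \dots$ with $x = QR$, so the neglected
quartic term steepens the apparent slope as the window widens (about
+1.2 % at $Q_{\max}R_g = 1$, monotone in the window edge, vanishing as
it shrinks). The property tests assert this direction and magnitude.

## Problem sizes and runtime choices

The Monte-Carlo recovery study in the test suite uses 200 replicates of
the six-point series at 1 % noise for the headline check (median $R_i$
within 15 % of truth) and 40–60 replicates for the noise-ordering and
undefined-$R_i$ properties; these sizes give stable medians while
keeping the whole suite in a few seconds. The diagnostics null
calibration uses 1000 draws of 21 standardized residuals.

## Known limitations

* The virial stage assumes the dilute expansion $S(0) = 1 - 2nB_{22}$;
  beyond $2n|B_{22}| \sim 0.1$ the abscissa and $S(0)$ both lose
  meaning, and the code refuses $S(0) \le 0$ outright.
* $R_i^2$ can be fitted negative on noisy or repulsion-dominated series;
  it is reported as such rather than clipped.
* No resolution smearing: fitted $R_g$ values from heavily smeared
  instruments will be biased irrespective of this analysis.
* The mixed-sign weak-mode integrand regime (attractive and repulsive
  parts cancelling in $\int V\,d\mathbf r$) has no defined $R_i$; the
  code surfaces the ill-conditioning instead of choosing a value.
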