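---
title: "Quantifying osmotic contributions to cerebrospinal fluid secretion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying osmotic contributions to cerebrospinal fluid secretion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfosmosis)
```

## The question

Cerebrospinal fluid (CSF) is secreted across the choroid plexus epithelium
at a high rate (about 6.8 µl min⁻¹ in the adult rat) even though the
osmolality of CSF and plasma is essentially equal. If water crossed the
epithelium only by conventional osmosis, the measured osmotic water
permeability would demand a large trans-epithelial gradient; if instead
local osmotic gradients formed in flow-protected pockets between the
luminal microvilli, a "standing gradient" could in principle couple solute
pumping to water flow without any bulk gradient. This package implements
the quantitative chain that tests both possibilities: morphometry-derived
membrane geometry, a dye-dilution secretion estimator, the water
permeability calculus, and a standing-gradient boundary-value model of the
inter-microvillar space, together with seeded generators that make every
estimator testable by parameter recovery.

## Secretion from dye dilution

A dextran dye infused into a lateral ventricle at rate $r_i$ with inflow
fluorescence $C_i$ is diluted by newly formed CSF before collection at the
cisterna magna in 5-minute fractions:

$$V_p = r_i \frac{C_i - C_o}{C_o}.$$

`vp_from_dye()` applies the equation per fraction and `windowed_vp()`
averages it over an analysis window. The default windows follow the
experimental design: baseline 50–65 min after infusion start, inhibitor
effect 100–120 min, osmotic challenge 50–75 min; all are arguments, not
constants. Negative per-fraction values (net absorption) are retained in
window means: clipping them would bias the osmotic-challenge regression,
whose hypotonic side genuinely approaches zero or negative net secretion.
Percent inhibition is computed per animal first (each animal is its own
control) and averaged by the caller.

## The water-permeability chain

Regressing per-animal secretion rates on imposed ventricular osmolality
steps gives a slope $s$ in µl min⁻¹ mOsm⁻¹ (`osmotic_challenge_slope()`).
The chain in `permeability_chain()` is then

$$L_{p,\text{trans}} = \frac{s}{A}, \qquad
  L_{p,\text{membrane}} = 2\,L_{p,\text{trans}}, \qquad
  L_{p,\text{luminal,true}} = \frac{L_{p,\text{membrane}}}{\text{amplification}},$$

with $A$ the apparent (cross-sectional) area from tissue wet weight,
$A = m/(\rho_{\text{tissue}} h)$ (4.6 mg at 1 g cm⁻³ and 10 µm cell height
gives 4.6 cm²). The doubling reflects the luminal and basolateral
membranes in series; the amplification rescales to the true, microvillus-
folded membrane area. The required bulk gradient for conventional osmosis
is

$$\Delta\mathrm{Osm}_{req} = \frac{V_p / A}{L_p},$$

about 280–300 mOsm above plasma for the measured inputs — two orders of
magnitude above anything observed. `osmotic_pressure()` expresses such
gradients in van't Hoff pressure units ($\pi = \Delta C\,R\,T$ at
$T = 310$ K, the body temperature; R = 8.314 J mol⁻¹ K⁻¹).

Two input inconsistencies are worth knowing about. First, the printed
slope (0.023) over the printed area (4.6) gives
$L_{p,\text{trans}} = 8.33\times10^{-5}$ cm s⁻¹ Osm⁻¹ whereas the
published figure is $8.7\times10^{-5}$ — evidently computed from an
unrounded slope. The package computes from its inputs and documents the
~4% gap; the chain accepts an `lp_trans_override` to reproduce derived
values from the published permeability exactly. Second, a published
choroidal volume of $4.6\times10^{-9}$ cm³ is dimensionally inconsistent
with 4.6 mg at 1 g cm⁻³ ($4.6\times10^{-3}$ cm³); the downstream area of
4.6 cm² confirms the latter, which is what `apparent_area_from_mass()`
implements.

## Membrane geometry

Microvilli are modelled as cylinders of base radius $r$ and length $l$ at
areal density $\rho$ on a square lattice. The surface amplification is

$$\text{amplification} = 1 - \rho\pi r^2 + \rho\,2\pi r l$$

(flat membrane, minus occluded footprints, plus lateral walls). With
$\rho = 18$ µm⁻², $r = 0.06$ µm, $l = 1.71$ µm this is 12.4-fold,
reported as 12-fold at display precision. The bulbous tip (radius 0.12
µm) is ignored by default because no published formula includes it; a
hemispherical-cap term is available behind the `tip_cap` flag and raises
the factor by $\rho\,2\pi r_{tip}^2 \approx 1.6$. Whether the published
12-fold figure includes any tip or occlusion correction is not stated;
the plain cylinder form lands on it as printed.

The functional unit of the standing-gradient model is the void between
four microvilli: lattice spacing $p = 1/\sqrt{\rho}$, void cross-section
$a_v = p^2 - \pi r^2$, mapped to a hydraulically equivalent circular
cylinder. The default equivalence preserves cross-sectional area
($d = 2\sqrt{a_v/\pi}$); preserving the hydraulic radius instead
($d = 2a_v/(\pi r)$) is available via `hydraulic = "equal-radius"`. The
channel length defaults to the brush-border extent (1.5 µm) rather than
the microvillus length (1.71 µm) because interdigitation makes the
effective flow-protected depth shallower; both are published and the
length is an argument. Per-unit wall area is the unit's share of the
microvillar membrane plus the void base, so that summed over the
$\approx 8.3\times10^9$ units it recovers the true membrane area
(≈56–57 cm²).

## The standing-gradient model

One functional unit is a cylinder closed at the cell base ($x = 0$) and
open to the ventricle at the microvillar tips ($x = L$). Solute enters
through the walls at uniform flux density $\varphi$; at steady state the
whole-tissue solute input equals its removal by bulk CSF drainage, so

$$\varphi = \frac{V_p\,C_0}{n_{\text{units}}\,A_{\text{wall}}}$$

where $V_p C_0$ is the isotonic ion-transfer rate
(`ion_transfer_rate()`; 6.8 µl min⁻¹ at 307 mOsm and density 1.00 g
ml⁻¹ gives $3.48\times10^{-5}$ mmol s⁻¹, counting total osmotic
particles). The coupled steady-state system on $0 \le x \le L$ is

$$D C'' - (vC)' + \frac{s}{A_c}\varphi = 0, \qquad
  v' = \frac{s}{A_c} L_p \sigma\,(C - C_0),$$

with $v(0) = 0$, no diffusive flux through the closed base, and
$C(L) = C_0$. Here $s$ is the wetted perimeter, $A_c$ the channel
cross-section, and the osmotic driving term uses an isotonic cell
interior ($C_0$), the minimal assumption. The base membrane's solute and
water influx is folded into the distributed source via an effective
perimeter $s_{\text{eff}} = \pi d + A_c/L$, which conserves the
walls-plus-base totals exactly while keeping the clean $v(0)=0$ boundary.
Because the equivalent cylinder's lateral surface exceeds the per-unit
membrane share, applying the per-membrane-area flux density over it
slightly overestimates the channel's solute input — a deliberately
generous assumption for the standing-gradient hypothesis, consistent with
assuming that *all* secreted solute passes through the inter-microvillar
space.

### Numerical scheme

No two-point boundary-value collocation solver ships with the available R
stack, and the model is the package's scientific core, so the solver is
implemented here: a conservative finite-volume discretization (central
differencing; the Péclet number of the physiological problem is
$\sim 10^{-10}$) whose discrete face fluxes telescope, so solute
conservation holds to the iteration tolerance rather than the mesh order.
The water–solute coupling strength is measured by the dimensionless group
$\kappa = (s_{\text{eff}}/A_c) L_p C_0 L^2 / D$. In the physiological
regime ($\kappa \sim 10^{-3}$) a Picard iteration on the velocity field
converges in a handful of tridiagonal solves; for $\kappa > 0.5$ (e.g.
permeability sweeps far above the measured $L_p$) the solver switches to
Newton iteration on the full discrete system, whose Jacobian combines the
tridiagonal transport part with the lower-triangular velocity coupling.
Convergence is declared at a relative update below $10^{-12}$ (default);
non-convergence raises an error carrying the residual. Defaults: 1000
cells (mesh-doubling changes the flow by $\ll 0.1\%$), $D = 1.5\times
10^{-5}$ cm² s⁻¹ (aqueous NaCl at 37 °C — the diffusivity is not
published for this model, so it is exposed as an argument),
$\sigma = 1$ (semipermeable walls), $\bar V_w = 18$ cm³ mol⁻¹ (carried
for unit bookkeeping; the hydraulic $L_p$ already maps osmolarity to
volume flux).

An independent closed-form oracle validates the solver: dropping
advection from the solute balance gives
$c(x) = S_\varphi (L^2 - x^2)/(2D)$ and
$v(L) = S_{L_p} S_\varphi L^3 / (3D)$
(`standing_gradient_linearized()`), accurate to well under 1% whenever
the maximum excess is below 1% of $C_0$ — the physiological case, where
the excess tops out near 0.08 mOsm against a 307 mOsm bath.

With the study parameterization the model predicts a whole-tissue flow of
about 0.004 µl min⁻¹ — under 0.1% of the observed 6.8 µl min⁻¹ — and the
same conclusion holds at the lower secretion scale suggested by direct
measurement methods (1.9 µl min⁻¹, with the solute rate rescaled). The
emergent osmolarity (solute flux over water flux at the mouth) is far
above $C_0$, meaning the channel exports its solute mostly by diffusion,
not by carrying water with it: the geometry is simply too open for a
standing gradient to build up. As permeability grows the emergent
osmolarity falls monotonically towards $C_0$ (isotonic secretion), and as
$D$ grows the excess is washed out $\propto 1/D$ — both limits are
exercised in the test suite.

## Tracer kinetics and dose-response

`efflux_rate_constant()` implements the isotope protocol: counts at 0–80
s in 20-s steps, background-corrected by the extracellular mannitol
channel, log-transformed relative to $t=0$ and regressed on time; the
rate constant is the negated slope in min⁻¹. The exact background
formula is unpublished ("corrected for" only), so the default is direct
subtraction with an optional scale factor, clipping at zero with a
warning. `hill_fit()` fits
$Y = Y_{min} + (Y_{max}-Y_{min})/(1 + (IC_{50}/X)^{Hill})$
by bounded Levenberg–Marquardt with documented initialization (plateaus
from extremes, $IC_{50}$ from the geometric mean of the bracketing doses,
Hill slope 1, bounded to [0.1, 10]), making the fit deterministic.

## What the generators emulate — and what they do not

The generators embed known truths and the study's operating points:
5-minute fractions at 9 µl min⁻¹ infusion with multiplicative
fluorescence noise (CV 0.02, chosen so a baseline-window estimate carries
a standard error of ~0.2 µl min⁻¹, the scale of the published 6.8 ± 0.3);
an equilibration ramp over the first 30 minutes, truncated so analysis
windows see the exact steady state (the ramp is cosmetic and outside
every default window); n = 11 osmotic-challenge cohorts whose noise SD
comes from the closed-form R² calibration (`calibrate_noise_for_r2()`)
at the published fit quality of 0.48; Poisson count noise on efflux
(initial level 10⁴ counts, background 200 — typical scintillation
magnitudes); and additive noise at 2% of span on dose-response curves.
Each generator takes an explicit seed, restores the caller's RNG state,
and is byte-identical under a fixed seed.

They deliberately do not emulate: dextran leakage into parenchyma (shown
experimentally to be negligible), drifting physiological baselines,
animal-to-animal variance components beyond a single noise term,
counter dead-time or calibration, or bumetanide autofluorescence in
imaging. Passing recovery tests therefore demonstrates estimator
correctness under the stated noise models, not robustness to every
artefact of real recordings.

## Problem sizes and reproducibility

The test suite uses 200-replicate recovery studies for the perfusion and
challenge estimators, 300 for Poisson efflux, 500 for the R² calibration
check, and 400–2000-cell meshes for the solver; the whole suite runs in
about half a minute. The analysis scripts (`analysis/01…05`) rerun each
stage end-to-end and write their tables under `results/`;
`scripts/acceptance.R` recomputes the headline quantities from the
printed constants alone. Point estimates are used throughout by design —
the published ± SEM values are not propagated through the chain, matching
how the derivation is done in the source study.
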