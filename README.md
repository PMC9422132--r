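# csfosmosis

Quantitative analysis of cerebrospinal fluid (CSF) secretion by the
choroid plexus, for physiologists and modellers asking whether osmosis —
conventional or local — can account for the measured secretion rate.

The package implements the full analysis chain as testable R functions:

- **Secretion analysis** — CSF production from ventriculo-cisternal
  dye dilution, `Vp = ri (Ci − Co)/Co`, with windowed estimates,
  percent inhibition, and the osmotic-challenge regression.
- **Permeability calculus** — the derivation ledger from regression slope
  to trans-epithelial osmotic water permeability `Lp = slope/A`, the
  series-membrane split (×2), the true-area rescaling (÷ amplification),
  the required gradient `ΔOsm_req = (Vp/A)/Lp`, the isotonic ion-transfer
  rate `Vp·C₀`, and van't Hoff pressure equivalents.
- **Morphometry** — microvillar surface amplification
  `1 − ρπr² + ρ2πrl`, apparent area from wet weight, and the
  hydraulically equivalent cylindrical channel of the inter-microvillar
  functional unit.
- **Standing-gradient model** — the Diamond–Bossert coupled steady-state
  system `D C″ − (vC)′ + (s/A_c)φ = 0`, `v′ = (s/A_c) Lp σ (C − C₀)` on a
  channel closed at the cell base and open at the microvillar tips,
  solved by a conservative finite-volume scheme (Picard iteration in the
  weak-coupling regime, Newton beyond), scaled to whole-tissue flow.
- **Tracer kinetics** — isotope-efflux rate constants by log-linear
  regression, imaging-slope extraction, and four-parameter logistic
  (Hill/IC₅₀) fits.
- **Synthetic data** — seeded generators for every input stream, so each
  estimator is validated by parameter recovery without any raw data.

The numbered scripts under `analysis/` run the chain as a narrative
workflow and write tables under `results/`.

## Worked example

```r
library(csfosmosis)

# membrane geometry from printed morphometry
morph <- microvillus_morphometry()       # 1.71 um, r 0.06 um, 18 per um^2
amp   <- surface_amplification(morph)    # 12.40 -> "12-fold"
A     <- apparent_area_from_mass(tissue_gross())  # 4.6 cm^2
true_area(A, amp)                        # 57.0 cm^2

# can conventional osmosis drive 6.8 ul/min?
chain <- permeability_chain(slope_ul_min_mosm = 0.023, area_apparent_cm2 = A,
                            amplification = amp, vp_ul_min = 6.8,
                            plasma_osm_mosm = 306)
print(chain)
#> Osmotic water permeability chain
#>   slope                 : 0.023 ul/min/mOsm over 4.6 cm^2
#>   Lp trans-epithelial   : 8.33e-05 cm/s/Osm
#>   Lp per membrane       : 0.000167 cm/s/Osm
#>   Lp luminal, true area : 1.34e-05 cm/s/Osm (amplification 12.4)
#> Required osmotic gradient: 296 mOsm above plasma (~602 mOsm ventricular) to drive 6.8 ul/min

# can local standing gradients between microvilli?
report <- reproduce_headline()
print(report$standing_gradient)
#> Predicted local-osmosis flow 0.0044 ul/min = 0.0646% of the observed 6.8 ul/min
```

The verdict in numbers: conventional osmosis would need a ~300 mOsm
trans-epithelial gradient where ~1 mOsm is observed, and the
standing-gradient model assigns under 0.1% of the observed secretion to
local osmotic forces in the inter-microvillar space (its peak excess is
only ~0.08 mOsm above the 307 mOsm bath). CSF secretion must therefore
rely on mechanisms other than osmotic water flow.

Dye-dilution, efflux and dose-response estimators are validated by
recovery on seeded synthetic data, e.g.

```r
s <- simulate_perfusion(true_vp = 6.8, noise_cv = 0.02, seed = 20260930)
windowed_vp(s, c(50, 65))
#> CSF production 6.87 +/- 0.38 ul/min (n = 3 fractions, window 50-65 min)

e <- simulate_efflux(k_per_min = 0.40, seed = 20260930)
efflux_rate_constant(e)
#> Efflux rate constant 0.420 min^-1 (R^2 = 0.995, control)
percent_inhibition(0.40, 0.15)   # 62.5 (% reduction by NKCC1 inhibition)
```

See `vignettes/csf-secretion-analysis.Rmd` for the model derivations,
parameter choices, and numerical details.

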