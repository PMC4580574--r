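# paratymp

Quantitative tools for ontogenetic studies of the crocodylian middle-ear
(paratympanic) sinus system. The paratympanic sinuses are air-filled
epithelial evaginations of the pharynx that excavate the bones of the skull;
their volume and conformation change through growth and bear directly on
middle-ear acoustics. `paratymp` turns the three quantitative questions such
a study asks into tested, reproducible code:

1. **How big is each air space?** Per-compartment volume and surface area
   from segmented CT label volumes, plus splitting of confluent air spaces at
   their soap-bubble-like constrictions (`measure_compartment()`,
   `extract_isosurface()`, `split_at_constrictions()`).
2. **How does middle-ear volume scale with the rest of the head?**
   Reduced-major-axis (standardized major axis, SMA) allometry of
   log-transformed variables against a geometric-mean skull-size variable,
   with confidence intervals and slope tests against isometry nulls
   (`geometric_mean_size()`, `fit_sma()`, `slope_test()`, `run_allometry()`).
3. **What does the air space do acoustically?** A Helmholtz-resonator model
   of the middle-ear cavity with flanged/unflanged end corrections
   (`helmholtz_frequency()`, `resonance_series()`, `band_overlap()`).

A synthetic-data module (`generate_growth_series()`, `generate_phantom()`,
`analytic_metrics()`) generates ontogenetic series with known allometric
exponents and phantom label volumes with closed-form ground truth, so every
stage is testable without imaging data.

## The models

**Size.** Skull size is the geometric mean of 27 linear skull measurements
(GMS): `GMS = (prod m_i)^(1/27)`, computed in log space. Dorsal skull length
(DSL) is the series' primary size axis.

**Allometry.** All variables are log10-transformed and fitted by SMA:
`slope = sign(r) * s_y / s_x`, with the slope CI from
`B = F(1-a; 1, n-2) (1-r^2)/(n-2)` and bounds `slope (sqrt(B+1) +/- sqrt(B))`.
Isometry nulls are 3 (volume on a linear size), 1.5 (volume on an area) and
1 (volume on a volume); the slope test correlates the residual and fitted
axes under the null and refers `t = r_rf sqrt((n-2)/(1-r_rf^2))` to a
Student t with n-2 df. A fitted slope below a rejected null is negative
allometry: the air space grows more slowly than geometric similarity
predicts.

**Acoustics.** The middle-ear cavity is a Helmholtz resonator:
`f = (c / 2 pi) sqrt(A / (L V))` with aperture area A, cavity volume V, and
effective neck length `L = l + 1.4 r` for an unflanged aperture (e.g. the
subtympanic foramen) or `L = 1.7 r` for a flanged one (the tympanic
membrane, actual neck length zero), where `r = sqrt(A/pi)` is the
equivalent-circle radius. Under geometric growth, f scales as 1/size, so a
narrow observed band of resonant frequencies across a 19-fold size range
implies compensatory (frequency-locked) growth of the cavity.

## Worked example

```r
library(paratymp)

gen <- generate_growth_series(growth_series_config(seed = 42, n = 13))
rep <- run_allometry(gen$series)
rep[, c("regression", "n", "r2", "slope", "ci_low", "ci_high", "p", "decision")]
#>     regression  n     r2  slope ci_low ci_high         p              decision
#> 1  ME_v on GMS 13 0.9996 1.9863 1.9597  2.0132 7.034e-16    negative allometry
#> 2 ME_v on BC_v 13 0.9984 0.8333 0.8113  0.8558 1.048e-08    negative allometry
#> 3 ME_v on T_sa 13 0.9969 1.4758 1.4219  1.5317 3.563e-01 isometry not rejected
```

The 13-specimen synthetic series was generated with the default exponent
presets (middle-ear volume growing as GMS^1.9735), and the analysis recovers
that structure: middle-ear volume is in strong negative allometry with skull
size (slope 1.99, far below the isometric 3) and with braincase volume
(0.83 < 1), while tympanum area stays isometric with middle-ear volume
(CI spans the null 1.5, p = 0.36).

```r
sub <- gen$resonators[gen$resonators$aperture == "subtympanic", ]
out <- resonance_series(sub)
head(out$results, 3)
#>   specimen_id    aperture   r_mm   L_mm f_hz
#> 1      SYN001 subtympanic 0.2323 0.9555 4287
#> 2      SYN002 subtympanic 0.3746 1.5078 3543
#> 3      SYN003 subtympanic 0.6136 2.4865 2703
sprintf("band: %.0f-%.0f Hz (ratio %.2f)", out$band[1], out$band[2], out$band_ratio)
#> "band: 1331-4287 Hz (ratio 3.22)"
```

Because this series follows its own allometric scaling with no acoustic
compensation, the subtympanic resonance drifts 3.2-fold across the series;
regenerating with `compensation = "frequency_locked"` holds the band ratio
near 1, the signature of a middle ear tuned to a fixed frequency range
through growth.

```r
g <- resonator_geometry(10, 1000, "unflanged", neck_length_mm = 2)
helmholtz_frequency(g)
#> resonance: f = 2574 Hz (r = 1.784 mm, L = 4.498 mm)
```

A single cavity of 1000 mm^3 breathing through a 10 mm^2 unflanged aperture
with a 2 mm neck resonates at 2.57 kHz.

An end-to-end run (`run_pipeline(list(seed = 42, out_dir = "out"))`) writes
the series, the Table-shaped allometry report, per-aperture resonance bands
and a provenance-stamped JSON/markdown report; the same config and seed
reproduce every output byte-identically. A command-line wrapper is installed
at `inst/cli/paratymp`.

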