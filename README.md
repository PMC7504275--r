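# tgquant

Triacylglycerol (TG) analysis for high-temperature GC-FID peak tables, and
detection of rapeseed/olive oil blending from TG profiles.

TGs are >95% of an edible oil's mass, and their species profile is a
fingerprint that survives refining. `tgquant` covers the full workflow from
an integrated peak table (retention time, area) to an adulteration verdict:

* **Nomenclature & descriptors** — parse names like `OOLn` into acyls and
  compute CN (carbon number), DB (double bonds) and the equivalent carbon
  number **ECN = CN − 2·DB** (`parse_tg_name()`, `ecn()`, `tg_describe()`).
* **Identification** — relative retention times
  `rrt = (rt − rt_solvent)/(rt_IS − rt_solvent)` matched on a
  log(rrt)-versus-DB interpolation chart built from monoacid standards
  (`fit_identification_plot()`, `predict_rrt()`, `identify_peaks()`).
* **Quantitation** — internal-standard (trinonadecanoin, NNN) quantitation
  with relative response factors,
  `c_i = A_i/(RRF_i·A_IS) · m_IS/m_oil · 1000` mg/g, plus composition and
  ECN-group percentages (`quantify()`, `composition_percent()`,
  `ecn_group_composition()`).
* **Method validation** — recovery, RSD, intraday/interday precision, LOD
  and LOQ = 3·LOD (`recovery()`, `rsd()`, `precision()`, `lod_loq()`).
* **Adulteration screening** — indicator TGs (PPO, PPL, PSO for olive oil;
  OOLn for rapeseed) with LOD-derived detection floors, and blend-fraction
  estimation by weighted least squares under the linear mixing model
  `q = f·a + (1−f)·b` (`blend_model()`, `detect_indicators()`,
  `estimate_blend_fraction()`).
* **Simulation** — a seeded generator of realistic chromatogram peak
  tables (`sim_config()`, `generate_peak_table()`, `generate_blend_series()`)
  so every stage is testable without instrument data.

The packaged reference tables (17 TG standards; pure-oil and blend
compositions) ship as plain CSV under `inst/extdata/` and load via
`tg_standards()` and `oil_profile_fixture()`.

## Worked example

Simulate a 2.5% olive-in-rapeseed blend, run the pipeline, and screen it:

```r
library(tgquant)

cfg <- sim_config(seed = 42)             # study conditions, 5% area noise
bm  <- blend_model(cfg$profiles$OO, cfg$profiles$RRO)
mix <- mix_profiles(0.025, cfg$profiles$OO, cfg$profiles$RRO)

pt   <- generate_peak_table(mix, cfg, seed = 42)
prof <- analyze_peak_table(pt, cfg)      # identify -> assign -> quantify

floors <- indicator_floors(cfg$lod, union(bm$indicators_a, bm$indicators_b))
est <- estimate_blend_fraction(prof, bm, "a_in_b", rsd = cfg$rsd, floors = floors)
est$status
#> [1] "detected"
round(est$f_hat, 4)
#> [1] 0.0263
round(est$per_indicator$f_hat, 4)
#> [1] 0.0267 0.0255 0.0280
```

The blend is flagged through the olive-oil indicators and the weighted
least-squares inversion of the mixing model recovers the declared 2.5%
fraction (f̂ = 0.0263 under this draw of 5% area noise); the per-indicator
ratios `q_i / a_i` agree. The
numbered scripts under `analysis/` run the same machinery over the packaged
composition tables (descriptor checks, composition and ECN-group shares,
adulteration screening, simulation recovery) and write their tables under
`results/`.

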