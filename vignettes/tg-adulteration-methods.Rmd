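---
title: "Methods: TG identification, quantitation and oil-blend detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TG identification, quantitation and oil-blend detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgquant)
```

## The problem

Olive oil commands a price that invites blending with cheaper oils such as
refined rapeseed oil, and bulk physical properties (refractive index,
viscosity) cannot expose such blends. Triacylglycerols (TGs) make up more
than 95% of an edible oil's mass, and the TG *profile* — which molecular
species are present and at what level — differs between oils in ways that
survive refining. `tgquant` implements a complete high-temperature GC-FID
workflow over integrated peak tables: identify TG peaks from retention
behaviour, quantify them against an internal standard, and screen for
blending using indicator TGs under a linear mixing model.

## TG nomenclature and descriptors

A TG is named by concatenating three acyl codes (P = 16:0, S = 18:0,
O = 18:1, L = 18:2, Ln = 18:3, N = 19:0); `parse_tg_name()` tokenizes
greedily so "Ln" is one acyl, never "L" plus a stray letter. Three
descriptors drive everything downstream:

* **CN**, carbon number: total acyl-chain carbons (glycerol excluded), so
  CN(PPP) = 48;
* **DB**, total double bonds;
* **ECN = CN − 2·DB**, the equivalent carbon number. On a 65%-phenyl
  high-temperature column TGs elute roughly by CN and, within a CN, by DB,
  so TGs of equal ECN cluster; literature oil compositions are convention-
  ally reported as ECN-group percentages.

Positional isomers (OOP vs OPO) share an acyl multiset and co-elute on
this column class, so identity and aggregation are by multiset; sn-position
semantics are out of scope throughout.

## Retention model: the log(rrt)–DB chart

Absolute retention times drift run to run; the physically stable quantity
is the relative retention time

$$\mathrm{rrt} = \frac{rt_{\text{analyte}} - rt_{\text{solvent}}}
                     {rt_{\text{IS}} - rt_{\text{solvent}}},$$

which is invariant under affine rescaling of the time axis (a tested
property). Identification uses a chart in (DB, log rrt) space,
`fit_identification_plot()`:

1. saturated monoacid standards (PPP, SSS, NNN) sit on the DB = 0 axis;
2. monoacid unsaturated standards (OOO, LLL) are anchors at DB = 3, 6;
3. anchors of two acyls are joined by straight lines; a TG of two acyl
   types sits on the corresponding line at its DB, interpolated linearly
   in log rrt (`predict_rrt()`);
4. a TG of three acyl types sits "between the lines": we predict it as the
   log-scale mean of the pairwise-line interpolations whose DB span covers
   the TG's DB, an unbiased centre of the region, and widen the matching
   tolerance 1.5-fold for such predictions.

Two extensions make the chart total over the profiled TGs:

* **Virtual anchors.** Linolenoyl (Ln) has no monoacid standard in the
  set. Its anchor is inferred by inverting the two-acyl interpolation
  through OOLn along the O/Ln line, which reproduces OOLn's observed rrt
  exactly and lets POLn be predicted.
* **Saturated mixed TGs** (PPS: both acyls at DB = 0) cannot be separated
  in DB; they are interpolated in CN along the DB = 0 axis instead
  (predicts PPS at 0.764 vs 0.77 observed).

### Reference rrts and de-rounded collisions

For candidates that *are* standards, matching uses the observed standard
rrt rather than the chart prediction — exactly how an analyst uses the
chart. Observed rrts are tabulated to two decimals, which collapses pairs
of genuinely distinct species (OOP/PSO both print 0.85, SSO/SSS 0.91,
LLO/LLS 0.95) even though the method quantifies them separately, so the
column must resolve them. The reference table therefore "de-rounds" each
collision group deterministically: members are ordered by their chart-
predicted rrt and spaced 0.004 apart centred on the printed value, staying
inside the ±0.005 rounding band. Non-colliding standards keep their
printed value exactly, and every reference still rounds back to the
printed table at two decimals (a tested invariant).

### Matching and assignment

`identify_peaks()` reports, per peak, *every* candidate within tolerance
ranked by |Δ log rrt| — ambiguity (e.g. a peak at rrt 0.85) is data, never
silently resolved. The default tolerance, 0.0105 log-rrt units (≈ 0.01 rrt
in the TG elution region, the printed rounding grid), is configurable.
`assign_identities()` then resolves ranked sets one-to-one, greedily by
increasing distance, so adjacent OOP/PSO peaks each take their nearer
identity. Peaks with no candidate stay unknown; a below-floor area filter
removes solvent-tail artifacts before matching.

## Quantitation

Trinonadecanoin (NNN) is the internal standard because C19 acyls do not
occur in edible oils. Each TG's relative response factor is

$$\mathrm{RRF} = \frac{A_{\text{std}}/c_{\text{std}}}{A_{\text{IS}}/c_{\text{IS}}},$$

so a compound responding more strongly than NNN has RRF > 1 and its area
is divided by RRF:

$$c_i\ (\text{mg/g}) = \frac{A_i}{\mathrm{RRF}_i \cdot A_{\text{IS}}}
  \cdot \frac{m_{\text{IS}}}{m_{\text{oil}}} \cdot 1000 .$$

The formula's orientation is pinned by a round-trip property: simulating a
chromatogram from a profile with any positive RRF set and quantifying it
back reproduces the profile exactly at zero noise. Contents whose implied
in-vial concentration (30 mg oil + 3 mg NNN in 10 mL: 1 mg/g ↔ 3 µg/mL)
falls below the TG's LOD are reported **Nd** — a state distinct from zero,
preserved through file I/O as the token `"Nd"` and propagated as zero only
inside sums.

Composition percentages divide by the summed *quantified* TG mass, not by
1000 mg/g of oil — the convention under which the reported blend
percentages (OOP 9.24% at 2.5% olive-in-rapeseed) reproduce. Reported
figures use half-up rounding at the printed precision (integers for
pure-oil shares, two decimals for blend indicators); `composition_percent()`
itself returns exact values summing to 100.

## Validation metrics

`recovery()` (100·detected/spiked, flagged outside 70–130%), `rsd()`
(sample-sd/mean·100; the n−1 sd is chosen because replicate counts are
3–6), `precision()` (intraday: mean within-day RSD; interday: RSD of day
means) and `lod_loq()` implement the standard formulas. LOD uses the
blank-to-signal ratio at the lowest calibration level — a deliberately
literal implementation of an unusual, loosely specified rule — and LOQ is
defined as 3 × LOD. Measured recoveries and LODs are instrument
properties and are not simulation targets; the suite checks the formulas'
structural properties (scale invariance, the exact 3× ratio) instead.

## Adulteration detection and the mixing model

Indicator TGs are species quantified in one pure oil and Nd in the other:
PPO, PPL and PSO mark olive oil added to rapeseed; OOLn marks rapeseed
added to olive. `blend_model()` verifies this asymmetry against the stored
pure profiles. Blending is mass-linear,
$q_i = f\,a_i + (1-f)\,b_i$, ignoring the (sub-percent) density difference
between the oils since blends are prepared by mass.

**Detection floors.** An indicator flags a direction when its quantified
content reaches its floor. The default floor converts the TG's LOD through
the sample prep (LOD/3 in mg/g; TGs without a tabulated LOD conservatively
take the largest LOD, 0.330 µg/mL → 0.11 mg/g). Detection-limit floors —
rather than quantitation-limit floors — are the design choice because
flagging is a *detection* decision, and because at a 1% blend the
theoretical indicator contents (PPO 0.21, PPL 0.09, PSO 0.07 mg/g) sit
between the two: with LOQ floors a 1% olive-in-rapeseed blend could not
flag even in principle, while LOD floors flag it through all three
indicators. An LOQ-based floor remains available via the `floors`
argument.

**Fraction estimation.** Per indicator, $\hat f_i = q_i / a_i$. The
combined estimate solves the weighted least squares
$\min_f \sum_i w_i (q_i - b_i - f\,(a_i - b_i))^2$ over all TGs quantified
in either pure oil, clipped to [0, 1]. Weights are inverse squared
absolute uncertainties with each TG's reported RSD as the relative scale
(median RSD when unreported, and a 1 mg/g scale floor so Nd entries keep
finite weight); this makes the high-contrast indicator TGs dominate, as
they should, while abundant-but-similar species like OOO contribute little.

## The synthetic-data generator

`sim_config()` + `generate_peak_table()` emulate the study conditions: the
two packaged pure-oil profiles, blend fractions 1/2.5/5/10% in both
directions in triplicate, 30 mg oil + 3 mg NNN in 10 mL, the packaged
rrt/RRF/LOD tables, and 5% multiplicative area noise (lognormal, keeping
areas positive — matching the observed ≈5% area precision). Retention-time
jitter is Gaussian truncated at ±3σ and off by default (intraday rt spread
is < 0.5%; quantitation simulations exercise area noise); the precision
tests switch it on at 0.3%. The absolute time axis (solvent 2.0 min, IS
27.0 min) is an arbitrary fixed constant — only rrt matters, and the
generator places standards exactly at their reference rrt so zero-jitter
chromatograms reproduce the printed retention table at printed precision.
Positional isomers in a profile merge into one peak; TGs below LOD are
omitted and re-emerge as Nd. Every generator is a pure function of its
seed and leaves the caller's RNG state untouched.

What the generator does *not* emulate: raw detector traces (peak shapes,
baselines, integration error), retention drift within a run, matrix
effects on response factors, and — important for interpretation — the
non-linear enrichment visible in the measured blend profiles, where
indicator contents at low fractions exceed the linear mixing prediction
several-fold. Passing simulation tests therefore demonstrate correctness
of the estimators under the stated noise model, not immunity to real
instrument bias; on the measured blend profiles the package flags every
blend but over-estimates f, as the analysis scripts show honestly.

## Numerical choices and problem sizes

* Interpolation is linear in DB on the log(rrt) scale, the space the chart
  is drawn in; evaluated at integer DB.
* Matching tolerance 0.0105 log-rrt (≈ the 2-decimal rounding grid),
  ×1.5 for chart-predicted three-acyl TGs; ties in ranked sets break
  alphabetically for determinism.
* rrt is not strictly monotone in DB at fixed CN (SSO and SSS both ≈
  0.91); identification is tolerance-based, never order-based.
* Calibration r² is computed from residual and total sums of squares
  (degenerate zero-variance responses get r² = 0 and a nonlinearity flag;
  the flag floor 0.99 reflects the weakest curve observed in validation).
* The recovery study in the test suite runs 200 replicates per fraction ×
  2 directions × 4 fractions; the analysis driver uses 100 replicates.
  Monte-Carlo noise checks use 1000 draws.

## Known limitations

* Retention prediction requires every acyl to be anchored (directly or
  virtually); exotic acyls need either a standard or a registry entry plus
  a mixed standard to invert through.
* Peaks of distinct species closer than the tolerance are reported
  ambiguous; one-to-one assignment resolves them only when both are
  present. This mirrors the method's real resolution limit.
* The mixing model is two-component; ternary blends or adulterants other
  than the two profiled oils are out of scope, as are chemometric
  classifiers.
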