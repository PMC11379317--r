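---
title: "Bi-frequency acoustic estimation of copepod biomass: models and methods"
author: "zoosonde"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bi-frequency acoustic estimation of copepod biomass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoosonde)
```

## The problem

Copepods dominate mesozooplankton abundance in most productive shelf seas,
but they are weak acoustic targets: a 1 mm fluid-like body has a target
strength near −120 dB at 38 kHz. Single-frequency echo integration cannot
separate them from krill, fish, or other scatterers. The bi-frequency
approach exploits the fact that fluid-like scatterers sit deep in the
Rayleigh regime at 38 kHz but much less so at 120 kHz, so the dB difference
of the mean volume backscattering strength,
$\Delta\mathrm{MVBS} = \mathrm{MVBS}_{120} - \mathrm{MVBS}_{38}$, is large
and *size-dependent* for copepods, small for krill, and non-positive for
swim-bladdered fish. `zoosonde` turns this into a quantitative estimator of
copepod numerical density and dry-mass biomass and maps it geostatistically.

## Echo-integration grid

Raw Sv samples are resampled to analysis cells of 3 pings × 1 m between
10 and 200 m (`resampleToCells()`). All averaging happens on the linear
coefficient $s_v = 10^{\mathrm{Sv}/10}$; thresholds are applied in dB.
Design choices the data model fixes:

* cell lattice anchored at the first ping and the 10 m analysis ceiling;
  trailing partial cells are dropped rather than padded, so no cell mean is
  built from fewer members than the rest;
* depth positive down, bin intervals half-open $[z_\mathrm{top},
  z_\mathrm{bot})$, cell depth at the bin midpoint;
* the integration floor is applied **per raw sample** before averaging
  (mirroring echo-integration practice); a cell becomes missing only when
  every member fails;
* cells missing in either frequency are `EXCLUDED` everywhere downstream.

### The integration floor and weak scatterers

The classical −80 dB integration floor is the package default, but it
deserves a warning that the original workflow leaves implicit: under the
fluid-sphere model a realistic copepod layer (say 10 ind m⁻³ of 0.9 mm
animals) produces $\mathrm{Sv}_{38} \approx -111$ dB — *below* a −80 dB
floor. Applied literally at the sample level, the floor would blank the
weak channel entirely and no ΔMVBS could be formed. The floor is therefore
a per-run parameter (`svThresholdDb`); the bundled synthetic scenarios run
at −140 dB, below the simulated noise floor, so the weak-channel signal
survives. Users working from instruments with a hardware noise floor should
set it just above that floor, not at fish-survey levels.

## The discrimination cascade

`classifyCells()` applies, in fixed order: (1) the fish gate
$\Sigma\mathrm{MVBS} > -119$ dB; (2) $\Delta\mathrm{MVBS} < 2$ dB → OTHER;
(3) $[2, 7)$ dB → KRILL; (4) $[7, 25]$ dB → COPEPOD; (5) above 25 dB →
OTHER; (6) any non-fish cell with $\mathrm{MVBS}_{120} > -65$ dB → OTHER.
Points worth making explicit:

* $\Sigma$MVBS is the literal dB sum of the two channels — a discriminant
  score, not a physical power sum.
* The printed class windows "2–7" and "7–25" overlap at 7 dB; the package
  resolves the tie half-open, with exactly 7 dB going to copepod (the
  headline class).
* The −65 dB upper threshold is applied to the 120 kHz channel, where
  fluid-like scatterers are strongest; the source procedure does not name
  the channel. Note the interaction: a *very* dense copepod layer can
  legitimately exceed −65 dB at 120 kHz and will be discarded as "other" —
  the procedure trades a small high-density bias for robustness against
  residual fish echoes.
* The fish gate can be refit per survey with `fitFishThreshold()`: a
  two-component Gaussian mixture (EM, unequal variances, ten deterministic
  decile-split restarts — no RNG, hence bit-reproducible) whose decision
  boundary is the equal-weighted-density point between the component means,
  falling back to −119 dB when the components nearly coincide. The pipeline
  default keeps the fixed −119 dB gate (`fitFishThreshold = FALSE`): on
  scenes whose ∑MVBS histogram has more than two modes (fish + krill +
  copepod), a two-component fit can place the boundary between plankton
  modes instead of under the fish mode.
* The rescue pass (`rescueFluidInFish()`) is the package's reading of the
  "smoothing and reintegration" of fluid echoes inside fish schools, which
  the source does not define operationally: a single deterministic
  ping-major pass in which a FISH cell whose own ΔMVBS lies in a fluid
  window and whose 3×3 neighbourhood holds a fluid-like majority is
  relabelled to the class its ΔMVBS indicates.

## The high-pass fluid-sphere model

For a fluid sphere of radius $a$ with density contrast $g$ and sound-speed
contrast $h$ in water of sound speed $c$:

$$\sigma_{bs} = \frac{a^2 (ka)^4 \alpha^2}{1 + 4 (ka)^4 \alpha^2 / R^2},
\qquad R = \frac{gh - 1}{gh + 1}, \qquad
\alpha = \frac{1 - gh^2}{3gh^2} + \frac{1 - g}{1 + 2g},$$

with $k = 2\pi f / c$ and $\mathrm{TS} = 10\log_{10}\sigma_{bs}$. Defaults
$g = 1.02$, $h = 1.058$ are the standard literature values for fluid-like
crustaceans; $c = 1508$ m s⁻¹ corresponds to 14.9 °C / 35.7 PSU via the
Mackenzie nine-term formula (`soundSpeed()`, evaluated at a 50 m reference
depth by default). Two limits anchor the implementation and its tests:
the Rayleigh form $a^2(ka)^4\alpha^2$ as $ka \to 0$, and the plateau
$a^2 R^2/4$ as $ka \to \infty$. (A common printed form of the geometric
limit omits $R^2$; the limit implied by the full expression above is the
one implemented.)

$\Delta TS(a) = TS_{120} - TS_{38}$ is *globally* strictly decreasing in
$a$, from the closed-form ceiling $40\log_{10}(120/38) = 19.98$ dB toward
zero, which makes the size inversion (`invertSize()`, vectorized bisection
to $10^{-4}$ mm) unambiguous on any band.

### The size band, and two numerical caveats

The copepod analysis band defaults to $\Delta TS \in [7.0, 19.7]$ dB. The
band's size edges are **computed from the model** rather than hard-coded:
under the defaults they come out at 0.639 mm and 2.775 mm (ka 0.18–0.78 at
the geometric-mean frequency $f_m = \sqrt{f_{38} f_{120}}$). The printed
triplet usually quoted with this band (0.5 mm / 3.1 mm / ka 0.14–0.81) is
not exactly self-consistent with the model equations: the model's
$\Delta TS$ at 0.5 mm is 19.87 dB, not 19.7. The package treats the dB
edges as authoritative and lets the sizes follow.

ΔMVBS values outside the band clamp to the nearest edge and are flagged
(`clamped`); they are retained, as in the source procedure, rather than
discarded.

Second caveat: near the Rayleigh ceiling the curve is nearly flat —
around 0.9 mm, $\mathrm d\,\Delta TS / \mathrm d a \approx -2.7$ dB mm⁻¹
while $\mathrm d\,TS_{120}/\mathrm d a \approx +29$ dB mm⁻¹, so
1 dB of ΔMVBS noise maps to roughly 10 dB of TS error, i.e. an order of
magnitude in density. Size inversion of sub-millimetre copepods from noisy
38/120 kHz pairs is therefore intrinsically ill-conditioned; the package
documents this rather than hiding it, and its noise-recovery tests use a
mid-band truth size (1.5 mm, slope ≈ −7.5 dB mm⁻¹) where the inversion is
well conditioned. For field data the practical mitigations are averaging
to larger cells before inversion and treating sub-millimetre size
estimates as qualitative.

## Density, ESUs, biomass

Each copepod cell yields $N_f = 10^{(\mathrm{Sv}_f - TS_f)/10}$ ind m⁻³,
with per-cell size-specific TS (not a survey mean) and the 120 kHz channel
by default (the stronger fluid-like signal; 38 kHz is supported and agrees
within 1 % at zero noise). Densities integrate by the rectangle rule over
depth and are partitioned along-track into ESUs (default 0.001 nmi) by
cumulative great-circle distance. Biomass uses
$B = N \cdot DM_m$ with $DM_m$ either configured (217 µg default) or
recomputed from a scanner table: pixel areas convert at the 10.6 µm pitch
($S = \mathrm{px} \times 0.0106^2$ mm²), ESR is the area-equivalent circle
radius $\sqrt{S/\pi}$ (the source never defines its ESR–area relation; this
is the natural choice for 2-D scans), organisms with ESR > 0.5 mm are
retained, and $DM = aS^b$ with the literature subtropical-mesozooplankton
coefficients (45.25, 1.59) as *configuration*, not measurements — biomass
scales directly with them. NASC ($s_A = 4\pi \cdot 1852^2 \int s_v\,dz$)
is carried per ESU as an abundance proxy.

## Diel stratification

Solar altitude comes from a NOAA-style approximation (declination and
equation of time as short Fourier series in the fractional year; accuracy
well inside ±0.5° for contemporary dates, no refraction). ESUs with
altitude in (−18°, +18°) — dawn and dusk, when vertical migration is in
progress — are labelled `transition` and excluded from day/night
comparisons; boundaries are closed on the day/night side. The source text
says "azimuths" while parenthesizing altitudes; altitude is the physically
meaningful quantity and is what the package uses.

## Geostatistics

ESU biomass is interpolated by ordinary kriging on a 0.05° grid
(`ordinaryKrige()`): Matheron empirical variogram on great-circle
distances, weighted-least-squares fit (weights $n_p/h^2$) of a spherical
(default) or exponential model from a deterministic grid of starts, then
per-node solution of the standard OK system with the 16 nearest points.
Numerical choices: $\gamma(0) = 0$ so the predictor is exact at data
locations when the nugget is zero; the system is scaled by the sill before
solving (the weights are invariant, and unscaled semivariances of
mg m⁻² fields are ~10⁹ against the unbiasedness row of ones, which makes
`solve()` report singularity); a singular neighbourhood is retried once
with a 10⁻⁹ diagonal jitter; nodes outside the data's convex hull (or a
supplied polygon) are skipped; cell areas use spherical geometry and
shrink with cos(latitude). A fit whose range collapses below the first lag
is flagged `flat`. Total biomass is $B_t = \sum_i B_i A_i$ (mg → tons)
with negative predictions clipped to zero and counted. The CV aggregates
kriging variances under cell independence,
$\mathrm{CV} = 100\sqrt{\sum\sigma_i^2 A_i^2} / B_t$ — an approximation
(kriging errors are correlated), documented as such and not used as a
validation target. The source describes its interpolation both as "simple"
and as "ordinary" kriging; ordinary kriging is implemented, matching the
mapped product and the default of the cited toolchain. Moran's I with
row-standardized inverse-distance weights screens autocorrelation.

## The synthetic-survey generator

`syntheticTruth()` fixes a scene; `genSurvey()` forward-models it as
$s_{v,f} = N \cdot \sigma_{bs}(a, f)$ per cell plus Gaussian dB noise, so
at zero noise a copepod cell's ΔMVBS equals the model ΔTS of its size
*exactly* and the classify → invert chain is testable as an identity. The
defaults are the study conditions the package is validated under:

| quantity | default | rationale |
|---|---|---|
| pings / cells | 600 pings, 3×1 m cells, 10–200 m | one diel cycle at 144 s/ping; desk-scale |
| copepod density | 10 ind m⁻³ (day) | with the ×7 diel factor and ~75 m layer, areal biomass spans ~120–1100 mg m⁻², the range reported for productive upwelling shelves |
| patchiness | log-Gaussian, sd(log) = 0.5, AR(1) length 10 blocks | simplest structure matching patchy layers |
| size | ESR median 0.9 mm, sd(log) 0.15 | matches the reported mean size; gives mean individual DM ≈ 220 µg ≈ the 217 µg reference under the default allometry |
| krill | ESR 3.5 mm (model ΔTS ≈ 4.2 dB), rectangular patches | lands inside the 2–7 dB window by construction |
| fish | Sv₃₈ = −58 dB, ΔMVBS ~ U(−3, 0), rectangular schools | high ∑MVBS, non-positive ΔMVBS |
| noise | σ = 1 dB per sample and channel | typical calibrated-echosounder residual |
| nets | efficiency q = 0.1, Poisson counts, volume = 0.25 m² × height × 5 | reproduces the ~10× acoustic:net gap |

What the generator does *not* emulate: vertical migration of the layer
depth (only the density factor changes at night), school/patch morphology,
frequency-dependent noise, bubble attenuation, and net avoidance beyond
the scalar efficiency. Passing tests therefore demonstrate the estimator's
internal consistency and noise behaviour, not instrument-level realism.

Problem sizes used by the test-suite scenarios: surveys of 90–1200 pings ×
190 depth bins, 200 kriged ESUs on ~70 grid nodes, 5000-item scanner
tables; the full suite runs in well under a minute.

## Known limitations

* The band-edge ill-conditioning above: densities inverted from sizes
  ≲ 1 mm are noise-amplified and, in the clamped tail, biased high.
* The CV formula ignores spatial correlation of kriging errors.
* Isotropic variograms only; anisotropic plankton structure (fronts,
  along-shore bands) is not modelled.
* Single-species inversion: the dominant scatterer's signal is inverted;
  mixed assemblages inside one cell are attributed entirely to copepods.
* The allometric coefficients and g/h contrasts are literature values;
  biomass scales multiplicatively with any error in them.
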