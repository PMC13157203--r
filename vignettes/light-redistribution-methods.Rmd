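---
title: "Methods: modelling light redistribution by dissolving microneedle arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling light redistribution by dissolving microneedle arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnphotodose)
```

## The physical picture

A dissolving microneedle (MN) array pressed into skin during photodynamic
therapy does two jobs: its pyramidal tips carry the photosensitizer
precursor past the stratum corneum, and the same tips — through multiple
internal reflections and surface roughness — scatter the incident laser
beam into an almost isotropic emission. The package models the second job
at two levels:

* **Continuum model.** The array is idealized as a disk of radius $R$
  carrying isotropic point emitters at uniform surface density $\sigma$.
  Each emitter obeys the inverse-square law $I = I_0 (r_0/d)^2$ with
  reference intensity $I_0$ at distance $r_0$. Collecting the emitters in
  the annulus at radius $r$ (all at distance $d = \sqrt{\rho^2+r^2}$ from
  the on-axis point at distance $\rho$) and integrating over the disk with
  the substitution $x = r^2$ gives
  $$ I(\rho) \;=\; \pi \sigma I_0 r_0^2 \,
     \ln\!\frac{\rho^2 + R^2}{\rho^2} \; e^{-\alpha\rho}, $$
  where the Beer–Lambert factor $e^{-\alpha\rho}$ carries the medium's
  attenuation. The attenuation is applied **globally to the axial distance**
  $\rho$, not along each emitter's path $d_i$; since every $d_i \ge \rho$,
  the per-emitter variant (available in the Monte-Carlo oracle for
  sensitivity analysis) is bounded above by the global form, a fact the
  test suite asserts. This model is one-dimensional in $\rho$: the closed
  form holds only on the axis of symmetry.
* **Discrete model.** `array_intensity_bruteforce()` places one emitter at
  each tip of the real 19 × 19 grid and sums attenuated inverse-square
  contributions at an arbitrary 3-D point. It reduces to a single point
  source for a 1 × 1 array, agrees with the continuum model in the on-axis
  far field (within 1 % at twenty array diameters, using the
  equivalent-area radius and $\sigma = 1/\mathrm{pitch}^2$), and is the
  only supported route to off-axis points — the closed form is never
  extrapolated off axis.

### Numerical safeguards

The closed form diverges logarithmically as $\rho \to 0$ (the physical
point-source singularity). Rather than clamping, `disk_intensity()` takes a
configurable guard `rho_min` (default $10^{-6}$ µm) below which it raises
an explicit error; infinity is never returned silently.

Two independent oracles check the closed form. Adaptive quadrature
(`stats::integrate`, relative tolerance $10^{-10}$, absolute $10^{-12}$) of
the annular integrand reproduces it to better than $10^{-8}$ relative error
across $\rho/R \in \{0.1, 0.5, 1, 2, 10\}$. A seeded Monte-Carlo estimator
draws emitters area-uniformly ($r = R\sqrt{u}$) and reports its own
standard error; at $10^5$ emitters it agrees within three standard errors
(about 0.2 % relative). Seeding is mandatory and recorded in outputs.

## The directed-beam comparator

Directed surface illumination loses intensity to two mechanisms:
exponential attenuation and geometric dispersion of the diverging beam.
`directed_intensity()` defaults to the pure Beer–Lambert form
$I_0 e^{-\alpha z}$; its dispersion variant multiplies by $(r_0/z)^2$, the
inverse-square spreading of light from a point at the emission plane — the
same spreading law the disk's individual emitters obey, which makes the two
models commensurable.

`compare_models()` normalizes both profiles at the first grid depth and
reports the fractional difference in overall attenuation. The choice of
comparator matters, and the package is explicit about it:

* Against the **dispersive** beam (the default), the extended disk always
  attenuates more slowly, for every $R > 0$: each annulus term's
  normalized decay $(\rho_1^2+r^2)/(\rho_2^2+r^2)$ is shallower than the
  single surface point's $\rho_1^2/\rho_2^2$, so the log factor decreases
  sub-quadratically. The test suite sweeps $R/\rho \in [0.1, 10]$ and
  $\alpha\rho \in [0.1, 3]$ and asserts a strictly positive advantage
  everywhere.
* Against a **pure exponential** the ordering necessarily reverses — the
  disk's extra, strictly decreasing log factor can only speed up the decay
  — so a claim that an extended isotropic source "outlasts" directed light
  is meaningful only when the directed light carries its geometric
  dispersion. The package exposes both comparators rather than hiding the
  distinction.

A widely quoted ~30 % overall-attenuation difference between the two
illumination modes cannot be pinned down without the source size,
attenuation coefficient, depth range and normalization it was computed
with; `compare_models()` provides the machinery to explore it, and no test
asserts that number.

## What the synthetic renderer emulates

Real inputs would be 8-bit RGB photographs of the laser-illuminated array
taken at camera angles 0° (aligned with the beam), 24°, 31°, 57° and 77°.
The renderer produces a simplified 2-D band-pattern projection of that
scene, sufficient to exercise the downstream procedure:

* The array is a grid of **tip bands** (300 µm wide) separated by **gap
  bands** (50 µm) at a 350 µm pitch — the 50 µm figure is the edge-to-edge
  gap between bases and 350 µm the centre-to-centre pitch; both are stored,
  pitch is canonical. Rotating the camera by $\theta$ compresses the
  horizontal axis of the scene by $\cos\theta$; the vertical axis is
  unaffected.
* Within the illuminated beam window (2000–4000 µm in array coordinates,
  projected like everything else), **gap rows** carry the transmitted-light
  law `gap_law(θ)` — by default $200\cos^4\theta$ counts, peaked at 0°
  where the camera looks straight into the transmitted beam — with shallow
  shadows (fraction 0.85) at tip-column positions, which is what encodes
  the array pitch in the image. **Tip rows** carry the scattered-light law
  `tip_law(θ)` — by default a constant 150 counts, i.e. an isotropic
  scatterer — uniformly across the window: light reaching the camera from
  a tip row is dominated by tip scattering, and rendering the row
  angle-invariant is precisely the isotropy hypothesis the analysis is
  meant to recover. Both laws are synthetic stylizations chosen to
  reproduce the qualitative pattern (transmitted light falls off strongly
  with angle, scattered light does not); they are not fitted to any
  measurement.
* Gaussian noise (default sd 3 counts) is added per pixel before clipping
  to [0, 255] and rounding to 8-bit integers. Poisson shot noise was
  considered and rejected as unidentifiable at 8-bit depth. Red and blue
  channels are fixed fractions (0.20, 0.10) of green — the 543.5 nm laser
  is green, which is why the analysis uses the green plane.
* Rendering is deterministic under the spec's seed; a whole angle set is
  drawn from one seeded stream and shipped with a JSON manifest holding the
  spec echo and per-angle ground truth (law values and expected
  central-window means).

One quantization subtlety: with noise of a count or more, the 8-bit
rounding is dithered and the extracted window mean is an unbiased estimator
of the *raw* (unrounded) scene value; with zero noise it recovers the
*rounded* scene exactly. The manifest's expected means are computed
accordingly, so recovery tests can use the plain $3\sigma/\sqrt{n}$
tolerance at any noise level.

What the renderer does **not** emulate: ray-traced pyramid optics, camera
point-spread function or vignetting, polarizer physics (power attenuation
is folded into the laws' scale), perspective, or tissue. Passing the
recovery tests therefore shows the analysis chain is correct and unbiased
on scenes with known truth — not that real photographs obey the rendered
laws.

## The profile analysis

Following standard practice for these images, intensities come from the
green channel of the 8-bit RGB image (0–255). Five horizontal lines are
sampled per mode: `"line"` rows drawn at seeded-random positions within the
gap bands (manual line drawing is not reproducible, so seeded sampling is
the canonical stand-in), and `"MN"` rows through the centres of five
randomly chosen tip bands ("precisely at the tips"). The profile is the
exact per-column arithmetic mean of the sampled rows — computed before any
windowing, kept in floating point, never re-quantized.

Pixel positions are converted to micrometres via `um_per_px` (default
10 µm/px, 0-based origin at the image's left edge) and **de-projected** by
$1/\cos\theta$ so all angles share array coordinates; the central window
$[2000, 4000)$ µm is half-open and angle-consistent. The per-angle summary
is the mean over that window; the isotropy index is the population
coefficient of variation of the per-angle means for one label — this
package's own metric, lower meaning more isotropic, flagged as such in all
outputs.

At 77° the projected 50 µm gap spans $50\cos 77° / 10 \approx 1.1$ px —
below the 2 px limit at which tip and gap bands can still be told apart —
so `sample_profiles()` raises an explicit `unresolvable_projection` error
and the pipeline records the angle as excluded with that reason. The 2 px
threshold follows from the geometry: it keeps 57° (2.7 px) and rejects 77°,
the same exclusion made when analyzing real oblique photographs.

## Pipeline, seeds and problem sizes

`run_pipeline()` chains render → profiles → summaries → model comparison →
report. A single global seed fans out to per-stage child seeds by fixed
offsets (render +101, line sampling +211, MN sampling +307, oracle +401),
so stages are independently re-runnable; every CSV carries the config's
MD5 hash and seed in a header comment, and identical config + seed gives
byte-identical outputs. Dose arithmetic (`pdt_dose`) is
irradiance × 10⁻³ × seconds and is exact at the printed precision for the
standard protocol (125 mW/cm² × 1200 s = 150 J/cm²).

Default problem sizes — chosen as comfortable working sizes for a study of
this kind — are: 665 × 665 px images (19 × 350 µm at 10 µm/px), five
angles, $10^5$ Monte-Carlo emitters, a 50-point depth grid for the model
comparison, and pipeline optics describing the array as an equivalent disk
($R = 3750$ µm, $\sigma = 1/350^2\,$µm⁻², $r_0 = 450$ µm at tip-height
scale, $\alpha = 10^{-3}$ µm⁻¹ ≈ 1 mm⁻¹, an effective attenuation typical
of skin at green wavelengths). A full pipeline run takes a few seconds.

## Known limitations

* The closed form is on-axis only; off-axis queries must use the discrete
  brute-force model.
* The global $e^{-\alpha\rho}$ underestimates attenuation relative to
  per-emitter path lengths; the difference is quantifiable with the
  Monte-Carlo oracle but not folded into the closed form.
* No radiative-transfer or photon-migration physics: $\alpha$ is a single
  effective coefficient, with no wavelength dependence and no
  refractive-index step at the MN–tissue interface.
* The renderer's band-pattern is a deliberate simplification; conclusions
  about real photographs require real photographs.
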