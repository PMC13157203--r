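# mnphotodose

Dissolving microneedle (MN) arrays are being developed as dual-purpose
devices for photodynamic therapy (PDT) of skin lesions: the pyramidal tips
deliver the photosensitizer precursor through the stratum corneum, and the
same tips scatter the treatment light, redistributing a directed laser beam
into a near-isotropic emission that illuminates tissue more uniformly than
surface irradiation. `mnphotodose` is an R package for scientists studying
that optical behaviour. It provides:

* the analytic light-intensity model of the array as a **disk of isotropic
  emitters** with Beer–Lambert attenuation, plus independent quadrature,
  Monte-Carlo, and discrete-grid oracles that validate it;
* a **directed-beam comparator** (exponential attenuation, optional
  inverse-square geometric dispersion) and depth-profile comparison;
* a **seeded synthetic renderer** of 8-bit RGB photographs of a
  laser-illuminated 19×19 array at arbitrary camera angles, with stored
  ground truth, so the image-analysis stage is testable without
  experimental data;
* the **green-channel line-profile procedure**: five horizontal lines
  between the tips ("line") and five at the tips ("MN"), mean intensity vs
  lateral position, central-window (2000–4000 µm) angular summaries, and a
  coefficient-of-variation isotropy index;
* an end-to-end **pipeline** with YAML configuration, seed bookkeeping and
  PDT dose arithmetic, plus a thin command-line wrapper.

## The model

Each MN tip is treated as an isotropic emitter obeying the inverse-square
law, I = I₀(r₀/d)², with reference intensity I₀ at distance r₀. For
emitters spread uniformly at surface density σ over a disk of radius R, the
contribution of the annulus at radius r to the on-axis point at distance ρ
is dI = 2πrσI₀r₀²/(ρ² + r²) dr, and integrating over the disk (substituting
x = r²) gives the closed form

    I(ρ) = π σ I₀ r₀² ln( (ρ² + R²) / ρ² ) · e^(−αρ)

where α is the medium's attenuation coefficient (µm⁻¹). The logarithmic
dependence on ρ decays sub-quadratically, so the extended isotropic source
retains more intensity at depth than directed light, whose intensity falls
with both exponential attenuation and inverse-square geometric dispersion.
The optical dose of a PDT protocol is irradiance × time; the standard basal
cell carcinoma protocol of 125 mW/cm² for 20 min delivers exactly
150 J/cm².

## Worked example

```r
library(mnphotodose)

# closed form at rho = R with unit parameters: pi * ln 2
disk <- emitter_disk(R = 1, sigma = 1, I0 = 1, r0 = 1)
disk_intensity(1, disk)
#> [1] 2.177586

# independent Monte-Carlo oracle agrees within its standard error
mc <- disk_intensity_bruteforce(1, disk, n_emitters = 1e5, seed = 1)
c(estimate = mc$intensity, se = mc$se)
#>    estimate          se
#> 2.178641670 0.001393774

# protocol dose
pdt_dose(dose_params(125, 20 * 60))
#> [1] 150

# end-to-end synthetic study
report <- run_pipeline(default_run_config(seed = 1), out_dir = "run1")
#> [render] 5 angles, seed 102
#> [profiles] extracting line and MN profiles
#> [model] disk vs directed-beam comparison and oracle checks
#> [report] 4/5 angles analyzed; isotropy CV line 0.566, MN 0.000
```

The report says that of the five rendered camera angles (0°, 24°, 31°,
57°, 77°) the 77° view was excluded because the projected between-tip gap
collapses below the resolvable limit, and that across the analyzed angles
the between-tip ("line") central-window means vary strongly with angle
(coefficient of variation 0.566 — directly transmitted light) while the
at-tip ("MN") means are essentially angle-invariant (CV 0.0005 — isotropic
scattering). `run1/` contains the rendered PNGs with their ground-truth
manifest, profile and summary CSVs (each stamped with the config hash and
seed), and `report.json`.

A command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("exec","mnphotodose",package="mnphotodose"))') \
    dose --irradiance-mw-cm2 125 --minutes 20
#> 150 J/cm^2
```

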