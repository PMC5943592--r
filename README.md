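# retroshine

Quantitative analysis of **daytime pupil eyeshine** in cryptobenthic
fishes, built around the black scorpionfish (*Scorpaena porcus*) and the
question: does a glowing pupil hide better than a dark one?

Most fishes have dark pupils; a few ambush predators instead expose their
ocular reflector during the day, so the pupil shines with ambient light.
`retroshine` models pupil radiance as the sum of two channels —
*stratum-argenteum reflected* (SAR) eyeshine driven by side-welling light,
and *pigment-epithelium transmitted* (PET) eyeshine driven by down-welling
light —

```
L_pupil(exposed) = S(λ) · R_SAR(λ) + D(λ) · T_PET(λ)
L_pupil(shaded)  = S'(λ) · R_SAR(λ)
```

and provides the full workflow around that model:

* **Spectral core** — radiance/reflectance/transmittance spectra on a
  canonical 380–700 nm grid, long-format CSV I/O, trapezoidal integration,
  white-standard normalisation.
* **Eyeshine decomposition** — narrow- and broad-sense SAR reflectance,
  PET transmittance, iris/skin/model-pupil reflectance from
  spectroradiometric measurement sets.
* **Dark-adaptation fit** — gamma GLM (log link) of total reflectance vs
  time in darkness, with 95% credible intervals from 10000 simulation
  draws; a classed model object with the usual `print`, `summary`, `coef`,
  `confint`, `predict`, `simulate`, `residuals`, `plot` methods.
* **Field reconstruction** — forward prediction of pupil and iris radiance
  from lab components and measured illuminants, scored by the mean
  log10-ratio match (1 = perfect).
* **Prey-perspective visual model** — Govardovskii A1 pigment templates,
  quantum catches, receptor-noise chromatic distance (JND),
  double-cone achromatic Michelson contrast (`|C_m|`,
  `C_m = (L1 − L2)/(L1 + L2)`), three field viewing scenarios, and the
  skin-patch contrast distribution a camouflaged pupil should fall inside.
* **Synthetic generator** — seeded underwater light fields (Planck surface
  proxy, Jerlov-like attenuation), component spectra with the reported
  laboratory means, noisy field measurement sets, and dark-adaptation
  decay series; every pipeline input can be simulated deterministically.

## Worked example

One seeded end-to-end run — simulate, decompose, reconstruct, contrast:

```r
library(retroshine)
cfg <- run_config(seed = 1, output_dir = "readme_run")
res <- run_all(cfg)
print(res$table2, row.names = FALSE, digits = 3)
#>            scenario depth_m jnd_natural jnd_model michelson_natural michelson_model
#>     s1_both_exposed       7       0.559     0.588            0.0957           0.987
#>    s2_viewer_shaded       7       0.842     0.588            0.2895           0.987
#>  s3_predator_shaded       7       0.246     0.588            0.0640           0.987
#>     s1_both_exposed      15       0.519     0.537            0.0937           0.987
#>    s2_viewer_shaded      15       0.779     0.537            0.2866           0.987
#>  s3_predator_shaded      15       0.234     0.537            0.0646           0.987
```

Read: against the iris, a dark model pupil is near-maximal achromatic
contrast (`michelson_model ≈ 0.99`) in every scenario at both depths,
while the natural, eyeshine-lit pupil stays below 0.3 — inside the 0–0.62
contrast range of the fish's own skin patches
(`range(res$skin_contrasts$contrast)`), i.e. no more conspicuous than the
body patterning. Chromatic differences remain below 1 JND here, so
concealment is carried by the achromatic channel.

The dark-adaptation fit from the same run:

```r
res$darkfit
#> Dark-adaptation decay of pupil total reflectance
#> Gamma GLM (log link), 39 observations, 3 individuals
#> Time slope: -0.00976 per min (95% CrI -0.01227 to -0.00726) -> 0.97% change per min
#> R-squared (corr^2 fitted vs observed): 0.828
```

a ~1%-per-minute decay of pupil total reflectance in darkness, the
signature of the reflector being occluded. Reconstruction closes on this
synthetic data: the mean log10-ratio match between predicted and
"measured" field radiances is 1.0000 for pupil and iris under both
exposures.

A YAML config drives the same pipeline (`retroshine_run("run.yaml")`), and
all outputs (`components.csv`, `recon.json`, `table2.csv`,
`skin_contrasts.csv`, `darkfit.json`, `manifest.json`) are plain re-readable
files; two runs with the same seed are bit-identical.

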