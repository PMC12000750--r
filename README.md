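# osteochip

Quantitative analysis pipelines for osteochondral organ-on-chip
experiments: tested, reusable implementations of the measurements used to
characterize a microfluidic device that models the bone–cartilage
interface — two adjacent hydrogel chambers seeded with primary osteoblasts
and chondrocytes, flanked by perfusion channels — under control and
inflammatory (IL-1β / TNF-α) conditions.

The package is aimed at analysts working with this class of device who
need the published measurement logic as callable, validated functions
rather than interactive ImageJ / notebook workflows:

* **Solute transport** — cross-section intensity profiles from time-lapse
  fluorescence of the hydrogel chamber, centre saturation time, and a
  diffusivity estimate from the analytic two-source model
  (`extract_profile`, `saturation_time`, `estimate_diffusivity`). The
  concentration between two constant-concentration channels follows the
  1-D diffusion equation on `[0, W]`; the package evaluates the exact
  solution (method-of-images erfc fronts / Fourier sine series).
* **Viability** — live/dead counting by threshold + 3-D connected
  components: `100 × live / (live + dead)`, double-positives counted as
  dead (`quantify_viability`).
* **qPCR** — relative expression `2^(Ct_ref − Ct_target)`
  (`relative_expression`).
* **Secretome** — the multiplex cytokine pipeline: 10%-of-minimum
  imputation, strict variance-below-0.9 filtering, z-scoring, sample PCA
  with PC1/PC2 contributor ranking (spiked IL-1β / TNF-α excluded), and
  correlation-distance complete-linkage analyte clustering
  (`run_secretome_pipeline`).
* **Single-cell nascent protein in 3D** — nuclei-seeded watershed
  segmentation of metabolically labeled stacks, per-cell actin-mask
  subtraction to isolate the pericellular matrix, and the three-way
  negative / restricted / secreting classification with volume
  quantification (`quantify_stack`). Classification rule: a cell is
  *negative* below a detection floor, *restricted* when
  `nascent AND NOT actin` is empty, *secreting* otherwise.
* **Mechanics** — contact-point detection and closed-form Hertz fitting
  `F = (4/3)·E/(1−ν²)·√R·δ^(3/2)` over the 1–4 µm indentation window,
  with elasticity array maps per compartment (`hertz_fit`, `fit_array`).

Every input family has a ground-truthed synthetic generator
(`generate_cell_stack`, `generate_viability_stack`,
`generate_indentation_curve`, `generate_cytokine_table`,
`generate_diffusion_series`), so each pipeline is validated by parameter
recovery against known truth. True 3-D primitives (26-connectivity
labeling, anisotropic Euclidean distance transform, seeded watershed) are
implemented in C++ via Rcpp.

## Worked example

Simulate a labeled chondrocyte stack with a known 20/30/50 class
composition, quantify it, and fit one synthetic indentation curve:

```r
library(osteochip)

g <- generate_cell_stack(
  phenotype_params(n_cells = 40, shape = c(26, 300, 300)), seed = 1)
q <- quantify_stack(g$stack, analysis_config())
round(q$summary$class_fractions, 3)
#>   negative restricted  secreting
#>      0.175      0.300      0.525
table(g$truth$class) / 40
#>   negative restricted  secreting
#>      0.175      0.300      0.525
sec <- q$cells$class == "secreting" & !q$cells$border_touching
median(q$cells$extracellular_volume_um3[sec])
#> [1] 1192.8

crv <- generate_indentation_curve(
  curve_params(E_pa = 16e3, noise_sd_n = 1.5e-8), seed = 2)
off <- detect_contact_point(crv)
crv$indentation_um <- crv$indentation_um - off
hertz_fit(crv, nu = 0.5, window = c(1, 4))$E_pa / 1e3
#> [1] 15.99
```

The recovered class fractions equal the realized ground-truth draw
(at this noise level every cell is classified correctly), the median
pericellular deposition volume of secreting cells is ~1190 µm³, and the
Hertz fit recovers the 16 kPa modulus to 0.1% with the contact point found
at 1.996 µm of a true 2 µm offset.

## Analysis workflow

The `analysis/` directory holds numbered narrative drivers, one per
measurement family, each writing tables and a run manifest under
`results/`:

```sh
Rscript analysis/01_diffusion_transport.R
Rscript analysis/02_viability.R
Rscript analysis/03_qpcr_expression.R
Rscript analysis/04_secretome.R
Rscript analysis/05_nascent_protein.R
Rscript analysis/06_mechanics.R
```

## Documentation

The methods vignette (`vignettes/osteochip-methods.Rmd`) documents the
models, default parameters with units, the synthetic generators' scope,
and the numerical design choices.
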