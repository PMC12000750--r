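---
title: "Methods: quantitative pipelines for osteochondral organ-on-chip data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative pipelines for osteochondral organ-on-chip data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteochip)
```

osteochip implements the quantitative analyses used to characterize an
osteochondral unit-on-chip: a microfluidic device with adjacent bone and
cartilage hydrogel chambers, flanked by perfusion channels, hosting primary
osteoblasts and chondrocytes in 3D. Five measurement families are covered —
solute diffusion, live/dead viability, qPCR relative expression, multiplex
cytokine secretomics, single-cell nascent-protein imaging, and
nanoindentation mechanics — together with ground-truthed synthetic
generators for each input family, so that every pipeline can be validated by
parameter recovery. This vignette documents the models, the tunable
parameters and the design choices.

## Solute transport in the hydrogel chamber

The chip's chamber (width $W$ = 1200 µm by default, flanked by 250 µm
perfusion channels) is filled with hydrogel; a fluorescent solute injected
into both channels diffuses inward. We model the transverse concentration
profile with the one-dimensional diffusion equation on $[0, W]$ with
constant-concentration boundaries and zero initial interior concentration.
`diffusion_profile_analytic()` evaluates the exact solution by two
complementary expansions of the same boundary-value problem: while the
diffusion fronts are narrow relative to the chamber ($2\sqrt{Dt} < W$) a
method-of-images sum of erfc/erf fronts, and afterwards the Fourier sine
series; the branches agree to machine precision where they meet, and both
were cross-checked against a method-of-lines finite-difference solution
(the suite asserts pointwise agreement within 1% of the source level;
observed agreement is ~1e-7, limited by the oracle's grid). A truncated
two-front superposition was rejected because its error against the true
finite-domain solution reaches a few percent of the source level at
intermediate times, where the fronts begin to overlap.

Quantification mirrors the imaging workflow: `extract_profile()` samples a
cross-section line at pixel pitch (bilinear interpolation off-axis,
averaging across a configurable width), `normalized_center_intensity()`
tracks the chamber-centre intensity relative to the source level, and
`saturation_time()` reports the first sampled time at or above a threshold
fraction (default 0.95; "saturation" is used qualitatively in practice, so
the threshold is a config value). `estimate_diffusivity()` fits the
analytic model jointly to all frames, profiling the source amplitude out in
closed form so the estimate is invariant to intensity rescaling; the
remaining one-dimensional minimization is over $\log_{10} D$. A series with
no temporal information (all profiles flat) is rejected as
non-identifiable. The source level, when not supplied, is measured in the
perfusion-channel region of the first frame (the first 5% of the
quantification line); whether background subtraction should be applied
first is left off by default and configurable, since published profiles do
not state it.

## Live/dead viability

Viability images carry a calcein-AM (live) and an ethidium homodimer
(dead) channel. Each channel is thresholded (Otsu by default), labeled by
26-connected components in 3D and filtered by a minimum object volume
(default 25 µm³). Viability is $100 \times \mathrm{live} /
(\mathrm{live} + \mathrm{dead})$. An object positive in both channels —
majority of its live-channel voxels inside the dead mask — is counted
once, as dead: membrane-compromised cells take up both stains, and the
published counting rule does not address them, so the conservative choice
is documented here and implemented in `quantify_viability()`. The workflow
is validated at the scale it is used (≥ 250 cells per image), where counted
viability tracks ground truth within a fraction of a percentage point.

## qPCR relative expression

`relative_expression()` implements exactly
$2^{(\mathrm{Ct}_{\mathrm{ref}} - \mathrm{Ct}_{\mathrm{target}})}$ with 18S
ribosomal RNA as the usual housekeeping reference. No cross-plate or batch
normalization is applied — only the single printed formula — because the
measurement protocol specifies none. The reciprocal identity
$2^{\Delta} \cdot 2^{-\Delta} = 1$ holds to 1e-12.

## Secretome: multiplex cytokine analysis

A 20-analyte inflammation panel is measured on 48 conditioned-medium
samples (2 sexes × 2 conditions × 2 compartment outlets × 2 days × 3
units), in two paired datasets: raw median fluorescence intensities (MFI)
and standard-curve concentrations. `run_secretome_pipeline()` fixes the
published order of operations — impute → variance-filter → z-score →
decompose/cluster — as a single composed entry point:

* **Imputation** (`impute_missing()`): each missing entry becomes 10% of
  the analyte's minimum observed value. A fully missing analyte is an
  error, named explicitly.
* **Variance filter** (`filter_low_variance()`): analytes with sample
  variance strictly below 0.9 are removed. "Below" is strict, so exactly
  0.9 is retained. The variance is computed on the imputed,
  pre-standardization data with the unbiased ($n-1$) denominator; the
  threshold's scale is taken to be the concentration scale, since its
  units are not stated — both choices are config-visible.
* **Z-scoring** (`zscore_analytes()`): per-analyte mean 0, variance 1.
* **Sample PCA** (`pca_samples()`): computed on the standardized matrix
  (equivalently, correlation-matrix PCA — the raw-MFI alternative is
  available by skipping the z-score, but standardization is the default
  because analyte scales span decades). The spiked stimulation analytes
  (IL-1β, TNF-α) are excluded from the PCA path only: they are added to
  the medium to induce inflammation and would trivially dominate sample
  clustering. Each component's sign is fixed so its largest-magnitude
  loading is positive, removing the decomposition's sign indeterminacy.
  Explained-variance fractions are asserted against a direct covariance
  eigendecomposition to 1e-9.
* **Contributors** (`top_contributors()`): analyte $j$'s contribution is
  $\sum_c \lambda_c \ell_{jc}^2$ over the requested components
  (explained-variance-weighted squared loadings), normalized to sum to 1;
  ties rank alphabetically.
* **Analyte clustering** (`cluster_analytes()`): pairwise distance
  $d = 1 - r$ (Pearson), complete linkage, on the concentration path with
  the full post-filter panel (the spiked analytes stay here, as published
  cluster maps retain them). Complete linkage guarantees monotone merge
  heights.

The MFI path applies imputation and z-scoring but no variance filter before
PCA — the published preprocessing lists the filter for the concentration
dataset only — and the pipeline report records this asymmetry.

### The synthetic cytokine design

`generate_cytokine_table()` draws log-normal analyte values around
per-analyte baselines spread over ~2 decades (log-scale noise sd 0.35),
applies multiplicative condition/compartment effects, elevates the spiked
analytes 30-fold in inflamed rows, and masks 5% of entries completely at
random (no missingness mechanism is published; only the imputation rule
is). The default effect table upregulates a broad mediator panel under
inflammation with IL-6 (×10), IL-8 (×8) and MCP-1 (×6) as dominant
drivers — the structure reported for this system — plus a per-sample latent
response magnitude (log-sd 0.2) that makes responsive analytes co-vary the
way biological units do. With these defaults PC1 separates conditions and
the designated drivers top the PC1–2 contributor ranking; the real assay's
far higher PC1+PC2 share (>90%) reflects donor-level correlation across
nearly all analytes, which the generator does not attempt to reproduce —
passing recovery tests here validates the pipeline's arithmetic and
ordering, not the effect sizes of any particular experiment.

## Single-cell nascent-protein imaging

Metabolic labeling marks newly synthesized (methionine-containing)
proteins; confocal stacks carry nuclei, actin and nascent-protein channels
at 0.42 µm lateral pixels and 2 µm z-step (the package's default voxel
geometry, overridable everywhere through `voxel_size`). All µm↔voxel
conversions pass through the voxel size, and axes are fixed as
(channel, z, y, x) to prevent silent anisotropy bugs.

The workflow (`quantify_stack()`) composes:

1. **Nuclei segmentation** (`segment_nuclei()`): channel threshold (Otsu on
   the pooled voxel histogram by default — the original thresholds were
   matched to manual segmentation and are not published, so a fixed
   numeric override is supported), 26-connected 3D components, minimum
   nucleus volume 25 µm³, then watershed splitting of touching nuclei on
   the anisotropic Euclidean distance transform. Distance maxima are
   reduced by non-maximum suppression with a minimum split distance
   (default 5 µm, i.e. about one nucleus radius above): anisotropic
   sampling quantizes the distance transform into plateaus, and greedy
   suppression of shallower peaks near a deeper one is robust to those
   plateaus where linkage-style merging is not. A lone convex nucleus
   therefore always yields one seed; two merged 8 µm nuclei split.
2. **Territory assignment** (`assign_cell_territories()`): seeded watershed
   (priority-flood, deterministic FIFO tie-break) on the inverted combined
   actin + nascent intensity landscape over the union of both channels'
   foreground, then restricted to each seed's bounding box padded by the
   crop margin (default 10 µm — the published per-cell crop has no stated
   padding). Foreground voxels outside every crop stay unassigned.
3. **Actin-mask subtraction** (`extracellular_mask()`): per cell,
   `nascent AND NOT actin`. Only the actin mask is subtracted (not the
   nuclear region), exactly as the workflow is described.
4. **Classification** (`classify_cell()`): `negative` below a detection
   floor of 5 voxels (negativity is qualitative in the source workflow; a
   documented floor makes it testable), `restricted` when the subtraction
   is empty, `secreting` otherwise. Raising the floor can only move cells
   toward `negative`.
5. **Quantification**: volumes are voxel counts × voxel volume; mean
   intensities are reported alongside but all classification logic uses
   volume. Cells whose territory touches a lateral stack border are
   flagged rather than dropped: they stay in class counts but should be
   excluded from volume statistics, since their volumes are truncated.

`collagen_positive_fraction()` implements the published definition
directly: positives (≥ 5 above-threshold voxels in the cell's territory)
divided by the number of segmented nuclei, as a percent.

### The synthetic stack generator

Cells are geometric idealizations: an ellipsoidal nucleus (default
equatorial radius 4 ± 0.4 µm, axial ratio 0.8), a filled cell body
extending one cortical-shell thickness (2 µm) beyond it, and, for secreting
cells, a 2 µm pericellular shell of nascent signal outside the body.
Class labels are the first draw from the seeded RNG, so realized class
counts are replayable. The actin channel renders the *filled* body, not a
hollow annulus: the subtraction rule defines "extracellular" relative to
the actin mask, and a hollow annulus would leave the nuclear interior in
the extracellular mask, misclassifying every restricted cell — the filled
body is the mask-level idealization consistent with the published
empty-subtraction rule. Cells are placed by rejection sampling with
non-overlapping full extents (bounded retry budget; failure raises a
geometry error), noise (Gaussian, optional Poisson) is applied last, and
all ground truth is computed from the noiseless masks. On noiseless stacks
the pipeline's per-cell volumes equal ground truth exactly; at the default
noise (sd 0.02 on a [0,1] intensity scale) class fractions are recovered
within 5 percentage points at n = 100 cells. The generator makes no
attempt at morphological realism, optical point-spread blur or z-dependent
signal loss, so passing tests demonstrate correctness of the measurement
logic, not robustness to every imaging artifact of a real microscope.

## Nanoindentation mechanics

Load–indentation curves from a spherical probe (defaults: tip radius 25
µm, cantilever stiffness 0.5 N/m) are fitted with the Hertz
sphere-on-half-space law

$$F(\delta) = \tfrac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2},$$

over the fixed indentation window 1–4 µm (`hertz_fit()`), the window used
for on-chip hydrogel measurements. Because the model is linear in $E$, the
fit is closed-form least squares of load against $\delta^{3/2}$ — exact,
deterministic, and free of initialization choices. The Poisson ratio
defaults to 0.5 (incompressible hydrogel) and is configurable; fitted
moduli scale exactly as $(1-\nu^2)$. A curve that does not cover the
window raises an error rather than silently extrapolating. The quoted
"max load of 0.5 N/m" of the measurement protocol carries stiffness units
and is treated as an instrument setpoint, not a fitting input.

Contact-point detection (`detect_contact_point()`), performed by vendor
software in the original instrument, is implemented as: robust baseline
(median/MAD of the leading 20% of samples), coarse crossing at
baseline + 5 SD sustained for 3 samples, then refinement by the Hertzian
linearization $F^{2/3} \propto (\delta - \delta_0)$ fitted over the
high-load region, iterating the baseline re-estimate — exact on noiseless
power-law curves, and within the stated recovery bounds (bias < 1%,
CV < 5% at 1% load noise) across 5–50 kPa. The synthetic forward model
treats the recorded abscissa as indentation directly; cantilever
compliance is handled upstream by the instrument.

`fit_array()` maps curves to an elasticity map, flagging failed curves
(`accepted = FALSE`, with the reason) instead of dropping them, and
`summarize_map()` summarizes accepted entries per group. Group hypothesis
testing (rank-based or ANOVA) is delegated to standard R facilities.

## Problem sizes and numerical choices

The validation suite uses 100-cell stacks of 448 × 448 × 30 voxels (about
8.5 M voxels per channel) for classification recovery, 20 replicate curves
per modulus level for Hertz recovery, 48-sample × 20-analyte tables for
the secretome, 11-frame series at 4 µm pixels for diffusion, and 300-cell
images for viability — sizes chosen so each recovery experiment is
informative while the whole suite runs in minutes on one CPU. Thresholding
ties, watershed ties and component relabeling are all resolved by
deterministic voxel order; every generator is bit-reproducible for a fixed
seed; classed error conditions (`osteochip_*`) make every documented
failure mode testable.

## Known limitations

* The imaging model omits the optical point-spread function, z-attenuation
  and deconvolution; compensation for depth-dependent signal loss is out
  of scope.
* The transport model is one-dimensional with constant sources; decaying
  or flow-modulated source profiles, 2D anisotropy and photobleaching are
  not modeled.
* The Hertz fit assumes elastic, non-adhesive contact: no viscoelastic
  relaxation, no JKR/DMT corrections.
* The secretome generator's missingness is completely at random, and its
  effect sizes are illustrative defaults, not estimates of any donor
  population.
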