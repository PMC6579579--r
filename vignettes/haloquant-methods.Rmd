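---
title: "haloquant: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{haloquant: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haloquant)
```

## What this package computes

haloquant implements a cross-validated pipeline for *absolute* protein
copy numbers per cell — how many CTCF or cohesin (Rad21) molecules a
cell actually contains — and the downstream arithmetic that turns those
numbers into constraints on 3D genome organisation: the time-averaged
occupancy of a CTCF binding site and the genomic density of
loop-extruding cohesin complexes.

Three orthogonal abundance readouts are supported:

1. **In-gel fluorescence** (`gel_abundance()`): lysates of cells whose
   tagged protein carries a covalent fluorophore are run on a gel next
   to a titration of purified, identically labeled protein standard.
   The standard lanes give a fluorescence-per-molecule factor; dividing
   lysate band fluorescence by it and by the cell count per lane gives
   molecules per cell.
2. **Flow-cytometry cross-calibration** (`fcm_abundance()`): once one
   cell line has a trusted absolute number, any other tagged line can
   be calibrated against it by the ratio of background-subtracted mean
   fluorescence: `n_X = (I_X - I_bgX) / (I_std - I_bgStd) * n_std`.
3. **FCS-calibrated imaging** (`fit_autocorrelation()`,
   `segment_stack()`, `compartment_quant()`): fluorescence correlation
   spectroscopy measures absolute concentration at a spot; pairing FCS
   spots with image intensities yields a calibration factor `k_nM`
   (nM per AU) that converts segmented 3D confocal stacks into
   per-compartment concentrations `Ca = (It/Vp - Ib) * k_nM` and
   molecule numbers `Nt = Ca * V * NA`, with `NA = 0.602214086`
   molecules per µm³ per nM.

Two further modules supply biology-side inputs:
co-immunoprecipitation stoichiometry (`coip_stoichiometry()`: what
fraction of cohesin is dimeric) and DAPI/EdU cell-cycle classification
(`classify_cell_cycle()`: how many genome copies an average cycling
cell carries).

Every estimator has a matching generator in the synthetic-data module
(`gen_*`), which records ground truth so that the whole pipeline is
testable without microscope, cytometer or gel data.

## The FCS model

Autocorrelation curves are fitted with the standard two-component 3D
free-diffusion model for a Gaussian focal volume,

$$G(\tau) = G_\infty + \frac{1}{N}\left[f_1\, g(\tau;\tau_1) +
(1-f_1)\, g(\tau;\tau_2)\right],\qquad
g(\tau;\tau_d) = \frac{1}{1+\tau/\tau_d}
\frac{1}{\sqrt{1+\tau/(\kappa^2\tau_d)}},$$

without a triplet/blinking term. The source protocol defers the exact
functional form to its calibrated-imaging references; we adopt this
minimal standard model. The structure parameter $\kappa$ (axial/lateral
focal extent) is determined once from the dye calibration
(`fit_kappa = TRUE`) and then held fixed for cell measurements — it is
an instrument property, and letting it float in every cell fit makes
$N$ and $\kappa$ trade off against each other. Components are reported
with $\tau_1 < \tau_2$. When the two diffusion times collapse
(ratio < 1.2) the fraction $f_1$ is unidentifiable; the fit is
canonicalised to a single component ($f_1 = 1$) and flagged. The port
algorithm's "false convergence" on noisy curves is reported as a
usable fit with a `questionable_convergence` flag.

A dye solution of known concentration $C$ gives the effective confocal
volume $V_\mathrm{eff} = N/(C \cdot \mathrm{NA})$; concentrations then
follow from any cellular fit as $N/(V_\mathrm{eff}\cdot\mathrm{NA})$.

## 3D segmentation

`segment_stack()` reproduces the published processing order: optional
central crop, linear z-interpolation to isotropic voxels, 3D Gaussian
smoothing, nucleus detection from the DNA channel by per-plane Otsu
AND whole-stack Otsu, plausibility checks, iterative re-thresholding
(clipping above the 99th intensity percentile, at most 5 rounds),
removal of small masses, and a marker-based watershed on the
cell-boundary channel seeded with the nuclear masses. The boundary
stain is an exclusion marker (bright *outside* cells), so the
watershed floods the below-Otsu intracellular region from the nuclear
seeds; basins meet at intensity ridges between touching cells. The
reported cell is the largest in-range nucleus, with near-ties (within
1% volume) broken by centroid distance to the image centre.

Numerical choices that matter:

* **Otsu plateau**: the between-class variance is flat across an empty
  histogram gap; we take the midpoint of the maximising plateau, not
  its left edge, which would systematically dilate the foreground.
* **Gaussian σ = 0.3 µm** (default): enough to suppress shot noise at
  20 photons/AU while keeping the half-maximum boundary within half a
  voxel of the true edge. At σ = 0.5 µm the noiseless Dice drops below
  0.98.
* **Plausible nuclear volume [150, 4000] µm³, ≤ 20 nuclei**: generic
  mammalian interphase range; the source protocol used empirical
  ranges it does not print.
* **Quantification grid**: compartment sums (`It`, `Vp`, `V_µ`) are
  taken on the *original anisotropic grid*, with masks mapped back
  from the isotropic segmentation. Any resampling of the quantified
  channel mixes intensities across the nucleus/cytoplasm boundary and
  biases compartment means (linear interpolation: −3% on nuclear
  concentration in our phantoms; nearest-neighbour: −1.7%; original
  grid: −0.3%).
* The printed molecule-number equation multiplies total (not mean)
  intensity by the total volume, which is dimensionally inconsistent
  with the concentration equation; we implement the conserving form
  `Nt = Ca * V_µ * NA` (so nucleus + cytoplasm = cell exactly) and
  keep the literal form behind `compartment_quant(literal = TRUE)`.

## Downstream constraint arithmetic

With $f_b$ the specifically bound fraction, $n$ molecules per cell,
$S$ sites per haploid genome and $c$ genome copies,

$$f_\mathrm{occ} = \frac{f_b\, n}{c\, S},\qquad
d = \frac{f_e\, n_\mathrm{cohesin}}{c\, G_\mathrm{Mb}}
\quad(\text{per ring; halve for paired rings}),\qquad
\text{spacing} = 1000/d_\mathrm{units}\ \mathrm{kb}.$$

Genome copies are the expectation $2f_{G1} + 3f_S + 4f_{G2}$ (a mid-S
cell carries 3 copies). Cross-method estimates are combined by
arithmetic mean rounded to the nearest hundred with halves up — the
convention inferred from the published final averages (109,750 →
109,800; 109,350 → 109,400); it is documented here as inferred, not
stated. Occupancy assumes all sites equally likely to be occupied; no
heterogeneity model is provided.

The CoIP inversion uses the equal-likelihood pairing assumption (as
many bait:bait as bait:prey dimers, with both alleles expressed
equally): monomer signal $M = \%IP - 3\,\%CoIP$, so the dimer fraction
is $3\,\%CoIP/\%IP$. The random-pairing alternative (1:2:1, giving
$2\,\%CoIP/\%IP$) is available as `pairing = "random"` for sensitivity
analysis only. Out-of-model inputs ($\%CoIP > \%IP/3$) clamp to 1 with
an `out_of_model` flag — a violated assumption should be visible, not
silent. The estimate inherits the known caveat that lysis losses make
it an underestimate; no correction is attempted.

## The synthetic world

Generator defaults are the stated experimental conditions wherever the
source states them, and fixed realistic choices otherwise:

* `gen_gel_lanes()`: multiplicative zero-mean Gaussian band noise with
  CV 5% (typical gel densitometry repeatability); 6-point standard
  titration; lysate lanes at 0.5–1.5 × 10⁵ cells.
* `gen_fcm_events()`: per-cell signal lognormal (the published
  histograms are unimodal and right-skewed; no family is stated — this
  is our choice, σ = 0.4), additive lognormal autofluorescence in
  linear space. The labeled/unlabeled pair of a line shares its
  background event stream, so a zero-abundance labeled sample is
  event-identical to its control.
* `gen_fcs_curve()`: heteroscedastic noise, s.d. ∝ the square root of
  the normalised decay, so short lags are noisier, as in measured
  correlation curves.
* `gen_image_stack()`: ellipsoid nucleus (semi-axes 4 × 6 × 6 µm)
  strictly inside an ellipsoid cell (5.5 × 9 × 9 µm), 21 planes at
  600 nm z-spacing and 200 nm xy pixels as acquired; nuclear
  concentration 144.3 nM, cytoplasmic 7 nM (matching the >90% nuclear
  localisation), background 5 AU, `k_nM` = 2. Noise is optional
  Poisson photon noise (20 photons/AU in tests) plus Gaussian read
  noise; the acquisition protocol states no noise model. The test
  field of view is 19.2 µm rather than the 72 µm crop, purely for
  runtime; voxel geometry is unchanged.
* `gen_cell_cycle()`: fractions (10.2%, 73.9%, 15.9%); DAPI Gaussian
  at 2C/4C with CV 8%; mid-S DNA content uniform between 2C and 4C
  (simplest replication model); EdU 30-fold shifted in S.
* `gen_coip()`: forward model under the same pairing assumption the
  inversion uses, so the noiseless round trip is the identity for any
  dimer fraction in [0, 1].

What a green test does **not** establish: the generators contain no
debris/doublets, no spectral bleed-through, no optical PSF, no
mitotic cells, no chromatic offsets and no gel-lane spatial artefacts.
Recovery on this synthetic world validates the estimators' algebra and
robustness to the modelled noise, not instrument-specific systematics.

## Deliberate deviations

Two places where implementation experience overruled the initial
design:

* **Standard-curve weighting.** The straight unweighted origin fit is
  dominated by the brightest standard lane under constant-CV noise; at
  5% CV it recovers the slope within 5% in only ~85% of runs, which
  contradicts the intended ≥95% recovery property of the design. The
  default is therefore weighted least squares with weights 1/amount²
  (the maximum-likelihood slope under multiplicative noise, equal to
  the mean of per-lane intensity/amount ratios; ~99% recovery).
  `weighting = "none"` restores the unweighted fit.
* **EdU gate for exact round trips.** A quantile gate at 99.5% of the
  negative control mislabels 0.5% of EdU-negative events *by
  construction*, noise or not, so a noiseless generator→classifier
  round trip can never be exact under it. `edu_gate = "otsu"` (gap
  threshold on log EdU) is exact when the populations separate and is
  used by the noiseless self-test; the default remains the quantile
  gate.

One known structural error bound: segmentation places compartment
boundaries to the nearest voxel, so even noiseless molecule counts
carry a sub-voxel discretisation error (~10⁻⁴ relative in our
phantoms, well inside the 2% acceptance band but not 10⁻⁶).

## Limitations

* Band intensities, event tables and correlation curves are consumed
  as numbers; no densitometry, gating of raw scatter data, or photon
  trace correlation of real hardware data.
* Stacks are exchanged as in-memory arrays or a documented long-CSV
  text format; no TIFF reader is bundled.
* Interphase cells only; no mitotic handling, no karyotype-aware
  occupancy for aneuploid lines.
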