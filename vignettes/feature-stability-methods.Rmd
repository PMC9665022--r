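---
title: "Methods: radiomics feature stability across spectral PCCT reconstructions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomics feature stability across spectral PCCT reconstructions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The question the pipeline answers

Photon-counting CT yields many reconstructions of one scan — virtual
monoenergetic (VM) images from 40 to 120 keV, a polyenergetic image (T3D), a
virtual non-contrast image (VNC) and an iodine map. A radiomics feature is
clinically useful only if its value does not depend on which reconstruction it
was measured in, nor on exactly where the ROI was drawn. `pcctstab` implements
the full screening procedure that identifies such features: simulate (or load)
a multi-reconstruction cohort, extract a fixed 93-feature bank per ROI per
channel, measure cross-reconstruction consistency with ICC(3,1), compare
channel subsets and segmentation modes, and confirm
segmentation–resegmentation robustness with Lin's concordance correlation
coefficient (CCC).

# The phantom cohort model

Real patient scans cannot be redistributed, so the package ships a generative
phantom whose *statistical* structure matches what the analysis assumes:

* **Fixed anatomy per patient.** Each patient is a grid of six axis-aligned
  tissue blocks (air, lung, fat, psoas muscle, liver, spleen). The tissue's
  base attenuation map — its mean HU plus a Gaussian random texture field with
  a tissue-specific amplitude and correlation length — and its iodine
  concentration map are drawn once per patient and shared by all 12 channels.
  This is the anatomy-invariance assumption of the ICC design: raters
  (channels) rate the *same* targets.
* **Channel-specific intensity transforms.** A VM image at energy $E$ is
  $\mathrm{base} + \mathrm{iodine} \cdot e(E)$ with $e(E)$ a strictly
  decreasing enhancement curve (default 30 HU per mg/ml at 40 keV falling to
  4 HU per mg/ml at 120 keV). VNC is the base map alone; the iodine map is the
  iodine concentration in display units (100 per mg/ml, so one 25-unit gray
  bin is 0.25 mg/ml); T3D is a weighted average of the VM transforms (uniform
  weights by default). Energy-dependent iodine contrast is the physical
  mechanism that destabilizes intensity-coupled features across keV.
* **Independent per-channel noise**, with VM noise decreasing from 25 HU at
  40 keV to 9 HU at 120 keV (low-keV images are noisier), 12 HU for T3D and
  15 HU for VNC (material decomposition amplifies noise).
* **Correlated reconstruction residue in derived channels.** VNC and T3D are
  not direct reconstructions but products of spectral decomposition and
  full-spectrum weighting; real examples carry spatially structured artifacts
  (iodine-removal residue, beam hardening). The phantom models this as a
  channel-specific Gaussian random field (12 HU for VNC, 8 HU for T3D, 8 mm
  correlation length) added before the white noise. Unlike white noise this
  does not average out over an ROI, which is what makes the derived channels
  genuinely less consistent raters than the VM series — the mechanism behind
  the VM-only subset showing the highest average ICC.

Tissue defaults encode deliberate qualitative relationships rather than
calibrated dosimetry: air is pure image noise at −1000 HU (no texture, no
iodine); lung is "mostly air" (−900 HU, weak fine-grained texture of 10 HU at
1 mm correlation, 0.2 mg/ml iodine), so air and lung sit together in organ
space; liver and spleen share similar texture amplitudes and the strongest
iodine uptake (2.0 and 2.4 mg/ml), so they pair; fat is smooth and
contrast-free. An earlier draft gave lung a strong, smooth texture field; that
made lung the most texture-distinct organ and inverted the expected air–lung
adjacency, so the final model keeps lung's intrinsic texture below the noise
floor — which also reproduces the expected contrast between lung (anatomy
fixed across channels, hence stable features) and air (fresh noise per
channel, hence unstable features).

What the phantom does **not** emulate: anatomical shapes, partial-volume
edges, beam-hardening streaks tied to geometry, scanner dose and detector
physics, or realistic organ texture spectra. Consequently the *absolute* ICC
and CCC magnitudes of real tissue are out of reach by design, and the package
asserts only structural counts, exact statistic/matrix identities, and
qualitative orderings (subset and mode rankings, iodine-map separation,
air–lung adjacency).

# The segmentation plan

Per patient: 6 organs × {2D disk, 3D sphere} × {1 cm, 2 cm maximum diameter}
× 2 repeats = 48 segmentations. A brush mask contains every voxel whose
centre lies within the physical radius (inclusive boundary — a deterministic
tie-break), spacing-aware on anisotropic grids. Repeat 2 displaces the centre
by a uniformly random offset of at most `jitter_mm` (default 3 mm), the single
knob standing in for an independent manual redraw; masks are re-checked for
containment in their organ. With jitter 0 the repeats coincide and every CCC
is exactly 1, which the tests exploit as a degenerate control.

# The feature bank

93 non-shape features: 18 first-order, 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM,
5 NGTDM, the reference (IBSI-aligned) default set, with names frozen in
`inst/extdata/radiomics_feature_names.txt` and validated on every extraction.
Extraction settings: fixed bin width 25 HU anchored
at the ROI minimum (`level = floor((I - min)/25) + 1`), voxel array shift 0 in
Energy/RMS, no resampling.

Numerical conventions, all pinned and oracle-tested:

* distance-1 neighbourhoods; 13 unique directions in 3D, 4 in-plane for
  single-slice masks (out-of-plane directions would be structurally empty on a
  disk; they are removed so direction averaging runs over populated
  directions only);
* GLCM/GLRLM features computed per direction and averaged, matrices
  symmetrized; 26-connectivity zones (8 in 2D); GLDM dependence with exact
  level equality ($\alpha = 0$);
* every logarithm is base 2 with an additive $\varepsilon = 2.2\times10^{-16}$
  guard; NGTDM coarseness is capped at $10^6$ for zero denominators (constant
  ROI);
* GLDM `DependenceNonUniformityNormalized` uses the $\mathrm{DN}/N_z$
  normalization of the reference implementation;
* first-order percentiles use linear interpolation (type 7).

The test suite re-derives all five matrix families with independent
brute-force algorithms (exhaustive pair enumeration, line-wise run-length
encoding, flood fill) on random small ROIs and requires exact equality, plus
conservation identities (zone sizes, dependences and runs account for every
masked voxel).

# The statistics

**ICC(3,1)** — two-way mixed model, consistency, single rating; targets are
the patient × repeat ROI instances (20 in the default cohort — both repeats
enter as targets, the switchable default), raters the reconstruction
channels. Computed from explicit mean squares
$(\mathrm{MS}_\mathrm{rows} - \mathrm{MS}_\mathrm{err}) /
(\mathrm{MS}_\mathrm{rows} + (k-1)\mathrm{MS}_\mathrm{err})$, invariant under
common affine transforms and per-rater offsets. A zero denominator (constant
feature) raises a classed condition; tables record such cells as missing and
exclude them from averages with a logged count, so constant features (air) do
not poison subset comparisons.

**CCC** — Lin's original population-moment form
$2\,\mathrm{cov}(x,y) / (\sigma_x^2 + \sigma_y^2 + (\mu_x - \mu_y)^2)$ with
$1/n$ moments; mixing the $1/(n-1)$ convention into the means-difference term
is the classic silent bug, so the tests pin the convention against an
independent $r \cdot C_b$ factorization.

**Repeated-measures ANOVA with Greenhouse–Geisser correction** — subjects are
(feature, organ) pairs, conditions the four segmentation modes, values their
ICCs. $\hat\varepsilon = (\mathrm{tr}\,C)^2 / ((k-1)\,\mathrm{tr}\,C^2)$ with
$C$ the double-centered condition covariance, clamped to $[1/(k-1), 1]$; both
raw and corrected p-values are reported. Note that deflating both degrees of
freedom is only guaranteed conservative for clearly significant F; near
$F \approx 1$ the corrected p can cross below the uncorrected one, so no
ordering between the two is asserted there. A matrix with no condition
variance at all returns $F = 0$, $p = 1$, $\varepsilon = 1$ rather than 0/0.

**Correlation structure.** Channel similarity is *feature-wise*: for each
feature, the Pearson correlation between channels across all ROIs, averaged
over features (features with zero variance in any channel are skipped). This
was chosen over z-scoring-and-stacking because stacked moments are dominated
by heavy-tailed features (energies, the capped coarseness); averaging
per-feature correlations weighs every feature equally. Organ profiles are the
organ means per (feature, channel), standardized across organs within each
row, then Pearson-correlated. Both use average-linkage clustering on
$1 - r$, exported as Newick strings.

# The decision rules

* Reliability bands with closed lower bounds: excellent $\geq 0.75$, good
  $[0.60, 0.75)$, fair $[0.40, 0.60)$, poor below. The inclusive 0.75 is
  forced by the band edges themselves (0.60–0.74 is good, so 0.75 must open
  the excellent band).
* Stage 1: a feature survives with ICC $\geq 0.75$ in $\geq 4$ organs
  ("more than 3"), evaluated on the winning subset/mode table. Both knobs are
  exposed in `stability_criteria()`; the organ universe is whatever organs the
  table contains, never hard-coded.
* Stage 2: the quantifier "CCC > 0.6 in $\geq$ 3 organs in $\geq$ 6
  VM reconstructions" nests ambiguously. The default reading counts a channel
  as passing when at least 3 organs pass within it, and requires at least 6
  passing channels (`ccc_nesting = "per_channel"`); the per-organ reading is
  available behind the same switch and reports state which was used.
* Winners (subset, mode) are chosen by highest mean ICC with fixed documented
  tie-break priorities (VM-only before without-iodine before all; larger and
  3D modes first); an exact tie across all four modes is flagged instead of
  resolved.

Both selection stages are monotone under criterion tightening, and both are
tested against brute-force evaluation of the quantified rules on random
tables.

# Validating the screen end to end

Planting "known stable" features at the image level is not controllable —
every feature is a nonlinear functional of the image — so the package
includes `simulate_feature_table()`, a generative model of the *feature
table*: each (feature, organ) has a base level and standard-normal patient
effects; planted-stable features add only small measurement noise (so ICC and
CCC approach 1), unstable features receive strong channel-by-target
interaction noise (ICC near 0) and repeat noise (CCC near 0), and smaller
segmentation modes are proportionally noisier (so 3D-2 cm wins the mode
comparison). The acceptance suite requires the two-stage screen to return
exactly the planted set in at least 90% of 20 seeded runs.

# Problem sizes used by the tests

Chosen so the full suite and the acceptance script each run comfortably on a
single CPU:

* structural-count check and the acceptance script: the default cohort —
  10 patients, 128×128×40 voxels at 0.7×0.7×1.5 mm, 12 channels,
  480 segmentations, 535,680 feature values;
* seeded ordering checks: 20 cohorts of 10 patients on a 56×84×21 grid at
  1.6×1.6×2.75 mm — the same design (48 segmentations, 12 channels, all four
  modes) at coarser resolution;
* oracle suites: 50 random matrices / ROIs per statistic and matrix family;
* unit tests: a 32×48×12 grid at 2×2×3 mm.

# Known limitations

* Absolute feature values depend on conventions the source protocol leaves
  open (GLCM distance, aggregation mode, connectivity); the reference defaults
  are used and documented above, but other choices change absolute values.
* The phantom's block anatomy has no partial-volume boundaries, so masks never
  straddle tissue edges; real resegmentation variability includes edge
  effects the jitter model does not produce.
* Organ-level conclusions (which organ is "most stable") reflect the phantom's
  tissue parameters, not physiology; only the procedure and the qualitative
  orderings transfer to real data.
* The dendrograms use average linkage on $1 - r$; other linkages can reorder
  merges when correlations are close.
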