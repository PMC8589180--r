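---
title: "Mapping deep-capillary telangiectasia onto photoreceptor disruption: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping deep-capillary telangiectasia onto photoreceptor disruption: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octamap)
```

## The problem

Macular telangiectasia type 2 (MacTel) combines a vascular lesion — dilated,
non-tapering telangiectatic capillaries in the deep capillary plexus (DCP) —
with neurodegenerative photoreceptor damage that appears on en-face OCT as
graded hyporeflectivity of the outer retinal bands: attenuation of the
interdigitation zone (IZ), loss of the IZ with an intact ellipsoid zone (EZ)
above it, and frank EZ loss. `octamap` quantifies how these two processes
overlap in space on paired 3 mm × 3 mm (304 × 304 px) en-face OCT/OCTA
images, and whether the milder grade of disruption at baseline (IZ loss)
predicts where the severe grade (EZ loss) appears at follow-up.

Two analyses are provided:

* **Cross-sectional**: per eye, segment the telangiectasia footprint from
  the DCP angiogram, decompose the traced disruption regions into exclusive
  classes, convert pixel counts to mm², express overlaps as a percentage of
  the telangiectasia area, and relate everything to the ordinal disease
  stage (Spearman) and to pooled stage groups (GEE with eyes nested in
  patients).
* **Longitudinal**: register the follow-up scan to baseline through the
  superficial capillary plexus (SCP), subtract EZ-loss masks to obtain new
  loss and recovery, and summarize the predictive value of baseline IZ loss
  for new EZ loss as chance-normalized rPPV/rNPV.

Patient scans cannot be shipped, so a first-class synthetic-scene generator
stands in for them; every stage of the pipeline is tested against that
generator's pixel-exact ground truth.

## Image operators

**Phansalkar local thresholding** binarizes vessels inside the marked
telangiectasia zone. A pixel with normalized intensity $I(x) \in [0,1]$ is
foreground when $I(x) > T(x)$ with

$$T(x) = \mu(x)\left(1 + p\,e^{-q\mu(x)} + k\left(\frac{\sigma(x)}{r} - 1\right)\right),$$

where $\mu$ and $\sigma$ are the mean and standard deviation over a circular
window (clipped to the image at borders). Defaults are the widely used
constants $k = 0.25$, $r = 0.5$, $p = 2$, $q = 10$ with window radius 15 px,
matching the common ImageJ Auto Local Threshold settings; all are exposed in
`phansalkar_params()`. Images are normalized by their maximum first, so the
operator is invariant to positive intensity rescaling. The suite checks the
operator against a literal per-pixel double-loop implementation of the
formula.

**Maximum-entropy (Kapur) thresholding** extracts bright SCP large vessels:
the global level maximizes the sum of Shannon entropies of the normalized
histogram below and above the candidate split (256 bins over the intensity
range; empty bins contribute $0\log 0 := 0$; ties break toward the lowest
level). A constant image has no meaningful split and is an error. The
large-vessel mask keeps only components that survive a morphological opening
at half the minimum width and are both large (≥ 300 px) and thick (maximum
inscribed width ≥ 4 px); these filters are configuration, not biology, and
are exposed in `pipeline_config()`.

**Hole filling** turns binarized vessel walls into circumscribed areas:
background components not 4-connected to the image border are added to the
8-connected foreground (the standard duality). It is idempotent and
monotone, and is verified against a border flood-fill oracle.

**Telangiectasia circumscription** is
`fill_holes(phansalkar(dcp) ∩ roi)` followed by removal of isolated
components below 10 px, always a subset of the marked ROI. Superficial
large-vessel projections that would masquerade as telangiectasia are removed
by subtraction (`exclude_artifacts()`), the conservative quantitative
reading of "distinguishing" artifact from true vessels; the removed pixel
count is reported so an overlay-only policy remains auditable.

## Regions, areas and overlaps

Traced regions arrive as three nested combined masks: A (attenuation + IZ
loss + EZ loss), B (IZ loss + EZ loss) and C (EZ loss) — every EZ-loss pixel
also has IZ loss, so C ⊆ B ⊆ A. Exclusive classes follow by subtraction
(attenuation-only = A \\ B, IZ-loss-only = B \\ C), and the three exclusive
classes partition A exactly, a conservation property asserted pixel-exactly
in the tests. Independent mask files may violate nesting; the default
`clip` policy restores it (clipping B to A, then C to B) and counts the
clipped pixels, while `strict` makes any violation an error. Areas are
pixel counts times the squared pitch (one pixel = $(3/304)^2 \approx
9.74\times10^{-5}$ mm²); overlaps are shared pixels as a percentage of the
telangiectasia footprint, undefined (NA, not zero) for eyes without
telangiectasia. Polygon ROIs are rasterized with the even-odd rule on
pixel centres (0-based coordinates).

## Longitudinal analysis

Registration estimates a dense deformation field from the SCP angiograms —
the superficial vasculature carries stable landmarks, while the pathology
itself changes — and the same field transfers the follow-up IZ/EZ regions
into the baseline frame. The estimator is a phase-correlation translation
initialization followed by multiresolution demons-style refinement
(intensity-driven updates, Gaussian fluid/diffusion regularization,
three levels at 1/4, 1/2 and full resolution) minimizing mean squared
intensity error. The contract is the field, not the optimizer: any scheme
recovering a smooth 3 px warp to ≤ 1 px mean endpoint error satisfies it
(the implementation typically achieves ~0.1–0.2 px on synthetic pairs).
Masks are transferred by nearest-neighbour resampling, so they stay binary
and an identity field is exact.

Change maps are plain set differences: new loss = follow-up \\ baseline,
recovery = baseline \\ follow-up. The pipeline applies an 8 px
minimum-component filter to change maps (configurable; 0 disables) to
suppress hairline residue along region boundaries from sub-pixel
registration error; genuine new-loss blobs are an order of magnitude larger.

Predictive values are computed within an analysis domain $\Omega$ and
normalized by chance:

$$\mathrm{PPV} = \frac{|new \cap iz|}{|iz \cap \Omega|},\quad
\mathrm{NPV} = \frac{|\Omega \setminus (iz \cup new)|}{|\Omega \setminus iz|},\quad
\mathrm{rPPV} = \frac{\mathrm{PPV}}{\mathrm{prev}},\quad
\mathrm{rNPV} = \frac{\mathrm{NPV}}{1-\mathrm{prev}},$$

with $\mathrm{prev} = |new \cap \Omega|/|\Omega|$. A value of 1 is chance
level. $\Omega$ defaults to the scan minus established baseline EZ loss —
new loss cannot occur where loss already exists — which also reproduces the
internal consistency of the quantities above (a ~9 mm² domain with
~0.05 mm² of new loss gives a prevalence near 0.6%, so a PPV near 9%
normalizes to an rPPV near 15); `pv_domain(type = "full")` switches to the
whole scan. Per-eye values are averaged arithmetically across eyes, never
pooled over pixels. Eyes with no baseline IZ loss have undefined PPV and
are excluded from the mean as NA.

## Cohort statistics

* **Spearman correlation** (`spearman_cor`): Pearson correlation of
  midranks; stage is ordinal, so no linearity between stages is assumed.
  Two-tailed p-values by exact permutation enumeration for n ≤ 10 and the
  $t$ approximation above; both paths are exposed.
* **ICC** (`icc_agreement`): two-way random-effects, absolute-agreement,
  single-measures ICC(2,1) from the two-way ANOVA mean squares — the common
  default for inter-grader agreement; p from $F = MSR/MSE$.
* **GEE** (`gee_gauss`): Gaussian identity-link GEE with exchangeable
  working correlation, the conventional reading for a continuous outcome
  with two eyes per patient. The correlation parameter comes from moment
  equations on standardized residual cross-products, coefficients from
  iteratively reweighted least squares (tolerance 1e-8, at most 100
  iterations), and inference from the robust sandwich covariance, so a
  misspecified working correlation costs efficiency, not validity. With
  singleton clusters the fit reduces exactly to OLS with HC0 covariance
  (tested against an independent implementation). `gee_group_test` gives
  the 2-df Wald chi-square for the pooled-group factor and the three
  pairwise contrasts with Bonferroni adjustment (adjusted p = min(1, 3p)).
  Null simulations at 200 clusters hold the 5% size within Monte-Carlo
  error.
* Eyes whose overlap is undefined are dropped pairwise with a logged count,
  not imputed as zero.

## What the synthetic generator emulates

`generate_scene()` draws, per eye: exclusive class areas and the
telangiectasia area from zero-truncated normals at the configured group
means and SDs; nested star-shaped regions (harmonic radial perturbations
around a jittered foveal centre) rasterized to those areas, so C ⊆ B ⊆ A
holds exactly; a telangiectasia footprint assembled from round blobs placed
into each class at sampled per-eye overlap fractions; a DCP angiogram in
which the telangiectatic vessels are bright loops with 3–5 px walls whose
filled footprint is the truth mask, over a random-walk capillary mesh; an
SCP angiogram with 2–3 thick bright vessels; a photoreceptor slab at 0.7 of
dynamic range depressed by 0.15/0.35/0.55 over the three classes; and
multiplicative gamma speckle with unit mean and contrast 0.1. The record of
every choice the data could not fix (vessel appearance, wall widths,
intensities) is this vignette; the qualitative constraint is that
local thresholding must separate the dilated vessels nontrivially.

Design notes that required a decision:

* **Truncated-normal areas.** Truncating a normal at zero raises its mean —
  nearly doubling it for the early-stage EZ-loss class (0.016 ± 0.031 mm²).
  The location parameter is therefore re-calibrated so the zero-truncated
  mean equals the configured target; SDs are left as configured. Without
  this, seed-averaged areas could not converge to the targets.
* **Overlap fractions vary per eye.** The overlap of telangiectasia with
  each class is sampled per eye around the configured means with the
  cohort's SDs, rather than frozen at the mean, reproducing between-eye
  dispersion. The three fractions live on a simplex; the EZ and
  attenuation fractions share one quantile in opposite directions (a finite
  footprint redistributes between classes) and the EZ fraction shares its
  quantile with the EZ area (eyes with more EZ loss show more overlap —
  and a sampled overlap never outruns the region able to host it). Because
  clamping to the simplex shrinks the means — strongly in advanced disease,
  where targets sum to ~0.94 — pre-projection locations are calibrated on a
  deterministic quantile grid so post-projection means equal the targets.
* **Measurability.** No ground-truth telangiectasia is placed under the
  (dilated) SCP large-vessel footprint: the DCP signal there is projection
  artifact, unmeasurable by construction, and the quantitative pipeline
  removes it. Similarly, the capillary mesh is cleared in and immediately
  around the telangiectatic footprint, emulating a tightly marked lesion
  zone in which the dilated vessels dominate the signal.
* **Blob placement.** Footprint blobs are ≥ 10 px (smaller fragments are
  indistinguishable from speckle and would be eaten by the pipeline's speck
  filter); the last blob is rim-trimmed so each zone lands on its target to
  within 9 px.

`generate_longitudinal()` warps a baseline scene with a smooth random
displacement field (sum of Gaussian bumps scaled to a 3 px maximum, stored
with its numerical inverse so registration can be scored against truth),
adds new EZ-loss blobs — total area 0.052 ± 0.022 mm², a sampled 90–95%
confined to the warped baseline IZ-loss-only class — and peels a recovery
rim of 0.045 ± 0.023 mm² from the established EZ boundary. Follow-up
nesting is preserved because new EZ loss implies IZ loss. The follow-up
regime for cohort simulations (`longitudinal_scene_params()`) uses baseline
IZ loss of 0.6 ± 0.2 mm² and EZ loss of 0.25 ± 0.2 mm², the setting in
which new EZ loss can arise and its prediction is informative.

`generate_cohort()` lays out eyes under patients (about two thirds of
patients contribute both eyes; the two eyes share a unit-mean lognormal
area-scale effect, giving the within-patient correlation the GEE adjusts
for) with stages spanning 0–6 pooled as early (0–2), moderate (3–5) and
advanced (6).

**What passing tests do and do not show.** The generator reproduces the
cohort's areas, overlap dispersion and longitudinal magnitudes, but not OCT
physics: no SSADA decorrelation statistics, no B-scan volumes, no motion or
shadow artifacts, and only a binary stand-in for projection artifacts.
Passing tests therefore demonstrate that the quantification chain is
correct and well-calibrated on data with this statistical structure,
not that the segmentation would reach the same accuracy on device images.

## Numerical choices and degenerate inputs

* Problem sizes: simulations run at the native 304 × 304 grid; cohort
  checks use 50 seeds per group, longitudinal summaries 50 pairs, GEE size
  checks 1000 replicates at 200 clusters — enough for the 2-SE /
  Monte-Carlo tolerances they are compared at.
* Registration iterates 100/60/20 times at the three levels with early
  stopping after 12 non-improving iterations; displacements are capped at
  20 px; a run that cannot improve on the identity alignment warns and
  returns the best field found.
* Constant images: Phansalkar returns all-background for a zero image;
  max-entropy thresholding errors ("degenerate histogram"), which the
  artifact-mask wrapper converts to an empty mask with a warning.
* Empty telangiectasia gives NA overlaps (with a warning), never 0; empty
  predictive-value domains are an error; zero prevalence leaves rPPV
  undefined.
* Exact Spearman p-values enumerate up to 10! permutations in
  constant-memory chunks; ties use midranks throughout.
* The exchangeable correlation estimate is clamped to [-0.95/(max cluster
  size - 1), 0.95] for stability at small cluster counts.
* All randomness descends from one integer seed per scene/pair/run;
  identical seeds give bit-identical outputs, and pipeline outputs embed a
  hash of the scientific configuration (paths excluded).

## Known limitations

* The generator's vessel morphology is stylized; Phansalkar parameters that
  work here may need re-tuning on device images, whose contrast depends on
  the acquisition protocol.
* Registration is validated on smooth synthetic warps up to 3 px; real
  longitudinal pairs with saccadic artifacts or segmentation-plane errors
  are outside the tested envelope.
* The GEE sandwich is slightly liberal below ~50 clusters, as usual; the
  package reports it as computed.
* Removing projection-artifact pixels from area totals versus only
  displaying them as an overlay is a protocol choice; removal is the default,
  the count is logged, and an overlay-only policy remains available.
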