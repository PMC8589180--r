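# octamap

Quantifying the spatial overlap of deep-capillary-plexus (DCP)
telangiectasia with graded photoreceptor disruption on en-face OCT/OCTA in
macular telangiectasia type 2 (MacTel), including the longitudinal,
chance-normalized predictive value of baseline interdigitation-zone (IZ)
loss for new ellipsoid-zone (EZ) loss.

## Who this is for

Researchers analyzing paired 3 mm × 3 mm (304 × 304 px) en-face OCT
angiograms (superficial and deep plexus) and photoreceptor-slab images with
traced disruption regions — and anyone who needs the underlying operators:
Phansalkar local thresholding, Kapur maximum-entropy thresholding, hole
filling, nested-region decomposition, elastic mask transfer between visits,
and relative predictive values. A synthetic-scene generator with pixel-exact
ground truth stands in for patient data, so the full pipeline runs and is
tested without any download.

## The quantities at the core

Per eye, the traced combined regions A ⊇ B ⊇ C (A = IZ attenuation + IZ
loss + EZ loss, B = IZ loss + EZ loss, C = EZ loss) are decomposed by
subtraction into exclusive classes; areas are pixel counts × (3/304)² mm²,
and each overlap is

```
overlap(class) = 100 · |telangiectasia ∩ class| / |telangiectasia|   [%]
```

with the telangiectasia footprint segmented by Phansalkar local thresholding
inside the marked zone, hole-filled, and cleaned of superficial large-vessel
projection artifacts (max-entropy threshold + size/width filter).

Longitudinally, with the follow-up registered to baseline via the SCP and
`new = followupEZ \ baselineEZ` inside the domain Ω (scan minus baseline EZ
loss):

```
PPV  = |new ∩ iz| / |iz ∩ Ω|        rPPV = PPV / prevalence
NPV  = |Ω \ (iz ∪ new)| / |Ω \ iz|  rNPV = NPV / (1 − prevalence)
```

where `prevalence = |new ∩ Ω| / |Ω|`; rPPV = rNPV = 1 means chance level.

## Worked example

```r
library(octamap)

sc <- generate_scene(scene_params("advanced", seed = 42))
sc
#> <octa_scene> 304 px, 3 mm field, stage group 'advanced', seed 42
#>   truth areas (mm^2): tel 0.742 | attn-only 0.899 | IZ-loss-only 1.373 | EZ 1.829

rec <- analyze_eye(sc, data.frame(patient_id = "P001", eye_id = "E001",
                                  laterality = "OD", stage = 6))
round(rec[, 6:12], 3)
#>   tel_area_mm2 attn_area_mm2 izloss_area_mm2 ezloss_area_mm2 overlap_attn_pct
#> 1        0.742         0.899           1.373           1.829            1.641
#>   overlap_izloss_pct overlap_ezloss_pct
#> 1             24.951             73.409
```

The eye carries 0.74 mm² of segmented telangiectasia, of which 73.4% lies
inside EZ loss and only 1.6% inside mere IZ attenuation — the advanced-stage
pattern in which the vascular lesion colocalizes with the severe
photoreceptor damage.

```r
pair <- generate_longitudinal(sc, longitudinal_params(seed = 7))
row <- analyze_pair(pair)   # registers SCP, transfers masks, derives change
round(row[, c("new_ez_mm2", "ppv", "npv", "prevalence", "rppv", "rnpv")], 4)
#>   new_ez_mm2    ppv    npv prevalence   rppv   rnpv
#> 1     0.0219 0.0145 0.9997     0.0031 4.7581 1.0027
```

Only 1.5% of the baseline IZ-loss area converted to new EZ loss (low PPV),
but that is 4.8× the chance rate (rPPV), while absence of IZ loss predicted
EZ integrity no better than chance (rNPV ≈ 1) — new loss is rare, but it
appears where IZ loss already was.

Cohort-level runs: `run_cross_sectional()` (stage correlations and pooled
stage-group GEE comparisons of areas and overlaps) and `run_longitudinal()`
(cohort mean ± SD of PPV/NPV/rPPV/rNPV), both reproducible from a single
seed and writing CSV tables plus a config-hashed run log when given an
output directory.

## Layout

- `R/` — operators (`phansalkar_threshold`, `max_entropy_threshold`,
  `fill_holes`), segmentation (`circumscribe_telangiectasia`,
  `scp_artifact_mask`, `exclude_artifacts`), regions (`decompose_regions`,
  `area_mm2`, `percent_overlap`), registration (`register_scp`,
  `warp_mask`), longitudinal analysis (`ez_change`, `predictive_values`),
  statistics (`spearman_cor`, `icc_agreement`, `gee_gauss`,
  `gee_group_test`, `cross_sectional_report`), synthetic data
  (`generate_scene`, `generate_longitudinal`, `generate_cohort`) and the
  pipeline (`run_cross_sectional`, `run_longitudinal`).
- `vignettes/overlap-mapping-methods.Rmd` — the model, parameter choices,
  generator design and limitations.
- `tests/testthat/` — oracle-backed unit, property and acceptance tests.
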