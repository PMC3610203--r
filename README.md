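# scarq

Quantification of left-ventricular (LV) myocardial scar extent from late
gadolinium enhancement cardiovascular magnetic resonance (LGE-CMR)
segmentations — for imaging researchers and electrophysiology groups who
need reproducible scar indices (percent scar, scar mass, transmural extent)
to study arrhythmic risk in coronary artery disease, e.g. around ICD
implantation.

`scarq` starts where segmentation ends. Inputs are per-slice endocardial and
epicardial contour polygons (mm), a co-registered binary scar raster
(scar vs normal myocardium), pixel spacing / slice span, and the anterior RV
insertion angle. Outputs are the global scar burden and, on the AHA
17-segment model, the per-segment transmural scar extent by four estimators
that deliberately answer different questions about the same lesion:

| estimator | definition | character |
|---|---|---|
| STAB | scar area / myocardial area in the segment | averaged, area based |
| STLB | `100 * sum(scar chord length) / sum(wall chord length)` over radial chords from the endocardial centroid | averaged, line based |
| WIT  | intensity-weighted scar mass fraction, `w = clamp((I - remote)/(core - remote), 0, 1)` (binary mass fraction without an intensity channel) | averaged, partial-volume aware |
| SMST | `100 * max(scar/wall)` over the segment's chords | extremal, keeps spatial concentration |

Per-segment values are binned into the 1–24 / 25–49 / 50–74 / 75–100 %
quartiles (scar ≥ 75 % = transmural). Percent scar is the volume-weighted
scar fraction of the myocardium; LV mass uses 1.05 g/cm³; scar mass is
percent scar × LV mass by construction.

The package also ships synthetic validation phantoms — annular LV stacks
bearing wedge-shaped scars with closed-form expectations for every metric —
a toy cohort simulator, and the 2×2 diagnostic layer (median
dichotomization, sensitivity/specificity/PPV/NPV, Fisher's exact test) used
to evaluate dichotomized scar indices against an arrhythmic endpoint.

## Worked example

A 10-slice annular phantom (endo 20 mm, epi 30 mm, 1 mm pixels, 10 mm
slices) with a 60° wedge of half-wall depth aligned to the first basal
sector:

```r
library(scarq)
stack <- make_annulus_stack(n_slices = 10, r_endo = 20, r_epi = 30,
                            pixel_spacing = 1, slice_span = 10)
ph <- apply_wedges(stack, wedge_spec(theta_start = 0, theta_span = pi/3, depth = 0.5))
summarize_patient(stack, ph$scar)
#> <patient_scar_summary>
#>   LV mass 164.2 g | scar mass 12.5 g | percent scar 7.6%
#>   STAB quartiles [1-24 / 25-49 / 50-74 / >=75]: 0 / 3 / 0 / 0 (total 3)
#>   STLB quartiles [1-24 / 25-49 / 50-74 / >=75]: 0 / 1 / 2 / 0 (total 3)
#>   WIT  quartiles [1-24 / 25-49 / 50-74 / >=75]: 0 / 3 / 0 / 0 (total 3)
#>   SMST quartiles [1-24 / 25-49 / 50-74 / >=75]: 0 / 0 / 3 / 0 (total 3)
```

The closed forms give LV mass 164.9 g, percent scar 7.5 %, and for the
affected basal segment STLB 50, SMST 50, STAB = WIT 45. Measured:

```r
subset(segment_transmurality(stack, ph$scar), has_scar)
#>    segment_id  stab  stlb   wit  smst has_scar
#> 1           1 45.59 50.03 45.59 55.32     TRUE
#> 7           7 45.59 50.03 45.59 55.32     TRUE
#> 13         13 30.43 33.36 30.43 55.06     TRUE
```

Segments 1 and 7 see the full wedge (their sectors coincide with it);
apical segment 13 spans 90°, so it averages the same lesion over a wider
sector. STLB lands within 0.1 pp of truth; SMST reads ~55 rather than 50
because a maximum taken over chords against a binary 1 mm raster inherits
the positive extreme of half-pixel boundary noise (~+4–5 pp on a 10 mm
wall, halving with pixel size) — see the methods vignette for the full
analysis.

The 2×2 layer, on the event counts of a 66-patient split at a 2-segment
STLB ≥ 50 % cut (11/30 events above vs 3/36 at or below):

```r
diagnostic_stats(tp = 11, fp = 19, fn = 3, tn = 33)
#> <diagnostic_stats> tp=11 fp=19 fn=3 tn=33
#>   sensitivity 79% (0.7857)
#>   specificity 63% (0.6346)
#>   ppv         37% (0.3667)
#>   npv         92% (0.9167)
```

## Layout

- `R/` — geometry & AHA mapping, metrics, phantoms, cohort statistics, IO.
- `tests/testthat/` — unit, property and oracle-equivalence suites
  (independent point-in-polygon, dense chord casting and hypergeometric
  enumeration oracles live in `helper-oracles.R`).
- `vignettes/scar-quantification.Rmd` — the methods vignette: model,
  estimator definitions, numerical choices and known limitations.
- `exec/scarq` — command-line wrapper.
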