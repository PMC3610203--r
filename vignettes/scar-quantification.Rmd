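---
title: "Quantifying LV scar extent: model, estimators and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying LV scar extent: model, estimators and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scarq)
```

## The measurement problem

In patients with coronary artery disease, myocardial scar imaged by late
gadolinium enhancement CMR (LGE-CMR) is the substrate for re-entrant
ventricular arrhythmia, and quantitative indices of scar extent — percent
scar, scar mass, and the transmural depth of scar within the wall — are used
to stratify arrhythmic risk around ICD implantation. "Transmurality",
however, is not one number: estimators that normalize by the whole segment
average away the spatial concentration of a lesion, while an extremal
estimator keeps it. `scarq` implements four such estimators side by side so
their divergence on the same lesion can be studied quantitatively.

The package works downstream of segmentation: its inputs are, per short-axis
slice, the endocardial and epicardial contour polygons (mm, image frame), a
co-registered binary scar raster (scar vs normal myocardium — deliberately a
binary classification, with no peri-infarct "gray zone" modelling), pixel
spacing, the axial span of each slice, and the angular position of the
anterior RV insertion.

## Global burden

A pixel belongs to the myocardium when its center lies inside the epicardial
and outside (or on) the endocardial contour. With voxel volume
$v_i = d_x d_y \cdot \mathrm{span}_i$,

$$\mathrm{percent\ scar} = 100 \cdot
  \frac{\sum_i v_i\,\#\{\text{scar pixels}\}_i}
       {\sum_i v_i\,\#\{\text{myocardial pixels}\}_i},
\qquad
\mathrm{LV\ mass} = \rho \sum_i v_i\,\#\{\text{myo}\}_i,$$

with $\rho = 1.05\ \mathrm{g/cm^3}$ (standard myocardial density), and scar
mass is exactly percent scar $\times$ LV mass / 100 — the three quantities
share the same voxel sums, so this identity holds to machine precision by
construction. Scar pixels found outside the myocardium are clipped on load,
with a warning reporting the count.

## The AHA mapping

Slices are apportioned to basal/mid/apical levels by contiguous thirds of
the slice count, remainder basal-first then mid — the common equal-thirds
reading of the 17-segment model when no anatomical landmarks are encoded in
the input. Within a level, sectors are counted counterclockwise from the
anterior RV insertion angle (a required input, not auto-detected): six
60-degree sectors at the basal and mid levels (segments 1–6, 7–12), four
90-degree sectors apically (13–16). Sector boundaries are half-open, so
every angle maps to exactly one segment. Segment 17, the apex cap, has no
short-axis wall to cast chords through; the package reports it only as a
scar present/absent flag taken from the most apical slice, and the quartile
profiles count segments 1–16.

## The four transmurality estimators

Per segment, with areas/masses accumulated over the segment's slices:

* **STAB** (area based): $100 \cdot A_\mathrm{scar} / A_\mathrm{myo}$,
  normalized by the myocardial area actually present in the sector (not a
  nominal sector area — an explicit assumption of this implementation).
* **STLB** (line based): chords are cast from the endocardial centroid at
  uniform angles within the sector (default 60 per sector); each chord runs
  between its endocardial and epicardial crossings. The default average is
  thickness-weighted, $100\sum \ell_\mathrm{scar} / \sum \ell_\mathrm{wall}$;
  an unweighted per-chord mean is available (`stlb_weighted = FALSE`).
* **WIT** (intensity-weighted mass fraction):
  $100 \sum_{p \in \mathrm{scar}} w_p m_p / \sum_{p} m_p$ with
  $w_p = \mathrm{clamp}\{(I_p - I_\mathrm{remote})/(I_\mathrm{core} -
  I_\mathrm{remote}), 0, 1\}$ — a declared linear partial-volume ramp,
  isolated behind one function. Without an intensity channel $w_p = 1$ and
  WIT reduces to the binary scar mass fraction, which equals STAB under
  uniform voxel size (asserted to $10^{-9}$ in the tests).
* **SMST** (spatial maximal): $100 \max_\mathrm{chords}
  \ell_\mathrm{scar}/\ell_\mathrm{wall}$ — the only estimator that retains
  the spatial concentration of a lesion: a narrow transmural needle scores
  near 100 while STLB stays near the needle's angular fraction.

A segment without a single scar pixel scores zero on all four estimators
(`has_scar` is exactly "contains at least one scar pixel"); segments with no
myocardial pixels report missing values, not zeros. An optional
minimum-scar-area filter (mm²) exists and defaults to off.

Transmural extent is binned into 1–24 / 25–49 / 50–74 / 75–100 %, half-open
below, with 75 inclusive upward (scar $\ge 75$% is transmural); values below
1% round into the first bin, so the bin counts always sum to the number of
scarred segments.

## Chord sampling and sub-pixel numerics

Each chord is sampled at 200 equidistant midpoints. Two lookup rules are
offered:

* `interp = "bilinear"` (default): the scar and myocardium rasters are
  bilinearly interpolated at the sample points and the chord's scar length
  is $\ell_\mathrm{wall}\cdot\sum b_\mathrm{scar} / \sum b_\mathrm{myo}$.
  Normalizing by the interpolated myocardium cancels the shared half-pixel
  quantization of the two fields at the endocardial and epicardial edges.
* `interp = "nearest"`: each sample contributes the binary scar status of
  its containing pixel.

The conditional-bilinear rule is the default because the plain
nearest-pixel rule is systematically biased low: samples just inside the
wall fall in pixels whose centers lie outside it, which on a 10 mm wall at
1 mm pixels depresses STLB by about 2 percentage points. With the default
rule, STLB on the analytic phantom below is accurate to ~0.1 pp, stable
under chord-count doubling (< 0.05 pp) and under pixel halving (< 0.5 pp).

**SMST carries an irreducible positive quantization bias.** The boundary of
a binary raster can only be localized pointwise to roughly ±0.3–0.5 pixel,
whatever the interpolation; STLB averages that noise away across a sector's
~25 independent boundary pixels, but SMST is a maximum and inherits the
*extreme* of the noise instead. On a 10 mm wall at 1 mm pixels this
amounts to about +4 to +5 pp (the analytic phantom with true maximal
transmurality 50% measures ~55), halving as pixel size halves. No estimator
honoring the binary raster contract can do better: reducing the per-chord
error below ~0.1 px would require averaging the whole sector boundary,
i.e. ceasing to be a maximum. Property tests therefore bound SMST against
truth by a one-sided band of one pixel per wall thickness, while the three
averaged estimators are held to ~1–2% of truth at default resolution.
Downstream this bias is usually immaterial — quartile binning at 25/50/75%
absorbs it except within ~5 pp of a cut.

## The phantom module

`make_annulus_stack()` builds stacks of identical circular annuli (sampled
as ≥256-vertex polygons; 256 vs 1024 vertices changes rasterized area by
< 0.1%), and `apply_wedges()` adds endocardium-attached wedge scars of
chosen angular span and fractional depth $d$. Concentric circles are
deliberately unrealistic: they are the geometry for which every estimator
has a closed form. For a wedge of depth $d$ covering a fraction $f$ of a
sector of an annulus with radii $r_1 < r_2$:

$$\mathrm{STLB} = 100\,d f,\quad \mathrm{SMST} = 100\,d,\quad
\mathrm{STAB} = \mathrm{WIT} = 100 f\,
\frac{(r_1 + d(r_2-r_1))^2 - r_1^2}{r_2^2 - r_1^2}.$$

Overlapping wedges resolve, per angular interval, to the deepest wedge.
`phantom_truth()` evaluates these forms from the wedge specification alone,
never from the rasters, so measured-vs-truth comparisons are genuine
two-route checks. Noise and partial-volume ramps affect only the intensity
channel; the binary mask stays geometric, keeping the binary-path truths
exact. The LV center sits on the grid center, which with the even default
grid side is a pixel corner, preserving the 4-fold symmetry of the
rasterization.

What the phantoms do *not* emulate: crescent-shaped ventricles, wall
thickness variation, papillary anatomy, through-plane curvature near the
apex, acquisition artifacts or surface-coil bias. Passing phantom tests
demonstrates the geometry and arithmetic of the estimators, not robustness
to real segmentation noise.

The property battery uses 200 random multi-wedge phantoms at a reduced size
(3 slices, ~14/23 mm radii) to keep the suite fast; the analytic reference
phantom (10 slices, 20/30 mm, 1 mm pixels) carries the tight-tolerance
assertions. Across the battery, per-segment Pearson correlations among
STAB/STLB/WIT exceed 0.99 — the three normalized estimators are nearly
affine functions of one another on endocardium-attached lesions — while
SMST decouples when lesions are spatially concentrated.

## The toy cohort and the 2x2 layer

`make_cohort()` draws per-patient scar mass from a log-normal (default
median 20 g, `sdlog` 0.5, i.e. mean ≈ 23 g, spread comparable to a typical
ICD cohort) and a binary endpoint from
$P(\mathrm{event}) = \mathrm{logit}^{-1}(\alpha + \beta\,\mathrm{mass})$
with defaults $\alpha = -3$, $\beta = 0.08\,\mathrm{g^{-1}}$, giving an
event rate near one in five for a 66-patient cohort. The simulator feeds
only the dichotomization layer: survival modelling is out of scope.

`dichotomize_median()` cuts at the sample median, strictly-above = positive
(ties at the median go to the negative group, deterministically).
`diagnostic_stats()` reports sensitivity, specificity, PPV and NPV both as
raw fractions and as integer percentages rounded half away from zero — the
rounding used for printed clinical values; raw fractions are always
retained because printed percentages do not always round-trip. A statistic
with an empty denominator is missing, not zero. `fisher_exact()` is the
two-sided conditional exact test (delegated to `stats::fisher.test`, and
cross-checked in the tests against a direct hypergeometric enumeration to
$10^{-12}$).

One statistical subtlety: Fisher's exact p-value is discrete and
conservative, so under a null simulation its distribution *dominates* the
uniform ($P(p \le \alpha) \le \alpha$, $E[p] \ge 1/2$) rather than matching
it; the null-calibration test asserts exactly that property.

## Degenerate inputs and tie-breaks

* endocardium not strictly inside the epicardium, zero-thickness walls,
  non-positive spacings: typed geometry errors naming the slice;
* chords that miss a contour are dropped with a warning; a sector losing
  all its chords is an error;
* all-identical cohort values: a flagged degenerate split, not an error;
* intensity calibration requires core > remote;
* angular wrap-around is handled modulo $2\pi$ everywhere; sector and bin
  edges are half-open as stated above.

## Known limitations

* SMST's quantization bias, quantified above.
* The slice-to-level rule and the sector origin convention are assumptions;
  inputs produced under other conventions must be rotated/relabelled before
  loading.
* STAB normalizes by the myocardial area present in the sector; tools that
  normalize by a nominal AHA sector area will differ where the wall is
  incomplete.
* The phantom closed forms assume endocardium-attached scars; detached
  (mid-wall) lesions are measurable but have no analytic truth here.
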