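---
title: "Automated oral cytology risk stratification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated oral cytology risk stratification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oralcyto)
```

## The problem

Brush cytology is a minimally invasive route to early detection of oral
squamous cell carcinoma (OSCC) and the dysplastic lesions that precede it,
but reading smears requires a cytopathologist, and manual scoring detects
high-grade dysplasia (HGD) poorly. Portable slide-scanning microscopes make
it practical to digitise a smear as on the order of 100--125 circular
fields and push the reading to software. `oralcyto` implements that
software path end to end:

1. **Segmentation** — find the circular field of view (FOV), detect stained
   cell mass, split touching cells, and cut out per-cell regions of
   interest (ROIs);
2. **Quality control** — discard clumps, shadow artifacts, unstained debris
   and anucleate fragments;
3. **Scoring** — assign each surviving cell an atypia score in $[0, 1]$
   through a pluggable scorer contract;
4. **Aggregation** — reduce each patient's cells to three features;
5. **Risk stratification** — a two-test cascade separating OSCC risk, HGD
   risk, and low-grade/benign (LGD/BNG) patients;
6. **Evaluation** — the full diagnostic-statistics suite (sensitivity,
   specificity, accuracy, predictive values, Cohen's kappa, McNemar, ROC).

No clinical images ship with the package. Every stage is exercised against
a built-in synthetic cytology generator with exact ground truth, which is
first-class, tested code.

## Synthetic data: what it emulates and what it does not

`scene_spec()` describes one microscope field: by default a 2592 x 1936
8-bit RGB frame at 1.9 px/µm, a bright circular FOV (radius 900 px) on a
dark vignette, and squamous cells rendered as rotated, anti-aliased
ellipses (major diameter 25--60 µm) with darker, blue-dominant nuclei.
Atypia is rendered *morphologically*: atypical cells draw their nucleus
area fraction from 0.25--0.45 instead of 0.08--0.20 and get lobed,
irregular boundaries. This choice mirrors the fact that clinical atypia
criteria are nuclear and morphological, and it is what gives the
morphometric reference scorer its signal. Shadow artifacts — the main
optical confounder on portable scanners — are dark, red-dominant
(red/green about 1.5), semi-transparent blobs. Gaussian pixel noise
(sd 5/255 by default) is added last; the paper-thin alpha band at each
ellipse boundary straddles the ground-truth `d <= 1` contour symmetrically,
so mask areas are exact when antialiasing is disabled.

Identical specs (including the seed) render byte-identical images. Slides
derive per-field seeds as `(master * 10007 + i) mod (2^31 - 1)` — a
splittable counter scheme that keeps every derived seed a valid 32-bit
integer and lets any field be regenerated in isolation.

What the generator does **not** emulate: real Papanicolaou stain chemistry
and its colour variability, focus gradients, overlapping cell sheets,
keratinised debris, and scanner-specific optics. Tests passing on this
generator therefore demonstrate the correctness of the algorithms under
controlled conditions, not clinical performance.

`cohort_spec()` generates per-cell *score tables* directly, bypassing
images, for work on aggregation and classification at full cohort scale.
Each class draws per-patient latent parameters (atypical fraction,
atypical-component mean, normal-component mean) from between-patient
distributions, then draws cell scores from the two-component mixture:
normal scores clipped to $[0, 0.5]$, atypical to $(0.5, 1]$. The defaults
are the published class statistics for oral cytology cohorts: atypical-cell
percentages 14% (BNG/LGD), 16% (HGD) and 39% (OSCC); mean atypical-cell
scores 0.78, 0.76 and 0.71; mean all-cell scores 0.17, 0.21 and 0.40;
15 patients per class and 200 cells per patient. Two published quirks are
preserved deliberately: the *low-grade* class has the highest mean
atypical-cell score (0.78 > 0.76 > 0.71), and the figure-caption values
(OSCC fraction 0.38, HGD = LGD = 0.17) differ slightly from the running
text (0.39/0.16/0.14); the generator defaults follow the text, and every
parameter is overridable so tests can construct either ordering. The
benign class reuses the LGD parameters since published statistics pool
"BNG/LGD". The printed ± values are interpreted as *between-patient*
standard deviations; a separate `cell_sd` (default 0.05) governs
within-patient spread.

## Segmentation

The FOV is estimated from **three boundary pixels**: rays are cast inward
from the image border along six equally spaced directions and the first
pixel whose green intensity exceeds the global Otsu threshold is recorded;
the three hits maximising their minimum pairwise angular separation define
the circle via the closed-form circumcentre. Collinear triples retry with
rotated scan lines; a uniform frame raises "FOV not detected"; a frame
with no vignette returns border points flagged low-confidence. On
synthetic fields the recovered circle is within ~1 px of truth, and the
circumcircle itself reconstructs 1000 random circles to better than 1e-6
relative error.

Cell mass is thresholded in the **green channel** (highest stain contrast)
with Otsu's method computed from in-FOV pixels only, keeping the dark
side. A contrast gate (the two Otsu side means must differ by at least 25
intensity levels) stops a cell-free field from percolating noise into
foreground. Components below 25 px² are removed as specks, interior holes
are filled, and the image outside the dilated high-level ROIs is cleared.

Touching cells are split by a **distance-transform watershed**
(`EBImage::watershed`) with peak neighbourhood `ext` of half the minimum
separation (default 10 µm at the image's pixel scale) and merge tolerance
2: clump saddles (roughly 0.3 of the cell radius for cells overlapping at
1.5 radii) are far deeper and stay split, while sub-pixel ridge
fluctuations are merged away. Interior hole-filling during mask cleanup
matters here: a single bright noise pixel inside a cell would otherwise
carve its distance-map ridge into two peaks separated by a deep false
saddle. One-pixel ridges between labels
are erased so components stay disconnected under 8-connectivity. Particle
analysis then emits per-component ROIs with bounding box, area (px² and
µm²), ellipse-fit axes from second moments (with the 1/12 px² pixel-extent
correction, which makes a 10 x 20 rectangle report aspect 2.000), centroid
and per-channel means, ordered by bounding-box `(y0, x0)`.

Coordinates are 1-based with `x` = column and `y` = row, and bounding
boxes are inclusive — the native R convention, used consistently across
masks, ROIs and manifests.

## Quality control

Four checks run in a fixed order with short-circuiting, all thresholds
open in `qc_criteria()` (no numeric value here is prescribed by the
method statement; each default is a package choice calibrated to squamous
cells at 20--70 µm):

| check | rule | default |
|---|---|---|
| size/aspect | area within bounds, aspect below max (inclusive) | 150--4000 µm², 3.0 |
| shadow | mean red / mean green at most the cutoff (inclusive) | 1.15 |
| hematoxylin area | fraction of pixels with blue >= red and luminance below the ROI's Otsu split | >= 0.05 |
| nucleus | red-channel threshold + particle analysis finds a particle of minimal area; largest stored | >= 10 µm² |

The shadow ratio direction (red over green, with an inclusive upper bound)
is a package decision; shadows on portable scanners are dark and
red-dominant while basophilic stain is not. On generator defaults, 100% of
intact synthetic cells pass and 100% of shadows fail in the shipped test
runs; the acceptance suite asserts >= 90% for both.

## Scoring

The scorer contract is one score in $[0, 1]$ per ROI (0 normal, 1
atypical), with "atypical" meaning **strictly** above 0.5 — a score of
exactly 0.5 is not atypical. Reported bins are $[0,0.3)$, $[0.3,0.5)$,
$[0.5,0.7)$, $[0.7,0.9)$, $[0.9,1]$: half-open, closed on the left, top
bin closed (the verbal ranges in the source material overlap at their
endpoints; this convention resolves them).

Production deployments slot a CNN behind this contract (transfer-learned
classifiers of the Inception V3 family, trained on the order of 4000
epochs at learning rate 0.01, have filled this role); no trained weights
or clinical images are available to this package, so it ships a
**morphometric reference scorer** instead: ridge-regularised logistic
regression (`glmnet`, alpha 0, lambda 0.01 by default) on area, aspect,
nucleus/cell area ratio, boundary irregularity (the isoperimetric quotient
perimeter²/4πA), and per-channel means, standardised on the training set.
Its logistic output is the score. A stratified 90/10 train/validation
split reports validation accuracy as metadata; the returned scorer is
refitted on all examples. External scorers are plain functions of the ROI
table; out-of-range scores are rejected naming the ROI.

## Aggregation and the cascade

Per patient, with $s_i$ the cell scores and the atypia rule $s > 0.5$:

$$\text{percentage atypical} = 100 \cdot \frac{|\{i : s_i > 0.5\}|}{n},
\qquad
\text{mean atypical score} = \frac{\sum_{s_i > 0.5} s_i}{|\{i : s_i > 0.5\}|},
\qquad
\text{mean score} = \frac{\sum_i s_i}{n}.$$

A patient with no atypical cell has an *undefined* mean atypical score —
represented explicitly as `NA`, never coerced to 0 — and is treated by
Test 2 as an automatic negative: under the cascade's logic a patient with
zero atypical cells cannot be high grade.

**Test 1** is a linear-kernel SVM (`e1071`, cost 1, features standardised
to training mean/variance) on (mean score, percentage atypical) — two
strongly correlated features (Pearson r > 0.99 on generator-default
cohorts) — flagging OSCC risk against everyone else. The decision rule is
stored as explicit weights so models serialise to JSON and predict
identically forever. **Test 2** applies only to Test-1 negatives: an ROC
cutoff on the mean atypical-cell score alone, derived by contrasting OSCC
against LGD training patients and then used to separate HGD from
LGD/benign. "Optimal" is Youden's $J = \text{sens} + \text{spec} - 1$
maximised over candidate thresholds (midpoints between adjacent sorted
unique training scores), ties resolved toward the lower cutoff, i.e.
toward sensitivity. Patients at or above the cutoff are called HGD risk.
The three strata partition every cohort, and instrumentation asserts
Test 2 is never evaluated on a Test-1 positive.

The cohort split is seeded, 50/50 by default, and stratified by class with
largest-remainder per-class allocation (ties to class order): a 60-patient
cohort splits exactly 30/30 while every class stays within one patient of
its proportional share. Stratification is switchable; the published design
says only "randomly selected". `compare_learners()` refits the Test-1
task with five learners (linear SVM, random forest, logistic regression,
LDA, k-NN) under one shared standardisation, split and seed.

## Evaluation statistics

`metrics_from_counts()` keeps raw fractions and reports percents rounded
half-up, integer by default or one-decimal — both styles appear in
clinical tables. Half-up arithmetic means 13/15 reports as 87, even though
the source tables print "88 (13/15)" for that ratio; the package follows
the arithmetic and records the discrepancy here. Zero-denominator metrics
are undefined (`NA`), never 0.

Cohen's kappa is the unweighted $(p_o - p_e)/(1 - p_e)$ with both
agreement terms reported, undefined (flagged) when $p_e = 1$. McNemar's
test uses the exact two-sided binomial $p = \min(1,\, 2\,P(X \le \min(b,c)))$
for $b + c < 25$ and the continuity-corrected $\chi^2$
$(|b-c|-1)^2/(b+c)$ otherwise — the switch point is a package choice, and
every result carries its method tag. ROC analysis enumerates midpoint
thresholds, computes AUC by trapezoid, and picks the Youden cutoff with
ties toward the lower threshold; AUC is invariant under strictly
increasing score transforms. Group comparisons use Kruskal--Wallis,
Pearson correlation, and a Kolmogorov--Smirnov normality check with
estimated parameters (method-tagged as such, since estimation makes it
approximate; in tests it is the implementation, never the oracle — those
are `e1071::classAgreement`, `stats::mcnemar.test` and `pROC`).

The manual cytology score sums seven binary features (multi-nucleation,
mitotic figures, prominent nucleoli, altered N:C ratio, hyperchromatic
nucleus, irregular nuclear membrane, abnormal cell shape) and calls a case
positive strictly above 3. The methods literature lists six features and
names abnormal cell shape among the most diagnostic; both variants are
supported and seven is the default.

## Numerical and design choices

* **Otsu** is a 256-bin histogram routine returning the bin boundary
  `k - 0.5`; comparisons on fractional values (luminance means) use
  `floor(value) < threshold` to stay on the bin scale.
* **Watershed tolerance 2 / ext half the minimum separation** — see the
  segmentation section for the saddle-depth reasoning.
* **Stain palette ranges** are constrained so that even worst-case
  independent channel draws keep stained cells' red/green below the 1.15
  shadow cutoff; shadows sit near 1.5.
* **Degenerate inputs**: empty score lists error; empty masks pass through
  as empty; a mean green of zero fails the shadow check; both-raters-
  constant kappa and `b = c = 0` McNemar are flagged degenerate rather
  than silently numeric.
* **Problem sizes in the shipped checks** (package choices): 50
  native-size fields for the segmentation oracle, 6 mixed fields for QC
  discrimination, 20 seeded cohort replicates (60 patients x 200 cells)
  for cascade recovery, 200 simulations for the Kruskal--Wallis type-I
  rate, 1000 random circles for circumcircle recovery. The demonstration
  pipeline (`pipeline_config()`) uses reduced 640 x 480 fields at 1 px/µm
  with 4 patients per class so a complete simulate-to-evaluate run
  finishes in well under a minute; scale is a matter of configuration.

## Known limitations

* The reference scorer is morphometric; it is a stand-in honouring the
  scoring contract, not a reimplementation of a CNN, and its accuracy on
  real smears is unknown.
* Overlapping-cell resolution beyond the distance-transform watershed is
  out of scope (heavily overlapping sheets will under-segment).
* The generator's stain model is stylised; colour-based QC thresholds
  (shadow ratio, hematoxylin rule) will need recalibration on real
  scanner output.
* Published clinical agreement values (tele-cytology vs microscopy kappa
  0.67--0.72) depend on patient images that were never deposited; the
  package covers the *implementations* of those statistics with oracle
  tests instead of reproducing the clinical numbers.
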