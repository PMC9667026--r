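---
title: "Non-contact ovine morphometrics: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-contact ovine morphometrics: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Weighing and measuring grazing sheep by hand is slow, stresses the animals,
and carries zoonotic risk. A practical alternative is to photograph each
animal from the side and from above as it walks through a race, segment the
animal from the background, and compute its body-size traits from the
silhouette alone. `ovimetry` implements the downstream half of such a
system: it takes binary masks (segmentation itself is a pluggable upstream
step, e.g. an instance-segmentation CNN), finds anatomical landmarks on the
silhouette contour, converts pixel distances to centimetres through a
camera-distance-dependent scale model, and derives the eight standard
traits — height at wither (HW), body slanting length (BSL), chest depth
(CD), hip height (HH), shoulder width (SW), rump width (RW), chest
circumference (CC), shank circumference (SC). A biometric layer relates
those traits to body weight (BW): descriptive statistics, Spearman rank
correlation, one-way ANOVA by sex, and bidirectional stepwise linear
regression, with the reference flock's published sex-specific prediction
equations shipped as evaluable fixtures.

## Landmark rules

All rules operate on the closed outer contour of the largest foreground
component, traced with Moore-neighbour 8-connectivity, clockwise in image
coordinates (x rightward, y downward), starting from the
topmost-then-leftmost boundary pixel. The animal is normalized to face
right; `normalize_pose()` mirrors the mask when the topmost silhouette
point (carried by the head in a standing pose) lies in the left half.

Three families of rules are used, each restricted to a configurable search
box expressed as fractions of the silhouette bounding box
(`range_config()`):

* **Range-restricted extrema.** The head vertex is the y-minimal contour
  point in the right-half head box; the hip top is the y-minimal point in
  the left-half box; the facial vertex is the globally x-maximal point; the
  front hoof is the x-maximal point among contour points supported by the
  convex hull in the lower half. Ties always break to the smallest contour
  index, so every detector is deterministic.
* **Chord-distance rules.** The withers is the point of the dorsal arc
  between hip top and head vertex farthest from the chord through those two
  anchors ("straight line b"). The chest front (brisket) is the point of
  the frontal arc between the facial vertex and the front hoof closest to
  the chord through them, with the distance computed from the implicit line
  equation `d = |ax + by + c| / sqrt(a^2 + b^2)`.
* **Curvature rules.** The sciatic tuberosity (rear anchor of BSL), the
  chest bottom (sternum), and the four dorsal width points (scapular and
  hip protrusions, left and right of the body axis) are maxima of the
  u-chord curvature inside their boxes. The estimator is the Menger
  (inverse circumradius) curvature of the triangle formed with neighbours
  `u` chord steps away: rotation invariant, exactly `1/r` on circles, and
  robust to pixel noise because the chord spans many pixels.

Derived quantities: HW and HH are vertical drops from withers / hip top to
the ground line (the contour's maximal y); CD is the vertical distance from
withers to chest bottom; BSL is the Euclidean distance from brisket to
sciatic tuberosity; SW and RW are the |Δy| of the paired dorsal points; CC
is the perimeter of an ellipse with semi-axes SW/2 and CD/2 (the ovine
thorax cross-section is close to an ellipse whose axes are the dorsal chest
width and the lateral chest depth); SC is π times the foreleg width
measured one third of the way down from the chest bottom to the hoof, where
the metacarpus is thinnest.

### Design choices in the landmark layer

Several points are under-determined by the verbal protocol; the package
resolves them as follows.

* **Convexity filter on curvature maxima.** Unsigned curvature is as large
  at concave corners (leg–belly and neck–head junctions) as at the skeletal
  prominences the rules target, and those junctions fall inside the search
  boxes. Since every targeted feature is a convex prominence, the detectors
  attach the orientation sign to the Menger estimate and maximise over
  convex points only.
* **Chord step `u`.** The default is 1% of the contour point count
  (minimum 3). The chord must span many pixels for noise immunity, but the
  estimate at a corner "bleeds" roughly `u` points along the contour in
  each direction; at 2% of a typical 6,000-point contour that halo is about
  10 cm of arc and crosses search-box boundaries, while 1% (50–70 px)
  keeps corner evidence local and still spans far more than the pixel
  noise. `u` is exposed as an argument everywhere.
* **Withers chord anchors.** The chord is taken through the head vertex and
  the hip top — the two dorsal anchors already computed — rather than a
  separate "dorsal nail" point; with the head carried above the back line,
  the perpendicular distance is maximised at the withers.
* **Chest-front arc trimming.** The minimum-distance rule is ill-posed near
  its own anchors: the chord passes through the nose and the hoof, the
  muzzle and chin occupy roughly the first quarter of the frontal arc, and
  the lower foreleg converges onto the chord all the way down to the hoof.
  `detect_chest_front()` therefore excludes the head-dominated quarter on
  the nose side and the leg-dominated 30% on the hoof side (both
  configurable), searching the neck underside and chest only.
* **Search boxes.** The published protocol shows its per-landmark pickup
  ranges only pictorially, so the `range_config()` defaults encode typical
  ovine proportions (e.g. head box x ∈ [0.55, 1], y ∈ [0, 0.5]; sciatic box
  x ∈ [0, 0.2], y ∈ [0.3, 0.8]) and every box is a plain argument.
* **Shank side.** The shank is measured on the leg whose cross-section is
  nearest the detected front hoof, matching the manual convention of using
  a forelimb.

## Pixel-to-centimetre calibration

The px-per-cm ratio depends on the distance between animal surface and
camera ("closer is large, farther is small"), and the relation is curved.
The reference rig photographs a plate of 7 × 7 cm squares at 5 cm steps
over each camera's range of motion (back view: 0–105 cm; side view:
0–50 cm); `mean_ratio()` turns one photograph's corner gaps into a ratio
sample and `fit_scale_model()` fits `ratio = c2 d² + c1 d + c0` by ordinary
least squares on the raw polynomial design, unweighted, reporting R². The
two views have different optics and are modelled independently; conversions
outside the fitted range of motion warn. The fit is exact (machine
precision, R² = 1) on noise-free quadratic input, which is how the shipped
reference equations (back intercept 1.9325 px/cm, side intercept 21.314
px/cm) are recovered in the tests and the acceptance script.

Optional per-trait multiplicative correction factors
(`correction_coefficient()`, the mean of paired manual/machine ratios on a
validation set) compensate systematic biases such as wool thickness; they
default to 1.

## The biometric layer

`describe_traits()` reports mean, SD, CV (100·SD/mean), extrema and counts
per trait and sex. `spearman_test()` uses average ranks for ties and the
t approximation for significance — rank correlation is preferred because
field trait data are outlier-prone and not reliably normal.
`anova_by_sex()` is a plain one-way ANOVA. `ols_fit()` wraps least squares
and reports the quantities conventional for weight-prediction equations:
coefficients with t tests, standard error of estimate (root residual mean
square), R², adjusted R², MSE (residual mean square; SE² = MSE) and the
overall F test. `stepwise_bw()` implements bidirectional selection: the
candidate with the smallest partial-F p-value enters while p ≤ 0.05, and
after each entry any included predictor whose partial-F p-value exceeds
0.05 is removed; the emitted object is the full ladder of nested models, as
such analyses are conventionally reported. The entry threshold is read as a
p-value ("traits significant at 0.05"), the removal threshold is set equal
to it, and no multiple-testing correction is applied, matching the
reference analysis. Missing data are handled by complete-case filtering
only (`filter_complete()`), with the removal reasons (unrecorded, missing
weight, missing body size) counted and reported.

The nine published sex-specific equations (three for ewes, six for rams)
are shipped in `published_weight_models()`; the five-variable ram row is
labelled inconsistently in the source (the label says HW where the printed
equation uses SW) and the printed equation is followed. The accuracies
quoted alongside the final models (83.9% rams, 79.4% ewes) match the ewes'
adjusted R² but neither ram R²; both R² variants are included without
attempting a reconciliation.

## The synthetic generator

Because no per-animal images or raw trait records are published, validation
uses a generator with known ground truth (`sample_sheep_spec()`,
`render_sheep_side()`, `render_sheep_dorsal()`, `generate_trait_table()`,
`generate_calibration_samples()`, `generate_manifest()`). All generators
are pure functions of (configuration, seed).

* **Trait draws** come from a truncated multivariate normal with the
  reference flock's sex-specific means and SDs and an exchangeable
  correlation of 0.6 among the eight size traits (only selected rank
  correlations are published — e.g. 0.88 for wither height vs hip height in
  ewes — so a single configurable value is used; any positive semi-definite
  matrix can be supplied). Draws are truncated at the flock's observed
  min/max by rejection, a documented deviation from pure normality that
  avoids anatomically impossible animals. Renderer draws additionally
  enforce hip height within [0.985, 1.10] of wither height and chest depth
  within [0.35, 0.58] of wither height.
* **Body weight** is generated from the final sex-specific published
  equation plus Gaussian noise at that equation's standard error of
  estimate (4.49 kg ewes, 3.75 kg rams), so refitting a generated table
  recovers the generating coefficients within sampling error.
* **Silhouettes** are parametric composites rasterized by even-odd scanline
  fill at a known scale (default 12 px/cm, about a 1,000 px body): a level
  back between a hip ridge (apex = HH) and the withers point (= HW), a neck
  rising to a raised head with an ear peak (the head vertex) and a pointed
  muzzle (the facial vertex), a brisket corner and a sternum corner
  (HW − CD above ground), a protruding sciatic pin-bone tip at 78% of HH,
  and four tapering legs whose below-knee width equals SC/π. The dorsal
  outline carries corner-like scapular and hip protrusions whose apex
  separations equal SW and RW exactly. Every landmark's true pixel position
  is recorded at render time, and each geometric feature is built so that
  the rule that should find it is its unique optimum inside the default
  search box (e.g. the pin-bone tip is sharper than the croup turn, the
  sternum corner sharper than the brisket corner). Small seeded pose jitter
  (head lift, far-leg stance) varies the silhouettes across animals.

What the generator does **not** emulate: wool texture and boundary
fuzziness, segmentation errors, occlusion, walking poses with swinging
legs, tails, and multi-animal scenes. Passing the closed-loop tests
therefore demonstrates that the geometry rules are implemented correctly
and are stable across the flock's size distribution — not that the pipeline
is robust to real segmentation noise. An optional boundary dilation stands
in qualitatively for wool (default off) without claiming fidelity.

## Numerical choices

* Ellipse perimeter: fixed 64-node Gauss–Legendre quadrature of
  `4∫₀^{π/2} √(α²cos²t + β²sin²t) dt` with a split-interval refinement
  check at 1e-8; degenerate axes give the exact limits (2πr for a circle,
  4α for a segment). Tested against the complete elliptic integral of the
  second kind to 1e-6.
* Convex hull: `grDevices::chull()` normalised to counterclockwise
  mathematical orientation with collinear interior vertices dropped; an
  all-collinear input degenerates to its two extreme points.
* Contour tracing: Moore-neighbour with Jacob's stopping criterion;
  grayscale inputs binarize at 127/255 (configurable); interior holes are
  ignored; the largest connected component is selected via
  `EBImage::bwlabel()`.
* Ties everywhere break to the smallest contour index; all randomness is
  funnelled through explicit seed arguments that save and restore the
  caller's RNG state.

## Validation scale and statistical test design

The closed-loop property checks run 200 seeded silhouettes (both views,
alternating sex) at a 1,000 px body length, a size at which per-landmark
localisation error has median ≲ 2 px, and verify that directly measured
traits (HW, HH, BSL, CD) recover truth within 5% and width/girth traits
(SW, RW, SC, CC) within 8% — widths rely on corner localisation and ellipse
and circle approximations, hence the looser band, mirroring the error
ordering reported for manual-vs-machine comparisons. Stepwise support
recovery uses a planted predictor with a 5-residual-SD effect among five
noise candidates over 100 seeded trials. The type-I check uses a single
all-noise candidate per trial: the procedure's entry test is controlled at
α = 0.05 *per candidate*, so the no-admission rate is 0.95 for one
candidate and `0.95^k` for k independent candidates by construction — only
the single-candidate design makes "empty in ≥ 90 of 100 runs" a sound
consequence of the stated α. OLS parameter recovery refits 25 generated ewe
tables (n = 219) and checks 2-SE coverage plus unbiasedness of the mean
error.

## Known limitations

* Segmentation quality is assumed; there is no hole repair, occlusion
  handling, or multi-animal separation.
* The chest-front rule remains the most delicate detector: it depends on a
  chord between two other detections and on arc-trim fractions; on real
  images with extended head poses the trims may need adjustment.
* CC uses shoulder width as the chest-width proxy (the dorsal chest width
  itself is not separately measurable from the protrusion rule), so CC
  inherits SW's wool bias.
* The machine-derived body weight reported alongside the reference
  manual-vs-machine comparison has no stated provenance and is not
  reproduced; BW enters this package either from scale hardware or from
  the regression equations.
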