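---
title: "Methods: automated airspace morphometry in lungmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated airspace morphometry in lungmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lungmorph)
```

This vignette documents the models and procedures implemented in
`lungmorph`, the assumptions behind them, the parameters that matter, and
the choices made where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## 1. The segmentation model

An H&E-stained lung section imaged in transmitted light is, to first
approximation, a two-class image: bright empty space (slide background,
airspace lumina, vessel lumina) and darker stained tissue. Eosin and
hematoxylin both absorb strongly in green, so the **green channel** of the
RGB raster carries the largest tissue/background contrast; it is used
verbatim as the 8-bit working image.

**Thresholding.** The green-channel histogram of a parenchyma section is
unimodal — a dominant background peak with a long dark tissue tail —
because tissue walls are thin and cover a small area fraction. Bimodal
methods (Otsu) place their threshold inside the background peak and lose
wall structure. We use the maximum-deviation ("corner") rule for unimodal
histograms: draw the straight line from the histogram peak to the last
nonzero bin on the tail side, and take the bin maximizing perpendicular
distance to that line. Numerical conventions, fixed so results are
reproducible: the tail side is the side with the longer reach from the
peak; distance ties break toward the peak; a peak at the tail end
degenerates to the peak index itself. Tissue polarity is `intensity <=
threshold` (tissue is dark).

**Lumen labeling.** The inverted tissue mask is labeled by 4-connected
components. Components touching the image border are empty slide around
the section, not airspaces, and are discarded; this same convention
reappears in the intercept scan (section 2). 4-connectivity is chosen for
lumina so that two cavities meeting only at a pixel corner stay separate;
wall components (below) use 8-connectivity for the complementary reason.

**Vessel and bronchiole exclusion.** Vessel and bronchiole lumina would
otherwise be counted as (large) airspaces. They are identified by their
wall thickness: binary erosion of the tissue mask with a structuring
element of size 7 removes alveolar septa (1–3 px at typical 10x
calibration) and keeps only thick walls. "Size 7" is read as a 7x7 square
(side length); a disk of diameter 7 is available via `se_shape = "disk"`
— for walls much thicker than 7 px the difference is immaterial. Erosion
treats out-of-image pixels as background, so objects shrink at the
border. Each surviving wall component is replaced by its convex hull,
which closes the wall ring across its lumen; any labeled region whose
centroid lies inside (or exactly on — conservative exclusion) a hull is
deleted. The hull/intersection step runs on a raster downsampled by
factor 4 using **OR-pooling** (block-wise logical OR), not subsampling:
pooling guarantees no surviving wall pixel vanishes. Centroids are
computed at full resolution and mapped into downsampled coordinates by
the continuous transform `(c - 0.5)/f + 0.5`. Descriptor extraction
always runs at full resolution.

Two open points were resolved as follows: no size filter is applied to
eroded wall components before hull computation, and no minimum-area
filter is applied to accepted airspaces by default (`min_area_px`
exposes one), since the source protocol applies none at this stage.

## 2. Descriptors

For accepted region $i$ with pixel count $n_i$ and calibration $p$
(µm/pixel), the area is $A_i = n_i p^2$ and the **equivalent diameter**
is $d_i = 2\sqrt{A_i/\pi}$ — the diameter of the circle with the same
area. The weighted mean diameter family is the ratio of consecutive raw
moments,

$$D_v = \frac{\langle d^{v+1}\rangle}{\langle d^v\rangle},$$

so $D_0$ is the arithmetic mean and increasing $v$ weights enlarged
airspaces more heavily. By Cauchy–Schwarz on the moment sequence,
$D_0 \le D_1 \le D_2$ with equality iff all diameters are equal; this is
property-tested. The central-moment forms are

$$D_1 = \mu\left(1 + \frac{\sigma^2}{\mu^2}\right), \qquad
D_2 = \frac{\mu^3 + 3\mu\sigma^2 + \gamma\sigma^3}{\mu^2 + \sigma^2},$$

with $\mu, \sigma^2, \gamma$ the **population** (1/n) mean, variance and
standardized skewness — only the population convention makes these exact
for empirical samples, and the suite verifies both routes agree to 1e-9
relative. The $D_2$ expansion above is the exact algebraic expansion of
$\langle d^3\rangle/\langle d^2\rangle$; a variant form sometimes quoted
with $\sigma^2$ added to dimensionless terms is dimensionally
inconsistent and is not used — the moment-ratio definition is canonical
here.

**Mean linear intercept.** The labeled image is raster-scanned row by
row; every maximal run of airspace pixels bounded on *both* ends by a
non-airspace pixel contributes one intercept of length
`run length × p`. Runs touching the image border lack a bounding wall
and are excluded (the literal "between two consecutive null pixels"
rule). $L_m$ is the mean of all intercepts pooled over the section —
pooled, not averaged per row. Scanning is horizontal only by default; a
`scan_vertical` flag adds column runs. One consistent convention is
preferable to an unstated mixture; on isotropic scenes the two
directions are exchangeable.

Note a structural consequence of intercept pooling: a region of diameter
$d$ contributes about $d$ intercepts of mean length $\pi d/4$, so on a
field of disjoint round airspaces $L_m \approx (\pi/4)\,
\langle d^2\rangle/\langle d\rangle$ — a length-weighted, $D_1$-like
statistic. $L_m$ therefore *does* respond to focal enlargement, but less
than $D_2$: the test suite shows that on a 20-small + 2-large scene
(30 µm vs 300 µm) the excess of $D_2$ over the plain mean exceeds the
excess of $L_m$ over its homogeneous-equivalent value $(\pi/4) D_0$, and
that the across-scene relative gain detected by $D_2$ exceeds the gain
detected by $L_m$.

**Per-animal aggregation.** Multiple sections per animal can be
aggregated either by pooling regions before computing descriptors (the
default, reconstructing pooled moment sums from per-section counts and
D-values) or by averaging per-section descriptors; the choice is exposed
because the source protocol does not state it.

## 3. Micro-CT density features

From a HU-calibrated volume and a *given* lung mask (lung and airway
segmentation are upstream concerns; airway voxels are assumed already
removed): MLVI is the mean in-mask intensity and VBT the percentage of
in-mask voxels **strictly** below −900 HU (a boundary voxel at exactly
−900 is not counted — the literal reading of "below"). −900 HU is the
conventional murine hyperinflation threshold: values below it are rare
in healthy animals. No soft-tissue cap is applied to MLVI.

## 4. Statistics and the classifier harness

Group summaries are median and IQR with type-7 (linear interpolation)
quantiles. The Mann-Whitney U test counts pairs (ties half); for
combined $n \le 12$ without ties the two-sided p-value is exact by
enumeration of all rank assignments ($p = \min(1, 2\min(P(U\le u),
P(U\ge u)))$); otherwise the normal approximation with tie correction
and no continuity correction is used, with the degenerate zero-variance
case mapped to $p = 1$. Significance is flagged at $P \le 0.01$.

The **gold standard** labels an animal diseased iff its D2 strictly
exceeds the 3rd quartile (type 7) of the control animals' D2.

The classifier is a soft-margin SVM with Gaussian RBF kernel
$\exp(-\gamma\|x - x'\|^2)$, solved in the dual with `quadprog` (a
`1e-8` ridge on the kernel matrix ensures positive-definiteness; the
intercept is averaged over free support vectors, falling back to the
KKT-bound midpoint). Protocol: stratified seeded 60/40 train/test split;
z-scoring on training statistics (unstated in the source protocol but
necessary — raw features span HU to mL/cmH₂O and an RBF kernel on
unscaled features is degenerate); grid search over $\gamma$ at decade
points in $(10^{-9}, 10^{3})$ and cost in $(10^{-1}, 10^{13})$ by
stratified 5-fold cross-validated accuracy with folds shared across the
grid; accuracy ties prefer the smaller cost, then the smaller $\gamma$.
Grid corners that fail numerically (extreme cost on degenerate folds)
score NA and are skipped rather than aborting. The selected pair is
refit on the full training split; ROC, trapezoidal AUC and f1 (at
decision value 0, diseased positive) are measured on the untouched test
split. The trapezoidal AUC with tie-grouped thresholds equals the
rank-sum probability $U/(n_1 n_2)$ exactly, which the suite asserts to
1e-9. `best_feature_combination()` evaluates all $2^k - 1$ subsets under
a shared seed (hence shared split), ranked by AUC then f1. Whether the
original 60/40 split was per time point or global is unstated; the
harness splits globally on whatever table it is given.

## 5. The synthetic world

`render_scene()` emulates exactly the features the segmentation relies
on: thin-walled elliptical airspaces (wall 1–3 px), thick-walled vessel
rings (wall ≥ 10 px, strictly thicker than any airspace wall), a bright
background (green level 230), dark red-dominant tissue (green level 40),
and optional additive Gaussian noise clipped to [0, 255] applied after
rasterization. A pixel belongs to a shape iff its center lies inside the
analytic boundary, and ground-truth areas are computed from the
*rasterized* regions, so oracle comparisons carry no discretization
slack. Default calibration is 0.725 µm/pixel (typical 10x whole-slide
acquisition); it is a free parameter. `random_scene()` places shapes by
rejection sampling with a 4 px separation margin, so every lumen is
enclosed by its own wall.

What the generator does **not** emulate: realistic H&E texture and
staining variation, shared septal walls between adjacent alveoli,
partial structures at the field border, tissue folds and debris, or 3D
histology. A green segmentation test therefore establishes that the
algorithm implements its specification — not that it is robust to
real-slide artifacts.

`render_hu_volume()` constructs an ellipsoidal "lung" inside the volume
and fills it so that exactly `round(f·N)` voxels lie strictly below
−900 HU and the in-mask mean equals the request to machine precision
(zero-sum jitter within each stratum, shrunk to respect the −900
boundary with a ±1 HU guard band). Infeasible requests (e.g. all voxels
below −900 but a mean above it) error rather than silently adjusting.

`simulate_cohort()` draws two groups from per-feature Gaussians. Where
the source study prints values, defaults follow it: control D2 100 µm
with a +80 µm treated shift (the 24 h control/elastase medians ~100.4
vs ~179.6 µm), control VBT 2.5% (healthy animals stay below 5%) with a
+12 point shift. The remaining features have no printed values; realistic
murine defaults were chosen once: MLVI −350 HU (shift −80, emphysematous
lungs darken), mainstem bronchus radii 420/380 µm (mild dilation +40/+30),
resistance 0.55 cmH₂O/mL/s (+0.15), compliance 0.045 mL/cmH₂O (−0.008,
matching the acute-phase *decrease* reported in the first 24 h),
cytokines at relative expression 1 with 1.2–2.5-fold shifts. These are a
stated world for exercising the harness, not a calibrated disease model.

## 6. Batch processing

The original analysis ran as a networked job queue across machines; here
it is a local multi-process queue with the same exactly-once contract:
one job per raster file in deterministic lexicographic order, failures
recorded per job without aborting the queue, results sorted by job id so
the output table is byte-identical across worker counts. Raster I/O is
PNG (plus plain-text NetPBM); pixel size is always an explicit
calibration parameter, never read from image metadata. Label maps are
stored losslessly across two 8-bit PNG channels (high/low byte).

## 7. Known limitations

* The segmentation assumes the unimodal-histogram regime; sections
  dominated by tissue (little background) would break the corner rule's
  tail-side heuristic.
* Vessel exclusion relies on wall thickness surviving a size-7 erosion;
  vessels with walls thinner than ~7 px at the working calibration will
  not be excluded, and a hull spanning an unrelated nearby centroid
  would wrongly delete an airspace (not observed in the synthetic
  world, where shapes are separated).
* Lm excludes border-touching runs; on small fields with large airspaces
  this discards a nontrivial fraction of chords.
* The SVM dual QP is dense ($O(n^2)$ memory, $O(n^3)$ solve); the
  harness targets cohort-scale data (hundreds of animals), not
  image-scale data.
* Published AUCs from the original 60-animal in vivo dataset are not
  reproducible here — the data are not deposited; the harness reproduces
  the protocol, not the numbers.
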