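# lungmorph

Automated histomorphometry of airspace enlargement in lung tissue sections,
with micro-CT density descriptors and a classifier-evaluation harness.

## The problem

Emphysema is the permanent enlargement of airspaces distal to the terminal
bronchioles, with destruction of alveolar walls. Quantifying it on
H&E-stained sections has classically relied on the **mean linear intercept**
(Lm) — the mean length of line segments spanning airspaces between tissue
walls. Lm is really a surface-to-volume proxy: it underestimates severity in
heterogeneous samples where a few enlarged airspaces sit among many normal
alveoli. The moment-weighted diameter family corrects this. For airspace
areas \(A_i\), the equivalent diameter is

    d_i = 2 * sqrt(A_i / pi)

and the descriptor family is the ratio of consecutive raw moments of the
diameter distribution,

    D_v = <d^(v+1)> / <d^v>,   v = 0, 1, 2, ...

`D0` is the plain mean; `D2 = <d^3>/<d^2>` weights enlarged airspaces
heavily and is the most sensitive descriptor of focal disease. Equivalent
central-moment forms are `D1 = mu (1 + sigma^2/mu^2)` and
`D2 = (mu^3 + 3 mu sigma^2 + gamma sigma^3) / (mu^2 + sigma^2)`.

Computing these automatically on whole-lobe sections requires segmenting
*bona-fide* airspaces: blood vessels and bronchioles have bright lumina too
and must be excluded. The pipeline implemented here is:

1. extract the **green channel** (largest contrast for red/blue H&E tissue);
2. **maximum-deviation unimodal ("corner") thresholding** of the intensity
   histogram (histology histograms are unimodal, so Otsu-style bimodal
   methods fail) to get a tissue mask;
3. invert the mask and label luminal structures by **connected components**
   (border-connected background discarded);
4. **binary erosion** (structuring element of size 7) so only the thickest
   walls — vessel and bronchiole walls — survive;
5. **convex hulls** of the surviving walls on a 4x OR-pooled downsampled
   grid (pooling so no wall pixel is lost);
6. delete every labeled region whose **centroid falls inside a hull**; the
   remainder are accepted airspaces, measured at full resolution.

The package also computes micro-CT density descriptors from a HU-calibrated
volume and a given lung mask — **MLVI** (mean lung voxel intensity) and
**VBT** (% of lung voxels below −900 HU) — plus median/IQR group summaries,
Mann-Whitney U tests, and an RBF-kernel SVM harness (grid search over kernel
width and soft margin, stratified 60/40 split, cross-validated model
selection, ROC/AUC/f1, exhaustive feature-subset comparison against a
D2-derived gold standard: diseased iff D2 exceeds the control 3rd quartile).

A synthetic-scene generator with exact ground truth (thin-walled airspaces,
thick-walled vessels, calibrated HU volumes, two-group feature cohorts)
makes every stage testable without external data.

## Worked example

```r
library(lungmorph)

spec  <- random_scene(n_airspaces = 25, n_vessels = 2, noise_sd = 8, seed = 7)
scene <- render_scene(spec)
map   <- segment_section(scene$image)
map
#> airspace_map: 25 regions, 600 x 600 px at 0.725 um/px
compute_descriptors(map)
#> descriptors: Lm = 14.25 um | D0 = 18.87 | D1 = 19.19 | D2 = 19.52 um (25 airspaces, 688 intercepts)
```

All 25 true airspaces are recovered and both vessel lumina are excluded;
the diameter moments sit just above the mean (D0 ≤ D1 ≤ D2 always holds,
with near-equality here because the scene is homogeneous). Lm is smaller
than D0 because the mean chord of a convex region is shorter than its
diameter (π/4 of it, for circles).

```r
hv <- render_hu_volume(c(16, 24, 24), 0.25, -550, seed = 7)
compute_ct_features(hv$volume, hv$mask)
#> ct_features: MLVI = -550.0 HU | VBT = 25.00% (n = 2880 voxels)

tab <- simulate_cohort(15, seed = 7)
group_statistics(tab, c("D2", "VBT"))[, c(1, 2, 4, 7, 8)]
#>   feature control_median treated_median      p_value significant
#> 1      D2     100.437678     175.320336 3.066978e-06        TRUE
#> 2     VBT       2.071851      14.977375 3.066978e-06        TRUE

train_and_evaluate(tab, c("MLVI", "VBT"),
                   grid_search_config(gamma_values = c(0.01, 0.1, 1),
                                      cost_values  = c(1, 10, 100),
                                      n_folds = 3, seed = 7))
#> roc_result [MLVI+VBT]: AUC = 0.938, f1 = 0.875 (gamma = 0.1, cost = 10)
```

The simulated elastase-model cohort separates cleanly in D2 and VBT
(two-sided Mann-Whitney, significant at P ≤ 0.01), and the density-feature
classifier reaches AUC 0.94 on the held-out 40% test split.

## Command line

```sh
Rscript exec/lungmorph simulate --type scene --out /tmp/s --seed 3 \
    --n-airspaces 20 --n-vessels 1
Rscript exec/lungmorph segment --image /tmp/s.png --pixel-size-um 0.725 \
    --out /tmp/seg
Rscript exec/lungmorph batch --dir /tmp/images --pixel-size-um 0.725 \
    --out /tmp/results.csv --workers 4
```

Each run writes a `*.manifest.json` recording the resolved parameters.

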