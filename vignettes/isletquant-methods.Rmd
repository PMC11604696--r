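---
title: "Quantifying islet composition from multiplex immunofluorescence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying islet composition from multiplex immunofluorescence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isletquant)
```

## The measurement problem

Pancreatic islets are clusters of hormone-producing endocrine cells — beta
(insulin), alpha (glucagon), delta (somatostatin) — embedded in exocrine
tissue. Multiplexed immunofluorescence panels stain three markers plus a
nuclear counterstain on thin sections: panel A is insulin / proinsulin /
PC1/3 (the prohormone convertase that matures proinsulin into insulin),
panel B is glucagon / somatostatin / PC1/3. The questions asked of such
images are quantitative: what fraction of the islet area is occupied by
each hormone, how large are individual beta and alpha cells and their
nuclei, what fraction of cells is positive for each marker combination
(single / double / triple positive), how strongly does PC1/3 co-localise
with insulin or glucagon at the granule level, and how do all of these
shift across donor groups — non-diabetic (ND), autoantibody-positive
(AAb+), recent-onset and long-duration type 1 diabetes, type 2 diabetes.

`isletquant` implements two independent measurement arms and a
donor-level statistics layer:

* **Whole-islet arm** — channel registration, optional flat-field
  correction, islet detection by Otsu thresholding of the summed marker
  channels, background subtraction, per-islet occupied-area fractions,
  intensities, and Manders co-localisation coefficients.
* **Single-cell arm** — nucleus detection (Gaussian-of-scale blob seeds +
  seeded watershed; a classical, deterministic stand-in for a trained
  star-convex network), geodesic cytoplasm expansion bounded by a Voronoi
  rule and by stained-tissue support, per-cell mean intensities, per-batch
  positivity thresholds, combinatorial phenotype classification,
  morphometry (nucleus/cytoplasm ratio), and per-cell co-localisation.

Because real donor images of this kind are not freely redistributable, the
package ships a synthetic image generator with complete per-cell ground
truth; every stage of the pipeline is validated against that truth.

## The synthetic world

`render_islet_image()` draws islets of at least 10 endocrine cells.
Cells are star-convex polygons (a randomly perturbed ellipse radius
function); delta cells receive an aspect ratio of 3.5 to reproduce the
elongated profiles that defeat 2D single-cell segmentation. The nucleus is
a concentric shrunken copy of the cell outline, which guarantees
containment for any aspect ratio and keeps both area distributions
unbiased. Per-cell areas are drawn from lognormal models; the rendered
mask areas (pixel count x calibration^2) are written to the truth table,
so the noiseless identity between truth and image is exact by
construction.

Marker intensity follows a two-state model: a positive cell paints a
uniform cytoplasmic base carrying `base_share` (default 0.6) of its
signal over its whole footprint plus bright granules on a random
`granule_density` (0.45) subset of cytoplasm pixels; the granule intensity
is calibrated so the cell-mask mean equals the drawn per-cell mean
exactly. Negative cells paint a dim uniform level (the tissue
autofluorescence floor, mean 600 of 65535). Co-localisation between a
configured channel pair is generated by a shared granule subset: in a
double-positive cell a fraction `coloc_fraction` of each channel's
granules is common to both, and the channel-specific remainders are
disjoint. With per-cell thresholds that separate base from granules, the
per-cell Manders M1 equals `coloc_fraction` analytically, which is what
the recovery tests assert.

On top of the signal the generator adds a constant background, a linear
illumination gradient of configurable amplitude, white Gaussian noise and
optional integer channel shifts. Intensities are 16-bit; a draw that
would clip the dynamic range is truncated at a documented cap (< 0.5% of
the mass) rather than silently clipped, and the renderer raises an error
if a pixel still exceeds the range.

What the generator does **not** emulate: point-spread blur, tissue
autofluorescence texture, insulitis and immune infiltrates, amyloid, 3D
sectioning artefacts, or touching cells (cells keep a >= 1 px rasterised
gap, which is what makes exact noiseless count recovery a meaningful
contract). A green test therefore establishes the correctness of the
measurement machinery on a stated world, not performance on real
confocal data.

### Donor-group presets

`make_group_preset()` encodes the group differences as generator
parameters: beta cytoplasmic area means 86.83 / 73.52 / 49.75 um^2 for
ND / recent / long-duration type 1 diabetes, beta nuclear-area medians
30.69 / 25.40 um^2, alpha cytoplasm medians 96.07 / 75.15 / 76.37 um^2,
islet-adjacent exocrine cell areas 95.76 / 86.42 um^2, collapsing
insulin/proinsulin positivity with partially retained PC1/3, per-cell
proinsulin/insulin intensity ratios 1.009 / 0.823 / 0.171, and
co-localisation fractions (insulin--PC1/3 0.845 in ND vs 0.347 in
long-duration disease; glucagon--PC1/3 0.624 / 0.817 / 0.730). AAb+
donors mirror ND (no reported significant differences in these
read-outs); T2D differs only in the alpha-cell read-outs.

One deliberate deviation: the long-duration preset keeps a 10% residual
beta-cell pool with 50% insulin positivity (instead of the reported
~0.4% insulin-positive islet cells), because a scaled-down cohort of a
few hundred cells per donor would otherwise contain no measurable beta
cells at all and the morphometry read-out would be undefined. The
within-beta positivity was reduced so the PC1/3-positive islet fraction
still lands near its reported value.

## Numerical and design choices

**Otsu thresholding.** `otsu_threshold()` quantises the observed range to
256 levels and returns the cut maximising between-class variance; the
test suite verifies exact agreement with an exhaustive search on every
image. Two behaviours are worth knowing. First, between-class variance is
constant across an empty inter-mode gap, so the maximiser sits at the
lower edge of the gap (scikit-image behaves identically) — thresholds for
well-separated modes are valid but not centred. Second, on histograms
with three modes (background, dim tissue, bright marker) the single cut
can land at either boundary depending on the mass balance; the package
therefore applies Otsu on log intensities where the decision is
background-vs-tissue, and a second-stage Otsu above the first cut where
the decision is tissue-vs-granule.

**Islet detection.** The summed marker channels are thresholded (log-Otsu),
closed with a 5 um disk, hole-filled and labelled. Each component is then
(i) required to contain at least 8% marker-positive pixels — an
endocrine-purity criterion that stands in for the trained pixel
classifier and rejects sheets of dim exocrine tissue (purity ~2%) while
keeping dim-cell-rich islets of long-standing disease (~15%) — and (ii)
restricted to its stained-tissue pixels above a robust background floor
(median + 6 MAD of the non-islet region), so unstained interstitial space
does not count as islet area. Components below `min_cells` x 120 um^2 are
discarded, implementing the >= 10 cells-per-cluster rule. A limitation to
keep in mind: a marker-negative cell at the islet *margin* is optically
invisible and cannot be claimed by any intensity-based detector; interior
negative cells are recovered via hole filling and the tissue floor, and
nuclei within 5 um of islet tissue are tagged as islet cells.

**Channel alignment.** Integer shifts are estimated by FFT
cross-correlation of low-pass (sigma 1.5 px) copies — the punctate
granule texture differs between channels and can anti-correlate at lag 0,
so registration must ride on the shared cell-scale structure. Estimated
shifts beyond `max_shift_px` (10) are rejected with a warning and the
plane passes through unshifted. The nuclear channel is not aligned
against hormone channels (nuclei are holes in the cytoplasmic signal and
correlate poorly).

**Illumination correction.** `correct_illumination()` divides by a heavily
smoothed copy of the plane and rescales to preserve the global mean. This
self-division estimator is only valid when no sparse bright structures
dominate the field; on islet images the estimated "field" tracks the
islets themselves and distorts absolute intensities. The pipeline
therefore ships the operator (contract-tested on constructed gradients)
but leaves it off by default; the small linear gradients the generator
produces are harmless to the threshold-adaptive operators.

**Cell segmentation.** Nuclei are seeded from local maxima of the lightly
smoothed nuclear plane inside its Otsu foreground and grown by seeded
watershed; fragments whose mutual boundary is no shallower (in the
foreground distance transform) than ~1.6 px below either fragment's depth
are merged — this repairs over-splitting of elongated nuclei without
merging genuinely touching nuclei, whose waist is several pixels
shallower than their centres. Cells expand geodesically up to 5 um from
the nucleus (the usual single-cell expansion convention), confined to
stained tissue above the background floor and to the islet mask plus a
one-expansion margin, with contested pixels resolved by the nearest-seed
(Voronoi) rule. Cytoplasm = cell minus nucleus; N/C = nucleus /
cytoplasm area.

**Positivity thresholds.** A cell is positive when its mean intensity
reaches the marker threshold (ties count positive). Thresholds default to
Otsu on the per-cell mean distribution, derived per donor (one staining
batch per donor panel) with a cohort-pooled fallback, and a fold-change
guard (3x between class means) prevents Otsu from fabricating positives
out of a unimodal all-negative distribution. Threshold classification can
track a configured positive fraction to within ~1 point only when the
positive intensity mode is separated relative to its spread; with a broad
lognormal tail (cv 0.3) about 2-3% of genuine positives per marker fall
below any single batch threshold. That behaviour is intrinsic to
threshold classifiers, not a defect, and the acceptance fixture for
phenotype recovery therefore states a tight positive mode (cv 0.15).

**Co-localisation.** `manders_coefficients()` implements
M1 = sum of A-intensity on pixels positive for both channels / sum of
A-intensity on A-positive pixels (M2 symmetric), bounded in [0, 1] and
undefined (NA, with warning) when a channel has no positive pixels.
Islet-level coefficients use a two-stage Otsu (granule-level) threshold;
per-cell coefficients derive each cell's own base/granule cut, which
makes the recovered M1 equal the generated sharing fraction regardless of
cell brightness. Both M1 and M2 are always reported; by convention the
summary tables quote M1 with PC1/3 as the A channel.

**Statistics.** Donor-level aggregation produces exactly one value per
donor per metric (mean or median over that donor's cells or islets).
Group comparison gates on per-group Shapiro-Wilk at alpha = 0.05: if all
groups are compatible with normality, one-way ANOVA with Tukey HSD;
otherwise Kruskal-Wallis with Dunn's test (Holm adjustment; implemented
in-package with tie correction). Groups with fewer than 3 donors are
excluded with a warning. The paired within-donor contrast (e.g. glucagon
intensity in PC1/3-positive vs PC1/3-negative alpha cells) uses a
random-intercept-per-donor linear mixed model; only a random intercept is
fitted because cohorts of <= 10 donors cannot identify random slopes. The
Wald t statistic is referred to n_donors - 1 degrees of freedom, and a
paired t test on donor-level condition means is reported alongside as a
validation. Simulation tests pin the gated procedure's type-I error to
0.05 +/- 0.02 and its power above 0.9 for a 2-sigma shift at 10 donors
per group.

**Determinism.** Every stochastic step runs under an explicitly derived
seed (children derived from the master seed stay below 2^31), the
pipeline writes a resolved-configuration snapshot next to its outputs,
and a re-run with the same configuration reproduces all CSVs
byte-identically. No manual-correction step exists by design, and the run
log records that fact.

## Scale of the shipped worlds

The default field is 512 x 512 px at 0.5 um/px (a typical 20x confocal
sampling) with ~25 cells per islet — a deliberately scaled-down world
compared with real sections (median islet areas in adult pancreas
correspond to several hundred cells). All invariants tested here are
scale-free; tests state their cohort sizes explicitly and the acceptance
criteria run within minutes on one CPU.

## Known limitations

* Marker-negative cells at islet margins are invisible to intensity-based
  islet detection; per-islet denominators for phenotype fractions can
  miss a few such cells in heavily regressed islets.
* The islet "area" is stained-tissue area (interstitial gaps excluded),
  which is the natural definition in this synthetic world but differs
  from a filled-object area on blurrier real images.
* The self-division illumination-correction estimator is unusable on
  fields dominated by sparse bright objects (kept off by default).
* Exocrine tissue denser than ~50% of the non-islet area would shift the
  robust background floor; the generator keeps exocrine coverage below
  that.
* TIFF I/O is a minimal uncompressed 16-bit baseline implementation with
  a JSON sidecar for calibration and channel names; compressed or tiled
  TIFFs are out of scope.
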