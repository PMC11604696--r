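# isletquant

Quantitative analysis of multiplex immunofluorescence images of pancreatic
islets, for researchers studying endocrine cell composition and prohormone
processing across diabetes stages.

Islet sections are stained with three-marker panels plus a nuclear
counterstain — panel A: insulin (INS), proinsulin (ProINS), prohormone
convertase 1/3 (PC1/3); panel B: glucagon (GCG), somatostatin (SST),
PC1/3 — and imaged at known pixel calibration. `isletquant` answers the
standard quantitative questions at two resolutions:

* **Whole-islet arm** — islets are detected by Otsu thresholding of the
  summed marker channels (after channel registration), the non-islet
  background median is subtracted, and each islet object carries its area
  (μm²), per-channel occupied-area fraction
  `frac_c = #{x ∈ islet : I_c(x) ≥ t_c} / #islet`, mean/median
  intensities, and Manders co-localisation coefficients

  ```
  M1 = Σ_x I_A(x) · [I_A(x) ≥ t_A][I_B(x) ≥ t_B] / Σ_x I_A(x) · [I_A(x) ≥ t_A]
  ```

  (M2 symmetric), both in [0, 1].

* **Single-cell arm** — nuclei are detected on the nuclear channel (blob
  seeds + seeded watershed), cells grow geodesically up to 5 μm bounded by
  a Voronoi rule and by stained tissue, and every cell carries per-channel
  mean intensities, nucleus/cytoplasm areas, the N/C ratio, marker
  positivity flags (mean ≥ batch threshold; combinations such as
  INS⁺ProINS⁺PC1/3⁺ partition all cells), per-cell Manders coefficients
  and the proinsulin/insulin intensity ratio.

* **Statistics** — one value per donor per metric; group comparison is
  gated on per-group Shapiro–Wilk normality (one-way ANOVA + Tukey, or
  Kruskal–Wallis + Dunn/Holm), and paired within-donor contrasts use a
  random-intercept mixed model. A phenotype-trajectory table tracks the
  8 marker-combination fractions across disease-stage groups.

Because donor images of this kind are not redistributable, the package
includes a **synthetic islet image generator** with full per-cell ground
truth (`render_islet_image()`, `render_cohort()`), parameterised by
donor-group presets (`make_group_preset()`): non-diabetic,
autoantibody-positive, recent-onset and long-duration type 1 diabetes,
and type 2 diabetes, encoding the reported group differences in cell
sizes, marker positivity, intensity ratios and co-localisation. Every
pipeline stage is validated against that ground truth.

## Worked example

```r
library(isletquant)

cfg   <- make_group_preset("ND", panel = "A")   # non-diabetic preset
synth <- render_islet_image(cfg, seed = 42)
synth$image
#> islet_image: 512 x 512 px, 4 channel(s) [DAPI, INS, ProINS, PC13], 0.5 um/px, 16-bit

ires <- analyze_islets(synth$image)             # whole-islet arm
as.data.frame(ires)[, c("islet_id", "area_um2", "frac_INS", "frac_PC13",
                        "mean_rfu_INS", "m1_INS_PC13")]
#>   islet_id area_um2 frac_INS frac_PC13 mean_rfu_INS m1_INS_PC13
#> 1        1     3013    0.803     0.371        0.145       0.323
#> 2        2     2014    0.960     0.835        0.171       0.528

cells <- analyze_cells(attr(ires, "image"), attr(ires, "islets"),
                       coloc_pair = c("INS", "PC13"))   # single-cell arm
isl <- cells[cells$in_islet]
#> islet cells: 44 | triple-positive: 72.7% | beta cytoplasm: 83.5 um^2 | median N/C: 0.38
#> median proinsulin/insulin ratio: 1.006 | mean cell M1(INS,PC1/3): 0.854
```

Reading the numbers: both detected islets are mostly insulin-occupied
(80–96% of their stained area), 73% of their cells are triple-positive,
the mean insulin-positive beta-cell cytoplasm is 83.5 μm² (this preset
generates cells with mean 86.83 μm²), the per-cell proinsulin/insulin
ratio sits at ~1.0 (the configured non-diabetic processing ratio is
1.009), and the mean per-cell insulin–PC1/3 Manders coefficient is 0.854
against a generated granule-sharing fraction of 0.845.

The full cohort pipeline (generate → analyze-islets → analyze-cells →
stats → trajectory, with a resolved-config snapshot, plain-text log, and
byte-reproducible CSVs) runs via `run_pipeline(pipeline_config(...))` or
from the command line:

```sh
inst/scripts/isletquant run --config my_config.json
```

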