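# trabtex

Texture–shape fusion and dispersion-penalized feature selection for
trabecular bone images at low optical magnification.

## The problem

Osteoporosis degrades trabecular microarchitecture: estrogen-deficient
(ovariectomized, OVX) bone shows a coarser, sparser, more perforated
trabecular network than sham-operated (SHAM) controls. A low-power lens
captures a whole bone section in one image, but the image is too blurry
for plain texture statistics. `trabtex` implements a recognition
pipeline for exactly this regime, aimed at image-analysis researchers
working with small two-class histology datasets:

1. **Texture** — 11 gray-level co-occurrence (GLCM) and 4 run-length
   (GLRLM) parameters in the four canonical directions (0°, 45°, 90°,
   135°), computed on a 64-level quantized image.
2. **Direction weighting** — per-sample weights from the variation
   coefficients of the most direction-sensitive parameter of each
   family (correlation for the GLCM, long run emphasis for the GLRLM):
   for sample *i*, `v(i,j) = |x(i,j) − x̄ᵢ| / x̄ᵢ` and
   `w(i,j) = v(i,j)/Σⱼv(i,j)`; every parameter is collapsed to
   `p̄ᵢ = Σⱼ w(i,j) p(i,j)`. The GLCM distance defaults to 3, where
   the parameters stabilize (`distance_stability()`).
3. **Shape** — 6 dimensionless ratios (solidity, regional density,
   correction rate, convexity, roundness, length–width ratio) and the
   7 Hu invariant moments of each delineated trabecular region,
   area-weighted into one 13-value descriptor per image.
4. **Selection** — the 28 fused features enter a sparse model that
   penalizes within-class scatter on top of the Lasso:

   min₍b₎ ‖Ab − Y‖² + ‖C₁∘b‖²_F/n₁ + ‖C₂∘b‖²_F/n₂ + λ₁‖b‖₁

   where `Cₖ` is class k's column-centered block; solved by ISTA
   (proximal gradient with step 1/L, L the top eigenvalue of
   2AᵀA + (2/n₁)D₁ + (2/n₂)D₂). Setting the dispersion terms to zero
   recovers the plain Lasso baseline.
5. **Evaluation** — linear SVM under leave-one-out cross-validation;
   ACC, sensitivity, specificity and Youden index (SEN + SPE − 1) for
   six pipeline variants (TNS, TSNS, TYS, TSYS, TSYLS, TSYLC).

A synthetic generator (`gen_trabecular_image`, `gen_dataset`) emulates
the two-class low-magnification regime — thresholded anisotropic
Gaussian random fields with class-dependent fineness, fill, and
trabecular perforation, plus between-animal variability — so the whole
pipeline is testable without the original microscopy data. See
`vignettes/trabtex-methods.Rmd` for the model details and design
choices.

## Worked example

```r
library(trabtex)

# one synthetic SHAM-like image with its trabecular mask
img <- gen_trabecular_image(sham_params(), seed = 1)
f <- extract_image_features(img$image, img$mask)
round(f$features[c("contrast", "correlation", "entropy",
                   "long_run_emphasis", "solidity", "convexity",
                   "length_width_ratio")], 4)
#>           contrast        correlation            entropy  long_run_emphasis
#>           118.8757             0.7981             7.5645             1.1502
#>           solidity          convexity length_width_ratio
#>             0.5223             0.5397             1.5528
```

`f$features` holds all 28 values (15 direction-weighted texture + 13
shape). High entropy (7.56 nats) and a long-run emphasis close to 1
reflect fine, complex texture; solidity and convexity near 0.5 say the
trabecular regions are markedly non-convex.

The direction-weighting chain on a sentinel measured as (1, 2, 3, 4)
across the four directions:

```r
w <- direction_weights(variation_coefficients(c(1, 2, 3, 4)))
w
#> [1] 0.375 0.125 0.125 0.375
weighted_value(w, c(10, 20, 30, 40))
#> [1] 25
```

Directions deviating most from the sentinel's mean get the largest
weights. A classifier scoring sensitivity 88.20% and specificity
90.22% has

```r
youden(0.8820, 0.9022)
#> [1] 0.7842
```

— above the 0.7 conventionally required for clinical usability.

A full synthetic study (34 SHAM + 18 OVX images, all six variants):

```r
ds <- gen_dataset(seed = 1)
fe <- extract_dataset_features(ds)
reports <- run_all_variants(fe)
sapply(reports, function(r) r$ACC)
```

## Command line

A thin CLI over the same functions is installed at
`inst/cli/trabtex`:

```sh
Rscript inst/cli/trabtex simulate --out data/ --seed 1
Rscript inst/cli/trabtex extract  --dataset data/ --out features.csv
Rscript inst/cli/trabtex run-all  --dataset data/ --out report.json
```

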