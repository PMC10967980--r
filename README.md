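# ctenhance

Dual-path enhancement of CT slices for segmentation preprocessing, with a
full binary-segmentation evaluation suite and a synthetic CT phantom
generator.

## The problem

Segmentation models (SAM-style promptable segmenters included) consume
8-bit images, but CT lives in Hounsfield units, roughly [−1024, 3071] HU.
A plain min-max conversion squeezes the ~20–40 HU differences between
liver parenchyma, adjacent soft tissue and hypodense lesions into a gray
level or two, and low-dose acquisition adds noise (σ ∝ 1/√dose: a 50%
dose cut costs ≈41% more noise). Models fed such conversions segment
poorly for reasons that have nothing to do with the model.

`ctenhance` implements a deterministic enhancement pipeline for this
setting:

1. **Perona–Malik anisotropic diffusion** in HU:
   `I ← I + λ Σ_d c_d ∇_d I` with conduction `c_d = exp(−(∇_d I / κ)²)`
   over the four cardinal neighbours — denoises while edges (large
   gradients) insulate;
2. a **global path**: min-max normalization to 8-bit, then global
   histogram equalization through the empirical CDF
   (`p_k = round(255 · s_k)`);
3. a **local path**: HU **window leveling** — the window
   `[c − w/2, c + w/2]` maps linearly onto [0, 255] (slope `g/w`,
   intercept `(w/2 − c)·g/w`, `g = 255`), everything outside saturates;
4. a **weighted fusion** `round(α·local + (1−α)·global)` of the two 8-bit
   renderings.

It also ships the standard eight segmentation metrics (IoU, Dice,
accuracy, precision, recall, sensitivity, F1, specificity) computed from
pixel confusion counts with tidy per-case/mean-row reports, and a liver CT
phantom generator (known ground-truth masks, dose-dependent Gaussian
noise) so the whole pipeline is exercisable and testable without any
external dataset.

I/O: DICOM series (uncompressed little-endian subset, reader and fixture
writer included), NIfTI-1 via RNifti, 8-bit grayscale PNG, binary masks as
{0,255} PNG or {0,1} NIfTI.

## Worked example

Generate a half-dose phantom, enhance it, segment it with the bundled toy
segmenter (fixed threshold + largest connected component), and score the
result against the known truth:

```r
library(ctenhance)

case <- make_phantom(phantom_spec(seed = 7, dose_fraction = 0.5))
case
#> <phantom_case> 128x128, dose 0.50, sigma 16.97 HU, seed 7; liver 2579 px, lesions 154 px

out  <- enhance(case$image, pipeline_config(variant = "proposed"))
pred <- segment_liver(out)
metrics_report(mask_metrics(pred, case$liver_mask, case_id = "phantom-7"))
#> <metrics_report> 1 case(s)
#>    case_id    iou   dice accuracy precision recall sensitivity     f1 specificity
#>  phantom-7 0.9792 0.9895   0.9967    0.9914 0.9876      0.9876 0.9895      0.9984

base <- enhance(case$image, pipeline_config(variant = "normalization"))
mask_metrics(segment_liver(base), case$liver_mask)$iou
#> [1] 0.284
```

The noise σ is 12/√0.5 ≈ 17 HU at half dose. Under the same fixed
segmenter the fused enhancement reaches liver IoU 0.9792 while the plain
min-max baseline manages 0.2840 — the baseline compresses liver and
surrounding soft tissue onto the same side of any threshold, which is
precisely the failure mode the pipeline exists to fix. `tidy()`,
`glance()` and `autoplot()` work on every report, and
`compare_reports()` prints per-metric deltas using the rounded-mean
convention of published 4-decimal tables.

A command-line front end (`inst/cli/ctenhance.R`) wraps the same
functions:

```sh
Rscript inst/cli/ctenhance.R phantom --dose 0.5 --seed 7 --out ph/
Rscript inst/cli/ctenhance.R enhance --input ph/image.nii.gz --output enh/ \
    --variant proposed --alpha 0.5 --window-center 60 --window-width 200
Rscript inst/cli/ctenhance.R evaluate --pred pred/ --truth truth/ --out report.csv
Rscript inst/cli/ctenhance.R compare reportA.csv reportB.csv
```

See `vignettes/ct-enhancement-methods.Rmd` for the model details,
parameter rationale, numerical tie-breaks, and what the phantom does and
does not emulate.

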