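# mwdhseg

Seeded wavelet-domain segmentation of pelvic cone-beam CT (CBCT) slices.

Daily CBCT drives adaptive radiotherapy of the prostate, but the images are
noisy and — for patients tracked with implanted electromagnetic
transponders — crossed by metal streak artifacts. `mwdhseg` segments a
soft-tissue structure (bladder, prostate, rectum) from a **single
user-selected pixel** inside it, with no deformable registration and no
trained model:

1. **Transform.** An undecimated three-channel *double-Haar* filter bank
   (taps `h0 = (1,2,1)/4`, `h1 = (1,0,-1)/2`, `h2 = (1,-2,1)/4`; synthesis
   `g0 = (1,2,1)/4`, `g1 = (-1,0,1)/4`, `g2 = (1,-2,1)/4`) decomposes the
   slice into nine same-sized sub-bands through a 3×3 moving window, with
   exact perfect reconstruction: `Σᵢ Gᵢ(z)Hᵢ(z) = z⁻²`.
2. **Adaptive thresholds.** On the low-frequency band, a seed-initialized
   two-class iterative mean clustering (Ridler–Calvard/ISODATA) yields
   `T_L`, the midpoint of the converged class means. On the eight
   high-frequency bands, a Lee minimum-mean-square-error filter
   (`ŵ = m + k(w − m)`, `k = max(0, v − σ²)/v`) denoises the coefficients,
   which are then hard-thresholded at `T_H = 3·σ̂` with
   `σ̂ = median(|w₁₁|)/0.6745`.
3. **Reconstruction.** The low band is replaced by the two-level class-mean
   image, the thresholded high bands are kept, and the wavelet synthesis is
   binarized midway between the class means — the retained edge
   coefficients make the mask exact on noiseless two-level images.
   Connected-component and hole-filling postprocessing around the seed
   finishes the mask.

Evaluation follows the standard overlap metrics
`DSC = 2|A∩B|/(|A|+|B|)`, `Sensitivity = |A∩B|/|B|`,
`Inclusiveness = |A∩B|/|A|` and signed `ΔV = (|A|−|B|)/|B|·100%` for a
segmentation `A` against ground truth `B`. A synthetic pelvic phantom
(elliptical organs, Gaussian noise, transponder discs with decaying radial
streaks, optional rectal gas pocket) provides reproducible ground truth in
four scenarios: `baseline`, `beacons`, `low_contrast_prostate`,
`gas_filled_rectum`.

## Worked example

```r
library(mwdhseg)

ph  <- generate_phantom(default_scenarios()$beacons)   # 3 beacons in the prostate
res <- segment_slice(ph$image, ph$suggested_seeds$prostate)
unlist(res$thresholds)
#>      t_low     t_high
#> 106.907000   8.021118

evaluate_masks(res$mask, ph$truth_masks$prostate)
#> DSC 0.967 | sensitivity 0.936 | inclusiveness 1.000 | dV -6.40% (seg 995 / truth 1063 px)
```

`t_low ≈ 106.9` is the clustering threshold separating the organ class
(class mean ≈ 162.9) from the background class (≈ 50.9) on the low band;
`t_high ≈ 8.0` is three times the streak-robust noise estimate on the
coefficient scale. Despite three saturated beacon discs and their streaks
crossing the prostate, the mask covers 93.6% of the true organ and contains
no false positives (inclusiveness 1.0), for a Dice coefficient of 0.967.
Batch evaluation over all organs of the same slice:

```r
tbl <- batch_evaluate(lapply(c("bladder", "prostate", "rectum"), function(org) {
  r <- segment_slice(ph$image, ph$suggested_seeds[[org]])
  list(seg = r$mask, ground = ph$truth_masks[[org]], label = org)
}))
tbl[, 1:5]
#>      label   dsc sensitivity inclusiveness delta_v_percent
#> 1  bladder 1.000       1.000             1             0.0
#> 2 prostate 0.967       0.936             1            -6.4
#> 3   rectum 1.000       1.000             1             0.0
```

The same workflow is available from a shell via the thin CLI (seed
coordinates are **0-based** `row,col` there):

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "mwdhseg.R", package = "mwdhseg"))')
Rscript $CLI phantom  --scenario baseline --out ph/
Rscript $CLI segment  --input ph/image.png --seed 94,79 --out seg/
Rscript $CLI evaluate --seg seg/mask.png --ground ph/truth_prostate.png --out ev/
```

`segment` also accepts NIfTI files and DICOM series directories, and writes
the mask plus a JSON manifest echoing the thresholds, seed and
configuration hash.

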