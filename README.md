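# woundqc

Acquisition-time quality control for wound photographs taken with a color
reference sticker, plus the analysis layer to evaluate such a tool in a
two-arm home-imaging study.

Patients documenting chronic wounds at home (e.g. digital ulcers on the
fingers) produce photographs of uneven quality. Two problems can be caught
*while the patient is still holding the camera*: the square 36-patch color
reference sticker is missing or too small in the frame, and the image is
out of focus. `woundqc` implements the corresponding quality gate:

* **Sticker detection** by rectangular morphology: foreground segmentation,
  connected components, minimum-area rectangle fit, rectangularity / aspect
  / size screening, optional verification of the 6 × 6 patch grid.
* **Sharpness** as the variance of the Laplacian
  (`∇²I ≈ I(x−1,y) + I(x+1,y) + I(x,y−1) + I(x,y+1) − 4 I(x,y)`, replicate
  borders) restricted to the detected sticker region (**CCS**, color
  checker sharpness) — the sticker's printed content is constant across
  images, which makes the score comparable where whole-image sharpness
  would not be.
* A **pass/retake decision** with machine-readable reasons
  (`checker_not_found`, `checker_too_small`, `blurry`).

The study layer computes the color checker detection ratio
(**CCDR** = detected / collected images), CCS medians and quartiles,
subjective-usability ratios, compliance (performed / 16 assigned
assessment days, capped at 1), duration outlier filtering (3 scaled MADs
from the median), Wilcoxon rank-sum group comparisons and duration trends.
A deterministic synthetic generator renders wound scenes with a 36-patch
sticker and exact corner ground truth, and simulates whole study cohorts.

## Worked example

```r
library(woundqc)

# a sharp synthetic scene and a defocused one (sigma = 6 px)
sg <- render_scene(scene_spec(blur_sigma = 0, noise_sd = 4, seed = 7))
assess_quality(sg$image)
#> <quality_decision> PASS (sharpness 1135.6)

blurry <- render_scene(scene_spec(blur_sigma = 6, noise_sd = 4, seed = 7))
assess_quality(blurry$image)
#> <quality_decision> RETAKE [blurry] (sharpness 138.2)
```

The sharp scene's sticker region scores a Laplacian variance of 1135.6,
far above the default pass threshold of 483 (the calibrated midpoint
between sharp and heavily blurred synthetic scenes); blurring the same
scene collapses the score to 138.2 and the gate asks for a retake.

```r
# a simulated two-arm cohort at the study's operating point
report <- quality_report(generate_cohort(cohort_spec(seed = 1)))
report
#> <quality_report>
#>
#> Group summaries:
#>     group n_images n_detected  ccdr ccs_median ccs_q25 ccs_q75 usable_ratio
#>  feedback      210        203 0.967        903     767    1035        0.890
#>     basic      190        165 0.868        706     551     899        0.858
#>
#> Pooled CCS comparison: <rank_sum_result> z = 7.300, p = 2.869e-13
#>   (normal approximation; n = 203 vs 165)
#>
#> Compliance (median ratio): 0.88
```

The feedback arm detects the sticker in ~97% of images versus ~87% in the
basic arm, its sharpness distribution sits visibly higher (median ≈ 903 vs
≈ 706), and the rank-sum test flags the difference decisively — the
behavior the quality-feedback mechanism is designed to produce.

A thin command line wrapper ships with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/woundqc.R", package="woundqc"))')
Rscript $CLI assess wound.png                       # JSON verdict, exit 0/1
Rscript $CLI batch images/ --out manifest.csv
Rscript $CLI report --manifest manifest.csv --out report.json
Rscript $CLI synth scene --out scenes/ --n 10 --blur 0,1,2 --seed 7
```

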