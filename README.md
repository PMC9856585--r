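# sliceResponse

Quantifies treatment response in ex vivo cultured tumor-slice fluorescence
microscopy — the functional assay in which precision-cut slices of a
patient's tumor (e.g. head-and-neck squamous cell carcinoma) are
irradiated or cisplatin-treated in culture, and the response is read out
days later from multichannel images of fixed sections.

The package implements the full measurement chain:

* **Segmentation** — classical nucleus segmentation from DAPI/p63
  (background subtraction, Otsu, watershed), with the assay's nucleus
  filters: nuclei crossing the image border and nuclei smaller than
  10 µm² are excluded.
* **Focus analysis** — maximum projection of the three-plane 53BP1
  z-stack, noise-adaptive Laplacian-of-Gaussian detection of DNA-damage
  foci (53BP1, RAD51) inside retained nuclei, half-maximum focus sizing,
  and focus counts expressed per sphere-equivalent nuclear volume
  `V = (4/3)·π·(A/π)^{3/2}`.
* **Scoring** — per-nucleus EdU/TUNEL/geminin/p63 positivity (Otsu on the
  per-nucleus mean-intensity distribution by default), and the RECAP
  homologous-recombination score: the percentage of geminin-positive
  cells with ≥ 5 RAD51 foci, scored on a seeded subsample of ~100 cells.
* **Response calls** — relative proliferation
  `100 × EdU⁺(treated) / EdU⁺(untreated)` at the 5 Gy classification
  dose, classified *sensitive* (< 30%), *intermediate*, or *resistant*
  (≥ 60%); the treated/untreated TUNEL ratio; HR-proficiency (RECAP
  > 50%); two-tailed equal-variance Student *t* across fields of view and
  Kruskal–Wallis (tie-corrected) across nuclei.
* **Synthetic slices** — a seeded generator of calibrated multichannel
  TIFFs with exact ground truth (nucleus masks, marker flags, focus
  counts and areas), used to validate every stage.

## Worked example

Simulate a small radiosensitive experiment (untreated + 5 Gy, three
fields each; the 5 Gy condition scales proliferation by 0.2, apoptosis by
2, and the 53BP1 focus rate by 3), then run the pipeline:

```r
library(sliceResponse)

sc <- sliceScenario(widthPx = 320L, heightPx = 320L, nNuclei = 80L,
                    seed = 7L,
                    treatmentEffect = list(
                      untreated = c(rp = 1,   ra = 1, rf = 1),
                      `5Gy`     = c(rp = 0.2, ra = 2, rf = 3)))
res <- generateExperiment(sc, data.frame(condition = c("untreated", "5Gy"),
                                         nFov = c(3L, 3L)), "demo")
rep <- runPipeline(runConfig(manifest = res$manifest,
                             outputDir = "demo/report"))

rep$samples[, c("condition", "nFov", "meanFracEdu", "semFracEdu",
                "meanFracTunel")]
#>   condition nFov meanFracEdu semFracEdu meanFracTunel
#> 1       5Gy    3       0.079     0.0156        0.0512
#> 2 untreated    3       0.285     0.0320        0.0340

rep$response[, c("condition", "relativeProliferation", "irClass",
                 "apoptosisRatio", "recapPercent", "hrProficient",
                 "pEdu", "pFoci")]
#>   condition relativeProliferation   irClass apoptosisRatio recapPercent
#> 1       5Gy                  27.7 sensitive           1.51         54.2
#>   hrProficient    pEdu    pFoci
#> 1         TRUE 0.00446 1.95e-19
```

Reading the output: proliferation dropped to 27.7% of the untreated
level — below the 30% boundary, so the sample classifies **sensitive**;
apoptosis rose 1.5-fold; 54.2% of geminin-positive cells carried ≥ 5
RAD51 foci, so the sample is HR-proficient; the EdU drop is significant
across fields (*t*-test, p = 0.004) and the 53BP1 focus-density shift is
significant across nuclei (Kruskal–Wallis, p ≈ 2·10⁻¹⁹). The report
directory additionally holds per-cell, per-field, exclusion-count and
configuration-echo files.

A command-line wrapper with `simulate` and `run` subcommands is installed
at `inst/scripts/slicepipe.R`.

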