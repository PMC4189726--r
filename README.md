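# lgequant

Threshold-based quantification of myocardial late gadolinium enhancement
(LGE) on short-axis cardiac MR, for imaging scientists comparing scar
segmentation techniques — particularly in hypertrophic cardiomyopathy
(HCM), where enhancement is patchy and non-uniform and the choice of
signal-intensity (SI) threshold changes the measured scar burden
substantially.

The package implements the standard semi-automated operators over a fixed
myocardial contour set:

* **STRM k** — threshold μ<sub>ref</sub> + k·σ<sub>ref</sub> of a remote
  (non-enhanced) myocardial reference ROI, k = 2…6;
* **FWHM** — threshold = ½ · max SI of an enhancement-core ROI;
* **OAT** — Otsu's auto-threshold, maximizing between-class variance of
  the myocardial SI histogram;
* **MANUAL** — a reproducible surrogate of expert slide-bar adjustment:
  an exhaustive sweep returning the threshold whose mask maximizes Dice
  overlap with a target segmentation.

On top of these: per-study LGE volume/mass/%LV quantification
(Σ area × slice thickness, × 1.05 g/ml), Bland–Altman agreement
(mean difference ± 1.96·SD limits of agreement) and ICC(2,1), a method
ranking by |mean difference|, and a synthetic short-axis phantom generator
with known per-pixel scar ground truth (graded border zone, dense core,
Rician noise, coil shading, auto-derived reference ROIs, simulated
observers) so that accuracy-versus-expert and inter-observer
reproducibility experiments run end to end with no patient data.

## Worked example

```r
library(lgequant)

# a synthetic HCM-like study with known ground truth
ph <- generatePhantom(phantomSpec(rngSeed = 11L))
ph
#> PhantomStudy 'phantom': 6 slices, true LGE mass 3.474 g

seg <- segmentPhantom(ph)                      # 7 operators + manual sweep
studyTotals(phantomStudy(ph), seg)[, c("method", "total_lge_g", "lge_pct")]
#>        method total_lge_g   lge_pct
#> FWHM     FWHM    1.218336 0.8281110
#> MANUAL MANUAL    3.029376 2.0590868
#> OAT       OAT   12.380928 8.4153984
#> STRM2   STRM2    5.367264 3.6481647
#> STRM3   STRM3    2.782416 1.8912265
#> STRM4   STRM4    1.778112 1.2085944
#> STRM5   STRM5    0.987840 0.6714414
#> STRM6   STRM6    0.576240 0.3916741
```

The manual sweep (3.03 g) sits close to the 3.47 g ground truth; the STRM
family shrinks monotonically as k rises from 2 to 6 (5.37 g → 0.58 g);
FWHM, keyed to half of the bright-core maximum, under-segments the graded
border zone, while Otsu's threshold drops into the remote-myocardium
histogram on sparsely enhanced slices and over-segments heavily (12.4 g) —
each operator failing in the direction it is known for.  Scaled to a
cohort, the same pattern becomes the method comparison:

```r
acc <- runAccuracyExperiment(nStudies = 30, seed = 1)
acc$ranked   # per-method mean difference vs manual (g), 95% LoA, ICC

rep <- runReproducibilityExperiment(nStudies = 30, seed = 1)
rep$table    # per-method inter-observer limits of agreement
```

Real studies load from a NIfTI volume plus a contour/ROI JSON sidecar:

```r
st  <- loadStudy("images.nii.gz", "contours.json")
seg <- segmentStudy(st, c("STRM3", "FWHM", "OAT"))
quantifyStudy(st, subset(seg, method == "STRM3"))
```

A thin command-line wrapper with `simulate`, `segment`, `quantify`,
`compare`, `reproducibility` and `run-all` subcommands ships at
`inst/cli/lgequant.R`.

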