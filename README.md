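# ctfat

Density-window fat volumetrics for whole-body X-ray micro-computed
tomography of fish.

## What this package is for

Body fat content matters in fish physiology and aquaculture — for feeding
programmes, product quality and welfare — and is traditionally measured by
dissection and chemical analysis. Micro-CT offers a non-destructive
alternative: X-ray attenuation, expressed in Hounsfield units (HU, water =
0, air = −1000), separates adipose tissue (mildly negative HU) from lean
tissue and bone, so fat can be segmented and measured in situ in three
dimensions.

`ctfat` implements the complete radiological workflow for researchers who
want to quantify fat in whole-fish scans, and — because no public scans
exist for this protocol — a digital-phantom suite that validates every
stage against known ground truth:

* **Calibration** — the pure-fat attenuation value is estimated from
  ellipsoidal ROIs (each > 400 voxels) on an ex-vivo scan of dissected
  visceral fat; for gilthead seabream this gives −115 HU, the lower bound
  of the fat window \[−115, +50\] HU.
* **Segmentation** — the whole body is a seeded 3D isocontour inside the
  body window \[−1000, +2500\] HU, with scanner-bed voxels excluded via an
  empty-bed reference scan; fat is the in-window subset of the body.
* **Volumetrics** — per specimen: total volume *V*, fat volume *V_fat*
  (voxel count × voxel volume), and fat fraction
  *f = 100 · V_fat / V* (%); per cohort: mean ± SD (n − 1).
* **Group statistics** — fed vs starved cohorts compared per parameter by
  the pooled two-sample Student t-test,
  *t = (x̄₁ − x̄₂) / √(s_p² (1/n₁ + 1/n₂))*, df = n₁ + n₂ − 2,
  significant at p < 0.05.
* **Phantoms** — stylised digital fish (tissue compartments with Gaussian
  noise and partial-volume blur, exact label-map ground truth) and an
  optional parallel-beam projection / filtered-back-projection stage.

## Worked example

Calibrate the fat value on an ex-vivo phantom, then run the full fed vs
starved analysis on six phantoms per group:

```r
library(ctfat)

exvivo <- make_exvivo_fat_phantom(mean_hu = -115, sd_hu = 15, seed = 1)
cal <- calibrate_fat_hu(exvivo, default_calibration_rois(exvivo))
print(cal)
#> fat_calibration: -115 HU (unrounded -115.048) from 6 ROIs (> 400 voxels each)
#>  roi n_voxels   mean_hu    sd_hu
#>    1      456 -115.4620 14.66333
#>    2      464 -114.4227 15.97190
#>    3      465 -114.8242 15.15022
#>    4      465 -115.0662 14.52725
#>    5      464 -115.1506 15.52453
#>    6      456 -115.3601 14.79375

report <- run_pipeline(pipeline_config(conditions = c("fed", "starved"),
                                       n_per_group = 6, seed = 1))
print(report)
#> ctfat_report
#>   calibration : -115 HU (unrounded -115.409)
#>   fat window  : [-115.409, 50] HU
#>   specimens   : 12
#>   fed       : total 70.532 ± 0.893 cm^3, fat 53.188 ± 0.860 %
#>   starved   : total 36.640 ± 1.556 cm^3, fat 44.735 ± 1.784 %
#>   significant : weight_g, length_cm, total_volume_cm3, fat_volume_cm3, fat_fraction_pct (alpha = 0.05)

print(report$comparison)
#> cohort_comparison (alpha = 0.05); '*' marks p < alpha
#>   weight_g             55.558 ± 7.824   vs   19.612 ± 0.961    p = 5.715e-07 *
#>   length_cm            16.273 ± 0.980   vs   12.445 ± 0.765    p = 1.965e-05 *
#>   total_volume_cm3     70.532 ± 0.893   vs   36.640 ± 1.556    p = 5.347e-13 *
#>   fat_volume_cm3       37.512 ± 0.621   vs   16.404 ± 1.186    p = 3.248e-12 *
#>   fat_fraction_pct     53.188 ± 0.860   vs   44.735 ± 1.784    p = 1.054e-06 *
```

Reading the output: the ex-vivo calibration recovers the configured fat
attenuation (−115 HU) and builds the fat window from its unrounded value.
The fed cohort's recovered total volume (70.5 ± 0.9 cm³) sits within ~1 %
of the generating value (71.289 cm³), the starved cohort at 36.6 vs
37.101 cm³, and every biometric parameter separates significantly between
groups — starved fish are roughly half the fed volume. Fat-fraction
*estimates* carry a known bias at this coarse phantom scale (the window's
lower bound sits exactly on the fat mean, and lean tissue overlaps the
window's upper end); the per-specimen records in `report$records` carry
the ground-truth columns alongside the estimates so the bias is always
visible. See the methods vignette (`vignettes/fat-volumetrics.Rmd`) for
the full analysis.

Setting `output_dir` in the config additionally writes per-specimen NIfTI
label maps (0 background, 1 body, 2 fat, 3 bed), volumetrics and t-test
CSVs, the calibration report, and a JSON run manifest; re-running the same
config reproduces every file bit for bit.

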