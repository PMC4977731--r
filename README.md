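# relaxometry

Vendor-independent T1 and T2 relaxation mapping for quantitative MRI.

MRI scanners compute T1/T2 parameter maps with inline algorithms that are
neither documented nor portable across vendors, yet the maps drive
quantitative decisions: myocardial extracellular volume, oedema detection,
tumour characterisation, non-invasive blood oximetry. `relaxometry`
reconstructs pixelwise and ROI-mean relaxation maps from multi-timepoint
image series with every numerical step open, configurable and tested — for
imaging scientists who need reproducible maps and for methodologists who
need a reference implementation to validate against.

## The models and the pipeline

Seven sequence families are supported, each as a 3-parameter and (where
defined) a 2-parameter mono-exponential fit:

* **T1 recovery** — inversion-recovery spin echo (magnitude,
  `S(t) = |A(1 − B e^(−t/T1))|`), PSIR (signed), saturation-recovery bSSFP,
  and MOLLI in magnitude or PSIR form with the Look-Locker correction
  `T1 = T1*(B − 1)` applied after fitting.
* **T2 decay** — single-/multi-echo spin echo and T2-prepared bSSFP,
  `S(t) = A e^(−t/T2) + B` with `B ≥ 0` (3-parameter) or `B = 0`
  (2-parameter); the 3-parameter T2-prep fit can take a saturation-recovery
  anchor image that pins the offset.

Per pixel: T1 starts from a two-pass lookup-table search over 0–4000 ms
(50 ms coarse grid, then a 5 ms grid within ±100 ms, minimum sum of
absolute error on normalized signals); T2 starts from a weighted log-linear
regression with stepwise echo truncation down to three points. Initial T2
values outside the open interval 0 < T2 < 400 ms are excluded and emit 0.
Estimates are refined by a C++ Nelder-Mead simplex that converges when the
relaxation-time spread between consecutive simplexes falls below 0.10 ms.
Each pixel carries a normalized mean-absolute-residual percentage;
agreement against a reference is summarized by modified Bland-Altman
statistics (bias ± SD, 95 % limits of agreement, in ms and %).

A built-in simulator generates 12-vial gel-phantom series (T1 214–1643 ms,
T2 46–338 ms at 1.5 T; 229–1752 / 45–316 ms at 3 T) with Rician or Gaussian
noise and exact ground truth, so the whole pipeline is testable without
scanner data.

## Worked example

Simulate a noisy 1.5 T phantom, fit a 3-parameter saturation-recovery map,
and compare per-vial means against ground truth:

```r
library(relaxometry)

spec <- default_eurospin_specs("1.5T", shape = c(64, 64),
                               model = signal_model("sr_bssfp", "3p"),
                               noise_sigma = 2, seed = 11)   # SNR 50 at A = 100
sim <- simulate_series(spec)
sim$series
#> <image_series> 64 x 64, 18 frames (signed)
#>   times (ms): 150 300 400 500 700 900 1100 1300 1800 2000 2500 3000 3700 4300 5000 5600 6300 8000

map <- fit_map(sim$series, spec$model,
               roi = roi_mask(Reduce(`|`, sim$truth$vial_masks)))
map
#> <relaxation_map> sr_bssfp 3p, 64 x 64
#>   pixels: 4096 total, 544 fitted, 544 refined, 0 excluded
#>   tau range (refined): 178.0 - 1830.9 ms

pairs <- per_vial_means(map, sim$truth$vials$T1, sim$truth$vial_masks)
stats <- bland_altman(pairs$measured, pairs$reference)
glance(stats)
#> # A tibble: 1 × 9
#>   bias_ms sd_ms loa_low_ms loa_high_ms bias_pct sd_pct loa_low_pct loa_high_pct     n
#>     <dbl> <dbl>      <dbl>       <dbl>    <dbl>  <dbl>       <dbl>        <dbl> <int>
#> 1    2.34  4.20      -5.89        10.6    0.266  0.778       -1.26         1.79    12
```

Per-vial means sit within a few ms of truth: bias 2.3 ms (0.27 %) with
95 % limits of agreement −5.9 to +10.6 ms across the 12 vials. A
ROI-mean fit of a single vial runs the same engine on the averaged signal:

```r
fit_roi_mean(sim$series, spec$model, roi = roi_mask(sim$truth$vial_masks[[9]]))
#> <relax_fit> sr_bssfp 3p
#>   tau = 940.01 ms, A = 99.83, B = 0.9988
#>   residual = 0.282 %, refined = TRUE, excluded = FALSE, 42 iterations
```

(vial 9's true T1 is 942.4 ms). `autoplot(map)`, `autoplot(stats)` and
`plot_fit_curve()` draw the map, the Bland-Altman plot and individual curve
fits; `tidy()`/`glance()` give tabular access to every result type.

Maps read and write as 64-bit NIfTI (+ JSON provenance), image series load
from DICOM directories (standard timing tags) or NIfTI-plus-JSON-sidecar
pairs, and a command-line wrapper covers the simulate/fit/validate cycle:

```sh
Rscript inst/cli/relaxometry simulate --preset eurospin-1.5T --model sr_bssfp \
    --snr 50 --seed 11 --out phantom/
Rscript inst/cli/relaxometry fit --model sr_bssfp --variant 3p \
    --volume phantom/series.nii.gz --sidecar phantom/series.json --out maps/
Rscript inst/cli/relaxometry validate --candidate maps/ \
    --reference phantom/reference.csv --vials phantom/vial_labels.nii.gz \
    --parameter T1 --out report/
```

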