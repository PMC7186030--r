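# eitperf

Functional electrical impedance tomography (EIT) of regional lung
perfusion with a conductive saline bolus — a complete simulation and
analysis pipeline in R.

## The problem

EIT images the impedance distribution of a chest cross-section from a
16-electrode belt at ~13 frames/s, noninvasively and at the bedside. Its
natural chest signal is ventilation; the perfusion signal is an order of
magnitude smaller. Injecting a hypertonic-saline bolus into the pulmonary
circulation provides an impedance contrast agent: wherever blood carries
the bolus, regional impedance falls transiently, and a territory whose
artery is occluded (the situation of pulmonary embolism) shows no fall.
From the local time–impedance dilution curve, indicator-dilution theory
gives regional flow information: for a fixed indicator amount *m*
transiting a territory with flow *F*, the Stewart–Hamilton relation

```
AUC = m / F        (area under the dilution curve ∝ 1/flow)
```

plus the curve parameters appearance time, appearance-to-peak time and
mean transit time (the first temporal moment ∫t·c dt / ∫c dt).

`eitperf` is aimed at researchers studying EIT perfusion imaging and
perfusion-defect detection who need a controlled, fully synthetic test
bed. It provides:

* a 2D thorax phantom (two lungs, cardiac region, unit-disk boundary)
  with tidal ventilation and regional gamma-variate bolus kinetics under
  three injection scenarios: **distal** (bolus only into the
  catheter-side branch territory), **proximal with inflated balloon**
  (that territory occluded — a simulated embolism), **proximal with
  deflated balloon** (both lungs perfused);
* a triangular-FEM forward solver for the 16-electrode adjacent-drive
  protocol (208 channels/frame, 77 ms/frame, 1000-frame measurements);
* normalized-difference reconstruction to 32×32 tomograms by
  equipotential-band back-projection and by a Tikhonov-regularized
  sensitivity operator;
* functional images of ventilation (end-inspiratory − end-expiratory)
  and perfusion (pre-bolus − bolus-arrival);
* dilution-curve extraction and metrics, relative-flow estimation from
  1/AUC, and perfusion-defect detection;
* CSV/YAML/PNG writers with exact round-trips, a Markdown run report,
  and a thin command-line front end
  (`inst/exec/eitperf.R simulate|acquire|reconstruct|fimage|dilution|report`).

## Worked example

A distal bolus (15 ml into the left branch territory) at 1% electrode
noise, reconstructed with the sensitivity operator and analysed at the
dorsal sampling pixels of the two lungs:

```r
library(eitperf)

op  <- build_operator(method = "regularized_sensitivity")
cfg <- scenario_config("distal", catheter_side = "left",
                       noise_sd = 0.01, seed = 1)
run <- run_scenario(cfg, op = op)

run$images$times[run$arrival_index]   # bolus arrival: 12.0 s
run$metrics
#>   region defined peak_amplitude appearance_time time_to_peak    auc mean_transit_time
#> 1  right   FALSE             NA              NA           NA     NA                NA
#> 2   left    TRUE          0.152            3.08         11.0  0.952              12.2
```

The ipsilateral (left) dorsal curve carries a clear first-pass bolus —
peak impedance fall 0.152, appearing 3.1 s after injection, peaking at
11.0 s, mean transit 12.2 s — while the contralateral pixel has no
defined signal (its peak stays within 3× the baseline noise), which is
the distal-injection laterality finding. With the balloon inflated
(proximal 20 ml injection, left branch occluded), the occluded territory
shows as a perfusion defect confined to the left lung:

```r
cfg2 <- scenario_config("proximal_inflated", catheter_side = "left", seed = 1)
run2 <- run_scenario(cfg2, op = op)
tidy(detect_perfusion_defect(run2$perfusion,
     list(right = run2$masks$right_lung, left = run2$masks$left_lung)))
#>   lung  n_pixels defect_fraction
#> 1 right      116           0
#> 2 left       116           0.138
```

and with the balloon deflated, a 2:1 left/right flow split is recovered
from the per-lung curve areas via 1/AUC:

```r
cfg3 <- scenario_config("proximal_deflated",
                        flow_split = c(right = 1/3, left = 2/3), seed = 1)
run3 <- run_scenario(cfg3, op = op)
tidy(estimate_relative_flow(
  lung_roi_metrics(run3$images, run3$masks, run3$injection_frame)))
#>   region   auc relative_flow
#> 1 right  1.25          0.341
#> 2 left   0.646         0.659
```

Result objects have `tidy()`/`glance()` methods and `autoplot()`
graphics (`autoplot(run$perfusion)`, `autoplot(run$curves$left)`,
`plot_global_signal()`).

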