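---
title: "Imaging regional lung perfusion with a conductive bolus: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imaging regional lung perfusion with a conductive bolus: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eitperf)
```

## The problem

Electrical impedance tomography (EIT) reconstructs the distribution of
electrical impedance in a body cross-section from boundary current
injections and voltage measurements. In the chest, impedance is dominated
by the air content of the lungs, which makes EIT a good ventilation
monitor but a poor perfusion monitor: the blood-related impedance signal
is an order of magnitude smaller than the ventilation signal. A way
around this is an intravascular impedance contrast agent — a hypertonic
saline bolus injected into the pulmonary circulation. Where blood carries
the conductive bolus, regional impedance falls transiently; where a
vessel is occluded (as in pulmonary embolism), no fall occurs. Tracking
that transient with fast difference imaging turns EIT into a bedside
perfusion camera, and indicator-dilution theory (Stewart–Hamilton) links
the local time–impedance curve to regional blood flow.

`eitperf` implements this pipeline end to end on a synthetic thorax
phantom: scenario generation (where does the bolus go), forward
simulation of the acquisition, difference reconstruction, functional
imaging of ventilation and perfusion, dilution-curve analysis, relative
flow estimation, and perfusion-defect detection. Because no real data
from the underlying animal protocol are available, the phantom is a
first-class, tested component: it defines the ground truth against which
every downstream step is validated.

## The acquisition model

Sixteen point electrodes sit equally spaced on the boundary of a unit
disk; electrode 1 at the ventral midline, numbering clockwise viewed from
cranial (our convention — the protocol does not fix one). Current is
driven through each adjacent electrode pair in turn and differential
voltages are read from the 13 adjacent pairs not involving a driven
electrode: 16 × 13 = 208 channels per frame, one frame per 77 ms, 1000
frames per measurement (77 s, ≈13 frames/s).

The forward problem — the conduction equation
$\nabla\!\cdot(\sigma\nabla u) = 0$ on the disk with a $\pm I$
point-electrode Neumann drive — is solved by linear triangular finite
elements on a polar mesh (default 32 concentric rings × 96 angular
spokes, ≈3100 nodes). Spoke 1 is aligned with the ventral midline, so
every electrode coincides exactly with a boundary node and no
electrode-placement discretization error enters. Conductivity is sampled
per element from the phantom's Cartesian grid (piecewise constant at the
element centroid). The pure-Neumann nullspace is removed by pinning the
central node; since all outputs are inter-electrode differences, they are
gauge-invariant, and the symmetric stiffness matrix makes the
measurements reciprocal to solver round-off. On the default mesh the
homogeneous-disk voltages agree with the closed-form boundary potential
$u(\theta) = \frac{I}{\pi\sigma}\,
\ln\frac{|\sin((\theta-\theta_-)/2)|}{|\sin((\theta-\theta_+)/2)|}$
to about 0.1% (the test suite asserts 2%). We also implemented the
simpler 5-point finite-volume scheme on the Cartesian phantom grid with
nearest-node point electrodes; its staircase Neumann boundary left
10–28% errors in individual adjacent channels at a 64×64 grid (still
2–4% after cut-cell face weighting and interpolated electrode
footprints), so the FEM formulation is the one shipped.

Measurement noise is additive Gaussian on the voltages only (noise enters
at the electrodes, not in the physics), with standard deviation expressed
as a fraction of the mean absolute voltage, and seeded: an acquisition is
bit-reproducible given (configuration, seed).

## The thorax phantom and the three injection scenarios

The phantom is a 2D transverse section: two elliptical lungs at
(±0.45, −0.05) with semi-axes (0.32, 0.45), a cardiac ellipse at
(0.05, 0.35) with semi-axes (0.22, 0.18), +y ventral, on a unit disk.
These positions are our choice (drawn to resemble a supine pig section);
nothing downstream depends on their exact values. Baseline
conductivities: background 1.0, lung 0.35 (air-filled lung conducts
poorly), heart 1.5 (blood-rich), in arbitrary units — only ratios matter
for difference imaging.

Tidal ventilation at 12 breaths/min multiplies lung conductivity by
$1 - A\,(1-\cos 2\pi f t)/2$ with amplitude $A = 0.2$: conductivity is
minimal (impedance maximal) at end-inspiration, and the term is zero at
end-expiration, which is where bolus scenarios freeze it (all bolus
measurements are taken during a breath hold at end-expiration).

A Swan–Ganz catheter sits in one pulmonary-artery branch. Its territory
is modelled as the dorsal-most fraction (`occluded_fraction`, default
0.4) of the ipsilateral lung's pixels by y-rank; gross anatomy does not
determine the extent of a single branch's territory, so it is an
explicit free parameter rather than an inferred value. Three bolus scenarios:

* **distal** (15 ml): the bolus exits at the catheter tip, perfusing only
  the catheter-side territory;
* **proximal, balloon inflated** (20 ml): the balloon interrupts flow in
  the branch; the bolus reaches the heart and every lung region *except*
  the occluded territory, whose concentration stays identically zero;
  the interrupted flow is renormalized over the open regions;
* **proximal, balloon deflated** (20 ml): the bolus reaches the heart and
  both lungs.

Regional bolus kinetics are gamma-variates
$c(t) = a\,s^{\alpha}e^{\alpha(1-s)}$, $s = (t-t_0-t_{\rm inj})/t_p$,
with shared shape ($\alpha = 3$, $t_p = 4$ s — transit well inside a
40 s record) and path-length-ordered delays (heart 1 s before lungs 3 s
for proximal injections; 2 s for the distal territory). Injection is at
5 s, leaving 65 pre-injection baseline frames.

### How flow enters the curves

Regional amplitudes follow the Stewart–Hamilton relation under a fixed
indicator amount per territory: the area under a territory's
concentration curve equals (injected amount)/(territory flow), so
$a_r = g\cdot\frac{V_{\rm ml}}{20}\cdot\frac{0.5}{\phi_r}$, where
$\phi_r$ is the territory's fraction of cardiac output and the gain $g$
(default 0.3) is calibrated so that a whole lung at the default 50/50
split and a 20 ml bolus peaks at a 30% relative conductivity increase.
Consequently AUC ∝ 1/flow — which is exactly the relation the
downstream flow estimator inverts — and total indicator mass, in
Stewart–Hamilton form $\sum_r \phi_r \cdot {\rm AUC}_r$, is invariant to
the flow split (the suite checks 1%). An alternative convention (mass
routed in proportion to flow) makes regional AUC independent of the
split and the split unidentifiable from areas alone; the convention used
here is the one under which cross-region flow ratios are defined, and it
is only meaningful for proximal scenarios, where every open territory
receives the bolus.

## Reconstruction

Difference imaging works on normalized channel differences
$d_c = (V_c - V^{\rm ref}_c)/V^{\rm ref}_c$ against a reference state —
the mean of all pre-injection frames for bolus runs, a marked
end-expiration frame for ventilation runs. Two linear operators map
$d \in \mathbb{R}^{208}$ to a 32×32 image (row 1 ventral, column 1 the
animal's right; positive pixel = impedance rose; saline arrival therefore
shows as negative pixels):

* **Back-projection** (the classic approach for this protocol, and the
  default imaging operator): each channel spreads its normalized
  difference uniformly over the band of pixels between the two
  equipotential curves of the homogeneous-disk drive field terminating at
  its measurement electrodes; pixel values are the weight-normalized sum
  over channels, then smoothed with a 3×3 uniform in-disk kernel. The
  historical algorithm's exact filtering is not recoverable from the
  literature, so pixel values are implementation-specific; the suite
  asserts structural properties (linearity, support, sign, localization
  within 2 of 32 pixels for small perturbations at 8 canonical
  positions).
* **Regularized sensitivity**: the Jacobian $J$ of log-voltages with
  respect to log-conductivity about the homogeneous disk (assembled from
  the FEM solution gradients, aggregated to image pixels), inverted as
  $\hat{\delta} = J^{\top}(JJ^{\top}+\lambda I)^{-1} d$ with
  $\lambda = 10^{-3}\,\sigma_{\max}^2(J)$ by default.

The two operators cross-validate each other: peaks for the same
single-blob data agree within 3 pixels. They serve different purposes,
and this division of labour is deliberate. Back-projection reproduces
qualitative functional images well, but its equipotential bands couple
distant co-band regions: about 4% of a strong ipsilateral peak appears
at the contralateral dorsal sampling pixel, and lung-ROI areas are
distorted enough to misestimate a 4:1 flow split by ~50%. The
sensitivity operator trades higher noise amplification for much lower
deterministic cross-talk (below the 1%-voltage-noise floor) and
recovers 1:1/2:1/4:1 splits to <5% noiseless. All quantitative analyses
(laterality statistics, flow recovery, defect detection) therefore run on
the regularized-sensitivity reconstruction, while back-projection remains
the default for imaging.

## Functional images and dilution analysis

**Ventilation fEIT**: peaks/troughs of the global in-mask signal are
detected with a half-breath-period minimum separation (window endpoints
count when they dominate their visible window, so the end-expiration at
frame 1 is kept); the image is the per-pixel mean over breaths of
(end-inspiratory − preceding end-expiratory) impedance change.
Ventilated lung appears as large positive values.

**Perfusion fEIT**: (mean pre-bolus) − (mean of a 3-frame window centred
on the bolus arrival), so an impedance fall is positive. Arrival is the
frame minimizing the mean in-ROI pixel value, accepted only if its depth
exceeds 3× the pre-injection SD of the ROI signal (earliest index on
ties). The 3-frame window suppresses single-frame noise without blurring
the transit.

**Dilution curves** are baseline-subtracted, sign-flipped pixel or
ROI-mean time courses. For curve statistics on noisy single-pixel data we
apply a centred moving average (9 frames = 0.69 s; the transit spans
roughly 100 frames, so the induced peak attenuation is below 1%), while
`baseline_sd` is always reported from the unsmoothed pre-injection
signal. Metrics: appearance time (first sustained crossing of 5% of
peak, 2-frame persistence — the persistence rule keeps noise from
triggering onsets), time to peak, appearance-to-peak, AUC (trapezoid from
appearance to the first return below the appearance level, completed by a
gamma-variate fit when the record truncates the washout), and mean
transit time (first temporal moment over the same support). For a pure
gamma-variate with $\alpha = 3$, $t_p = 4$ the 5%-support truncation
biases the MTT by ≈1.8% against the analytic first moment
$t_0 + t_p(\alpha+1)/\alpha$ — inside the 2% the suite allows, and
documented rather than patched with a tail correction. Curves whose peak
does not exceed 3× baseline SD are reported as *undefined*, never as
zeros.

**Relative flow** is $1/{\rm AUC}$ over regions with defined metrics,
normalized to 1; occluded (undefined) regions are reported as flow 0. No
absolute calibration is attempted: the proportionality constant of
Stewart–Hamilton would require knowing the effective indicator amount per
region, which difference EIT does not measure.

**Defect detection** labels a lung pixel as defect when its perfusion
value is below 0.2× the median over all lung pixels. With 208
measurements the point-spread function fills the occluded territory with
40–60% of the neighbouring perfused signal, so at `occluded_fraction`
0.4 the detected defect fraction is ≈0.14 rather than the nominal 0.4;
it grows monotonically with the true occluded extent (≈0.03/0.14/0.32
at 0.2/0.4/0.6) and the contralateral lung stays clean. A threshold this
strict (20% of median) separates only the deepest core of the cold spot;
this resolution limit is inherent to 16-electrode difference EIT, not to
the implementation, and we report it as a known limitation rather than
tuning the threshold to the phantom.

## Statistical choices for the noisy laterality checks

The headline qualitative result — ipsilateral fall for distal injection,
contralateral-only fall with the balloon inflated, bilateral fall with it
deflated — is asserted on dorsal-pixel curves at 1% voltage noise over 5
seeds as: signal present ⇔ smoothed curve peak > 5× baseline SD, absent
⇔ < 3× baseline SD, evaluated on the median across seeds. The median is
used because the bound sits at the noise-order-statistic edge: the
maximum of ~340 independent noise frames alone reaches ≈3 SD, so a
single seed can cross 3 SD with zero true signal and individual seeds are
not informative at that bound.

## Problem sizes and defaults

Simulations in the tests and the acceptance script use the 64×64 phantom
grid, the default 32×96 FEM mesh, 400-frame (30.8 s) bolus records —
long enough to contain the full washout of the default kinetics — and
260-frame (4-breath) ventilation records, with the single full-length
1000-frame protocol run exercised once. A 400-frame acquisition solves in
a few seconds; identical consecutive fields (the breath-hold baseline)
are factorized once and reused.

## Known limitations

* 2D circular geometry, point electrodes, no contact impedance, no 3D
  current spreading, no cardiac-cycle pulsatility — by design out of
  scope.
* The phantom's bolus kinetics are idealized gamma-variates with shared
  shape; real curves show recirculation and dispersion differences that
  the generator does not emulate, so passing tests validate the
  pipeline's mechanics and its resolution limits, not physiological
  realism.
* Absolute pixel values of the back-projection are implementation-
  specific; only structural properties are comparable across
  implementations.
* Flow ratios are defined only for proximal scenarios (all territories
  sampled by the same injection); a distal injection perfuses one
  territory and supports no cross-region comparison.
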