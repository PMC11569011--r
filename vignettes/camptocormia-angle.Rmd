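---
title: "Measuring the camptocormia angle with four accelerometers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the camptocormia angle with four accelerometers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camptokin)
```

## The measurement problem

Camptocormia — involuntary, non-fixed forward flexion of the trunk during
standing, walking and sitting — is a common postural complication of
advanced Parkinson's disease.  Treatment studies need a quantitative
outcome, and the accepted one is the camptocormia angle (CA).  Two
definitions coexist: the *perpendicular* CA (spine line L5→C7 against the
vertical) and the consensus-recommended *malleolus* CA (spine line against
the L5→lateral-malleolus line), with CA > 30° under the malleolus method
defining the syndrome.  Photograph-based assessment is momentary, confined
to the clinic, and exposed to white-coat effects; `camptokin` implements a
wearable alternative: four tri-axial accelerometers (C7, L5, mid-thigh,
mid-shank) yield both CA variants continuously, with gravity as the
absolute reference so no drift accumulates over time.

## The model chain

**Inclinations from gravity.**  With channels in g and the longitudinal
sensor axis reading $a_x = -1$ g at upright stance, trunk sensors give
$\varphi = -\arctan(\sqrt{a_y^2+a_z^2}/a_x)$ and leg sensors the signed
$\varphi = -\arctan(a_y/\sqrt{a_x^2+a_z^2})$.  Both are realized with the
two-argument arctangent, so a horizontal trunk sensor cleanly returns 90°
instead of dividing by zero.  These formulas return inclination *to the
vertical*, not a sagittal-plane projection: lateral and oblique lean are
absorbed into the same angle, and no plane separation is attempted.

**Perpendicular CA.**  The spine is modeled as a flexible chain of
vertebrae with fixed heights and mobility, which linearizes to
$$CA_{per} = 0.3856 + 0.4542\,\varphi_{L5} + 0.5458\,\varphi_{C7}.$$
The coefficients sum to one, so a rigidly tilted trunk maps to its tilt
plus the small intercept.  The model's validity for negative or very large
inclinations is not established; the package computes it everywhere but
treats $|CA_{per}| > 90^\circ$ as suspicious territory for interpretation,
not as an error.

**Leg angle.**  Thigh and shank are two coupled pendula rotating in the
sagittal plane.  From segment lengths $u, l$ (measured on the subject,
meters) and inclinations $\varphi_{TH}, \varphi_{SH}$: knee angle
$\theta = 180 - \varphi_{TH} - \varphi_{SH}$, vertical drops
$Z_u = u\cos\varphi_{TH}$, $Z_l = l\cos\varphi_{SH}$, hip–ankle distance
$H$ by the cosine law, magnitude $\arccos((Z_u+Z_l)/H)$, and the sign of
the anterior ankle offset $u\sin\varphi_{TH} - l\sin\varphi_{SH}$ decides
anterior (+) versus posterior (−), i.e. whether the foot is in front of
the frontal plane.  The malleolus CA is the exact sum
$CA_{mal} = CA_{per} + \Phi_{leg}$ at every sample.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `sample_rate` | 128 | Hz | native IMU rate assumed throughout |
| `sg_order` | 3 | – | polynomial order of the smoothing filter |
| `sg_window_s` | 1.0 | s | smoothing window; see below |
| `u_m`, `l_m` | – | m | thigh/shank lengths; scale the leg geometry |
| confidence band | [0.5, 1.5] | g | samples with gravity magnitude outside are masked |
| cutoff | 30 | deg | clinical camptocormia threshold (strict `>`) |
| `hyperextension_tol` | 0.5 | deg | knee angles up to 180.5° stay valid |
| calibration window | first 60 | s | upright stance for zero calibration |

The filter order is fixed at three; the window length is a package choice:
1 s (129 samples at 128 Hz) matches the 1-s windows used for evaluation
and suppresses gait-band noise while passing postural transitions.  Any
signal component faster than roughly half the window is attenuated — a
deliberate trade-off, since CA progression monitoring targets sustained
posture, not swing-phase dynamics.

## Numerical choices

* **Filter edges.**  The Savitzky–Golay implementation (`signal::sgolayfilt`)
  evaluates the polynomial fit of the first/last full window at the edge
  positions; no zero padding, same output length, and polynomials up to
  order three are reproduced exactly everywhere (verified to ~1e-12 in the
  tests).
* **arccos conditioning.**  $(Z_u+Z_l)/H$ sits exactly at 1 for a straight
  vertical leg, where $\arccos$ loses half the floating-point precision.
  Since $H^2$ equals the anterior offset squared plus $(Z_u+Z_l)^2$, the
  magnitude equals $\mathrm{atan2}(|u\sin\varphi_{TH}-l\sin\varphi_{SH}|,
  Z_u+Z_l)$; the implementation switches to that identical form when the
  argument is within $10^{-7}$ of one, so collinear postures evaluate
  exactly.  Arguments beyond $1+10^{-9}$ are a numerical-inconsistency
  warning and mask the sample rather than being clamped silently.
* **Knee validity.**  Knee angles outside $(0, 180.5]$ degrees mask the
  sample.  The half-degree of tolerated hyperextension is deliberate:
  an exactly straight leg sits on the 180° boundary, filter ripple of
  order $10^{-3}$ degrees would otherwise make it flicker invalid, and
  mild genu recurvatum is physiologic while the formulas stay
  well-defined there.
* **Masking, not dropping.**  Low-confidence samples (acceleration
  magnitude far from 1 g) and invalid leg geometry propagate as masks so
  all series stay aligned; window averages use the unmasked part and
  a window is masked only when empty.
* **Binning.**  The MAD histogram bins by reference angle rounded to the
  nearest whole degree, half away from zero.

## Calibration

*Zero calibration* averages each inclination channel over a 60-s upright
window and subtracts it — appropriate when the subject can truly stand
upright; in a subject standing with residual lean it removes that lean
too, shifting all subsequent angles by it (visible as a constant offset
against an absolute reference).  *Patient-specific calibration* instead
anchors the IMU CA to two photo-derived angles taken in the standing
forward-lean posture: offsets `photo − measured` are added to subsequent
`ca_per`/`ca_mal`.  The third offset, `offset_leg`, is the approximately
constant gap between leg angles referenced at L5 versus at the hip axis
(iliac crest), estimated once as the mean difference of the two
marker-based leg references over a still window.  The three offsets are
kept orthogonal: enabling `offset_leg` and `offset_mal` on the same stream
would double-correct the leg contribution and is refused at run time.
Whether a published analysis subtracts `offset_leg` in addition to
`offset_mal` is a choice the user must make explicitly here.

## Reference reconstruction from markers

The optical reference uses displacement vectors between markers: trunk
angle from $C7 - L5$, leg angles from $L5 - LM$ and $IC - LM$, each
against the vertical, the leg references as absolute values.  Printed
formulations of such marker angles sometimes show sums of absolute
coordinates in the numerator; sums are not translation-invariant and
cannot define a segment direction, so this package uses differences
throughout, consistent with the denominators — and verifies azimuthal and
translational invariance by property tests.  Note one asymmetry inherited
from the definitions: the marker leg references are unsigned while the IMU
leg angle is signed, so for postures oscillating around vertical the
reference folds negative excursions onto the positive side.  Comparisons
in such phases (walking-like blocks) overstate the error of the malleolus
chain; the per-activity split makes this visible instead of hiding it.

## The synthetic test bed

The study-style recording behind the method is not publicly deposited, so
the generator replaces it.  A posture script prescribes activity blocks —
defaults mirror a four-minute assessment: 60 s standing upright, 50 s
standing with forward lean, 25 s walking, 80 s mimicked parkinsonian gait
— each with trunk and leg trajectories (constant, ramp or sinusoid).
Trunk inclinations are derived by inverting the spine model under a
configurable distribution ratio $\varphi_{C7}/\varphi_{L5}$ (default 1:
any pair satisfying the model is equally valid truth); leg truths follow
the pendulum geometry exactly.  Markers are placed on the same geometry,
with the L5 marker derived from the hip position by an exact rotation
about the ankle so the L5-vs-IC leg-frame gap is a constructed constant
(default 0°; set `l5_gap_deg = 7` to emulate the anatomical offset).
White accelerometer noise, short motion-artifact bursts and marker jitter
are additive, all driven by one seed.

Two generator choices deserve emphasis.  First, blocks are blended across
boundaries with a quintic smoothstep (default 4 s), keeping the truth
twice continuously differentiable and hence inside the passband of the
order-3 filter; without it, posture steps would smear across the window
and dominate closed-loop error.  Second, the "walking" blocks model slow
whole-leg sway (~0.1 Hz) with a knee-flexion oscillation, not true ~1 Hz
gait: cadence-rate content is attenuated by the 1-s smoothing window by
design, so a generator emulating real swing phases would measure the
filter, not the geometry.  Consequently the closed-loop tests demonstrate
that the *math chain* is exact (noise-free recovery below 0.01° RMSE over
the full default script) and that the noise path behaves (static-block
RMSE well under 1° at 0.02 g noise) — they do not demonstrate accuracy
under real gait dynamics, soft-tissue artifact, sensor migration or
out-of-plane leg motion, which are exactly the error sources a laboratory
validation against motion capture must quantify.

Problem sizes used by the test suite: the full 215-s default script at
128 Hz (27 520 samples) for the closed-loop checks, a ~14 000-point
parameter grid for the leg-geometry oracle comparison, and second-scale
fixtures elsewhere; the whole suite runs in well under a minute.

## Known limitations

* Planar two-pendulum leg model: out-of-plane leg motion is model error by
  construction; seven-degree-of-freedom leg models are out of scope.
* No gyroscope/magnetometer fusion and no orientation filters: during
  strong accelerations the gravity direction is unobservable and samples
  are masked rather than estimated.
* The spine-model coefficients are population-level; subject-specific
  spine geometry enters only through calibration.
* The unsigned marker leg reference limits validation near vertical legs
  (sign information is lost in the reference, not in the measurement).
* Automated activity recognition is not included; activity segments are
  supplied as annotations.
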