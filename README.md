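# camptokin

Continuous measurement of the camptocormia angle from four body-worn
accelerometers.

Camptocormia is a pathological, non-fixed forward flexion of the trunk that
affects a substantial fraction of patients with advanced Parkinson's
disease.  Its severity is quantified by the **camptocormia angle (CA)**,
conventionally measured on photographs in two ways:

* **perpendicular method** — the angle between the L5→C7 spine line and the
  vertical to ground;
* **malleolus method** — the angle between the L5→C7 line and the L5→lateral
  malleolus line.  This is the consensus-recommended definition; forward
  flexion exceeding **30°** under it defines camptocormia.

Photographs capture a single instant in a clinical setting.  This package
implements a wearable alternative for clinicians and movement scientists:
four tri-axial accelerometers (at C7, L5, mid-thigh and mid-shank, sampled
at 128 Hz) measure both CA variants continuously, using gravity as the
absolute inclination reference so that no drift accumulates.

## Method

Each sensor reports the gravity projection on its axes.  Trunk and leg
inclinations follow from

```
phi_C7, phi_L5 = -atan( sqrt(a_y^2 + a_z^2) / a_x )          (trunk sensors)
phi_TH, phi_SH = -atan( a_y / sqrt(a_x^2 + a_z^2) )          (leg sensors)
```

computed quadrant-safely.  The perpendicular CA comes from an affine
spine-chain model of the two trunk inclinations (the spine treated as a
flexible chain of vertebrae of fixed heights and mobility):

```
CA_per = 0.3856 + 0.4542 * phi_L5 + 0.5458 * phi_C7        [degrees]
```

The leg contribution treats thigh (length `u`) and shank (length `l`) as
two coupled planar pendula: knee angle `theta = 180 - phi_TH - phi_SH`,
vertical drops `Z_u = u cos(phi_TH)`, `Z_l = l cos(phi_SH)`, hip–ankle
distance `H = sqrt(u^2 + l^2 - 2 u l cos(theta))` by the cosine law, and

```
Phi_leg = arccos( (Z_u + Z_l) / H ),   signed by the ankle's anterior offset
CA_mal  = CA_per + Phi_leg
```

Raw channels are smoothed with a third-order Savitzky–Golay filter.  Two
calibration procedures are provided (zero calibration over a 60-s upright
stance; patient-specific calibration against a photo-derived CA in the
forward-lean posture), plus estimation of the roughly constant `offset_leg`
between leg angles referenced at L5 versus at the hip axis (iliac crest).
Validation utilities reconstruct reference angles from optical motion-
capture markers (C7, L5, IC, LM) and compare the streams by per-activity
RMSE over 1-s windows and a MAD-by-angle histogram.  Because the study
recording behind the method is not publicly deposited, the package includes
a forward-kinematics generator that produces matched synthetic
accelerometer channels and marker trajectories from prescribed posture
scripts — the test bed for the whole pipeline.

## Worked example

Generate a four-activity synthetic recording (60 s standing upright, 50 s
standing with forward lean, 25 s walking, 80 s mimicked parkinsonian gait,
with 0.02 g accelerometer noise), run the full pipeline, and compare with
the marker-based reference:

```r
library(camptokin)

syn  <- ca_synth(seed = 1, noise = noise_model(accel_sigma_g = 0.02))
proc <- ca_process(syn$accel, anthropometry(u_m = 0.45, l_m = 0.45))
proc$series
#> <camptocormia_series> 27520 samples @ 128 Hz, 27356 valid
#>   ca_per:  mean  21.97 deg, range [1.66, 40.20]
#>   ca_mal:  mean  24.33 deg, range [1.52, 48.88]

ev <- ca_evaluate(proc$series, syn$markers, syn$segments)
ev$per
#> <evaluation_report> 1.0-s window comparison
#>   standing_upright         n=   60  RMSE = 0.071 deg
#>   standing_forward_lean    n=   50  RMSE = 0.073 deg
#>   walking                  n=   25  RMSE = 0.069 deg
#>   parkinsonian_gait        n=   80  RMSE = 0.064 deg
#>   all                      n=  215  RMSE = 0.069 deg

mean(classify_camptocormia(proc$series$ca_mal), na.rm = TRUE)
#> [1] 0.569   # fraction of samples above the 30-degree cutoff
```

The RMSE table reads: within each annotated activity, the perpendicular CA
averaged over 1-s windows deviates from the optical reference by less than
a tenth of a degree on this clean synthetic recording — the residual is
sensor noise surviving the Savitzky–Golay filter, since generator and
pipeline share exact geometry.  On real recordings, soft-tissue artifact,
sensor misalignment and out-of-plane leg motion dominate instead.

The same pipeline is scriptable from a shell via the thin CLI in
`exec/camptokin` (subcommands `synth`, `process`, `evaluate`, `calibrate`).

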