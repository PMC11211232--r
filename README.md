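# synaps4d

Synchronized free-running 4D flow MRI at desk scale: simulation,
reconstruction and flow quantification in one R package.

## The problem

4D flow MRI measures a cardiac-phase-resolved, three-directional velocity
field over the whole heart, but the phase-contrast (PC) acquisition that
encodes velocity has low blood-to-myocardium contrast, so vessels are hard
to delineate and dynamic lumen segmentation is unreliable. A bright-blood,
fat-suppressed anatomical sequence (fast interrupted steady-state, FISS)
has the missing contrast but no velocity information. The synchronization
strategy implemented here acquires both free-running 3D radial sequences
back-to-back with an interrupt under 2 s, extracts cardiac triggers and a
unitless respiratory curve from pilot-tone (PT) signals recorded
continuously across both, corrects respiratory motion of both datasets
with one focused-navigation (fNAV) model fitted on the FISS data
(displacement `d(t) = c * r(t)` applied as a k-space phase, coefficients
found by minimizing gradient-image entropy), reconstructs both with k-t
sparse SENSE

    0.5 * sum_p ||E_p x_p - y_p||^2 + lambda_t TV_cardiac(x) + lambda_s TV_spatial(x)

on a shared 20-phase cardiac grid (published weights 0.03/0.015 for FISS,
0.0075/0.015 for PC), decodes balanced 4-point velocity encoding
(`v = (2 venc / pi) t(H) phi / 4`, venc 150 cm/s), and combines the FISS
magnitude with the PC velocity voxel-for-voxel.

Since no raw data of this kind is public, the package ships a dynamic
beating, breathing torso phantom (two aorta-like vessels with pulsatile
parabolic flow, two contrast mechanisms, multi-channel PT mixtures) and
validates the pipeline by parameter recovery: programmed stroke volume,
peak velocity, displacement coefficients, trigger times and contrast
orderings must survive the full acquisition-to-quantification round trip.

Audience: MRI reconstruction researchers and students who want a complete,
inspectable, tested implementation of physiological synchronization between
neighbouring acquisitions without scanner access.

## Worked example

```r
library(synaps4d)

res <- run_pipeline(pipeline_config(), out_dir = "session")
print(res$report)
```

which prints (64x64 slice, 8 phases, 64 FISS + 150 PC interleaves, about
three minutes on one core):

```
Flow report
  AAo: net volume 24.1 mL (truth 25.0), peak flow 148.7 mL/s (truth 155.0), Dice 0.81
  DAo: net volume 24.1 mL (truth 25.0), peak flow 149.1 mL/s (truth 155.0), Dice 0.81
  contrast ratio: FISS 2.17 vs PC 0.78
  fNAV coefficients (mm): 0.00, -0.09, 10.13 (truth 0, 0, 8)
```

Reading: the net volume through each vessel plane recovers the programmed
25 mL stroke volume within 4%; peak flow matches the bin-averaged
programmed pulse (the instantaneous systolic peak is unobservable at 8
phases); dynamic segmentation on the combined (FISS-magnitude) images
overlaps the true lumen at Dice 0.81, while the same tracing on native PC
magnitude loses the vessel (Dice 0.06 in the full report) — the contrast
ratios (bright-blood 2.17 vs 0.78) are why. The fNAV z coefficient exceeds
its 8 mm truth because the PT-derived curve is unit-normalized after
filtering; the displacement waveform `c * r(t)` that the correction
applies is accurate, and fitting against the known curve recovers
(0, 0, 8) within 0.15 mm (see the methods vignette).

Session directories hold every intermediate: raw containers, triggers,
the motion model, objective traces, NIfTI volumes
(`synaps_mag`, `synaps_vx/vy/vz`, `native_*`), per-phase flow curves (CSV)
and `report.json`.

A thin CLI wraps the same stages:

```sh
inst/cli/synaps4d run-all --config cfg.yaml --out session
inst/cli/synaps4d simulate --out session   # ... physio moco recon combine quantify
```

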