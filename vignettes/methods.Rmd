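---
title: "Synchronized free-running 4D flow: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchronized free-running 4D flow: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Whole-heart 4D flow MRI measures a time-resolved, three-directional velocity
field, but the phase-contrast (PC) readout that encodes velocity has poor
blood-to-myocardium contrast, which makes vessel delineation and dynamic
segmentation unreliable. A bright-blood, fat-suppressed anatomical sequence
(fast interrupted steady-state, FISS) has exactly the contrast that PC
lacks, but carries no velocity information. `synaps4d` implements the
synchronization strategy that joins the two: acquire both free-running 3D
radial sequences back-to-back (with an acquisition interrupt under 2 s),
track cardiac and respiratory motion continuously with pilot-tone (PT)
signals that span both acquisitions, and use that single physiological
record to bin, motion-correct and reconstruct both datasets on a common
cardiac grid, so the FISS magnitude can be combined voxel-for-voxel with
the PC velocity maps.

The package is a desk-scale re-creation of that pipeline: a dynamic digital
torso phantom replaces the scanner, and every downstream stage — trajectory
generation, multi-coil non-uniform Fourier encoding, PT processing,
focused-navigation (fNAV) motion correction, k-t sparse SENSE
reconstruction, balanced 4-point velocity decoding, and flow
quantification — is real, tested code. Validation is by parameter recovery:
the phantom's programmed stroke volume, peak velocity, displacement
coefficients, triggers and contrast orderings must come back out of the
pipeline.

## The phantom and what it does (and does not) emulate

The phantom is a single-slice torso in the (y, z) plane: a soft-tissue
ellipse, a peripheral fat layer, a contracting myocardial annulus with a
blood pool, and two through-plane vessels standing in for the ascending
(AAo) and descending aorta (DAo). The through-plane direction is x, so
through-plane flow coexists with in-plane superior-inferior (z) respiratory
motion — both of the quantities the pipeline must recover are observable in
a 2D simulation. The `c_x` coefficient is through-plane and therefore
unobservable in this mode; the fitter pins it at zero.

Key time functions:

* **Cardiac**: phase advances linearly at `heart_rate_hz` (default 1.2 Hz).
  The vessel velocity pulse is a raised cosine occupying the first 35% of
  the RR interval; vessel cross-sectional area rises by 10% in systole and
  the blood-pool radius contracts by 25%. The peak on-axis velocity is
  calibrated by numerical quadrature so that one beat integrates exactly to
  `stroke_volume_ml` (default 25 mL per vessel, which keeps peak velocity
  near 110 cm/s, safely under the 150 cm/s venc).
* **Velocity profile**: parabolic, `v(rho) = vmax(t) (1 - (rho/R)^2)`,
  zero outside the vessels; AAo flow is +x and DAo flow is -x so that each
  plane's normal can be chosen to make systolic flow positive.
* **Respiration**: `r(t) = 2 ((1 - cos(2 pi f t)) / 2)^p - 1` with `p = 2`
  (default rate 0.25 Hz). The squared raised cosine spends most of its time
  near end-expiration, as free breathing does. The asymmetry is not
  cosmetic: a pure cosine is symmetric about zero, so the polarity of a
  unitless curve recovered from PT data would be undecidable, and with it
  the sign of the fNAV coefficients. With the asymmetric waveform the
  package canonicalizes polarity by placing the long plateau at negative
  values. Displacement is `c_true * r(t)` with `c_true =
  resp_amplitude_mm`, default (0, 0, 8) mm.
* **Pilot tone**: each of 12 channels mixes the respiratory curve and a
  cardiac waveform (`-cos(2 pi phase) - 0.2 cos(4 pi phase)`, one sharp
  minimum per beat at the onset) with seeded weights, linear drift, a step
  offset at the inter-sequence gap, and Gaussian noise. The waveform is
  deliberately fundamental-dominated: PT amplitude modulations are smooth,
  and a narrowband extraction of a pulse train could never correlate
  strongly with its own source.

Rasterization uses 4x supersampling with box averaging, which stabilizes
partial-volume edges and therefore area measurements at 2 mm voxels.

What the phantom does **not** emulate: relaxation and steady-state signal
evolution, off-resonance, turbulence and non-laminar profiles, non-rigid or
rotational respiratory motion (motion enters the simulation exactly as a
rigid translation, i.e. the same linear k-space phase the correction
removes — this makes fNAV recovery exactly identifiable and is a stated
limitation of rigid autofocus correction in general), heart-rate
variability, and eddy-current background phase. Passing the recovery tests
therefore demonstrates internal consistency of the pipeline under its own
motion model, not robustness to the full physics of in-vivo data.

## Trajectories and schedules

Full-scale defaults follow the published protocol: FISS with 2000
interleaves x 24 readouts (6 modules of 4, TR 2.94 ms); PC with 4820
interleaves x 21 readouts — one superior-inferior (SI) projection plus 5
readout lines, each repeated for the 4 points of balanced velocity encoding
(TR 5.3 ms, venc 150 cm/s); 220 mm field of view, 2.0 mm resolution, 2x
readout oversampling. In 3D the directions follow a golden-angle spiral
phyllotaxis over the half-sphere (azimuth increment `2 pi (1 - 1/phi^2)`,
polar index interleaved); in the 2D test mode the same scheduler emits
golden-angle spokes, which keeps every downstream stage testable in
minutes. SI projections are generated and stored for format fidelity but
consumed by no stage. Each readout samples the symmetric diameter
`k_i = kmax (2i - N)/N`, which includes exactly one k = 0 sample.

## Encoding model

The forward operator is a discrete-image NUDFT: each readout sees the
phantom frozen at its own timestamp (cardiac state quantized to 64 rendered
frames), weighted by smooth complex coil sensitivities normalized to unit
sum of squares. This pairs the simulator with an exact adjoint, enabling
matrix oracles in the tests. Velocity encodes as the voxelwise phase
`phi_seg = (pi / (2 venc)) h_seg . v` with the balanced rows
`(-1,-1,-1), (1,1,-1), (1,-1,1), (-1,1,1)` (so `t(H) H = 4 I`, and a
single component at venc produces a paired-segment difference of pi);
respiratory displacement enters as the Fourier-shift phase
`exp(-2 pi i k . d(t))`. The NUDFT kernels exploit the equal spacing of
radial samples: the per-voxel phasors along one readout form a geometric
sequence, so one cos/sin pair per voxel per readout yields all samples by
complex-multiply recurrences. This keeps the exact transform (no gridding
approximation) fast enough for desk-scale iterative reconstruction.

## Physiology from the pilot tone

Cardiac: PCA (at most 8 components) followed by symmetric FastICA (tanh
nonlinearity, seeded deterministic initialization — written in-package);
the component whose spectral power concentrates in the cardiac band
0.5-3.0 Hz (30-180 bpm) is selected, band-passed +/- 0.3 Hz around its
spectral peak (zero-phase), and its polarity canonicalized so the sharper
extremum family are minima — the heuristic is evaluated on the component
limited to the full cardiac band, where waveform asymmetry survives but
wideband noise does not. Triggers are the interior local minima with a
refractory spacing of half the dominant period, refined by parabolic
interpolation. If no component concentrates at least 20% of its power in
the band, extraction fails loudly rather than returning noise.

Respiratory: the principal component dominant in 0.05-0.7 Hz (3-42
breaths/min), low-passed at 2.5x its spectral peak (capped at the band
edge — wide enough to keep the first harmonic that carries the waveform's
asymmetry), then linearly detrended **per sequence**: each side of the
inter-sequence gap gets its own fitted line, which removes drift and the
step offset between the two acquisitions in a single deterministic
regression. The result is normalized to unit maximum amplitude.

Binning is linear within each trigger interval (`floor(frac * P)`, default
20 phases; 8 at desk scale), computed once from the shared record and
applied to both sequences' timestamps; readouts outside the trigger span
are discarded with a flag.

## fNAV motion correction

The three displacement coefficients scale the unitless respiratory curve
into millimeters per axis. They are fitted by minimizing the entropy of the
gradient image — `-sum p log p` over the normalized gradient magnitudes —
of a pooled density-compensated reconstruction of the corrected FISS data,
over a central half-FOV region of interest containing the heart. The
optimizer is derivative-free coordinate descent: a 2 mm coarse grid within
+/- 25 mm per axis, then golden-section refinement to 0.1 mm, two sweeps,
with the coarse scan repeated each sweep so a poor early conditional
minimum on one axis cannot trap the search. The inner reconstruction uses
every 4th readout; golden-angle subsets keep near-uniform coverage, and the
entropy surrogate does not need the full dataset. The same fitted model —
coefficients and curve on the shared clock — corrects both sequences.

One identifiability note: the physics only determines the product
`c * r(t)`. When the curve is estimated from PT data, low-pass filtering
flattens the sharp end-inspiratory excursions, so the unit-normalized
estimate runs slightly smaller than the true curve inside the short FISS
window and the fitted coefficient compensates upward (about 25% at the
default settings) while the displacement waveform itself — what the
correction actually applies — remains accurate. Coefficient recovery is
therefore validated against the known curve, and the end-to-end run is
validated on what it must deliver: a sharp reconstruction and correct flow.

## Reconstruction

After normalizing each acquisition to the maximum of a pooled gridded
reconstruction (|k|-ramp density compensation with the k = 0 weight set to
half the first nonzero weight, adjoint NUDFT, conjugate-sensitivity coil
combination), each sequence is reconstructed by minimizing

    0.5 sum_p ||E_p x_p - y_p||^2 + lambda_t TV_card(x) + lambda_s TV_sp(x)

with cyclic first differences along the cardiac dimension, non-cyclic
spatial first differences, and the published weights (FISS 0.03/0.015, PC
0.0075/0.015 — cardiac/spatial, on the normalized scale). The absolute
value is smoothed as `sqrt(|d|^2 + 1e-6)`. The solver is Polak-Ribiere
nonlinear conjugate gradient: because the data term is quadratic, one
forward evaluation of the search direction gives the exact data-term
minimizer along the line, and backtracking on the full objective from that
point guarantees a non-increasing trace. Each of the four PC encoding
segments is reconstructed as its own k-t problem (matching the
x-y-z-cardiac-velocity-encode dataset shape) and decoded with
`v = (2 venc / pi) t(H) phi / 4`. Wrapping is resolved by searching integer
2-pi wrap candidates and keeping the solution whose components lie within
[-venc, venc] with the smallest common background phase; this makes the
encode-decode round trip exact for any velocity magnitude below venc, at
the cost of assuming background phase below pi/2 — reasonable here since no
eddy-current phase is simulated (none is modelled in the pipeline either;
a polynomial background-phase correction would slot in before decoding if
real data required it). The desk-scale solver runs 10 iterations at
tolerance 1e-5; the operator-oracle tests run the same solver to full
convergence on 16^2 problems.

## Quantification

Measurement planes (the slice itself in 2D, with per-vessel normal signs
making systolic flow positive) yield per-phase magnitude and through-plane
velocity. Dynamic vessel tracing emulates semi-automatic contouring with a
deterministic rule: the blood-pool reference is the median intensity of the
phase-1 seed component (bootstrapped from a 3x3 neighbourhood), the local
background is the median of an expanded bounding box around that component,
the threshold sits halfway between the two (a full-width-at-half-maximum
edge criterion, which places the boundary at the true lumen edge regardless
of the surrounding tissue intensity), the mask is the connected component
containing the seed, and the seed propagates as the previous mask's
centroid, re-anchoring to the initial seed if the centroid drifts off the
component. Flow rate is `Q_p = sum v * pixel area` (0.01 mL/s per
cm/s*mm^2), net volume integrates Q over the RR interval, and curves are
aligned at peak systole (circular shift of the argmax) before comparison.
Agreement statistics are Pearson correlation, linear regression,
Bland-Altman bias with 1.96-SD limits, mean absolute error, and a two-sided
Wilcoxon signed-rank test with the Bonferroni divisor applied at the
reporting layer (8 paired comparisons in the standard report).

On low-contrast PC magnitude the tracing may flood into adjacent tissue or
lose the vessel entirely; the report then records zero overlap and
undefined flow metrics for that pathway rather than aborting — the
comparison of interest is precisely that the anatomical pathway does not do
this.

## Problem sizes and numerical choices

The default study conditions are a 64x64 slice at 2.0 mm (128 mm FOV), 8
cardiac phases, 64 FISS interleaves (1536 readouts, ~4.5 s) and 150 PC
interleaves (3150 readouts, ~16.7 s), 2 coils, noiseless k-space, PT at
50 Hz with noise 0.1 and drift 0.5/min, and a 1.5 s gap. These sizes put
every phase bin near the radial Nyquist count so that the recovery targets
reflect the method rather than undersampling artifacts; the published
regularization weights are kept. Quantities whose in-vivo magnitudes
depend on volunteer anatomy (contrast ratios, Dice, area correlations) are
validated as orderings between the combined and native pathways, not as
absolute values. With 8 bins, the systolic pulse (35% of the RR) is
averaged within each bin, so peak-velocity recovery is assessed against
the bin-averaged programmed pulse — the instantaneous peak is unobservable
at any finite phase count and the ~10% bin-averaging deficit is a property
of the protocol, not the solver.

Degenerate inputs are handled deterministically: zero-gradient entropy
returns an infinite sentinel, an all-zero respiratory curve yields zero
coefficients with a warning, a constant cardiac signal yields no triggers
with a warning, empty phase bins and vanished vessel components raise
errors naming the bin or phase, and containers carry a format version that
is checked on read.

## Known limitations

Single-slice geometry is the tested configuration; the trajectory,
encoding and reconstruction code paths accept 3D inputs but 3D runs at
full matrix size are outside desk scale, as are respiratory-resolved (5D)
reconstructions. The motion model is rigid translation only. No background
phase, relaxation, or trajectory-error effects are simulated. The
segmentation rule is intentionally simple; it is a stand-in for
semi-automatic expert contouring, not a general vessel segmenter.
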