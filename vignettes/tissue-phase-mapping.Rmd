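---
title: "Tissue phase mapping of the rodent left ventricle: models, conventions and design notes"
author: "tpmcmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue phase mapping: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

Phase-contrast (velocity-encoded) cine CMR encodes tissue velocity into the
phase of the MR signal, frame by frame through the cardiac cycle.  In a
mid-ventricular short-axis slice of a rat heart this yields, after
reconstruction, a three-component velocity field at every pixel and every
3.2 ms frame — enough temporal and spatial resolution to resolve regional
myocardial motion in 32 circumferential segments and to integrate the
velocities into material trajectories and circumferential strain.  The
catch is that the raw data are multi-coil complex images per velocity
encoding, contaminated by eddy-current background phases and
motion-related ghosting that is *geometrically systematic* (it falls along
the phase-encode axis, so it biases some segments and not others), and
the analysis chain — segmentation, bulk-motion handling, coordinate
decomposition, tracking, strain, regional indices — involves many small
conventions that must be fixed before any two datasets can be compared.

`tpmcmr` implements that chain end to end and validates it against a
synthetic deforming-annulus phantom with closed-form velocity and strain
ground truth.

# Velocity reconstruction

**Encoding model.**  Nine encoding points: a velocity-compensated
reference plus eight rows at the corners of a symmetric cube
$(\pm 1,\pm 1,\pm 1)/\sqrt 3$, a balanced unit-norm set spanning 3D.  The
first-moment matrix is normalized so that a velocity of venc along a
unit-moment row produces a phase of exactly $\pi$; it is configurable and
stored in the container, since balanced schemes differ between sites.

**Coil combination.**  Each encoded series is multiplied by the complex
conjugate of the reference series per coil and summed over coils before
taking the argument.  Coil phases cancel in the conjugate product, and
each coil contributes with weight $|S_e||S_0|$.  Pixels with vanishing
combined signal get phase 0 and a low-signal flag.

**Eddy-current correction.**  The spatially specific correction is
represented by a polynomial surrogate: per encoding point, a 2D polynomial
(default order 1) is least-squares fitted to the *temporal-mean* phase over
user-declared static tissue, excluding fold-over regions, and subtracted
from all frames.  An order-$k$ fit removes any additive polynomial field of
order $\le k$ exactly — the property the test suite asserts.  Order 1 is
the default because the dominant residual eddy-current term after a
well-adjusted preparation delay is close to linear across a 50 mm FOV;
higher orders are available but need proportionally more static pixels.

**Decode.**  Per pixel and frame the eight phase differences are solved
for the 3-vector velocity by least squares.  A per-pixel magnitude weight
is sometimes advertised for this solve; because it is one scalar shared by
all eight equations of a pixel, it cancels from the normal equations, so
the implementation uses the plain solve.  Phases within 1 % of $\pi$ flag
the pixel as potentially wrapped; no unwrapping is attempted (the venc of
13.9 cm/s comfortably exceeds rodent myocardial velocities) and flagged
pixels are removed from the myocardial mask downstream.

# Geometry and conventions

Pixel $i$ (0-based) sits at $(i - (N-1)/2)\,\Delta x$ mm; x grows with
column, y with row (down, as displayed).  The myocardial mask is the set of
pixel centres inside the epicardial and outside the endocardial polygon.
Sparse key-frame contours are resampled to 256 vertices, equally spaced in
arc length and anchored where the ray from the polygon centroid towards the
anterior papillary landmark crosses the boundary — this materially matches
vertices across key frames — then interpolated linearly in time with
periodic closure across the cycle end.  Resampling preserves the polygon's
own traversal orientation, so clockwise and counter-clockwise annotations
behave identically.

Segments: 32 angular sectors anchored at the anterior papillary landmark,
counted counter-clockwise as displayed (configurable), index
$\lfloor 32\,\Delta\theta/2\pi \rfloor$ with boundary ties to the lower
index.  The LV centre is the epicardial centroid per frame (robust to
endocardial irregularity after infarction); mask, centre and segment
boundaries follow the LV through the cycle.

**Radial sign.**  Radial velocity is positive *towards* the centre:
contraction positive.  The opposite convention is common, so this is worth
restating: a systolic inward wall motion appears as a positive radial peak.

# Bulk motion, waveforms, key timepoints

The mask-mean in-plane velocity vector is subtracted per frame (bulk
motion); the through-plane component is untouched.  Regional waveforms are
segment means; the global waveform is the mean over all mask pixels, not
the mean of segment means (segments have unequal pixel counts).  Peak
systole is the frame of maximum global radial velocity; end-systole the
frame of minimum endocardial polygon area; end-diastole comes from the
annotation (the acquisition is R-peak triggered, so the cycle's first
frame).  Ties resolve to the earliest frame.

A consequence of subtracting the mask mean is worth knowing when
interpreting dyssynchrony: any component of a regional timing pattern that
amounts to rigid translation of the whole ventricle (a first-harmonic,
"rocking" pattern) is partly absorbed by the bulk correction, by design —
rigid translation carries no deformation information.  Synthetic
delay-recovery experiments in this package therefore impose a
second-harmonic (quadrupole) delay profile, which has no translation
component; with it the cross-correlation index recovers the imposed delay
SD to well within one frame.

# Trajectories and strain

**Fourier tracking.**  Every mask pixel of the origin frame seeds a path.
Velocities are integrated with explicit Euler steps of one frame spacing,
looking velocity up by nearest neighbour in space at the current position
and frame-wise in time, forward over one full cycle and backward likewise;
the two passes are blended linearly in elapsed time,
$x(t') = (1 - t'/T)\,x_{\text{fwd}} + (t'/T)\,x_{\text{bwd}}$,
which enforces *exact* closure of every path.  Euler with per-frame
velocities matches the near-instantaneous character of the data; the test
suite bounds the induced error against RK4 integration of the analytic
phantom field at a 10-fold finer step (RMS below half a pixel at the
default resolution).  Velocity outside the mask but inside the FOV is used
as-is during integration; paths are judged afterwards.

**Mask filter.**  Paths travelling out of the myocardial mask at any frame
are discarded, with no other filtering.  Membership is judged against the
contour band (inside epi, outside endo) — the continuous form of the pixel
mask — because testing against the rasterized mask discards wall-hugging
paths for half-pixel reasons; a strict pixel-mask mode is available.  On
the default phantom roughly four of five end-diastolic seeds survive; the
losses are concentrated in the one-pixel epicardial boundary ring, where
the phantom's exactly-zero exterior velocity stalls nearest-neighbour
lookups while the wall retreats inward by about 1.5 pixels.  In vivo the
exterior carries nonzero signal, so this is a conservative, synthetic-data
-specific loss mode.

**Dual origins.**  Tracking runs twice, from end-diastole and from
end-systole (the in-slice myocardial area is larger at end-systole, so the
second origin contributes seeds the first cannot).  Each tracing yields
segment-mean positions $x_s(t)$ over the seeds of segment $s$, and
segmental circumferential Lagrangian strain from the chord between the two
adjacent segments:
$$
Sc_s(t) = \frac{\lVert x_{s-1}(t) - x_{s+1}(t)\rVert}
               {\lVert x_{s-1}(t_{ED}) - x_{s+1}(t_{ED})\rVert} - 1 ,
$$
indices mod 32, chord (straight-line) distance exactly as written, no
arc-length correction.  The reference frame is identified with end-diastole
— the strain's own normalization makes $Sc_s(t_{ED}) = 0$ exactly for
closed paths, and the acceptance machinery verifies this to machine
precision.  The two tracings are averaged segment-wise; a segment with no
valid trajectories is flagged missing together with its two neighbours
(their chords involve it), and the average falls back to the available
curve.

Each *single-origin* tracing carries per-segment sampling scatter of a few
tenths of a percent strain: a segment mean over ~10 pixels samples a
stretch that varies from about −12 % at the epicardium to −37 % at the
endocardium of the incompressible phantom, so which pixels survive matters.
The two tracings scatter independently; their segment-wise average is what
the package reports, and on the delay-free phantom its 32 end-systolic
values cluster with SD below 0.5 %strain.

**Polygon strain.**  As an internal control, a mask-derived global strain
is computed from the contour perimeters,
$Sc_g(t) = \tfrac12[(L_{epi}(t)-L_{epi})/L_{epi} +
(L_{endo}(t)-L_{endo})/L_{endo}]$ with end-diastolic references.  On
incompressible deformation this *overestimates* the mid-wall strain in
magnitude (the endocardial border shortens more than mid-wall fibres), and
the test suite asserts that direction.

# Dual rotated acquisitions

Ghosting falls along the phase-encode axis of each acquisition; rotating
the FOV at least 30° between two acquisitions makes the artifacts land in
different anatomical places so that averaging attenuates them.  The two
acquisitions are processed fully independently — including their own
papillary-anchored segment division, which is what reconciles the rotation:
segment $s$ is the same anatomical sector in both.  Before averaging, the
second run's time axis is stretched by the factor (grid 0.80–1.25, step
0.005) maximizing the Pearson correlation of the global radial waveforms,
with cubic-spline resampling; the grid covers the observed heart-rate
variability of anesthetized rats (SD ≈ 10 bpm on ≈ 370 bpm) with a wide
margin.  A maximum correlation below 0.5 warns that the acquisitions are
inconsistent.  Averaging is segment-by-index, element-wise; strain is
re-referenced afterwards so the end-diastolic frame stays exactly zero.

# Regional indices

Five indices quantify regional function, all on the radial waveforms and
segmental strain: dispersion of peak motion (SD over segments of regional
radial velocity at peak systole, cm/s); dispersion of peak strain (SD of
segmental Sc at end-systole, %strain); coherence of motion waveforms (mean
Pearson correlation of each regional waveform against the global one) and
its dispersion (SD of those correlations); and the index of dyssynchrony
(SD, in ms, of the per-segment circular cross-correlation delays against
the global waveform, searched within ±25 % of the cycle to avoid half-cycle
aliasing and refined to sub-frame precision by quadratic interpolation of
the correlation peak).  The sample (n−1) SD convention is the default
throughout, population SD being available by flag.  Zero-variance
waveforms have no defined correlation or delay; they are excluded and
reported.  Cross-modality strain comparison resamples full-cycle curves to
23 equally spaced points with a periodic cubic spline and synchronizes
them circularly at peak global Sc; agreement is summarized as Bland–Altman
bias ± 1.96·SD of the paired differences.

# The synthetic phantom

The phantom emulates the acquisition this method targets: a rat
mid-ventricular short-axis cine, 128×128 matrix over a 50×50 mm FOV,
70 frames at 3.2 ms (one cycle at ≈ 268 bpm), venc 13.9 cm/s, four receive
coils, and an optional second acquisition rotated 30° in-plane.

**Motion model.**  An incompressible annulus (end-diastolic radii 3 and
5 mm) deforms by the area-preserving radial map
$r(r_0,t) = \sqrt{r_0^2 - a(\theta_0, t)}$ with
$a = a_{peak}\,h(\theta_0)\,w(t - d(\theta_0))$: $w$ is a raised-cosine
activation pulse occupying the first 40 % of the cycle (smooth, periodic,
analytically differentiable), $h$ a per-sector hypokinesia scaling and $d$
a per-sector activation delay, both piecewise constant over the 32
end-diastolic sectors and blended over 5° at boundaries so the velocity
field stays continuous.  A rigid twist (default peak 0.10 rad) and a
uniform through-plane velocity (default peak 2 cm/s) are superposed.  The
default contraction amplitude 0.19 puts the analytic mid-wall strain at
−19 %strain, a normal-rat value; peak mask-mean radial velocity lands near
2.7 cm/s.  Velocities are the exact time derivative of the map and the
strain function its exact mid-wall circumferential stretch minus one, so
every pipeline stage can be checked against closed forms.  Annulus area is
conserved *exactly* (the sector-wise activation cancels between the inner
and outer radius), paths close exactly over one cycle, and an activation
amplitude that would collapse the lumen is rejected at construction.

**Signal model.**  Magnitude classes: myocardium 1.0, static chest-wall
patches 0.6, black-blood lumen 0.05, air 0.02.  Eight static square
patches (7 mm side) ring the heart at 45° spacing near the FOV edge; they
give the eddy-current fit its static tissue, and they are placed so that
the simulated ghost — a single replica of the moving-tissue signal,
circularly shifted by half the FOV along the phase-encode axis, scaled by
`ghostAmplitude`, with an independent complex gain per encoding point and
acquisition — lands on *different* patches in differently rotated
acquisitions.  Each acquisition's background-phase fit then sees its own
geometrically systematic perturbation, which is exactly the scenario
segment-wise averaging of the rotated pair is supposed to attenuate, and
the acceptance suite verifies that it does.  Coil sensitivities are smooth
low-order polynomial complex maps, deterministic from the seed.  A
`driftCmS` offset adds a spatially uniform in-plane velocity over the whole
FOV at render time, emulating a residual background-phase error; bulk
correction must (and does, to 1e−9) remove its influence on strain.

**What the phantom does not emulate** — and hence what passing tests do
not show about real data: thermal noise and coil noise correlation,
k-space effects (the ghost is injected in image space), respiratory
motion, ECG trigger jitter, through-plane motion of anatomy into the
slice, and real post-infarction mechanics (the hypokinesia/delay model
produces the dysfunctional *phenotype* — reduced strain, higher
dispersions, higher dyssynchrony — not infarct physics).  Tests passing on
the phantom certify the correctness of the computational chain and its
conventions, not in-vivo robustness.

# Numerical choices and degenerate inputs

Explicit tolerances: encode→decode round trips to < 1e−9 cm/s; wrap
flagging at 1 % below $\pi$; polygon vertices count 256; segment-boundary
ties to the lower index; delay search window ±25 % of the cycle; stretch
grid 0.80–1.25 by 0.005.  Hard errors with named causes: annulus collapse,
rank-deficient encoding moments, insufficient static region for the
polynomial order, empty myocardial mask, zero baseline chord, degenerate
(zero-perimeter) polygon, all trajectories leaving the mask, missing
required annotation inputs.  Containers are a hierarchical array tree
addressed by slash-paths (`/encoded/complex`, `/meta/venc`, ...),
serialized with R's native serialization; a missing dataset is reported by
its path.

Test problem sizes are chosen to exercise the defaults where the claims
are about the default geometry (128×128 × 70 frames for strain recovery,
tracking accuracy, delay recovery, ghost averaging) and 48–64 pixel grids
with 16–40 frames where the property under test is resolution-independent
(round trips, invariances, I/O).

# Known limitations

Strain is two-dimensional and circumferential only; through-plane motion
enters the velocity data but not the strain.  The chord approximation
under-resolves sharp circumferential strain gradients at sector borders.
Trajectory survival near the epicardial border depends on the tissue
signal outside the wall (see the tracking section).  The eddy-current
surrogate is polynomial; strongly non-polynomial background phases would
need a higher order and correspondingly more static tissue.  Temporal
alignment assumes the two acquisitions differ by a global time scaling,
not beat-to-beat shape changes.
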