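---
title: "Detecting phase singularities in simulated cardiac fibrillation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting phase singularities in simulated cardiac fibrillation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiralps)
```

## The problem

During atrial or ventricular fibrillation, electrical activation is
organized around rotors: spiral waves whose pivot — the *phase
singularity* (PS) — is a point with no defined phase around which the
neighboring phases span the full cycle from $-\pi$ to $\pi$. Locating PS
points in voltage maps matters both for mechanistic studies and for
ablation targeting, and because clinical mapping systems must do it in
near real time, the computational cost of the detector matters too.

`spiralps` implements and compares two detectors on 2D
transmembrane-voltage movies:

* the classical **Iyer–Gray line-integral criterion**: a pixel is a PS
  when the discrete line integral of the phase gradient around its eight
  neighbors is $\pm 2\pi$ (winding number $\pm 1$);
* a **location-centric criterion**: a pixel is a PS at frame $n{+}1$ when
  its own phase makes a large negative temporal jump,
  $\Delta\theta = \theta_{n+1} - \theta_n < M$ with $M = -\pi$ by
  default. No neighbor values are read, which removes the memory
  indirection that dominates the line-integral method's cost and makes
  the criterion trivially parallel and applicable on irregular meshes.

## Phase construction

Phase is obtained by time-delay embedding of the local voltage:

$$\theta(x, y, t) = \mathrm{atan2}\!\big(V(t+\tau) - \bar V,\; V(t) - \bar V\big),$$

with delay $\tau = 30$ ms by default and $\bar V(x,y)$ the per-pixel mean
of the signal over the analysis record (`compute_vmean()`). Values lie in
$(-\pi, \pi]$. Two conventions are worth making explicit:

* **Argument order.** The delayed sample is the ordinate (first `atan2`
  argument). The opposite order only mirrors the phase plane and flips
  every chirality; `compute_phase(..., delayed_first = FALSE)` selects it.
* **Degenerate pixels.** A pixel exactly flat at $\bar V$ has no defined
  angle; it is assigned phase 0 and excluded from PS candidacy rather
  than being allowed to produce arbitrary detections.

$\tau$ must be an integer multiple of the frame interval; the package
refuses to interpolate because resampling the phase plane silently
changes both detectors' inputs.

**The averaging window matters.** $\bar V$ is the origin of the phase
plane and is meant to be the mean *during fibrillation*. If a reentry
self-terminates partway through a recording and quiescent frames are
averaged in, $\bar V$ is dragged toward the resting potential, the
embedded trajectories no longer enclose the origin, and the
location-centric criterion in particular loses its signal (its negative
jumps arise when a trajectory passes close to the origin). The helper
`activity_window()` returns the interval during which the spatial voltage
range exceeds a threshold (default 25 mV) *and* new depolarization is
still occurring (the excited-pixel fraction still rising — after the last
wavefront dies, the tissue only repolarizes and that tail is excluded);
all shipped analyses restrict the record to that window before computing
$\bar V$.

## The temporal-jump criterion and what it can and cannot see

The temporal difference is deliberately **not wrapped**: wrapping into
$(-\pi,\pi]$ would make values below $-\pi$ impossible and empty the
criterion. Only negative jumps are singular — the upstroke of an action
potential produces a large *positive* jump, which is why the default
threshold is one-sided.

The criterion detects a *temporal* discontinuity of the phase function
and therefore requires the local signal structure to change: at a
perfectly motionless core pixel whose surroundings rotate rigidly, the
embedded phase advances smoothly by $-\omega\,\Delta t$ per frame
everywhere, no raw difference ever falls below $-\pi$, and the criterion
is silent. This is an intrinsic blind spot of the method for static,
non-excited cores, distinct from the line-integral criterion which sees
the spatial winding regardless of motion. The package's analytic fixture
(below) makes the blind spot reproducible: on a rigidly rotating cosine
field with a fixed core the Iyer–Gray detector pins the core in every
frame while the location-centric detector returns an empty set. On
simulated fibrillation the cores meander and the embedded trajectories of
near-core pixels repeatedly cross the phase-plane origin, which is
exactly where the temporal jumps appear; the two detectors then agree to
within a few display pixels (the package's central empirical result).

Detections report **all flagged pixels** — the line-integral method
typically marks a small cluster (often ~4 pixels) around a rotor tip, the
location-centric method one or a few — because that is what the raw
criteria produce; an optional 8-connected centroid reducer
(`reduce_clusters()`) exists but is off by default everywhere.

## Agreement metric

Pooled trajectories (all detections over the analysis window, as spatial
point sets) are compared with the symmetric Hausdorff distance
$$H(A,B) = \max\big(h(A,B),\, h(B,A)\big), \qquad
  h(A,B) = \max_{p \in A}\min_{q \in B} \lVert p - q\rVert,$$
in mm. Points are first snapped to the 0.5 mm *display* resolution (the
compute grid is 0.25 mm), mirroring how maps are read; each point moves
by at most $0.25\sqrt2$ mm under snapping, so $H$ changes by at most
$0.5\sqrt2$ mm, which the test suite asserts on random sets. An empty detection set makes
the distance undefined and is an explicit error, never `NaN`.
`compare_methods()` computes the phase once and evaluates both detectors;
`sweep_compare()` repeats the comparison across $\tau$, the threshold
$M$, the phase sampling interval, or the remodeling scenario.

## The simulator

Test inputs are generated internally by a monodomain reaction-diffusion
solver,
$$\partial_t V = -\,(I_{\mathrm{ion}} + I_{\mathrm{stim}})/C_m
  + D\,\nabla^2 V,$$
with the Courtemanche–Ramirez–Nattel (CRN) human atrial ionic model
(21 state variables), $D = 0.001\ \mathrm{cm^2/ms}$,
$C_m = 1\ \mu\mathrm{F/cm^2}$, a 0.25 mm grid and 1 ms default sampling.
The CRN implementation reproduces the published resting potential
(−81.2 mV) and an APD$_{90}$ near 300 ms, and the test suite checks the
single-cell action potential against an independent transcription of the
model integrated with `deSolve::lsoda` (resting V and APD$_{90}$ within
2%).

Remodeling scenarios are named multiplier sets on maximal conductances
(`scenario_preset()`): control; 0.3×I$_{CaL}$ (stable-rotor substrate);
0.7×I$_{Na}$; the seven-multiplier AF set (I$_{Na}$ −10%, I$_{to}$ −70%,
I$_{CaL}$ −70%, I$_{Kur}$ −50%, SR Ca$^{2+}$ leak +25%, I$_{K1}$ +100%,
I$_{NaCa,max}$ +40%); and reduced gap-junctional coupling (0.7×D,
0.3×D).

### Numerical scheme

* **Space.** Explicit 5-point Laplacian; no-flux boundaries by cell-face
  reflection, which conserves the discrete spatial mean exactly (asserted
  in a passive-diffusion test). The stability number
  $4 D \Delta t/\Delta x^2 = 0.64$ at the default settings.
* **Time.** The macro step is $\Delta t_{\max} = 0.1$ ms (diffusion and
  quiet cells); any cell whose projected voltage change over a macro step
  exceeds `dv_max_mv` (0.8 mV) is sub-stepped at
  $\Delta t_{\min} = 0.01$ ms with the diffusion contribution held fixed
  over the macro step. The effective time step therefore varies within
  [0.01, 0.1] ms *per cell*. A globally switched step was rejected
  because a propagating wavefront exists somewhere at essentially every
  instant of fibrillation, which degenerates a global rule to
  $\Delta t_{\min}$ everywhere at ~10× the cost for no accuracy gain at
  the wavefronts, where the error actually lives.
* **Gates.** The 12 voltage-dependent gates advance by Rush–Larsen
  (exact exponential relaxation toward the tabulated steady state);
  rates, steady states and the voltage-dependent current factors are
  linearly interpolated from tables on a 0.05 mV grid. Calcium-coupled
  gates and concentrations use forward Euler at the local step.
* **Fast path.** Fully repolarized cells (V < −72 mV, negligible
  previous dV/dt, no incoming diffusion or stimulus) sit at the model's
  resting steady state and skip the ionic evaluation; every 100th macro
  step forces a full sweep. The scheme is deterministic — identical
  configurations yield bit-identical movies, which a test asserts.
* **Blow-up guard.** Non-finite or |V| > 300 mV aborts with the time and
  cell index.

### Spiral initiation at desk scale

The cross-field protocol — a vertical S1 followed 300 ms later by a
horizontal S2 — initiates reentry when S2 meets the repolarization tail
of S1 inside the sheet. On a 15 cm sheet the S1 wave itself takes ~340 ms
to cross, so the 300 ms coupling lands in the vulnerable window for any
substrate. On desk-scale sheets (5–12 cm) the crossing time is far
shorter than 300 ms, and two things must be recreated through the
*conditioning drive* (the coupling interval itself being a fixed study
condition): the vulnerable window must sit inside the sheet, and the
reentrant wavelength must be short enough for the rotor to outlive its
formation transient.

* Control-class substrates (control, 0.7×I$_{Na}$, reduced-D) use a
  short S1 burst — three beats at a 330 ms cycle — before S2. Rate
  adaptation shortens the action potential enough that the refractory
  tail sits mid-sheet at S2 time and the first reentrant loops fit a
  7.5×7.5 cm sheet (5×5 cm for 0.3×D, whose conduction velocity and
  hence wavelength are smallest).
* 0.3×I$_{CaL}$ keeps two S1 beats at a 350 ms cycle but needs a
  12×12 cm sheet: its first-loop wavelength (~90 mm) does not complete a
  loop on smaller sheets — verified empirically at 5, 6, 7.5 and 10 cm —
  consistent with such substrates being studied on 15 cm domains.
* The AF remodeling set, with the shortest action potential, recovers
  everywhere within the coupling interval on short paths; it uses a
  single S1 with a longer propagation path (a larger sheet or corner
  drive) so that part of the sheet is still refractory at S2.

Stimuli are current injections of 25 pA/pF for 2 ms (about twice the
diastolic threshold of ~12 pA/pF); markedly stronger S2 pulses were
found to fire relative-refractory tissue directly and erase the very
conduction block the protocol needs. S1 is a full-height 2 mm strip on
the left edge (or a 10 mm corner block for the AF condition); S2 is the
entire bottom half. The geometry, drive and amplitudes are recorded in
movie provenance.

Analysis windows are protocol-relative (starting 50 ms after S2, up to
1 s) and activity-gated: on the smaller sheets the control-like reentries
self-terminate after roughly 0.5 s and the analysis stops with them.

## The fast surrogate

For CI-speed tests the package ships a two-variable Aliev–Panfilov
excitable medium (`surrogate_spiral()`): plane wave from the left edge,
lower half erased at 90 ms, the free end curls into a rotor that is
sustained on a 3×3 cm sheet in well under a second of compute. Defaults
($a = 0.1$, $k = 8$, $\varepsilon_0 = 0.01$, $\mu_1 = 0.2$,
$\mu_2 = 0.3$, 3 ms per model time unit) were calibrated once for a
rotor period of ~120 ms and a wavelength that fits the sheet; $u$ maps to
a pseudo-voltage $-85 + 110\,u$ mV. The surrogate reproduces the
*structure* of fibrillation maps (meandering core, wavefront geometry)
but not cardiac restitution, waveform shape, or conduction-velocity
scales, so quantitative agreement numbers from it do not transfer to the
CRN runs; it is used where a deterministic, cheap rotor is all a test
needs. The first ~250 ms contain the artificial wave-break transient and
are excluded from comparison windows.

## The analytic fixture

`analytic_spiral_movie()` renders
$V = \mathrm{offset} + \mathrm{amp}\cdot
 \cos(\mathrm{atan2}(y - y_0, x - x_0) + k\,d - \omega t)$
with an exactly known core path, giving ground truth to pixel precision.
With $\omega\tau = \pi/2$ the embedded phase reconstructs the spatial
phase field exactly, and the Iyer–Gray detector localizes the core within
one pixel in every frame (asserted). As discussed above, the
location-centric criterion is structurally blind on this fixture when the
core is static; the orbiting-core variant is used to validate trajectory
recovery for the line-integral method.

## Performance comparison

`benchmark_detectors()` times detection only (the phase movie is shared,
I/O excluded), discards a warm-up pass, and reports medians over
repeats on a monotonic clock. Only the *direction* of the comparison is
meaningful across machines and languages; on equal inputs the
location-centric pass touches each pixel once per frame pair while the
line-integral pass reads eight neighbors per interior pixel, and the
measured ratio is consistently above 1.

## Problem sizes used by the shipped analyses

The packaged acceptance analysis (`scripts/acceptance.R`) uses: control
and 0.7×D on 300×300 cells (7.5×7.5 cm) with the 3×330 ms burst drive;
0.3×D on 200×200 (5×5 cm); 0.3×I$_{CaL}$ (2×350 ms drive) and the AF
set (single S1) on 480×480 (12×12 cm); analysis windows of 0.4–0.5 s at
1 ms sampling (0.1 ms for the sampling-robustness case). These sizes
were chosen so that each substrate sustains reentry through its analysis
window, while a full run of all conditions completes in well under half
an hour on one core. The 0.7×I$_{Na}$ condition is not part of the
default analysis: with the fixed 300 ms coupling it failed to sustain
reentry on any sheet up to 7.5 cm under the drives above, and a second
12 cm condition does not fit the analysis' runtime envelope.

## Known limitations

* The solver is 2D, homogeneous and isotropic: no fiber orientation,
  fibrosis, or 3D extension; the location-centric method's selling point
  on irregular meshes is argued, not exercised, here.
* Whole-record $\bar V$ precludes streaming use; a fixed empirical origin
  or single-AP mean can be supplied via `compute_phase(vmean = ...)` but
  is not the tested default.
* Desk-scale reentry is transient for control-like substrates; pooled
  windows are correspondingly shorter than on a 15 cm sheet, which adds
  a few tenths of a mm of variability to Hausdorff distances.
* The exact PS birth sites depend on the unspecified details of the
  initiation geometry; only statistical and structural behavior is
  reproducible, and all agreement metrics are defined over pooled
  trajectories, not individual birth events.
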