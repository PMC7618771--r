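---
title: "Simulation-based optimization and quantification of DANTE-SPACE vessel wall imaging"
author: "vwisim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-based optimization and quantification of DANTE-SPACE vessel wall imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vwisim)
```

## The problem

Intracranial vessel wall imaging (VWI) tries to delineate the thin arterial
wall of the Circle of Willis against two bright neighbours: blood inside the
lumen and CSF outside. T2-weighted DANTE-SPACE attacks both at once: a DANTE
preparation — a long train of low-flip hard pulses interleaved with dephasing
gradients — attenuates *moving* spins (blood, pulsatile CSF) while static
tissue survives through stimulated-echo pathways, and a variable-flip-angle
3D turbo-spin-echo (SPACE) readout then acquires the T2-weighted image. How
well this works depends sensitively on the DANTE parameters (flip angle,
pulse count, gradient moment, interpulse time), on field strength, and on
physiological motion. `vwisim` implements the full simulation and
quantification chain: an extended-phase-graph (EPG) sequence engine with
flow, diffusion and transmit-field (B1+) effects; protocol optimization by
parameter sweeps; phase-only parallel-transmit (pTx) shim design; coil
combination in SNR units; and vessel-sharpness quantification by polar
unwrapping, boundary acutance and the RMS radial signal gradient (G_RMS).

## The EPG engine and its oracle

The engine tracks complex configuration-state amplitudes F(k) (transverse)
and Z(k) (longitudinal), indexed by the integer number of dephasing-gradient
units k wound into the magnetization pattern (`dk_per_shift` rad/mm per
unit). Four operators act on an `epg_state`:

* `epg_rf()` — the per-order unitary RF rotation (Weigel-style operator
  set, with `Fm[k]` storing conj(F(-k)) so one 3x3 matrix serves all
  orders);
* `epg_relax()` — T2 decay of transverse orders, T1 decay of longitudinal
  orders, recovery of Z(0) toward 1;
* `epg_grad_shift()` — integer shifts of the transverse ladder with the
  F+/F- crossover at order 0, Z unshifted; amplitudes beyond `max_order`
  are dropped;
* `epg_flow_diffusion()` — coherent flow phase `k * dk * v * dt` on both
  transverse and longitudinal orders (a moving cohort translates the wound
  pattern), plus diffusion damping `exp(-D kbar^2 dt)` with the standard
  transition moment `(k^2 + k + 1/3) dk^2` while the gradient is on
  (hard-gradient approximation; ramps are ignored).

Sequences are expressed as plain tabular event lists (`epg_events`), and the
same list drives two independent engines: the EPG operators above and a
brute-force Bloch oracle (`run_isochromat_events()`) that integrates
rotation matrices per isochromat over positions spread uniformly across one
dephasing period. The two share no code, so every sign and phase convention
is cross-checked; the packaged tests require agreement below 1% (static) and
2% (constant flow) on randomized DANTE+SPACE trains, and they agree to
machine precision for plug flow. Diffusion cannot be represented by a finite
deterministic isochromat ensemble and is instead verified against its closed
form.

`max_order` defaults to the total number of unit shifts over the simulated
repetitions (DANTE pulses plus two per readout interval, per TR) so nothing
is truncated while populated orders still carry signal; doubling it changes
packaged-protocol results by less than 0.1%.

## Tissues, motion, and intravoxel distributions

Relaxation, diffusion and mean-speed constants for vessel wall (VW), CSF and
blood at 3T and 7T are shipped as a plain-text preset table
(`tissue_preset_table()`). Motion is modelled at three scales:

1. **Cohort waveforms** (`make_waveform()`): one cardiac cycle, periodic,
   scaled so mean |v| matches the preset (CSF 0.367, VW 0.054, blood
   24.0 cm/s). CSF and VW use a bidirectional two-harmonic shape with zero
   net flow and at least two zero crossings per cycle; blood a strictly
   positive two-harmonic shape with a systolic peak. The literature
   waveforms these emulate are not published; only the means are. The
   cardiac period defaults to 1000 ms.
2. **Velocity sampling**: velocities are taken at interval midpoints
   (intervals of ~1 ms are short against the cardiac period).
3. **Intravoxel distributions**: blood is laminar — velocity scales uniform
   on [0, 2] x mean, integrated by an 8-point midpoint rule; CSF and VW are
   plug flow with a 10% Gaussian spread (5-node Gauss-Hermite). Complex
   echo amplitudes are averaged across the quadrature, so intravoxel
   dephasing is represented.

## Protocols and the VFA readout

`protocol()` bundles DANTE, SPACE, optional spatial-saturation and B1
settings; four presets ship as editable INI files. The 7T presets use
TR/TE_eq = 2620/165 ms, echo spacing 4.62 ms, ETL 74; the 3T preset TR
2.10 s, echo spacing 5.0 ms (a placeholder for the unpublished minimum), and
ETL 59 — scan time is matrix-fixed, so matched scan time implies
ETL ~ 74 x 2.10/2.62. The 3T preset adds a 70 mm saturation slab between
DANTE and readout, modelled as complete nulling of in-band cohorts
(inflowing blood) with T1 recovery afterwards; no slab profile. The
literature 7T preset ships with its DANTE values unset, because they were
never published.

DANTE dephasing gradients are set to the per-axis hardware maxima of the
scanners the protocols target (80 mT/m at 3T, 70 mT/m at 7T) with a 0.5 ms
on-time: at maximum slew a full-amplitude trapezoid inside a 1 ms interpulse
interval carries almost exactly the moment of a 0.5 ms rectangle, so this is
the attainable per-interval moment of a "scanner-limited" dephasing lobe.
The interpulse time defaults to 1.0 ms, typical of DANTE implementations.

The SPACE refocusing train is generated by `vfa_train()`: the prescribed
echo evolution falls from the first echo (default start flip 120 deg) with a
fast transition constant (40 ms) onto a plateau at 40% of the first echo.
A strictly constant plateau is infeasible for finite T1/T2 — no refocusing
train can hold echo amplitudes above the pseudo-steady-state decay — so the
plateau decays at the relaxation-limited rate
sin^2(a/2)/T2 + cos^2(a/2)/T1 evaluated at a nominal 60 deg plateau flip,
the slowest evolution a train can sustain. Each flip is solved against the
actual EPG forward model by root-finding on the rising branch (echo
amplitude is not monotone in flip once stimulated pathways contribute), so
the achieved evolution matches the prescription exactly for the reference
tissue and the smaller-flip, lower-SAR branch is returned. An explicit flip
list can be supplied instead.

## Full-protocol simulation

`simulate_protocol()` runs at least two full repetitions from thermal
equilibrium — DANTE, optional saturation, readout, recovery — and reports
the echo magnitude at the k-space-centre echo, `round(TE_eq / esp)` (echo 36
of 74 at 7T, 33 of 59 at 3T, i.e. linear reordering), of the final TR, so
magnetization history from the previous repetition is included; second- and
third-TR signals agree within 1% for the packaged protocols under
constant-velocity flow. During DANTE, blood experiences the
suppression-site (neck) B1 scale and CSF/VW the imaging-site scale; the
readout uses the imaging-site scale for all tissues.

`csf_reduction()` compares the pulsatile-CSF signal with and without the
DANTE module (everything else identical). Because an ungated acquisition
samples arbitrary cardiac phases at DANTE onset, the signals are averaged
over eight evenly spaced cardiac start phases before the ratio is taken.
The reduction is extremely sensitive to inputs that were never published:
the waveform shape (time spent near the velocity zero-crossings, where CSF
is transiently static and survives through stimulated echoes), the
interpulse time and the gradient moment — per-interval dephasing at the CSF
mean speed is of order 0.01-0.04 rad, near the static stopband of a
150-250-pulse train. Under the conditions above the package computes
reductions of roughly 74% (150 pulses x 8 deg) and 81% (250 x 12 deg) at
3T; both engines agree on these numbers to machine precision, so they are a
property of the chosen physiological parameterization, not of the
implementation.

## Optimization

`sweep_parameter()` sweeps one DANTE parameter at a time with the others
fixed (the joint 4-D search is deliberately out of scope for runtime), for
pulsating and stationary vessel walls. The selection objective
(`sweep_objective()`) maximizes the pulsating VW-CSF contrast subject to a
blood-signal ceiling (default 0.02 of M0) and at most 5% loss of
stationary-VW contrast; `select_optimum()` picks per-parameter optima with
ties broken toward the lower SAR proxy (`n * flip^2`), then the shorter
preparation. `optimize_tr()` maximizes signal/sqrt(TR) on a TR grid, ties
toward the shorter TR. Both are validated against exhaustive-search oracles
on planted-optimum grids. Under this package's physiological
parameterization the swept 7T objective is maximal at weaker DANTE
preparation than the published 170-pulse/12-deg setting — with
scanner-limit gradient moments, simulated CSF is already well suppressed at
low flip angles, so the VW-signal cost of stronger preparation dominates;
this is the same parameterization sensitivity discussed above.

## RF shim design

`design_shim()` finds phase-only (unit-amplitude) per-channel phases
maximizing mean neck |B1+| subject to the Circle-of-Willis mean not
dropping below its CP-mode value (a constraint, not a weighted sum, because
the design goal is "more neck B1+ without losing CoW B1+"). Multi-start
penalized Nelder-Mead (32 starts: CP plus random draws, seed-exposed), with
raw starts kept as candidates so CP is never beaten by infeasibility, and a
slightly raised interior floor so penalized optima land feasible-side;
`universal_shim()` optimizes the across-subject mean with the constraint
holding per subject, using the mean of squared violations so duplicated
subjects change nothing. On 4-channel synthetic maps the result matches an
exhaustive 10-degree phase grid within 1%. `make_b1_maps()` builds the
synthetic multi-channel maps: channel phases agree moderately in the head
and are spread in the neck, so CP-mode cancels there by a designed dropoff
(default 0.5) that a shim can recover. Real in vivo map databases are
outside the package; the published 32% blood-suppression improvement is
only checkable against such a database, so the synthetic criterion is the
qualitative one (neck gain > 1 at CoW ratio >= 1).

## SNR-units reconstruction

`snr_combine()` evaluates, per voxel,
`sqrt(2/R) |S^H N^-1 I| / sqrt(S^H N^-1 S)` from channel images I,
sensitivities S and the per-complex-sample noise covariance N. Convention:
the combined complex estimate has unit variance in each of its real and
imaginary parts for noise-only input — one SNR unit is the per-component
noise standard deviation — enforced by a pseudo-replica test over more than
a million samples (within 2%). The combination equals a whitened
matched-filter oracle to machine precision and is invariant to global
sensitivity scaling. Parallel-imaging unaliasing, spike correction and
sensitivity self-calibration are established external algorithms and are
not reimplemented: callers supply sensitivities and unaliased channel data,
and undersampling enters only through sqrt(2/R). `fermi_filter()` applies
the radial window 1/(1 + exp((r - r0)/w)) with w = 8 k-space samples and
r0 = 0.98 x Nyquist (the cutoff is not published); `zero_pad_recon()`
zero-pads centred k-space (e.g. 2x: 0.47 mm acquired to 0.23 mm
reconstructed) with normalization fixed to the acquired grid so pixel
values are padding-invariant.

## Vessel phantoms and acutance quantification

`make_phantom()` builds an annular vessel cross-section in SNR units:
lumen at the blood signal, wall at the VW signal, surround alternating
CSF/brain-tissue per 60-degree sector (outer wall contrast in vivo is
wall-to-CSF in some directions, wall-to-tissue in others). The
piecewise-constant scene is convolved with a Gaussian PSF and point-sampled
at pixel centres; the default FWHM is 1.2 x the acquired 0.47 mm pixel
(0.56 mm) — zero-pad interpolation to the 0.23 mm reconstruction grid adds
no resolution, so a sharper PSF would be unphysical. Signal fractions map
to SNR units via `snr_scale` (default 100) and white noise is added
(seeded).

`polar_unwrap()` samples 90 radial directions clockwise from the vertical
by bilinear interpolation at 0.05 mm radial steps. `find_boundaries()`
differentiates each profile radially and, around user-supplied seed radii
(CSV files replace interactive clicking so runs are reproducible), selects
the gradient extremum of the appropriate sign *nearest the seed* — so a
displaced seed still locks onto the same edge — then refines to sub-sample
precision with the gradient centroid of the contiguous above-half-peak run
(the bilinear gradient is piecewise constant within a pixel span, so a bare
argmax is biased to the start of a plateau; the centroid is tie-free,
offset-invariant and scale-equivariant). Directions without a usable
extremum are flagged and excluded. Note that the gradient extremum of a
blurred annulus sits slightly off the pre-blur disc radius (edge-overlap
tilt); the recovery tests therefore compare against the analytic extremum
of the known blurred profile.

`boundary_acutance()` reports, per direction and boundary, the maximum
contrast among samples in a 0.3 mm window centred on the boundary divided
by the window length (CNR/mm; the published description says only "scaled
to CNR/mm units" — this normalization is applied uniformly, so protocol
comparisons are unaffected by the choice). `g_rms()` implements
G_RMS = sqrt(sum(G_i^2)/n) over the radial differences G_i between the
boundaries, reported per mm; the unit-step value ([1, 3, 7] -> sqrt(10)) is
exposed as `g_rms_profile()`. 60-degree sub-segment means support
segment-wise correlation plots, and `compare_protocols()` runs the paired
one-tailed t-test (null: no improvement; significance 0.05) with mean
ratio and 95% spread, flagging zero-variance differences as degenerate.

## What the synthetic data do and do not show

The generators make every module testable without downloads, and they are
first-class, seeded, tested code. They emulate: pulsatile bidirectional CSF
with the published mean speed; laminar arterial blood; CP-mode neck dropoff
of a multi-channel head coil; annular vessels blurred by a
reconstruction-scale PSF; correlated multi-coil noise. They do not emulate:
the true (unpublished) third-ventricle CSF waveform shape, real B1+ field
distributions, anatomically realistic vessel geometry, partial-volume and
motion artifacts, or scanner-specific SAR. Tests passing on synthetic data
therefore validate the machinery and its contracts — operator correctness,
oracle equivalence, metric definitions, optimizer logic — but reproduce
published in vivo effect sizes only to the extent that the emulated
physiology matches the real one; the CSF-suppression percentages are the
clearest example of a result that is implementation-exact but
parameterization-sensitive.

## Numerical choices and limitations

Problem sizes used throughout: two simulated repetitions per signal
(steady-state checked against three); eight cardiac phases per CSF
reduction; 5-point Gauss-Hermite / 8-point laminar quadrature; sweep grids
of five values per parameter in the packaged checks; 64-128 pixel phantoms;
10 noise seeds for parameter recovery. Degenerate inputs are handled
explicitly: zero-pulse DANTE is the identity, zero-contrast images flag all
directions, zero-variance paired differences are reported as degenerate
rather than fed to a t-test, and all-zero-sensitivity voxels are zeroed and
flagged. Known limitations: the readout's per-interval dephasing reuses the
DANTE gradient unit (one shared configuration ladder), slab and slice
profiles are not modelled, gradient ramps are ignored, and B1+ enters as
scalar per-site scales during simulation rather than full maps.
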