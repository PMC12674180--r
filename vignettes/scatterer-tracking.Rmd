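---
title: "Continuous scatterer tracking for plane-wave flow simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous scatterer tracking for plane-wave flow simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsetrack)
```

## The problem

Ultrasound simulations of blood flow need a scattering medium whose motion
follows a realistic velocity field. For simple geometries (a rotating disk,
parabolic tube flow) particle positions can be written down analytically.
For complex pulsatile flow — reverse, rotational, out-of-plane, helical —
the velocity history comes from a computational flow model on a mesh, and
the scatterers must be advected through it. The hard part is doing this
*continuously* over many cardiac cycles: scatterers must enter and leave
the domain without periodic global reseeding, because reseeding breaks the
slow-time correlation of the speckle and makes continuous high-frame-rate
acquisitions impossible to emulate.

`pulsetrack` implements a tracking engine with three pieces that make the
concentration stable without reseeding:

1. **Refresh zones** — boxes at every flow inlet and outlet whose
   scatterers are deleted and randomly re-drawn before each time step.
   They act as particle sources and sinks; nothing inside the imaging
   region is ever touched, so speckle stays continuous.
2. **A stagnation threshold** — scatterers that are both slower than a
   velocity threshold *and* closer than a distance threshold to the edge
   of the flow are removed. This prunes particles that strand just outside
   the flow or pile up in near-wall dead zones, while leaving momentarily
   slow particles in the core of a pulsatile flow alone.
3. **Full-volume tracking with an elevation slice** — the whole 3-D
   scatterer population is advected every step, but only particles within
   the elevation slice of the imaging plane are passed to the ultrasound
   simulator. Out-of-plane motion therefore moves scatterers in and out of
   the image exactly as in vivo.

A bespoke plane-wave point-target simulator, a delay-and-sum beamformer,
lag-one-autocorrelation colour Doppler, and a multi-angle least-squares
vector-flow estimator close the loop, so transmit schemes and velocity
estimators can be exercised end to end on known ground truth.

## The velocity-field container

Flow models arrive on non-uniform meshes. `regrid_fdm()` aligns each frame
onto a uniform node-centred grid (default spacing d = 0.1 mm) by scattered
-data linear interpolation. Two details matter:

* **Null-point padding.** Before interpolating, every uniform-grid node
  farther than `factor * d` from the nearest mesh point is declared a
  *null* node and appended to the interpolation sources with zero
  velocity. This makes the interpolated field decay to zero at the flow
  boundary instead of extrapolating wildly. The default factor is 1.5
  (threshold 3d/2). We note the geometric description sometimes attached
  to this value — the half-diagonal of a grid cell — is actually
  `sqrt(3)/2 * d ~ 0.87 d`; the package keeps 1.5 as the default and the
  factor configurable, taking no position on which was intended.
* **The interpolant.** The regridder is a local linear least-squares fit
  over the `k` nearest sources (default 12). Like a Delaunay-based linear
  interpolant it reproduces affine fields exactly — which is the testable
  contract — and it is robust on anisotropic point distributions. Nearest
  -neighbour queries use an exact cell-list index; a brute-force scan is
  the test oracle.

Node order is x-fastest; velocities are stored as an
(n_nodes x 3 x n_frames) array. Units are mm, mm/s and ms throughout.
Advancing time by one full cycle reproduces the field exactly; simulation
time is rolled over modulo the cycle period so any number of cardiac
cycles can be simulated from a single-cycle field.

## The synthetic flow generator

`make_field()` provides analytic, periodic fields so every downstream
stage is testable without external data: uniform translation, solid-body
rotation, a waveform-modulated Poiseuille pipe, and a helical U-bend tube.
`default_aorta_like_spec()` mimics the cadence and dynamic range of a
murine aortic flow model: 100 ms cycle sampled every 2 ms on a 0.1 mm
grid, ~500 mm/s peak speed, a diastolic trough near zero, and a brief
reverse-flow lobe, inside a bent tube with a superposed helical swirl.

Deliberate simplifications, and what they imply:

* Pulsatility is waveform-modulated Poiseuille, not a Womersley solution.
  The artifact tests tracking and estimation, not pulsatile fluid
  mechanics; an analytic profile gives exact ground truth at every point.
* The pipe generator has an optional `radial_drift` term (outward radial
  speed as a fraction of peak). Real complex flow continually transports
  particles across streamlines into the near-wall low-velocity shell;
  pure Poiseuille has no such transport, so this term is the controlled
  stand-in used to exercise the stagnation machinery. It makes the field
  weakly divergent by construction — it is a stress input, not a physical
  flow model.
* Passing synthetic-field tests shows the machinery is correct under
  known kinematics; it does not certify behaviour on any particular
  FSI/CFD output, where mesh resolution and wall motion add effects the
  generator does not emulate.

The blood rheology of the source flow model is recorded via the
Carreau–Yasuda apparent-viscosity law (`carreau_yasuda_viscosity()`),
with zero-/infinite-shear limits 11 and 2 cP, power-law index 0.71,
transition parameter 0.2 and relaxation time 1.5 — the relaxation time is
printed without units in the source table and is taken as seconds here.
The viscosity model documents the provenance of such fields; the tracker
itself treats scatterers as massless tracers and never evaluates it.

## Tracking: parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| concentration | 0.25 | pts per wavelength cubed | 10.6 scatterers per 4 x 5.3 x 2 wavelength resolution cell; at least 10 per cell are needed for fully developed speckle (floor: 0.23) |
| dt | 1/PRF | ms | one advection per transmit; `substeps` subdivides it when the PRF is low |
| stagnation v_threshold | 1 | mm/s | small enough to spare momentarily slow core particles in diastole |
| stagnation d_threshold | 2 d | mm | restricts removal to the edge of the flow; large search distances would remove core particles during diastole |
| elevation_half_width | 0.25 | mm | half of the ~0.53 mm elevation cell; the printed one-sided form "y < 0.25 mm" is implemented as \|y\| < 0.25 about the imaging plane, flagged as an interpretation |

Per step the engine executes: sample velocity (trilinear in space, linear
in time, rollover modulo the cycle) -> explicit-Euler advance -> purge
refresh zones and bounding-box escapees -> remove stagnant scatterers ->
slice the elevation for the simulator -> repopulate the zones. The
stagnation test reuses the advecting velocity of the step rather than
re-interpolating at the new position; at tracking time steps (<= 0.5 ms)
the difference is far below the 1 mm/s threshold granularity.

Numerical choices:

* **Integrator.** Explicit Euler, deliberately: it is the update rule the
  procedure defines, and its error is controlled by the time step (the
  `substeps` option implements the higher-rate intermediate stepping
  suggested for low-PRF runs). On solid-body rotation the radius drift is
  bounded by (omega dt)^2/2 per step, verified in the tests.
* **Zone membership** uses closed boxes (boundary points belong to the
  zone) for deterministic tie-breaking.
* **Repopulation count** is the deterministic `round(concentration x zone
  flow volume)`, not a Poisson draw — reproducibility is worth more than
  the negligible variance contribution at realistic concentrations. The
  zone flow volume is the exact overlap of the zone box with the union of
  grid-cell cubes centred on flow nodes; this matches the acceptance
  region of the rejection sampler, so a repopulated zone holds exactly
  the configured concentration (node counting alone would overfill the
  zone by the clipped boundary cells — about 20 % for a 0.5 mm zone).
* **Scatterers that leave the grid bounding box** are removed at the next
  purge; an unstated but necessary companion to the zone/stagnation
  rules.
* **Randomness.** The tracker owns one sequential RNG stream seeded from
  `rng_seed` (seeding, amplitudes and repopulation draw from it in a
  fixed order), so runs are bit-reproducible from a single integer; the
  previous global RNG state is restored afterwards.

If the refresh zones are large enough — deeper along the flow axis than
the largest per-step displacement — a fully seeded pipe holds its probe
concentration: over four cycles the test suite observes a probe mean
within a few percent of the 0.25 seeding with a standard deviation of
about 0.02, and a near-zero linear drift. Undersized zones cannot
resupply the systolic flux and a void advects downstream within two
cycles; both behaviours are asserted in `test-acceptance.R`.

## Ultrasound chain

The simulator is a minimal linear point-target model: per transmit, each
scatterer contributes a Gaussian-enveloped sinusoid delayed by the
plane-wave transmit time (z cos(theta) + x sin(theta))/c plus the exact
element distance on receive (the elevation offset lengthens the path; no
elevation weighting, no attenuation, no directivity, no noise). Any
point-target simulator could be slotted in instead — the tracking engine
is not tied to this one. Defaults: f0 = 15 MHz, angles (-10, 0, 10)
degrees, PRF 30 kHz (10 kHz compounded), c = 1540 m/s configurable (the
25.5 cm/s aliasing velocity often quoted for this configuration back-
solves to c = 1530 m/s; both are representable). The pulse's -6 dB
fractional bandwidth defaults to 0.53, i.e. a 14–22 MHz passband at 15
MHz. Element count and pitch (128, 0.1 mm) are configuration entries, not
claims about a specific probe.

Beamforming is standard IQ delay-and-sum: mix-down, zero-phase low-pass,
linear complex interpolation at the two-way delay with phase rotation at
f0, constant-F-number aperture (default F# 2, never narrower than one
element), optional Hann receive apodization, coherent compounding across
angles with per-angle images retained. Colour Doppler uses a zero-phase
order-4 Butterworth high-pass along slow time (cutoff 0.1 of Nyquist) and
the Kasai lag-one autocorrelation estimator in sliding windows (64
samples, shift 4 by default; zero-padding to 256 for spectrograms). The
wall filter is applied with steady-state initial conditions and odd
reflection padding, so a constant input filters to (numerical) zero with
no edge transient; estimation windows additionally skip an `edge_guard`
(default `ceiling(0.6 / cutoff)` samples, auto-shortened on short
ensembles) at each end of the filtered series, because windows that
overlap the filter's edge ring carry a few-percent phase bias on short
slow-time records.

Vector flow inverts, per pixel and window, the multi-angle forward model

    dphi_i = (2 pi f0) / (c PRF_a) * (Vz (1 + cos theta_i) + Vx sin theta_i)

by unweighted least squares over the steering angles (QR; exact on
consistent phases), then gates pixels whose filtered-IQ power is below a
threshold (default -30 dB re max) to exactly zero. The model assumes a
steered transmit and broadside receive; the sign convention of the output
follows the image axes (Vx right, Vz down), whereas the colour-Doppler
map is positive toward the transducer.

### Known estimator behaviour (documented, not hidden)

* **Broadband migration bias.** On beamformed speckle the lag-one phase
  rate is a few percent below the nominal 2 k v: as scatterers migrate
  through the range gate, the envelope re-weights aperture contributions
  whose residual phases differ. The deficit grows roughly with the square
  of the fractional bandwidth (~1 % at 0.3, ~3.5 % at 0.6 with a flat
  aperture) and is part of why estimates recover within, rather than
  exactly at, the programmed velocities.
* **Near-horizontal flow.** As flow tends to horizontal the per-angle
  Doppler frequencies fall toward the wall-filter cutoff; the filter then
  eats the slow side of the (transit-broadened) spectrum asymmetrically
  and the lateral estimate degrades sharply — at 20 degrees from
  horizontal and moderate speeds the lateral component can be tens of
  percent low. At speeds near 0.8 of the aliasing velocity all per-angle
  components clear the passband and both components recover within 10 %
  of the speed; the acceptance chain demonstrates exactly this and the
  Hann receive apodization is used there because the wider, cleaner
  mainlobe reduces transit broadening.

## Problem sizes

The test and acceptance runs use desk-scale problems chosen to exercise
every mechanism: a 6 mm x 1 mm-radius pipe (12–13 k flow nodes, ~4,700
tracked scatterers) for four 100 ms cycles at dt = 0.5 ms; the helical
aorta-like field (12.6 k flow nodes) for shorter property checks; and
126-transmit (42-frame) ultrasound sequences of ~1,000-scatterer clouds
on 121 x 41-pixel grids. These sizes reproduce the qualitative regimes of
full-scale runs (stable concentration, void propagation, estimator
recovery) with runtimes of seconds to a couple of minutes per experiment.

## Limitations

* The ultrasound model omits diffraction, elevation focusing, attenuation
  and noise; contrasts and point-spread details will differ from a full
  spatial-impulse-response simulator, though the tracking engine is
  agnostic to which simulator consumes its scatterer stream.
* Scatterers are massless, non-interacting tracers; no inertia, no
  acoustic radiation force.
* The synthetic fields are kinematic stand-ins. Conclusions about a real
  vessel require regridding that vessel's own flow model, which this
  package ingests but does not produce.
* Reading solver-native mesh formats (VTK etc.) is out of scope; the
  `fdm_series()` constructor takes plain point/velocity arrays.
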