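---
title: "Sound-evoked steady streaming in a two-chamber cochlea model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sound-evoked steady streaming in a two-chamber cochlea model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(otostream)
```

## The problem

Drugs against sensorineural hearing loss must reach hair cells deep in the
cochlea, but the cochlea can only be accessed at its basal end and passive
diffusion along its 10-20 mm length is far too slow.  Sound itself offers a
pump: the travelling wave that a tone evokes on the basilar membrane drives
an oscillatory flow in the two fluid chambers, and that oscillation
rectifies, at second order, into a *steady streaming* flow.  A single tone
streams only near its characteristic place; a comb of tones whose places
are spaced by a few hundred micrometres merges the per-tone vortices into a
"streaming channel" that transports particles millimetres along the
membrane.  `otostream` simulates this mechanism end to end: membrane wave
(WKB) -> oscillatory Stokes flow -> time-averaged Lagrangian mean ->
finite-mass particle transport and transport-time prediction.

## The membrane model

The transmembrane pressure phasor obeys the transmission-line equation
$\tilde p'' = 2 i \omega \rho_0 \tilde p / (Z h)$ with the local strip
impedance
$$Z(x) = \left[\, i\omega m(x) + \xi - i K(x)/\omega \,\right] / A ,$$
where $m$ and $K$ follow exponential profiles fitted to gerbil
measurements ($m$: 32 -> 65 ng and $K$: 1 -> 0.03 N/m over 7 mm; strip
area $A$ = 8 um x 186 um).  The WKB solution has local wavenumber
$k = \sqrt{2\omega\rho_0/(i Z h)}$ (negative-imaginary branch) and
velocity $\tilde V = V_0 (Z_0/Z)^{3/4} e^{-i\int_0^x k\,dx'}$.

Two length-scale conventions circulate for these profiles; fitting the
measured endpoints gives $l_K \approx 2.0$ mm, $l_m \approx 9.9$ mm and
hence the tonotopic map constant
$2/(1/l_K + 1/l_m) \approx 3.3$ mm per log-frequency, which we adopt.

The damping $\xi$ is spatially constant but level-dependent
(60/80/100 dB SPL -> 10/500/2000 nN s/m), a lumped stand-in for the active
process's compressive nonlinearity; between table levels $\log\xi$ is
interpolated linearly in SPL, outside it is clamped with a warning.  In
multi-tone stimuli each tone carries the damping of its own level; two-tone
suppression is outside the model, which is why combs with place spacing at
or below 100 um are refused.

### Which wave drives the fluid: the "active" carrier

With the parameters above, the *passive* WKB wave at 20 kHz and 80 dB
($\xi$ = 500 nN s/m) accumulates so much decay $e^{\int \mathrm{Im}\,k\,dx}$
on its way to the resonance place that its magnitude falls monotonically
from the base: the amplitude growth $(Z_0/Z)^{3/4}$ (a factor ~4.7) loses
to the accumulated attenuation (a factor ~20).  A wave that peaks at the
characteristic place at these levels - the observed behaviour of real
cochleae, where the active process feeds energy into the travelling wave -
requires the propagation losses to be offset basal to the place.  The
package therefore offers two drive variants in `as_membrane_motion()`:

* `"active"` (default): the amplitude follows the WKB envelope
  $V_0 |Z_0/Z|^{3/4}$ up to the characteristic place (argmin $|Z|$) and
  the full evanescent decay beyond it;
* `"attenuated"`: the verbatim passive solution.

The `"active"` variant reproduces the expected travelling-wave shape
(growth to a peak at the place, sharp apical cut-off) and streaming
magnitudes of a few hundred nm/s at 20 kHz / 80 dB, consistent with prior
estimates for comparable configurations; the
`"attenuated"` variant yields ~30x weaker streaming displaced toward the
base.  `characteristic_place()` accordingly defines the peak as the
envelope maximum, which coincides with the undamped resonance condition
$\omega^2 = K/m$ at every calibrated damping (1.13 mm for 20 kHz).

Amplitude convention: the analytic module writes physical signals as
$\tilde z e^{i\omega t} + \mathrm{c.c.}$ with $p_0 = \sqrt 2 \times$ RMS
(so 80 dB SPL -> $p_0$ = 0.283 Pa and a physical peak pressure of
$2 p_0$); the flow solvers use $\mathrm{Re}[z e^{i\omega t}]$ phasors, and
`as_membrane_motion()` doubles the phasor when crossing that interface.

### A known limitation: the 60-dB damping value

The calibrated $\xi$ = 10 nN s/m at 60 dB implies a resonance quality
$\sqrt{Km}/\xi \approx 570$: a response peak only ~7 um wide and ~30x
taller (per unit pressure) than the 80-dB peak.  Measured basilar-membrane
tuning is far broader (quality of order 10), and a linear model is in any
case invalid inside so narrow a nonlinear peak region.  The consequence,
visible in the acceptance report, is that streaming near the place does
*not* grow monotonically across 60/80/100 dB in this model: the 60-dB
sliver streams about as strongly as the 80-dB peak, and the log-log
pressure exponent fitted across the three calibrated levels comes out
near 0.5 instead of the ~1.3 expected from a mildly compressive map.  We
deliberately do not re-fit $\xi$ (the table is part of the model
definition); the exponent is reported as computed.  For the same reason
the *shape* of the normalized streaming profile at the place varies
between table levels, although at fixed damping it is exactly
level-independent (pure quadratic scaling).

## The flow model

**Oscillatory (first order).**  The Reynolds number is tiny while the
Womersley number is large, so the chamber flow obeys the unsteady Stokes
equations; for a single harmonic,
$i\omega\hat u = -\nabla\hat p/\rho_0 + \nu\nabla^2\hat u$,
$\nabla\cdot\hat u = 0$.  The membrane enters as a transpiration boundary
condition $\hat v = \hat V(x)$ on both faces of the *mean* (flat) membrane
line - displacements (nm-um) are minute against the 0.5 mm chamber height
- with no tangential slip; all outer walls are rigid (the oval and round
windows need not be modelled because the membrane motion is prescribed).
The chambers connect through the helicotrema, whose length is not reported
for the gerbil; we default to 0.5 mm (configurable) and note that the full
oscillatory volume flux passes through it.

The discretization is a marker-and-cell staggered grid: uniform spacing in
x (20 um by default, 50 um "coarse", 11.2 um "fine"), geometric vertical
refinement toward the membrane so at least three cells sit inside the
Stokes layer $\delta_\nu = \sqrt{2\nu/\omega}$ (4 um at 20 kHz), and a
sparse direct solve of the complex saddle-point system with the pressure
pinned in one cell.  Discrete continuity holds to solver precision
(`flux_audit()`), the time-averaged power input through the membrane
matches the viscous dissipation to well under 1% (`energy_audit()`), and
probe values change by under 2% on refinement.

**Steady (second order).**  Averaging the quadratic terms over a cycle
leaves three ingredients, all derived from the complex convective product
$C = (\hat u^*\!\cdot\!\nabla)\hat u$:

* Reynolds-stress forcing $F = -(\rho_0/2)\,\mathrm{Re}\,C$ of a *steady*
  Stokes problem (the streaming Reynolds number is tiny, so the mean flow
  does not advect itself);
* the boundary slip $\bar u(0) = -\tfrac12\mathrm{Re}[\hat\xi_{bm}^*
  \partial_y \hat u]$ from transferring no-slip on the moving membrane to
  the mean line (the sign follows from the Taylor expansion and is
  confirmed by the vortex orientation; the normal component vanishes by
  continuity), evaluated with one-sided second-order stencils;
* the Stokes drift $u_{sd} = -\mathrm{Im}\,C/(2\omega)$, whose sign and
  conjugation convention are pinned by the closed-form progressive-wave
  result $U^2 k/(2\omega)$ and verified against brute-force trajectory
  averaging in the test suite.

The primary observable is the Lagrangian mean
$u_{ss} = \bar u + u_{sd}$ - the transport velocity of tracers.  Distinct
frequencies contribute additively (cross terms average to zero), so a comb
field is the sum of per-tone solves; duplicate frequencies are refused.
In this perturbative formulation the streaming is *exactly* quadratic in
the stimulus amplitude, which renders the amplitude-scaling trick used by
time-domain solvers (scale up x300, scale the streaming back by 300^2)
unnecessary - it survives as a property test.

```{r pure-tone, eval = FALSE}
props <- membrane_properties()
geom <- cochlea_geometry() # 7 mm x 2 x 0.5 mm, dx = 20 um
sf <- solve_streaming(tone(20e3, spl = 80), props, geom)
glance(sf) # max |u_ss| ~ 3.5e-7 m/s near the 1.1 mm place
autoplot(sf)
```

## Particle transport

Drug carriers are modelled as 200 nm neutrally buoyant spheres with Stokes
drag; their relaxation time (~2.2 ns) is so far below the acoustic period
that the drag is integrated exactly over each step (exponential
integrator, midpoint sampling of the carrier flow) - an explicit scheme at
these stiffness ratios would require nanosecond steps.  Wall and membrane
impacts reflect the normal velocity with restitution 0.95 and remove a
friction fraction 10^-3 of the tangential velocity.  Finite-mass and
passive trajectories agree to well below 0.1% of the path length
(Stokes number $\omega\tau_p \ll 1$), which justifies the default fast
mode: advection in the steady Lagrangian mean field only, with the
displacement per step capped at half a cell.  `transport_time()`
integrates $\int dx/u_{ss}$ along the near-membrane channel lane and
reports unreachable targets with the blocking station.

For the 10-tone, $\delta$ = 330 um comb at 80 dB (anchored so the highest
frequency peaks 0.25 mm from the base; the published experiments use 10
superposed frequencies), the package produces the expected transport
picture: a connected apex-ward channel within ~50 um of both membrane
faces spanning the 0.25-3.2 mm place range at 150-700 nm/s, vertical
inflow toward the membrane at the basal edge of the global eddy, and
basal particles captured into the channel and carried millimetres apically
within hours.  The predicted 0.25 -> 3 mm transport time along the lane is
about 2 h; the corresponding published figure ("around 5 h") is itself
inconsistent with the speed range quoted beside it (1-3 um/s implies tens
of minutes), so it is reported but not used as a reference value.

## The time-domain oracle

An independent check of the whole second-order machinery: a small
time-domain incompressible Navier-Stokes solver (theta-scheme viscous
terms with theta = 0.5 by default - the first-order implicit-Euler choice
of typical transient solvers is available but its amplitude error at
affordable steps-per-cycle is larger than the effect being measured -
Adams-Bashforth-2 explicit advection, incremental pressure projection,
same staggered grid) integrates the genuine oscillating flow with the
membrane transpiration $V(x,t) = \sum_j \mathrm{Re}[\hat V_j e^{i\omega_j t}]$
and tracks passive tracers; their per-cycle drift after a transient is the
Lagrangian mean by construction, with no perturbation theory involved.

Validation runs use a deliberately rescaled configuration - 50 Hz Gaussian
travelling wave, kinematic viscosity 10^-4 m^2/s, 4 x 1.6 mm domain on a
61 x 40 grid - chosen so the outer mean flow establishes within a fraction
of a cycle ($h^2/\nu \approx 6$ ms against a 20 ms period); at cochlear
parameters the establishment time ($h^2/\nu \approx 4$ min) exceeds any
affordable integration, which is also why the frequency-domain
formulation, not the oracle, produces all headline numbers.  At 96 steps
per cycle and 14 cycles the tracer drift matches the frequency-domain
Lagrangian mean within 10% at all probes (aggregate ~6%), for a
single tone and for a genuinely two-frequency run against the superposed
prediction; drift scales by 300^2 +- 2% when the drive is scaled by 300.
Because the oracle keeps its membrane flat, these comparisons switch the
moving-boundary slip term off; the slip term is therefore validated only
through its analytic derivation and the vortex structure, a stated
limitation.

## Numerical choices and degenerate inputs

* WKB grid: refined until spacing $\le \lambda/20$ locally; cumulative
  trapezoidal phase integral; nodes with self-consistency ratio
  $|\hat p'/\hat p|/|k| > 0.3$ trigger a warning.
* Geometry: membrane end snapped to a grid face; helicotrema must span at
  least two cells; geometries that cannot resolve the Stokes layer at the
  requested frequency are refused at solve time.
* Pressure nullspace pinned in the top basal corner cell; the discarded
  continuity row is redundant because the boundary fluxes balance
  identically.
* Oracle time step: at least 10 steps per cycle of the highest frequency
  (64-96 in validation runs); the realized Courant number is tracked and
  capped below 1.
* Particle seeding: cell-centred uniform block per chamber, optional
  jitter under a seed; ensembles are bit-reproducible and
  order-independent.
* Problem sizes: production streaming runs use the 350 x 66 default grid
  (~23k cells, ~8 s per tone); unit tests run on 40 x 48 to 140 x 60
  grids; the oracle on 61 x 40.

## What the synthetic validation cases do and do not show

The Gaussian-envelope travelling waves used in the solver tests and oracle
comparisons exercise every term of the streaming formulation, but they are
smooth, single-scale fields; they do not probe the sharp apical cut-off of
a real travelling wave, 3-D and coiled geometry, compliant windows,
longitudinal membrane motion, two-tone suppression, Brownian motion of
200 nm particles, or perilymph/endolymph differences - all outside this
model.  Passing tests show the equations above are solved correctly and
consistently across two independent formulations, not that the simplified
cochlea is a complete description of the organ.
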