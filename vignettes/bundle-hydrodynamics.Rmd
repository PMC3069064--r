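---
title: "Hydrodynamics of the inner hair cell stereocilia bundle: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrodynamics of the inner hair cell stereocilia bundle: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical model

`ciliasim` simulates the fluid-structure interaction of an inner hair cell
(IHC) stereocilia bundle in the subtectorial space, the endolymph-filled gap
between the reticular lamina (RL) below and the tectorial membrane (TM)
above. Because IHC stereocilia stand in nearly straight rows forming a
fence, with within-row gaps (~100 nm) much smaller than the clearance above
the tallest row (~1000 nm), the dominant flow passes over the bundle rather
than around individual stereocilia, and the model is two-dimensional: a
rectangular fluid domain 20 um long and 5 um high (the subtectorial gap at
the low-frequency apex of the guinea-pig cochlea), with a three-row bundle
standing at its center.

The fluid is viscous and incompressible (density 1000 kg/m^3, kinematic
viscosity 0.7e-2 cm^2/s) and obeys the Navier-Stokes equations. The bundle
is a set of Lagrangian elastic point chains immersed in this fluid and
coupled to it by the immersed-boundary (IB) method: elastic forces computed
on the chains are spread onto the fluid grid through a regularized delta
kernel, and the chains are advected with the kernel-interpolated fluid
velocity (the no-slip condition on every element).

**Geometry.** Three rows at 75 nm Lagrangian point spacing; the tallest row
reaches to 0.5 um below the TM (height 4.5 um). Relative row heights
(1 : 0.65 : 0.35) and diameters (shaft 200 nm, base 400 nm, linear taper
over the basal third) are reconstructions exposed as configuration knobs —
the quantities a calibrated use of the model would adjust. Adjacent rows
are `sqrt(170^2 - 75^2)` nm apart so that a tip link attached from a
shorter row's tip to the taller neighbour's point one spacing higher has a
rest length of exactly 170 nm. Two gated tip links (tallest-middle and
middle-shortest) and six ungated horizontal top connectors (three per
adjacent-row pair, over the top tenth of the shorter member) connect the
rows; all links are linear springs of stiffness 5e-4 N/m. The tallest row
stands on the left: with the drive sign convention below, this is the
orientation for which a rightward RL displacement carries the row tips
leftward relative to their bases and stretches the tip links.

**Elasticity.** Each chain carries a stretching energy
`1/2 (E A / r0) (|dX| - r0)^2` per segment and a bending energy
`1/2 (E I / r0) (theta - theta0)^2` per triad of consecutive points, with
`E = 2.3` GPa (effective Young's modulus of F-actin), `A = pi d^2/4`,
`I = pi d^4/64` from the local diameter, and `theta0` the construction
angle (zero for straight rows). Forces are exact negative gradients of
these energies, which the test suite verifies against central differences.
Only the basal insertion point of each row is anchored — kinematically
prescribed to follow the RL — so a row pivots freely about its insertion,
consistent with the classic picture of stereocilia rotating about their
basal insertion into the cuticular plate. (A target-spring anchoring
stiffness is retained in the configuration for users who disable the
kinematic override.)

**Drive.** The RL performs an orbital oscillation at 200 Hz emulating an
acoustically driven preparation at 98 dB SPL: `x(theta) = -A_h cos(theta)`,
`y(theta) = +A_v cos(theta)` (clockwise sense), so at drive phase
`theta = 180` degrees the RL is maximally right and down. The measured
orbit is not available, so the amplitudes are calibration parameters with
defaults `A_h = 25 nm` and `A_v = 5 nm`; `A_v` is chosen so that a free-end
doubling of the forced-end displacement would correspond to a 10 nm row
length change (see `free_end_reflection()`), and the user-facing
calibration procedure is to match the simulated tallest-row horizontal
amplitude and phase to a measurement. A half-cycle raised-cosine ramp
multiplies the drive so the flow starts from rest. The TM (top wall) is
horizontally fixed and vertically co-moves with the RL, so the gap height
never changes; the side boundaries impose the analytic oscillatory
Stokes-channel profile `Re[U e^{iwt} sinh(k(H-y))/sinh(kH)]`,
`k = sqrt(iw/nu)`, of a channel with one oscillating wall (vertical side
velocity zero, matching that no-bundle solution).

**Scenarios.** `normal` (gap 5 um), `widened_gap` (gap and clearance both
+5 um, all else identical), `horizontal_only` (`A_v = 0`, all else
identical). Default runs are 4 cycles of which the first 2 (ramp plus
transient) are discarded; dt is 1/1000th of the drive period.

## Numerical scheme

The fluid solver is a Chorin projection method on a staggered (MAC) grid:
cell-centered pressure, face-centered velocities, square cells. The nominal
78 nm spacing is realized as `h = 78.125` nm (256 x 64 cells for the normal
gap); `half` and `quarter` resolutions scale both counts down. Advection is
explicit centered (Reynolds numbers are of order 1e-3; a `stokes` switch
drops the term), diffusion is Crank-Nicolson — at these scales the explicit
diffusion number `nu dt/h^2` is in the hundreds, so implicit treatment is
a necessity, not a refinement. The pressure Poisson problem with Neumann
conditions is diagonalized by discrete cosine transforms in both
directions (implemented as precomputed orthogonal transform matrices, exact
to rounding), giving post-projection divergence at machine precision; the
solver enforces a 1e-10 relative divergence contract on every step. The
Helmholtz systems of the implicit diffusion are prefactorized sparse
Cholesky solves. Against the analytic oscillatory channel solution, the
scheme converges at second order in `h` and `dt` (verified in the tests).

**IB coupling.** The four-point piecewise-algebraic regularized delta
kernel is used for both spreading and interpolation, each velocity
component with its own staggered offsets. The kernel satisfies the
partition-of-unity and first-moment conditions, so spreading conserves
force and torque and interpolation is exact on linear fields; spreading
and interpolation are adjoint. Kernel support reaching outside the domain
is clipped and logged: this only happens within two cells of the RL, where
the anchored bases sit, and its consequence is discussed under
*limitations*.

**Stiff coupling.** An actin rod at 2.3 GPa is about five orders of
magnitude stiffer than the hydrodynamic forcing, and the classic explicit
IB update is unconditionally unstable at `dt = period/1000` (coupled
growth factors up to ~1e6 for grid-scale longitudinal modes). The engine
therefore uses a linearly implicit coupling. Writing `S` for spreading,
`S*` for interpolation and `L` for one linear fluid step, the Lagrangian
mobility `M = S* L S` (velocity response at every boundary point to a unit
force at each boundary degree of freedom) and the elastic force Jacobian
`J` at the rest geometry are precomputed; each step solves the small dense
system `(I - dt M J) dX = dt (U0 + M F(X))` for the boundary displacement
(with prescribed anchored displacements moved to the right-hand side) and
applies the linearized force `F(X) + J dX` to the fluid, which is then
stepped once and the boundary advected with the interpolated velocity.
Because all displacements stay far below one grid cell, the frozen `M` and
`J` remain accurate (their error is suppressed by the same implicit
factor); they are rebuilt automatically if the boundary drifts by more
than a quarter cell. The pipeline is fully deterministic — no random
numbers are used anywhere.

**Gating springs.** The gating spring is a 5 nm rest-length extension of a
tip link, triggered when its signed tension reaches a threshold and ramped
over an elongation time `tau_o` (default 1 us); open gates latch, with an
optional hysteresis reclosure. The printed threshold (26.5 nN) together
with the printed link stiffness (5e-4 N/m) would require ~53 um of tip-link
stretch — unreachable by nanometre-scale bundle motion, whose tensions are
piconewtons — so with default parameters the gate never fires; both values
are configuration fields, and a `scheduled` trigger mode opens the gate at
a prescribed drive phase instead. For the nanovortex experiment the gate
additionally supports a `prescribed` elongation mode: on opening, the gate
end of the tip link (its lower end, on the shorter row's tip) is
kinematically displaced by the 5 nm extension along the link within the
elongation time — the impulsively moved plate of Rayleigh's problem — so
that the elongation actually stirs the fluid. In pure rest-length mode a
2.5 pN force shift moves the attachment by picometres and no flow
signature above background could ever arise.

## Diagnostics

- `tip_link_trace()`: signed stretch (against the closed-gate rest length,
  so compression is negative and the gate increment is bookkept
  separately), signed tension and gate state versus drive phase, per link,
  over the analyzed cycles; `tip_link_sync()` reports quadratically
  interpolated peak phases and the phase of the joint (summed) maximum.
- `row_kinematics()`: per-row rotation of the base-to-tip chord relative
  to rest and arclength change; both are translation invariant, hence
  identical in the lab and RL frames, and vanish identically under rigid
  translation.
- `detect_vortices()`: candidate eddies are strict local vorticity extrema;
  a candidate is accepted when the streamfunction, evaluated in the frame
  moving with the local mean flow inside a sub-micron window, attains its
  window extremum strictly inside — the exact condition for a closed
  streamline around the candidate. Pure shear yields no detections and the
  criterion is invariant under superposition of a uniform flow.
- `rayleigh_vorticity()`: the impulsively-started-plate vorticity scale
  `omega = (A/tau_o)/sqrt(pi nu tau_o)` of a gating spring elongating by
  `A` in time `tau_o`.
- `transport_estimates()`: diffusive calcium supply rate `D/l^2` (~1.4e4/s
  for `D = 4e-6 cm^2/s`, `l = 170 nm`), its reciprocal time (~72 us), the
  calcium influx implied by a 500 pA transduction current under a
  concentration-proportional carrier split between 20 uM Ca2+ and 160 mM
  K+ with divalent charge (~2e5 ions/s, an order-of-magnitude construction
  by design), and the critical elongation time `tau_crit ~ 0.39 us` solving
  `1/omega(tau) = l^2/D`, below which vortical convection can augment
  diffusion.
- `free_end_reflection()`: an independent 1D elastic-rod computation
  demonstrating the free-end doubling of a longitudinal displacement pulse
  (leapfrog at unit Courant number, verified against the d'Alembert images
  solution), the argument behind reading a row length change of twice the
  vertical drive amplitude.

## Design choices on genuinely open points

- **Exact discrete energy prefactors** of the fiber model are taken in the
  standard discrete-fiber form (axial `E A / r0`, flexural `E I / r0`),
  chosen for dimensional consistency and gradient verifiability.
- **Anchoring** uses kinematic prescription of the base points rather than
  stiff target springs: a 100x-stiffest-element spring at this time step
  would itself be explicitly unstable, and prescription is what the
  no-slip update specifies for anchored points anyway.
- **Orientation** (tallest row left) follows from requiring positive
  tip-link stretch at phase 180 under the fixed drive sign convention.
- **Orbit sense** defaults to clockwise with a configuration switch; only
  the component phasing fixed by the 180-degree convention matters for the
  reported observables.
- **Vertical side boundary velocity** is zero — literally the no-bundle
  analytic solution, and mass-compatible with the co-moving walls.
- **Grid dimensioning**: 78 nm is treated as nominal; 78.125 nm divides
  the domain exactly.
- **Joint peak phase** is operationalized as the peak of the summed
  stretch trace, which reduces to the common peak phase whenever the two
  links are synchronized.
- **Analysis problem sizes**: the worked analyses and the acceptance
  recomputation use the quarter-resolution grid (64 x 16 cells for the
  normal gap) and 4 drive cycles with 2 discarded; half and full
  resolution reproduce the same qualitative picture (peak phases within a
  few degrees), and a full-resolution normal run is a few minutes on one
  core.

## What the model does and does not reproduce

The simulated bundle is in the drag-dominated regime: the rows pivot about
their insertions following the local fluid displacement, so row rotations
peak near phase 180 (maximal RL displacement), the tallest and shortest
rows rotate most, and the upper tip link is stretched towards phase 180.
This reproduces the qualitative mechanism by which the confined shear flow
times tip-link tension.

Two published observations are *not* reproduced, for reasons that appear
to be structural to this model class, and the package reports them as
computed rather than adjusting parameters towards them:

1. **Vertical-drive effects (row length changes, lower-link
   synchronization).** With both walls co-moving vertically, a uniform
   vertical translation of the fluid plus the horizontal Stokes solution
   satisfies the equations everywhere except within about one gap height
   of the side walls, and that disturbance decays like `exp(-pi x / H)` —
   a factor ~2e-3 at the bundle. A massless, neutrally buoyant immersed
   boundary therefore cannot feel the vertical acceleration to first
   order: simulated runs with and without vertical drive are nearly
   identical. Arclength changes of ~10 nm would require ~1e2 nN of axial
   force on a 2.3 GPa actin rod, five orders of magnitude above the
   piconewton hydrodynamic forcing; the free-end doubling argument invokes
   rod inertia (elastic waves), which a massless IB fiber at 200 Hz cannot
   supply (its quarter-wave resonance is ~1e8 Hz). Consequently the lower
   tip link peaks roughly in anti-phase to the upper one — exactly the
   behaviour expected of a horizontal-only drive — and the measured mean
   peak row length change is ~1 nm, concentrated in the near-wall segments
   (see limitations).
2. **Always-compressed upper link in the widened gap.** A strictly
   negative stretch over the whole cycle requires a rectified (DC) offset
   larger than the oscillation amplitude; in this linear quasi-static
   regime the simulated DC offsets are an order of magnitude too small.

## Limitations

- Within two grid cells of the RL the delta-kernel support is clipped at
  the wall, so the rods cannot fully enforce their rigidity on the fluid
  there; the residual is a sub-nanometre oscillatory arclength artifact in
  the basal segments, which dominates the row length-change observable at
  these forcing levels. Physical axial strains at piconewton forcing would
  be of order 1e-13 m.
- The side-boundary profile is ramped multiplicatively during the start-up
  half cycle, which is exact only after the ramp; the transient cycles are
  discarded before analysis.
- At quarter resolution the 152.6 nm inter-row gaps are narrower than a
  grid cell, so hydrodynamic shielding between rows is under-resolved;
  half and full resolution sharpen the row-to-row differences without
  changing the phase picture.
- 3D effects (flow between stereocilia within a row, V/W-shaped outer hair
  cell bundles), ion-channel kinetics, adaptation, and an explicit calcium
  concentration field are out of scope; calcium transport enters only
  through the closed-form order-of-magnitude estimates above.

## Reproducing the headline numbers

```{r}
library(ciliasim)

rec <- run_simulation(make_scenario("normal", resolution = "quarter"))
tip_link_sync(rec)          # peak phases of the two tip links
row_kinematics_summary(rec) # peak rotations and length changes per row

nanovortex_experiment()     # scheduled gate opening + eddy detection
transport_estimates()       # D/l^2, tau_crit, influx estimates
free_end_reflection()$ratio # 2
```

`scripts/acceptance.R` recomputes the two headline quantities (joint
tip-link peak phase; mean peak row length change) from a fresh normal run
and writes them as JSON; see the README for how to invoke it.
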