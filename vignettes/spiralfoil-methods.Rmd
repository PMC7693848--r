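---
title: "Modelling hydrofoil-enhanced spiral CTC enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hydrofoil-enhanced spiral CTC enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The system being modelled

Circulating tumor cells (CTCs) are rare epithelial cells, typically around
17 µm in diameter, carried in blood alongside white blood cells (WBCs,
around 10 µm) that outnumber them by four to six orders of magnitude.
Label-free enrichment exploits this size difference with inertial
microfluidics: in a spiral channel of rectangular cross-section
(300 µm × 100 µm here), the balance between the net inertial lift

$$F_L = \frac{2\,\rho\,U_{avg}^2\,a^4\,c_L}{D_H^2}$$

and the drag of the Dean secondary flow

$$F_D = 3\pi\,\mu\,U_D\,a$$

drives particles of diameter $a$ to size-dependent lateral equilibrium
positions ($\rho$, $\mu$: fluid density and viscosity; $U_{avg}$: mean
axial speed; $c_L$: lift coefficient; $D_H = 2wh/(w+h)$: hydraulic
diameter; $U_D$: Dean vortex speed). Because $F_L/F_D \propto a^3$, a
17 µm cell is held to its focal axis almost five times more strongly than
a 10 µm cell. In the device modelled here, the spiral pre-focuses the two
populations onto axes roughly 100 µm and 160 µm from the inner channel
wall, and a cambered hydrofoil (NACA9730 section, 300 µm chord, 30°
attack) placed downstream widens the gap between the streams before a
half-elliptic separation wall (50 µm minor diameter, centered on the
17 µm focal axis) divides the channel into a narrow CTC outlet passage
(75 µm) and a wide waste passage (175 µm).

Separation quality is scored with the chromatography-style resolution

$$R = \frac{1.18\, s_p}{w_{CTC} + w_{WBC}},$$

where $s_p$ is the distance between the stream peaks and the $w$ are the
half-height (FWHM) widths of the stream distributions. $R > 1$ means the
streams no longer overlap. For the canonical inlet streams (peaks 100 and
160 µm, FWHM 15.8 µm each) the upstream resolution is
$1.18 \times 60 / 31.6 = 2.24$; the design rules implemented in
`evaluate_design_rules()` ask the spiral to deliver roughly $R \approx 1$
and the hydrofoil to raise the downstream value to 10 or more.

The "width at half the height of the distribution peaks" is interpreted
as the FWHM throughout; that convention is the one under which the 1.18
prefactor gives the classic non-overlap threshold at $R = 1$. The 15.8 µm
default width is obtained by inverting the resolution statistic at the
known upstream value 2.24 with a 60 µm peak separation and equal widths —
measured intensity profiles for this device do not resolve the
widths directly, and the equal-width assumption is the neutral completion.

## Geometry

`naca4_profile()` implements the standard NACA 4-digit section: a
piecewise-quadratic camber line broken at $p\cdot c$, a thickness
polynomial applied perpendicular to the camber line, and the closed
trailing-edge coefficient ($-0.1036$) so the polygon is simple. NACA9730
is taken literally — 9% camber at 70% chord with an unusually thick 30%
section; the thickness is what makes the foil an effective deflector at
this scale. `place_hydrofoil()` applies a rigid nose-down rotation about
the leading edge and a translation to the anchor.

Two placement parameters are not fixed by the device description and
were chosen once, on geometric grounds:

* **Foil anchor** `c(300, 195)` µm. The leading edge sits one chord
  downstream of the inlet. A literal mid-channel anchor (y = 150 µm) puts
  the rotated trailing edge exactly on the reference wall
  ($150 - 300\sin 30° = 0$), sealing the lower passage; no particle (and
  almost no fluid) could pass under the foil. At y = 195 µm the passage
  under the trailing edge is ≈ 45 µm — comfortably wider than the 17 µm
  particles — and the under-foil duct captures about a third of the flux,
  which is the share carried by the 17 µm stream (its ±3σ band spans
  cumulative flux fractions ≈ 0.19–0.34). The 10 µm stream
  (fractions ≈ 0.47–0.62) passes over the suction side.
* **Wall nose at x = 700 µm**, i.e. 140 µm after the foil trailing edge,
  just downstream of the recirculation region behind the foil, with the
  straight divider continuing 50 µm past the elliptic nose to the outlet
  boundary at x = 800 µm. The half-ellipse nose (aspect 2) is the minimal
  completion of a half-ellipsoid wall; the straight continuation models the
  entrance of the physical outlet channels.

The outlet partition 75 / 50 / 175 µm across the 300 µm width follows
from the wall centerline at 100 µm. The coordinate convention places
y = 0 at the *reference wall*, the wall nearest the 17 µm focal axis.
Labelling the walls inner/outer is ambiguous for this device (a wall
centered 100 µm from the outer wall is irreconcilable with a foil that
pushes the CTC stream to the inner wall and a narrow CTC outlet), and
the reference-wall convention is the only arrangement in which the wall dissects the 17 µm
stream at its peak in the reference run while the foil deflects that
stream into the CTC passage.

## Flow solver

`solve_flow()` marches the unsteady incompressible Navier–Stokes
equations to steady state with a Chorin projection scheme on a MAC
staggered grid: hybrid central/upwind advection (central below cell
Péclet 2), explicit central diffusion, and a direct sparse Cholesky
pressure solve whose factorization is reused across all pseudo-time
steps. Solids enter as staircase velocity masks; enclosed fluid pockets
created by the staircase at sharp trailing edges are detected by flood
fill from the outlet and solidified so the pressure system stays
positive-definite. The march stops when the velocity field changes by
less than `steady_tol` (relative to the mean inlet speed) over 200 steps.

Because the channel is three times wider than it is deep, the
out-of-plane walls dominate the viscous drag. The solver therefore runs a
depth-averaged ("2.5D") model by default: a Hele-Shaw-type friction term
$-12\nu u / h_{depth}^2$ in both momentum equations, with the matching
developed inlet profile (plug core with side layers of width
$h_{depth}/\sqrt{12} \approx 29$ µm). This, rather than a channel-wide
parabola, is the lateral profile a shallow rectangular duct actually
develops. Setting `depth_friction = FALSE` recovers the ideal plane
channel, which is the limit the Poiseuille unit tests check against. The
channel depth also normalizes the prescribed volumetric flow rate
(1.2 mL/min ≡ 2×10⁻⁴ m²/s of 2D flux, mean speed 0.667 m/s,
channel Reynolds number ≈ 100–200): particle routing in the downstream
region is inertia-dominated, which is why a Stokes model would not
reproduce the observed behavior.

**Outlet boundary condition.** The modeled domain ends where the chip's
outlet channels begin, and those channels — not the 800 µm segment —
fix how the flow divides between the outlets. At the device Reynolds
number a short splitter samples the oncoming stream without suction bias,
so in the reference (no-foil) geometry the flow should divide in
proportion to the passage widths (equal mean speeds,
$q_{ctc}/q = 75/250 = 0.30$). `calibrate_outlet_bc()` finds, by secant
iteration with warm-started solves, the constant back-pressure offset on
the CTC branch that realizes this split in the reference geometry
(about −210 Pa at the default grid). That offset is a property of the
external network: it is reused unchanged for the hydrofoil and
wall-panning runs, in which the flow split is then free to respond to the
foil — the under-foil jet raises the CTC share from ≈ 0.30 to ≈ 0.37,
which is precisely the mechanism that routes the whole 17 µm stream into
the CTC channel.

## Particle transport

Particles are passive tracers with a finite-radius wall standoff
(`advect()`): 4th-order Runge–Kutta streamline integration with a 1 µm
spatial step, tangential projection of the velocity within one radius of
any surface, and a positional correction that keeps centers at least one
radius away from walls and solids. Inertial lift and Dean drag are *not*
applied inside the short downstream segment — they act over the
centimeters of spiral upstream, where they set the focused inlet
distributions that the transport stage consumes; over the ≈ 1 ms transit
of the downstream domain their lateral displacement is negligible
compared to the standoff and streamline effects.

Seeding discretizes each class's Gaussian stream into 50 equal-spaced
bins over ±3σ (weights proportional to the density, normalized), one
particle per bin, clamped one radius off the walls. A particle stalled
at the wall nose within one standoff is assigned to the outlet matching
its side of the wall centerline; an exact centerline hit goes to waste,
the conservative choice for recovery claims. Downstream distributions
are measured where trajectories cross a station one wall minor diameter
(50 µm) upstream of the nose tip, as a weighted histogram (2 µm bins,
parabolic mode refinement, half-height width read directly off the
histogram with a one-bin floor). With the hydrofoil the 17 µm stream
arrives as a near-wall jet only a few microns wide, so the width floor is
what keeps the downstream resolution finite.

## Performance statistics

`performance_stats` implements the enrichment formulas exactly as used in
two-cycle operation: bead recovery and purity; WBC depletion
$100(1 - n^{ctc}_{cycle}/n_{inlet})$ and CTC recovery
$100(1 - n^{waste}_{cycle}/n_{inlet})$, with *both* cycles referenced to
the original inlet counts so cycle-2 values are cumulative; viable and
total cell loss from Trypan-blue counts; the enrichment factor
$100/(100 - \text{depletion})$ (an 88.3% depletion is ≈ 8.5×,
order-of-magnitude "~10×"); and volume/time bookkeeping at the 2:3
outlet volume ratio (9.0 mL in → 3.6 mL CTC + 5.4 mL waste, 7.5 min at
1.2 mL/min). Reported cycle-2 output volumes for such devices (1.5/2.1 mL from
3.6 mL) deviate slightly from an exact 2:3 split (1.44/2.16 mL); the
bookkeeping uses the exact ratio.

`linear_fit_recovery()` regresses recovered on spiked counts *through the
origin* — a zero-spike sample recovers zero cells — and reports 100× the
slope with the through-origin $R^2$. The origin constraint is the
physically forced intercept convention and is unbiased on proportional
data.

## Synthetic data

The generators in `synthetic_data` produce every input the pipeline
consumes, under the statistical structure the analysis assumes, so the
whole package is testable without laboratory data:

* `gen_intensity_profile()`: two Gaussians (peaks 100/160 µm, FWHM
  15.8 µm) plus constant baseline and additive Gaussian noise.
* `gen_spiking_series()`: 15 spiking levels spanning 50–3500 cells
  (geometric spacing, matching serial dilution), recovered counts
  binomial with per-cell capture probability 0.771 (cycle 1); the
  conditional cycle-2 capture 0.655/0.771 = 0.849 makes the two-cycle
  cumulative recovery 65.5%.
* `gen_cycle_counts()`: WBC carryover 0.369 (cycle 1) then conditionally
  0.317, chosen so cumulative depletion is
  $100(1 - 0.369 \times 0.317) = 88.3\%$.
* `gen_viability_counts()`: inlet viability 0.816 with independent
  binomial thinning of the viable and dead pools (so viable ≤ total on
  every draw).

Counting noise is *binomial only*: each cell is captured or lost
independently. Real count data may be overdispersed (pipetting error,
clumping, counting-chamber variation), and the generators make no attempt
to model RBC-lysis losses, strainer losses, or dead volume. Passing
parameter-recovery tests therefore demonstrates that the estimators are
consistent under independent-capture sampling at realistic counts — not
that real experiments would show these variances. Every generator is
seeded and byte-reproducible; the fixture writer records the seed and all
parameters in a JSON manifest.

## Numerical choices and degenerate inputs

* Grid 4 µm for production/desk-scale runs (2 µm supported; halving the
  cell size moves the outlet split by well under two percentage points),
  solver steady tolerance 10⁻⁴, CFL safety 0.35.
* Desk-scale problem sizes: 800 µm × 300 µm domain (200 × 75 cells at
  4 µm), 50 seeding bins per class (100 particles), 100 replicate seeds
  for Monte-Carlo parameter recovery. The full two-configuration study
  solves in a few minutes on one core.
* Two-Gaussian fits run Levenberg–Marquardt from the two strongest local
  maxima of the 5-point-smoothed profile (maxima with prominence under 5%
  of the range are ignored), baseline initialized at the profile minimum.
  Single-peak profiles return one distribution with a degeneracy warning
  rather than a forced two-component fit.
* Discretization bins falling outside the channel are clipped and the
  weights renormalized, with a warning; bins inside solids are dropped
  likewise at seeding.
* `downstream_distribution()` floors the measured width at one histogram
  bin when all weight lands in a single bin.
* Stuck trajectories (speed below 10⁻⁴ of the mean for 25 consecutive
  steps, or step budget exhausted) are tolerated up to 5% of class
  weight; more raises an error.

## Limitations

The flow model is depth-averaged: Dean vortices, vertical migration and
any three-dimensional structure around the foil are outside its scope,
so full 3D CFD results can be matched only at scaled-down fidelity. The outlet network is reduced to a single
calibrated back-pressure offset. Particle transport ignores
particle–particle interactions, deformability and adhesion. The wall
shear stress helper uses the wide-slot formula, which gives 40 Pa
(400 dyn/cm²) at the operating point; shear figures sometimes quoted as tens of dyn/cm² for this operating
point are not reproducible from standard formulas and are deliberately
not used as a reference quantity.
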