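---
title: "Modelling ascitic currents and ovarian wall shear stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ascitic currents and ovarian wall shear stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(asciflow)
```

## The physical problem

In advanced high-grade serous ovarian cancer, litres of ascitic fluid
accumulate in the peritoneal cavity. Each breath displaces the diaphragm
against that fluid column, and because the cavity is closed, the displaced
volume must circulate. The resulting ascitic currents sweep over the
ovaries and impose a fluid shear stress (FSS) on the tumour surface that
is far larger than the sub-1-dyne/cm² interstitial levels usually assumed
for solid tumours. `asciflow` simulates this mechanism end to end — from
the prescribed diaphragm kinematics to the per-ovary shear statistics —
and inverts a companion perfusion-bioreactor model so that in vitro
experiments can be run at the shear levels the cavity model predicts
(1, 5 and 11 dynes/cm²; 1 Pa = 10 dynes/cm²).

The patient CT segmentation behind the original cavity geometry is not
publicly available, so the package generates a *synthetic* cavity: a box
of ascites-scale volume with a deformable top (the diaphragm), fixed
lateral walls and floor, and two spherical-cap "ovary" protrusions on the
floor. Everything the forcing model needs — a top surface, lateral walls
and ovary wall patches at a reference height — is present; nothing
patient-specific is pretended.

## Governing model

### Boundary kinematics

The diaphragm forcing is kinematic. With $z$ the cranio-caudal axis and
$z_{top}$ the top of the ascites, the prescribed boundary displacement is

$$ d_z(x, t) = -A\,\varphi(z)\, s(t), \qquad
   \varphi(z) = \operatorname{clamp}\!\Big(\frac{z - z_{ov}}{z_{top} - z_{ov}}, 0, 1\Big), $$

so deformation decays linearly from full amplitude at the top to zero at
the ovary reference height $z_{ov}$; the region at and below the ovaries
is stationary. The presets are `regular` ($A = 6.0$ cm, $f = 0.37$ Hz)
and `active` ($A = 8.0$ cm, $f = 1.0$ Hz), run for three cycles by
default.

The waveform $s(t)$ is not dictated by the physiology inputs beyond
amplitude and frequency; the package defaults to a raised cosine
$s = (1 - \cos 2\pi f t)/2$ because it starts from rest with zero
velocity (no impulsive start), with `sine` as an alternative. Excursion
direction is caudal (compression) by default and configurable.

Volume preservation is enforced by a lateral compensation: a spatially
uniform normal-displacement magnitude on the lateral patch, weighted by
the same $\varphi(z)$, whose value is obtained by 1-D root-finding on the
*exactly computed* enclosed volume of the displaced boundary (divergence
theorem over the oriented boundary facets), seeded with the first-order
estimate $\delta A_{top}/A_{lat}$. This makes the isovolumetry constraint
hold to the root-finder tolerance ($\sim 10^{-12}$ relative), not merely
to first order — the alternative reading of "equal lateral deformations"
(lateral magnitude equal to the vertical amplitude) would not preserve
volume at finite amplitude and is not implemented.

The boundary field is propagated into the volume as a pseudo-solid: a
homogeneous linear-elastic solve ($\nu = 0.3$, modulus arbitrary since
only the Dirichlet data matter) with optional inverse-volume Jacobian
stiffening (exponent 1 by default) that stiffens small cells against
inversion. With stiffening disabled the solve reproduces affine boundary
data exactly, which is one of the test oracles.

### Flow

The fluid is incompressible and Newtonian (density 1017.5 kg/m³,
viscosity 0.0012 Pa·s — ascitic values) and satisfies the arbitrary
Lagrangian–Eulerian Navier–Stokes equations on the moving mesh,

$$ \rho\Big(\partial_t u\big|_{\chi} + ((u - w)\cdot\nabla) u\Big)
   = \nabla\cdot\big(-pI + \mu(\nabla u + \nabla u^T)\big), \qquad
   \nabla\cdot u = 0, $$

with $w$ the mesh velocity and no-slip $u = w$ on every wall (cavity and
ovaries). Discretization: Taylor–Hood ($P_2/P_1$) elements by default,
with an equal-order $P_1/P_1$ pair stabilized by a Brezzi–Pitkäranta
pressure Laplacian as the cheaper alternative; backward differencing in
time (order 1 default, order 2 available), with mesh geometry and mesh
velocity evaluated at the new time level with the same difference order.
This treatment preserves uniform flow on a rigidly translating mesh
*exactly* (the discrete geometric-conservation check, asserted to
$10^{-8}$ in the tests and observed at $10^{-15}$). All-Dirichlet
enclosed flow leaves the pressure defined up to a constant; a zero-mean
Lagrange multiplier fixes it and simultaneously absorbs the (tiny)
residual mass defect of the Dirichlet data, which is what keeps the
all-Dirichlet problem well posed.

At ascitic viscosity the cavity flow is strongly convection-dominated at
desk resolution (cell Reynolds numbers in the hundreds), so the cavity
defaults add streamline diffusion
$\sum_e \tau_e\,\rho(\beta\cdot\nabla u, \beta\cdot\nabla v)_e$ with
$\tau_e = c\,h_e/(2|\beta|_e)$, $c = 0.5$. The term vanishes identically
for uniform and unidirectional fields, so it does not pollute the
quiescent, translation, Poiseuille or Womersley oracles; it adds $O(h)$
crosswind-free damping along streamlines in the cavity. The nonlinear
convection is handled by Picard iteration; the cavity defaults cap it at
two iterations per step, which is a first-order-consistent semi-implicit
linearization of the same order as the BDF1 integrator — the achieved
increment is recorded on every state, and full Picard or Newton iteration
to tolerance is available through `solver_settings()`.

### Wall shear stress

Traction is recovered variationally (consistent flux): the discrete
momentum residual tested with boundary basis functions equals the
boundary virtual work, so nodal tractions $t = \sigma n$ solve a boundary
mass system. This is substantially more accurate than differentiating
the velocity at the wall and is the reason the Poiseuille wall-shear
oracle converges at second order on linear elements. The wall shear
stress is the tangential projection $\tau_w = t - (t\cdot \tilde n)\tilde n$
taken along the *weak* normal $\tilde n \propto M_b^{-1}\oint n N_i\,ds$:
with that choice a hydrostatic pressure shift contributes exactly along
$\tilde n$ and drops out of $\tau_w$ identically (the package asserts
invariance to $10^{-12}$), which a geometric averaged normal does not
achieve at patch junctions.

Reported metrics, defined explicitly because the headline numbers depend
on them: **mean FSS** is the area-weighted spatial mean over a patch,
then time-averaged over the snapshots of the final forcing cycle;
**peak FSS** is the maximum over patch nodes and final-cycle snapshots
(not a percentile); **mean speed** is the volume-weighted mean of $|u|$
time-averaged over the final cycle; **peak speed** the max over nodes and
snapshots. FSS is reported in dynes/cm² (exactly $10\times$ Pa), speeds
in cm/s.

### Bioreactor

The in vitro translation uses the stated two-stage decoupling rather
than one conjugate simulation. Stage one: unidirectional Brinkman flow
$\mu_{eff}\nabla^2 u - (\mu/k)u = -G$ through the hydrogel plug
cross-section (no-slip walls, $\mu_{eff} = \mu/\phi_g$ as the standard
closure), with $G$ scaled so each of the 8 radial chambers passes
$Q/8$; the volume-averaged superficial speed $U_{gel} = Q/(8A)$ feeds
stage two. When the screening length $\sqrt{k\mu_{eff}/\mu}$ is far below
the mesh size the uniform Darcy profile is returned directly (the limit
is mass-dominated and exact to the stated 1%). Stage two: steady Stokes
flow (Navier–Stokes automatically above cell Reynolds 0.1) in an open
channel with an idealized cell on the floor — a circular cap of radius
7.5 µm protruding 70% of its radius, in a 100 µm channel with fully
developed inflow — and the FSS profile along the cell surface arclength.
The inverse design exploits Stokes linearity (one forward solve fixes the
FSS-per-speed slope; bracketed root-finding takes over when convection is
active) and *re-verifies* every operating point with a fresh forward
solve.

The cell and channel dimensions and the hydrogel permeability/porosity
are deliberately configuration values with documented placeholder
defaults (and a warning when used): no printed values exist for them, so
the package treats them as rig calibration. Consequently the specific
pump rates are illustrative; the properties that *are* asserted are
forward/inverse consistency (≤1%), speed ratios 1 : 5 : 11 (≤1%), slope
constancy across a decade of speeds (≤0.5%), and mesh convergence of the
peak.

## Synthetic geometry and what passing tests mean

The default cavity is a 2-D vertical mid-plane cross-section 0.18 m wide
and 0.20 m high with two ovary caps of radius 1.5 cm protruding 1.05 cm
from the floor at thirds of the width ($z_{ov} = 1.05$ cm); the 3-D mode
targets a 2.5 L fluid volume (ascites volumes in advanced disease exceed
2,500 mL) with configurable aspect ratios, and the generator hits the
target analytically to well within 2%. Meshing is structured
(mirror-symmetric in $x$, so left/right ovary metrics agree to roundoff —
the symmetry check), with the floor displaced onto the cap surfaces; an
optional deterministic jitter (hash-based, independent of R's RNG state)
perturbs interior nodes for robustness studies.

The generator emulates the *mechanism* — an enclosed deformable fluid
volume with ovary wall patches below the stationarity height — not the
patient anatomy: no organ-space tortuosity, no paracolic gutters, no
boundary-layer prisms, and a graph-type floor rather than free-form
ovaries. Passing tests therefore demonstrate that the numerical pipeline
is correct (oracles, conservation, symmetry, convergence) and that the
*ordering* of breathing regimes is reproduced (active > regular in every
velocity and FSS metric, approach to a periodic state within three
cycles); they do not reproduce the patient-specific magnitudes, which
depend on the unavailable CT mesh. On the default synthetic cavity the
regular preset yields means/peaks of the same order as the
patient-geometry values, which is as far as a stand-in geometry can
honestly go.

## Numerical choices

* **Quadrature** — Grundmann–Möller degree-5 rules on triangles and
  tetrahedra, validated against exact barycentric-monomial integrals.
* **Time step** — cavity runs use 80 implicit steps per forcing cycle
  (CFL ≈ 0.5 at the active preset); the Womersley verification uses
  BDF2 with 96 steps/cycle for 4 cycles (the start-up transient decays
  below $10^{-2}$ after three viscous times).
* **Problem sizes** — chosen as the package's desk-scale defaults:
  cavity 28×13 structured cells (mesh size 6.5 mm); Poiseuille
  convergence at 6/12/24 cells across the channel; sphere meridian mesh
  24×12 and 48×24 with geometric wall grading; bioreactor channel
  ~96×26 with sinh clustering at the bump. Every resolution is a
  function argument, so refinement studies are one-liners.
* **Degenerate inputs** — inverted cells, unlabelled boundary facets,
  non-protruding ovary spheres, insufficient displacement history,
  unknown presets/patches/cases all error with actionable messages;
  element inversion during mesh motion names the remedy (stiffening or
  smaller amplitude).
* **Ties and edges** — at patch junctions a boundary dof belongs to
  several patches; ovary patches win the per-dof label so their rim
  nodes count toward ovary metrics, while area-weighted means use the
  patch's own facet weights.
* **Determinism** — no RNG anywhere in the solvers; the config digest is
  an MD5 of a canonical (name-sorted) JSON serialization, stable under
  field reordering.

## Known limitations

* Laminar flow at all presets; the active-preset Reynolds number is
  logged, not modelled differently (no turbulence model).
* The periodic-state criterion (relative cycle-to-cycle velocity L2
  residual, 5% default threshold) is this package's operationalization;
  only the decreasing trend is asserted.
* The consistent-flux field oscillates slightly on coarsely faceted
  *curved* boundaries; the sphere verification evaluates the stress
  directly from the adjacent element instead (both extractions are in
  the package).
* 3-D cavity meshing, kinematics, mesh motion and the flow assembly are
  dimension-generic, but the acceptance-scale flow runs are 2-D; 3-D
  flow solves at realistic resolution are outside desk-scale budgets.
* Pulsatile bioreactor waveforms are not modelled: operating points are
  set by the steady design model, matching how the shear levels are
  defined.

## Reproducing the study figures

The numbered drivers under `analysis/` run the three studies
(verification, cavity currents, bioreactor design) and write their
tables and figures under `results/`; `scripts/acceptance.R` recomputes
the headline quantities in one pass. See the README for the exact
commands and example output.
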