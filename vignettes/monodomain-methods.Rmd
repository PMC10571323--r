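---
title: "Models and numerical methods in monodomain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in monodomain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science and the numerical
choices behind it: the governing equations, the cellular models and their
units, the discretization, the benchmark harness, and the places where a
design decision was genuinely open.

## The monodomain model

The transmembrane potential $u$ of cardiac tissue obeys a reaction–diffusion
equation on a domain $\Omega \subset \mathbb{R}^3$ partitioned into labelled
subdomains $\Omega_i$ (healthy tissue, border zones, scar, chambers with
different cell types):

$$
\frac{\partial u}{\partial t} + I_{ion}(u, \mathbf{w}^i)
  - \nabla\cdot(\mathbf{D}^i \nabla u) = I_{app}(\mathbf{x}, t)
  \quad\text{in } \Omega_i,
\qquad
\frac{d\mathbf{w}^i}{dt} = \mathbf{H}^i(u, \mathbf{w}^i),
$$

with homogeneous Neumann conditions on the outer boundary (an electrically
isolated tissue block) and flux continuity across subdomain interfaces.
Both conditions are natural in the finite-element formulation, so no
boundary bookkeeping is needed anywhere in the package.

The conduction tensor encodes the myocyte architecture through a per-node
orthonormal frame — fiber $\mathbf{f}_0$, sheetlet $\mathbf{s}_0$,
sheet-normal $\mathbf{n}_0$:

$$
\mathbf{D}^i = \sigma_l^i\, \mathbf{f}_0\otimes\mathbf{f}_0
 + \sigma_t^i\, \mathbf{s}_0\otimes\mathbf{s}_0
 + \sigma_n^i\, \mathbf{n}_0\otimes\mathbf{n}_0 .
$$

Conductivities are expressed in m²/s, i.e. already divided by
$\chi_m C_m$; `normalize_formulation()` converts data given in the
capacitance form ($\hat I / C_m$, $\hat{\mathbf{D}} / (\chi_m C_m)$).

Non-conductive regions (dense scar) are excluded from the conduction solve
entirely: a DOF supported only on non-conductive elements is dropped from
the linear system. A DOF on the interface between conductive and
non-conductive tissue is retained — it belongs to conductive elements and
participates in their integrals. The literature leaves this interface
convention open; retaining shared DOFs is this package's choice and gives
a no-flux block boundary without any extra constraint.

## Ionic models and units

Four models are built in, each implemented from its original publication
and kept in its native units (potential in mV for the physiological models,
dimensionless for the phenomenological ones; time in ms):

* **Aliev–Panfilov** — two-variable phenomenological model; its native time
  unit is mapped to milliseconds through the `time_scale_ms` parameter
  (12.9 ms per unit, the original calibration). For display,
  $u_{mV} = 100u - 80$.
* **Bueno–Orovio** (minimal ventricular model) — 3 gates; the epicardial,
  endocardial and mid-myocardial parameter sets are selectable;
  $u_{mV} = 85.7u - 84$.
* **TTP06** (ten Tusscher–Panfilov 2006) — 18 ionic variables; epicardial,
  endocardial and M-cell variants differ in the transient-outward and
  slow-delayed-rectifier conductances and the s-gate kinetics.
* **CRN** (Courtemanche–Ramirez–Nattel 1998) — 20 ionic variables, human
  atrium. The IKur conductance is split into `gKur_fix` + `gKur_var`
  (voltage-dependent part) so remodelling protocols can scale them
  separately.

Per-region parameter overrides (e.g. reduced `GNa`, `GCaL` in a border
zone) are plain named lists validated against each model's parameter table;
unknown names are rejected listing the valid ones.

The tissue layer runs in SI units (volts, seconds): `u_tissue =
unit_scale * u_model` with `unit_scale = 1e-3` for the mV models and `1`
for the dimensionless ones, and ionic rates convert with one audited factor
(`unit_scale * 1000`; conveniently, 1 mV/ms equals 1 V/s). All subdomains
of one problem must share a potential unit — mixing a dimensionless and a
mV-based model in one domain would make the shared field $u$ meaningless.

A caveat the test suite encodes: the published initial states of the
physiological models are *near*-equilibria, not exact fixed points — at the
published TTP06 epicardial values the net current is ≈1.3·10⁻³ mV/ms, so an
unstimulated cell drifts by a fraction of a millivolt per second. Exact
rest-state preservation is therefore asserted on the phenomenological
models (whose resting state is an exact equilibrium), while the
physiological models are required to stay within their intrinsic drift.

## Time discretization: IMEX BDF with closed-form gates

Time derivatives use backward differentiation formulas of order
$\sigma \in \{1,2,3\}$, $\partial_t f \approx (\alpha f_{n+1} -
f_{BDF,n})/\Delta t$, with matching explicit extrapolations $f_{EXT,n+1}$.
Startup bootstraps with lower orders (BDF1, then BDF2) for the first
$\sigma - 1$ steps, raising the extrapolation order alongside.

Each step:

1. **Ionic update.** At every DOF, gating variables — whose dynamics is
   affine in the gate at frozen drivers, $dg/dt = (g_\infty - g)/\tau$ —
   are advanced by the closed-form implicit inversion
   $g_{n+1} = (g_{BDF,n} + \Delta t\, g_\infty/\tau)/(\alpha +
   \Delta t/\tau)$ with $g_\infty, \tau$ evaluated at the extrapolated
   state; all other variables (concentrations, the Aliev–Panfilov recovery
   variable) are explicit. No iterative nonlinear solve exists anywhere.
   Gates are clamped to $[0,1]$ after each update (extrapolation can
   overshoot); clamp counts are reported at the end of a run.
2. **Ionic current interpolation (ICI).** $I_{ion}$ is evaluated at the
   DOF support points using $(u_{EXT,n+1}, \mathbf{w}_{n+1})$ and carried
   into the weak form by per-element mass blocks,
   $s_{n+1} = \sum_i \mathsf{M}^i \mathsf{I}^i_{ion}$.
3. **Potential solve.** The linear system
   $(\frac{\alpha}{\Delta t}\mathsf{M} + \mathsf{K})\,u_{n+1} =
   \frac{1}{\Delta t}\mathsf{M} u_{BDF,n} - s_{n+1} + f_{n+1}$ is solved
   with the matrix assembled once per run and prefactored (supernodal
   sparse Cholesky; a Jacobi-preconditioned CG with configurable relative
   tolerance, default 1e-10, is selectable). The applied-current vector
   $f_{n+1}$ uses the stimulus gate at $t_{n+1}$, consistent with the
   implicit left-hand side; the 0D pacing integrator uses the same
   convention so that a zero-conductivity tissue run reproduces the
   single-cell trajectory to solver precision (an equivalence the tests
   assert at 1e-10 for all four models).

The right-hand side uses $\mathsf{M} u_{BDF,n}$ — the form consistent with
the BDF left-hand side, which reduces to backward Euler at $\sigma = 1$.

**Determinism by construction.** All operators are assembled from
per-element blocks concatenated in a canonical global element order, and
the ICI vector is applied through a stacked per-element operator whose
floating-point evaluation does not depend on how elements are grouped into
subdomains. Splitting a homogeneous slab into layers with identical
properties therefore reproduces the unpartitioned run *bit-for-bit*, and a
checkpointed run resumes exactly (the checkpoint serializes every history
vector plus scheme order, time step and a mesh fingerprint, all of which
are verified on restore).

## Space discretization

Continuous Lagrange elements of degree 1 or 2 on tetrahedra and hexahedra
(VTK vertex/edge/face orderings; geometry is always the straight-sided
linear/trilinear map, so quadratic spaces are subparametric). Quadrature:
tensor Gauss–Legendre with $(p+1)^3$ points on hexahedra — the minimum
exact rule for the consistent mass matrix on parallelepipeds — and
published symmetric simplex rules of degree $2p$ on tetrahedra (4-point
degree-2, 11-point degree-4); the tests verify monomial exactness
directly. Mass matrices are consistent (never lumped).

The fiber frame is stored at mesh nodes, interpolated to quadrature points
with the FE basis and re-orthonormalised there by Gram–Schmidt with fiber
priority (the interpolation rule for frames is not canonical; this choice
keeps $\mathbf{D}$'s eigenvalues exactly $\{\sigma_l, \sigma_t,
\sigma_n\}$ at every quadrature point).

Fiber generation covers the slab family: a transmural Laplace coordinate
$\phi$ (harmonic, 0 on the endocardial face, 1 on the epicardial face)
drives a linear in-plane rotation $\alpha(\phi) = \alpha_{endo} +
\phi(\alpha_{epi} - \alpha_{endo})$ (e.g. +60° to −60°). Full ventricular
and atrial rule-based methods are out of scope; those fiber fields are
imported from VTU point-data arrays instead (default names `fibers`,
`sheets`, `sheet_normals`, overridable), re-normalised on import with
near-zero vectors rejected.

## Stimulation

$I_{app}(\mathbf{x}, t) = \sum_i A_i\, g^t_i(t)\, g^x_i(\mathbf{x})$ with
indicator shapes (cube, sphere, plane slab) or a Gaussian normalised to
peak 1 — so the amplitude is read directly in V/s; the half-open time gate
$[t_0, t_0 + d)$ makes behaviour at step boundaries unambiguous. Pulse
trains are given as explicit start-time lists or a (period, count)
shorthand. $g^x$ is evaluated at DOF support points, consistent with ICI.

## The slab benchmark harness

The verification surface is the community *N*-version benchmark: a
(3 × 7 × 20) mm slab, fibers along the long axis, epicardial TTP06,
(1.5 mm)³ corner stimulus of 35.714 V/s for 2 ms, BDF2, P1 elements.
The monodomain conductivities are the harmonic means of the benchmark's
intra/extracellular values divided by $\chi_m C_m = 140\,\text{mm}^{-1}
\times 0.01\,\mu\text{F/mm}^2$, giving $\sigma_l = 9.5298\cdot10^{-5}$,
$\sigma_t = \sigma_n = 1.2576\cdot10^{-5}$ m²/s (the printed stimulus
amplitude equals the benchmark's 50 000 µA/cm³ under the same convention,
which pins the units down). Activation time is the instant of maximum
discrete $\partial u/\partial t$ per DOF (first occurrence on ties,
tracked online as a running maximum of backward differences; DOFs whose
peak never exceeds the threshold, 10 V/s by default, are "never
activated"). Probe points: P1 the stimulated corner, P8 the opposite
corner, P9 the centroid; activation is also sampled at 50 equispaced
points on the P1–P8 diagonal by FE interpolation.

Problem sizes in the default suite and the acceptance script are the two
desk-scale pairs (dx = 0.5 mm / Δt = 0.05 ms and dx = 0.2 mm / Δt =
0.01 ms). At dx = 0.5 mm this consistent-mass ICI discretization
propagates slower than converged (latest activation ≈62 ms), so the
harness runs the coarse benchmark to 70 ms to reach full activation; the
refinement sequence descends monotonically towards the published
fine-grid reference (≈42 ms latest activation), which the desk-scale runs
bracket from above. The full refinement study — down to dx = 0.05 mm and
Δt = 0.001 ms, on hexahedra and on Kuhn-split tetrahedra — is reached
through `scripts/benchmark_fine.R`; those runs take hours on one CPU.

The conduction-velocity anisotropy law is checked on a thin bar: planar
waves along the fiber and sheet directions must show
$CV_l/CV_t = \sqrt{\sigma_l/\sigma_t}$. The bar is stimulated over a fixed
1 mm end slab — a stimulated sliver that shrinks with the mesh would fall
below the liminal volume at fine resolutions and fail to initiate. At
dx = 0.1 mm the measured ratio is within a few percent of the law;
transverse propagation needs that resolution because its upstroke spans
only a few hundred micrometres.

## Parameter files and outputs

Simulations are configured by plain-text files of `key = value` lines in
bracketed sections, generated as self-documenting templates at three
verbosity levels (`minimal`, `default`, `full`). Keys absent from a file
keep their defaults; unknown keys, malformed lines, and volume-label
mismatches are rejected with line numbers. Per-region sections
(`Volumetric: <label>`) carry material IDs, conductivities, the ionic
model and cell type, parameter overrides, and `Disable conduction` for
scar. The defaults reproduce the slab-benchmark configuration.

Outputs: ASCII VTU snapshot series (potential in tissue units and rescaled
millivolts, activation map on the final snapshot) referenced by a PVD
collection, and CSV traces of min/max/probe values over time. Checkpoints
are RDS payloads with metadata guards.

## What the synthetic setups do and do not show

Every test input is generated in code: structured slabs, Kuhn-split
tetrahedral meshes, analytic fiber frames, and the benchmark stimulus.
These exercise the full numerical pipeline — anisotropic assembly,
IMEX coupling, heterogeneous subdomains, activation mapping — under exactly
known conditions, which is what makes properties like 0D equivalence,
partition invisibility and the anisotropy law provable. They do not probe
unstructured patient-specific geometry quality, strongly curved fiber
fields, or re-entrant arrhythmia dynamics over seconds; on such inputs the
same solver runs, but accuracy claims must be re-established by the usual
refinement studies.

## Known limitations

* Serial only; the per-step cost is dominated by the sparse triangular
  solves and the ionic kernels, both single-threaded here.
* Hexahedral geometry is treated as trilinear; exactness statements for
  quadrature hold on parallelepiped elements (always true for the built-in
  slab family).
* Mixed tet/hex meshes, ventricular/atrial rule-based fiber generation,
  bidomain and eikonal models are out of scope.
* The quadratic hex space carries 27 nodes per element; its memory use
  makes degree 2 practical only at moderate mesh sizes in R.
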