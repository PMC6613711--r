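---
title: "Modelling whole-organ circulation and perfusion with perfusim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling whole-organ circulation and perfusion with perfusim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfusim)
```

## The model

perfusim simulates blood flow through an organ on two coupled scales.

**Macro scale.** Vessels that are resolved by imaging (or by the synthetic
generator) form an undirected graph per compartment — one arterial, one
venous. Flow through an edge between nodes $j$ and $k$ follows the
Hagen–Poiseuille law for laminar flow of a Newtonian fluid in a rigid tube,

$$\tilde q_{jk} = \kappa_{jk}\,(\tilde p_j - \tilde p_k),
  \qquad \kappa_{jk} = \frac{\pi R_{jk}^4}{8 \mu L_{jk}},$$

with $L_{jk}$ the geodesic medial-axis length and $R_{jk}$ the mean tubular
radius. Interior nodes satisfy Kirchhoff mass balance; *root terminals* —
degree-1 nodes where the network crosses the organ boundary — carry
Dirichlet pressures (the arterial inlet and venous outlet pressures).

**Micro scale.** Capillary flow is not resolvable voxel by voxel and is
treated as two interpenetrating porous media (arterial and venous
compartments) obeying Darcy's law $u_\beta = -(k_\beta/\mu)\nabla p_\beta$,
$\beta \in \{a, v\}$, with no-flow conditions on the tissue boundary.
Perfusion is defined as the volume flux transiting from the arterial to the
venous compartment,

$$P = \alpha\,(p_a - p_v) \quad [\mathrm{s^{-1}}],$$

a sink for the arterial and a source for the venous pressure equation. The
proportionality field $\alpha$ lumps capillary density and microstructural
organization. $P$ is reported in the conventional ml/min/100ml through the
factor 6000.

**Coupling.** A vessel terminal ending inside the tissue cannot inject its
flow into a single point — that is a Dirac source, singular both physically
and numerically. Instead each interior terminal distributes its flow over a
ball of radius $\epsilon$ through the compactly supported bump kernel

$$\eta(x) = C\,\exp\!\big(1/(|x|^2 - 1)\big)\ \ (|x|<1), \qquad
  \eta^\epsilon(x) = \epsilon^{-n}\,\eta(x/\epsilon),$$

which is $C^1$, positive on the open unit ball and integrates to one. The
normalization constant $C$ has no closed form; it is computed once per
dimension by adaptive quadrature of the radial integral and cached. On the
grid we evaluate $\eta^\epsilon$ at voxel centers, zero it outside the
tissue mask and renormalize so the **discrete** integral over the mask is
exactly one. This makes mass balance hold to machine precision even when
the support ball is clipped by the organ boundary; a kernel that merely
samples the continuous normalization would silently lose the clipped mass.
The closure linking the two scales demands that the terminal flow scale
with the pressure drop between the terminal node and the kernel-weighted
mean tissue pressure,

$$\tilde q_k = \frac{\gamma_\beta}{\mu}\Big(\tilde p_k -
  \sum_i w_k(x_i)\, p_\beta(x_i)\,|\Omega_i|\Big),$$

with $\gamma_\beta$ [m$^3$] an effective conductance of the unresolved
sub-kernel vasculature: larger $\gamma$ means a smaller pressure drop
between the tree and the continuum.

## Parameters

| Parameter | Symbol | Unit | Tongue preset | Brain preset |
|---|---|---|---|---|
| viscosity | $\mu$ | Pa s | 3.00e-3 | 3.00e-3 |
| support radius | $\epsilon$ | mm | 10.0 | 30.0 |
| hematocrit | Hct | – | 0.40 | 0.40 |
| perfusion proportionality | $\alpha$ | m s kg$^{-1}$ | 1.00e-6 | 1.00e-5 |
| permeability (a / v) | $k_\beta$ | m$^2$ | 1.0 / 5.0 e-12 | 12.5 / 25.0 e-12 |
| porosity (a / v) | $\phi_\beta$ | – | 0.05 / 0.10 | 0.05 / 0.10 |
| boundary pressure (a / v) | $p_{\beta,0}$ | kPa | 10.6 / 1.60 | 13.3 / 0.66 |
| pressure-drop parameter | $\gamma_\beta$ | m$^3$ | 0.01e-12 | 0.20e-12 |

The porosity $\phi_\beta$ is the cerebral blood volume fraction of
neuroimaging. For brain-style runs the grey-matter $\alpha$ is set 1.6
times the white-matter value, and the piecewise-constant maps of $k_\beta$,
$\phi_\beta$ and $\alpha$ are smoothed with a masked, renormalized Gaussian
(truncation radius 2.5 mm, sd 1.5 mm) to emulate partial-volume mixing at
tissue interfaces. A note on units: the closure parameter and boundary
pressures enter the solver in SI (Pa, m$^3$); the presets convert the
conventional kPa / $10^{-12}$ m$^3$ table values.

## Discretization and solvers

The Darcy operators are discretized by the finite-volume two-point flux
approximation (TPFA): one transmissibility per interior face, the harmonic
mean of the half-cell conductivities $k_\beta/\mu$ times face area over
center distance. Harmonic averaging is the standard TPFA choice and is
exact for layered media; faces to unmasked voxels get no entry, which *is*
the no-flow boundary condition. The coupled unknown vector concatenates
voxel pressures of both compartments and nodal pressures of both trees. In
the voxel rows the terminal flow is substituted through the attached edge's
Poiseuille relation (two node-pressure entries per voxel in a kernel
support); the pressure-continuity closure becomes the terminal node's own
row. This keeps every block sparse — substituting the closure into the
voxel rows instead would create dense rank-one blocks of support-pair size.
Dirichlet rows are identity rows.

Small systems are solved by a complete sparse LU factorization. Wide
kernels (the brain preset's $\epsilon$ = 30 mm reaches thousands of voxels
per terminal) make the terminal rows near-dense, and fill-reducing
orderings then let the factorization fill in catastrophically. For such
systems the solver switches to GMRES, left-preconditioned by a
block-diagonal operator: a supernodal Cholesky of the (symmetric positive
semi-definite) voxel block after a $10^{-10}$-relative diagonal shift, plus
a dense factorization of the small node block. The coupling the
preconditioner ignores has rank bounded by twice the number of terminal
node columns, so GMRES converges in a correspondingly bounded number of
iterations (a dozen in practice); one step of iterative refinement follows
because a left-preconditioned residual can plateau above the achievable
solution accuracy. The relative residual tolerance is $10^{-6}$ and is
verified on the unpreconditioned system after the solve.

## Vessel-graph extraction

Binary vessel masks become graphs in two stages, both built on a
second-order fast-marching eikonal solver ($|\nabla T| = 1/S$):

1. *Reconnection.* Adaptive thresholding of an angiographic intensity
   volume (local mean + $k$·sd over a moving window; defaults 15 voxels
   and $k = 3$) leaves disconnected satellites. Each satellite is joined
   to the largest component by backtracing the arrival-time field solved
   with the intensity itself as speed — the path of least arrival time
   follows bright, vessel-like structure — and dilating the path to a tube
   whose radius is the mean of the two structures' mean radii. Satellites
   are processed farthest-first (by Euclidean distance to the root
   structure), and the arrival field is re-solved after every merge.
2. *Skeletonization.* Inside a connected mask the speed is the distance to
   the mask complement plus a small $\xi = 0.1$, so fronts run fastest
   along tube centers. Zero arrival time is imposed on the root patches
   where the mask meets the tissue boundary (the seed set can also be
   supplied explicitly). Leafs are regional maxima of the arrival time;
   tracing from each leaf by discrete steepest descent over the
   26-neighbourhood yields medial-axis paths, and a node is created
   wherever a path first meets a previously traced path — splitting the
   met edge — or a root patch.

Two robustness devices matter in practice. First, descent is *discrete*
rather than gradient-interpolated: it is monotone by construction, cannot
stall on interpolated plateaus, and directly produces the voxel paths that
the downstream discretization needs. Second, every traced path claims a
*capture zone* of its local tube radius; later backtraces entering the zone
are bridged to the nearest traced voxel. Without this, arrival-time maxima
on the staircase walls of oblique tubes spawn spur branches that run
parallel to the true centerline for many radii. Remaining short spurs
(terminal edges shorter than three local radii) are pruned and the
resulting degree-2 nodes merged, as in standard skeleton post-processing.
Edge radii are estimated as the mean distance-to-complement along the
medial axis; regional-maxima plateaus collapse to their centroid voxel.

The junction volume of a node — needed as a tracer mixing volume — is not
prescribed by the continuous model; we define it as the vessel-mask voxels
nearer (geodesically) to the node center than to any edge's medial axis,
with a floor of one voxel.

## Indicator dilution

Tracer transport rides on the solved flow field with an upstream
finite-volume scheme: upwind face concentrations for voxel-voxel advection,
the upstream compartment's concentration for the perfusion exchange, the
upstream side (node or kernel-weighted tissue) for terminal exchange, and
plug-flow chains of subsegments along edges — one subsegment per
medial-axis voxel, disc-like volumes from assigning every vessel voxel to
its nearest axis point, ordered downstream by the solved flow. Nodes and
subsegments use full porosity. Where a terminal acts as a sink we take the
kernel-weighted *tissue* concentration as the upstream value and write the
node update as $V\,d\tilde c/dt = |\tilde q|\,(c_{\text{upstream}} -
\tilde c)$; this is the only reading under which every internal exchange
cancels in the global mass budget, and the package asserts that budget —
stored mass change equals time step times (inflow − outflow) — at every
step of the test suite.

The bolus enters at arterial inlet roots as a gamma-variate input
$c_{AIF}(t) = C_0 (t - t_0)^A e^{-(t-t_0)/B}$ with $A = 3$, $B = 1$ s,
peaking at $t_0 + AB$. The delay defaults to $t_0 = 7.5$ s so the bolus
falls inside the default 120 s window; $C_0$ defaults to 1 mol m$^{-3}$ and
only scales the output linearly. Time integration is backward Euler with a
step of ten times the tightest CFL bound (read off the operator diagonal)
and one factorization reused across all steps; with upwinding this
combination preserves positivity unconditionally. Voxel frames are sampled
every 5 s for maps and plotting.

Derived maps: the observable concentration
$C = (c_a\phi_a + c_v\phi_v)(1 - \mathrm{Hct})$, time to peak (TTP) as the
sample time of the per-voxel maximum of $C$ (undefined-flagged where the
curve stays flat), and mean transit time via the kinetic identity
MTT $= (\phi_a + \phi_v)/P$ where $P > 0$.

## Sensitivity analysis

Relative sensitivities $c^*_i = (x_i/y)\,\partial y/\partial x_i$ are
estimated by multiplicative 1 % perturbations of whole parameter fields
($\alpha$, $\mu$, $\phi_\beta$, $k_\beta$, $\gamma_\beta$) against the
outputs $p_a$, $p_v$, $P$, TTP and MTT, with a forward stencil by default
(half the cost; a central stencil is available). A viscosity perturbation
consistently rescales the cached edge conductances. For a pure power law
$y = x^m$ the coefficient is the exponent $m$, which anchors the unit
tests; on the simulated fixtures $\alpha$ relates positively to $P$ and
negatively to MTT, and MTT's coefficient w.r.t. $\phi_v$ equals
$\phi_v/(\phi_a + \phi_v)$ analytically.

## The synthetic generator, and what it does not show

`make_paired_scenario()` builds the study conditions every test runs under:
an elliptical quasi-2D tissue slab (40 × 33 mm field of view, 128 × 108
voxels at scale 1, thickness one voxel) with one arterial and one mirrored
venous binary tree rooted on the lower boundary — inlet and outlet at the
bottom — and the tongue-preset parameters above; or, for the brain preset,
a 48³-voxel two-tissue ellipsoid (120 mm field of view) with the 1.6-fold
inner $\alpha$ contrast. Tree geometry (depth 3, trunk 26 % of the short
field-of-view axis, length decay 0.58, radius decay 0.78, half-angle 28°)
was chosen once so that the trees interdigitate without intersecting, each
keeps exactly one boundary root, and all leafs stay clear of the boundary
at every refinement scale. Generation is deterministic given the seed.

These fixtures emulate the *structure* of the real inputs — masks with
roots on the organ hull, disjoint tree topologies, two-tissue parameter
contrast — but not their complexity: real vascular networks are not binary
trees, real masks have noisy, anisotropic boundaries, and real parameter
fields vary continuously. Passing tests therefore demonstrate correctness
of the numerics and conservation structure, and scale invariance of the
perfusion estimate, on geometries with known ground truth; they do not by
themselves reproduce organ-level physiological values, which depend on the
actual vascular geometry.

Problem sizes used throughout (scale-1 fixture ~11 k masked voxels, scale-4
~180 k, brain fixture ~37 k) keep a full test run in a few minutes on one
core while remaining large enough for the discretization asymptotics to
show; the refinement study holds the physical field of view fixed and
scales the matrix size by 1, 2 and 4.

## Numerical choices and degenerate inputs

* Eikonal solves use second-order upwind fast marching with exact arrival
  initialization in a two-voxel collar around the seed set; with unit
  speed the arrival field matches Euclidean distance to well under a voxel
  on 50³ grids.
* The Euclidean distance transform is the exact separable
  parabolic-envelope algorithm, with anisotropic voxel sizes respected.
* Kernels narrower than a voxel collapse to the Dirac limit — all weight
  in the terminal's voxel — which is the correct $\epsilon \to 0$ limit of
  the support function.
* Terminals whose support misses the mask entirely ("orphan terminals"),
  masks without boundary contact ("no root points"), graphs without
  degree-1 nodes, and compartments with neither a pressurized root nor
  perfusion coupling ("floating compartment") are rejected with specific
  errors rather than producing silently wrong systems.
* Edges with zero solved flow keep their declared from→to subsegment
  order and are flagged with a warning; their chains carry no transport.
* Root-terminal classification uses a one-voxel-diagonal tolerance to the
  tissue boundary shell, since discrete masks never intersect a continuous
  boundary exactly.

## Known limitations

Rheology is Newtonian with a global constant viscosity (no
Fåhræus–Lindqvist radius dependence); vessel walls are rigid; flow is
steady during tracer transit; tracer diffusion and blood–brain-barrier
leakage are not modelled; permeabilities are isotropic scalars. The
whole-organ human-brain geometry of the original imaging pipeline (tens of
millions of active voxels) is beyond a desktop run; the brain-style fixture
reproduces the qualitative grey-over-white perfusion ordering, not the
published organ-level means.
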