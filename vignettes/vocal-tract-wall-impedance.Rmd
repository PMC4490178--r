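---
title: "Vocal-tract acoustics with impedance walls: models, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vocal-tract acoustics with impedance walls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtfem)
```

## The physical model

The vocal tract is treated as an air-filled cavity whose acoustics obey the
Helmholtz equation for the complex pressure amplitude $\tilde p$,

$$(-\kappa^2 - \nabla^2)\,\tilde p = 0, \qquad \kappa = \omega / c,$$

under the $e^{+j\omega t}$ time convention, with a constant speed of sound
$c = 350$ m/s and density $\rho_0 = 1.15$ kg/m³ (warm humid air). The
boundary is partitioned into three surfaces:

* **glottis** — a prescribed normal pressure gradient $\tilde f_0$
  (an acoustic monopole source, standing in for the pulsating glottal
  flow);
* **mouth** — an impedance condition
  $\nabla \tilde p \cdot \mathbf n = -j \kappa c \rho_0 \tilde p / Z_\text{mouth}$
  representing radiation into open air;
* **wall** — the same form with $Z_\text{wall}$, representing the yielding
  tissue boundary.

Discretizing the weak form with linear or quadratic tetrahedra yields

$$(-\omega^2 \mathbf M + j\omega\,\mathbf D(\omega) + \mathbf K(\omega))\,
  \mathbf P = \mathbf g,$$

where the surface matrices enter $\mathbf D$ scaled by
$\rho_0\,\mathrm{Re}(Z)/|Z|^2$ and $\mathbf K$ scaled by
$\omega\,\rho_0\,\mathrm{Im}(Z)/|Z|^2$. Two consequences built into the
code: a surface with $|Z| \to \infty$ contributes nothing (the acoustically
hard limit), and a purely reactive load only detunes the stiffness. The
factor $1/c^2$ is folded into $\mathbf M$ so that the assembled system
reproduces the free-field dispersion $\kappa = \omega/c$; this convention
is asserted in the resonance tests. The right-hand side $\mathbf g$
integrates $\tilde f_0$ over the glottal patch — a driven system is
required because the transfer function is defined from the forced
response.

All pressure degrees of freedom on the mouth patch are constrained to a
single master value (constraint elimination), so "the pressure at the
mouth" $\tilde p_1$ is well defined, and the transfer function is

$$TF(\omega) = \left| \tilde p_1(\omega) / (j\omega\,\tilde f_0) \right|,$$

a mouth-flow-to-glottal-flow ratio up to constants. Formants are its local
maxima; bandwidths are half-power (−3 dB) widths.

### Impedance models

* `z_sphere` — radiating half-sphere with the same cross-section as the
  mouth, $r = \sqrt{A/2\pi}$: the standard spherical-wave absorption
  model.
* `z_piston` — rigid circular piston ($a = \sqrt{A/\pi}$) in an infinite
  baffle, using Bessel $J_1$ and Struve $H_1$ functions.
* `z_lf_piston` — the two-term small-argument expansion of the piston.
  Valid for $\kappa a \lesssim 0.1$; it has no high-frequency limit by
  construction.
* `z_wall` $= b/A + j\omega\,m/A$ — an areal damper–mass sheet. Each wall
  element acts as an independent local oscillator; no tissue continuum or
  shear coupling is modelled.

`wall_spec("hard")` and `radiation_spec("hard")` omit the boundary term
entirely (homogeneous Neumann). This is the exact $|Z|\to\infty$ limit and
avoids the conditioning artifacts of emulating a rigid surface with a
large finite impedance.

## The inverse problem

Measured formant frequencies and bandwidths are inverted into wall
parameters in four steps:

1. **Grid sweep** (`sweep_parameter_grid`) — simulate the transfer
   function on a logarithmic $(m/A,\ b/A)$ grid spanning
   $[2.5\times 10^2,\ 2.5\times 10^5]$ g/m² and $[1,\ 10^5]$ N·s/m³ (the
   established physical limits: below them formants leave the band of
   interest, above them the wall is indistinguishable from rigid).
   Formants of each run are tracked against the hard-wall reference by
   greedy nearest-frequency matching; where the peak structure changes too
   much to map (high damping with low mass), grid points are masked —
   these are the "white islands" of the objective surfaces.
2. **Bilinear patches** (`fit_patch`) — on each grid cell the sampled
   formant frequency and bandwidth surfaces are interpolated by
   $[m/A,\ b/A,\ mb/A^2,\ 1]\cdot\psi$, solving a 4×4 system per cell so
   the corners are matched exactly.
3. **Level-curve intersection** (`level_curve_intersection`) — the target
   formant frequency and bandwidth each define a level curve on the patch;
   substituting one bilinear constraint into the other gives a quadratic
   whose roots are computed in closed form (in normalized cell coordinates
   for conditioning). An interior common root is the optimal
   $(m/A,\ b/A)$ pair.
4. **Fallbacks** (`select_optimum`) — if the curves exist but never cross,
   the densely sampled point minimizing the summed log-space distance to
   both curves is reported (`nearest_neighbour`); if a target is
   unreachable on the whole valid grid, the maximum $m/A$ is reported
   (`saturated_mass`). Both mirror the established practice for this
   procedure.

Per-formant optima are joined into frequency-dependent functions
(`build_impedance_function`): constant across each formant's bandwidth (to
avoid instabilities from steep slopes at the anchors) and joined between
formants by a shape-preserving monotone cubic (`monoH.FC`), which cannot
overshoot and so cannot introduce non-plausible extra peaks; extrapolation
beyond the outer formants is constant.

### Design choices where the method is underdetermined

* **Two interior roots in one cell**: the root with the smaller $b/A$
  (less dissipative wall) is returned. The choice is documented and only
  matters on the measure-zero set of doubly intersecting patches.
* **Nearest-neighbour metric**: Euclidean distance in
  $(\log_{10} m/A,\ \log_{10} b/A)$, matching the logarithmic grid.
* **Matching window**: 20 % of the reference formant frequency by
  default, the right scale for human tracts where five formants crowd
  0–4 kHz. For the uniform-tube fixture the tests use a window of 1.3,
  because the tube has only two widely separated resonances below 2 kHz
  while wall loading legitimately shifts F1 by more than 100 %; greedy
  global-nearest matching keeps the attribution unambiguous there.
* **Bandwidth convention**: −3 dB (half-power), the standard resonance
  definition. Measured target tables produced by inverse filtering may use
  a different implicit convention; all model-side quantities use −3 dB
  consistently.
* **Peak refinement**: 3-point parabolic interpolation on the dB curve
  (resonances are locally quadratic in dB), crossings by linear
  interpolation of dB samples.

## The synthetic geometry generator

`build_tube_mesh` lofts a straight tube through an area function: layered
polygonal cross-sections, extruded into prisms, split into tetrahedra with
a conforming diagonal rule, and tagged glottis/mouth/wall automatically.
Cross-section polygons are radially rescaled so their area equals the
requested cross-sectional area *exactly*, which makes geometric summaries
independent of angular resolution. Quadratic (10-node) elements are
produced by inserting mid-edge nodes on straight edges.

This generator emulates what a one-dimensional description of the tract
can express: the area function. It does **not** reproduce tract curvature
(which lowers formants), side branches (piriform sinuses, vallecula),
the wedge-shaped lip opening, teeth, or any segmentation noise of real
imaging data. Tests passing on tube fixtures therefore demonstrate the
correctness of the solver, the formant analysis and the inversion
machinery — not the anatomical fidelity of any particular tract model.
Real applications should import segmented meshes via `read_mesh`
(Gmsh MSH v2.2 with physical groups named `glottis`, `mouth`, `wall`).

## Numerical choices

* **Quadrature**: Grundmann–Möller rules of degree 5 on triangles and
  tetrahedra, generated in code and verified against exact simplex
  monomial integrals. Since all elements are affine, element integrals
  reduce to precomputed reference matrices scaled by per-element Jacobian
  quantities, and assembly is fully vectorized.
* **Linear solves**: direct factorization per frequency (the damping and
  stiffness matrices are frequency dependent, so modal superposition does
  not apply). Small coupled systems (≤ 700 unknowns) use dense complex LU;
  larger systems are solved as the equivalent real block system
  $\begin{pmatrix} A_r & -A_i \\ A_i & A_r \end{pmatrix}$ with sparse LU.
  Undamped configurations fall back to a real sparse solve.
* **Singular bins**: with hard walls everywhere an undamped resonance can
  make a bin singular; the solver reports the frequency and continues the
  sweep rather than regularizing, since any finite radiation damping
  removes the issue.
* **Mesh adequacy**: a warning is raised below 8 elements per wavelength
  at the top of the sweep, the usual rule of thumb for resolving acoustic
  pressure fields.
* **Struve $H_1$**: ascending power series up to $x = 25$, asymptotic
  expansion through $x^{-10}$ beyond; the switchover keeps the relative
  error near $10^{-8}$, validated against the integral representation.
* **Frequency resolution**: 5 Hz steps throughout, fine enough that
  halving it moves Lorentzian-fixture formants by < 0.2 % and bandwidths
  by < 1 %.

## The parameter-recovery study

The strongest end-to-end check inverts synthetic "measurements" whose
ground truth is known: a wall $(m/A,\ b/A)$ is drawn, the tube's formants
are simulated, and the full pipeline must recover both parameters within
one grid cell in at least 95 % of 20 seeded draws.

Draws come from $m/A \in [1, 4]$ kg/m² and $b/A \in [100, 2000]$ N·s/m³
(log-uniform). This is the regime of a millimetres-thick, water-density
tissue layer — the scale of tract mucosa — and of moderate dissipation,
and it is where the inverse problem is well posed. Outside it the problem
degenerates for physical reasons, not algorithmic ones: a heavy wall
($m/A \gtrsim 10$ kg/m²) is acoustically rigid, so damping has no
observable effect and $b/A$ cannot be identified; a light, strongly damped
wall suppresses F1 entirely, so no peak mapping exists (the white-island
regime) and the procedure can only report its fallback statuses. The
recovery test documents the method's domain of validity rather than
averaging over draws it cannot, even in principle, invert.

Problem sizes used by the test suite and chosen as this package's own
study conditions: tube fixtures of 17.5 cm × 1.5 cm radius; a ~150-DOF
linear mesh for grid sweeps (each full 5 Hz sweep solves in well under a
second); a ~1000-DOF quadratic mesh for the resonance-accuracy checks,
whose first three closed–open and closed–closed tube modes sit within
0.4 % of the analytic values; a 5 × 6 logarithmic parameter grid for
recovery. The production defaults remain finer (quadratic elements,
5 points per decade).

## Known limitations

* The wall model is global: one $(m/A, b/A)$ pair for the entire wall at
  a time. Position-dependent impedance maps are out of scope.
* The radiation models assume an idealized exterior (sphere or baffle);
  no exterior domain, perfectly matched layer, or head geometry is
  modelled.
* No transient simulation, mean flow, thermoviscous losses, or
  fluid–structure interaction with tissue continua.
* Formant attribution across a parameter grid is heuristic wherever the
  peak structure changes; masked grid regions are the honest expression
  of that limit.
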