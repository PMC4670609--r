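---
title: "Modeling concentric and eccentric cardiac hypertrophy with finite growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling concentric and eccentric cardiac hypertrophy with finite growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cardiogrowth)
```

## The model

Chronic cardiac hypertrophy is modeled as *finite growth*: the deformation
gradient of the ventricular wall is decomposed multiplicatively,

$$ F = F^e \, F^g , $$

where only the elastic part $F^e$ generates stress and $F^g$ encodes the
locally grown, in general incompatible, stress-free configuration. Growth is
parameterized by a single scalar multiplier $\vartheta$ per integration
point, in one of two modes that map directly onto the two clinical
phenotypes:

* **Transverse growth (concentric hypertrophy).** Parallel deposition of
  sarcomeres thickens the myocyte cross-section perpendicular to its long
  axis $f_0$:
  $F^g = \vartheta I + (1-\vartheta)\, f_0 \otimes f_0$, so
  $\det F^g = \vartheta^2$ and $\vartheta = 1.4$ means 40 % cell
  thickening. This is the wall-thickening phenotype of pressure overload
  (diastolic heart failure).
* **Longitudinal growth (eccentric hypertrophy).** Serial sarcomere
  deposition lengthens the myocyte:
  $F^g = I + (\vartheta-1)\, f_0 \otimes f_0$, $\det F^g = \vartheta$.
  This is the chamber-dilation phenotype of volume overload (systolic heart
  failure).

Both growth tensors are rank-one updates of the identity, so their inverses
have Sherman–Morrison closed forms; `transverse_elastic_tensor()` and
`longitudinal_elastic_tensor()` implement them and are verified against
generic matrix inversion to $10^{-12}$.

Growth evolves by stretch-driven kinetics,

$$ \dot\vartheta = \frac{1}{\tau}\,\langle \lambda - \lambda^{crit} \rangle , $$

with $\lambda = |F f_0|$ the **total** fiber stretch, $\tau$ a time constant
in normalized time, and $\langle\cdot\rangle$ the Macaulay bracket: growth
is strictly one-way and activates only above the homeostatic threshold.
$\lambda^{crit}$ is not a free parameter — it is *calibrated* per
integration point as the converged fiber stretch under baseline
end-diastolic load (`calibrate_lambda_crit()`), so an immediate re-run of
the baseline produces exactly zero growth everywhere.

Note that for transverse growth $F^g f_0 = f_0$, so the total and the
elastic fiber stretch coincide identically; the choice between them (an
ambiguity for the longitudinal mode) is made in favor of the total stretch,
which preserves the characteristic positive feedback of eccentric growth:
dilation raises the fiber stretch, which sustains further dilation.

## Passive myocardium

The wall is a quasi-incompressible orthotropic Fung-type material. With the
volumetric/isochoric split $J^e = \det F^e$,
$\bar E^e = \tfrac12 (J^{e\,-2/3} F^{e\,T} F^e - I)$:

$$ \psi = \frac{1}{2 D_0}\left[ (J^e)^2 - 2\ln J^e \right]
        + \frac{C_0}{2}\left[ e^{\bar E^e : B_0 : \bar E^e} - 1 \right] . $$

The quadratic form is evaluated in the local fiber/sheet/normal frame with
weights $B_{ff}, B_{ss}, B_{nn}$ on normal strains and $2B_{fs}, 2B_{fn},
2B_{sn}$ on the symmetric shear pairs. Defaults are the healthy-human set
$C_0 = 0.115$ kPa, $B_{ff} = 14.4$, $B_{ss} = B_{nn} = 0.4\,B_{ff}$,
$B_{fs} = B_{fn} = 0.35\,B_{ff}$, $B_{sn} = 0.2\,B_{ff}$, exposed both as
explicit weights and through the reduced two-parameter scaling
`scale_weights(C0, B0)`. The compressibility parameter is taken as
$D_0 = 0.001\ \mathrm{kPa^{-1}}$ — reciprocal-stress units are the only
dimensionally consistent reading of the volumetric ansatz — giving a
volumetric stiffness of $2/D_0 = 2000$ kPa at the unstrained state, three
to four orders of magnitude above the low-strain shear stiffness. This
contrast drives several numerical choices below.

Stresses follow from the chain rule through the split:
$S^e = \partial\psi/\partial E^e$ with the standard deviatoric projection of
the fictitious isochoric stress, the growth pull-back
$S = F^{g\,-1} S^e F^{g\,-T}$, and the push-forward
$\sigma = F S F^T / J$. The isochoric projection is certified by a
finite-difference energy-consistency test (stress vs. central differences of
the energy, $10^{-6}$ relative over 100 random states) rather than by
formula matching.

## Finite elements

* **Elements.** Displacement-based tetrahedra. Linear tets carry one
  integration point and one growth internal variable at the barycenter —
  the bookkeeping used by coarse clinical meshes — and are the scenario
  default. Quadratic (10-node) tets with 4-point quadrature are available
  for accuracy-critical work; their midside nodes are curved onto the exact
  wall surfaces (isoparametric geometry), which was required to bring the
  thick-walled-sphere benchmark inside 1 % at moderate resolution. The
  displacement-only penalty formulation locks for linear tets near
  incompressibility, so quantitative benchmarks use the quadratic elements
  while the organ-scale phenotype runs use linear ones (the phenotypes are
  qualitative contrasts, not point predictions).
* **Follower pressure.** Cavity pressure acts on the deformed endocardial
  surface along its current normal; the load vector is integrated with a
  3-point triangle rule (exact for the flat and quadratic facets used). The
  resultant over a closed surface vanishes to machine precision.
* **Tangent.** The element tangent is assembled from *central* differences
  of the internal force (relative perturbation $10^{-7}$), the facet
  tangent of the follower load from central differences at the facet level.
  Forward differences were measurably insufficient: with a $\sim 10^3$
  stiffness contrast between the penalty and the shear response, their
  truncation error is comparable to the soft-mode stiffness and degrades
  Newton to a slow linear iteration.
* **Linear solver.** The tangent is symmetric up to the small follower-load
  asymmetry. Systems below 1500 unknowns are solved by exact unsymmetric
  sparse LU; larger systems use a CHOLMOD LDL factorization of the
  symmetrized matrix — an inexact Newton step whose contraction factor is
  the relative asymmetry (about $10^{-1}$ at peak cavity pressure, far less
  elsewhere) — with an accuracy check and LU fallback.
* **Globalization.** Damped Newton: the full step is halved while it
  inverts an element, overflows, or fails to reduce the residual; several
  consecutive non-decreasing or creeping iterations abort the load level so
  the caller can cut the increment. Loads are ramped through configurable
  fractions with automatic halving. Transitions between pressure levels
  (overload ramp, unloading, PV sweeps) use warm-started continuation with
  adaptive bisection; if the warm-started path encounters a limit point
  (deflation of an inflated soft shell does), the solve restarts at the
  target load from a rescaled displacement. Convergence is declared at a
  relative residual of $10^{-9}$ against the external load or total
  internal force.

The material at its physiological parameters is *extremely* soft at low
strain ($C_0 \approx 0.1$ kPa before exponential stiffening), so even small
loads produce finite rotations and the early ramp levels dominate solver
cost; this is a property of the calibrated material, not of the
discretization.

## Synthetic geometry and fibers

The built-in generator produces a truncated prolate-ellipsoid left
ventricle: endocardial semi-axes 45 mm (long) and 22 mm (short), wall
thickness 10 mm at the equator and 6 mm at the apex, truncated at 40 % of
the long semi-axis — an idealized healthy human LV with an unloaded cavity
of about 69 mL. A structured longitudinal–circumferential–transmural grid
of hexahedral cells is subdivided by the Freudenthal/Kuhn pattern, which is
face-consistent across the periodic seam; cells touching the apex collapse
into wedges. The mesh is deterministic — no randomness enters anywhere in
the pipeline.

Fibers follow the conventional rule-based architecture: the helix angle
rotates linearly from $+60^\circ$ at the endocardium to $-60^\circ$ at the
epicardium (configurable; anatomic fiber maps provide no single canonical
value), sheets point transmurally outward, and degenerate apex elements
fall back to a long-axis-aligned frame (logged). One orthonormal frame is
stored per element.

What the generator does *not* emulate: the right ventricle and septum, the
atria, valves and their annuli, pericardial constraint, residual prestress
of the imaged state, and anatomic fiber dispersion. Passing tests on this
geometry therefore demonstrate the mechanics of the growth model, not
patient-level prediction. The basal-ring perimeter is reported as a crude
idealized analog of an annular perimeter.

## Scenario protocol and study conditions

The overload protocol mirrors the standard end-diastolic loading sequence:
calibrate at baseline (LV 5 mmHg; a right-sided baseline of 2 mmHg applies
only when a bi-ventricular mesh is supplied), double the pressure of the
overloaded chamber (LV 10 mmHg), hold it while growth evolves, then unload.
Time is normalized ($\tau = 1$); one unit corresponds to months-to-years of
physical remodeling. The explicit staggered update uses $\Delta t = 0.1$ —
at $\Delta t = 0.25$ the explicit growth/equilibrium coupling was observed
to destabilize during the fast early-growth phase. The growth phase ends
when the largest multiplier reaches `theta_stop = 1.4` (40 % cell
thickening/lengthening, the upper end of the hypertrophic range the model
targets) or after `n_steps` (default 60), whichever comes first. Growth is
restricted to elements labeled as ventricular wall.

Problem sizes: the organ-scale scenarios in the test suite and the
acceptance script use a 12 × 6 × 2 mesh (792 linear tetrahedra, one
integration point each) — the coarsest resolution at which the phenotypes
are cleanly resolved; the sphere benchmark uses a quadratic hemispherical
shell at 12 × 6 × 2. Finer meshes (the default target edge length
generates ~3900 elements) reproduce the same phenomenology and are
practical for longer interactive runs.

## Known behavior and limitations

* **Concentric phenotype.** Under left overload in transverse mode the
  chamber volume rises slightly, peaks, and then falls below its
  early-growth peak while the wall thickens substantially — the classic
  pressure-overload picture. However, on a *free-standing* idealized LV the
  growth stimulus does not fully deactivate within a feasible simulation
  window: outward thickening elastically stretches epicardial fibers above
  their (low) homeostatic threshold, and because transverse growth leaves
  the fiber direction ungrown, this circumferential stretch is not relieved
  by further growth. The mean stimulus decays slowly while a localized
  epicardial band keeps growing. Wall-volume growth rates therefore remain
  at several percent per normalized time unit at the end of the growth
  window instead of falling below 1 %. The effect is insensitive to the
  helix-angle choice (tested at 0°/0° and ±60°) and to the time step. We
  attribute the difference from the four-chamber saturation behavior to the
  missing epicardial constraints of a full anatomy (right ventricle,
  atria, vessel anchoring), which are explicitly out of scope here.
* **Eccentric phenotype.** Longitudinal growth shows the expected positive
  feedback: monotone chamber dilation with persistent stimulus and
  markedly smaller relative wall-volume growth than the concentric run
  ($\det F^g = \vartheta$ vs. $\vartheta^2$). Beyond $\vartheta_{max}
  \approx 1.6$ the idealized ventricle leaves the physiological regime and
  the volume trend becomes shape-dominated, another reason for the
  $\vartheta$-anchored stopping rule.
* **Compliance.** PV probing of the grown states reproduces the expected
  signs: concentric growth shifts the passive PV relation toward smaller
  volumes (stiffer ventricle), eccentric growth toward larger volumes
  (more compliant ventricle). The growth field is frozen during probing,
  so the residual stresses of the incompatible grown state are retained.
* The bi-ventricular generator and septal-curvature diagnostic are not
  implemented; right-overload scenarios require an externally supplied
  tagged mesh (Gmsh MSH v4.1) and are refused otherwise.

## Worked example

```{r example}
library(cardiogrowth)

cfg <- scenario_config(
  geometry = lv_geometry_params(nc = 12, nl = 6, nt = 2),
  mode     = "transverse",   # concentric hypertrophy
  n_steps  = 60, theta_stop = 1.4)

res <- run_pathology(cfg)
tail(res$records)
saturation_metrics(res)

# compliance shift at the 5 mmHg probe
merge(res$pv_pre, res$pv_post, by = "pressure_mmhg",
      suffixes = c("_pre", "_post"))
```
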