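---
title: "Charge-based BEM forward modelling with b-refinement: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge-based BEM forward modelling with b-refinement: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The forward problem and the charge formulation

EEG and MEG forward modelling asks for the scalp potential and the external
magnetic field generated by a current dipole inside a piecewise-homogeneous
conductor (a head segmented into nested compartments: skin, skull, CSF,
brain, ...). `chargebem` solves this with a boundary element method whose
unknown is the induced surface charge density on the conductivity
interfaces, rather than the surface potential. With the scaled charge
density $c = \rho/\varepsilon_0$ on the interfaces $S$, the governing
integral equation is

$$ c(\mathbf r) \;=\; K(\mathbf r)\, \mathbf n(\mathbf r)\cdot
   \int_S \frac{c(\mathbf r')}{2\pi}
   \frac{\mathbf r-\mathbf r'}{|\mathbf r-\mathbf r'|^3}\,ds'
   \;+\; 2K(\mathbf r)\,\mathbf E^i(\mathbf r)\cdot\mathbf n(\mathbf r),
   \qquad \mathbf r \in S, $$

where $K = (\sigma_\text{in}-\sigma_\text{out})
/(\sigma_\text{in}+\sigma_\text{out})$ is the conductivity contrast of the
interface, $\mathbf n$ its outward normal, and $\mathbf E^i$ the primary
(infinite-medium) field of the dipole, $\varphi^i(\mathbf r) =
\mathbf m\cdot(\mathbf r - \mathbf r_d)/(4\pi\sigma
|\mathbf r-\mathbf r_d|^3)$ with moment $\mathbf m$ in A·m. Working in
$c$ removes $\varepsilon_0$ from the solve entirely.

Discretized with one unknown per triangular facet this is $x = \hat A x +
b$ with $b = 2K\,\mathbf E^i\cdot\mathbf n$ per facet, solved matrix-free by
unrestarted GMRES with $x_0 = b$. The operator application never forms a
matrix: far interactions are summed directly (an exchangeable backend), near
interactions are replaced by precomputed analytic triangle integrals.

## b-refinement

Head meshes at standard resolution (1–2 mm cortical edge lengths, or the
coarse sphere fixtures here) under-resolve the field of a dipole sitting a
fraction of an edge length beneath an interface. The package's core
algorithm refines the mesh *a priori*, once, before the solve:

1. compute the right-hand side $b$ on the current mesh (the zeroth GMRES
   iterate — hence "b-refinement");
2. select every facet whose total charge magnitude $|q_m| = |A_m b_m|$
   exceeds $k\,\overline{|q|}$, the mean taken over all facets of all
   compartments jointly;
3. split selected facets 4:1 through their edge midpoints (children have
   exactly a quarter of the parent area); bisect border facets with one
   hanging midpoint; promote facets with two or more hanging midpoints to a
   full 4:1 split (this closure rule keeps the mesh watertight with bounded
   aspect ratios);
4. apply one Taubin pass (factors $+0.60$ then $-0.62$) to the newly created
   vertices, restoring smooth curvature to the locally planar subdivided
   patches;
5. repeat for a fixed number of steps (4 on the sphere fixtures).

The threshold constant $k$ is dimensionless with a useful range of roughly
5–10; the validation runs use $k = 5$ (the aggressive end gives slightly
better amplitude accuracy at ~5 % extra facets; $k = 7$, the generic
default, also passes validation). Growth is modest: the coarse sphere
fixture grows from 10.6k to ~14k facets over four steps, all of it within
~20 original edge lengths of the source.

Two deliberate choices where the procedure is underdetermined: smoothing
moves only the vertices created in the current step (the motivation is to
re-curve the new locally planar patches, and moving pre-existing vertices
would perturb already-converged regions), and the analytic-integration ball
around the dipole (below) is held at a fixed physical radius — 3 *original*
average edge lengths — rather than shrinking with the refined facets.

## Operator discretization

Each facet carries a constant charge density collocated at its centroid.
Three tiers make up one operator application:

* **Analytic near field.** For each facet, its 64 nearest facets by
  centroid distance (self included) contribute exact normal-flux integrals
  of a constant-density planar source triangle, *averaged over the
  observation facet* by a 16-point barycentric rule. Plain
  observation-centroid collocation carries a first-order-in-$h$ flux bias
  (measured: the uniform-charge flux identity on a 10k-facet sphere holds
  only to 1.5 %, however many neighbors are used); observation averaging
  removes the first-order term. The self pair is the principal value: a
  flat facet's own charge has zero normal-flux average over itself.
* **Far field.** Point charges at centroids plus the analytic quadrupole
  (second-moment) term of each source triangle, which cancels the
  $O((h/R)^2)$ error that otherwise accumulates systematically across
  closely spaced parallel interfaces (the CSF–brain gap is 2 mm while
  coarse facets are ~9 mm). An annulus of next-nearest pairs (ranks 65–256)
  uses subdivided-source quadrature instead of the expansion, which is
  unreliable below about two facet sizes. These are backend accuracy
  settings, in the same sense as the precision of a fast-multipole backend;
  the analytic integral count per facet stays at 64.
* **Flux conservation.** A unit charge on facet $j$ sends exact flux
  $2\pi A_j$ through its own closed surface and $4\pi A_j$ through each
  enclosing one. The discretization loses a small first-order fraction of
  this, and the loss is amplified into a large amplitude bias wherever the
  exterior signal is attenuated (the insulating skull: conductivity ratio
  1:165 across CSF/skull). The operator therefore rescales each source
  column so its measured total flux matches the exact target, the target
  recovered per compartment by rounding the measured column sum to the
  nearest admissible winding number (0, 1 or 2). An additive
  diagonal-completion variant was tested and rejected: it fixes topography
  but misattributes ~35 % of amplitude.

With all three tiers the flux identity $A\cdot\mathbf 1 = \mathbf 1$ on a
10.6k-facet unit-contrast sphere holds to 0.2 % (max) / 0.06 % (rms).

Near the dipole, the right-hand side uses the exact area-averaged flux of
the dipole field through each facet (a solid-angle-gradient closed form)
instead of the centroid value, for every facet within 3 original edge
lengths of a source; this is what makes $b$ meaningful on facets comparable
in size to the source distance, and it is also the quantity the refinement
thresholds.

One consequence of an accurate flux identity: when the outermost interface
borders an insulator ($K = 1$), the uniform charge on it becomes a
near-null mode of $I - \hat A$ (its image under $\hat A$ is itself to
0.1 %), which stalls the Krylov iteration and lets an unphysical constant
charge leak into the solution. Because a current dipole induces zero total
charge, the solver deflates this mode by augmenting the operator with the
total-charge constraint; convergence on the coarse two-shell test drops
from a 200-iteration stall to 9 iterations, and charge neutrality of the
solution follows from the constraint rather than from post-hoc projection.

GMRES runs unrestarted to a relative residual of $10^{-6}$ (typically ~20
iterations on the four-layer fixture). The tolerance is deliberately
tighter than the validation band: the skin potential of a model with an
insulating layer lives in strongly attenuated operator modes that converge
last, and at $10^{-4}$ the tangential-dipole topography error is visibly
(nearly two-fold) worse while the residual already looks small.

## Observables

The potential at any point is the primary dipole potential plus the
single-layer potential of the solved charge; facets within five average
edge lengths contribute their exact analytic integral (finite even on the
facet itself, so on-skin electrodes are handled without regularization),
the rest their centroid monopole. Skin potentials are reported in the
zero-mean gauge.

The magnetic field is the primary Biot–Savart term plus the
surface-potential (Geselowitz) secondary term over all interfaces,
$-\frac{\mu_0}{4\pi}\sum_f (\sigma_\text{in}-\sigma_\text{out})_f\,
\varphi(\mathbf c_f)\,A_f\,\mathbf n_f\times(\mathbf r-\mathbf c_f)
/|\mathbf r-\mathbf c_f|^3$, with the sign convention validated against the
Sarvas closed form. Because the MEG observation shell sits only ~one facet
size away from the skin, single-point quadrature per facet is badly wrong
there (15.7 % vector RDM even with exact potentials, measured on the coarse
fixture); each facet is therefore midpoint-subdivided until its sub-facet
size is below ~0.35 of its distance to the nearest observation point
(capped at 4³ sub-facets), with the potential re-evaluated at sub-facet
centroids.

Errors use the two standard scale metrics: RDM
$\lVert a/\lVert a\rVert - b/\lVert b\rVert\rVert \in [0,2]$ and relative
L2 $\lVert a-b\rVert/\lVert b\rVert$; potentials are mean-removed before
both, vector fields are flattened three components per point.

## Reference solutions

* **EEG:** the Legendre-series potential of a dipole inside the innermost
  region of an $N$-layer concentric sphere with insulating exterior. Per
  degree $n$ the two-term radial solutions of all layers are coupled by
  potential/current continuity and the outer Neumann condition; the basis
  is scaled per layer (powers of radius ratios only) so the system stays
  well conditioned to $n = 400$ and beyond. Truncation is adaptive
  (relative tail below $10^{-10}$, three consecutive quiet terms); a fixed
  truncation mode supports convergence studies. The series is checked
  against an independently derived generating-function closed form for the
  homogeneous sphere (agreement $10^{-11}$).
* **MEG:** the Sarvas closed form for any spherically symmetric conductor;
  radial dipoles are exactly silent, and the radial field component equals
  that of the primary term — both used as identities in the test suite.

## The sphere fixtures: what they emulate and what they do not

The built-in generator reproduces the four-layer validation geometry:
concentric interfaces at 92/86/80/78 mm (2 mm CSF–brain gap), SimNIBS
conductivities (skin 0.465, skull 0.010, CSF 1.654, brain 0.275 S/m), and a
dipole of 4×10⁻¹¹ A·m placed 2 mm inside the brain interface, tangential or
radial. The exact radii are fixture parameters (chosen here; only the 2 mm
gaps are prescribed by the validation design), so absolute error numbers
depend mildly on them. Shells are icospheres built by $k^2$-section of the
icosahedron faces — facet counts $20k^2$ for any integer $k$ — so a target
edge length can be met within 15 %, and nine graded resolutions between
~6k and ~400k facets exist as required by the convergence-family runs. The
default coarse fixture uses an 8.5 mm edge target (10.6k facets,
gap-to-edge ratio 0.23).

Passing the sphere validation demonstrates correct physics (interface
contrasts, skull attenuation, near-singular source handling) and correct
numerics at realistic contrast ratios. It does not exercise cortical
geometry: thin folded sheets, non-convex interfaces, or meshes with highly
non-uniform quality. The refinement-selection rule and the operator tiers
are geometry-agnostic, but the error magnitudes measured here should not be
quoted for realistic heads.

## Numerical choices and degenerate inputs

* Duplicate vertices are merged at $10^{-9}$ m; STL/OFF/PLY files are
  assumed millimeters (`unit_scale = 1e-3`).
* Degenerate (zero-area) facets are an error naming the facet; non-watertight
  or inward-oriented compartments are rejected at assembly.
* The analytic triangle integrals guard the edge-line singularity (the
  $t_0\ln(\cdot)$ product is set to zero when the observation point lies on
  an edge line); the dipole facet-average falls back to the centroid value
  with a warning if the closed form degenerates.
* Dipoles at the exact center of the analytic sphere, or outside the
  innermost region, are rejected by the series (not needed by any fixture).
* Pseudoinverse rank truncation defaults to
  `max(dim) * .Machine$double.eps` on the singular values; the minimum-norm
  solver goes through the adjoint normal equations with an eigenvalue
  truncated fallback for rank-deficient Gram matrices, giving an
  implementation route independent of the SVD pseudoinverse.
* The lead-field builder refines once for a whole dipole cluster when all
  dipoles fall within a 7 mm ball, else per dipole.

## Problem sizes used by the shipped runs

The test suite and the acceptance script run entirely on generated
fixtures: the headline validation uses the 10.6k-facet four-layer sphere
(≈14k after refinement; two dipole orientations), the property checks use
single shells of 0.5k–10.6k facets, and the inverse-localization checks use
a 500-facet shell with 8–10 dipoles. A full validation run takes on the
order of 1–2 minutes on one CPU with the direct backend.

## Known limitations

* Zeroth-order (piecewise-constant) elements with centroid collocation;
  accuracy beyond the validation band would need Galerkin double integrals
  or higher-order elements.
* The direct $O(n^2)$ backend is practical to a few times $10^5$ facets; a
  fast-multipole backend would slot behind `apply_operator()`'s backend
  contract but is not shipped.
* Refinement driven by the right-hand side cannot anticipate secondary
  (induced-charge) concentrations away from the source; sources whose
  right-hand side is confined to a few facets (surface electrodes) would
  need a different driver.
* Anisotropic conductivity, distributed sources, and volume meshes are out
  of scope.
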