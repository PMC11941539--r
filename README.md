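# chargebem

Matrix-free charge-based boundary element method (BEM) for the EEG/MEG
forward problem on nested piecewise-homogeneous head models, with a
one-time adaptive mesh pre-refinement ("b-refinement") around the dipole
source, analytic multilayer-sphere and Sarvas reference solutions for
validation, and a small lead-field / minimum-norm source-localization
layer.

## Who this is for

Researchers in computational neuroimaging who need fast, validated forward
solutions — scalp potentials and external magnetic fields of cortical
current dipoles — on multi-compartment conductor models (skin, skull, CSF,
brain), and a controlled environment for studying how mesh resolution near
the source limits BEM accuracy.

## The model

The unknown is the induced surface charge density on the conductivity
interfaces. In scaled units `c = rho / eps0`:

    c(r) = K(r) n(r) . \int_S  c(r') (r - r') / (2 pi |r - r'|^3) ds'
           + 2 K(r) E_i(r) . n(r),     r on S

with conductivity contrast `K = (sigma_in - sigma_out) / (sigma_in +
sigma_out)` per interface and the primary dipole field `E_i` (moment in
A·m). Discretized one-unknown-per-facet, this is `x = A x + b` with
`b = 2 K E_i . n`, solved matrix-free by unrestarted GMRES from `x0 = b`.

The package's core algorithm, *b-refinement*, uses that same right-hand
side `b` to refine the mesh once, before the solve: facets whose total
charge `|A_m b_m|` exceeds `k` times the mean (k ~ 5–10) are split 4:1,
border facets are bisected to keep the mesh watertight, new vertices get a
Taubin smoothing pass (+0.60 / −0.62), and the estimate-select-subdivide
loop repeats for a fixed number of steps (4 on the sphere fixtures).

Observables are the skin potential (zero-mean gauge) and the external
magnetic field (primary Biot–Savart plus the surface-potential secondary
term). Accuracy is quantified by RDM (shape) and relative L2 (shape +
amplitude) errors against closed-form references: the N-layer
concentric-sphere Legendre series for EEG and the Sarvas formula for MEG.

## Worked example

The headline validation: a four-layer concentric sphere (interfaces at
92/86/80/78 mm, SimNIBS conductivities, ~10.6k facets) with a tangential
dipole of 4e-11 A·m placed 2 mm under the brain interface — closer to the
interface than the 8.8 mm facets are wide:

```r
library(chargebem)
report <- run_validation(run_config(dipole_type = "tangential"))
print(report)
#> run_report (tangential dipole): 10600 -> 14000 facets, 21 GMRES iterations
#>   EEG skin potential: RDM 5.11%  L2 8.88%
#>   MEG B field:        RDM 8.28%  L2 8.29%
```

The report compares the refined BEM solution against the analytic series
(potential at all skin vertices) and the Sarvas field (10 mm outside the
skin). Without refinement the same mesh gives 6.3 % RDM but 56 % relative
L2 — the near-source charge peak is unresolvable at the original
resolution, and the amplitude of the whole solution suffers. Four
refinement steps (+32 % facets, all near the source) bring every error
below 10 %.

The pieces compose directly if you want to drive them yourself:

```r
spec   <- four_layer_sphere_spec(0.0085)       # edge target in meters
model  <- assemble(generate_sphere_shells(spec))
dip    <- validation_dipole(spec, "tangential")
model  <- b_refine(model, dip, refinement_config(k = 5, steps = 4))
nf     <- precompute_nearfield(model, 64)      # analytic neighbor integrals
b      <- initial_estimate(model, facet_normal_field(dip, model))
sol    <- solve_charge(model, b, nf)
skin   <- model$compartments[[1]]$mesh
phi    <- potential_at(sol, model, dip, skin$vertices, zero_mean = TRUE)
```

Arbitrary head models enter through `read_surface()` (STL/OFF/PLY,
millimeters by default) and `compartment()`; a thin command-line front end
(`inst/cli/chargebem`) wraps mesh audit, fixture generation, forward solves
and the validation run.

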