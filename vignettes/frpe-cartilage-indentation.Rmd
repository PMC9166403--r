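---
title: "Fibril-reinforced poroelastic cartilage: model, indentation simulation, and inverse identification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fibril-reinforced poroelastic cartilage: model, indentation simulation, and inverse identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The material model

Articular cartilage is modelled as a fibril-reinforced poroelastic (FRPE)
mixture: a porous solid skeleton saturated by mobile interstitial fluid. The
total Cauchy stress splits into effective solid stresses and the pore
pressure,

$$\sigma_{tot} = \sigma_f + \sigma_{nf} - p\,I,$$

where $\sigma_{nf}$ is the stress of the isotropic non-fibrillar
(proteoglycan) matrix, $\sigma_f$ the stress of the tension-only collagen
fibril network, and $p$ the pore pressure.

**Non-fibrillar matrix.** A compressible neo-Hookean solid,

$$\sigma_{nf} = \tfrac{1}{2} K_{nf}\left(J - \tfrac{1}{J}\right) I +
  \frac{G_{nf}}{J}\left(F F^{\mathsf T} - J^{2/3} I\right),$$

with $J = \det F$ and the bulk and shear moduli derived from the Young's
modulus $E_{nf}$ and Poisson's ratio $\nu_{nf}$ in the usual isotropic way
(`derived_moduli()`).

**Fibril network.** Each material point carries a set of fibril directions:
four *primary* fibrils following the arcade of collagen in cartilage
(surface-parallel in the superficial zone, rotating across the middle zone,
surface-normal in the deep zone), and thirteen *secondary* directions in a
fixed quasi-uniform spherical arrangement (three coordinate axes, six face
diagonals, four body diagonals). A fibril with reference direction $e_0$ has
nominal strain $\varepsilon_f = |F e_0| - 1$ and carries stress
$E_f \varepsilon_f$ when stretched and nothing in compression. Primary
fibrils are weighted by $\rho_z C$ and secondary ones by $\rho_z$, where $C$
is the primary-to-secondary density ratio, and each fibril contributes
$\sigma_{f,i}\, \hat e_i \otimes \hat e_i$ along its deformed direction.

**Fluid.** Darcy flow $q = -k \nabla p$ with strain-dependent permeability

$$k = k_0 \left(\frac{e + 1}{1 + e_0}\right)^M = k_0 J^M,$$

where the void ratio $e = n_{fl}/(1 - n_{fl})$ follows from the fluid
fraction; the identity $(e+1)/(1+e_0) = J$ holds exactly under affine
pore-volume kinematics, so the law is evaluated directly in terms of $J$.
The fluid fraction profile defaults to $n_{fl} = 0.8 - 0.15\,h$ over the
normalized depth $h$.

Default parameters are those identified for healthy rat tibial cartilage:
$E_f = 3.13$ MPa, $E_{nf} = 0.83$ MPa, $\nu_{nf} = 0.42$,
$k_0 = 3.30\times10^{-15}\,\mathrm{m^4 N^{-1} s^{-1}}$
($3.3\times10^{-3}$ in the package's mm-N-s units), $M = 1.67$,
$C = 12.16$. The meniscus parameter set derives its fibril modulus from the
circumferential Young's modulus, $E_f = E_\theta / (C\,n_{f,p})$; evaluating
it with $E_\theta = 184$ MPa, $C = 12.16$ and $n_{f,p} = 4$ gives
$3.7829 \to 3.78$ MPa at two decimals (one unit in the last digit below the
commonly quoted 3.79).

### Choices the model statement leaves open

* **Fibril strain measure.** The fibril law is stated in terms of a fibril
  strain without fixing its measure; we use the nominal stretch change
  $|Fe_0|-1$ along the convected direction — the simplest measure consistent
  with the linear tension-only law, and identical to the small-strain limit.
* **Collagen density profile.** $\rho_z$ defaults to 1 (uniform with depth);
  a function of depth can be supplied. No depth profile is asserted because
  none is identifiable from a single force curve.
* **Zone boundaries.** Superficial 0–10%, middle 10–40%, deep 40–100% of the
  thickness, with a linear rotation of the primary direction across the
  middle zone. Configurable via `architecture_config()`.
* **Secondary fibril count.** Thirteen fixed directions; the set is symmetric
  under reflections in both in-plane axes, which an axisymmetric model
  requires (otherwise a material point would generate spurious
  circumferential shear).

## The finite-element engine

The indentation experiment is axisymmetric: a cylindrical specimen
(radius 1.5 mm, thickness ≈ 0.13 mm) indented on the axis by a rigid,
impermeable, frictionless sphere (radius 175 µm). The engine uses 4-node
bilinear quadrilaterals with equal-order displacement/pore-pressure
interpolation (the CAX4P element class), 2×2 Gauss quadrature,
updated-coordinate kinematics for the finite 30% indentation, and
backward-Euler time integration of the fluid mass balance. The Jacobian of
each element is formed by central finite differences of its residual, so the
residual is the single source of truth; global systems are dense-factorized
(problem sizes are a few hundred to a few thousand unknowns).

Boundary conditions: the base is fixed and impermeable; the symmetry axis
has zero radial displacement and no radial flux; the outer wall and the
non-contacting surface drain freely ($p = 0$); surface nodes in contact are
sealed, and their pressure unknown is released again if they separate.
Contact with the analytic sphere is enforced node-wise by Lagrange
multipliers on the vertical gap function; since the gradient of that gap is
parallel to the sphere normal, the multiplier force is the frictionless
normal load. The active set is updated inside the Newton loop
(penetration activates, adhesive multipliers release), with geometric
pre-activation at the start of each substep. Steps that fail to converge are
bisected (up to `2^max_halve` substeps).

Numerical choices worth knowing:

* **Tension-only kink regularization.** The fibril law is $C^0$ but not
  $C^1$ at zero strain, which degrades Newton convergence to a slow linear
  rate whenever fibrils sit on the taut/slack boundary. The implementation
  blends the law quadratically over a strain width of $10^{-5}$: exactly
  zero in compression, tangent-continuous in tension, stress offset at most
  $E_f \cdot 5\times10^{-6}$ per unit weight — far below any measured or
  simulated force scale.
* **Convergence.** Newton iterations stop when the max-norm increment falls
  below `newton_tol` ($10^{-9}$ by default, in mm/MPa/N); up to 60
  iterations per substep.
* **Equal-order u–p elements** can exhibit spurious pressure modes under
  fast loading; ramp steps are kept moderate and a checkerboard-pressure
  diagnostic (`attr(curve, "diagnostics")$checkerboard`) is reported with
  every run. Values stay well below 0.1 in the default protocol.
* **Time grid.** 20 uniform steps across the 1 s ramp, then geometric growth
  (ratio 1.2, capped at 20 s) across the 400 s hold. The coarsened `"fit"`
  preset uses 6 ramp steps, ratio 1.8, an 8×5 mesh.

The engine is verified against independent closed forms: the ramp-driven 1-D
consolidation series (confined compression, fibrils disabled — base-pressure
history within 2%), the Hertzian contact force (drained, fibril-free,
thick-specimen limit — within 10%), drained uniaxial-strain equilibrium
(machine-precision-level agreement with the hand-evaluated neo-Hookean
stress), global force equilibrium (indenter force equals base reaction), and
discrete mass conservation (cumulative efflux equals volume change).

## Protocols

* `run_stress_relaxation()`: ramp-and-hold spherical indentation
  (0.04 mm at 0.04 mm/s, 400 s hold by default), returning the indenter
  reaction-force curve. The physical experiment's 0.01 N contact criterion
  is modelled as a post-hoc alignment (`apply_contact_criterion()`), not a
  simulated pre-step: the simulation starts from geometric touch.
* `run_unconfined_compression()`: frictionless impermeable platens,
  free-draining lateral wall, run to pore-pressure equilibrium
  (residual-to-peak pressure below $10^{-4}$). The apparent Poisson's ratio
  is the negative lateral-to-axial strain ratio from the outer-edge radial
  displacement. With the reference cartilage parameters at 10% strain the
  package obtains ≈ 0.096 — tensed superficial and secondary fibrils
  restrain lateral expansion, pulling the tissue-level ratio far below the
  matrix value of 0.42. The 10% strain level is this package's choice; the
  ratio varies mildly with strain (run a sweep over `strain` to see).
* `run_confined_compression()`: rigid impermeable ring, porous top platen —
  the 1-D consolidation benchmark; `consolidation_base_pressure()` is the
  matching analytic series.

## Inverse identification

`fit_frpe()` identifies $(E_f, E_{nf}, k_0, M)$ with $\nu_{nf}$ fixed at
0.42 by minimizing the normalized mean squared error between measured and
simulated forces. Because the model statement does not define the
normalization, the package divides the mean squared force difference by the
mean squared measured force (scale-free); peak-force normalization is
available by configuration.

The search runs from several Latin-hypercube starting points (five by
default), each a Nelder-Mead simplex descent in transformed parameters
($k_0$ on a log10 scale; box bounds enforced by reflection), and then —
this package's own design choice — a damped Gauss–Newton
(Levenberg–Marquardt) polish of each endpoint on the force residual vector.
The polish matters: the NMSE surface has a narrow curved valley in which
$E_f$ and $M$ trade off, and a pure simplex descends it impractically
slowly, while Gauss–Newton steps reach the valley floor in a handful of
iterations. The global minimum is *accepted* when all successful starts
agree within 1% per parameter, mirroring the same-result-from-different-
guesses acceptance rule used with simplex searches in this field.

**Identifiability.** At the standard indentation amplitude the objective
responds strongly to $E_f$, $E_{nf}$ and $k_0$ (a ±20% perturbation moves
the NMSE by more than $10^{-4}$) but only weakly to $M$ (≈ $7\times10^{-6}$),
which enters solely through the compression-induced permeability reduction.
Noiseless self-generated curves are still recovered to machine precision,
but under measurement noise $M$ is the least constrained parameter — in
line with its large between-animal spread in published fits.

## Synthetic data and what the tests do (and do not) show

Because no raw indentation curves are publicly deposited, the package ships
a generator with known ground truth. `generate_curve()` forward-simulates
the protocol, resamples onto a compact acquisition grid (10 Hz on the ramp,
30 log-spaced points per decade of relaxation) and adds i.i.d. Gaussian
noise with standard deviation 3.5 mN — the axial force resolution of the
load cell used in the experiments this emulates. `generate_sample_set()`
draws cohorts (six samples by default) from independent truncated normal
distributions centred on the published fitted means with the published
between-animal standard deviations, and thicknesses around 0.13 mm
(truncated to 0.11–0.18 mm).

The generator emulates the protocol, the force scale, the instrument noise
floor and the between-animal parameter spread. It does **not** emulate
surface roughness or imperfect contact detection, site-to-site thickness
error, heteroscedastic or drifting load-cell noise, inter-parameter
correlations across animals, or model misspecification (the data are
generated by the same constitutive family that is fitted). Passing recovery
tests therefore demonstrate that the *pipeline* is correct and that the
parameters are identifiable at the stated noise level — not that the FRPE
model is the right description of any particular tissue.

A deliberate consequence of adding instrument-resolution noise to a single
synthetic curve: with peak forces around 30 mN, 3.5 mN of white noise caps
the attainable coefficient of determination well below what is reported for
fits to averaged experimental curves (averaging across sites and animals
suppresses the noise floor by the square root of the number of curves). The
recovery study reports the R² values it actually achieves; see the test
suite for the quantitative outcome.

## Problem sizes

Default production runs use a 14×10 graded mesh (140 elements, ≈ 500
unknowns) and 67 time steps; refinement studies double both mesh directions.
Fitting runs use the coarsened 8×5 mesh with 27 time steps, and recovery
studies pair two optimizer starts with the Levenberg–Marquardt polish. These
sizes were chosen so the full verification suite — including two complete
inverse identifications and a six-sample noisy recovery study — runs on a
single CPU in well under half an hour; all physical benchmarks
(consolidation, Hertz, equilibrium checks) are mesh-converged at these
sizes to the tolerances quoted above.

## Known limitations

* Equal-order u–p interpolation is not inf–sup stable; very fast ramps on
  coarse meshes can show pressure checkerboarding (monitored, not
  stabilized).
* Node-to-analytic-surface contact with bilinear elements resolves the
  contact radius to one element; force accuracy relies on the graded mesh.
* The meniscus parameter set participates in the material layer only; no
  meniscus geometry is meshed.
* Viscoelastic fibrils, osmotic swelling, and damage/adaptation laws are out
  of scope.

## A worked example

```{r example}
library(frpefit)

params <- cartilage_params()
curve <- run_stress_relaxation(params, indentation_protocol(),
                               solver_config("default"))
max(curve$force_N)          # peak at the end of the 1 s ramp
tail(curve$force_N, 1)      # relaxed force after 400 s

# synthesize a measurement and recover the parameters (noise-free curves
# are recovered exactly; see the identifiability discussion above for what
# instrument-level noise does to a single curve)
meas <- generate_curve(params, noise_sd = 0, seed = 1)
fit <- fit_frpe(meas, indentation_protocol(), fit_config(n_starts = 2))
tidy(fit)
glance(fit)
autoplot(fit)
```
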