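---
title: "Biomechanically induced wavefront aberrations after myopic LASIK: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomechanically induced wavefront aberrations after myopic LASIK: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyefem)
```

## The question the package answers

Conventional myopic laser refractive surgery (LASIK) reshapes the anterior
cornea by cutting a hinged lamellar flap and photoablating the stromal bed
beneath it. Beyond the intended refractive change, the procedure weakens the
cornea mechanically: under the eye's internal pressure the thinned
post-operative cornea deforms differently than the intact one, and that
*differential* deformation shows up clinically as residual wavefront error —
a hyperopic shift of the spherical equivalent and increased high-order
aberrations (spherical aberration, coma, trefoil).

`eyefem` quantifies this purely biomechanical contribution. It builds a
whole-eye finite-element model, simulates the surgery geometrically, inflates
the pre- and post-operative globes by the same intraocular pressure (IOP),
and converts the difference of the two corneal surface responses into Zernike
wavefront aberrations. Everything downstream of the geometry — the
constitutive model, the solver, the optical conversion — is exercised by
analytic oracles and synthetic fixtures, so each stage can be validated in
isolation.

## Geometry and mesh

The globe is axisymmetric in its reference state: a scleral sphere of outer
radius 12 mm centred at the origin carrying a corneal cap whose anterior
(radius 7.7 mm) and posterior (6.8 mm) surfaces are spheres with centres on
the optical (+Z) axis, 0.5 mm apical thickness. These are classic
Gullstrand-style schematic dimensions; the source study names the schematic
eye but prints no dimensions, so the values are externally sourced and every
one is a parameter of `eye_geometry()`. The corneoscleral junction (limbus)
sits at transverse radius 5.9 mm, and scleral thickness grades linearly in
polar angle from 0.5 mm at the limbus to 1.0 mm at the posterior pole —
standard anatomical ranges. A 4 mm diameter patch around the posterior pole
(the scleral canal region) is fully constrained, mirroring how an eye is held
by the optic-nerve tissues; this is the only displacement boundary condition.

`build_eye_geometry()` produces an all-hexahedral mesh by extruding an
all-quad surface mesh through the wall: a square-core polar cap over the
cornea (so there is no polar degeneracy), latitude bands over the sclera, and
a second square core at the posterior pole. Corneal columns run along the
anterior-surface normal and carry a through-thickness interface exactly at
flap depth; ring stations are snapped onto the optical-zone edge (3 mm) and
the flap radius (4 mm) so that surgical boundaries coincide with element
boundaries. Three resolution profiles are built in: coarse (~900 hexahedra),
fast (~2 400) and production (~5 300). The profiles were sized so that a full
sweep runs in minutes on one CPU; the mesh-quality invariants (cavity-area
closure and convergence, ablation-volume accuracy) are asserted at the
production profile in the test suite.

The hinged flap is cut as a crack: every node on the lamellar interface at
100 µm depth and on the vertical lateral cut at the flap edge is duplicated,
except along the 4 mm hinge arc where the layers keep sharing nodes. (A
vertical sidecut is assumed; the bevel geometry is not modelled.) The
Munnerlyn ablation is then applied as a geometric subtraction *before*
loading: bed and flap nodes inside the optical zone move axially down by the
local ablation depth and deeper bed nodes are re-spaced, so the flap is
repositioned onto the new bed and the anterior surface carries the intended
profile in the stress-free reference state. Physiological prestress is not
recovered first — the analysis differences two *loaded* states, so both
solves see the same loading history and the common part cancels.

## Constitutive model

Cornea and sclera are isotropic, incompressible, hyperelastic Ogden solids:

$$W = \sum_i \frac{\mu_i}{\alpha_i}\left(\bar\lambda_1^{\alpha_i} +
\bar\lambda_2^{\alpha_i} + \bar\lambda_3^{\alpha_i} - 3\right),$$

with deviatoric principal stretches $\bar\lambda_p = J^{-1/3}\lambda_p$. The
baseline fit uses two corneal terms ($\mu_{1,2} = 0.003535$ MPa,
$\alpha_1 = 103.51$, $\alpha_2 = 103.61$ — kept distinct although nearly
identical) and one scleral term ($\mu_1 = 0.030224$ MPa,
$\alpha_1 = 182.73$). The exponents near 100 encode very strong strain
stiffening: at 1 % equibiaxial strain the tangent modulus is already several
times the small-strain Young modulus $3\mu_0$ (with
$\mu_0 = \tfrac12\sum\alpha_i\mu_i$). Eight additional one-term parameter
cases spanning corneal stiffness from roughly 0.1 to 3.9 MPa ship as a JSON
data file (`material_cases()`); cases 6–8 reuse the case-5 scleral
parameters, reading the source's blank table cells as "sclera held constant".
Each case carries a nominal operating-point Young modulus label. Those labels
are metadata only: no tangent- or secant-modulus extraction we examined
reproduces them (they fall *below* the small-strain modulus $3\mu_0$, which a
stiffening material cannot do at any positive operating strain), so
`tangent_modulus_at_iop()` implements a documented Laplace-membrane
operating-point definition instead and the labels are not asserted anywhere.

Incompressibility ($d_1 = 0$) is enforced by a volumetric penalty
$\tfrac{\kappa}{2}(J-1)^2$ with $\kappa = 1000\,\mu_0$ per tissue,
integrated at the element centre only (selective reduced integration) while
the deviatoric response uses full 2×2×2 quadrature — the standard remedy for
volumetric locking of trilinear bricks. Measured volume change at 15 mm Hg is
below 0.5 %.

## The inflation solver

`solve_inflation()` solves quasi-static equilibrium in a total-Lagrangian
setting. The deviatoric Ogden stress is evaluated spectrally (Jacobi
eigendecomposition of $C$ at every quadrature point); element tangents are
central finite differences of the exact internal-force routine, which
captures material and geometric stiffness consistently and keeps the
constitutive code in one place. IOP (converted as 1 mm Hg = 1.333×10⁻⁴ MPa)
acts as a follower pressure on every inner-cavity facet of the deformed
configuration — a constant-pressure load, not a sealed fluid volume, because
the modelled load is "IOP applied normal to all inner surfaces". The
follower-load stiffness is included analytically; without it, Newton
convergence degrades to a slow linear rate on the near-inextensible bending
modes of the shell.

Newton's method runs under a quadratic load ramp (small early increments,
because the stiffening material is softest near the unloaded state) with a
secant predictor extrapolating each converged increment, and a backtracking
line search. The linearised systems are solved by supernodal sparse Cholesky
on the symmetrised tangent (the true tangent is symmetric up to
finite-difference noise and the small skew part of the load stiffness), with
a diagonal-shift retry and unsymmetric LU as fallbacks. The default
convergence tolerance is 1e-6 relative residual; the finite-difference
tangent has an accuracy floor near 1e-7 relative, and 1e-6 leaves the
equilibrium error orders of magnitude below the mesh discretisation error,
so tightening it further buys nothing. Stagnation below 1e-4 relative is
accepted rather than failed.

### Flap interface modes

The crack faces come in coincident node pairs, so the interface is treated by
node-pair penalties (stiffness 1000 MPa/mm × tributary area — penetrations
stay below 10⁻⁵ mm at physiological contact pressures). Four modes exist:

* `"no-separation"` (default): normal tractions transmitted in both
  directions, free tangential slip. This models a repositioned flap adhering
  to the bed before healing, and is the default for a concrete reason: with
  purely unilateral contact the one-element-thick flap — attached only along
  its hinge — rotates bodily off the bed as the cornea inflates (gaps of
  ~0.1 mm, a tilt-dominated induced spectrum), which does not describe a
  clinically repositioned flap and contradicts the defocus/spherical-
  aberration-dominated spectra the model is meant to reproduce.
* `"frictionless-contact"`: unilateral contact (separation allowed), for
  sensitivity studies of a non-adherent flap.
* `"bonded"`: all components tied; mechanically a healed interface,
  equivalent to the uncut mesh up to penalty compliance.
* `"free-crack"`: no interaction.

## From displacement to wavefront

For each corneal surface the nodal displacement $(\Delta X, \Delta Y,
\Delta Z)$ is converted to an axial surface change against the undeformed
reference surface evaluated at the *displaced* transverse position:

$$D = \Delta Z - \left(z_0(X{+}\Delta X, Y{+}\Delta Y) - z_0(X, Y)\right),$$

where $z_0$ is the sphere sag $\sqrt{R^2 - x^2 - y^2}$ pre-operatively and
the sphere-minus-Munnerlyn sag post-operatively (using the actual ablated
reference avoids spurious steps at the optical-zone edge). The optical path
difference is $\mathrm{OPD} = \Delta n \cdot D$; the anterior surface uses
$\Delta n = n_c - 1 = 0.376$. For the posterior surface the physically
consistent step is cornea→aqueous, $\Delta n = 1.376 - 1.336 = 0.040$, which
is the default; a configuration switch (`delta_n_posterior = 0.376`) applies
the anterior relation literally on both surfaces for comparison. Under the
0.040 step the posterior contribution comes out roughly an order of magnitude
below the anterior one, consistent with the physics.

OPD samples at surface mesh nodes inside the pupil are projected onto
orthonormal (OSA/ANSI-style) Zernike polynomials by linear least squares,
with conditioning guards (≥3 samples per mode, design-matrix condition
check). The induced aberration is the coefficient-wise difference post − pre
over the same pupil; differencing removes the common response to IOP,
including the large rigid-ish motion caused by the fixed posterior patch.
Defocus converts to a refraction shift via
$\Delta D = -4\sqrt{3}\,c_2^0 / r^2$ (µm, mm), so the negative induced
defocus of central thinning appears as a positive, hyperopic shift. The pupil
stays centred on the optical axis in decentration runs — the ablation moves,
not the pupil.

Mode naming follows the clinical convention: defocus (2,0), primary
astigmatism (2,±2), coma (3,±1), trefoil (3,±3), primary spherical
aberration (4,0). The hinge sits superiorly (+Y) by default
(`flap_spec(hinge_angle = …)` rotates it): a superior hinge makes the
flap-induced asymmetries appear as *vertical* coma and *y*-trefoil — the
asymmetric terms reported for this kind of model — and keeps the X axis
clean for the X-decentration experiments, whose signatures (x-astigmatism,
horizontal coma) would otherwise be entangled with the flap's own
astigmatism. Where a trend concerns coma generically, checks use the coma
magnitude $\sqrt{(c_3^1)^2 + (c_3^{-1})^2}$ rather than a single signed
component.

## Synthetic fixtures: what they do and do not show

`make_displacement_with_known_aberration()` inverts the optical stage: it
constructs a purely axial nodal field on a sphere whose exact OPD equals a
requested Zernike combination (plus optional Gaussian OPD noise — noise is
placed on the OPD because fitting error is what propagates to coefficient
tables). Sampling uses a sunflower spiral for well-conditioned fits. The
round trip is the identity to 10⁻⁶ µm at zero noise, which validates the
sag projection, the index-step scaling, the basis and the least-squares fit —
but deliberately says nothing about the solver: fields are smooth, exactly
known, and have none of the spatial correlation or mesh-induced roughness of
FEM output. The solver itself is validated separately against the
closed-form incompressible thick-shell inflation quadrature
(`closed_form_sphere_inflation()`), on shell meshes built by the same
generator as the eye. Because the posterior patch pins the globe, the shell
expands about the patch; the comparison metric is the fitted change in
sphere radius away from the patch, which matches the closed form to well
under 1 % at the coarse profile already.

## Numerical choices and degenerate inputs

* Unit system mm–MPa–N throughout; 1 mm Hg = 1.333×10⁻⁴ MPa.
* `Ds = 0` is the exact identity everywhere (no tissue removed, zero
  ablation depth); cut + null ablation + node merge reproduces the intact
  mesh node-for-node, which is a regression test.
* Ablation deeper than the residual stromal bed, flaps thicker than the
  cornea, optical zones (with decentration) beyond the flap, non-positive
  radii and self-intersecting shells are all rejected with diagnostics.
* Degenerate Zernike designs (too few nodes in the pupil, rank deficiency)
  are refused with advice to sample more densely rather than silently
  regularised.
* A full-circumference hinge is the documented limiting case of no crack:
  the mesh is returned topologically unchanged.
* The solver refuses compressible (`d1 > 0`) inputs — incompressibility is a
  structural assumption of the spectral stress and the penalty formulation.

## Problem sizes used by tests and the acceptance script

The bundled validation uses the coarse profile for the IOP, decentration and
stiffness-case trends, and the fast profile for the refraction sweep and the
headline magnitudes (the induced spherical aberration changes sign at low
corrections only once the pupil is resolved by ~10 radial rings, which the
coarse profile does not provide). Production resolution is reserved for
mesh-quality invariants. These sizes are the package's fast-profile design
point: a single inflation solve costs seconds at coarse and tens of seconds
at fast resolution, so complete sweeps remain interactive.

## Known limitations

* The cornea is spherical — no asphericity, no patient topography; only pure
  myopic corrections are implemented (the Munnerlyn hyperopic profile is out
  of scope).
* No epithelial remodelling, wound healing, or viscoelasticity; the induced
  aberrations are instantaneous hyperelastic effects.
* Isotropic Ogden tissue — no collagen-fibril anisotropy; the stiffness
  cases bracket population variability instead.
* Constant-pressure follower load, not a coupled fluid cavity; IOP is
  assumed unchanged by surgery.
* The induced spherical aberration at extreme corrections runs somewhat
  above the magnitudes reported for comparable commercial-solver models
  (the defocus-derived quantities agree closely); the flap interface
  treatment and the unknown schematic-eye dimensions of those models are the
  plausible sources. The trend structure (sign change, monotone growth) is
  reproduced at the fast profile.
* With the correction fixed at −6 D, this model's induced spherical
  aberration *increases* mildly with IOP (while coma increases, as
  expected); comparable commercial-solver models have reported a mild
  decrease. The disagreement is resolution-stable here and is reported as a
  known divergence rather than hidden.
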