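---
title: "Curvature-composition coupling in multicomponent membranes: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-composition coupling in multicomponent membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memphase)
```

## The model

`memphase` evaluates the equilibrium theory of a two-component fluid
membrane whose elastic constants depend on the local composition. The state
is a closed (or periodically closed) surface together with an order
parameter $\phi \in [0,1]$, the molar fraction of component A — think of a
giant unilamellar vesicle carrying a raft-forming, more ordered lipid
species A in a disordered matrix B. The free energy is

$$F \;=\; \underbrace{\frac{\mu}{2}\int (\nabla_s\phi)^2\,dA}_{F_p}
\;+\; \underbrace{\int \Big[\tfrac{k(\phi)}{2}(2H)^2 + \bar k(\phi) K
      + \sigma(\phi) + V(\phi)\Big] dA}_{F_s}
\;+\; \underbrace{P\!\int dV}_{F_v},$$

with the symmetric double well $V(\phi) = \tfrac{\lambda}{2}\phi^2(1-\phi)^2$
and the linear mixing rules $k(\phi) = k_B + (k_A-k_B)\phi$, likewise for
$\bar k$ and $\sigma$. The model assumes a fluid membrane (no shear
elasticity), weak-to-strong segregation bridged by a diffuse interface, and
linear composition dependence of the moduli — adequate for lipid mixtures
whose rigidities differ by a factor of order two, but not for solid/fluid
(protein- or gel-phase) mixtures, where series-spring mixing would be more
appropriate.

Stationarity with respect to the two independent variations gives the pair
of pointwise Euler–Lagrange equations the package evaluates:
$G_\phi - \mu\Delta_s\phi = 0$ for the composition, and for the normal
displacement

$$\Delta_s\frac{G_H}{2} + \bar\Delta_s G_K + (2H^2-K)G_H + 2KH\,G_K - 2HG
+ \mu(\kappa_n - H)(\nabla_s\phi)^2 + P = 0,$$

where $G(H,K,\phi)$ is the integrand of $F_s$ and $\kappa_n$ is the normal
curvature along $\nabla_s\phi$. There is no independent tangential force
balance: tangential displacements are reparameterizations, and the package
verifies numerically that they change $F$ only at second order once the
composition equation holds (exactly so for uniform fields).

### Sign conventions

The normal points outward and the curvature tensor is
$L_{ij} = \mathbf n\cdot\partial_i\partial_j\mathbf r$, so a sphere of
radius $R$ has $H = -1/R$, $K = 1/R^2$, and a cylinder $H = -1/(2R)$,
$K = 0$. All residual formulas and all tests are written in this
convention; the patch constructors assert it.

## The two surface operators

$\Delta_s = (\sqrt g)^{-1}\partial_i(\sqrt g\, g^{ij}\partial_j)$ is the
ordinary Laplace–Beltrami operator. The second operator,
$\bar\Delta_s = (\sqrt g)^{-1}\partial_i(\sqrt g\, K (L^{-1})^{ij}\partial_j)$,
arises from the first variation of the Gaussian-rigidity energy
$\int \bar k(\phi) K\, dA$, which no longer integrates to a topological
constant when $\bar k$ varies.

A genuine subtlety hides in the coefficient tensor $K(L^{-1})^{ij}$. Where
$L$ is invertible it equals the adjugate $2Hg^{ij}-L^{ij}$ by
Cayley–Hamilton, which on a cylinder is *not* zero (it is
$\mathrm{diag}(0, -1/R)$ in the $(\Psi,z)$ chart). The model, however, uses
the operator in the form "$K$ times $L^{-1}$" and takes the product as zero
wherever $K = 0$; this is the convention under which the two identities
that the framework relies on hold simultaneously:

* on a sphere, $\bar\Delta_s = -(1/R)\,\Delta_s$;
* on any developable surface (cylinder, cone), $\bar\Delta_s \equiv 0$.

`memphase` implements exactly this convention: the coefficient is the
adjugate-based $K L^{-1}$ where $|K|$ is above a relative threshold and
exactly zero at parabolic points. The price is that the first-variation
identity $\delta K = \bar\Delta_s\psi + 2HK\psi + \phi^i\partial_iK$ is
reproduced on spheres but *not* on developable surfaces (where the true
variational coefficient is the nonzero adjugate); `check_first_variations()`
is therefore exercised on spheres. The physical payoff of the convention is
the nanotube diagnostic: a sharp change of $\bar k(\phi)$ produces a
divergent $\bar\Delta_s\bar k$ unless $K \to 0$, so cylindrical and conical
protrusions are the regions where composition-driven Gaussian-rigidity
gradients are admissible. `gaussian_rigidity_diagnostic()` flags exactly
the coincidence of sharp $\bar k$ variation with $K \approx 0$.

### Discretization

Patches are structured grids on a chart $(u_1, u_2)$. Both operators use a
conservative (flux-form) discretization with face-averaged coefficients:
constants are annihilated exactly, and self-adjointness with respect to the
$\sqrt g$-weighted inner product holds to rounding by construction — the
test suite checks $10^{-10}$ on random fields. The sphere chart places
nodes at $\theta_i = (i-\tfrac12)\pi/n_\theta$ so the poles are excluded;
the boundary faces sit exactly at the poles where $\sqrt g = 0$, so the
natural zero-flux closure is exact and no pole regularization is needed.
Spherical harmonics come out as discrete eigenfunctions with second-order
eigenvalue convergence. Cylinders are closed periodically in $z$ so that
operator tests are boundary-free; physically open cylinders are a
documented reinterpretation and require $z$-periodic fields. Quadrature is
the midpoint/trapezoid rule with $\sqrt g$ weights (spectrally accurate on
periodic directions); the Gaussian term $\int\bar k(\phi)K\,dA$ is
integrated as an ordinary surface integral, never via Gauss–Bonnet, because
$\bar k$ varies.

Surfaces of revolution (`make_axisymmetric()`) and the perturbed surfaces
of the variation checker build their metric and curvature by second-order
finite differences of the embedding; sphere and cylinder constructors store
analytic geometry so that operator tests isolate the stencil error.

## Equilibrium radii

On a sphere, the composition equation fixes
$\mu\Delta_s\phi = (2\Delta k + \Delta\bar k)/R^2 + \Delta\sigma + V'(\bar\phi)$,
and substituting this into the normal balance eliminates the composition
Laplacian, leaving a cubic in the radius:

$$P R^3 + K_2 R^2 - K_1 = 0,\qquad
K_1 = \frac{(2\Delta k + \Delta\bar k)^2}{\mu},\qquad
K_2 = 2\sigma_{\rm mix} + \lambda\bar\phi^2(1-\bar\phi)^2
 - \frac{(\Delta\sigma + V'(\bar\phi))(2\Delta k + \Delta\bar k)}{\mu}.$$

Rather than transcribing closed-form radical expressions — which are easy
to garble (in particular whether $K_1$ carries $1/\mu$ or $1/\mu^2$) — the
package derives the radius relations directly by this elimination from the
equation pair, and `verify_radius()` closes the loop by substituting every
root back into the residual modules. The elimination fixes
$K_1 \propto 1/\mu$. At $P = 0$
the isotonic radius is $R = \sqrt{K_1/K_2}$: a positive radius requires
$2\Delta k + \Delta\bar k \neq 0$ and $K_2 > 0$, which is the framework's
necessity statement that stable isotonic multicomponent vesicles need
distinct elastic moduli between the components. The cylinder analogue
eliminates the same way and yields
$R = \sqrt{(\mu k_{\rm mix} + 4\Delta k^2)\,/\,(2\mu\sigma_{\rm mix}
+ \lambda\mu\bar\phi^2(1-\bar\phi)^2 - 4\Delta k(\Delta\sigma + V'(\bar\phi)))}$.

Roots are found exactly (`polyroot`) and cross-checked by bracketed
root-finding; the physical root is the smallest positive real root whose
eliminated-system residual vanishes. Absence of a root is a *result*
(`found = FALSE`), not an error, because the necessity claim makes the
"none" outcome meaningful. A uniform composition at a fixed radius is
generically *not* an exact solution of the composition equation (that is
the point of the elimination), so `verify_radius()` reports both the
eliminated-system residual (which must vanish at a true root) and the raw
uniform-field residual norms for transparency.

One dimensional-analysis note: $\mu$ multiplies $(\nabla_s\phi)^2\,dA$ and
is therefore free of length dimension; under a rescaling of lengths only
$\sigma, \lambda \to /s^2$ and $P \to /s^3$ transform, and all radii scale
by $s$. The test suite asserts exactly this.

The constrained-Willmore scaling diagnostic works the same way at the level
of a single sphere family: $E(R) = 8\pi\kappa + 4\pi\Lambda R^2 +
\tfrac{4\pi}{3}P R^3$ is stationary where $2\Lambda + P R = 0$, and the
virial combination $2\Lambda A + 3PV$ vanishes there. Note the stationary
point is a maximum of $E$ along $R$ (with $\Lambda > 0$, $P < 0$), so the
package locates it as a root of $dE/dR$ rather than by minimization; with
a single constraint the same scaling argument forces that constraint's
multiplier to zero.

## The 1D kink and the relaxation scheme

The diffuse interface between the two wells reduces, on a flat or
large-radius geometry, to the 1D problem $\mu\phi'' = V'(\phi)$ with
$\phi(\pm\infty) = 0, 1$, whose first integral
$\tfrac{\mu}{2}\phi'^2 = V(\phi)$ gives the tanh kink
$\phi = \tfrac12[1 + \tanh(x / (2\sqrt{\mu/\lambda}))]$, width
$d = 4\sqrt{\mu/\lambda}$ and line tension $\sqrt{\mu\lambda}/6$.
`solve_kink()` is the package's independent numerical oracle for these
closed forms: damped Newton on the finite-difference system, started from
the analytic profile, with the first-integral residual reported as an
equilibrium check. Width is measured as
$(\phi_{\max}-\phi_{\min})/\max|\phi'|$ — linear extrapolation through the
steepest point — because that estimator reproduces the prefactor 4 exactly
for the tanh profile. The default domain (length 40, 2001 nodes at
$\mu = \lambda = 1$) keeps boundary effects below the $10^{-4}$ level; a
warning fires below 20 interface widths.

The model itself is equilibrium-only; to *reach* solutions of the
composition equation on a fixed geometry, `relax_composition()` provides
explicit-Euler gradient descent in two flavors. The nonconserved scheme
$\phi \leftarrow \phi - \mathrm{d}t\,(G_\phi - \mu\Delta_s\phi)$ descends
$F$ directly and stationarity means the composition equation holds
pointwise. The conserved scheme
$\phi \leftarrow \phi + \mathrm{d}t\,\Delta_s(G_\phi - \mu\Delta_s\phi)$
preserves $\int\phi\,dA$ to rounding (the flux-form Laplacian telescopes),
and its stationary states satisfy the composition equation only up to an
additive constant — a composition chemical potential, which the trajectory
reports. The equilibrium theory is silent on whether total composition is
constrained, so both behaviors are provided rather than guessing; the
residual reported by the conserved scheme is the surface-mean-free part.
Steps are accepted only if the energy does not increase, with step halving
and mild regrowth; this is deliberately simple (grids are small) and makes
the energy trace monotone by construction, which the tests assert. The
conserved scheme is a fourth-order stiff flow and is correspondingly slow
on fine grids; tests exercise its invariants (mass, monotonicity) at small
sizes rather than deep convergence.

## Synthetic fields and what the tests do (and do not) show

`make_fixture_field()` generates the composition fields used throughout:
uniform values, single spherical/Fourier harmonics, tanh band patterns
(kink pairs), and seeded smooth random fields built from a fixed low-order
harmonic basis — all clipped to $[0,1]$ and byte-reproducible for a given
seed. These emulate the *shape* of composition patterns (caps, bands,
mottled mixtures) on exactly representable geometries. They do not emulate
thermal fluctuations, composition-dependent kinetics, coupled shape
evolution, or real lipidomic parameter values; passing tests therefore
demonstrate the internal consistency and convergence of the discretized
equilibrium framework, not agreement with any particular experimental
vesicle.

Problem sizes were chosen once, as the smallest that cleanly separate
truncation error from rounding: operator grids of $24^2$–$96^2$ ($800$
latitude points only where a $10^{-6}$ quadrature check demands it), kink
grids of 1501–2001 nodes, 200 random parameter draws for the radius
cross-validation, and relaxations of at most a few thousand explicit steps
on $20^2$–$8\times256$ grids.

## Numerical choices and degenerate inputs

* **Parabolic threshold.** The $\bar\Delta_s$ coefficient is zeroed where
  $|K| \le 10^{-10}\max|K|$; an all-parabolic patch (cylinder) short-circuits
  to the zero operator.
* **Degenerate gradients.** Where $(\nabla_s\phi)^2 < 10^{-14}$, $\kappa_n$
  is masked to 0; the shape-equation term multiplies it by
  $(\nabla_s\phi)^2$, so the product is well-defined.
* **Root selection.** Smallest positive real cubic root passing the
  eliminated-residual check; repeated/degenerate cubics are reported, not
  silently resolved.
* **Composition outside $[0,1]$.** The linear mixing rule extrapolates with
  a warning (`mix_moduli`); the relaxation loop extrapolates quietly and can
  optionally clip.
* **$\lambda(T) = \lambda_0(1 - T/T_c)$** is clamped at 0 above $T_c$ with a
  warning: above the critical temperature the components mix and a negative
  well depth would invert the potential. Clamping is a policy choice; the
  alternative (letting $\lambda$ go negative) is not implemented.
* **Ternary crossover.** The homogeneous ternary density has axis-type
  minima $(\pm m, 0)$ with energy $-\alpha^2/(4\beta)$ and diagonal-type
  minima $(\pm m', \pm m')$ with energy $-\alpha^2/(2(\beta+2\gamma))$;
  the classifier compares these closed forms and the crossover is located
  by bisection, reproducing $\gamma_{\rm crit} = \beta/2$. Exact ties are
  reported as `"degenerate"`.
* **Determinism.** Every random fixture takes a mandatory seed; CLI runs
  are pure functions of (config, seed) and print 12 significant digits so
  repeated CSV outputs are byte-identical.

## Known limitations

* No second-variation (stability) analysis of the equilibrium radii.
* No unstructured meshes, genus $\ge 1$ surfaces, topology changes, or
  remeshing; the axisymmetric constructor does not detect self-intersecting
  profiles.
* The $\bar\Delta_s$ convention sacrifices the $\delta K$ identity on
  developable surfaces, as discussed above.
* Non-uniform-composition cylinder radii (where the $\kappa_n$ gradient
  term survives) are evaluated only pointwise through the residual module,
  not solved for.
* Spontaneous curvature, area-difference elasticity, adhesion,
  electrostatics, open edges and all dynamics (hydrodynamics, flip-flop,
  thermal noise) are out of scope.
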