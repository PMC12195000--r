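# The three-part free energy F = Fp + Fs + Fv and the scaling diagnostics.
#
# Fp = (mu/2) int (grad_s phi)^2 dA      composition-gradient energy
# Fs = int G(H, K, phi) dA               curvature elasticity + tension + well
# Fv = P * V                             volume (pressure) term
# with kernel G = (k(phi)/2)(2H)^2 + kbar(phi) K + sigma(phi) + V(phi).

#' Free-energy kernel G(H, K, phi) and its partial derivatives
#'
#' Pointwise elastic energy density of the multicomponent membrane,
#' G = (k(phi)/2)(2H)^2 + kbar(phi) K + sigma(phi) + V(phi), under the linear
#' mixing rule for the moduli. The partial derivatives G_phi, G_H, G_K needed
#' by the Euler-Lagrange residuals are returned alongside.
#'
#' @param H Mean curvature (scalar or matrix).
#' @param K Gaussian curvature (same shape as `H`).
#' @param phi Composition (same shape).
#' @param m A [component_moduli()] bundle.
#' @param c A [coupling_params()] bundle (supplies the double-well lambda).
#' @return A list with `G`, `G_phi`, `G_H`, `G_K`, each the shape of `H`.
#' @export
energy_density <- function(H, K, phi, m, c) {
  stopifnot(inherits(m, "component_moduli"), inherits(c, "coupling_params"))
  mx <- mix_moduli(phi, m)
  list(G = 2 * mx$k * H^2 + mx$kbar * K + mx$sigma + double_well(phi, c$lam),
       G_phi = 2 * m$dk * H^2 + m$dkbar * K + m$dsigma +
         double_well_prime(phi, c$lam),
       G_H = 4 * mx$k * H,
       G_K = mx$kbar)
}

#' Total free energy of a composition field on a patch
#'
#' Quadrature of (mu/2)(grad_s phi)^2 + G over the patch, plus P * V for a
#' closed patch. Returned as an itemized breakdown whose parts sum to the
#' total.
#'
#' @param patch A `membrane_patch`.
#' @param phi Field matrix on the patch grid.
#' @param m A [component_moduli()] bundle.
#' @param c A [coupling_params()] bundle.
#' @return An object of class `energy_breakdown`: list with `Fp` (gradient
#'   energy), `bending`, `gaussian`, `tension`, `potential` (the four parts
#'   of Fs), `Fs`, `Fv`, and `total`.
#' @export
total_energy <- function(patch, phi, m, c) {
  stopifnot(inherits(patch, "membrane_patch"))
  if (c$P != 0 && !isTRUE(patch$closed))
    stop("P != 0 requires a closed patch")
  mx <- mix_moduli(phi, m)
  grad <- surface_gradient(patch, phi)
  Fp <- patch_integral(patch, (c$mu / 2) * grad$grad_sq)
  bending <- patch_integral(patch, 2 * mx$k * patch$H^2)
  gaussian <- patch_integral(patch, mx$kbar * patch$K)
  tension <- patch_integral(patch, mx$sigma)
  potential <- patch_integral(patch, double_well(phi, c$lam))
  Fv <- if (c$P != 0) c$P * patch_volume(patch) else 0
  Fs <- bending + gaussian + tension + potential
  structure(list(Fp = Fp, bending = bending, gaussian = gaussian,
                 tension = tension, potential = potential,
                 Fs = Fs, Fv = Fv, total = Fp + Fs + Fv),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("energy breakdown:\n")
  for (nm in c("Fp", "bending", "gaussian", "tension", "potential", "Fv", "total"))
    cat(sprintf("  %-10s %.10g\n", nm, x[[nm]]))
  invisible(x)
}

#' Constraint multipliers for the scaling diagnostic
#'
#' @param Lambda Area multiplier (energy / length^2).
#' @param P Volume multiplier / pressure (energy / length^3).
#' @param kappa_w Willmore bending rigidity (energy).
#' @return An object of class `constraint_multipliers`.
#' @export
constraint_multipliers <- function(Lambda = 0, P = 0, kappa_w = 1) {
  stopifnot(is.finite(Lambda), is.finite(P), is.finite(kappa_w))
  structure(list(Lambda = Lambda, P = P, kappa_w = kappa_w),
            class = "constraint_multipliers")
}

#' Scaling diagnostic of the constrained Willmore energy
#'
#' Evaluates E(s) = int 2 kappa H^2 dA + Lambda * A + P * V on rescaled
#' copies r -> (1 + s) r of a closed patch. The Willmore part is scale
#' invariant, so dE/ds at s = 0 isolates the constraint contributions
#' 2 Lambda A + 3 P V: in equilibrium this virial combination vanishes, and
#' with only one constraint active its multiplier must be zero.
#'
#' @param patch A closed `membrane_patch`.
#' @param mult A [constraint_multipliers()] bundle.
#' @param ds Finite-difference step for dE/ds.
#' @return A list with `willmore`, `A`, `V`, `dE_ds` (centered finite
#'   difference at s = 0), and `virial` = 2 Lambda A + 3 P V.
#' @export
scaling_check <- function(patch, mult, ds = 1e-5) {
  stopifnot(inherits(patch, "membrane_patch"), isTRUE(patch$closed),
            inherits(mult, "constraint_multipliers"))
  Etot <- function(s) {
    p <- rescale_patch(patch, 1 + s)
    patch_integral(p, 2 * mult$kappa_w * p$H^2) +
      mult$Lambda * patch_area(p) + mult$P * patch_volume(p)
  }
  A <- patch_area(patch); V <- patch_volume(patch)
  list(willmore = patch_integral(patch, 2 * mult$kappa_w * patch$H^2),
       A = A, V = V,
       dE_ds = (Etot(ds) - Etot(-ds)) / (2 * ds),
       virial = 2 * mult$Lambda * A + 3 * mult$P * V)
}

#' Stationary radius of the constrained sphere energy
#'
#' Locates the stationary radius of E(R) = 8 pi kappa + Lambda 4 pi R^2
#' + P (4 pi / 3) R^3 numerically (root of the centered-difference dE/dR;
#' with an area multiplier and a negative pressure the stationary point is
#' the constrained equilibrium) and reports the virial combination
#' 2 Lambda A + 3 P V there.
#'
#' @param mult A [constraint_multipliers()] bundle; requires a bracketable
#'   stationary point (e.g. Lambda > 0, P < 0).
#' @param interval Search interval for the stationary radius.
#' @return A list with `R`, `A`, `V`, `energy`, and `virial`.
#' @export
sphere_energy_stationary_radius <- function(mult, interval = c(1e-3, 1e3)) {
  E <- function(R) 8 * pi * mult$kappa_w + mult$Lambda * 4 * pi * R^2 +
    mult$P * (4 * pi / 3) * R^3
  h <- 1e-5
  dE <- function(R) (E(R + h) - E(R - h)) / (2 * h)
  R <- stats::uniroot(dE, interval, tol = 1e-13)$root
  A <- 4 * pi * R^2; V <- (4 * pi / 3) * R^3
  list(R = R, A = A, V = V, energy = E(R),
       virial = 2 * mult$Lambda * A + 3 * mult$P * V)
}
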