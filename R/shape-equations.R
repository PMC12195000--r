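# Pointwise Euler-Lagrange residuals of the coupled curvature-composition
# equilibrium equations, their specializations to spheres, cylinders and
# constant-mean-curvature surfaces, and the first-variation identity checker.
#
# Composition equation:  G_phi - mu Delta_s phi = 0
# Normal force balance:  Delta_s(G_H/2) + Dbar_s(G_K) + (2H^2 - K) G_H
#                          + 2 K H G_K - 2 H G + mu (kappa_n - H)(grad phi)^2
#                          + P = 0

residual_norms <- function(patch, f) {
  A <- patch_area(patch)
  list(max_abs = max(abs(f)),
       rms = sqrt(patch_integral(patch, f^2) / A))
}

#' Composition Euler-Lagrange residual
#'
#' Pointwise residual of the composition equation G_phi - mu Delta_s phi,
#' with G_phi = 2 k'(phi) H^2 + kbar'(phi) K + sigma'(phi)
#' + lam phi (1 - phi)(1 - 2 phi) under the linear mixing rule. Zero at an
#' equilibrium composition field.
#'
#' @param patch A `membrane_patch`.
#' @param phi Composition field matrix.
#' @param m A [component_moduli()] bundle.
#' @param c A [coupling_params()] bundle.
#' @return Residual field matrix (energy / length^2 per unit phi).
#' @export
composition_residual <- function(patch, phi, m, c) {
  ed <- energy_density(patch$H, patch$K, phi, m, c)
  ed$G_phi - c$mu * laplace_beltrami(patch, phi)
}

#' Normal-direction Euler-Lagrange residual (shape equation)
#'
#' Pointwise residual of the normal force balance of the generalized
#' free energy, using the two discrete surface operators. The
#' mu (kappa_n - H)(grad_s phi)^2 term is set to exact zero where the
#' squared gradient is below threshold.
#'
#' @inheritParams composition_residual
#' @return Residual field matrix (energy / length^3).
#' @export
normal_residual <- function(patch, phi, m, c) {
  if (c$P != 0 && !isTRUE(patch$closed))
    warning("P term included on an open patch")
  ed <- energy_density(patch$H, patch$K, phi, m, c)
  grad <- surface_gradient(patch, phi)
  kn <- normal_curvature_along(patch, phi)
  kn_term <- c$mu * (kn$kappa_n - patch$H) * grad$grad_sq
  kn_term[grad$grad_sq < 1e-14] <- 0
  laplace_beltrami(patch, ed$G_H / 2) +
    gaussian_laplace_beltrami(patch, ed$G_K) +
    (2 * patch$H^2 - patch$K) * ed$G_H +
    2 * patch$K * patch$H * ed$G_K -
    2 * patch$H * ed$G +
    kn_term + c$P
}

residual_fields <- function(patch, comp, normal) {
  structure(list(comp = comp, normal = normal,
                 comp_norms = residual_norms(patch, comp),
                 normal_norms = residual_norms(patch, normal)),
            class = "residual_fields")
}

#' @export
print.residual_fields <- function(x, ...) {
  cat(sprintf("residual fields: comp max|.| %.4g (rms %.4g); normal max|.| %.4g (rms %.4g)\n",
              x$comp_norms$max_abs, x$comp_norms$rms,
              x$normal_norms$max_abs, x$normal_norms$rms))
  invisible(x)
}

#' Specialized residuals on a spherical patch
#'
#' Evaluates the sphere-specialized equilibrium equations (written with the
#' explicit spherical operators, H = kappa_n = -1/R, K = 1/R^2):
#' composition (1/R^2)(2 k' + kbar') + sigma' + dV/dphi - mu Delta_s phi and
#' normal -(1/R) Delta_s(2 k + kbar) + 2 sigma/R + (lam/R) phi^2(1-phi)^2 + P.
#' On a sphere the normal balance is independent of the composition gradient:
#' the mu (kappa_n - H)(grad phi)^2 term vanishes identically.
#'
#' @inheritParams composition_residual
#' @param patch A sphere `membrane_patch`.
#' @return A `residual_fields` object with `comp`, `normal` and their norms.
#' @export
sphere_residuals <- function(patch, phi, m, c) {
  stopifnot(patch$kind == "sphere")
  R <- patch$R
  mx <- mix_moduli(phi, m)
  comp <- (2 * m$dk + m$dkbar) / R^2 + m$dsigma +
    double_well_prime(phi, c$lam) - c$mu * laplace_beltrami(patch, phi)
  normal <- -(1 / R) * laplace_beltrami(patch, 2 * mx$k + mx$kbar) +
    2 * mx$sigma / R + (c$lam / R) * phi^2 * (1 - phi)^2 + c$P
  residual_fields(patch, comp, normal)
}

#' Specialized residuals on a cylindrical patch
#'
#' Evaluates the cylinder-specialized equilibrium equations (H = -1/(2R),
#' K = 0, Dbar_s = 0): composition k'/(2R^2) + sigma' + dV/dphi
#' - mu Delta_s phi and normal -(1/R) Delta_s k - k/(2R^3) + sigma/R
#' + (lam/(2R)) phi^2 (1-phi)^2 + mu (kappa_n + 1/(2R)) (grad phi)^2 + P,
#' with kappa_n computed along the composition gradient.
#'
#' @inheritParams composition_residual
#' @param patch A cylinder `membrane_patch`.
#' @return A `residual_fields` object.
#' @export
cylinder_residuals <- function(patch, phi, m, c) {
  stopifnot(patch$kind == "cylinder")
  R <- patch$R
  mx <- mix_moduli(phi, m)
  comp <- m$dk / (2 * R^2) + m$dsigma +
    double_well_prime(phi, c$lam) - c$mu * laplace_beltrami(patch, phi)
  grad <- surface_gradient(patch, phi)
  kn <- normal_curvature_along(patch, phi)
  kn_term <- c$mu * (kn$kappa_n + 1 / (2 * R)) * grad$grad_sq
  kn_term[grad$grad_sq < 1e-14] <- 0
  normal <- -(1 / R) * laplace_beltrami(patch, mx$k) -
    mx$k / (2 * R^3) + mx$sigma / R +
    (c$lam / (2 * R)) * phi^2 * (1 - phi)^2 + kn_term + c$P
  residual_fields(patch, comp, normal)
}

#' Specialized residuals on a constant-mean-curvature patch
#'
#' For a patch with H = H0 everywhere: composition
#' 2 k' H0^2 + kbar' K + sigma' + dV/dphi - mu Delta_s phi, and normal
#' 2 H0 Delta_s k + Dbar_s kbar + 4 k H0 (H0^2 - K) - 2 sigma H0
#' - lam H0 phi^2(1-phi)^2 + mu (kappa_n - H0)(grad phi)^2 + P.
#' At H0 = 0 the pair reduces to the minimal-surface equations
#' kbar' K + sigma' + dV/dphi - mu Delta_s phi = 0 and
#' Dbar_s kbar + mu kappa_n (grad phi)^2 + P = 0.
#'
#' @inheritParams composition_residual
#' @param H0 The constant mean curvature; defaults to the patch mean.
#' @param tol Tolerance on max|H - H0| for accepting the patch as CMC.
#' @return A `residual_fields` object.
#' @export
cmc_residuals <- function(patch, phi, m, c, H0 = NULL, tol = 1e-8) {
  if (is.null(H0)) H0 <- mean(patch$H)
  if (max(abs(patch$H - H0)) > tol)
    stop("patch is not CMC within tolerance: max|H - H0| = ",
         format(max(abs(patch$H - H0))))
  K <- patch$K
  mx <- mix_moduli(phi, m)
  comp <- 2 * m$dk * H0^2 + m$dkbar * K + m$dsigma +
    double_well_prime(phi, c$lam) - c$mu * laplace_beltrami(patch, phi)
  grad <- surface_gradient(patch, phi)
  kn <- normal_curvature_along(patch, phi)
  kn_term <- c$mu * (kn$kappa_n - H0) * grad$grad_sq
  kn_term[grad$grad_sq < 1e-14] <- 0
  normal <- 2 * H0 * laplace_beltrami(patch, mx$k) +
    gaussian_laplace_beltrami(patch, mx$kbar) +
    4 * mx$k * H0 * (H0^2 - K) - 2 * mx$sigma * H0 -
    c$lam * H0 * phi^2 * (1 - phi)^2 + kn_term + c$P
  residual_fields(patch, comp, normal)
}

#' General residual pair on any patch
#'
#' Convenience wrapper bundling [composition_residual()] and
#' [normal_residual()] with their norms.
#'
#' @inheritParams composition_residual
#' @return A `residual_fields` object.
#' @export
general_residuals <- function(patch, phi, m, c) {
  residual_fields(patch,
                  composition_residual(patch, phi, m, c),
                  normal_residual(patch, phi, m, c))
}

# covariant divergence of a contravariant tangent field
covariant_divergence <- function(patch, v1, v2) {
  (d1c(patch$sqrtg * v1, patch$du1, patch$periodic1) +
     d2c(patch$sqrtg * v2, patch$du2, patch$periodic2)) / patch$sqrtg
}

#' First-variation identity check
#'
#' Deforms the embedding by eps * (phi1 e_1 + phi2 e_2 + psi n), recomputes
#' the discrete geometry from the deformed embedding, and compares centered
#' finite differences (X(eps) - X(-eps)) / (2 eps) against the analytic
#' first-variation formulas for sqrt(g), A, H, K and V:
#' delta sqrt(g) = sqrt(g)(div phi^i - 2 H psi), delta A = integral of that,
#' delta H = (2H^2 - K) psi + (1/2) Delta_s psi + phi^i d_i H,
#' delta K = Dbar_s psi + 2 H K psi + phi^i d_i K, delta V = int psi dA.
#' Both sides are evaluated through the same finite-difference geometry
#' pipeline so that grid discretization error largely cancels; the residual
#' discrepancy decays at second order in eps down to the grid floor.
#'
#' @param patch A `membrane_patch`.
#' @param psi Normal perturbation field matrix.
#' @param tangential Optional list with contravariant components `v1`, `v2`
#'   of the tangential perturbation (default zero).
#' @param eps_grid Perturbation amplitudes, largest first.
#' @return A list with `table` (data frame: identity, eps, fd, formula,
#'   discrepancy) and `orders` (estimated convergence order per identity;
#'   NA when the discrepancy has hit the grid floor).
#' @export
check_first_variations <- function(patch, psi, tangential = NULL,
                                   eps_grid = c(1e-2, 5e-3, 2.5e-3)) {
  stopifnot(inherits(patch, "membrane_patch"))
  z <- matrix(0, patch$n1, patch$n2)
  v1 <- if (is.null(tangential)) z else tangential$v1
  v2 <- if (is.null(tangential)) z else tangential$v2

  # baseline finite-difference geometry and tangent frame
  base <- patch_from_embedding(patch$kind, patch$u1, patch$u2,
                               patch$x, patch$y, patch$z,
                               patch$periodic1, patch$periodic2, patch$closed)
  e1 <- list(x = d1c(patch$x, patch$du1, patch$periodic1),
             y = d1c(patch$y, patch$du1, patch$periodic1),
             z = d1c(patch$z, patch$du1, patch$periodic1))
  e2 <- list(x = d2c(patch$x, patch$du2, patch$periodic2),
             y = d2c(patch$y, patch$du2, patch$periodic2),
             z = d2c(patch$z, patch$du2, patch$periodic2))
  deformed <- function(eps) {
    patch_from_embedding(patch$kind, patch$u1, patch$u2,
      patch$x + eps * (v1 * e1$x + v2 * e2$x + psi * base$nx),
      patch$y + eps * (v1 * e1$y + v2 * e2$y + psi * base$ny),
      patch$z + eps * (v1 * e1$z + v2 * e2$z + psi * base$nz),
      patch$periodic1, patch$periodic2, patch$closed)
  }

  div_t <- covariant_divergence(base, v1, v2)
  formula <- list(
    sqrtg = base$sqrtg * (div_t - 2 * base$H * psi),
    A = patch_integral(base, div_t - 2 * base$H * psi),
    H = (2 * base$H^2 - base$K) * psi + 0.5 * laplace_beltrami(base, psi) +
      v1 * d1c(base$H, base$du1, base$periodic1) +
      v2 * d2c(base$H, base$du2, base$periodic2),
    K = gaussian_laplace_beltrami(base, psi) + 2 * base$H * base$K * psi +
      v1 * d1c(base$K, base$du1, base$periodic1) +
      v2 * d2c(base$K, base$du2, base$periodic2),
    V = if (isTRUE(patch$closed)) patch_integral(base, psi) else NA_real_)

  rows <- list()
  for (eps in eps_grid) {
    pp <- deformed(eps); pm <- deformed(-eps)
    fd <- list(
      sqrtg = (pp$sqrtg - pm$sqrtg) / (2 * eps),
      A = (patch_area(pp) - patch_area(pm)) / (2 * eps),
      H = (pp$H - pm$H) / (2 * eps),
      K = (pp$K - pm$K) / (2 * eps),
      V = if (isTRUE(patch$closed))
        (patch_volume(pp) - patch_volume(pm)) / (2 * eps) else NA_real_)
    for (id in names(formula)) {
      fv <- formula[[id]]; dv <- fd[[id]]
      if (is.matrix(fv)) {
        scale <- max(sqrt(patch_integral(base, fv^2) / patch_area(base)), 1e-12)
        disc <- sqrt(patch_integral(base, (dv - fv)^2) / patch_area(base)) / scale
        rows[[length(rows) + 1]] <- data.frame(
          identity = id, eps = eps, fd = NA_real_, formula = NA_real_,
          discrepancy = disc)
      } else if (is.finite(fv)) {
        rows[[length(rows) + 1]] <- data.frame(
          identity = id, eps = eps, fd = dv, formula = fv,
          discrepancy = abs(dv - fv) / max(abs(fv), 1e-12))
      }
    }
  }
  tab <- do.call(rbind, rows)
  orders <- vapply(unique(tab$identity), function(id) {
    d <- tab$discrepancy[tab$identity == id]
    e <- tab$eps[tab$identity == id]
    if (length(d) < 2 || any(d < 1e-11)) return(NA_real_)
    stats::coef(stats::lm(log(d) ~ log(e)))[2]
  }, numeric(1))
  names(orders) <- unique(tab$identity)
  list(table = tab, orders = orders)
}

#' Gaussian-rigidity nanotube diagnostic
#'
#' Computes the field Dbar_s kbar(phi) together with |K|, flagging nodes
#' where a sharp variation of the Gaussian modulus coincides with K near 0.
#' Sharp modulus variation on a developable region (K = 0) costs nothing
#' through this term, which is why cylindrical and conical protrusions are
#' the favored local structures for abrupt Gaussian-rigidity changes; on
#' curved regions (K away from 0) the same variation is penalized.
#'
#' @inheritParams composition_residual
#' @param grad_quantile Quantile of |grad kbar| above which variation counts
#'   as sharp.
#' @param K_tol Threshold on |K| (relative to its patch maximum) below which
#'   a node counts as developable.
#' @return A list with `dbar_kbar` (field), `abs_K`, `sharp` (logical),
#'   `tube_favorable` (logical: sharp variation AND K ~ 0).
#' @export
gaussian_rigidity_diagnostic <- function(patch, phi, m,
                                         grad_quantile = 0.9, K_tol = 1e-8) {
  kbar <- mix_moduli(phi, m)$kbar
  grad <- surface_gradient(patch, kbar)
  gmag <- sqrt(grad$grad_sq)
  thr <- stats::quantile(gmag, grad_quantile)
  sharp <- gmag > thr & gmag > 1e-12
  developable <- abs(patch$K) <= K_tol * max(abs(patch$K), 1e-300)
  list(dbar_kbar = gaussian_laplace_beltrami(patch, kbar),
       abs_K = abs(patch$K),
       sharp = sharp,
       tube_favorable = sharp & developable)
}
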