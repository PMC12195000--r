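# Parametric surface patches and discrete differential operators.
#
# A patch is a structured grid over a chart (u1, u2) carrying the embedding
# r(u1,u2), outward unit normal, metric g_ij, area element sqrt(g), extrinsic
# curvature tensor L_ij, mean curvature H and Gaussian curvature K. Scalar
# fields are plain matrices conforming to the grid. Sign convention
# throughout: outward normal, L_ij = n . d2r/du_i du_j, so a sphere has
# H = -1/R, K = 1/R^2 and a cylinder H = -1/(2R), K = 0.

new_membrane_patch <- function(kind, u1, u2, du1, du2, periodic1, periodic2,
                               x, y, z, nx, ny, nz,
                               g11, g12, g22, L11, L12, L22,
                               H, K, R = NA_real_, closed = FALSE,
                               analytic = FALSE) {
  detg <- g11 * g22 - g12^2
  if (any(detg <= 0)) stop("metric not positive definite on patch")
  structure(list(
    kind = kind, u1 = u1, u2 = u2, du1 = du1, du2 = du2,
    periodic1 = periodic1, periodic2 = periodic2,
    n1 = length(u1), n2 = length(u2),
    x = x, y = y, z = z, nx = nx, ny = ny, nz = nz,
    g11 = g11, g12 = g12, g22 = g22, detg = detg, sqrtg = sqrt(detg),
    gi11 = g22 / detg, gi12 = -g12 / detg, gi22 = g11 / detg,
    L11 = L11, L12 = L12, L22 = L22,
    H = H, K = K, R = R, closed = closed, analytic = analytic),
    class = "membrane_patch")
}

#' @export
print.membrane_patch <- function(x, ...) {
  cat(sprintf("membrane_patch: %s grid %d x %d (%s, %s)\n", x$kind,
              x$n1, x$n2,
              if (x$periodic1) "periodic" else "open",
              if (x$periodic2) "periodic" else "open"))
  cat(sprintf("  H in [%.4g, %.4g], K in [%.4g, %.4g], area %.6g\n",
              min(x$H), max(x$H), min(x$K), max(x$K), patch_area(x)))
  invisible(x)
}

#' Spherical surface patch
#'
#' Latitude-longitude chart of a sphere of radius `R` with the poles excluded
#' by a half-cell offset: theta_i = (i - 1/2) pi / n_theta, Psi_j periodic.
#' Metric and curvature data are stored analytically (H = -1/R, K = 1/R^2,
#' outward normal), so operator tests measure only the stencil error.
#'
#' @param R Sphere radius, > 0.
#' @param n_theta,n_psi Grid resolution (>= 8 each).
#' @return A `membrane_patch`.
#' @export
make_sphere <- function(R, n_theta = 48, n_psi = 48) {
  stopifnot(R > 0, n_theta >= 8, n_psi >= 8)
  du1 <- pi / n_theta
  du2 <- 2 * pi / n_psi
  theta <- (seq_len(n_theta) - 0.5) * du1
  psi <- (seq_len(n_psi) - 1) * du2
  st <- sin(theta); ct <- cos(theta)
  cp <- cos(psi); sp <- sin(psi)
  x <- R * outer(st, cp); y <- R * outer(st, sp); z <- R * outer(ct, rep(1, n_psi))
  one <- matrix(1, n_theta, n_psi)
  stm <- outer(st, rep(1, n_psi))
  new_membrane_patch("sphere", theta, psi, du1, du2, FALSE, TRUE,
    x, y, z, x / R, y / R, z / R,
    g11 = R^2 * one, g12 = 0 * one, g22 = R^2 * stm^2,
    L11 = -R * one, L12 = 0 * one, L22 = -R * stm^2,
    H = -one / R, K = one / R^2, R = R, closed = TRUE, analytic = TRUE)
}

#' Cylindrical surface patch
#'
#' Chart (Psi, z), both directions closed periodically (torus-like closure in
#' z) so that operator tests are boundary-free; fields placed on the patch
#' should be z-periodic. Analytic curvatures H = -1/(2R), K = 0 with outward
#' normal.
#'
#' @param R Cylinder radius, > 0.
#' @param L Cylinder length (z period), > 0.
#' @param n_psi,n_z Grid resolution.
#' @return A `membrane_patch`.
#' @export
make_cylinder <- function(R, L, n_psi = 48, n_z = 48) {
  stopifnot(R > 0, L > 0, n_psi >= 8, n_z >= 8)
  du1 <- 2 * pi / n_psi
  du2 <- L / n_z
  psi <- (seq_len(n_psi) - 1) * du1
  zz <- (seq_len(n_z) - 1) * du2
  cp <- cos(psi); sp <- sin(psi)
  x <- R * outer(cp, rep(1, n_z)); y <- R * outer(sp, rep(1, n_z))
  z <- outer(rep(1, n_psi), zz)
  one <- matrix(1, n_psi, n_z)
  new_membrane_patch("cylinder", psi, zz, du1, du2, TRUE, TRUE,
    x, y, z, x / R, y / R, 0 * one,
    g11 = R^2 * one, g12 = 0 * one, g22 = one,
    L11 = -R * one, L12 = 0 * one, L22 = 0 * one,
    H = -one / (2 * R), K = 0 * one, R = R, closed = FALSE, analytic = TRUE)
}

# ---- finite differences on the parameter grid -------------------------------

# centered first derivative along dim 1 (2nd order; one-sided at open ends)
d1c <- function(f, du, periodic) {
  n <- nrow(f)
  if (periodic) {
    (f[c(2:n, 1), , drop = FALSE] - f[c(n, 1:(n - 1)), , drop = FALSE]) / (2 * du)
  } else {
    d <- (rbind(f[2:n, , drop = FALSE], 0) - rbind(0, f[1:(n - 1), , drop = FALSE])) / (2 * du)
    d[1, ] <- (-3 * f[1, ] + 4 * f[2, ] - f[3, ]) / (2 * du)
    d[n, ] <- (3 * f[n, ] - 4 * f[n - 1, ] + f[n - 2, ]) / (2 * du)
    d
  }
}

d2c <- function(f, du, periodic) t(d1c(t(f), du, periodic))

# conservative divergence term along dim 1: (1/du) * d/du1 (c * d f/du1)
# with face-averaged coefficient; zero flux through open-boundary faces.
flux_div1 <- function(f, cc, du, periodic) {
  n <- nrow(f)
  if (periodic) {
    ip <- c(2:n, 1)
    Fface <- 0.5 * (cc + cc[ip, , drop = FALSE]) *
      (f[ip, , drop = FALSE] - f) / du             # face i+1/2
    (Fface - Fface[c(n, 1:(n - 1)), , drop = FALSE]) / du
  } else {
    Fint <- 0.5 * (cc[1:(n - 1), , drop = FALSE] + cc[2:n, , drop = FALSE]) *
      (f[2:n, , drop = FALSE] - f[1:(n - 1), , drop = FALSE]) / du
    up <- rbind(Fint, 0)    # flux at face i+1/2 (0 at the last boundary face)
    lo <- rbind(0, Fint)    # flux at face i-1/2
    (up - lo) / du
  }
}

flux_div2 <- function(f, cc, du, periodic) t(flux_div1(t(f), t(cc), du, periodic))

# generic divergence-form operator (1/sqrtg) d_i ( sqrtg C^ij d_j f )
# for a symmetric coefficient tensor C. Mixed terms use centered stencils
# (exactly antisymmetric on periodic directions); they vanish on the
# orthogonal charts used by the constructors.
div_form_operator <- function(patch, f, C11, C12, C22) {
  w <- patch$sqrtg
  out <- flux_div1(f, w * C11, patch$du1, patch$periodic1) +
         flux_div2(f, w * C22, patch$du2, patch$periodic2)
  if (any(C12 != 0)) {
    out <- out +
      d1c(w * C12 * d2c(f, patch$du2, patch$periodic2), patch$du1, patch$periodic1) +
      d2c(w * C12 * d1c(f, patch$du1, patch$periodic1), patch$du2, patch$periodic2)
  }
  out / w
}

#' Surface gradient of a scalar field
#'
#' Contravariant components v^i = g^ij d_j f of the intrinsic gradient, plus
#' the squared norm (grad_s f)^2 = g^ij d_i f d_j f.
#'
#' @param patch A `membrane_patch`.
#' @param f Matrix conforming to the patch grid.
#' @return A list with `v1`, `v2` (contravariant components) and `grad_sq`.
#' @export
surface_gradient <- function(patch, f) {
  stopifnot(inherits(patch, "membrane_patch"), all(dim(f) == c(patch$n1, patch$n2)))
  f1 <- d1c(f, patch$du1, patch$periodic1)
  f2 <- d2c(f, patch$du2, patch$periodic2)
  list(v1 = patch$gi11 * f1 + patch$gi12 * f2,
       v2 = patch$gi12 * f1 + patch$gi22 * f2,
       grad_sq = patch$gi11 * f1^2 + 2 * patch$gi12 * f1 * f2 + patch$gi22 * f2^2)
}

#' Laplace-Beltrami operator
#'
#' Intrinsic surface Laplacian in divergence form,
#' Delta_s f = (1/sqrt(g)) d_i ( sqrt(g) g^ij d_j f ), discretized with
#' face-averaged flux coefficients so that constants are annihilated exactly
#' and the operator is self-adjoint with respect to the sqrt(g)-weighted
#' inner product by construction.
#'
#' @inheritParams surface_gradient
#' @return Matrix of the same shape as `f`.
#' @export
laplace_beltrami <- function(patch, f) {
  stopifnot(inherits(patch, "membrane_patch"), all(dim(f) == c(patch$n1, patch$n2)))
  div_form_operator(patch, f, patch$gi11, patch$gi12, patch$gi22)
}

# Coefficient tensor K * (L^-1)^ij of the Gaussian-weighted operator.
# Where the curvature tensor is invertible this is the adjugate adj(L)/det(g);
# at parabolic points (K = 0) the product K * L^-1 is taken as exactly zero,
# which reproduces the operator's vanishing on developable surfaces.
gaussian_coefficient_tensor <- function(patch) {
  detL <- patch$L11 * patch$L22 - patch$L12^2
  keep <- abs(patch$K) > 1e-10 * max(abs(patch$K))
  if (max(abs(patch$K)) == 0) keep <- patch$K != 0   # all-parabolic patch
  z <- matrix(0, patch$n1, patch$n2)
  C11 <- z; C12 <- z; C22 <- z
  C11[keep] <- patch$L22[keep] / patch$detg[keep]
  C12[keep] <- -patch$L12[keep] / patch$detg[keep]
  C22[keep] <- patch$L11[keep] / patch$detg[keep]
  list(C11 = C11, C12 = C12, C22 = C22)
}

#' Gaussian-curvature-weighted Laplace-Beltrami operator
#'
#' The second surface operator,
#' Delta-bar_s f = (1/sqrt(g)) d_i ( sqrt(g) K (L^-1)^ij d_j f ),
#' built from the curvature tensor. On a sphere of radius R it equals
#' -(1/R) Delta_s; on a cylinder (or any developable surface, K = 0) it
#' vanishes identically, the parabolic-point convention K * L^-1 -> 0 being
#' applied there. This operator arises from the first variation of the
#' Gaussian-rigidity energy and controls where sharp variation of the
#' Gaussian modulus is energetically admissible.
#'
#' @inheritParams surface_gradient
#' @return Matrix of the same shape as `f`.
#' @export
gaussian_laplace_beltrami <- function(patch, f) {
  stopifnot(inherits(patch, "membrane_patch"), all(dim(f) == c(patch$n1, patch$n2)))
  C <- gaussian_coefficient_tensor(patch)
  if (max(abs(C$C11), abs(C$C12), abs(C$C22)) == 0)
    return(matrix(0, patch$n1, patch$n2))
  div_form_operator(patch, f, C$C11, C$C12, C$C22)
}

#' Normal curvature along the gradient of a field
#'
#' kappa_n = L_ij t^i t^j with t the g-unit tangent along grad_s f. Where
#' the gradient magnitude falls below `threshold` the value is set to exact 0
#' (in the shape equation the kappa_n term is multiplied by (grad_s phi)^2,
#' so the product remains well-defined).
#'
#' @inheritParams surface_gradient
#' @param threshold Squared-gradient cutoff below which kappa_n is masked to 0.
#' @return A list with `kappa_n` (matrix) and `mask` (logical matrix, TRUE
#'   where the gradient was below threshold).
#' @export
normal_curvature_along <- function(patch, f, threshold = 1e-14) {
  g <- surface_gradient(patch, f)
  num <- patch$L11 * g$v1^2 + 2 * patch$L12 * g$v1 * g$v2 + patch$L22 * g$v2^2
  den <- patch$g11 * g$v1^2 + 2 * patch$g12 * g$v1 * g$v2 + patch$g22 * g$v2^2
  mask <- den < threshold
  kn <- matrix(0, patch$n1, patch$n2)
  kn[!mask] <- num[!mask] / den[!mask]
  list(kappa_n = kn, mask = mask)
}

#' Integrate a scalar field over the patch
#'
#' Midpoint/trapezoid quadrature with sqrt(g) weights (spectrally accurate on
#' periodic directions).
#'
#' @inheritParams surface_gradient
#' @return Scalar integral of `f` dA.
#' @export
patch_integral <- function(patch, f) {
  sum(f * patch$sqrtg) * patch$du1 * patch$du2
}

#' Patch surface area
#' @param patch A `membrane_patch`.
#' @return Area (quadrature of sqrt(g)).
#' @export
patch_area <- function(patch) {
  patch_integral(patch, matrix(1, patch$n1, patch$n2))
}

#' Enclosed volume of a closed patch
#'
#' V = (1/3) closed-integral of n . r dA (divergence theorem applied to the
#' position field).
#'
#' @param patch A closed `membrane_patch`.
#' @return Enclosed volume.
#' @export
patch_volume <- function(patch) {
  if (!isTRUE(patch$closed)) stop("volume requires a closed patch")
  patch_integral(patch, (patch$nx * patch$x + patch$ny * patch$y +
                           patch$nz * patch$z) / 3)
}

#' Rescale a patch about the origin
#'
#' Applies r -> s r: the embedding is multiplied by `s`, the metric by s^2,
#' curvatures H by 1/s and K by 1/s^2.
#'
#' @param patch A `membrane_patch`.
#' @param scale Positive scale factor.
#' @return The rescaled `membrane_patch`.
#' @export
rescale_patch <- function(patch, scale) {
  stopifnot(scale > 0)
  s <- scale
  new_membrane_patch(patch$kind, patch$u1, patch$u2, patch$du1, patch$du2,
    patch$periodic1, patch$periodic2,
    s * patch$x, s * patch$y, s * patch$z, patch$nx, patch$ny, patch$nz,
    s^2 * patch$g11, s^2 * patch$g12, s^2 * patch$g22,
    s * patch$L11, s * patch$L12, s * patch$L22,
    patch$H / s, patch$K / s^2,
    R = patch$R * s, closed = patch$closed, analytic = patch$analytic)
}

#' Surface patch from an embedding grid
#'
#' Builds a patch from sampled embedding coordinates, computing metric,
#' normal and curvature by second-order finite differences. Used for
#' surfaces of revolution and for the perturbed surfaces of the
#' first-variation checks. The normal is oriented away from the z-axis
#' (outward for the surfaces of revolution produced here); self-intersecting
#' inputs are not detected.
#'
#' @param kind Label for the patch.
#' @param u1,u2 Parameter sample vectors (uniform spacing).
#' @param x,y,z Embedding coordinate matrices (n1 x n2).
#' @param periodic1,periodic2 Periodicity flags of the two directions.
#' @param closed Whether the surface encloses a volume.
#' @return A `membrane_patch` with finite-difference geometry.
#' @export
patch_from_embedding <- function(kind, u1, u2, x, y, z,
                                 periodic1, periodic2, closed = FALSE) {
  du1 <- u1[2] - u1[1]; du2 <- u2[2] - u2[1]
  dx1 <- d1c(x, du1, periodic1); dy1 <- d1c(y, du1, periodic1); dz1 <- d1c(z, du1, periodic1)
  dx2 <- d2c(x, du2, periodic2); dy2 <- d2c(y, du2, periodic2); dz2 <- d2c(z, du2, periodic2)
  g11 <- dx1^2 + dy1^2 + dz1^2
  g12 <- dx1 * dx2 + dy1 * dy2 + dz1 * dz2
  g22 <- dx2^2 + dy2^2 + dz2^2
  cx <- dy1 * dz2 - dz1 * dy2
  cy <- dz1 * dx2 - dx1 * dz2
  cz <- dx1 * dy2 - dy1 * dx2
  cn <- sqrt(cx^2 + cy^2 + cz^2)
  nx <- cx / cn; ny <- cy / cn; nz <- cz / cn
  # orient away from the z-axis (outward for surfaces of revolution)
  rho <- sqrt(x^2 + y^2)
  ok <- rho > 1e-12
  if (mean((nx * x + ny * y)[ok] / rho[ok]) < 0) {
    nx <- -nx; ny <- -ny; nz <- -nz
  }
  d11 <- function(f) d1c(d1c(f, du1, periodic1), du1, periodic1)
  d22 <- function(f) d2c(d2c(f, du2, periodic2), du2, periodic2)
  d12 <- function(f) d2c(d1c(f, du1, periodic1), du2, periodic2)
  L11 <- nx * d11(x) + ny * d11(y) + nz * d11(z)
  L12 <- nx * d12(x) + ny * d12(y) + nz * d12(z)
  L22 <- nx * d22(x) + ny * d22(y) + nz * d22(z)
  detg <- g11 * g22 - g12^2
  H <- (g22 * L11 - 2 * g12 * L12 + g11 * L22) / (2 * detg)
  K <- (L11 * L22 - L12^2) / detg
  new_membrane_patch(kind, u1, u2, du1, du2, periodic1, periodic2,
    x, y, z, nx, ny, nz, g11, g12, g22, L11, L12, L22, H, K,
    closed = closed, analytic = FALSE)
}

#' Surface of revolution from a sampled profile
#'
#' Revolves a profile curve (rho(s), z(s)) about the z-axis. Geometry is
#' finite-differenced and converges to the analytic values for sphere and
#' cylinder profiles under refinement.
#'
#' @param profile A list or data frame with numeric vectors `rho` (> 0 away
#'   from the poles), `z`, and optionally `s` (uniform parameter; defaults to
#'   an index-based parameter).
#' @param n_psi Azimuthal resolution.
#' @param closed Whether the revolved surface encloses a volume.
#' @return A `membrane_patch`.
#' @export
make_axisymmetric <- function(profile, n_psi = 48, closed = FALSE) {
  rho <- profile$rho; zz <- profile$z
  stopifnot(length(rho) >= 8, length(rho) == length(zz), all(rho > 0))
  s <- if (!is.null(profile$s)) profile$s else seq_along(rho) - 1
  du2 <- 2 * pi / n_psi
  psi <- (seq_len(n_psi) - 1) * du2
  x <- outer(rho, cos(psi)); y <- outer(rho, sin(psi))
  z <- outer(zz, rep(1, n_psi))
  patch_from_embedding("axisymmetric", s, psi, x, y, z,
                       periodic1 = FALSE, periodic2 = TRUE, closed = closed)
}

#' Tabulate a patch (and optional field) as a data frame
#'
#' @param x A `membrane_patch`.
#' @param row.names,optional Unused, present for S3 compatibility.
#' @param phi Optional field matrix to include as a `phi` column.
#' @param ... Unused.
#' @return A data frame with columns u1, u2, x, y, z, H, K (and phi).
#' @export
as.data.frame.membrane_patch <- function(x, row.names = NULL, optional = FALSE,
                                         phi = NULL, ...) {
  df <- data.frame(
    u1 = rep(x$u1, times = x$n2), u2 = rep(x$u2, each = x$n1),
    x = as.vector(x$x), y = as.vector(x$y), z = as.vector(x$z),
    H = as.vector(x$H), K = as.vector(x$K))
  if (!is.null(phi)) df$phi <- as.vector(phi)
  df
}

#' Write a patch to CSV
#'
#' @param patch A `membrane_patch`.
#' @param path Output file path.
#' @param phi Optional field matrix.
#' @export
write_patch_csv <- function(patch, path, phi = NULL) {
  df <- as.data.frame(patch, phi = phi)
  df[] <- lapply(df, function(v) signif(v, 12))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a patch to a legacy VTK structured grid
#'
#' ASCII legacy-VTK STRUCTURED_GRID with H, K and any named scalar fields as
#' point data, for inspection in ParaView and friends.
#'
#' @param patch A `membrane_patch`.
#' @param path Output file path (conventionally `.vtk`).
#' @param fields Named list of field matrices to attach as point data.
#' @export
write_patch_vtk <- function(patch, path, fields = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "membrane_patch", "ASCII", "DATASET STRUCTURED_GRID",
               sprintf("DIMENSIONS %d %d 1", patch$n1, patch$n2),
               sprintf("POINTS %d double", patch$n1 * patch$n2)), con)
  pts <- cbind(as.vector(patch$x), as.vector(patch$y), as.vector(patch$z))
  writeLines(apply(pts, 1, function(p) paste(sprintf("%.12g", p), collapse = " ")), con)
  all_fields <- c(list(H = patch$H, K = patch$K), fields)
  writeLines(sprintf("POINT_DATA %d", patch$n1 * patch$n2), con)
  for (nm in names(all_fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.12g", as.vector(all_fields[[nm]])), con)
  }
  invisible(path)
}
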