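test_that("composition residual vanishes in the fully symmetric case", {
  sp <- make_sphere(1, 24, 24)
  m <- equal_moduli(k = 2, kbar = -0.3, sigma = 1)
  cc <- default_coupling()
  phi <- matrix(0.5, 24, 24)  # symmetric point: all phi-derivatives vanish
  expect_lt(max(abs(composition_residual(sp, phi, m, cc))), 1e-12)
})

test_that("uniform-composition sphere residuals match the specialized forms", {
  m <- default_moduli()
  cc <- coupling_params(2, 1, -0.5)
  R <- 1.3
  sp <- make_sphere(R, 24, 24)
  for (pb in c(0.2, 0.7)) {
    phi <- matrix(pb, 24, 24)
    comp <- composition_residual(sp, phi, m, cc)
    expect_equal(comp,
                 matrix((2 * m$dk + m$dkbar) / R^2 + m$dsigma +
                          double_well_prime(pb, cc$lam), 24, 24),
                 tolerance = 1e-12)
    nr <- normal_residual(sp, phi, m, cc)
    sigma_mix <- mix_moduli(pb, m)$sigma
    expect_equal(nr,
                 matrix(2 * sigma_mix / R + (cc$lam / R) * pb^2 * (1 - pb)^2 + cc$P,
                        24, 24),
                 tolerance = 1e-12)
  }
})

test_that("the classic homogeneous sphere balance 2 sigma / R + P = 0 holds", {
  m <- equal_moduli(k = 1, sigma = 1)
  cc <- coupling_params(lam = 2, mu = 1, P = -2)
  sp <- make_sphere(1, 24, 24)
  for (pb in c(0, 1)) {
    res <- general_residuals(sp, matrix(pb, 24, 24), m, cc)
    expect_lt(res$comp_norms$max_abs, 1e-10)
    expect_lt(res$normal_norms$max_abs, 1e-10)
  }
})

test_that("the kappa_n - H gradient term vanishes identically on spheres", {
  sp <- make_sphere(1.2, 48, 48)
  phi <- smooth_random_field(sp, seed = 21)
  g <- surface_gradient(sp, phi)
  kn <- normal_curvature_along(sp, phi)
  term <- (kn$kappa_n - sp$H) * g$grad_sq
  term[kn$mask] <- 0
  expect_lt(max(abs(term)), 1e-12)
})

test_that("specialized sphere residuals agree with the general operators", {
  m <- default_moduli()
  cc <- coupling_params(1.5, 0.8, 0.3)
  sp <- make_sphere(1.4, 48, 48)
  phi <- make_fixture_field(sp, "harmonic:2,1,0.2")
  gen <- general_residuals(sp, phi, m, cc)
  spc <- sphere_residuals(sp, phi, m, cc)
  expect_equal(gen$comp, spc$comp, tolerance = 1e-10)
  expect_equal(gen$normal, spc$normal, tolerance = 1e-10)
})

test_that("specialized cylinder residuals agree with the general operators", {
  m <- default_moduli()
  cc <- coupling_params(1.5, 0.8, 0)
  cy <- make_cylinder(0.9, 6, 32, 48)
  phi <- make_fixture_field(cy, "band:3,2")
  gen <- general_residuals(cy, phi, m, cc)
  spc <- cylinder_residuals(cy, phi, m, cc)
  expect_equal(gen$comp, spc$comp, tolerance = 1e-10)
  expect_equal(gen$normal, spc$normal, tolerance = 1e-10)
  # phi = f(z): the kappa_n term reduces to mu (1/(2R)) (dphi/dz)^2,
  # i.e. kappa_n itself vanishes along the axis
  kn <- normal_curvature_along(cy, phi)
  expect_equal(max(abs(kn$kappa_n)), 0)
})

test_that("uniform single-component cylinder balances at R = sqrt(k/(2 sigma))", {
  k <- 1.8; sigma <- 0.4
  m <- equal_moduli(k = k, sigma = sigma)
  cc <- coupling_params(2, 1, 0)
  R <- sqrt(k / (2 * sigma))
  cy <- make_cylinder(R, 4, 24, 24)
  res <- cylinder_residuals(cy, matrix(1, 24, 24), m, cc)
  expect_lt(res$normal_norms$max_abs, 1e-12)
})

test_that("CMC specialization is consistent with spheres and minimal surfaces", {
  m <- default_moduli()
  cc <- coupling_params(1.5, 0.8, 0.2)
  sp <- make_sphere(1.4, 32, 32)
  phi <- make_fixture_field(sp, "harmonic:2,0,0.2")
  cmc <- cmc_residuals(sp, phi, m, cc)
  spc <- sphere_residuals(sp, phi, m, cc)
  expect_equal(cmc$comp, spc$comp, tolerance = 1e-10)
  expect_equal(cmc$normal, spc$normal, tolerance = 1e-10)
  expect_error(cmc_residuals(make_cylinder(1, 4, 16, 16), phi[1:16, 1:16], m, cc,
                             H0 = 0, tol = 1e-8),
               "not CMC")

  # catenoid: a minimal surface (H0 = 0); at the symmetric composition with
  # equal Gaussian moduli and tensions both residuals reduce to ~0 and P
  ss <- seq(-1, 1, length.out = 160)
  cat_patch <- make_axisymmetric(list(s = ss, rho = cosh(ss), z = rev(ss)), 32)
  expect_lt(max(abs(cat_patch$H)), 2e-3)
  m_sym <- component_moduli(2, 1, -0.3, -0.3, 0.7, 0.7)
  phic <- matrix(0.5, cat_patch$n1, cat_patch$n2)
  res0 <- cmc_residuals(cat_patch, phic, m_sym, coupling_params(1, 1, 0), H0 = 0,
                        tol = 1e-2)
  expect_lt(max(abs(res0$comp)), 1e-10)
  expect_lt(max(abs(res0$normal)), 1e-10)
})

test_that("composition residual is the functional derivative of the energy", {
  m <- default_moduli()
  cc <- default_coupling()
  rel_err <- function(n) {
    sp <- make_sphere(1, n, n)
    phi <- make_fixture_field(sp, "harmonic:2,1,0.2")
    dphi <- smooth_random_field(sp, seed = 5) - 0.5
    eps <- 1e-4
    fd <- (total_energy(sp, phi + eps * dphi, m, cc)$total -
             total_energy(sp, phi - eps * dphi, m, cc)$total) / (2 * eps)
    pred <- patch_integral(sp, composition_residual(sp, phi, m, cc) * dphi)
    abs(fd - pred) / abs(pred)
  }
  e64 <- rel_err(64)
  expect_lt(e64, 5e-3)
  expect_gt(rel_err(32) / e64, 2)  # discrepancy shrinks under refinement
})

test_that("normal residual is the shape derivative for advected composition", {
  m <- default_moduli()
  cc <- coupling_params(2, 1, -0.5)
  sp <- make_sphere(1, 64, 64)
  phi <- make_fixture_field(sp, "harmonic:2,1,0.2")
  psi <- 0.1 * (1 + 0.3 * outer(cos(sp$u1), rep(1, sp$n2)))
  base <- patch_from_embedding("sphere", sp$u1, sp$u2, sp$x, sp$y, sp$z,
                               FALSE, TRUE, closed = TRUE)
  deform <- function(eps) patch_from_embedding("sphere", sp$u1, sp$u2,
    sp$x + eps * psi * base$nx, sp$y + eps * psi * base$ny,
    sp$z + eps * psi * base$nz, FALSE, TRUE, closed = TRUE)
  eps <- 1e-3
  fd <- (total_energy(deform(eps), phi, m, cc)$total -
           total_energy(deform(-eps), phi, m, cc)$total) / (2 * eps)
  pred <- patch_integral(sp, normal_residual(sp, phi, m, cc) * psi)
  expect_equal(fd, pred, tolerance = 1e-2)
})

test_that("tangential perturbations change the energy only at second order", {
  m <- default_moduli()
  cc <- coupling_params(2, 1, -0.5)
  sp <- make_sphere(1, 48, 48)
  phiu <- matrix(0.3, sp$n1, sp$n2)  # uniform: the composition equation's
  # gradient source term vanishes, so tangential moves are pure
  # reparameterizations
  v1 <- 0.1 * outer(sin(sp$u1), rep(1, sp$n2))
  v2 <- 0.05 * matrix(1, sp$n1, sp$n2)
  e1 <- lapply(list(sp$x, sp$y, sp$z), function(w) memphase:::d1c(w, sp$du1, FALSE))
  e2 <- lapply(list(sp$x, sp$y, sp$z), function(w) memphase:::d2c(w, sp$du2, TRUE))
  base <- patch_from_embedding("sphere", sp$u1, sp$u2, sp$x, sp$y, sp$z,
                               FALSE, TRUE, closed = TRUE)
  en <- function(p) total_energy(p, phiu, m, cc)$total
  F0 <- en(base)
  dF <- vapply(c(0.02, 0.01), function(eps) {
    p <- patch_from_embedding("sphere", sp$u1, sp$u2,
      sp$x + eps * (v1 * e1[[1]] + v2 * e2[[1]]),
      sp$y + eps * (v1 * e1[[2]] + v2 * e2[[2]]),
      sp$z + eps * (v1 * e1[[3]] + v2 * e2[[3]]),
      FALSE, TRUE, closed = TRUE)
    en(p) - F0
  }, numeric(1))
  expect_lt(abs(dF[1]), 1e-4 * abs(F0))
  expect_gt(dF[1] / dF[2], 3)  # ~eps^2 scaling
  expect_lt(dF[1] / dF[2], 5)
})

test_that("first-variation identities hold with the expected convergence", {
  sp <- make_sphere(1, 96, 96)
  psi <- 0.1 * (1 + 0.3 * outer(cos(sp$u1), rep(1, sp$n2)))
  vc <- check_first_variations(sp, psi, eps_grid = c(0.4, 0.2, 0.1))
  tab <- vc$table
  small <- tab[tab$eps == 0.1, ]
  expect_lt(small$discrepancy[small$identity == "A"], 1e-5)
  expect_lt(small$discrepancy[small$identity == "V"], 1e-4)
  expect_lt(small$discrepancy[small$identity == "sqrtg"], 1e-3)
  expect_lt(small$discrepancy[small$identity == "H"], 1e-3)
  expect_lt(small$discrepancy[small$identity == "K"], 1e-3)
  expect_gt(vc$orders[["K"]], 1.7)  # second-order in the amplitude
  expect_gt(vc$orders[["V"]], 1.7)

  # constant normal displacement: dA/deps = 8 pi R psi (d(4 pi R^2)/dR)
  vc2 <- check_first_variations(sp, matrix(0.05, 96, 96), eps_grid = 0.01)
  dA <- vc2$table[vc2$table$identity == "A", ]
  expect_equal(dA$fd, 8 * pi * 0.05, tolerance = 2e-3)
  dV <- vc2$table[vc2$table$identity == "V", ]
  expect_equal(dV$fd, 4 * pi * 0.05, tolerance = 2e-3)  # int psi dA

  # tangential-only perturbations leave area and volume unchanged
  z <- matrix(0, 96, 96)
  tang <- list(v1 = 0.1 * outer(sin(sp$u1), rep(1, sp$n2)),
               v2 = 0.05 * matrix(1, 96, 96))
  vt <- check_first_variations(sp, z, tang, eps_grid = 1e-3)
  expect_lt(abs(vt$table$fd[vt$table$identity == "A"]), 1e-6)
  expect_lt(abs(vt$table$fd[vt$table$identity == "V"]), 1e-6)
})

test_that("Gaussian-rigidity diagnostic flags developable regions", {
  m <- default_moduli()
  cy <- make_cylinder(1, 8, 16, 64)
  phi_band <- make_fixture_field(cy, "band:4,3")
  diag_cy <- gaussian_rigidity_diagnostic(cy, phi_band, m)
  expect_identical(max(abs(diag_cy$dbar_kbar)), 0)  # K = 0: no obstruction
  expect_true(any(diag_cy$tube_favorable))

  sp <- make_sphere(1.5, 48, 48)
  phi_cap <- make_fixture_field(sp, "band:1.2,0.8")
  diag_sp <- gaussian_rigidity_diagnostic(sp, phi_cap, m)
  kbar <- mix_moduli(phi_cap, m)$kbar
  expect_equal(diag_sp$dbar_kbar, -(1 / 1.5) * laplace_beltrami(sp, kbar),
               tolerance = 1e-12)
  expect_gt(max(abs(diag_sp$dbar_kbar)), 0)
  expect_false(any(diag_sp$tube_favorable))  # nowhere developable

  phi_u <- matrix(0.4, 48, 48)
  expect_identical(max(abs(gaussian_rigidity_diagnostic(sp, phi_u, m)$dbar_kbar)), 0)
})
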