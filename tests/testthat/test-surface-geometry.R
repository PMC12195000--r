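test_that("sphere patch carries the analytic curvatures and measures", {
  sp <- make_sphere(1, 32, 32)
  expect_true(all(sp$H == -1))
  expect_true(all(make_sphere(2, 16, 16)$K == 0.25))
  expect_error(make_sphere(-1), "R > 0")

  fine <- make_sphere(1.3, 800, 16)
  expect_equal(patch_area(fine), 4 * pi * 1.3^2, tolerance = 1e-6)
  expect_equal(patch_volume(fine), (4 * pi / 3) * 1.3^3, tolerance = 1e-6)
  expect_equal(patch_integral(make_sphere(2, 800, 16), make_sphere(2, 800, 16)$K),
               4 * pi, tolerance = 1e-5)  # Gauss-Bonnet
})

test_that("cylinder patch carries the analytic curvatures and area", {
  cy <- make_cylinder(1, 4, 16, 16)
  expect_true(all(cy$H == -0.5))
  expect_true(all(cy$K == 0))
  expect_equal(patch_area(make_cylinder(0.7, 5, 32, 32)), 2 * pi * 0.7 * 5,
               tolerance = 1e-12)  # sqrt(g) constant: quadrature exact
})

test_that("principal curvatures are real on every constructed patch", {
  tt <- (seq_len(160) - 0.5) * pi / 160
  patches <- list(make_sphere(1, 24, 24), make_cylinder(1, 4, 24, 24),
                  make_axisymmetric(list(s = tt, rho = sin(tt), z = cos(tt)), 24,
                                    closed = TRUE))
  for (p in patches) expect_true(all(p$H^2 - p$K >= -1e-12))
})

test_that("rescaling transforms embedding, curvatures and measures correctly", {
  sp <- make_sphere(1, 24, 24)
  sp2 <- rescale_patch(sp, 2)
  expect_equal(sp2$R, 2)
  expect_equal(sp2$H, sp$H / 2)
  expect_equal(sp2$K, sp$K / 4)
  expect_equal(patch_area(sp2), 4 * patch_area(sp))
  expect_equal(patch_volume(sp2), 8 * patch_volume(sp))
  s <- 1.3
  cy <- make_cylinder(1, 4, 16, 16)
  expect_equal(patch_area(rescale_patch(cy, s)), s^2 * patch_area(cy))
})

test_that("both operators annihilate constants and are discretely self-adjoint", {
  for (patch in list(make_sphere(1, 32, 32), make_cylinder(1, 4, 32, 32))) {
    const <- matrix(2.7, patch$n1, patch$n2)
    expect_true(max(abs(laplace_beltrami(patch, const))) < 1e-12)
    expect_true(max(abs(gaussian_laplace_beltrami(patch, const))) < 1e-12)
    f <- smooth_random_field(patch, seed = 11)
    g <- smooth_random_field(patch, seed = 12)
    for (op in list(laplace_beltrami, gaussian_laplace_beltrami)) {
      lhs <- patch_integral(patch, f * op(patch, g))
      rhs <- patch_integral(patch, g * op(patch, f))
      expect_lt(abs(lhs - rhs), 1e-10)
    }
  }
})

test_that("spherical harmonics are eigenfunctions with order >= 2 accuracy", {
  eig_err <- function(n, l, R = 1.5) {
    sp <- make_sphere(R, n, n)
    Pl <- pracma::legendre(l, cos(sp$u1))[1, ]
    f <- outer(Pl, rep(1, sp$n2))
    lam_exact <- -l * (l + 1) / R^2
    max(abs(laplace_beltrami(sp, f) - lam_exact * f)) / abs(lam_exact)
  }
  for (l in c(1, 3)) {
    e1 <- eig_err(24, l); e2 <- eig_err(48, l)
    expect_lt(e2, 2e-3 * l^2)
    expect_gt(log2(e1 / e2), 1.7)  # ~second-order convergence
  }
})

test_that("cylinder Fourier modes are eigenfunctions of the Laplacian", {
  L <- 5
  cy <- make_cylinder(1, L, 16, 64)
  f <- outer(rep(1, cy$n1), cos(2 * pi * cy$u2 / L))
  expect_equal(laplace_beltrami(cy, f), -(2 * pi / L)^2 * f, tolerance = 2e-3)
})

test_that("the Gaussian-weighted operator obeys the sphere and cylinder identities", {
  sp <- make_sphere(2, 32, 32)
  f <- smooth_random_field(sp, seed = 3)
  expect_equal(gaussian_laplace_beltrami(sp, f),
               -(1 / 2) * laplace_beltrami(sp, f), tolerance = 1e-12)
  cy <- make_cylinder(1, 4, 24, 24)
  g <- smooth_random_field(cy, seed = 4)
  expect_identical(max(abs(gaussian_laplace_beltrami(cy, g))), 0)
})

test_that("surface gradient reproduces analytic gradients", {
  sp <- make_sphere(1, 64, 64)
  expect_identical(max(abs(surface_gradient(sp, matrix(5, 64, 64))$grad_sq)), 0)
  f <- outer(cos(sp$u1), rep(1, sp$n2))
  expect_equal(surface_gradient(sp, f)$grad_sq,
               outer(sin(sp$u1)^2, rep(1, sp$n2)), tolerance = 1e-3)
  cy <- make_cylinder(2, 4, 16, 64)
  fz <- outer(rep(1, cy$n1), cy$u2)  # f = z: unit axial gradient
  gz <- surface_gradient(cy, fz)
  # centered difference across the periodic seam is wrong only at the seam rows
  interior <- 2:(cy$n2 - 1)
  expect_equal(gz$grad_sq[, interior], matrix(1, cy$n1, length(interior)),
               tolerance = 1e-12)
})

test_that("normal curvature along the gradient picks the right section", {
  sp <- make_sphere(2, 32, 32)
  f <- outer(cos(sp$u1), rep(1, sp$n2))
  kn <- normal_curvature_along(sp, f)
  expect_equal(kn$kappa_n[!kn$mask],
               rep(-0.5, sum(!kn$mask)), tolerance = 1e-12)
  cy <- make_cylinder(2, 4, 16, 32)
  fz <- outer(rep(1, cy$n1), sin(2 * pi * cy$u2 / 4))   # axial variation: flat section
  knz <- normal_curvature_along(cy, fz)
  expect_equal(max(abs(knz$kappa_n)), 0)
  fpsi <- outer(sin(cy$u1), rep(1, cy$n2))              # circumferential: kappa = -1/R
  knp <- normal_curvature_along(cy, fpsi)
  expect_equal(knp$kappa_n[!knp$mask], rep(-0.5, sum(!knp$mask)), tolerance = 1e-12)
})

test_that("surfaces of revolution converge to the analytic geometries", {
  herr <- function(ns) {
    tt <- (seq_len(ns) - 0.5) * pi / ns
    ax <- make_axisymmetric(list(s = tt, rho = sin(tt), z = cos(tt)), 16,
                            closed = TRUE)
    max(abs(ax$H + 1))
  }
  expect_lt(herr(160), 1e-3)
  expect_gt(log2(herr(80) / herr(160)), 1.5)  # refinement convergence

  # straight vertical profile: cylinder limit away from the ends
  zz <- seq(0, 4, length.out = 120)
  ax <- make_axisymmetric(list(s = zz, rho = rep(1.5, 120), z = rev(zz)), 24)
  interior <- 10:110
  expect_equal(ax$H[interior, ], matrix(-1 / 3, length(interior), 24),
               tolerance = 1e-10)
  expect_true(max(abs(laplace_beltrami(ax, matrix(1, ax$n1, ax$n2)))) < 1e-12)
})

test_that("patch export produces consistent tables and legacy VTK", {
  sp <- make_sphere(1, 8, 8)
  phi <- make_fixture_field(sp, "uniform:0.3")
  df <- as.data.frame(sp, phi = phi)
  expect_equal(nrow(df), 64)
  expect_named(df, c("u1", "u2", "x", "y", "z", "H", "K", "phi"))
  expect_equal(df$x^2 + df$y^2 + df$z^2, rep(1, 64), tolerance = 1e-12)

  csv <- tempfile(fileext = ".csv")
  write_patch_csv(sp, csv, phi = phi)
  back <- utils::read.csv(csv)
  expect_equal(back$H, rep(-1, 64))

  vtk <- tempfile(fileext = ".vtk")
  write_patch_vtk(sp, vtk, fields = list(phi = phi))
  lines <- readLines(vtk)
  expect_equal(lines[4], "DATASET STRUCTURED_GRID")
  expect_true(any(grepl("SCALARS phi double 1", lines)))
  expect_equal(sum(grepl("^POINTS", lines)), 1)
})
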