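# Shared parameter bundles and small builders for the test suite.

default_moduli <- function() component_moduli(kA = 2, kB = 1,
                                              kbarA = -0.4, kbarB = -0.2,
                                              sigmaA = 1, sigmaB = 0.8)

equal_moduli <- function(k = 1, kbar = 0, sigma = 1)
  component_moduli(k, k, kbar, kbar, sigma, sigma)

default_coupling <- function(P = 0) coupling_params(lam = 2, mu = 1, P = P)

random_moduli <- function() component_moduli(
  kA = runif(1, 0.1, 5), kB = runif(1, 0.1, 5),
  kbarA = runif(1, 0.1, 5), kbarB = runif(1, 0.1, 5),
  sigmaA = runif(1, 0.1, 5), sigmaB = runif(1, 0.1, 5))

random_coupling <- function(P = 0) coupling_params(
  lam = runif(1, 0, 10), mu = runif(1, 0.1, 10), P = P)

smooth_random_field <- function(patch, seed, amp = 0.2)
  make_fixture_field(patch, sprintf("random:%g", amp), seed = seed)

# smallest positive root of the sphere cubic by log-grid bracketing (oracle)
bracket_sphere_root <- function(cub, lo = 1e-8, hi = 1e8, n = 1200) {
  f <- function(R) cub$a3 * R^3 + cub$a2 * R^2 + cub$a0
  Rs <- exp(seq(log(lo), log(hi), length.out = n))
  v <- vapply(Rs, f, numeric(1))
  idx <- which(sign(v[-1]) * sign(v[-n]) < 0)
  if (!length(idx)) return(NA_real_)
  min(vapply(idx, function(i) uniroot(f, c(Rs[i], Rs[i + 1]), tol = 1e-15)$root,
             numeric(1)))
}
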