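#' Component elastic moduli for a two-component membrane
#'
#' Bundles the per-component elastic constants of a binary fluid membrane:
#' bending rigidity, Gaussian (saddle-splay) rigidity and tension for the
#' A and B lipid components. All energies are in units of kBT; lengths are
#' in a user-chosen length unit (no conversion layer is provided).
#'
#' @param kA,kB Bending rigidity of component A / B (energy). Must be > 0.
#' @param kbarA,kbarB Gaussian rigidity of component A / B (energy).
#' @param sigmaA,sigmaB Tension of component A / B (energy / length^2).
#' @return An object of class `component_moduli`, a list with the six moduli
#'   plus derived accessors `dk = kA - kB`, `dkbar = kbarA - kbarB`,
#'   `dsigma = sigmaA - sigmaB`.
#' @examples
#' m <- component_moduli(kA = 2, kB = 1, kbarA = -0.5, kbarB = -0.2,
#'                       sigmaA = 1, sigmaB = 0.8)
#' mix_moduli(0.5, m)
#' @export
component_moduli <- function(kA, kB, kbarA = 0, kbarB = 0,
                             sigmaA = 0, sigmaB = 0) {
  stopifnot(is.numeric(kA), is.numeric(kB), kA > 0, kB > 0,
            is.finite(kbarA), is.finite(kbarB),
            is.finite(sigmaA), is.finite(sigmaB))
  structure(list(kA = kA, kB = kB, kbarA = kbarA, kbarB = kbarB,
                 sigmaA = sigmaA, sigmaB = sigmaB,
                 dk = kA - kB, dkbar = kbarA - kbarB,
                 dsigma = sigmaA - sigmaB),
            class = "component_moduli")
}

#' Phase-field coupling parameters
#'
#' The double-well coupling strength `lam`, the gradient-energy coefficient
#' `mu`, and the transmembrane pressure difference `P` entering the volume
#' term of the free energy. `mu` penalizes composition gradients on the
#' surface and, together with `lam`, sets the diffuse interface width
#' 4*sqrt(mu/lam) and the line tension sqrt(mu*lam)/6.
#'
#' @param lam Double-well coupling (energy / length^2), >= 0.
#' @param mu Gradient coefficient (energy), > 0.
#' @param P Transmembrane pressure difference (energy / length^3).
#' @return An object of class `coupling_params`.
#' @export
coupling_params <- function(lam, mu, P = 0) {
  stopifnot(lam >= 0, mu > 0, is.finite(P))
  structure(list(lam = lam, mu = mu, P = P), class = "coupling_params")
}

#' Ternary Landau free-energy parameters
#'
#' Coefficients of the two-order-parameter quartic density used for ternary
#' lipid mixtures: `alpha < 0` drives separation, `beta > 0` stabilizes the
#' wells, `gamma` is the cross-coupling that selects between two-phase and
#' three-phase coexistence, and `kappa_grad` weights the gradient terms.
#'
#' @param alpha Quadratic coefficient (alpha < 0 drives demixing).
#' @param beta Quartic coefficient, must be > 0.
#' @param gamma Cross-coupling coefficient.
#' @param kappa_grad Gradient-energy coefficient, >= 0.
#' @return An object of class `ternary_params` carrying the coefficients and
#'   `gamma_crit = beta / 2`, the analytic coexistence crossover.
#' @export
ternary_params <- function(alpha, beta, gamma, kappa_grad = 0) {
  stopifnot(beta > 0, is.finite(alpha), is.finite(gamma), kappa_grad >= 0)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 kappa_grad = kappa_grad, gamma_crit = beta / 2),
            class = "ternary_params")
}

#' Temperature dependence of the double-well coupling
#'
#' Linear (Flory-like) vanishing of the demixing coupling at the critical
#' temperature: lambda(T) = lambda0 * (1 - T/Tc).
#'
#' @param lam0 Coupling at T = 0 (energy / length^2).
#' @param Tc Critical demixing temperature (K), > 0.
#' @return An object of class `temperature_model`.
#' @export
temperature_model <- function(lam0, Tc) {
  stopifnot(is.finite(lam0), Tc > 0)
  structure(list(lam0 = lam0, Tc = Tc), class = "temperature_model")
}

#' Linearly mixed moduli at composition phi
#'
#' Evaluates the composition-dependent moduli under the linear mixing rule
#' k(phi) = kB + (kA - kB) phi (and likewise for the Gaussian rigidity and
#' tension). `phi` is the molar fraction of component A, so phi = 0 recovers
#' pure B and phi = 1 pure A.
#'
#' @param phi Molar fraction of component A; values outside [0, 1] are
#'   evaluated with a warning (the linear rule extrapolates).
#' @param m A [component_moduli()] bundle.
#' @return A list with vectors `k`, `kbar`, `sigma` matching `phi` in shape.
#' @export
mix_moduli <- function(phi, m) {
  stopifnot(inherits(m, "component_moduli"))
  if (any(phi < 0 | phi > 1, na.rm = TRUE))
    warning("phi outside [0, 1]: linear mixing rule extrapolated")
  list(k     = m$kB     + m$dk     * phi,
       kbar  = m$kbarB  + m$dkbar  * phi,
       sigma = m$sigmaB + m$dsigma * phi)
}

#' Symmetric double-well potential
#'
#' V(phi) = (lam/2) phi^2 (1 - phi)^2, with wells at the pure phases
#' phi = 0 and phi = 1 and a barrier at phi = 1/2. Symmetric under
#' phi -> 1 - phi.
#'
#' @param phi Composition (any numeric shape).
#' @param lam Coupling strength, >= 0.
#' @return Energy density, same shape as `phi`.
#' @export
double_well <- function(phi, lam) {
  stopifnot(lam >= 0)
  (lam / 2) * phi^2 * (1 - phi)^2
}

#' Derivative of the double-well potential
#'
#' dV/dphi = lam * phi (1 - phi) (1 - 2 phi); this is the potential term that
#' appears in every composition Euler-Lagrange equation. Vanishes at the two
#' wells and at the symmetric barrier top.
#'
#' @inheritParams double_well
#' @return dV/dphi, same shape as `phi`.
#' @export
double_well_prime <- function(phi, lam) {
  lam * phi * (1 - phi) * (1 - 2 * phi)
}

#' Ternary Landau free-energy density
#'
#' f = (alpha/2)(phi1^2 + phi2^2) + (beta/4)(phi1^4 + phi2^4)
#'   + gamma phi1^2 phi2^2 + (kappa/2)[(grad phi1)^2 + (grad phi2)^2],
#' symmetric under phi1 <-> phi2.
#'
#' @param phi1,phi2 Order parameters.
#' @param grad1_sq,grad2_sq Squared gradient magnitudes (>= 0); pass 0 for
#'   the homogeneous analysis.
#' @param t A [ternary_params()] bundle.
#' @return Free-energy density.
#' @export
ternary_density <- function(phi1, phi2, grad1_sq = 0, grad2_sq = 0, t) {
  stopifnot(inherits(t, "ternary_params"),
            all(grad1_sq >= 0), all(grad2_sq >= 0))
  (t$alpha / 2) * (phi1^2 + phi2^2) +
    (t$beta / 4) * (phi1^4 + phi2^4) +
    t$gamma * phi1^2 * phi2^2 +
    (t$kappa_grad / 2) * (grad1_sq + grad2_sq)
}

# Homogeneous minimum along the axis family (+-m, 0)/(0, +-m) and along the
# diagonal family (+-m', +-m'); closed forms used as the classifier.
ternary_family_minima <- function(t) {
  m_axis <- sqrt(-t$alpha / t$beta)
  e_axis <- -t$alpha^2 / (4 * t$beta)
  bg <- t$beta + 2 * t$gamma
  if (bg > 0) {
    m_diag <- sqrt(-t$alpha / bg)
    e_diag <- -t$alpha^2 / (2 * bg)
  } else {
    # density unbounded below along the diagonal
    m_diag <- Inf
    e_diag <- -Inf
  }
  list(m_axis = m_axis, e_axis = e_axis, m_diag = m_diag, e_diag = e_diag)
}

#' Ground states of the homogeneous ternary density
#'
#' Minimizes the homogeneous part of the ternary density over (phi1, phi2)
#' and classifies the global-minimum family: minima on the axes
#' ((+-m, 0), (0, +-m)) correspond to two-phase coexistence, minima on the
#' diagonals ((+-m', +-m')) to three-phase coexistence. The crossover
#' cross-coupling gamma_crit is located by bisection on the energy difference
#' of the two families at fixed alpha, beta.
#'
#' @param t A [ternary_params()] bundle with `alpha < 0`, `beta > 0`.
#' @param tol Energy-difference tolerance below which the classification is
#'   reported as `"degenerate"`.
#' @return A list with `family` (`"axis"`, `"diagonal"` or `"degenerate"`),
#'   `minima` (matrix of global minimizers, one per row), `energy` (minimum
#'   density value), and `gamma_crit_bisection` (crossover located numerically
#'   at the bundle's alpha, beta).
#' @export
ternary_ground_states <- function(t, tol = 1e-12) {
  stopifnot(inherits(t, "ternary_params"), t$alpha < 0, t$beta > 0)
  fam <- ternary_family_minima(t)
  de <- fam$e_axis - fam$e_diag
  family <- if (abs(de) <= tol) "degenerate" else if (de < 0) "axis" else "diagonal"
  minima <- switch(family,
    axis = rbind(c(fam$m_axis, 0), c(-fam$m_axis, 0),
                 c(0, fam$m_axis), c(0, -fam$m_axis)),
    diagonal = {
      m <- fam$m_diag
      rbind(c(m, m), c(m, -m), c(-m, m), c(-m, -m))
    },
    degenerate = rbind(c(fam$m_axis, 0), c(fam$m_diag, fam$m_diag)))
  energy <- min(fam$e_axis, fam$e_diag)

  # Bisection on gamma: diagonal family wins for small gamma, axis for large.
  ediff <- function(g) {
    tt <- ternary_params(t$alpha, t$beta, g, t$kappa_grad)
    f <- ternary_family_minima(tt)
    f$e_axis - f$e_diag
  }
  lo <- 0; hi <- max(2 * t$beta, 1)
  gamma_crit <- if (ediff(lo) * ediff(hi) <= 0) {
    stats::uniroot(ediff, c(lo, hi), tol = 1e-12)$root
  } else NA_real_

  list(family = family, minima = minima, energy = energy,
       gamma_crit_bisection = gamma_crit)
}

#' Temperature-dependent coupling lambda(T)
#'
#' lambda(T) = lambda0 (1 - T/Tc), clamped at 0 for T >= Tc (above the
#' critical temperature the components mix and the demixing coupling is
#' switched off; a warning is emitted when the clamp engages).
#'
#' @param tm A [temperature_model()].
#' @param T Temperature (K), >= 0.
#' @return Coupling lambda at temperature `T`.
#' @export
lambda_of_T <- function(tm, T) {
  stopifnot(inherits(tm, "temperature_model"), all(T >= 0))
  lam <- tm$lam0 * (1 - T / tm$Tc)
  if (any(lam < 0)) {
    warning("T >= Tc: lambda clamped at 0 (mixing regime)")
    lam <- pmax(lam, 0)
  }
  lam
}

#' Closed-form diffuse interface width
#'
#' Width of the 1D equilibrium kink between the two wells,
#' d = 4 sqrt(mu/lam), measured by linear extrapolation through the point of
#' steepest slope. Increases with the gradient coefficient mu and decreases
#' with the well depth lam.
#'
#' @param mu Gradient coefficient, > 0.
#' @param lam Double-well coupling, > 0.
#' @return Interface width (length).
#' @export
kink_width_closed_form <- function(mu, lam) {
  stopifnot(all(mu > 0), all(lam > 0))
  4 * sqrt(mu / lam)
}

#' Closed-form line tension of the diffuse interface
#'
#' Excess energy per unit length of the 1D equilibrium kink,
#' sigma_line = sqrt(mu * lam) / 6 (the Cahn-Hilliard quadrature of
#' mu (phi')^2 over the exact tanh profile).
#'
#' @inheritParams kink_width_closed_form
#' @param lam Double-well coupling, >= 0.
#' @return Line tension (energy / length).
#' @export
line_tension_closed_form <- function(mu, lam) {
  stopifnot(all(mu >= 0), all(lam >= 0))
  sqrt(mu * lam) / 6
}

#' Read a membrane parameter set from a YAML or JSON config file
#'
#' The config must use keys exactly `kA, kB, kbarA, kbarB, sigmaA, sigmaB,
#' lambda, mu, P`, with optional blocks `ternary{alpha, beta, gamma, kappa}`
#' and `temperature{lambda0, Tc}`. Unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `moduli` ([component_moduli()]), `coupling`
#'   ([coupling_params()]), and optionally `ternary`, `temperature`.
#' @export
read_params <- function(path) {
  stopifnot(file.exists(path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  params_from_list(cfg)
}

#' Build a parameter set from a plain list
#'
#' @param cfg A list following the [read_params()] schema.
#' @return Same as [read_params()].
#' @export
params_from_list <- function(cfg) {
  top_keys <- c("kA", "kB", "kbarA", "kbarB", "sigmaA", "sigmaB",
                "lambda", "mu", "P", "ternary", "temperature")
  unknown <- setdiff(names(cfg), top_keys)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         " (allowed: ", paste(top_keys, collapse = ", "), ")")
  need <- c("kA", "kB", "lambda", "mu")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("missing required config keys: ", paste(miss, collapse = ", "))
  grab <- function(key, default = 0) if (is.null(cfg[[key]])) default else cfg[[key]]
  out <- list(
    moduli = component_moduli(cfg$kA, cfg$kB,
                              grab("kbarA"), grab("kbarB"),
                              grab("sigmaA"), grab("sigmaB")),
    coupling = coupling_params(cfg$lambda, cfg$mu, grab("P")))
  if (!is.null(cfg$ternary)) {
    tk <- setdiff(names(cfg$ternary), c("alpha", "beta", "gamma", "kappa"))
    if (length(tk)) stop("unknown ternary keys: ", paste(tk, collapse = ", "))
    out$ternary <- ternary_params(cfg$ternary$alpha, cfg$ternary$beta,
                                  cfg$ternary$gamma,
                                  if (is.null(cfg$ternary$kappa)) 0 else cfg$ternary$kappa)
  }
  if (!is.null(cfg$temperature)) {
    tk <- setdiff(names(cfg$temperature), c("lambda0", "Tc"))
    if (length(tk)) stop("unknown temperature keys: ", paste(tk, collapse = ", "))
    out$temperature <- temperature_model(cfg$temperature$lambda0, cfg$temperature$Tc)
  }
  out
}
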