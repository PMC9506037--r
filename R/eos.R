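# CPA equation-of-state core.
#
# Pressure:  P = RT/(Vm-b) - a(T)/(Vm(Vm+b))
#              - (1/2)(RT/Vm)(1 + rho dln g/drho) sum_i x_i sum_Ai (1 - X_Ai)
# with g = 1/(1 - 1.9 eta), eta = b rho / 4, and the unbonded-site
# fractions X_Ai solving  X_Ai = 1/(1 + rho sum_j x_j sum_Bj X_Bj D^AiBj).
#
# The exported functions here are pure-R compositions of the individual
# terms; the compiled core in src/cpa.cpp evaluates the same model for
# the equilibrium and regression hot paths, and the two routes are
# compared in the test suite.

#' Soave temperature function of the attractive parameter
#'
#' `a(T) = a0 * (1 + c1 (1 - sqrt(T/Tc)))^2`, used unchanged above the
#' critical temperature (supercritical extrapolation of the same form).
#'
#' @param comp A [cpa_component].
#' @param T Temperature, K.
#' @return Attractive parameter, L^2·bar/mol^2 (vectorized over `T`).
#' @export
soave_a <- function(comp, T) {
  stopifnot(inherits(comp, "cpa_component"))
  if (any(T <= 0)) stop("temperature must be positive")
  comp$a0 * (1 + comp$c1 * (1 - sqrt(T / comp$tc)))^2
}

#' van der Waals one-fluid mixing rules
#'
#' `a_mix = sum_ij x_i x_j sqrt(a_i a_j)(1 - kij)`, `b_mix = sum_i x_i b_i`,
#' with the cross co-volumes `b_ij = (b_i + b_j)/2` used in the
#' association strength.
#'
#' @param mix A [cpa_mixture].
#' @param x Mole fractions.
#' @param T Temperature, K.
#' @return List with `a_mix`, `b_mix` and the `b_ij` matrix.
#' @export
mix_ab <- function(mix, x, T) {
  stopifnot(inherits(mix, "cpa_mixture"))
  x <- .check_composition(x, mix$nc)
  ai <- vapply(mix$components, soave_a, 0, T = T)
  sq <- sqrt(outer(ai, ai))
  a_mix <- sum(outer(x, x) * sq * (1 - mix$kij))
  b_i <- vapply(mix$components, `[[`, 0, "b")
  list(a_mix = a_mix, b_mix = sum(x * b_i),
       b_ij = outer(b_i, b_i, function(u, v) (u + v) / 2))
}

#' Radial distribution function of the CPA association term
#'
#' `g = 1/(1 - 1.9 eta)` with the reduced density `eta = b rho / 4`, and
#' its logarithmic density derivative `rho dln g/drho = 1.9 eta g`.
#'
#' @param eta Reduced density, in `[0, 1/1.9)`.
#' @return List with `g` and `rho_dlng_drho` (vectorized).
#' @export
radial_distribution <- function(eta) {
  if (any(eta < 0) || any(eta >= 1 / 1.9))
    stop("reduced density must lie in [0, 1/1.9)")
  g <- 1 / (1 - 1.9 * eta)
  list(g = g, rho_dlng_drho = 1.9 * eta * g)
}

#' Cross-association parameters for a binary pair
#'
#' CR-1: arithmetic-mean energy and geometric-mean volume (both members
#' must self-associate).  mCR-1: arithmetic-mean energy with a
#' non-self-associating member contributing zero, and an adjustable
#' (stored) volume.  Explicit: both values stored on the interaction.
#'
#' @param pair A [cpa_binary] with `cross_rule != "none"`.
#' @param comp_i,comp_j The two [cpa_component]s.
#' @return List with `eps_cross` (bar·L/mol) and `beta_cross`.
#' @export
#' @examples
#' cross_association_parameters(
#'   cpa_binary("glycerol", "methanol", 0.0836, "CR1"),
#'   get_component("glycerol"), get_component("methanol"))
cross_association_parameters <- function(pair, comp_i, comp_j) {
  stopifnot(inherits(pair, "cpa_binary"))
  switch(pair$cross_rule,
    "none" = stop("pair declares no cross association"),
    "CR1" = {
      if (comp_i$beta_assoc <= 0 || comp_j$beta_assoc <= 0)
        stop("CR1 requires both components to self-associate (",
             comp_i$name, " / ", comp_j$name, ")")
      list(eps_cross = (comp_i$eps_assoc + comp_j$eps_assoc) / 2,
           beta_cross = sqrt(comp_i$beta_assoc * comp_j$beta_assoc))
    },
    "mCR1" = list(eps_cross = (comp_i$eps_assoc + comp_j$eps_assoc) / 2,
                  beta_cross = pair$beta_cross),
    "explicit" = list(eps_cross = pair$eps_cross,
                      beta_cross = pair$beta_cross))
}

#' Association strength between one site pair
#'
#' `Delta = g [exp(eps/(RT)) - 1] b_ij beta`; zero whenever `beta = 0`
#' (inactive pair) or `eps = 0`.
#'
#' @param T Temperature, K.
#' @param g Radial distribution function value.
#' @param bij Cross co-volume `(b_i + b_j)/2`, L/mol.
#' @param eps Association energy, bar·L/mol.
#' @param beta Association volume, dimensionless.
#' @return Association strength, L/mol (vectorized / matrix-valued).
#' @export
association_strength <- function(T, g, bij, eps, beta) {
  g * (exp(eps / (.RGAS * T)) - 1) * bij * beta
}

# Site-pair association-strength table for a mixture at (T, g).
.delta_table <- function(mix, T, g) {
  if (mix$ns == 0) return(matrix(0, 0, 0))
  association_strength(T, g, mix$bij_mat, mix$eps_mat, mix$beta_mat)
}

#' Solve the unbonded-site-fraction equations
#'
#' Fixed point of `X_s = 1/(1 + rho sum_t x[comp(t)] mult_t X_t Delta_st)`
#' with site multiplicities folded into the sums.  Damped successive
#' substitution (damping 0.5) with a bounded Newton fall-back when
#' convergence stalls.
#'
#' @param rho Molar density, mol/L.
#' @param x Component mole fractions.
#' @param delta Site-pair association-strength matrix, L/mol.
#' @param site_comp Integer vector: owning component of each site class.
#' @param site_mult Multiplicity of each site class.
#' @param tol Convergence tolerance on the fixed-point defect.
#' @param max_iter Iteration cap.
#' @return List with `X`, `residual` (max fixed-point defect) and
#'   `iterations`.
#' @export
solve_site_fractions <- function(rho, x, delta, site_comp, site_mult,
                                 tol = 1e-12, max_iter = 1e4) {
  ns <- length(site_comp)
  if (ns == 0) return(list(X = numeric(0), residual = 0, iterations = 0L))
  stopifnot(rho > 0, all(is.finite(delta)))
  M <- rho * delta * rep(x[site_comp] * site_mult, each = ns)
  X <- rep(1, ns)
  fp <- function(X) 1 / (1 + drop(M %*% X))
  it <- 0L
  repeat {
    Xn <- fp(X)
    res <- max(abs(Xn - X))
    if (res < tol) { X <- Xn; break }
    X <- 0.5 * Xn + 0.5 * X
    it <- it + 1L
    if (it >= 200L) break
  }
  if (it >= 200L) {
    # Newton on F(X) = X - 1/(1 + M X)
    while (it < max_iter) {
      u <- 1 + drop(M %*% X)
      FF <- X - 1 / u
      if (max(abs(FF)) < tol) break
      J <- diag(ns) + M / u^2
      X <- X - solve(J, FF)
      X <- pmin(pmax(X, 1e-12), 1)
      it <- it + 1L
    }
  }
  res <- max(abs(X - fp(X)))
  if (res > tol * 10)
    stop(sprintf("site-fraction solver did not converge (residual %.3g after %d iterations)",
                 res, it))
  list(X = X, residual = res, iterations = it)
}

#' Closed-form site fraction for symmetric pure-fluid schemes
#'
#' For a pure fluid whose scheme has `n` equivalent positive/negative
#' site pairs (n = 1 for 2B, 2 for 4C, 3 for 3x2B) or a single
#' self-pairing site (1A), the site-fraction equation reduces to a
#' quadratic with root `X = (-1 + sqrt(1 + 4 n rho Delta)) / (2 n rho Delta)`,
#' extended by continuity to `X = 1` at `rho Delta = 0`.  Used as the
#' analytic oracle for the iterative solver.
#'
#' @param scheme `"1A"`, `"2B"`, `"4C"` or `"3x2B"`.
#' @param rho_delta `rho * Delta`, dimensionless (vectorized).
#' @return Site fraction X.
#' @export
closed_form_site_fraction <- function(scheme, rho_delta) {
  n <- switch(scheme, "1A" = 1, "2B" = 1, "4C" = 2, "3x2B" = 3,
              stop("unsupported scheme: ", scheme))
  stopifnot(all(rho_delta >= 0))
  out <- rep(1, length(rho_delta))
  nz <- rho_delta > 0
  out[nz] <- (-1 + sqrt(1 + 4 * n * rho_delta[nz])) / (2 * n * rho_delta[nz])
  out
}

# Shared R-side state evaluation (reference route).
.state_r <- function(mix, T, Vm, x) {
  x <- .check_composition(x, mix$nc)
  ab <- mix_ab(mix, x, T)
  if (Vm <= ab$b_mix) stop("molar volume must exceed the mixture co-volume")
  rho <- 1 / Vm
  eta <- ab$b_mix * rho / 4
  rd <- radial_distribution(eta)
  if (mix$ns > 0) {
    delta <- .delta_table(mix, T, rd$g)
    sf <- solve_site_fractions(rho, x, delta, mix$sites$comp, mix$sites$mult)
    X <- sf$X
  } else X <- numeric(0)
  xm <- if (mix$ns > 0) x[mix$sites$comp] * mix$sites$mult else numeric(0)
  h <- sum(xm * (1 - X))
  list(ab = ab, rho = rho, eta = eta, g = rd$g, rdlng = rd$rho_dlng_drho,
       X = X, xm = xm, h = h)
}

#' CPA pressure
#'
#' Evaluates the pressure-explicit equation of state at `(T, Vm, x)`:
#' the SRK repulsive/attractive terms plus the Wertheim association
#' contribution.  For mixtures with no active association sites this is
#' exactly the SRK pressure.
#'
#' @param mix A [cpa_mixture].
#' @param T Temperature, K.
#' @param Vm Molar volume, L/mol (must exceed the mixture co-volume).
#' @param x Mole fractions.
#' @return Pressure, bar.
#' @export
cpa_pressure <- function(mix, T, Vm, x) {
  st <- .state_r(mix, T, Vm, x)
  .RGAS * T / (Vm - st$ab$b_mix) - st$ab$a_mix / (Vm * (Vm + st$ab$b_mix)) -
    0.5 * (.RGAS * T / Vm) * (1 + st$rdlng) * st$h
}

#' Reduced residual Helmholtz energy
#'
#' `a_res = A_res/(nRT) = -ln(1 - b rho) - a/(bRT) ln(1 + b rho)
#'   + sum_i x_i sum_Ai (ln X_Ai - X_Ai/2 + 1/2)`;
#' its volume derivative reproduces the pressure equation,
#' `P = -RT da_res/dVm + RT/Vm` (checked numerically in the tests).
#'
#' @inheritParams cpa_pressure
#' @return Dimensionless reduced residual Helmholtz energy.
#' @export
cpa_ares <- function(mix, T, Vm, x) {
  st <- .state_r(mix, T, Vm, x)
  b <- st$ab$b_mix
  -log(1 - b * st$rho) - st$ab$a_mix / (b * .RGAS * T) * log(1 + b * st$rho) +
    sum(st$xm * (log(st$X) - st$X / 2 + 0.5))
}

.phase_hint_code <- function(phase) {
  switch(match.arg(phase, c("auto", "liquid", "vapor")),
         auto = 0L, liquid = 1L, vapor = 2L)
}

#' Solve for the molar volume at given pressure
#'
#' Locates all volume roots of `P(T, Vm) = P` by a sign scan on a
#' log-spaced grid from just above the co-volume to `1e3 RT/P`, refining
#' each bracket.  With several roots, `phase = "liquid"` selects the
#' smallest, `"vapor"` the largest, and `"auto"` the root of lower
#' residual Gibbs energy (ties resolve to the vapor-like root).
#'
#' @inheritParams cpa_pressure
#' @param P Pressure, bar.
#' @param phase `"auto"`, `"liquid"` or `"vapor"`.
#' @return Molar volume, L/mol, with attributes `roots` (all roots found,
#'   ascending) and `nroots`.
#' @export
solve_volume <- function(mix, T, P, x, phase = "auto") {
  stopifnot(T > 0, P > 0)
  x <- .check_composition(x, mix$nc)
  out <- cpp_volume(mix$cpp, T, P, x, .phase_hint_code(phase))
  if (out$nroots == 0) stop("no volume root found at T = ", T, " K, P = ", P, " bar")
  structure(out$V, roots = out$roots, nroots = out$nroots)
}

#' Log fugacity coefficients
#'
#' Analytic `ln phi_i = d(n a_res)/dn_i|_(T,V) - ln Z` evaluated at the
#' volume root for the requested phase, with the association
#' contribution using the stationarity of the site-fraction equations.
#'
#' @inheritParams solve_volume
#' @param phase `"auto"`, `"liquid"` or `"vapor"`.
#' @return Named vector of `ln phi_i`, with attributes `V`, `Z` and
#'   `nroots`.
#' @export
fugacity_coefficients <- function(mix, T, P, x, phase = "auto") {
  stopifnot(T > 0, P > 0)
  x <- .check_composition(x, mix$nc)
  out <- cpp_lnphi(mix$cpp, T, P, x, .phase_hint_code(phase))
  if (out$nroots == 0) stop("no volume root found at T = ", T, " K, P = ", P, " bar")
  structure(setNames(out$lnphi, mix$names), V = out$V, Z = out$Z,
            nroots = out$nroots)
}
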