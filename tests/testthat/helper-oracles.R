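# Shared oracles and fixtures, independent of the package's evaluation
# paths wherever they double-check one.

R_BAR <- 0.083145

# SRK closed forms in the pressure-explicit (T, P, Z) formulation --
# an algebraically independent route from the package's (T, V)
# Helmholtz-derivative implementation.
srk_pressure_oracle <- function(a, b, T, V) {
  R_BAR * T / (V - b) - a / (V * (V + b))
}

srk_ares_oracle <- function(a, b, T, V) {
  -log(1 - b / V) - a / (b * R_BAR * T) * log(1 + b / V)
}

# ln phi from the classic dimensionless-group form:
# ln phi_i = (b_i/b)(Z-1) - ln(Z-B) - (A/B)(2 sum_j x_j a_ij / a - b_i/b) ln(1+B/Z)
srk_lnphi_oracle <- function(ai, bi, kij, x, T, V) {
  aij <- sqrt(outer(ai, ai)) * (1 - kij)
  a <- sum(outer(x, x) * aij)
  b <- sum(x * bi)
  P <- srk_pressure_oracle(a, b, T, V)
  Z <- P * V / (R_BAR * T)
  A <- a * P / (R_BAR * T)^2
  B <- b * P / (R_BAR * T)
  term <- 2 * colSums(x * aij) / a - bi / b
  (bi / b) * (Z - 1) - log(Z - B) - (A / B) * term * log(1 + B / Z)
}

# pure-fluid CPA mixture builders used across tests
mix_pure <- function(name) cpa_mixture(list(get_component(name)))

# two inert model fluids for ideal-like binary tests (explicit zero kij)
inert_pair_mixture <- function() {
  light <- cpa_component("light_gas", mw = 40, tc = 300, a0 = 3.5,
                         b = 0.027, c1 = 0.75)
  heavy <- cpa_component("heavy_oil", mw = 200, tc = 550, a0 = 25,
                         b = 0.12, c1 = 1.1)
  cpa_mixture(list(light, heavy),
              binaries = list(cpa_binary("light_gas", "heavy_oil", 0)))
}

# five-point central-difference derivative of n*ares with respect to
# n_i at fixed total volume (numerical oracle for fugacity coefficients)
num_dnares <- function(mix, T, Vtot, n, i, h = 1e-4) {
  f <- function(d) {
    nv <- n; nv[i] <- nv[i] + d
    nt <- sum(nv)
    nt * cpa_ares(mix, T, Vtot / nt, nv / nt)
  }
  (f(-2 * h) - 8 * f(-h) + 8 * f(h) - f(2 * h)) / (12 * h)
}

# five-point derivative of ares with respect to volume (pressure oracle);
# the step scales with the distance to the co-volume pole, which sets the
# curvature scale of the repulsive term
num_dares_dV <- function(mix, T, V, x) {
  b <- sum(x * mix$cpp$b)
  h <- 6e-4 * (V - b)
  f <- function(d) cpa_ares(mix, T, V + d, x)
  (f(-2 * h) - 8 * f(-h) + 8 * f(h) - f(2 * h)) / (12 * h)
}
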