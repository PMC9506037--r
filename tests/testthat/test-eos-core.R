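# Equation-of-state core: Soave term, mixing rules, association term,
# site fractions, pressure, residual Helmholtz energy, volume roots and
# fugacity coefficients.

test_that("Soave attractive parameter equals a0 at Tc and the hand value off Tc", {
  co2 <- get_component("CO2")
  expect_equal(soave_a(co2, 304.2), 3.5079)
  expect_equal(soave_a(get_component("methanol"), 512.6), 4.0531)
  hand <- 3.5079 * (1 + 0.7602 * (1 - sqrt(273.15 / 304.2)))^2
  expect_equal(soave_a(co2, 273.15), hand, tolerance = 1e-12)
  expect_equal(round(hand, 3), 3.793)
  expect_error(soave_a(co2, -1), "positive")
})

test_that("van der Waals mixing rules: pure limit, hand value, annihilated cross term", {
  mm <- cpa_mixture(c("CO2", "methanol"))
  co2 <- get_component("CO2")
  pure <- mix_ab(mm, c(1, 0), 304.2)
  expect_equal(pure$a_mix, co2$a0)
  expect_equal(pure$b_mix, co2$b)
  eq <- mix_ab(mm, c(0.5, 0.5), 304.2)   # both at their Tc values? no: T fixed
  a1 <- soave_a(co2, 304.2); a2 <- soave_a(get_component("methanol"), 304.2)
  hand <- 0.25 * (a1 + a2) + 0.5 * sqrt(a1 * a2) * (1 - 0.0479)
  expect_equal(eq$a_mix, hand, tolerance = 1e-12)
  expect_equal(eq$b_ij[1, 2], (0.0272 + 0.0310) / 2)
  # kij = 1 annihilates the cross term
  m1 <- cpa_mixture(c("CO2", "methanol"),
                    binaries = list(cpa_binary("CO2", "methanol", 1)))
  expect_equal(mix_ab(m1, c(0.5, 0.5), 350)$a_mix,
               (soave_a(co2, 350) + soave_a(get_component("methanol"), 350)) / 4,
               tolerance = 1e-12)
})

test_that("radial distribution function and its density derivative", {
  z <- radial_distribution(0)
  expect_equal(z$g, 1); expect_equal(z$rho_dlng_drho, 0)
  expect_equal(radial_distribution(0.25)$g, 1 / 0.525, tolerance = 1e-12)
  expect_equal(radial_distribution(0.1)$rho_dlng_drho, 0.19 / 0.81,
               tolerance = 1e-12)
  # analytic derivative against central differences of ln g(eta(rho))
  b <- 0.1
  for (rho in c(0.5, 2, 6)) {
    h <- 1e-6 * rho
    num <- rho * (log(radial_distribution(b * (rho + h) / 4)$g) -
                  log(radial_distribution(b * (rho - h) / 4)$g)) / (2 * h)
    expect_equal(radial_distribution(b * rho / 4)$rho_dlng_drho, num,
                 tolerance = 1e-8)
  }
  expect_error(radial_distribution(1 / 1.9), "1/1.9")
})

test_that("cross-association combining rules (CR-1, mCR-1, explicit)", {
  gly <- get_component("glycerol"); met <- get_component("methanol")
  cr1 <- cross_association_parameters(
    cpa_binary("glycerol", "methanol", 0.0836, "CR1"), gly, met)
  expect_equal(cr1$eps_cross, (207.85 + 245.91) / 2)
  expect_equal(cr1$beta_cross, sqrt(0.0133 * 0.0161), tolerance = 1e-12)
  expect_equal(round(cr1$beta_cross, 5), 0.01463)

  co2 <- get_component("CO2")
  m <- cross_association_parameters(
    cpa_binary("CO2", "glycerol", 0.3084, "mCR1", beta_cross = 0.0979),
    co2, gly)
  expect_equal(m$eps_cross, 207.85 / 2)
  expect_equal(m$beta_cross, 0.0979)

  ex <- cross_association_parameters(get_binary("CO2", "methanol"), co2, met)
  expect_equal(ex$eps_cross, 123.8); expect_equal(ex$beta_cross, 0.0196)

  expect_error(cross_association_parameters(
    cpa_binary("CO2", "glycerol", 0, "CR1"), co2, gly), "self-associate")
})

test_that("association strength: zero limits and hand evaluation", {
  expect_equal(association_strength(400, 1.2, 0.05, 100, 0), 0)
  expect_equal(association_strength(400, 1.2, 0.05, 0, 0.02), 0)
  hand <- 1.2 * (exp(207.85 / (0.083145 * 400)) - 1) * 0.0696 * 0.0133
  expect_equal(association_strength(400, 1.2, 0.0696, 207.85, 0.0133), hand)
  expect_equal(round(hand, 3), 0.574)
})

test_that("closed-form site fractions for the symmetric schemes", {
  expect_equal(closed_form_site_fraction("2B", 0), 1)
  expect_equal(closed_form_site_fraction("2B", 1), (sqrt(5) - 1) / 2,
               tolerance = 1e-14)
  expect_equal(closed_form_site_fraction("2B", 2), 0.5)
  expect_equal(closed_form_site_fraction("4C", 1), 0.5)
  expect_equal(closed_form_site_fraction("3x2B", 1), (-1 + sqrt(13)) / 6,
               tolerance = 1e-14)
  expect_error(closed_form_site_fraction("5D", 1), "unsupported")
})

test_that("iterative site-fraction solver agrees with the closed forms", {
  rho <- 5
  grid <- c(0, 10^seq(-3, 3, length.out = 60))
  schemes <- list("1A" = cbind(1), "2B" = matrix(c(0, 1, 1, 0), 2),
                  "4C" = matrix(c(0, 1, 1, 0), 2),
                  "3x2B" = matrix(c(0, 1, 1, 0), 2))
  mult <- list("1A" = 1, "2B" = c(1, 1), "4C" = c(2, 2), "3x2B" = c(3, 3))
  for (sch in names(schemes)) {
    for (rd in grid) {
      delta <- schemes[[sch]] * rd / rho
      sf <- solve_site_fractions(rho, 1, delta,
                                 rep(1L, nrow(delta)), mult[[sch]])
      expect_equal(sf$X, rep(closed_form_site_fraction(sch, rd),
                             nrow(delta)), tolerance = 1e-10)
      expect_lte(sf$residual, 1e-11)
    }
  }
  # all-zero association strength leaves every site free
  sf0 <- solve_site_fractions(3, c(0.4, 0.6), matrix(0, 3, 3),
                              c(1L, 2L, 2L), c(1, 2, 2))
  expect_equal(sf0$X, rep(1, 3))
})

test_that("site fractions are symmetric and monotone in density and volume", {
  gly <- cpa_mixture("glycerol")
  rhos <- seq(0.5, 12, length.out = 12)
  Xs <- sapply(rhos, function(rho) {
    g <- radial_distribution(gly$cpp$b[1] * rho / 4)$g
    delta <- association_strength(350, g, gly$bij_mat, gly$eps_mat, gly$beta_mat)
    solve_site_fractions(rho, 1, delta, gly$sites$comp, gly$sites$mult)$X
  })
  expect_equal(Xs[1, ], Xs[2, ], tolerance = 1e-12)   # X+ == X-
  expect_true(all(diff(Xs[1, ]) < 0))                 # non-increasing in rho
  # monotone in the association volume at fixed state
  Xb <- sapply(c(0.005, 0.0133, 0.05, 0.2), function(beta) {
    g <- radial_distribution(gly$cpp$b[1] * 8 / 4)$g
    delta <- association_strength(350, g, gly$bij_mat, gly$eps_mat,
                                  0 * gly$beta_mat + beta * (gly$beta_mat > 0))
    solve_site_fractions(8, 1, delta, gly$sites$comp, gly$sites$mult)$X[1]
  })
  expect_true(all(diff(Xb) < 0))
})

test_that("with no active sites the CPA reduces exactly to SRK", {
  mm <- cpa_mixture(c("CO2", "methyl_palmitate"))
  expect_equal(mm$ns, 0L)
  ai_f <- function(T) vapply(mm$components, soave_a, 0, T = T)
  bi <- mm$cpp$b
  for (T in c(280, 320, 400)) {
    ai <- ai_f(T)
    for (x1 in c(0, 0.3, 1)) {
      x <- c(x1, 1 - x1)
      a <- sum(outer(x, x) * sqrt(outer(ai, ai)) * (1 - mm$kij))
      b <- sum(x * bi)
      for (V in c(1.2 * b, 3 * b, 2)) {
        expect_equal(cpa_pressure(mm, T, V, x),
                     srk_pressure_oracle(a, b, T, V), tolerance = 1e-12)
        expect_equal(cpa_ares(mm, T, V, x),
                     srk_ares_oracle(a, b, T, V), tolerance = 1e-12)
      }
    }
  }
})

test_that("pressure recovers the ideal-gas limit at large volume", {
  mm <- cpa_mixture(c("CO2", "methanol"))
  V <- 1e6
  P <- cpa_pressure(mm, 400, V, c(0.5, 0.5))
  expect_equal(P * V / (0.083145 * 400), 1, tolerance = 1e-4)
  expect_equal(cpa_ares(mm, 400, 1e8, c(0.5, 0.5)), 0, tolerance = 1e-6)
  expect_error(cpa_pressure(mm, 400, 0.01, c(0.5, 0.5)), "co-volume")
})

test_that("compiled evaluation path matches the pure-R composition term by term", {
  cases <- list(list(mix = cpa_mixture("glycerol"), x = 1),
                list(mix = cpa_mixture(c("CO2", "glycerol")), x = c(0.2, 0.8)),
                list(mix = cpa_mixture(c("CO2", "methanol", "glycerol")),
                     x = c(0.3, 0.5, 0.2)))
  for (cs in cases) {
    b <- sum(cs$x * cs$mix$cpp$b)
    for (T in c(310, 390)) for (V in c(1.3 * b, 0.5, 5)) {
      st <- cpaeos:::cpp_state(cs$mix$cpp, T, V, cs$x)
      expect_equal(st$P, cpa_pressure(cs$mix, T, V, cs$x), tolerance = 1e-11)
      expect_equal(st$ares, cpa_ares(cs$mix, T, V, cs$x), tolerance = 1e-11)
    }
  }
})

test_that("pressure equals the volume derivative of the residual Helmholtz energy", {
  mixes <- list(cpa_mixture("glycerol"),
                cpa_mixture(c("CO2", "methanol", "glycerol")))
  xs <- list(1, c(0.3, 0.45, 0.25))
  for (k in seq_along(mixes)) {
    mix <- mixes[[k]]; x <- xs[[k]]
    b <- sum(x * mix$cpp$b)
    for (T in c(320, 420)) for (V in c(1.4 * b, 0.3, 3)) {
      P_from_a <- -0.083145 * T * num_dares_dV(mix, T, V, x) +
        0.083145 * T / V
      expect_equal(cpa_pressure(mix, T, V, x), P_from_a,
                   tolerance = 1e-9)
    }
  }
})

test_that("analytic fugacity coefficients match numerical composition derivatives", {
  mix <- cpa_mixture(c("CO2", "methanol", "glycerol"))
  set.seed(11)
  for (rep in 1:6) {
    x <- as.numeric(rmultinom(1, 1000, c(0.3, 0.4, 0.3))) / 1000
    if (any(x == 0)) next
    T <- runif(1, 300, 420); P <- runif(1, 5, 200)
    for (phase in c("liquid", "vapor")) {
      lp <- fugacity_coefficients(mix, T, P, x, phase)
      V <- attr(lp, "V"); Z <- attr(lp, "Z")
      num <- vapply(1:3, function(i) num_dnares(mix, T, V, x, i), 0) - log(Z)
      expect_equal(as.numeric(lp), num, tolerance = 1e-6)
    }
  }
})

test_that("pure-fluid fugacity from the mixture expression and the ideal-gas limit", {
  # mixture route with a degenerate composition equals the pure route
  mm <- cpa_mixture(c("methanol", "CO2"))
  lp_mix <- fugacity_coefficients(mm, 330, 2, c(1, 0), "liquid")
  lp_pure <- fugacity_coefficients(mix_pure("methanol"), 330, 2, 1, "liquid")
  expect_equal(unname(lp_mix[1]), unname(lp_pure[1]), tolerance = 1e-9)
  # ln phi -> 0 as P -> 0 (vapor branch)
  lp0 <- fugacity_coefficients(cpa_mixture(c("CO2", "methanol")),
                               350, 1e-8, c(0.5, 0.5), "vapor")
  expect_lt(max(abs(lp0)), 1e-6)
})

test_that("volume solver satisfies its contract and selects the stable root", {
  mm <- cpa_mixture(c("CO2", "methanol"))
  # ideal-gas regime
  V <- solve_volume(mm, 500, 0.01, c(0.5, 0.5))
  expect_equal(as.numeric(V), 0.083145 * 500 / 0.01, tolerance = 1e-2)
  # residual contract across conditions
  for (T in c(280, 330)) for (P in c(1, 20, 60)) {
    for (ph in c("liquid", "vapor")) {
      V <- solve_volume(mm, T, P, c(0.4, 0.6), phase = ph)
      expect_lte(abs(cpa_pressure(mm, T, V, c(0.4, 0.6)) - P) / P, 1e-9)
    }
  }
  # two-root state: the auto choice minimizes residual Gibbs energy,
  # checked against a dense volume scan
  co2 <- mix_pure("CO2")
  T <- 260; ps <- pure_saturation("CO2", T)
  for (P in c(0.95 * ps$P, 1.05 * ps$P)) {
    V <- solve_volume(co2, T, P, 1, phase = "auto")
    roots <- attr(V, "roots")
    expect_gte(length(roots), 2)
    gres <- vapply(roots, function(v) {
      Z <- P * v / (0.083145 * T)
      cpa_ares(co2, T, v, 1) + Z - 1 - log(Z)
    }, 0)
    expect_equal(V, roots[which.min(gres)], tolerance = 1e-10,
                 ignore_attr = TRUE)
    # dense scan: no root of P(V)=P with lower Gibbs energy was missed
    Vg <- exp(seq(log(min(roots) * 0.9), log(max(roots) * 1.1), length.out = 400))
    f <- vapply(Vg, function(v) cpa_pressure(co2, T, v, 1) - P, 0)
    sign_changes <- sum(abs(diff(sign(f))) > 0)
    expect_lte(sign_changes, 3)
  }
})
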