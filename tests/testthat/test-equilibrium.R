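# Phase-equilibrium solvers: saturation, bubble/dew, flash, isotherms,
# vapor-composition minimum.

test_that("pure saturation satisfies fugacity equality and the equal-area rule", {
  ps <- pure_saturation("CO2", 273.15)
  expect_lte(ps$residual, 1e-10)
  expect_lt(ps$Vliq, ps$Vvap)
  # Maxwell equal-area construction on the same isotherm: the integral
  # of P(V) between the coexisting volumes equals Psat * (Vvap - Vliq)
  co2 <- mix_pure("CO2")
  area <- integrate(function(v) vapply(v, function(vv)
    cpa_pressure(co2, 273.15, vv, 1), 0),
    ps$Vliq, ps$Vvap, rel.tol = 1e-10)$value
  expect_equal(area, ps$P * (ps$Vvap - ps$Vliq), tolerance = 1e-6)
})

test_that("saturation pressure increases monotonically with temperature", {
  Ts <- seq(220, 300, by = 10)
  P <- NA
  psat <- vapply(Ts, function(T) {
    P <<- pure_saturation("CO2", T, P_init = if (is.na(P)) NULL else P)$P
  }, 0)
  expect_true(all(diff(psat) > 0))
})

test_that("saturation fails informatively above the two-phase limit", {
  expect_error(pure_saturation("CO2", 320), "supercritical")
})

test_that("bubble point reduces to pure saturation in the pure limit", {
  mm <- cpa_mixture(c("CO2", "methanol"))
  eq <- bubble_pressure(mm, 280, c(1, 0))
  expect_true(eq$converged)
  expect_equal(eq$P, pure_saturation("CO2", 280)$P, tolerance = 1e-7)
  eq2 <- bubble_pressure(mm, 330, c(0, 1))
  expect_equal(eq2$P, pure_saturation("methanol", 330)$P, tolerance = 1e-7)
})

test_that("bubble, dew and flash are mutually consistent", {
  mixes <- list(cpa_mixture(c("CO2", "methanol")),
                cpa_mixture(c("CO2", "glycerol", "methanol")))
  comps <- list(c(0.25, 0.75), c(0.30, 0.02, 0.68))
  for (k in seq_along(mixes)) {
    mix <- mixes[[k]]
    eq <- bubble_pressure(mix, 313, comps[[k]])
    expect_true(eq$converged)
    expect_lte(eq$residual, 1e-8)
    expect_equal(sum(eq$y), 1, tolerance = 1e-12)
    # dew at the bubble vapor reproduces the same pressure
    dq <- dew_pressure(mix, 313, eq$y)
    expect_true(dq$converged)
    expect_equal(dq$P, eq$P, tolerance = 1e-6)
    expect_equal(unname(dq$x), unname(eq$x), tolerance = 1e-5)
    # flash slightly below the bubble pressure gives a small vapor fraction
    # with compositions bracketing the bubble result
    fl <- pt_flash(mix, 313, eq$P * 0.995, comps[[k]])
    expect_true(fl$converged)
    expect_gt(fl$vapor_fraction, 0)
    expect_lt(fl$vapor_fraction, 0.2)
    mb <- comps[[k]] - fl$vapor_fraction * fl$y -
      (1 - fl$vapor_fraction) * fl$x
    expect_lte(max(abs(mb)), 1e-10)
    # flash above the bubble pressure: single liquid phase
    fa <- pt_flash(mix, 313, eq$P * 1.05, comps[[k]])
    expect_identical(fa$flag, "single_phase")
    expect_equal(fa$vapor_fraction, 0)
  }
})

test_that("flash round-trip: bubble pressure recovers the flash state", {
  mm <- cpa_mixture(c("CO2", "methanol"))
  fl <- pt_flash(mm, 313, 40, c(0.4, 0.6))
  expect_true(fl$converged && fl$flag == "ok")
  eq <- bubble_pressure(mm, 313, fl$x)
  expect_equal(eq$P, 40, tolerance = 1e-6)
  expect_equal(unname(eq$y), unname(fl$y), tolerance = 1e-6)
})

test_that("dew point drops a zero vapor component from the liquid", {
  mt <- cpa_mixture(c("CO2", "glycerol", "methanol"))
  eqb <- bubble_pressure(mt, 313, c(0.3, 0.02, 0.68))
  y <- c(eqb$y[1], 0, 1 - eqb$y[1])
  dq <- dew_pressure(mt, 313, y / sum(y))
  expect_true(dq$converged)
  expect_lte(dq$x[2], 1e-12)
})

test_that("isotherm tracing is monotone, warm-started and refinement-stable", {
  mp <- cpa_mixture(c("CO2", "PEG200"))
  expect_equal(nrow(trace_isotherm(mp, 313, numeric(0))), 0L)
  grid <- seq(0.05, 0.5, by = 0.05)
  iso <- trace_isotherm(mp, 313, grid)
  expect_true(all(iso$converged))
  expect_true(all(diff(iso$P) > 0))  # dilute branch: P increasing in x1
  # halving the step changes interpolated pressures by < 0.1 %
  iso2 <- trace_isotherm(mp, 313, seq(0.05, 0.5, by = 0.025))
  Pi <- approx(iso2$x1, iso2$P, xout = grid)$y
  expect_lt(max(abs(Pi - iso$P) / iso$P), 1e-3)
  # the pressure-grid sweep inverts the composition sweep
  isoP <- trace_isotherm(mp, 313, P = iso$P[c(2, 5, 8)])
  expect_true(all(isoP$converged))
  expect_equal(isoP$x1, iso$x1[c(2, 5, 8)], tolerance = 1e-6)
  expect_error(trace_isotherm(mp, 313), "exactly one")
})

test_that("heavy-component vapor fraction shows an interior minimum for CO2-glycerol", {
  mg <- cpa_mixture(c("CO2", "glycerol"))   # one-site parameter set
  vm <- vapor_composition_minimum(mg, 323, c(5, 350), n_scan = 30)
  expect_true(vm$interior)
  expect_gt(vm$P_min, 5); expect_lt(vm$P_min, 350)
  ok <- !is.na(vm$scan$y_heavy)
  expect_lte(vm$y_heavy_min, min(vm$scan$y_heavy[ok]))
})

test_that("a monotone ideal-like system returns the boundary, not a spurious minimum", {
  mix <- inert_pair_mixture()
  vm <- vapor_composition_minimum(mix, 280, c(2, 12), n_scan = 12)
  expect_false(vm$interior)
  ok <- !is.na(vm$scan$y_heavy)
  expect_true(all(diff(vm$scan$y_heavy[ok]) < 0))  # pure dilution branch
})

test_that("ternary predictions accept only binary-level inputs", {
  # assembling a ternary with an undeclared pair fails loudly, naming it
  expect_error(cpa_mixture(c("CO2", "methanol", "tributyrin")),
               "methanol / tributyrin")
  # declared explicit zero makes the same mixture legal
  mix <- cpa_mixture(c("CO2", "methanol", "tributyrin"),
                     binaries = list(cpa_binary("methanol", "tributyrin", 0)))
  expect_identical(mix$nc, 3L)
})
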