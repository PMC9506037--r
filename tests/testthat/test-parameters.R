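# Parameter registry and molecular-weight correlations.

test_that("registry returns tabulated pure-fluid parameters verbatim", {
  co2 <- get_component("CO2")
  expect_equal(co2$a0, 3.5079)
  expect_equal(co2$b, 0.0272)
  expect_equal(co2$c1, 0.7602)
  expect_equal(co2$tc, 304.2)
  expect_identical(co2$scheme, "none")

  gly <- get_component("glycerol")
  expect_equal(gly$a0, 11.80)
  expect_equal(gly$b, 0.0696)
  expect_equal(gly$c1, 0.90)
  expect_equal(gly$eps_assoc, 207.85)
  expect_equal(gly$beta_assoc, 0.0133)
  expect_identical(gly$scheme, "3x2B")

  peg <- get_component("PEG200")
  expect_equal(peg$a0, 54.688)   # linear-correlation value is the working a0
  expect_equal(peg$b, 0.1797)
  expect_equal(peg$c1, 1.4135)
  expect_equal(peg$eps_assoc, 143.37)
  expect_equal(peg$beta_assoc, 0.0188)
  expect_identical(peg$scheme, "4C")

  acid <- get_component("lauric_acid")
  expect_equal(acid$beta_assoc, 7.75e-4)
  expect_identical(acid$scheme, "1A")
})

test_that("component lookup is case-insensitive with synonyms, unknown names rejected", {
  expect_identical(get_component("co2")$name, "CO2")
  expect_identical(get_component("Tetraethylene Glycol")$name,
                   "tetraethylene_glycol")
  expect_identical(get_component("TEG")$name, "triethylene_glycol")
  expect_error(get_component("unobtainium"), "registry")
})

test_that("binary registry returns printed parameters and named variants", {
  b <- get_binary("CO2", "PEG300")
  expect_equal(b$kij, -0.0200)
  expect_identical(b$cross_rule, "none")
  # order-insensitive
  expect_equal(get_binary("PEG300", "CO2")$kij, -0.0200)

  bm <- get_binary("CO2", "methanol")
  expect_equal(bm$kij, 0.0479)
  expect_equal(bm$eps_cross, 123.8)
  expect_equal(bm$beta_cross, 0.0196)
  expect_identical(bm$cross_rule, "explicit")

  # the two published CO2-glycerol parameterizations
  inert <- get_binary("CO2", "glycerol", variant = "inert")
  expect_equal(inert$kij, 0.1643)
  expect_identical(inert$cross_rule, "none")
  onesite <- get_binary("CO2", "glycerol", variant = "one-site")
  expect_equal(onesite$kij, 0.3084)
  expect_equal(onesite$beta_cross, 0.0979)
  expect_identical(get_binary("CO2", "glycerol")$variant, "one-site")
  expect_setequal(attr(get_binary("CO2", "glycerol"), "variants"),
                  c("inert", "one-site"))

  expect_equal(get_binary("methyl_oleate", "methyl_palmitate")$kij, 0)
  expect_error(get_binary("CO2", "unobtainium"))
  expect_error(get_binary("methanol", "ethanol"), "no binary parameters")
})

test_that("least-squares mw correlation matches the normal-equations oracle", {
  comps <- lapply(c("ethylene_glycol", "diethylene_glycol",
                    "triethylene_glycol", "tetraethylene_glycol"),
                  get_component)
  mw <- vapply(comps, `[[`, 0, "mw")
  a0 <- vapply(comps, `[[`, 0, "a0")
  for (form in c("linear", "quadratic")) {
    fit <- fit_mw_correlation(mw, a0, form)
    deg <- if (form == "linear") 1 else 2
    X <- outer(mw, 0:deg, `^`)
    beta <- solve(t(X) %*% X, t(X) %*% a0)   # normal equations, by hand
    expect_equal(fit$coefficients, drop(beta), tolerance = 1e-9)
  }
})

test_that("mw correlation is exact on data lying on a line or parabola", {
  fit <- fit_mw_correlation(c(0, 1), c(0, 1), "linear")
  expect_equal(fit$coefficients, c(0, 1), tolerance = 1e-12)
  mw <- c(50, 120, 260, 410)
  val <- 2 - 0.03 * mw + 4e-4 * mw^2
  fq <- fit_mw_correlation(mw, val, "quadratic")
  expect_lt(fq$rss, 1e-12)
  expect_equal(predict(fq, 300), 2 - 0.03 * 300 + 4e-4 * 300^2,
               tolerance = 1e-10)
})

test_that("mw correlation rejects underdetermined or duplicated input", {
  expect_error(fit_mw_correlation(c(1, 2), c(1, 2), "quadratic"), "at least 3")
  expect_error(fit_mw_correlation(c(1, 1, 2), c(1, 2, 3), "linear"), "distinct")
})

test_that("glycol fits reproduce the tabulated polyethylene-glycol parameters", {
  tab <- peg_param_table(c(150, 200, 300, 400, 600))
  expect_equal(tab$b, c(0.1332, 0.1797, 0.2726, 0.3654, 0.5512),
               tolerance = 1e-3)
  expect_equal(tab$a0_linear, c(39.197, 54.688, 85.670, 116.652, 178.616),
               tolerance = 1e-3)
  expect_equal(tab$a0_quadratic, c(38.023, 56.337, 102.004, 159.723, 311.315),
               tolerance = 5e-4)
  # tabulated c1/Tc returned verbatim at the five anchor masses
  expect_equal(tab$c1, c(1.2993, 1.4135, 1.5744, 1.6885, 1.8494))
  expect_equal(tab$tc, c(766, 812, 961, 1186, 1860))
})

test_that("predicted PEG component matches the directly fitted glycol", {
  p400 <- predict_peg_component(400)
  expect_equal(p400$b, 0.3654, tolerance = 1e-3)
  expect_equal(p400$a0, 116.652, tolerance = 1e-3)
  expect_equal(p400$c1, 1.6885)
  expect_equal(p400$tc, 1186)
  # at the tetraethylene-glycol molar mass the correlation reproduces
  # the directly fitted co-volume to 1%
  teg <- get_component("triethylene_glycol")
  expect_equal(predict_peg_component(150.17)$b, teg$b, tolerance = 0.01)
  expect_error(predict_peg_component(30), "domain")
  expect_error(predict_peg_component(700), "domain")
})

test_that("PEG prediction is continuous in molar mass", {
  mws <- seq(63, 649, length.out = 120)
  vals <- vapply(mws, function(m) {
    p <- suppressMessages(predict_peg_component(m))
    c(p$a0, p$b, p$c1, p$tc)
  }, numeric(4))
  steps <- abs(t(diff(t(vals))))
  # piecewise-linear in all four parameters: increments stay bounded by
  # a modest multiple of the mean increment (no jumps)
  for (r in 1:4) expect_lt(max(steps[r, ]), 12 * mean(steps[r, ]))
})

test_that("empty parameter-table request yields a header-only table", {
  tab <- peg_param_table(numeric(0))
  expect_equal(nrow(tab), 0L)
  expect_true(all(c("mw", "a0_linear", "a0_quadratic", "b", "c1") %in%
                  names(tab)))
})
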