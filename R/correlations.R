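# Molecular-weight correlations for pure-fluid parameters.
#
# Within a homologous family (here the ethylene-glycol oligomers) the
# co-volume b is close to linear in molar mass and the attractive energy
# a0 is linear to mildly quadratic, provided the association parameters
# are held constant across the family.  Fitting these trends on the four
# glycols with known parameters lets the package predict parameters for
# polyethylene glycols of arbitrary average molar mass.

#' Fit a parameter-versus-molecular-weight correlation
#'
#' Ordinary least squares in the monomial basis of molecular weight.
#'
#' @param mw Molecular weights, g/mol (distinct values).
#' @param value Parameter values at each `mw`.
#' @param form `"linear"` or `"quadratic"`.
#' @param parameter_name Optional label (e.g. `"a0"`, `"b"`).
#' @return Object of class `cpa_mw_correlation` with elements
#'   `coefficients` (intercept first), `form`, `domain` (mw range of the
#'   fitted points) and `parameter_name`.  Supports [predict()].
#' @export
#' @examples
#' fit_mw_correlation(c(0, 1), c(0, 1), "linear")
fit_mw_correlation <- function(mw, value, form = c("linear", "quadratic"),
                               parameter_name = NULL) {
  form <- match.arg(form)
  stopifnot(length(mw) == length(value))
  ncoef <- if (form == "linear") 2L else 3L
  if (length(unique(mw)) < length(mw))
    stop("mw values must be distinct")
  if (length(mw) < ncoef)
    stop(sprintf("%s fit needs at least %d points, got %d",
                 form, ncoef, length(mw)))
  fit <- if (form == "linear") lm(value ~ mw) else lm(value ~ mw + I(mw^2))
  structure(list(coefficients = unname(coef(fit)),
                 form = form,
                 domain = range(mw),
                 parameter_name = parameter_name,
                 rss = sum(fit$residuals^2)),
            class = "cpa_mw_correlation")
}

#' @export
predict.cpa_mw_correlation <- function(object, mw, ...) {
  co <- object$coefficients
  out <- co[1] + co[2] * mw
  if (object$form == "quadratic") out <- out + co[3] * mw^2
  out
}

#' @export
print.cpa_mw_correlation <- function(x, ...) {
  cat(sprintf("<cpa_mw_correlation> %s in mw (%s), domain [%.4g, %.4g] g/mol\n",
              x$parameter_name %||% "parameter", x$form,
              x$domain[1], x$domain[2]))
  cat("  coefficients (intercept first):",
      paste(signif(x$coefficients, 6), collapse = ", "), "\n")
  invisible(x)
}

# The four glycol oligomers anchoring the correlations.
.glycol_family <- c("ethylene_glycol", "diethylene_glycol",
                    "triethylene_glycol", "tetraethylene_glycol")

# Fit the family correlations from the registry at run time (so that
# reproduction of the tabulated PEG parameters is a genuine computation,
# not a stored constant).
.glycol_correlations <- function() {
  comps <- lapply(.glycol_family, get_component)
  mw <- vapply(comps, `[[`, 0, "mw")
  list(b = fit_mw_correlation(mw, vapply(comps, `[[`, 0, "b"),
                              "linear", parameter_name = "b"),
       a0_linear = fit_mw_correlation(mw, vapply(comps, `[[`, 0, "a0"),
                                      "linear", parameter_name = "a0"),
       a0_quadratic = fit_mw_correlation(mw, vapply(comps, `[[`, 0, "a0"),
                                         "quadratic", parameter_name = "a0"))
}

.peg_mw_domain <- c(62, 650)
.peg_knots <- c("PEG150", "PEG200", "PEG300", "PEG400", "PEG600")

#' Predict CPA parameters for a polyethylene glycol of given molar mass
#'
#' `b` and `a0` come from least-squares correlations on the four glycol
#' oligomers; the association parameters are held constant across the
#' family (4C scheme, eps = 143.37 bar·L/mol, beta = 0.0188).  At the five
#' tabulated average molar masses (150, 200, 300, 400, 600 g/mol) `c1`
#' and `Tc` are the registry values verbatim; in between they are
#' piecewise-linear in molar mass (clamped outside the tabulated range),
#' since no functional form for them is established.
#'
#' @param mw Average molar mass, g/mol, within \[62, 650\].
#' @param a0_form Correlation used for `a0`: `"linear"` (the working
#'   choice for phase-equilibrium work) or `"quadratic"`.
#' @return A [cpa_component] named `PEG<mw>`.
#' @export
#' @examples
#' predict_peg_component(400)
predict_peg_component <- function(mw, a0_form = c("linear", "quadratic")) {
  a0_form <- match.arg(a0_form)
  stopifnot(is.numeric(mw), length(mw) == 1L)
  if (mw < .peg_mw_domain[1] || mw > .peg_mw_domain[2])
    stop(sprintf("mw = %g g/mol outside the correlation domain [%g, %g]",
                 mw, .peg_mw_domain[1], .peg_mw_domain[2]))
  corr <- .glycol_correlations()
  b <- predict(corr$b, mw)
  a0 <- predict(if (a0_form == "linear") corr$a0_linear else corr$a0_quadratic, mw)
  knots <- lapply(.peg_knots, get_component)
  kmw <- vapply(knots, `[[`, 0, "mw")
  hit <- which(abs(kmw - mw) < 1e-9)
  if (length(hit) == 1L) {
    c1 <- knots[[hit]]$c1
    tc <- knots[[hit]]$tc
  } else {
    c1 <- approx(kmw, vapply(knots, `[[`, 0, "c1"), xout = mw, rule = 2)$y
    tc <- approx(kmw, vapply(knots, `[[`, 0, "tc"), xout = mw, rule = 2)$y
    if (mw < min(kmw) || mw > max(kmw))
      message(sprintf("note: c1/Tc for mw = %g g/mol taken from the nearest tabulated PEG (extrapolation)", mw))
  }
  ref <- get_component("ethylene_glycol") # family association parameters
  cpa_component(name = sprintf("PEG%g", mw), mw = mw, tc = tc,
                a0 = a0, b = b, c1 = c1,
                eps_assoc = ref$eps_assoc, beta_assoc = ref$beta_assoc,
                scheme = "4C")
}

#' Tabulate predicted polyethylene-glycol parameters
#'
#' One row per requested molar mass with both the linear and the
#' quadratic `a0` correlation values alongside `b`, `c1`, `Tc` and the
#' (constant) association parameters.
#'
#' @param mw Numeric vector of average molar masses, g/mol.
#' @return A data.frame with columns `mw`, `tc`, `a0_quadratic`,
#'   `a0_linear`, `b`, `c1`, `eps_assoc`, `beta_assoc`.
#' @export
peg_param_table <- function(mw) {
  cols <- c("mw", "tc", "a0_quadratic", "a0_linear", "b", "c1",
            "eps_assoc", "beta_assoc")
  if (length(mw) == 0L) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    return(out)
  }
  rows <- lapply(mw, function(m) {
    lin <- predict_peg_component(m, "linear")
    quad <- predict_peg_component(m, "quadratic")
    data.frame(mw = m, tc = lin$tc, a0_quadratic = quad$a0,
               a0_linear = lin$a0, b = lin$b, c1 = lin$c1,
               eps_assoc = lin$eps_assoc, beta_assoc = lin$beta_assoc)
  })
  do.call(rbind, rows)
}
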