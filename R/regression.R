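# Parameter regression: %AAD metric, binary-parameter fits with
# phase-specific objectives, pure-fluid parameter fits to saturation data.

#' Percent average absolute deviation
#'
#' `100 * mean(|exp - calc| / exp)`.
#'
#' @param calc Calculated values.
#' @param exp Experimental (reference) values, strictly nonzero.
#' @return Percent AAD.
#' @export
percent_aad <- function(calc, exp) {
  if (length(calc) != length(exp)) stop("calc and exp must have equal length")
  if (any(exp == 0)) stop("percent AAD undefined for zero reference values")
  100 * mean(abs(exp - calc) / abs(exp))
}

#' @export
print.cpa_fit <- function(x, ...) {
  cat("<cpa_fit>", x$description, "\n")
  cat("  parameters:", paste(sprintf("%s = %.6g", names(x$parameters),
                                     x$parameters), collapse = ", "), "\n")
  cat(sprintf("  objective %.6g after %d evaluations (%s)\n",
              x$objective, x$evaluations,
              if (x$converged) "converged" else "NOT converged"))
  if (length(x$aad)) {
    cat("  % AAD:", paste(sprintf("%s = %.3g", names(x$aad), x$aad),
                          collapse = ", "), "\n")
  }
  invisible(x)
}

# bubble pressures for all records carrying liquid compositions,
# warm-started within each isotherm
.calc_bubble_P <- function(mix, data, cache = NULL) {
  out <- rep(NA_real_, nrow(data))
  for (Tv in unique(data$T)) {
    rows <- which(data$T == Tv & !is.na(data$x1))
    rows <- rows[order(data$x1[rows])]
    Pw <- NULL; Kw <- NULL
    for (r in rows) {
      key <- paste0("b", r)
      if (!is.null(cache) && !is.null(cache[[key]])) {
        Pw <- cache[[key]]$P; Kw <- cache[[key]]$K
      }
      eq <- tryCatch(bubble_pressure(mix, Tv, c(data$x1[r], 1 - data$x1[r]),
                                     P_init = Pw, K_init = Kw),
                     error = function(e) NULL)
      if (!is.null(eq) && eq$converged) {
        out[r] <- eq$P; Pw <- eq$P; Kw <- eq$K_values
        if (!is.null(cache)) cache[[key]] <- list(P = Pw, K = Kw)
      } else { Pw <- NULL; Kw <- NULL }
    }
  }
  out
}

# coexistence (x1, y2) at each record's (T, P), warm-started in P
.calc_coexistence <- function(mix, data, cache = NULL) {
  x1c <- y2c <- rep(NA_real_, nrow(data))
  for (Tv in unique(data$T)) {
    rows <- which(data$T == Tv)
    rows <- rows[order(data$P[rows])]
    st <- NULL; x1w <- 0.2
    for (r in rows) {
      key <- paste0("c", r)
      if (!is.null(cache) && !is.null(cache[[key]])) st <- cache[[key]]
      sol <- tryCatch(.binary_xy_at_TP(mix, Tv, data$P[r],
                                       x1_init = x1w, state = st),
                      error = function(e) NULL)
      if (!is.null(sol) && sol$eq$converged &&
          abs(sol$eq$P - data$P[r]) <= 1e-6 * data$P[r]) {
        x1c[r] <- sol$eq$x[1]; y2c[r] <- sol$eq$y[2]
        st <- sol$state; x1w <- sol$eq$x[1]
        if (!is.null(cache)) cache[[key]] <- st
      } else st <- NULL
    }
  }
  list(x1 = x1c, y2 = y2c)
}

.fit_binary_mix <- function(comps, kij, cross_rule, beta_cross, eps_cross) {
  bn <- if (cross_rule == "none") cpa_binary(comps[[1]]$name, comps[[2]]$name, kij)
  else cpa_binary(comps[[1]]$name, comps[[2]]$name, kij, cross_rule,
                  eps_cross = eps_cross, beta_cross = beta_cross)
  cpa_mixture(comps, binaries = list(bn))
}

#' Fit binary interaction parameters to VLE data
#'
#' Estimates one temperature-independent `kij` (optionally together with
#' the cross-association volume `beta_cross` under the mCR-1 rule) by
#' bounded minimization of a relative squared-error objective on the
#' quantity the data report: bubble pressure at measured liquid
#' compositions (`"pressure"`), liquid-phase light-component fraction at
#' measured (T, P) (`"liquid_x"`), heavy-component vapor fraction
#' (`"vapor_y"`), or both compositions (`"combined"`).  Two-parameter
#' fits use multi-start local optimization to avoid secondary minima.
#'
#' @param data A `vle_dataset` (or data.frame with columns `T`, `P`,
#'   `x1`, `x2`, `y1`, `y2`, `NA` marking unmeasured phases).
#' @param components Two component identifiers or [cpa_component]s;
#'   defaults to the dataset's `components` attribute.
#' @param free `"kij"` or `c("kij", "beta_cross")`.
#' @param objective Objective choice (see above).
#' @param cross_rule Cross-association rule for the pair; defaults to
#'   `"mCR1"` when `beta_cross` is free, `"none"` otherwise.
#' @param kij_bounds,beta_bounds Box bounds for the search.
#' @param n_starts Number of starts for the two-parameter fit.
#' @return Object of class `cpa_fit`: fitted `parameters`, `objective`,
#'   post-fit `aad` breakdown (percent, on every quantity the data
#'   report), `evaluations`, `converged`.
#' @export
fit_binary <- function(data, components = attr(data, "components"),
                       free = "kij",
                       objective = c("pressure", "liquid_x", "vapor_y", "combined"),
                       cross_rule = NULL,
                       kij_bounds = c(-0.3, 0.5), beta_bounds = c(1e-4, 0.5),
                       n_starts = 5) {
  objective <- match.arg(objective)
  stopifnot(all(free %in% c("kij", "beta_cross")), "kij" %in% free)
  two_par <- "beta_cross" %in% free
  if (is.null(cross_rule)) cross_rule <- if (two_par) "mCR1" else "none"
  if (is.null(components) || length(components) != 2)
    stop("two components must be identified (dataset attribute or argument)")
  comps <- lapply(components, function(cc)
    if (inherits(cc, "cpa_component")) cc else get_component(cc))
  data <- as.data.frame(data)
  if (nrow(data) == 0) stop("empty dataset")
  has_x <- !is.na(data$x1); has_y <- !is.na(data$y2)
  need <- switch(objective,
                 pressure = has_x, liquid_x = has_x,
                 vapor_y = has_y, combined = has_x | has_y)
  if (!any(need))
    stop("dataset reports no records usable for objective '", objective, "'")
  w <- if (!is.null(data$weight)) data$weight else rep(1, nrow(data))
  eps_cross <- if (cross_rule == "mCR1")
    (comps[[1]]$eps_assoc + comps[[2]]$eps_assoc) / 2 else NULL

  nev <- 0L
  # note: warm starts are shared only along an isotherm within one
  # evaluation; sharing them across parameter evaluations can hand the
  # bubble solver a wrong-branch initialization for asymmetric systems
  obj <- function(par) {
    nev <<- nev + 1L
    kij <- par[1]
    bc <- if (two_par) par[2] else NULL
    mix <- .fit_binary_mix(comps, kij, cross_rule, bc, eps_cross)
    err <- numeric(0); ww <- numeric(0)
    if (objective == "pressure") {
      Pc <- .calc_bubble_P(mix, data)
      sel <- has_x
      e <- (Pc[sel] - data$P[sel]) / data$P[sel]
      e[is.na(e)] <- 10
      err <- e; ww <- w[sel]
    } else {
      cx <- .calc_coexistence(mix, data)
      if (objective %in% c("liquid_x", "combined")) {
        sel <- has_x
        e <- (cx$x1[sel] - data$x1[sel]) / data$x1[sel]
        e[is.na(e)] <- 10
        err <- c(err, e); ww <- c(ww, w[sel])
      }
      if (objective %in% c("vapor_y", "combined")) {
        sel <- has_y
        e <- (cx$y2[sel] - data$y2[sel]) / data$y2[sel]
        e[is.na(e)] <- 10
        err <- c(err, e); ww <- c(ww, w[sel])
      }
    }
    sum(ww * err^2)
  }

  if (!two_par) {
    op <- optimize(obj, interval = kij_bounds, tol = 1e-7)
    pars <- c(kij = op$minimum); fval <- op$objective
    converged <- TRUE
  } else {
    starts <- cbind(seq(kij_bounds[1] + 0.1, kij_bounds[2] - 0.1,
                        length.out = n_starts),
                    exp(seq(log(0.01), log(0.3), length.out = n_starts)))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      op <- tryCatch(
        optim(starts[s, ], obj, method = "L-BFGS-B",
              lower = c(kij_bounds[1], beta_bounds[1]),
              upper = c(kij_bounds[2], beta_bounds[2]),
              control = list(parscale = c(0.1, 0.05), factr = 1e7)),
        error = function(e) NULL)
      if (!is.null(op) && (is.null(best) || op$value < best$value)) best <- op
    }
    if (is.null(best)) stop("all optimization starts failed")
    pars <- c(kij = best$par[1], beta_cross = best$par[2])
    fval <- best$value
    converged <- best$convergence == 0
  }

  # post-fit AAD breakdown on everything the dataset reports
  mix <- .fit_binary_mix(comps, pars[["kij"]], cross_rule,
                         if (two_par) pars[["beta_cross"]] else NULL, eps_cross)
  aad <- c()
  if (any(has_x)) {
    Pc <- .calc_bubble_P(mix, data)
    okp <- has_x & !is.na(Pc)
    if (any(okp)) aad["pressure"] <- percent_aad(Pc[okp], data$P[okp])
  }
  if (any(has_x) || any(has_y)) {
    cx <- .calc_coexistence(mix, data)
    okx <- has_x & !is.na(cx$x1)
    if (any(okx)) aad["x1"] <- percent_aad(cx$x1[okx], data$x1[okx])
    oky <- has_y & !is.na(cx$y2)
    if (any(oky)) aad["y2"] <- percent_aad(cx$y2[oky], data$y2[oky])
  }
  structure(list(parameters = pars, objective = fval, aad = aad,
                 evaluations = nev, converged = converged,
                 cross_rule = cross_rule,
                 description = sprintf("%s / %s (%s objective)",
                                       comps[[1]]$name, comps[[2]]$name,
                                       objective)),
            class = "cpa_fit")
}

#' Fit pure-component physical parameters to saturation data
#'
#' Adjusts `a0`, `b` and `c1` (association energy and volume held fixed,
#' as within a homologous family) by minimizing summed squared relative
#' deviations of saturation pressure and liquid molar volume with equal
#' weights.
#'
#' @param template A [cpa_component] supplying `Tc`, the fixed
#'   association parameters and the scheme.
#' @param data data.frame with columns `T` (K), `Psat` (bar), `Vliq`
#'   (L/mol); at least 6 records.
#' @return `cpa_fit` with fitted `parameters` (`a0`, `b`, `c1`),
#'   `component` (the refitted [cpa_component]) and percent `aad` in
#'   `Psat` and `Vliq`.
#' @export
fit_pure <- function(template, data) {
  stopifnot(inherits(template, "cpa_component"))
  data <- as.data.frame(data)
  if (nrow(data) < 6) stop("at least 6 saturation records are required")
  data <- data[order(data$T), ]
  mk <- function(a0, b, c1)
    cpa_component(template$name, template$mw, template$tc, a0, b, c1,
                  template$eps_assoc, template$beta_assoc, template$scheme)
  calc <- function(comp) {
    Pc <- Vc <- rep(NA_real_, nrow(data))
    Pw <- NULL
    for (r in seq_len(nrow(data))) {
      ps <- tryCatch(pure_saturation(comp, data$T[r], P_init = Pw),
                     error = function(e) NULL)
      if (!is.null(ps)) { Pc[r] <- ps$P; Vc[r] <- ps$Vliq; Pw <- ps$P }
      else Pw <- NULL
    }
    list(P = Pc, V = Vc)
  }
  nev <- 0L
  obj <- function(par) {
    nev <<- nev + 1L
    comp <- tryCatch(mk(exp(par[1]), exp(par[2]), par[3]),
                     error = function(e) NULL)
    if (is.null(comp)) return(1e8)
    cc <- calc(comp)
    e <- c((cc$P - data$Psat) / data$Psat, (cc$V - data$Vliq) / data$Vliq)
    e[is.na(e)] <- 100
    sum(e^2)
  }
  # data-driven initialization: co-volume from the densest liquid record,
  # attractive parameter from a Clausius-Clapeyron estimate of Pc
  b0 <- 0.8 * min(data$Vliq)
  nr <- nrow(data)
  slope <- (log(data$Psat[nr]) - log(data$Psat[nr - 1])) /
    (1 / data$T[nr] - 1 / data$T[nr - 1])
  Pc_est <- exp(log(data$Psat[nr]) + slope * (1 / template$tc - 1 / data$T[nr]))
  a0_0 <- 0.42748 * .RGAS^2 * template$tc^2 / max(Pc_est, 1)
  p0 <- c(log(a0_0), log(b0), 1.0)
  op <- optim(p0, obj, method = "Nelder-Mead",
              control = list(maxit = 500, reltol = 1e-11))
  if (op$value >= 1e8) stop("pure-parameter fit failed to evaluate")
  pars <- c(a0 = exp(op$par[1]), b = exp(op$par[2]), c1 = op$par[3])
  comp <- mk(pars[["a0"]], pars[["b"]], pars[["c1"]])
  cc <- calc(comp)
  ok <- !is.na(cc$P)
  # identifiability check: flat objective along a0 at fixed fit quality
  structure(list(parameters = pars, objective = op$value,
                 aad = c(Psat = percent_aad(cc$P[ok], data$Psat[ok]),
                         Vliq = percent_aad(cc$V[ok], data$Vliq[ok])),
                 evaluations = nev, converged = op$convergence == 0,
                 component = comp,
                 description = sprintf("pure-fluid parameters for %s",
                                       template$name)),
            class = "cpa_fit")
}
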