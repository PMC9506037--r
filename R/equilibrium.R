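# Phase-equilibrium algorithms on top of the EoS core: pure-fluid
# saturation, bubble/dew points, isothermal two-phase flash, isotherm
# tracing and the vapor-composition-minimum locator.

.psat_cache <- new.env(parent = emptyenv())

.comp_hash <- function(comp) {
  paste(comp$name, comp$a0, comp$b, comp$c1, comp$tc,
        comp$eps_assoc, comp$beta_assoc, sep = "|")
}

.pure_mixture <- function(comp) cpa_mixture(list(comp))

.lnphi <- function(mix, T, P, x, hint) cpp_lnphi(mix$cpp, T, P, x, hint)

# distinct liquid and vapor roots at (T, P)?
.two_roots <- function(mix, T, P) {
  v <- cpp_volume(mix$cpp, T, P, 1, 0L)
  v$nroots >= 2 && (max(v$roots) - min(v$roots)) > 1e-9 * max(v$roots)
}

#' Pure-component saturation pressure
#'
#' Solves the phase-equilibrium condition `ln phi_liq = ln phi_vap` for a
#' pure fluid at temperature `T`.  A coarse logarithmic pressure scan
#' locates the two-root window and brackets the fugacity-equality root,
#' which is then polished to `|ln phi_L - ln phi_V| <= 1e-10`; a supplied
#' `P_init` short-circuits the scan with a secant iteration.
#'
#' @param comp A [cpa_component] or registry name.
#' @param T Temperature, K (must admit two volume roots: subcritical for
#'   the model).
#' @param P_init Optional initial pressure guess, bar.
#' @return List with `P` (bar), `Vliq`, `Vvap` (L/mol), `residual` and
#'   `iterations`.
#' @export
pure_saturation <- function(comp, T, P_init = NULL) {
  if (!inherits(comp, "cpa_component")) comp <- get_component(comp)
  mix <- .pure_mixture(comp)
  Vl <- Vv <- NA_real_
  fres <- function(P) {
    v <- cpp_volume(mix$cpp, T, P, 1, 0L)
    if (v$nroots < 2) return(NA_real_)
    Vl <<- min(v$roots); Vv <<- max(v$roots)
    if ((Vv - Vl) <= 1e-9 * Vv) return(NA_real_)
    # compare full fugacities ln(phi P) at each branch's computed
    # pressure: insensitive to the residual volume-refinement error
    ll <- cpp_lnphi_TV(mix$cpp, T, Vl, 1)
    lv <- cpp_lnphi_TV(mix$cpp, T, Vv, 1)
    if (!is.finite(ll$P) || !is.finite(lv$P) || ll$P <= 0 || lv$P <= 0)
      return(NA_real_)
    (ll$lnphi + log(ll$P)) - (lv$lnphi + log(lv$P))
  }
  it <- 0L
  secant_polish <- function(P0) {
    p1 <- P0; f1 <- fres(p1)
    if (is.na(f1)) return(NULL)
    best_p <- p1; best_f <- abs(f1); best_V <- c(Vl, Vv)
    p2 <- P0 * 1.05; f2 <- fres(p2)
    while (!is.na(f2) && it < 60L) {
      if (abs(f2) < best_f) { best_p <- p2; best_f <- abs(f2); best_V <- c(Vl, Vv) }
      if (abs(f2) < 1e-13 || abs(f2 - f1) < 1e-300) break
      p3 <- exp(log(p2) - f2 * (log(p2) - log(p1)) / (f2 - f1))
      p1 <- p2; f1 <- f2; p2 <- p3; f2 <- fres(p3)
      it <<- it + 1L
    }
    if (best_f <= 1e-10)
      list(P = best_p, Vliq = best_V[1], Vvap = best_V[2],
           residual = best_f, iterations = it)
    else NULL
  }
  if (!is.null(P_init)) {
    out <- secant_polish(P_init)
    if (!is.null(out)) return(out)
  }
  # coarse scan for the two-root window
  Pg <- exp(seq(log(1e-12), log(1e4), length.out = 140))
  fg <- vapply(Pg, fres, 0)
  ok <- which(!is.na(fg))
  if (length(ok) == 0)
    stop(sprintf("%s at T = %g K: no two-root pressure window (supercritical for the model)",
                 comp$name, T), call. = FALSE)
  br <- NULL
  for (k in ok[-length(ok)]) {
    if (!is.na(fg[k]) && !is.na(fg[k + 1]) && fg[k] * fg[k + 1] <= 0) {
      br <- c(Pg[k], Pg[k + 1]); break
    }
  }
  if (is.null(br)) {
    # refine across the (possibly narrow, near-critical) window,
    # extending one coarse step beyond its edges
    w <- c(Pg[max(min(ok) - 1L, 1L)], Pg[min(max(ok) + 1L, length(Pg))])
    Pg2 <- exp(seq(log(w[1]), log(w[2]), length.out = 400))
    fg2 <- vapply(Pg2, fres, 0)
    ok2 <- which(!is.na(fg2))
    for (k in ok2[-length(ok2)])
      if (!is.na(fg2[k]) && !is.na(fg2[k + 1]) && fg2[k] * fg2[k + 1] <= 0) {
        br <- c(Pg2[k], Pg2[k + 1]); break
      }
    if (is.null(br))
      stop(sprintf("%s at T = %g K: no saturation root in the two-phase window",
                   comp$name, T), call. = FALSE)
  }
  sol <- uniroot(function(lp) fres(exp(lp)), log(br), tol = 1e-14)
  P <- exp(sol$root)
  # polish to the stated fugacity-equality residual
  out <- secant_polish(P)
  if (is.null(out))
    stop(sprintf("%s at T = %g K: saturation polish stalled above the residual target",
                 comp$name, T), call. = FALSE)
  out$iterations <- out$iterations + sol$iter
  out
}

# Saturation pressure, extrapolated outside the model's two-root window
# via ln P linear in 1/T from two anchors found by scanning fractions of
# the nominal critical temperature (the model's own critical point can
# sit well below the tabulated Tc for correlation-derived parameters).
# Initialization quality only; never used as a converged result.
.psat_estimate <- function(comp, T) {
  key <- paste(.comp_hash(comp), signif(T, 12), sep = "@")
  hit <- .psat_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- tryCatch(pure_saturation(comp, T)$P, error = function(e) NULL)
  if (is.null(val)) {
    anchors <- NULL
    for (f in seq(0.90, 0.30, by = -0.05)) {
      Ta <- f * comp$tc
      akey <- paste(.comp_hash(comp), signif(Ta, 12), sep = "@")
      pa <- .psat_cache[[akey]]
      if (is.null(pa)) {
        pa <- tryCatch(pure_saturation(comp, Ta)$P, error = function(e) NA_real_)
        .psat_cache[[akey]] <- pa
      }
      if (!is.na(pa)) anchors <- rbind(anchors, c(Ta, pa))
      if (!is.null(anchors) && nrow(anchors) >= 2) break
    }
    if (is.null(anchors) || nrow(anchors) < 2)
      stop(sprintf("%s: no subcritical anchors found for saturation-pressure extrapolation",
                   comp$name), call. = FALSE)
    T1 <- anchors[1, 1]; p1 <- anchors[1, 2]
    T2 <- anchors[2, 1]; p2 <- anchors[2, 2]
    slope <- (log(p2) - log(p1)) / (1 / T2 - 1 / T1)
    val <- exp(log(p1) + slope * (1 / T - 1 / T1))
  }
  .psat_cache[[key]] <- val
  val
}

.psat_all <- function(mix, T)
  vapply(mix$components, .psat_estimate, 0, T = T)

.equilibrium_result <- function(T, P, x, y, K, beta = NA_real_,
                                residual = NA_real_, iterations = NA_integer_,
                                converged = FALSE, flag = "ok", names = NULL) {
  if (!is.null(names)) { names(x) <- names(y) <- names(K) <- names }
  structure(list(T = T, P = P, x = x, y = y, K_values = K,
                 vapor_fraction = beta, residual = residual,
                 iterations = iterations, converged = converged, flag = flag),
            class = "cpa_equilibrium")
}

#' @export
print.cpa_equilibrium <- function(x, ...) {
  cat(sprintf("<cpa_equilibrium> T = %.2f K, P = %.4g bar (%s, %d iter, residual %.2g)\n",
              x$T, x$P, x$flag, x$iterations, x$residual))
  m <- rbind(x = x$x, y = x$y, K = x$K_values)
  print(signif(m, 6))
  if (!is.na(x$vapor_fraction))
    cat(sprintf("  vapor fraction %.4g mol/mol\n", x$vapor_fraction))
  invisible(x)
}

# fugacity-equality defect max_i |ln(y_i phi_i^V) - ln(x_i phi_i^L)|
.fug_residual <- function(x, y, lpL, lpV) {
  keep <- x > 0 & y > 0
  if (!any(keep)) return(Inf)
  max(abs(log(y[keep]) + lpV[keep] - log(x[keep]) - lpL[keep]))
}

#' Bubble-point pressure at fixed liquid composition
#'
#' phi-phi successive substitution on the K-values with a secant update
#' of pressure driving `sum_i x_i K_i` to one.  Initialization is
#' Raoult-type from pure saturation pressures, extrapolated in `ln P`
#' versus `1/T` for components above their two-root limit (supercritical
#' CO2).  A collapse onto the trivial solution `x = y` is flagged as a
#' near-critical failure rather than returned as converged.
#'
#' @param mix A [cpa_mixture].
#' @param T Temperature, K.
#' @param x Liquid mole fractions.
#' @param P_init,K_init Optional warm starts.
#' @param tol Convergence tolerance on the fugacity-equality residual.
#' @param max_iter Iteration cap.
#' @return A `cpa_equilibrium` result (fields `T`, `P`, `x`, `y`,
#'   `K_values`, `residual`, `iterations`, `converged`, `flag`).
#' @export
bubble_pressure <- function(mix, T, x, P_init = NULL, K_init = NULL,
                            tol = 1e-9, max_iter = 2000) {
  x <- .check_composition(x, mix$nc)
  psat <- .psat_all(mix, T)
  P <- P_init %||% sum(x * psat)
  K <- K_init %||% (psat / P)
  lnP_prev <- NA_real_; lnS_prev <- NA_real_
  flag <- "ok"; converged <- FALSE
  lpL <- lpV <- rep(NA_real_, mix$nc); y <- x
  for (it in seq_len(max_iter)) {
    y <- x * K; S0 <- sum(y); y <- y / S0
    lpL <- .lnphi(mix, T, P, x, 1L)$lnphi
    lpV <- .lnphi(mix, T, P, y, 2L)$lnphi
    if (length(lpL) == 0 || length(lpV) == 0) { flag <- "no_root"; break }
    Knew <- exp(lpL - lpV)
    dK <- max(abs(log(pmax(Knew, 1e-300)) - log(pmax(K, 1e-300))))
    K <- Knew
    S <- sum(x * K)
    lnS <- log(S)
    if (abs(S - 1) < 1e-11 && dK < 1e-10) { converged <- TRUE; break }
    if (it > 10 && max(abs(x - y)) < 1e-5) { flag <- "trivial"; break }
    # successive substitution P <- P*S (damped); secant acceleration only
    # close to the solution, where ln S is a smooth function of ln P
    lnP <- log(P)
    step <- if (abs(lnS) < 0.05 && !is.na(lnS_prev) &&
                abs(lnS - lnS_prev) > 1e-14) {
      max(min(-lnS * (lnP - lnP_prev) / (lnS - lnS_prev), log(2)), -log(2))
    } else max(min(lnS, log(3)), -log(3))
    lnP_prev <- lnP; lnS_prev <- lnS
    P <- exp(lnP + step)
    if (!is.finite(P) || P <= 0) { flag <- "diverged"; break }
  }
  y <- x * K / sum(x * K)
  res <- .fug_residual(x, y, lpL, lpV)
  if (converged && res > tol) converged <- FALSE
  if (flag == "trivial") converged <- FALSE
  .equilibrium_result(T, P, x, y, K, residual = res, iterations = it,
                      converged = converged, flag = flag, names = mix$names)
}

#' Dew-point pressure at fixed vapor composition
#'
#' Mirror image of [bubble_pressure()]: drives `sum_i y_i / K_i` to one.
#'
#' @inheritParams bubble_pressure
#' @param y Vapor mole fractions.
#' @return A `cpa_equilibrium` result.
#' @export
dew_pressure <- function(mix, T, y, P_init = NULL, K_init = NULL,
                         tol = 1e-9, max_iter = 2000) {
  y <- .check_composition(y, mix$nc)
  psat <- .psat_all(mix, T)
  P <- P_init %||% (1 / sum(y / psat))
  K <- K_init %||% (psat / P)
  lnP_prev <- NA_real_; lnS_prev <- NA_real_
  flag <- "ok"; converged <- FALSE
  lpL <- lpV <- rep(NA_real_, mix$nc); x <- y
  for (it in seq_len(max_iter)) {
    x <- ifelse(y > 0, y / K, 0); S0 <- sum(x); x <- x / S0
    lpL <- .lnphi(mix, T, P, x, 1L)$lnphi
    lpV <- .lnphi(mix, T, P, y, 2L)$lnphi
    if (length(lpL) == 0 || length(lpV) == 0) { flag <- "no_root"; break }
    Knew <- exp(lpL - lpV)
    dK <- max(abs(log(pmax(Knew, 1e-300)) - log(pmax(K, 1e-300))))
    K <- Knew
    S <- sum(ifelse(y > 0, y / K, 0))
    lnS <- log(S)
    if (abs(S - 1) < 1e-11 && dK < 1e-10) { converged <- TRUE; break }
    if (it > 10 && max(abs(x - y)) < 1e-5) { flag <- "trivial"; break }
    lnP <- log(P)
    step <- if (abs(lnS) < 0.05 && !is.na(lnS_prev) &&
                abs(lnS - lnS_prev) > 1e-14) {
      max(min(-lnS * (lnP - lnP_prev) / (lnS - lnS_prev), log(2)), -log(2))
    } else max(min(-lnS, log(3)), -log(3))
    lnP_prev <- lnP; lnS_prev <- lnS
    P <- exp(lnP + step)
    if (!is.finite(P) || P <= 0) { flag <- "diverged"; break }
  }
  x <- ifelse(y > 0, y / K, 0); x <- x / sum(x)
  res <- .fug_residual(x, y, lpL, lpV)
  if (converged && res > tol) converged <- FALSE
  if (flag == "trivial") converged <- FALSE
  .equilibrium_result(T, P, x, y, K, residual = res, iterations = it,
                      converged = converged, flag = flag, names = mix$names)
}

#' Isothermal two-phase flash at fixed overall composition
#'
#' Rachford-Rice inner solve for the vapor fraction with phi-phi
#' successive substitution on the K-values.  Overall compositions whose
#' Rachford-Rice function has no root in (0, 1) are reported as single
#' phase with vapor fraction 0 or 1.
#'
#' @inheritParams bubble_pressure
#' @param P Pressure, bar.
#' @param z Overall mole fractions.
#' @return A `cpa_equilibrium` result including `vapor_fraction`.
#' @export
pt_flash <- function(mix, T, P, z, K_init = NULL, tol = 1e-9, max_iter = 2000) {
  z <- .check_composition(z, mix$nc)
  psat <- .psat_all(mix, T)
  K <- K_init %||% (psat / P)
  rr <- function(beta, K) sum(z * (K - 1) / (1 + beta * (K - 1)))
  beta <- NA_real_; x <- z; y <- z
  lpL <- lpV <- rep(NA_real_, mix$nc)
  flag <- "ok"; converged <- FALSE; single <- 0L
  for (it in seq_len(max_iter)) {
    g0 <- rr(0, K); g1 <- rr(1, K)
    if (g0 <= 0) {            # all liquid at this K
      beta <- 0; x <- z; y <- z * K / sum(z * K); single <- single + 1L
    } else if (g1 >= 0) {     # all vapor
      beta <- 1; y <- z; x <- (z / K) / sum(z / K); single <- single + 1L
    } else {
      beta <- uniroot(rr, c(0, 1), K = K, tol = 1e-14)$root
      x <- z / (1 + beta * (K - 1)); x <- x / sum(x)
      y <- K * x; y <- y / sum(y)
      single <- 0L
    }
    lpL <- .lnphi(mix, T, P, x, 1L)$lnphi
    lpV <- .lnphi(mix, T, P, y, 2L)$lnphi
    Knew <- exp(lpL - lpV)
    dK <- max(abs(log(pmax(Knew, 1e-300)) - log(pmax(K, 1e-300))))
    K <- Knew
    if (dK < 1e-11) { converged <- TRUE; break }
    if (single >= 25L) { converged <- TRUE; flag <- "single_phase"; break }
  }
  if (beta %in% c(0, 1)) {
    flag <- "single_phase"
    res <- 0
  } else {
    res <- .fug_residual(x, y, lpL, lpV)
    if (converged && res > tol) converged <- FALSE
  }
  .equilibrium_result(T, P, x, y, K, beta = beta, residual = res,
                      iterations = it, converged = converged, flag = flag,
                      names = mix$names)
}

#' Trace a binary isotherm over a liquid-composition or pressure grid
#'
#' With `x1`, sweeps [bubble_pressure()] over liquid mole fractions of
#' the first component; with `P`, sweeps the two-phase coexistence
#' solver over pressures.  Each point is warm-started from its
#' neighbour; failures are flagged per point and do not abort the
#' sweep.
#'
#' @param mix A two-component [cpa_mixture].
#' @param T Temperature, K.
#' @param x1 Grid of liquid mole fractions of component 1.
#' @param P Alternatively, a grid of pressures, bar.
#' @return data.frame with columns `T`, `P`, `x1`, `x2`, `y1`, `y2`,
#'   `residual`, `iterations`, `converged`.
#' @export
trace_isotherm <- function(mix, T, x1 = NULL, P = NULL) {
  stopifnot(mix$nc == 2L)
  if (is.null(x1) == is.null(P))
    stop("supply exactly one of x1 (composition grid) or P (pressure grid)")
  out <- data.frame(T = numeric(0), P = numeric(0), x1 = numeric(0),
                    x2 = numeric(0), y1 = numeric(0), y2 = numeric(0),
                    residual = numeric(0), iterations = integer(0),
                    converged = logical(0))
  if (!is.null(P)) {
    st <- NULL; x1w <- 0.05
    for (Pv in P) {
      r <- tryCatch(.binary_xy_at_TP(mix, T, Pv, x1_init = x1w, state = st),
                    error = function(e) NULL)
      if (!is.null(r) && r$eq$converged) {
        eq <- r$eq
        out[nrow(out) + 1L, ] <- list(T, Pv, eq$x[1], eq$x[2], eq$y[1],
                                      eq$y[2], eq$residual, eq$iterations, TRUE)
        st <- r$state; x1w <- eq$x[1]
      } else {
        out[nrow(out) + 1L, ] <- list(T, Pv, NA_real_, NA_real_, NA_real_,
                                      NA_real_, NA_real_, NA_integer_, FALSE)
        st <- NULL
      }
    }
    return(out)
  }
  if (length(x1) == 0) return(out)
  P_init <- NULL; K_init <- NULL
  for (xv in x1) {
    eq <- tryCatch(bubble_pressure(mix, T, c(xv, 1 - xv),
                                   P_init = P_init, K_init = K_init),
                   error = function(e) NULL)
    if (is.null(eq)) {
      out[nrow(out) + 1L, ] <- list(T, NA_real_, xv, 1 - xv, NA_real_,
                                    NA_real_, NA_real_, NA_integer_, FALSE)
      P_init <- NULL; K_init <- NULL
    } else {
      out[nrow(out) + 1L, ] <- list(T, eq$P, xv, 1 - xv, eq$y[1], eq$y[2],
                                    eq$residual, eq$iterations, eq$converged)
      if (eq$converged) { P_init <- eq$P; K_init <- eq$K_values }
    }
  }
  out
}

# Coexistence of a binary at fixed (T, P) by direct phi-phi successive
# substitution: for a binary the two-phase compositions follow exactly
# from the K-values, x1 = (1 - K2)/(K1 - K2), y_i = K_i x_i.
.binary_xy_direct <- function(mix, T, P, K_init = NULL, tol = 1e-9,
                              max_iter = 400) {
  psat <- .psat_all(mix, T)
  K <- K_init %||% (psat / P)
  lpL <- lpV <- c(NA_real_, NA_real_); x <- y <- c(NA_real_, NA_real_)
  converged <- FALSE; flag <- "ok"
  for (it in seq_len(max_iter)) {
    dK12 <- K[1] - K[2]
    if (!is.finite(dK12) || abs(dK12) < 1e-10) { flag <- "degenerate_K"; break }
    x1 <- (1 - K[2]) / dK12
    if (!is.finite(x1) || x1 <= 0 || x1 >= 1) { flag <- "single_phase"; break }
    x <- c(x1, 1 - x1); y <- K * x
    lpL <- .lnphi(mix, T, P, x, 1L)$lnphi
    lpV <- .lnphi(mix, T, P, y / sum(y), 2L)$lnphi
    if (length(lpL) == 0 || length(lpV) == 0) { flag <- "no_root"; break }
    Knew <- exp(lpL - lpV)
    dK <- max(abs(log(pmax(Knew, 1e-300)) - log(pmax(K, 1e-300))))
    K <- Knew
    if (dK < 1e-11) { converged <- TRUE; break }
    if (it > 10 && abs(K[1] - 1) < 1e-5 && abs(K[2] - 1) < 1e-5) {
      flag <- "trivial"; break
    }
  }
  res <- if (converged) .fug_residual(x, y / sum(y), lpL, lpV) else Inf
  if (converged && res > tol) converged <- FALSE
  .equilibrium_result(T, P, x, y / sum(y), K, residual = res, iterations = it,
                      converged = converged, flag = flag, names = mix$names)
}

# Coexistence compositions of a binary at fixed (T, P).  The direct
# successive substitution above is attempted first (warm-started);
# failures fall back to a bracket-safeguarded secant on bubbleP(x1) = P.
.binary_xy_at_TP <- function(mix, T, P, x1_init = 0.5, state = NULL) {
  stopifnot(mix$nc == 2L)
  dir <- tryCatch(
    .binary_xy_direct(mix, T, P, K_init = if (!is.null(state)) state$K else NULL),
    error = function(e) NULL)
  if (!is.null(dir) && dir$converged)
    return(list(eq = dir, state = list(K = dir$K_values, P = P)))
  Kw <- if (!is.null(state)) state$K else NULL
  Pw <- if (!is.null(state)) state$P else NULL
  feval <- function(x1) {
    eq <- bubble_pressure(mix, T, c(x1, 1 - x1), P_init = Pw, K_init = Kw)
    if (eq$converged) {
      Kw <<- eq$K_values; Pw <<- eq$P
      list(f = eq$P - P, eq = eq)
    } else {
      # beyond the solubility limit (or collapsed): treat as too high
      Pw <<- NULL; Kw <<- NULL
      list(f = 1e6 * P, eq = eq)
    }
  }
  a <- NA_real_; fa <- NA_real_; b <- NA_real_; fb <- NA_real_ # bracket
  x1 <- min(max(x1_init, 1e-6), 1 - 1e-6)
  r1 <- feval(x1); f1 <- r1$f
  x2 <- min(max(x1 * (if (f1 > 0) 0.9 else 1.1), 1e-6), 1 - 1e-6)
  r2 <- feval(x2); f2 <- r2$f
  upd <- function(xx, ff) {
    if (ff > 0) { if (is.na(b) || xx < b) { b <<- xx; fb <<- ff } }
    else { if (is.na(a) || xx > a) { a <<- xx; fa <<- ff } }
  }
  upd(x1, f1); upd(x2, f2)
  best <- if (r2$eq$converged && (!r1$eq$converged || abs(f2) < abs(f1))) r2 else r1
  for (it in 1:80) {
    if (!best$eq$converged && it > 1 && is.na(a) && is.na(b)) break
    if (abs(best$f) <= 1e-8 * P) break
    xn <- if (abs(f2 - f1) > 1e-300) x2 - f2 * (x2 - x1) / (f2 - f1) else NA_real_
    if (is.na(xn) || xn <= 0 || xn >= 1 ||
        (!is.na(a) && !is.na(b) && (xn <= min(a, b) || xn >= max(a, b))))
      xn <- if (!is.na(a) && !is.na(b)) (a + b) / 2 else
        min(max(x2 * (if (f2 > 0) 0.7 else 1.3), 1e-7), 1 - 1e-7)
    rn <- feval(xn)
    upd(xn, rn$f)
    x1 <- x2; f1 <- f2; x2 <- xn; f2 <- rn$f
    if (rn$eq$converged && (!best$eq$converged || abs(rn$f) < abs(best$f)))
      best <- rn
    if (!is.na(a) && !is.na(b) && abs(b - a) < 1e-13) break
  }
  list(eq = best$eq, state = list(K = Kw, P = Pw))
}

#' Locate the vapor-phase minimum of the heavy component along an isotherm
#'
#' For a binary whose heavy component's vapor mole fraction passes
#' through a minimum when plotted against pressure, sweeps the
#' coexistence curve over a pressure grid and refines the interior
#' minimizer by golden-section search.  If the sweep is monotone the
#' boundary point is returned and flagged.
#'
#' @param mix A two-component [cpa_mixture]; component 2 is taken as the
#'   heavy (low-volatility) compound.
#' @param T Temperature, K.
#' @param P_range Pressure interval to search, bar.
#' @param n_scan Number of sweep points.
#' @return List with `P_min` (bar), `y_heavy_min`, `interior` (logical)
#'   and the sweep data.frame `scan` (columns `P`, `x1`, `y_heavy`).
#' @export
vapor_composition_minimum <- function(mix, T, P_range, n_scan = 40) {
  stopifnot(mix$nc == 2L, length(P_range) == 2L, P_range[1] < P_range[2])
  Pg <- seq(P_range[1], P_range[2], length.out = n_scan)
  yh <- rep(NA_real_, n_scan); x1s <- rep(NA_real_, n_scan)
  st <- NULL; x1_prev <- 0.05
  for (k in seq_along(Pg)) {
    r <- tryCatch(.binary_xy_at_TP(mix, T, Pg[k], x1_init = x1_prev, state = st),
                  error = function(e) NULL)
    if (!is.null(r) && r$eq$converged) {
      yh[k] <- r$eq$y[2]; x1s[k] <- r$eq$x[1]
      st <- r$state; x1_prev <- r$eq$x[1]
    }
  }
  scan <- data.frame(P = Pg, x1 = x1s, y_heavy = yh)
  okk <- which(!is.na(yh))
  if (length(okk) < 3) stop("two-phase region not found across the pressure range")
  k <- okk[which.min(yh[okk])]
  if (k == okk[1] || k == okk[length(okk)])
    return(list(P_min = Pg[k], y_heavy_min = unname(yh[k]),
                interior = FALSE, scan = scan))
  # golden-section refinement on the bracket around the discrete minimum
  yfun <- function(P) {
    r <- .binary_xy_at_TP(mix, T, P, x1_init = x1_prev, state = st)
    r$eq$y[2]
  }
  lo <- Pg[max(k - 1, 1)]; hi <- Pg[min(k + 1, n_scan)]
  gr <- (sqrt(5) - 1) / 2
  c1 <- hi - gr * (hi - lo); c2 <- lo + gr * (hi - lo)
  f1 <- yfun(c1); f2 <- yfun(c2)
  while (hi - lo > 1e-4 * (P_range[2] - P_range[1])) {
    if (f1 < f2) { hi <- c2; c2 <- c1; f2 <- f1
      c1 <- hi - gr * (hi - lo); f1 <- yfun(c1)
    } else { lo <- c1; c1 <- c2; f1 <- f2
      c2 <- lo + gr * (hi - lo); f2 <- yfun(c2) }
  }
  Pm <- (lo + hi) / 2
  list(P_min = Pm, y_heavy_min = unname(yfun(Pm)), interior = TRUE, scan = scan)
}
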