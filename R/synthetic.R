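# Synthetic pseudo-experimental datasets.
#
# The literature VLE measurements behind the bundled binary parameters
# are not redistributable, so the package generates model-consistent
# pseudo-data with the same structure: isothermal binary T-P-x-y records
# (with liquid-only and vapor-only variants mimicking triglyceride data
# availability), fixed-composition multicomponent bubble curves, and
# pure-fluid saturation tables.  Zero-noise datasets are exactly
# model-consistent, which underpins every parameter-recovery test.

#' Noise specification for synthetic datasets
#'
#' Multiplicative (relative) noise, reflecting the relative-deviation
#' metrics used throughout: a noisy value is `value * exp(sigma * z)`,
#' `z ~ N(0,1)`.  `scatter_mode = "heavy_tailed"` replaces the vapor
#' noise scale by `sigma_log_y` (log-normal scatter up to an order of
#' magnitude and beyond), emulating heavy-compound vapor-fraction data
#' whose sources disagree by factors of 10-100.
#'
#' @param sigma_P Relative standard deviation on pressure.
#' @param sigma_y Relative standard deviation on the heavy-compound
#'   vapor fraction (normal mode).
#' @param scatter_mode `"normal"` or `"heavy_tailed"`.
#' @param sigma_log_y Log-scale sigma for heavy-tailed vapor scatter.
#' @param seed Integer seed; generation is reproducible for a fixed seed.
#' @return Object of class `cpa_noise`.
#' @export
noise_spec <- function(sigma_P = 0.01, sigma_y = 0.10,
                       scatter_mode = c("normal", "heavy_tailed"),
                       sigma_log_y = log(10) / 2, seed = 1L) {
  scatter_mode <- match.arg(scatter_mode)
  stopifnot(sigma_P >= 0, sigma_y >= 0, sigma_log_y >= 0)
  structure(list(sigma_P = sigma_P, sigma_y = sigma_y,
                 scatter_mode = scatter_mode, sigma_log_y = sigma_log_y,
                 seed = as.integer(seed)),
            class = "cpa_noise")
}

.mult_noise <- function(v, sigma) {
  if (sigma == 0) return(v)
  v * exp(rnorm(length(v), 0, sigma))
}

#' Generate a synthetic pure-fluid saturation dataset
#'
#' Evenly spaced temperatures across `T_range`; saturation pressures and
#' liquid molar volumes from the model with multiplicative log-normal
#' noise of relative scale `noise$sigma_P` on both.
#'
#' @param comp A [cpa_component] or registry name.
#' @param T_range Temperature interval, K (two-phase for the model).
#' @param n Number of records.
#' @param noise A [noise_spec()].
#' @return data.frame with columns `T`, `Psat` (bar), `Vliq` (L/mol).
#' @export
gen_pure_saturation <- function(comp, T_range, n, noise = noise_spec()) {
  if (!inherits(comp, "cpa_component")) comp <- get_component(comp)
  stopifnot(length(T_range) == 2L, T_range[1] < T_range[2], n >= 2)
  Tg <- seq(T_range[1], T_range[2], length.out = n)
  P <- V <- rep(NA_real_, n); Pw <- NULL
  for (k in seq_len(n)) {
    ps <- tryCatch(pure_saturation(comp, Tg[k], P_init = Pw),
                   error = function(e) NULL)
    if (is.null(ps))
      stop(sprintf("no saturation solution for %s at %g K: temperature range extends beyond the model's two-phase region",
                   comp$name, Tg[k]))
    P[k] <- ps$P; V[k] <- ps$Vliq; Pw <- ps$P
  }
  set.seed(noise$seed)
  out <- data.frame(T = Tg, Psat = .mult_noise(P, noise$sigma_P),
                    Vliq = .mult_noise(V, noise$sigma_P))
  attr(out, "component") <- comp$name
  attr(out, "noise") <- noise
  out
}

#' Generate a synthetic binary VLE dataset
#'
#' Traces bubble-point isotherms over a liquid-composition grid at each
#' temperature, then applies multiplicative noise to pressure and to the
#' heavy-compound vapor fraction.  `mode` mimics the data-availability
#' patterns of the literature sources: `"liquid_only"` drops the vapor
#' compositions, `"vapor_only"` the liquid ones.
#'
#' @param mix A two-component [cpa_mixture] (component 1 = light).
#' @param T_list Temperatures, K.
#' @param x1_grid Liquid mole fractions of component 1 to trace.
#' @param noise A [noise_spec()].
#' @param mode `"full"`, `"liquid_only"` or `"vapor_only"`.
#' @return A `vle_dataset`: data.frame with columns `T`, `P`, `x1`,
#'   `x2`, `y1`, `y2`, `weight` (`NA` for unmeasured phases) and
#'   attributes `components` and `noise`.
#' @export
gen_binary_vle <- function(mix, T_list, x1_grid, noise = noise_spec(),
                           mode = c("full", "liquid_only", "vapor_only")) {
  mode <- match.arg(mode)
  stopifnot(mix$nc == 2L)
  rows <- list()
  for (Tv in T_list) {
    iso <- trace_isotherm(mix, Tv, x1_grid)
    bad <- !iso$converged
    if (any(bad))
      message(sprintf("dropped %d non-converged point(s) at T = %g K",
                      sum(bad), Tv))
    rows[[length(rows) + 1L]] <- iso[!bad, ]
  }
  iso <- do.call(rbind, rows)
  if (nrow(iso) == 0) stop("no converged isotherm points to build a dataset from")
  set.seed(noise$seed)
  P <- .mult_noise(iso$P, noise$sigma_P)
  sig_y <- if (noise$scatter_mode == "heavy_tailed") noise$sigma_log_y else noise$sigma_y
  y2 <- pmin(.mult_noise(iso$y2, sig_y), 0.999999)
  out <- data.frame(T = iso$T, P = P, x1 = iso$x1, x2 = iso$x2,
                    y1 = 1 - y2, y2 = y2, weight = 1)
  if (mode == "liquid_only") out$y1 <- out$y2 <- NA_real_
  if (mode == "vapor_only") out$x1 <- out$x2 <- NA_real_
  structure(out, components = mix$names, noise = noise, mode = mode,
            class = c("vle_dataset", "data.frame"))
}

#' Generate synthetic multicomponent bubble-point curves
#'
#' Bubble pressures along a temperature grid at each fixed global
#' (liquid) composition, with multiplicative pressure noise.
#'
#' @param mix A [cpa_mixture].
#' @param compositions Matrix or data.frame, one row per mixture, columns
#'   matching the mixture components.
#' @param T_grid Temperatures, K.
#' @param noise A [noise_spec()].
#' @return data.frame with columns `mixture`, `T`, `P`, `converged`,
#'   `y_<component>` vapor fractions.
#' @export
gen_multicomponent_bubble <- function(mix, compositions, T_grid,
                                      noise = noise_spec()) {
  compositions <- as.matrix(compositions)
  stopifnot(ncol(compositions) == mix$nc)
  rows <- list()
  for (m in seq_len(nrow(compositions))) {
    x <- as.numeric(compositions[m, ])
    Pw <- NULL; Kw <- NULL
    for (Tv in T_grid) {
      eq <- tryCatch(bubble_pressure(mix, Tv, x, P_init = Pw, K_init = Kw),
                     error = function(e) NULL)
      if (is.null(eq) || !eq$converged) {
        rows[[length(rows) + 1L]] <- c(mixture = m, T = Tv, P = NA_real_,
                                       converged = 0, setNames(rep(NA_real_, mix$nc),
                                                               paste0("y_", mix$names)))
        Pw <- NULL; Kw <- NULL
      } else {
        rows[[length(rows) + 1L]] <- c(mixture = m, T = Tv, P = eq$P,
                                       converged = 1,
                                       setNames(eq$y, paste0("y_", mix$names)))
        Pw <- eq$P; Kw <- eq$K_values
      }
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  out$converged <- out$converged == 1
  set.seed(noise$seed)
  out$P <- .mult_noise(out$P, noise$sigma_P)
  attr(out, "components") <- mix$names
  attr(out, "noise") <- noise
  out
}

# Synthetic default ester profile (mole fractions): a typical soy-type
# distribution; NOT a measured composition -- replace with the analysis
# of the actual biodiesel sample when available.
.default_ester_profile <- c("C16:0" = 0.11, "C18:0" = 0.04,
                            "C18:1" = 0.23, "C18:2" = 0.54, "C18:3" = 0.08)

.ester_names <- c("C16:0" = "methyl_palmitate", "C18:0" = "methyl_stearate",
                  "C18:1" = "methyl_oleate", "C18:2" = "methyl_linoleate",
                  "C18:3" = "methyl_linolenate")

#' Build a CO2 + biodiesel mixture from an ester profile
#'
#' Biodiesel is represented as a five-ester mixture (C16:0, C18:0,
#' C18:1, C18:2, C18:3 methyl esters).  CO2-ester interaction parameters
#' come from the registry; ester-ester pairs carry explicit zero `kij`;
#' esters carry no association sites in this mixture (CO2 is inert
#' toward them).
#'
#' @param ester_fractions Named mole fractions over
#'   `c("C16:0","C18:0","C18:1","C18:2","C18:3")`, summing to 1.  The
#'   default is a synthetic soy-type profile bundled for testing, not a
#'   measured sample composition.
#' @return A six-component [cpa_mixture] (CO2 first) with the ester
#'   profile attached as attribute `ester_fractions`.
#' @export
#' @examples
#' mix <- make_biodiesel_mixture()
#' biodiesel_overall(mix, x_co2 = 0.8)
make_biodiesel_mixture <- function(ester_fractions = .default_ester_profile) {
  if (is.null(names(ester_fractions)) ||
      !setequal(names(ester_fractions), names(.ester_names)))
    stop("ester_fractions must be named over ",
         paste(names(.ester_names), collapse = ", "))
  ester_fractions <- ester_fractions[names(.ester_names)]
  if (any(ester_fractions < 0) || abs(sum(ester_fractions) - 1) > 1e-8)
    stop("ester fractions must be nonnegative and sum to 1")
  mix <- cpa_mixture(c("CO2", unname(.ester_names)))
  attr(mix, "ester_fractions") <- ester_fractions
  mix
}

#' Overall composition of a CO2 + biodiesel feed
#'
#' @param mix Mixture from [make_biodiesel_mixture()].
#' @param x_co2 Overall CO2 mole fraction.
#' @return Mole-fraction vector over the six components.
#' @export
biodiesel_overall <- function(mix, x_co2) {
  fr <- attr(mix, "ester_fractions")
  if (is.null(fr)) stop("mixture does not carry an ester profile")
  stopifnot(x_co2 >= 0, x_co2 <= 1)
  setNames(c(x_co2, (1 - x_co2) * as.numeric(fr)), mix$names)
}

.ternary_fixtures <- list(
  co2_glycerol_methanol = list(
    components = c("CO2", "glycerol", "methanol"),
    compositions = rbind(c(0.3373, 0.0212, 0.6415),
                         c(0.4352, 0.0180, 0.5468),
                         c(0.5359, 0.0148, 0.4493),
                         c(0.6430, 0.0114, 0.3456))),
  co2_glycerol_ethanol = list(
    components = c("CO2", "glycerol", "ethanol"),
    compositions = rbind(c(0.1333, 0.0413, 0.8254),
                         c(0.2808, 0.0342, 0.6850),
                         c(0.4276, 0.0273, 0.5451),
                         c(0.4985, 0.0239, 0.4776))),
  co2_methanol_lauric_acid = list(
    components = c("CO2", "methanol", "lauric_acid"),
    compositions = rbind(c(0.6675, 0.2217, 0.1108),
                         c(0.7492, 0.1672, 0.0836),
                         c(0.8248, 0.1168, 0.0584)))
)

#' Bundled ternary global compositions
#'
#' The fixed global compositions at which the bundled ternary
#' bubble-point predictions are evaluated (one row per mixture), with
#' the corresponding mixture assembled purely from binary registry
#' parameters -- the solvers accept no ternary adjustments.
#'
#' @param system One of `"co2_glycerol_methanol"`,
#'   `"co2_glycerol_ethanol"`, `"co2_methanol_lauric_acid"`.
#' @return List with `mixture` (a [cpa_mixture]) and `compositions`
#'   (matrix, columns named by component).
#' @export
ternary_fixture <- function(system = names(.ternary_fixtures)) {
  system <- match.arg(system)
  fx <- .ternary_fixtures[[system]]
  comps <- fx$compositions
  colnames(comps) <- fx$components
  list(mixture = cpa_mixture(fx$components), compositions = comps)
}
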