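# Bundled pure-fluid and binary parameter registry.
#
# Parameters are stored in inst/extdata/cpa_parameters.json in fixed units
# (a0: L^2.bar/mol^2, b: L/mol, eps: bar.L/mol, T: K) and loaded once per
# session.  Users can point CPAEOS_REGISTRY at their own JSON file with the
# same schema to add components.

.registry_env <- new.env(parent = emptyenv())

.registry_path <- function() {
  p <- Sys.getenv("CPAEOS_REGISTRY", "")
  if (nzchar(p)) return(p)
  system.file("extdata", "cpa_parameters.json", package = "cpaeos")
}

.registry <- function() {
  if (is.null(.registry_env$reg)) {
    reg <- jsonlite::fromJSON(.registry_path(), simplifyVector = FALSE)
    .registry_env$reg <- reg
  }
  .registry_env$reg
}

# Case-insensitive canonical identifier: spaces and hyphens collapse to
# underscores, then the synonym table applies.
.canonical_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  reg <- .registry()
  key <- gsub("[ -]+", "_", trimws(name))
  comp_names <- vapply(reg$components, `[[`, "", "name")
  hit <- comp_names[tolower(comp_names) == tolower(key)]
  if (length(hit) == 1L) return(hit)
  syn <- reg$synonyms[[tolower(key)]]
  if (!is.null(syn)) return(syn)
  stop(sprintf("component '%s' is not in the cpaeos parameter registry (see list_components())",
               name), call. = FALSE)
}

#' Construct a pure-component CPA parameter set
#'
#' The five CPA parameters plus the critical temperature and the
#' association scheme for one fluid.  Schemes: `"none"` (inert),
#' `"1A"` (one bipolar site, organic acids), `"2B"` (one donor + one
#' acceptor, alcohols), `"4C"` (two + two, glycols), `"3x2B"` (three +
#' three, glycerol), `"solvation"` (one positive cross-association-only
#' site, e.g. CO2 toward hydrogen-bonding partners).
#'
#' @param name Identifier.
#' @param mw Molar mass, g/mol.
#' @param tc Critical temperature, K.
#' @param a0 Attractive-energy parameter, L^2·bar/mol^2.
#' @param b Co-volume, L/mol.
#' @param c1 Soave slope, dimensionless.
#' @param eps_assoc Association energy, bar·L/mol.
#' @param beta_assoc Association volume, dimensionless.
#' @param scheme Association scheme identifier.
#' @return Object of class `cpa_component`.
#' @export
cpa_component <- function(name, mw, tc, a0, b, c1,
                          eps_assoc = 0, beta_assoc = 0, scheme = "none") {
  scheme <- match.arg(scheme, c("none", "1A", "2B", "4C", "3x2B", "solvation"))
  stopifnot(b > 0, a0 >= 0, tc > 0, mw > 0,
            eps_assoc >= 0, beta_assoc >= 0)
  if (scheme %in% c("none", "solvation") && (eps_assoc != 0 || beta_assoc != 0))
    stop("scheme '", scheme, "' requires eps_assoc = beta_assoc = 0")
  if (!scheme %in% c("none", "solvation") && beta_assoc <= 0)
    stop("self-associating scheme '", scheme, "' requires beta_assoc > 0")
  structure(list(name = name, mw = mw, tc = tc, a0 = a0, b = b, c1 = c1,
                 eps_assoc = eps_assoc, beta_assoc = beta_assoc,
                 scheme = scheme),
            class = "cpa_component")
}

#' @export
print.cpa_component <- function(x, ...) {
  cat(sprintf("<cpa_component> %s (scheme %s)\n", x$name, x$scheme))
  cat(sprintf("  mw %.2f g/mol, Tc %.1f K\n", x$mw, x$tc))
  cat(sprintf("  a0 %.4g L^2.bar/mol^2, b %.4g L/mol, c1 %.4g\n",
              x$a0, x$b, x$c1))
  if (x$eps_assoc > 0)
    cat(sprintf("  eps %.4g bar.L/mol, beta %.4g\n", x$eps_assoc, x$beta_assoc))
  invisible(x)
}

#' Look up a pure component in the bundled registry
#'
#' Returns the tabulated parameter set verbatim (no unit conversion).
#' Identifiers are case-insensitive; spaces and hyphens are equivalent to
#' underscores, and a small synonym list is honoured.
#'
#' @param name Component identifier, e.g. `"CO2"`, `"glycerol"`, `"PEG200"`.
#' @return A [cpa_component] object.  Polyethylene-glycol entries carry the
#'   linear-correlation `a0` as the working value and the quadratic one in
#'   the `a0_poly` attribute.
#' @details Setting the environment variable `CPAEOS_REGISTRY` to a JSON
#'   file with the same schema as `inst/extdata/cpa_parameters.json`
#'   (fields `components`, `binaries`, `synonyms`; units fixed as
#'   documented there) replaces the bundled registry, letting users add
#'   components and pairs.
#' @export
#' @examples
#' get_component("CO2")
#' get_component("tetraethylene glycol")
get_component <- function(name) {
  reg <- .registry()
  cname <- .canonical_name(name)
  rec <- NULL
  for (r in reg$components) if (r$name == cname) { rec <- r; break }
  out <- cpa_component(rec$name, rec$mw, rec$tc, rec$a0, rec$b, rec$c1,
                       rec$eps_assoc, rec$beta_assoc, rec$scheme)
  if (!is.null(rec$a0_poly)) attr(out, "a0_poly") <- rec$a0_poly
  out
}

#' List the components available in the registry
#' @return Character vector of canonical component names.
#' @export
list_components <- function() {
  vapply(.registry()$components, `[[`, "", "name")
}

#' Construct a binary-interaction parameter set
#'
#' One temperature-independent `kij` plus the cross-association rule for a
#' component pair.  Cross rules: `"none"` (no cross association), `"CR1"`
#' (arithmetic-mean energy, geometric-mean volume; both members must
#' self-associate), `"mCR1"` (arithmetic-mean energy with a
#' non-self-associating partner contributing zero; adjustable volume),
#' `"explicit"` (both cross parameters given).
#'
#' @param i,j Component identifiers.
#' @param kij Binary interaction parameter, dimensionless.
#' @param cross_rule One of `"none"`, `"CR1"`, `"mCR1"`, `"explicit"`.
#' @param eps_cross Cross-association energy, bar·L/mol (`"explicit"` only).
#' @param beta_cross Cross-association volume (`"mCR1"`, `"explicit"`).
#' @param variant Optional label distinguishing alternative parameterizations
#'   of the same pair.
#' @return Object of class `cpa_binary`.
#' @export
cpa_binary <- function(i, j, kij = 0, cross_rule = "none",
                       eps_cross = NULL, beta_cross = NULL, variant = NULL) {
  cross_rule <- match.arg(cross_rule, c("none", "CR1", "mCR1", "explicit"))
  if (cross_rule == "mCR1" && is.null(beta_cross))
    stop("mCR1 requires beta_cross")
  if (cross_rule == "explicit" && (is.null(eps_cross) || is.null(beta_cross)))
    stop("explicit cross rule requires eps_cross and beta_cross")
  structure(list(i = i, j = j, kij = kij, cross_rule = cross_rule,
                 eps_cross = eps_cross, beta_cross = beta_cross,
                 variant = variant),
            class = "cpa_binary")
}

#' @export
print.cpa_binary <- function(x, ...) {
  cat(sprintf("<cpa_binary> %s / %s%s: kij = %.4g, cross rule %s\n",
              x$i, x$j,
              if (is.null(x$variant)) "" else sprintf(" [%s]", x$variant),
              x$kij, x$cross_rule))
  if (!is.null(x$eps_cross)) cat(sprintf("  eps_cross  %.4g bar.L/mol\n", x$eps_cross))
  if (!is.null(x$beta_cross)) cat(sprintf("  beta_cross %.4g\n", x$beta_cross))
  invisible(x)
}

#' Look up a binary parameter set in the bundled registry
#'
#' Pair lookup is order-insensitive.  Pairs with several published
#' parameterizations (CO2-glycerol: `"inert"` and `"one-site"`) return
#' their default variant unless `variant` selects one; the available
#' variant names are attached as the `"variants"` attribute.
#'
#' @param i,j Component identifiers.
#' @param variant Optional variant name.
#' @return A [cpa_binary] object.
#' @export
#' @examples
#' get_binary("CO2", "PEG300")
#' get_binary("CO2", "glycerol", variant = "inert")
get_binary <- function(i, j, variant = NULL) {
  ci <- .canonical_name(i); cj <- .canonical_name(j)
  hits <- Filter(function(r) (r$i == ci && r$j == cj) || (r$i == cj && r$j == ci),
                 .registry()$binaries)
  if (length(hits) == 0L)
    stop(sprintf("no binary parameters for pair %s / %s in the cpaeos registry",
                 ci, cj), call. = FALSE)
  variants <- vapply(hits, function(r) r$variant %||% "", "")
  pick <- if (!is.null(variant)) {
    w <- which(variants == variant)
    if (length(w) != 1L)
      stop(sprintf("pair %s / %s has no variant '%s' (available: %s)",
                   ci, cj, variant, paste(variants, collapse = ", ")),
           call. = FALSE)
    hits[[w]]
  } else if (length(hits) == 1L) hits[[1L]] else {
    defs <- vapply(hits, function(r) isTRUE(r$default), NA)
    hits[[which(defs)[1L]]]
  }
  out <- cpa_binary(pick$i, pick$j, pick$kij, pick$cross_rule,
                    pick$eps_cross, pick$beta_cross, pick$variant)
  if (length(hits) > 1L) attr(out, "variants") <- variants
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
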