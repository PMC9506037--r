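# Mixture assembly: components + binary interactions -> site catalog and
# resolved cross-association tables.
#
# Site bookkeeping follows the association-scheme conventions:
#   1A    one bipolar site        (organic acids; pairs with itself)
#   2B    one positive + one negative site (alcohols)
#   4C    two positive + two negative     (water, glycols)
#   3x2B  three positive + three negative (glycerol)
# A component with no self-association sites acquires one positive
# solvation site when (and only when) a binary interaction declaring
# mCR1 or explicit cross parameters involves it; in all other mixtures
# it is inert.

.scheme_sites <- function(scheme) {
  switch(scheme,
         "none"      = NULL,
         "solvation" = data.frame(polarity = "pos", mult = 1),
         "1A"   = data.frame(polarity = "bi",  mult = 1),
         "2B"   = data.frame(polarity = c("pos", "neg"), mult = c(1, 1)),
         "4C"   = data.frame(polarity = c("pos", "neg"), mult = c(2, 2)),
         "3x2B" = data.frame(polarity = c("pos", "neg"), mult = c(3, 3)),
         stop("unknown association scheme: ", scheme))
}

.polarity_compatible <- function(p1, p2) {
  p1 == "bi" | p2 == "bi" | (p1 == "pos" & p2 == "neg") | (p1 == "neg" & p2 == "pos")
}

#' Assemble a mixture specification
#'
#' Builds the full CPA mixture description: ordered components, the
#' symmetric `kij` matrix, the association-site catalog (with solvation
#' sites activated on inert components that a binary declares as
#' cross-associating) and the resolved site-pair energy/volume tables.
#'
#' Binary parameters are taken from the bundled registry for every pair
#' unless an entry in `binaries` overrides them.  A pair absent from both
#' is an error that lists every missing pair: an interaction must be
#' declared explicitly (including explicit zeros, as for ester-ester
#' pairs), never assumed.
#'
#' @param components Character vector of registry names, or a list of
#'   [cpa_component] objects.
#' @param binaries Optional list of [cpa_binary] objects overriding or
#'   supplementing the registry (e.g. a registry variant, or a candidate
#'   `kij` during regression).
#' @return Object of class `cpa_mixture`.
#' @export
#' @examples
#' cpa_mixture(c("CO2", "methanol"))
#' cpa_mixture(c("CO2", "glycerol"),
#'             binaries = list(get_binary("CO2", "glycerol", variant = "inert")))
cpa_mixture <- function(components, binaries = NULL) {
  comps <- lapply(components, function(cc)
    if (inherits(cc, "cpa_component")) cc else get_component(cc))
  nc <- length(comps)
  nm <- vapply(comps, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate components in mixture: ",
                              paste(nm[duplicated(nm)], collapse = ", "))

  # resolve binary interactions: overrides first, then registry
  pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "\r")
  override <- list()
  for (bn in binaries %||% list()) {
    stopifnot(inherits(bn, "cpa_binary"))
    override[[pair_key(bn$i, bn$j)]] <- bn
  }
  inter <- vector("list", nc * nc); dim(inter) <- c(nc, nc)
  kij <- matrix(0, nc, nc)
  missing_pairs <- character(0)
  if (nc > 1) for (i in 1:(nc - 1)) for (j in (i + 1):nc) {
    key <- pair_key(nm[i], nm[j])
    bn <- override[[key]]
    if (is.null(bn)) {
      bn <- tryCatch(get_binary(nm[i], nm[j]), error = function(e) NULL)
    }
    if (is.null(bn)) { missing_pairs <- c(missing_pairs, paste(nm[i], nm[j], sep = " / ")); next }
    inter[[i, j]] <- inter[[j, i]] <- bn
    kij[i, j] <- kij[j, i] <- bn$kij
  }
  if (length(missing_pairs))
    stop("no binary parameters declared for pair(s): ",
         paste(missing_pairs, collapse = "; "),
         " (declare an explicit cpa_binary, zero included)", call. = FALSE)

  # site catalog; solvation sites on inert partners of mCR1/explicit pairs
  cross_declared <- rep(FALSE, nc)
  if (nc > 1) for (i in 1:nc) for (j in 1:nc) {
    bn <- inter[[i, j]]
    if (!is.null(bn) && bn$cross_rule %in% c("mCR1", "explicit"))
      cross_declared[i] <- TRUE
  }
  site_rows <- list()
  for (i in seq_len(nc)) {
    sch <- comps[[i]]$scheme
    if (sch == "none" && cross_declared[i]) sch <- "solvation"
    ss <- .scheme_sites(sch)
    if (!is.null(ss)) {
      ss$comp <- i
      site_rows[[length(site_rows) + 1L]] <- ss
    }
  }
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(polarity = character(0), mult = numeric(0), comp = integer(0))
  ns <- nrow(sites)

  eps_mat <- beta_mat <- bij_mat <- matrix(0, ns, ns)
  if (ns > 0) for (s in seq_len(ns)) for (t in seq_len(ns)) {
    i <- sites$comp[s]; j <- sites$comp[t]
    bij_mat[s, t] <- (comps[[i]]$b + comps[[j]]$b) / 2
    if (!.polarity_compatible(sites$polarity[s], sites$polarity[t])) next
    if (i == j) {
      if (comps[[i]]$beta_assoc > 0) {
        eps_mat[s, t] <- comps[[i]]$eps_assoc
        beta_mat[s, t] <- comps[[i]]$beta_assoc
      }
    } else {
      bn <- inter[[i, j]]
      if (!is.null(bn) && bn$cross_rule != "none") {
        cp <- cross_association_parameters(bn, comps[[i]], comps[[j]])
        eps_mat[s, t] <- cp$eps_cross
        beta_mat[s, t] <- cp$beta_cross
      }
    }
  }

  structure(list(
    components = comps, names = nm, nc = nc,
    interactions = inter, kij = kij,
    sites = sites, ns = ns,
    eps_mat = eps_mat, beta_mat = beta_mat, bij_mat = bij_mat,
    cpp = list(nc = nc, ns = ns,
               a0 = vapply(comps, `[[`, 0, "a0"),
               b  = vapply(comps, `[[`, 0, "b"),
               c1 = vapply(comps, `[[`, 0, "c1"),
               tc = vapply(comps, `[[`, 0, "tc"),
               kij = kij,
               site_comp = as.integer(sites$comp),
               site_mult = as.numeric(sites$mult),
               eps_mat = eps_mat, beta_mat = beta_mat, bij_mat = bij_mat),
    cache = new.env(parent = emptyenv())
  ), class = "cpa_mixture")
}

#' @export
print.cpa_mixture <- function(x, ...) {
  cat(sprintf("<cpa_mixture> %d component(s): %s\n", x$nc,
              paste(x$names, collapse = ", ")))
  if (x$nc > 1) {
    cat("  kij matrix:\n")
    k <- x$kij; dimnames(k) <- list(x$names, x$names)
    print(signif(k, 4))
  }
  if (x$ns > 0) {
    cat(sprintf("  %d association site class(es):\n", x$ns))
    s <- x$sites
    for (r in seq_len(nrow(s)))
      cat(sprintf("    %s: %s x%g\n", x$names[s$comp[r]], s$polarity[r], s$mult[r]))
  } else cat("  no active association sites\n")
  invisible(x)
}

.check_composition <- function(x, nc) {
  if (length(x) != nc) stop("composition has length ", length(x), ", expected ", nc)
  if (any(x < -1e-12)) stop("negative mole fraction")
  if (abs(sum(x) - 1) > 1e-8) stop("mole fractions must sum to 1 (got ", sum(x), ")")
  pmax(x, 0)
}
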