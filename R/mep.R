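## Electrostatic-potential-surface based cocrystal screening.
##
## Surface extrema of the molecular electrostatic potential (MEP, mapped on
## an electron-density isosurface) parameterize hydrogen-bond donor (alpha)
## and acceptor (beta) strengths. Pairing the strongest donors with the
## strongest acceptors estimates solid-state interaction energies, and the
## difference between the mixed (cocrystal) and pure-component pairings is
## the formation energy gain delta E_MEP, negative when cocrystallization
## is electrostatically favourable.

#' Stoichiometric ratio of a two-component crystal
#'
#' API:coformer molar ratio, reduced to lowest terms on construction.
#'
#' @param m positive integer count of API molecules.
#' @param n positive integer count of coformer molecules.
#' @return an object of class `stoichiometry` (named integer vector).
#' @examples
#' stoichiometry(2, 4)  # reduces to 1:2
#' @export
stoichiometry <- function(m, n) {
  m <- as.integer(m)
  n <- as.integer(n)
  if (is.na(m) || is.na(n) || m < 1L || n < 1L) {
    stop("stoichiometric counts must be positive integers")
  }
  gcd <- function(a, b) if (b == 0L) a else gcd(b, a %% b)
  g <- gcd(m, n)
  structure(c(m = m %/% g, n = n %/% g), class = "stoichiometry")
}

#' @export
print.stoichiometry <- function(x, ...) {
  cat(sprintf("%d:%d\n", x[["m"]], x[["n"]]))
  invisible(x)
}

#' @export
format.stoichiometry <- function(x, ...) {
  sprintf("%d:%d", x[["m"]], x[["n"]])
}

#' Parse a "m:n" stoichiometry string
#'
#' @param x character vector like `"1:2"`.
#' @return a list of [stoichiometry] objects (a single object if `length(x)`
#'   is 1).
#' @export
parse_stoichiometry <- function(x) {
  out <- lapply(x, function(s) {
    tok <- strsplit(s, ":", fixed = TRUE)[[1L]]
    if (length(tok) != 2L) stop("cannot parse stoichiometry '", s, "'")
    stoichiometry(as.integer(tok[1L]), as.integer(tok[2L]))
  })
  if (length(out) == 1L) out[[1L]] else out
}

#' Hydrogen-bond interaction sites from MEP surface extrema
#'
#' Converts lists of local maxima (positive, donor sites) and minima
#' (negative, acceptor sites) of the surface electrostatic potential into
#' dimensionless H-bond parameters: `alpha = k_alpha * V_max` for donors and
#' `beta = -k_beta * V_min` for acceptors. The calibration constants default
#' to 1/52 mol/kJ, a package convention chosen so that a strong donor
#' extremum of about +52 kJ/mol maps to alpha = 1; both are configurable.
#'
#' @param maxima numeric vector of surface potential maxima, kJ/mol (>= 0).
#' @param minima numeric vector of surface potential minima, kJ/mol (<= 0).
#' @param molecule_label,conformer_label labels carried through reports.
#' @param k_alpha,k_beta calibration constants, mol/kJ.
#' @return an object of class `site_set`: list with `molecule_label`,
#'   `conformer_label` and a data frame `sites` (`kind`,
#'   `surface_potential`, `parameter`).
#' @examples
#' sites_from_extrema(maxima = c(52, 30), minima = c(-104),
#'                    molecule_label = "demo")
#' @export
sites_from_extrema <- function(maxima = numeric(0), minima = numeric(0),
                               molecule_label = "molecule",
                               conformer_label = "conf-1",
                               k_alpha = 1 / 52, k_beta = 1 / 52) {
  if (length(maxima) + length(minima) == 0L) {
    stop("at least one surface extremum is required")
  }
  if (any(maxima < 0)) stop("surface maxima must be >= 0 (donor sites)")
  if (any(minima > 0)) stop("surface minima must be <= 0 (acceptor sites)")
  if (k_alpha <= 0 || k_beta <= 0) stop("calibration constants must be > 0")
  sites <- data.frame(
    kind = rep(c("donor", "acceptor"), c(length(maxima), length(minima))),
    surface_potential = c(maxima, minima),
    parameter = c(k_alpha * maxima, -k_beta * minima),
    stringsAsFactors = FALSE
  )
  structure(
    list(molecule_label = molecule_label, conformer_label = conformer_label,
         sites = sites),
    class = "site_set"
  )
}

#' @export
print.site_set <- function(x, ...) {
  nd <- sum(x$sites$kind == "donor")
  na <- sum(x$sites$kind == "acceptor")
  cat(sprintf("<site set '%s' (%s): %d donor(s), %d acceptor(s)>\n",
              x$molecule_label, x$conformer_label, nd, na))
  invisible(x)
}

#' Read / write site sets as JSON
#'
#' The JSON schema carries `molecule_label`, `conformer_label`, `maxima`
#' and `minima` (kJ/mol); parameters are recomputed on read with the given
#' calibration.
#'
#' @param path JSON file path.
#' @param ... passed to [sites_from_extrema()] (calibration constants).
#' @return `read_site_set()` returns a [sites_from_extrema()] site set;
#'   `write_site_set()` returns `path` invisibly.
#' @export
read_site_set <- function(path, ...) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("molecule_label", "maxima", "minima")
  if (!all(need %in% names(x))) {
    stop("site-set JSON must contain: ", paste(need, collapse = ", "))
  }
  sites_from_extrema(
    maxima = as.numeric(unlist(x$maxima)),
    minima = as.numeric(unlist(x$minima)),
    molecule_label = x$molecule_label,
    conformer_label = if (is.null(x$conformer_label)) "conf-1"
                      else x$conformer_label,
    ...
  )
}

#' @param site_set a site set.
#' @rdname read_site_set
#' @export
write_site_set <- function(site_set, path) {
  stopifnot(inherits(site_set, "site_set"))
  s <- site_set$sites
  jsonlite::write_json(
    list(
      molecule_label = site_set$molecule_label,
      conformer_label = site_set$conformer_label,
      maxima = s$surface_potential[s$kind == "donor"],
      minima = s$surface_potential[s$kind == "acceptor"]
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

.site_params <- function(site_set, kind) {
  s <- site_set$sites
  s$parameter[s$kind == kind]
}

#' Optimal donor-acceptor pairing energy
#'
#' Pairs donors (sorted by decreasing alpha) with acceptors (sorted by
#' decreasing beta) and returns the interaction energy
#' `E = -sum(alpha_k * beta_k)` over the `min(#donors, #acceptors)` pairs.
#' By the rearrangement inequality this sorted pairing maximizes
#' `sum(alpha * beta)` over all matchings, i.e. it yields the most negative
#' (most stabilizing) energy. Unpaired sites contribute nothing.
#'
#' @param alphas numeric vector of donor parameters (>= 0), or a `site_set`.
#' @param betas numeric vector of acceptor parameters (>= 0); ignored when
#'   `alphas` is a site set.
#' @return a list of class `pairing_result`: `pairs` (data frame `alpha`,
#'   `beta`), `unpaired` (count), `energy` (kJ/mol, <= 0).
#' @examples
#' pairing_energy(alphas = c(3, 2), betas = c(5, 1))$energy  # -17
#' @export
pairing_energy <- function(alphas, betas = numeric(0)) {
  if (inherits(alphas, "site_set")) {
    betas <- .site_params(alphas, "acceptor")
    alphas <- .site_params(alphas, "donor")
  }
  if (length(alphas) + length(betas) == 0L) {
    stop("no interaction sites supplied")
  }
  if (any(alphas < 0) || any(betas < 0)) {
    stop("H-bond parameters must be non-negative")
  }
  a <- sort(alphas, decreasing = TRUE)
  b <- sort(betas, decreasing = TRUE)
  k <- min(length(a), length(b))
  pairs <- data.frame(alpha = a[seq_len(k)], beta = b[seq_len(k)])
  structure(
    list(
      pairs = pairs,
      unpaired = length(a) + length(b) - 2L * k,
      energy = -sum(pairs$alpha * pairs$beta)
    ),
    class = "pairing_result"
  )
}

#' @export
print.pairing_result <- function(x, ...) {
  cat(sprintf("<pairing: %d pair(s), %d unpaired, E = %.3f kJ/mol>\n",
              nrow(x$pairs), x$unpaired, x$energy))
  invisible(x)
}

.replicate_params <- function(x, times) rep(x, times = times)

#' Cocrystal formation energy gain from MEP-derived sites
#'
#' Estimates the electrostatic energy gain of forming an m:n cocrystal:
#' \deqn{\Delta E_{MEP} = E_{CC} - (m E_{API} + n E_{coformer})}
#' where `E_CC` is the optimal donor-acceptor pairing energy over the pooled
#' sites of m API copies and n coformer copies, and `E_API`, `E_coformer`
#' are each component's own (single-molecule) pairing energies. The pooled
#' optimum is always at least as stabilizing as the separate ones, so the
#' gain cannot exceed zero. A gain at or below the threshold (default
#' -11 kJ/mol, the literature's ~50% formation-probability anchor) flags the
#' pair as a likely cocrystal former.
#'
#' @param api,coformer site sets from [sites_from_extrema()].
#' @param stoich a [stoichiometry] (API:coformer).
#' @param threshold decision threshold in kJ/mol (default -11).
#' @return an object of class `screen_result`: list with `stoichiometry`,
#'   `E_CC`, `E_API`, `E_FL` (coformer), `delta_E_MEP` (all kJ/mol) and
#'   `likely`.
#' @examples
#' api <- sites_from_extrema(maxima = c(52, 40), minima = -30,
#'                           molecule_label = "api")
#' fl <- sites_from_extrema(minima = c(-80, -20), molecule_label = "flavone")
#' delta_E_MEP(api, fl, stoichiometry(1, 2))
#' @export
delta_E_MEP <- function(api, coformer, stoich = stoichiometry(1, 1),
                        threshold = -11) {
  stopifnot(inherits(api, "site_set"), inherits(coformer, "site_set"),
            inherits(stoich, "stoichiometry"))
  m <- stoich[["m"]]
  n <- stoich[["n"]]
  a_cc <- c(rep(.site_params(api, "donor"), m),
            rep(.site_params(coformer, "donor"), n))
  b_cc <- c(rep(.site_params(api, "acceptor"), m),
            rep(.site_params(coformer, "acceptor"), n))
  e_one <- function(ss) {
    a <- .site_params(ss, "donor")
    b <- .site_params(ss, "acceptor")
    if (length(a) == 0L || length(b) == 0L) 0 else pairing_energy(a, b)$energy
  }
  E_CC <- if (length(a_cc) == 0L || length(b_cc) == 0L) 0 else
    pairing_energy(a_cc, b_cc)$energy
  E_API <- e_one(api)
  E_FL <- e_one(coformer)
  delta <- E_CC - (m * E_API + n * E_FL)
  structure(
    list(
      pair = c(api = api$molecule_label, coformer = coformer$molecule_label),
      stoichiometry = stoich,
      E_CC = E_CC, E_API = E_API, E_FL = E_FL,
      delta_E_MEP = delta,
      threshold = threshold,
      likely = delta <= threshold
    ),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "<MEP screen %s/%s %s: dE_MEP = %.2f kJ/mol (%s at %.0f kJ/mol)>\n",
    x$pair[["api"]], x$pair[["coformer"]], format(x$stoichiometry),
    x$delta_E_MEP, if (x$likely) "likely" else "unlikely", x$threshold
  ))
  invisible(x)
}

#' Screen a pair of molecules across stoichiometric ratios
#'
#' Runs [delta_E_MEP()] for each requested API:coformer ratio and flags the
#' ratio with the most negative formation energy gain as preferred.
#' Duplicate ratios (after reduction) are collapsed with a warning.
#'
#' @inheritParams delta_E_MEP
#' @param ratios a list of [stoichiometry] objects (or a character vector
#'   like `c("1:1", "1:2", "2:1")`).
#' @return a data frame of class `mep_screen_table` with one row per ratio:
#'   `stoichiometry`, `E_CC`, `E_API`, `E_FL`, `delta_E_MEP`, `likely`,
#'   `preferred`.
#' @examples
#' api <- sites_from_extrema(maxima = c(52, 40), minima = -30,
#'                           molecule_label = "api")
#' fl <- sites_from_extrema(minima = c(-80, -20), molecule_label = "flavone")
#' screen_stoichiometries(api, fl, c("1:1", "1:2", "2:1"))
#' @export
screen_stoichiometries <- function(api, coformer,
                                   ratios = c("1:1", "1:2", "2:1"),
                                   threshold = -11) {
  if (is.character(ratios)) {
    ratios <- lapply(ratios, parse_stoichiometry)
  }
  if (inherits(ratios, "stoichiometry")) ratios <- list(ratios)
  if (length(ratios) == 0L) stop("ratio list must not be empty")
  keys <- vapply(ratios, format, character(1))
  if (anyDuplicated(keys)) {
    warning("duplicate stoichiometric ratios collapsed: ",
            paste(unique(keys[duplicated(keys)]), collapse = ", "))
    ratios <- ratios[!duplicated(keys)]
    keys <- keys[!duplicated(keys)]
  }
  res <- lapply(ratios, function(s) delta_E_MEP(api, coformer, s, threshold))
  out <- data.frame(
    stoichiometry = keys,
    E_CC = vapply(res, `[[`, numeric(1), "E_CC"),
    E_API = vapply(res, `[[`, numeric(1), "E_API"),
    E_FL = vapply(res, `[[`, numeric(1), "E_FL"),
    delta_E_MEP = vapply(res, `[[`, numeric(1), "delta_E_MEP"),
    likely = vapply(res, `[[`, logical(1), "likely"),
    stringsAsFactors = FALSE
  )
  out$preferred <- seq_len(nrow(out)) == which.min(out$delta_E_MEP)
  attr(out, "pair") <- c(api = api$molecule_label,
                         coformer = coformer$molecule_label)
  attr(out, "threshold") <- threshold
  class(out) <- c("mep_screen_table", "data.frame")
  out
}

#' Write an MEP screening table to CSV
#'
#' @param x a table from [screen_stoichiometries()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_mep_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
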