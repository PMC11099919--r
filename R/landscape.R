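## Post-processing of crystal-energy-landscape tables produced by crystal
## structure prediction: cocrystal formation energies relative to the most
## stable pure-component polymorphs, the feasibility cutoff, ranking
## margins, stoichiometry-corrected stability comparisons, and aggregation
## of pairwise intermolecular interaction energies.
##
## Sign convention: lattice energies are negative for stable crystals and
## are stored per formula unit (one m:n stoichiometric unit).

#' Reference energy of a pure component
#'
#' The lattice energy per molecule of a component's most stable polymorph,
#' used as the reference when computing cocrystal formation energies.
#'
#' @param name component label.
#' @param E_latt_min lattice energy, kJ/mol per molecule; must be negative.
#' @return an object of class `component_reference`.
#' @export
component_reference <- function(name, E_latt_min) {
  if (!is.finite(E_latt_min) || E_latt_min >= 0) {
    stop("E_latt_min must be negative (negative-stable convention)")
  }
  structure(list(name = name, E_latt_min = E_latt_min),
            class = "component_reference")
}

#' Assemble a crystal energy landscape
#'
#' @param structures data frame with columns `label`, `space_group`,
#'   `z_prime`, `E_latt` (kJ/mol per formula unit, negative-stable),
#'   `density` (g/cm^3), `dE_intra` (kJ/mol, >= 0), `m`, `n`
#'   (API:coformer counts; reduced on construction).
#' @param api_ref,coformer_ref [component_reference()] objects.
#' @return an object of class `energy_landscape`.
#' @export
energy_landscape <- function(structures, api_ref, coformer_ref) {
  stopifnot(inherits(api_ref, "component_reference"),
            inherits(coformer_ref, "component_reference"))
  need <- c("label", "space_group", "z_prime", "E_latt", "density",
            "dE_intra", "m", "n")
  if (!all(need %in% names(structures))) {
    stop("structures must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(structures) == 0L) stop("landscape must contain structures")
  if (any(structures$density <= 0)) stop("densities must be positive")
  if (any(structures$dE_intra < 0)) {
    stop("intramolecular penalties must be >= 0")
  }
  red <- t(mapply(function(m, n) unclass(stoichiometry(m, n)),
                  structures$m, structures$n))
  structures$m <- red[, 1L]
  structures$n <- red[, 2L]
  structure(
    list(structures = structures, api_ref = api_ref,
         coformer_ref = coformer_ref),
    class = "energy_landscape"
  )
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat(sprintf(
    "<energy landscape: %d structures; refs %s (%.1f), %s (%.1f) kJ/mol>\n",
    nrow(x$structures), x$api_ref$name, x$api_ref$E_latt_min,
    x$coformer_ref$name, x$coformer_ref$E_latt_min
  ))
  invisible(x)
}

#' Read / write landscape tables
#'
#' Landscape CSV columns: `label`, `space_group`, `z_prime`,
#' `E_latt_kjmol`, `density_gcm3`, `dE_intra_kjmol`, `m`, `n`. Component
#' CSV columns: `name`, `E_latt_min_kjmol` (the API row first).
#'
#' @param structures_path landscape CSV path.
#' @param components_path component-reference CSV path.
#' @return an [energy_landscape()].
#' @export
read_landscape <- function(structures_path, components_path) {
  st <- utils::read.csv(structures_path, stringsAsFactors = FALSE)
  need <- c("label", "space_group", "z_prime", "E_latt_kjmol",
            "density_gcm3", "dE_intra_kjmol", "m", "n")
  if (!all(need %in% names(st))) {
    stop("landscape CSV must have columns: ", paste(need, collapse = ", "))
  }
  co <- utils::read.csv(components_path, stringsAsFactors = FALSE)
  if (!all(c("name", "E_latt_min_kjmol") %in% names(co)) || nrow(co) < 2L) {
    stop("component CSV must have columns name,E_latt_min_kjmol and ",
         "two rows (API first, coformer second)")
  }
  energy_landscape(
    data.frame(
      label = st$label, space_group = st$space_group, z_prime = st$z_prime,
      E_latt = st$E_latt_kjmol, density = st$density_gcm3,
      dE_intra = st$dE_intra_kjmol, m = st$m, n = st$n,
      stringsAsFactors = FALSE
    ),
    component_reference(co$name[1L], co$E_latt_min_kjmol[1L]),
    component_reference(co$name[2L], co$E_latt_min_kjmol[2L])
  )
}

#' @param landscape an [energy_landscape()].
#' @param dir output directory for `structures.csv` and `components.csv`.
#' @rdname read_landscape
#' @export
write_landscape <- function(landscape, dir) {
  stopifnot(inherits(landscape, "energy_landscape"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  st <- landscape$structures
  utils::write.csv(
    data.frame(
      label = st$label, space_group = st$space_group, z_prime = st$z_prime,
      E_latt_kjmol = st$E_latt, density_gcm3 = st$density,
      dE_intra_kjmol = st$dE_intra, m = st$m, n = st$n
    ),
    file.path(dir, "structures.csv"), row.names = FALSE
  )
  utils::write.csv(
    data.frame(
      name = c(landscape$api_ref$name, landscape$coformer_ref$name),
      E_latt_min_kjmol = c(landscape$api_ref$E_latt_min,
                           landscape$coformer_ref$E_latt_min)
    ),
    file.path(dir, "components.csv"), row.names = FALSE
  )
  invisible(dir)
}

#' Cocrystal formation energy of a predicted structure
#'
#' For an m:n structure with lattice energy `E_latt` per formula unit,
#' `dE_form = E_latt - (m * E_api + n * E_coformer)` against the most stable
#' pure-component polymorphs. Negative values mean the cocrystal packing is
#' more stable than the separated components.
#'
#' @param E_latt lattice energy per formula unit, kJ/mol (vectorized).
#' @param m,n stoichiometric counts (vectorized).
#' @param api_ref,coformer_ref [component_reference()] objects.
#' @return formation energy/energies, kJ/mol.
#' @export
formation_energy <- function(E_latt, m, n, api_ref, coformer_ref) {
  if (missing(api_ref) || missing(coformer_ref)) {
    stop("both component references are required")
  }
  stopifnot(inherits(api_ref, "component_reference"),
            inherits(coformer_ref, "component_reference"))
  E_latt - (m * api_ref$E_latt_min + n * coformer_ref$E_latt_min)
}

#' Thermodynamically feasible subset of a landscape
#'
#' Structures whose formation energy is strictly below zero (the
#' feasibility cutoff) are potential cocrystals; structures at exactly zero
#' are tagged marginal. The feasible subset is returned sorted by
#' increasing formation energy, with the stabilization of the global
#' minimum and the rank-1/rank-2 margin.
#'
#' @param landscape an [energy_landscape()].
#' @return a list of class `feasibility_summary`: `subset` (data frame with
#'   a `dE_form` column), `count`, `marginal` (labels at exactly 0),
#'   `best_dE_form`, `margin_12` (kJ/mol; `NA` with fewer than two feasible
#'   structures).
#' @export
feasible_set <- function(landscape) {
  stopifnot(inherits(landscape, "energy_landscape"))
  st <- landscape$structures
  st$dE_form <- formation_energy(st$E_latt, st$m, st$n,
                                 landscape$api_ref, landscape$coformer_ref)
  feas <- st[st$dE_form < 0, , drop = FALSE]
  feas <- feas[order(feas$dE_form), , drop = FALSE]
  structure(
    list(
      subset = feas,
      count = nrow(feas),
      marginal = st$label[st$dE_form == 0],
      best_dE_form = if (nrow(feas) > 0L) feas$dE_form[1L] else NA_real_,
      margin_12 = if (nrow(feas) >= 2L) {
        feas$dE_form[2L] - feas$dE_form[1L]
      } else NA_real_
    ),
    class = "feasibility_summary"
  )
}

#' @export
print.feasibility_summary <- function(x, ...) {
  cat(sprintf("<feasible set: %d structure(s) below cutoff", x$count))
  if (x$count > 0L) {
    cat(sprintf("; best dE_form %.2f kJ/mol", x$best_dE_form))
  }
  if (!is.na(x$margin_12)) {
    cat(sprintf("; rank-1/2 margin %.2f kJ/mol", x$margin_12))
  }
  cat(">\n")
  invisible(x)
}

#' Stoichiometry-corrected lattice energy
#'
#' To compare lattice energies of cocrystals with different coformer
#' content, the coformer reference lattice energy is subtracted for each
#' excess coformer molecule, bringing an m:n entry onto an m:n_target
#' basis. Structures differing in API count are not comparable this way.
#'
#' @param E_latt lattice energy per formula unit, kJ/mol.
#' @param stoich a [stoichiometry()] of the entry.
#' @param target a [stoichiometry()] giving the comparison basis.
#' @param coformer_ref the coformer [component_reference()].
#' @return corrected lattice energy, kJ/mol, on the target basis.
#' @examples
#' fl <- component_reference("FL", -100)
#' stoichiometry_normalize(-350, stoichiometry(1, 2), stoichiometry(1, 1),
#'                         fl)  # -250
#' @export
stoichiometry_normalize <- function(E_latt, stoich, target, coformer_ref) {
  stopifnot(inherits(stoich, "stoichiometry"),
            inherits(target, "stoichiometry"),
            inherits(coformer_ref, "component_reference"))
  if (stoich[["m"]] != target[["m"]]) {
    stop("API counts differ (", stoich[["m"]], " vs ", target[["m"]],
         "); entries are not comparable by coformer correction")
  }
  E_latt - (stoich[["n"]] - target[["n"]]) * coformer_ref$E_latt_min
}

#' Aggregate pairwise intermolecular interaction energies
#'
#' Summarizes a table of pairwise interaction energies around central
#' molecules of one species: per partner species, the sum of all
#' interactions and the single strongest (most negative) one. When the
#' structure has several symmetry-independent central molecules (tagged via
#' `central_tag`), each is summarized separately and the summaries are
#' averaged.
#'
#' @param interactions data frame with columns `central` (species label),
#'   `partner`, `energy` (kJ/mol) and optionally `central_tag`
#'   (symmetry-independent molecule id) and `contact` (free-text tag).
#' @param central central species label to summarize.
#' @return a data frame with one row per partner species: `partner`,
#'   `sum_energy`, `strongest`, plus a `total` attribute with the
#'   all-partner sum.
#' @examples
#' x <- data.frame(central = "SG", partner = "SG",
#'                 energy = c(-105.9, -62.5, -59.6, 28.1))
#' aggregate_pairwise(x, "SG")
#' @export
aggregate_pairwise <- function(interactions, central) {
  need <- c("central", "partner", "energy")
  if (!all(need %in% names(interactions))) {
    stop("interactions must have columns: ", paste(need, collapse = ", "))
  }
  x <- interactions[interactions$central == central, , drop = FALSE]
  if (nrow(x) == 0L) {
    stop("no interactions recorded for central species '", central, "'")
  }
  if (any(!is.finite(x$energy))) stop("non-finite interaction energies")
  if (is.null(x$central_tag)) x$central_tag <- "mol-1"
  per_tag <- lapply(split(x, x$central_tag), function(g) {
    s <- vapply(split(g$energy, g$partner), sum, numeric(1))
    st <- vapply(split(g$energy, g$partner), min, numeric(1))
    data.frame(partner = names(s), sum_energy = unname(s),
               strongest = unname(st), stringsAsFactors = FALSE)
  })
  partners <- sort(unique(x$partner))
  out <- data.frame(
    partner = partners,
    sum_energy = vapply(partners, function(p) {
      mean(vapply(per_tag, function(d) {
        if (p %in% d$partner) d$sum_energy[d$partner == p] else 0
      }, numeric(1)))
    }, numeric(1)),
    strongest = vapply(partners, function(p) {
      vals <- unlist(lapply(per_tag, function(d) {
        if (p %in% d$partner) d$strongest[d$partner == p] else NULL
      }))
      mean(vals)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "central") <- central
  attr(out, "total") <- sum(out$sum_energy)
  out
}

#' Read a pairwise-interaction CSV
#'
#' Expects columns `central`, `partner`, `energy_kjmol`, optionally
#' `contact` and `central_tag`.
#'
#' @param path CSV path.
#' @return a data frame suitable for [aggregate_pairwise()].
#' @export
read_pairwise <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("central", "partner", "energy_kjmol")
  if (!all(need %in% names(df))) {
    stop("pairwise CSV must have columns: ", paste(need, collapse = ", "))
  }
  names(df)[names(df) == "energy_kjmol"] <- "energy"
  df
}

#' Plot an energy landscape
#'
#' Lattice energy (per formula unit) against density, with the feasible
#' subset (formation energy below the cutoff) highlighted and the cutoff
#' drawn as a dashed line.
#'
#' @param x an [energy_landscape()].
#' @param ... further arguments passed to [graphics::plot()].
#' @return the [feasible_set()] summary, invisibly.
#' @export
plot.energy_landscape <- function(x, ...) {
  st <- x$structures
  fs <- feasible_set(x)
  cutoff <- st$m * x$api_ref$E_latt_min + st$n * x$coformer_ref$E_latt_min
  feas <- st$label %in% fs$subset$label
  graphics::plot(
    st$density, st$E_latt,
    pch = ifelse(feas, 19, 1),
    col = ifelse(feas, "firebrick", "grey40"),
    xlab = expression(paste("density / g ", cm^-3)),
    ylab = expression(paste(E[latt], " / kJ ", mol^-1)), ...
  )
  if (length(unique(cutoff)) == 1L) {
    graphics::abline(h = cutoff[1L], lty = 2L)
  }
  invisible(fs)
}
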