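## Polymorph and cocrystal thermodynamics from DSC/TGA observables:
## the Burger-Ramberger heat-of-fusion rule, transition enthalpy and
## temperature estimation from melting data, energy/temperature diagram
## bookkeeping, and solvate stoichiometry from gravimetric mass loss.

.C_TO_K <- 273.15

#' Celsius/kelvin helpers
#'
#' @param x temperatures.
#' @return converted temperatures.
#' @export
celsius_to_kelvin <- function(x) x + .C_TO_K

#' @rdname celsius_to_kelvin
#' @export
kelvin_to_celsius <- function(x) x - .C_TO_K

#' A melting event of one solid form
#'
#' Temperatures are accepted in degrees Celsius and stored in kelvin.
#'
#' @param form form label (e.g. `"I_CC"`).
#' @param T_fus_C melting (fusion onset) temperature, degrees Celsius.
#' @param H_fus enthalpy of fusion, kJ/mol.
#' @param u_T optional temperature uncertainty, K.
#' @param u_H optional enthalpy uncertainty, kJ/mol.
#' @return an object of class `fusion_datum` with `T_fus` in kelvin.
#' @examples
#' fusion_datum("I_CC", 171.3, 52.0, u_T = 0.1, u_H = 0.3)
#' @export
fusion_datum <- function(form, T_fus_C, H_fus, u_T = NA_real_,
                         u_H = NA_real_) {
  T_fus <- celsius_to_kelvin(T_fus_C)
  if (!is.finite(T_fus) || T_fus <= 0) stop("T_fus must be positive (K)")
  if (!is.finite(H_fus) || H_fus <= 0) stop("H_fus must be positive")
  structure(
    list(form = form, T_fus = T_fus, H_fus = H_fus, u_T = u_T, u_H = u_H),
    class = "fusion_datum"
  )
}

#' @export
print.fusion_datum <- function(x, ...) {
  cat(sprintf("<%s: T_fus %.1f K (%.1f C), H_fus %.1f kJ/mol>\n",
              x$form, x$T_fus, kelvin_to_celsius(x$T_fus), x$H_fus))
  invisible(x)
}

#' Read a fusion-data table
#'
#' CSV columns: `form`, `T_fus_C`, `H_fus_kjmol`, optional `u_T`, `u_H`.
#'
#' @param path CSV path.
#' @return a named list of [fusion_datum()] objects.
#' @export
read_fusion_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("form", "T_fus_C", "H_fus_kjmol")
  if (!all(need %in% names(df))) {
    stop("fusion CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(df$u_T)) df$u_T <- NA_real_
  if (is.null(df$u_H)) df$u_H <- NA_real_
  out <- lapply(seq_len(nrow(df)), function(i) {
    fusion_datum(df$form[i], df$T_fus_C[i], df$H_fus_kjmol[i],
                 df$u_T[i], df$u_H[i])
  })
  names(out) <- df$form
  out
}

#' Heat-of-fusion rule for a polymorph pair
#'
#' The Burger-Ramberger heat-of-fusion rule: if the higher-melting form has
#' the lower enthalpy of fusion the pair is enantiotropic (the stability
#' order inverts at a transition point below melting) and the higher-melting
#' form is the high-temperature form; if the higher-melting form also has
#' the higher enthalpy of fusion the pair is monotropic. When the enthalpy
#' difference is within the combined stated uncertainties, or the melting
#' points coincide, the verdict is indeterminate.
#'
#' @param a,b [fusion_datum()] objects for the two forms.
#' @return an object of class `relation_verdict`: list with `relation`
#'   (`"enantiotropic"`, `"monotropic"` or `"indeterminate"`) and
#'   `high_temperature_form` (label, or `NA`).
#' @examples
#' heat_of_fusion_rule(fusion_datum("I_CC", 171.3, 52.0),
#'                     fusion_datum("II_CC", 174.6, 47.5))
#' @export
heat_of_fusion_rule <- function(a, b) {
  stopifnot(inherits(a, "fusion_datum"), inherits(b, "fusion_datum"))
  if (identical(a$form, b$form)) stop("the two forms must be distinct")
  if (a$T_fus == b$T_fus) {
    warning("equal melting points; heat-of-fusion rule is indeterminate")
    return(structure(
      list(relation = "indeterminate", high_temperature_form = NA_character_),
      class = "relation_verdict"
    ))
  }
  hi <- if (a$T_fus > b$T_fus) a else b
  lo <- if (a$T_fus > b$T_fus) b else a
  dH <- hi$H_fus - lo$H_fus
  u <- sum(c(a$u_H, b$u_H), na.rm = TRUE)
  relation <- if (abs(dH) <= u) {
    "indeterminate"
  } else if (dH < 0) {
    "enantiotropic"
  } else {
    "monotropic"
  }
  structure(
    list(
      relation = relation,
      high_temperature_form = if (relation == "enantiotropic") hi$form
                              else NA_character_
    ),
    class = "relation_verdict"
  )
}

#' @export
print.relation_verdict <- function(x, ...) {
  cat(sprintf("<heat-of-fusion rule: %s%s>\n", x$relation,
              if (!is.na(x$high_temperature_form)) {
                paste0(", high-T form ", x$high_temperature_form)
              } else ""))
  invisible(x)
}

#' Transition enthalpy, entropy, and temperature of a polymorph pair
#'
#' For an enantiotropic pair, estimates the solid-solid transition from the
#' melting data alone under the assumption that the heat capacities of the
#' two solids are equal (delta Cp = 0): the transition enthalpy is the
#' difference of the fusion enthalpies, the transition entropy is the
#' difference of the fusion entropies `H_fus/T_fus`, and the transition
#' temperature is where the two Gibbs-energy lines cross,
#' `T_trans = H_trans / S_trans`.
#'
#' @param a,b [fusion_datum()] objects.
#' @param force compute even when [heat_of_fusion_rule()] does not return an
#'   enantiotropic verdict.
#' @return an object of class `transition_estimate`: `H_trans` (kJ/mol,
#'   lower-melting minus higher-melting fusion enthalpy), `S_trans`
#'   (J/(mol K)), `T_trans` (K), `T_trans_C` (degrees Celsius),
#'   `low_form`, `high_form`.
#' @examples
#' transition_thermo(fusion_datum("I_CC", 171.3, 52.0),
#'                   fusion_datum("II_CC", 174.6, 47.5))
#' @export
transition_thermo <- function(a, b, force = FALSE) {
  stopifnot(inherits(a, "fusion_datum"), inherits(b, "fusion_datum"))
  if (!force) {
    v <- suppressWarnings(heat_of_fusion_rule(a, b))
    if (v$relation != "enantiotropic") {
      stop("forms are not enantiotropic by the heat-of-fusion rule (",
           v$relation, "); use force = TRUE to compute anyway")
    }
  }
  lo <- if (a$T_fus <= b$T_fus) a else b
  hi <- if (a$T_fus <= b$T_fus) b else a
  H_trans <- lo$H_fus - hi$H_fus
  S_trans <- lo$H_fus / lo$T_fus - hi$H_fus / hi$T_fus  # kJ/(mol K)
  if (S_trans == 0) {
    stop("transition entropy is zero; transition temperature undefined")
  }
  T_trans <- H_trans / S_trans
  structure(
    list(
      H_trans = H_trans,
      S_trans = 1000 * S_trans,
      T_trans = T_trans,
      T_trans_C = kelvin_to_celsius(T_trans),
      low_form = lo$form, high_form = hi$form
    ),
    class = "transition_estimate"
  )
}

#' @export
print.transition_estimate <- function(x, ...) {
  cat(sprintf(
    "<%s -> %s: H_trans %.2f kJ/mol, S_trans %.2f J/(mol K), T_trans %.1f K (%.1f C)>\n",
    x$low_form, x$high_form, x$H_trans, x$S_trans, x$T_trans, x$T_trans_C
  ))
  invisible(x)
}

#' Semischematic energy/temperature diagram specification
#'
#' Serializes the event structure of an energy/temperature diagram for a
#' polymorph pair: enthalpy isobar levels for the two solids and the melt,
#' and the ordered temperature events. For an enantiotropic pair the
#' Gibbs-energy lines cross at the transition temperature, which must lie
#' below both melting points; a violated ordering raises an error naming
#' the inequality.
#'
#' @param a,b [fusion_datum()] objects.
#' @param estimate a [transition_thermo()] result for enantiotropic pairs;
#'   omit (`NULL`) for monotropic pairs.
#' @return an object of class `et_diagram`: list with `relation`, `isobars`
#'   (named enthalpy levels, melt = 0 reference at the lower melting point),
#'   `events` (data frame `temperature_K`, `temperature_C`, `event`,
#'   ordered), `crossing_K` (`NA` when monotropic).
#' @export
et_diagram <- function(a, b, estimate = NULL) {
  stopifnot(inherits(a, "fusion_datum"), inherits(b, "fusion_datum"))
  lo <- if (a$T_fus <= b$T_fus) a else b
  hi <- if (a$T_fus <= b$T_fus) b else a
  relation <- if (is.null(estimate)) "monotropic" else "enantiotropic"
  events <- data.frame(
    temperature_K = c(lo$T_fus, hi$T_fus),
    event = paste0("T_fus(", c(lo$form, hi$form), ")"),
    stringsAsFactors = FALSE
  )
  crossing <- NA_real_
  if (!is.null(estimate)) {
    stopifnot(inherits(estimate, "transition_estimate"))
    crossing <- estimate$T_trans
    if (!(crossing < lo$T_fus)) {
      stop(sprintf(
        "inconsistent diagram: T_trans (%.1f K) < T_fus(%s) (%.1f K) violated",
        crossing, lo$form, lo$T_fus
      ))
    }
    if (crossing <= 0) stop("inconsistent diagram: T_trans must be positive")
    events <- rbind(
      data.frame(temperature_K = crossing, event = "T_trans",
                 stringsAsFactors = FALSE),
      events
    )
  }
  events <- events[order(events$temperature_K), , drop = FALSE]
  events$temperature_C <- kelvin_to_celsius(events$temperature_K)
  # Enthalpy levels relative to the melt (H_liq = 0): each solid sits its
  # fusion enthalpy below the melt.
  isobars <- c(-lo$H_fus, -hi$H_fus, 0)
  names(isobars) <- c(lo$form, hi$form, "liquid")
  structure(
    list(relation = relation, isobars = isobars,
         events = events[, c("temperature_K", "temperature_C", "event")],
         crossing_K = crossing),
    class = "et_diagram"
  )
}

#' @export
print.et_diagram <- function(x, ...) {
  cat(sprintf("<energy/temperature diagram (%s)>\n", x$relation))
  for (i in seq_len(nrow(x$events))) {
    cat(sprintf("  %-14s %7.1f K (%6.1f C)\n", x$events$event[i],
                x$events$temperature_K[i], x$events$temperature_C[i]))
  }
  invisible(x)
}

#' Solvate stoichiometry from gravimetric mass loss
#'
#' Converts a desolvation mass-loss fraction `w` into moles of solvent per
#' mole of host: `x = w * M_host / ((1 - w) * M_solvent)`. The rounded
#' value (one decimal) gives the conventional solvate stoichiometry label
#' (1.0 = monosolvate, 0.5 = hemisolvate, ...).
#'
#' @param fraction mass-loss fraction in \[0, 1).
#' @param host_molar_mass molar mass of the desolvated host, g/mol (for a
#'   cocrystal solvate: the sum over one stoichiometric unit).
#' @param solvent_molar_mass molar mass of the solvent, g/mol.
#' @return a list of class `solvate_stoichiometry`: `x` (mol solvent per
#'   mol host) and `x_rounded` (one decimal).
#' @examples
#' solvate_stoichiometry(0.131, 470.54, 74.12)  # ~1.0 mol t-BuOH
#' @export
solvate_stoichiometry <- function(fraction, host_molar_mass,
                                  solvent_molar_mass) {
  if (!is.finite(fraction) || fraction < 0 || fraction >= 1) {
    stop("mass-loss fraction must lie in [0, 1)")
  }
  if (host_molar_mass <= 0 || solvent_molar_mass <= 0) {
    stop("molar masses must be positive")
  }
  x <- fraction * host_molar_mass / ((1 - fraction) * solvent_molar_mass)
  structure(
    list(x = x, x_rounded = round(x, 1L)),
    class = "solvate_stoichiometry"
  )
}

#' @export
print.solvate_stoichiometry <- function(x, ...) {
  cat(sprintf("<solvate stoichiometry: %.3f mol/mol (reported %.1f)>\n",
              x$x, x$x_rounded))
  invisible(x)
}

#' Mass-loss fraction corresponding to a solvate stoichiometry
#'
#' Inverse of [solvate_stoichiometry()]: the gravimetric mass-loss fraction
#' expected for `x` moles of solvent per mole of host.
#'
#' @param x mol solvent per mol host.
#' @inheritParams solvate_stoichiometry
#' @return mass-loss fraction in \[0, 1).
#' @export
mass_loss_fraction <- function(x, host_molar_mass, solvent_molar_mass) {
  if (any(x < 0)) stop("x must be >= 0")
  x * solvent_molar_mass / (host_molar_mass + x * solvent_molar_mass)
}
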