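## Seeded generators emulating the inputs each pipeline stage consumes:
## MEP-derived site sets, crystal-energy landscapes with a programmed
## feasible count and ranking gap, and DSC/TGA traces with programmed
## events. Every generator records its seed and serializes the programmed
## ground truth alongside the generated data, so tests compare against the
## construction rather than re-deriving it.

# Run code under a local RNG state; the caller's stream is untouched.
.with_seed <- function(seed, code) {
  if (!is.null(globalenv()$.Random.seed)) {
    old <- globalenv()$.Random.seed
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Exhaustive maximum of sum(alpha * beta) over all matchings of the smaller
# side into the larger; independent oracle for the sorted-pairing energy.
# Only tractable for small site counts.
.matching_energy_exhaustive <- function(alphas, betas) {
  if (length(alphas) == 0L || length(betas) == 0L) return(0)
  if (length(alphas) > length(betas)) {
    tmp <- alphas
    alphas <- betas
    betas <- tmp
  }
  k <- length(alphas)
  n <- length(betas)
  if (choose(n, k) * factorial(k) > 5e6) {
    stop("site sets too large for exhaustive matching")
  }
  best <- 0
  rec <- function(i, avail, acc) {
    if (i > k) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    for (j in which(avail)) {
      avail2 <- avail
      avail2[j] <- FALSE
      rec(i + 1L, avail2, acc + alphas[i] * betas[j])
    }
  }
  rec(1L, rep(TRUE, n), 0)
  -best
}

#' Generate a random API/coformer site-set pair
#'
#' Draws donor and acceptor surface-potential magnitudes uniformly from
#' `magnitude_range` (kJ/mol) for both molecules and computes, by exhaustive
#' enumeration of donor-acceptor matchings, the reference formation energy
#' gain for each requested stoichiometry. The exhaustive reference is
#' independent of the sorted-pairing implementation in [delta_E_MEP()].
#'
#' @param seed integer seed.
#' @param n_donors,n_acceptors site counts per molecule; either scalars
#'   (same for both molecules) or length-2 vectors `(API, coformer)`.
#' @param magnitude_range `c(lo, hi)` potential magnitudes, kJ/mol, > 0.
#' @param ratios stoichiometries for the oracle (characters like `"1:2"`).
#' @param k_alpha,k_beta calibration constants (see [sites_from_extrema()]).
#' @return a list with `api`, `coformer` (site sets), `oracle` (data frame
#'   `stoichiometry`, `delta_E_MEP`), and `seed`.
#' @export
gen_site_sets <- function(seed, n_donors = 2L, n_acceptors = 2L,
                          magnitude_range = c(10, 60),
                          ratios = c("1:1", "1:2", "2:1"),
                          k_alpha = 1 / 52, k_beta = 1 / 52) {
  if (length(n_donors) == 1L) n_donors <- rep(n_donors, 2L)
  if (length(n_acceptors) == 1L) n_acceptors <- rep(n_acceptors, 2L)
  if (any(n_donors < 0L) || any(n_acceptors < 0L)) {
    stop("site counts must be >= 0")
  }
  if (sum(n_donors) + sum(n_acceptors) == 0L) {
    stop("at least one molecule must carry at least one site")
  }
  if (magnitude_range[1L] <= 0 || diff(magnitude_range) < 0) {
    stop("magnitude_range must be positive and ordered")
  }
  .with_seed(seed, {
    draw <- function(n) stats::runif(n, magnitude_range[1L],
                                     magnitude_range[2L])
    mk <- function(label, nd, na) {
      sites_from_extrema(
        maxima = draw(nd), minima = -draw(na),
        molecule_label = label, k_alpha = k_alpha, k_beta = k_beta
      )
    }
    # sites_from_extrema() rejects empty site sets, so give a siteless
    # molecule a token zero-potential acceptor only if truly empty
    mk_safe <- function(label, nd, na) {
      if (nd + na == 0L) {
        sites_from_extrema(minima = 0, molecule_label = label,
                           k_alpha = k_alpha, k_beta = k_beta)
      } else {
        mk(label, nd, na)
      }
    }
    api <- mk_safe("api-synth", n_donors[1L], n_acceptors[1L])
    cof <- mk_safe("coformer-synth", n_donors[2L], n_acceptors[2L])

    params <- function(ss, kind) ss$sites$parameter[ss$sites$kind == kind]
    oracle <- do.call(rbind, lapply(ratios, function(r) {
      s <- parse_stoichiometry(r)
      m <- s[["m"]]
      n <- s[["n"]]
      a_cc <- c(rep(params(api, "donor"), m), rep(params(cof, "donor"), n))
      b_cc <- c(rep(params(api, "acceptor"), m),
                rep(params(cof, "acceptor"), n))
      E_CC <- .matching_energy_exhaustive(a_cc, b_cc)
      E_API <- .matching_energy_exhaustive(params(api, "donor"),
                                           params(api, "acceptor"))
      E_FL <- .matching_energy_exhaustive(params(cof, "donor"),
                                          params(cof, "acceptor"))
      data.frame(stoichiometry = r,
                 delta_E_MEP = E_CC - (m * E_API + n * E_FL),
                 stringsAsFactors = FALSE)
    }))
    list(api = api, coformer = cof, oracle = oracle, seed = seed)
  })
}

# Space groups commonly adopted by organic molecular crystals.
.common_space_groups <- c("P21/c", "P-1", "P212121", "P21", "Pbca", "C2/c",
                          "Pna21", "Cc")

#' Generate a crystal energy landscape with programmed figures of merit
#'
#' Builds a landscape in which exactly `n_feasible` structures fall below
#' the cocrystal formation-energy cutoff and, when `n_feasible >= 2`, the
#' gap between the two most stable feasible structures equals `gap_12`.
#' Remaining structures are placed above the cutoff. Densities, space
#' groups and intramolecular penalties are sampled from ranges typical of
#' organic molecular crystals.
#'
#' @param seed integer seed.
#' @param n_structures total structure count.
#' @param n_feasible programmed number of structures below the cutoff.
#' @param gap_12 programmed rank-1/rank-2 formation-energy gap, kJ/mol.
#' @param stoich the landscape's [stoichiometry()].
#' @param api_E,coformer_E reference lattice energies per molecule, kJ/mol.
#' @return a list with `landscape` (an [energy_landscape()]), `truth`
#'   (list `n_feasible`, `gap_12`, `best_dE_form`), and `seed`.
#' @export
gen_landscape <- function(seed, n_structures = 30L, n_feasible = 7L,
                          gap_12 = 7.8, stoich = stoichiometry(1, 1),
                          api_E = -130, coformer_E = -105) {
  if (n_feasible > n_structures) {
    stop("n_feasible cannot exceed n_structures")
  }
  if (gap_12 < 0) stop("gap_12 must be >= 0")
  if (n_feasible < 2L && gap_12 > 0) {
    stop("a rank-1/rank-2 gap needs at least two feasible structures")
  }
  stopifnot(inherits(stoich, "stoichiometry"))
  .with_seed(seed, {
    m <- stoich[["m"]]
    n <- stoich[["n"]]
    base <- m * api_E + n * coformer_E
    dE <- numeric(0)
    if (n_feasible >= 2L) {
      rest <- sort(stats::runif(n_feasible - 1L, -9, -0.5))
      dE <- c(rest[1L] - gap_12, rest)
    } else if (n_feasible == 1L) {
      dE <- stats::runif(1L, -13, -1)
    }
    n_above <- n_structures - n_feasible
    dE <- c(dE, sort(stats::runif(n_above, 0.5, 20)))
    st <- data.frame(
      label = sprintf("str-%03d", seq_len(n_structures)),
      space_group = sample(.common_space_groups, n_structures,
                           replace = TRUE),
      z_prime = sample(c(1, 2), n_structures, replace = TRUE,
                       prob = c(0.85, 0.15)),
      E_latt = base + dE,
      density = stats::runif(n_structures, 1.2, 1.7),
      dE_intra = stats::runif(n_structures, 0, 18),
      m = m, n = n,
      stringsAsFactors = FALSE
    )
    ls <- energy_landscape(st,
                           component_reference("api-synth", api_E),
                           component_reference("coformer-synth", coformer_E))
    list(
      landscape = ls,
      truth = list(
        n_feasible = n_feasible,
        gap_12 = if (n_feasible >= 2L) gap_12 else NA_real_,
        best_dE_form = if (n_feasible > 0L) min(dE) else NA_real_
      ),
      seed = seed
    )
  })
}

#' Generate a synthetic DSC trace with programmed melting events
#'
#' Each event is a Gaussian endotherm on a gently sloping linear baseline.
#' The peak is placed so that the tangent-at-inflection onset equals the
#' programmed fusion temperature (for a Gaussian the extrapolated onset is
#' exactly two standard deviations below the apex), and its area encodes
#' the programmed molar fusion enthalpy for the given sample mass, molar
#' mass and heating rate. Optional Gaussian noise is added as a fraction of
#' the tallest peak.
#'
#' @param seed integer seed (used only for the noise).
#' @param events data frame (or list coercible to one) with columns
#'   `T_fus_C` (onset, degrees Celsius, increasing, separated by at least
#'   5 K) and `H_fus_kjmol`.
#' @param noise_sigma noise standard deviation as a fraction of the tallest
#'   peak height.
#' @param sample_mass_mg,molar_mass,heating_rate instrument settings
#'   (mg, g/mol, K/min).
#' @param peak_sigma Gaussian peak width, K.
#' @param step temperature sampling step, K.
#' @param pad trace extension beyond the first/last event, K.
#' @return a list with `trace` (data frame `temperature_C`, `signal` in
#'   mW), `truth` (the programmed events), instrument settings and `seed`.
#' @export
gen_dsc_trace <- function(seed, events, noise_sigma = 0,
                          sample_mass_mg = 3, molar_mass = 470.54,
                          heating_rate = 10, peak_sigma = 1.0,
                          step = 0.05, pad = 15) {
  events <- as.data.frame(events)
  if (nrow(events) > 0L) {
    if (!all(c("T_fus_C", "H_fus_kjmol") %in% names(events))) {
      stop("events needs columns T_fus_C, H_fus_kjmol")
    }
    if (is.unsorted(events$T_fus_C, strictly = TRUE)) {
      stop("events must be in strictly increasing temperature order")
    }
    if (nrow(events) > 1L && any(diff(events$T_fus_C) < 5)) {
      stop("events must be separated by at least 5 K")
    }
    if (any(events$H_fus_kjmol <= 0)) stop("fusion enthalpies must be > 0")
  }
  lo <- if (nrow(events) > 0L) min(events$T_fus_C) - pad else 25
  hi <- if (nrow(events) > 0L) max(events$T_fus_C) + pad else 125
  temp <- seq(lo, hi, by = step)
  beta <- heating_rate / 60                        # K/s
  baseline <- 0.5 + 0.002 * (temp - lo)
  sig <- baseline
  heights <- numeric(nrow(events))
  for (i in seq_len(nrow(events))) {
    # area in mW*K encoding H_fus kJ/mol
    area <- events$H_fus_kjmol[i] * 1000 * beta * sample_mass_mg / molar_mass
    h <- area / (peak_sigma * sqrt(2 * pi))
    heights[i] <- h
    center <- events$T_fus_C[i] + 2 * peak_sigma   # tangent onset = center-2s
    sig <- sig + h * exp(-(temp - center)^2 / (2 * peak_sigma^2))
  }
  if (noise_sigma > 0 && length(heights) > 0L) {
    sig <- sig + .with_seed(seed, stats::rnorm(
      length(sig), sd = noise_sigma * max(heights)
    ))
  } else if (noise_sigma > 0) {
    sig <- sig + .with_seed(seed, stats::rnorm(length(sig),
                                               sd = noise_sigma))
  }
  list(
    trace = data.frame(temperature_C = temp, signal = sig),
    truth = events,
    sample_mass_mg = sample_mass_mg, molar_mass = molar_mass,
    heating_rate = heating_rate, seed = seed
  )
}

#' Generate a synthetic TGA trace with programmed mass-loss steps
#'
#' Each step is a logistic (sigmoidal) mass loss centred at its `T_mid`;
#' step fractions are relative to the initial mass and must sum to less
#' than 1. Optional Gaussian noise is added as a fraction of the initial
#' mass.
#'
#' @param seed integer seed (used only for the noise).
#' @param steps data frame with columns `T_mid_C` (increasing, separated by
#'   at least 5 times their width) and `fraction`.
#' @param noise_sigma noise standard deviation as a fraction of the initial
#'   mass.
#' @param initial_mass_mg starting sample mass, mg.
#' @param width logistic step width parameter, K.
#' @param step temperature sampling step, K.
#' @param pad trace extension beyond the first/last step, K.
#' @return a list with `trace` (data frame `temperature_C`, `signal` in
#'   mg), `truth`, `initial_mass_mg` and `seed`.
#' @export
gen_tga_trace <- function(seed, steps, noise_sigma = 0,
                          initial_mass_mg = 5, width = 2,
                          step = 0.1, pad = 25) {
  steps <- as.data.frame(steps)
  if (nrow(steps) > 0L) {
    if (!all(c("T_mid_C", "fraction") %in% names(steps))) {
      stop("steps needs columns T_mid_C, fraction")
    }
    if (is.unsorted(steps$T_mid_C, strictly = TRUE)) {
      stop("steps must be in strictly increasing temperature order")
    }
    if (nrow(steps) > 1L && any(diff(steps$T_mid_C) < 5 * width)) {
      stop("steps overlap: midpoints must be separated by at least 5 widths")
    }
    if (any(steps$fraction <= 0) || sum(steps$fraction) >= 1) {
      stop("step fractions must be positive and sum to less than 1")
    }
  }
  lo <- if (nrow(steps) > 0L) min(steps$T_mid_C) - pad else 25
  hi <- if (nrow(steps) > 0L) max(steps$T_mid_C) + pad else 225
  temp <- seq(lo, hi, by = step)
  lost <- rep(0, length(temp))
  for (i in seq_len(nrow(steps))) {
    lost <- lost + steps$fraction[i] /
      (1 + exp(-(temp - steps$T_mid_C[i]) / width))
  }
  mass <- initial_mass_mg * (1 - lost)
  if (noise_sigma > 0) {
    mass <- mass + .with_seed(seed, stats::rnorm(
      length(mass), sd = noise_sigma * initial_mass_mg
    ))
  }
  list(
    trace = data.frame(temperature_C = temp, signal = mass),
    truth = steps,
    initial_mass_mg = initial_mass_mg,
    seed = seed
  )
}
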