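## Extraction of fusion data from DSC traces and mass-loss fractions from
## TGA traces. Conventions: heat-flow signal in mW (endotherm up) against
## temperature in degrees Celsius; onset by intersection of the tangent at
## the steepest point of the leading edge with a linear baseline; enthalpy
## by baseline-subtracted trapezoidal integration converted to kJ/mol with
## the sample mass, molar mass, and heating rate.

#' Read / write a two-column instrument trace
#'
#' CSV with columns `temperature_C` and `signal` (mW for DSC, mg for TGA).
#'
#' @param path CSV path.
#' @return a data frame with columns `temperature_C`, `signal`.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("temperature_C", "signal") %in% names(df))) {
    stop("trace CSV must have columns temperature_C,signal")
  }
  df
}

#' @param trace a trace data frame.
#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace[, c("temperature_C", "signal")], path,
                   row.names = FALSE)
  invisible(path)
}

# Robust linear baseline: iteratively refit excluding points far above the
# line (endothermic peaks are positive excursions).
.dsc_baseline <- function(temp, sig, n_iter = 6L) {
  keep <- rep(TRUE, length(sig))
  fit <- NULL
  for (i in seq_len(n_iter)) {
    fit <- stats::lm.fit(cbind(1, temp[keep]), sig[keep])
    pred <- cbind(1, temp) %*% fit$coefficients
    resid <- sig - pred
    s <- stats::mad(resid[keep])
    keep_new <- resid < 3 * max(s, 1e-12) | resid <= 0
    if (all(keep_new == keep)) break
    keep <- keep_new
  }
  drop(cbind(1, temp) %*% fit$coefficients)
}

.running_mean <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- k %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Extract melting events from a DSC trace
#'
#' Detects endothermic peaks above the noise level on a robust linear
#' baseline, measures each event's extrapolated onset temperature (tangent
#' at the steepest point of the leading edge intersected with the baseline)
#' and its enthalpy of fusion (baseline-subtracted trapezoidal integral,
#' converted to kJ/mol).
#'
#' @param trace data frame with `temperature_C` (monotone increasing) and
#'   `signal` (heat flow, mW, endotherm up).
#' @param sample_mass_mg sample mass, mg.
#' @param molar_mass molar mass of the melting phase, g/mol.
#' @param heating_rate heating rate, K/min.
#' @param min_rel_height peak-detection floor as a fraction of the largest
#'   baseline excursion (guards against detecting noise when the trace is
#'   featureless).
#' @return a list of [fusion_datum()] objects (empty when no peak is
#'   found), in temperature order, with forms labelled `"peak-1"`,
#'   `"peak-2"`, ... Overlapping events are flagged with a warning.
#' @export
extract_fusion_data <- function(trace, sample_mass_mg, molar_mass,
                                heating_rate = 10, min_rel_height = 0.05) {
  temp <- trace$temperature_C
  sig <- trace$signal
  if (length(temp) < 10L) stop("trace too short")
  if (any(diff(temp) <= 0)) stop("temperature axis must increase monotonely")
  if (sample_mass_mg <= 0 || molar_mass <= 0 || heating_rate <= 0) {
    stop("sample mass, molar mass and heating rate must be positive")
  }
  resid <- sig - .dsc_baseline(temp, sig)
  sigma <- stats::mad(resid[resid <= stats::quantile(resid, 0.9)])
  if (!is.finite(sigma)) sigma <- 0
  thr <- 5 * sigma + min_rel_height * max(resid, 0)
  if (thr <= 0 || !any(resid > thr)) return(list())

  above <- resid > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  peak_runs <- which(runs$values & runs$lengths >= 3L)
  if (length(peak_runs) == 0L) return(list())

  sm <- .running_mean(resid, if (sigma > 0) 9L else 1L)
  out <- list()
  regions <- matrix(NA_integer_, length(peak_runs), 2L)
  for (k in seq_along(peak_runs)) {
    i0 <- starts[peak_runs[k]]
    i1 <- ends[peak_runs[k]]
    apex <- i0 - 1L + which.max(resid[i0:i1])
    h <- resid[apex]
    floor_h <- 0.005 * h
    lo <- i0
    while (lo > 1L && sm[lo - 1L] > floor_h) lo <- lo - 1L
    hi <- i1
    n <- length(resid)
    while (hi < n && sm[hi + 1L] > floor_h) hi <- hi + 1L
    regions[k, ] <- c(lo, hi)
    # enthalpy: trapezoidal integral of the residual over the region
    idx <- lo:hi
    area <- sum(diff(temp[idx]) *
                  (utils::head(resid[idx], -1L) + utils::tail(resid[idx], -1L)) / 2)
    beta <- heating_rate / 60                       # K/s
    H_kjmol <- area * molar_mass / (beta * sample_mass_mg) / 1000
    # onset: tangent at the steepest leading-edge point
    lead <- lo:apex
    slope <- c(NA, diff(sm[lead]) / diff(temp[lead]))
    j <- lead[which.max(slope)]
    T_on <- temp[j] - sm[j] / max(slope, na.rm = TRUE)
    out[[k]] <- fusion_datum(sprintf("peak-%d", k), T_on, H_kjmol)
  }
  if (length(peak_runs) > 1L) {
    for (k in seq_len(length(peak_runs) - 1L)) {
      if (regions[k, 2L] >= regions[k + 1L, 1L]) {
        warning("overlapping peaks detected; integrals may be biased")
      }
    }
  }
  out[order(vapply(out, `[[`, numeric(1), "T_fus"))]
}

#' Extract a mass-loss fraction from a TGA trace
#'
#' The fraction of the initial sample mass lost between two plateau
#' temperatures: `(mass at T1 - mass at T2) / initial mass`. Plateau masses
#' are averaged over a small temperature window; if the trace is still
#' changing at an endpoint a warning is issued and the windowed mean is
#' used regardless.
#'
#' @param trace data frame with `temperature_C` (monotone increasing) and
#'   `signal` (sample mass, mg).
#' @param range numeric `c(T1, T2)` bracketing the step(s), degrees Celsius.
#' @param window half-width of the plateau averaging window, K.
#' @return mass-loss fraction (dimensionless).
#' @export
extract_mass_loss <- function(trace, range, window = 2) {
  temp <- trace$temperature_C
  mass <- trace$signal
  if (any(diff(temp) <= 0)) stop("temperature axis must increase monotonely")
  if (any(mass <= 0)) stop("sample mass must stay positive")
  if (length(range) != 2L || range[1L] >= range[2L]) {
    stop("range must be c(T1, T2) with T1 < T2")
  }
  plateau_mass <- function(T0) {
    sel <- abs(temp - T0) <= window
    if (!any(sel)) {
      sel <- which.min(abs(temp - T0))
      warning(sprintf("no trace points within %g K of %g C; using nearest",
                      window, T0))
    }
    m <- mass[sel]
    t <- temp[sel]
    if (length(m) >= 3L) {
      drift <- abs(stats::coef(stats::lm.fit(cbind(1, t), m))[2L]) *
        (2 * window)
      if (drift > 0.005 * mass[1L]) {
        warning(sprintf(
          "trace is not flat around %g C; using windowed mean anyway", T0
        ))
      }
    }
    mean(m)
  }
  m0 <- mean(mass[seq_len(min(10L, length(mass)))])
  (plateau_mass(range[1L]) - plateau_mass(range[2L])) / m0
}
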