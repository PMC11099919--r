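## Relaxed-scan potential energy surface grids over two dihedral angles.

#' Construct a dihedral-scan potential energy surface grid
#'
#' Holds a conformational energy surface scanned over two dihedral angles on
#' uniform grids (degrees, on \[0, 360)). Energies are stored relative to the
#' grid minimum in kJ/mol; both axes are treated as periodic with period
#' 360 degrees.
#'
#' @param phi1 numeric vector of first-dihedral grid values (degrees),
#'   uniformly spaced.
#' @param phi2 numeric vector of second-dihedral grid values (degrees),
#'   uniformly spaced.
#' @param energies numeric matrix, `length(phi1)` x `length(phi2)`, kJ/mol.
#'   Shifted so that the minimum is zero.
#' @return an object of class `pes_grid`.
#' @examples
#' g <- pes_grid(seq(0, 330, 30), seq(0, 330, 30),
#'               matrix(runif(144), 12, 12))
#' @export
pes_grid <- function(phi1, phi2, energies) {
  energies <- as.matrix(energies)
  .check_uniform <- function(v, nm) {
    if (length(v) < 2L) stop(nm, " grid needs at least 2 values")
    d <- diff(v)
    if (max(abs(d - d[1L])) > 1e-8) stop(nm, " grid is not uniform")
    d[1L]
  }
  .check_uniform(phi1, "phi1")
  .check_uniform(phi2, "phi2")
  if (nrow(energies) != length(phi1) || ncol(energies) != length(phi2)) {
    stop("energies must be length(phi1) x length(phi2)")
  }
  if (!all(is.finite(energies))) stop("non-finite energies")
  energies <- energies - min(energies)
  structure(
    list(phi1 = phi1 %% 360, phi2 = phi2 %% 360, energies = energies),
    class = "pes_grid"
  )
}

#' @export
print.pes_grid <- function(x, ...) {
  cat(sprintf(
    "<PES grid: %d x %d nodes, step %g x %g deg, max %.2f kJ/mol>\n",
    length(x$phi1), length(x$phi2),
    diff(x$phi1[1:2]), diff(x$phi2[1:2]), max(x$energies)
  ))
  invisible(x)
}

#' Read a PES grid from CSV
#'
#' Expects columns `phi1`, `phi2`, `energy_kjmol` covering a complete
#' rectangular grid.
#'
#' @param path CSV file path.
#' @return a [pes_grid] object.
#' @export
read_pes_grid <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("phi1", "phi2", "energy_kjmol")
  if (!all(need %in% names(df))) {
    stop("PES CSV must have columns: ", paste(need, collapse = ", "))
  }
  p1 <- sort(unique(df$phi1))
  p2 <- sort(unique(df$phi2))
  if (nrow(df) != length(p1) * length(p2)) {
    stop("PES CSV does not cover a complete rectangular grid")
  }
  e <- matrix(NA_real_, length(p1), length(p2))
  e[cbind(match(df$phi1, p1), match(df$phi2, p2))] <- df$energy_kjmol
  pes_grid(p1, p2, e)
}

#' Locate strict local minima on a periodic PES grid
#'
#' A grid node is a strict local minimum when its energy is strictly below
#' all 8 neighbours, with periodic wrap-around on both dihedral axes.
#' Plateau nodes (equal to the lowest neighbour) are not reported; if any
#' exist a warning is issued.
#'
#' @param grid a [pes_grid] object.
#' @return a data frame with columns `phi1`, `phi2`, `energy` (kJ/mol),
#'   sorted by increasing energy.
#' @examples
#' e <- matrix(5, 12, 12); e[9, 10] <- 0
#' locate_pes_minima(pes_grid(seq(0, 330, 30), seq(0, 330, 30), e))
#' @export
locate_pes_minima <- function(grid) {
  stopifnot(inherits(grid, "pes_grid"))
  e <- grid$energies
  n1 <- nrow(e)
  n2 <- ncol(e)
  wrap <- function(i, n) ((i - 1L) %% n) + 1L
  lowest_nb <- matrix(Inf, n1, n2)
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      nb <- e[wrap(seq_len(n1) + di, n1), wrap(seq_len(n2) + dj, n2),
              drop = FALSE]
      lowest_nb <- pmin(lowest_nb, nb)
    }
  }
  strict <- e < lowest_nb
  plateau <- e == lowest_nb
  if (any(plateau)) {
    warning(sum(plateau), " plateau node(s) found; only strict minima ",
            "are reported")
  }
  idx <- which(strict, arr.ind = TRUE)
  out <- data.frame(
    phi1 = grid$phi1[idx[, 1L]],
    phi2 = grid$phi2[idx[, 2L]],
    energy = e[idx]
  )
  out[order(out$energy, out$phi1, out$phi2), , drop = FALSE]
}
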