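## Molecular-complementarity descriptors for coformer screening:
## dimensions of the principal-axis box enclosing the van der Waals volume,
## plus two polarity descriptors (dipole moment, fraction of N/O atoms).
## A pair of molecules passes when every enabled descriptor difference
## falls inside its configured band.

# Deterministic low-discrepancy point set on the unit sphere (Fibonacci
# lattice). Reproducible, near-uniform; adequate for peak-to-peak extents.
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (sqrt(5) - 1) * seq_len(n)   # golden-angle increments
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Van der Waals bounding-box shape descriptors
#'
#' Samples points on every atom's van der Waals sphere with a deterministic
#' Fibonacci lattice, takes principal axes from the covariance of the point
#' cloud, and measures the peak-to-peak extent of the cloud along each axis.
#' The sorted extents S <= M <= L describe the box enclosing the molecular
#' van der Waals volume in its principal orientation; they are rotation and
#' translation invariant to within the sampling tolerance (about 0.02 A at
#' the default density).
#'
#' Because the axes re-orient as atoms are added, the sorted extents of a
#' grown molecule are not guaranteed to dominate those of the original
#' element-wise; along any fixed set of axes (argument `axes`) the extents
#' are monotone in the atom set.
#'
#' @param molecule a [molecule] object.
#' @param surface_samples_per_atom points sampled per atom sphere (>= 50).
#' @param axes optional 3 x 3 orthonormal matrix (columns = axes). When
#'   given, extents are measured along these axes instead of the cloud's
#'   own principal axes, and they are returned unsorted in axis order.
#' @return an object of class `shape_descriptors`: list with `S`, `M`, `L`
#'   (angstrom), `S_over_L`, `M_over_L`, `extents` (in axis order) and
#'   `axes`.
#' @examples
#' ch <- molecule("C", matrix(0, 1, 3))
#' vdw_box(ch)  # S = M = L = 3.4 (sphere diameter)
#' @export
vdw_box <- function(molecule, surface_samples_per_atom = 400L,
                    axes = NULL) {
  stopifnot(inherits(molecule, "coform_molecule"))
  if (surface_samples_per_atom < 50L) {
    stop("surface_samples_per_atom must be at least 50")
  }
  xyz <- .coords(molecule)
  r <- molecule$atoms$vdw_radius
  sph <- .fibonacci_sphere(as.integer(surface_samples_per_atom))
  pts <- do.call(rbind, lapply(seq_len(nrow(xyz)), function(i) {
    sweep(sph * r[i], 2L, xyz[i, ], "+")
  }))
  ctr <- colMeans(pts)
  pc <- sweep(pts, 2L, ctr)
  if (is.null(axes)) {
    axes <- eigen(crossprod(pc) / nrow(pc), symmetric = TRUE)$vectors
  } else {
    axes <- as.matrix(axes)
    if (!isTRUE(all.equal(crossprod(axes), diag(3), tolerance = 1e-8))) {
      stop("axes must be a 3 x 3 orthonormal matrix")
    }
  }
  extents <- apply(pc %*% axes, 2L, function(v) diff(range(v)))
  ext <- sort(extents)
  structure(
    list(S = ext[1L], M = ext[2L], L = ext[3L],
         S_over_L = ext[1L] / ext[3L], M_over_L = ext[2L] / ext[3L],
         extents = extents, axes = axes),
    class = "shape_descriptors"
  )
}

#' @export
print.shape_descriptors <- function(x, ...) {
  cat(sprintf(
    "<vdW box: S %.2f, M %.2f, L %.2f A; S/L %.3f, M/L %.3f>\n",
    x$S, x$M, x$L, x$S_over_L, x$M_over_L
  ))
  invisible(x)
}

#' Polarity descriptors
#'
#' Bundles the two polarity descriptors used in complementarity screening:
#' the molecular dipole moment and the fraction of N and O atoms. The
#' dipole is taken from the molecule if stored, computed from partial
#' charges when available, and may be supplied directly.
#'
#' @param molecule a [molecule] object.
#' @param dipole optional dipole moment (debye) overriding the molecule's.
#' @param heavy_only passed to [fraction_NO()].
#' @return an object of class `polarity_descriptors`: list with `dipole`
#'   (debye) and `fno`.
#' @export
polarity_descriptors <- function(molecule, dipole = NULL,
                                 heavy_only = FALSE) {
  stopifnot(inherits(molecule, "coform_molecule"))
  if (is.null(dipole)) dipole <- molecule$dipole_moment
  if (is.null(dipole)) {
    if (anyNA(molecule$atoms$charge)) {
      stop("no dipole available: store dipole_moment on the molecule, ",
           "supply `dipole`, or provide partial charges")
    }
    dipole <- dipole_from_charges(molecule)
  }
  if (dipole < 0) stop("dipole moment must be >= 0")
  structure(
    list(dipole = dipole, fno = fraction_NO(molecule, heavy_only)),
    class = "polarity_descriptors"
  )
}

#' Default complementarity threshold bands
#'
#' Literature-style default bands on the absolute API-coformer descriptor
#' differences: `dS_over_L` and `dM_over_L` (box-ratio differences),
#' `dS` (short-axis difference, angstrom), `ddipole` (debye) and `dfno`
#' (N/O-fraction difference). These defaults are editable conventions, not
#' fitted values; any screening study should review them against its own
#' reference set (see [mc_thresholds_yaml()]).
#'
#' @return named list of `c(lower, upper)` bands.
#' @export
mc_default_thresholds <- function() {
  list(
    dS_over_L = c(0, 0.28),
    dM_over_L = c(0, 0.30),
    dS = c(0, 2.2),
    ddipole = c(0, 7.0),
    dfno = c(0, 0.11)
  )
}

#' Read / write complementarity thresholds as YAML
#'
#' The YAML maps each enabled descriptor to a two-element `[lower, upper]`
#' band on the absolute difference.
#'
#' @param path YAML file path.
#' @param thresholds named list of bands (see [mc_default_thresholds()]).
#' @return `read_mc_thresholds()` returns the named list of bands;
#'   `mc_thresholds_yaml()` writes and returns `path` invisibly.
#' @export
read_mc_thresholds <- function(path) {
  x <- yaml::read_yaml(path)
  lapply(x, function(b) {
    b <- as.numeric(unlist(b))
    if (length(b) != 2L || b[1L] > b[2L]) {
      stop("each threshold band must be [lower, upper]")
    }
    b
  })
}

#' @rdname read_mc_thresholds
#' @export
mc_thresholds_yaml <- function(thresholds = mc_default_thresholds(), path) {
  yaml::write_yaml(lapply(thresholds, as.numeric), path)
  invisible(path)
}

#' Molecular-complementarity pass/fail screen
#'
#' Compares API and coformer shape and polarity descriptors. For each
#' enabled descriptor the absolute difference is tested against its
#' configured `[lower, upper]` band; the pair passes overall only if every
#' enabled descriptor passes. Descriptors are symmetric in the two
#' molecules.
#'
#' @param api_shape,cof_shape [vdw_box()] results.
#' @param api_pol,cof_pol [polarity_descriptors()] results.
#' @param thresholds named list of bands; see [mc_default_thresholds()].
#'   Only descriptors named here are evaluated.
#' @return an object of class `mc_verdict`: data frame `per_descriptor`
#'   (`descriptor`, `difference`, `lower`, `upper`, `pass`) plus an
#'   `overall` attribute-style field.
#' @examples
#' m <- molecule(c("C", "O"), rbind(c(0, 0, 0), c(1.2, 0, 0)),
#'               dipole_moment = 2)
#' s <- vdw_box(m); p <- polarity_descriptors(m, dipole = 2)
#' mc_screen(s, p, s, p)$overall  # identical molecules pass
#' @export
mc_screen <- function(api_shape, api_pol, cof_shape, cof_pol,
                      thresholds = mc_default_thresholds()) {
  stopifnot(inherits(api_shape, "shape_descriptors"),
            inherits(cof_shape, "shape_descriptors"),
            inherits(api_pol, "polarity_descriptors"),
            inherits(cof_pol, "polarity_descriptors"))
  diffs <- c(
    dS_over_L = abs(api_shape$S_over_L - cof_shape$S_over_L),
    dM_over_L = abs(api_shape$M_over_L - cof_shape$M_over_L),
    dS = abs(api_shape$S - cof_shape$S),
    ddipole = abs(api_pol$dipole - cof_pol$dipole),
    dfno = abs(api_pol$fno - cof_pol$fno)
  )
  enabled <- names(thresholds)
  unknown <- setdiff(enabled, names(diffs))
  if (length(unknown) > 0L) {
    stop("unknown descriptor(s) in threshold config: ",
         paste(unknown, collapse = ", "))
  }
  bad <- vapply(thresholds, function(b) length(b) != 2L, logical(1))
  if (any(bad)) {
    stop("threshold config must give a [lower, upper] band for: ",
         paste(enabled[bad], collapse = ", "))
  }
  per <- data.frame(
    descriptor = enabled,
    difference = unname(diffs[enabled]),
    lower = vapply(thresholds, `[`, numeric(1), 1L),
    upper = vapply(thresholds, `[`, numeric(1), 2L),
    stringsAsFactors = FALSE
  )
  per$pass <- per$difference >= per$lower & per$difference <= per$upper
  structure(
    list(per_descriptor = per, overall = all(per$pass)),
    class = "mc_verdict"
  )
}

#' @export
print.mc_verdict <- function(x, ...) {
  cat(sprintf("<complementarity verdict: %s>\n",
              if (x$overall) "PASS" else "FAIL"))
  p <- x$per_descriptor
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-10s |diff| = %8.4f  band [%g, %g]  %s\n",
                p$descriptor[i], p$difference[i], p$lower[i], p$upper[i],
                if (p$pass[i]) "pass" else "FAIL"))
  }
  invisible(x)
}
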