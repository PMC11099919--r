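## Molecular geometry container and I/O (XYZ, SDF V2000).

#' Construct a molecule
#'
#' A molecule is an ordered collection of atoms with Cartesian coordinates in
#' angstrom. Van der Waals radii are filled from the internal Bondi table.
#' Partial atomic charges (elementary charge units) are optional, but if any
#' atom carries one, all must, and they must sum to the net charge.
#'
#' @param element character vector of element symbols.
#' @param xyz numeric matrix (n x 3) of Cartesian coordinates, angstrom.
#' @param name molecule label.
#' @param net_charge integer net molecular charge.
#' @param charge optional numeric vector of partial charges, e.
#' @param conformer conformer label.
#' @param dipole_moment optional dipole moment in debye; if `NULL` and
#'   partial charges are present it can be computed with
#'   [dipole_from_charges()].
#' @param radii optional named numeric vector overriding van der Waals radii.
#' @return an object of class `coform_molecule`: a list with elements
#'   `name`, `atoms` (data frame: `element`, `x`, `y`, `z`, `charge`,
#'   `vdw_radius`), `net_charge`, `conformer`, `dipole_moment`, `comment`.
#' @examples
#' water <- molecule(
#'   element = c("O", "H", "H"),
#'   xyz = rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0))
#' )
#' molar_mass(water)
#' @export
molecule <- function(element, xyz, name = "molecule", net_charge = 0L,
                     charge = NULL, conformer = "conf-1",
                     dipole_moment = NULL, radii = NULL) {
  xyz <- as.matrix(xyz)
  if (length(element) < 1L) stop("a molecule needs at least one atom")
  if (nrow(xyz) != length(element) || ncol(xyz) != 3L) {
    stop("xyz must be an n x 3 matrix matching length(element)")
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (!is.null(charge)) {
    if (length(charge) != length(element)) {
      stop("charge must have one value per atom")
    }
    if (abs(sum(charge) - net_charge) > 1e-6) {
      stop(sprintf(
        "partial charges sum to %.6f but net_charge is %d",
        sum(charge), as.integer(net_charge)
      ))
    }
  }
  atoms <- data.frame(
    element = as.character(element),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = if (is.null(charge)) NA_real_ else charge,
    vdw_radius = vdw_radius(element, override = radii),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      name = name, atoms = atoms, net_charge = as.integer(net_charge),
      conformer = conformer, dipole_moment = dipole_moment, comment = ""
    ),
    class = "coform_molecule"
  )
}

#' @export
print.coform_molecule <- function(x, ...) {
  cat(sprintf(
    "<molecule '%s' (%s): %d atoms, formula %s, net charge %+d>\n",
    x$name, x$conformer, nrow(x$atoms), molecular_formula(x), x$net_charge
  ))
  invisible(x)
}

#' Hill-order molecular formula
#'
#' @param molecule a [molecule] object.
#' @return a character scalar such as `"C15H10O2"`.
#' @export
molecular_formula <- function(molecule) {
  stopifnot(inherits(molecule, "coform_molecule"))
  counts <- table(molecule$atoms$element)
  elems <- names(counts)
  hill <- c(
    intersect(c("C", "H"), elems),
    sort(setdiff(elems, c("C", "H")))
  )
  paste0(hill, ifelse(counts[hill] > 1L, counts[hill], ""), collapse = "")
}

.coords <- function(molecule) {
  as.matrix(molecule$atoms[, c("x", "y", "z")])
}

#' Read a molecular geometry file
#'
#' Supports plain XYZ (comment line preserved) and SDF/MOL V2000 (the
#' `M  CHG` block is parsed into partial charges and the net charge; the data
#' items block is ignored). Van der Waals radii are filled from the internal
#' Bondi table.
#'
#' @param path path to the file.
#' @param format `"xyz"` or `"sdf"`; the default guesses from the file
#'   extension.
#' @return a [molecule] object.
#' @seealso [write_geometry()]
#' @export
read_geometry <- function(path, format = c("auto", "xyz", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      xyz = "xyz", sdf = "sdf", mol = "sdf",
      stop("cannot guess format from extension '", ext,
           "'; pass format explicitly")
    )
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "xyz") .read_xyz(lines, path) else .read_sdf(lines, path)
}

.parse_error <- function(path, line, msg) {
  stop(sprintf("%s: line %d: %s", path, line, msg), call. = FALSE)
}

.read_xyz <- function(lines, path) {
  if (length(lines) < 3L) .parse_error(path, length(lines), "truncated XYZ")
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) .parse_error(path, 1L, "invalid atom count")
  if (length(lines) < n + 2L) {
    .parse_error(path, length(lines), sprintf("expected %d atom lines", n))
  }
  comment <- lines[2L]
  elem <- character(n)
  xyz <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(tok) < 4L) .parse_error(path, ln, "need 'El x y z'")
    coords <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(coords)) .parse_error(path, ln, "non-numeric coordinate")
    elem[i] <- tok[1L]
    xyz[i, ] <- coords
  }
  if (any(!elem %in% names(.bondi_radii))) {
    bad <- which(!elem %in% names(.bondi_radii))[1L]
    .parse_error(path, bad + 2L, paste0("unknown element symbol '",
                                        elem[bad], "'"))
  }
  mol <- molecule(elem, xyz,
                  name = tools::file_path_sans_ext(basename(path)))
  mol$comment <- comment
  mol
}

.read_sdf <- function(lines, path) {
  if (length(lines) < 4L) .parse_error(path, length(lines), "truncated SDF")
  counts <- lines[4L]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  if (is.na(n_atoms) || n_atoms < 1L) {
    .parse_error(path, 4L, "invalid atom count in counts line")
  }
  if (!grepl("V2000", counts)) {
    .parse_error(path, 4L, "only V2000 connection tables are supported")
  }
  if (length(lines) < 4L + n_atoms) {
    .parse_error(path, length(lines), "truncated atom block")
  }
  elem <- character(n_atoms)
  xyz <- matrix(NA_real_, n_atoms, 3L)
  for (i in seq_len(n_atoms)) {
    ln <- 4L + i
    l <- lines[ln]
    coords <- suppressWarnings(as.numeric(c(
      substr(l, 1L, 10L), substr(l, 11L, 20L), substr(l, 21L, 30L)
    )))
    if (anyNA(coords)) .parse_error(path, ln, "non-numeric coordinate")
    sym <- trimws(substr(l, 32L, 34L))
    if (!nzchar(sym)) .parse_error(path, ln, "missing element symbol")
    elem[i] <- sym
    xyz[i, ] <- coords
  }
  if (any(!elem %in% names(.bondi_radii))) {
    bad <- which(!elem %in% names(.bondi_radii))[1L]
    .parse_error(path, bad + 4L, paste0("unknown element symbol '",
                                        elem[bad], "'"))
  }
  # M  CHG blocks override any charge column codes (V2000 semantics)
  chg <- integer(n_atoms)
  has_chg <- FALSE
  for (l in grep("^M  CHG", lines, value = TRUE)) {
    tok <- strsplit(trimws(l), "\\s+")[[1L]]
    k <- as.integer(tok[3L])
    vals <- as.integer(tok[-(1:3)])
    if (length(vals) != 2L * k) {
      .parse_error(path, which(lines == l)[1L], "malformed M  CHG record")
    }
    idx <- vals[seq(1L, 2L * k, by = 2L)]
    chg[idx] <- vals[seq(2L, 2L * k, by = 2L)]
    has_chg <- TRUE
  }
  name <- trimws(lines[1L])
  if (!nzchar(name)) name <- tools::file_path_sans_ext(basename(path))
  mol <- molecule(elem, xyz, name = name, net_charge = sum(chg),
                  charge = if (has_chg) as.numeric(chg) else NULL)
  mol
}

#' Write a molecular geometry file
#'
#' Writes plain XYZ (the stored comment line is preserved) or SDF V2000
#' (partial integer charges, if present, are emitted as an `M  CHG` block; no
#' bond block is written).
#'
#' @param molecule a [molecule] object.
#' @param path output path.
#' @param format `"xyz"` or `"sdf"`; the default guesses from the extension.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(molecule, path, format = c("auto", "xyz", "sdf")) {
  stopifnot(inherits(molecule, "coform_molecule"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, xyz = "xyz", sdf = "sdf", mol = "sdf",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  a <- molecule$atoms
  if (format == "xyz") {
    lines <- c(
      as.character(nrow(a)),
      molecule$comment,
      sprintf("%-3s %14.6f %14.6f %14.6f", a$element, a$x, a$y, a$z)
    )
  } else {
    header <- c(molecule$name, "  coform", "")
    counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), 0L)
    atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                     a$x, a$y, a$z, a$element)
    chg_lines <- character(0)
    if (!anyNA(a$charge) && any(a$charge != 0)) {
      nz <- which(a$charge != 0)
      if (any(abs(a$charge[nz] - round(a$charge[nz])) > 1e-9)) {
        warning("non-integer partial charges cannot be stored in SDF; ",
                "M  CHG block omitted")
      } else {
        chunks <- split(nz, ceiling(seq_along(nz) / 8L))
        chg_lines <- vapply(chunks, function(ix) {
          paste0("M  CHG", sprintf("%3d", length(ix)),
                 paste0(sprintf("%4d%4d", ix, round(a$charge[ix])),
                        collapse = ""))
        }, character(1))
      }
    }
    lines <- c(header, counts, atoms, chg_lines, "M  END", "$$$$")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Fraction of nitrogen and oxygen atoms
#'
#' The proportion of N and O atoms in a molecule, one of the polarity
#' descriptors used in molecular-complementarity coformer screening. By
#' convention the denominator includes hydrogens; set `heavy_only = TRUE`
#' to count heavy atoms only.
#'
#' @param molecule a [molecule] object.
#' @param heavy_only if `TRUE`, exclude hydrogen from the denominator.
#' @return a fraction in \[0, 1\].
#' @examples
#' fl <- molecule(rep(c("C", "H", "O"), c(15, 10, 2)), matrix(0, 27, 3))
#' fraction_NO(fl)           # 2/27
#' fraction_NO(fl, TRUE)     # 2/17
#' @export
fraction_NO <- function(molecule, heavy_only = FALSE) {
  stopifnot(inherits(molecule, "coform_molecule"))
  el <- molecule$atoms$element
  denom <- if (heavy_only) sum(el != "H") else length(el)
  if (denom == 0L) stop("no atoms in denominator")
  sum(el %in% c("N", "O")) / denom
}

# 1 e*angstrom = 4.80320471 debye (e / (1e-21/c) esu*cm conversion)
.DEBYE_PER_E_ANGSTROM <- 4.80320471

#' Dipole moment from partial charges
#'
#' Magnitude of the point-charge dipole sum(q_i r_i), converted from
#' e*angstrom to debye. For a neutral molecule the result is independent of
#' the coordinate origin; for an ion it is origin-dependent and a warning is
#' issued.
#'
#' @param molecule a [molecule] object whose atoms all carry partial charges.
#' @return dipole moment in debye.
#' @examples
#' hf <- molecule(c("H", "F"), rbind(c(0, 0, 0), c(1, 0, 0)),
#'                charge = c(0.5, -0.5))
#' dipole_from_charges(hf)  # 0.5 e*A = 2.40 D
#' @export
dipole_from_charges <- function(molecule) {
  stopifnot(inherits(molecule, "coform_molecule"))
  q <- molecule$atoms$charge
  if (anyNA(q)) {
    stop("all atoms must carry partial charges; supply dipole_moment ",
         "directly when charges are unavailable")
  }
  if (molecule$net_charge != 0L) {
    warning("molecule is charged; dipole moment is origin-dependent")
  }
  mu <- colSums(q * .coords(molecule))
  sqrt(sum(mu^2)) * .DEBYE_PER_E_ANGSTROM
}
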