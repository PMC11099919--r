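# Shared helpers: small geometries and random orthogonal matrices.

# Water with a realistic geometry (angstrom).
make_water <- function(...) {
  molecule(
    element = c("O", "H", "H"),
    xyz = rbind(c(0, 0, 0.1173),
                c(0, 0.7572, -0.4692),
                c(0, -0.7572, -0.4692)),
    name = "water", ...
  )
}

# A bent 8-atom chain, asymmetric enough to have distinct box extents.
make_chain <- function() {
  molecule(
    element = c("C", "C", "C", "N", "O", "H", "H", "H"),
    xyz = rbind(
      c(0, 0, 0), c(1.5, 0, 0), c(3.0, 0.4, 0), c(4.3, 1.0, 0.3),
      c(-1.1, 0.6, 0.4), c(0.2, -1.0, 0.3), c(1.4, 0.9, -0.6),
      c(3.1, -0.5, 0.9)
    ),
    name = "chain"
  )
}

# Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_molecule <- function(mol, R, shift = c(0, 0, 0)) {
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, shift, "+")
  molecule(mol$atoms$element, xyz, name = mol$name,
           net_charge = mol$net_charge,
           charge = if (anyNA(mol$atoms$charge)) NULL else mol$atoms$charge)
}

# Printed melting data for the solid forms discussed throughout the tests.
sg_fl_form_I <- function() fusion_datum("I_CC", 171.3, 52.0, 0.1, 0.3)
sg_fl_form_II <- function() fusion_datum("II_CC", 174.6, 47.5, 0.1, 0.1)
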