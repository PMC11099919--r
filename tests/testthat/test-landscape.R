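# Crystal-energy-landscape post-processing.

ref_api <- function() component_reference("API", -130)
ref_fl <- function() component_reference("FL", -100)

make_structures <- function(E_latt, m = 1L, n = 1L) {
  k <- length(E_latt)
  data.frame(
    label = sprintf("s%02d", seq_len(k)),
    space_group = "P21/c", z_prime = 1,
    E_latt = E_latt, density = 1.4, dE_intra = 0,
    m = m, n = n, stringsAsFactors = FALSE
  )
}

test_that("formation energy is the lattice energy minus component sums", {
  expect_equal(formation_energy(-230, 1, 1, ref_api(), ref_fl()), 0)
  # a structure built 13 kJ/mol below its components
  expect_equal(formation_energy(-243, 1, 1, ref_api(), ref_fl()), -13)
  expect_equal(formation_energy(-345, 1, 2, ref_api(), ref_fl()), -15)
  expect_error(formation_energy(-243, 1, 1), "required")
})

test_that("formation energies match a row-by-row spreadsheet recomputation", {
  set.seed(21)
  E <- -230 + runif(25, -15, 20)
  m <- sample(1:2, 25, replace = TRUE)
  n <- sample(1:2, 25, replace = TRUE)
  got <- formation_energy(E, m, n, ref_api(), ref_fl())
  byhand <- vapply(seq_along(E), function(i) {
    E[i] - (m[i] * -130 + n[i] * -100)
  }, numeric(1))
  expect_equal(got, byhand)
})

test_that("the feasible set honours the strict cutoff and sorts ascending", {
  ls <- energy_landscape(
    make_structures(c(-243, -235.2, -228, -230, -231)),
    ref_api(), ref_fl()
  )
  fs <- feasible_set(ls)
  expect_equal(fs$count, 3L)
  expect_equal(fs$subset$label, c("s01", "s02", "s05"))
  expect_equal(fs$best_dE_form, -13)
  expect_equal(fs$margin_12, 13 - 5.2)
  expect_equal(fs$marginal, "s04")

  empty <- feasible_set(energy_landscape(make_structures(c(-220, -210)),
                                         ref_api(), ref_fl()))
  expect_equal(empty$count, 0L)
  expect_true(is.na(empty$margin_12))
})

test_that("feasible count never grows when references stabilize", {
  set.seed(31)
  st <- make_structures(-230 + runif(40, -12, 12))
  for (shift in c(0, 2, 5, 9)) {
    a <- feasible_set(energy_landscape(st,
                                       component_reference("API", -130 - shift),
                                       ref_fl()))
    b <- feasible_set(energy_landscape(st, ref_api(), ref_fl()))
    expect_lte(a$count, b$count)
  }
})

test_that("stoichiometry correction reproduces relative stability tables", {
  fl <- ref_fl()
  s11 <- stoichiometry(1, 1)
  s12 <- stoichiometry(1, 2)
  expect_equal(stoichiometry_normalize(-250, s11, s11, fl), -250)
  expect_equal(stoichiometry_normalize(-350, s12, s11, fl), -250)
  expect_error(
    stoichiometry_normalize(-350, stoichiometry(2, 1), s11, fl),
    "API counts differ"
  )

  # three cocrystals on a common 1:1 basis, independent arithmetic oracle
  E <- c(A = -232, B = -236, D = -344)
  stoich <- list(A = s11, B = s11, D = s12)
  got <- vapply(names(E), function(k) {
    stoichiometry_normalize(E[[k]], stoich[[k]], s11, fl)
  }, numeric(1))
  byhand <- c(A = -232, B = -236, D = -344 - (2 - 1) * (-100))
  expect_equal(got, byhand)
  expect_equal(names(sort(got - got["D"])), c("D", "B", "A"))
})

test_that("normalize-then-form equals form at the original stoichiometry", {
  set.seed(4)
  for (i in 1:10) {
    E <- -330 + runif(1, -10, 10)
    s <- stoichiometry(1, sample(2:3, 1))
    t <- stoichiometry(1, 1)
    direct <- formation_energy(E, s[["m"]], s[["n"]], ref_api(), ref_fl())
    via <- formation_energy(
      stoichiometry_normalize(E, s, t, ref_fl()), t[["m"]], t[["n"]],
      ref_api(), ref_fl()
    )
    expect_equal(via, direct, tolerance = 1e-12)
  }
})

test_that("landscape tables round-trip through CSV", {
  g <- gen_landscape(17, n_structures = 12, n_feasible = 3, gap_12 = 2.5)
  dir <- withr::local_tempdir()
  write_landscape(g$landscape, dir)
  back <- read_landscape(file.path(dir, "structures.csv"),
                         file.path(dir, "components.csv"))
  expect_equal(back$structures$E_latt, g$landscape$structures$E_latt)
  expect_equal(back$api_ref, g$landscape$api_ref)
  fs <- feasible_set(back)
  expect_equal(fs$count, 3L)
  expect_equal(fs$margin_12, 2.5, tolerance = 1e-9)
})

test_that("pairwise aggregation sums and picks the strongest interaction", {
  one <- data.frame(central = "X", partner = "X", energy = -10)
  a <- aggregate_pairwise(one, "X")
  expect_equal(a$sum_energy, -10)
  expect_equal(a$strongest, -10)

  # guanidine-sulfonamide style central molecule with one repulsive contact
  x <- data.frame(central = "SG", partner = "SG",
                  energy = c(-105.9, -62.5, -59.6, 28.1))
  a <- aggregate_pairwise(x, "SG")
  expect_equal(a$strongest, -105.9)
  expect_equal(a$sum_energy, -199.9)

  expect_error(aggregate_pairwise(one, "Y"), "no interactions")
})

test_that("symmetry-independent central molecules are averaged", {
  x <- data.frame(
    central = "SG",
    partner = rep(c("SG", "FL"), each = 4),
    energy = c(-100, -60, -90, -70, -30, -10, -20, -24),
    central_tag = rep(c("a", "b"), 4)
  )
  a <- aggregate_pairwise(x, "SG")
  # per-tag summaries computed by hand, then averaged
  expect_equal(a$sum_energy[a$partner == "SG"],
               mean(c(-100 - 90, -60 - 70)))
  expect_equal(a$strongest[a$partner == "SG"], mean(c(-100, -70)))
  expect_equal(a$sum_energy[a$partner == "FL"],
               mean(c(-30 - 20, -10 - 24)))
  expect_equal(attr(a, "total"),
               sum(a$sum_energy))
})

test_that("pairwise CSV reader renames the energy column", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(central = "A", partner = "B", energy_kjmol = -5,
                       contact = "N-H...O"), path, row.names = FALSE)
  df <- read_pairwise(path)
  expect_true("energy" %in% names(df))
  expect_equal(aggregate_pairwise(df, "A")$sum_energy, -5)
})
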