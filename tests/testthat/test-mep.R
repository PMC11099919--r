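# MEP-derived site sets, optimal pairing, and the formation energy gain.

test_that("stoichiometries reduce and parse", {
  expect_equal(unclass(stoichiometry(2, 4)), c(m = 1L, n = 2L))
  expect_equal(format(parse_stoichiometry("3:6")), "1:2")
  expect_error(stoichiometry(0, 1), "positive")
})

test_that("site parameters follow the calibration constants", {
  s <- sites_from_extrema(maxima = 52, minima = -104,
                          k_alpha = 1 / 52, k_beta = 1 / 52)
  expect_equal(s$sites$parameter[s$sites$kind == "donor"], 1.0)
  expect_equal(s$sites$parameter[s$sites$kind == "acceptor"], 2.0)
  expect_error(sites_from_extrema(maxima = c(10, -5)), "maxima")
  expect_error(sites_from_extrema(minima = c(-10, 5)), "minima")
  expect_error(sites_from_extrema(), "at least one")
})

test_that("site sets round-trip through JSON", {
  s <- sites_from_extrema(maxima = c(52, 31.5), minima = c(-60, -12),
                          molecule_label = "demo", conformer_label = "c2")
  path <- withr::local_tempfile(fileext = ".json")
  write_site_set(s, path)
  back <- read_site_set(path)
  expect_equal(back$molecule_label, "demo")
  expect_equal(back$conformer_label, "c2")
  expect_equal(back$sites, s$sites)
})

test_that("sorted pairing reproduces hand-worked energies", {
  expect_equal(pairing_energy(2, 3)$energy, -6)
  r <- pairing_energy(c(3, 1), 2)
  expect_equal(r$energy, -6)
  expect_equal(r$unpaired, 1L)
  # best of the two perfect matchings of {3,2} vs {5,1}: 3*5+2*1 = 17
  expect_equal(pairing_energy(c(3, 2), c(5, 1))$energy, -17)
})

test_that("sorted pairing equals the exhaustive-matching maximum", {
  exhaustive <- coform:::.matching_energy_exhaustive
  set.seed(101)
  for (rep in 1:60) {
    a <- runif(sample(0:6, 1), 0, 3)
    b <- runif(sample(0:6, 1), 0, 3)
    if (length(a) + length(b) == 0) next
    expect_equal(pairing_energy(a, b)$energy, exhaustive(a, b),
                 tolerance = 1e-12)
  }
})

test_that("complementary site sets give dE equal to the mixed pairing", {
  api <- sites_from_extrema(maxima = c(40, 20), molecule_label = "api")
  cof <- sites_from_extrema(minima = c(-50, -10), molecule_label = "cof")
  r <- delta_E_MEP(api, cof, stoichiometry(1, 1))
  expect_equal(r$E_API, 0)
  expect_equal(r$E_FL, 0)
  expect_lt(r$E_CC, 0)
  expect_equal(r$delta_E_MEP, r$E_CC)
})

test_that("identical balanced site sets give zero gain at 1:1", {
  s1 <- sites_from_extrema(maxima = c(45, 30), minima = c(-45, -30),
                           molecule_label = "a")
  s2 <- sites_from_extrema(maxima = c(45, 30), minima = c(-45, -30),
                           molecule_label = "b")
  r <- delta_E_MEP(s1, s2, stoichiometry(1, 1))
  # the combined optimal matching decomposes into the two separate ones
  expect_equal(r$delta_E_MEP, 0, tolerance = 1e-12)
})

test_that("dE_MEP matches the exhaustive oracle and stays non-positive", {
  for (seed in 1:25) {
    g <- gen_site_sets(seed, n_donors = 2, n_acceptors = 2,
                       ratios = c("1:1", "1:2", "2:1"))
    for (k in seq_len(nrow(g$oracle))) {
      r <- delta_E_MEP(g$api, g$coformer,
                       parse_stoichiometry(g$oracle$stoichiometry[k]))
      expect_equal(r$delta_E_MEP, g$oracle$delta_E_MEP[k],
                   tolerance = 1e-10)
      expect_lte(r$delta_E_MEP, 1e-9)
    }
  }
})

test_that("dE_MEP is symmetric under swapping the two components", {
  g <- gen_site_sets(5, n_donors = c(3, 1), n_acceptors = c(1, 3))
  r12 <- delta_E_MEP(g$api, g$coformer, stoichiometry(2, 3))
  r21 <- delta_E_MEP(g$coformer, g$api, stoichiometry(3, 2))
  expect_equal(r12$delta_E_MEP, r21$delta_E_MEP, tolerance = 1e-12)
})

test_that("scaling all site parameters by c scales energies by c^2", {
  g <- gen_site_sets(9)
  scale_set <- function(s, c) {
    s$sites$parameter <- s$sites$parameter * c
    s
  }
  r1 <- delta_E_MEP(g$api, g$coformer, stoichiometry(1, 2))
  r2 <- delta_E_MEP(scale_set(g$api, 1.7), scale_set(g$coformer, 1.7),
                    stoichiometry(1, 2))
  expect_equal(r2$delta_E_MEP, 1.7^2 * r1$delta_E_MEP, tolerance = 1e-12)
  expect_equal(r2$E_CC, 1.7^2 * r1$E_CC, tolerance = 1e-12)
})

test_that("stoichiometry screening flags the most negative ratio", {
  # acceptor-rich coformer vs donor-rich API: 1:2 at least as good as 1:1
  api <- sites_from_extrema(maxima = c(50, 42, 35), minima = -8,
                            molecule_label = "api")
  cof <- sites_from_extrema(minima = c(-48, -30), molecule_label = "cof")
  tab <- screen_stoichiometries(api, cof, c("1:1", "1:2", "2:1"))
  expect_equal(nrow(tab), 3L)
  expect_lte(tab$delta_E_MEP[tab$stoichiometry == "1:2"],
             tab$delta_E_MEP[tab$stoichiometry == "1:1"])
  expect_equal(sum(tab$preferred), 1L)
  expect_equal(tab$delta_E_MEP,
               tab$E_CC - (as.integer(sub(":.*", "", tab$stoichiometry)) *
                             tab$E_API +
                           as.integer(sub(".*:", "", tab$stoichiometry)) *
                             tab$E_FL))

  expect_error(screen_stoichiometries(api, cof, list()), "empty")
  expect_warning(screen_stoichiometries(api, cof, c("1:1", "2:2")),
                 "duplicate")
})
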