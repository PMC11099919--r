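# DSC peak extraction and TGA mass-loss extraction, against generator
# ground truth.

test_that("a noise-free endotherm is recovered within 0.2 K and 1%", {
  g <- gen_dsc_trace(1, data.frame(T_fus_C = 171.3, H_fus_kjmol = 52.0),
                     noise_sigma = 0)
  ev <- extract_fusion_data(g$trace, g$sample_mass_mg, g$molar_mass,
                            g$heating_rate)
  expect_length(ev, 1L)
  expect_equal(kelvin_to_celsius(ev[[1]]$T_fus), 171.3, tolerance = 0.2)
  expect_equal(ev[[1]]$H_fus, 52.0, tolerance = 52.0 * 0.01)
})

test_that("a flat trace yields no events", {
  g <- gen_dsc_trace(1, data.frame(T_fus_C = numeric(0),
                                   H_fus_kjmol = numeric(0)))
  expect_length(extract_fusion_data(g$trace, 3, 470.54), 0L)
  # flat but noisy: the noise floor must not spawn spurious peaks
  gn <- gen_dsc_trace(2, data.frame(T_fus_C = numeric(0),
                                    H_fus_kjmol = numeric(0)),
                      noise_sigma = 0.01)
  expect_length(extract_fusion_data(gn$trace, 3, 470.54), 0L)
})

test_that("two separated peaks come back in temperature order", {
  g <- gen_dsc_trace(3, data.frame(T_fus_C = c(96.5, 171.3),
                                   H_fus_kjmol = c(21.1, 52.0)),
                     noise_sigma = 0)
  ev <- extract_fusion_data(g$trace, g$sample_mass_mg, g$molar_mass,
                            g$heating_rate)
  expect_length(ev, 2L)
  expect_equal(kelvin_to_celsius(ev[[1]]$T_fus), 96.5, tolerance = 0.3)
  expect_equal(kelvin_to_celsius(ev[[2]]$T_fus), 171.3, tolerance = 0.3)
  expect_equal(ev[[1]]$H_fus, 21.1, tolerance = 21.1 * 0.02)
  expect_equal(ev[[2]]$H_fus, 52.0, tolerance = 52.0 * 0.02)
})

test_that("generator rejects unordered or overlapping events", {
  expect_error(gen_dsc_trace(1, data.frame(T_fus_C = c(170, 100),
                                           H_fus_kjmol = c(10, 10))),
               "increasing")
  expect_error(gen_dsc_trace(1, data.frame(T_fus_C = c(100, 103),
                                           H_fus_kjmol = c(10, 10))),
               "5 K")
  expect_error(gen_dsc_trace(1, data.frame(T_fus_C = 100,
                                           H_fus_kjmol = -1)),
               "> 0")
})

test_that("DSC traces and generators are seed-deterministic", {
  ev <- data.frame(T_fus_C = 120, H_fus_kjmol = 30)
  a <- gen_dsc_trace(7, ev, noise_sigma = 0.01)
  b <- gen_dsc_trace(7, ev, noise_sigma = 0.01)
  c <- gen_dsc_trace(8, ev, noise_sigma = 0.01)
  expect_identical(a$trace, b$trace)
  expect_false(identical(a$trace, c$trace))
})

test_that("median enthalpy error stays below 3% at 1% noise", {
  errs <- vapply(1:100, function(seed) {
    g <- gen_dsc_trace(seed, data.frame(T_fus_C = 171.3,
                                        H_fus_kjmol = 52.0),
                       noise_sigma = 0.01)
    ev <- extract_fusion_data(g$trace, g$sample_mass_mg, g$molar_mass,
                              g$heating_rate)
    if (length(ev) != 1L) return(NA_real_)
    abs(ev[[1]]$H_fus - 52.0) / 52.0
  }, numeric(1))
  expect_true(all(is.finite(errs)))
  expect_lt(median(errs), 0.03)
})

test_that("a programmed single TGA step is recovered within 0.002", {
  g <- gen_tga_trace(1, data.frame(T_mid_C = 120, fraction = 0.131),
                     noise_sigma = 0.001)
  w <- extract_mass_loss(g$trace, c(97, 143))
  expect_equal(w, 0.131, tolerance = 0.002 / 0.131)
})

test_that("a constant-mass trace gives zero loss", {
  g <- gen_tga_trace(1, data.frame(T_mid_C = numeric(0),
                                   fraction = numeric(0)))
  expect_equal(extract_mass_loss(g$trace, c(50, 200)), 0)
})

test_that("a range spanning two steps returns their sum", {
  g <- gen_tga_trace(2, data.frame(T_mid_C = c(90, 160),
                                   fraction = c(0.05, 0.08)),
                     noise_sigma = 0)
  w <- extract_mass_loss(g$trace, c(67, 183))
  expect_equal(w, 0.13, tolerance = 1e-3)
  # and the two individual plateaus separate them
  w1 <- extract_mass_loss(g$trace, c(67, 125))
  expect_equal(w1, 0.05, tolerance = 1e-3)
})

test_that("non-plateau endpoints trigger a warning with a usable fallback", {
  g <- gen_tga_trace(3, data.frame(T_mid_C = 120, fraction = 0.2))
  expect_warning(extract_mass_loss(g$trace, c(118, 145)), "not flat")
})

test_that("generator rejects impossible step specifications", {
  expect_error(gen_tga_trace(1, data.frame(T_mid_C = c(100, 104),
                                           fraction = c(0.1, 0.1))),
               "overlap")
  expect_error(gen_tga_trace(1, data.frame(T_mid_C = c(100, 150),
                                           fraction = c(0.6, 0.5))),
               "sum to less than 1")
})

test_that("traces round-trip through CSV", {
  g <- gen_dsc_trace(4, data.frame(T_fus_C = 100, H_fus_kjmol = 20))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(g$trace, path)
  back <- read_trace(path)
  expect_equal(back$temperature_C, g$trace$temperature_C)
  expect_equal(back$signal, g$trace$signal)
})
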