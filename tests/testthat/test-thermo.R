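# Heat-of-fusion rule, transition thermodynamics, diagrams, solvates.

test_that("heat-of-fusion rule reproduces the study's verdicts", {
  # flavone polymorphs: higher-melting form also has the higher enthalpy
  v <- heat_of_fusion_rule(fusion_datum("II_FL", 96.5, 21.1, 0.1, 0.2),
                           fusion_datum("III_FL", 95.6, 19.6, 0.2, 0.2))
  expect_equal(v$relation, "monotropic")
  expect_true(is.na(v$high_temperature_form))

  # sulfaguanidine/flavone cocrystal polymorphs
  v <- heat_of_fusion_rule(sg_fl_form_I(), sg_fl_form_II())
  expect_equal(v$relation, "enantiotropic")
  expect_equal(v$high_temperature_form, "II_CC")

  # dapsone/flavone cocrystal polymorphs
  v <- heat_of_fusion_rule(fusion_datum("A_CC", 112.4, 27.3, 0.1, 0.4),
                           fusion_datum("B_CC", 109.5, 30.1, 0.1, 0.4))
  expect_equal(v$relation, "enantiotropic")
  expect_equal(v$high_temperature_form, "A_CC")
})

test_that("the rule is antisymmetric in argument order", {
  a <- sg_fl_form_I()
  b <- sg_fl_form_II()
  expect_equal(heat_of_fusion_rule(a, b), heat_of_fusion_rule(b, a))
})

test_that("uncertainty overlap and equal melting points are indeterminate", {
  v <- heat_of_fusion_rule(fusion_datum("P1", 100, 20.0, u_H = 0.5),
                           fusion_datum("P2", 101, 20.3, u_H = 0.5))
  expect_equal(v$relation, "indeterminate")
  expect_warning(
    v <- heat_of_fusion_rule(fusion_datum("P1", 100, 20),
                             fusion_datum("P2", 100, 25)),
    "equal melting"
  )
  expect_equal(v$relation, "indeterminate")
})

test_that("transition thermodynamics follow the dCp = 0 construction", {
  tt <- transition_thermo(sg_fl_form_I(), sg_fl_form_II())
  expect_equal(tt$H_trans, 4.5, tolerance = 1e-12)
  # independent arithmetic: S = H_lo/T_lo - H_hi/T_hi, T = H/S
  S <- 52.0 / (171.3 + 273.15) - 47.5 / (174.6 + 273.15)
  expect_equal(tt$T_trans, 4.5 / S, tolerance = 1e-9)
  expect_equal(tt$S_trans, 1000 * S, tolerance = 1e-9)
  expect_lt(tt$T_trans, min(sg_fl_form_I()$T_fus, sg_fl_form_II()$T_fus))
  expect_gt(tt$T_trans, 0)

  # monotropic input refuses without force
  a <- fusion_datum("II_FL", 96.5, 21.1)
  b <- fusion_datum("III_FL", 95.6, 19.6)
  expect_error(transition_thermo(a, b), "not enantiotropic")
  expect_s3_class(transition_thermo(a, b, force = TRUE),
                  "transition_estimate")

  # identical data: zero transition entropy, undefined temperature
  x <- fusion_datum("X", 100, 20)
  y <- fusion_datum("Y", 100, 20)
  expect_error(transition_thermo(x, y, force = TRUE), "zero")
})

test_that("T_trans is invariant when both enthalpies are scaled", {
  base <- transition_thermo(sg_fl_form_I(), sg_fl_form_II())
  for (c in c(0.5, 2, 7.3)) {
    s <- transition_thermo(fusion_datum("I_CC", 171.3, 52.0 * c),
                           fusion_datum("II_CC", 174.6, 47.5 * c))
    expect_equal(s$T_trans, base$T_trans, tolerance = 1e-9)
    expect_equal(s$H_trans, base$H_trans * c, tolerance = 1e-9)
  }
})

test_that("energy/temperature diagrams order events correctly", {
  a <- sg_fl_form_I()
  b <- sg_fl_form_II()
  tt <- transition_thermo(a, b)
  d <- et_diagram(a, b, tt)
  expect_equal(d$events$event,
               c("T_trans", "T_fus(I_CC)", "T_fus(II_CC)"))
  expect_equal(d$events$temperature_C, c(tt$T_trans_C, 171.3, 174.6),
               tolerance = 1e-9)
  expect_equal(unname(d$isobars), c(-52.0, -47.5, 0))

  # monotropic pair: no crossing below melting
  dm <- et_diagram(fusion_datum("II_FL", 96.5, 21.1),
                   fusion_datum("III_FL", 95.6, 19.6))
  expect_equal(dm$relation, "monotropic")
  expect_true(is.na(dm$crossing_K))

  # forced inconsistent estimate: crossing above both melting points
  bad <- transition_thermo(a, b)
  bad$T_trans <- max(a$T_fus, b$T_fus) + 10
  expect_error(et_diagram(a, b, bad), "T_trans.*T_fus")
})

test_that("solvate stoichiometry reproduces the printed mass-loss cases", {
  # 13.1% loss of t-BuOH from a 1:1 dapsone/flavone host -> monosolvate
  s <- solvate_stoichiometry(0.131, 248.30 + 222.24, 74.12)
  expect_equal(s$x, 0.957, tolerance = 1e-3)
  expect_equal(s$x_rounded, 1.0)

  # 1.8% water loss -> hemihydrate
  s <- solvate_stoichiometry(0.018, 470.54, 18.02)
  expect_equal(s$x, 0.479, tolerance = 1e-3)
  expect_equal(s$x_rounded, 0.5)

  expect_equal(solvate_stoichiometry(0, 470.54, 18.02)$x, 0)
  expect_error(solvate_stoichiometry(1, 470.54, 18.02), "\\[0, 1\\)")
})

test_that("solvate stoichiometry inverts its forward map monotonically", {
  M_host <- 470.54
  M_solv <- 74.12
  w <- seq(0.001, 0.6, length.out = 40)
  x <- vapply(w, function(wi) {
    solvate_stoichiometry(wi, M_host, M_solv)$x
  }, numeric(1))
  expect_true(all(diff(x) > 0))
  w_back <- mass_loss_fraction(x, M_host, M_solv)
  expect_equal(w_back, w, tolerance = 1e-12)
})

test_that("fusion tables read from CSV with units converted", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(form = c("I_CC", "II_CC"),
                       T_fus_C = c(171.3, 174.6),
                       H_fus_kjmol = c(52.0, 47.5),
                       u_T = c(0.1, 0.1), u_H = c(0.3, 0.1)),
            path, row.names = FALSE)
  fus <- read_fusion_table(path)
  expect_equal(fus$I_CC$T_fus, 171.3 + 273.15)
  expect_equal(fus$II_CC$H_fus, 47.5)
  expect_equal(heat_of_fusion_rule(fus$I_CC, fus$II_CC)$relation,
               "enantiotropic")
})
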