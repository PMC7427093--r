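test_that("water viscosity matches handbook values and decreases with temperature", {
  # handbook: 0.7972 mPa s at 30 C, 0.8900 mPa s at 25 C
  expect_lt(abs(water_viscosity(303.15) - 0.797e-3), 5e-7)
  expect_lt(abs(water_viscosity(298.15) - 0.890e-3), 5e-7)
  expect_gt(water_viscosity(293.15), water_viscosity(303.15))
  expect_gt(water_viscosity(303.15), water_viscosity(313.15))
  expect_error(water_viscosity(272), "273.15")
  expect_error(water_viscosity(380), "373.15")
})

test_that("rotational and translational radii reproduce the reference values", {
  cond <- conditions(303.15)
  expect_lt(abs(tau_c_to_rh(6.03, cond) - 1.96), 0.005)
  expect_lt(abs(d_to_rh(154e-12, cond) - 1.805), 0.006)  # prints as 1.80-1.81
  # independent hand evaluations of the closed forms
  expect_lt(abs(tau_c_to_rh(10.3, cond) - 2.346), 0.005)
  expect_lt(abs(d_to_rh(123e-12, cond) - 2.264), 0.005)
  expect_error(tau_c_to_rh(-1), "positive")
  expect_error(d_to_rh(0), "positive")
})

test_that("forward and inverse hydrodynamic transforms are exact round trips", {
  cond <- conditions(303.15, field_mhz = 600)
  for (r in c(0.5, 1.0, 2.0, 5.0, 10.0)) {
    expect_equal(tau_c_to_rh(rh_to_tau_c(r, cond), cond), r, tolerance = 1e-9)
    expect_equal(d_to_rh(rh_to_d(r, cond), cond), r, tolerance = 1e-9)
  }
})

test_that("halving the viscosity doubles D and halves tau_c at fixed radius", {
  c1 <- conditions(303.15, viscosity = 0.8e-3)
  c2 <- conditions(303.15, viscosity = 0.4e-3)
  expect_equal(rh_to_d(2, c2), 2 * rh_to_d(2, c1), tolerance = 1e-12)
  expect_equal(rh_to_tau_c(2, c2), rh_to_tau_c(2, c1) / 2, tolerance = 1e-12)
})

test_that("the calibrated power law reproduces the reference monomer masses", {
  expect_lt(abs(rh_to_mw(1.96) - 13.0), 0.05)
  expect_lt(abs(rh_to_mw(1.80) - 10.2), 0.05)
  # strictly monotone
  r <- seq(0.5, 5, by = 0.1)
  expect_true(all(diff(rh_to_mw(r)) > 0))
  # calibration regenerates the shipped constants from the reference pairs
  cal <- calibrate_rh_mw(c(1.96, 1.80), c(13.0, 10.2))
  expect_equal(cal$A, 1.91, tolerance = 0.01)
  expect_equal(cal$b, 2.85, tolerance = 0.01)
  expect_equal(mw_to_rh(rh_to_mw(1.7)), 1.7, tolerance = 1e-9)
})

test_that("sequence masses use average residue weights plus one water", {
  expect_equal(sequence_mw("GS"), 0.16215, tolerance = 1e-4)
  expect_equal(sequence_mw(""), 0.0180, tolerance = 1e-3)
  expect_lt(sequence_mw("GG"), sequence_mw("GS"))
  expect_error(sequence_mw("GXS"), "X")
  expect_error(sequence_mw("GXS"), "position 2")
})

test_that("oligomer calls separate monomer from cross-linked dimer", {
  cond <- conditions(303.15)
  mono <- classify_oligomer(tau_c = 6.0, D = 154e-12, mw_monomer = 10.6, cond = cond)
  expect_identical(mono$label, "monomer")
  expect_identical(mono$n_oligomer, 1L)
  dim <- classify_oligomer(tau_c = 10.3, D = 123e-12, mw_monomer = 10.6, cond = cond)
  expect_identical(dim$label, "dimer")
  expect_identical(dim$n_oligomer, 2L)
  # predicted mass exactly equal to the monomer mass
  mw <- rh_to_mw(tau_c_to_rh(6.0, cond))
  exact <- classify_oligomer(tau_c = 6.0, mw_monomer = mw, cond = cond)
  expect_identical(exact$n_oligomer, 1L)
  expect_error(classify_oligomer(mw_monomer = 10), "At least one")
})

test_that("an ideal rigid dimer scaling flips the call from monomer to dimer", {
  cond <- conditions(303.15)
  mono <- classify_oligomer(tau_c = 6.0, D = 154e-12, mw_monomer = 10.6, cond = cond)
  expect_identical(mono$n_oligomer, 1L)
  # sphere model: doubling the volume doubles tau_c and scales D by 2^(-1/3)
  dimer <- classify_oligomer(tau_c = 2 * 6.0, D = 154e-12 * 2^(-1 / 3),
                             mw_monomer = 10.6, cond = cond)
  expect_identical(dimer$n_oligomer, 2L)
})

test_that("the full measurement table yields monomer calls except for the cross-linked row", {
  tbl <- tibble::tibble(
    construct = c("rat DD", "rat DD C416S", "rat DD C416S cross-linked",
                  "human DD", "human DD 2nd state"),
    tau_c_ns = c(6.0, 6.1, 10.3, 6.1, 6.0),
    D_m2s = c(154e-12, 151e-12, 123e-12, 151e-12, NA),
    mw_kda = c(10.6, 10.6, 21.2 / 2, 10.5, 10.5)
  )
  out <- oligomer_state(tbl, conditions(303.15))
  expect_identical(out$label,
                   c("monomer", "monomer", "dimer", "monomer", "monomer"))
})
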