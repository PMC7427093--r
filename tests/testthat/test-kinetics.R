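test_that("first-order fits recover printed rate constants and half-lives", {
  t <- c(0, 2, 4, 6, 9, 12, 16, 19)
  for (k in c(0.1406, 0.0491)) {
    tc <- tibble::tibble(time = t, value = exp(-k * t))
    f <- fit_first_order(tc)
    expect_equal(f$k, k, tolerance = 1e-10)
    expect_equal(f$t_half, log(2) / k, tolerance = 1e-10)
  }
  # the two reference half-lives: ~5 and ~14 days
  expect_equal(log(2) / 0.1406, 4.93, tolerance = 0.01)
  expect_equal(log(2) / 0.0491, 14.1, tolerance = 0.01)
  # self-consistency identity
  f <- fit_first_order(tibble::tibble(time = t, value = exp(-0.2 * t)))
  expect_equal(f$t_half * f$k, log(2), tolerance = 1e-12)
})

test_that("degenerate and invalid first-order inputs are caught", {
  t <- c(0, 2, 4, 6)
  expect_warning(
    fit_first_order(tibble::tibble(time = t, value = rep(1, 4))),
    "Degenerate")
  expect_error(
    fit_first_order(tibble::tibble(time = t, value = c(1, 0.5, -0.1, 0.2))),
    "positive")
  expect_error(
    fit_first_order(tibble::tibble(time = t[1:3], value = exp(-t[1:3]))),
    "4 time points")
})

test_that("the closed-form second-order solution matches a numerical ODE integration", {
  skip_if_not_installed("deSolve")
  M0 <- 1e-3; k <- 1.08e-3
  times <- c(0, 3600, 7200, 3600 * 24, 3600 * 70)
  ode <- deSolve::ode(
    y = c(M = M0), times = times,
    func = function(t, y, p) list(-p$k * y^2), parms = list(k = k),
    rtol = 1e-10, atol = 1e-14
  )
  expect_equal(second_order_monomer(times, M0, k), unname(ode[, "M"]),
               tolerance = 1e-6)
  # initial condition and half-consumption point
  expect_equal(second_order_monomer(0, M0, k), M0)
  expect_equal(second_order_monomer(1 / (M0 * k), M0, k), M0 / 2)
})

test_that("second-order fits recover the generating rate constants exactly without noise", {
  for (k in c(1.08e-3, 9.65e-3)) {
    tc <- gen_dimerization_course(k = k, M0 = 1e-3, noise = "none")
    f <- fit_second_order(tc, M0 = 1e-3)
    expect_equal(f$k, k, tolerance = 1e-8)
  }
  # no dimerization: fitted k indistinguishable from zero
  tc0 <- gen_dimerization_course(k = 0, M0 = 1e-3, noise = "none")
  f0 <- fit_second_order(tc0, M0 = 1e-3)
  expect_lt(f0$k, 1e-10)
})

test_that("the rate constant is invariant across LPR in mole/mole units", {
  k <- 1.08e-3
  t <- seq(0, 70 * 3600, length.out = 8)
  f1000 <- fit_second_order(gen_dimerization_course(k = k, M0 = 1 / 1000,
                                                    times = t, noise = "none"),
                            M0 = 1 / 1000)
  f200 <- fit_second_order(gen_dimerization_course(k = k, M0 = 1 / 200,
                                                   times = t, noise = "none"),
                           M0 = 1 / 200)
  expect_equal(f1000$k, k, tolerance = 1e-8)
  expect_equal(f200$k, k, tolerance = 1e-8)
})

test_that("fitted rates order the fast and slow variants across many seeds", {
  t <- seq(0, 70 * 3600, length.out = 8)
  for (s in 1:100) {
    fast <- fit_second_order(
      gen_dimerization_course(k = 9.65e-3, M0 = 1e-3, times = t,
                              noise_sd = 0.03, seed = s), M0 = 1e-3)$k
    slow <- fit_second_order(
      gen_dimerization_course(k = 1.08e-3, M0 = 1e-3, times = t,
                              noise_sd = 0.03, seed = s + 1000), M0 = 1e-3)$k
    expect_gt(fast, slow)
  }
})

test_that("gel monomer fractions are mass fractions per lane", {
  expect_equal(
    gel_monomer_fraction(tibble::tibble(band = "monomer", intensity = 1))$fraction, 1)
  expect_equal(
    gel_monomer_fraction(tibble::tibble(band = c("monomer", "dimer"),
                                        intensity = c(1, 1)))$fraction, 0.5)
  expect_equal(
    gel_monomer_fraction(tibble::tibble(band = c("monomer", "dimer", "tetramer"),
                                        intensity = c(2, 1, 1)))$fraction, 0.5)
  multi <- tibble::tibble(lane = c(1, 1, 2, 2),
                          band = c("monomer", "dimer", "monomer", "dimer"),
                          intensity = c(3, 1, 1, 3))
  out <- gel_monomer_fraction(multi)
  expect_equal(out$fraction, c(0.75, 0.25))
  expect_error(
    gel_monomer_fraction(tibble::tibble(band = "monomer", intensity = 0)),
    "all-zero")
  expect_error(
    gel_monomer_fraction(tibble::tibble(band = "blob", intensity = 1)),
    "band")
})

test_that("the membrane LPR estimator reproduces the reference E. coli estimate", {
  out <- lpr_ecoli()
  expect_equal(out$n_lip, 2 * 4 / 0.6e-6, tolerance = 1e-9)  # 1.33e7 lipids/cell
  expect_equal(out$lpr, 191, tolerance = 0.005)
  expect_equal(out$lpr_1sf, 200)
  # doubling the expression level halves the LPR
  g <- lpr_ecoli_geometry()
  g2 <- cell_geometry(g$s_cell_um2, g$s_lip_um2, 2 * g$c_prot_g_l,
                      g$mw_g_mol, g$c_cell_per_ml, g$avogadro)
  expect_equal(lpr_membrane(g2)$lpr, out$lpr / 2, tolerance = 1e-9)
  expect_error(cell_geometry(4, 0.6e-6, -1, 21486, 24e8), "positive")
})
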