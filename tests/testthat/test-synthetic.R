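test_that("every generator is a pure function of its parameters and seed", {
  expect_identical(gen_tract_decays(seed = 5), gen_tract_decays(seed = 5))
  expect_identical(gen_pgste_series(seed = 5), gen_pgste_series(seed = 5))
  expect_identical(gen_dilution_series(seed = 5), gen_dilution_series(seed = 5))
  expect_identical(gen_dimerization_course(seed = 5),
                   gen_dimerization_course(seed = 5))
  expect_identical(gen_gel_course(seed = 5), gen_gel_course(seed = 5))
  expect_identical(gen_two_state_projection(seed = 5),
                   gen_two_state_projection(seed = 5))
  expect_identical(gen_deamidation_series(seed = 5),
                   gen_deamidation_series(seed = 5))
  expect_identical(gen_hsqc_pair(seed = 5), gen_hsqc_pair(seed = 5))
  # different seeds differ (noise actually applied)
  expect_false(identical(gen_pgste_series(seed = 5), gen_pgste_series(seed = 6)))
  # generators do not disturb the caller's RNG stream
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(gen_pgste_series(seed = 99))
    after <- runif(1)
  })
  expect_identical(before, after)
})

test_that("each estimator closes the loop on its generator without noise", {
  cond <- conditions(field_mhz = 600)
  # TRACT pair
  tr <- tract_fit(gen_tract_decays(6.03, residues = 1:3, cond = cond,
                                   noise = "none"), cond)
  expect_equal(tr$tau_c_ns, rep(6.03, 3), tolerance = 1e-5)
  # gradient series
  s <- gen_pgste_series(D = 154e-12, noise = "none")
  expect_equal(stejskal_tanner_fit(s, attr(s, "delta"), attr(s, "Delta"))$D,
               154e-12, tolerance = 1e-9)
  # dilution
  expect_equal(extrapolate_D0(gen_dilution_series(noise = "none"))$D0,
               154e-12, tolerance = 1e-6)
  # dimerization
  expect_equal(fit_second_order(gen_dimerization_course(k = 1.08e-3, noise = "none"),
                                M0 = 1e-3)$k, 1.08e-3, tolerance = 1e-8)
  # projection
  expect_equal(two_state_populations(
    gen_two_state_projection(p1 = 0.7, noise = "none"))$populations[1],
    0.7, tolerance = 1e-6)
  # deamidation peak lists
  co <- population_course_to_kinetics(
    gen_deamidation_series(k_days = 0.1406, noise = "none"), 352, state = "asn")
  expect_equal(fit_first_order(co)$k, 0.1406, tolerance = 1e-8)
})

test_that("simulated attenuation decays monotonically and kinetics start at one", {
  s <- gen_pgste_series(D = 154e-12, noise = "none")
  expect_lt(s$intensity[nrow(s)], s$intensity[1])
  k0 <- gen_dimerization_course(k = 0, noise = "none")
  expect_true(all(k0$value == 1))
})

test_that("a 60-residue ensemble at 3% noise lands within 0.1 ns of the truth", {
  cond <- conditions(field_mhz = 600)
  d <- gen_tract_decays(tau_c = 5.78, residues = 339:398, cond = cond,
                        noise = "gaussian_relative", noise_sd = 0.03, seed = 1)
  ens <- ensemble_tau_c(tract_fit(d, cond))
  expect_lt(abs(ens$tau_c_mean - 5.78), 0.1)
})

test_that("the gradient-series estimator is unbiased at the 0.5% level", {
  Ds <- vapply(1:50, function(s) {
    ser <- gen_pgste_series(D = 154e-12, noise = "gaussian_relative",
                            noise_sd = 0.01, seed = s)
    stejskal_tanner_fit(ser, attr(ser, "delta"), attr(ser, "Delta"))$D
  }, numeric(1))
  expect_lt(abs(mean(Ds) - 154e-12) / 154e-12, 0.005)
})

test_that("emitted gel tables conserve mass per lane", {
  g <- gen_gel_course(k = 1.08e-3, noise = "none")
  sums <- dplyr::summarise(dplyr::group_by(g, lane),
                           total = sum(intensity))$total
  expect_true(all(abs(sums - sums[1]) < 1e-10 * sums[1]))
  # and in concentration terms monomer + 2 * (dimer pairs) is constant
  M0 <- attr(g, "M0")
  fr <- gel_monomer_fraction(g)
  monomer <- fr$fraction * M0
  dimerised <- (1 - fr$fraction) * M0   # total protein locked in oligomers
  expect_true(all(abs(monomer + dimerised - M0) < 1e-10))
})

test_that("overlapping projection components are flagged", {
  expect_warning(
    out <- gen_two_state_projection(centers = c(8.00, 8.01),
                                    widths = c(0.05, 0.05), noise = "none"),
    "ill-conditioned")
  expect_true(attr(out, "overlap_warning"))
})
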