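# Independent re-implementation of the cross-correlation closed form,
# written directly from the physical definition (different arrangement of
# constants than the package path).
eta_oracle <- function(tau_c_ns, field_mhz, r_nh = 1.02e-10,
                       dsigma = 160e-6, theta_deg = 17) {
  mu0 <- 4e-7 * pi
  h <- 6.62607015e-34
  gH <- 2.6752218744e8
  gN <- 2.7126189e7
  B0 <- field_mhz * 1e6 / (gH / (2 * pi))
  wN <- gN * B0
  tc <- tau_c_ns * 1e-9
  J <- function(w) 0.4 * tc / (1 + (w * tc)^2)
  (mu0 * gH * gN * h / (16 * pi^2 * r_nh^3)) *
    (gN * B0 * dsigma / 3) *
    (4 * J(0) + 3 * J(wN)) *
    0.5 * (3 * cos(theta_deg * pi / 180)^2 - 1)
}

test_that("the cross-correlation forward model matches an independent evaluation", {
  cond <- conditions(field_mhz = 600)
  for (tc in c(2, 6, 10.3, 25)) {
    expect_equal(eta_xy_forward(tc, cond), eta_oracle(tc, 600), tolerance = 1e-10)
  }
  expect_equal(eta_xy_forward(6, conditions(field_mhz = 800)),
               eta_oracle(6, 800), tolerance = 1e-10)
})

test_that("eta_xy grows with tau_c and vanishes in the fast-tumbling limit", {
  cond <- conditions(field_mhz = 600)
  expect_gt(eta_xy_forward(8, cond), eta_xy_forward(6, cond))
  expect_gt(eta_xy_forward(6, cond), eta_xy_forward(4, cond))
  expect_lt(eta_xy_forward(1e-3, cond), 1e-2)
  # strictly increasing over the whole bracket at several fields
  for (f in c(400, 600, 800, 1000)) {
    eta <- eta_xy_forward(seq(0.1, 100, length.out = 500),
                          conditions(field_mhz = f))
    expect_true(all(diff(eta) > 0))
  }
  expect_error(eta_xy_forward(6, conditions()), "field_mhz")
})

test_that("mono-exponential fitting recovers rates and enforces preconditions", {
  t <- seq(0.002, 0.25, length.out = 10)
  clean <- tibble::tibble(delay_s = t, intensity = 100 * exp(-20 * t))
  f <- fit_monoexponential(clean)
  expect_equal(f$R, 20, tolerance = 1e-8)
  expect_equal(f$I0, 100, tolerance = 1e-6)
  # 2% noise, seeded: R within 3 standard errors
  noisy <- withr::with_seed(42, dplyr::mutate(
    clean, intensity = intensity * (1 + rnorm(length(t), 0, 0.02))))
  fn <- fit_monoexponential(noisy)
  expect_lt(abs(fn$R - 20), 3 * fn$R_se)
  # log-linear route agrees on clean data
  fl <- fit_monoexponential(clean, method = "log_linear")
  expect_equal(fl$R, 20, tolerance = 1e-8)
  # fewer than 4 points rejected
  expect_error(
    fit_monoexponential(tibble::tibble(delay_s = c(0, 0.1),
                                       intensity = c(100, 13.5))),
    "4 delay points")
})

test_that("TRACT inversion is an exact round trip in both tumbling regimes", {
  cond <- conditions(field_mhz = 600)
  for (tc in c(6.03, 10.3)) {
    eta <- eta_xy_forward(tc, cond)
    rec <- tract_tau_c(15 - eta, 15 + eta, cond)
    expect_equal(rec, tc, tolerance = 1e-6)
  }
  expect_error(tract_tau_c(10, 9, cond), "R_beta > R_alpha")
  # out-of-bracket eta
  expect_error(tract_tau_c(1, 1 + 2 * eta_xy_forward(100, cond) * 1.5, cond),
               "bracket")
})

test_that("root-finding inversion agrees with a brute-force grid scan", {
  cond <- conditions(field_mhz = 600)
  grid <- seq(0.1, 100, length.out = 1e4)
  eta_grid <- eta_xy_forward(grid, cond)
  step <- grid[2] - grid[1]
  tcs <- withr::with_seed(7, runif(20, 0.5, 50))
  for (tc in tcs) {
    eta <- eta_xy_forward(tc, cond)
    by_grid <- grid[which.min(abs(eta_grid - eta))]
    by_root <- tract_tau_c(10, 10 + 2 * eta, cond)
    expect_lt(abs(by_root - by_grid), step)
  }
})

test_that("per-residue fits and ensemble averaging recover the generating tau_c", {
  cond <- conditions(field_mhz = 600)
  d <- gen_tract_decays(tau_c = 6.03, residues = 339:342, cond = cond,
                        noise = "none")
  tr <- tract_fit(d, cond)
  expect_equal(nrow(tr), 4L)
  expect_true(all(abs(tr$tau_c_ns - 6.03) < 1e-5))
  expect_true(all(tr$R_beta > tr$R_alpha))
  expect_equal(tr$eta_xy, (tr$R_beta - tr$R_alpha) / 2, tolerance = 1e-12)

  ens <- ensemble_tau_c(tr)
  expect_equal(ens$tau_c_mean, 6.03, tolerance = 1e-5)
  expect_equal(ens$tau_c_sd, 0, tolerance = 1e-4)
  # residue-window selection
  expect_equal(ensemble_tau_c(tr, residues = 339:340)$n, 2L)
  expect_error(ensemble_tau_c(tr, residues = 1:5), "at least 2")
})

test_that("ensemble mean is plain arithmetic over the selection", {
  fake <- tibble::tibble(residue = 1:3, tau_c_ns = c(5, 6, 7))
  ens <- ensemble_tau_c(fake)
  expect_equal(ens$tau_c_mean, 6)
  expect_equal(ens$tau_c_sd, 1)
})

test_that("median recovered tau_c stays within 2% of truth at 3% decay noise", {
  cond <- conditions(field_mhz = 600)
  d <- gen_tract_decays(tau_c = 6.0, residues = 1:100, cond = cond,
                        noise = "gaussian_relative", noise_sd = 0.03, seed = 123)
  tr <- tract_fit(d, cond)
  expect_lt(abs(median(tr$tau_c_ns) - 6.0) / 6.0, 0.02)
})

test_that("the monomer/dimer ensemble difference reproduces the cross-linking decrement", {
  cond <- conditions(field_mhz = 600)
  mono <- tract_fit(gen_tract_decays(5.78, residues = 339:398, cond = cond,
                                     noise_sd = 0.03, seed = 1), cond)
  dimer <- tract_fit(gen_tract_decays(6.83, residues = 339:398, cond = cond,
                                      noise_sd = 0.03, seed = 2), cond)
  diff <- tau_c_difference(ensemble_tau_c(mono), ensemble_tau_c(dimer))
  expect_lt(abs(diff$delta_tau_c - 1.05), 0.1)
  expect_gt(diff$delta_se, 0)
})
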