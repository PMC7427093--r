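test_that("the oligostate workflow composes relaxation, diffusion and the call", {
  cond_field <- dd_config(field_mhz = 600)
  decays <- gen_tract_decays(tau_c = 6.0, residues = 339:348,
                             cond = conditions(field_mhz = 600), noise = "none")
  grad <- gen_pgste_series(D = 154e-12, noise = "none")
  rep <- run_workflow("oligostate",
                      list(decays = decays, gradient_series = grad,
                           mw_monomer = 10.6),
                      config = cond_field)
  expect_s3_class(rep, "dd_report")
  expect_identical(rep$results$label, "monomer")
  expect_equal(rep$details$ensemble$tau_c_mean, 6.0, tolerance = 1e-4)
  expect_equal(rep$details$pgste$D, 154e-12, tolerance = 1e-9)

  # dimer-regime bundle
  decays_d <- gen_tract_decays(tau_c = 10.3, residues = 339:348, r2_base = 14,
                               cond = conditions(field_mhz = 600), noise = "none")
  grad_d <- gen_pgste_series(D = 123e-12, noise = "none")
  rep_d <- run_workflow("oligostate",
                        list(decays = decays_d, gradient_series = grad_d,
                             mw_monomer = 10.6),
                        config = cond_field)
  expect_identical(rep_d$results$label, "dimer")
})

test_that("the deamidation workflow recovers the first-order rate", {
  pk <- gen_deamidation_series(k_days = 0.1406, noise = "none")
  rep <- run_workflow("deamidation",
                      list(peaklists = pk, probe_residue = 352, state = "asn"))
  expect_equal(rep$results$k, 0.1406, tolerance = 1e-6)
  expect_equal(rep$results$t_half, log(2) / 0.1406, tolerance = 1e-6)
})

test_that("the dimerization workflow recovers the second-order rate from a gel table", {
  g <- gen_gel_course(k = 1.08e-3, M0 = 1e-3, noise = "none")
  rep <- run_workflow("dimerization", list(gel_table = g, lpr = 1000))
  expect_equal(rep$results$k, 1.08e-3, tolerance = 1e-6)
})

test_that("empty or incomplete inputs abort with a stage-qualified message", {
  expect_error(run_workflow("oligostate", list()), "non-empty")
  expect_error(run_workflow("deamidation", list(probe_residue = 352)),
               "peaklists")
  expect_error(run_workflow("dimerization", list(gel_table = tibble::tibble())),
               "lpr")
})

test_that("reports are reproducible for identical inputs and configuration", {
  pk <- gen_deamidation_series(k_days = 0.1406, noise_sd = 0.02, seed = 4)
  r1 <- run_workflow("deamidation", list(peaklists = pk, probe_residue = 352,
                                         state = "asn"))
  r2 <- run_workflow("deamidation", list(peaklists = pk, probe_residue = 352,
                                         state = "asn"))
  expect_equal(r1$results, r2$results)
})

test_that("tidiers return one-row summaries and per-term tables", {
  f <- fit_first_order(tibble::tibble(time = c(0, 2, 4, 6, 9, 12, 16, 19),
                                      value = exp(-0.1406 * c(0, 2, 4, 6, 9, 12, 16, 19))))
  expect_identical(tidy(f)$term, c("k", "t_half", "I0"))
  expect_equal(glance(f)$t_half, log(2) / 0.1406, tolerance = 1e-8)
  s <- gen_pgste_series(noise = "none")
  st <- stejskal_tanner_fit(s, attr(s, "delta"), attr(s, "Delta"))
  expect_equal(tidy(st)$estimate[1], 154e-12, tolerance = 1e-8)
  pr <- two_state_populations(gen_two_state_projection(p1 = 0.7, noise = "none"))
  expect_equal(sum(tidy(pr)$population), 1, tolerance = 1e-12)
  expect_false(glance(pr)$degenerate)
})

test_that("autoplot methods return ggplot objects", {
  f <- fit_first_order(tibble::tibble(time = c(0, 2, 4, 6, 9, 12, 16, 19),
                                      value = exp(-0.14 * c(0, 2, 4, 6, 9, 12, 16, 19))))
  expect_s3_class(ggplot2::autoplot(f), "ggplot")
  s <- gen_pgste_series(noise = "none")
  expect_s3_class(ggplot2::autoplot(
    stejskal_tanner_fit(s, attr(s, "delta"), attr(s, "Delta"))), "ggplot")
  pr <- two_state_populations(gen_two_state_projection(p1 = 0.7, noise = "none"))
  expect_s3_class(ggplot2::autoplot(pr), "ggplot")
  prof <- tibble::tibble(residue = 1:5, gcs = c(0, 0.05, 0.3, 0.1, 0))
  expect_s3_class(plot_gcs_profile(prof), "ggplot")
})
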