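# Seeded generators emulating every input the analyses consume. Each is a
# pure function of (parameters, seed): the same call yields byte-identical
# output, and the matching estimator applied to a noiseless output returns
# the generating parameters to numerical precision.

.apply_noise <- function(y, noise, sd, seed_stream = NULL) {
  noise <- match.arg(noise, c("none", "gaussian_relative", "gaussian_absolute"))
  if (sd < 0) abort("`noise_sd` must be >= 0.")
  switch(noise,
    none = y,
    gaussian_relative = y * (1 + stats::rnorm(length(y), 0, sd)),
    gaussian_absolute = y + stats::rnorm(length(y), 0, sd)
  )
}

#' Simulate TROSY/anti-TROSY relaxation decay pairs
#'
#' Generates per-residue alpha/beta mono-exponential decay pairs whose
#' rates straddle a base transverse rate by the dipole-CSA
#' cross-correlation rate at the chosen correlation time:
#' `R_alpha = R2 - eta_xy(tau_c)`, `R_beta = R2 + eta_xy(tau_c)`. The
#' generator shares [eta_xy_forward()] with the estimator, so
#' [tract_fit()] on a noiseless output recovers `tau_c` exactly.
#'
#' @param tau_c Generating rotational correlation time, ns.
#' @param residues Residue numbers (default the 60-residue window
#'   339:398).
#' @param cond A [conditions()] object with `field_mhz` set.
#' @param params A [spin_params()] object.
#' @param delays Relaxation delays in seconds.
#' @param r2_base Base transverse relaxation rate, s^-1.
#' @param r2_jitter Standard deviation of per-residue variation of
#'   `r2_base` (s^-1); affects both components of a residue equally, so
#'   the extracted `eta_xy` is untouched.
#' @param noise Noise model on intensities: `"none"`,
#'   `"gaussian_relative"` (sd relative to each point) or
#'   `"gaussian_absolute"` (sd in intensity units; initial intensity is
#'   100).
#' @param noise_sd Noise standard deviation (default 0.02 relative).
#' @param seed Integer seed; fixed seed implies identical output.
#' @return A long tibble with columns `residue`, `component`, `delay_s`,
#'   `intensity`, ready for [tract_fit()].
#' @examples
#' d <- gen_tract_decays(tau_c = 6.03, noise = "none")
#' @export
gen_tract_decays <- function(tau_c = 6.03, residues = 339:398,
                             cond = conditions(field_mhz = 600),
                             params = spin_params(),
                             delays = seq(0.002, 0.25, length.out = 16),
                             r2_base = 12, r2_jitter = 0,
                             noise = "gaussian_relative", noise_sd = 0.02,
                             seed = 1L) {
  if (tau_c <= 0) abort("`tau_c` must be positive (ns).")
  eta <- eta_xy_forward(tau_c, cond, params)
  if (r2_base <= eta) {
    abort(sprintf("`r2_base` (%.3g) must exceed eta_xy (%.3g) so both rates stay positive.",
                  r2_base, eta))
  }
  withr::with_seed(seed, {
    r2 <- r2_base + stats::rnorm(length(residues), 0, r2_jitter)
    grid <- tidyr::expand_grid(
      residue = residues,
      component = c("alpha", "beta"),
      delay_s = delays
    )
    grid$rate <- r2[match(grid$residue, residues)] +
      ifelse(grid$component == "beta", eta, -eta)
    grid$intensity <- .apply_noise(100 * exp(-grid$rate * grid$delay_s),
                                   noise, noise_sd)
    dplyr::select(grid, -"rate")
  })
}

#' Simulate a pulsed-field-gradient echo-attenuation series
#'
#' Stejskal-Tanner attenuation over a gradient ramp at a chosen diffusion
#' coefficient; [stejskal_tanner_fit()] on a noiseless output recovers
#' `D` exactly.
#'
#' @param D Generating diffusion coefficient, m^2 s^-1.
#' @param gradients Gradient strengths, T m^-1 (default 16 points,
#'   0.02-0.5).
#' @param delta Gradient pulse length, s (default 4 ms).
#' @param Delta Diffusion delay, s (default 100 ms).
#' @param gamma Gyromagnetic ratio, rad s^-1 T^-1 (default 1H).
#' @param I0 Intensity at zero gradient.
#' @param noise,noise_sd,seed As in [gen_tract_decays()].
#' @return A tibble with `gradient_Tm`, `intensity` and attributes
#'   `delta`, `Delta`, `gamma`, `D_true`.
#' @export
gen_pgste_series <- function(D = 154e-12,
                             gradients = seq(0.02, 0.5, length.out = 16),
                             delta = 0.004, Delta = 0.1, gamma = .gamma_1H,
                             I0 = 100, noise = "gaussian_relative",
                             noise_sd = 0.02, seed = 1L) {
  if (D <= 0) abort("`D` must be positive (m^2 s^-1).")
  b <- (gamma * gradients * delta)^2 * (Delta - delta / 3)
  withr::with_seed(seed, {
    out <- tibble(
      gradient_Tm = gradients,
      intensity = .apply_noise(I0 * exp(-D * b), noise, noise_sd)
    )
    attr(out, "delta") <- delta
    attr(out, "Delta") <- Delta
    attr(out, "gamma") <- gamma
    attr(out, "D_true") <- D
    out
  })
}

#' Simulate a concentration-dependence (dilution) series
#'
#' Linear obstruction model `D(c) = D0 (1 - k_c c)` sampled at the given
#' concentrations; [extrapolate_D0()] on a noiseless output recovers the
#' intercept exactly.
#'
#' @param D0 Infinite-dilution diffusion coefficient, m^2 s^-1.
#' @param k_c Obstruction slope, L mol^-1 (default 45.5, a ~4.5 percent
#'   reduction at 1 mM).
#' @param concentrations Sample concentrations, mol L^-1.
#' @param rel_err Reported per-point error as a fraction of D.
#' @param noise,noise_sd,seed As in [gen_tract_decays()].
#' @return A tibble with `conc_M`, `D_m2s`, `D_err`.
#' @export
gen_dilution_series <- function(D0 = 154e-12, k_c = 45.5,
                                concentrations = c(0.25e-3, 0.5e-3, 1e-3),
                                rel_err = 0.013,
                                noise = "gaussian_relative", noise_sd = 0.01,
                                seed = 1L) {
  if (D0 <= 0) abort("`D0` must be positive.")
  withr::with_seed(seed, {
    D <- .apply_noise(D0 * (1 - k_c * concentrations), noise, noise_sd)
    tibble(conc_M = concentrations, D_m2s = D, D_err = rel_err * D)
  })
}

#' Simulate a second-order dimerization time course
#'
#' Monomer fractions from the closed form [second_order_monomer()] plus
#' noise, in the mole-per-mole-lipid unit system. [fit_second_order()] on
#' a noiseless output recovers `k` exactly.
#'
#' @param k Second-order rate constant, (mole_lipid/mole_protein) s^-1.
#' @param M0 Initial monomer concentration, mole/mole lipid (1/LPR).
#' @param times Sampling times in seconds (default 8 points over 70 h).
#' @param noise,noise_sd,seed Noise model on the fractions (default 3
#'   percent relative, the typical densitometry repeatability).
#' @return A tibble with `time` (s) and `value` (monomer fraction,
#'   clamped to (0, 1]), with attributes `M0` and `k_true`.
#' @export
gen_dimerization_course <- function(k = 1.08e-3, M0 = 1e-3,
                                    times = seq(0, 70 * 3600, length.out = 8),
                                    noise = "gaussian_relative",
                                    noise_sd = 0.03, seed = 1L) {
  if (k < 0) abort("`k` must be >= 0.")
  frac <- second_order_monomer(times, M0, k) / M0
  withr::with_seed(seed, {
    v <- .apply_noise(frac, noise, noise_sd)
    out <- tibble(time = times, value = pmin(pmax(v, 1e-6), 1))
    attr(out, "M0") <- M0
    attr(out, "k_true") <- k
    out
  })
}

#' Simulate a non-reducing gel band table for a dimerization course
#'
#' Companion emitter to [gen_dimerization_course()]: partitions the
#' oligomerized mass `1 - f(t)` into dimer and tetramer bands by a fixed
#' mixing fraction, preserving total mass per lane, and applies
#' densitometry noise to the band intensities. Feeding the table through
#' [gel_monomer_fraction()] and [fit_second_order()] closes the loop on
#' `k`.
#'
#' @inheritParams gen_dimerization_course
#' @param dimer_split Fraction of oligomerized mass appearing in the
#'   dimer band (remainder in tetramer; default 0.8).
#' @return A long tibble with `lane`, `time`, `band`, `intensity` and
#'   attributes `M0`, `k_true`.
#' @export
gen_gel_course <- function(k = 1.08e-3, M0 = 1e-3,
                           times = seq(0, 70 * 3600, length.out = 8),
                           dimer_split = 0.8,
                           noise = "gaussian_relative", noise_sd = 0.03,
                           seed = 1L) {
  if (dimer_split < 0 || dimer_split > 1) abort("`dimer_split` must be in [0, 1].")
  frac <- second_order_monomer(times, M0, k) / M0
  lanes <- tibble(
    lane = seq_along(times), time = times,
    monomer = frac,
    dimer = (1 - frac) * dimer_split,
    tetramer = (1 - frac) * (1 - dimer_split)
  )
  long <- tidyr::pivot_longer(lanes, cols = c("monomer", "dimer", "tetramer"),
                              names_to = "band", values_to = "intensity")
  withr::with_seed(seed, {
    long$intensity <- pmax(.apply_noise(100 * long$intensity, noise, noise_sd), 0)
    out <- dplyr::arrange(long, .data$lane)
    attr(out, "M0") <- M0
    attr(out, "k_true") <- k
    out
  })
}

#' Simulate a two-component 1D spectral projection
#'
#' Sum of two Lorentzian lines with areas in proportion `p1 : 1 - p1` on a
#' uniform ppm grid; [two_state_populations()] on a noiseless output
#' recovers the populations. Centers closer than half the larger
#' linewidth are flagged (attribute `overlap_warning`), since the
#' deconvolution becomes ill-conditioned.
#'
#' @param p1 Population of the first component, in [0, 1].
#' @param centers Line centers, ppm.
#' @param widths Half-widths at half maximum, ppm.
#' @param ppm Uniform acquisition grid.
#' @param total_area Summed area of both lines.
#' @param noise,seed Noise model; for `"gaussian_absolute"` the sd is
#'   `noise_sd` times the maximum clean amplitude (so `noise_sd = 0.01`
#'   is "1 percent noise").
#' @param noise_sd Noise level (default 0.01).
#' @return A tibble with `ppm`, `amplitude` and attributes `p1_true`,
#'   `overlap_warning`.
#' @export
gen_two_state_projection <- function(p1 = 0.5, centers = c(7.85, 8.25),
                                     widths = c(0.025, 0.025),
                                     ppm = seq(7.5, 8.6, length.out = 256),
                                     total_area = 1,
                                     noise = "gaussian_absolute",
                                     noise_sd = 0.01, seed = 1L) {
  if (p1 < 0 || p1 > 1) abort("`p1` must be in [0, 1].")
  clean <- .lorentz(ppm, centers[1], widths[1], p1 * total_area) +
    .lorentz(ppm, centers[2], widths[2], (1 - p1) * total_area)
  overlap <- abs(diff(centers)) < max(widths) / 2
  if (overlap) {
    warn("Line centers are closer than half a linewidth; deconvolution will be ill-conditioned.")
  }
  withr::with_seed(seed, {
    sd_abs <- if (noise == "gaussian_absolute") noise_sd * max(clean) else noise_sd
    out <- tibble(ppm = ppm,
                  amplitude = .apply_noise(clean, noise, sd_abs))
    attr(out, "p1_true") <- p1
    attr(out, "overlap_warning") <- overlap
    out
  })
}

#' Simulate time-stamped peak lists for a deamidation course
#'
#' Emits a stacked peak list in which the probe residue's unmodified
#' (asparagine) state fades as `exp(-k t)` while the modified (aspartate)
#' state grows complementarily, total intensity conserved. Piping the
#' result through [population_course_to_kinetics()] and
#' [fit_first_order()] closes the loop on `k`.
#'
#' @param k_days First-order rate constant, days^-1.
#' @param times Sampling times in days (default the 0-19 day cadence of a
#'   roughly three-week incubation).
#' @param probe_residue Probe residue number (default 352).
#' @param noise,noise_sd,seed Noise on intensities (default 2 percent
#'   relative).
#' @return A tibble with `residue`, `resname`, `shift_h_ppm`,
#'   `shift_n_ppm`, `intensity`, `state` (`"asn"`/`"asp"`), `time`
#'   (days), with attribute `k_true`.
#' @export
gen_deamidation_series <- function(k_days = 0.1406,
                                   times = c(0, 2, 4, 6, 9, 12, 16, 19),
                                   probe_residue = 352,
                                   noise = "gaussian_relative",
                                   noise_sd = 0.02, seed = 1L) {
  if (k_days < 0) abort("`k_days` must be >= 0.")
  I0 <- 100
  grid <- tidyr::expand_grid(time = times, state = c("asn", "asp"))
  grid$intensity_clean <- ifelse(
    grid$state == "asn",
    I0 * exp(-k_days * grid$time),
    I0 * (1 - exp(-k_days * grid$time))
  )
  withr::with_seed(seed, {
    out <- tibble(
      residue = probe_residue,
      resname = ifelse(grid$state == "asn", "N", "D"),
      shift_h_ppm = ifelse(grid$state == "asn", 8.10, 8.35),
      shift_n_ppm = ifelse(grid$state == "asn", 118.2, 120.9),
      intensity = .apply_noise(grid$intensity_clean, noise, noise_sd),
      state = grid$state,
      time = grid$time
    )
    attr(out, "k_true") <- k_days
    out
  })
}

#' Simulate a pair of peak lists with localized perturbations
#'
#' Reference and perturbed amide peak lists for chemical-shift
#' perturbation analysis: a chosen subset of residues is displaced by a
#' stated generalized-shift magnitude (split between the proton and
#' nitrogen dimensions), the rest move only by noise.
#'
#' @param residues Residue numbers.
#' @param perturbed Residues to displace.
#' @param magnitude GCS magnitude of the displacement, ppm.
#' @param weight Nitrogen weight defining the GCS (see [gcs()]).
#' @param noise_sd Standard deviation of random shift scatter applied to
#'   both lists, ppm (proton scale; nitrogen scatter is `noise_sd /
#'   weight`).
#' @param seed Integer seed.
#' @return A list with elements `a` and `b`, each a peak-list tibble.
#' @export
gen_hsqc_pair <- function(residues = 339:417, perturbed = integer(),
                          magnitude = 0.3, weight = dd_config()$gcs_weight,
                          noise_sd = 0, seed = 1L) {
  withr::with_seed(seed, {
    n <- length(residues)
    base <- tibble(
      residue = residues,
      shift_h_ppm = stats::runif(n, 7.2, 9.4),
      shift_n_ppm = stats::runif(n, 108, 128)
    )
    b <- base
    idx <- base$residue %in% perturbed
    # split the GCS magnitude evenly between the two dimensions
    dh <- magnitude / sqrt(2)
    dn <- magnitude / (sqrt(2) * weight)
    b$shift_h_ppm[idx] <- b$shift_h_ppm[idx] + dh
    b$shift_n_ppm[idx] <- b$shift_n_ppm[idx] + dn
    if (noise_sd > 0) {
      base$shift_h_ppm <- base$shift_h_ppm + stats::rnorm(n, 0, noise_sd)
      base$shift_n_ppm <- base$shift_n_ppm + stats::rnorm(n, 0, noise_sd / weight)
      b$shift_h_ppm <- b$shift_h_ppm + stats::rnorm(n, 0, noise_sd)
      b$shift_n_ppm <- b$shift_n_ppm + stats::rnorm(n, 0, noise_sd / weight)
    }
    list(a = base, b = b)
  })
}
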