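#' Amide spin constants for the TRACT forward model
#'
#' Geometry and interaction constants of the backbone amide 15N-1H pair
#' used in the dipole-CSA cross-correlation rate: the effective N-H bond
#' length, the 15N chemical-shift anisotropy and the angle between the CSA
#' principal axis and the N-H vector.
#'
#' @param r_nh N-H distance in meters (default 1.02e-10).
#' @param dsigma_n 15N CSA, dimensionless (default -160e-6, i.e. -160 ppm).
#' @param theta_deg Angle between CSA axis and N-H bond, degrees
#'   (default 17).
#' @return A list of class `dd_spin_params`.
#' @export
spin_params <- function(r_nh = 1.02e-10, dsigma_n = -160e-6, theta_deg = 17) {
  stopifnot(r_nh > 0, theta_deg >= 0, theta_deg <= 90)
  structure(list(r_nh = r_nh, dsigma_n = dsigma_n, theta_deg = theta_deg),
            class = "dd_spin_params")
}

# Rigid-rotor spectral density, tau_c in seconds
.J <- function(omega, tau_c) (2 / 5) * tau_c / (1 + (omega * tau_c)^2)

#' Transverse dipole-CSA cross-correlation rate
#'
#' Forward model of the TRACT experiment: the interference between the
#' 15N-1H dipolar coupling and the 15N CSA splits the relaxation of the
#' two 15N doublet components, whose rates differ by twice
#' \deqn{\eta_{xy} = p\, \delta_N\, (4 J(0) + 3 J(\omega_N))\, P_2(\cos\theta)}
#' with \eqn{p = \mu_0 \gamma_H \gamma_N h / (16 \pi^2 r_{NH}^3)},
#' \eqn{\delta_N = \gamma_N B_0 \Delta\sigma_N / 3}, the rigid-rotor
#' spectral density \eqn{J(\omega) = (2/5) \tau_c / (1 + (\omega\tau_c)^2)}
#' and \eqn{P_2(x) = (3x^2 - 1)/2}. The magnitude is returned (the sign
#' convention cancels in the rate difference). Strictly increasing in
#' `tau_c` over the protein regime, which makes the inversion in
#' [tract_tau_c()] unique.
#'
#' @param tau_c Rotational correlation time in nanoseconds (vectorised).
#' @param cond A [conditions()] object with `field_mhz` set.
#' @param params A [spin_params()] object.
#' @return Cross-correlation rate in s^-1.
#' @examples
#' eta_xy_forward(6, conditions(field_mhz = 600))
#' @export
eta_xy_forward <- function(tau_c, cond = conditions(field_mhz = 600),
                           params = spin_params()) {
  cond <- as_conditions(cond)
  if (is.null(cond$field_mhz)) {
    abort("`cond$field_mhz` must be set for relaxation calculations.")
  }
  if (any(!is.finite(tau_c)) || any(tau_c <= 0)) {
    abort("`tau_c` must be positive and finite (nanoseconds).")
  }
  B0 <- cond$field_mhz * 1e6 * 2 * pi / .gamma_1H
  omega_N <- abs(.gamma_15N) * B0
  p <- .mu0 * .gamma_1H * abs(.gamma_15N) * .hplanck / (16 * pi^2 * params$r_nh^3)
  dN <- abs(.gamma_15N) * B0 * abs(params$dsigma_n) / 3
  theta <- params$theta_deg * pi / 180
  P2 <- (3 * cos(theta)^2 - 1) / 2
  tc <- tau_c * 1e-9
  p * dN * (4 * .J(0, tc) + 3 * .J(omega_N, tc)) * P2
}

#' Rotational correlation time from TROSY/anti-TROSY relaxation rates
#'
#' Given the relaxation rates of the slowly (alpha, TROSY) and rapidly
#' (beta, anti-TROSY) relaxing 15N doublet components, forms
#' \eqn{\eta_{xy} = (R_\beta - R_\alpha)/2} and inverts the forward model
#' [eta_xy_forward()] for the correlation time by bracketed root finding
#' on [0.1, 100] ns (unique by monotonicity; converged to 1e-7 ns).
#'
#' @param R_alpha,R_beta Relaxation rates in s^-1 with `R_beta > R_alpha`.
#' @param cond A [conditions()] object with `field_mhz` set.
#' @param params A [spin_params()] object.
#' @param bracket Search interval for tau_c in ns.
#' @return Correlation time in nanoseconds.
#' @examples
#' eta <- eta_xy_forward(6.03, conditions(field_mhz = 600))
#' tract_tau_c(10 - eta, 10 + eta, conditions(field_mhz = 600)) # 6.03
#' @export
tract_tau_c <- function(R_alpha, R_beta, cond = conditions(field_mhz = 600),
                        params = spin_params(), bracket = c(0.1, 100)) {
  if (!(length(R_alpha) == 1 && length(R_beta) == 1)) {
    abort("`R_alpha` and `R_beta` must be single rates (s^-1).")
  }
  if (!is.finite(R_alpha) || !is.finite(R_beta) || R_beta <= R_alpha) {
    abort("Need finite rates with R_beta > R_alpha (the anti-TROSY component relaxes faster).")
  }
  eta <- (R_beta - R_alpha) / 2
  lo <- eta_xy_forward(bracket[1], cond, params)
  hi <- eta_xy_forward(bracket[2], cond, params)
  if (eta < lo || eta > hi) {
    abort(sprintf(
      "eta_xy = %.4g s^-1 is outside the invertible range [%.4g, %.4g] for tau_c in [%g, %g] ns; widen `bracket`.",
      eta, lo, hi, bracket[1], bracket[2]
    ))
  }
  uniroot(function(tc) eta_xy_forward(tc, cond, params) - eta,
          interval = bracket, tol = 1e-7)$root
}

#' Fit a mono-exponential decay
#'
#' Unweighted nonlinear least squares of \eqn{I(t) = I_0 e^{-Rt}} to an
#' intensity-versus-delay record (additive-noise model appropriate for
#' TROSY decay data). A log-linear fit of `ln I` on `t` is available via
#' `method = "log_linear"` and is also used internally for starting
#' values.
#'
#' @param data A data frame with the delay and intensity columns.
#' @param delay,intensity Column names (tidy-eval) holding delays in
#'   seconds (strictly increasing, >= 4 points) and intensities.
#' @param method `"nls"` (default) or `"log_linear"`.
#' @return An object of class `dd_decay_fit` with elements `R`, `R_se`,
#'   `I0`, `n`, `method`, `residual_norm` and the data. Supports [tidy()],
#'   [glance()] and [ggplot2::autoplot()].
#' @examples
#' d <- tibble::tibble(t = seq(0, 0.2, length.out = 8),
#'                     I = 100 * exp(-20 * t))
#' fit_monoexponential(d, t, I)$R
#' @export
fit_monoexponential <- function(data, delay = delay_s, intensity = intensity,
                                method = c("nls", "log_linear")) {
  method <- match.arg(method)
  t <- dplyr::pull(data, {{ delay }})
  y <- dplyr::pull(data, {{ intensity }})
  if (length(t) < 4) {
    abort("Mono-exponential fitting needs at least 4 delay points.")
  }
  if (any(diff(t) <= 0) || any(t < 0)) {
    abort("Delays must be non-negative and strictly increasing (seconds).")
  }
  if (y[1] <= 0) abort("Intensity at the first delay must be positive.")
  # log-linear starting values (positive points only)
  pos <- y > 0
  if (sum(pos) < 3) abort("Too few positive intensities for a decay fit.")
  ll <- lm(log(y[pos]) ~ t[pos])
  R0 <- unname(max(-coef(ll)[2], 1e-6))
  I00 <- unname(exp(coef(ll)[1]))
  if (method == "log_linear") {
    R <- unname(-coef(ll)[2]); R_se <- unname(suppressWarnings(sqrt(vcov(ll)[2, 2])))
    I0 <- unname(I00)
    resid <- y - I0 * exp(-R * t)
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ I0 * exp(-R * t),
                        start = list(I0 = I00, R = R0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) abort(paste0("Mono-exponential fit failed: ",
                                       conditionMessage(e)))
    )
    cf <- coef(fit)
    R <- unname(cf["R"]); I0 <- unname(cf["I0"])
    R_se <- unname(suppressWarnings(sqrt(diag(vcov(fit))))["R"])
    resid <- stats::residuals(fit)
  }
  structure(
    list(R = R, R_se = R_se, I0 = I0, n = length(t), method = method,
         residual_norm = sqrt(sum(resid^2)),
         data = tibble(delay_s = t, intensity = y)),
    class = "dd_decay_fit"
  )
}

#' @export
print.dd_decay_fit <- function(x, ...) {
  cat(sprintf("<dd_decay_fit> R = %.4g +/- %.2g s^-1, I0 = %.4g (%d points, %s)\n",
              x$R, x$R_se, x$I0, x$n, x$method))
  invisible(x)
}

#' Per-residue TRACT analysis of a decay table
#'
#' Fits every (residue, component) decay with [fit_monoexponential()],
#' pairs the alpha (TROSY) and beta (anti-TROSY) rates per residue and
#' inverts the cross-correlation rate for the rotational correlation time
#' with [tract_tau_c()]. The per-residue uncertainty is propagated from
#' the two rate standard errors through the numerically differentiated
#' inverse.
#'
#' @param data Long-format decay table with columns `residue`, `component`
#'   (`"alpha"`/`"beta"`), `delay_s`, `intensity`; an optional `resname`
#'   column is carried through.
#' @param cond A [conditions()] object with `field_mhz` set.
#' @param params A [spin_params()] object.
#' @param method Decay-fit method passed to [fit_monoexponential()].
#' @return A tibble with one row per residue: `residue`, `R_alpha`,
#'   `R_alpha_se`, `R_beta`, `R_beta_se`, `eta_xy`, `tau_c_ns`,
#'   `tau_c_err`.
#' @export
tract_fit <- function(data, cond = conditions(field_mhz = 600),
                      params = spin_params(), method = "nls") {
  data <- as_tibble(data)
  need <- c("residue", "component", "delay_s", "intensity")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Decay table lacks column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  if (!all(data$component %in% c("alpha", "beta"))) {
    abort("`component` must be 'alpha' or 'beta'.")
  }
  resnames <- if ("resname" %in% names(data)) {
    dplyr::distinct(data, .data$residue, .data$resname)
  } else NULL
  rates <- data |>
    dplyr::group_by(.data$residue, .data$component) |>
    dplyr::arrange(.data$delay_s, .by_group = TRUE) |>
    dplyr::group_modify(function(df, key) {
      f <- fit_monoexponential(df, method = method)
      tibble(R = f$R, R_se = f$R_se)
    }) |>
    dplyr::ungroup()
  wide <- tidyr::pivot_wider(rates, names_from = "component",
                             values_from = c("R", "R_se"))
  if (!all(c("R_alpha", "R_beta") %in% names(wide))) {
    abort("Each residue needs both an alpha and a beta decay.")
  }
  out <- wide |>
    dplyr::rowwise() |>
    dplyr::mutate(
      eta_xy = (.data$R_beta - .data$R_alpha) / 2,
      tau_c_ns = tract_tau_c(.data$R_alpha, .data$R_beta, cond, params),
      tau_c_err = {
        eta_se <- sqrt(.data$R_se_alpha^2 + .data$R_se_beta^2) / 2
        # numeric slope of the forward model at the solution
        h <- 1e-3
        deta <- (eta_xy_forward(.data$tau_c_ns + h, cond, params) -
                   eta_xy_forward(.data$tau_c_ns - h, cond, params)) / (2 * h)
        eta_se / deta
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::rename(R_alpha_se = "R_se_alpha", R_beta_se = "R_se_beta") |>
    dplyr::select(dplyr::all_of(c("residue", "R_alpha", "R_alpha_se",
                                  "R_beta", "R_beta_se", "eta_xy",
                                  "tau_c_ns", "tau_c_err")))
  if (!is.null(resnames)) out <- dplyr::left_join(out, resnames, by = "residue")
  out
}

#' Ensemble-average correlation time over a residue window
#'
#' Arithmetic mean, standard deviation and standard error of the
#' per-residue correlation times within a residue range — the
#' domain-average mobility reported for a folded core.
#'
#' @param results A [tract_fit()] tibble (columns `residue`, `tau_c_ns`).
#' @param residues Optional integer vector (e.g. `339:417`) restricting
#'   the average to the domain core; `NULL` uses all rows.
#' @return A one-row tibble: `n`, `tau_c_mean`, `tau_c_sd`, `tau_c_sem`.
#' @export
ensemble_tau_c <- function(results, residues = NULL) {
  results <- as_tibble(results)
  if (!all(c("residue", "tau_c_ns") %in% names(results))) {
    abort("`results` must carry `residue` and `tau_c_ns` columns (see `tract_fit()`).")
  }
  sel <- if (is.null(residues)) results else
    dplyr::filter(results, .data$residue %in% residues)
  if (nrow(sel) < 2) {
    abort("Ensemble averaging needs at least 2 residues in the selection.")
  }
  tibble(
    n = nrow(sel),
    tau_c_mean = mean(sel$tau_c_ns),
    tau_c_sd = sd(sel$tau_c_ns),
    tau_c_sem = sd(sel$tau_c_ns) / sqrt(nrow(sel))
  )
}

#' Difference of two ensemble correlation times
#'
#' `mean(b) - mean(a)` with the standard errors combined in quadrature —
#' e.g. the mobility decrement of a domain upon covalent cross-linking.
#'
#' @param a,b One-row tibbles from [ensemble_tau_c()] (a = reference
#'   state, b = perturbed state).
#' @return A one-row tibble: `delta_tau_c`, `delta_se`.
#' @export
tau_c_difference <- function(a, b) {
  tibble(
    delta_tau_c = b$tau_c_mean - a$tau_c_mean,
    delta_se = sqrt(a$tau_c_sem^2 + b$tau_c_sem^2)
  )
}
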