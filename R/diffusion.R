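#' Fit Stejskal-Tanner echo attenuation
#'
#' Nonlinear least squares of the pulsed-field-gradient stimulated-echo
#' attenuation law
#' \deqn{I(g) = I_0 \exp(-D (s \gamma g \delta)^2 (\Delta - \delta/3))}
#' to an intensity-versus-gradient series, yielding the translational
#' diffusion coefficient. `shape_factor` s is 1 for rectangular gradient
#' pulses (default) and 2/pi for sine-shaped pulses.
#'
#' @param data A data frame with columns `gradient_Tm` (gradient strength
#'   in T m^-1, strictly increasing, >= 5 points) and `intensity`.
#' @param delta Gradient pulse length in seconds.
#' @param Delta Diffusion delay in seconds (must exceed `delta`).
#' @param gamma Gyromagnetic ratio of the observed nucleus in
#'   rad s^-1 T^-1 (default 1H).
#' @param shape_factor Gradient shape factor (default 1, rectangular).
#' @return An object of class `dd_st_fit` with `D`, `D_se`, `I0`, the
#'   b-values and data. Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()]. A warning is raised when the attenuation is
#'   non-monotone beyond the fitted noise level.
#' @examples
#' s <- gen_pgste_series(D = 154e-12, noise = "none")
#' stejskal_tanner_fit(s, delta = attr(s, "delta"), Delta = attr(s, "Delta"))$D
#' @export
stejskal_tanner_fit <- function(data, delta, Delta, gamma = .gamma_1H,
                                shape_factor = 1) {
  data <- as_tibble(data)
  if (!all(c("gradient_Tm", "intensity") %in% names(data))) {
    abort("`data` must have columns `gradient_Tm` and `intensity`.")
  }
  g <- data$gradient_Tm; y <- data$intensity
  if (length(g) < 5) abort("Gradient series needs at least 5 points.")
  if (any(diff(g) <= 0)) abort("Gradient strengths must be strictly increasing.")
  if (!(delta > 0 && Delta > delta)) {
    abort("Need 0 < delta < Delta (seconds).")
  }
  if (y[1] <= 0) abort("Intensity at the minimum gradient must be positive.")
  b <- (shape_factor * gamma * g * delta)^2 * (Delta - delta / 3)
  # log-linear start
  pos <- y > 0
  ll <- lm(log(y[pos]) ~ b[pos])
  D0 <- unname(max(-coef(ll)[2], 1e-16))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ I0 * exp(-D * b),
                      start = list(I0 = unname(exp(coef(ll)[1])), D = D0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) abort(paste0("Stejskal-Tanner fit failed: ",
                                     conditionMessage(e)))
  )
  cf <- coef(fit); se <- suppressWarnings(sqrt(diag(vcov(fit))))
  resid <- stats::residuals(fit)
  sigma <- sqrt(sum(resid^2) / max(1, length(y) - 2))
  rises <- diff(y) > 3 * sigma
  if (any(rises)) {
    warn("Echo attenuation is non-monotone beyond the noise level; check for convection or phasing artefacts.")
  }
  structure(
    list(D = unname(cf["D"]), D_se = unname(se["D"]), I0 = unname(cf["I0"]),
         n = length(g), residual_norm = sqrt(sum(resid^2)),
         data = tibble(gradient_Tm = g, b = b, intensity = y),
         delta = delta, Delta = Delta, gamma = gamma,
         shape_factor = shape_factor),
    class = "dd_st_fit"
  )
}

#' @export
print.dd_st_fit <- function(x, ...) {
  cat(sprintf("<dd_st_fit> D = %.4g +/- %.2g m^2 s^-1 (%d gradients)\n",
              x$D, x$D_se, x$n))
  invisible(x)
}

#' Extrapolate a dilution series to infinite dilution
#'
#' Weighted linear fit of the first-order concentration dependence
#' \eqn{D(c) = D_0 (1 - k_c c)}: the intercept is the self-diffusion
#' coefficient free of obstruction and crowding. With a single
#' concentration no extrapolation is possible; that D is returned as
#' `D0` with `extrapolated = FALSE`.
#'
#' @param data A data frame with columns `conc_M` (mol L^-1), `D_m2s` and
#'   optionally `D_err` (used as 1/err^2 weights).
#' @return An object of class `dd_dilution_fit` with `D0`, `D0_se`, `k_c`
#'   (L mol^-1), `extrapolated` and the data. Supports [tidy()] and
#'   [glance()].
#' @examples
#' d <- tibble::tibble(conc_M = c(2.5e-4, 5e-4, 1e-3),
#'                     D_m2s = 154e-12 * (1 - 45 * conc_M))
#' extrapolate_D0(d)$D0
#' @export
extrapolate_D0 <- function(data) {
  data <- as_tibble(data)
  if (!all(c("conc_M", "D_m2s") %in% names(data))) {
    abort("`data` must have columns `conc_M` and `D_m2s`.")
  }
  if (any(data$conc_M < 0) || any(data$D_m2s <= 0)) {
    abort("Concentrations must be non-negative and D values positive.")
  }
  n_conc <- length(unique(data$conc_M))
  if (n_conc < 2) {
    warn("Single concentration: returning D as D0 without extrapolation.")
    return(structure(
      list(D0 = mean(data$D_m2s),
           D0_se = if ("D_err" %in% names(data)) mean(data$D_err) else NA_real_,
           k_c = NA_real_, k_c_se = NA_real_, extrapolated = FALSE,
           data = data),
      class = "dd_dilution_fit"
    ))
  }
  w <- if ("D_err" %in% names(data) && all(is.finite(data$D_err)) &&
           all(data$D_err > 0)) 1 / data$D_err^2 else NULL
  fit <- lm(D_m2s ~ conc_M, data = data, weights = w)
  cf <- coef(fit)
  se <- suppressWarnings(sqrt(diag(vcov(fit))))
  D0 <- unname(cf[1])
  slope <- unname(cf[2])
  structure(
    list(D0 = D0,
         D0_se = unname(se[1]),
         k_c = -slope / D0,          # D(c) = D0 (1 - k_c c)
         k_c_se = unname(se[2]) / D0,
         extrapolated = TRUE,
         data = data),
    class = "dd_dilution_fit"
  )
}

#' @export
print.dd_dilution_fit <- function(x, ...) {
  cat(sprintf("<dd_dilution_fit> D0 = %.4g +/- %.2g m^2 s^-1%s\n",
              x$D0, x$D0_se,
              if (x$extrapolated) sprintf(", k_c = %.3g L mol^-1", x$k_c)
              else " (single concentration, not extrapolated)"))
  invisible(x)
}
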