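#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   labs theme_minimal
#' @export
ggplot2::autoplot

#' Diagnostic plots for fitted objects
#'
#' `autoplot()` methods overlay the fitted model on the data for each fit
#' class; `plot_gcs_profile()` and `plot_tauc_profile()` draw the
#' per-residue bar profiles.
#'
#' @param object A fitted object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name ddstate-plots
NULL

.curve_tbl <- function(x, f, n = 200) {
  xs <- seq(min(x), max(x), length.out = n)
  tibble(x = xs, y = f(xs))
}

#' @rdname ddstate-plots
#' @export
autoplot.dd_decay_fit <- function(object, ...) {
  fit <- .curve_tbl(object$data$delay_s,
                    function(t) object$I0 * exp(-object$R * t))
  ggplot(object$data, aes(x = .data$delay_s, y = .data$intensity)) +
    geom_line(data = fit, aes(x = .data$x, y = .data$y), colour = "grey40") +
    geom_point() +
    labs(x = "relaxation delay (s)", y = "intensity",
         title = sprintf("R = %.3g +/- %.2g s^-1", object$R, object$R_se)) +
    theme_minimal()
}

#' @rdname ddstate-plots
#' @export
autoplot.dd_st_fit <- function(object, ...) {
  fit <- .curve_tbl(object$data$b,
                    function(b) object$I0 * exp(-object$D * b))
  ggplot(object$data, aes(x = .data$b, y = .data$intensity)) +
    geom_line(data = fit, aes(x = .data$x, y = .data$y), colour = "grey40") +
    geom_point() +
    labs(x = expression(b ~ (s ~ m^-2)), y = "intensity",
         title = sprintf("D = %.4g m^2 s^-1", object$D)) +
    theme_minimal()
}

#' @rdname ddstate-plots
#' @export
autoplot.dd_kinetic_fit <- function(object, ...) {
  f <- if (object$model == "first_order") {
    function(t) object$I0 * exp(-object$k * t)
  } else {
    function(t) second_order_monomer(t, object$M0, object$k) / object$M0
  }
  fit <- .curve_tbl(object$data$time, f)
  ylab <- if (object$model == "first_order") "value" else "monomer fraction"
  ggplot(object$data, aes(x = .data$time, y = .data$value)) +
    geom_line(data = fit, aes(x = .data$x, y = .data$y), colour = "grey40") +
    geom_point() +
    labs(x = sprintf("time (%s)", object$time_unit), y = ylab,
         title = sprintf("%s: k = %.4g +/- %.2g", object$model,
                         object$k, object$k_se)) +
    theme_minimal()
}

#' @rdname ddstate-plots
#' @export
autoplot.dd_deconv_fit <- function(object, ...) {
  shape <- if (object$lineshape == "lorentzian") .lorentz else .gauss
  x <- object$data$ppm
  comps <- purrr::imap(object$areas, function(a, i) {
    tibble(ppm = x,
           amplitude = shape(x, object$centers[i], object$widths[i], a),
           component = paste0("state ", i))
  })
  comp_tbl <- dplyr::bind_rows(comps)
  ggplot(object$data, aes(x = .data$ppm, y = .data$amplitude)) +
    geom_point(size = 0.6, colour = "grey50") +
    geom_line(data = comp_tbl, aes(colour = .data$component)) +
    ggplot2::scale_x_reverse() +
    labs(x = "ppm", y = "amplitude",
         title = sprintf("populations: %s",
                         paste(sprintf("%.2f", object$populations),
                               collapse = " / "))) +
    theme_minimal()
}

#' @rdname ddstate-plots
#' @param profile A tibble with `residue` and `gcs` columns.
#' @param threshold Classification cutoff drawn as a horizontal line.
#' @export
plot_gcs_profile <- function(profile, threshold = dd_config()$gcs_threshold) {
  ggplot(profile, aes(x = .data$residue, y = .data$gcs)) +
    geom_col(width = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    labs(x = "residue", y = "generalized chemical shift (ppm)") +
    theme_minimal()
}

#' @rdname ddstate-plots
#' @param results A [tract_fit()] tibble.
#' @export
plot_tauc_profile <- function(results) {
  ggplot(results, aes(x = .data$residue, y = .data$tau_c_ns)) +
    geom_col(width = 0.8) +
    ggplot2::geom_errorbar(aes(ymin = .data$tau_c_ns - .data$tau_c_err,
                               ymax = .data$tau_c_ns + .data$tau_c_err),
                           width = 0) +
    labs(x = "residue", y = expression(tau[c] ~ (ns))) +
    theme_minimal()
}
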