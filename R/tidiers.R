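#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for fitted objects
#'
#' broom-style `tidy()` (one row per estimated term) and `glance()` (one
#' row per fit) methods for the package's fit classes.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name ddstate-tidiers
NULL

#' @rdname ddstate-tidiers
#' @export
tidy.dd_decay_fit <- function(x, ...) {
  tibble(term = c("R", "I0"),
         estimate = c(x$R, x$I0),
         std.error = c(x$R_se, NA_real_))
}

#' @rdname ddstate-tidiers
#' @export
glance.dd_decay_fit <- function(x, ...) {
  tibble(R = x$R, R_se = x$R_se, I0 = x$I0, n = x$n,
         residual_norm = x$residual_norm, method = x$method)
}

#' @rdname ddstate-tidiers
#' @export
tidy.dd_st_fit <- function(x, ...) {
  tibble(term = c("D", "I0"),
         estimate = c(x$D, x$I0),
         std.error = c(x$D_se, NA_real_))
}

#' @rdname ddstate-tidiers
#' @export
glance.dd_st_fit <- function(x, ...) {
  tibble(D = x$D, D_se = x$D_se, I0 = x$I0, n = x$n,
         residual_norm = x$residual_norm)
}

#' @rdname ddstate-tidiers
#' @export
tidy.dd_dilution_fit <- function(x, ...) {
  tibble(term = c("D0", "k_c"),
         estimate = c(x$D0, x$k_c),
         std.error = c(x$D0_se, x$k_c_se))
}

#' @rdname ddstate-tidiers
#' @export
glance.dd_dilution_fit <- function(x, ...) {
  tibble(D0 = x$D0, D0_se = x$D0_se, k_c = x$k_c,
         extrapolated = x$extrapolated, n = nrow(x$data))
}

#' @rdname ddstate-tidiers
#' @export
tidy.dd_kinetic_fit <- function(x, ...) {
  if (x$model == "first_order") {
    tibble(term = c("k", "t_half", "I0"),
           estimate = c(x$k, x$t_half, x$I0),
           std.error = c(x$k_se, x$k_se * log(2) / x$k^2, NA_real_))
  } else {
    tibble(term = "k", estimate = x$k, std.error = x$k_se)
  }
}

#' @rdname ddstate-tidiers
#' @export
glance.dd_kinetic_fit <- function(x, ...) {
  if (x$model == "first_order") {
    tibble(model = x$model, k = x$k, k_se = x$k_se, t_half = x$t_half,
           time_unit = x$time_unit, n = x$n)
  } else {
    tibble(model = x$model, k = x$k, k_se = x$k_se, M0 = x$M0, n = x$n)
  }
}

#' @rdname ddstate-tidiers
#' @export
tidy.dd_deconv_fit <- function(x, ...) {
  k <- length(x$populations)
  tibble(component = seq_len(k),
         population = x$populations,
         center_ppm = x$centers,
         width_ppm = x$widths,
         area = x$areas)
}

#' @rdname ddstate-tidiers
#' @export
glance.dd_deconv_fit <- function(x, ...) {
  tibble(n_components = length(x$populations),
         lineshape = x$lineshape,
         degenerate = x$degenerate,
         residual_norm = x$residual_norm)
}
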