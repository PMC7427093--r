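#' Fit first-order decay kinetics
#'
#' Models an irreversible first-order loss \eqn{I(t) = I_0 e^{-kt}} — e.g.
#' the disappearance of an asparagine-bearing protein state undergoing
#' spontaneous deamidation. The default fit is a weighted linear
#' regression of `ln(value)` on time (the presentation-space fit for data
#' plotted on a log scale); a direct nonlinear fit is available via
#' `method = "nonlinear"`.
#'
#' @param data A data frame with columns `time`, `value` and optionally
#'   `error` (standard errors of `value`; propagated into log-space
#'   weights for the default method).
#' @param time_unit Unit tag carried into the result (`"days"` default,
#'   or `"seconds"`, `"hours"`).
#' @param method `"log_linear"` (default) or `"nonlinear"`.
#' @return An object of class `dd_kinetic_fit` with `model =
#'   "first_order"`, the rate `k` (per `time_unit`), `k_se`, the
#'   half-life `t_half = ln 2 / k`, `I0`, and the data. Supports
#'   [tidy()], [glance()] and [ggplot2::autoplot()].
#' @examples
#' tc <- tibble::tibble(time = c(0, 2, 4, 6, 9, 12, 16, 19),
#'                      value = exp(-0.1406 * time))
#' fit_first_order(tc)$t_half # ~4.93 days
#' @export
fit_first_order <- function(data, time_unit = "days",
                            method = c("log_linear", "nonlinear")) {
  method <- match.arg(method)
  data <- as_tibble(data)
  if (!all(c("time", "value") %in% names(data))) {
    abort("`data` must have columns `time` and `value`.")
  }
  t <- data$time; y <- data$value
  if (length(t) < 4) abort("First-order fitting needs at least 4 time points.")
  if (any(diff(t) <= 0)) abort("Times must be strictly increasing.")
  if (any(y <= 0)) {
    abort("All values must be positive for first-order (log-space) fitting.")
  }
  if (method == "log_linear") {
    w <- if ("error" %in% names(data) && all(is.finite(data$error)) &&
             all(data$error > 0)) (y / data$error)^2 else NULL
    fit <- lm(log(y) ~ t, weights = w)
    k <- -unname(coef(fit)[2])
    k_se <- unname(suppressWarnings(sqrt(vcov(fit)[2, 2])))
    I0 <- exp(unname(coef(fit)[1]))
  } else {
    ll <- lm(log(y) ~ t)
    fit <- minpack.lm::nlsLM(y ~ I0 * exp(-k * t),
                             start = list(I0 = unname(exp(coef(ll)[1])),
                                          k = unname(max(-coef(ll)[2], 1e-8))))
    cf <- coef(fit)
    k <- unname(cf["k"]); I0 <- unname(cf["I0"])
    k_se <- unname(suppressWarnings(sqrt(diag(vcov(fit))))["k"])
  }
  if (k <= 0 || k < 2 * k_se) {
    warn(sprintf(
      "Degenerate first-order fit: k = %.3g +/- %.3g per %s is indistinguishable from no decay.",
      k, k_se, time_unit))
  }
  structure(
    list(model = "first_order", k = k, k_se = k_se,
         t_half = log(2) / k, I0 = I0, time_unit = time_unit,
         method = method, n = length(t),
         data = tibble(time = t, value = y)),
    class = "dd_kinetic_fit"
  )
}

#' Monomer concentration under irreversible second-order dimerization
#'
#' Closed-form solution of \eqn{d[M]/dt = -k[M]^2}:
#' \deqn{[M]_t = [M]_0 / (1 + [M]_0 k t).}
#' Concentrations are in mole-protein per mole-lipid (the natural unit for
#' a membrane-confined reaction), so `k` carries units of
#' (mole_lipid/mole_protein) per second.
#'
#' @param t Time in seconds (vectorised).
#' @param M0 Initial monomer concentration, mole/mole lipid.
#' @param k Second-order rate constant, (mole_lipid/mole_protein) s^-1.
#' @return Monomer concentration at `t`, mole/mole lipid.
#' @examples
#' second_order_monomer(1 / (1e-3 * 1.08e-3), M0 = 1e-3, k = 1.08e-3) # M0/2
#' @export
second_order_monomer <- function(t, M0, k) {
  if (M0 <= 0) abort("`M0` must be positive (mole/mole lipid).")
  if (k < 0) abort("`k` must be non-negative.")
  if (any(t < 0)) abort("`t` must be non-negative (seconds).")
  M0 / (1 + M0 * k * t)
}

#' Fit irreversible second-order dimerization kinetics
#'
#' Nonlinear least squares of the closed form [second_order_monomer()] to
#' a monomer-fraction time course. Fractions are converted to mole/mole
#' concentrations via the known initial loading `M0 = 1/LPR`, so the
#' fitted rate constant is in the lipid-relative unit system and directly
#' comparable across membranes of different lipid-to-protein ratio.
#'
#' @param data A data frame with columns `time` (seconds) and `value`
#'   (monomer fraction in (0, 1]); optional `error` column used as
#'   1/err^2 weights.
#' @param M0 Initial monomer concentration in mole-protein per mole-lipid
#'   (i.e. 1/LPR).
#' @return An object of class `dd_kinetic_fit` with `model =
#'   "second_order"`, `k` ((mole_lipid/mole_protein) s^-1), `k_se`, `M0`
#'   and the data.
#' @examples
#' tc <- gen_dimerization_course(k = 1.08e-3, M0 = 1e-3, noise = "none")
#' fit_second_order(tc, M0 = 1e-3)$k
#' @export
fit_second_order <- function(data, M0) {
  data <- as_tibble(data)
  if (!all(c("time", "value") %in% names(data))) {
    abort("`data` must have columns `time` (s) and `value` (monomer fraction).")
  }
  if (M0 <= 0) abort("`M0` must be positive (mole/mole lipid; M0 = 1/LPR).")
  t <- data$time; f <- data$value
  if (length(t) < 4) abort("Second-order fitting needs at least 4 time points.")
  if (any(f <= 0) || any(f > 1 + 1e-6)) {
    abort("`value` must be monomer fractions in (0, 1].")
  }
  M <- f * M0
  # two-point closed-form start: 1/M = 1/M0 + k t
  inv_slope <- (1 / M[length(M)] - 1 / M[1]) / (t[length(t)] - t[1])
  # floor the start at a rate producing ~10% decay over the course, so a
  # flat (k ~ 0) course still starts the optimizer off the boundary
  k0 <- max(inv_slope, 0.1 / (M0 * max(t)))
  w <- if ("error" %in% names(data) && all(is.finite(data$error)) &&
           all(data$error > 0)) 1 / data$error^2 else NULL
  # fit on the O(1) fraction scale; the model is f(t) = 1/(1 + M0 k t)
  fit <- tryCatch(
    if (is.null(w)) {
      minpack.lm::nlsLM(f ~ 1 / (1 + M0 * k * t),
                        start = list(k = k0), lower = 0,
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    } else {
      minpack.lm::nlsLM(f ~ 1 / (1 + M0 * k * t),
                        start = list(k = k0), weights = w, lower = 0,
                        control = minpack.lm::nls.lm.control(maxiter = 500))
    },
    error = function(e) abort(paste0(
      "Second-order fit failed: ", conditionMessage(e),
      " (residual norm at start: ",
      signif(sqrt(sum((f - 1 / (1 + M0 * k0 * t))^2)), 4), ")"))
  )
  k <- unname(coef(fit)["k"])
  k_se <- unname(suppressWarnings(sqrt(diag(vcov(fit))))["k"])
  structure(
    list(model = "second_order", k = k, k_se = k_se, M0 = M0,
         time_unit = "seconds", n = length(t),
         residual_norm = sqrt(sum(stats::residuals(fit)^2)),
         data = tibble(time = t, value = f)),
    class = "dd_kinetic_fit"
  )
}

#' @export
print.dd_kinetic_fit <- function(x, ...) {
  if (x$model == "first_order") {
    cat(sprintf("<dd_kinetic_fit> first-order: k = %.4g +/- %.2g per %s, t1/2 = %.3g %s\n",
                x$k, x$k_se, x$time_unit, x$t_half, x$time_unit))
  } else {
    cat(sprintf("<dd_kinetic_fit> second-order: k = %.4g +/- %.2g (mol_lipid/mol_protein) s^-1, M0 = %.3g\n",
                x$k, x$k_se, x$M0))
  }
  invisible(x)
}

#' Monomer fraction from gel band densitometry
#'
#' Converts non-reducing SDS-PAGE band intensities into the monomer mass
#' fraction `I_monomer / sum(I)`, per lane. Band intensity is taken as
#' proportional to protein mass, so no molar correction is applied to
#' oligomer bands.
#'
#' @param data A data frame with columns `band` (one of `monomer`,
#'   `dimer`, `tetramer`, `hexamer`, `higher`) and `intensity` (>= 0);
#'   optional `lane` and `time` columns group lanes.
#' @return A tibble with one row per lane: grouping columns plus
#'   `fraction`.
#' @examples
#' gel_monomer_fraction(tibble::tibble(band = c("monomer", "dimer"),
#'                                     intensity = c(1, 1)))
#' @export
gel_monomer_fraction <- function(data) {
  data <- as_tibble(data)
  if (!all(c("band", "intensity") %in% names(data))) {
    abort("`data` must have columns `band` and `intensity`.")
  }
  valid <- c("monomer", "dimer", "tetramer", "hexamer", "higher")
  if (!all(data$band %in% valid)) {
    abort(paste0("`band` must be one of: ", paste(valid, collapse = ", "), "."))
  }
  if (any(data$intensity < 0)) abort("Band intensities must be non-negative.")
  groups <- intersect(c("lane", "time"), names(data))
  out <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      total = sum(.data$intensity),
      fraction = sum(.data$intensity[.data$band == "monomer"]) / sum(.data$intensity),
      .groups = "drop"
    )
  if (any(out$total == 0)) {
    abort("A lane has all-zero band intensities; the monomer fraction is undefined.")
  }
  dplyr::select(out, -"total")
}

#' Cell geometry for the lipid-to-protein-ratio estimate
#'
#' @param s_cell_um2 Surface area of one cell, square micrometers.
#' @param s_lip_um2 Surface area of one lipid molecule, square
#'   micrometers.
#' @param c_prot_g_l Protein expression level, grams per litre of
#'   culture.
#' @param mw_g_mol Protein molecular mass, g mol^-1.
#' @param c_cell_per_ml Cell density, cells per millilitre.
#' @param avogadro Avogadro constant (full CODATA value by default; the
#'   order-of-magnitude presets round it).
#' @return A list of class `dd_cell_geometry`.
#' @export
cell_geometry <- function(s_cell_um2, s_lip_um2, c_prot_g_l, mw_g_mol,
                          c_cell_per_ml, avogadro = .N_A) {
  vals <- c(s_cell_um2, s_lip_um2, c_prot_g_l, mw_g_mol, c_cell_per_ml, avogadro)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All cell-geometry fields must be finite and strictly positive.")
  }
  structure(list(s_cell_um2 = s_cell_um2, s_lip_um2 = s_lip_um2,
                 c_prot_g_l = c_prot_g_l, mw_g_mol = mw_g_mol,
                 c_cell_per_ml = c_cell_per_ml, avogadro = avogadro),
            class = "dd_cell_geometry")
}

#' Lipid-to-protein molar ratio of a cell membrane
#'
#' Estimates the LPR of an expression host membrane from cell geometry and
#' expression level: the number of lipids per cell is
#' \eqn{N_{lip} = 2 S_{cell} / S_{lip}} (two leaflets), the number of
#' target-protein molecules per cell is
#' \eqn{N_{prot} = C_{prot} N_A / (MW \cdot C_{cell})}, and
#' \eqn{LPR = N_{lip} / N_{prot}}. The one-significant-figure rounding is
#' the natural presentation for an order-of-magnitude estimate.
#'
#' @param geom A [cell_geometry()] object.
#' @return A one-row tibble: `n_lip`, `n_prot` (molecules per cell),
#'   `lpr`, `lpr_1sf`.
#' @examples
#' lpr_membrane(lpr_ecoli_geometry()) # ~191, 1 s.f. 200
#' @export
lpr_membrane <- function(geom) {
  stopifnot(inherits(geom, "dd_cell_geometry"))
  n_lip <- 2 * geom$s_cell_um2 / geom$s_lip_um2
  c_cell_per_l <- geom$c_cell_per_ml * 1000
  n_prot <- geom$c_prot_g_l * geom$avogadro / (geom$mw_g_mol * c_cell_per_l)
  lpr <- n_lip / n_prot
  tibble(n_lip = n_lip, n_prot = n_prot, lpr = lpr, lpr_1sf = signif(lpr, 1))
}

#' E. coli membrane geometry preset
#'
#' The standard constants for an induced E. coli culture expressing a
#' single-pass membrane receptor: cell surface 4 um^2, DMPC-like lipid
#' area 0.6e-6 um^2, expression level 6 mg L^-1, protein mass
#' 21486 g mol^-1, cell density 24e8 cells mL^-1 and Avogadro's number
#' rounded to 6e23 (an order-of-magnitude estimate keeps rounded
#' constants throughout).
#'
#' @return A [cell_geometry()] object.
#' @export
lpr_ecoli_geometry <- function() {
  cell_geometry(s_cell_um2 = 4, s_lip_um2 = 0.6e-6,
                c_prot_g_l = 6e-3, mw_g_mol = 21486,
                c_cell_per_ml = 24e8, avogadro = 6e23)
}

#' @rdname lpr_membrane
#' @export
lpr_ecoli <- function(geom = lpr_ecoli_geometry()) lpr_membrane(geom)
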