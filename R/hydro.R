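#' Hydrodynamic radius from the rotational correlation time
#'
#' Inverts the Stokes-Einstein-Debye relation
#' \deqn{\tau_c = 4 \pi \eta r_h^3 / (3 k_B T)}
#' for the radius of the equivalent sphere: a molecule tumbling with
#' correlation time `tau_c` under the given temperature and viscosity has
#' \deqn{r_h = (3 k_B T \tau_c / (4 \pi \eta))^{1/3}.}
#'
#' @param tau_c Rotational correlation time in nanoseconds (vectorised).
#' @param cond A [conditions()] object.
#' @return Hydrodynamic radius in nanometers.
#' @examples
#' tau_c_to_rh(6.03, conditions(303.15)) # ~1.96 nm
#' @export
tau_c_to_rh <- function(tau_c, cond = conditions()) {
  cond <- as_conditions(cond)
  if (any(!is.finite(tau_c)) || any(tau_c <= 0)) {
    abort("`tau_c` must be positive and finite (nanoseconds).")
  }
  r_m <- (3 * .kB * cond$temperature * tau_c * 1e-9 /
            (4 * pi * cond$viscosity))^(1 / 3)
  r_m * 1e9
}

#' @rdname tau_c_to_rh
#' @param r_h Hydrodynamic radius in nanometers.
#' @export
rh_to_tau_c <- function(r_h, cond = conditions()) {
  cond <- as_conditions(cond)
  if (any(!is.finite(r_h)) || any(r_h <= 0)) {
    abort("`r_h` must be positive and finite (nanometers).")
  }
  4 * pi * cond$viscosity * (r_h * 1e-9)^3 / (3 * .kB * cond$temperature) * 1e9
}

#' Hydrodynamic radius from the translational diffusion coefficient
#'
#' The Stokes-Einstein relation \eqn{D = k_B T / (6 \pi \eta r_h)} solved
#' for the radius.
#'
#' @param D Translational diffusion coefficient in m^2 s^-1 (vectorised).
#' @param cond A [conditions()] object.
#' @return Hydrodynamic radius in nanometers.
#' @examples
#' d_to_rh(154e-12, conditions(303.15)) # ~1.80 nm
#' @export
d_to_rh <- function(D, cond = conditions()) {
  cond <- as_conditions(cond)
  if (any(!is.finite(D)) || any(D <= 0)) {
    abort("`D` must be positive and finite (m^2 s^-1).")
  }
  .kB * cond$temperature / (6 * pi * cond$viscosity * D) * 1e9
}

#' @rdname d_to_rh
#' @param r_h Hydrodynamic radius in nanometers.
#' @export
rh_to_d <- function(r_h, cond = conditions()) {
  cond <- as_conditions(cond)
  if (any(!is.finite(r_h)) || any(r_h <= 0)) {
    abort("`r_h` must be positive and finite (nanometers).")
  }
  .kB * cond$temperature / (6 * pi * cond$viscosity * r_h * 1e-9)
}

#' Effective molecular weight of a globular protein from its radius
#'
#' Two-parameter power law \eqn{MW = A r_h^b} (kDa, nm) relating the
#' hydrodynamic radius of the equivalent sphere to the mass of a compact
#' globular protein. The shipped constants A = 1.91, b = 2.85 were
#' calibrated once against monomeric death-domain reference pairs
#' (1.96 nm / 13.0 kDa and 1.80 nm / 10.2 kDa); [calibrate_rh_mw()]
#' regenerates them from any such pair set. The power law is an
#' approximation: compact folded monomers are reproduced to the printed
#' precision, elongated or cross-linked species can deviate by a few
#' percent.
#'
#' @param r_h Hydrodynamic radius in nanometers (vectorised).
#' @param A,b Calibration constants; defaults from [dd_config()].
#' @return Molecular weight in kDa.
#' @examples
#' rh_to_mw(1.96) # ~13.0 kDa
#' @export
rh_to_mw <- function(r_h, A = dd_config()$mw_A, b = dd_config()$mw_b) {
  if (any(!is.finite(r_h)) || any(r_h <= 0)) {
    abort("`r_h` must be positive and finite (nanometers).")
  }
  A * r_h^b
}

#' @rdname rh_to_mw
#' @param mw Molecular weight in kDa.
#' @export
mw_to_rh <- function(mw, A = dd_config()$mw_A, b = dd_config()$mw_b) {
  if (any(!is.finite(mw)) || any(mw <= 0)) abort("`mw` must be positive (kDa).")
  (mw / A)^(1 / b)
}

#' Calibrate the radius-to-mass power law
#'
#' Least-squares fit of \eqn{\log MW = \log A + b \log r_h} to reference
#' (radius, mass) pairs; with exactly two pairs this is the line through
#' them.
#'
#' @param r_h Radii in nm.
#' @param mw Masses in kDa.
#' @return A list with elements `A` (kDa) and `b`.
#' @examples
#' calibrate_rh_mw(c(1.96, 1.80), c(13.0, 10.2))
#' @export
calibrate_rh_mw <- function(r_h, mw) {
  if (length(r_h) < 2 || length(r_h) != length(mw)) {
    abort("Need at least two (r_h, mw) pairs of equal length.")
  }
  if (any(r_h <= 0) || any(mw <= 0)) abort("Radii and masses must be positive.")
  fit <- lm(log(mw) ~ log(r_h))
  list(A = unname(exp(coef(fit)[1])), b = unname(coef(fit)[2]))
}

# Standard average masses of amino-acid residues (Da), i.e. the monomer
# masses minus one water; a chain's mass is the residue sum plus 18.01528.
.residue_mass <- c(
  A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
  S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326
)
.water_mass <- 18.01528

#' Average molecular weight of a protein sequence
#'
#' Sums standard average (not monoisotopic) residue masses and adds one
#' water for the free termini. The empty sequence returns the mass of
#' water.
#'
#' @param sequence A character vector of one-letter amino-acid sequences
#'   (the 20 canonical codes; case-insensitive, whitespace ignored).
#' @return Mass in kDa, one value per input sequence.
#' @examples
#' sequence_mw("GS") # 0.16215 kDa
#' @export
sequence_mw <- function(sequence) {
  vapply(sequence, function(s) {
    s <- toupper(gsub("[[:space:]]", "", s))
    if (nchar(s) == 0) return(.water_mass / 1000)
    aa <- strsplit(s, "")[[1]]
    bad <- which(!aa %in% names(.residue_mass))
    if (length(bad)) {
      abort(sprintf(
        "Unknown amino-acid code '%s' at position %d (only the 20 canonical one-letter codes are accepted).",
        aa[bad[1]], bad[1]
      ))
    }
    (sum(.residue_mass[aa]) + .water_mass) / 1000
  }, numeric(1), USE.NAMES = FALSE)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Call the oligomeric state from hydrodynamic observables
#'
#' The core inference: converts a rotational correlation time and/or a
#' translational diffusion coefficient to hydrodynamic radii
#' ([tau_c_to_rh()], [d_to_rh()]), maps each radius to an effective
#' molecular weight ([rh_to_mw()]) and compares the mean predicted mass
#' with the sequence mass of the monomer. The oligomer number is the mean
#' predicted-to-monomer mass ratio rounded half away from zero (clamped to
#' at least 1); labels are `monomer` (n = 1), `dimer` (n = 2),
#' `higher-order` (n >= 3). When the rotational and translational calls
#' disagree after rounding, the rotational call is reported (rotation is
#' the lead observable) and `disagreement` is set.
#'
#' @param tau_c Rotational correlation time in ns, or `NA`.
#' @param D Translational diffusion coefficient in m^2 s^-1, or `NA`.
#' @param mw_monomer Monomer molecular weight in kDa.
#' @param cond A [conditions()] object.
#' @param A,b Radius-to-mass calibration constants (see [rh_to_mw()]).
#' @return A one-row tibble: `rh_rot`, `rh_trans` (nm), `mw_rot`,
#'   `mw_trans`, `mw_monomer` (kDa), `n_oligomer`, `label`, `disagreement`.
#' @examples
#' classify_oligomer(tau_c = 6.0, D = 154e-12, mw_monomer = 10.6)
#' classify_oligomer(tau_c = 10.3, D = 123e-12, mw_monomer = 10.6)
#' @export
classify_oligomer <- function(tau_c = NA, D = NA, mw_monomer, cond = conditions(),
                              A = dd_config()$mw_A, b = dd_config()$mw_b) {
  cond <- as_conditions(cond)
  if (!is.numeric(mw_monomer) || length(mw_monomer) != 1 || mw_monomer <= 0) {
    abort("`mw_monomer` must be a single positive number (kDa).")
  }
  has_rot   <- length(tau_c) == 1 && is.finite(tau_c)
  has_trans <- length(D) == 1 && is.finite(D)
  if (!has_rot && !has_trans) {
    abort("At least one of `tau_c` and `D` must be given.")
  }
  rh_rot   <- if (has_rot)   tau_c_to_rh(tau_c, cond) else NA_real_
  rh_trans <- if (has_trans) d_to_rh(D, cond)         else NA_real_
  mw_rot   <- if (has_rot)   rh_to_mw(rh_rot, A, b)   else NA_real_
  mw_trans <- if (has_trans) rh_to_mw(rh_trans, A, b) else NA_real_

  n_of <- function(mw_pred) max(1, round_half_away(mw_pred / mw_monomer))
  n_mean <- n_of(mean(c(mw_rot, mw_trans), na.rm = TRUE))
  disagreement <- FALSE
  n <- n_mean
  if (has_rot && has_trans) {
    n_rot <- n_of(mw_rot); n_trans <- n_of(mw_trans)
    if (n_rot != n_trans) {
      disagreement <- TRUE
      n <- n_rot
    }
  }
  label <- if (n == 1) "monomer" else if (n == 2) "dimer" else "higher-order"
  tibble(
    rh_rot = rh_rot, rh_trans = rh_trans,
    mw_rot = mw_rot, mw_trans = mw_trans,
    mw_monomer = mw_monomer,
    n_oligomer = as.integer(n), label = label,
    disagreement = disagreement
  )
}

#' Oligomeric-state table for a set of constructs
#'
#' Data-frame front end to [classify_oligomer()]: one row per construct
#' with measured observables in, the full hydrodynamic chain out.
#'
#' @param data A data frame with columns `construct`, `tau_c_ns`, `D_m2s`
#'   (either observable may be `NA` per row) and either an `mw_kda` column
#'   or the `mw_monomer` argument; optional `tau_c_err`, `D_err` columns
#'   are carried through.
#' @param cond A [conditions()] object.
#' @param mw_monomer Monomer mass in kDa applied to every row lacking
#'   `mw_kda`.
#' @param A,b Radius-to-mass calibration constants.
#' @return A tibble with the input identification columns plus the columns
#'   of [classify_oligomer()].
#' @examples
#' tbl <- tibble::tibble(
#'   construct = c("DD", "DD cross-linked"),
#'   tau_c_ns = c(6.0, 10.3), D_m2s = c(154e-12, 123e-12)
#' )
#' oligomer_state(tbl, mw_monomer = 10.6)
#' @export
oligomer_state <- function(data, cond = conditions(), mw_monomer = NULL,
                           A = dd_config()$mw_A, b = dd_config()$mw_b) {
  data <- as_tibble(data)
  if (!nrow(data)) abort("`data` has no rows.")
  if (!"construct" %in% names(data)) data$construct <- paste0("row", seq_len(nrow(data)))
  if (!"tau_c_ns" %in% names(data)) data$tau_c_ns <- NA_real_
  if (!"D_m2s" %in% names(data)) data$D_m2s <- NA_real_
  if (all(is.na(data$tau_c_ns)) && all(is.na(data$D_m2s))) {
    abort("`data` must carry at least one of `tau_c_ns`, `D_m2s` with values.")
  }
  mono <- if ("mw_kda" %in% names(data)) data$mw_kda else {
    if (is.null(mw_monomer)) {
      abort("Supply a per-row `mw_kda` column or the `mw_monomer` argument (kDa).")
    }
    rep(mw_monomer, nrow(data))
  }
  calls <- purrr::pmap(
    list(data$tau_c_ns, data$D_m2s, mono),
    function(tc, d, m) classify_oligomer(tau_c = tc, D = d, mw_monomer = m,
                                         cond = cond, A = A, b = b)
  )
  dplyr::bind_cols(
    dplyr::select(data, dplyr::any_of(c("construct", "tau_c_ns", "tau_c_err",
                                        "D_m2s", "D_err", "conc_M"))),
    dplyr::bind_rows(calls)
  )
}
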