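#' Generalized chemical-shift change
#'
#' Weighted Euclidean combination of amide proton and nitrogen shift
#' differences,
#' \deqn{GCS = \sqrt{\Delta\delta_H^2 + (w\,\Delta\delta_N)^2},}
#' the per-residue scalar used to quantify a perturbation between two
#' states in 1H,15N correlation spectra. The default nitrogen weight 0.2
#' compensates for the wider 15N dispersion.
#'
#' @param delta_h,delta_n Shift differences in ppm (vectorised).
#' @param weight Nitrogen weight (> 0; default 0.2).
#' @return GCS in ppm.
#' @examples
#' gcs(0.06, 0.5) # 0.1166
#' @export
gcs <- function(delta_h, delta_n, weight = dd_config()$gcs_weight) {
  if (!is.numeric(weight) || length(weight) != 1 || weight <= 0) {
    abort("`weight` must be a single positive number.")
  }
  sqrt(delta_h^2 + (weight * delta_n)^2)
}

#' Per-residue chemical-shift perturbation profile
#'
#' Matches two peak lists by `(residue, atom)` key and computes the
#' generalized chemical-shift change per residue. Residues present in
#' only one list are dropped (peak matching relies on assignments, no
#' nearest-peak fallback).
#'
#' @param a,b Peak-list tibbles (see [read_peak_list()]): columns
#'   `residue`, `shift_h_ppm`, `shift_n_ppm`; optional `resname`.
#' @param weight Nitrogen weight passed to [gcs()].
#' @return A tibble with `residue` (+ `resname` when available),
#'   `delta_h`, `delta_n`, `gcs`.
#' @export
gcs_profile <- function(a, b, weight = dd_config()$gcs_weight) {
  need <- c("residue", "shift_h_ppm", "shift_n_ppm")
  for (nm in list(a = a, b = b)) {
    if (!all(need %in% names(nm))) {
      abort("Peak lists need columns `residue`, `shift_h_ppm`, `shift_n_ppm`.")
    }
  }
  joined <- dplyr::inner_join(
    dplyr::select(as_tibble(a), dplyr::any_of(c("residue", "resname")),
                  h_a = "shift_h_ppm", n_a = "shift_n_ppm"),
    dplyr::select(as_tibble(b), "residue",
                  h_b = "shift_h_ppm", n_b = "shift_n_ppm"),
    by = "residue"
  )
  if (!nrow(joined)) abort("No residues shared between the two peak lists.")
  joined |>
    dplyr::mutate(
      delta_h = .data$h_b - .data$h_a,
      delta_n = .data$n_b - .data$n_a,
      gcs = gcs(.data$delta_h, .data$delta_n, weight)
    ) |>
    dplyr::select(dplyr::any_of(c("residue", "resname")), "delta_h",
                  "delta_n", "gcs")
}

#' Classify significantly perturbed residues
#'
#' Residues whose generalized chemical-shift change strictly exceeds the
#' threshold (default 0.1 ppm).
#'
#' @param profile A tibble with columns `residue` and `gcs` (see
#'   [gcs_profile()]).
#' @param threshold Cutoff in ppm (strict inequality).
#' @return The subset of `profile` rows with `gcs > threshold`.
#' @examples
#' p <- tibble::tibble(residue = 1:3, gcs = c(0.05, 0.2, 0.1))
#' classify_perturbed(p) # residue 2 only
#' @export
classify_perturbed <- function(profile, threshold = dd_config()$gcs_threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    abort("`threshold` must be a single positive number (ppm).")
  }
  if (!all(c("residue", "gcs") %in% names(profile))) {
    abort("`profile` must have columns `residue` and `gcs`.")
  }
  dplyr::filter(as_tibble(profile), .data$gcs > threshold)
}

.rc_ca_table <- function() {
  path <- system.file("extdata", "random_coil_ca.csv", package = "ddstate")
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  setNames(tab$shift_ca_ppm, tab$residue)
}

#' Secondary C-alpha chemical shift
#'
#' Observed minus random-coil C-alpha shift,
#' \eqn{\Delta\delta = \delta_{obs} - \delta_{rc}(residue)}. Sustained
#' positive runs (> ~0.7 ppm over four or more consecutive residues)
#' indicate alpha-helix; sustained negative runs indicate extended
#' structure. The shipped random-coil reference is the Wishart et al.
#' (1995) peptide set without neighbour corrections.
#'
#' @param delta_obs Observed C-alpha shift(s) in ppm.
#' @param residue One-letter code(s), same length as `delta_obs` (or
#'   length 1).
#' @param rc_table Named numeric vector of random-coil shifts; defaults
#'   to the shipped table.
#' @return Secondary shift(s) in ppm.
#' @examples
#' secondary_shift_ca(54.8, "A") # +2.3, helical sign
#' @export
secondary_shift_ca <- function(delta_obs, residue, rc_table = .rc_ca_table()) {
  residue <- toupper(residue)
  bad <- setdiff(unique(residue), names(rc_table))
  if (length(bad)) {
    abort(paste0("No random-coil C-alpha reference for residue code(s): ",
                 paste(bad, collapse = ", "), "."))
  }
  delta_obs - unname(rc_table[residue])
}

#' Secondary-shift profile for a C-alpha peak table
#'
#' @param data A data frame with columns `residue`, `resname` (one-letter
#'   code) and `shift_ca_ppm`.
#' @param rc_table Random-coil reference (see [secondary_shift_ca()]).
#' @return The input with a `secondary_shift` column appended.
#' @export
secondary_shift_profile <- function(data, rc_table = .rc_ca_table()) {
  data <- as_tibble(data)
  need <- c("residue", "resname", "shift_ca_ppm")
  if (!all(need %in% names(data))) {
    abort("`data` needs columns `residue`, `resname`, `shift_ca_ppm`.")
  }
  dplyr::mutate(data,
                secondary_shift = secondary_shift_ca(.data$shift_ca_ppm,
                                                     .data$resname, rc_table))
}

.lorentz <- function(x, center, width, area) {
  (area / pi) * width / ((x - center)^2 + width^2)
}
.gauss <- function(x, center, width, area) {
  # width = half width at half maximum for parity with the Lorentzian
  s <- width / sqrt(2 * log(2))
  area * exp(-(x - center)^2 / (2 * s^2)) / (s * sqrt(2 * pi))
}

#' Two-state populations by lineshape deconvolution
#'
#' Fits a sum of Lorentzian (default) or Gaussian lines to a 1D spectral
#' projection of a resolved probe resonance and reports the component
#' areas normalized to total 1 — the relative populations of the
#' spectroscopically distinct states. Starting centers come from the two
#' highest well-separated local maxima; a component whose area collapses
#' below 1 percent of the total flags the fit as degenerate
#' (single-state data).
#'
#' @param data A data frame with columns `ppm` (uniform grid, >= 32
#'   points) and `amplitude`.
#' @param n_components Number of lines (currently 1 or 2; default 2).
#' @param lineshape `"lorentzian"` (default) or `"gaussian"`.
#' @return An object of class `dd_deconv_fit` with `populations`,
#'   `centers`, `widths` (HWHM, ppm), `areas`, `degenerate` and the data.
#'   Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @examples
#' pr <- gen_two_state_projection(p1 = 0.7, noise = "none")
#' two_state_populations(pr)$populations
#' @export
two_state_populations <- function(data, n_components = 2,
                                  lineshape = c("lorentzian", "gaussian")) {
  lineshape <- match.arg(lineshape)
  data <- as_tibble(data)
  if (!all(c("ppm", "amplitude") %in% names(data))) {
    abort("`data` must have columns `ppm` and `amplitude`.")
  }
  x <- data$ppm; y <- data$amplitude
  if (length(x) < 32) abort("Projection needs at least 32 grid points.")
  dx <- diff(x)
  if (any(abs(dx - dx[1]) > 1e-6 * abs(dx[1]))) {
    abort("`ppm` must be a uniform grid.")
  }
  if (!n_components %in% c(1, 2)) abort("`n_components` must be 1 or 2.")
  shape <- if (lineshape == "lorentzian") .lorentz else .gauss

  # crude peak picking for starting values
  ord <- order(y, decreasing = TRUE)
  c1 <- x[ord[1]]
  span <- diff(range(x))
  w0 <- span / 20
  total_area <- sum(y) * abs(dx[1])
  if (n_components == 1) {
    fit <- minpack.lm::nlsLM(
      y ~ shape(x, c1f, w1, a1),
      start = list(c1f = c1, w1 = w0, a1 = total_area),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
    cf <- coef(fit)
    areas <- abs(cf["a1"]); centers <- cf["c1f"]; widths <- abs(cf["w1"])
  } else {
    # second start: highest point at least 3 linewidths from the first
    far <- abs(x[ord] - c1) > 3 * w0
    c2 <- if (any(far)) x[ord][which(far)[1]] else c1 + span / 4
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ shape(x, c1f, w1, a1) + shape(x, c2f, w2, a2),
        start = list(c1f = c1, w1 = w0, a1 = total_area / 2,
                     c2f = c2, w2 = w0, a2 = total_area / 2),
        lower = c(min(x), 1e-6 * span, 0, min(x), 1e-6 * span, 0),
        upper = c(max(x), span, Inf, max(x), span, Inf),
        control = minpack.lm::nls.lm.control(maxiter = 1000)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      # effectively single-state data: the two-line problem is singular,
      # so fit one line and report the second component as empty
      single <- two_state_populations(data, n_components = 1,
                                      lineshape = lineshape)
      warn("One component's area collapsed below 1% of the total; the projection is effectively single-state.")
      return(structure(
        list(populations = c(1, 0),
             centers = c(single$centers, NA_real_),
             widths = c(single$widths, NA_real_),
             areas = c(single$areas, 0),
             lineshape = lineshape, degenerate = TRUE,
             residual_norm = single$residual_norm,
             data = data),
        class = "dd_deconv_fit"
      ))
    }
    cf <- coef(fit)
    areas <- c(cf["a1"], cf["a2"])
    if (any(areas < 0)) abort("Deconvolution reached a negative amplitude.")
    centers <- c(cf["c1f"], cf["c2f"]); widths <- abs(c(cf["w1"], cf["w2"]))
    # report components in order of decreasing area
    o <- order(areas, decreasing = TRUE)
    areas <- areas[o]; centers <- centers[o]; widths <- widths[o]
  }
  pops <- unname(areas / sum(areas))
  degenerate <- n_components == 2 && min(pops) < 0.01
  if (degenerate) {
    warn("One component's area collapsed below 1% of the total; the projection is effectively single-state.")
  }
  structure(
    list(populations = pops, centers = unname(centers),
         widths = unname(widths), areas = unname(areas),
         lineshape = lineshape, degenerate = degenerate,
         residual_norm = sqrt(sum(stats::residuals(fit)^2)),
         data = data),
    class = "dd_deconv_fit"
  )
}

#' @export
print.dd_deconv_fit <- function(x, ...) {
  cat(sprintf("<dd_deconv_fit> %s, populations: %s%s\n",
              x$lineshape,
              paste(sprintf("%.3f", x$populations), collapse = " / "),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Extract a kinetic time course from time-stamped peak lists
#'
#' Pulls the intensity of a probe residue in a reference state out of a
#' series of time-stamped peak lists and normalizes it to the first time
#' point, producing the `(time, value)` record that [fit_first_order()]
#' consumes — e.g. the fading of the unmodified asparagine form of a
#' deamidating protein. Time points where the probe is absent are
#' recorded as gaps (`NA`), never interpolated.
#'
#' @param peaklists A tibble of stacked peak lists with columns `residue`,
#'   `intensity`, `time` and optionally `state`.
#' @param probe_residue Residue number of the probe.
#' @param state Reference-state label to follow (default the first state
#'   seen for the probe; ignored when there is no `state` column).
#' @return A `(time, value)` tibble ordered by time, with attribute
#'   `gaps` listing times where the probe was missing. A warning flags
#'   courses with fewer than 4 usable points (below the fit minimum).
#' @export
population_course_to_kinetics <- function(peaklists, probe_residue,
                                          state = NULL) {
  peaklists <- as_tibble(peaklists)
  need <- c("residue", "intensity", "time")
  if (!all(need %in% names(peaklists))) {
    abort("`peaklists` needs columns `residue`, `intensity`, `time`.")
  }
  probe <- dplyr::filter(peaklists, .data$residue == probe_residue)
  if (!nrow(probe)) {
    abort(sprintf("Probe residue %s is absent from every time point.", probe_residue))
  }
  if ("state" %in% names(peaklists)) {
    if (is.null(state)) state <- probe$state[1]
    probe <- dplyr::filter(probe, .data$state == !!state)
    if (!nrow(probe)) {
      abort(sprintf("Probe residue %s has no entries in state '%s'.",
                    probe_residue, state))
    }
  }
  times <- sort(unique(peaklists$time))
  course <- tibble(time = times) |>
    dplyr::left_join(dplyr::select(probe, "time", value = "intensity"),
                     by = "time") |>
    dplyr::arrange(.data$time)
  gaps <- course$time[is.na(course$value)]
  course <- dplyr::filter(course, !is.na(.data$value))
  course$value <- course$value / course$value[1]
  if (nrow(course) < 4) {
    warn(sprintf("Only %d usable time points; below the first-order fit minimum of 4.",
                 nrow(course)))
  }
  attr(course, "gaps") <- gaps
  course
}
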