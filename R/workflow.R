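#' Run an end-to-end analysis workflow
#'
#' Composes the package's stages into the three standard narratives:
#'
#' * `"oligostate"` — per-residue TRACT fit (when decay data are given)
#'   and/or Stejskal-Tanner fit (when a gradient series is given),
#'   followed by the hydrodynamic chain and the oligomer call. Inputs:
#'   any of `decays`, `gradient_series` (with `delta`/`Delta`
#'   attributes), `hydro_table`; plus `mw_monomer` (kDa) and optionally
#'   `residues` for the ensemble window.
#' * `"deamidation"` — probe-state time course from stacked peak lists
#'   ([population_course_to_kinetics()]) and a first-order fit. Inputs:
#'   `peaklists`, `probe_residue`, optional `state`, `time_unit`.
#' * `"dimerization"` — per-lane monomer fractions from a gel table and
#'   a second-order fit in mole-per-mole-lipid units. Inputs: `gel_table`
#'   (or a ready `course`), `lpr` (so `M0 = 1/lpr`).
#'
#' Any stage failure aborts with the stage name attached; the report
#' records every parameter used so a rerun with identical inputs and
#' configuration reproduces the results table exactly.
#'
#' @param name One of `"oligostate"`, `"deamidation"`, `"dimerization"`.
#' @param inputs Named list of inputs (see above).
#' @param config A [dd_config()].
#' @return An object of class `dd_report`: list with `stage`,
#'   `parameters`, `results` (a tibble), `details`, `warnings`.
#' @examples
#' tbl <- tibble::tibble(construct = "DD", tau_c_ns = 6.0, D_m2s = 154e-12)
#' run_workflow("oligostate", list(hydro_table = tbl, mw_monomer = 10.6))
#' @export
run_workflow <- function(name = c("oligostate", "deamidation", "dimerization"),
                         inputs, config = dd_config()) {
  name <- match.arg(name)
  if (missing(inputs) || !is.list(inputs) || !length(inputs)) {
    abort("`inputs` must be a non-empty named list; see ?run_workflow for each workflow's schema.")
  }
  warnings_seen <- character()
  run_stage <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        abort(paste0("Workflow '", name, "' failed at stage '", stage, "': ",
                     conditionMessage(e)))
      }),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen,
                            paste0("[", stage, "] ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
  }
  cond <- conditions_from_config(config)
  details <- list()

  if (name == "oligostate") {
    if (is.null(inputs$mw_monomer) && is.null(inputs$hydro_table)) {
      abort("oligostate needs `mw_monomer` (kDa) or a hydro table with an `mw_kda` column.")
    }
    tau_c <- NA_real_; D <- NA_real_
    if (!is.null(inputs$decays)) {
      tr <- run_stage("tract", tract_fit(inputs$decays, cond,
                                         spin_params(config$r_nh, config$dsigma_n,
                                                     config$theta_deg)))
      ens <- run_stage("tract", ensemble_tau_c(tr, inputs$residues))
      tau_c <- ens$tau_c_mean
      details$tract <- tr
      details$ensemble <- ens
    }
    if (!is.null(inputs$gradient_series)) {
      gs <- inputs$gradient_series
      st <- run_stage("pgste", stejskal_tanner_fit(
        gs, delta = attr(gs, "delta"), Delta = attr(gs, "Delta"),
        gamma = attr(gs, "gamma") %||% .gamma_1H))
      D <- st$D
      details$pgste <- st
    }
    results <- if (!is.null(inputs$hydro_table)) {
      run_stage("hydro", oligomer_state(inputs$hydro_table, cond,
                                        mw_monomer = inputs$mw_monomer,
                                        A = config$mw_A, b = config$mw_b))
    } else {
      run_stage("hydro", classify_oligomer(tau_c = tau_c, D = D,
                                           mw_monomer = inputs$mw_monomer,
                                           cond = cond,
                                           A = config$mw_A, b = config$mw_b))
    }
  } else if (name == "deamidation") {
    if (is.null(inputs$peaklists) || is.null(inputs$probe_residue)) {
      abort("deamidation needs `peaklists` and `probe_residue`.")
    }
    course <- run_stage("course", population_course_to_kinetics(
      inputs$peaklists, inputs$probe_residue, inputs$state))
    fit <- run_stage("first_order", fit_first_order(
      course, time_unit = inputs$time_unit %||% "days"))
    results <- glance(fit)
    details$course <- course
    details$fit <- fit
  } else {
    if (is.null(inputs$lpr)) abort("dimerization needs `lpr` (so M0 = 1/LPR).")
    course <- if (!is.null(inputs$course)) inputs$course else {
      if (is.null(inputs$gel_table)) {
        abort("dimerization needs a `gel_table` or a ready `course`.")
      }
      fr <- run_stage("gel", gel_monomer_fraction(inputs$gel_table))
      if (!"time" %in% names(fr)) {
        abort("The gel table needs a `time` column (seconds) for kinetics.")
      }
      tibble(time = fr$time, value = fr$fraction)
    }
    M0 <- 1 / inputs$lpr
    fit <- run_stage("second_order", fit_second_order(course, M0 = M0))
    results <- glance(fit)
    details$course <- course
    details$fit <- fit
  }

  structure(
    list(stage = name,
         parameters = c(unclass(config),
                        list(mw_monomer = inputs$mw_monomer %||% NA,
                             lpr = inputs$lpr %||% NA)),
         results = results,
         details = details,
         warnings = warnings_seen,
         version = as.character(utils::packageVersion("ddstate"))),
    class = "dd_report"
  )
}

#' @export
print.dd_report <- function(x, ...) {
  cat(sprintf("<dd_report> workflow '%s' (ddstate %s)\n", x$stage, x$version))
  print(x$results)
  if (length(x$warnings)) {
    cat("Warnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}
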