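# Shared CSV/TSV readers. All tables are UTF-8 with dot-decimal numbers;
# leading lines of the form "# key=value" are parsed into a metadata
# header returned as attributes.

.read_meta <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (l in meta_lines) {
    m <- regmatches(l, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_.]*)\\s*=\\s*(.+)\\s*$", l))[[1]]
    if (length(m) == 3) {
      val <- suppressWarnings(as.numeric(m[3]))
      kv[[m[2]]] <- if (is.na(val)) trimws(m[3]) else val
    }
  }
  kv
}

.read_csv_checked <- function(path, required, label, optional = character()) {
  if (!file.exists(path)) abort(paste0(label, " file not found: ", path))
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- tryCatch(
    readr::read_delim(path, delim = delim, comment = "#", trim_ws = TRUE,
                      show_col_types = FALSE, locale = readr::locale(decimal_mark = ".")),
    error = function(e) abort(paste0("Cannot parse ", label, " table '", path,
                                     "': ", conditionMessage(e)))
  )
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    abort(paste0(label, " table '", path, "' lacks mandatory column(s): ",
                 paste(missing_cols, collapse = ", "), "."))
  }
  tab
}

#' Read a hydrodynamic measurement table
#'
#' One row per construct/sample with the measured rotational correlation
#' time and/or translational diffusion coefficient. Columns: `construct`,
#' `tau_c_ns`, `tau_c_err`, `D_m2s`, `D_err`, `conc_M`; missing values
#' are empty cells, but every row must carry at least one of `tau_c_ns`
#' and `D_m2s`.
#'
#' @param path CSV/TSV file path.
#' @return A validated tibble ready for [oligomer_state()].
#' @export
read_hydro_table <- function(path) {
  tab <- .read_csv_checked(path, required = "construct", label = "hydro")
  if (!any(c("tau_c_ns", "D_m2s") %in% names(tab))) {
    abort(paste0("hydro table '", path,
                 "' must have at least one of the columns `tau_c_ns`, `D_m2s`."))
  }
  for (col in c("tau_c_ns", "tau_c_err", "D_m2s", "D_err", "conc_M")) {
    if (!col %in% names(tab)) tab[[col]] <- NA_real_
  }
  bare <- is.na(tab$tau_c_ns) & is.na(tab$D_m2s)
  if (any(bare)) {
    abort(paste0("Row(s) ", paste(which(bare), collapse = ", "),
                 " of '", path, "' carry neither tau_c_ns nor D_m2s."))
  }
  neg <- c(tab$tau_c_ns, tab$D_m2s, tab$conc_M)
  if (any(neg <= 0, na.rm = TRUE)) {
    abort("All present tau_c_ns, D_m2s and conc_M values must be positive.")
  }
  as_tibble(tab)
}

#' Read a long-format relaxation decay table
#'
#' Columns: `residue`, `component` (`alpha`/`beta`), `delay_s`,
#' `intensity`; optional `resname`.
#'
#' @param path CSV/TSV file path.
#' @return A tibble ready for [tract_fit()].
#' @export
read_decay_table <- function(path) {
  as_tibble(.read_csv_checked(
    path, required = c("residue", "component", "delay_s", "intensity"),
    label = "decay"))
}

#' Read a pulsed-field-gradient attenuation series
#'
#' Two data columns `gradient_Tm`, `intensity` plus metadata header lines
#' `# delta_s=...`, `# Delta_s=...` and optionally `# gamma=...`
#' (rad s^-1 T^-1, default 1H).
#'
#' @param path CSV file path.
#' @return A tibble with attributes `delta`, `Delta`, `gamma`, ready for
#'   [stejskal_tanner_fit()].
#' @export
read_gradient_series <- function(path) {
  meta <- .read_meta(path)
  tab <- .read_csv_checked(path, required = c("gradient_Tm", "intensity"),
                           label = "gradient")
  if (is.null(meta$delta_s) || is.null(meta$Delta_s)) {
    abort(paste0("Gradient series '", path,
                 "' must carry '# delta_s=' and '# Delta_s=' metadata lines."))
  }
  out <- as_tibble(tab)
  attr(out, "delta") <- meta$delta_s
  attr(out, "Delta") <- meta$Delta_s
  attr(out, "gamma") <- meta$gamma %||% .gamma_1H
  out
}

#' Read a dilution series
#'
#' Columns: `conc_M`, `D_m2s`, optional `D_err`.
#'
#' @param path CSV file path.
#' @return A tibble ready for [extrapolate_D0()].
#' @export
read_dilution_table <- function(path) {
  as_tibble(.read_csv_checked(path, required = c("conc_M", "D_m2s"),
                              label = "dilution"))
}

#' Read a kinetic time course
#'
#' Columns: `time`, `value`, optional `error`; a `# unit=` metadata line
#' tags the time unit (returned as the `time_unit` attribute, default
#' `"days"`).
#'
#' @param path CSV file path.
#' @return A tibble ready for [fit_first_order()] / [fit_second_order()].
#' @export
read_time_course <- function(path) {
  meta <- .read_meta(path)
  tab <- .read_csv_checked(path, required = c("time", "value"),
                           label = "time-course")
  out <- as_tibble(tab)
  attr(out, "time_unit") <- meta$unit %||% "days"
  out
}

#' Read a gel densitometry table
#'
#' Columns: `lane`, `band` (`monomer`, `dimer`, `tetramer`, `hexamer` or
#' `higher`), `intensity`; optional `time`.
#'
#' @param path CSV file path.
#' @return A tibble ready for [gel_monomer_fraction()].
#' @export
read_gel_table <- function(path) {
  as_tibble(.read_csv_checked(path, required = c("lane", "band", "intensity"),
                              label = "gel"))
}

#' Read an amide peak list (CSV dialect)
#'
#' Columns: `residue`, `w_N_ppm`, `w_H_ppm`; optional `resname`, `atom`,
#' `intensity`, `state`, `time`. Shift columns are standardized to
#' `shift_n_ppm` / `shift_h_ppm`. Amide shifts outside the plausible
#' windows (1H 5-12 ppm, 15N 100-135 ppm) are flagged with a warning,
#' not dropped.
#'
#' @param path CSV file path.
#' @return A tibble ready for [gcs_profile()].
#' @export
read_peak_list <- function(path) {
  tab <- .read_csv_checked(path, required = c("residue", "w_N_ppm", "w_H_ppm"),
                           label = "peak list")
  out <- dplyr::rename(as_tibble(tab), shift_n_ppm = "w_N_ppm",
                       shift_h_ppm = "w_H_ppm")
  odd <- out$shift_h_ppm < 5 | out$shift_h_ppm > 12 |
    out$shift_n_ppm < 100 | out$shift_n_ppm > 135
  if (any(odd, na.rm = TRUE)) {
    warn(sprintf("%d peak(s) fall outside the plausible amide windows (1H 5-12, 15N 100-135 ppm).",
                 sum(odd, na.rm = TRUE)))
  }
  out
}

#' Read a Sparky-style peak list
#'
#' Whitespace-separated `.list` export with an assignment column in the
#' `G353N-H` convention (residue one-letter code, residue number, the two
#' correlated atoms) followed by the w1 (15N) and w2 (1H) shifts and
#' optionally a height column.
#'
#' @param path `.list` file path.
#' @return A tibble with `residue`, `resname`, `atom_w1`, `atom_w2`,
#'   `shift_n_ppm`, `shift_h_ppm` and `intensity` (NA when absent).
#' @export
read_sparky_list <- function(path) {
  if (!file.exists(path)) abort(paste0("Peak-list file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lines <- lines[!grepl("^Assignment", lines)]  # header row
  rows <- lapply(lines, function(l) {
    parts <- strsplit(l, "\\s+")[[1]]
    m <- regmatches(parts[1],
                    regexec("^([A-Za-z])(\\d+)([A-Za-z0-9']+)-([A-Za-z0-9']+)$",
                            parts[1]))[[1]]
    if (length(m) != 5) {
      abort(paste0("Cannot parse assignment '", parts[1],
                   "' (expected e.g. 'G353N-H')."))
    }
    w <- suppressWarnings(as.numeric(parts[2:3]))
    if (any(is.na(w))) {
      abort(paste0("Non-numeric shift in line: '", l, "'."))
    }
    tibble(
      resname = toupper(m[2]), residue = as.integer(m[3]),
      atom_w1 = m[4], atom_w2 = m[5],
      shift_n_ppm = w[1], shift_h_ppm = w[2],
      intensity = if (length(parts) >= 4)
        suppressWarnings(as.numeric(parts[4])) else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Read a 1D spectral projection
#'
#' Two columns: `ppm`, `amplitude`.
#'
#' @param path CSV file path.
#' @return A tibble ready for [two_state_populations()].
#' @export
read_projection <- function(path) {
  as_tibble(.read_csv_checked(path, required = c("ppm", "amplitude"),
                              label = "projection"))
}

#' Sequence masses from a FASTA file
#'
#' Reads a (multi-record) FASTA of amino-acid sequences and computes the
#' average molecular weight of each chain via [sequence_mw()].
#'
#' @param path FASTA file path.
#' @return A tibble with `name` (full description line), `length` and
#'   `mw_kda`.
#' @export
fasta_mw <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("The Biostrings package is required for FASTA input.")
  }
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  seqs <- Biostrings::readAAStringSet(path)
  tibble(
    name = names(seqs),
    length = Biostrings::width(seqs),
    mw_kda = sequence_mw(as.character(seqs))
  )
}
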