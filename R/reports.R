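#' The calcineurin CaM-binding peptide (CaNp)
#'
#' The 24-residue CaM-binding segment of the calcineurin A catalytic
#' subunit, author-numbered 391-414.
#'
#' @return list with `sequence` (one-letter string), `start`, `end`,
#'   and named landmark residues (`tether`, `anchors`).
#' @export
canp_peptide <- function() {
  list(sequence = "ARKEVIRNKIRAIGKMARVFSVLR",
       start = 391L, end = 414L,
       tether = 404L,
       anchors = c(396L, 400L, 410L, 413L))
}

#' Full geometric analysis of a CaM-peptide complex
#'
#' Orchestrates the module analyses on one structure: ensemble
#' RMSD-to-mean statistics, peptide kink angle, interdomain pseudo-C2
#' symmetry, hydrophobic anchors and binding mode, and intermolecular
#' salt bridges. Every parameter used is echoed into the report. The
#' report adds no computation of its own.
#'
#' @param ensemble an `"ensemble"` (or a PDB path, parsed first).
#' @param receptor_chain,peptide_chain chain ids.
#' @param n_domain_range,c_domain_range receptor domain residue
#'   ranges.
#' @param peptide_range peptide residue range entering RMSD/axis fits.
#' @param split_residue peptide tether residue for the kink.
#' @param offset interdomain correspondence offset.
#' @param contact_cutoff,salt_bridge_cutoff Angstrom.
#' @param major_threshold anchor major/minor threshold.
#' @param json_path optional path; when given, the report is written
#'   as JSON.
#' @return a list report (invisibly when `json_path` is given).
#' @export
analyze_complex <- function(ensemble,
                            receptor_chain, peptide_chain,
                            n_domain_range, c_domain_range,
                            peptide_range, split_residue,
                            offset = 73L,
                            contact_cutoff = 4.5,
                            salt_bridge_cutoff = 4.0,
                            major_threshold = 5L,
                            json_path = NULL) {
  if (is.character(ensemble)) ensemble <- parse_structure(ensemble)
  if (peptide_range[1L] > peptide_range[2L]) {
    stop("peptide_range reversed")
  }
  if (n_domain_range[1L] > n_domain_range[2L] ||
      c_domain_range[1L] > c_domain_range[2L]) {
    stop("domain range reversed")
  }
  at <- ensemble$atoms
  for (ch in c(receptor_chain, peptide_chain)) {
    if (!any(at$chain == ch)) stop("chain '", ch, "' not in structure")
  }
  n_spec <- domain_spec(receptor_chain, n_domain_range, "N-domain")
  c_spec <- domain_spec(receptor_chain, c_domain_range, "C-domain")
  pep_spec <- selection_spec(peptide_chain, peptide_range, "heavy")

  rms_sel <- selection_spec(peptide_chain, peptide_range, "backbone")
  stats_pep <- if (n_models(ensemble) >= 2L) {
    ensemble_rmsd_to_mean(ensemble, rms_sel)
  } else NULL
  kink <- kink_angle_ensemble(ensemble, peptide_chain, split_residue)
  tr <- interdomain_transform(ensemble, n_spec, c_spec, offset)
  axis <- fit_helix_axis(chain_ca(ensemble, peptide_chain, peptide_range))
  sym <- c2_deviation(tr, axis)
  anchors <- identify_anchors(ensemble, pep_spec, n_spec, c_spec,
                              cutoff = contact_cutoff,
                              major_threshold = major_threshold)
  pattern <- if (nrow(anchors) > 0L) spacing_pattern(anchors) else NULL
  bridges <- find_salt_bridges(ensemble, peptide_chain, receptor_chain,
                               cutoff = salt_bridge_cutoff)
  report <- list(
    id = ensemble$id,
    parameters = list(receptor_chain = receptor_chain,
                      peptide_chain = peptide_chain,
                      n_domain_range = n_domain_range,
                      c_domain_range = c_domain_range,
                      peptide_range = peptide_range,
                      split_residue = split_residue, offset = offset,
                      contact_cutoff = contact_cutoff,
                      salt_bridge_cutoff = salt_bridge_cutoff,
                      major_threshold = major_threshold),
    ensemble_stats = if (is.null(stats_pep)) NULL else {
      list(mean_rmsd = stats_pep$mean_rmsd, sd_rmsd = stats_pep$sd_rmsd)
    },
    kink = kink[c("mean", "sd")],
    symmetry = list(screw_angle = sym$interdomain$angle,
                    c2_deviation = sym$c2_deviation,
                    screw_angle_deviation = sym$screw_angle_deviation,
                    axis_tilt = sym$axis_tilt),
    anchors = anchors,
    binding_mode = if (is.null(pattern)) NULL else {
      list(indices = pattern$indices, mode_label = pattern$mode_label,
           orientation = pattern$orientation)
    },
    salt_bridges = bridges)
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    return(invisible(report))
  }
  report
}

#' DLS calibration report
#'
#' Fits the double-log calibration on standards read from a CSV
#' (columns `label`, `rh_nm`, `mr_kda`) or a data.frame, and estimates
#' the molecular weight at the query radius.
#'
#' @param standards CSV path or data.frame.
#' @param query_rh_nm hydrodynamic radius to evaluate, nm.
#' @param json_path optional JSON output path.
#' @return list report with fit parameters, estimate and warnings.
#' @export
calibrate_dls <- function(standards, query_rh_nm, json_path = NULL) {
  if (is.character(standards)) {
    standards <- utils::read.table(standards, header = TRUE, sep = ",",
                                   stringsAsFactors = FALSE)
  }
  curve <- fit_loglog_calibration(standards)
  warn <- character()
  if (curve$n_points == 2L) warn <- c(warn, "n_points = 2: exact line")
  est <- withCallingHandlers(
    estimate_mr(curve, query_rh_nm),
    warning = function(w) {
      warn <<- c(warn, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  report <- list(curve = unclass(curve), query_rh_nm = query_rh_nm,
                 mr_kda = est, warnings = warn)
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA)
    return(invisible(report))
  }
  report
}

#' CD difference-spectrum helicity report
#'
#' Reads complex and free spectra (CSV columns `wavelength_nm`,
#' `delta_eps`, or `"cd_spectrum"` objects), forms the difference and
#' estimates the two-state helix fraction at 222 nm.
#'
#' @param complex_spec,free_spec CSV paths or `"cd_spectrum"` objects.
#' @param n_residues peptide residue count, used to report the
#'   helical-residue estimate and (for per-mole spectra) to convert to
#'   the per-residue scale of the reference coefficients.
#' @param spectrum_units `"per_residue"` when the difference spectrum
#'   is already amide-normalized, `"per_mole"` when it is per mole of
#'   protein (then divided by `n_residues` before comparison).
#' @param ref_helix_222,ref_coil_222 two-state references at 222 nm.
#' @param json_path optional JSON output path.
#' @return list with the helix fraction, estimated helical residue
#'   count and flags.
#' @export
calibrate_cd <- function(complex_spec, free_spec, n_residues = 1,
                         spectrum_units = c("per_residue", "per_mole"),
                         ref_helix_222 = -11.1, ref_coil_222 = -0.3,
                         json_path = NULL) {
  spectrum_units <- match.arg(spectrum_units)
  read_spec <- function(x) {
    if (inherits(x, "cd_spectrum")) return(x)
    df <- utils::read.table(x, header = TRUE, sep = ",",
                            stringsAsFactors = FALSE)
    cd_spectrum(df$wavelength_nm, df$delta_eps)
  }
  cs <- read_spec(complex_spec)
  fs <- read_spec(free_spec)
  diff <- cd_difference(cs, fs)
  flags <- character()
  if (all(abs(diff$delta_eps) < 1e-9)) {
    flags <- c(flags, "zero difference spectrum: helicity undefined")
  }
  divisor <- if (spectrum_units == "per_mole") n_residues else 1
  f <- estimate_helix_fraction(diff, ref_helix_222, ref_coil_222,
                               n_residues = divisor)
  report <- list(helix_fraction = f,
                 helical_residues = round(f * n_residues),
                 n_residues = n_residues,
                 ref_helix_222 = ref_helix_222,
                 ref_coil_222 = ref_coil_222,
                 flags = flags)
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA)
    return(invisible(report))
  }
  report
}

#' Write a contact table as TSV
#' @param contacts a `"contact_table"` data.frame.
#' @param path output path.
#' @export
write_contact_table <- function(contacts, path) {
  utils::write.table(contacts, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
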