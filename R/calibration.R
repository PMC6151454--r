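#' Fit a double-logarithmic DLS size calibration
#'
#' Ordinary least squares of `log10(Mr)` on `log10(RH)` over globular
#' protein standards, the standard empirical relation between
#' hydrodynamic radius and molecular weight. The full-fit line (not
#' piecewise interpolation between bracketing standards) is used for
#' prediction.
#'
#' @param points data.frame with columns `rh_nm` (hydrodynamic radius,
#'   nm) and `mr_kda` (molecular weight, kDa); optionally `label`.
#' @return `"calibration_curve"`: `slope`, `intercept` (log10 space),
#'   `r_squared`, `n_points`, `rh_range`.
#' @export
fit_loglog_calibration <- function(points) {
  if (nrow(points) < 2L) stop("need at least 2 calibration points")
  if (any(points$rh_nm <= 0) || any(points$mr_kda <= 0)) {
    stop("radii and weights must be positive")
  }
  if (nrow(points) == 2L && points$rh_nm[1L] == points$rh_nm[2L] &&
      points$mr_kda[1L] != points$mr_kda[2L]) {
    stop("degenerate fit: two points with equal radius, different weight")
  }
  lx <- log10(points$rh_nm)
  ly <- log10(points$mr_kda)
  fit <- stats::lm(ly ~ lx)
  r2 <- if (stats::var(ly) == 0) 1 else {
    1 - sum(stats::residuals(fit)^2) / sum((ly - mean(ly))^2)
  }
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2, n_points = nrow(points),
                 rh_range = range(points$rh_nm)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve: log10(Mr) = %.3f + %.3f log10(RH), r2 %.4f, n %d>\n",
    x$intercept, x$slope, x$r_squared, x$n_points))
  invisible(x)
}

#' Estimate molecular weight from hydrodynamic radius
#'
#' Evaluates the calibration line: `Mr = 10^(intercept +
#' slope * log10(RH))`. Warns when the query radius lies outside the
#' standards' range (extrapolation).
#'
#' @param curve a `"calibration_curve"`.
#' @param rh_nm hydrodynamic radius, nm.
#' @return molecular weight, kDa.
#' @export
estimate_mr <- function(curve, rh_nm) {
  if (any(rh_nm <= 0)) stop("radius must be positive")
  out_of_range <- rh_nm < curve$rh_range[1L] | rh_nm > curve$rh_range[2L]
  if (any(out_of_range)) {
    warning("query radius outside calibration range [",
            curve$rh_range[1L], ", ", curve$rh_range[2L],
            "] nm: extrapolating", call. = FALSE)
  }
  10^(curve$intercept + curve$slope * log10(rh_nm))
}

#' Construct a CD spectrum
#' @param wavelength wavelengths, nm, strictly increasing.
#' @param delta_eps molar CD absorption coefficient per wavelength,
#'   M^-1 cm^-1.
#' @export
cd_spectrum <- function(wavelength, delta_eps) {
  if (length(wavelength) != length(delta_eps)) {
    stop("wavelength/delta_eps length mismatch")
  }
  if (any(diff(wavelength) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  structure(list(wavelength = as.numeric(wavelength),
                 delta_eps = as.numeric(delta_eps)),
            class = "cd_spectrum")
}

#' Difference of two CD spectra (complex minus free)
#'
#' On identical wavelength grids the subtraction is pointwise; on
#' different grids the free spectrum is linearly interpolated onto the
#' complex spectrum's grid points within the overlapping wavelength
#' range.
#'
#' @param complex_spec,free_spec `"cd_spectrum"` objects.
#' @return a `"cd_spectrum"` of the difference.
#' @export
cd_difference <- function(complex_spec, free_spec) {
  wc <- complex_spec$wavelength
  wf <- free_spec$wavelength
  if (length(wc) == length(wf) && all(wc == wf)) {
    return(cd_spectrum(wc, complex_spec$delta_eps - free_spec$delta_eps))
  }
  lo <- max(min(wc), min(wf))
  hi <- min(max(wc), max(wf))
  if (lo > hi) stop("no wavelength overlap")
  keep <- wc >= lo & wc <= hi
  f_interp <- stats::approx(wf, free_spec$delta_eps, xout = wc[keep])$y
  cd_spectrum(wc[keep], complex_spec$delta_eps[keep] - f_interp)
}

#' Two-state helicity estimate from the 222 nm CD signal
#'
#' Linear two-state (helix/coil) estimator:
#' `f = (de222 - ref_coil) / (ref_helix - ref_coil)`, clamped to
#' `[0, 1]`, with the 222 nm value linearly interpolated from the
#' spectrum grid. The default per-residue reference coefficients
#' (helix -11.1, coil -0.3 M^-1 cm^-1) are common literature
#' conventions for amide-normalized spectra; supply `n_residues` to
#' convert a per-mole spectrum to per-residue before comparison.
#'
#' @param spec a `"cd_spectrum"` covering 222 nm.
#' @param ref_helix_222,ref_coil_222 reference Delta-epsilon at
#'   222 nm for full helix and full coil (must differ).
#' @param n_residues divisor converting per-mole to per-residue
#'   Delta-epsilon (default 1: spectrum already per-residue).
#' @return helix fraction in `[0, 1]`.
#' @export
estimate_helix_fraction <- function(spec, ref_helix_222 = -11.1,
                                    ref_coil_222 = -0.3,
                                    n_residues = 1) {
  if (ref_helix_222 == ref_coil_222) stop("reference values must differ")
  if (222 < min(spec$wavelength) || 222 > max(spec$wavelength)) {
    stop("222 nm outside spectrum grid")
  }
  de222 <- stats::approx(spec$wavelength, spec$delta_eps, xout = 222)$y /
    n_residues
  f <- (de222 - ref_coil_222) / (ref_helix_222 - ref_coil_222)
  max(0, min(1, f))
}
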