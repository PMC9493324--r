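# Domain types for instrument traces and titrations, peak extraction,
# shift classification, quench-ratio tabulation and molar-ellipticity
# conversion.

AXIS_KINDS <- c("wavelength_nm", "wavenumber_cm-1")

#' Construct a spectrum
#'
#' A single instrument trace: a strictly increasing axis grid (wavelength in
#' nm or wavenumber in cm-1) with one signal value per grid point, plus the
#' acquisition temperature and sample metadata.
#'
#' @param axis numeric, strictly increasing grid of axis values (length >= 3).
#' @param signal numeric, same length as `axis`. Fluorescence intensities
#'   (`signal_kind = "intensity"`) must be non-negative; absorbance and CD
#'   signals may take any finite value.
#' @param axis_kind `"wavelength_nm"` or `"wavenumber_cm-1"`.
#' @param temperature acquisition temperature in kelvin.
#' @param sample_id free-text sample identifier.
#' @param excitation_nm optional excitation wavelength (nm).
#' @param signal_kind `"intensity"` (fluorescence, a.u.), `"absorbance"`, or
#'   `"cd"` (circular dichroism signal in degrees).
#' @return An object of class `quench_spectrum`.
#' @examples
#' wl <- seq(300, 500, 2)
#' sp <- spectrum(wl, 100 * exp(-(wl - 338)^2 / 800), temperature = 298)
#' find_peak(sp)
#' @export
spectrum <- function(axis, signal, axis_kind = c("wavelength_nm", "wavenumber_cm-1"),
                     temperature = NA_real_, sample_id = "",
                     excitation_nm = NULL,
                     signal_kind = c("intensity", "absorbance", "cd")) {
  axis_kind <- match.arg(axis_kind)
  signal_kind <- match.arg(signal_kind)
  axis <- as.numeric(axis)
  signal <- as.numeric(signal)
  if (length(axis) < 3L || length(axis) != length(signal))
    stop("axis and signal must have equal length >= 3", call. = FALSE)
  if (anyNA(axis) || any(!is.finite(axis)))
    stop("axis values must be finite", call. = FALSE)
  if (any(diff(axis) <= 0))
    stop("axis must be strictly increasing", call. = FALSE)
  if (anyNA(signal) || any(!is.finite(signal)))
    stop("all signal values must be finite", call. = FALSE)
  if (signal_kind == "intensity" && any(signal < 0))
    stop("fluorescence intensities must be non-negative", call. = FALSE)
  structure(
    list(axis = axis, signal = signal, axis_kind = axis_kind,
         signal_kind = signal_kind, temperature = as.numeric(temperature),
         sample_id = as.character(sample_id),
         excitation_nm = if (is.null(excitation_nm)) NULL else as.numeric(excitation_nm)),
    class = "quench_spectrum")
}

#' @export
print.quench_spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s: %d points, %s %.6g-%.6g, T = %s K, sample '%s'\n",
              x$signal_kind, length(x$axis), x$axis_kind,
              min(x$axis), max(x$axis),
              format(x$temperature), x$sample_id))
  invisible(x)
}

#' Construct a titration series
#'
#' An ordered set of spectra recorded at one temperature over increasing
#' quencher concentrations, including the mandatory zero-quencher reference
#' (the F0 spectrum). All member spectra must share one axis grid and one
#' temperature. Spectra are sorted by concentration.
#'
#' @param spectra list of [spectrum()] objects.
#' @param quencher_conc numeric, quencher (ligand) concentration in mol/L per
#'   spectrum; must be unique, non-negative, and contain exactly one zero.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(spectra, quencher_conc) {
  if (!is.list(spectra) || !all(vapply(spectra, inherits, logical(1), "quench_spectrum")))
    stop("spectra must be a list of quench_spectrum objects", call. = FALSE)
  quencher_conc <- as.numeric(quencher_conc)
  if (length(spectra) != length(quencher_conc))
    stop("one concentration per spectrum required", call. = FALSE)
  if (anyNA(quencher_conc) || any(quencher_conc < 0))
    stop("quencher concentrations must be finite and non-negative", call. = FALSE)
  ord <- order(quencher_conc)
  spectra <- spectra[ord]
  quencher_conc <- quencher_conc[ord]
  if (anyDuplicated(quencher_conc))
    stop("quencher concentrations must be unique", call. = FALSE)
  if (sum(quencher_conc == 0) != 1L)
    stop("no F0 reference: exactly one zero-concentration spectrum required",
         call. = FALSE)
  ax <- spectra[[1L]]$axis
  tk <- spectra[[1L]]$temperature
  for (sp in spectra[-1L]) {
    if (!isTRUE(all.equal(sp$axis, ax, tolerance = 0)) && !identical(sp$axis, ax))
      stop("all member spectra must share an identical axis grid", call. = FALSE)
    same_t <- identical(sp$temperature, tk) ||
      (is.finite(sp$temperature) && is.finite(tk) && sp$temperature == tk)
    if (!same_t)
      stop("all member spectra must share one temperature", call. = FALSE)
  }
  structure(list(spectra = spectra, quencher_conc = quencher_conc,
                 temperature = tk),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("<titration series> %d spectra at T = %s K, [Q] = %s mol/L\n",
              length(x$spectra), format(x$temperature),
              paste(signif(x$quencher_conc, 4), collapse = ", ")))
  invisible(x)
}

# centered moving average with symmetric window, shrunk at the edges so the
# smoothed trace keeps full length; requires a uniform grid for window > 1
.smooth_signal <- function(axis, signal, window) {
  if (window == 1L) return(signal)
  d <- diff(axis)
  if (max(d) - min(d) > 1e-8 * max(abs(d)))
    stop("smoothing window > 1 requires a uniform axis grid", call. = FALSE)
  n <- length(signal)
  h <- (window - 1L) %/% 2L
  out <- numeric(n)
  cs <- cumsum(c(0, signal))
  for (i in seq_len(n)) {
    lo <- max(1L, i - h)
    hi <- min(n, i + h)
    out[i] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  out
}

# vertex of the parabola through three points (Newton form); returns NULL when
# the points are not concave so callers can fall back to the grid maximum
.parabola_vertex <- function(x, y) {
  d1 <- (y[2] - y[1]) / (x[2] - x[1])
  d2 <- (y[3] - y[2]) / (x[3] - x[2])
  a <- (d2 - d1) / (x[3] - x[1])
  if (!is.finite(a) || a >= 0) return(NULL)
  xv <- (x[1] + x[2]) / 2 - d1 / (2 * a)
  yv <- y[1] + d1 * (xv - x[1]) + a * (xv - x[1]) * (xv - x[2])
  list(position = xv, height = yv)
}

#' Locate the emission or absorption band maximum
#'
#' Finds the global signal maximum after centered moving-average smoothing.
#' Interior maxima are refined by a parabola through the three grid points
#' around the discrete maximum (method `"parabolic"`); maxima on the grid
#' boundary are returned as-is (method `"argmax"`) with `boundary = TRUE` and
#' a warning, since a boundary maximum usually means the band was not fully
#' scanned.
#'
#' @param spectrum a [spectrum()] object.
#' @param window odd integer >= 1, moving-average width in grid points.
#'   `window = 1` disables smoothing. Windows > 1 require a uniform grid.
#' @return An object of class `peak_info` with fields `position` (axis
#'   units), `height` (signal units), `method`, `boundary`, `axis_kind`.
#' @export
find_peak <- function(spectrum, window = 5L) {
  stopifnot(inherits(spectrum, "quench_spectrum"))
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd integer >= 1", call. = FALSE)
  if (window > length(spectrum$axis))
    stop("window exceeds spectrum length", call. = FALSE)
  if (diff(range(spectrum$signal)) == 0)
    stop("no peak: spectrum is flat", call. = FALSE)
  sm <- .smooth_signal(spectrum$axis, spectrum$signal, window)
  idx <- which.max(sm)
  n <- length(sm)
  boundary <- idx == 1L || idx == n
  if (boundary) {
    warning("peak lies on the grid boundary; position not refined",
            call. = FALSE)
    res <- list(position = spectrum$axis[idx], height = sm[idx],
                method = "argmax")
  } else {
    v <- .parabola_vertex(spectrum$axis[(idx - 1L):(idx + 1L)],
                          sm[(idx - 1L):(idx + 1L)])
    if (is.null(v)) {
      res <- list(position = spectrum$axis[idx], height = sm[idx],
                  method = "argmax")
    } else {
      res <- list(position = v$position, height = v$height,
                  method = "parabolic")
    }
  }
  structure(c(res, list(boundary = boundary, axis_kind = spectrum$axis_kind)),
            class = "peak_info")
}

#' @export
print.peak_info <- function(x, ...) {
  cat(sprintf("<peak> position %.4g (%s), height %.4g, method %s%s\n",
              x$position, x$axis_kind, x$height, x$method,
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Classify a band-position shift between two peaks
#'
#' Compares an observed peak position against a reference on the same axis.
#' Direction is defined on the stored axis: a decrease is a `"downshift"`, an
#' increase an `"upshift"`, and changes within `tolerance` are `"none"`. On a
#' wavelength axis a downshift is the spectroscopist's blue shift and an
#' upshift a red shift; the human-readable `label` says so.
#'
#' @param reference,observed `peak_info` objects sharing one `axis_kind`.
#' @param tolerance non-negative shift magnitude (axis units) treated as no
#'   change.
#' @return An object of class `shift_call` with fields `direction`
#'   (`"downshift"`, `"upshift"`, `"none"`), `delta` (observed - reference),
#'   `axis_kind` and `label`.
#' @export
classify_shift <- function(reference, observed, tolerance = 0.5) {
  stopifnot(inherits(reference, "peak_info"), inherits(observed, "peak_info"))
  if (!identical(reference$axis_kind, observed$axis_kind))
    stop("peaks lie on different axis kinds", call. = FALSE)
  if (tolerance < 0) stop("tolerance must be non-negative", call. = FALSE)
  delta <- observed$position - reference$position
  direction <- if (abs(delta) <= tolerance) "none"
               else if (delta < 0) "downshift" else "upshift"
  on_wavelength <- reference$axis_kind == "wavelength_nm"
  label <- switch(direction,
    none = "no significant shift",
    downshift = if (on_wavelength)
      sprintf("blue shift of %.3g nm", -delta)
    else sprintf("downshift of %.3g cm-1", -delta),
    upshift = if (on_wavelength)
      sprintf("red shift of %.3g nm", delta)
    else sprintf("upshift of %.3g cm-1", delta))
  structure(list(direction = direction, delta = delta,
                 axis_kind = reference$axis_kind, label = label),
            class = "shift_call")
}

#' @export
print.shift_call <- function(x, ...) {
  cat(sprintf("<shift> %s (delta = %+.4g on %s)\n", x$label, x$delta, x$axis_kind))
  invisible(x)
}

#' Tabulate Stern-Volmer quench ratios from a titration series
#'
#' Reads F0 from the zero-quencher spectrum at its band maximum and F from
#' every quenched spectrum, then tabulates F0/F and (F0-F)/F per
#' concentration. In the default `reference_peak` mode all intensities are
#' read at the fixed wavelength of the unquenched band maximum (the standard
#' Stern-Volmer convention); `per_spectrum_peak` reads each spectrum at its
#' own maximum. Intensities are raw signal values at the grid point nearest
#' the located maximum.
#'
#' Rows with F > F0 (fluorescence enhancement, e.g. scatter) are flagged in
#' the `enhancement` column; downstream fits exclude them.
#'
#' @param series a [titration_series()].
#' @param at `"reference_peak"` (default) or `"per_spectrum_peak"`.
#' @param window smoothing window passed to [find_peak()].
#' @return A data frame of class `quench_ratio_table` with columns
#'   `quencher_conc`, `F0_over_F`, `F0_minus_F_over_F`, `enhancement`, and
#'   attributes `temperature` and `eval_wavelength`.
#' @export
quench_ratios <- function(series, at = c("reference_peak", "per_spectrum_peak"),
                          window = 5L) {
  stopifnot(inherits(series, "titration_series"))
  at <- match.arg(at)
  ref_i <- which(series$quencher_conc == 0)
  ref <- series$spectra[[ref_i]]
  pk <- find_peak(ref, window)
  ref_idx <- which.min(abs(ref$axis - pk$position))
  F0 <- ref$signal[ref_idx]
  Fvals <- vapply(seq_along(series$spectra), function(i) {
    sp <- series$spectra[[i]]
    if (at == "reference_peak" || i == ref_i) {
      sp$signal[ref_idx]
    } else {
      pki <- find_peak(sp, window)
      sp$signal[which.min(abs(sp$axis - pki$position))]
    }
  }, numeric(1))
  if (F0 <= 0 || any(Fvals <= 0))
    stop("non-positive intensity at the evaluation wavelength", call. = FALSE)
  out <- data.frame(
    quencher_conc = series$quencher_conc,
    F0_over_F = F0 / Fvals,
    F0_minus_F_over_F = F0 / Fvals - 1,
    enhancement = Fvals > F0 & series$quencher_conc > 0)
  attr(out, "temperature") <- series$temperature
  attr(out, "eval_wavelength") <- ref$axis[ref_idx]
  attr(out, "eval_mode") <- at
  class(out) <- c("quench_ratio_table", "data.frame")
  out
}

#' Construct a circular dichroism record
#'
#' A CD spectrum (signal theta in degrees) together with the metadata needed
#' for molar-ellipticity conversion: molar protein concentration, cuvette
#' path length and residue count. Instruments commonly report millidegrees;
#' set `from_millideg = TRUE` to divide the signal by 1000 on input.
#'
#' @param spectrum a [spectrum()] with `signal_kind = "cd"`, theta in degrees.
#' @param protein_conc protein concentration, mol/L (> 0).
#' @param path_length light path, cm (> 0).
#' @param residue_count number of residues per protein (integer >= 1); this is
#'   the residue number of the normalisation, not the gas constant.
#' @param mean_residue_weight optional mean residue weight (g/mol), carried as
#'   metadata only.
#' @param from_millideg if `TRUE`, the signal is converted from mdeg to deg.
#' @return An object of class `cd_record`.
#' @export
cd_record <- function(spectrum, protein_conc, path_length, residue_count,
                      mean_residue_weight = NULL, from_millideg = FALSE) {
  stopifnot(inherits(spectrum, "quench_spectrum"))
  if (!is.finite(protein_conc) || protein_conc <= 0)
    stop("protein_conc must be > 0", call. = FALSE)
  if (!is.finite(path_length) || path_length <= 0)
    stop("path_length must be > 0", call. = FALSE)
  residue_count <- as.integer(residue_count)
  if (is.na(residue_count) || residue_count < 1L)
    stop("residue_count must be an integer >= 1", call. = FALSE)
  if (from_millideg) spectrum$signal <- spectrum$signal / 1000
  structure(list(spectrum = spectrum, protein_conc = protein_conc,
                 path_length = path_length, residue_count = residue_count,
                 mean_residue_weight = mean_residue_weight),
            class = "cd_record")
}

#' Convert a CD record to molar ellipticity
#'
#' Pointwise conversion of the CD signal theta (degrees) to molar ellipticity
#' `[theta] = theta / (R * C * l * 10)` in deg.cm^2.dmol^-1, where R is the
#' residue count, C the molar protein concentration and l the path length in
#' cm. Metadata (axis, temperature, sample) is propagated.
#'
#' @param record a [cd_record()].
#' @return A [spectrum()] whose signal is molar ellipticity.
#' @export
molar_ellipticity <- function(record) {
  stopifnot(inherits(record, "cd_record"))
  sp <- record$spectrum
  sp$signal <- sp$signal /
    (record$residue_count * record$protein_conc * record$path_length * 10)
  sp
}
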