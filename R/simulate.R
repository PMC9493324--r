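# Seeded generative model of the titration experiments: a 1:1 (or n-site)
# static-quenching isotherm with temperature-dependent Ka derived from
# (dH, dS), a Gaussian emission band near 338 nm that blue-shifts with bound
# fraction, multiplicative measurement noise, and companion functional-assay
# tables with known monotone trends.

#' Ground truth for the synthetic titration model
#'
#' Full parameterisation of the generative model. The defaults emulate the
#' emulated study design: (dH, dS) = (5225 J/mol, 112.98 J/mol/K), the van't
#' Hoff line through apparent binding constants of 0.8-1.3e5 L/mol over
#' 273-338 K (an endothermic, entropy-driven, hydrophobically bound 1:1
#' complex); an emission band at 338 nm of 20 nm Gaussian width that
#' blue-shifts by up to 3 nm at full saturation; and 1% multiplicative
#' intensity noise.
#'
#' @param delta_H association enthalpy, J/mol.
#' @param delta_S association entropy, J/mol/K.
#' @param n_sites stoichiometry exponent n (> 0).
#' @param F0 unquenched peak intensity, a.u. (> 0).
#' @param band_center0 unquenched emission band center, nm.
#' @param band_width Gaussian sigma of the emission band, nm (> 0).
#' @param blueshift_max band-center displacement at full saturation, nm (>= 0).
#' @param noise_rel relative (multiplicative) noise sd (>= 0).
#' @param seed integer RNG seed.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(delta_H = 5225, delta_S = 112.98, n_sites = 1,
                         F0 = 1000, band_center0 = 338, band_width = 20,
                         blueshift_max = 3, noise_rel = 0.01, seed = 1L) {
  if (!is.finite(F0) || F0 <= 0) stop("F0 must be > 0", call. = FALSE)
  if (!is.finite(band_width) || band_width <= 0)
    stop("band_width must be > 0", call. = FALSE)
  if (!is.finite(noise_rel) || noise_rel < 0)
    stop("noise_rel must be >= 0", call. = FALSE)
  if (!is.finite(blueshift_max) || blueshift_max < 0)
    stop("blueshift_max must be >= 0", call. = FALSE)
  if (!is.finite(n_sites) || n_sites <= 0)
    stop("n_sites must be > 0", call. = FALSE)
  structure(list(delta_H = delta_H, delta_S = delta_S, n_sites = n_sites,
                 F0 = F0, band_center0 = band_center0,
                 band_width = band_width, blueshift_max = blueshift_max,
                 noise_rel = noise_rel, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Experimental design grid for the simulator
#'
#' Defaults mirror the emulated experiment: four incubation temperatures
#' {273, 298, 318, 338} K, five nonzero quencher levels 2-10 umol/L plus the
#' zero-quencher reference, and a 300-500 nm emission grid at 1 nm steps.
#'
#' @param temperatures kelvin.
#' @param concentrations quencher concentrations, mol/L, including 0.
#' @param wavelengths emission wavelength grid, nm.
#' @return An object of class `design_grid`.
#' @export
design_grid <- function(temperatures = c(273, 298, 318, 338),
                        concentrations = c(0, 2, 4, 6, 8, 10) * 1e-6,
                        wavelengths = seq(300, 500, by = 1)) {
  if (!any(concentrations == 0))
    stop("concentrations must include the zero reference", call. = FALSE)
  if (anyDuplicated(concentrations) || any(concentrations < 0))
    stop("concentrations must be unique and non-negative", call. = FALSE)
  if (any(temperatures <= 0)) stop("temperatures must be > 0", call. = FALSE)
  structure(list(temperatures = sort(temperatures),
                 concentrations = sort(concentrations),
                 wavelengths = wavelengths),
            class = "design_grid")
}

#' Binding constant from ground-truth thermodynamics
#'
#' Inverts the van't Hoff relation: `Ka(T) = exp(-dH/(R T) + dS/R)`,
#' R = 8.314 J/mol/K.
#'
#' @param truth a [ground_truth()], or a numeric dH (J/mol) together with
#'   `delta_S`.
#' @param temperature kelvin (> 0), vectorised.
#' @param delta_S entropy, J/mol/K, used when `truth` is numeric.
#' @return Ka in L/mol.
#' @export
ka_from_thermo <- function(truth, temperature, delta_S = NULL) {
  if (inherits(truth, "ground_truth")) {
    dH <- truth$delta_H; dS <- truth$delta_S
  } else {
    dH <- truth; dS <- delta_S
    if (is.null(dS)) stop("delta_S required", call. = FALSE)
  }
  if (any(temperature <= 0)) stop("temperature must be > 0", call. = FALSE)
  exp(-dH / (GAS_CONSTANT * temperature) + dS / GAS_CONSTANT)
}

#' Simulate fluorescence titration series
#'
#' Forward model, chosen as the exact conjugate of the fitting equations:
#' for each temperature T and quencher concentration Q, the bound fraction is
#' `b = Ka Q^n / (1 + Ka Q^n)` and the peak intensity
#' `F = F0 / (1 + Ka Q^n)`, so that `(F0 - F)/F = Ka Q^n` holds exactly and
#' the Stern-Volmer slope equals Ka for n = 1. The emission band is a
#' Gaussian centered at `band_center0 - blueshift_max * b`; every sampled
#' point is multiplied by `(1 + noise_rel * z)`, z standard normal from a
#' generator seeded with `truth$seed` (so the same seed scales, never
#' re-draws, across noise levels). Negative products are floored at zero.
#' Free-ligand depletion is ignored (quencher in excess).
#'
#' @param truth a [ground_truth()].
#' @param grid a [design_grid()].
#' @param ka_override optional named vector/list mapping temperature (K) to
#'   Ka (L/mol), bypassing [ka_from_thermo()] — lets callers pin Ka directly.
#' @return Named list of [titration_series()], one per temperature.
#' @export
simulate_titration <- function(truth = ground_truth(), grid = design_grid(),
                               ka_override = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(grid, "design_grid"))
  set.seed(truth$seed)
  wl <- grid$wavelengths
  out <- lapply(grid$temperatures, function(tk) {
    Ka <- if (!is.null(ka_override)) {
      v <- ka_override[[as.character(tk)]]
      if (is.null(v)) stop("ka_override missing temperature ", tk, call. = FALSE)
      v
    } else ka_from_thermo(truth, tk)
    spectra <- lapply(grid$concentrations, function(q) {
      kq <- Ka * q^truth$n_sites
      b <- kq / (1 + kq)
      Fpk <- truth$F0 / (1 + kq)
      center <- truth$band_center0 - truth$blueshift_max * b
      signal <- Fpk * exp(-(wl - center)^2 / (2 * truth$band_width^2))
      z <- stats::rnorm(length(wl))
      signal <- pmax(signal * (1 + truth$noise_rel * z), 0)
      spectrum(wl, signal, axis_kind = "wavelength_nm", temperature = tk,
               sample_id = sprintf("synthetic_T%g", tk), excitation_nm = 280)
    })
    titration_series(spectra, grid$concentrations)
  })
  names(out) <- paste0(vapply(grid$temperatures, function(tk)
    sprintf("synthetic_T%g", tk), character(1)), "@", grid$temperatures)
  out
}

#' Simulate functional-assay tables
#'
#' Generates DPPH, foaming and emulsion measurement tables over an ordered
#' set of ligand/protein ratio labels, with linear trends in the ratio index
#' chosen so that, in expectation, scavenging and foaming capacity increase
#' with ligand ratio while foam stability (loss form decreasing), EAI
#' decreases and ESI increases — the monotone directions of the emulated
#' assays. Measured quantities carry multiplicative Gaussian noise from a
#' generator seeded with `seed`.
#'
#' @param truth a [ground_truth()]; supplies the default seed and noise.
#' @param ratio_labels ordered character labels of the ligand ratios.
#' @param seed RNG seed (defaults to `truth$seed`).
#' @param noise_rel relative noise sd (defaults to `truth$noise_rel`).
#' @return List of data frames `dpph`, `foam`, `emulsion` in the CSV
#'   dialects read by the assay processors.
#' @export
simulate_assays <- function(truth = ground_truth(),
                            ratio_labels = c("0%", "2%", "4%", "6%", "8%", "10%"),
                            seed = truth$seed, noise_rel = truth$noise_rel) {
  stopifnot(length(ratio_labels) >= 1L)
  set.seed(seed)
  i <- seq_along(ratio_labels) - 1L
  noisy <- function(x) pmax(x * (1 + noise_rel * stats::rnorm(length(x))), 0)
  # DPPH: scavenging rises 30% -> 55% across ratios
  A_0 <- rep(0.8, length(i))
  A_C <- noisy(A_0 * (1 - (0.30 + 0.05 * i)))
  dpph <- data.frame(ratio_label = ratio_labels, A_C = A_C, A_0 = A_0)
  # Foaming: whipped volume grows with ratio, unwhipped fixed -> FC rises;
  # foam surviving 20 min grows with ratio -> FS (loss) falls
  V_b <- rep(50, length(i))
  V_a <- noisy(60 + 2 * i)
  V_F0 <- pmax(V_a - V_b, 1)
  V_Ft <- pmin(noisy(V_F0 * (0.5 + 0.06 * i)), V_F0)
  foam <- data.frame(ratio_label = ratio_labels, V_a = V_a, V_b = V_b,
                     V_F0 = V_F0, V_Ft = V_Ft, t_min = 20)
  # Emulsion: initial turbidity falls with ratio -> EAI falls; retained
  # fraction rises -> ESI rises
  A0e <- noisy(0.5 - 0.03 * i)
  A10 <- pmax(A0e * (0.6 + 0.05 * i), 0)
  emulsion <- data.frame(ratio_label = ratio_labels, A_0 = A0e, A_10 = A10,
                         C_mg_per_mL = 1, oil_fraction = 0.25, dilution = 100)
  list(dpph = dpph, foam = foam, emulsion = emulsion)
}
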