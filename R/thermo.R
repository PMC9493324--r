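# Van't Hoff decomposition, Gibbs free energy, driving-force classification
# and spontaneity. All energies in J/mol; R fixed at 8.314 J/mol/K.

GAS_CONSTANT <- 8.314

`%||%` <- function(a, b) if (is.null(a)) b else a

.ka_map <- function(ka_by_temperature) {
  if (is.data.frame(ka_by_temperature)) {
    stopifnot(all(c("temperature", "Ka") %in% names(ka_by_temperature)) ||
                all(c("temperature_K", "Ka") %in% names(ka_by_temperature)))
    tk <- ka_by_temperature$temperature %||% ka_by_temperature$temperature_K
    ka <- ka_by_temperature$Ka
  } else if (is.list(ka_by_temperature) &&
             all(vapply(ka_by_temperature, inherits, logical(1), "binding_fit"))) {
    tk <- vapply(ka_by_temperature, `[[`, numeric(1), "temperature")
    ka <- vapply(ka_by_temperature, `[[`, numeric(1), "Ka")
  } else {
    ka <- as.numeric(ka_by_temperature)
    tk <- as.numeric(names(ka_by_temperature))
    if (anyNA(tk))
      stop("ka_by_temperature must be a named vector (names = temperature K), data frame, or list of binding fits",
           call. = FALSE)
  }
  ord <- order(tk)
  list(temperature = tk[ord], Ka = ka[ord])
}

#' Van't Hoff decomposition of a binding constant
#'
#' Fits ln Ka = -dH/(R T) + dS/R by ordinary least squares of ln Ka against
#' 1/T, assuming a temperature-independent enthalpy. The slope gives
#' `delta_H = -slope * R` (J/mol) and the intercept
#' `delta_S = intercept * R` (J/mol/K), R = 8.314 J/mol/K. With exactly two
#' temperatures the line is solved exactly and `r_squared` is 1.
#'
#' @param ka_by_temperature named numeric vector of Ka (L/mol) with
#'   temperatures (K) as names, a data frame with columns
#'   `temperature`/`temperature_K` and `Ka`, or a list of [double_log_fit()]
#'   results.
#' @return A list with `delta_H` (J/mol), `delta_S` (J/mol/K), `r_squared`,
#'   `gas_constant`, `n_points`.
#' @export
vant_hoff_fit <- function(ka_by_temperature) {
  m <- .ka_map(ka_by_temperature)
  tk <- m$temperature; ka <- m$Ka
  if (length(tk) < 2L)
    stop("at least 2 temperatures required", call. = FALSE)
  if (anyDuplicated(tk))
    stop("duplicate temperatures", call. = FALSE)
  if (any(!is.finite(tk)) || any(tk <= 0)) stop("temperatures must be > 0", call. = FALSE)
  if (any(!is.finite(ka)) || any(ka <= 0)) stop("Ka values must be > 0", call. = FALSE)
  x <- 1 / tk
  y <- log(ka)
  if (length(tk) == 2L) {
    slope <- (y[2L] - y[1L]) / (x[2L] - x[1L])
    intercept <- y[1L] - slope * x[1L]
    r2 <- 1
  } else {
    fit <- stats::lm(y ~ x)
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
    r2 <- .r_squared(y, stats::fitted(fit))
  }
  list(delta_H = -slope * GAS_CONSTANT, delta_S = intercept * GAS_CONSTANT,
       r_squared = r2, gas_constant = GAS_CONSTANT, n_points = length(tk))
}

#' Gibbs free energy of binding
#'
#' `dG(T) = dH - T * dS`, exact arithmetic, all energies in J/mol.
#'
#' @param delta_H enthalpy change, J/mol.
#' @param delta_S entropy change, J/mol/K.
#' @param temperatures temperatures, K (> 0).
#' @return Named numeric vector of dG (J/mol), names = temperatures.
#' @export
gibbs_free_energy <- function(delta_H, delta_S, temperatures) {
  temperatures <- as.numeric(temperatures)
  if (any(!is.finite(temperatures)) || any(temperatures <= 0))
    stop("temperatures must be positive", call. = FALSE)
  stats::setNames(delta_H - temperatures * delta_S, temperatures)
}

#' Gibbs free energy from a binding constant (diagnostic route)
#'
#' `dG = -R T ln Ka`, the direct route from a measured binding constant.
#' Reported alongside the van't Hoff route as a consistency diagnostic; the
#' two need not agree when Ka and (dH, dS) come from different fits.
#'
#' @param Ka binding constant, L/mol (> 0).
#' @param temperature kelvin (> 0).
#' @return dG in J/mol (vectorised).
#' @export
gibbs_from_ka <- function(Ka, temperature) {
  if (any(Ka <= 0) || any(temperature <= 0))
    stop("Ka and temperature must be > 0", call. = FALSE)
  -GAS_CONSTANT * temperature * log(Ka)
}

#' Classify the dominant binding force from thermodynamic signs
#'
#' Sign heuristic for the dominant non-covalent interaction: both dH and dS
#' positive indicates hydrophobic interaction; both negative indicates van
#' der Waals forces and hydrogen bonding; any other sign pattern (including
#' exact zeros) is left indeterminate.
#'
#' @param delta_H enthalpy change, J/mol.
#' @param delta_S entropy change, J/mol/K.
#' @return `"hydrophobic"`, `"vdw_and_hbond"`, or `"indeterminate"`.
#' @export
classify_driving_force <- function(delta_H, delta_S) {
  if (!is.finite(delta_H) || !is.finite(delta_S))
    stop("delta_H and delta_S must be finite", call. = FALSE)
  if (delta_H > 0 && delta_S > 0) "hydrophobic"
  else if (delta_H < 0 && delta_S < 0) "vdw_and_hbond"
  else "indeterminate"
}

#' Spontaneity of binding
#'
#' A process is spontaneous at a temperature iff dG < 0 there.
#'
#' @param gibbs named numeric vector of dG (J/mol), e.g. from
#'   [gibbs_free_energy()].
#' @return Named logical vector.
#' @export
spontaneity <- function(gibbs) {
  stats::setNames(as.numeric(gibbs) < 0, names(gibbs))
}

#' Full thermodynamic analysis of Ka(T)
#'
#' Convenience wrapper: [vant_hoff_fit()] then [gibbs_free_energy()] at the
#' input temperatures, [classify_driving_force()] and [spontaneity()], plus
#' the diagnostic -RT ln Ka column.
#'
#' @inheritParams vant_hoff_fit
#' @return An object of class `thermo_result` with fields `delta_H`,
#'   `delta_S`, `r_squared`, `gibbs`, `gibbs_from_ka`, `gas_constant`,
#'   `force_call`, `spontaneous`, `table`.
#' @export
thermo_analysis <- function(ka_by_temperature) {
  m <- .ka_map(ka_by_temperature)
  fit <- vant_hoff_fit(ka_by_temperature)
  gibbs <- gibbs_free_energy(fit$delta_H, fit$delta_S, m$temperature)
  structure(list(
    delta_H = fit$delta_H, delta_S = fit$delta_S, r_squared = fit$r_squared,
    gibbs = gibbs,
    gibbs_from_ka = stats::setNames(gibbs_from_ka(m$Ka, m$temperature),
                                    m$temperature),
    gas_constant = fit$gas_constant,
    force_call = classify_driving_force(fit$delta_H, fit$delta_S),
    spontaneous = spontaneity(gibbs),
    table = data.frame(T_K = m$temperature, Ka = m$Ka, lnKa = log(m$Ka),
                       dG_J_per_mol = unname(gibbs))),
    class = "thermo_result")
}

#' @export
print.thermo_result <- function(x, ...) {
  cat(sprintf("<van't Hoff analysis> dH = %.4g J/mol, dS = %.4g J/mol/K, r2 = %.3f\n",
              x$delta_H, x$delta_S, x$r_squared))
  cat(sprintf("  driving force: %s; spontaneous at %d/%d temperatures\n",
              x$force_call, sum(x$spontaneous), length(x$spontaneous)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write a thermodynamics result to CSV
#'
#' Emits columns `T_K`, `lnKa`, `dG_J_per_mol` (van't Hoff route) and
#' `dG_from_Ka_J_per_mol` (diagnostic), preceded by comment lines carrying
#' dH, dS and r2.
#'
#' @param result a [thermo_analysis()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_thermo_csv <- function(result, path) {
  stopifnot(inherits(result, "thermo_result"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# dH_J_per_mol=%.15g", result$delta_H),
               sprintf("# dS_J_per_mol_K=%.15g", result$delta_S),
               sprintf("# r2=%.15g", result$r_squared)), con)
  df <- result$table[, c("T_K", "lnKa", "dG_J_per_mol")]
  df$dG_from_Ka_J_per_mol <- unname(result$gibbs_from_ka)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
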