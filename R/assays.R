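# Scalar functional-property indices: DPPH radical scavenging, foaming
# capacity/stability, emulsifying activity/stability. All functions are
# vectorised over their measurement arguments; the process_* wrappers append
# computed columns to the standard CSV tables.

#' DPPH radical scavenging activity
#'
#' `(1 - A_C/A_0) * 100` percent, where `A_C` is the 517 nm absorbance of the
#' sample with DPPH and `A_0` the blank.
#'
#' @param A_C absorbance of sample + DPPH (>= 0).
#' @param A_0 absorbance of the blank (> 0).
#' @return Scavenging activity, percent.
#' @export
dpph_scavenging <- function(A_C, A_0) {
  if (any(A_0 <= 0)) stop("A_0 must be > 0", call. = FALSE)
  if (any(A_C < 0)) stop("A_C must be >= 0", call. = FALSE)
  (1 - A_C / A_0) * 100
}

#' Foaming capacity
#'
#' As printed: `FC = (V_a - V_b)/V_a * 100`, with `V_a` the sample volume
#' with whipping and `V_b` without. The common alternative normalises by the
#' unwhipped volume (`convention = "unwhipped"`).
#'
#' @param V_a volume with whipping, mL (> 0).
#' @param V_b volume without whipping, mL (>= 0).
#' @param convention `"whipped"` (as printed; divide by V_a) or
#'   `"unwhipped"` (divide by V_b).
#' @return Foaming capacity, percent.
#' @export
foaming_capacity <- function(V_a, V_b, convention = c("whipped", "unwhipped")) {
  convention <- match.arg(convention)
  if (any(V_a < 0) || any(V_b < 0)) stop("volumes must be >= 0", call. = FALSE)
  if (convention == "whipped") {
    if (any(V_a == 0)) stop("V_a must be > 0", call. = FALSE)
    (V_a - V_b) / V_a * 100
  } else {
    if (any(V_b == 0)) stop("V_b must be > 0", call. = FALSE)
    (V_a - V_b) / V_b * 100
  }
}

#' Foaming stability (foam-loss form, as printed)
#'
#' `FS = (V_F0 - V_Ft)/V_F0 * 100`: the percentage of foam volume lost
#' between 0 and t minutes. Note this measures loss, so larger values mean a
#' less stable foam; [foam_retention()] gives the complementary 100 - FS.
#'
#' @param V_F0 foam volume at 0 min, mL (> 0).
#' @param V_Ft foam volume at t min, mL (>= 0).
#' @return Foam loss, percent.
#' @export
foaming_stability <- function(V_F0, V_Ft) {
  if (any(V_F0 <= 0)) stop("V_F0 must be > 0", call. = FALSE)
  if (any(V_Ft < 0)) stop("V_Ft must be >= 0", call. = FALSE)
  (V_F0 - V_Ft) / V_F0 * 100
}

#' Foam retention
#'
#' Convenience complement of [foaming_stability()]: `100 - FS`, the
#' percentage of foam surviving to t minutes.
#'
#' @inheritParams foaming_stability
#' @return Foam retention, percent.
#' @export
foam_retention <- function(V_F0, V_Ft) 100 - foaming_stability(V_F0, V_Ft)

#' Emulsifying activity index
#'
#' Default mode `"pearce_kinsella"` is the standard turbidimetric EAI,
#' `2 * 2.303 * A_0 * dilution / (C * (1 - phi) * 1e4)` m^2/g, with `A_0`
#' the 500 nm absorbance of the diluted emulsion at 0 min, `dilution` the
#' dilution factor (typically 100), `C` the protein concentration in mg/mL
#' and `phi` the oil volume fraction. Mode `"as_printed"` evaluates the
#' absorbance-free form `2 * 2.303 / (C * (1 - phi) * 10)` for comparison
#' with reports that use it literally.
#'
#' @param A_0_emul absorbance of the diluted emulsion at 0 min (>= 0).
#' @param C_protein protein concentration, mg/mL (> 0).
#' @param oil_fraction oil phase volume fraction, in [0, 1).
#' @param dilution dilution factor (>= 1).
#' @param mode `"pearce_kinsella"` (default) or `"as_printed"`.
#' @return EAI in m^2/g.
#' @export
emulsifying_activity_index <- function(A_0_emul, C_protein, oil_fraction,
                                       dilution = 100,
                                       mode = c("pearce_kinsella", "as_printed")) {
  mode <- match.arg(mode)
  if (any(C_protein <= 0)) stop("C_protein must be > 0", call. = FALSE)
  if (any(oil_fraction < 0 | oil_fraction >= 1))
    stop("oil_fraction must lie in [0, 1)", call. = FALSE)
  if (any(dilution < 1)) stop("dilution must be >= 1", call. = FALSE)
  if (mode == "pearce_kinsella") {
    if (any(A_0_emul < 0)) stop("A_0_emul must be >= 0", call. = FALSE)
    2 * 2.303 * A_0_emul * dilution / (C_protein * (1 - oil_fraction) * 1e4)
  } else {
    2 * 2.303 / (C_protein * (1 - oil_fraction) * 10)
  }
}

#' Emulsion stability index
#'
#' `ESI = A_10/A_0 * 100` percent: the fraction of the initial emulsion
#' absorbance retained after 10 minutes.
#'
#' @param A_0_emul absorbance at 0 min (> 0).
#' @param A_10 absorbance at 10 min (>= 0).
#' @return ESI, percent.
#' @export
emulsion_stability_index <- function(A_0_emul, A_10) {
  if (any(A_0_emul <= 0)) stop("A_0_emul must be > 0", call. = FALSE)
  if (any(A_10 < 0)) stop("A_10 must be >= 0", call. = FALSE)
  A_10 / A_0_emul * 100
}

#' Compute scavenging column for a DPPH table
#'
#' @param df data frame with columns `ratio_label`, `A_C`, `A_0`.
#' @return `df` with an appended `scavenging_pct` column.
#' @export
process_dpph <- function(df) {
  stopifnot(all(c("A_C", "A_0") %in% names(df)))
  df$scavenging_pct <- dpph_scavenging(df$A_C, df$A_0)
  df
}

#' Compute FC/FS columns for a foaming table
#'
#' Appends `FC_pct` and `FS_pct` (foam-loss form). Rows where the foam
#' volume grew on standing (`V_Ft > V_F0`) are flagged in `foam_gain`, and
#' stability values outside [0, 100] are flagged in `out_of_range` — flagged,
#' never clamped.
#'
#' @param df data frame with columns `ratio_label`, `V_a`, `V_b`, `V_F0`,
#'   `V_Ft`, `t_min`.
#' @param fc_convention passed to [foaming_capacity()].
#' @return `df` with appended computed and flag columns.
#' @export
process_foam <- function(df, fc_convention = "whipped") {
  stopifnot(all(c("V_a", "V_b", "V_F0", "V_Ft") %in% names(df)))
  df$FC_pct <- foaming_capacity(df$V_a, df$V_b, fc_convention)
  df$FS_pct <- foaming_stability(df$V_F0, df$V_Ft)
  df$foam_gain <- df$V_Ft > df$V_F0
  df$out_of_range <- df$FS_pct < 0 | df$FS_pct > 100
  df
}

#' Compute EAI/ESI columns for an emulsion table
#'
#' @param df data frame with columns `ratio_label`, `A_0`, `A_10`,
#'   `C_mg_per_mL`, `oil_fraction`, `dilution`.
#' @param eai_mode passed to [emulsifying_activity_index()].
#' @return `df` with appended `EAI_m2_per_g`, `ESI_pct`, `eai_mode`,
#'   `out_of_range` columns.
#' @export
process_emulsion <- function(df, eai_mode = "pearce_kinsella") {
  stopifnot(all(c("A_0", "A_10", "C_mg_per_mL", "oil_fraction", "dilution") %in% names(df)))
  df$EAI_m2_per_g <- emulsifying_activity_index(df$A_0, df$C_mg_per_mL,
                                                df$oil_fraction, df$dilution,
                                                eai_mode)
  df$ESI_pct <- emulsion_stability_index(df$A_0, df$A_10)
  df$eai_mode <- eai_mode
  df$out_of_range <- df$ESI_pct < 0 | df$ESI_pct > 100
  df
}
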