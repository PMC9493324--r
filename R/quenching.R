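# Stern-Volmer quenching fit, bimolecular quenching constant, quenching
# mechanism classification, and the double-logarithmic binding fit.

# normalise ratio-table input: accepts the quench_ratio_table produced by
# quench_ratios() or any data frame with quencher_conc[_M] and F0_over_F
.as_ratio_table <- function(ratios) {
  stopifnot(is.data.frame(ratios))
  if (!"quencher_conc" %in% names(ratios) && "quencher_conc_M" %in% names(ratios))
    ratios$quencher_conc <- ratios$quencher_conc_M
  if (!all(c("quencher_conc", "F0_over_F") %in% names(ratios)))
    stop("ratio table needs columns quencher_conc (or quencher_conc_M) and F0_over_F",
         call. = FALSE)
  if (!"F0_minus_F_over_F" %in% names(ratios))
    ratios$F0_minus_F_over_F <- ratios$F0_over_F - 1
  if (!"enhancement" %in% names(ratios))
    ratios$enhancement <- FALSE
  ratios
}

.r_squared <- function(obs, fitted) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(1)
  max(0, min(1, 1 - sum((obs - fitted)^2) / sst))
}

#' Stern-Volmer quenching fit
#'
#' Fits the Stern-Volmer relation F0/F = 1 + K_SV [Q] by ordinary least
#' squares of the quench ratio against quencher concentration. The slope is
#' the Stern-Volmer constant K_SV (L/mol); the bimolecular quenching rate
#' constant is kq = K_SV / tau0, with tau0 the unquenched fluorophore
#' lifetime (default 1e-8 s). By default the intercept is free, which lets it
#' diagnose curvature; the relation itself forces intercept 1, so a fitted
#' intercept further than 0.1 from 1 raises a warning and sets
#' `intercept_flag`. `constrain_intercept = TRUE` fits through (0, 1).
#'
#' Rows flagged `enhancement` (F > F0) are excluded before fitting.
#'
#' @param ratios a [quench_ratios()] table, or a data frame with columns
#'   `quencher_conc` (mol/L) and `F0_over_F`.
#' @param tau0 unquenched fluorescence lifetime, seconds.
#' @param temperature kelvin; taken from the table attribute when absent.
#' @param constrain_intercept fit through (0, 1) instead of a free intercept.
#' @return An object of class `quenching_fit` with fields `K_SV`,
#'   `intercept`, `kq`, `tau0`, `r_squared`, `stderr_K_SV`, `temperature`,
#'   `n_points`, `intercept_flag`.
#' @export
stern_volmer_fit <- function(ratios, tau0 = 1e-8, temperature = NULL,
                             constrain_intercept = FALSE) {
  ratios <- .as_ratio_table(ratios)
  if (is.null(temperature))
    temperature <- attr(ratios, "temperature") %||% NA_real_
  if (!is.finite(tau0) || tau0 <= 0) stop("tau0 must be > 0", call. = FALSE)
  keep <- !ratios$enhancement
  q <- ratios$quencher_conc[keep]
  y <- ratios$F0_over_F[keep]
  if (length(unique(q)) < 3L)
    stop("underdetermined: at least 3 distinct concentrations required",
         call. = FALSE)
  if (diff(range(q)) == 0)
    stop("zero concentration spread", call. = FALSE)
  if (constrain_intercept) {
    slope <- sum(q * (y - 1)) / sum(q^2)
    intercept <- 1
    fitted <- 1 + slope * q
    se <- if (length(q) > 1L)
      sqrt(sum((y - fitted)^2) / (length(q) - 1L) / sum(q^2)) else NA_real_
    r2 <- .r_squared(y, fitted)
  } else {
    fit <- stats::lm(y ~ q)
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
    # summary.lm warns on exact data ("essentially perfect fit"); the
    # standard error is still well defined (zero), so silence it here
    se <- unname(suppressWarnings(summary(fit))$coefficients["q", "Std. Error"])
    r2 <- .r_squared(y, stats::fitted(fit))
  }
  intercept_flag <- abs(intercept - 1) > 0.1
  if (intercept_flag)
    warning(sprintf("fitted intercept %.3g deviates from 1 by more than 0.1; Stern-Volmer linearity is questionable",
                    intercept), call. = FALSE)
  structure(list(K_SV = slope, intercept = intercept, kq = slope / tau0,
                 tau0 = tau0, r_squared = r2, stderr_K_SV = se,
                 temperature = temperature, n_points = length(q),
                 intercept_flag = intercept_flag),
            class = "quenching_fit")
}

#' @export
print.quenching_fit <- function(x, ...) {
  cat(sprintf("<Stern-Volmer fit> K_SV = %.4g L/mol, kq = %.4g L/mol/s (tau0 = %.3g s), intercept = %.4g, r2 = %.3f, T = %s K\n",
              x$K_SV, x$kq, x$tau0, x$intercept, x$r_squared,
              format(x$temperature)))
  invisible(x)
}

#' Double-logarithmic binding fit
#'
#' Fits the double-logarithmic quenching relation
#' log10((F0-F)/F) = log10(Ka) + n log10([Q]) by ordinary least squares. The
#' slope estimates the binding-site number n and the intercept the apparent
#' binding constant Ka (base-10 logarithms throughout). Rows with zero
#' concentration, non-positive (F0-F)/F, or an enhancement flag are dropped
#' (with a warning when that loses data); at least 3 usable rows remain or an
#' error is raised.
#'
#' @inheritParams stern_volmer_fit
#' @return An object of class `binding_fit` with fields `Ka` (L/mol), `n`,
#'   `r_squared`, `temperature`, `n_points`, `dropped_rows`.
#' @export
double_log_fit <- function(ratios, temperature = NULL) {
  ratios <- .as_ratio_table(ratios)
  if (is.null(temperature))
    temperature <- attr(ratios, "temperature") %||% NA_real_
  nz <- ratios[ratios$quencher_conc > 0, ]
  usable <- !nz$enhancement & nz$F0_minus_F_over_F > 0
  if (any(!usable))
    warning(sum(!usable),
            " row(s) with non-positive (F0-F)/F or enhancement dropped from double-log fit",
            call. = FALSE)
  nz <- nz[usable, ]
  if (nrow(nz) < 3L)
    stop("fewer than 3 usable rows for the double-log fit", call. = FALSE)
  lx <- log10(nz$quencher_conc)
  ly <- log10(nz$F0_minus_F_over_F)
  fit <- stats::lm(ly ~ lx)
  n <- unname(stats::coef(fit)[2L])
  Ka <- 10^unname(stats::coef(fit)[1L])
  structure(list(Ka = Ka, n = n,
                 r_squared = .r_squared(ly, stats::fitted(fit)),
                 temperature = temperature, n_points = nrow(nz),
                 dropped_rows = sum(!usable)),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<double-log binding fit> Ka = %.4g L/mol, n = %.4g, r2 = %.3f, T = %s K\n",
              x$Ka, x$n, x$r_squared, format(x$temperature)))
  invisible(x)
}

.mechanism_input <- function(fits) {
  if (is.data.frame(fits)) {
    stopifnot(all(c("temperature", "K_SV") %in% names(fits)))
    df <- data.frame(temperature = fits$temperature, K_SV = fits$K_SV,
                     kq = if ("kq" %in% names(fits)) fits$kq else fits$K_SV / 1e-8,
                     stderr_K_SV = if ("stderr_K_SV" %in% names(fits))
                       fits$stderr_K_SV else NA_real_)
  } else {
    stopifnot(is.list(fits),
              all(vapply(fits, inherits, logical(1), "quenching_fit")))
    df <- data.frame(
      temperature = vapply(fits, `[[`, numeric(1), "temperature"),
      K_SV = vapply(fits, `[[`, numeric(1), "K_SV"),
      kq = vapply(fits, `[[`, numeric(1), "kq"),
      stderr_K_SV = vapply(fits, function(f) f$stderr_K_SV %||% NA_real_,
                           numeric(1)))
  }
  df[order(df$temperature), ]
}

#' Classify the quenching mechanism
#'
#' Combines the two standard diagnostics of static versus dynamic quenching:
#' (A) the bimolecular quenching rate constant kq compared with the
#' diffusion-controlled collision limit (2e10 L/mol/s) — every kq above the
#' limit is static evidence, every kq below it dynamic evidence; and (B) the
#' temperature trend of K_SV — non-increasing with temperature (successive
#' increases within one pooled standard error count as ties) is static
#' evidence, an increasing trend dynamic evidence. The verdict is `"static"`
#' or `"dynamic"` only when both criteria agree; otherwise `"ambiguous"`.
#' The reported trend is the sign of the OLS slope of K_SV against T, with
#' changes within the pooled standard error reported as `"flat"`.
#'
#' @param fits list of [stern_volmer_fit()] results at distinct temperatures
#'   (>= 2), or a data frame with columns `temperature`, `K_SV` and
#'   optionally `kq`, `stderr_K_SV`.
#' @param diffusion_limit diffusion collision constant, L/mol/s.
#' @return An object of class `mechanism_call` with fields `verdict`,
#'   `kq_exceeds_diffusion_limit` (per temperature),
#'   `ksv_temperature_trend`, `diffusion_limit`, `table`.
#' @export
classify_mechanism <- function(fits, diffusion_limit = 2e10) {
  df <- .mechanism_input(fits)
  if (nrow(df) < 2L || anyDuplicated(df$temperature))
    stop("trend undefined: at least 2 distinct temperatures required",
         call. = FALSE)
  pooled_se <- if (all(is.na(df$stderr_K_SV))) 0
               else sqrt(mean(df$stderr_K_SV^2, na.rm = TRUE))
  slope <- unname(stats::coef(stats::lm(df$K_SV ~ df$temperature))[2L])
  span <- abs(slope) * diff(range(df$temperature))
  trend <- if (span <= pooled_se) "flat"
           else if (slope < 0) "decreasing" else "increasing"
  exceeds <- df$kq > diffusion_limit
  a_static <- all(exceeds)
  a_dynamic <- all(df$kq < diffusion_limit)
  b_static <- all(diff(df$K_SV) <= pooled_se)
  b_dynamic <- trend == "increasing"
  verdict <- if (a_static && b_static) "static"
             else if (a_dynamic && b_dynamic) "dynamic"
             else "ambiguous"
  structure(list(verdict = verdict,
                 kq_exceeds_diffusion_limit = stats::setNames(exceeds, df$temperature),
                 ksv_temperature_trend = trend,
                 diffusion_limit = diffusion_limit,
                 table = df),
            class = "mechanism_call")
}

#' @export
print.mechanism_call <- function(x, ...) {
  cat(sprintf("<mechanism call> %s (K_SV trend %s; kq > %.3g L/mol/s at %d/%d temperatures)\n",
              x$verdict, x$ksv_temperature_trend, x$diffusion_limit,
              sum(x$kq_exceeds_diffusion_limit),
              length(x$kq_exceeds_diffusion_limit)))
  invisible(x)
}
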