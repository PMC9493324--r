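# Long-format delimited-text I/O for titration spectra.
#
# Dialect: UTF-8 CSV, mandatory header, decimal point, columns
#   sample_id, temperature_K, quencher_conc_M, axis_kind, axis_value, signal
# One row per (spectrum, grid point); rows group into titration series by
# (sample_id, temperature_K).

SPECTRA_COLUMNS <- c("sample_id", "temperature_K", "quencher_conc_M",
                     "axis_kind", "axis_value", "signal")

.numeric_or_die <- function(x, col, header_offset = 1L) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !(is.na(x) | x == "" | x == "NA"))
  if (length(bad))
    stop(sprintf("non-numeric value in column '%s' at row %d", col,
                 bad[1L] + header_offset), call. = FALSE)
  if (anyNA(v))
    stop(sprintf("missing value in column '%s' at row %d", col,
                 which(is.na(v))[1L] + header_offset), call. = FALSE)
  v
}

#' Read titration spectra from long-format CSV
#'
#' Reads a long-format spectra table (columns `sample_id`, `temperature_K`,
#' `quencher_conc_M`, `axis_kind`, `axis_value`, `signal`) and assembles one
#' [titration_series()] per (sample, temperature) group. Each group must
#' contain a zero-concentration reference spectrum and all spectra in a group
#' must share one axis grid.
#'
#' @param path CSV file path.
#' @param signal_kind signal kind forwarded to [spectrum()].
#' @return Named list of `titration_series` (names `sample_id@T`).
#' @seealso [write_spectra_csv()] for the inverse.
#' @export
read_spectra_csv <- function(path, signal_kind = "intensity") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  missing_cols <- setdiff(SPECTRA_COLUMNS, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("empty spectra file", call. = FALSE)
  df$temperature_K <- .numeric_or_die(df$temperature_K, "temperature_K")
  df$quencher_conc_M <- .numeric_or_die(df$quencher_conc_M, "quencher_conc_M")
  df$axis_value <- .numeric_or_die(df$axis_value, "axis_value")
  df$signal <- .numeric_or_die(df$signal, "signal")
  if (!all(df$axis_kind %in% AXIS_KINDS))
    stop("unknown axis_kind at row ",
         which(!(df$axis_kind %in% AXIS_KINDS))[1L] + 1L, call. = FALSE)
  key <- paste(df$sample_id, df$temperature_K, df$quencher_conc_M,
               df$axis_value, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (series, concentration, axis_value) at row ",
         which(duplicated(key))[1L] + 1L, call. = FALSE)

  groups <- split(df, list(df$sample_id, df$temperature_K), drop = TRUE, sep = "@")
  out <- lapply(groups, function(g) {
    concs <- sort(unique(g$quencher_conc_M))
    if (!any(concs == 0))
      stop("no F0 reference in series '", g$sample_id[1L], "' at ",
           g$temperature_K[1L], " K", call. = FALSE)
    spectra <- lapply(concs, function(q) {
      s <- g[g$quencher_conc_M == q, ]
      s <- s[order(s$axis_value), ]
      spectrum(s$axis_value, s$signal, axis_kind = s$axis_kind[1L],
               temperature = s$temperature_K[1L], sample_id = s$sample_id[1L],
               signal_kind = signal_kind)
    })
    titration_series(spectra, concs)
  })
  out[order(names(out))]
}

#' Write titration spectra to long-format CSV
#'
#' Inverse of [read_spectra_csv()]. Numeric values are written with 15
#' significant digits so that a write/read round trip is lossless to at least
#' 12 significant digits.
#'
#' @param series_list a `titration_series` or a list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(series_list, path) {
  if (inherits(series_list, "titration_series")) series_list <- list(series_list)
  rows <- lapply(series_list, function(ts) {
    do.call(rbind, lapply(seq_along(ts$spectra), function(i) {
      sp <- ts$spectra[[i]]
      data.frame(sample_id = sp$sample_id,
                 temperature_K = sprintf("%.15g", sp$temperature),
                 quencher_conc_M = sprintf("%.15g", ts$quencher_conc[i]),
                 axis_kind = sp$axis_kind,
                 axis_value = sprintf("%.15g", sp$axis),
                 signal = sprintf("%.15g", sp$signal))
    }))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = c(1L, 4L),
                   fileEncoding = "UTF-8")
  invisible(path)
}
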