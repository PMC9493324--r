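# Orchestration: configuration, the simulate -> analyze -> report workflow,
# and a machine-readable results bundle. Every analysis decision (evaluation
# mode, tau0, EAI mode, conventions, constants) is surfaced in the config and
# echoed into the report's provenance block.

.validation_error <- function(...) {
  stop(structure(class = c("quenchbind_validation_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Default pipeline configuration
#'
#' A plain nested list; serialise it to YAML or JSON for the command line.
#' `simulate` holds the [ground_truth()] and [design_grid()] parameters;
#' `analyze` holds every analysis decision: quench-ratio evaluation mode and
#' smoothing window, tau0, diffusion limit, shift tolerance (nm), EAI mode
#' and foaming-capacity convention.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    simulate = list(
      truth = unclass(ground_truth()),
      grid = list(temperatures = c(273, 298, 318, 338),
                  concentrations = c(0, 2, 4, 6, 8, 10) * 1e-6,
                  wavelengths = c(300, 500, 1)),  # min, max, step
      ratio_labels = c("0%", "2%", "4%", "6%", "8%", "10%"),
      assays = TRUE),
    analyze = list(
      eval_mode = "reference_peak",
      window = 5,
      tau0 = 1e-8,
      diffusion_limit = 2e10,
      shift_tolerance = 0.5,
      eai_mode = "pearce_kinsella",
      fc_convention = "whipped"),
    input = list(spectra = NULL, dpph = NULL, foam = NULL, emulsion = NULL,
                 ka_table = NULL, delta_H = NULL, delta_S = NULL))
}

#' Read a pipeline configuration file
#'
#' YAML or JSON (by extension), merged over [default_config()] so partial
#' configs are valid.
#'
#' @param path config file path (`.yaml`/`.yml`/`.json`).
#' @return Configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) .validation_error("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
          else .validation_error("unsupported config format: .", ext)
  merge_into <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge_into(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  merge_into(default_config(), user)
}

.config_fingerprint <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(tmp))
}

.truth_from_config <- function(config) {
  tr <- config$simulate$truth
  if (!is.finite(tr$noise_rel) || tr$noise_rel < 0)
    .validation_error("invalid ground truth: noise_rel must be >= 0")
  ok <- try(do.call(ground_truth, tr), silent = TRUE)
  if (inherits(ok, "try-error"))
    .validation_error("invalid ground truth: ",
                      attr(ok, "condition")$message)
  ok
}

.grid_from_config <- function(config) {
  g <- config$simulate$grid
  wl <- g$wavelengths
  if (length(wl) == 3L && wl[2L] > wl[1L] && wl[3L] > 0 &&
      (wl[2L] - wl[1L]) / wl[3L] > 3)
    wl <- seq(wl[1L], wl[2L], by = wl[3L])
  design_grid(g$temperatures, g$concentrations, wl)
}

#' Simulate a titration + assay bundle to disk
#'
#' Writes `spectra.csv`, the three assay tables, and `manifest.json`
#' (the full ground truth and design, for later parameter-recovery scoring)
#' into `out_dir`. Deterministic for a fixed seed.
#'
#' @param config configuration list or path (see [default_config()],
#'   [read_config()]).
#' @param out_dir output directory (created if needed).
#' @param seed optional integer overriding the ground-truth seed.
#' @return Named list of written paths, invisibly.
#' @export
run_simulate <- function(config = default_config(), out_dir, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (!is.null(seed)) config$simulate$truth$seed <- as.integer(seed)
  truth <- .truth_from_config(config)
  grid <- .grid_from_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(spectra = file.path(out_dir, "spectra.csv"),
                manifest = file.path(out_dir, "manifest.json"))
  series <- simulate_titration(truth, grid)
  write_spectra_csv(series, paths$spectra)
  if (isTRUE(config$simulate$assays)) {
    assays <- simulate_assays(truth, config$simulate$ratio_labels)
    for (nm in names(assays)) {
      paths[[nm]] <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(assays[[nm]], paths[[nm]], row.names = FALSE)
    }
  }
  manifest <- list(truth = unclass(truth),
                   grid = list(temperatures = grid$temperatures,
                               concentrations = grid$concentrations,
                               wavelengths = range(grid$wavelengths)),
                   tool = list(package = "quenchbind",
                               version = as.character(utils::packageVersion("quenchbind"))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}

.analyze_series <- function(series, an) {
  ratios <- quench_ratios(series, at = an$eval_mode, window = an$window)
  sv <- stern_volmer_fit(ratios, tau0 = an$tau0)
  dl <- double_log_fit(ratios)
  pk_first <- find_peak(series$spectra[[1L]], an$window)
  pk_last <- find_peak(series$spectra[[length(series$spectra)]], an$window)
  shift <- classify_shift(pk_first, pk_last, tolerance = an$shift_tolerance)
  list(temperature = series$temperature, ratios = ratios,
       stern_volmer = sv, binding = dl,
       peak_unquenched = pk_first, peak_quenched = pk_last, shift = shift)
}

#' Run the full quenching/binding analysis
#'
#' Executes quench-ratio tabulation, Stern-Volmer and double-log fits per
#' temperature, mechanism classification, van't Hoff decomposition with
#' Gibbs energies, driving-force and spontaneity calls, peak/shift analysis,
#' and (when provided) the functional-assay indices. In skip-spectra mode
#' (`input$ka_table`, a CSV of `temperature_K, Ka`) only the thermodynamic
#' branch runs; supplying `input$delta_H`/`delta_S` adds a Gibbs column from
#' those user values alongside the fitted route.
#'
#' @param config configuration list or file path.
#' @param out_dir optional; when given, `report.json` and result CSVs are
#'   written there.
#' @return An object of class `analysis_report`.
#' @export
run_analyze <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  an <- config$analyze
  inp <- config$input
  report <- list(provenance = list(
    inputs = Filter(Negate(is.null), inp[c("spectra", "dpph", "foam", "emulsion", "ka_table")]),
    config = config[c("analyze")],
    config_hash = .config_fingerprint(config[c("analyze", "input")]),
    tool = list(package = "quenchbind",
                version = as.character(utils::packageVersion("quenchbind")))))

  per_temp <- NULL
  ka_map <- NULL
  if (!is.null(inp$spectra)) {
    if (!file.exists(inp$spectra))
      .validation_error("spectra file not found: ", inp$spectra)
    series_list <- read_spectra_csv(inp$spectra)
    per_temp <- lapply(series_list, .analyze_series, an = an)
    per_temp <- per_temp[order(vapply(per_temp, `[[`, numeric(1), "temperature"))]
    ka_map <- data.frame(
      temperature = vapply(per_temp, `[[`, numeric(1), "temperature"),
      Ka = vapply(per_temp, function(x) x$binding$Ka, numeric(1)))
    report$quenching <- lapply(per_temp, function(x) {
      c(unclass(x$stern_volmer),
        list(binding_Ka = x$binding$Ka, binding_n = x$binding$n,
             binding_r_squared = x$binding$r_squared))
    })
    report$peaks <- lapply(per_temp, function(x)
      list(temperature = x$temperature,
           unquenched_nm = x$peak_unquenched$position,
           quenched_nm = x$peak_quenched$position,
           shift = unclass(x$shift)))
    if (length(per_temp) >= 2L)
      report$mechanism <- unclass(classify_mechanism(
        lapply(per_temp, `[[`, "stern_volmer"), an$diffusion_limit))
  } else if (!is.null(inp$ka_table)) {
    if (!file.exists(inp$ka_table))
      .validation_error("Ka table not found: ", inp$ka_table)
    kt <- utils::read.csv(inp$ka_table)
    if (!all(c("temperature_K", "Ka") %in% names(kt)))
      .validation_error("ka_table needs columns temperature_K, Ka")
    ka_map <- data.frame(temperature = kt$temperature_K, Ka = kt$Ka)
  } else {
    .validation_error("config must name input$spectra or input$ka_table")
  }

  if (!is.null(ka_map) && nrow(ka_map) >= 2L) {
    th <- thermo_analysis(ka_map)
    report$thermodynamics <- list(
      delta_H_J_per_mol = th$delta_H, delta_S_J_per_mol_K = th$delta_S,
      r_squared = th$r_squared, gas_constant = th$gas_constant,
      force_call = th$force_call,
      gibbs_J_per_mol = as.list(th$gibbs),
      gibbs_from_ka_J_per_mol = as.list(th$gibbs_from_ka),
      spontaneous = as.list(th$spontaneous))
    if (!is.null(inp$delta_H) && !is.null(inp$delta_S)) {
      g_user <- gibbs_free_energy(inp$delta_H, inp$delta_S, ka_map$temperature)
      report$thermodynamics$user_supplied <- list(
        delta_H_J_per_mol = inp$delta_H, delta_S_J_per_mol_K = inp$delta_S,
        force_call = classify_driving_force(inp$delta_H, inp$delta_S),
        gibbs_J_per_mol = as.list(g_user),
        spontaneous = as.list(spontaneity(g_user)))
    }
    report$thermo_result <- th
  }

  assay_tabs <- list()
  if (!is.null(inp$dpph) && file.exists(inp$dpph))
    assay_tabs$dpph <- process_dpph(utils::read.csv(inp$dpph))
  if (!is.null(inp$foam) && file.exists(inp$foam))
    assay_tabs$foam <- process_foam(utils::read.csv(inp$foam), an$fc_convention)
  if (!is.null(inp$emulsion) && file.exists(inp$emulsion))
    assay_tabs$emulsion <- process_emulsion(utils::read.csv(inp$emulsion), an$eai_mode)
  if (length(assay_tabs)) report$assays <- assay_tabs

  report <- structure(report, class = "analysis_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report_json(report, file.path(out_dir, "report.json"))
    if (!is.null(report$thermo_result))
      write_thermo_csv(report$thermo_result,
                       file.path(out_dir, "thermodynamics.csv"))
    for (nm in names(assay_tabs))
      utils::write.csv(assay_tabs[[nm]],
                       file.path(out_dir, paste0(nm, "_indices.csv")),
                       row.names = FALSE)
  }
  report
}

#' Serialise an analysis report to JSON
#'
#' Lossless (full-precision) JSON; [read_report_json()] round-trips it.
#'
#' @param report an `analysis_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  x <- unclass(report)
  x$thermo_result <- NULL  # redundant with $thermodynamics; not JSON-friendly
  x <- rapply(x, function(v) if (is.data.frame(v)) as.list(v) else v,
              classes = "data.frame", how = "replace")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, null = "null")
  invisible(path)
}

#' Read back a serialised analysis report
#'
#' @param path path written by [write_report_json()].
#' @return The report as a nested list (class `analysis_report`).
#' @export
read_report_json <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = FALSE),
            class = "analysis_report")
}

#' Render a human-readable summary of an analysis report
#'
#' @param report an `analysis_report` (in-memory or from
#'   [read_report_json()]).
#' @param file passed to [cat()]; default prints to the console.
#' @return The summary lines, invisibly.
#' @export
render_report <- function(report, file = "") {
  fmt1 <- function(x) format(signif(as.numeric(x), 6))
  lines <- character()
  add <- function(...) lines <<- c(lines, paste0(...))
  add("Quenching / binding analysis report")
  add("===================================")
  if (!is.null(report$quenching)) {
    add("Per-temperature fits:")
    for (q in report$quenching)
      add(sprintf("  T = %s K: K_SV = %s L/mol, kq = %s L/mol/s, Ka = %s L/mol, n = %s",
                  fmt1(q$temperature), fmt1(q$K_SV), fmt1(q$kq),
                  fmt1(q$binding_Ka), fmt1(q$binding_n)))
  }
  if (!is.null(report$mechanism)) {
    add(sprintf("Quenching mechanism: %s (K_SV trend %s vs temperature)",
                report$mechanism$verdict, report$mechanism$ksv_temperature_trend))
  }
  if (!is.null(report$peaks)) {
    for (p in report$peaks)
      add(sprintf("  T = %s K: emission maximum %s -> %s nm (%s)",
                  fmt1(p$temperature), fmt1(p$unquenched_nm),
                  fmt1(p$quenched_nm), p$shift$label))
  }
  th <- report$thermodynamics
  if (!is.null(th)) {
    add(sprintf("Thermodynamics: dH = %s J/mol, dS = %s J/mol/K (r2 = %s)",
                fmt1(th$delta_H_J_per_mol), fmt1(th$delta_S_J_per_mol_K),
                fmt1(th$r_squared)))
    add(sprintf("  driving force: %s; spontaneous at %d/%d temperatures",
                th$force_call,
                sum(unlist(th$spontaneous)), length(th$spontaneous)))
    for (tk in names(th$gibbs_J_per_mol))
      add(sprintf("  dG(%s K) = %s J/mol", tk, fmt1(th$gibbs_J_per_mol[[tk]])))
  }
  if (!is.null(report$assays))
    add(sprintf("Assay tables processed: %s",
                paste(names(report$assays), collapse = ", ")))
  cat(paste(lines, collapse = "\n"), "\n", file = file)
  invisible(lines)
}

#' @export
print.analysis_report <- function(x, ...) {
  render_report(x)
  invisible(x)
}
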