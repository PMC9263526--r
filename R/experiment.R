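#' Initial concentration from the dosed solute mass
#'
#' In transient-uptake experiments the very first bulk samples are unreliable
#' (uptake starts before the liquid is homogeneous), so the initial
#' concentration is computed from the weighed solute mass and the liquid
#' volume instead of being measured.
#'
#' @param solute_mass_mg Mass of solute dosed, mg (> 0).
#' @param liquid_volume_L Liquid volume, L (> 0).
#' @return Initial concentration \eqn{C_0} in mg/L.
#' @examples
#' estimate_initial_concentration(300, 0.3)  # 1000 mg/L
#' @export
estimate_initial_concentration <- function(solute_mass_mg, liquid_volume_L) {
  stopifnot(solute_mass_mg > 0, liquid_volume_L > 0)
  solute_mass_mg / liquid_volume_L
}

#' Assemble an uptake experiment from a concentration time series
#'
#' Bundles a bulk-concentration time series with the experiment geometry and
#' solute identity into the object the fitting functions consume. The initial
#' concentration is derived from the dosed mass, not from the first sample.
#'
#' @param data A data frame with columns `time_s` (strictly increasing,
#'   \eqn{\ge 0}) and `conc_mg_L` (positive). At least 5 samples are
#'   required; the canonical design uses 25.
#' @param system A [granule_system()].
#' @param solute_mass_mg Dosed solute mass, mg.
#' @param mw_da Solute molecular weight, Da (optional, used for scaling).
#' @param label Optional solute label.
#'
#' @return An object of class `uptake_experiment`: a list with `data`
#'   (tibble), `system`, `solute_mass_mg`, `mw_da`, `label` and the derived
#'   `C_0` (mg/L).
#' @examples
#' sys <- granule_system(1.1e-3, 0.06, 0.24)
#' d <- tibble::tibble(time_s = c(60, 300, 900, 1800, 3600),
#'                     conc_mg_L = c(590, 560, 540, 525, 510))
#' uptake_experiment(d, sys, solute_mass_mg = 150)
#' @export
uptake_experiment <- function(data, system, solute_mass_mg, mw_da = NA_real_,
                              label = NULL) {
  stopifnot(is.data.frame(data), inherits(system, "granule_system"),
            solute_mass_mg > 0)
  missing_cols <- setdiff(c("time_s", "conc_mg_L"), names(data))
  if (length(missing_cols)) {
    abort(sprintf("experiment data is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "granulediff_input_error")
  }
  data <- tibble::as_tibble(data[, c("time_s", "conc_mg_L")])
  if (nrow(data) < 5) {
    abort("an uptake experiment needs at least 5 samples",
          class = "granulediff_input_error")
  }
  if (any(diff(data$time_s) <= 0) || any(data$time_s < 0)) {
    abort("time_s must be non-negative and strictly increasing",
          class = "granulediff_input_error")
  }
  if (any(data$conc_mg_L <= 0)) {
    abort("concentrations must be positive", class = "granulediff_input_error")
  }
  structure(
    list(data = data, system = system, solute_mass_mg = solute_mass_mg,
         mw_da = mw_da, label = label,
         C_0 = estimate_initial_concentration(solute_mass_mg,
                                              system$liquid_volume_L)),
    class = "uptake_experiment")
}

#' @export
print.uptake_experiment <- function(x, ...) {
  cat(sprintf("<uptake_experiment> %s%d samples over %.0f s, C_0 = %.3g mg/L, alpha = %.3g\n",
              if (!is.null(x$label)) paste0(x$label, ": ") else "",
              nrow(x$data), max(x$data$time_s), x$C_0, x$system$alpha))
  invisible(x)
}

#' Read an uptake experiment from CSV + metadata
#'
#' The time series is a CSV with columns `time_s, conc_mg_L`; the metadata a
#' YAML or JSON file with fields `radius_m`, `granule_volume_L`,
#' `liquid_volume_L`, `temperature_C`, `solute_mass_mg` and optionally
#' `mw_da`, `label`.
#'
#' @param csv_path Path to the time-series CSV.
#' @param meta_path Path to the metadata YAML/JSON.
#' @return An [uptake_experiment()].
#' @export
read_uptake_experiment <- function(csv_path, meta_path) {
  if (!file.exists(csv_path)) {
    abort(sprintf("experiment CSV not found: %s", csv_path),
          class = "granulediff_input_error")
  }
  if (!file.exists(meta_path)) {
    abort(sprintf("experiment metadata not found: %s", meta_path),
          class = "granulediff_input_error")
  }
  data <- readr::read_csv(csv_path, show_col_types = FALSE)
  meta <- if (grepl("\\.json$", meta_path, ignore.case = TRUE)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(meta_path)
  }
  need <- c("radius_m", "granule_volume_L", "liquid_volume_L",
            "temperature_C", "solute_mass_mg")
  missing_f <- setdiff(need, names(meta))
  if (length(missing_f)) {
    abort(sprintf("experiment metadata is missing field(s): %s",
                  paste(missing_f, collapse = ", ")),
          class = "granulediff_input_error")
  }
  sys <- granule_system(meta$radius_m, meta$granule_volume_L,
                        meta$liquid_volume_L, meta$temperature_C)
  uptake_experiment(data, sys, meta$solute_mass_mg,
                    mw_da = meta$mw_da %||% NA_real_,
                    label = meta$label %||% NULL)
}

#' Write an uptake experiment to CSV + metadata YAML
#'
#' Inverse of [read_uptake_experiment()]; used by the synthetic-data
#' generator to produce fixtures in the exact formats the fitting layer
#' reads.
#'
#' @param exp An [uptake_experiment()].
#' @param csv_path,meta_path Output paths.
#' @return Invisibly, the experiment.
#' @export
write_uptake_experiment <- function(exp, csv_path, meta_path) {
  stopifnot(inherits(exp, "uptake_experiment"))
  readr::write_csv(exp$data, csv_path)
  meta <- list(radius_m = exp$system$radius_m,
               granule_volume_L = exp$system$granule_volume_L,
               liquid_volume_L = exp$system$liquid_volume_L,
               temperature_C = exp$system$temperature_K - 273.15,
               solute_mass_mg = exp$solute_mass_mg,
               mw_da = exp$mw_da)
  if (!is.null(exp$label)) meta$label <- exp$label
  yaml::write_yaml(meta, meta_path)
  invisible(exp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
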