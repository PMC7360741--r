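#' Run configuration
#'
#' Bundles every tunable of the pipeline with its default. Defaults follow
#' the published protocol: cells kept when area > 10 px and quality index
#' >= 0.9; expression defined as intensities above the spot-level 85th
#' percentile; the boundary domain built from 50 µm circles; 500 bootstrap
#' refits with 90% selection- and sign-stability thresholds; networks
#' thresholded at the 99th percentile; a 5-year prediction horizon.
#'
#' @param percentile_threshold expression-threshold percentile in (0, 100).
#' @param circle_diameter_um tessellation circle diameter, micrometres.
#' @param center_spacing_um circle-centre grid spacing; default
#'   `circle_diameter_um / 10` keeps circles densely overlapping.
#' @param n_bootstraps bootstrap refits per stability screen.
#' @param stability_threshold minimum selection / sign-consistency fraction.
#' @param network_percentile percentile for network edge thresholding.
#' @param min_cell_size_px cells kept when size is strictly greater.
#' @param min_quality cells kept when quality index is `>=` this value.
#' @param horizon_years prediction horizon in years.
#' @param n_bins histogram bins on [-1, 1] for partial-correlation
#'   group distributions.
#' @param raw_intensities if TRUE the input intensities are raw and QC
#'   applies the log2 transform; default assumes log2 on input.
#' @param missing_max_frac feature columns missing in more than this
#'   fraction of patients are dropped; the rest are median-imputed.
#' @param seed integer seed recorded in every output.
#' @param paths named list of file paths (free-form, echoed to outputs).
#' @return a `run_config` list.
#' @export
run_config <- function(percentile_threshold = 85,
                       circle_diameter_um = 50,
                       center_spacing_um = circle_diameter_um / 10,
                       n_bootstraps = 500,
                       stability_threshold = 0.9,
                       network_percentile = 99,
                       min_cell_size_px = 10,
                       min_quality = 0.9,
                       horizon_years = 5,
                       n_bins = 40,
                       raw_intensities = FALSE,
                       missing_max_frac = 0.2,
                       seed = 1L,
                       paths = list()) {
  stopifnot(percentile_threshold > 0, percentile_threshold < 100,
            circle_diameter_um > 0,
            center_spacing_um > 0,
            center_spacing_um <= circle_diameter_um / 2,
            n_bootstraps >= 0,
            stability_threshold > 0, stability_threshold <= 1,
            network_percentile >= 0, network_percentile < 100,
            min_cell_size_px >= 0,
            min_quality >= 0, min_quality <= 1,
            horizon_years > 0, n_bins >= 2,
            missing_max_frac >= 0, missing_max_frac < 1)
  structure(list(percentile_threshold = percentile_threshold,
                 circle_diameter_um = circle_diameter_um,
                 center_spacing_um = center_spacing_um,
                 n_bootstraps = as.integer(n_bootstraps),
                 stability_threshold = stability_threshold,
                 network_percentile = network_percentile,
                 min_cell_size_px = min_cell_size_px,
                 min_quality = min_quality,
                 horizon_years = horizon_years,
                 n_bins = as.integer(n_bins),
                 raw_intensities = isTRUE(raw_intensities),
                 missing_max_frac = missing_max_frac,
                 seed = as.integer(seed),
                 paths = paths),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#' @param path `.yaml`/`.yml` or `.json` file whose keys match the
#'   arguments of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals[intersect(names(vals), known)])
}

#' Write a run configuration
#' @param config a `run_config`.
#' @param path output path; format chosen by extension (`.json` or YAML).
#' @return the path, invisibly.
#' @export
write_run_config <- function(config, path) {
  vals <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

# Stable short hash of a config, for output sidecars: a polynomial
# rolling hash over the serialized config (avoids a digest dependency).
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 5381
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 33 + b) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}
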