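#' @importFrom data.table fread fwrite as.data.table :=
NULL

# Required non-intensity columns of a cell table. `compartment` /
# `ecad_positive` are alternatives: at least one must be present.
.cell_table_core <- c("cell_id", "spot_id", "slide_id", "x", "y",
                      "size_px", "quality_index")

#' Construct and validate a cell table
#'
#' A cell table holds one row per segmented cell of one or more TMA spots:
#' identifiers, centroid position in micrometres, cell area in pixels (at
#' x20 magnification), a per-cell quality index in [0, 1], the epithelial /
#' stromal compartment (or E-cadherin positivity from which it is derived),
#' and one intensity column per panel biomarker (log2 arbitrary units).
#'
#' @param df data.frame with the required columns (`cell_id`, `spot_id`,
#'   `slide_id`, `x`, `y`, `size_px`, `quality_index`, and `compartment`
#'   and/or `ecad_positive`) plus one numeric column per panel marker.
#' @param panel a [biomarker_panel()].
#' @return a `cell_table`: a data.frame carrying the panel as an attribute.
#' @export
cell_table <- function(df, panel) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_core <- setdiff(.cell_table_core, names(df))
  if (length(missing_core)) {
    stop("cell table is missing required column(s): ",
         paste(missing_core, collapse = ", "))
  }
  if (!("compartment" %in% names(df)) && !("ecad_positive" %in% names(df))) {
    stop("cell table needs a 'compartment' or 'ecad_positive' column")
  }
  missing_markers <- setdiff(as.character(panel), names(df))
  if (length(missing_markers)) {
    stop("cell table is missing intensity column(s) for panel marker(s): ",
         paste(missing_markers, collapse = ", "))
  }
  for (m in as.character(panel)) {
    if (!is.numeric(df[[m]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[m]]))) & !is.na(df[[m]]))
      stop("non-numeric intensity in column '", m, "' (first bad row: ",
           if (length(bad)) bad[1] else NA, ")")
    }
  }
  if (!all(is.finite(df$x)) || !all(is.finite(df$y))) {
    stop("cell coordinates x, y must be finite")
  }
  if (any(df$size_px < 0, na.rm = TRUE)) stop("size_px must be >= 0")
  if (any(df$quality_index < 0 | df$quality_index > 1, na.rm = TRUE)) {
    stop("quality_index must lie in [0, 1]")
  }
  dup <- duplicated(df[c("spot_id", "cell_id")])
  if (any(dup)) {
    stop("duplicate cell_id within a spot: ",
         paste(utils::head(unique(df$cell_id[dup]), 5), collapse = ", "))
  }
  structure(df, panel = panel, class = c("cell_table", "data.frame"))
}

#' Panel attached to a cell table
#' @param table a `cell_table`.
#' @return the [biomarker_panel()] the table was validated against.
#' @export
panel_of <- function(table) attr(table, "panel")

#' Read a cell table from a delimited file
#'
#' Accepts comma- or tab-separated UTF-8 files with a header row (the
#' delimiter is sniffed). Columns not in the core schema or the panel are
#' ignored with a warning.
#'
#' @param path file path.
#' @param panel a [biomarker_panel()] naming the expected intensity columns.
#' @return a validated `cell_table`.
#' @export
read_cell_table <- function(path, panel) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  known <- c(.cell_table_core, "compartment", "ecad_positive",
             as.character(panel))
  extra <- setdiff(names(df), known)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
    df <- df[setdiff(names(df), extra)]
  }
  if ("ecad_positive" %in% names(df)) {
    df$ecad_positive <- as.logical(df$ecad_positive)
  }
  cell_table(df, panel)
}

#' Write a cell table to CSV
#'
#' @param table a `cell_table`.
#' @param path output path (`.csv`, comma-separated UTF-8 with header).
#' @param sidecar write a JSON sidecar (`<path>.meta.json`) recording the
#'   panel and, when present, the seed and config hash attributes.
#' @return the path, invisibly.
#' @export
write_cell_table <- function(table, path, sidecar = TRUE) {
  data.table::fwrite(as.data.frame(table), path)
  if (sidecar) write_sidecar(path, list(panel = as.character(panel_of(table))))
  invisible(path)
}

#' Construct and validate a patient survival table
#'
#' One row per patient: follow-up time in years (> 0), a recurrence
#' indicator in {0, 1}, and the clinical covariates used by the clinical
#' comparison model (TNM stage I/II/III, age in years, gender).
#'
#' @param df data.frame with columns `patient_id`, `time`, `event`, and
#'   optionally `stage`, `age`, `gender`.
#' @return a `survival_table` data.frame.
#' @export
survival_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- c("patient_id", "time", "event")
  missing_core <- setdiff(req, names(df))
  if (length(missing_core)) {
    stop("survival table is missing required column(s): ",
         paste(missing_core, collapse = ", "))
  }
  if (anyDuplicated(df$patient_id)) stop("duplicate patient_id")
  if (any(!is.finite(df$time)) || any(df$time <= 0)) {
    stop("follow-up time must be finite and > 0")
  }
  if (!all(df$event %in% c(0, 1))) stop("event indicator must be 0 or 1")
  if ("stage" %in% names(df)) {
    bad <- setdiff(unique(as.character(df$stage)), c("I", "II", "III"))
    if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
    df$stage <- factor(as.character(df$stage), levels = c("I", "II", "III"))
  }
  structure(df, class = c("survival_table", "data.frame"))
}

#' Read a patient survival table
#' @param path CSV/TSV file with header (`patient_id`, `time`, `event`, ...).
#' @return a validated `survival_table`.
#' @export
read_survival_table <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  survival_table(as.data.frame(data.table::fread(path, header = TRUE)))
}

#' Write a patient survival table to CSV
#' @param surv a `survival_table`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_survival_table <- function(surv, path) {
  data.table::fwrite(as.data.frame(surv), path)
  invisible(path)
}

# JSON sidecar with provenance for an output file.
write_sidecar <- function(path, extra = list()) {
  meta <- c(list(written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 package = "domainsurv",
                 version = as.character(utils::packageVersion("domainsurv"))),
            extra)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(NULL)
}
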