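#' Filter cells on size and quality
#'
#' Keeps cells whose segmented area is strictly greater than
#' `min_size_px` pixels (at x20 magnification) and whose quality index is
#' greater than or equal to `min_quality`. Note the asymmetry: the size
#' cut is strict, the quality cut is inclusive.
#'
#' @param table a `cell_table`.
#' @param min_size_px size cut in pixels (default 10).
#' @param min_quality quality cut in [0, 1] (default 0.9).
#' @return the filtered `cell_table`, with an attribute `removed` giving
#'   the number of cells failing each criterion (a cell can fail both).
#' @export
filter_cells <- function(table, min_size_px = 10, min_quality = 0.9) {
  fail_size <- !(table$size_px > min_size_px)
  fail_quality <- !(table$quality_index >= min_quality)
  keep <- !fail_size & !fail_quality
  if (!any(keep)) warning("all cells removed by QC filters")
  out <- table[keep, , drop = FALSE]
  attr(out, "panel") <- panel_of(table)
  attr(out, "log2_transformed") <- attr(table, "log2_transformed")
  class(out) <- class(table)
  attr(out, "removed") <- c(size = sum(fail_size), quality = sum(fail_quality))
  out
}

#' Log2-transform raw intensities
#'
#' Applies `log2(x + 1)` to every panel intensity column. The table is
#' flagged so a second application is refused: downstream statistics
#' assume a single transform.
#'
#' @param table a `cell_table` with raw (non-negative) intensities.
#' @return the transformed `cell_table` with attribute
#'   `log2_transformed = TRUE`.
#' @export
log2_transform <- function(table) {
  if (isTRUE(attr(table, "log2_transformed"))) {
    stop("intensities are already log2-transformed")
  }
  panel <- panel_of(table)
  for (m in as.character(panel)) {
    v <- table[[m]]
    if (any(v < 0, na.rm = TRUE)) {
      bad <- table$cell_id[which(v < 0)[1]]
      stop("negative raw intensity for marker '", m, "' (cell ", bad, ")")
    }
    table[[m]] <- log2(v + 1)
  }
  attr(table, "log2_transformed") <- TRUE
  table
}

#' Median-normalize intensities across slides
#'
#' Removes slide-to-slide non-biological variability by shifting each
#' slide's log2 intensities additively, per biomarker, so that all slide
#' medians equal the grand median (the median of the per-slide medians).
#' An additive shift on the log2 scale is multiplicative on the raw scale
#' and preserves within-slide rank order, so Kendall correlations are
#' unaffected.
#'
#' @param table a `cell_table` covering one or more slides (`slide_id`).
#' @return the normalized `cell_table`; after the call the per-slide
#'   per-biomarker medians agree across slides to machine precision.
#' @export
median_normalize <- function(table) {
  panel <- as.character(panel_of(table))
  slides <- unique(table$slide_id)
  if (length(slides) <= 1L) return(table)
  for (m in panel) {
    med <- tapply(table[[m]], table$slide_id, stats::median, na.rm = TRUE)
    if (any(is.na(med))) {
      warning("slide(s) with no usable cells skipped for marker ", m)
    }
    grand <- stats::median(med, na.rm = TRUE)
    shift <- grand - med[as.character(table$slide_id)]
    shift[is.na(shift)] <- 0
    table[[m]] <- table[[m]] + as.numeric(shift)
  }
  table
}

#' Run the full QC stage
#'
#' Applies, in order: the log2 transform (only when the config marks the
#' input as raw), the size/quality cell filters, and slide-median
#' normalization.
#'
#' @param table a `cell_table`.
#' @param config a [run_config()].
#' @return the QC'd `cell_table`.
#' @export
qc_cells <- function(table, config = run_config()) {
  if (config$raw_intensities) table <- log2_transform(table)
  table <- filter_cells(table, config$min_cell_size_px, config$min_quality)
  median_normalize(table)
}
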