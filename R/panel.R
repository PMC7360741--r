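#' Define a biomarker panel
#'
#' A biomarker panel is an ordered set of unique biomarker names, optionally
#' annotated with category labels. The order is fixed for a run and defines
#' the indexing of every downstream feature vector (mean-intensity features
#' come first in panel order, pairwise correlation features follow in
#' lexicographic pair order by panel index).
#'
#' @param markers character vector of biomarker names (unique, non-empty).
#' @param categories optional character vector of category labels, recycled
#'   or one per marker.
#' @return an object of class `biomarker_panel`: a character vector of marker
#'   names with an optional `categories` attribute.
#' @examples
#' panel <- biomarker_panel(c("ECAD", "CD3", "VIM"))
#' length(panel)
#' @export
biomarker_panel <- function(markers, categories = NULL) {
  markers <- as.character(markers)
  if (length(markers) == 0L) stop("panel must contain at least one biomarker")
  if (anyDuplicated(markers)) {
    stop("duplicate biomarker names in panel: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  }
  if (any(!nzchar(markers))) stop("empty biomarker name in panel")
  structure(markers, categories = categories, class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat("<biomarker_panel> ", length(x), " markers: ",
      paste(utils::head(unclass(x), 8), collapse = ", "),
      if (length(x) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Names of the full per-domain feature vector for a panel
#'
#' For a panel of P markers the feature vector has length P + P(P-1)/2:
#' `mean__<marker>` for each marker followed by `tau__<m1>__<m2>` for each
#' unordered pair (i < j in panel order). For the default 55-marker panel
#' this is the M = 1540 feature layout.
#'
#' @param panel a [biomarker_panel()].
#' @return character vector of feature names.
#' @examples
#' feature_names(biomarker_panel(c("A", "B", "C")))
#' @export
feature_names <- function(panel) {
  p <- as.character(panel)
  means <- paste0("mean__", p)
  if (length(p) < 2L) return(means)
  pairs <- utils::combn(p, 2L)
  c(means, paste0("tau__", pairs[1L, ], "__", pairs[2L, ]))
}
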