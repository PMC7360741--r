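#' Assign epithelial / stromal compartments
#'
#' Cells carrying E-cadherin membrane labeling are epithelial; every
#' remaining cell is stromal. When a `compartment` column is already
#' present it is validated and passed through unchanged; otherwise it is
#' derived from `ecad_positive`. The partition is exhaustive and
#' exclusive.
#'
#' @param table a `cell_table`.
#' @return the `cell_table` with a `compartment` column in
#'   {"epithelial", "stromal"}.
#' @export
assign_compartments <- function(table) {
  if ("compartment" %in% names(table)) {
    bad <- setdiff(unique(as.character(table$compartment)),
                   c("epithelial", "stromal"))
    if (length(bad)) stop("unknown compartment label(s): ",
                          paste(bad, collapse = ", "))
    return(table)
  }
  if (!("ecad_positive" %in% names(table))) {
    stop("need an 'ecad_positive' or 'compartment' column to assign compartments")
  }
  table$compartment <- ifelse(as.logical(table$ecad_positive),
                              "epithelial", "stromal")
  table
}

#' Tessellate the epithelial-stromal boundary domain of one spot
#'
#' Three-step construction of the boundary band: (1) lay partially
#' overlapping circles of diameter `circle_diameter_um` on a square grid
#' of spacing `center_spacing_um` covering the spot's bounding box;
#' (2) retain only circles containing at least one epithelial and one
#' stromal cell; (3) take the union of the retained circles. Cells whose
#' centroid falls inside the union form the epithelial-stromal domain.
#' With the default 50 µm circles and dense cells along a straight
#' interface, the band's perpendicular width converges to 100 µm (twice
#' the diameter) as the grid spacing shrinks.
#'
#' @param table a `cell_table` for a single spot, compartments assigned.
#' @param circle_diameter_um circle diameter in micrometres (default 50).
#' @param center_spacing_um grid spacing; must be at most half the
#'   diameter so neighbouring circles overlap (default diameter / 10).
#' @return a `domain_assignment`: list with logical vectors `epithelial`,
#'   `stromal`, `epi_stromal` (one entry per cell, in table row order),
#'   the retained circle `centers` (matrix of x, y), and the geometry
#'   parameters.
#' @export
tessellate_boundary <- function(table,
                                circle_diameter_um = 50,
                                center_spacing_um = circle_diameter_um / 10) {
  if (center_spacing_um > circle_diameter_um / 2) {
    stop("center_spacing_um must be <= circle_diameter_um / 2 ",
         "so that circles partially overlap")
  }
  table <- assign_compartments(table)
  n <- nrow(table)
  epi <- table$compartment == "epithelial"
  if (n == 0L) {
    warning("empty spot: empty domain assignment")
    centers <- matrix(numeric(0), ncol = 2,
                      dimnames = list(NULL, c("x", "y")))
    return(structure(list(epithelial = logical(0), stromal = logical(0),
                          epi_stromal = logical(0), centers = centers,
                          circle_diameter_um = circle_diameter_um,
                          center_spacing_um = center_spacing_um),
                     class = "domain_assignment"))
  }
  r <- circle_diameter_um / 2
  gx <- seq(min(table$x), max(table$x), by = center_spacing_um)
  gy <- seq(min(table$y), max(table$y), by = center_spacing_um)
  grid <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)

  # A circle is retained iff it holds >= 1 epithelial and >= 1 stromal
  # centroid. Chunk over grid rows to bound the distance-matrix size.
  keep <- logical(nrow(grid))
  x <- table$x; y <- table$y
  chunk <- max(1L, floor(4e6 / n))
  for (start in seq(1L, nrow(grid), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(grid))
    d2 <- outer(grid$x[idx], x, "-")^2 + outer(grid$y[idx], y, "-")^2
    inside <- d2 <= r^2
    keep[idx] <- (inside %*% epi > 0) & (inside %*% (!epi) > 0)
  }
  centers <- as.matrix(grid[keep, , drop = FALSE])
  colnames(centers) <- c("x", "y")

  band <- logical(n)
  if (nrow(centers)) {
    chunk <- max(1L, floor(4e6 / nrow(centers)))
    for (start in seq(1L, n, by = chunk)) {
      idx <- start:min(start + chunk - 1L, n)
      d2 <- outer(x[idx], centers[, "x"], "-")^2 +
            outer(y[idx], centers[, "y"], "-")^2
      band[idx] <- rowSums(d2 <= r^2) > 0
    }
  }
  structure(list(epithelial = epi, stromal = !epi, epi_stromal = band,
                 centers = centers,
                 circle_diameter_um = circle_diameter_um,
                 center_spacing_um = center_spacing_um),
            class = "domain_assignment")
}

#' @export
print.domain_assignment <- function(x, ...) {
  cat("<domain_assignment> ", length(x$epithelial), " cells: ",
      sum(x$epithelial), " epithelial, ", sum(x$stromal), " stromal, ",
      sum(x$epi_stromal), " in the epithelial-stromal band (",
      nrow(x$centers), " circles retained)\n", sep = "")
  invisible(x)
}

#' Split a spot into its three spatial-domain tables
#'
#' The epithelial and stromal tables partition the spot's cells; the
#' epithelial-stromal table holds every cell inside the boundary band,
#' drawn from both compartments (the band overlaps both domains, which
#' keep their band cells).
#'
#' @param table a `cell_table` for one spot.
#' @param assignment the matching [tessellate_boundary()] result.
#' @return named list of three `cell_table`s:
#'   `epithelial`, `stromal`, `epi_stromal`.
#' @export
split_domains <- function(table, assignment) {
  if (length(assignment$epithelial) != nrow(table)) {
    stop("assignment does not match the table (different cell counts)")
  }
  subset_ct <- function(keep) {
    out <- table[keep, , drop = FALSE]
    attr(out, "panel") <- panel_of(table)
    class(out) <- class(table)
    out
  }
  list(epithelial = subset_ct(assignment$epithelial),
       stromal = subset_ct(assignment$stromal),
       epi_stromal = subset_ct(assignment$epi_stromal))
}

#' Measure the perpendicular width of the boundary band
#'
#' The epithelial-stromal domain is the union of the retained circles,
#' so its width perpendicular to a straight vertical interface is the
#' extent of that union along x: from the leftmost retained centre minus
#' the circle radius to the rightmost plus it. (`method = "cells"`
#' instead measures the extent of the member cells, which understates
#' the region width by up to one cell-grid step per side.)
#'
#' @param table the spot's `cell_table`.
#' @param assignment a [tessellate_boundary()] result for the spot.
#' @param axis `"x"` (vertical interface, default) or `"y"`.
#' @param method `"union"` (default) or `"cells"`.
#' @return width in micrometres (0 when the band is empty).
#' @export
band_width <- function(table, assignment, axis = c("x", "y"),
                       method = c("union", "cells")) {
  axis <- match.arg(axis)
  method <- match.arg(method)
  if (method == "union") {
    v <- assignment$centers[, axis]
    if (!length(v)) return(0)
    return(max(v) - min(v) + assignment$circle_diameter_um)
  }
  v <- table[[axis]][assignment$epi_stromal]
  if (!length(v)) return(0)
  max(v) - min(v)
}
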