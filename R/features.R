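#' Nearest-rank expression threshold
#'
#' The expression threshold for one biomarker on one spot is the
#' nearest-rank percentile of the cell-level intensity distribution: the
#' smallest observed value with at least `percentile` per cent of values
#' less than or equal to it. Only intensities strictly above the
#' threshold count as expression; restricting to the right tail is
#' deliberately conservative and keeps false-positive expression out of
#' the features.
#'
#' @param values numeric intensities (at least one finite value).
#' @param percentile rank in [0, 100).
#' @return list with `threshold`, `retained` (values strictly above it),
#'   and `retained_idx` (their positions in `values`).
#' @examples
#' expression_threshold(1:100, 85)$threshold  # 85; 15 values retained
#' @export
expression_threshold <- function(values, percentile = 85) {
  v <- values[is.finite(values)]
  if (!length(v)) stop("no finite intensity values")
  s <- sort(v)
  k <- max(1L, ceiling(percentile / 100 * length(s)))
  thr <- s[k]
  idx <- which(is.finite(values) & values > thr)
  list(threshold = thr, retained = values[idx], retained_idx = idx)
}

#' Spot-level expression thresholds for every panel biomarker
#'
#' Thresholds are anchored to the whole spot's intensity distribution
#' (one distribution per biomarker per spot) and then applied inside each
#' of the spot's spatial domains.
#'
#' @param table the spot's full `cell_table`.
#' @param panel a [biomarker_panel()].
#' @param percentile threshold percentile (default 85).
#' @return named numeric vector of thresholds, one per marker.
#' @export
spot_thresholds <- function(table, panel, percentile = 85) {
  vapply(as.character(panel),
         function(m) expression_threshold(table[[m]], percentile)$threshold,
         numeric(1))
}

#' Tie-corrected Kendall rank correlation (tau-b)
#'
#' Thin guard around `stats::cor(..., method = "kendall")`: returns `NA`
#' (a missing feature, not an error) when fewer than 3 paired
#' observations are available or either vector is constant.
#'
#' @param x,y paired numeric vectors.
#' @return tau-b in [-1, 1], or `NA_real_`.
#' @export
kendall_tau <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(NA_real_)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
  stats::cor(x, y, method = "kendall")
}

#' Thresholded mean-intensity features of one domain
#'
#' Per biomarker, the mean intensity over the domain's cells that express
#' the marker (intensity strictly above the spot-level threshold).
#' Missing when no domain cell passes.
#'
#' @param domain a domain `cell_table`.
#' @param panel a [biomarker_panel()].
#' @param percentile threshold percentile, used only when `thresholds`
#'   is NULL.
#' @param thresholds spot-level thresholds from [spot_thresholds()];
#'   when NULL they are computed from the domain table itself.
#' @return named numeric vector `mean__<marker>` (NA = missing).
#' @export
mean_intensity_features <- function(domain, panel, percentile = 85,
                                    thresholds = NULL) {
  markers <- as.character(panel)
  if (nrow(domain) == 0L) {
    warning("empty domain: all mean-intensity features missing")
    out <- rep(NA_real_, length(markers))
    names(out) <- paste0("mean__", markers)
    return(out)
  }
  if (is.null(thresholds)) {
    thresholds <- spot_thresholds(domain, panel, percentile)
  }
  out <- vapply(markers, function(m) {
    v <- domain[[m]]
    v <- v[is.finite(v) & v > thresholds[[m]]]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  names(out) <- paste0("mean__", markers)
  out
}

#' Pairwise Kendall-correlation features of one domain
#'
#' For each unordered biomarker pair (i < j in panel order), tau-b over
#' the domain cells expressing both markers (each intensity strictly
#' above its own spot-level threshold). Missing when fewer than 3 cells
#' co-express the pair.
#'
#' @inheritParams mean_intensity_features
#' @return named numeric vector `tau__<m1>__<m2>` of length P(P-1)/2.
#' @export
correlation_features <- function(domain, panel, percentile = 85,
                                 thresholds = NULL) {
  markers <- as.character(panel)
  if (length(markers) < 2L) return(stats::setNames(numeric(0), character(0)))
  if (is.null(thresholds) && nrow(domain) > 0L) {
    thresholds <- spot_thresholds(domain, panel, percentile)
  }
  pairs <- utils::combn(seq_along(markers), 2L)
  nm <- paste0("tau__", markers[pairs[1L, ]], "__", markers[pairs[2L, ]])
  if (nrow(domain) == 0L) {
    return(stats::setNames(rep(NA_real_, ncol(pairs)), nm))
  }
  expressed <- lapply(markers, function(m) {
    v <- domain[[m]]
    is.finite(v) & v > thresholds[[m]]
  })
  out <- vapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    both <- expressed[[i]] & expressed[[j]]
    if (sum(both) < 3L) return(NA_real_)
    kendall_tau(domain[[markers[i]]][both], domain[[markers[j]]][both])
  }, numeric(1))
  stats::setNames(out, nm)
}

#' Assemble the full per-domain feature vector
#'
#' Concatenates the thresholded mean-intensity features and the pairwise
#' Kendall-correlation features in fixed panel order, giving a vector of
#' length P + P(P-1)/2 (M = 1540 for the 55-marker panel).
#'
#' @param domain a domain `cell_table`.
#' @param panel a [biomarker_panel()].
#' @param config a [run_config()] (supplies the threshold percentile).
#' @param thresholds optional spot-level thresholds ([spot_thresholds()]).
#' @return named numeric vector; `NA` entries mark missing features.
#' @export
assemble_feature_vector <- function(domain, panel, config = run_config(),
                                    thresholds = NULL) {
  p <- config$percentile_threshold
  if (is.null(thresholds) && nrow(domain) > 0L) {
    thresholds <- spot_thresholds(domain, panel, p)
  }
  out <- c(mean_intensity_features(domain, panel, p, thresholds),
           correlation_features(domain, panel, p, thresholds))
  expected <- feature_names(panel)
  stopifnot(identical(names(out), expected))
  out
}

#' Per-patient feature matrices for all spatial domains
#'
#' Runs the feature engine over a cohort of spots: for each patient's
#' spot, computes the spot-level expression thresholds, dissects the spot
#' into the three spatial domains, and assembles one feature vector per
#' domain plus one for the undissected spot (the input to the null
#' model).
#'
#' @param spots named list of per-patient `cell_table`s (names are
#'   patient ids), already QC'd and with compartments assignable.
#' @param panel a [biomarker_panel()].
#' @param config a [run_config()].
#' @return list of four numeric matrices (patients x features):
#'   `epithelial`, `stromal`, `epi_stromal`, `spot`.
#' @export
cohort_features <- function(spots, panel, config = run_config()) {
  stopifnot(length(spots) > 0, !is.null(names(spots)))
  fn <- feature_names(panel)
  empty <- function() matrix(NA_real_, nrow = length(spots), ncol = length(fn),
                             dimnames = list(names(spots), fn))
  out <- list(epithelial = empty(), stromal = empty(),
              epi_stromal = empty(), spot = empty())
  for (i in seq_along(spots)) {
    tab <- assign_compartments(spots[[i]])
    thr <- spot_thresholds(tab, panel, config$percentile_threshold)
    asg <- tessellate_boundary(tab, config$circle_diameter_um,
                               config$center_spacing_um)
    doms <- split_domains(tab, asg)
    for (d in names(doms)) {
      out[[d]][i, ] <- suppressWarnings(
        assemble_feature_vector(doms[[d]], panel, config, thr))
    }
    out$spot[i, ] <- suppressWarnings(
      assemble_feature_vector(tab, panel, config, thr))
  }
  out
}

#' Prepare a feature matrix for penalized regression
#'
#' Penalized Cox regression needs complete columns. Feature columns
#' missing in more than `max_missing_frac` of patients are dropped; the
#' remaining missing entries are imputed with the cohort (column) median.
#' Constant columns are dropped as well (they carry no information and
#' cannot be standardized).
#'
#' @param X patients x features numeric matrix (NA = missing).
#' @param max_missing_frac drop threshold (default 0.2).
#' @return list with the completed matrix `X`, `dropped` column names,
#'   and the logical `imputed` mask.
#' @export
prepare_feature_matrix <- function(X, max_missing_frac = 0.2) {
  miss <- colMeans(is.na(X))
  keep <- miss <= max_missing_frac
  X2 <- X[, keep, drop = FALSE]
  imputed <- is.na(X2)
  for (j in seq_len(ncol(X2))) {
    if (any(imputed[, j])) {
      X2[imputed[, j], j] <- stats::median(X2[, j], na.rm = TRUE)
    }
  }
  sds <- apply(X2, 2, stats::sd)
  nonconst <- is.finite(sds) & sds > 0
  dropped <- c(colnames(X)[!keep], colnames(X2)[!nonconst])
  list(X = X2[, nonconst, drop = FALSE], dropped = dropped,
       imputed = imputed[, nonconst, drop = FALSE])
}
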