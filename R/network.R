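#' Shrunken Kendall correlation matrix of one patient's domain
#'
#' Builds the N x N Kendall correlation matrix over the selected
#' biomarkers from one patient's domain cells (unit diagonal; pairs with
#' too few co-expressing cells are set to 0 with a message), then
#' applies the smallest shrinkage \eqn{C \leftarrow (1-\delta) C +
#' \delta I}, \eqn{\delta \in \{0, 0.01, 0.02, \ldots\}}, that makes the
#' minimum eigenvalue at least `eig_floor`, guaranteeing positive
#' definiteness and hence invertibility.
#'
#' @param domain one patient's domain `cell_table`.
#' @param biomarkers character vector of selected biomarker names
#'   (N >= 2), a subset of the panel.
#' @param percentile expression-threshold percentile (default 85);
#'   thresholds are computed from the domain table unless supplied.
#' @param thresholds optional named spot-level thresholds.
#' @param eig_floor minimum-eigenvalue target (default 1e-6).
#' @return list with the shrunken matrix `C` and the shrinkage `delta`.
#' @export
build_correlation_matrix <- function(domain, biomarkers, percentile = 85,
                                     thresholds = NULL, eig_floor = 1e-6) {
  biomarkers <- as.character(biomarkers)
  N <- length(biomarkers)
  if (N < 2L) stop("need at least 2 biomarkers for a correlation matrix")
  taus <- correlation_features(domain, biomarker_panel(biomarkers),
                               percentile, thresholds)
  C <- diag(1, N)
  dimnames(C) <- list(biomarkers, biomarkers)
  pairs <- utils::combn(seq_len(N), 2L)
  vals <- unname(taus)
  n_missing <- sum(is.na(vals))
  if (n_missing) {
    message(n_missing, " biomarker pair(s) without enough co-expressing ",
            "cells: tau set to 0")
    vals[is.na(vals)] <- 0
  }
  for (k in seq_len(ncol(pairs))) {
    C[pairs[1L, k], pairs[2L, k]] <- vals[k]
    C[pairs[2L, k], pairs[1L, k]] <- vals[k]
  }
  shrink_to_pd(C, eig_floor)
}

# Smallest delta on the 0.01 grid with min eigenvalue >= floor.
shrink_to_pd <- function(C, eig_floor = 1e-6) {
  delta <- 0
  repeat {
    Cs <- (1 - delta) * C + delta * diag(nrow(C))
    ev <- min(eigen(Cs, symmetric = TRUE, only.values = TRUE)$values)
    if (ev >= eig_floor) return(list(C = Cs, delta = delta))
    delta <- delta + 0.01
    if (delta > 1) stop("shrinkage failed to reach positive definiteness")
  }
}

#' Partial correlations from a positive-definite correlation matrix
#'
#' Inverts C to the precision matrix P and computes
#' \eqn{\rho_{ij} = -p_{ij} / \sqrt{p_{ii} p_{jj}}} for \eqn{i \ne j}:
#' the association between biomarkers i and j after controlling for all
#' other selected biomarkers. Diagonal set to 1 by convention.
#'
#' @param C symmetric positive-definite correlation matrix.
#' @return the partial-correlation matrix (same dimnames).
#' @export
partial_correlations <- function(C) {
  ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) stop("C is not positive definite; apply shrinkage first")
  P <- solve(C)
  d <- sqrt(diag(P))
  rho <- -P / outer(d, d)
  diag(rho) <- 1
  dimnames(rho) <- dimnames(C)
  rho
}

#' Binned group distributions of a partial correlation
#'
#' Histograms the per-patient partial-correlation values of one
#' biomarker pair on fixed equal-width bins over the compact support
#' [-1, 1], separately for the two outcome groups, with a small
#' pseudocount per bin before normalization (so the Jensen-Shannon
#' divergence is defined even for empty bins).
#'
#' @param values numeric per-patient partial correlations in [-1, 1].
#' @param groups outcome labels aligned to `values` (2 levels; the
#'   first level is taken as the recurrence group).
#' @param n_bins number of bins (default 40).
#' @param pseudocount added to every bin (default 1e-12).
#' @return list of two probability vectors, named by group level.
#' @export
group_distributions <- function(values, groups, n_bins = 40,
                                pseudocount = 1e-12) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("need exactly 2 outcome groups")
  breaks <- seq(-1, 1, length.out = n_bins + 1)
  out <- lapply(levels(groups), function(g) {
    v <- values[groups == g & !is.na(values)]
    if (!length(v)) stop("no patients in group '", g, "'")
    h <- graphics::hist(pmin(pmax(v, -1), 1), breaks = breaks,
                        plot = FALSE)$counts + pseudocount
    h / sum(h)
  })
  names(out) <- levels(groups)
  out
}

#' Jensen-Shannon divergence (bits)
#'
#' \eqn{\mathrm{JSD}(P, Q) = \tfrac12 KL(P \| M) + \tfrac12 KL(Q \| M)}
#' with \eqn{M = (P + Q)/2} and base-2 logarithms, so the divergence is
#' symmetric and bounded in [0, 1]; the convention 0 log 0 = 0 applies.
#'
#' @param p,q probability vectors on the same support (each summing to
#'   1 within 1e-8).
#' @return divergence in bits.
#' @export
jsd <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must share a support")
  if (abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8) {
    stop("p and q must each sum to 1")
  }
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  kl(p, m) / 2 + kl(q, m) / 2
}

#' Jensen-Shannon information-distance matrix between outcome groups
#'
#' For each biomarker pair, collects the per-patient partial
#' correlations, bins them into the two outcome groups' distributions,
#' and records their Jensen-Shannon divergence: the differential change
#' in that pairwise association between recurrence and no-recurrence
#' patients.
#'
#' @param partials list of per-patient partial-correlation matrices
#'   (identical dimnames), one per patient.
#' @param outcomes outcome labels aligned to `partials` (2 levels).
#' @param n_bins histogram bins on [-1, 1] (default 40).
#' @return symmetric N x N matrix of divergences (zero diagonal), class
#'   `information_distance_matrix`.
#' @export
distance_matrix <- function(partials, outcomes, n_bins = 40) {
  stopifnot(length(partials) == length(outcomes), length(partials) >= 2)
  outcomes <- as.factor(outcomes)
  if (any(table(outcomes) < 2)) stop("need >= 2 patients per outcome group")
  nm <- rownames(partials[[1]])
  N <- length(nm)
  D <- matrix(0, N, N, dimnames = list(nm, nm))
  pairs <- utils::combn(seq_len(N), 2L)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    vals <- vapply(partials, function(M) M[i, j], numeric(1))
    dist <- group_distributions(vals, outcomes, n_bins)
    D[i, j] <- D[j, i] <- jsd(dist[[1]], dist[[2]])
  }
  structure(D, class = c("information_distance_matrix", class(D)))
}

#' Threshold an information-distance matrix into a network
#'
#' Retains the edges whose distance is strictly greater than the
#' nearest-rank `percentile` of the upper-triangle distances; every
#' selected biomarker remains a node, so the network may contain
#' isolated nodes and disconnected subnetworks.
#'
#' @param D an [distance_matrix()] result (or symmetric matrix).
#' @param percentile edge-retention percentile (default 99).
#' @return a `domain_network`: list with `nodes`, an `edges` data.frame
#'   (`node_i`, `node_j`, `weight`), and the `threshold` used.
#' @export
threshold_network <- function(D, percentile = 99) {
  nm <- rownames(D)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  w <- D[pairs]
  if (!length(w)) stop("need at least one biomarker pair")
  s <- sort(w)
  k <- max(1L, ceiling(percentile / 100 * length(s)))
  thr <- s[k]
  keep <- w > thr
  edges <- data.frame(node_i = nm[pairs[keep, 1]],
                      node_j = nm[pairs[keep, 2]],
                      weight = w[keep], stringsAsFactors = FALSE)
  edges <- edges[order(-edges$weight), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nm, edges = edges, threshold = thr,
                 percentile = percentile),
            class = "domain_network")
}

#' @export
print.domain_network <- function(x, ...) {
  cat("<domain_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges above the ", x$percentile, "th percentile (threshold ",
      signif(x$threshold, 4), ")\n", sep = "")
  invisible(x)
}

#' Export a domain network
#'
#' Writes GraphML (for graph tools) and a TSV edge list
#' (`node_i`, `node_j`, `weight`), plus a plain node list usable as
#' input to external enrichment tools. Isolated nodes are preserved in
#' the GraphML and node list.
#'
#' @param net a [threshold_network()] result.
#' @param path base path; `.graphml`, `.edges.tsv`, and `.nodes.txt`
#'   are appended.
#' @return named character vector of the written paths, invisibly.
#' @export
export_network <- function(net, path) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(net$edges)) {
    el <- rbind(match(net$edges$node_i, net$nodes),
                match(net$edges$node_j, net$nodes))
    g <- igraph::add_edges(g, as.vector(el), weight = net$edges$weight)
  }
  paths <- c(graphml = paste0(path, ".graphml"),
             edges = paste0(path, ".edges.tsv"),
             nodes = paste0(path, ".nodes.txt"))
  igraph::write_graph(g, paths[["graphml"]], format = "graphml")
  data.table::fwrite(net$edges, paths[["edges"]], sep = "\t")
  writeLines(net$nodes, paths[["nodes"]])
  invisible(paths)
}

#' Read a domain network back from its GraphML export
#' @param path the `.graphml` file written by [export_network()].
#' @return a `domain_network`.
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- igraph::V(g)$name
  if (igraph::ecount(g)) {
    el <- igraph::as_edgelist(g)
    edges <- data.frame(node_i = el[, 1], node_j = el[, 2],
                        weight = igraph::E(g)$weight,
                        stringsAsFactors = FALSE)
    edges <- edges[order(-edges$weight), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(node_i = character(0), node_j = character(0),
                        weight = numeric(0))
  }
  structure(list(nodes = nodes, edges = edges, threshold = NA_real_,
                 percentile = NA_real_),
            class = "domain_network")
}

#' Infer the recurrence-associated network of one spatial domain
#'
#' End-to-end per-domain network inference: per patient, build the
#' shrunken Kendall correlation matrix over the selected biomarkers and
#' convert it to partial correlations; then compute the Jensen-Shannon
#' distance matrix between the recurrence and no-recurrence groups and
#' threshold it at the configured percentile.
#'
#' @param domain_tables named list of per-patient domain `cell_table`s.
#' @param outcomes binary outcome per patient (1 = recurrence), aligned.
#' @param biomarkers selected biomarker names (N >= 2).
#' @param config a [run_config()].
#' @return list with `network`, `distances`, and `partials`.
#' @export
infer_domain_network <- function(domain_tables, outcomes, biomarkers,
                                 config = run_config()) {
  partials <- lapply(domain_tables, function(tab) {
    cm <- build_correlation_matrix(tab, biomarkers,
                                   config$percentile_threshold)
    partial_correlations(cm$C)
  })
  grp <- factor(ifelse(outcomes == 1, "recurrence", "no_recurrence"),
                levels = c("recurrence", "no_recurrence"))
  D <- distance_matrix(partials, grp, config$n_bins)
  list(network = threshold_network(D, config$network_percentile),
       distances = D, partials = partials)
}
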