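# Independent brute-force oracles used to check the implementation.

# Kendall tau-b by explicit enumeration of all n(n-1)/2 pairs.
tau_brute <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1
      if (s < 0) disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  tie_term <- function(v) {
    t <- table(v)
    sum(t * (t - 1) / 2)
  }
  n1 <- tie_term(x); n2 <- tie_term(y)
  den <- sqrt((n0 - n1) * (n0 - n2))
  if (den == 0) return(NA_real_)
  (conc - disc) / den
}

# ROC AUC as the concordant-pair fraction (ties count one half).
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Partial correlation of variables i and j given the rest, by explicit
# residualization against the remaining variables (Schur complement of
# the conditioning block), independent of the precision-matrix route.
pcor_brute <- function(C, i, j) {
  o <- setdiff(seq_len(nrow(C)), c(i, j))
  if (!length(o)) return(C[i, j])
  S <- C[c(i, j), c(i, j)] -
    C[c(i, j), o, drop = FALSE] %*%
    solve(C[o, o, drop = FALSE], C[o, c(i, j), drop = FALSE])
  S[1, 2] / sqrt(S[1, 1] * S[2, 2])
}

# Product-limit survival estimate at each event time, by hand.
km_brute <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (k in seq_along(ts)) {
    at_risk <- sum(time >= ts[k])
    d <- sum(time == ts[k] & event == 1)
    s <- s * (1 - d / at_risk)
    out[k] <- s
  }
  data.frame(time = ts, surv = out)
}

# Small hand-writable cell table around a 2-marker panel.
toy_panel <- function(markers = c("MA", "MB")) biomarker_panel(markers)

toy_cells <- function(n = 6, markers = c("MA", "MB"), spot = "S1",
                      slide = "SL1", seed = 1) {
  set.seed(seed)
  df <- data.frame(cell_id = sprintf("c%02d", seq_len(n)), spot_id = spot,
                   slide_id = slide, x = runif(n, 0, 100),
                   y = runif(n, 0, 100), size_px = 20, quality_index = 1,
                   ecad_positive = rep(c(TRUE, FALSE), length.out = n),
                   stringsAsFactors = FALSE)
  for (m in markers) df[[m]] <- round(runif(n, 2, 10), 3)
  cell_table(df, biomarker_panel(markers))
}

# Cell table from explicit coordinates/labels (markers get noise).
cells_at <- function(x, y, ecad, markers = c("MA", "MB"), seed = 1) {
  set.seed(seed)
  df <- data.frame(cell_id = sprintf("c%03d", seq_along(x)),
                   spot_id = "S1", slide_id = "SL1", x = x, y = y,
                   size_px = 20, quality_index = 1, ecad_positive = ecad,
                   stringsAsFactors = FALSE)
  for (m in markers) df[[m]] <- rnorm(length(x), 6, 1)
  cell_table(df, biomarker_panel(markers))
}

# Random positive-definite correlation matrix.
random_pd_corr <- function(n, seed) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  S <- crossprod(A) + diag(n) * 0.5
  stats::cov2cor(S)
}
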