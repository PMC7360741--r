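test_that("shrinkage leaves positive-definite matrices untouched", {
  C <- random_pd_corr(4, seed = 1)
  out <- domainsurv:::shrink_to_pd(C)
  expect_equal(out$delta, 0)
  expect_equal(out$C, C)
  I4 <- diag(4)
  expect_equal(domainsurv:::shrink_to_pd(I4)$C, I4)
})

test_that("rank-deficient matrices receive the smallest qualifying shrinkage", {
  C <- random_pd_corr(4, seed = 2)
  # duplicate a variable: perfectly collinear, singular
  C5 <- rbind(cbind(C, C[, 4]), c(C[4, ], 1))
  out <- domainsurv:::shrink_to_pd(C5)
  expect_gt(out$delta, 0)
  ev <- eigen(out$C, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 1e-6)
  # one grid step less shrinkage must fail the floor
  less <- (1 - (out$delta - 0.01)) * C5 + (out$delta - 0.01) * diag(5)
  expect_lt(min(eigen(less, symmetric = TRUE,
                      only.values = TRUE)$values), 1e-6)
})

test_that("partial correlations match the residualization oracle", {
  C2 <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(partial_correlations(C2)[1, 2], 0.5)

  C3 <- matrix(0.5, 3, 3); diag(C3) <- 1
  expect_equal(partial_correlations(C3)[1, 2], 1 / 3, tolerance = 1e-12)

  expect_equal(partial_correlations(diag(4)),
               diag(4))

  for (n in 3:5) {
    for (s in 1:4) {
      C <- random_pd_corr(n, seed = 100 * n + s)
      rho <- partial_correlations(C)
      for (i in 1:(n - 1)) {
        for (j in (i + 1):n) {
          expect_equal(rho[i, j], pcor_brute(C, i, j), tolerance = 1e-10)
        }
      }
      expect_equal(rho, t(rho))
    }
  }
  expect_error(partial_correlations(matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("per-patient correlation matrices are built from domain taus", {
  set.seed(30)
  n <- 400
  z <- rnorm(n)
  df <- data.frame(cell_id = sprintf("c%04d", 1:n), spot_id = "S1",
                   slide_id = "SL1", x = runif(n, 0, 100),
                   y = runif(n, 0, 100), size_px = 20, quality_index = 1,
                   ecad_positive = TRUE,
                   MA = 6 + 1.5 * z + rnorm(n, 0, 0.5),
                   MB = 6 + 1.5 * z + rnorm(n, 0, 0.5),
                   MC = rnorm(n, 6))
  tab <- cell_table(df, biomarker_panel(c("MA", "MB", "MC")))
  out <- suppressMessages(
    build_correlation_matrix(tab, c("MA", "MB", "MC"), percentile = 50))
  expect_equal(diag(out$C), rep(1, 3), ignore_attr = TRUE)
  expect_equal(out$C, t(out$C))
  expect_gt(out$C["MA", "MB"], out$C["MA", "MC"])
  expect_error(build_correlation_matrix(tab, "MA"), "at least 2")
})

test_that("group distributions are normalized histograms on [-1, 1]", {
  vals <- c(rep(0.05, 6), rep(-0.9, 4))
  groups <- rep(c("recur", "none"), c(6, 4))
  d <- group_distributions(vals, groups, n_bins = 40)
  expect_equal(sum(d$recur), 1)
  expect_equal(sum(d$none), 1)
  expect_gt(max(d$none), 0.999)    # all mass in the 0.05 bin
  expect_gt(max(d$recur), 0.999)   # all mass in the -0.9 bin
  # identical samples give identical distributions
  d2 <- group_distributions(rep(c(0.2, -0.4), 10),
                            rep(c("a", "b"), each = 10), 40)
  expect_equal(d2$a, d2$b)
  expect_error(group_distributions(0.5, factor("a", levels = c("a", "b"))),
               "group")
  # uniform draws spread roughly evenly over the bins
  set.seed(9)
  u <- runif(2000, -1, 1)
  du <- group_distributions(c(u, u), rep(c("a", "b"), each = 2000), 40)
  expect_true(all(abs(du$a - 1 / 40) < 0.01))
})

test_that("Jensen-Shannon divergence has its closed-form values and bounds", {
  p <- c(0.5, 0.5); q <- c(1, 0)
  expect_equal(jsd(p, p), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)  # disjoint support: 1 bit
  m <- c(0.75, 0.25)
  direct <- (0.5 * log2(0.5 / 0.75) + 0.5 * log2(0.5 / 0.25)) / 2 +
    (1 * log2(1 / 0.75)) / 2
  expect_equal(jsd(p, q), direct)
  expect_equal(round(jsd(p, q), 4), 0.3113)
  set.seed(10)
  for (rep in 1:20) {
    a <- runif(12); a <- a / sum(a)
    b <- runif(12); b <- b / sum(b)
    expect_equal(jsd(a, b), jsd(b, a))
    expect_gte(jsd(a, b), 0)
    expect_lte(jsd(a, b), 1)
  }
  expect_error(jsd(c(0.5, 0.4), q), "sum to 1")
})

test_that("distance matrices localize a planted group difference", {
  set.seed(12)
  nm <- c("A", "B", "C", "D")
  mk <- function(rho_ab) {
    M <- diag(4); dimnames(M) <- list(nm, nm)
    M[1, 2] <- M[2, 1] <- rho_ab + rnorm(1, 0, 0.05)
    M[3, 4] <- M[4, 3] <- rnorm(1, 0, 0.05)
    M
  }
  partials <- c(lapply(1:20, function(i) mk(0.6)),
                lapply(1:20, function(i) mk(0.0)))
  outcomes <- rep(c("recur", "none"), each = 20)
  D <- distance_matrix(partials, outcomes, n_bins = 40)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 4), ignore_attr = TRUE)
  ut <- D[upper.tri(D)]
  expect_length(ut, 6L)                  # N(N-1)/2 unique entries
  expect_equal(max(ut), D["A", "B"])     # planted pair dominates

  # label-permutation within identical data gives ~zero distances
  same <- c(lapply(1:20, function(i) mk(0.3)),
            lapply(1:20, function(i) mk(0.3)))
  D0 <- distance_matrix(same, outcomes, n_bins = 10)
  expect_lt(max(D0), 0.25)
})

test_that("network thresholding keeps only edges above the percentile", {
  set.seed(13)
  N <- 15  # 105 pairs
  w <- matrix(0, N, N, dimnames = list(paste0("m", 1:N), paste0("m", 1:N)))
  vals <- sample(seq(0.001, 0.105, length.out = 105))
  w[upper.tri(w)] <- vals
  w <- w + t(w)
  net <- threshold_network(w, percentile = 99)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, max(vals))
  expect_length(net$nodes, N)

  net0 <- threshold_network(w, percentile = 0)
  expect_equal(nrow(net0$edges), 104L)   # all above the minimum

  w_tied <- matrix(0.5, N, N, dimnames = dimnames(w))
  diag(w_tied) <- 0
  net_t <- threshold_network(w_tied, percentile = 99)
  expect_equal(nrow(net_t$edges), 0L)    # strict inequality under ties
})

test_that("networks round-trip through GraphML with isolated nodes", {
  net <- structure(list(
    nodes = c("A", "B", "C"),
    edges = data.frame(node_i = "A", node_j = "B", weight = 0.42,
                       stringsAsFactors = FALSE),
    threshold = 0.1, percentile = 99), class = "domain_network")
  base <- withr::local_tempfile()
  paths <- export_network(net, base)
  expect_true(all(file.exists(paths)))
  back <- read_network(paths[["graphml"]])
  expect_setequal(back$nodes, net$nodes)
  expect_equal(nrow(back$edges), 1L)
  expect_equal(back$edges$weight, 0.42)
  expect_setequal(unlist(back$edges[, c("node_i", "node_j")]),
                  c("A", "B"))
  # edge list exports the same weights
  el <- read.delim(paths[["edges"]])
  expect_equal(el$weight, 0.42)
  # empty graph still round-trips
  net0 <- net; net0$edges <- net$edges[0, ]
  paths0 <- export_network(net0, paste0(base, "_empty"))
  back0 <- read_network(paths0[["graphml"]])
  expect_equal(nrow(back0$edges), 0L)
  expect_setequal(back0$nodes, net$nodes)
})
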