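#' Configuration of a synthetic hyperplexed TMA cohort
#'
#' Describes the generative model used to emulate a hyperplexed TMA
#' cohort: per-patient 0.6-mm spots with a central epithelial blob and
#' surrounding stroma, log2-scale biomarker intensities driven by a
#' latent-factor Gaussian model with compartment-specific loadings (so
#' the two compartments carry different pairwise rank-correlation
#' structure), and recurrence times drawn from a proportional-hazards
#' model on planted per-domain feature drivers with uniform right
#' censoring.
#'
#' @param n_patients cohort size.
#' @param n_markers panel size (default 55; markers named `M01`...).
#' @param n_epithelial,n_stromal cells per compartment per spot.
#' @param spot_diameter_um spot diameter (default 600, a 0.6-mm core).
#' @param blob_radius_um radius of the central epithelial blob.
#' @param band_halfwidth_um half-width of the interface band inside
#'   which planted epithelial-stromal effects act (default 50).
#' @param base_mean baseline log2 intensity of every marker.
#' @param cell_sd per-cell intensity noise sd (log2 units).
#' @param patient_sd sd of per-patient per-marker random shifts.
#' @param n_factors latent factors per compartment.
#' @param loading_sd sd of the random baseline factor loadings.
#' @param mean_effect_sd per-SD log2 shift a planted mean feature
#'   applies to its marker in its domain.
#' @param tau_loading loading strength modulated by a planted tau
#'   feature's driver (controls how far the pair's tau moves).
#' @param planted data.frame with columns `domain` (one of
#'   `epithelial`, `stromal`, `epi_stromal`), `feature` (a
#'   `mean__<m>` or `tau__<m1>__<m2>` name), `beta` (log hazard ratio
#'   per SD of the feature's driver); NULL for a null cohort. Optional
#'   columns: `driver` (an id; rows sharing an id share the per-patient
#'   latent draw, e.g. a marker redistributing between compartments)
#'   and `effect` (multiplier on the cell-level shift, default 1; use
#'   -1 for the compartment the marker moves out of). The linear
#'   predictor sums `beta` x driver draw over rows.
#' @param target_event_frac recurrence fraction within the horizon the
#'   baseline hazard is calibrated to (default 65/432).
#' @param horizon_years horizon (default 5).
#' @param censor_max censoring times are uniform on (0, censor_max);
#'   default 1.5 x horizon.
#' @param qc_fail_frac fraction of cells drawn to fail size/quality QC.
#' @param seed integer seed.
#' @return a `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(n_patients = 60,
                                    n_markers = 55,
                                    n_epithelial = 150,
                                    n_stromal = 150,
                                    spot_diameter_um = 600,
                                    blob_radius_um = 180,
                                    band_halfwidth_um = 50,
                                    base_mean = 6,
                                    cell_sd = 1,
                                    patient_sd = 0.3,
                                    n_factors = 3,
                                    loading_sd = 0.3,
                                    mean_effect_sd = 1,
                                    tau_loading = 1.2,
                                    planted = NULL,
                                    target_event_frac = 65 / 432,
                                    horizon_years = 5,
                                    censor_max = 1.5 * horizon_years,
                                    qc_fail_frac = 0.05,
                                    seed = 1L) {
  markers <- sprintf("M%02d", seq_len(n_markers))
  if (!is.null(planted)) {
    stopifnot(all(c("domain", "feature", "beta") %in% names(planted)))
    bad_dom <- setdiff(planted$domain,
                       c("epithelial", "stromal", "epi_stromal"))
    if (length(bad_dom)) stop("unknown planted domain(s): ",
                              paste(bad_dom, collapse = ", "))
    ok <- planted$feature %in% feature_names(biomarker_panel(markers))
    if (!all(ok)) stop("planted feature(s) not in the panel layout: ",
                       paste(planted$feature[!ok], collapse = ", "))
  }
  stopifnot(target_event_frac > 0, target_event_frac < 1,
            censor_max > horizon_years * 0)
  structure(list(n_patients = as.integer(n_patients), markers = markers,
                 n_epithelial = as.integer(n_epithelial),
                 n_stromal = as.integer(n_stromal),
                 spot_diameter_um = spot_diameter_um,
                 blob_radius_um = blob_radius_um,
                 band_halfwidth_um = band_halfwidth_um,
                 base_mean = base_mean, cell_sd = cell_sd,
                 patient_sd = patient_sd, n_factors = n_factors,
                 loading_sd = loading_sd,
                 mean_effect_sd = mean_effect_sd,
                 tau_loading = tau_loading, planted = planted,
                 target_event_frac = target_event_frac,
                 horizon_years = horizon_years, censor_max = censor_max,
                 qc_fail_frac = qc_fail_frac, seed = as.integer(seed)),
            class = "synthetic_cohort_config")
}

# Parse planted feature names into marker indices.
.parse_planted <- function(planted, markers) {
  if (is.null(planted) || nrow(planted) == 0) return(NULL)
  driver <- if ("driver" %in% names(planted)) planted$driver else
    seq_len(nrow(planted))
  effect <- if ("effect" %in% names(planted)) planted$effect else
    rep(1, nrow(planted))
  out <- lapply(seq_len(nrow(planted)), function(k) {
    f <- planted$feature[k]
    if (grepl("^mean__", f)) {
      list(type = "mean", domain = planted$domain[k],
           m = match(sub("^mean__", "", f), markers),
           beta = planted$beta[k], feature = f,
           driver = driver[k], effect = effect[k])
    } else {
      ms <- strsplit(sub("^tau__", "", f), "__", fixed = TRUE)[[1]]
      list(type = "tau", domain = planted$domain[k],
           m = match(ms, markers), beta = planted$beta[k], feature = f,
           driver = driver[k], effect = effect[k])
    }
  })
  out
}

#' Generate one synthetic TMA spot
#'
#' Places epithelial cells (E-cadherin positive) uniformly inside a
#' central blob and stromal cells in the surrounding annulus of a
#' circular spot, then draws log2 intensities from the latent-factor
#' model: baseline + per-patient shift + compartment-specific factor
#' term + cell noise. Planted drivers in `state` shift a marker's mean
#' (mean features) or add a shared pair loading (tau features) within
#' the feature's domain. Cell sizes and quality indices are drawn so a
#' small configured fraction fails the QC filters.
#'
#' @param config a [synthetic_cohort_config()].
#' @param state per-patient latent state from the cohort generator; for
#'   a standalone spot pass `NULL` (all drivers zero).
#' @param seed integer seed.
#' @param patient_id,slide_id identifiers stamped on the cells.
#' @return a `cell_table`.
#' @export
generate_spot <- function(config, state = NULL, seed = 1L,
                          patient_id = "P1", slide_id = "S1") {
  set.seed(seed)
  markers <- config$markers
  P <- length(markers)
  R <- config$spot_diameter_um / 2
  n_epi <- config$n_epithelial; n_str <- config$n_stromal
  # uniform in disc / annulus via inverse-CDF on the radius
  r_epi <- config$blob_radius_um * sqrt(stats::runif(n_epi))
  th_epi <- stats::runif(n_epi, 0, 2 * pi)
  r_str <- sqrt(stats::runif(n_str, config$blob_radius_um^2, R^2))
  th_str <- stats::runif(n_str, 0, 2 * pi)
  x <- R + c(r_epi * cos(th_epi), r_str * cos(th_str))
  y <- R + c(r_epi * sin(th_epi), r_str * sin(th_str))
  epi <- c(rep(TRUE, n_epi), rep(FALSE, n_str))
  n <- n_epi + n_str
  radius <- c(r_epi, r_str)
  in_band <- abs(radius - config$blob_radius_um) <= config$band_halfwidth_um

  if (is.null(state)) {
    state <- list(loadings = .baseline_loadings(config), drivers = list())
  }
  intens <- matrix(stats::rnorm(n * P, config$base_mean, config$cell_sd),
                   n, P, dimnames = list(NULL, markers))
  shift <- state$patient_shift
  if (!is.null(shift)) intens <- sweep(intens, 2, shift, "+")
  for (comp in c("epithelial", "stromal")) {
    rows <- if (comp == "epithelial") which(epi) else which(!epi)
    if (!length(rows)) next
    L <- state$loadings[[comp]]
    z <- matrix(stats::rnorm(length(rows) * ncol(L)), length(rows), ncol(L))
    intens[rows, ] <- intens[rows, ] + z %*% t(L)
  }
  # planted per-patient drivers: domain-localized mean shifts and
  # pair-specific shared factors
  for (d in state$drivers) {
    rows <- switch(d$domain,
                   epithelial = which(epi),
                   stromal = which(!epi),
                   epi_stromal = which(in_band))
    if (!length(rows)) next
    if (d$type == "mean") {
      eff <- if (is.null(d$effect)) 1 else d$effect
      intens[rows, d$m] <- intens[rows, d$m] +
        config$mean_effect_sd * eff * d$value
    } else {
      strength <- config$tau_loading * stats::pnorm(d$value)
      zp <- stats::rnorm(length(rows))
      intens[rows, d$m[1]] <- intens[rows, d$m[1]] + strength * zp
      intens[rows, d$m[2]] <- intens[rows, d$m[2]] + strength * zp
    }
  }

  n_fail <- round(config$qc_fail_frac * n)
  size_px <- stats::rpois(n, 40) + 11
  quality <- 1 - stats::rbeta(n, 1, 40) * 0.1
  if (n_fail > 0) {
    fail_idx <- sample(n, n_fail)
    half <- seq_len(ceiling(n_fail / 2))
    size_px[fail_idx[half]] <- sample(0:10, length(half), replace = TRUE)
    rest <- setdiff(seq_along(fail_idx), half)
    quality[fail_idx[rest]] <- stats::runif(length(rest), 0.5, 0.89)
  }
  df <- data.frame(cell_id = sprintf("%s_c%04d", patient_id, seq_len(n)),
                   spot_id = patient_id, slide_id = slide_id,
                   x = x, y = y, size_px = size_px,
                   quality_index = pmin(pmax(quality, 0), 1),
                   ecad_positive = epi, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(intens))
  out <- cell_table(df, biomarker_panel(markers))
  attr(out, "log2_transformed") <- TRUE
  out
}

.baseline_loadings <- function(config) {
  P <- length(config$markers)
  list(epithelial = matrix(stats::rnorm(P * config$n_factors, 0,
                                        config$loading_sd),
                           P, config$n_factors),
       stromal = matrix(stats::rnorm(P * config$n_factors, 0,
                                     config$loading_sd),
                        P, config$n_factors))
}

# Expected fraction of patients with an observed event within the
# horizon, under exponential event times with rate h0*exp(eta) and
# uniform censoring on (0, cmax); closed form, used for bisection.
.expected_event_frac <- function(h0, eta, horizon, cmax) {
  r <- h0 * exp(eta)
  h <- min(horizon, cmax)
  p <- (h - (1 - exp(-r * h)) / r + pmax(cmax - h, 0) *
          (1 - exp(-r * h))) / cmax
  mean(p)
}

# Calibrate the baseline hazard so the expected within-horizon event
# fraction matches the target.
calibrate_baseline_hazard <- function(eta, target, horizon, cmax) {
  f <- function(log_h0) {
    .expected_event_frac(exp(log_h0), eta, horizon, cmax) - target
  }
  exp(stats::uniroot(f, c(-20, 5), tol = 1e-10)$root)
}

#' Generate a full synthetic cohort
#'
#' Draws per-patient latent drivers for every planted feature, generates
#' each patient's spot from them, and simulates recurrence: the linear
#' predictor is \eqn{\eta_i = \sum_k \beta^*_k u_{ik}} over the planted
#' features' standardized drivers \eqn{u}, event times are exponential
#' with rate \eqn{h_0 e^{\eta}} (with \eqn{h_0} calibrated by root
#' finding so the expected within-horizon recurrence fraction matches
#' the configured target), and censoring is uniform on
#' (0, `censor_max`). Clinical covariates (age, gender, stage) are drawn
#' independently of outcome unless `stage_beta` is nonzero.
#'
#' @param config a [synthetic_cohort_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param stage_beta optional log hazard ratio per stage step
#'   (I -> II -> III); default 0.
#' @return list with `spots` (named list of `cell_table`s), `surv`
#'   (a `survival_table`), and `truth` (planted table, per-patient
#'   drivers, `eta`, `h0`, seed).
#' @export
generate_cohort <- function(config, seed = config$seed, stage_beta = 0) {
  set.seed(seed)
  n <- config$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  planted <- .parse_planted(config$planted, config$markers)
  k <- length(planted)
  driver_ids <- unique(vapply(planted, function(p) as.character(p$driver),
                              character(1)))
  u <- matrix(stats::rnorm(n * length(driver_ids)), n, length(driver_ids),
              dimnames = list(ids, driver_ids))
  # per-row driver values (rows sharing a driver id share the draw)
  drivers <- if (k) {
    m <- vapply(planted, function(p) u[, as.character(p$driver)],
                numeric(n))
    dimnames(m) <- list(ids, vapply(planted, `[[`, "", "feature"))
    m
  } else matrix(numeric(0), n, 0)
  loadings <- .baseline_loadings(config)
  age <- round(stats::rnorm(n, 65, 10))
  gender <- sample(c("F", "M"), n, replace = TRUE)
  stage <- sample(c("I", "II", "III"), n, replace = TRUE,
                  prob = c(0.3, 0.4, 0.3))
  eta <- if (k) drop(drivers %*% vapply(planted, `[[`, numeric(1), "beta"))
         else rep(0, n)
  eta <- eta + stage_beta * (match(stage, c("I", "II", "III")) - 2)
  h0 <- calibrate_baseline_hazard(eta, config$target_event_frac,
                                  config$horizon_years, config$censor_max)
  t_event <- stats::rexp(n, h0 * exp(eta))
  t_cens <- stats::runif(n, 0, config$censor_max)
  if (all(t_cens < t_event)) {
    warning("all patients censored; resampling censoring times")
    t_cens <- stats::runif(n, 0, config$censor_max)
  }
  time <- round(pmin(t_event, t_cens) * 365.25) / 365.25  # quantize to days
  time <- pmax(time, 1 / 365.25)
  event <- as.integer(t_event <= t_cens)
  spot_seeds <- sample.int(2^31 - 2, n)
  spots <- vector("list", n)
  for (i in seq_len(n)) {
    st <- list(loadings = loadings,
               patient_shift = stats::rnorm(length(config$markers), 0,
                                            config$patient_sd),
               drivers = lapply(seq_len(k), function(j) {
                 c(planted[[j]], list(value = drivers[i, j]))
               }))
    spots[[i]] <- generate_spot(config, st, seed = spot_seeds[i],
                                patient_id = ids[i],
                                slide_id = sprintf("S%d", 1 + (i - 1) %% 4))
  }
  names(spots) <- ids
  surv <- survival_table(data.frame(patient_id = ids, time = time,
                                    event = event, stage = stage,
                                    age = age, gender = gender,
                                    stringsAsFactors = FALSE))
  list(spots = spots, surv = surv,
       truth = list(planted = config$planted, drivers = drivers,
                    eta = eta, h0 = h0, seed = seed))
}

#' Feature-level synthetic cohort for model testing
#'
#' Generates the cohort directly at the feature-matrix level: a
#' patients x features matrix with independent standard-normal columns
#' carrying the full 1540-name layout of a synthetic panel, a planted
#' sparse coefficient vector with a stated hazard ratio per SD, and
#' exponential proportional-hazards recurrence times with uniform right
#' censoring. This isolates the selection/estimation pipeline from the
#' feature engine, giving exact control of per-feature effect sizes.
#'
#' @param n patients.
#' @param n_markers panel size defining the feature layout (default 55,
#'   hence 1540 features).
#' @param n_planted number of features with nonzero coefficients.
#' @param hr_per_sd hazard ratio per SD of each planted feature
#'   (default 2); half the planted coefficients are flipped negative.
#' @param target_event_frac expected within-horizon event fraction.
#' @param horizon_years horizon (default 5).
#' @param censor_max uniform censoring upper bound.
#' @param seed integer seed.
#' @return list with `X`, `surv`, `planted` (names), `beta_star`
#'   (named true coefficients).
#' @export
simulate_feature_cohort <- function(n = 400, n_markers = 55,
                                    n_planted = 10, hr_per_sd = 2,
                                    target_event_frac = 0.3,
                                    horizon_years = 5,
                                    censor_max = 1.5 * horizon_years,
                                    seed = 1L) {
  set.seed(seed)
  fn <- feature_names(biomarker_panel(sprintf("M%02d", seq_len(n_markers))))
  p <- length(fn)
  X <- matrix(stats::rnorm(n * p), n, p,
              dimnames = list(sprintf("P%03d", seq_len(n)), fn))
  planted <- sample(fn, n_planted)
  beta_star <- stats::setNames(rep(log(hr_per_sd), n_planted), planted)
  flip <- seq_len(n_planted) %% 2 == 0
  beta_star[flip] <- -beta_star[flip]
  eta <- drop(X[, planted, drop = FALSE] %*% beta_star)
  h0 <- calibrate_baseline_hazard(eta, target_event_frac, horizon_years,
                                  censor_max)
  t_event <- stats::rexp(n, h0 * exp(eta))
  t_cens <- stats::runif(n, 0, censor_max)
  time <- pmax(round(pmin(t_event, t_cens) * 365.25) / 365.25, 1 / 365.25)
  surv <- survival_table(data.frame(patient_id = rownames(X), time = time,
                                    event = as.integer(t_event <= t_cens),
                                    stringsAsFactors = FALSE))
  list(X = X, surv = surv, planted = planted, beta_star = beta_star,
       eta = eta)
}

#' Cohort preset mirroring the study's shape
#'
#' Convenience preset for integration tests: 432 patients on a
#' 55-marker panel with exactly 65 recurrences within the 5-year
#' horizon. Latent proportional-hazards event times are drawn as in
#' [generate_cohort()]; the 65 patients with the smallest latent times
#' are then assigned recurrence, with their times mapped monotonically
#' onto an even grid over (0, 5] (so each year holds events), and the
#' remainder are followed event-free past the horizon. The exact counts
#' are thereby guaranteed rather than met only in expectation.
#'
#' @param seed integer seed.
#' @param n_epithelial,n_stromal cells per compartment (small defaults
#'   keep the preset fast).
#' @return as [generate_cohort()].
#' @export
make_paper_scale_fixture <- function(seed = 1L, n_epithelial = 60,
                                     n_stromal = 60) {
  config <- synthetic_cohort_config(
    n_patients = 432, n_markers = 55,
    n_epithelial = n_epithelial, n_stromal = n_stromal,
    planted = data.frame(
      domain = c("epithelial", "stromal", "epi_stromal"),
      feature = c("mean__M01", "mean__M02", "tau__M03__M04"),
      beta = c(0.7, -0.7, 0.5)),
    target_event_frac = 65 / 432, seed = seed)
  cohort <- generate_cohort(config, seed = seed)
  surv <- cohort$surv
  set.seed(seed + 1L)
  latent <- stats::rexp(nrow(surv), cohort$truth$h0 *
                          exp(cohort$truth$eta))
  recur <- order(latent)[seq_len(65)]
  surv$event <- 0L
  surv$event[recur] <- 1L
  surv$time[recur] <- seq(0.2, 5, length.out = 65)[rank(latent[recur])]
  nonrec <- setdiff(seq_len(nrow(surv)), recur)
  surv$time[nonrec] <- stats::runif(length(nonrec), 5.01, 7.5)
  cohort$surv <- survival_table(as.data.frame(surv))
  cohort
}

#' Synthetic spot with a straight epithelial/stromal interface
#'
#' Cells on a regular square grid filling a rectangle, E-cadherin
#' positive to the right of a straight vertical interface and negative
#' to the left. Used to check the tessellation geometry: with dense
#' cells, the boundary band around the interface should reach a
#' perpendicular width of twice the circle diameter.
#'
#' @param interface_x x position of the interface in micrometres.
#' @param half_width rectangle half-width either side of the interface.
#' @param height rectangle height.
#' @param grid_um cell grid spacing (default 2).
#' @param n_markers panel size (intensities are noise; default 2).
#' @param seed integer seed for the intensity noise.
#' @return a `cell_table`.
#' @export
make_interface_spot <- function(interface_x = 300, half_width = 150,
                                height = 60, grid_um = 2, n_markers = 2,
                                seed = 1L) {
  set.seed(seed)
  xs <- seq(interface_x - half_width, interface_x + half_width, by = grid_um)
  ys <- seq(0, height, by = grid_um)
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(g)
  markers <- sprintf("M%02d", seq_len(n_markers))
  df <- data.frame(cell_id = sprintf("c%06d", seq_len(n)),
                   spot_id = "SPOT1", slide_id = "S1",
                   x = g$x, y = g$y, size_px = 20, quality_index = 1,
                   ecad_positive = g$x >= interface_x,
                   stringsAsFactors = FALSE)
  for (m in markers) df[[m]] <- stats::rnorm(n, 6, 1)
  out <- cell_table(df, biomarker_panel(markers))
  attr(out, "log2_transformed") <- TRUE
  out
}
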