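#' Cox log partial likelihood (Breslow ties)
#'
#' Direct evaluation of the log partial likelihood
#' \deqn{\log L(\beta) = \sum_k \left[ \sum_{i: \mathrm{event\ at\ } t_k}
#'   \eta_i - d_k \log \sum_{i \in R_k} e^{\eta_i} \right]}
#' where \eqn{\eta = X\beta}, the sum runs over distinct event times
#' \eqn{t_k}, \eqn{d_k} is the number of events at \eqn{t_k}, and the
#' risk set \eqn{R_k} holds the patients with follow-up \eqn{\ge t_k}.
#' Tied event times are handled by the Breslow approximation, which is
#' the likelihood exactly as written above.
#'
#' @param X patients x features numeric matrix (rows aligned to `surv`).
#' @param beta coefficient vector (length = ncol(X)).
#' @param surv a `survival_table` (or data.frame with `time`, `event`).
#' @return the log partial likelihood (scalar).
#' @export
cox_log_partial_likelihood <- function(X, beta, surv) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == nrow(surv), ncol(X) == length(beta))
  if (sum(surv$event) == 0) stop("no events: partial likelihood undefined")
  eta <- drop(X %*% beta)
  event_times <- sort(unique(surv$time[surv$event == 1]))
  ll <- 0
  for (tk in event_times) {
    at_k <- surv$event == 1 & surv$time == tk
    risk <- surv$time >= tk
    ll <- ll + sum(eta[at_k]) - sum(at_k) * log(sum(exp(eta[risk])))
  }
  ll
}

# Year-of-recurrence strata used for every stratified resample/split:
# events within the horizon fall into their (ceiling) recurrence year,
# everyone else into a single "no recurrence by horizon" stratum.
# Strata with fewer than `min_size` patients are merged with the nearest
# earlier year (degenerate strata would make a 50/50 split meaningless).
recurrence_strata <- function(surv, horizon_years = 5, min_size = 2L) {
  yr <- ifelse(surv$event == 1 & surv$time <= horizon_years,
               pmin(ceiling(surv$time), horizon_years), 0)
  tab <- table(yr)
  small <- as.numeric(names(tab))[tab < min_size & as.numeric(names(tab)) > 0]
  for (s in sort(small, decreasing = TRUE)) {
    target <- if (any(yr < s & yr > 0)) max(yr[yr < s & yr > 0]) else
      if (any(yr > s)) min(yr[yr > s]) else 0
    yr[yr == s] <- target
  }
  factor(yr)
}

# Stratified bootstrap resample: sample with replacement within each
# recurrence-year stratum, preserving stratum sizes (risk-set-aware).
stratified_resample <- function(strata) {
  idx <- integer(0)
  for (s in levels(strata)) {
    members <- which(strata == s)
    if (length(members)) {
      idx <- c(idx, sample(members, length(members), replace = TRUE))
    }
  }
  sort(idx)
}

# Standardize columns; constant columns get scale 1 (coefficient 0 anyway).
standardize_columns <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(X = scale(X, center = ctr, scale = scl), center = ctr, scale = scl)
}

#' Fit a penalized Cox model (LASSO or ridge)
#'
#' Cross-validated penalized Cox regression at `alpha = 1` (LASSO, used
#' for feature selection) or `alpha = 0` (ridge, used for coefficient
#' learning), via \pkg{glmnet}. Features are standardized to zero mean
#' and unit variance internally so that the penalty treats
#' mean-intensity and correlation features comparably; coefficients are
#' reported on the standardized scale with the transform stored.
#'
#' @param X patients x features matrix (complete; see
#'   [prepare_feature_matrix()]).
#' @param surv a `survival_table` aligned to the rows of `X`.
#' @param alpha 1 (LASSO) or 0 (ridge).
#' @param seed integer seed for the cross-validation folds.
#' @param nfolds CV folds (default 10).
#' @return a `penalized_cox_fit`: list with `beta` (named, standardized
#'   scale), `lambda` (CV-selected), `alpha`, `center`, `scale`,
#'   `lambda_path`, `cvm` (mean CV partial-likelihood deviance),
#'   `converged`.
#' @export
fit_penalized_cox <- function(X, surv, alpha = 1, seed = 1L, nfolds = 10L) {
  stopifnot(alpha %in% c(0, 1))
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must be complete; run prepare_feature_matrix() first")
  if (sum(surv$event) == 0) stop("no events: cannot fit a Cox model")
  if (ncol(X) < 2L) stop("glmnet needs at least 2 feature columns")
  std <- standardize_columns(X)
  y <- survival::Surv(surv$time, surv$event)
  set.seed(seed)
  cv <- glmnet::cv.glmnet(std$X, y, family = "cox", alpha = alpha,
                          standardize = FALSE, nfolds = nfolds)
  beta <- drop(as.matrix(stats::coef(cv, s = "lambda.min")))
  structure(list(beta = beta, lambda = cv$lambda.min, alpha = alpha,
                 center = std$center, scale = std$scale,
                 lambda_path = cv$lambda, cvm = cv$cvm,
                 converged = TRUE, glmnet_fit = cv$glmnet.fit),
            class = "penalized_cox_fit")
}

#' @export
print.penalized_cox_fit <- function(x, ...) {
  cat("<penalized_cox_fit> alpha=", x$alpha, ", lambda=",
      signif(x$lambda, 4), ", ", sum(x$beta != 0), "/", length(x$beta),
      " nonzero coefficients\n", sep = "")
  invisible(x)
}

# Ridge (or, for a single feature, unpenalized) Cox coefficients on
# standardized columns at a fixed lambda; the per-bootstrap workhorse of
# the sign-stability screen.
.ridge_coef <- function(Xs, y, lambda, lambda_path = NULL) {
  if (ncol(Xs) == 1L) {
    fit <- tryCatch(
      survival::coxph(y ~ Xs, control = survival::coxph.control(iter.max = 50)),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(survival::coxph(y ~ Xs))
      })
    if (is.null(fit)) return(NULL)
    return(stats::setNames(stats::coef(fit), colnames(Xs)))
  }
  fit <- tryCatch(
    glmnet::glmnet(Xs, y, family = "cox", alpha = 0, standardize = FALSE,
                   lambda = lambda_path),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  drop(as.matrix(stats::coef(fit, s = lambda, exact = FALSE)))
}

#' Bootstrap stability selection of LASSO Cox features
#'
#' The regularization strength is first fixed by 10-fold cross-validated
#' partial-likelihood deviance on the full data. Each of `n_boot`
#' stratified bootstrap resamples (sampling with replacement within
#' recurrence-year strata, so the per-year proportion of recurrences is
#' preserved) then refits the LASSO path at that strength and records the
#' selected (nonzero) feature set. A feature is retained when it is
#' selected in at least `threshold` of the successful bootstrap refits.
#'
#' @param X complete patients x features matrix.
#' @param surv aligned `survival_table`.
#' @param n_boot number of bootstrap refits (protocol default 500).
#' @param threshold minimum selection frequency (protocol default 0.9).
#' @param seed integer seed.
#' @param horizon_years horizon defining the recurrence-year strata.
#' @return list with `selected` (feature names), `report` (a
#'   `stability_report` data.frame of per-feature frequencies),
#'   `lambda`, `n_failed`.
#' @export
stability_select <- function(X, surv, n_boot = 500L, threshold = 0.9,
                             seed = 1L, horizon_years = 5) {
  X <- as.matrix(X)
  full <- fit_penalized_cox(X, surv, alpha = 1, seed = seed)
  lambda <- full$lambda
  # refitting the path below the chosen lambda is wasted work
  lambda_path <- full$lambda_path[full$lambda_path >= lambda]
  std <- standardize_columns(X)
  strata <- recurrence_strata(surv, horizon_years)
  counts <- stats::setNames(numeric(ncol(X)), colnames(X))
  n_ok <- 0L
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- stratified_resample(strata)
    yb <- survival::Surv(surv$time[idx], surv$event[idx])
    fit <- tryCatch(
      glmnet::glmnet(std$X[idx, , drop = FALSE], yb, family = "cox",
                     alpha = 1, standardize = FALSE,
                     lambda = lambda_path),
      error = function(e) NULL)
    if (is.null(fit)) next
    bb <- drop(as.matrix(stats::coef(fit, s = lambda, exact = FALSE)))
    counts <- counts + (bb != 0)
    n_ok <- n_ok + 1L
  }
  if (n_ok == 0L) stop("every bootstrap LASSO fit failed")
  freq <- counts / n_ok
  report <- data.frame(feature = colnames(X), selection_freq = freq,
                       row.names = NULL)
  class(report) <- c("stability_report", "data.frame")
  attr(report, "n_bootstraps") <- n_ok
  attr(report, "threshold") <- threshold
  attr(report, "seed") <- seed
  list(selected = colnames(X)[freq >= threshold], report = report,
       lambda = lambda, n_failed = n_boot - n_ok)
}

#' Bootstrap sign-stability screen of the ridge coefficients
#'
#' For the features surviving selection-stability, the ridge (L2) Cox
#' refit is repeated on stratified bootstrap resamples; a feature is kept
#' when its coefficient carries the same sign as the full-data ridge
#' refit in at least `threshold` of the successful refits.
#'
#' @param X matrix restricted to the stability-selected features.
#' @param surv aligned `survival_table`.
#' @inheritParams stability_select
#' @return list with `selected`, `report` (`sign_freq` per feature),
#'   `reference_beta` (full-data ridge coefficients), `n_failed`.
#' @export
sign_stability_check <- function(X, surv, n_boot = 500L, threshold = 0.9,
                                 seed = 1L, horizon_years = 5) {
  X <- as.matrix(X)
  if (ncol(X) == 0L) {
    return(list(selected = character(0),
                report = data.frame(feature = character(0),
                                    sign_freq = numeric(0)),
                reference_beta = numeric(0), n_failed = 0L))
  }
  std <- standardize_columns(X)
  y <- survival::Surv(surv$time, surv$event)
  if (ncol(X) >= 2L) {
    set.seed(seed)
    cv <- glmnet::cv.glmnet(std$X, y, family = "cox", alpha = 0,
                            standardize = FALSE, nfolds = 10L)
    lambda <- cv$lambda.min
    lambda_path <- cv$lambda[cv$lambda >= cv$lambda.min]
    ref <- drop(as.matrix(stats::coef(cv, s = "lambda.min")))
  } else {
    lambda <- 0; lambda_path <- NULL
    ref <- .ridge_coef(std$X, y, lambda)
  }
  strata <- recurrence_strata(surv, horizon_years)
  agree <- stats::setNames(numeric(ncol(X)), colnames(X))
  n_ok <- 0L
  set.seed(seed + 1L)
  for (b in seq_len(n_boot)) {
    idx <- stratified_resample(strata)
    yb <- survival::Surv(surv$time[idx], surv$event[idx])
    bb <- .ridge_coef(std$X[idx, , drop = FALSE], yb, lambda, lambda_path)
    if (is.null(bb)) next
    agree <- agree + (sign(bb) == sign(ref))
    n_ok <- n_ok + 1L
  }
  if (n_ok == 0L) stop("every bootstrap ridge fit failed")
  freq <- agree / n_ok
  report <- data.frame(feature = colnames(X), sign_freq = freq,
                       row.names = NULL)
  list(selected = colnames(X)[freq >= threshold], report = report,
       reference_beta = ref, n_failed = n_boot - n_ok)
}

#' Fit the recurrence-guided model of one spatial domain
#'
#' The two-step per-domain pipeline: (1) LASSO feature selection with
#' bootstrap selection-stability; (2) sign-stability screening of the
#' ridge coefficients; (3) a final ridge (L2) Cox refit on the surviving
#' features only, decoupling coefficient learning from the full
#' feature set. With `config$n_bootstraps = 0` the stability screens are
#' skipped and the selection is the plain cross-validated LASSO support
#' (the fast mode used inside the model-comparison harness).
#'
#' @param X patients x features matrix for the domain (may contain NA;
#'   the missing-feature policy of [prepare_feature_matrix()] is applied).
#' @param surv aligned `survival_table`.
#' @param config a [run_config()].
#' @return a `domain_model`: list with `features` (final names), `beta`
#'   (standardized scale), `center`, `scale`, `stability` /
#'   `sign_stability` reports, `degenerate` flag.
#' @export
fit_domain_model <- function(X, surv, config = run_config()) {
  X <- as.matrix(X)
  prep <- prepare_feature_matrix(X, config$missing_max_frac)
  Xc <- prep$X
  if (sum(surv$event) == 0) stop("no events: cannot fit a Cox model")
  stab_report <- NULL; sign_report <- NULL
  if (config$n_bootstraps > 0L) {
    st <- stability_select(Xc, surv, config$n_bootstraps,
                           config$stability_threshold, config$seed,
                           config$horizon_years)
    stab_report <- st$report
    sel <- st$selected
    if (length(sel)) {
      sg <- sign_stability_check(Xc[, sel, drop = FALSE], surv,
                                 config$n_bootstraps,
                                 config$stability_threshold,
                                 config$seed + 1000L,
                                 config$horizon_years)
      sign_report <- sg$report
      sel <- sg$selected
    }
  } else {
    fit <- fit_penalized_cox(Xc, surv, alpha = 1, seed = config$seed)
    sel <- names(fit$beta)[fit$beta != 0]
  }
  if (!length(sel)) {
    warning("no feature survived selection: degenerate model (risk = 1)")
    return(structure(list(features = character(0), beta = numeric(0),
                          center = numeric(0), scale = numeric(0),
                          stability = stab_report,
                          sign_stability = sign_report,
                          degenerate = TRUE),
                     class = "domain_model"))
  }
  Xs <- Xc[, sel, drop = FALSE]
  std <- standardize_columns(Xs)
  y <- survival::Surv(surv$time, surv$event)
  if (length(sel) >= 2L) {
    set.seed(config$seed + 2000L)
    cv <- glmnet::cv.glmnet(std$X, y, family = "cox", alpha = 0,
                            standardize = FALSE, nfolds = 10L)
    beta <- drop(as.matrix(stats::coef(cv, s = "lambda.min")))
  } else {
    beta <- .ridge_coef(std$X, y, 0)
  }
  structure(list(features = sel, beta = beta,
                 center = std$center, scale = std$scale,
                 stability = stab_report, sign_stability = sign_report,
                 degenerate = FALSE),
            class = "domain_model")
}

#' @export
print.domain_model <- function(x, ...) {
  if (x$degenerate) {
    cat("<domain_model> degenerate (no features selected; risk = 1)\n")
  } else {
    cat("<domain_model> ", length(x$features), " features: ",
        paste(utils::head(x$features, 5), collapse = ", "),
        if (length(x$features) > 5) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Linear predictor of a domain model on new patients
#'
#' @param model a `domain_model`.
#' @param X feature matrix containing at least the model's features
#'   (NAs are imputed with the model's training centers, i.e. treated as
#'   an average patient for that feature).
#' @return numeric vector of linear predictors (0 for a degenerate
#'   model).
#' @export
domain_linear_predictor <- function(model, X) {
  if (model$degenerate) return(rep(0, nrow(X)))
  miss <- setdiff(model$features, colnames(X))
  if (length(miss)) stop("feature matrix lacks model feature(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  Xs <- as.matrix(X[, model$features, drop = FALSE])
  for (j in seq_along(model$features)) {
    na <- is.na(Xs[, j])
    if (any(na)) Xs[na, j] <- model$center[j]
  }
  Xs <- scale(Xs, center = model$center, scale = model$scale)
  drop(Xs %*% model$beta)
}

#' Fit the spatial model across the three domains
#'
#' Fits the two-step recurrence-guided model independently in each
#' spatial domain and stores the multiplicative combination rule: the
#' overall hazard-ratio score of a patient is the product of the three
#' domain hazard ratios, \eqn{\prod_s e^{f_s^T \beta_s}}.
#'
#' @param features list of patients x features matrices, one per domain;
#'   names must cover `epithelial`, `stromal`, `epi_stromal`.
#' @param surv aligned `survival_table`.
#' @param config a [run_config()].
#' @return a `spatial_model`: list of `domain_model`s plus metadata.
#' @export
fit_spatial_model <- function(features, surv, config = run_config()) {
  domains <- c("epithelial", "stromal", "epi_stromal")
  stopifnot(all(domains %in% names(features)))
  fits <- lapply(domains, function(d) {
    cfg <- config
    cfg$seed <- config$seed + match(d, domains) * 10000L
    fit_domain_model(features[[d]], surv, cfg)
  })
  names(fits) <- domains
  structure(list(domains = fits, seed = config$seed,
                 config_hash = config_hash(config)),
            class = "spatial_model")
}

#' @export
print.spatial_model <- function(x, ...) {
  cat("<spatial_model> domains:\n")
  for (d in names(x$domains)) {
    cat("  ", d, ": ", length(x$domains[[d]]$features), " features\n",
        sep = "")
  }
  invisible(x)
}

#' Combined hazard-ratio score of the spatial model
#'
#' @param model a `spatial_model`.
#' @param features list of per-domain feature matrices for the patients
#'   to score (same names/layout as in [fit_spatial_model()]); a missing
#'   domain contributes a zero linear predictor, with a warning.
#' @return strictly positive hazard-ratio scores
#'   \eqn{\exp(\sum_s f_s^T \beta_s)}.
#' @export
combined_risk <- function(model, features) {
  lp <- NULL
  for (d in names(model$domains)) {
    if (is.null(features[[d]])) {
      warning("domain '", d, "' missing from features: using zero ",
              "linear predictor")
      next
    }
    lpd <- domain_linear_predictor(model$domains[[d]], features[[d]])
    lp <- if (is.null(lp)) lpd else lp + lpd
  }
  if (is.null(lp)) stop("no domain features supplied")
  exp(lp)
}

#' Fit the null (undissected) model
#'
#' The identical two-step pipeline applied once to the feature vector of
#' the whole, spatially undissected spot; the comparison baseline that
#' isolates the contribution of spatial dissection.
#'
#' @param spot_features patients x features matrix computed over all
#'   cells of each spot.
#' @inheritParams fit_domain_model
#' @return a `domain_model`.
#' @export
fit_null_model <- function(spot_features, surv, config = run_config()) {
  fit_domain_model(spot_features, surv, config)
}

#' Fit the clinical comparison model
#'
#' Unpenalized Cox proportional-hazards fit on age, gender, and TNM
#' stage (one-hot against stage I).
#'
#' @param surv a `survival_table` with `age`, `gender`, `stage`.
#' @return a `clinical_model` wrapping the `coxph` fit.
#' @export
fit_clinical_model <- function(surv) {
  need <- c("age", "gender", "stage")
  miss <- setdiff(need, names(surv))
  if (length(miss)) stop("survival table lacks clinical covariate(s): ",
                         paste(miss, collapse = ", "))
  df <- as.data.frame(surv)
  df$gender <- factor(df$gender)
  fit <- survival::coxph(survival::Surv(time, event) ~ age + gender + stage,
                         data = df)
  flagged <- !is.null(fit$info) ||
    any(!is.finite(stats::coef(fit))) ||
    any(abs(stats::coef(fit)) > 20)
  structure(list(fit = fit, flagged = flagged), class = "clinical_model")
}

#' Risk score (linear predictor) of the clinical model
#' @param model a `clinical_model`.
#' @param surv survival table of patients to score.
#' @return numeric linear predictors.
#' @export
clinical_risk <- function(model, surv) {
  df <- as.data.frame(surv)
  glev <- model$fit$xlevels[["gender"]]
  df$gender <- factor(df$gender,
                      levels = if (is.null(glev)) unique(df$gender) else glev)
  unname(stats::predict(model$fit, newdata = df, type = "lp"))
}
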