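#' Stratified 50/50 train/test split
#'
#' Patients are stratified by recurrence year (events within the horizon
#' by their year of recurrence, everyone else into a single
#' no-recurrence stratum) and each stratum is split approximately in
#' half by seeded sampling, so the per-year proportion of recurrences is
#' the same in the training and testing sets — a form of risk-set
#' sampling that keeps each yearly risk set populated in both halves.
#'
#' @param surv a `survival_table`.
#' @param horizon_years horizon defining the year strata (default 5).
#' @param seed integer seed.
#' @param train_frac training fraction (default 0.5).
#' @return list with integer row indices `train` and `test`
#'   (a partition of the patients).
#' @export
stratified_bootstrap_split <- function(surv, horizon_years = 5, seed = 1L,
                                       train_frac = 0.5) {
  strata <- recurrence_strata(surv, horizon_years)
  set.seed(seed)
  train <- integer(0)
  for (s in levels(strata)) {
    members <- which(strata == s)
    if (!length(members)) next
    n_tr <- round(length(members) * train_frac)
    n_tr <- min(max(n_tr, if (length(members) > 1) 1L else 0L),
                length(members))
    train <- c(train, sample(members, n_tr))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(nrow(surv)), train))
}

#' Binary recurrence outcome at a horizon
#'
#' Positive = recurrence within the horizon; negative = event-free with
#' follow-up reaching the horizon. Patients censored before the horizon
#' without an event carry no binary label and are masked out of binary
#' ROC analyses (they still contribute to Cox, Kaplan-Meier, and
#' time-dependent analyses through their censoring information).
#'
#' @param surv a `survival_table`.
#' @param horizon_years horizon (default 5).
#' @return list with integer `labels` (1/0/NA) and logical `usable`.
#' @export
binary_outcome_at_horizon <- function(surv, horizon_years = 5) {
  pos <- surv$event == 1 & surv$time <= horizon_years
  neg <- surv$event == 0 & surv$time >= horizon_years |
         surv$event == 1 & surv$time > horizon_years
  labels <- ifelse(pos, 1L, ifelse(neg, 0L, NA_integer_))
  list(labels = labels, usable = !is.na(labels))
}

#' Empirical ROC curve
#'
#' Sweeps every observed score as a classification threshold (score >=
#' threshold calls a positive) and records sensitivity and specificity.
#' The AUC is computed as the Mann-Whitney concordance probability
#' between the positive and negative score distributions (ties count
#' 1/2), which equals the area under the empirical curve.
#'
#' @param scores numeric risk scores (higher = predicted positive).
#' @param labels binary labels in {0, 1} (NAs dropped).
#' @return a `roc_result`: list with `thresholds`, `sensitivity`,
#'   `specificity`, `auc`, `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  ok <- !is.na(labels) & is.finite(scores)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC needs both classes present (", n_pos, " positives, ",
         n_neg, " negatives)")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[labels == 0] < t), numeric(1))
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("<roc_result> AUC = ", signif(x$auc, 4), " (", x$n_pos,
      " positives, ", x$n_neg, " negatives)\n", sep = "")
  invisible(x)
}

#' Youden operating point of an ROC curve
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over the curve's
#' thresholds; ties are broken toward higher specificity (the more
#' conservative call).
#'
#' @param roc a [roc_curve()] result.
#' @return list with `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_operating_point <- function(roc) {
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[which.max(roc$specificity[best])]
  list(threshold = roc$thresholds[best],
       sensitivity = roc$sensitivity[best],
       specificity = roc$specificity[best],
       youden = j[best])
}

#' Positive and negative likelihood ratios
#'
#' LR+ = sens / (1 - spec): the factor by which the odds of recurrence
#' rise after a positive call. LR- = (1 - sens) / spec: the factor after
#' a negative call.
#'
#' @param sens sensitivity in [0, 1].
#' @param spec specificity in [0, 1].
#' @return list with `lr_plus` (may be `Inf` when spec = 1) and
#'   `lr_minus`.
#' @export
likelihood_ratios <- function(sens, spec) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1)
  lr_plus <- if (spec == 1) Inf else sens / (1 - spec)
  lr_minus <- if (spec == 0) Inf else (1 - sens) / spec
  list(lr_plus = lr_plus, lr_minus = lr_minus)
}

#' Kaplan-Meier curves for score-stratified risk groups
#'
#' Dichotomizes patients at a threshold (normally the training-set
#' Youden operating point) and computes the product-limit recurrence-free
#' survival curve of each group.
#'
#' @param scores risk scores (score >= threshold = high risk).
#' @param surv a `survival_table` aligned to `scores`.
#' @param threshold risk-score cutoff.
#' @return list with `fit` (a `survfit` object stratified by group),
#'   `group` (factor "low"/"high"), and the `threshold`.
#' @export
km_curves <- function(scores, surv, threshold) {
  group <- factor(ifelse(scores >= threshold, "high", "low"),
                  levels = c("low", "high"))
  if (any(table(group) == 0)) {
    warning("one risk group is empty: single-curve output")
  }
  df <- data.frame(time = surv$time, event = surv$event, group = group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  list(fit = fit, group = group, threshold = threshold)
}

# Kaplan-Meier estimate of the censoring survivor function G(t),
# evaluated just before t (left-continuous), for IPCW weights.
censoring_survfit <- function(surv) {
  fit <- survival::survfit(survival::Surv(surv$time, 1 - surv$event) ~ 1)
  function(t) {
    # G(t-) = P(censoring time >= t)
    vapply(t, function(ti) {
      keep <- fit$time < ti
      if (!any(keep)) 1 else min(fit$surv[keep])
    }, numeric(1))
  }
}

#' Time-dependent AUC (cumulative cases / dynamic controls, IPCW)
#'
#' At each time t, cases are patients with an observed event by t and
#' controls are patients still event-free beyond t; both are weighted by
#' the inverse of the Kaplan-Meier censoring survivor function so that
#' the estimate is consistent under independent censoring.
#'
#' @param scores risk scores (higher = earlier recurrence predicted).
#' @param surv aligned `survival_table`.
#' @param times evaluation times (default years 1..5).
#' @return data.frame with `time`, `auc` (NA where no case or no
#'   control exists), `n_cases`, `n_controls`.
#' @export
time_dependent_auc <- function(scores, surv, times = 1:5) {
  G <- censoring_survfit(surv)
  out <- lapply(times, function(t) {
    case <- surv$event == 1 & surv$time <= t
    ctrl <- surv$time > t
    if (!any(case) || !any(ctrl)) {
      return(data.frame(time = t, auc = NA_real_,
                        n_cases = sum(case), n_controls = sum(ctrl)))
    }
    w_case <- 1 / G(surv$time[case])
    w_ctrl <- rep(1 / G(t), sum(ctrl))
    sc <- scores[case]; sn <- scores[ctrl]
    cmp <- outer(sc, sn, function(a, b) (a > b) + 0.5 * (a == b))
    w <- outer(w_case, w_ctrl)
    data.frame(time = t, auc = sum(w * cmp) / sum(w),
               n_cases = sum(case), n_controls = sum(ctrl))
  })
  do.call(rbind, out)
}

# Mean-intensity column subset of a full feature matrix.
intensity_columns <- function(X) {
  X[, grepl("^mean__", colnames(X)), drop = FALSE]
}

#' Six-model comparison harness
#'
#' For each of `n_splits` stratified train/test splits, fits the six
#' comparison models on the training half and records each model's test
#' AUC for the binary recurrence-at-horizon outcome: (1) clinical
#' (age/gender/stage Cox), (2) intensity (mean-intensity features of the
#' undissected spot), (3) null (all 1540 undissected-spot features),
#' (4) intensity + clinical, (5) spatial (the three-domain model), and
#' (6) spatial + clinical. The "+ clinical" variants concatenate the
#' model's risk score with the clinical covariates in an unpenalized Cox
#' fit on the training half.
#'
#' @param features list of per-domain feature matrices as returned by
#'   [cohort_features()] (`epithelial`, `stromal`, `epi_stromal`,
#'   `spot`).
#' @param surv aligned `survival_table` with clinical covariates.
#' @param config a [run_config()]; `config$n_bootstraps` controls the
#'   stability screens inside each split (0 = plain cross-validated
#'   LASSO selection, the default harness mode).
#' @param n_splits number of train/test splits (default 50).
#' @param models character subset of the six model names.
#' @return data.frame with one row per (split, model) and columns
#'   `split`, `model`, `auc` (NA where a fit failed, with a message).
#' @export
compare_models <- function(features, surv, config = run_config(),
                           n_splits = 50L,
                           models = c("clinical", "intensity", "null",
                                      "intensity_clinical", "spatial",
                                      "spatial_clinical")) {
  models <- match.arg(models, several.ok = TRUE)
  horizon <- config$horizon_years
  rows <- list()
  for (b in seq_len(n_splits)) {
    sp <- stratified_bootstrap_split(surv, horizon, seed = config$seed + b)
    tr <- sp$train; te <- sp$test
    surv_tr <- surv[tr, , drop = FALSE]
    surv_te <- surv[te, , drop = FALSE]
    lab <- binary_outcome_at_horizon(surv_te, horizon)
    cfg <- config; cfg$seed <- config$seed + b
    scores <- list()

    get_scores <- function(name) {
      tryCatch(switch(name,
        clinical = {
          m <- fit_clinical_model(surv_tr)
          list(train = clinical_risk(m, surv_tr),
               test = clinical_risk(m, surv_te))
        },
        intensity = {
          m <- fit_domain_model(intensity_columns(features$spot)[tr, ,
                                                                 drop = FALSE],
                                surv_tr, cfg)
          list(train = domain_linear_predictor(
                 m, intensity_columns(features$spot)[tr, , drop = FALSE]),
               test = domain_linear_predictor(
                 m, intensity_columns(features$spot)[te, , drop = FALSE]))
        },
        null = {
          m <- fit_null_model(features$spot[tr, , drop = FALSE], surv_tr, cfg)
          list(train = domain_linear_predictor(
                 m, features$spot[tr, , drop = FALSE]),
               test = domain_linear_predictor(
                 m, features$spot[te, , drop = FALSE]))
        },
        spatial = {
          ftr <- lapply(features[c("epithelial", "stromal", "epi_stromal")],
                        function(M) M[tr, , drop = FALSE])
          fte <- lapply(features[c("epithelial", "stromal", "epi_stromal")],
                        function(M) M[te, , drop = FALSE])
          m <- fit_spatial_model(ftr, surv_tr, cfg)
          list(train = log(combined_risk(m, ftr)),
               test = log(combined_risk(m, fte)))
        }), error = function(e) {
          message("split ", b, ", model ", name, " failed: ",
                  conditionMessage(e))
          NULL
        })
    }

    base_needed <- unique(sub("_clinical$", "",
                              setdiff(models, "clinical")))
    for (name in intersect(c("clinical", base_needed),
                           c("clinical", "intensity", "null", "spatial"))) {
      scores[[name]] <- get_scores(name)
    }
    combine_clinical <- function(base) {
      if (is.null(scores[[base]])) return(NULL)
      df_tr <- data.frame(time = surv_tr$time, event = surv_tr$event,
                          score = scores[[base]]$train,
                          age = surv_tr$age,
                          gender = factor(surv_tr$gender),
                          stage = surv_tr$stage)
      fit <- tryCatch(
        survival::coxph(survival::Surv(time, event) ~ score + age + gender +
                          stage, data = df_tr),
        error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      df_te <- data.frame(score = scores[[base]]$test, age = surv_te$age,
                          gender = factor(surv_te$gender,
                                          levels = fit$xlevels[["gender"]]),
                          stage = surv_te$stage)
      list(test = unname(stats::predict(fit, newdata = df_te, type = "lp")))
    }
    if ("intensity_clinical" %in% models) {
      scores$intensity_clinical <- combine_clinical("intensity")
    }
    if ("spatial_clinical" %in% models) {
      scores$spatial_clinical <- combine_clinical("spatial")
    }

    for (name in models) {
      auc <- NA_real_
      s <- scores[[name]]
      if (!is.null(s) && sum(lab$labels == 1, na.rm = TRUE) > 0 &&
          sum(lab$labels == 0, na.rm = TRUE) > 0) {
        auc <- tryCatch(roc_curve(s$test, lab$labels)$auc,
                        error = function(e) NA_real_)
      }
      rows[[length(rows) + 1L]] <- data.frame(split = b, model = name,
                                              auc = auc)
    }
  }
  do.call(rbind, rows)
}
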