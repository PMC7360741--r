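#' Run the full analysis pipeline
#'
#' Orchestrates QC -> spatial dissection -> feature engineering ->
#' two-step model fitting -> evaluation -> network inference on a cohort
#' of per-patient spots, writing every artifact (with JSON sidecars
#' carrying the seed and config hash) under `out_dir`. Re-running with
#' the same config and seed reproduces all stochastic outputs.
#'
#' @param spots named list of per-patient `cell_table`s (names are
#'   patient ids matching the survival table).
#' @param surv a `survival_table` for the same patients.
#' @param config a [run_config()].
#' @param out_dir output directory (created); NULL to skip writing.
#' @param n_splits evaluation splits for the model-comparison harness
#'   (default 20); 0 skips the comparison.
#' @return list with `features`, `model` (spatial), `null_model`,
#'   `risk` (combined hazard-ratio scores), `evaluation` (ROC at the
#'   horizon, operating point, likelihood ratios, time-dependent AUC,
#'   model comparison), and `networks` (per domain; NULL where fewer
#'   than 2 biomarkers were selected).
#' @export
run_pipeline <- function(spots, surv, config = run_config(),
                         out_dir = NULL, n_splits = 20L) {
  stopifnot(!is.null(names(spots)))
  orphans <- c(setdiff(names(spots), surv$patient_id),
               setdiff(surv$patient_id, names(spots)))
  if (length(orphans)) {
    stop("patient ids do not reconcile between cell and survival tables: ",
         paste(utils::head(orphans, 10), collapse = ", "))
  }
  spots <- spots[surv$patient_id]
  if (sum(surv$event) == 0) stop("no events: cannot fit a Cox model")

  spots_qc <- lapply(spots, qc_cells, config = config)
  panel <- panel_of(spots_qc[[1]])
  features <- cohort_features(spots_qc, panel, config)

  model <- fit_spatial_model(features, surv, config)
  null_model <- fit_null_model(features$spot, surv, config)
  risk <- combined_risk(model, features)

  lab <- binary_outcome_at_horizon(surv, config$horizon_years)
  evaluation <- list()
  if (sum(lab$labels == 1, na.rm = TRUE) > 0 &&
      sum(lab$labels == 0, na.rm = TRUE) > 0) {
    roc <- roc_curve(log(risk), lab$labels)
    op <- youden_operating_point(roc)
    evaluation <- list(
      roc = roc, operating_point = op,
      likelihood_ratios = likelihood_ratios(op$sensitivity,
                                            op$specificity),
      km = km_curves(log(risk), surv, op$threshold),
      auc_t = time_dependent_auc(log(risk), surv,
                                 seq_len(config$horizon_years)))
  }
  if (n_splits > 0L) {
    evaluation$comparison <- compare_models(features, surv, config,
                                            n_splits = n_splits)
  }

  networks <- list()
  doms <- split_cohort_domains(spots_qc, config)
  for (d in c("epithelial", "stromal", "epi_stromal")) {
    bm <- selected_biomarkers(model$domains[[d]])
    networks[[d]] <- if (length(bm) >= 2) {
      suppressMessages(
        infer_domain_network(doms[[d]], lab$labels, bm, config))
    } else NULL
  }

  result <- list(features = features, model = model,
                 null_model = null_model, risk = risk,
                 evaluation = evaluation, networks = networks,
                 config = config, seed = config$seed)
  if (!is.null(out_dir)) write_pipeline_outputs(result, surv, out_dir)
  result
}

# Per-patient domain tables for the whole cohort.
split_cohort_domains <- function(spots_qc, config) {
  out <- list(epithelial = list(), stromal = list(), epi_stromal = list())
  for (id in names(spots_qc)) {
    tab <- assign_compartments(spots_qc[[id]])
    asg <- tessellate_boundary(tab, config$circle_diameter_um,
                               config$center_spacing_um)
    doms <- split_domains(tab, asg)
    for (d in names(out)) out[[d]][[id]] <- doms[[d]]
  }
  out
}

#' Biomarkers named by a domain model's selected features
#' @param model a `domain_model`.
#' @return character vector of unique biomarker names appearing in the
#'   model's `mean__` / `tau__` features.
#' @export
selected_biomarkers <- function(model) {
  f <- model$features
  unique(unlist(lapply(f, function(x) {
    strsplit(sub("^(mean|tau)__", "", x), "__", fixed = TRUE)[[1]]
  })))
}

write_pipeline_outputs <- function(result, surv, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  meta <- list(seed = cfg$seed, config_hash = config_hash(cfg))
  for (d in names(result$features)) {
    p <- file.path(out_dir, paste0("features_", d, ".csv"))
    data.table::fwrite(data.frame(patient_id = rownames(result$features[[d]]),
                                  result$features[[d]],
                                  check.names = FALSE), p)
    write_sidecar(p, meta)
  }
  rp <- file.path(out_dir, "risk_scores.csv")
  data.table::fwrite(data.frame(patient_id = surv$patient_id,
                                risk = result$risk), rp)
  write_sidecar(rp, meta)
  mp <- file.path(out_dir, "spatial_model.json")
  model_json <- lapply(result$model$domains, function(m) {
    list(features = m$features, beta = as.list(m$beta),
         center = as.list(m$center), scale = as.list(m$scale),
         degenerate = m$degenerate)
  })
  jsonlite::write_json(c(model_json, meta), mp, auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(result$evaluation$comparison)) {
    cp <- file.path(out_dir, "model_comparison.csv")
    data.table::fwrite(result$evaluation$comparison, cp)
    write_sidecar(cp, meta)
  }
  for (d in names(result$networks)) {
    if (is.null(result$networks[[d]])) next
    dp <- file.path(out_dir, paste0("distance_matrix_", d, ".csv"))
    data.table::fwrite(as.data.frame(result$networks[[d]]$distances), dp)
    export_network(result$networks[[d]]$network,
                   file.path(out_dir, paste0("network_", d)))
  }
  invisible(out_dir)
}
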