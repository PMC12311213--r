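# End-to-end experiment: simulate (or load) cohorts, select features on the
# training cohort, build one graph per cohort per similarity threshold,
# train one GCN per threshold, evaluate every cohort, and compare the
# thresholded models.

#' Experiment configuration
#'
#' Defaults reproduce the study conditions: cohorts of 621/112/87 patients
#' with metastasis prevalences 0.346/0.402/0.402, 2048 deep features,
#' cosine-similarity thresholds 0.60/0.70/0.80/0.95, 22 selected features,
#' and a probability cutoff of 0.5 for thresholded metrics.
#'
#' @param cohorts optional named list (`train`, `val1`, `val2`) of
#'   `lg_cohort`; when `NULL` they are simulated with
#'   [make_study_cohorts()].
#' @param thresholds cosine-similarity thresholds, each in (-1, 1].
#' @param n_features selected-feature count; `NULL` lets RFECV pick the
#'   cross-validation optimum, the default fixes 22.
#' @param selection a [selection_config()].
#' @param gcn a [gcn_config()] (its seed is re-derived per threshold).
#' @param cutoff probability cutoff for diagnostic reports.
#' @param n_boot bootstrap resamples for confidence intervals.
#' @param class_separation generative separation used when simulating.
#' @param seed global seed; all stage seeds derive from it via
#'   [stage_seed()].
#' @param out_dir optional directory for artifacts (reports, edge lists,
#'   training histories, run manifest).
#' @return an `lg_experiment_config`.
#' @export
experiment_config <- function(cohorts = NULL,
                              thresholds = c(0.60, 0.70, 0.80, 0.95),
                              n_features = 22L,
                              selection = selection_config(),
                              gcn = gcn_config(),
                              cutoff = 0.5, n_boot = 2000L,
                              class_separation = 2, seed = 1L,
                              out_dir = NULL) {
  stopifnot(length(thresholds) >= 1, all(thresholds > -1 & thresholds <= 1))
  structure(list(cohorts = cohorts, thresholds = thresholds,
                 n_features = n_features, selection = selection, gcn = gcn,
                 cutoff = cutoff, n_boot = n_boot,
                 class_separation = class_separation,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "lg_experiment_config")
}

#' Run the full experiment
#'
#' Stages: simulate (or take) the three cohorts; fit the feature selection
#' on the training cohort; build a patient graph per cohort per threshold;
#' train one GCN per threshold on the training graph; predict every
#' cohort; produce per-cohort diagnostic reports and the cross-model
#' comparison (Pearson agreement, repeated-measures ANOVA, pairwise DeLong
#' p-values, decision curves). Every stochastic stage draws its seed from
#' the global seed, so a rerun with the same config reproduces every
#' number.
#'
#' @param config an [experiment_config()].
#' @return an `lg_experiment`: `selection`, `edge_counts` (cohort x
#'   threshold), `fits`, `predictions` (per cohort, n x thresholds),
#'   `reports` (per cohort per threshold), `comparison` (per cohort),
#'   `bayes_auc` (when simulated), `manifest`.
#' @export
run_experiment <- function(config = experiment_config()) {
  seed <- config$seed
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
  }

  cohorts <- run_stage("simulate", {
    if (is.null(config$cohorts))
      make_study_cohorts(stage_seed(seed, "simulate"),
                         class_separation = config$class_separation)
    else config$cohorts
  })
  stopifnot(all(c("train", "val1", "val2") %in% names(cohorts)))

  sel_cfg <- config$selection
  sel_cfg$seed <- stage_seed(seed, "select")
  selection <- run_stage("select", {
    select_features(cohorts$train$features, cohorts$train$labels, sel_cfg,
                    config$n_features)
  })

  tables <- run_stage("node-tables", lapply(cohorts, function(co)
    node_table(co$ids, apply_selection(selection, co$features), co$labels)))

  thr_names <- sprintf("threshold_%02d", round(100 * config$thresholds))
  sims <- lapply(tables, function(tb)
    cosine_similarity_matrix(tb$X, tb$ids))

  graphs <- run_stage("graph", {
    g <- lapply(names(tables), function(ck) {
      lapply(config$thresholds, function(th)
        assemble_graph(tables[[ck]], th, S = sims[[ck]]))
    })
    names(g) <- names(tables)
    for (ck in names(g)) names(g[[ck]]) <- thr_names
    g
  })

  edge_counts <- sapply(graphs, function(gl)
    vapply(gl, function(g) nrow(g$edges), numeric(1)))

  fits <- run_stage("train", {
    out <- lapply(seq_along(config$thresholds), function(ti) {
      cfg <- config$gcn
      cfg$seed <- stage_seed(seed, paste0("train-", thr_names[ti]))
      gcn_train(graphs$train[[ti]], cohorts$train$labels, cfg)
    })
    names(out) <- thr_names
    out
  })

  predictions <- run_stage("predict", {
    out <- lapply(names(tables), function(ck) {
      P <- vapply(seq_along(config$thresholds), function(ti)
        gcn_predict(graphs[[ck]][[ti]], fits[[ti]]),
        numeric(tables[[ck]]$X |> nrow()))
      colnames(P) <- thr_names
      P
    })
    names(out) <- names(tables)
    out
  })

  reports <- run_stage("evaluate", {
    out <- lapply(names(tables), function(ck) {
      rep_by_thr <- lapply(thr_names, function(tn)
        diagnostic_report(predictions[[ck]][, tn], tables[[ck]]$labels,
                          cutoff = config$cutoff, n_boot = config$n_boot,
                          seed = stage_seed(seed, paste0("report-", ck, "-",
                                                         tn))))
      names(rep_by_thr) <- thr_names
      rep_by_thr
    })
    names(out) <- names(tables)
    out
  })

  comparison <- run_stage("compare", {
    out <- lapply(names(tables), function(ck) {
      P <- predictions[[ck]]
      k <- ncol(P)
      dl_p <- dl_z <- matrix(NA_real_, k, k, dimnames = list(thr_names,
                                                             thr_names))
      for (a in seq_len(k)) for (b in seq_len(k)) if (a < b) {
        dl <- delong_test(P[, a], P[, b], tables[[ck]]$labels)
        dl_p[a, b] <- dl_p[b, a] <- dl$p
        dl_z[a, b] <- dl$z
        dl_z[b, a] <- -dl$z
      }
      # cross-model statistics need at least two thresholded models
      list(pearson_r = if (k >= 2) agreement_matrix(P),
           anova = if (k >= 2) rm_anova(P),
           delong_p = dl_p, delong_z = dl_z,
           dca = lapply(stats::setNames(thr_names, thr_names), function(tn)
             decision_curve(P[, tn], tables[[ck]]$labels)))
    })
    names(out) <- names(tables)
    out
  })

  result <- structure(list(
    selection = selection, thresholds = config$thresholds,
    threshold_names = thr_names, edge_counts = edge_counts, fits = fits,
    predictions = predictions, reports = reports, comparison = comparison,
    labels = lapply(tables, `[[`, "labels"),
    bayes_auc = cohorts$train$truth$bayes_auc,
    config = config, manifest = NULL), class = "lg_experiment")

  if (!is.null(config$out_dir))
    result$manifest <- run_stage("write", write_experiment(result, graphs,
                                                           config$out_dir))
  result
}

# Write the artifact tree and a run manifest with per-file digests.
write_experiment <- function(result, graphs, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_selection_json(result$selection, file.path(out_dir, "selection.json"))
  for (ck in names(graphs)) for (tn in names(graphs[[ck]])) {
    tag <- paste0(ck, "_", tn)
    write_edge_tsv(graphs[[ck]][[tn]], file.path(out_dir,
                                                 paste0("edges_", tag, ".tsv")))
    jsonlite::write_json(graph_summary(graphs[[ck]][[tn]]),
                         file.path(out_dir, paste0("graph_", tag, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  for (tn in names(result$fits)) {
    utils::write.csv(result$fits[[tn]]$history,
                     file.path(out_dir, paste0("history_", tn, ".csv")),
                     row.names = FALSE)
    write_gcn_checkpoint(result$fits[[tn]],
                         file.path(out_dir, paste0("gcn_", tn, ".json")))
  }
  for (ck in names(result$predictions)) for (tn in colnames(result$predictions[[ck]]))
    utils::write.csv(roc_auc(result$predictions[[ck]][, tn],
                             result$labels[[ck]])$curve,
                     file.path(out_dir, paste0("roc_", ck, "_", tn, ".csv")),
                     row.names = FALSE)
  for (ck in names(result$reports)) for (tn in names(result$reports[[ck]]))
    jsonlite::write_json(result$reports[[ck]][[tn]],
                         file.path(out_dir,
                                   paste0("report_", ck, "_", tn, ".json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (ck in names(result$comparison)) {
    cmp <- result$comparison[[ck]]
    if (!is.null(cmp$pearson_r))
      utils::write.csv(cmp$pearson_r,
                       file.path(out_dir, paste0("pearson_", ck, ".csv")))
    utils::write.csv(cmp$delong_p,
                     file.path(out_dir, paste0("delong_p_", ck, ".csv")))
    for (tn in names(cmp$dca))
      utils::write.csv(cmp$dca[[tn]],
                       file.path(out_dir, paste0("dca_", ck, "_", tn, ".csv")),
                       row.names = FALSE)
    if (!is.null(cmp$anova))
      jsonlite::write_json(cmp$anova,
                           file.path(out_dir, paste0("anova_", ck, ".json")),
                           auto_unbox = TRUE, digits = NA)
  }
  files <- sort(list.files(out_dir, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  cfg <- result$config
  cfg$cohorts <- NULL
  cfg$out_dir <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("lymphgraph")),
    seed = result$config$seed,
    config = cfg,
    digests = as.list(tools::md5sum(files)),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest
}
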