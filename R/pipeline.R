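task_positive <- function(task) {
  switch(task, pathology = "ACP", braf = "mutant", ctnnb1 = "mutant",
         stopf("unknown task '%s'", task))
}

task_labels <- function(cohort, task) {
  field <- switch(task, pathology = "label_pathology", braf = "label_braf",
                  ctnnb1 = "label_ctnnb1")
  vapply(cohort, `[[`, "", field)
}

#' Run the full radiomics pipeline on a cohort
#'
#' Orchestrates extract -> robustness screen -> normalize -> bootstrap
#' ranking -> forward selection -> evaluation -> nomogram for each task, and
#' writes every artifact (feature table, ICC report, rankings, selected
#' subsets, metrics, nomograms, log) into a run directory stamped with the
#' configuration hash and seed. Reruns with the same configuration
#' reproduce the metrics exactly.
#'
#' In `"extended"` mode the per-task feature subsets from a previous main
#' run are applied directly (no re-screening or re-selection), matching the
#' extension protocol of evaluating frozen features on an enlarged cohort.
#'
#' @param cohort list of cases ([generate_cohort()] / [read_cohort()])
#' @param atlas atlas-center table
#' @param out_dir run directory (created; artifacts are overwritten)
#' @param tasks subset of c("pathology", "braf", "ctnnb1")
#' @param d a [discretization_spec()]
#' @param sel_cfg a [selection_config()]
#' @param eval_seed seed for the outer evaluation
#' @param n_folds,n_trees outer-model settings
#' @param mode `"main"` or `"extended"`
#' @param selected for extended mode: named list task -> character vector of
#'   frozen feature names
#' @return named list per task: `selected`, `metrics`, `nomogram`; plus
#'   `features`, `icc_report` (main mode) and `out_dir`
#' @export
run_pipeline <- function(cohort, atlas, out_dir,
                         tasks = c("pathology", "braf", "ctnnb1"),
                         d = discretization_spec(),
                         sel_cfg = selection_config(),
                         eval_seed = 1, n_folds = 10, n_trees = 500,
                         mode = c("main", "extended"), selected = NULL) {
  mode <- match.arg(mode)
  tasks <- match.arg(tasks, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(out_dir, "log.txt")
  logln <- function(...) cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "),
                             sprintf(...), "\n", sep = "",
                             file = logfile, append = TRUE)
  stage <- function(name, expr) {
    logln("start %s", name)
    tryCatch(expr, error = function(e) {
      logln("FAILED %s: %s", name, conditionMessage(e))
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  cfg_stamp <- list(hash = config_hash(list(d, sel_cfg, eval_seed, n_folds,
                                            n_trees, mode, tasks)),
                    seed = eval_seed, mode = mode)
  jsonlite::write_json(cfg_stamp, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE)

  feats <- stage("extract", extract_cohort_features(cohort, atlas, d))
  write.csv(feats, file.path(out_dir, "features.csv"), row.names = FALSE)
  fx <- feats[setdiff(names(feats), "case_id")]
  case_ids <- feats$case_id

  icc_report <- NULL
  if (mode == "main") {
    cases <- lapply(cohort, function(case)
      volume_with_mask(case$volume, case$mask, case$spacing_mm))
    icc_report <- stage("robustness", robustness_screen(cases, d))
    write.csv(icc_report, file.path(out_dir, "icc_report.csv"),
              row.names = FALSE)
    robust <- icc_report$feature[icc_report$pass]
    keep <- names(fx)[feature_category(names(fx)) %in%
                        c("location", "clinical") | names(fx) %in% robust]
    logln("robust image features: %d of %d; %d features enter selection",
          length(robust), nrow(icc_report), length(keep))
    fx <- fx[keep]
  }

  norm <- stage("normalize", suppressWarnings(normalize_features(fx)))
  xn <- norm$features

  out <- list(features = feats, icc_report = icc_report, out_dir = out_dir)
  for (task in tasks) {
    labels <- task_labels(cohort, task)
    if (length(unique(labels)) < 2) {
      logln("task %s skipped: single-class labels", task)
      next
    }
    pos <- task_positive(task)
    if (mode == "main") {
      ranked <- stage(paste0("stage2-", task),
                      stage2_rank(xn, labels, sel_cfg, pos, case_ids))
      write.csv(ranked, file.path(out_dir, paste0("ranked_", task, ".csv")),
                row.names = FALSE)
      sfs <- stage(paste0("stage3-", task),
                   stage3_sfs(xn, labels, ranked, sel_cfg, pos, case_ids))
      chosen <- sfs$features
      jsonlite::write_json(
        list(task = task, features = chosen, k = sfs$k,
             accuracy = sfs$accuracy, trace = sfs$trace),
        file.path(out_dir, paste0("selected_", task, ".json")),
        auto_unbox = TRUE, digits = NA)
    } else {
      chosen <- selected[[task]]
      if (is.null(chosen)) stopf("extended mode needs selected[['%s']]", task)
      missing <- setdiff(chosen, names(xn))
      if (length(missing))
        stopf("extended table lacks selected feature(s): %s",
              paste(missing, collapse = ", "))
      sfs <- NULL
    }
    ev <- stage(paste0("evaluate-", task),
                evaluate_model(xn[chosen], labels, pos, n_folds, n_trees,
                               derive_seed(eval_seed, task), case_ids))
    jsonlite::write_json(ev$metrics,
                         file.path(out_dir, paste0("metrics_", task, ".json")),
                         auto_unbox = TRUE, digits = NA)
    write.csv(ev$scores, file.path(out_dir, paste0("scores_", task, ".csv")),
              row.names = FALSE)
    nom <- stage(paste0("nomogram-", task),
                 fit_nomogram(xn[chosen], labels, pos))
    jsonlite::write_json(
      list(task = task, coefficients = as.list(nom$coefficients),
           point_scale = nom$point_scale, c_index = nom$c_index,
           separated = nom$separated),
      file.path(out_dir, paste0("nomogram_", task, ".json")),
      auto_unbox = TRUE, digits = NA)
    out[[task]] <- list(selected = chosen, sfs = sfs, metrics = ev$metrics,
                        scores = ev$scores, nomogram = nom)
    logln("task %s done: |subset| = %d, AUC = %.3f", task, length(chosen),
          ev$metrics$auc)
  }
  out
}
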