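#' Configuration of a full pipeline run
#'
#' Nested configuration for the end-to-end analysis: cohort generation,
#' preprocessing, model, training, stratification and survival. A single
#' master seed fans out to fixed per-stage seeds (master + small offsets)
#' so every stage is independently rerunnable; the effective configuration
#' is serialised into the run directory, from which the run is exactly
#' reproducible.
#'
#' @param n_grade1,n_grade2,n_grade3 patients per grade.
#' @param slices_per_patient training slices per patient (even, 4..14).
#' @param phase_set input phases, `"post"` or `"pre_post"`.
#' @param profile training profile, `"test"` or `"paper"` (see
#'   [train_config()]).
#' @param bootstrap resamples for AUC and C-index intervals.
#' @param seed master seed.
#' @param cohort_args extra arguments passed to [cohort_spec()].
#' @param n_gradcam how many stratified patients get a Grad-CAM export.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(n_grade1 = 150L, n_grade2 = 400L, n_grade3 = 150L,
                       slices_per_patient = 8L,
                       phase_set = "post",
                       profile = "test",
                       bootstrap = 1000L,
                       seed = 1L,
                       cohort_args = list(),
                       n_gradcam = 2L) {
  structure(
    list(n_grade1 = as.integer(n_grade1), n_grade2 = as.integer(n_grade2),
         n_grade3 = as.integer(n_grade3),
         slices_per_patient = as.integer(slices_per_patient),
         phase_set = phase_set, profile = profile,
         bootstrap = as.integer(bootstrap), seed = as.integer(seed),
         cohort_args = cohort_args, n_gradcam = as.integer(n_gradcam)),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the `yaml` package is needed to read YAML configs", call. = FALSE)
  do.call(run_config, yaml::read_yaml(path))
}

log_line <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  cat(msg, "\n", file = log_path, append = TRUE)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on one synthetic cohort: simulate the grade-1/3
#' development patients and the grade-2 application patients; preprocess to
#' tumour crops; split grade-1/3 patients 80/20; train the CNN on augmented
#' training slices; evaluate patient-level ROC/AUC with stratified
#' bootstrap intervals on both splits; select the Youden threshold on the
#' training-set scores; stratify the grade-2 patients into DRG2-/DRG2+;
#' compare the strata's characteristics; and run the RFS analysis
#' (Kaplan-Meier, log-rank, both Cox models, paired-bootstrap C-index
#' comparison). Artifacts (`config.json`, `roc.json`, `threshold.json`,
#' `strata.csv`, `group_comparison.json`, `rfs.json`, `loss.csv`,
#' `km.png`, `gradcam/*.png`, `run.log`) are written to `out_dir` when it
#' is given.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return A list of class `pipeline_result` with elements `cohort_dev`
#'   (clinical tibble of the grade-1/3 cohort), `split`, `model`,
#'   `loss_history`, `roc_train`, `roc_test`, `threshold`, `strata`,
#'   `comparison`, `rfs`, `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    log_path <- file.path(out_dir, "run.log")
    cat("", file = log_path)
  } else log_path <- nullfile()
  seed <- config$seed

  log_line(log_path, "simulate: ", config$n_grade1, "+", config$n_grade3,
           " grade-1/3 and ", config$n_grade2, " grade-2 patients")
  spec_dev <- do.call(cohort_spec, c(
    list(n_per_grade = c(config$n_grade1, 0L, config$n_grade3),
         seed = seed),
    config$cohort_args))
  cohort_dev <- simulate_cohort(spec_dev, keep_volumes = FALSE)
  spec_g2 <- do.call(cohort_spec, c(
    list(n_per_grade = c(0L, config$n_grade2, 0L), seed = seed + 1L),
    config$cohort_args))
  cohort_g2 <- simulate_cohort(spec_g2, keep_volumes = FALSE)
  # ids are per-spec; make the application cohort distinct
  cohort_g2$clinical$patient_id <- sub("^P", "G", cohort_g2$clinical$patient_id)
  names(cohort_g2$crops) <- cohort_g2$clinical$patient_id

  tcfg <- train_config(profile = config$profile, seed = seed + 2L)
  split <- split_patients(cohort_dev$clinical, tcfg$train_fraction,
                          seed = seed + 3L)
  log_line(log_path, "split: ", length(split$train), " train / ",
           length(split$test), " test patients")

  labels <- stats::setNames(as.integer(cohort_dev$clinical$nhg == 3L),
                            cohort_dev$clinical$patient_id)
  set.seed(seed + 4L)
  samples <- unlist(lapply(split$train, function(pid) {
    make_training_slices(cohort_dev$crops[[pid]],
                         k = config$slices_per_patient,
                         label = labels[[pid]])
  }), recursive = FALSE)
  log_line(log_path, "train: ", length(samples), " slices, ",
           tcfg$epochs, " epochs (profile ", config$profile, ")")
  model <- build_grade_cnn(model_config(), seed = seed + 5L)
  trained <- train_cnn(model, samples, tcfg)
  model <- trained$model
  log_line(log_path, "final training loss ",
           sprintf("%.4f", utils::tail(trained$loss_history, 1)))

  score_split <- function(ids) {
    sc <- score_patients(model, cohort_dev$crops, ids)
    list(scores = sc$score, labels = unname(labels[ids]))
  }
  tr <- score_split(split$train)
  te <- score_split(split$test)
  roc_train <- bootstrap_auc_ci(tr$scores, tr$labels, B = config$bootstrap,
                                seed = seed + 6L)
  roc_test <- bootstrap_auc_ci(te$scores, te$labels, B = config$bootstrap,
                               seed = seed + 7L)
  log_line(log_path, sprintf("AUC train %.3f [%.3f-%.3f], test %.3f [%.3f-%.3f]",
                             roc_train$auc, roc_train$ci_low, roc_train$ci_high,
                             roc_test$auc, roc_test$ci_low, roc_test$ci_high))
  thr <- youden_threshold(tr$scores, tr$labels)
  log_line(log_path, sprintf("Youden threshold %.4f (J = %.3f)",
                             thr$threshold, thr$youden_j))
  # scores live in (0, 1); an infinite sentinel can only appear when every
  # training score ties, in which case the midpoint rule degenerates
  thr_use <- if (is.finite(thr$threshold)) thr$threshold else 0.5

  strata <- classify_grade2(model, cohort_g2, thr_use)
  log_line(log_path, "strata: ", sum(strata$drg_label == "DRG2-"), " DRG2- / ",
           sum(strata$drg_label == "DRG2+"), " DRG2+ of ", nrow(strata))
  comparison <- compare_groups(strata, cohort_g2$clinical)
  rfs <- run_rfs_analysis(cohort_g2$clinical, strata, B = config$bootstrap,
                          seed = seed + 8L)
  log_line(log_path, sprintf(
    "Cox C-index %.3f -> %.3f (delta %.4f, p = %.4g); DRG2+ adjusted HR %.2f [%.2f-%.2f]",
    rfs$cindex$c_base, rfs$cindex$c_full, rfs$cindex$delta_mean,
    rfs$cindex$p_value, rfs$cox_full$table$hr[1],
    rfs$cox_full$table$hr_low[1], rfs$cox_full$table$hr_high[1]))

  result <- structure(
    list(cohort_dev = cohort_dev$clinical, cohort_g2 = cohort_g2$clinical,
         split = split, model = model, loss_history = trained$loss_history,
         roc_train = roc_train, roc_test = roc_test, threshold = thr,
         strata = strata, comparison = comparison, rfs = rfs,
         config = config),
    class = "pipeline_result"
  )
  if (!is.null(out_dir))
    write_pipeline_artifacts(result, cohort_g2, out_dir, log_path)
  result
}

write_pipeline_artifacts <- function(result, cohort_g2, out_dir, log_path) {
  cfg <- result$config
  # checkpoint: the grade_cnn carries weights, architecture config and seed
  saveRDS(list(model = result$model, run_config = unclass(cfg)),
          file.path(out_dir, "model.rds"))
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(
    list(train = glance(result$roc_train), test = glance(result$roc_test)),
    file.path(out_dir, "roc.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA)
  jsonlite::write_json(
    result$threshold[c("threshold", "youden_j", "sensitivity", "specificity")],
    file.path(out_dir, "threshold.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as_tibble(result$strata),
                   file.path(out_dir, "strata.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(summary = result$comparison$summary, tests = result$comparison$tests,
         n = as.list(result$comparison$n)),
    file.path(out_dir, "group_comparison.json"), dataframe = "rows",
    auto_unbox = TRUE, digits = NA)
  rfs <- result$rfs
  jsonlite::write_json(
    list(logrank = rfs$logrank,
         cox_base = list(terms = tidy(rfs$cox_base),
                         summary = glance(rfs$cox_base)),
         cox_full = list(terms = tidy(rfs$cox_full),
                         summary = glance(rfs$cox_full)),
         cindex = tidy(rfs$cindex)),
    file.path(out_dir, "rfs.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA)
  utils::write.csv(
    data.frame(epoch = seq_along(result$loss_history),
               loss = result$loss_history),
    file.path(out_dir, "loss.csv"), row.names = FALSE)
  tryCatch({
    grDevices::png(file.path(out_dir, "km.png"), width = 900, height = 600)
    print(plot_km(rfs$km))
    grDevices::dev.off()
    dir.create(file.path(out_dir, "gradcam"), showWarnings = FALSE)
    cam_ids <- utils::head(result$strata$patient_id, cfg$n_gradcam)
    crops <- cohort_crops(cohort_g2)
    for (pid in cam_ids) {
      sl <- make_eval_slice(crops[[pid]])
      cam <- grad_cam(result$model, sl)
      grDevices::png(file.path(out_dir, "gradcam",
                               paste0(pid, "_cam.png")), 600, 600)
      print(autoplot(cam, underlay = sl$x[1, , ]))
      grDevices::dev.off()
    }
  }, error = function(e) {
    log_line(log_path, "plot export skipped: ", conditionMessage(e))
  })
  invisible(out_dir)
}
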