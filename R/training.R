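#' Training configuration
#'
#' Hyperparameters of the weighted binary cross-entropy / Adam training
#' loop. `profile = "paper"` is the full-scale schedule (1100 epochs, batch
#' 512, learning rate 5e-6) appropriate to real multi-centre cohorts;
#' `profile = "test"` is the desk-scale schedule used throughout this
#' package's tests and examples (15 epochs, batch 64, learning rate 2e-4),
#' sized for the easier synthetic task on a single CPU.
#'
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size (slices).
#' @param epochs number of passes over the training slices.
#' @param train_fraction patient fraction assigned to training in
#'   [split_patients()].
#' @param seed seed controlling shuffling.
#' @param profile `"test"`, `"paper"`, or `"custom"` (use the explicit
#'   arguments).
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 2e-4, batch_size = 64L,
                         epochs = 15L, train_fraction = 0.8, seed = 1L,
                         profile = c("custom", "test", "paper")) {
  profile <- match.arg(profile)
  if (profile == "paper") {
    learning_rate <- 5e-6; batch_size <- 512L; epochs <- 1100L
  } else if (profile == "test") {
    learning_rate <- 2e-4; batch_size <- 64L; epochs <- 15L
  }
  if (learning_rate <= 0 || batch_size < 1 || epochs < 1)
    stop("learning_rate, batch_size and epochs must be positive", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         epochs = as.integer(epochs), train_fraction = train_fraction,
         seed = as.integer(seed), profile = profile),
    class = "train_config"
  )
}

#' Stratified patient-level train/test split
#'
#' Splits patients (never slices) into training and testing sets,
#' stratified by grade, so no slice of a test patient can ever enter
#' training. Deterministic given the seed.
#'
#' @param clinical tibble with `patient_id` and `nhg` columns (typically
#'   the grade-1/grade-3 rows of a cohort).
#' @param train_fraction fraction of each grade assigned to training.
#' @param seed integer seed.
#' @return List with `train` and `test` character vectors of patient ids.
#' @export
split_patients <- function(clinical, train_fraction = 0.8, seed = 1L) {
  grades <- sort(unique(clinical$nhg))
  if (any(table(clinical$nhg) < 2L))
    stop("need at least 2 patients per grade to split", call. = FALSE)
  set.seed(seed)
  train <- character(0)
  for (g in grades) {
    ids <- clinical$patient_id[clinical$nhg == g]
    n_tr <- round(train_fraction * length(ids))
    train <- c(train, sample(ids, n_tr))
  }
  list(train = sort(train),
       test = sort(setdiff(clinical$patient_id, train)))
}

#' Inverse-frequency class weights
#'
#' Weight for class c proportional to `n_total / (2 n_c)`, normalised so
#' the two class weights average 1; balanced labels give (1, 1) and the
#' minority class is up-weighted by the class ratio.
#'
#' @param labels 0/1 vector.
#' @return Named numeric vector `c(w0, w1)`.
#' @export
class_weights <- function(labels) {
  n <- c(sum(labels == 0), sum(labels == 1))
  if (any(n == 0L))
    stop("both classes must be present to compute class weights", call. = FALSE)
  w <- length(labels) / (2 * n)
  w <- w / mean(w)
  c(w0 = w[1], w1 = w[2])
}

#' Train the CNN on labelled slices
#'
#' Minimises class-weighted binary cross-entropy on the sigmoid
#' probabilities with Adam (beta1 = 0.9, beta2 = 0.999, eps = 1e-8).
#' Per-sample weights are the inverse-frequency [class_weights()] of the
#' training labels. Shuffling is seeded, so a repeated run with the same
#' configuration returns an identical loss history and identical weights.
#'
#' @param model a `grade_cnn`.
#' @param samples list of labelled `slice_sample` objects.
#' @param config a [train_config()].
#' @param verbose print the loss every few epochs?
#' @return List with `model` (trained `grade_cnn`) and `loss_history`
#'   (numeric, one mean weighted loss per epoch).
#' @export
train_cnn <- function(model, samples, config = train_config(profile = "test"),
                      verbose = FALSE) {
  stopifnot(inherits(model, "grade_cnn"), inherits(config, "train_config"))
  if (length(samples) == 0L) stop("no training samples", call. = FALSE)
  labels <- vapply(samples, function(s) as.numeric(s$label), numeric(1))
  if (any(is.na(labels))) stop("all training samples must be labelled", call. = FALSE)
  cw <- class_weights(labels)
  sw <- ifelse(labels == 1, cw["w1"], cw["w0"])
  x_all <- slice_batch(samples)
  n <- length(samples)
  ccfg <- cpp_config(model$config)

  w <- model$weights
  m_state <- weight_map(function(a) a * 0, w)
  v_state <- weight_map(function(a) a * 0, w)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  loss_history <- numeric(config$epochs)

  set.seed(config$seed)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    ep_loss <- 0
    for (s0 in starts) {
      idx <- ord[s0:min(s0 + config$batch_size - 1L, n)]
      res <- .cnn_batch_grad(w, ccfg,
                             x_all[, , , idx, drop = FALSE],
                             labels[idx], sw[idx])
      if (!is.finite(res$loss))
        stop("non-finite loss at epoch ", epoch,
             "; lower the learning rate", call. = FALSE)
      ep_loss <- ep_loss + res$loss * length(idx)
      step <- step + 1L
      lr_t <- config$learning_rate * sqrt(1 - b2^step) / (1 - b1^step)
      m_state <- weight_map(function(m, g) b1 * m + (1 - b1) * g,
                            m_state, res$grads)
      v_state <- weight_map(function(v, g) b2 * v + (1 - b2) * g^2,
                            v_state, res$grads)
      w <- weight_map(function(wt, m, v) wt - lr_t * m / (sqrt(v) + eps),
                      w, m_state, v_state)
    }
    loss_history[epoch] <- ep_loss / n
    if (verbose && (epoch %% 5L == 0L || epoch == 1L))
      message(sprintf("epoch %3d  loss %.4f", epoch, loss_history[epoch]))
  }
  model$weights <- w
  list(model = model, loss_history = loss_history)
}

#' Score patients with the single evaluation slice
#'
#' One probability per patient: the network's output on the deterministic
#' evaluation slice of the patient's crop (see [make_eval_slice()]).
#' Patients whose crop is missing are dropped with a warning.
#'
#' @param model a trained `grade_cnn`.
#' @param crops named list of `tumor_crop` objects (names are patient ids).
#' @param patient_ids which patients to score, in order; default all crops.
#' @return Tibble with `patient_id`, `score`, in the requested order.
#' @export
score_patients <- function(model, crops, patient_ids = names(crops)) {
  missing <- setdiff(patient_ids, names(crops))
  if (length(missing) > 0) {
    warning("no crop for patient(s) ", paste(missing, collapse = ", "),
            "; skipped", call. = FALSE)
    patient_ids <- setdiff(patient_ids, missing)
  }
  slices <- lapply(crops[patient_ids], make_eval_slice)
  tibble(patient_id = patient_ids,
         score = as.numeric(predict(model, slices)))
}

#' Area under the ROC curve
#'
#' The rank (Mann-Whitney) form: the probability that a random positive
#' scores above a random negative, counting ties as one half.
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute an AUC", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified bootstrap confidence interval for the AUC
#'
#' Percentile interval over `B` patient-level resamples drawn with
#' replacement within each class, so every resample contains both classes.
#' Deterministic given the seed.
#'
#' @param scores,labels per-patient scores and 0/1 labels.
#' @param B number of resamples.
#' @param conf confidence level.
#' @param seed integer seed.
#' @return Object of class `roc_result`: list with `auc`, `ci_low`,
#'   `ci_high`, `n_bootstrap`, `conf`, `scores`, `labels`.
#' @export
bootstrap_auc_ci <- function(scores, labels, B = 1000L, conf = 0.95,
                             seed = 1L) {
  if (B < 100L) warning("B < 100 gives unstable percentile intervals", call. = FALSE)
  auc <- roc_auc(scores, labels)
  i1 <- which(labels == 1); i0 <- which(labels == 0)
  set.seed(seed)
  reps <- vapply(seq_len(B), function(b) {
    j <- c(i0[sample.int(length(i0), replace = TRUE)],
           i1[sample.int(length(i1), replace = TRUE)])
    roc_auc(scores[j], labels[j])
  }, numeric(1))
  qs <- unname(quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  structure(
    list(auc = auc, ci_low = qs[1], ci_high = qs[2],
         n_bootstrap = as.integer(B), conf = conf,
         scores = scores, labels = labels),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.3f [%d%% CI %.3f-%.3f], n = %d (%d bootstrap resamples)\n",
              x$auc, round(100 * x$conf), x$ci_low, x$ci_high,
              length(x$labels), x$n_bootstrap))
  invisible(x)
}

#' Youden-index operating threshold
#'
#' Scans every candidate cutoff (midpoints between adjacent sorted unique
#' scores, plus -Inf and +Inf sentinels) under the decision rule
#' `score >= threshold` is positive, and returns the cutoff maximising
#' Youden's J = sensitivity + specificity - 1. Ties are broken towards the
#' smallest threshold.
#'
#' @param scores,labels per-patient scores and 0/1 labels.
#' @return Object of class `threshold_result`: list with `threshold`,
#'   `youden_j`, `sensitivity`, `specificity`.
#' @export
youden_threshold <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to pick a threshold", call. = FALSE)
  u <- sort(unique(scores))
  candidates <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- NULL
  for (t in candidates) {
    sens <- sum(scores >= t & labels == 1) / n1
    spec <- sum(scores < t & labels == 0) / n0
    j <- sens + spec - 1
    if (is.null(best) || j > best$youden_j + 1e-12) {
      best <- list(threshold = t, youden_j = j, sensitivity = sens,
                   specificity = spec)
    }
  }
  structure(best, class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("threshold %.4g  (J = %.3f; sensitivity %.3f, specificity %.3f)\n",
              x$threshold, x$youden_j, x$sensitivity, x$specificity))
  invisible(x)
}

#' Sweep the number of training slices per patient
#'
#' Retrains the network for each slice count `k` and reports patient-level
#' training and testing AUC with bootstrap confidence intervals — the
#' standard report for choosing how much of the tumour volume to feed the
#' model.
#'
#' @param cohort a `dce_cohort` containing grade-1 and grade-3 patients.
#' @param ks even slice counts to try.
#' @param config a [train_config()] reused for every `k`.
#' @param B bootstrap resamples for the AUC intervals.
#' @param model_seed seed for each run's weight initialisation.
#' @return Tibble with one row per `k`: `slices_per_patient`, `n_train`,
#'   `n_test`, `auc_train`, `ci_train_low`, `ci_train_high`, `auc_test`,
#'   `ci_test_low`, `ci_test_high`.
#' @export
sweep_slices <- function(cohort, ks = c(4L, 6L, 8L, 10L, 12L, 14L),
                         config = train_config(profile = "test"),
                         B = 1000L, model_seed = 1L) {
  stopifnot(inherits(cohort, "dce_cohort"))
  crops <- cohort_crops(cohort)
  clinical <- cohort$clinical[cohort$clinical$nhg %in% c(1L, 3L), ]
  split <- split_patients(clinical, config$train_fraction, seed = config$seed)
  labels <- stats::setNames(as.integer(clinical$nhg == 3L),
                            clinical$patient_id)
  rows <- lapply(ks, function(k) {
    set.seed(config$seed + k)
    samples <- unlist(lapply(split$train, function(pid) {
      make_training_slices(crops[[pid]], k = k, label = labels[[pid]])
    }), recursive = FALSE)
    model <- build_grade_cnn(model_config(), seed = model_seed)
    trained <- train_cnn(model, samples, config)
    auc_of <- function(ids, seed_off) {
      sc <- score_patients(trained$model, crops, ids)
      bootstrap_auc_ci(sc$score, unname(labels[ids]), B = B,
                       seed = config$seed + seed_off)
    }
    a_tr <- auc_of(split$train, 1000L + k)
    a_te <- auc_of(split$test, 2000L + k)
    tibble(slices_per_patient = as.integer(k),
           n_train = length(split$train), n_test = length(split$test),
           auc_train = a_tr$auc, ci_train_low = a_tr$ci_low,
           ci_train_high = a_tr$ci_high,
           auc_test = a_te$auc, ci_test_low = a_te$ci_low,
           ci_test_high = a_te$ci_high)
  })
  dplyr::bind_rows(rows)
}
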