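test_that("the patient split is stratified, leak-free, and deterministic", {
  clin <- tibble::tibble(patient_id = sprintf("P%02d", 1:20),
                         nhg = rep(c(1L, 3L), each = 10))
  sp <- split_patients(clin, 0.8, seed = 5)
  expect_length(sp$train, 16)
  expect_length(sp$test, 4)
  g <- function(ids) table(clin$nhg[clin$patient_id %in% ids])
  expect_equal(unname(c(g(sp$train))), c(8, 8))
  expect_equal(unname(c(g(sp$test))), c(2, 2))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(split_patients(clin, 0.8, seed = 5), sp)
  expect_error(split_patients(clin[clin$nhg == 1, ][1, ], 0.8, 1), "at least 2")
})

test_that("class weights follow the inverse-frequency rule", {
  expect_equal(unname(class_weights(rep(c(0, 1), 25))), c(1, 1))
  w <- class_weights(rep(c(0, 1), c(162, 269)))
  expect_equal(unname(w["w0"] / w["w1"]), 269 / 162)
  expect_equal(unname(mean(w)), 1)
  expect_error(class_weights(rep(1, 10)), "both classes")
})

test_that("roc_auc matches the all-pairs statistic on random instances", {
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 0, 1)), 0.75)
  expect_equal(roc_auc(rep(0.3, 8), rep(c(0, 1), 4)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  set.seed(40)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force some ties
    expect_equal(roc_auc(scores, labels), auc_all_pairs(scores, labels))
  }
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  for (i in 1:20) {
    labels <- c(0, 1, sample(0:1, 30, replace = TRUE))
    scores <- round(runif(32), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, labels), ref)
  }
})

test_that("youden_threshold equals an exhaustive scan and uses >= at ties", {
  r <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(r$threshold, 0.5)
  expect_equal(r$youden_j, 1)
  expect_equal(r$youden_j, r$sensitivity + r$specificity - 1)

  # two optima at J = 0.5; the smaller threshold wins
  r2 <- youden_threshold(c(0.2, 0.4, 0.6, 0.8), c(0, 1, 0, 1))
  expect_equal(r2$threshold, 0.3)
  expect_equal(r2$youden_j, 0.5)

  expect_error(youden_threshold(1:3, c(1, 1, 1)), "both classes")

  set.seed(42)
  for (i in 1:200) {
    n <- sample(4:40, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(1:2, 1))
    got <- youden_threshold(scores, labels)
    ref <- youden_scan(scores, labels)
    expect_equal(got$threshold, ref$threshold)
    expect_equal(got$youden_j, ref$youden_j)
    expect_true(got$youden_j >= -1 && got$youden_j <= 1)
  }
})

test_that("the bootstrap AUC interval is stratified, ordered, deterministic", {
  scores <- c(0.05, 0.1, 0.2, 0.85, 0.9, 0.95)
  labels <- c(0, 0, 0, 1, 1, 1)
  r <- bootstrap_auc_ci(scores, labels, B = 200, seed = 9)
  expect_equal(r$ci_low, 1.0)   # every stratified resample separates
  expect_equal(r$ci_high, 1.0)
  expect_equal(r$auc, 1.0)
  set.seed(43)
  sc <- runif(40); lb <- rep(0:1, 20)
  r1 <- bootstrap_auc_ci(sc, lb, B = 300, seed = 4)
  r2 <- bootstrap_auc_ci(sc, lb, B = 300, seed = 4)
  expect_identical(r1[c("auc", "ci_low", "ci_high")],
                   r2[c("auc", "ci_low", "ci_high")])
  expect_lte(r1$ci_low, r1$auc + 1e-9)
  expect_gte(r1$ci_high, r1$auc - 1e-9)
  expect_warning(bootstrap_auc_ci(sc, lb, B = 50, seed = 1), "unstable")
})

test_that("training overfits a small labelled set and is reproducible", {
  coh <- small_cohort()
  crops <- cohort_crops(coh)
  clin <- coh$clinical[coh$clinical$nhg %in% c(1L, 3L), ]
  labels <- setNames(as.integer(clin$nhg == 3L), clin$patient_id)
  set.seed(50)
  samples <- unlist(lapply(clin$patient_id, function(pid)
    make_training_slices(crops[[pid]], 4, label = labels[[pid]])),
    recursive = FALSE)
  model <- build_grade_cnn(seed = 11)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 8, epochs = 40,
                      seed = 12)
  tr <- train_cnn(model, samples, cfg)
  expect_length(tr$loss_history, 40)
  p <- predict(tr$model, samples)
  y <- vapply(samples, `[[`, 0L, "label")
  expect_equal(mean((p >= 0.5) == (y == 1)), 1.0)  # overfit sanity
  expect_lt(tr$loss_history[40], tr$loss_history[1])

  # byte-identical reruns under one seed
  cfg2 <- train_config(learning_rate = 1e-3, batch_size = 8, epochs = 3,
                       seed = 12)
  t1 <- train_cnn(build_grade_cnn(seed = 11), samples, cfg2)
  t2 <- train_cnn(build_grade_cnn(seed = 11), samples, cfg2)
  expect_identical(t1$loss_history, t2$loss_history)
  expect_identical(t1$model$weights, t2$model$weights)

  expect_error(train_cnn(model, list(), cfg), "no training samples")
})

test_that("patient scoring emits one ordered score per patient", {
  coh <- small_cohort()
  crops <- cohort_crops(coh)
  m <- fresh_model()
  ids <- names(crops)[c(3, 1, 2)]
  sc <- score_patients(m, crops, ids)
  expect_equal(sc$patient_id, ids)
  expect_true(all(sc$score > 0 & sc$score < 1))
  # identical images give identical scores
  crops2 <- crops; crops2[["DUP"]] <- crops[[ids[1]]]
  sc2 <- score_patients(m, crops2, c(ids[1], "DUP"))
  expect_equal(sc2$score[1], sc2$score[2])
  expect_warning(score_patients(m, crops, c(ids, "MISSING")), "skipped")
})

test_that("the slices-per-patient sweep emits a full report", {
  spec <- cohort_spec(n_per_grade = c(6, 0, 6), seed = 77)
  coh <- simulate_cohort(spec, keep_volumes = FALSE)
  cfg <- train_config(learning_rate = 5e-4, batch_size = 16, epochs = 2,
                      seed = 3)
  rep <- sweep_slices(coh, ks = c(4L, 6L), config = cfg, B = 100)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$slices_per_patient, c(4L, 6L))
  expect_true(all(rep$auc_train >= 0 & rep$auc_train <= 1))
  expect_true(all(rep$ci_test_low <= rep$auc_test + 1e-9 &
                    rep$auc_test <= rep$ci_test_high + 1e-9))
})
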