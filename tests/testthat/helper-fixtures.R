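# shared fixtures, built once per test run

# a small study whose four phases are given directly
toy_study <- function(pre, post1, post2, post3, patient_id = "T001",
                      spacing = c(1, 1, 1)) {
  phases <- list(pre = pre, post1 = post1, post2 = post2, post3 = post3)
  structure(
    list(patient_id = patient_id, phases = phases,
         voxel_spacing_mm = spacing,
         centroid_index = round(dim(pre) / 2),
         superior_is_increasing = TRUE),
    class = "dce_study"
  )
}

# a crop filled with a constant per slice (slice s has value s - 1, i.e. the
# 0-based slice index), for indexing tests
indexed_crop <- function() {
  x <- array(0, dim = c(3, 14, 64, 64))
  for (s in 1:14) x[, s, , ] <- s - 1
  structure(list(x = x, patient_id = "IDX", origin = c(1, 1, 1)),
            class = "tumor_crop")
}

.fixture_env <- new.env(parent = emptyenv())

# small reusable cohort (volumes kept) for preprocessing / stratification
small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- simulate_cohort(
      cohort_spec(n_per_grade = c(4L, 6L, 4L), seed = 400L))
  }
  .fixture_env$small
}

# an untrained network shared across model tests
fresh_model <- function() {
  if (is.null(.fixture_env$model))
    .fixture_env$model <- build_grade_cnn(model_config(), seed = 99L)
  .fixture_env$model
}
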