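test_that("latent aggressiveness follows the grade-specific distributions", {
  set.seed(1)
  draws <- function(g, n) vapply(seq_len(n),
                                 function(i) sample_latent(g)$aggressiveness,
                                 numeric(1))
  a1 <- draws(1, 2000); a3 <- draws(3, 2000); a2 <- draws(2, 2000)
  expect_true(all(a1 >= 0 & a1 <= 1))
  expect_true(all(a2 >= 0 & a2 <= 1))
  # Beta(2,8) and Beta(8,2) means
  expect_equal(mean(a1), 0.2, tolerance = 0.05)
  expect_equal(mean(a3), 0.8, tolerance = 0.05)
  expect_equal(mean(a2), 0.5, tolerance = 0.05)
  expect_error(sample_latent(5), "unknown grade")
  expect_error(sample_latent(0), "unknown grade")
})

test_that("imaging parameters are monotone in aggressiveness before noise", {
  a <- seq(0, 1, by = 0.01)
  mu <- latent_means(a)
  for (v in names(mu)) expect_true(all(diff(mu[[v]]) >= 0), info = v)
})

test_that("rendered tumours enhance, wash out, and have the right volume", {
  spec0 <- cohort_spec(n_per_grade = c(1, 0, 0), noise_sd = 0)
  latent <- structure(
    list(grade = 1L, aggressiveness = 0.5, radius_mm = 8,
         washin_amplitude = 1.0, washout_rate = 1.0, rim_fraction = 0,
         margin_irregularity = 0),
    class = "latent_tumor")
  set.seed(2)
  study <- render_dce(latent, spec0, centroid_index = c(16, 48, 48))

  # tumour mask from geometry: exact 8 mm sphere at (2,1,1) mm spacing
  shp <- spec0$image_shape
  dz <- ((1:shp[1]) - 16) * 2
  dy <- ((1:shp[2]) - 48); dx <- ((1:shp[3]) - 48)
  r2 <- outer(outer(dz^2, dy^2, `+`), dx^2, `+`)
  mask <- r2 <= 8^2
  vol_mm3 <- sum(mask) * prod(spec0$voxel_spacing_mm)
  expect_lt(abs(vol_mm3 - 4 / 3 * pi * 8^3) / (4 / 3 * pi * 8^3), 0.10)

  # enhancement: post1 above pre inside the tumour
  expect_gt(mean(study$phases$post1[mask]), mean(study$phases$pre[mask]))
  # washout at rate 1: post3 below post1 in the core
  core <- r2 <= (0.5 * 8)^2
  expect_lt(mean(study$phases$post3[core]), mean(study$phases$post1[core]))
  # and the kinetic curve is exact with zero noise: S(p)/S0 - 1
  s0 <- study$phases$pre[16, 48, 48]
  e1 <- study$phases$post1[16, 48, 48] / s0 - 1
  e3 <- study$phases$post3[16, 48, 48] / s0 - 1
  expect_equal(e3 / e1, (1 - 0.3^3) / (1 - 0.3^1) * exp(-1 * 2),
               tolerance = 1e-10)

  # a tumour too large for its centroid is rejected
  expect_error(render_dce(latent, spec0, centroid_index = c(3, 48, 48)),
               "exceeds the volume")
})

test_that("clinical covariates shift with aggressiveness as specified", {
  lat <- function(a) structure(
    list(grade = 2L, aggressiveness = a, radius_mm = 8,
         washin_amplitude = 1, washout_rate = 0.2, rim_fraction = 0.5,
         margin_irregularity = 0.1),
    class = "latent_tumor")
  set.seed(3)
  n <- 3000
  low <- dplyr::bind_rows(lapply(seq_len(n), function(i) sample_clinical(lat(0))))
  high <- dplyr::bind_rows(lapply(seq_len(n), function(i) sample_clinical(lat(1))))
  # stated mean age difference of 6 years
  expect_equal(mean(low$age) - mean(high$age), 6, tolerance = 0.8)
  # logistic links: more advanced T stage and more TNBC at high a
  expect_gt(mean(high$t_stage %in% c("2", "3", "4")),
            mean(low$t_stage %in% c("2", "3", "4")))
  expect_gt(mean(high$subtype == "ER-/HER2-"), mean(low$subtype == "ER-/HER2-"))
  # subscores always map back to the generating grade
  expect_true(all(nhg_from_subscores(low$tubule, low$pleomorphism,
                                     low$mitotic) == 2L))
  expect_true(all(nhg_from_subscores(high$tubule, high$pleomorphism,
                                     high$mitotic) == 2L))
})

test_that("grade banding and subtype derivation are deterministic rules", {
  expect_equal(nhg_from_subscores(1, 1, 1), 1L)
  expect_equal(nhg_from_subscores(2, 2, 2), 2L)
  expect_equal(nhg_from_subscores(3, 3, 3), 3L)
  expect_equal(nhg_from_subscores(c(1, 3), c(2, 3), c(2, 2)), c(1L, 3L))
  expect_error(nhg_from_subscores(0, 1, 1), "outside")
  expect_equal(molecular_subtype(c(1, 1, 0, 0), c(0, 1, 1, 0)),
               c("ER+/HER2-", "ER+/HER2+", "ER-/HER2+", "ER-/HER2-"))
})

test_that("survival sampling matches the exponential/censoring construction", {
  spec0 <- cohort_spec(hazard_baseline = 0.02, beta_aggressiveness = 0,
                       beta_t2 = 0, beta_node = 0, beta_tnbc = 0,
                       censor_window_months = c(1e5, 1e5 + 1))
  lat <- function(a) structure(
    list(grade = 2L, aggressiveness = a, radius_mm = 8, washin_amplitude = 1,
         washout_rate = 0.2, rim_fraction = 0.5, margin_irregularity = 0.1),
    class = "latent_tumor")
  clin <- tibble::tibble(t_stage = "1", n_stage = "0", subtype = "ER+/HER2-")
  set.seed(4)
  recs <- dplyr::bind_rows(lapply(1:4000, function(i)
    sample_survival(lat(0.5), clin, spec0)))
  # essentially no censoring: median equals ln(2)/h
  expect_equal(median(recs$followup_months), log(2) / 0.02, tolerance = 0.1)
  expect_true(all(recs$followup_months <= 1e5 + 1))

  # with the default window, follow-up never exceeds the censor bound
  specd <- cohort_spec()
  set.seed(5)
  recs2 <- dplyr::bind_rows(lapply(1:500, function(i)
    sample_survival(lat(0.9), clin, specd)))
  expect_true(all(recs2$followup_months <= specd$censor_window_months[2]))

  # beta_aggressiveness = 0: event times at a = 0.1 and a = 0.9 are
  # indistinguishable
  set.seed(6)
  t_lo <- vapply(1:2000, function(i)
    sample_survival(lat(0.1), clin, spec0)$followup_months, numeric(1))
  t_hi <- vapply(1:2000, function(i)
    sample_survival(lat(0.9), clin, spec0)$followup_months, numeric(1))
  expect_gt(suppressWarnings(ks.test(t_lo, t_hi)$p.value), 0.01)

  bad <- spec0; bad$hazard_baseline <- 0
  expect_error(sample_survival(lat(0.5), clin, bad), "positive")
})

test_that("cohort generation is deterministic, complete, and guarded", {
  spec5 <- cohort_spec(n_per_grade = c(5, 5, 5), seed = 123)
  c1 <- simulate_cohort(spec5)
  c2 <- simulate_cohort(spec5)
  expect_identical(c1$clinical, c2$clinical)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  utils::write.csv(c1$clinical, f1, row.names = FALSE)
  utils::write.csv(c2$clinical, f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  expect_equal(nrow(c1$clinical), 15)
  expect_length(c1$studies, 15)
  expect_true(all(vapply(c1$studies, function(s) length(s$phases), 1L) == 4L))
  expect_setequal(c1$clinical$nhg, c(1L, 2L, 3L))

  expect_error(cohort_spec(n_per_grade = c(0, 0, 0)) |> simulate_cohort(),
               "zero patients")
  # crops-only generation leaves the clinical table untouched
  c3 <- simulate_cohort(spec5, keep_volumes = FALSE)
  expect_identical(c1$clinical, c3$clinical)
  expect_null(c3$studies)
  expect_equal(dim(c3$crops[[1]]$x), c(3L, 14L, 64L, 64L))
})

test_that("grade 1 and grade 3 separate on simple kinetic features", {
  # the learnability guarantee behind the CNN task: a linear classifier on
  # (tumour volume, wash-in, late-phase change) separates the extreme grades
  set.seed(7)
  spec0 <- cohort_spec()
  feature_row <- function(grade) {
    latent <- sample_latent(grade)
    study <- render_dce(latent, spec0)
    ci <- study$centroid_index
    enh <- study$phases$post1 - study$phases$pre
    mask <- enh > 25   # enhancing voxels ~ tumour
    c(volume = sum(mask),
      washin = mean(enh[mask]),
      late = mean((study$phases$post3 - study$phases$post1)[mask]))
  }
  n <- 100
  feats <- rbind(t(vapply(1:n, function(i) feature_row(1), numeric(3))),
                 t(vapply(1:n, function(i) feature_row(3), numeric(3))))
  y <- rep(c(0, 1), each = n)
  df <- data.frame(feats, y = y)
  fit <- suppressWarnings(stats::glm(y ~ volume + washin + late, data = df,
                                     family = "binomial"))
  expect_gt(roc_auc(stats::fitted(fit), y), 0.9)
})

test_that("the survival generator reproduces its own hazard ratio and curve", {
  spec0 <- cohort_spec(beta_aggressiveness = 1.5, beta_t2 = 0, beta_node = 0,
                       beta_tnbc = 0)
  lat <- function(a) structure(
    list(grade = 2L, aggressiveness = a, radius_mm = 8, washin_amplitude = 1,
         washout_rate = 0.2, rim_fraction = 0.5, margin_irregularity = 0.1),
    class = "latent_tumor")
  clin <- tibble::tibble(t_stage = "1", n_stage = "0", subtype = "ER+/HER2-")
  set.seed(8)
  n <- 1000
  arm <- function(a) dplyr::bind_rows(lapply(seq_len(n), function(i)
    sample_survival(lat(a), clin, spec0)))
  lo <- arm(0.2); hi <- arm(0.9)
  dat <- dplyr::bind_rows(dplyr::mutate(lo, g = 0), dplyr::mutate(hi, g = 1))
  fit <- survival::coxph(survival::Surv(followup_months, event) ~ g,
                         data = dat)
  # true log-HR between the arms is 1.5 * 0.7
  expect_equal(unname(fit$coefficients), 1.5 * 0.7, tolerance = 0.15)

  # KM on each arm tracks the exponential survivor within binomial error
  for (a in c(0.2, 0.9)) {
    d <- if (a == 0.2) lo else hi
    km <- km_estimate(d$followup_months, d$event)
    h <- spec0$hazard_baseline * exp(1.5 * a)
    at <- km$time <= stats::quantile(d$followup_months, 0.8)
    s_true <- exp(-h * km$time[at])
    tol <- 3 * sqrt(pmax(s_true * (1 - s_true), 0.002) / n)
    expect_true(all(abs(km$estimate[at] - s_true) < pmax(tol, 0.04)))
  }
})

test_that("a cohort round-trips through NIfTI + CSV on disk", {
  coh <- simulate_cohort(cohort_spec(n_per_grade = c(1, 0, 1), seed = 31))
  dir <- tempfile("cohort_")
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "clinical.csv")))
  expect_true(file.exists(file.path(dir, "spec.json")))
  expect_length(list.files(dir, pattern = "nii.gz$"), 8)
  back <- read_cohort(dir)
  expect_equal(back$clinical$patient_id, coh$clinical$patient_id)
  expect_equal(back$clinical$followup_months, coh$clinical$followup_months)
  expect_equal(back$studies[[1]]$phases$post2, coh$studies[[1]]$phases$post2,
               tolerance = 1e-6)
  expect_equal(back$spec$n_per_grade, coh$spec$n_per_grade)
  unlink(dir, recursive = TRUE)
})
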