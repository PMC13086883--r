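#' Latent tumour model
#'
#' Each synthetic tumour is governed by a single latent aggressiveness score
#' `a` in \[0, 1\]: grade-1 tumours draw `a` from Beta(2, 8) (mean 0.2),
#' grade-3 tumours from Beta(8, 2) (mean 0.8), and grade-2 tumours uniformly
#' on \[0, 1\], so the intermediate grade genuinely spans "grade-1-like" to
#' "grade-3-like" biology and sub-stratification has a recoverable ground
#' truth. The imaging parameters are monotone maps of `a` plus bounded
#' uniform noise: more aggressive tumours are larger, enhance more strongly,
#' wash out faster, show stronger rim enhancement and have more irregular
#' margins.
#'
#' @param grade tumour grade, 1, 2 or 3.
#' @return A list of class `latent_tumor` with fields `grade`,
#'   `aggressiveness`, `radius_mm`, `washin_amplitude`, `washout_rate`
#'   (per phase interval), `rim_fraction` and `margin_irregularity`.
#' @seealso [latent_means()] for the deterministic (noise-free) parameter
#'   maps.
#' @export
sample_latent <- function(grade) {
  if (length(grade) != 1L || !grade %in% c(1, 2, 3))
    stop("unknown grade: ", format(grade), " (must be 1, 2 or 3)",
         call. = FALSE)
  a <- switch(as.character(grade),
    "1" = rbeta(1, 2, 8),
    "2" = runif(1),
    "3" = rbeta(1, 8, 2)
  )
  mu <- latent_means(a)
  structure(
    list(
      grade = as.integer(grade),
      aggressiveness = a,
      radius_mm = clip(mu$radius_mm + runif(1, -1, 1), 3, 13),
      washin_amplitude = max(mu$washin_amplitude + runif(1, -0.1, 0.1), 0.1),
      washout_rate = max(mu$washout_rate + runif(1, -0.05, 0.05), 0),
      rim_fraction = clip(mu$rim_fraction + runif(1, -0.05, 0.05), 0, 1),
      margin_irregularity = max(mu$margin_irregularity + runif(1, -0.03, 0.03), 0)
    ),
    class = "latent_tumor"
  )
}

#' Deterministic imaging-parameter maps
#'
#' The noise-free component of the latent model: every map is non-decreasing
#' in aggressiveness, which is what links image phenotype to outcome in the
#' synthetic cohorts.
#'
#' @param a aggressiveness in \[0, 1\] (vectorised).
#' @return A list of numeric vectors: `radius_mm`, `washin_amplitude`,
#'   `washout_rate`, `rim_fraction`, `margin_irregularity`.
#' @export
latent_means <- function(a) {
  list(
    radius_mm = 5 + 7 * a,
    washin_amplitude = 0.6 + 0.8 * a,
    washout_rate = 0.45 * a,
    rim_fraction = clip(0.15 + 0.6 * a, 0, 1),
    margin_irregularity = 0.25 * a
  )
}

# Wash-in profile of the 3-point post-contrast curve: fraction of the peak
# enhancement reached at phase p (p = 1, 2, 3). Saturating, bounded by 1.
phase_rise <- function(p) 1 - 0.3^p

#' Render a 4-phase DCE phantom study
#'
#' Builds one patient's pre-contrast + 3 post-contrast volumes. Background
#' parenchyma sits at a baseline of 100 with mild uniform enhancement; the
#' tumour is an irregular sphere (its radius is modulated over direction by
#' smooth angular noise scaled by `margin_irregularity`) whose voxels follow
#' the discrete wash-in/washout curve
#' \deqn{S(p) = S_0 (1 + E_v \, r(p) \, e^{-w (p-1)}), \quad p = 1, 2, 3,}
#' where \eqn{r(p) = 1 - 0.3^p} is a saturating wash-in profile, `w` the
#' washout rate, and the local enhancement amplitude \eqn{E_v} is boosted in
#' an outer rim shell (and damped in the core) in proportion to
#' `rim_fraction`. The pre-contrast phase carries no enhancement term.
#' Additive Gaussian noise with sd `spec$noise_sd` is applied to every
#' phase.
#'
#' @param latent a `latent_tumor`.
#' @param spec a [cohort_spec()].
#' @param patient_id identifier stored with the study.
#' @param centroid_index optional integer (slice, row, col) tumour centroid;
#'   by default the volume centre jittered by up to 2 voxels.
#' @return An object of class `dce_study`: list with `patient_id`, `phases`
#'   (list of 4 arrays `pre`, `post1`, `post2`, `post3`),
#'   `voxel_spacing_mm`, `centroid_index`, and `superior_is_increasing`
#'   (slice-axis orientation flag).
#' @export
render_dce <- function(latent, spec, patient_id = "P0001",
                       centroid_index = NULL) {
  shp <- spec$image_shape
  sp <- spec$voxel_spacing_mm
  if (is.null(centroid_index)) {
    centroid_index <- round(shp / 2) + sample(-2:2, 3, replace = TRUE)
  }
  centroid_index <- as.integer(centroid_index)
  if (any(centroid_index < 1L) || any(centroid_index > shp))
    stop("centroid_index outside the volume", call. = FALSE)

  r_max <- latent$radius_mm * (1 + latent$margin_irregularity)
  half_extent_vox <- ceiling(r_max / sp)
  if (any(centroid_index - half_extent_vox < 1L) ||
      any(centroid_index + half_extent_vox > shp))
    stop("tumour (radius ", signif(r_max, 3),
         " mm) exceeds the volume bounds at this centroid", call. = FALSE)

  # smooth angular margin perturbation: low-order directional harmonics with
  # random coefficients, clipped to [-1, 1]
  cf <- runif(4, -0.5, 0.5)
  bg_enhancement <- clip(rnorm(1, 0.10, 0.02), 0.02, 0.2)

  # bounding box around the tumour
  lo <- centroid_index - half_extent_vox
  hi <- centroid_index + half_extent_vox
  dz <- (lo[1]:hi[1] - centroid_index[1]) * sp[1]
  dy <- (lo[2]:hi[2] - centroid_index[2]) * sp[2]
  dx <- (lo[3]:hi[3] - centroid_index[3]) * sp[3]
  g <- expand.grid(dz = dz, dy = dy, dx = dx, KEEP.OUT.ATTRS = FALSE)
  r <- sqrt(g$dz^2 + g$dy^2 + g$dx^2)
  with_r <- r > 0
  theta <- ifelse(with_r, acos(clip(g$dz / pmax(r, 1e-12), -1, 1)), 0)
  phi <- atan2(g$dy, g$dx)
  f <- clip(cf[1] * sin(theta) * cos(phi) +
              cf[2] * sin(theta) * sin(phi) +
              cf[3] * cos(theta) +
              cf[4] * sin(2 * theta) * cos(phi), -1, 1)
  r_local <- latent$radius_mm * (1 + latent$margin_irregularity * f)
  inside <- r <= r_local

  s0_bg <- 100
  s0_tum <- 110
  rim_thickness <- 0.3
  in_rim <- inside & (r >= (1 - rim_thickness) * r_local)
  ev <- numeric(length(r))
  ev[inside] <- latent$washin_amplitude * (1 - 0.3 * latent$rim_fraction)
  ev[in_rim] <- latent$washin_amplitude * (1 + latent$rim_fraction)

  nvox <- prod(shp)
  box_dim <- hi - lo + 1L
  box_index <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3],
                                     KEEP.OUT.ATTRS = FALSE))
  flat <- box_index[, 1] + (box_index[, 2] - 1L) * shp[1] +
    (box_index[, 3] - 1L) * shp[1] * shp[2]

  phases <- vector("list", 4L)
  names(phases) <- c("pre", "post1", "post2", "post3")
  for (p in 0:3) {
    vol <- rep(s0_bg, nvox)
    if (p >= 1) vol <- vol * (1 + bg_enhancement * phase_rise(p))
    tum <- rep(s0_tum, length(r))
    if (p >= 1) {
      tum <- s0_tum * (1 + ev * phase_rise(p) *
                         exp(-latent$washout_rate * (p - 1)))
    }
    vol[flat[inside]] <- tum[inside]
    if (spec$noise_sd > 0) vol <- vol + rnorm(nvox, 0, spec$noise_sd)
    phases[[p + 1L]] <- array(vol, dim = shp)
  }

  structure(
    list(
      patient_id = patient_id,
      phases = phases,
      voxel_spacing_mm = sp,
      centroid_index = centroid_index,
      superior_is_increasing = TRUE
    ),
    class = "dce_study"
  )
}

#' @export
print.dce_study <- function(x, ...) {
  cat("<dce_study>", x$patient_id, "-", length(x$phases), "phases of",
      paste(dim(x$phases[[1]]), collapse = " x "), "voxels, centroid (",
      paste(x$centroid_index, collapse = ", "), ")\n")
  invisible(x)
}

# subscore compositions (tubule, pleomorphism, mitotic in 1..3) for each sum
subscore_compositions <- function(total) {
  g <- expand.grid(t = 1:3, p = 1:3, m = 1:3)
  g[g$t + g$p + g$m == total, , drop = FALSE]
}

#' Sample a clinical record linked to a latent tumour
#'
#' Covariates shift with aggressiveness `a` in the directions seen in
#' real grade-stratified breast-cancer cohorts: age decreases (mean
#' `56 - 6 a`), the probabilities of T stage >= 2 and nodal invasion rise on
#' the logistic scale, ER positivity falls and HER2 positivity rises, so the
#' triple-negative fraction grows with `a`. The three Nottingham subscores
#' are drawn inside the grade's band (sums 3-5, 6-7 or 8-9), tilted towards
#' the top of the band as `a` grows, so the recorded grade always maps back
#' to the generating grade.
#'
#' @param latent a `latent_tumor`.
#' @param patient_id identifier.
#' @return One-row tibble with the clinical columns (`age`, `t_stage`,
#'   `n_stage`, `m_stage`, `er`, `pr`, `her2`, `subtype`, `tubule`,
#'   `pleomorphism`, `mitotic`, `nhg`).
#' @export
sample_clinical <- function(latent, patient_id = "P0001") {
  a <- latent$aggressiveness
  age <- rnorm(1, 56 - 6 * a, 10)

  t_ge2 <- runif(1) < plogis(-1 + 2.2 * a)
  t_stage <- if (!t_ge2) "1" else sample(c("2", "3", "4"), 1,
                                         prob = c(0.75, 0.20, 0.05))
  if (runif(1) < 0.01) t_stage <- "X"

  n_ge1 <- runif(1) < plogis(-1.2 + 1.6 * a)
  n_stage <- if (!n_ge1) "0" else sample(c("1", "2", "3"), 1,
                                         prob = c(0.70, 0.20, 0.10))
  if (runif(1) < 0.02) n_stage <- "X"

  m_stage <- sample(c("0", "1", "X"), 1,
                    prob = c(0.96 - 0.04 * a, 0.01 + 0.04 * a, 0.03))

  er <- as.integer(runif(1) < plogis(2.5 - 3 * a))
  her2 <- as.integer(runif(1) < (0.10 + 0.15 * a))
  pr <- if (er == 1L) as.integer(runif(1) < 0.85) else as.integer(runif(1) < 0.05)

  band <- list(`1` = c(3L, 5L), `2` = c(6L, 7L), `3` = c(8L, 9L))[[as.character(latent$grade)]]
  total <- band[1] + rbinom(1, band[2] - band[1], clip(a, 0.02, 0.98))
  comp <- subscore_compositions(total)
  pick <- comp[sample(nrow(comp), 1), ]
  nhg <- nhg_from_subscores(pick$t, pick$p, pick$m)
  stopifnot(nhg == latent$grade)

  tibble(
    patient_id = patient_id,
    age = age,
    t_stage = t_stage,
    n_stage = n_stage,
    m_stage = m_stage,
    er = er, pr = pr, her2 = her2,
    subtype = molecular_subtype(er, her2),
    tubule = pick$t, pleomorphism = pick$p, mitotic = pick$m,
    nhg = nhg
  )
}

#' Nottingham grade from its subscores
#'
#' Sums tubule formation, nuclear pleomorphism and mitotic count (each 1-3)
#' and maps 3-5 to grade 1, 6-7 to grade 2, 8-9 to grade 3.
#'
#' @param tubule,pleomorphism,mitotic integer subscores in 1..3
#'   (vectorised).
#' @return Integer grade vector.
#' @export
nhg_from_subscores <- function(tubule, pleomorphism, mitotic) {
  s <- tubule + pleomorphism + mitotic
  if (any(s < 3 | s > 9)) stop("subscore sum outside 3..9", call. = FALSE)
  ifelse(s <= 5, 1L, ifelse(s <= 7, 2L, 3L))
}

#' Molecular subtype from receptor status
#'
#' Deterministic ER/HER2 classification into the four standard categories.
#'
#' @param er,her2 binary receptor indicators (vectorised).
#' @return Character vector with levels `ER+/HER2-`, `ER+/HER2+`,
#'   `ER-/HER2+`, `ER-/HER2-`.
#' @export
molecular_subtype <- function(er, her2) {
  dplyr::case_when(
    er == 1 & her2 == 0 ~ "ER+/HER2-",
    er == 1 & her2 == 1 ~ "ER+/HER2+",
    er == 0 & her2 == 1 ~ "ER-/HER2+",
    TRUE ~ "ER-/HER2-"
  )
}

#' Sample a censored recurrence-free-survival record
#'
#' Event times are exponential with hazard
#' \deqn{h = h_0 \exp(\beta_a a + \beta_{T2} 1[T \ge 2] + \beta_N 1[N \ge 1]
#'   + \beta_{TNBC} 1[ER-/HER2-]),}
#' censoring times uniform on the spec's censor window; follow-up is the
#' minimum of the two and the event indicator records whether the event came
#' first.
#'
#' @param latent a `latent_tumor`.
#' @param clinical the matching one-row clinical tibble.
#' @param spec a [cohort_spec()].
#' @return One-row tibble `followup_months`, `event`.
#' @export
sample_survival <- function(latent, clinical, spec) {
  if (!is.finite(spec$hazard_baseline) || spec$hazard_baseline <= 0)
    stop("`hazard_baseline` must be positive", call. = FALSE)
  h <- spec$hazard_baseline * exp(
    spec$beta_aggressiveness * latent$aggressiveness +
      spec$beta_t2 * as.numeric(clinical$t_stage %in% c("2", "3", "4")) +
      spec$beta_node * as.numeric(clinical$n_stage %in% c("1", "2", "3")) +
      spec$beta_tnbc * as.numeric(clinical$subtype == "ER-/HER2-")
  )
  t_event <- rexp(1, rate = h)
  t_censor <- runif(1, spec$censor_window_months[1], spec$censor_window_months[2])
  tibble(
    followup_months = min(t_event, t_censor),
    event = as.integer(t_event <= t_censor)
  )
}

#' Generate a complete synthetic cohort
#'
#' Draws `sum(spec$n_per_grade)` patients; for each one a latent tumour, a
#' 4-phase DCE phantom study, a clinical record and a censored survival
#' record. The whole cohort is a deterministic function of the spec
#' (all randomness is drawn from R's generator seeded with `spec$seed`).
#'
#' With `keep_volumes = FALSE` each study is immediately normalised,
#' reduced to the three post-contrast phases and cropped to the standard
#' 3 x 14 x 64 x 64 tumour window (see [crop_tumor()]), and the full
#' volumes are discarded; this keeps a several-hundred-patient cohort in a
#' few hundred MB. The clinical table is identical either way.
#'
#' @param spec a [cohort_spec()].
#' @param keep_volumes keep the full 4-phase volumes (`$studies`)? If
#'   `FALSE`, only the tumour crops (`$crops`) are kept.
#' @return An object of class `dce_cohort`: list with `clinical` (tibble:
#'   identifiers, latent truth `latent_a`, imaging centroid, clinical and
#'   survival columns), `studies` (named list of `dce_study` or `NULL`),
#'   `crops` (named list of `tumor_crop` or `NULL`) and `spec`.
#' @export
simulate_cohort <- function(spec, keep_volumes = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_total <- sum(spec$n_per_grade)
  if (n_total == 0L) stop("cohort spec requests zero patients", call. = FALSE)
  set.seed(spec$seed)

  grades <- rep.int(1:3, spec$n_per_grade)
  ids <- sprintf("P%04d", seq_len(n_total))
  studies <- if (keep_volumes) vector("list", n_total) else NULL
  crops <- if (!keep_volumes) vector("list", n_total) else NULL
  rows <- vector("list", n_total)

  for (i in seq_len(n_total)) {
    latent <- sample_latent(grades[i])
    study <- render_dce(latent, spec, patient_id = ids[i])
    clin <- sample_clinical(latent, patient_id = ids[i])
    surv <- sample_survival(latent, clin, spec)
    rows[[i]] <- dplyr::bind_cols(
      clin, surv,
      tibble(
        centroid_slice = study$centroid_index[1],
        centroid_row = study$centroid_index[2],
        centroid_col = study$centroid_index[3],
        latent_a = latent$aggressiveness
      )
    )
    if (keep_volumes) {
      studies[[i]] <- study
    } else {
      crops[[i]] <- crop_tumor(select_input_phases(normalize_phases(study)),
                               study$centroid_index)
    }
  }

  clinical <- dplyr::bind_rows(rows)
  if (keep_volumes) names(studies) <- ids else names(crops) <- ids
  structure(
    list(clinical = clinical, studies = studies, crops = crops, spec = spec),
    class = "dce_cohort"
  )
}

#' @export
print.dce_cohort <- function(x, ...) {
  cat("<dce_cohort>", nrow(x$clinical), "patients (",
      paste(x$spec$n_per_grade, collapse = "/"), "per grade ),",
      if (is.null(x$studies)) "crops only" else "full volumes", "\n")
  invisible(x)
}

#' Write a cohort to disk
#'
#' Volumes go out as one NIfTI file per phase (`<pid>_phase0.nii.gz` ..
#' `_phase3.nii.gz`), the clinical table as `clinical.csv`, and the
#' generator parameters as `spec.json`, so an exported cohort is
#' self-describing.
#'
#' @param cohort a `dce_cohort` generated with `keep_volumes = TRUE`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dce_cohort"))
  if (is.null(cohort$studies))
    stop("cohort was generated without full volumes; nothing to export",
         call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (study in cohort$studies) {
    for (p in 0:3) {
      img <- RNifti::asNifti(study$phases[[p + 1L]],
                             pixdim = study$voxel_spacing_mm)
      RNifti::writeNifti(img, file.path(dir, sprintf("%s_phase%d.nii.gz",
                                                     study$patient_id, p)))
    }
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  spec_out <- cohort$spec
  class(spec_out) <- NULL
  jsonlite::write_json(spec_out, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `clinical.csv`, `spec.json` and the
#'   per-phase NIfTI files.
#' @return A `dce_cohort` with full volumes.
#' @export
read_cohort <- function(dir) {
  clinical <- as_tibble(utils::read.csv(file.path(dir, "clinical.csv"),
                                        colClasses = c(t_stage = "character",
                                                       n_stage = "character",
                                                       m_stage = "character")))
  sp <- jsonlite::read_json(file.path(dir, "spec.json"), simplifyVector = TRUE)
  spec <- cohort_spec(
    n_per_grade = sp$n_per_grade, image_shape = sp$image_shape,
    voxel_spacing_mm = sp$voxel_spacing_mm, noise_sd = sp$noise_sd,
    hazard_baseline = sp$hazard_baseline,
    beta_aggressiveness = sp$beta_aggressiveness, beta_t2 = sp$beta_t2,
    beta_node = sp$beta_node, beta_tnbc = sp$beta_tnbc,
    censor_window_months = sp$censor_window_months, seed = sp$seed
  )
  studies <- lapply(seq_len(nrow(clinical)), function(i) {
    pid <- clinical$patient_id[i]
    phases <- lapply(0:3, function(p) {
      img <- RNifti::readNifti(file.path(dir, sprintf("%s_phase%d.nii.gz",
                                                      pid, p)))
      array(as.numeric(img), dim = dim(img))
    })
    names(phases) <- c("pre", "post1", "post2", "post3")
    structure(
      list(patient_id = pid, phases = phases,
           voxel_spacing_mm = spec$voxel_spacing_mm,
           centroid_index = c(clinical$centroid_slice[i],
                              clinical$centroid_row[i],
                              clinical$centroid_col[i]),
           superior_is_increasing = TRUE),
      class = "dce_study"
    )
  })
  names(studies) <- clinical$patient_id
  structure(
    list(clinical = clinical, studies = studies, crops = NULL, spec = spec),
    class = "dce_cohort"
  )
}

#' Eligible patient counts of the public source collections
#'
#' The grade-eligible patient counts printed for the two public DCE-MRI
#' collections this pipeline was designed around: the development collection
#' (NHG1/NHG3 used for training and testing, NHG2 reserved for
#' stratification) and the external-validation collection.
#'
#' @return Tibble with columns `collection`, `group`, `n`.
#' @export
reference_cohorts <- function() {
  tibble(
    collection = c("development", "development", "development",
                   "external_validation", "external_validation"),
    group = c("NHG1", "NHG3", "NHG2", "NHG1", "NHG3"),
    n = c(162L, 269L, 456L, 12L, 25L)
  )
}
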