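#' Specify a synthetic DCE-MRI cohort
#'
#' A `cohort_spec` bundles every parameter of the synthetic cohort generator:
#' how many patients to draw per Nottingham grade, the voxel grid of the
#' 4-phase phantom volumes, the image noise level, and the ground-truth
#' survival model (a proportional-hazards exponential with uniform right
#' censoring) whose log-hazard is linear in the latent tumour aggressiveness
#' and in three clinical indicators.
#'
#' The generator defaults define the package's reference study conditions:
#' 32 x 96 x 96 voxel volumes at 2 mm slice thickness and 1 mm in-plane
#' resolution (comfortably containing the 14 x 64 x 64 crop), additive
#' Gaussian image noise with sd 5 on a parenchyma baseline of 100, a
#' baseline hazard of 0.004 events/month, a log-hazard of 1.5 per unit of
#' latent aggressiveness, and censoring drawn uniformly on 24-120 months.
#'
#' @param n_per_grade integer vector of length 3: number of patients with
#'   NHG1, NHG2 and NHG3 tumours.
#' @param image_shape integer vector (slices, rows, cols) of every phase
#'   volume.
#' @param voxel_spacing_mm numeric length 3, voxel size in mm along
#'   (slice, row, col).
#' @param noise_sd standard deviation of additive Gaussian image noise, in
#'   intensity units (parenchyma baseline is 100).
#' @param hazard_baseline baseline hazard of the exponential event-time
#'   model, per month; must be positive.
#' @param beta_aggressiveness,beta_t2,beta_node,beta_tnbc log-hazard
#'   coefficients for latent aggressiveness, T stage >= 2, nodal invasion
#'   (N >= 1) and triple-negative subtype.
#' @param censor_window_months length-2 interval from which censoring times
#'   are drawn uniformly.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the spec (including this seed).
#'
#' @return An object of class `cohort_spec` (a named list).
#' @seealso [simulate_cohort()]
#' @export
cohort_spec <- function(n_per_grade = c(150L, 400L, 150L),
                        image_shape = c(32L, 96L, 96L),
                        voxel_spacing_mm = c(2, 1, 1),
                        noise_sd = 5,
                        hazard_baseline = 0.004,
                        beta_aggressiveness = 1.5,
                        beta_t2 = 0.6,
                        beta_node = 0.4,
                        beta_tnbc = 0.7,
                        censor_window_months = c(24, 120),
                        seed = 1L) {
  n_per_grade <- as.integer(n_per_grade)
  if (length(n_per_grade) != 3L || any(is.na(n_per_grade)) || any(n_per_grade < 0L))
    stop("`n_per_grade` must be three non-negative integers", call. = FALSE)
  if (length(image_shape) != 3L || any(image_shape < 16L))
    stop("`image_shape` must be three integers >= 16", call. = FALSE)
  if (length(voxel_spacing_mm) != 3L || any(voxel_spacing_mm <= 0))
    stop("`voxel_spacing_mm` must be three positive numbers", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!is.finite(hazard_baseline) || hazard_baseline <= 0)
    stop("`hazard_baseline` must be a positive number", call. = FALSE)
  betas <- c(beta_aggressiveness, beta_t2, beta_node, beta_tnbc)
  if (any(!is.finite(betas))) stop("hazard coefficients must be finite", call. = FALSE)
  if (length(censor_window_months) != 2L ||
      censor_window_months[1] < 0 ||
      diff(censor_window_months) < 0)
    stop("`censor_window_months` must be an ordered non-negative interval", call. = FALSE)
  structure(
    list(
      n_per_grade = n_per_grade,
      image_shape = as.integer(image_shape),
      voxel_spacing_mm = as.numeric(voxel_spacing_mm),
      noise_sd = noise_sd,
      hazard_baseline = hazard_baseline,
      beta_aggressiveness = beta_aggressiveness,
      beta_t2 = beta_t2,
      beta_node = beta_node,
      beta_tnbc = beta_tnbc,
      censor_window_months = as.numeric(censor_window_months),
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat("  patients per grade:", paste(x$n_per_grade, collapse = "/"), "\n")
  cat("  volume:", paste(x$image_shape, collapse = " x "),
      "voxels at", paste(x$voxel_spacing_mm, collapse = " x "), "mm\n")
  cat("  image noise sd:", x$noise_sd, "\n")
  cat(sprintf("  hazard: h0 = %g/month, beta = (a %g, T2 %g, N+ %g, TNBC %g)\n",
              x$hazard_baseline, x$beta_aggressiveness, x$beta_t2,
              x$beta_node, x$beta_tnbc))
  cat("  censoring: Uniform(", paste(x$censor_window_months, collapse = ", "),
      ") months; seed", x$seed, "\n")
  invisible(x)
}
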