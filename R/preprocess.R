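#' Joint min-max normalisation of a 4-phase study
#'
#' One global (min, max) is computed jointly over the pre-contrast and the
#' three post-contrast phases of a patient and every voxel of every phase is
#' mapped to `(v - min) / (max - min)`. Normalising jointly (never
#' per-phase) preserves the phase-to-phase intensity ordering that carries
#' the kinetic signal. Idempotent: normalising twice gives bitwise the same
#' result.
#'
#' @param study a `dce_study` with four phases.
#' @return The study with all phases rescaled to \[0, 1\].
#' @export
normalize_phases <- function(study) {
  stopifnot(inherits(study, "dce_study"))
  if (length(study$phases) != 4L)
    stop("study ", study$patient_id, " does not have 4 phases", call. = FALSE)
  rng <- range(unlist(lapply(study$phases, range)))
  if (rng[1] == rng[2])
    stop("study ", study$patient_id,
         " has constant intensity; cannot min-max normalise", call. = FALSE)
  study$phases <- lapply(study$phases,
                         function(v) (v - rng[1]) / (rng[2] - rng[1]))
  study
}

#' Select the network input phases
#'
#' Stacks three of the four phases as the CNN's input channels. The default
#' (`"post"`) uses the three post-contrast phases in acquisition order,
#' which carry the wash-in/washout kinetics; `"pre_post"` instead uses
#' pre-contrast + the first two post-contrast phases.
#'
#' @param study a normalised `dce_study`.
#' @param phase_set `"post"` or `"pre_post"`.
#' @return Array of dim (slices, rows, cols, 3) with attributes
#'   `patient_id` and `phase_names`.
#' @export
select_input_phases <- function(study, phase_set = c("post", "pre_post")) {
  stopifnot(inherits(study, "dce_study"))
  phase_set <- match.arg(phase_set)
  wanted <- switch(phase_set,
                   post = c("post1", "post2", "post3"),
                   pre_post = c("pre", "post1", "post2"))
  if (!all(wanted %in% names(study$phases)))
    stop("study ", study$patient_id, " lacks the phases ",
         paste(setdiff(wanted, names(study$phases)), collapse = ", "),
         call. = FALSE)
  shp <- dim(study$phases[[1]])
  out <- array(0, dim = c(shp, 3L))
  for (ch in 1:3) out[, , , ch] <- study$phases[[wanted[ch]]]
  attr(out, "patient_id") <- study$patient_id
  attr(out, "phase_names") <- wanted
  out
}

#' Crop the tumour window
#'
#' Extracts the standard 3 x 14 x 64 x 64 (phase x slice x row x col) crop
#' around the tumour centroid. The 14 slices cover centroid - 7 ..
#' centroid + 6, so the centroid slice sits at crop slice 8 (1-based); the
#' 64 x 64 in-plane window is centred so the centroid falls on row 33 /
#' col 33 (1-based). Voxels outside the volume are zero-padded and the crop
#' origin (first included volume index along each axis, possibly < 1) is
#' recorded.
#'
#' @param stack 4-d array from [select_input_phases()].
#' @param centroid_index integer (slice, row, col), 1-based, inside the
#'   volume.
#' @return Object of class `tumor_crop`: list with `x` (array
#'   3 x 14 x 64 x 64), `patient_id`, `origin`.
#' @export
crop_tumor <- function(stack, centroid_index) {
  shp <- dim(stack)[1:3]
  centroid_index <- as.integer(centroid_index)
  if (any(centroid_index < 1L) || any(centroid_index > shp))
    stop("centroid_index (", paste(centroid_index, collapse = ", "),
         ") outside the volume", call. = FALSE)
  z0 <- centroid_index[1] - 7L   # first crop slice
  r0 <- centroid_index[2] - 32L  # first crop row
  c0 <- centroid_index[3] - 32L  # first crop col
  x <- array(0, dim = c(3L, 14L, 64L, 64L))
  zz <- z0:(z0 + 13L); zin <- which(zz >= 1L & zz <= shp[1])
  rr <- r0:(r0 + 63L); rin <- which(rr >= 1L & rr <= shp[2])
  cc <- c0:(c0 + 63L); cin <- which(cc >= 1L & cc <= shp[3])
  for (ch in 1:3)
    x[ch, zin, rin, cin] <- stack[zz[zin], rr[rin], cc[cin], ch]
  structure(
    list(x = x,
         patient_id = attr(stack, "patient_id") %||% NA_character_,
         origin = c(z0, r0, c0)),
    class = "tumor_crop"
  )
}

# number of slices selected for each flip type at k slices per patient:
# 4 + 4 flipped out of 14 scales as round(2k/7)
flip_counts <- function(k) {
  n_flip <- round(2 * k / 7)
  c(hflip = n_flip, vflip = n_flip, none = k - 2 * n_flip)
}

new_slice_sample <- function(x, patient_id, slice_index, augmentation,
                             label = NA_integer_) {
  structure(
    list(x = x, patient_id = patient_id, slice_index = slice_index,
         augmentation = augmentation, label = label),
    class = "slice_sample"
  )
}

#' Training slices with flip augmentation
#'
#' Takes the `k` crop slices closest to the central slice (the contiguous
#' window mirroring the crop's own 7-below/6-above centering), then
#' replaces `round(2k/7)` of them by their horizontal flips and another
#' `round(2k/7)` by their vertical flips, leaving the remainder unchanged,
#' so exactly `k` samples per patient enter training. At the full `k = 14`
#' this gives 4 + 4 flipped and 6 unchanged. Which slices are flipped is
#' drawn from R's generator, so it is seed-deterministic.
#'
#' @param crop a `tumor_crop`.
#' @param k even number of slices per patient, between 4 and 14.
#' @param label optional class label (0/1) attached to every sample.
#' @return List of `k` `slice_sample` objects (each `x` is 3 x 64 x 64).
#' @export
make_training_slices <- function(crop, k = 8L, label = NA_integer_) {
  stopifnot(inherits(crop, "tumor_crop"))
  if (length(k) != 1L || k %% 2 != 0 || k < 4 || k > 14)
    stop("`k` must be an even number of slices in 4..14", call. = FALSE)
  k <- as.integer(k)
  positions <- (8L - k %/% 2L):(8L + k %/% 2L - 1L)
  counts <- flip_counts(k)
  assignment <- rep(c("hflip", "vflip", "none"), counts)[sample.int(k)]
  lapply(seq_len(k), function(i) {
    s <- positions[i]
    x <- crop$x[, s, , , drop = TRUE]
    x <- switch(assignment[i],
                hflip = x[, , 64:1],   # mirror left/right
                vflip = x[, 64:1, ],   # mirror anterior/posterior
                none = x)
    new_slice_sample(x, crop$patient_id, s, assignment[i], label)
  })
}

#' Evaluation slice
#'
#' The single deterministic slice used to score a patient: crop slice 8
#' (1-based; the slice the centroid falls on under the package's
#' 7-below/6-above centering), with no augmentation. Two calls on the same
#' crop return identical samples.
#'
#' @param crop a `tumor_crop`.
#' @param label optional class label.
#' @return One `slice_sample` (`x` is 3 x 64 x 64).
#' @export
make_eval_slice <- function(crop, label = NA_integer_) {
  stopifnot(inherits(crop, "tumor_crop"))
  s <- 8L
  new_slice_sample(crop$x[, s, , , drop = TRUE], crop$patient_id, s, "none",
                   label)
}

# stack slice samples into the (64, 64, 3, N) batch array the CNN kernels
# expect
slice_batch <- function(samples) {
  if (inherits(samples, "slice_sample")) samples <- list(samples)
  n <- length(samples)
  x <- array(0, dim = c(64L, 64L, 3L, n))
  for (i in seq_len(n)) x[, , , i] <- aperm(samples[[i]]$x, c(2, 3, 1))
  x
}

# crops for every patient of a cohort, rendering lazily when only full
# volumes are stored
cohort_crops <- function(cohort, phase_set = "post") {
  stopifnot(inherits(cohort, "dce_cohort"))
  if (!is.null(cohort$crops)) return(cohort$crops)
  crops <- lapply(cohort$studies, function(study) {
    crop_tumor(select_input_phases(normalize_phases(study),
                                   phase_set = phase_set),
               study$centroid_index)
  })
  names(crops) <- names(cohort$studies)
  crops
}
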