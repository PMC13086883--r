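#' Stratify grade-2 patients with the trained model
#'
#' Scores every grade-2 patient on the single evaluation slice (the same
#' rule as testing) and labels those at or above the operating threshold
#' `DRG2+` (NHG3-like, higher risk) and the rest `DRG2-` (NHG1-like). A
#' score exactly at the threshold is `DRG2+`. The result always partitions
#' the input cohort.
#'
#' @param model a trained `grade_cnn`.
#' @param cohort a `dce_cohort` whose patients are all grade 2 (or a
#'   grade-2 subset is passed via `patient_ids`).
#' @param threshold operating threshold in (0, 1), typically the Youden
#'   cutoff from training.
#' @param patient_ids optional subset of patients to stratify.
#' @return Tibble of class `drg_strata`: `patient_id`, `score`,
#'   `drg_label` (factor `DRG2-`/`DRG2+`), `threshold`.
#' @export
classify_grade2 <- function(model, cohort, threshold, patient_ids = NULL) {
  stopifnot(inherits(cohort, "dce_cohort"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("`threshold` must be inside (0, 1)", call. = FALSE)
  clinical <- cohort$clinical
  if (!is.null(patient_ids))
    clinical <- clinical[clinical$patient_id %in% patient_ids, ]
  if (any(clinical$nhg != 2L))
    stop("classify_grade2() received ", sum(clinical$nhg != 2L),
         " non-grade-2 patient(s); refusing to mix grades", call. = FALSE)
  crops <- cohort_crops(cohort)
  scored <- score_patients(model, crops, clinical$patient_id)
  out <- dplyr::mutate(
    scored,
    drg_label = factor(ifelse(.data$score >= threshold, "DRG2+", "DRG2-"),
                       levels = c("DRG2-", "DRG2+")),
    threshold = threshold
  )
  class(out) <- c("drg_strata", class(out))
  out
}

# variables compared between strata and how
comparison_plan <- function() {
  list(continuous = "age",
       categorical = c("t_stage", "n_stage", "m_stage", "subtype",
                       "er", "pr", "her2",
                       "tubule", "pleomorphism", "mitotic"))
}

#' Compare clinical characteristics between DRG2 strata
#'
#' Baseline-characteristics table for the two strata: mean +/- sd and a
#' two-sided independent t-test for continuous variables, per-level counts
#' and percentages with a chi-square test for categorical variables
#' (switching to Fisher's exact test when any expected cell count is below
#' 5). No multiplicity correction is applied.
#'
#' @param strata a `drg_strata` tibble from [classify_grade2()].
#' @param clinical clinical tibble with one row per stratified patient.
#' @return Object of class `group_comparison`: list with `summary` (tidy
#'   per-variable-per-level tibble), `tests` (per-variable statistic, test
#'   name, p-value) and `n` (named group sizes).
#' @export
compare_groups <- function(strata, clinical) {
  dat <- dplyr::inner_join(as_tibble(strata)[, c("patient_id", "drg_label")],
                           clinical, by = "patient_id")
  n_groups <- table(dat$drg_label)
  if (any(n_groups == 0L))
    stop("both strata must be non-empty for a group comparison", call. = FALSE)
  plan <- comparison_plan()

  tests <- list(); summaries <- list()
  for (v in plan$continuous) {
    tt <- tryCatch(t.test(dat[[v]] ~ dat$drg_label), error = function(e) NULL)
    tests[[v]] <- if (is.null(tt)) {
      # degenerate (essentially constant) data
      tibble(variable = v, test = "t", statistic = NA_real_,
             p_value = NA_real_)
    } else {
      tibble(variable = v, test = "t", statistic = unname(tt$statistic),
             p_value = tt$p.value)
    }
    summaries[[v]] <- dat |>
      dplyr::group_by(.data$drg_label) |>
      dplyr::summarise(value = sprintf("%.2f ± %.2f",
                                       mean(.data[[v]]), sd(.data[[v]])),
                       .groups = "drop") |>
      dplyr::mutate(variable = v, level = "mean ± sd")
  }
  for (v in plan$categorical) {
    tab <- table(factor(dat[[v]]), dat$drg_label)
    if (nrow(tab) < 2L) {
      tests[[v]] <- tibble(variable = v, test = "none",
                           statistic = NA_real_, p_value = NA_real_)
    } else {
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        ft <- fisher.test(tab, simulate.p.value = nrow(tab) > 2 && ncol(tab) > 2,
                          B = 1e4)
        tests[[v]] <- tibble(variable = v, test = "fisher",
                             statistic = NA_real_, p_value = ft$p.value)
      } else {
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        tests[[v]] <- tibble(variable = v, test = "chisq",
                             statistic = unname(ct$statistic),
                             p_value = ct$p.value)
      }
    }
    summaries[[v]] <- as_tibble(as.data.frame(tab)) |>
      stats::setNames(c("level", "drg_label", "n")) |>
      dplyr::group_by(.data$drg_label) |>
      dplyr::mutate(value = sprintf("%d (%.2f%%)", .data$n,
                                    100 * .data$n / sum(.data$n))) |>
      dplyr::ungroup() |>
      dplyr::mutate(variable = v, level = as.character(.data$level)) |>
      dplyr::select("variable", "level", "drg_label", "value")
  }

  summary_tbl <- dplyr::bind_rows(summaries) |>
    dplyr::select("variable", "level", "drg_label", "value") |>
    tidyr::pivot_wider(names_from = "drg_label", values_from = "value")
  structure(
    list(summary = summary_tbl, tests = dplyr::bind_rows(tests),
         n = c(`DRG2-` = unname(n_groups["DRG2-"]),
               `DRG2+` = unname(n_groups["DRG2+"]))),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison: DRG2- (n =", x$n[1], ") vs DRG2+ (n =", x$n[2], ")\n")
  print(dplyr::left_join(x$summary, x$tests[, c("variable", "p_value")],
                         by = "variable"), n = Inf)
  invisible(x)
}
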