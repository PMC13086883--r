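#' Follow-up time and event indicator from dates
#'
#' Months from diagnosis to the first incident event (recurrence or
#' all-cause death) or, when no event occurred, to the last recurrence-free
#' assessment (right censoring). Days are converted with 30.4375
#' days/month.
#'
#' @param diagnosis_date,event_date,last_assessment_date `Date` vectors;
#'   `event_date` is `NA` for censored patients.
#' @return Tibble with `followup_months` and `event` (1 = event observed).
#' @export
build_followup <- function(diagnosis_date, event_date, last_assessment_date) {
  diagnosis_date <- as.Date(diagnosis_date)
  event_date <- as.Date(event_date)
  last_assessment_date <- as.Date(last_assessment_date)
  has_event <- !is.na(event_date)
  end <- dplyr::if_else(has_event, event_date, last_assessment_date)
  if (any(end < diagnosis_date, na.rm = TRUE))
    stop("event or assessment date precedes the diagnosis date", call. = FALSE)
  days <- as.numeric(end - diagnosis_date)
  tibble(followup_months = days / 30.4375, event = as.integer(has_event))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times follow-up times (months), all non-negative.
#' @param events 0/1 event indicators.
#' @return Tibble with one row per distinct observed time: `time`,
#'   `n_risk`, `n_event`, `n_censor`, `estimate` (survival probability just
#'   after `time`).
#' @export
km_estimate <- function(times, events) {
  if (length(times) < 1L) stop("need at least one subject", call. = FALSE)
  if (any(times < 0)) stop("negative follow-up times", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  tibble(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
         n_censor = fit$n.censor, estimate = fit$surv)
}

#' Log-rank test across survival groups
#'
#' @param times,events follow-up and event vectors.
#' @param group group membership (factor or character), at least 2
#'   non-empty groups.
#' @return List with `statistic` (chi-square), `df`, `p_value`.
#' @export
log_rank <- function(times, events, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2L)
    stop("log-rank needs at least two non-empty groups", call. = FALSE)
  sd_fit <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- length(sd_fit$n) - 1L
  list(statistic = unname(sd_fit$chisq), df = df,
       p_value = stats::pchisq(sd_fit$chisq, df, lower.tail = FALSE))
}

# expand a survival table to the model frame used by Cox fits:
# subtype becomes a factor with ER+/HER2- as reference
cox_frame <- function(table) {
  tab <- as_tibble(table)
  if ("subtype" %in% names(tab)) {
    lv <- c("ER+/HER2-", "ER+/HER2+", "ER-/HER2+", "ER-/HER2-")
    tab$subtype <- droplevels(
      factor(tab$subtype, levels = intersect(lv, unique(tab$subtype))))
  }
  if ("drg" %in% names(tab) && !is.numeric(tab$drg))
    tab$drg <- as.numeric(tab$drg == "DRG2+")
  tab
}

#' Cox proportional-hazards fit with Harrell's C
#'
#' Fits a Cox model by partial likelihood with Efron tie handling, reports
#' hazard ratios with Wald 95% confidence intervals and two-sided p-values,
#' and attaches the concordance index of the fitted linear predictor
#' computed by [c_index()].
#'
#' @param table data frame with `time`, `event` and the covariates.
#' @param covariates character vector of covariate names (a `subtype`
#'   column is treated as a factor with the ER+/HER2- reference).
#' @param conf confidence level for the hazard-ratio intervals.
#' @return Object of class `cox_rfs`: list with `fit` (the `coxph`
#'   object), `table` (tidy coefficient tibble), `c_index`, `n`,
#'   `n_events`.
#' @export
cox_fit <- function(table, covariates, conf = 0.95) {
  tab <- cox_frame(table)
  if (sum(tab$event) < 1L) stop("no events in the survival table", call. = FALSE)
  for (v in covariates) {
    if (!v %in% names(tab)) stop("covariate `", v, "` not in table", call. = FALSE)
    if (length(unique(tab[[v]])) < 2L)
      stop("covariate `", v, "` is constant", call. = FALSE)
  }
  fm <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fm, data = tab, ties = "efron")
  if (any(!is.finite(fit$coefficients)) ||
      any(!is.finite(sqrt(diag(fit$var)))))
    stop("Cox fit did not converge (separation or collinearity)", call. = FALSE)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  beta <- fit$coefficients
  se <- sqrt(diag(fit$var))
  tidy_tab <- tibble(
    term = names(beta),
    estimate = unname(beta),
    std_error = unname(se),
    hr = exp(unname(beta)),
    hr_low = exp(unname(beta) - z * se),
    hr_high = exp(unname(beta) + z * se),
    p_value = 2 * stats::pnorm(-abs(unname(beta) / se))
  )
  lp <- unname(fit$linear.predictors)
  structure(
    list(fit = fit, table = tidy_tab,
         c_index = c_index(lp, tab$time, tab$event),
         n = nrow(tab), n_events = sum(tab$event), conf = conf,
         covariates = covariates),
    class = "cox_rfs"
  )
}

#' @export
print.cox_rfs <- function(x, ...) {
  cat(sprintf("Cox RFS model: %d subjects, %d events, C-index %.3f\n",
              x$n, x$n_events, x$c_index))
  print(x$table)
  invisible(x)
}

#' Harrell's concordance index
#'
#' Fraction of comparable pairs in which the subject with the higher
#' linear predictor has the earlier event; predictor ties count one half.
#' A pair is comparable when the earlier time is an event time (tied event
#' times are not comparable).
#'
#' @param lp linear predictor (higher = higher risk).
#' @param times,events follow-up and event vectors.
#' @return C-index in \[0, 1\].
#' @export
c_index <- function(lp, times, events) {
  stopifnot(length(lp) == length(times), length(times) == length(events))
  res <- .c_index_pairs(as.numeric(lp), as.numeric(times), as.integer(events))
  if (res$comparable == 0)
    stop("no comparable pairs; cannot compute a concordance index", call. = FALSE)
  res$concordant / res$comparable
}

#' Paired bootstrap comparison of two nested Cox models
#'
#' Draws `B` patient-level resamples with replacement; on each resample
#' both the base and the full model are refitted (`refit = TRUE`, the
#' default) or the original fits are re-evaluated (`refit = FALSE`), and
#' the difference of concordance indices `delta = C_full - C_base` is
#' recorded. Reports the mean difference, the percentile confidence
#' interval, and a two-sided sign-fraction p-value
#' `2 min(frac(delta <= 0), frac(delta >= 0))` floored at `2/B`. Resamples
#' without events (or where a refit fails) are redrawn.
#'
#' @param table survival table (see [cox_fit()]).
#' @param covariates_base,covariates_full covariate sets; the full set must
#'   strictly contain the base set.
#' @param B number of resamples.
#' @param conf confidence level of the percentile interval.
#' @param seed integer seed.
#' @param refit refit both models on every resample?
#' @return Object of class `cindex_comparison`: list with `c_base`,
#'   `c_full` (full-data values), `delta_mean`, `ci_low`, `ci_high`,
#'   `p_value`, `B`, `deltas`, `refit`.
#' @export
paired_bootstrap_cindex <- function(table, covariates_base, covariates_full,
                                    B = 1000L, conf = 0.95, seed = 1L,
                                    refit = TRUE) {
  if (!all(covariates_base %in% covariates_full) ||
      length(covariates_full) <= length(covariates_base))
    stop("`covariates_full` must strictly contain `covariates_base`",
         call. = FALSE)
  tab <- cox_frame(table)
  base_fit <- cox_fit(tab, covariates_base)
  full_fit <- cox_fit(tab, covariates_full)
  n <- nrow(tab)
  set.seed(seed)
  deltas <- numeric(B)
  b <- 0L; tries <- 0L
  while (b < B) {
    tries <- tries + 1L
    if (tries > 50L * B)
      stop("too many degenerate bootstrap resamples", call. = FALSE)
    idx <- sample.int(n, n, replace = TRUE)
    res <- tab[idx, ]
    if (sum(res$event) < 1L) next
    d <- tryCatch({
      if (refit) {
        # small resamples can separate; the finite-coefficient guard below
        # rejects those, so convergence chatter is expected noise here
        cb <- suppressWarnings(cox_fit(res, covariates_base))
        cf <- suppressWarnings(cox_fit(res, covariates_full))
        cf$c_index - cb$c_index
      } else {
        lp_b <- unname(predict(base_fit$fit, newdata = res, type = "lp"))
        lp_f <- unname(predict(full_fit$fit, newdata = res, type = "lp"))
        c_index(lp_f, res$time, res$event) -
          c_index(lp_b, res$time, res$event)
      }
    }, error = function(e) NA_real_)
    if (is.na(d)) next
    b <- b + 1L
    deltas[b] <- d
  }
  qs <- unname(quantile(deltas, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  p <- 2 * min(mean(deltas <= 0), mean(deltas >= 0))
  p <- min(max(p, 2 / B), 1)
  structure(
    list(c_base = base_fit$c_index, c_full = full_fit$c_index,
         delta_mean = mean(deltas), ci_low = qs[1], ci_high = qs[2],
         p_value = p, B = as.integer(B), deltas = deltas, refit = refit,
         conf = conf),
    class = "cindex_comparison"
  )
}

#' @export
print.cindex_comparison <- function(x, ...) {
  cat(sprintf(
    "C-index %.3f -> %.3f; mean delta %.4f [%d%% CI %.4f, %.4f], p = %.4g (B = %d, %s)\n",
    x$c_base, x$c_full, x$delta_mean, round(100 * x$conf), x$ci_low,
    x$ci_high, x$p_value, x$B,
    if (x$refit) "refit per resample" else "fixed fits"))
  invisible(x)
}

#' Build the Cox survival table from clinical data and strata
#'
#' Derives the modelling columns: `time` (months), `event`, `age`,
#' `t2` (T stage >= 2), `node` (N stage >= 1), `subtype`, and `drg` when
#' strata are supplied. Patients with unknown T or N stage (`"X"`) or
#' missing follow-up are excluded; the excluded ids are attached as the
#' `"exclusions"` attribute.
#'
#' @param clinical clinical tibble.
#' @param strata optional `drg_strata` tibble; when given, only stratified
#'   patients are kept and a `drg` indicator is added.
#' @return Tibble with the modelling columns.
#' @export
make_survival_table <- function(clinical, strata = NULL) {
  tab <- as_tibble(clinical)
  excluded <- character(0)
  if (!is.null(strata)) {
    st <- as_tibble(strata)[, c("patient_id", "drg_label")]
    missing <- setdiff(tab$patient_id, st$patient_id)
    if (length(missing) > 0)
      excluded <- c(excluded, stats::setNames(missing,
                                              rep("no_stratum", length(missing))))
    tab <- dplyr::inner_join(tab, st, by = "patient_id")
  }
  bad_stage <- tab$patient_id[tab$t_stage == "X" | tab$n_stage == "X"]
  if (length(bad_stage) > 0)
    excluded <- c(excluded, stats::setNames(bad_stage,
                                            rep("stage_unknown", length(bad_stage))))
  bad_fu <- tab$patient_id[is.na(tab$followup_months)]
  if (length(bad_fu) > 0)
    excluded <- c(excluded, stats::setNames(bad_fu,
                                            rep("no_followup", length(bad_fu))))
  tab <- tab[!(tab$patient_id %in% c(bad_stage, bad_fu)), ]
  out <- tibble(
    patient_id = tab$patient_id,
    time = tab$followup_months,
    event = tab$event,
    age = tab$age,
    t2 = as.numeric(tab$t_stage %in% c("2", "3", "4")),
    node = as.numeric(tab$n_stage %in% c("1", "2", "3")),
    subtype = tab$subtype
  )
  if (!is.null(strata)) out$drg <- as.numeric(tab$drg_label == "DRG2+")
  attr(out, "exclusions") <- excluded
  out
}

#' Full recurrence-free-survival analysis
#'
#' The survival stage of the pipeline: Kaplan-Meier curves per arm (NHG1,
#' DRG2-, DRG2+, NHG3 when all are present; the DRG2 arms alone otherwise)
#' with a log-rank test, two Cox models on the stratified grade-2 patients
#' — base covariates age, T stage >= 2, nodal invasion and molecular
#' subtype, the full model adding the DRG2 label — and the paired-bootstrap
#' comparison of their concordance indices.
#'
#' @param clinical clinical tibble (any grades).
#' @param strata `drg_strata` for the grade-2 patients.
#' @param B bootstrap resamples for the C-index comparison.
#' @param seed integer seed.
#' @param refit refit Cox models per bootstrap resample?
#' @return Object of class `rfs_report`: list with `km` (per-arm tibble),
#'   `logrank`, `cox_base`, `cox_full`, `cindex` (a `cindex_comparison`),
#'   `arms`, `exclusions`.
#' @export
run_rfs_analysis <- function(clinical, strata, B = 1000L, seed = 1L,
                             refit = TRUE) {
  clinical <- as_tibble(clinical)
  st <- as_tibble(strata)[, c("patient_id", "drg_label")]
  g2_ids <- clinical$patient_id[clinical$nhg == 2L]
  missing <- setdiff(g2_ids, st$patient_id)
  if (length(missing) > 0)
    message("excluding ", length(missing),
            " grade-2 patient(s) without a stratum: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ...")

  arm <- dplyr::case_when(
    clinical$nhg == 1L ~ "NHG1",
    clinical$nhg == 3L ~ "NHG3",
    clinical$patient_id %in% st$patient_id[st$drg_label == "DRG2+"] ~ "DRG2+",
    clinical$patient_id %in% st$patient_id[st$drg_label == "DRG2-"] ~ "DRG2-",
    TRUE ~ NA_character_
  )
  keep <- !is.na(arm) & !is.na(clinical$followup_months)
  arms_present <- intersect(c("NHG1", "DRG2-", "DRG2+", "NHG3"),
                            unique(arm[keep]))
  km <- dplyr::bind_rows(lapply(arms_present, function(a) {
    i <- keep & arm == a
    dplyr::mutate(km_estimate(clinical$followup_months[i],
                              clinical$event[i]), arm = a, .before = 1)
  }))
  lr <- log_rank(clinical$followup_months[keep], clinical$event[keep],
                 arm[keep])

  surv_tab <- make_survival_table(clinical[clinical$nhg == 2L, ], strata)
  base_cov <- c("age", "node", "t2", "subtype")
  full_cov <- c("drg", base_cov)
  cox_base <- cox_fit(surv_tab, base_cov)
  cox_full <- cox_fit(surv_tab, full_cov)
  cmp <- paired_bootstrap_cindex(surv_tab, base_cov, full_cov, B = B,
                                 seed = seed, refit = refit)
  structure(
    list(km = km, logrank = lr, cox_base = cox_base, cox_full = cox_full,
         cindex = cmp, arms = arms_present,
         exclusions = attr(surv_tab, "exclusions")),
    class = "rfs_report"
  )
}

#' @export
print.rfs_report <- function(x, ...) {
  cat("RFS analysis —", paste(x$arms, collapse = ", "), "\n")
  cat(sprintf("log-rank chi-square %.2f on %d df, p = %.4g\n",
              x$logrank$statistic, x$logrank$df, x$logrank$p_value))
  cat("\nWithout DRG stratification:\n"); print(x$cox_base)
  cat("\nWith DRG stratification:\n"); print(x$cox_full)
  cat("\n"); print(x$cindex)
  invisible(x)
}
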