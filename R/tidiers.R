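#' Tidy a Cox RFS fit
#'
#' @param x a `cox_rfs` object.
#' @param ... unused.
#' @return Tibble with one row per model term: `term`, `estimate` (log
#'   hazard), `std_error`, `hr`, `hr_low`, `hr_high`, `p_value`.
#' @export
tidy.cox_rfs <- function(x, ...) x$table

#' One-row summary of a Cox RFS fit
#'
#' @param x a `cox_rfs` object.
#' @param ... unused.
#' @return Tibble with `n`, `n_events`, `c_index`, `log_partial_lik`.
#' @export
glance.cox_rfs <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, c_index = x$c_index,
         log_partial_lik = as.numeric(x$fit$loglik[2]))
}

#' Tidy an ROC result
#'
#' @param x a `roc_result` object.
#' @param ... unused.
#' @return Tibble of per-patient `score` and `label`.
#' @export
tidy.roc_result <- function(x, ...) {
  tibble(score = x$scores, label = x$labels)
}

#' One-row summary of an ROC result
#'
#' @param x a `roc_result` object.
#' @param ... unused.
#' @return Tibble with `auc`, `ci_low`, `ci_high`, `n`, `n_bootstrap`.
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, ci_low = x$ci_low, ci_high = x$ci_high,
         n = length(x$labels), n_bootstrap = x$n_bootstrap)
}

#' Tidy a paired C-index comparison
#'
#' @param x a `cindex_comparison` object.
#' @param ... unused.
#' @return One-row tibble with `c_base`, `c_full`, `delta_mean`, `ci_low`,
#'   `ci_high`, `p_value`, `B`.
#' @export
tidy.cindex_comparison <- function(x, ...) {
  tibble(c_base = x$c_base, c_full = x$c_full, delta_mean = x$delta_mean,
         ci_low = x$ci_low, ci_high = x$ci_high, p_value = x$p_value,
         B = x$B)
}
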