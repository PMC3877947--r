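#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an ROC result
#'
#' @param x a `roc_result`.
#' @param ... unused.
#' @return tibble of ROC curve points (`threshold`, `sensitivity`,
#'   `specificity`, `fpr`).
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname tidy.roc_result
#' @return for `glance`: one-row tibble with `auc`, `optimal_cutoff`,
#'   `sensitivity`, `specificity`, `n_event`, `n_nonevent`.
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, optimal_cutoff = x$optimal_cutoff,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 n_event = x$n_event, n_nonevent = x$n_nonevent)
}

#' Tidy an NRI result
#'
#' @param x an `nri_result`.
#' @param ... unused.
#' @return tibble with one row per stratum (`net_gain`, `p_value`, `n`) plus
#'   the total.
#' @export
tidy.nri_result <- function(x, ...) {
  tibble::tibble(
    term = c("event", "nonevent", "total"),
    net_gain = c(x$net_gain_event, x$net_gain_nonevent, x$total_nri),
    p_value = c(x$p_event, x$p_nonevent, x$p_total),
    n = c(x$n_event, x$n_nonevent, x$n_event + x$n_nonevent)
  )
}

#' @rdname tidy.nri_result
#' @export
glance.nri_result <- function(x, ...) {
  tibble::tibble(total_nri = x$total_nri, p_total = x$p_total,
                 scheme = x$scheme,
                 n_event = x$n_event, n_nonevent = x$n_nonevent)
}

#' Tidy a patient result
#'
#' @param x a `patient_result`.
#' @param ... unused.
#' @return the per-hot-spot table (without pixel masks).
#' @export
tidy.patient_result <- function(x, ...) {
  hs <- x$hotspots
  hs[setdiff(names(hs), "mask")]
}

#' @rdname tidy.patient_result
#' @export
glance.patient_result <- function(x, ...) {
  tibble::tibble(
    ann_value = x$ann_value, bsi = x$bsi,
    n_hotspots = nrow(x$hotspots),
    n_metastatic = sum(x$hotspots$metastatic),
    flags = paste(x$flags, collapse = ";")
  )
}
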