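# Validation statistics: empirical ROC with Youden-style optimal cutoff,
# paired AUC comparison (DeLong), proportion comparison, ordered risk
# categories and net reclassification improvement.

check_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    ok <- labels %in% c("metastasis", "no_metastasis")
    if (!all(ok)) stop("labels must be 'metastasis'/'no_metastasis' or 0/1",
                       call. = FALSE)
    labels <- as.numeric(labels == "metastasis")
  }
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary", call. = FALSE)
  if (length(unique(labels)) < 2)
    stop("both outcome classes must be present", call. = FALSE)
  labels
}

#' Empirical ROC analysis
#'
#' Builds the empirical ROC curve over all distinct score thresholds (positive
#' call: score >= threshold), computes the area under the curve by the
#' trapezoidal rule (equal to the Mann-Whitney statistic with ties counted
#' one half), and locates the optimal cutoff maximizing
#' sensitivity - (1 - specificity); ties are broken toward the higher
#' specificity (larger cutoff).
#'
#' @param cohort data frame with a score column and a label column.
#' @param score,label column names (strings) of the score and outcome; the
#'   label holds `"metastasis"`/`"no_metastasis"` or 1/0.
#' @return a `roc_result`: `curve` tibble (`threshold`, `sensitivity`,
#'   `specificity`, `fpr`), `auc`, `optimal_cutoff`, `sensitivity` and
#'   `specificity` at the cutoff, and class counts.
#' @examples
#' cohort <- tibble::tibble(score = c(.1, .2, .8, .9), label = c(0, 0, 1, 1))
#' roc_analysis(cohort)$auc  # 1
#' @export
roc_analysis <- function(cohort, score = "score", label = "label") {
  stopifnot(is.data.frame(cohort), score %in% names(cohort),
            label %in% names(cohort))
  s <- cohort[[score]]
  if (!all(is.finite(s))) stop("scores must be finite", call. = FALSE)
  y <- check_binary_labels(cohort[[label]])
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)

  thr <- sort(unique(s))
  sens <- vapply(thr, function(t) mean(s[y == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(s[y == 0] < t), numeric(1))
  curve <- tibble::tibble(threshold = c(-Inf, thr, Inf),
                          sensitivity = c(1, sens, 0),
                          specificity = c(0, spec, 1))
  curve$fpr <- 1 - curve$specificity
  curve <- curve[order(curve$fpr, curve$sensitivity), ]

  # trapezoidal AUC over the stored curve (ties appear as diagonal segments)
  auc <- sum(diff(rev(curve$fpr)) * (utils::head(rev(curve$sensitivity), -1) +
                                       utils::tail(rev(curve$sensitivity), -1)) / 2)
  auc <- abs(auc)

  j <- sens - (1 - spec)
  # rationally equal J values can differ by float rounding across thresholds,
  # so ties are detected with a tolerance before breaking toward specificity
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(spec[best])]   # ties -> higher specificity
  structure(list(curve = curve, auc = auc,
                 optimal_cutoff = thr[best],
                 sensitivity = sens[best], specificity = spec[best],
                 n_event = n1, n_nonevent = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC: AUC ", round(x$auc, 4), " (", x$n_event, " events / ",
      x$n_nonevent, " non-events)\n", sep = "")
  cat("optimal cutoff ", format(x$optimal_cutoff), ": sensitivity ",
      round(100 * x$sensitivity, 1), "%, specificity ",
      round(100 * x$specificity, 1), "%\n", sep = "")
  invisible(x)
}

# DeLong components: placement values and the AUC
delong_placements <- function(s, y) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), numeric(1))
  v01 <- vapply(neg, function(x) mean((pos > x) + 0.5 * (pos == x)), numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Compare two paired AUCs (DeLong)
#'
#' Two-sided test for the difference between the AUCs of two scores measured
#' on the same patients, using the DeLong correlated-ROC variance estimate.
#'
#' @param scores_a,scores_b numeric score vectors on identical patients.
#' @param labels binary outcomes (same conventions as [roc_analysis()]).
#' @return list: `auc_a`, `auc_b`, `delta_auc`, `z`, `p_value`.
#' @export
compare_auc <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels))
    stop("scores_a, scores_b and labels must have equal length", call. = FALSE)
  y <- check_binary_labels(labels)
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  delta <- pa$auc - pb$auc
  if (var_delta <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, delta_auc = delta, z = z, p_value = p)
}

#' Compare two proportions
#'
#' Two-sided test for a difference between two independent proportions:
#' chi-square with continuity correction, switching to Fisher's exact test
#' when any expected cell count falls below 5.
#'
#' @param k1,n1 events and total in group 1.
#' @param k2,n2 events and total in group 2.
#' @return list: `p_value`, `method`, `prop1`, `prop2`.
#' @export
compare_proportions <- function(k1, n1, k2, n2) {
  if (any(c(k1, n1, k2, n2) < 0) || k1 > n1 || k2 > n2 || n1 == 0 || n2 == 0)
    stop("invalid counts", call. = FALSE)
  tab <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    p <- stats::fisher.test(tab)$p.value
    method <- "fisher"
  } else {
    p <- stats::prop.test(c(k1, k2), c(n1, n2), correct = TRUE)$p.value
    method <- "chisq"
  }
  list(p_value = p, method = method, prop1 = k1 / n1, prop2 = k2 / n2)
}

#' Bin scores into the four ordered risk categories
#'
#' ANN scheme: `[0, 0.25)`, `[0.25, 0.50)`, `[0.50, 0.75)`, `[0.75, 1.00]`
#' (a value of exactly 0.25 falls in the second category). BSI scheme:
#' `[0, 0.1)`, `[0.1, 1)`, `[1, 5)`, `[5, Inf)` (a BSI of exactly 5 falls in
#' the top category).
#'
#' @param scores numeric vector; ANN scores must lie in `[0, 1]`, BSI scores
#'   must be non-negative.
#' @param scheme `"ANN"` or `"BSI"`.
#' @return integer categories 1-4 with a `labels` attribute.
#' @examples
#' bin_scores(c(0, 0.25, 0.74, 0.75), "ANN")  # 1 2 3 4
#' bin_scores(c(0, 0.1, 4.99, 5), "BSI")      # 1 2 3 4
#' @export
bin_scores <- function(scores, scheme = c("ANN", "BSI")) {
  scheme <- match.arg(toupper(scheme), c("ANN", "BSI"))
  if (anyNA(scores) || !all(is.finite(scores)))
    stop("scores must be finite", call. = FALSE)
  if (scheme == "ANN") {
    if (any(scores < 0 | scores > 1))
      stop("ANN scores must lie in [0, 1]", call. = FALSE)
    edges <- c(0.25, 0.50, 0.75)
    labels <- c("0 to 0.24", "0.25 to 0.49", "0.50 to 0.74", "0.75 to 1.00")
  } else {
    if (any(scores < 0)) stop("BSI scores must be non-negative", call. = FALSE)
    edges <- c(0.1, 1, 5)
    labels <- c("<0.1", "0.1 to 0.99", "1 to 4.99", ">=5")
  }
  cats <- 1L + (scores >= edges[1]) + (scores >= edges[2]) + (scores >= edges[3])
  attr(cats, "labels") <- labels
  attr(cats, "scheme") <- scheme
  cats
}

new_reclass_table <- function(counts, stratum, scheme, labels) {
  stopifnot(is.matrix(counts), all(dim(counts) == 4), all(counts >= 0),
            all(counts == round(counts)))
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, stratum = stratum, scheme = scheme,
                 labels = labels, n = sum(counts)),
            class = "reclass_table")
}

#' Cross-tabulate old vs new risk categories by outcome stratum
#'
#' @param old_categories,new_categories integer categories from [bin_scores()]
#'   using the same scheme.
#' @param labels binary outcomes (same conventions as [roc_analysis()]).
#' @return list with `event` and `nonevent` elements, each a `reclass_table`:
#'   a 4x4 count matrix (rows = old method, columns = new method) plus stratum
#'   metadata.
#' @export
reclassification_table <- function(old_categories, new_categories, labels) {
  if (length(old_categories) != length(new_categories) ||
      length(old_categories) != length(labels))
    stop("categories and labels must have equal length", call. = FALSE)
  so <- attr(old_categories, "scheme")
  sn <- attr(new_categories, "scheme")
  if (!is.null(so) && !is.null(sn) && !identical(so, sn))
    stop("old and new categories use different binning schemes", call. = FALSE)
  y <- check_binary_labels(labels)
  scheme <- if (!is.null(so)) so else "custom"
  cat_labels <- attr(old_categories, "labels")
  tab <- function(sel, stratum) {
    counts <- matrix(as.integer(table(factor(old_categories[sel], levels = 1:4),
                                      factor(new_categories[sel], levels = 1:4))),
                     4, 4, dimnames = list(old = cat_labels, new = cat_labels))
    new_reclass_table(counts, stratum, scheme, cat_labels)
  }
  list(event = tab(y == 1, "event"), nonevent = tab(y == 0, "nonevent"))
}

#' @export
print.reclass_table <- function(x, ...) {
  cat("reclassification table (", x$stratum, ", ", x$scheme, ", n = ", x$n,
      "); net gain ", sprintf("%+.1f%%", 100 * net_gain(x)), "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Net gain in reclassification proportion for one stratum
#'
#' The proportion of the stratum moved to a higher category by the new method
#' minus the proportion moved to a lower one:
#' (count above diagonal - count below diagonal) / stratum size. Signed; not
#' direction-corrected per outcome (the event/non-event correction happens in
#' [total_nri()]).
#'
#' @param table a `reclass_table` (or plain 4x4 matrix, rows = old method).
#' @return signed proportion in `[-1, 1]`.
#' @export
net_gain <- function(table) {
  counts <- if (inherits(table, "reclass_table")) table$counts else table
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts))
  n <- sum(counts)
  if (n == 0) stop("empty stratum", call. = FALSE)
  up <- sum(counts[upper.tri(counts)])
  down <- sum(counts[lower.tri(counts)])
  (up - down) / n
}

movement_test <- function(counts) {
  up <- sum(counts[upper.tri(counts)])
  down <- sum(counts[lower.tri(counts)])
  if (up + down == 0) return(list(z = 0, p = 1, up = up, down = down))
  z <- (up - down) / sqrt(up + down)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), up = up, down = down)
}

#' Total net reclassification improvement
#'
#' Combines the per-stratum net gains into the total NRI:
#' `net_gain(event) - net_gain(nonevent)` (upward movement is an improvement
#' for patients with the outcome, downward for patients without). Per-stratum
#' p-values use the asymptotic movement test z = (up - down)/sqrt(up + down);
#' the combined p-value uses the standard NRI z statistic.
#'
#' @param event_table,nonevent_table `reclass_table`s for the two outcome
#'   strata (same scheme).
#' @return an `nri_result`: `net_gain_event`, `net_gain_nonevent`,
#'   `total_nri` (signed proportions), and `p_event`, `p_nonevent`, `p_total`.
#' @export
total_nri <- function(event_table, nonevent_table) {
  stopifnot(inherits(event_table, "reclass_table"),
            inherits(nonevent_table, "reclass_table"))
  if (!identical(event_table$scheme, nonevent_table$scheme))
    stop("strata use different binning schemes", call. = FALSE)
  ge <- net_gain(event_table)
  gn <- net_gain(nonevent_table)
  me <- movement_test(event_table$counts)
  mn <- movement_test(nonevent_table$counts)
  var_e <- (me$up + me$down) / event_table$n^2
  var_n <- (mn$up + mn$down) / nonevent_table$n^2
  total <- ge - gn
  if (var_e + var_n == 0) {
    p_total <- 1
    z_total <- 0
  } else {
    z_total <- total / sqrt(var_e + var_n)
    p_total <- 2 * stats::pnorm(-abs(z_total))
  }
  structure(list(net_gain_event = ge, net_gain_nonevent = gn,
                 total_nri = total,
                 p_event = me$p, p_nonevent = mn$p, p_total = p_total,
                 z_total = z_total,
                 n_event = event_table$n, n_nonevent = nonevent_table$n,
                 scheme = event_table$scheme),
            class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat("NRI (", x$scheme, "): net gain events ",
      sprintf("%+.1f%%", 100 * x$net_gain_event), " (p = ",
      format.pval(x$p_event, digits = 2), "), non-events ",
      sprintf("%+.1f%%", 100 * x$net_gain_nonevent), " (p = ",
      format.pval(x$p_nonevent, digits = 2), ")\n", sep = "")
  cat("total NRI ", sprintf("%.1f%%", 100 * x$total_nri), " (p = ",
      format.pval(x$p_total, digits = 2), ")\n", sep = "")
  invisible(x)
}

#' Read a reclassification table from CSV
#'
#' Long format: columns `stratum` (`event`/`nonevent`), `old_category`,
#' `new_category` (integers 1-4) and `count`. Suitable for feeding published
#' 4x4 reclassification counts straight into [net_gain()] / [total_nri()].
#'
#' @param path CSV path.
#' @param scheme binning scheme label to attach (`"ANN"` or `"BSI"`).
#' @return list with `event` and `nonevent` `reclass_table`s.
#' @export
read_reclassification_table <- function(path, scheme = "ANN") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("stratum", "old_category", "new_category", "count") %in% names(df)))
  build <- function(stratum) {
    sub <- df[df$stratum == stratum, ]
    counts <- matrix(0, 4, 4)
    counts[cbind(sub$old_category, sub$new_category)] <- sub$count
    new_reclass_table(counts, stratum, scheme, NULL)
  }
  list(event = build("event"), nonevent = build("nonevent"))
}
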