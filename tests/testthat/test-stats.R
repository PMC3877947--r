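test_that("perfectly separated scores give AUC 1 with perfect cutoff", {
  cohort <- tibble::tibble(score = c(0.1, 0.2, 0.8, 0.9), label = c(0, 0, 1, 1))
  roc <- roc_analysis(cohort)
  expect_identical(roc$auc, 1)
  expect_identical(roc$sensitivity, 1)
  expect_identical(roc$specificity, 1)
})

test_that("all-tied scores give chance AUC", {
  cohort <- tibble::tibble(score = rep(0.4, 10), label = rep(c(0, 1), 5))
  expect_equal(roc_analysis(cohort)$auc, 0.5, tolerance = 1e-12)
})

test_that("single-class cohorts are rejected", {
  expect_error(roc_analysis(tibble::tibble(score = 1:4, label = rep(1, 4))),
               "both outcome classes")
})

test_that("trapezoidal AUC equals pair-counting and the cutoff matches brute
          force on random cohorts", {
  set.seed(2024)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    scores <- round(stats::runif(n), sample(c(1, 2, 6), 1))  # force some ties
    labels <- stats::rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    cohort <- tibble::tibble(score = scores, label = labels)
    roc <- roc_analysis(cohort)
    expect_equal(roc$auc, oracle_auc(scores, labels), tolerance = 1e-12)
    oc <- oracle_cutoff(scores, labels)
    expect_identical(roc$optimal_cutoff, oc$t)
    expect_equal(roc$sensitivity, oc$sens, tolerance = 1e-12)
    expect_equal(roc$specificity, oc$spec, tolerance = 1e-12)
  }
})

test_that("ROC curve is monotone from (0,0) to (1,1) and matches its own AUC", {
  set.seed(7)
  cohort <- tibble::tibble(score = stats::rnorm(80),
                           label = stats::rbinom(80, 1, 0.5))
  roc <- roc_analysis(cohort)
  curve <- tidy(roc)
  expect_true(all(diff(curve$fpr) >= 0))
  expect_true(all(diff(curve$sensitivity) >= 0))
  expect_equal(curve$fpr[1], 0)
  expect_equal(curve$sensitivity[nrow(curve)], 1)
})

test_that("comparing a predictor with itself gives delta 0 and p 1", {
  set.seed(1)
  s <- stats::runif(40)
  y <- stats::rbinom(40, 1, 0.5)
  y[1:2] <- c(0, 1)
  out <- compare_auc(s, s, y)
  expect_identical(out$delta_auc, 0)
  expect_identical(out$p_value, 1)
})

test_that("AUC antisymmetry: reversing a perfect predictor flips the AUC", {
  s <- c(0.1, 0.2, 0.8, 0.9)
  y <- c(0, 0, 1, 1)
  out <- compare_auc(s, 1 - s, y)
  expect_identical(out$auc_a, 1)
  expect_identical(out$auc_b, 0)
  expect_identical(out$delta_auc, 1)
  expect_error(compare_auc(s, s[-1], y), "equal length")
})

test_that("DeLong agrees with the independent pROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(99)
  for (i in 1:10) {
    y <- c(rep(0, 25), rep(1, 25))
    a <- y * 0.8 + stats::rnorm(50)
    b <- y * 0.5 + 0.5 * a + stats::rnorm(50)
    mine <- compare_auc(a, b, y)
    ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                          pROC::roc(y, b, quiet = TRUE), method = "delong")
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-9)
  }
})

test_that("proportion comparison matches its contracts", {
  expect_equal(compare_proportions(50, 100, 50, 100)$p_value, 1)
  # extreme split is significant, agreeing with the exact-test oracle verdict
  out <- compare_proportions(0, 10, 10, 10)
  expect_lt(out$p_value, 0.01)
  expect_lt(stats::fisher.test(matrix(c(0, 10, 10, 0), 2))$p.value, 0.01)
  # sparse expected cells switch to the exact test
  sparse <- compare_proportions(0, 5, 3, 5)
  expect_identical(sparse$method, "fisher")
  expect_equal(sparse$p_value,
               stats::fisher.test(matrix(c(0, 5, 3, 2), 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)
  a <- compare_proportions(30, 80, 45, 90)
  b <- compare_proportions(45, 90, 30, 80)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_error(compare_proportions(5, 3, 1, 2), "invalid counts")
})

test_that("score binning follows the printed category edges", {
  expect_identical(as.integer(bin_scores(c(0, 0.24, 0.25, 0.49, 0.5, 0.74, 0.75, 1), "ANN")),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_identical(as.integer(bin_scores(c(0, 0.09, 0.1, 0.99, 1, 4.99, 5, 40), "BSI")),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_error(bin_scores(c(-0.1), "ANN"), "\\[0, 1\\]")
  expect_error(bin_scores(c(1.2), "ANN"), "\\[0, 1\\]")
  expect_error(bin_scores(c(-2), "BSI"), "non-negative")
  # total and idempotent: every valid score maps to exactly one category
  set.seed(3)
  s <- stats::runif(1000)
  cats <- bin_scores(s, "ANN")
  expect_true(all(cats %in% 1:4))
})

test_that("reclassification tables cross-tabulate by stratum", {
  old <- bin_scores(c(0.1, 0.3, 0.6, 0.9, 0.2, 0.8), "ANN")
  new <- bin_scores(c(0.1, 0.3, 0.6, 0.9, 0.2, 0.8), "ANN")
  labels <- c(1, 1, 1, 0, 0, 0)
  tabs <- reclassification_table(old, new, labels)
  expect_true(all(tabs$event$counts[upper.tri(tabs$event$counts)] == 0))
  expect_true(all(tabs$event$counts[lower.tri(tabs$event$counts)] == 0))
  expect_identical(tabs$event$n, 3L)
  expect_identical(tabs$nonevent$n, 3L)
})

test_that("a single event patient moving 1 to 4 lands in cell (1,4)", {
  old <- bin_scores(c(0.1, 0.1), "ANN")
  new <- bin_scores(c(0.9, 0.1), "ANN")
  tabs <- reclassification_table(old, new, c(1, 0))
  expect_identical(tabs$event$counts[1, 4], 1L)
  expect_identical(sum(tabs$event$counts), 1L)
  expect_identical(tabs$nonevent$counts[1, 1], 1L)
})

test_that("mixed binning schemes are rejected", {
  a <- bin_scores(c(0.1, 0.9), "ANN")
  b <- bin_scores(c(0.1, 9), "BSI")
  expect_error(reclassification_table(a, b, c(0, 1)), "different binning")
})

test_that("net gain is antisymmetric under transposition and zero on the
          diagonal", {
  tabs <- ann_example_tables()
  for (t in tabs) {
    tt <- t
    tt$counts <- t(t$counts)
    expect_equal(net_gain(tt), -net_gain(t), tolerance = 1e-15)
  }
  diag_only <- tabs$event
  diag_only$counts <- diag(c(5L, 5L, 5L, 5L))
  expect_identical(net_gain(diag_only), 0)
  expect_error(net_gain(matrix(0, 4, 4)), "empty stratum")
})

test_that("total NRI flips sign when old and new methods are swapped", {
  tabs <- bsi_example_tables()
  fwd <- total_nri(tabs$event, tabs$nonevent)
  swapped_e <- tabs$event
  swapped_e$counts <- t(tabs$event$counts)
  swapped_n <- tabs$nonevent
  swapped_n$counts <- t(tabs$nonevent$counts)
  rev <- total_nri(swapped_e, swapped_n)
  expect_equal(rev$total_nri, -fwd$total_nri, tolerance = 1e-15)
})

test_that("identity reclassification gives zero NRI with p 1", {
  diag_t <- function(stratum) {
    t <- ann_example_tables()$event
    t$counts <- diag(c(10L, 10L, 10L, 10L))
    t$stratum <- stratum
    t$n <- 40L
    t
  }
  out <- total_nri(diag_t("event"), diag_t("nonevent"))
  expect_identical(out$total_nri, 0)
  expect_identical(out$p_total, 1)
  expect_identical(out$p_event, 1)
})

test_that("total_nri satisfies its own decomposition identity", {
  tabs <- ann_example_tables()
  out <- total_nri(tabs$event, tabs$nonevent)
  expect_equal(out$total_nri, out$net_gain_event - out$net_gain_nonevent,
               tolerance = 1e-12)
  td <- tidy(out)
  expect_identical(td$term, c("event", "nonevent", "total"))
})

test_that("binning plus tabulation reproduces a known joint distribution", {
  # reconstruct scores realizing the bundled ANN example table and check the
  # matrix round-trips through bin_scores + reclassification_table
  tabs <- ann_example_tables()
  mids <- c(0.1, 0.3, 0.6, 0.9)
  build <- function(tab, lab) {
    idx <- which(tab$counts > 0, arr.ind = TRUE)
    old <- rep(mids[idx[, 1]], tab$counts[idx])
    new <- rep(mids[idx[, 2]], tab$counts[idx])
    tibble::tibble(old = old, new = new, label = lab)
  }
  df <- dplyr::bind_rows(build(tabs$event, 1), build(tabs$nonevent, 0))
  re <- reclassification_table(bin_scores(df$old, "ANN"),
                               bin_scores(df$new, "ANN"), df$label)
  expect_identical(re$event$counts, matrix(as.integer(tabs$event$counts), 4, 4,
                                           dimnames = dimnames(re$event$counts)))
  expect_identical(sum(re$event$counts), 169L)
  expect_identical(sum(re$nonevent$counts), 334L)
})
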