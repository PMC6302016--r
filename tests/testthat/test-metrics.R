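test_that("confusion tally matches a hand count cell by cell", {
  cm <- confusion_from_predictions(c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_equal(cm[c("tp", "fn", "fp", "tn")], list(tp = 1L, fn = 1L, fp = 1L, tn = 1L))

  truth <- c(rep(1, 4), rep(0, 6))
  cm <- confusion_from_predictions(truth, truth)
  expect_equal(cm[c("tp", "tn", "fp", "fn")], list(tp = 4L, tn = 6L, fp = 0L, fn = 0L))

  set.seed(5)
  for (k in 1:20) {
    truth <- rbinom(50, 1, 0.3); screen <- rbinom(50, 1, 0.5)
    cm <- confusion_from_predictions(truth, screen)
    # brute-force tally
    expect_equal(cm$tp, sum(truth & screen))
    expect_equal(cm$fp, sum(!truth & screen))
    expect_equal(cm$tn, sum(!truth & !screen))
    expect_equal(cm$fn, sum(truth & !screen))
    # order invariance
    perm <- sample(50)
    expect_identical(unclass(confusion_from_predictions(truth[perm], screen[perm])),
                     unclass(cm))
  }
  expect_error(confusion_from_predictions(c(1, 0), 1),
               class = "uroscreen_contract_error")
})

test_that("metric formulas reproduce the false-negative accounting", {
  # 10 of 213 culture-positives missed in a 1220-sample cohort
  ms <- metrics_from_confusion(confusion_matrix(tp = 203, fp = 298, tn = 709, fn = 10))
  expect_equal(ms$se, 203 / 213)
  expect_equal(ms$prevalence, 213 / 1220)
  ms2 <- metrics_from_confusion(confusion_matrix(tp = 204, fp = 560, tn = 447, fn = 9))
  expect_equal(ms2$se, 204 / 213)
  # all-positive cohort, perfect screen
  ms3 <- metrics_from_confusion(confusion_matrix(tp = 7, fp = 0, tn = 0, fn = 0))
  expect_equal(ms3$se, 1)
  expect_equal(ms3$accuracy, 1)
  expect_equal(ms3$reduction, 0)
  expect_setequal(ms3$undefined, c("sp", "npv"))
  expect_true(is.na(ms3$sp))
})

test_that("Bayes identities agree with direct confusion accounting everywhere", {
  set.seed(31)
  for (k in 1:40) {
    cells <- rmultinom(1, size = sample(20:400, 1), prob = runif(4, 0.05, 1))[, 1]
    if (cells[1] + cells[4] == 0 || cells[2] + cells[3] == 0) next
    cm <- confusion_matrix(tp = cells[1], fp = cells[2], tn = cells[3], fn = cells[4])
    direct <- metrics_from_confusion(cm)
    via_rates <- rates_to_predictive_values(direct$se, direct$sp, direct$prevalence)
    for (f in c("ppv", "npv", "reduction", "accuracy"))
      expect_equal(via_rates[[f]], direct[[f]], tolerance = 1e-12)
    # reduction + screened-positive fraction = 1
    n <- sum(cells)
    expect_equal(direct$reduction + (cm$tp + cm$fp) / n, 1)
    # accuracy = 1 - error rate
    expect_equal(direct$accuracy, 1 - (cm$fp + cm$fn) / n)
  }
  ms <- rates_to_predictive_values(1, 1, 0.3)
  expect_equal(ms$ppv, 1); expect_equal(ms$npv, 1); expect_equal(ms$reduction, 0.7)
  expect_error(rates_to_predictive_values(1.2, 0.5, 0.5),
               class = "uroscreen_contract_error")
})

test_that("zero denominators flag metrics as undefined, never as zero", {
  ms <- rates_to_predictive_values(0, 1, 0.5)   # nothing screens positive
  expect_true(is.na(ms$ppv))
  expect_equal(ms$undefined, "ppv")
  ms2 <- metrics_from_confusion(confusion_matrix(tp = 0, fp = 0, tn = 5, fn = 3))
  expect_true(is.na(ms2$ppv))
  expect_false(is.na(ms2$npv))
})

test_that("Wilson interval matches the closed form and its boundaries", {
  expect_equal(proportion_ci(10, 10)[["upper"]], 1)
  expect_equal(proportion_ci(0, 10)[["lower"]], 0)
  # independent closed-form evaluation
  wilson <- function(x, n, level) {
    z <- qnorm(1 - (1 - level) / 2)
    p <- x / n
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    c(centre - half, centre + half)
  }
  for (case in list(c(50, 100), c(203, 213), c(3, 17))) {
    got <- proportion_ci(case[1], case[2], 0.95)
    expect_equal(unname(got), wilson(case[1], case[2], 0.95), tolerance = 1e-10)
    expect_true(got[["lower"]] <= case[1] / case[2] &&
                  case[1] / case[2] <= got[["upper"]])
  }
  expect_error(proportion_ci(11, 10), class = "uroscreen_contract_error")
})

test_that("metric sets serialize to JSON and one-row CSV with *_pct views", {
  ms <- metrics_from_confusion(confusion_matrix(tp = 203, fp = 298, tn = 709, fn = 10))
  jpath <- withr::local_tempfile(fileext = ".json")
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_metrics(ms, jpath)
  write_metrics(ms, cpath)
  j <- jsonlite::read_json(jpath)
  expect_equal(j$se, 203 / 213)
  expect_equal(j$se_pct, 95.3)
  csv <- readr::read_csv(cpath, show_col_types = FALSE)
  expect_equal(csv$sp, 709 / 1007)
  expect_equal(csv$sp_pct, 70.4)
  expect_equal(csv$reduction_pct, 58.9)
})
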