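test_that("the OR rule flags a sample when either channel reaches its cut-off", {
  rule <- dual_rule(138, 119.8)
  expect_equal(apply_rule(rule, bacteria = 150, wbc = 0), 1L)
  expect_equal(apply_rule(rule, bacteria = 0, wbc = 200), 1L)
  expect_equal(apply_rule(rule, bacteria = 0, wbc = 0), 0L)
  expect_equal(apply_rule(dual_rule(10, 10, combiner = "and"),
                          bacteria = c(15, 15), wbc = c(15, 5)), c(1L, 0L))
  expect_error(apply_rule(rule, bacteria = NA_real_, wbc = 1),
               class = "uroscreen_contract_error")
})

test_that("OR dominance: the combined rule is at least as sensitive and at most as specific as either channel alone", {
  set.seed(23)
  for (k in 1:15) {
    inst <- random_instance(40)
    tb <- sample(inst$bac, 1); tw <- sample(inst$wbc, 1)
    truth <- inst$truth
    m_or <- metrics_from_confusion(confusion_from_predictions(
      truth, apply_rule(dual_rule(tb, tw), inst$bac, inst$wbc)))
    m_b <- metrics_from_confusion(confusion_from_predictions(
      truth, as.integer(inst$bac >= tb)))
    m_w <- metrics_from_confusion(confusion_from_predictions(
      truth, as.integer(inst$wbc >= tw)))
    expect_gte(m_or$se, max(m_b$se, m_w$se))
    expect_lte(m_or$sp, min(m_b$sp, m_w$sp))
  }
})

test_that("joint optimization equals the naive double-loop search", {
  set.seed(41)
  for (k in 1:25) {
    inst <- random_instance(sample(10:45, 1))
    co <- make_cohort(inst$bac, inst$wbc, inst$truth)
    for (crit in c("youden", "se_floor")) {
      got <- optimize_dual(co, criterion = crit, se_target = 0.9)
      want <- dual_oracle(inst$bac, inst$wbc, inst$truth, crit, se_target = 0.9)
      expect_equal(got$rule$t_bac, want$t_bac)
      expect_equal(got$rule$t_wbc, want$t_wbc)
      expect_equal(got$metrics$se, want$se)
      expect_equal(got$metrics$sp, want$sp)
    }
  }
})

test_that("a signal-free WBC channel degrades the rule to the single bacteria marker", {
  set.seed(9)
  bac <- c(runif(20, 0, 50), runif(8, 40, 120))
  truth <- c(rep(0, 20), rep(1, 8))
  co <- make_cohort(bac, wbc = rep(5, 28), truth = truth)
  opt <- optimize_dual(co, criterion = "se_floor", se_target = 0.95)
  single <- best_single_cutoff(bac, truth, "se_floor", se_target = 0.95)
  expect_equal(opt$rule$t_wbc, Inf)
  expect_equal(opt$rule$t_bac, single$threshold)
  expect_equal(opt$metrics$se, single$metrics$se)
  expect_equal(opt$metrics$sp, single$metrics$sp)
})

test_that("restricting one channel to +Inf reproduces best_single_cutoff exactly", {
  set.seed(57)
  for (k in 1:12) {
    inst <- random_instance(sample(15:40, 1))
    co <- make_cohort(inst$bac, inst$wbc, inst$truth)
    for (crit in c("youden", "se_floor")) {
      viadual <- optimize_dual(co, criterion = crit, se_target = 0.9,
                               wbc_grid = Inf)
      single <- best_single_cutoff(inst$bac, inst$truth, crit, se_target = 0.9)
      expect_equal(viadual$rule$t_bac, single$threshold)
      expect_equal(viadual$rule$t_wbc, Inf)
      expect_identical(unclass(viadual$confusion), unclass(single$confusion))
    }
  }
})

test_that("an unachievable sensitivity floor reports the maximum achievable", {
  co <- make_cohort(c(1, 2, 3, 4), c(1, 1, 1, 1), c(0, 0, 1, 1))
  err <- expect_error(
    optimize_dual(co, criterion = "se_floor", se_target = 0.95,
                  bac_grid = Inf, wbc_grid = Inf),
    class = "uroscreen_contract_error")
  expect_match(conditionMessage(err), "max achievable se = 0")
})

test_that("the Pareto front equals brute-force dominance filtering and contains every optimum", {
  sep <- make_cohort(c(1, 2, 50, 60), c(1, 2, 3, 4), c(0, 0, 1, 1))
  front <- pareto_front(sep)
  expect_equal(nrow(front), 1L)
  expect_equal(front$se, 1); expect_equal(front$sp, 1)

  set.seed(83)
  for (k in 1:10) {
    inst <- random_instance(15)
    co <- make_cohort(inst$bac, inst$wbc, inst$truth)
    front <- pareto_front(co)
    want <- pareto_oracle(inst$bac, inst$wbc, inst$truth)
    expect_equal(nrow(front), nrow(want))
    expect_equal(front$se, want$se)
    expect_equal(front$sp, want$sp)
    # no member dominates another
    for (a in seq_len(nrow(front)))
      expect_false(any(front$se >= front$se[a] & front$sp >= front$sp[a] &
                         (front$se > front$se[a] | front$sp > front$sp[a])))
    # criterion optima sit on the front
    yo <- optimize_dual(co, "youden")$metrics
    fl <- optimize_dual(co, "se_floor", se_target = 0.8)$metrics
    expect_true(any(abs(front$se - yo$se) < 1e-12 & abs(front$sp - yo$sp) < 1e-12))
    expect_true(any(abs(front$se - fl$se) < 1e-12 & abs(front$sp - fl$sp) < 1e-12))
  }
})
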