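test_that("binormal AUC closed form behaves at its anchors", {
  expect_equal(binormal_auc(2, 2, 1, 1), 0.5)
  # independent evaluation of the normal CDF at (0, 1.386, 1, 1)
  expect_equal(binormal_auc(0, 1.386, 1, 1), pnorm(1.386 / sqrt(2)))
  expect_equal(binormal_auc(0, 1.386, 1, 1), 0.8365, tolerance = 5e-4)
  # swapping classes mirrors the value
  expect_equal(binormal_auc(1.386, 0, 1, 1), 1 - binormal_auc(0, 1.386, 1, 1))
  expect_error(binormal_auc(0, 1, -1, 1), class = "uroscreen_contract_error")
})

test_that("separation calibration inverts the closed form", {
  expect_equal(calibrate_separation(0.5), 0)
  expect_equal(calibrate_separation(0.943), 2.235, tolerance = 5e-4)
  for (target in c(0.6, 0.832, 0.864, 0.943, 0.99)) {
    for (sig in list(c(1, 1), c(0.5, 2))) {
      d <- calibrate_separation(target, sig[1], sig[2])
      expect_equal(binormal_auc(0, d, sig[1], sig[2]), target, tolerance = 1e-10)
    }
  }
  expect_error(calibrate_separation(1), class = "uroscreen_contract_error")
})

test_that("calibrated channels place the 95%-sensitivity cut-off where asked", {
  ch <- calibrated_channel(0.943, cutoff_at_se = 138)
  # 95% of the positive class lies at or above 138 counts/uL
  expect_equal(1 - pnorm(log(138), ch$mu_pos, ch$sigma_pos), 0.95)
  expect_equal(binormal_auc(ch), 0.943)
})

test_that("generation is deterministic and prefix-stable in n", {
  cfg <- function(n) generator_config(n = n, seed = 2024)
  a <- generate_cohort(cfg(80))
  b <- generate_cohort(cfg(80))
  expect_identical(a$samples, b$samples)
  longer <- generate_cohort(cfg(120))
  expect_identical(longer$samples[1:80, ], a$samples)
})

test_that("generated cohorts match their configured prevalence and class structure", {
  co <- generate_cohort(generator_config(n = 5000, seed = 99))
  truth <- culture_truth(co)
  # exact 99% binomial bounds around 213/1220
  bounds <- qbinom(c(0.005, 0.995), 5000, 213 / 1220)
  expect_gte(sum(truth), bounds[1])
  expect_lte(sum(truth), bounds[2])
  # contaminated samples are always truth-negative
  expect_true(all(truth[co$samples$contaminated] == 0L))
  # colony counts are consistent with the class labels
  expect_true(all(co$samples$culture_cfu_per_mL[truth == 1L] >= 1e5))
  expect_true(all(co$samples$culture_cfu_per_mL[truth == 0L] < 1e5))
})

test_that("uncorrelated channels show no within-class log-count correlation", {
  prof <- default_device_profile("UF1000i")
  prof$rho <- 0
  co <- generate_cohort(generator_config(n = 3000, seed = 5,
                                         contamination_rate = 0,
                                         device = prof))
  truth <- culture_truth(co)
  for (cls in c(0L, 1L)) {
    n_cls <- sum(truth == cls)
    r <- cor(log(co$samples$bacteria_per_uL[truth == cls]),
             log(co$samples$wbc_per_uL[truth == cls]))
    # zero up to sampling error: sd of r under independence is ~1/sqrt(n)
    expect_lt(abs(r), 3.5 / sqrt(n_cls))
  }
})

test_that("a shared scale shift rescales counts without touching separability", {
  base_prof <- default_device_profile("UF1000i")
  shifted_prof <- base_prof
  shift <- -log(138 / 5.7)
  shifted_prof$scale_shift <- base_prof$scale_shift + shift
  base <- generate_cohort(generator_config(n = 600, seed = 31, device = base_prof))
  shifted <- generate_cohort(generator_config(n = 600, seed = 31,
                                              device = shifted_prof))
  expect_equal(shifted$samples$bacteria_per_uL,
               base$samples$bacteria_per_uL * exp(shift), tolerance = 1e-12)
  truth <- culture_truth(base)
  expect_identical(truth, culture_truth(shifted))
  expect_equal(build_roc(shifted$samples$bacteria_per_uL, truth)$auc,
               build_roc(base$samples$bacteria_per_uL, truth)$auc,
               tolerance = 1e-12)
  cut_base <- best_single_cutoff(base$samples$bacteria_per_uL, truth,
                                 "se_floor", se_target = 0.95)
  cut_shift <- best_single_cutoff(shifted$samples$bacteria_per_uL, truth,
                                  "se_floor", se_target = 0.95)
  expect_equal(cut_shift$threshold / cut_base$threshold, exp(shift),
               tolerance = 1e-9)
  expect_equal(cut_shift$metrics$se, cut_base$metrics$se)
  expect_equal(cut_shift$metrics$sp, cut_base$metrics$sp)
})
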