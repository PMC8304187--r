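test_that("the default cohort has 65 patients and the documented columns", {
  coh <- generate_cohort(cohort_spec())
  expect_equal(nrow(coh), 65)
  expect_true(all(c("id", "age", "sex", "stage", "treatment", "bm_suv",
                    "tlg", "entropy", "time", "event", "true_bm_high",
                    "true_lp") %in% names(coh)))
  expect_true(all(coh$time > 0))
  expect_true(all(coh$event %in% 0:1))
  expect_true(all(coh$stage %in% c("I", "II", "III", "IV")))
})

test_that("cohort generation is reproducible under a fixed seed", {
  a <- generate_cohort(cohort_spec(seed = 42))
  b <- generate_cohort(cohort_spec(seed = 42))
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(cohort_spec(seed = 43))))
})

test_that("null cohorts (all planted log-HRs zero) yield Cox HRs near 1", {
  # average over replicates: a single n = 2000 draw has log-HR standard
  # error ~0.065, so the mean over 5 cohorts tests the 0.9-1.1 band at >3 SE
  hrs <- sapply(101:105, function(s) {
    spec <- cohort_spec(n = 2000, log_hr = c(bm_suv = 0, tlg = 0, entropy = 0,
                                             age = 0, stage3 = 0, stage4 = 0),
                        baseline_hazard = log(2) / 24, seed = s)
    coh <- generate_cohort(spec)
    fit <- cox_fit(coh, c("true_bm_high", "true_tlg_high",
                          "true_entropy_high"))
    fit$table$hr
  })
  expect_true(all(rowMeans(hrs) > 0.9 & rowMeans(hrs) < 1.1))
})

test_that("a planted HR of 2 is recovered within [1.8, 2.2] at n = 2000", {
  spec <- cohort_spec(n = 2000,
                      log_hr = c(bm_suv = log(2), tlg = 0, entropy = 0,
                                 age = 0, stage3 = 0, stage4 = 0),
                      baseline_hazard = log(2) / 24,
                      target_censoring = 0.2, seed = 7)
  coh <- generate_cohort(spec)
  coh$bm_high <- coh$true_bm_high
  fit <- cox_fit(coh, "bm_high")
  hr <- fit$table$hr[fit$table$covariate == "bm_high"]
  expect_gt(hr, 1.8)
  expect_lt(hr, 2.2)
})

test_that("realized censoring tracks the configured target within 5 points", {
  for (target in c(0.2, 0.43, 0.6)) {
    coh <- generate_cohort(cohort_spec(n = 1000, target_censoring = target,
                                       baseline_hazard = log(2) / 14,
                                       seed = round(100 * target)))
    expect_lt(abs(mean(coh$event == 0) - target), 0.05)
  }
})

test_that("planted log-hazard ratios are recovered without bias and with nominal coverage", {
  beta <- log(2)
  reps <- 200
  est <- se <- numeric(reps)
  for (r in seq_len(reps)) {
    spec <- cohort_spec(n = 500,
                        log_hr = c(bm_suv = beta, tlg = 0, entropy = 0,
                                   age = 0, stage3 = 0, stage4 = 0),
                        baseline_hazard = log(2) / 24,
                        target_censoring = 0.3, seed = 5000 + r)
    coh <- generate_cohort(spec)
    fit <- survival::coxph(survival::Surv(time, event) ~ true_bm_high,
                           data = coh)
    est[r] <- stats::coef(fit)[1]
    se[r] <- sqrt(stats::vcov(fit)[1, 1])
  }
  expect_lt(abs(mean(est) - beta), 0.1)
  cover <- mean(est - 1.96 * se <= beta & beta <= est + 1.96 * se)
  expect_gte(cover, 0.90)
  expect_lte(cover, 0.99)
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(n = 0), "n must be")
  expect_error(cohort_spec(baseline_hazard = -0.1), "positive rate")
  expect_error(cohort_spec(censor_rate = -1), "positive rate")
  expect_error(cohort_spec(stage_probs = c(0.5, 0.5, 0.5, 0.5)), "sum to 1")
})

test_that("the eligibility filter reproduces sequential exclusion arithmetic", {
  reg <- synthetic_registry(97, c(6, 14, 3, 4, 5), seed = 3)
  res <- apply_eligibility_filter(reg)
  expect_equal(res$n_eligible, 65)
  expect_equal(unname(res$exclusions), c(6, 14, 3, 4, 5))
  expect_setequal(res$eligible_ids, reg$id[reg$eligible])
})

test_that("an all-clear registry is fully eligible and an empty one handled", {
  reg <- synthetic_registry(10, c(0, 0, 0, 0, 0))
  res <- apply_eligibility_filter(reg)
  expect_equal(res$n_eligible, 10)
  expect_true(all(res$exclusions == 0))
  empty <- apply_eligibility_filter(reg[0, ])
  expect_equal(empty$n_eligible, 0L)
})

test_that("a patient matching two criteria is tallied only under the earlier one", {
  reg <- synthetic_registry(5, c(0, 0, 0, 0, 0))
  reg$supportive_care_only[2] <- TRUE
  reg$tumor_below_64_voxels[2] <- TRUE
  res <- apply_eligibility_filter(reg)
  expect_equal(unname(res$exclusions), c(0, 1, 0, 0, 0))
  expect_equal(res$n_eligible, 4)
})
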