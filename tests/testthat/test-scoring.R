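test_that("score assignment follows the strict-cutoff rules", {
  rule <- scoring_rule()
  # all factors below their cutoffs
  s0 <- assign_score(10, 3.0, 1.2, rule)
  expect_equal(s0$total, 0); expect_equal(s0$group, "0-2")
  # cohort-median TLG and marrow SUV exceed their cutoffs: 1 + 2 points
  s3 <- assign_score(55.54, 3.0, 1.74, rule)
  expect_equal(s3$total, 3); expect_equal(s3$group, "3")
  expect_equal(unname(s3$points), c(1, 0, 2))
  # boundary values score zero (comparisons are strict)
  sb <- assign_score(41.40, 3.40, 1.53, rule)
  expect_equal(sb$total, 0)
  # all high: the maximum summed score of 4
  s4 <- assign_score(100, 4.0, 2.0, rule)
  expect_equal(s4$total, 4); expect_equal(s4$group, "4")
})

test_that("missing factors are rejected naming the factor", {
  expect_error(assign_score(NA, 3.0, 1.2), "tlg")
  expect_error(assign_score(50, NA, 1.2), "entropy")
  expect_error(assign_score(50, 3.0, NA), "bm_suv")
})

test_that("attainable totals over the 8 indicator combinations are exactly 0..4", {
  rule <- scoring_rule()
  lo <- list(tlg = 10, entropy = 3.0, bm_suv = 1.2)
  hi <- list(tlg = 100, entropy = 4.0, bm_suv = 2.0)
  totals <- sapply(0:7, function(bits) {
    v <- lapply(c(tlg = 1, entropy = 2, bm_suv = 4), function(b)
      if (bitwAnd(bits, b) > 0) hi else lo)
    assign_score(v$tlg$tlg, v$entropy$entropy, v$bm_suv$bm_suv, rule)$total
  })
  expect_setequal(totals, 0:4)
  # group pooling: totals 0,1,2 share the reference group
  groups <- ifelse(totals <= 2, "0-2", as.character(totals))
  expect_setequal(groups, c("0-2", "3", "4"))
})

test_that("jointly rescaling TLG values and cutoff leaves every score unchanged", {
  set.seed(77)
  tlg <- stats::rlnorm(100, log(50), 1)
  ent <- stats::rnorm(100, 3.4, 0.3)
  bm <- stats::rlnorm(100, log(1.7), 0.2)
  k <- 12.5
  s1 <- assign_score(tlg, ent, bm, scoring_rule())
  s2 <- assign_score(tlg * k, ent, bm,
                     scoring_rule(tlg_cutoff = 41.40 * k))
  expect_identical(s1, s2)
})

test_that("the manual rule reproduces the reference cutoffs verbatim", {
  coh <- generate_cohort(cohort_spec(seed = 1))
  rule <- derive_rule(coh, "manual")
  expect_equal(rule$tlg_cutoff, 41.40)
  expect_equal(rule$entropy_cutoff, 3.40)
  expect_equal(rule$bm_suv_cutoff, 1.53)
  expect_equal(unname(rule$weights), c(1L, 1L, 2L))
})

test_that("derived cutoffs recover planted change-points within 10%", {
  spec <- cohort_spec(n = 600,
                      log_hr = c(bm_suv = log(4.3), tlg = log(3),
                                 entropy = log(3), age = 0,
                                 stage3 = 0, stage4 = 0),
                      baseline_hazard = log(2) / 24,
                      target_censoring = 0.25, seed = 19)
  coh <- generate_cohort(spec)
  rule <- derive_rule(coh, "derived")
  expect_lt(abs(rule$bm_suv_cutoff - 1.53) / 1.53, 0.10)
  expect_lt(abs(rule$tlg_cutoff - 41.40) / 41.40, 0.10)
  expect_lt(abs(rule$entropy_cutoff - 3.40) / 3.40, 0.10)
  expect_s3_class(attr(rule, "maxstat")$bm_suv, "cutoff_result")
})

test_that("a constant marker column makes rule derivation fail loudly", {
  coh <- generate_cohort(cohort_spec(n = 100, seed = 2))
  coh$tlg <- 50
  expect_error(derive_rule(coh, "derived"), "constant")
})

test_that("planted monotone effects produce ordered group hazards and survival", {
  spec <- cohort_spec(n = 2000, seed = 5)   # defaults plant positive effects
  coh <- generate_cohort(spec)
  rep <- evaluate_stratification(coh, scoring_rule())
  tab <- rep$overall$table
  expect_equal(tab$group, c("0-2", "3", "4"))
  expect_equal(sum(tab$n), 2000)
  expect_equal(tab$hr[1], 1)
  expect_gt(tab$hr[2], 1)
  expect_gt(tab$hr[3], tab$hr[2])
  mean_surv <- sapply(c("0-2", "3", "4"), function(g)
    mean(rep$scored$time[rep$scored$group == g]))
  expect_true(mean_surv[1] > mean_surv[2] && mean_surv[2] > mean_surv[3])
  expect_gt(rep$c_index$c_index, 0.5)
})

test_that("a score independent of survival has C-index near one half", {
  set.seed(23)
  cs <- replicate(100, {
    n <- 300
    score <- sample(0:4, n, replace = TRUE)
    tm <- stats::rexp(n, 0.05)
    harrell_c(score, tm, rep(1, n), n_boot = 0)$c_index
  })
  expect_lt(abs(mean(cs) - 0.5), 0.05)
})

test_that("subgroup tables partition the cohort in every split", {
  coh <- generate_cohort(cohort_spec(n = 400, seed = 13))
  rep <- evaluate_stratification(coh, scoring_rule())
  for (pair in list(c("stage_I_II", "stage_III_IV"),
                    c("surgery", "other_treatment"))) {
    n1 <- sum(rep$subgroups[[pair[1]]]$table$n)
    n2 <- sum(rep$subgroups[[pair[2]]]$table$n)
    expect_equal(n1 + n2, 400)
  }
})

test_that("an empty prognostic group keeps explicit missing markers", {
  coh <- generate_cohort(cohort_spec(n = 150, seed = 3))
  coh$bm_suv <- pmin(coh$bm_suv, 1.4)     # nobody exceeds the host cutoff
  rep <- evaluate_stratification(coh, scoring_rule())
  tab <- rep$overall$table
  expect_equal(tab$n[tab$group %in% c("3", "4")], c(0L, 0L))
  expect_true(all(is.na(tab$hr[tab$group == "4"])))
})
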