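test_that("Spearman correlation handles monotone, constant and null cases", {
  expect_equal(spearman_correlation(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_correlation(1:10, -(1:10)^2)$rho, -1)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_error(spearman_correlation(1:3, 1:4), "equal length")
  # null simulation: mean rho near 0
  set.seed(1)
  rhos <- replicate(200, spearman_correlation(stats::rnorm(1000),
                                              stats::rnorm(1000))$rho)
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("the log-rank scan statistic agrees with survdiff and the Cox score test", {
  set.seed(42)
  n <- 150
  x <- stats::rbinom(n, 1, 0.4)
  tm <- stats::rexp(n, 0.05 * exp(0.6 * x)) + stats::runif(n, 0, 1e-4)
  ev <- as.integer(stats::runif(n) < 0.8)
  lr <- petscore:::logrank_chisq(x, tm, ev)
  sd <- survival::survdiff(survival::Surv(tm, ev) ~ x)
  expect_equal(lr$chisq, sd$chisq, tolerance = 1e-9)
  # tie-free data: log-rank equals the Cox score test
  sc <- survival::coxph(survival::Surv(tm, ev) ~ x)$score
  expect_equal(lr$chisq, sc, tolerance = 1e-6)
})

test_that("maxstat recovers a planted cutpoint at 1.53 within 0.1 at n = 400", {
  set.seed(11)
  n <- 400
  x <- stats::rlnorm(n, log(1.74), 0.19)        # marrow-SUV-like marker
  g <- as.integer(x > 1.53)
  tm <- stats::rexp(n, 0.03 * exp(log(3) * g))
  cens <- stats::rexp(n, 0.0075)
  time <- pmin(tm, cens); ev <- as.integer(tm <= cens)
  res <- maxstat_cutoff(x, time, ev, variable = "bm_suv")
  expect_lt(abs(res$cutoff - 1.53), 0.1)
  expect_equal(res$direction, "high")
  expect_gte(res$statistic, 0)
  expect_true(res$cutoff > res$candidate_range[1] - 1e-12 &&
                res$cutoff < max(x))
})

test_that("maximal selection inflates the null statistic relative to a fixed cutpoint", {
  set.seed(3)
  max_stats <- fixed_stats <- numeric(200)
  for (r in 1:200) {
    n <- 60
    x <- stats::rnorm(n)
    time <- stats::rexp(n, 0.1)
    ev <- rep(1L, n)
    max_stats[r] <- maxstat_cutoff(x, time, ev)$statistic
    fixed_stats[r] <- petscore:::logrank_chisq(x > stats::median(x),
                                               time, ev)$chisq
  }
  # stochastically larger: compare distributions, not single draws
  expect_gt(mean(max_stats), mean(fixed_stats))
  expect_gt(stats::median(max_stats), stats::median(fixed_stats))
  expect_gt(mean(max_stats > fixed_stats), 0.5)
})

test_that("maxstat rejects degenerate inputs", {
  tm <- stats::rexp(50, 0.1); ev <- rep(1L, 50)
  expect_error(maxstat_cutoff(rep(2, 50), tm, ev), "constant")
  expect_error(maxstat_cutoff(stats::rnorm(10), tm[1:10], ev[1:10]), "20")
  expect_error(maxstat_cutoff(stats::rnorm(50), tm, rep(0L, 50)), "events")
})

test_that("maxstat cutpoint error shrinks as the cohort grows", {
  mae <- sapply(c(100, 400, 1600), function(n) {
    errs <- sapply(1:15, function(r) {
      set.seed(7000 + 17 * n + r)
      x <- stats::runif(n, 0, 3)
      g <- as.integer(x > 1.5)
      tm <- stats::rexp(n, 0.05 * exp(1.2 * g))
      ev <- rep(1L, n)
      abs(maxstat_cutoff(x, tm, ev)$cutoff - 1.5)
    })
    stats::median(errs)
  })
  expect_gt(mae[1], mae[3])
  expect_lte(mae[2], mae[1] + 1e-9)
})

test_that("Cox fit recovers a planted hazard ratio and flags separation", {
  coh <- simple_ph_cohort(2000, log(2), censor_rate = 0.0125, seed = 21)
  fit <- cox_fit(coh, "x")
  hr <- fit$table$hr[1]
  expect_gt(hr, 1.8); expect_lt(hr, 2.2)
  expect_true(fit$c_index$c_index > 0.5)
  # complete separation: all events in one arm, none in the other
  bad <- data.frame(x = rep(0:1, each = 25),
                    time = c(stats::rexp(25, 1), rep(10, 25)),
                    event = rep(c(1L, 0L), each = 25))
  expect_error(suppressWarnings(cox_fit(bad, "x")), "separation|diverged")
})

test_that("Cox confidence intervals achieve nominal coverage under the null", {
  cover <- logical(200)
  for (r in 1:200) {
    coh <- simple_ph_cohort(120, 0, censor_rate = 0.0125, seed = 900 + r)
    fit <- survival::coxph(survival::Surv(time, event) ~ x, data = coh)
    b <- stats::coef(fit)[1]; s <- sqrt(stats::vcov(fit)[1, 1])
    cover[r] <- (b - 1.96 * s) <= 0 && 0 <= (b + 1.96 * s)
  }
  expect_gte(mean(cover), 0.90)
})

test_that("Harrell's C honours its pair conventions", {
  # perfect concordance: risk equals negative survival time, no censoring
  tm <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(harrell_c(-tm, tm, rep(1, 6), n_boot = 0)$c_index, 1.0)
  # all risks tied: every usable pair counts 1/2
  expect_equal(harrell_c(rep(0, 6), tm, rep(1, 6), n_boot = 0)$c_index, 0.5)
  # censored-before-event pairs are unusable
  expect_error(harrell_c(1:3, c(1, 2, 3), c(0, 0, 0), n_boot = 0), "usable")
  # agreement with the survival package on tie-free data
  set.seed(5)
  n <- 300
  risk <- stats::rnorm(n)
  tm2 <- stats::rexp(n, exp(0.8 * risk) * 0.05)
  ev2 <- as.integer(stats::runif(n) < 0.7)
  ours <- harrell_c(risk, tm2, ev2, n_boot = 0)$c_index
  ref <- survival::concordance(survival::Surv(tm2, ev2) ~ risk,
                               reverse = TRUE)$concordance
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("a random predictor scores C near one half with a bootstrap interval covering it", {
  set.seed(31)
  cs <- replicate(100, {
    tm <- stats::rexp(500, 0.05)
    harrell_c(stats::rnorm(500), tm, rep(1, 500), n_boot = 0)$c_index
  })
  expect_lt(abs(mean(cs) - 0.5), 0.03)
  # bootstrap CI machinery: seeded and reproducible
  tm <- stats::rexp(200, 0.05)
  r <- stats::rnorm(200)
  a <- harrell_c(r, tm, rep(1, 200), n_boot = 200, seed = 4)
  b <- harrell_c(r, tm, rep(1, 200), n_boot = 200, seed = 4)
  expect_identical(a, b)
  expect_true(a$ci_lower <= a$c_index && a$c_index <= a$ci_upper)
})

test_that("the true linear predictor outperforms any single noised covariate", {
  wins <- 0L
  for (r in 1:50) {
    set.seed(1200 + r)
    n <- 500
    x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
    lp <- 0.8 * x1 + 0.8 * x2
    tm <- stats::rexp(n, 0.05 * exp(lp))
    c_lp <- harrell_c(lp, tm, rep(1, n), n_boot = 0)$c_index
    c_x1 <- harrell_c(x1, tm, rep(1, n), n_boot = 0)$c_index
    c_x2 <- harrell_c(x2, tm, rep(1, n), n_boot = 0)$c_index
    if (c_lp > max(c_x1, c_x2)) wins <- wins + 1L
  }
  expect_equal(wins, 50L)
})

test_that("the KM estimator matches the empirical survivor function without censoring", {
  km <- km_estimate(1:10, rep(1, 10), horizon = 5)
  expect_equal(km$horizon_surv, 0.5)
  expect_equal(km$median, 5)
  expect_equal(km$surv, 1 - (1:10) / 10)
  expect_false(km$extrapolated)
  # all censored: median is an explicit missing marker
  kmc <- km_estimate(1:10, rep(0, 10))
  expect_true(is.na(kmc$median))
  # horizon beyond follow-up is flagged
  expect_true(km_estimate(1:10, rep(1, 10), horizon = 99)$extrapolated)
})

test_that("the KM median of exponential survival with true median 14.1 is recovered at n = 5000", {
  set.seed(61)
  tm <- stats::rexp(5000, rate = log(2) / 14.1)
  km <- km_estimate(tm, rep(1, 5000))
  expect_gte(km$median, 13.4)
  expect_lte(km$median, 14.8)
  expect_true(km$median_ci[1] <= km$median && km$median <= km$median_ci[2])
})
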