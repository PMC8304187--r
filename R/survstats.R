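#' Spearman rank correlation
#'
#' Rank-based correlation with average ranks for ties and an asymptotic
#' two-sided p-value (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with \code{rho} and \code{p_value}.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 observations are required")
  if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

# Log-rank chi-square for a binary grouping, with hypergeometric variance
# (handles tied death times). Returns the statistic plus the score U so the
# risk direction is visible.
logrank_chisq <- function(group, time, event) {
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord] != 0; g_s <- group[ord] != 0
  ut <- unique(t_s)
  ti <- match(t_s, ut)
  U_len <- length(ut)
  cnt_all <- tabulate(ti, U_len)
  cnt_g <- tabulate(ti[g_s], U_len)
  d_all <- tabulate(ti[e_s], U_len)
  d_g <- tabulate(ti[e_s & g_s], U_len)
  at_risk <- rev(cumsum(rev(cnt_all)))
  at_risk_g <- rev(cumsum(rev(cnt_g)))
  use <- d_all > 0 & at_risk > 1
  n <- at_risk[use]; n1 <- at_risk_g[use]
  d <- d_all[use]; d1 <- d_g[use]
  U <- sum(d1 - d * n1 / n)
  V <- sum(d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1))
  chisq <- if (V > 0) U^2 / V else 0
  list(chisq = chisq, U = U, V = V)
}

#' Maximally selected chi-square cutpoint
#'
#' Scans candidate cutpoints (the observed values between the given
#' percentile bounds) and, for each, dichotomizes at "<= c vs > c" and
#' computes the log-rank chi-square; the cutpoint maximizing the statistic
#' is returned (ties broken toward the smaller cutoff). Because the
#' statistic is maximized over many candidate splits, its naive chi-square
#' p-value is optimistic; the improved Bonferroni-type p-value of the
#' maximally selected statistic is reported alongside for transparency.
#'
#' @param values numeric marker, non-constant.
#' @param time,event survival time and 0/1 event indicator.
#' @param bounds percentile bounds of the candidate grid (default 10th to
#'   90th percentile).
#' @param min_group smallest admissible group size per side (default 3).
#' @param variable optional marker name carried into the result.
#' @return A list of class \code{cutoff_result}: \code{variable},
#'   \code{cutoff}, \code{statistic} (maximal chi-square),
#'   \code{direction} (\code{"high"} if values above the cutoff carry the
#'   higher hazard), \code{p_naive}, \code{p_corrected},
#'   \code{n_candidates}, \code{candidate_range}.
#' @export
maxstat_cutoff <- function(values, time, event, bounds = c(0.1, 0.9),
                           min_group = 3L, variable = "value") {
  n <- length(values)
  if (length(time) != n || length(event) != n)
    stop("values, time and event must have equal length")
  if (n < 20L) stop("at least 20 subjects are required")
  if (sum(event != 0) < 5L) stop("at least 5 events are required")
  if (stats::sd(values) == 0)
    stop("marker is constant; no cutpoint can be selected")
  if (length(bounds) != 2L || bounds[1] >= bounds[2] ||
      bounds[1] <= 0 || bounds[2] >= 1)
    stop("bounds must be increasing percentiles strictly inside (0, 1)")

  qs <- stats::quantile(values, bounds, names = FALSE)
  cand <- sort(unique(values[values >= qs[1] & values <= qs[2]]))
  cand <- cand[cand < max(values)]   # "> c" must leave a non-empty high group

  best <- NULL
  stat <- rep(NA_real_, length(cand))
  for (k in seq_along(cand)) {
    g <- values > cand[k]
    if (min(sum(g), n - sum(g)) < min_group) next
    stat[k] <- logrank_chisq(g, time, event)$chisq
  }
  if (all(is.na(stat)))
    stop("no candidate cutpoint leaves both groups with at least ",
         min_group, " subjects")
  k <- which.max(stat)    # ties go to the smaller (earlier) cutoff
  lr <- logrank_chisq(values > cand[k], time, event)
  b <- sqrt(lr$chisq)
  q1 <- bounds[1]; q2 <- bounds[2]
  p_corr <- stats::dnorm(b) * (b - 1 / b) *
    log(q2 * (1 - q1) / (q1 * (1 - q2))) + 4 * stats::dnorm(b) / b
  structure(list(variable = variable, cutoff = cand[k],
                 statistic = lr$chisq,
                 direction = if (lr$U > 0) "high" else "low",
                 p_naive = stats::pchisq(lr$chisq, 1, lower.tail = FALSE),
                 p_corrected = min(1, max(0, p_corr)),
                 n_candidates = sum(!is.na(stat)),
                 candidate_range = range(cand)),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Maximally selected cutpoint for '%s': %.4g (chi-square %.2f, %s = risk)\n",
              x$variable, x$cutoff, x$statistic, x$direction))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit (Efron tie handling, via [survival::coxph()])
#' of the covariates of interest plus optional adjusters (the conventional
#' adjusted model uses age and sex). Hazard ratios, Wald confidence
#' intervals and p-values are reported per covariate, together with
#' Harrell's concordance index of the model's linear predictor. Warns (the
#' usual rule of thumb, not an error) when there are fewer than ten events
#' per free covariate; fails explicitly on non-convergence or monotone
#' likelihood (complete separation).
#'
#' @param cohort data.frame with \code{time}, \code{event} and the model
#'   columns.
#' @param covariates character vector of covariates of interest.
#' @param adjust character vector of adjusters (default none).
#' @param label model label carried into the result.
#' @param n_boot bootstrap resamples for the C-index interval (0 = point
#'   estimate only).
#' @param seed seed for the bootstrap.
#' @return A list of class \code{cox_model_result}: \code{label},
#'   \code{table} (covariate, hr, ci_lower, ci_upper, p_value),
#'   \code{c_index} (with CI columns when \code{n_boot > 0}), \code{n},
#'   \code{events}, \code{fit} (the underlying \code{coxph} object).
#' @export
cox_fit <- function(cohort, covariates, adjust = character(0),
                    label = paste(covariates, collapse = "+"),
                    n_boot = 0L, seed = 1L) {
  vars <- unique(c(covariates, adjust))
  miss <- setdiff(c("time", "event", vars), names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  nev <- sum(cohort$event != 0)
  if (nev < 10 * length(vars))
    warning(sprintf("only %d events for %d covariates (< 10 per covariate)",
                    nev, length(vars)))
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(vars, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = cohort, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite", conditionMessage(w)))
        stop("Cox fit failed (non-convergence or complete separation): ",
             conditionMessage(w), call. = FALSE)
      suppressWarnings(survival::coxph(fml, data = cohort, ties = "efron"))
    })
  sm <- summary(fit)
  if (any(!is.finite(stats::coef(fit))) || any(abs(stats::coef(fit)) > 15))
    stop("Cox fit failed: a coefficient diverged (complete separation of ",
         "an event group)")
  tab <- data.frame(covariate = rownames(sm$coefficients),
                    hr = sm$coefficients[, "exp(coef)"],
                    ci_lower = sm$conf.int[, "lower .95"],
                    ci_upper = sm$conf.int[, "upper .95"],
                    p_value = sm$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  risk <- stats::predict(fit, type = "lp")
  cidx <- harrell_c(risk, cohort$time, cohort$event, n_boot = n_boot,
                    seed = seed)
  structure(list(label = label, table = tab, c_index = cidx,
                 n = nrow(cohort), events = nev, fit = fit),
            class = "cox_model_result")
}

#' @export
print.cox_model_result <- function(x, ...) {
  cat(sprintf("Cox model '%s' (n = %d, events = %d, C-index %.3f)\n",
              x$label, x$n, x$events, x$c_index$c_index))
  print(x$table, digits = 3)
  invisible(x)
}

#' Harrell's concordance index
#'
#' The proportion of usable patient pairs in which the patient dying
#' earlier has the higher predicted risk. A pair is usable when the shorter
#' time is an event (or times are tied with discordant event status, in
#' which case the death is taken as the earlier outcome); tied event times
#' with both events are unusable. Risk ties count 0.5. The confidence
#' interval is a seeded percentile bootstrap over patients.
#'
#' Pair counting is done with O(n^2) matrices; intended for cohorts up to a
#' few thousand patients.
#'
#' @param risk numeric predicted risk (higher = worse).
#' @param time,event survival time and 0/1 event indicator.
#' @param n_boot bootstrap resamples (default 1000; 0 skips the interval).
#' @param conf_level confidence level (default 0.95).
#' @param seed bootstrap seed.
#' @return List with \code{c_index} and, when \code{n_boot > 0},
#'   \code{ci_lower}, \code{ci_upper}, \code{n_boot}.
#' @export
harrell_c <- function(risk, time, event, n_boot = 1000L, conf_level = 0.95,
                      seed = 1L) {
  n <- length(risk)
  if (length(time) != n || length(event) != n)
    stop("risk, time and event must have equal length")
  cstat <- function(idx) {
    r <- risk[idx]; t <- time[idx]; e <- event[idx] != 0
    em <- matrix(e, length(idx), length(idx))
    case <- (outer(t, t, `<`) & em) |
            (outer(t, t, `==`) & em & !t(em))   # row = case, col = control
    den <- sum(case)
    if (den == 0) return(NA_real_)
    conc <- sum(case & outer(r, r, `>`)) + 0.5 * sum(case & outer(r, r, `==`))
    conc / den
  }
  c0 <- cstat(seq_len(n))
  if (is.na(c0))
    stop("no usable pairs (no events, or all times tied with equal status)")
  out <- list(c_index = c0)
  if (n_boot > 0) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    cb <- vapply(seq_len(n_boot),
                 function(i) cstat(sample.int(n, n, replace = TRUE)),
                 numeric(1))
    cb <- cb[!is.na(cb)]
    a <- (1 - conf_level) / 2
    qs <- stats::quantile(cb, c(a, 1 - a), names = FALSE)
    out$ci_lower <- qs[1]; out$ci_upper <- qs[2]; out$n_boot <- n_boot
  }
  out
}

#' Kaplan-Meier survival summary
#'
#' Product-limit estimate via [survival::survfit()]; the reported median is
#' the earliest time at which the estimated survival drops to 0.5 or below,
#' with its confidence interval from the Brookmeyer-Crowley construction
#' (inverting the pointwise survival interval). Survival at a queried
#' horizon is read from the step function; a horizon beyond the last
#' observed time is flagged as extrapolated.
#'
#' @param time,event survival time (months) and 0/1 event indicator.
#' @param horizon optional time (months) at which to report survival.
#' @param conf_level confidence level (default 0.95).
#' @return A list of class \code{km_curve}: \code{time}, \code{surv},
#'   \code{n_risk}, \code{median}, \code{median_ci}, \code{horizon},
#'   \code{horizon_surv}, \code{extrapolated}, \code{n}, \code{events}.
#'   The median and its interval are \code{NA} when survival never reaches
#'   0.5.
#' @export
km_estimate <- function(time, event, horizon = NULL, conf_level = 0.95) {
  if (length(time) < 1L) stop("at least one subject is required")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.int = conf_level)
  tab <- summary(fit)$table
  # earliest time at which the step function reaches 0.5 (survfit instead
  # averages the two flanking times when S(t) hits 0.5 exactly)
  med <- if (any(fit$surv <= 0.5)) min(fit$time[fit$surv <= 0.5]) else NA_real_
  lcl <- unname(tab[grep("LCL", names(tab))])
  ucl <- unname(tab[grep("UCL", names(tab))])
  out <- list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
              median = med, median_ci = c(lcl, ucl),
              horizon = horizon, horizon_surv = NA_real_,
              extrapolated = FALSE,
              n = length(time), events = sum(event != 0))
  if (!is.null(horizon)) {
    out$horizon_surv <- summary(fit, times = horizon, extend = TRUE)$surv
    out$extrapolated <- horizon > max(time)
  }
  structure(out, class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  med <- if (is.na(x$median)) "not reached"
         else sprintf("%.1f (95%% CI %.1f-%.1f)", x$median,
                      x$median_ci[1], x$median_ci[2])
  cat(sprintf("Kaplan-Meier: n = %d, events = %d, median OS %s months\n",
              x$n, x$events, med))
  if (!is.null(x$horizon))
    cat(sprintf("  survival at %.4g months: %.3f%s\n", x$horizon,
                x$horizon_surv, if (x$extrapolated) " (extrapolated)" else ""))
  invisible(x)
}
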