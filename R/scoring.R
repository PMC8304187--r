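#' Tumor + host PET scoring rule
#'
#' The integrated "seed and soil" rule: each tumor factor — total lesion
#' glycolysis (TLG) and first-order entropy — contributes 1 point when its
#' value strictly exceeds its cutoff; the host factor — bone-marrow SUV —
#' contributes 2 points when it strictly exceeds its cutoff. Totals 0–2, 3
#' and 4 define the three prognostic groups. The weights (1, 1, 2) are
#' fixed constants of the design, not fitted quantities. Values exactly at
#' a cutoff score 0 for that factor.
#'
#' Default cutoffs are 41.40 g (TLG), 3.40 (entropy) and 1.53 (BM SUV).
#'
#' @param tlg_cutoff TLG cutoff in grams.
#' @param entropy_cutoff first-order entropy cutoff (bits).
#' @param bm_suv_cutoff bone-marrow SUV cutoff.
#' @return A list of class \code{scoring_rule}.
#' @export
scoring_rule <- function(tlg_cutoff = 41.40, entropy_cutoff = 3.40,
                         bm_suv_cutoff = 1.53) {
  for (v in c(tlg_cutoff, entropy_cutoff, bm_suv_cutoff))
    if (!is.finite(v)) stop("cutoffs must be finite")
  structure(list(tlg_cutoff = tlg_cutoff, entropy_cutoff = entropy_cutoff,
                 bm_suv_cutoff = bm_suv_cutoff,
                 weights = c(tlg = 1L, entropy = 1L, bm_suv = 2L),
                 groups = c("0-2", "3", "4")),
            class = "scoring_rule")
}

#' @export
print.scoring_rule <- function(x, ...) {
  cat(sprintf(paste0("PET scoring rule: TLG > %.4g g (1 pt), entropy > %.4g ",
                     "(1 pt), BM SUV > %.4g (2 pts); groups 0-2 / 3 / 4\n"),
              x$tlg_cutoff, x$entropy_cutoff, x$bm_suv_cutoff))
  invisible(x)
}

#' Assign the 0–4 prognostic score
#'
#' Strict ">" comparisons against the rule's cutoffs; the per-factor points
#' are summed into the total and mapped to the prognostic group
#' (\code{"0-2"}, \code{"3"} or \code{"4"}). Vectorized over patients.
#' Missing inputs are an error naming the factor, never a silent 0.
#'
#' @param tlg total lesion glycolysis (g).
#' @param entropy first-order entropy (bits).
#' @param bm_suv bone-marrow SUV.
#' @param rule a [scoring_rule()].
#' @return For scalar input, a list of class \code{risk_score} with
#'   \code{points} (named per-factor vector), \code{total}, \code{group};
#'   for vector input, a \code{data.frame} with columns \code{tlg_points},
#'   \code{entropy_points}, \code{bm_suv_points}, \code{total},
#'   \code{group}.
#' @examples
#' assign_score(55.54, 3.0, 1.74, scoring_rule())$total  # 3
#' @export
assign_score <- function(tlg, entropy, bm_suv, rule = scoring_rule()) {
  stopifnot(inherits(rule, "scoring_rule"))
  for (f in c("tlg", "entropy", "bm_suv")) {
    v <- get(f)
    if (length(v) == 0L || anyNA(v))
      stop(sprintf("factor '%s' is missing; the score requires all three factors", f))
  }
  n <- max(length(tlg), length(entropy), length(bm_suv))
  tlg <- rep_len(tlg, n); entropy <- rep_len(entropy, n)
  bm_suv <- rep_len(bm_suv, n)
  p_tlg <- as.integer(tlg > rule$tlg_cutoff) * rule$weights[["tlg"]]
  p_ent <- as.integer(entropy > rule$entropy_cutoff) * rule$weights[["entropy"]]
  p_bm <- as.integer(bm_suv > rule$bm_suv_cutoff) * rule$weights[["bm_suv"]]
  total <- p_tlg + p_ent + p_bm
  group <- ifelse(total <= 2L, "0-2", as.character(total))
  if (n == 1L) {
    structure(list(points = c(tlg = p_tlg, entropy = p_ent, bm_suv = p_bm),
                   total = total, group = group),
              class = "risk_score")
  } else {
    data.frame(tlg_points = p_tlg, entropy_points = p_ent,
               bm_suv_points = p_bm, total = total, group = group,
               stringsAsFactors = FALSE)
  }
}

#' @export
print.risk_score <- function(x, ...) {
  cat(sprintf("Risk score %d (group %s): TLG %d + entropy %d + BM SUV %d\n",
              x$total, x$group, x$points[["tlg"]], x$points[["entropy"]],
              x$points[["bm_suv"]]))
  invisible(x)
}

#' Derive a scoring rule from a cohort
#'
#' Either packages manual cutoffs (the defaults reproduce the reference
#' rule: TLG 41.40 g, entropy 3.40, BM SUV 1.53) or derives each cutoff
#' from the cohort by maximally selected chi-square ([maxstat_cutoff()])
#' on the three markers.
#'
#' @param cohort data.frame with \code{bm_suv}, \code{tlg}, \code{entropy},
#'   \code{time}, \code{event} (the latter two only for derived mode).
#' @param mode \code{"manual"} (default) or \code{"derived"}.
#' @param manual_cutoffs named list/vector of manual cutoffs
#'   (\code{tlg}, \code{entropy}, \code{bm_suv}).
#' @param ... passed to [maxstat_cutoff()] in derived mode.
#' @return A [scoring_rule()]; in derived mode the per-marker
#'   \code{cutoff_result}s are attached as attribute \code{"maxstat"}.
#' @export
derive_rule <- function(cohort, mode = c("manual", "derived"),
                        manual_cutoffs = c(tlg = 41.40, entropy = 3.40,
                                           bm_suv = 1.53),
                        ...) {
  mode <- match.arg(mode)
  if (mode == "manual") {
    return(scoring_rule(tlg_cutoff = manual_cutoffs[["tlg"]],
                        entropy_cutoff = manual_cutoffs[["entropy"]],
                        bm_suv_cutoff = manual_cutoffs[["bm_suv"]]))
  }
  need <- c("bm_suv", "tlg", "entropy", "time", "event")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  cuts <- lapply(c(tlg = "tlg", entropy = "entropy", bm_suv = "bm_suv"),
                 function(v) maxstat_cutoff(cohort[[v]], cohort$time,
                                            cohort$event, variable = v, ...))
  rule <- scoring_rule(tlg_cutoff = cuts$tlg$cutoff,
                       entropy_cutoff = cuts$entropy$cutoff,
                       bm_suv_cutoff = cuts$bm_suv$cutoff)
  attr(rule, "maxstat") <- cuts
  rule
}

subgroup_report <- function(scored, label) {
  groups <- c("0-2", "3", "4")
  km <- lapply(groups, function(g) {
    rows <- scored$group == g
    if (!any(rows)) return(NULL)
    km_estimate(scored$time[rows], scored$event[rows])
  })
  names(km) <- groups
  counts <- vapply(groups, function(g) sum(scored$group == g), integer(1))
  events <- vapply(groups, function(g)
    sum(scored$event[scored$group == g] != 0), integer(1))
  hr <- data.frame(group = groups, n = counts, events = events,
                   hr = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                   p_value = NA_real_,
                   median_os = vapply(km, function(k)
                     if (is.null(k)) NA_real_ else k$median, numeric(1)),
                   stringsAsFactors = FALSE)
  hr$hr[1] <- 1   # reference
  present <- groups[counts > 0]
  if (length(present) >= 2 && counts[1] > 0 && sum(events) > 0) {
    dat <- scored[scored$group %in% present, ]
    dat$group <- factor(dat$group, levels = present)
    fit <- tryCatch(cox_fit(dat, "group", label = label, n_boot = 0),
                    error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit)) {
      for (g in present[-1]) {
        row <- grep(paste0("group", g, "$"), fit$table$covariate)
        if (length(row) == 1) {
          k <- match(g, groups)
          hr$hr[k] <- fit$table$hr[row]
          hr$ci_lower[k] <- fit$table$ci_lower[row]
          hr$ci_upper[k] <- fit$table$ci_upper[row]
          hr$p_value[k] <- fit$table$p_value[row]
        }
      }
    }
  }
  list(label = label, table = hr, km = km)
}

#' Evaluate prognostic stratification of the scoring system
#'
#' Scores every patient, estimates per-group Kaplan-Meier curves, fits a
#' Cox model with the prognostic group as a categorical covariate
#' (reference group \code{"0-2"}), computes Harrell's C of the total score,
#' and repeats the group-wise comparison in the four predefined subgroups:
#' clinical stage I–II vs III–IV, and surgical resection vs other
#' treatments. Groups that are empty (overall or within a subgroup) keep
#' explicit \code{NA} markers instead of hazard ratios.
#'
#' @param cohort data.frame with \code{tlg}, \code{entropy}, \code{bm_suv},
#'   \code{time}, \code{event}, and (for subgroups) \code{stage},
#'   \code{treatment}.
#' @param rule a [scoring_rule()].
#' @param n_boot bootstrap resamples for the C-index interval.
#' @param seed bootstrap seed.
#' @return A list of class \code{stratification_report}: \code{overall}
#'   (group table + KM curves), \code{c_index}, \code{subgroups} (list by
#'   split), \code{scored} (the cohort with score columns).
#' @export
evaluate_stratification <- function(cohort, rule = scoring_rule(),
                                    n_boot = 0L, seed = 1L) {
  need <- c("tlg", "entropy", "bm_suv", "time", "event")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks columns: ", paste(miss, collapse = ", "))
  sc <- assign_score(cohort$tlg, cohort$entropy, cohort$bm_suv, rule)
  scored <- cbind(cohort, sc)
  overall <- subgroup_report(scored, "overall")
  cidx <- harrell_c(scored$total, scored$time, scored$event,
                    n_boot = n_boot, seed = seed)
  subgroups <- list()
  if ("stage" %in% names(scored)) {
    early <- scored$stage %in% c("I", "II")
    subgroups$stage_I_II <- subgroup_report(scored[early, ], "stage I-II")
    subgroups$stage_III_IV <- subgroup_report(scored[!early, ], "stage III-IV")
  }
  if ("treatment" %in% names(scored)) {
    surg <- scored$treatment == "surgery"
    subgroups$surgery <- subgroup_report(scored[surg, ], "surgical resection")
    subgroups$other_treatment <- subgroup_report(scored[!surg, ], "other treatments")
  }
  structure(list(overall = overall, c_index = cidx, subgroups = subgroups,
                 scored = scored, rule = rule),
            class = "stratification_report")
}

#' @export
print.stratification_report <- function(x, ...) {
  cat("Prognostic stratification by the PET scoring system\n")
  print(x$overall$table, digits = 3)
  cat(sprintf("C-index of the score: %.3f\n", x$c_index$c_index))
  invisible(x)
}
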