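#' Tertile assignment of eta
#'
#' Cut points at the empirical 1/3 and 2/3 quantiles of eta; groups are
#' labeled by decreasing eta — Q1 (highest eta, slowest vascular aging,
#' reference), Q2, Q3 (lowest eta, fastest aging). Intervals are closed on
#' the lower end of Q1 and half-open below: `eta >= c2 -> Q1`,
#' `c1 <= eta < c2 -> Q2`, `eta < c1 -> Q3`, so tie mass exactly at a cut
#' joins the higher-eta group.
#'
#' @param eta Numeric vector with at least 3 distinct values.
#' @return Object of class `tertile_assignment`: `cuts` (c1, c2) and
#'   `group` (factor Q1/Q2/Q3, Q1 first).
#' @export
tertile_assign <- function(eta) {
  if (length(unique(eta[!is.na(eta)])) < 3L)
    stopf("need at least 3 distinct eta values")
  cuts <- unname(quantile(eta, c(1, 2) / 3, na.rm = TRUE, type = 7))
  group <- factor(ifelse(eta >= cuts[2], "Q1",
                         ifelse(eta >= cuts[1], "Q2", "Q3")),
                  levels = c("Q1", "Q2", "Q3"))
  structure(list(cuts = cuts, group = group), class = "tertile_assignment")
}

#' Cox proportional-hazards fit for an exposure
#'
#' Partial-likelihood fit (Efron ties) of `Surv(time, status)` on an
#' exposure plus optional covariates. A numeric exposure is fitted as-is
#' (pass `-eta` for the "per 1 decrease" convention); a factor exposure is
#' fitted with its first level as reference (Q1 for tertiles). Warns when
#' there are fewer than 10 events per estimated coefficient.
#'
#' @param time Follow-up time.
#' @param status Event indicator (0/1).
#' @param exposure Numeric vector or factor.
#' @param covariates Optional data.frame (e.g. `data.frame(age = ...)`).
#' @return Data.frame with one row per exposure coefficient: `term`, `hr`,
#'   `lo`, `hi`, `p`; attributes `n`, `events`, `fit`.
#' @export
cox_fit <- function(time, status, exposure, covariates = NULL) {
  if (sum(status, na.rm = TRUE) == 0) stopf("no events")
  if (is.numeric(exposure) && var(exposure, na.rm = TRUE) == 0)
    stopf("exposure is constant across participants")
  df <- data.frame(.exposure = exposure)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df$.time <- time; df$.status <- status
  fml <- stats::reformulate(setdiff(names(df), c(".time", ".status")),
                            response = quote(survival::Surv(.time, .status)))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  sm <- summary(fit)
  n_coef <- length(coef(fit))
  if (sum(status, na.rm = TRUE) < 10 * n_coef)
    warnf("fewer than 10 events per coefficient (%d events, %d coefficients)",
          sum(status, na.rm = TRUE), n_coef)
  idx <- grep("^\\.exposure", rownames(sm$coefficients))
  terms <- sub("^\\.exposure", "", rownames(sm$coefficients)[idx])
  terms[terms == ""] <- "exposure"
  out <- data.frame(term = terms,
                    hr = sm$conf.int[idx, "exp(coef)"],
                    lo = sm$conf.int[idx, "lower .95"],
                    hi = sm$conf.int[idx, "upper .95"],
                    p = sm$coefficients[idx, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n") <- sm$n
  attr(out, "events") <- sm$nevent
  attr(out, "fit") <- fit
  out
}

#' k-group log-rank test
#'
#' @param time Follow-up time.
#' @param status Event indicator.
#' @param group Group labels (>= 2 groups, >= 1 event overall).
#' @return List: `chisq`, `df`, `p`.
#' @export
logrank_by_group <- function(time, status, group) {
  group <- droplevels(factor(group))
  if (nlevels(group) < 2L) stopf("need at least 2 groups")
  if (sum(status) == 0) stopf("no events")
  sd_ <- survival::survdiff(survival::Surv(time, status) ~ group)
  df <- length(sd_$n) - 1L
  list(chisq = sd_$chisq, df = df,
       p = pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Agreement between biological and chronological age
#'
#' Pearson correlation (with two-sided p) and the through-origin
#' proportional-agreement slope `sum(ba * ca) / sum(ca^2)`.
#'
#' @param ba Biological (vascular) age.
#' @param ca Chronological age.
#' @return List: `pearson_r`, `p`, `no_intercept_slope`, `n`.
#' @export
agreement_stats <- function(ba, ca) {
  keep <- !is.na(ba) & !is.na(ca)
  ba <- ba[keep]; ca <- ca[keep]
  if (length(ba) < 3L) stopf("need at least 3 complete pairs")
  if (var(ba) == 0 || var(ca) == 0) stopf("zero-variance input")
  ct <- cor.test(ba, ca)
  list(pearson_r = unname(ct$estimate), p = ct$p.value,
       no_intercept_slope = sum(ba * ca) / sum(ca^2), n = length(ba))
}

#' Cumulative incidence curves by group
#'
#' One-minus-Kaplan-Meier per group on the event-time grid, truncated at
#' the follow-up horizon. Curves are right-continuous step functions,
#' starting at (0, 0).
#'
#' @param time Follow-up time.
#' @param status Event indicator.
#' @param group Group labels.
#' @param horizon Truncation horizon (years).
#' @return Data.frame: `group`, `time`, `incidence`, `at_risk`.
#' @export
cumulative_incidence <- function(time, status, group, horizon = 10) {
  group <- droplevels(factor(group))
  sf <- survival::survfit(survival::Surv(time, status) ~ group)
  strata <- rep(names(sf$strata) %||% levels(group)[1], sf$strata %||% length(sf$time))
  strata <- sub("^group=", "", strata)
  out <- data.frame(group = strata, time = sf$time,
                    incidence = 1 - sf$surv, at_risk = sf$n.risk,
                    stringsAsFactors = FALSE)
  out <- out[out$time <= horizon, , drop = FALSE]
  starts <- data.frame(group = levels(group), time = 0, incidence = 0,
                       at_risk = as.vector(table(group)),
                       stringsAsFactors = FALSE)
  out <- rbind(starts, out)
  out <- out[order(match(out$group, levels(group)), out$time), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-subgroup Cox hazard ratios for eta
#'
#' Splits the cohort at a threshold of each stratifying factor and fits the
#' age-adjusted continuous-eta Cox model within each stratum. Strata
#' without events (or empty) are reported as non-estimable rather than
#' raising an error.
#'
#' @param records Cohort data.frame (`age`, the factors, time and status
#'   columns).
#' @param eta Per-participant eta aligned with `records`.
#' @param factors Named numeric vector or list of thresholds, e.g.
#'   `c(SBP = 140, FBG = 7)`.
#' @param time,status Column names.
#' @param adjust_age Adjust for chronological age (default TRUE).
#' @return Data.frame: `factor`, `stratum` (`low` = below threshold), `n`,
#'   `events`, `hr`, `lo`, `hi`, `p` (NA when non-estimable).
#' @export
risk_subgroup_analysis <- function(records, eta, factors,
                                   time = "followup_time",
                                   status = "cvd_event",
                                   adjust_age = TRUE) {
  assert_cols(records, c("age", time, status))
  if (any(names(factors) %in% c("eta", ".exposure")))
    warnf("stratifying on the exposure itself; estimates condition on the exposure")
  rows <- list()
  for (f in names(factors)) {
    thr <- factors[[f]]
    assert_cols(records, f)
    strata <- list(low = records[[f]] < thr, high = records[[f]] >= thr)
    for (sname in names(strata)) {
      sel <- strata[[sname]] & !is.na(strata[[sname]]) & !is.na(eta)
      n <- sum(sel)
      ev <- sum(records[[status]][sel])
      row <- data.frame(factor = f, stratum = sname, n = n, events = ev,
                        hr = NA_real_, lo = NA_real_, hi = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE)
      if (n >= 10 && ev >= 2 && var(eta[sel]) > 0) {
        fit <- tryCatch(suppressWarnings(cox_fit(
          records[[time]][sel], records[[status]][sel], -eta[sel],
          covariates = if (adjust_age) data.frame(age = records$age[sel]))),
          error = function(e) NULL)
        if (!is.null(fit)) row[, c("hr", "lo", "hi", "p")] <-
            fit[1, c("hr", "lo", "hi", "p")]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Full survival validation report for eta
#'
#' The evaluation battery on a follow-up cohort: continuous-eta Cox (crude
#' and age-adjusted, fitted on `-eta` so HR > 1 means faster vascular aging
#' raises risk), tertile Cox (Q1 reference, crude and adjusted), the
#' k-group log-rank test across tertiles, the restricted-cubic-spline
#' nonlinearity test of eta (age-adjusted), BA-vs-CA agreement statistics,
#' and 1 - KM cumulative-incidence curves by tertile.
#'
#' @param records Cohort data.frame with `age`, time and status columns.
#' @param scores Output of [score_cohort()] (columns `age`, `ba`, `eta`)
#'   aligned with `records` by `id` when present.
#' @param time,status Column names in `records`.
#' @param horizon Incidence-curve horizon (years).
#' @param rcs_k Spline knots for the nonlinearity test.
#' @return Object of class `survival_report`.
#' @export
eta_survival_report <- function(records, scores, time = "followup_time",
                                status = "cvd_event", horizon = 10,
                                rcs_k = 5) {
  assert_cols(records, c(time, status, "age"))
  if (!is.null(records$id) && !is.null(scores$id)) {
    m <- match(records$id, scores$id)
    keep <- !is.na(m)
    records <- records[keep, , drop = FALSE]
    scores <- scores[m[keep], , drop = FALSE]
  }
  eta <- scores$eta
  tt <- records[[time]]; ev <- records[[status]]
  tert <- tertile_assign(eta)
  age_cov <- data.frame(age = records$age)
  cont_crude <- cox_fit(tt, ev, -eta)
  cont_adj <- cox_fit(tt, ev, -eta, covariates = age_cov)
  tert_crude <- cox_fit(tt, ev, tert$group)
  tert_adj <- cox_fit(tt, ev, tert$group, covariates = age_cov)
  lr <- logrank_by_group(tt, ev, tert$group)
  nl <- tryCatch(rcs_cox(tt, ev, eta, covariates = age_cov, k = rcs_k),
                 error = function(e) NULL)
  agr <- agreement_stats(scores$ba, scores$age)
  ci <- cumulative_incidence(tt, ev, tert$group, horizon = horizon)
  structure(list(
    n = length(eta), events = sum(ev),
    continuous = list(crude = cont_crude, adjusted = cont_adj),
    tertile = list(cuts = tert$cuts, crude = tert_crude, adjusted = tert_adj),
    logrank = lr,
    rcs_nonlinearity_p = if (is.null(nl)) NA_real_ else nl$nonlin_p,
    agreement = agr,
    incidence_curves = ci, horizon = horizon
  ), class = "survival_report")
}

#' Serialize a survival report as JSON
#'
#' @param report A `survival_report`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written).
#' @export
serialize_report <- function(report, path = NULL) {
  x <- unclass(report)
  x$continuous <- lapply(x$continuous, function(d) as.list(d))
  x$tertile[c("crude", "adjusted")] <-
    lapply(x$tertile[c("crude", "adjusted")], function(d) as.list(d))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = I(17), null = "null",
                         dataframe = "columns")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' @export
print.survival_report <- function(x, ...) {
  cat(sprintf("Survival report: n = %d, events = %d\n", x$n, x$events))
  fmt <- function(d, lab) {
    for (i in seq_len(nrow(d)))
      cat(sprintf("  %-28s HR %.3f (%.3f-%.3f), p = %.3g\n",
                  paste(lab, d$term[i]), d$hr[i], d$lo[i], d$hi[i], d$p[i]))
  }
  fmt(x$continuous$crude, "eta per 1 decrease, crude")
  fmt(x$continuous$adjusted, "eta per 1 decrease, adj")
  fmt(x$tertile$adjusted, "tertile (adj)")
  cat(sprintf("  log-rank chi2 = %.2f (df %d), p = %.3g\n",
              x$logrank$chisq, x$logrank$df, x$logrank$p))
  cat(sprintf("  RCS nonlinearity p = %.3g\n", x$rcs_nonlinearity_p))
  cat(sprintf("  BA~CA r = %.3f, through-origin slope = %.3f\n",
              x$agreement$pearson_r, x$agreement$no_intercept_slope))
  invisible(x)
}
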