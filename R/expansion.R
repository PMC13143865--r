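#' Screen candidate biomarkers against eta tertiles by age group
#'
#' Within each age group (below / at-or-above `age_cutoff`), eta is cut
#' into tertiles and every candidate marker is tested for association
#' across the tertile groups. A candidate is selected iff its p-value is
#' below `alpha` in *both* age groups (the intersection rule). The default
#' screen is the Jonckheere-Terpstra monotone-trend test; the headline
#' difference test (ANOVA / Kruskal-Wallis by a normality screen) is
#' available via `test = "difference"`.
#'
#' @param records Chronic-disease-healthy records (markers on the raw
#'   scale).
#' @param eta Basic-model eta aligned with `records`.
#' @param candidates Candidate marker names.
#' @param age_cutoff Age-group boundary (years), default 50.
#' @param alpha Selection level per age group.
#' @param test `"jt"` (default) or `"difference"`.
#' @return Data.frame: `marker`, `p_young`, `p_old`, `selected`.
#' @export
select_candidates <- function(records, eta, candidates = CANDIDATE_MARKERS,
                              age_cutoff = 50, alpha = 0.05,
                              test = c("jt", "difference")) {
  test <- match.arg(test)
  assert_cols(records, c("age", candidates))
  groups <- list(young = records$age < age_cutoff,
                 old = records$age >= age_cutoff)
  if (any(!vapply(groups, any, TRUE))) stopf("an age group is empty")
  pmat <- sapply(names(groups), function(g) {
    sel <- groups[[g]]
    tert <- tertile_assign(eta[sel])
    vapply(candidates, function(m) {
      tr <- trend_tests(records[[m]][sel], tert$group)
      if (test == "jt") tr$jt_p else tr$headline_p
    }, 0)
  })
  data.frame(marker = candidates,
             p_young = pmat[, "young"], p_old = pmat[, "old"],
             selected = pmat[, "young"] < alpha & pmat[, "old"] < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Age-adjusted odds ratio per SD of eta, with bootstrap summary
#'
#' Logistic regression of prevalent CVD on standardized `-eta` plus
#' chronological age in the CVD-healthy case-control split. The reported
#' OR is per one SD *decrease* of eta, so OR > 1 means faster vascular
#' aging carries higher CVD odds. eta is standardized once on the full
#' dataset; the bootstrap resamples participants with replacement and
#' refits, summarizing the OR distribution (mean and 2.5/97.5 percentiles).
#'
#' @param records CVD-healthy records with a logical/0-1 `cvd_prevalent`
#'   column (or supply `cvd` directly).
#' @param eta Aligned eta values.
#' @param cvd Optional binary outcome overriding `records$cvd_prevalent`.
#' @param n_boot Bootstrap replicates, default 100.
#' @param seed Seed for the bootstrap.
#' @return List: `or` (point estimate), `se_log_or`, `ci` (Wald 95%),
#'   `boot` (`mean`, `lo`, `hi`, `n_ok`), `converged`, `n`, `cases`.
#' @export
or_per_sd <- function(records, eta, cvd = NULL, n_boot = 100, seed = 1L) {
  y <- cvd %||% records$cvd_prevalent
  if (is.null(y)) stopf("no binary CVD label found")
  y <- as.integer(y)
  keep <- !is.na(y) & !is.na(eta) & !is.na(records$age)
  y <- y[keep]; eta <- eta[keep]; age <- records$age[keep]
  if (length(unique(y)) < 2L) stopf("outcome has a single level")
  if (var(eta) == 0) stopf("eta has zero variance")
  x <- (-eta - mean(-eta)) / sd(eta)
  fit_one <- function(xx, yy, aa) {
    fit <- suppressWarnings(glm(yy ~ xx + aa, family = binomial()))
    ok <- fit$converged && abs(coef(fit)[["xx"]]) < 10
    list(or = exp(coef(fit)[["xx"]]),
         se = sqrt(diag(vcov(fit)))[["xx"]], ok = ok)
  }
  pt <- fit_one(x, y, age)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(length(y), replace = TRUE)
    r <- fit_one(x[i], y[i], age[i])
    if (r$ok) r$or else NA_real_
  }, 0)
  ok <- boot[!is.na(boot)]
  list(or = pt$or, se_log_or = pt$se,
       ci = exp(log(pt$or) + c(-1, 1) * qnorm(0.975) * pt$se),
       boot = list(mean = mean(ok), lo = unname(quantile(ok, 0.025)),
                   hi = unname(quantile(ok, 0.975)), n_ok = length(ok)),
       converged = pt$ok, n = length(y), cases = sum(y))
}

#' Greedy nested expansion of the vascular age model
#'
#' Starting from the fitted basic model, each remaining candidate marker is
#' tried in turn: the full pipeline (log transform, train-frozen z-score,
#' PCA over basic + accepted + candidate, KDM) is refitted on the training
#' split, eta is scored on the CVD-healthy case-control split, and the
#' age-adjusted OR per SD is computed. The best candidate is accepted iff
#' its point OR strictly exceeds the incumbent's; the loop stops when no
#' candidate improves the OR (`"no_improvement"`), candidates run out
#' (`"candidates_exhausted"`), or none were supplied (`"no_candidates"`).
#' Ties (ORs equal to 4 decimals) resolve to the earlier candidate in the
#' supplied order. The 100-replicate bootstrap is recorded per trial as an
#' uncertainty summary; selection uses the point OR.
#'
#' @param train Healthy-training records (raw scale, imputed, with MAP).
#' @param basic_model The fitted basic `vascular_age_model`.
#' @param candidates Candidate marker names.
#' @param cc_records CVD-healthy records (same sex filtering is applied
#'   from the model).
#' @param seed Seed; per-trial bootstrap seeds are derived from it.
#' @param n_boot Bootstrap replicates per trial.
#' @return List: `model` (tag `"expand"`), `trace` (data.frame, one row
#'   per tried candidate per iteration), `stop_reason`, `or_path`
#'   (accepted OR sequence, starting at the basic model's).
#' @export
greedy_expand <- function(train, basic_model, candidates, cc_records,
                          seed = 1L, n_boot = 100) {
  sex <- basic_model$sex
  cc <- if (!is.null(cc_records$sex))
    cc_records[cc_records$sex == sex, , drop = FALSE] else cc_records
  score_or <- function(model, trial_seed) {
    sc <- score_cohort(model, cc)
    or_per_sd(cc, sc$eta, n_boot = n_boot, seed = trial_seed)
  }
  base_or <- score_or(basic_model, sub_seed(seed, 0L))
  or_path <- base_or$or
  trace <- list()
  accepted <- character()
  remaining <- candidates
  stop_reason <- if (length(candidates) == 0L) "no_candidates" else NULL
  iter <- 0L
  incumbent <- base_or$or
  while (is.null(stop_reason)) {
    iter <- iter + 1L
    trial <- vector("list", length(remaining))
    for (ci in seq_along(remaining)) {
      cand <- remaining[ci]
      mk <- c(basic_model$markers, accepted, cand)
      res <- tryCatch({
        mod <- fit_vascular_age_model(
          train, markers = mk, sex = sex, tag = "nested",
          sign_convention = basic_model$pca$sign_convention,
          seed = seed)
        o <- score_or(mod, sub_seed(seed, iter * 1000L + ci))
        list(model = mod, or = o, error = NA_character_)
      }, error = function(e) list(model = NULL, or = NULL,
                                  error = conditionMessage(e)))
      ok <- !is.null(res$or) && res$or$converged
      trace[[length(trace) + 1L]] <- data.frame(
        iteration = iter, marker = cand,
        marker_set = paste(mk, collapse = "+"),
        or = if (!is.null(res$or)) res$or$or else NA_real_,
        boot_mean = if (!is.null(res$or)) res$or$boot$mean else NA_real_,
        boot_lo = if (!is.null(res$or)) res$or$boot$lo else NA_real_,
        boot_hi = if (!is.null(res$or)) res$or$boot$hi else NA_real_,
        converged = ok, accepted = FALSE,
        error = res$error %||% NA_character_,
        stringsAsFactors = FALSE)
      trial[[ci]] <- if (ok) res else NULL
    }
    ors <- vapply(trial, function(r) if (is.null(r)) -Inf else r$or$or, 0)
    if (all(!is.finite(ors))) { stop_reason <- "no_improvement"; break }
    best <- which.max(round(ors, 4))  # ties to 4 decimals -> earliest candidate
    if (ors[best] > incumbent) {
      accepted <- c(accepted, remaining[best])
      incumbent <- ors[best]
      or_path <- c(or_path, incumbent)
      ti <- length(trace) - length(remaining) + best
      trace[[ti]]$accepted <- TRUE
      remaining <- remaining[-best]
      if (length(remaining) == 0L) stop_reason <- "candidates_exhausted"
    } else stop_reason <- "no_improvement"
  }
  final <- fit_vascular_age_model(
    train, markers = c(basic_model$markers, accepted), sex = sex,
    tag = "expand", sign_convention = basic_model$pca$sign_convention,
    seed = seed)
  trace_df <- if (length(trace) > 0L) do.call(rbind, trace) else
    data.frame(iteration = integer(), marker = character(),
               marker_set = character(), or = numeric(),
               boot_mean = numeric(), boot_lo = numeric(),
               boot_hi = numeric(), converged = logical(),
               accepted = logical(), error = character(),
               stringsAsFactors = FALSE)
  list(model = final, trace = trace_df, stop_reason = stop_reason,
       or_path = or_path)
}

#' Write an expansion trace as CSV
#'
#' @param expansion Result of [greedy_expand()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_expansion_trace <- function(expansion, path) {
  write.csv(expansion$trace, path, row.names = FALSE)
  invisible(path)
}
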