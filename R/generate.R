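#' Simulate proportional-hazards event times
#'
#' Event times under a Weibull proportional-hazards model with cumulative
#' hazard `H(t) = lambda0 * exp(lp) * t^shape`: a standard-exponential draw
#' `E` is mapped to `T = (E / (lambda0 * exp(lp)))^(1/shape)`. With
#' `shape = 1` this is the exponential model, and scaling the rate by `c`
#' scales every event time by `1/c` exactly (for fixed draws `E`), which is
#' the proportional-hazards median-halving property the generator's tests
#' rely on.
#'
#' @param n Number of draws (ignored when `draws` supplied).
#' @param rate Per-individual rate multiplier `lambda0 * exp(lp)`; recycled.
#' @param shape Weibull shape (1 = exponential baseline).
#' @param draws Optional standard-exponential draws to reuse.
#' @return Numeric vector of event times (years).
#' @export
simulate_event_times <- function(n, rate, shape = 1, draws = NULL) {
  if (any(rate <= 0)) stopf("rate must be > 0")
  e <- draws %||% rexp(n)
  (e / rate)^(1 / shape)
}

apply_rule <- function(values, rule) {
  op <- match.fun(rule$op)
  out <- op(values, rule$value)
  out & !is.na(out)
}

#' Generate a synthetic cohort
#'
#' Draws, per participant: chronological age `ca ~ U(age_range)`, latent
#' acceleration `a_i ~ N(0, accel_sd^2)`, marker values
#' `intercept + slope * (ca + coupling * a_i) + N(0, sd^2)` (exponentiated
#' for skewed markers), chronic-disease flags from the threshold rules,
#' prevalent CVD from the logistic prevalence model, and an incident-CVD
#' event time from the proportional-hazards model
#' `lambda0 * exp(beta_age * ca + beta_a * a_i)`, administratively censored
#' at `followup_years`. Marker cells are then set missing completely at
#' random at `missing_rate`. Identical specs (including seed) produce
#' byte-identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame with one row per participant: `id`, `sex`, `age`,
#'   the generated markers, `flag_*` columns, `chronic_any`,
#'   `cvd_prevalent`, `cvd_event`, `followup_time`, `latent_accel`.
#' @export
generate_cohort <- function(spec) {
  spec <- validate_cohort_spec(spec)
  set.seed(spec$seed)
  per_sex <- lapply(c("male", "female"), function(sx) {
    n <- spec$n_per_sex
    tr <- spec$marker_trends[[sx]]
    ca <- runif(n, spec$age_range[1], spec$age_range[2])
    a  <- if (spec$accel_sd > 0) rnorm(n, 0, spec$accel_sd) else rep(0, n)
    markers <- matrix(NA_real_, n, nrow(tr),
                      dimnames = list(NULL, tr$marker))
    for (i in seq_len(nrow(tr))) {
      m <- tr$marker[i]
      cpl <- if (m %in% names(spec$coupling)) spec$coupling[[m]] else 0
      eff_age <- ca + cpl * a
      val <- tr$intercept[i] + tr$slope[i] * eff_age +
        (if (tr$sd[i] > 0) rnorm(n, 0, tr$sd[i]) else 0)
      if (m %in% spec$skewed_markers) val <- exp(val)
      markers[, i] <- val
    }
    df <- data.frame(sex = sx, age = ca, markers, stringsAsFactors = FALSE)
    # chronic flags on the noise-free-or-not generated values
    for (nm in names(spec$chronic_rules)) {
      rule <- spec$chronic_rules[[nm]]
      flag <- apply_rule(markers[, rule$marker], rule)
      if (spec$label_noise > 0) {
        flip <- runif(n) < spec$label_noise
        flag <- xor(flag, flip)
      }
      df[[paste0("flag_", nm)]] <- flag
    }
    flag_cols <- grep("^flag_", names(df), value = TRUE)
    df$chronic_any <- Reduce(`|`, df[flag_cols])
    lp_prev <- spec$prevalence$intercept + spec$prevalence$beta_age * ca +
      spec$prevalence$beta_a * a
    df$cvd_prevalent <- rbinom(n, 1, plogis(lp_prev)) == 1
    rate <- spec$hazard$lambda0 *
      exp(spec$hazard$beta_age * ca + spec$hazard$beta_a * a)
    tt <- simulate_event_times(n, rate, shape = spec$hazard$shape %||% 1)
    df$cvd_event <- as.integer(tt <= spec$followup_years)
    df$followup_time <- pmin(tt, spec$followup_years)
    df$latent_accel <- a
    df
  })
  out <- do.call(rbind, per_sex)
  out <- cbind(id = sprintf("P%05d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (spec$missing_rate > 0)
    out <- inject_missingness(out, spec$missing_rate)
  out
}

#' Set marker cells missing completely at random
#'
#' Each marker cell is independently set to `NA` with probability `rate`.
#' Age, sex, flags and outcomes are never touched.
#'
#' @param records Cohort data.frame.
#' @param rate Missingness probability in `[0, 1)`.
#' @param seed Optional seed; when `NULL` the current RNG stream is used
#'   (as inside [generate_cohort()]).
#' @param markers Marker columns to target.
#' @return The records with `NA`s injected.
#' @export
inject_missingness <- function(records, rate, seed = NULL,
                               markers = intersect(GENERATED_MARKERS, names(records))) {
  if (rate >= 1 || rate < 0) stopf("rate must be in [0, 1)")
  if (rate == 0) return(records)
  if (!is.null(seed)) set.seed(seed)
  mask <- matrix(runif(nrow(records) * length(markers)) < rate,
                 nrow = nrow(records))
  for (j in seq_along(markers))
    records[[markers[j]]][mask[, j]] <- NA_real_
  records
}

#' Assign analysis-split labels
#'
#' Writes a `split_label` partition over the non-excluded records:
#' `healthy_training` (no chronic flag, no prevalent CVD),
#' `chronic_case` (chronic flag, no prevalent CVD), and `cvd_case`
#' (prevalent CVD). The paper-style overlapping datasets (chronic-healthy,
#' CVD-healthy, cohort) are composed from these labels by
#' [split_dataset()].
#'
#' @param records Cohort data.frame with `flag_*` and `cvd_prevalent`.
#' @return The records with a `split_label` column.
#' @export
assign_splits <- function(records) {
  assert_cols(records, c("chronic_any", "cvd_prevalent"))
  lab <- ifelse(records$cvd_prevalent, "cvd_case",
                ifelse(records$chronic_any, "chronic_case", "healthy_training"))
  records$split_label <- lab
  records
}

#' Compose an analysis dataset from split labels
#'
#' * `healthy_training`: chronic-disease-free, CVD-free participants (model
#'   training).
#' * `chronic_healthy`: healthy controls plus non-CVD chronic-disease cases
#'   (candidate screening).
#' * `cvd_healthy`: healthy controls plus prevalent-CVD cases (case-control
#'   OR-per-SD evaluation).
#' * `cohort`: all participants free of CVD at baseline, with follow-up
#'   (survival validation).
#'
#' @param records Records carrying `split_label` (see [assign_splits()]).
#' @param which Dataset name.
#' @return The selected rows.
#' @export
split_dataset <- function(records,
                          which = c("healthy_training", "chronic_healthy",
                                    "cvd_healthy", "cohort")) {
  which <- match.arg(which)
  if (is.null(records$split_label)) records <- assign_splits(records)
  keep <- switch(which,
    healthy_training = records$split_label == "healthy_training",
    chronic_healthy  = records$split_label %in% c("healthy_training", "chronic_case"),
    cvd_healthy      = records$split_label %in% c("healthy_training", "cvd_case"),
    cohort           = records$split_label %in% c("healthy_training", "chronic_case")
  )
  records[keep, , drop = FALSE]
}

#' Write / read a cohort CSV
#'
#' Fixed, versioned column layout: `id`, `sex`, `age`, markers, `flag_*`,
#' `chronic_any`, `cvd_prevalent`, `cvd_event`, `followup_time`,
#' `latent_accel`, and `split_label` when present.
#'
#' @param records Cohort data.frame.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` the
#'   data.frame.
#' @export
write_cohort <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (nm in grep("^flag_|^chronic_any$|^cvd_prevalent$", names(df), value = TRUE))
    df[[nm]] <- as.logical(df[[nm]])
  df
}
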