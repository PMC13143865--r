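#' Default marker-vs-age trend table
#'
#' Per-sex linear trends (slope per effective year of vascular age, intercept
#' at age 0, residual SD) for every generated marker. Skewed markers (TG,
#' FBG, HbA1c, NLR, ESR) are parameterized on the natural-log scale and
#' exponentiated by the generator. Values are set so marker means and spreads
#' sit in physiologic ranges for an adult health-examination population
#' (e.g., baPWV about 1400 cm/s at age 45, SBP about 127 mmHg, ABI about
#' 1.11) and so the three vascular markers jointly carry a recoverable
#' latent-acceleration signal (see the methods vignette).
#'
#' @param sex `"male"` or `"female"`.
#' @return A data.frame with columns `marker`, `intercept`, `slope`, `sd`,
#'   and `log_scale`.
#' @export
default_marker_trends <- function(sex = c("male", "female")) {
  sex <- match.arg(sex)
  male <- data.frame(
    marker    = GENERATED_MARKERS,
    intercept = c(860, 1.25, 100, 62, 21.5, 4.0, 1.35, 2.2,
                  -0.10, 1.52, 1.60, 0.45, 1.2, 73),
    slope     = c(12, -0.003, 0.6, 0.30, 0.05, 0.012, -0.002, 0.012,
                  0.008, 0.0025, 0.0018, 0.002, 0.012, 0.02),
    sd        = c(100, 0.06, 9, 6, 2.8, 0.75, 0.28, 0.65,
                  0.45, 0.10, 0.07, 0.35, 0.55, 9),
    stringsAsFactors = FALSE
  )
  female <- male
  female$intercept <- c(820, 1.23, 96, 60, 20.5, 4.0, 1.50, 2.2,
                        -0.25, 1.52, 1.60, 0.45, 1.6, 73)
  female$slope[female$marker == "DBP"] <- 0.28
  out <- if (sex == "male") male else female
  out$log_scale <- out$marker %in% LOG_MARKERS
  out
}

#' Default chronic-disease threshold rules
#'
#' Single-threshold rules evaluated on the generated markers: lower-extremity
#' arterial blockage (ABI < 0.9), arterial calcification (ABI >= 1.4),
#' obesity (BMI >= 28 kg/m^2), elevated systolic/diastolic pressure
#' (SBP >= 140 / DBP >= 90 mmHg), and impaired fasting glucose
#' (FBG >= 7.0 mmol/L). Each rule produces a `flag_<name>` column; any true
#' flag marks the participant as a chronic-disease case.
#'
#' @return Named list of rules, each `list(marker, op, value)` with
#'   `op` one of `"<"`, `"<="`, `">"`, `">="`.
#' @export
default_chronic_rules <- function() {
  list(
    abi_low      = list(marker = "ABI", op = "<",  value = 0.9),
    abi_high     = list(marker = "ABI", op = ">=", value = 1.4),
    obesity      = list(marker = "BMI", op = ">=", value = 28),
    hypertension_sbp = list(marker = "SBP", op = ">=", value = 140),
    hypertension_dbp = list(marker = "DBP", op = ">=", value = 90),
    diabetes     = list(marker = "FBG", op = ">=", value = 7.0)
  )
}

#' Build a synthetic-cohort specification
#'
#' Describes a simulated health-examination cohort: sex-stratified uniform
#' ages, linear marker-age trends with Gaussian noise (log-normal for skewed
#' markers), a latent per-individual vascular-aging acceleration `a_i`
#' (years) loaded onto the vascular markers, proportional-hazards incident
#' CVD over a fixed follow-up window, a logistic prevalent-CVD model (for
#' the case-control split), threshold-based chronic-disease flags, and
#' missing-completely-at-random marker cells.
#'
#' @param n_per_sex Participants per sex.
#' @param age_range Chronological age interval (years), sampled uniformly.
#' @param marker_trends Named list with elements `male` and `female`, each a
#'   data.frame as returned by [default_marker_trends()].
#' @param skewed_markers Markers generated on the log scale.
#' @param accel_sd SD (years) of the latent acceleration `a_i`.
#' @param coupling Named vector: per-marker loading of `a_i` onto the
#'   marker's effective vascular age (`A_i = ca_i + coupling * a_i`).
#'   Defaults load the vascular markers (baPWV, ABI, SBP, DBP) with 1 and
#'   everything else with 0.
#' @param hazard List `lambda0` (baseline events/year), `beta_age` and
#'   `beta_a` (log-hazard per year of age / acceleration), `shape` (Weibull
#'   shape; 1 = exponential).
#' @param prevalence List `intercept`, `beta_age`, `beta_a` of the logistic
#'   model for prevalent CVD at baseline.
#' @param followup_years Administrative censoring horizon (years).
#' @param missing_rate MCAR probability for each marker cell, in `[0, 1)`.
#' @param chronic_rules Threshold rules, see [default_chronic_rules()].
#' @param label_noise Probability of flipping each chronic flag (label
#'   noise); default 0.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_sex = 1000,
                        age_range = c(20, 70),
                        marker_trends = list(male = default_marker_trends("male"),
                                             female = default_marker_trends("female")),
                        skewed_markers = LOG_MARKERS,
                        accel_sd = 5,
                        coupling = c(baPWV = 1, ABI = 1, SBP = 1, DBP = 1),
                        hazard = list(lambda0 = 2e-4, beta_age = 0.07,
                                      beta_a = 0.07, shape = 1),
                        prevalence = list(intercept = -8.5, beta_age = 0.10,
                                          beta_a = 0.10),
                        followup_years = 10,
                        missing_rate = 0.05,
                        chronic_rules = default_chronic_rules(),
                        label_noise = 0,
                        seed = 1L) {
  spec <- structure(list(
    n_per_sex = as.integer(n_per_sex), age_range = as.numeric(age_range),
    marker_trends = marker_trends, skewed_markers = skewed_markers,
    accel_sd = accel_sd, coupling = coupling, hazard = hazard,
    prevalence = prevalence, followup_years = followup_years,
    missing_rate = missing_rate, chronic_rules = chronic_rules,
    label_noise = label_noise, seed = as.integer(seed)
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
}

validate_cohort_spec <- function(spec) {
  if (spec$n_per_sex <= 0L) stopf("n_per_sex must be positive")
  if (length(spec$age_range) != 2L || diff(spec$age_range) <= 0)
    stopf("age_range must be an increasing interval")
  if (spec$accel_sd < 0) stopf("accel_sd must be >= 0")
  if (spec$missing_rate < 0 || spec$missing_rate >= 1)
    stopf("missing_rate must be in [0, 1)")
  if (spec$hazard$lambda0 <= 0) stopf("hazard$lambda0 must be > 0")
  if (is.null(spec$hazard$shape)) spec$hazard$shape <- 1
  for (sx in c("male", "female")) {
    tr <- spec$marker_trends[[sx]]
    if (is.null(tr)) stopf("marker_trends must have a '%s' element", sx)
    assert_cols(tr, c("marker", "intercept", "slope", "sd"),
                sprintf("marker_trends$%s", sx))
    if (any(tr$sd < 0)) stopf("residual SDs must be >= 0")
    if (anyDuplicated(tr$marker)) stopf("duplicate marker in trends")
  }
  bad <- setdiff(names(spec$coupling),
                 spec$marker_trends$male$marker)
  if (length(bad) > 0L)
    stopf("coupling names not in marker list: %s", paste(bad, collapse = ", "))
  spec
}

#' Write / read a cohort specification as YAML
#'
#' Serializes everything except function objects; threshold rules are plain
#' lists so the round trip is lossless.
#'
#' @param spec A `cohort_spec`.
#' @param path File path.
#' @return `write_cohort_spec` returns `path` invisibly; `read_cohort_spec`
#'   returns a `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  x <- unclass(spec)
  x$coupling <- as.list(x$coupling)
  x$marker_trends <- lapply(x$marker_trends, function(tr)
    lapply(seq_len(nrow(tr)), function(i) as.list(tr[i, , drop = FALSE])))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  x <- yaml::read_yaml(path)
  x$marker_trends <- lapply(x$marker_trends, function(rows)
    do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE))))
  x$coupling <- unlist(x$coupling)
  x$age_range <- as.numeric(unlist(x$age_range))
  do.call(cohort_spec, x[setdiff(names(x), character(0))])
}
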