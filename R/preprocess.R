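#' Mean arterial pressure
#'
#' `MAP = DBP + (SBP - DBP) / 3`, the standard one-third-pulse-pressure
#' formula. Vectorized; `NA`s propagate.
#'
#' @param sbp Systolic blood pressure (mmHg).
#' @param dbp Diastolic blood pressure (mmHg).
#' @return MAP in mmHg.
#' @export
compute_map <- function(sbp, dbp) {
  bad <- !is.na(sbp) & !is.na(dbp) & sbp < dbp
  if (any(bad))
    stopf("SBP < DBP for %d record(s): inputs look inverted", sum(bad))
  if (any(!is.na(dbp) & dbp <= 0)) stopf("DBP must be positive")
  dbp + (sbp - dbp) / 3
}

#' Apply inclusion and exclusion criteria
#'
#' Drops records lacking age, outside the study age range, carrying an
#' exclusion diagnosis flag, or missing more than `max_missing` of the
#' marker panel. Idempotent: applying it to its own output changes nothing.
#'
#' @param records Cohort data.frame.
#' @param age_range Inclusion age interval (years).
#' @param markers Marker panel over which missingness is counted.
#' @param exclusion_flags Names of logical columns that disqualify a record
#'   (e.g. malignancy or valve-disease flags); default none.
#' @param max_missing Maximum tolerated missing fraction of the panel.
#' @return `list(records = kept rows, exclusions = data.frame(id, reason))`.
#'   Reasons, in precedence order: `missing_age`, `age_range`,
#'   `exclusion_diagnosis`, `missingness`.
#' @export
apply_inclusion <- function(records, age_range = c(20, 70),
                            markers = intersect(ALL_MARKERS, names(records)),
                            exclusion_flags = character(),
                            max_missing = 0.5) {
  assert_cols(records, "age")
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  reason[is.na(records$age)] <- "missing_age"
  ok_age <- !is.na(records$age) &
    records$age >= age_range[1] & records$age <= age_range[2]
  reason[is.na(reason) & !ok_age] <- "age_range"
  for (fl in exclusion_flags) {
    hit <- isTRUE_vec(records[[fl]])
    reason[is.na(reason) & hit] <- "exclusion_diagnosis"
  }
  if (length(markers) > 0L) {
    miss_frac <- rowMeans(is.na(records[, markers, drop = FALSE]))
    reason[is.na(reason) & miss_frac > max_missing] <- "missingness"
  }
  keep <- is.na(reason)
  excl <- data.frame(id = if (!is.null(records$id)) records$id[!keep]
                     else which(!keep),
                     reason = reason[!keep], stringsAsFactors = FALSE)
  list(records = records[keep, , drop = FALSE], exclusions = excl)
}

isTRUE_vec <- function(x) !is.null(x) & !is.na(x) & x

#' Natural-log transform of skewed markers
#'
#' Applies `log()` in place to the listed markers only (default: TG, FBG,
#' HbA1c, ESR, NLR) and records the list in the `log_markers` attribute.
#'
#' @param records Cohort data.frame.
#' @param markers Markers to transform.
#' @return Transformed records.
#' @export
log_transform <- function(records, markers = intersect(LOG_MARKERS, names(records))) {
  for (m in markers) {
    v <- records[[m]]
    if (any(!is.na(v) & v <= 0))
      stopf("marker '%s' has non-positive values; cannot log-transform", m)
    records[[m]] <- log(v)
  }
  attr(records, "log_markers") <- markers
  records
}

#' Train-frozen z-score standardization
#'
#' `fit_standardizer()` computes per-marker means and SDs on the training
#' split only; `apply_standardizer()` transforms any split with those frozen
#' parameters; `invert_standardizer()` undoes it. Applying the fitted
#' parameters to the training data itself yields columns with mean 0 and
#' SD 1.
#'
#' @param records Training data.frame (markers already on their analysis
#'   scale, i.e. log-transformed where applicable).
#' @param markers Markers to standardize.
#' @param log_markers Markers that were log-transformed upstream; stored for
#'   provenance and model serialization.
#' @return An object of class `standardizer` with fields `markers`, `mean`,
#'   `sd`, `log_markers`.
#' @export
fit_standardizer <- function(records, markers,
                             log_markers = attr(records, "log_markers") %||% character()) {
  assert_cols(records, markers, "training records")
  if (nrow(records) == 0L) stopf("training split is empty")
  mu <- vapply(markers, function(m) mean(records[[m]], na.rm = TRUE), 0)
  sg <- vapply(markers, function(m) sd(records[[m]], na.rm = TRUE), 0)
  if (any(!is.finite(sg)) || any(sg <= 0))
    stopf("constant marker column(s): %s",
          paste(markers[!is.finite(sg) | sg <= 0], collapse = ", "))
  structure(list(markers = markers, mean = mu, sd = sg,
                 log_markers = intersect(log_markers, markers)),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param params A fitted `standardizer`.
#' @export
apply_standardizer <- function(params, records) {
  assert_cols(records, params$markers)
  for (m in params$markers)
    records[[m]] <- (records[[m]] - params$mean[[m]]) / params$sd[[m]]
  records
}

#' @rdname fit_standardizer
#' @export
invert_standardizer <- function(params, records) {
  assert_cols(records, params$markers)
  for (m in params$markers)
    records[[m]] <- records[[m]] * params$sd[[m]] + params$mean[[m]]
  records
}

#' @rdname fit_standardizer
#' @param path File path for JSON (de)serialization.
#' @export
write_standardizer <- function(params, path) {
  x <- list(markers = params$markers, mean = as.list(params$mean),
            sd = as.list(params$sd), log_markers = params$log_markers)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname fit_standardizer
#' @export
read_standardizer <- function(path) {
  x <- jsonlite::fromJSON(path)
  mk <- as.character(x$markers)
  structure(list(markers = mk,
                 mean = setNames(as.numeric(unlist(x$mean)[mk]), mk),
                 sd = setNames(as.numeric(unlist(x$sd)[mk]), mk),
                 log_markers = as.character(unlist(x$log_markers))),
            class = "standardizer")
}

#' One-call preprocessing pipeline
#'
#' Applies inclusion/exclusion, imputes missing marker cells per sex with
#' chained random forests, then derives MAP from the completed SBP/DBP.
#' Markers stay on their natural scale; log transformation and z-scoring
#' happen inside model fitting with train-frozen parameters.
#'
#' @param records Generated cohort.
#' @param seed Seed for imputation.
#' @param n_iterations Chained-imputation sweeps.
#' @param ... Passed to [apply_inclusion()].
#' @return `list(records, exclusions)` with completed markers and a `MAP`
#'   column.
#' @export
preprocess_cohort <- function(records, seed = 1L, n_iterations = 30, ...) {
  inc <- apply_inclusion(records, ...)
  rec <- inc$records
  mk <- intersect(GENERATED_MARKERS, names(rec))
  if (anyNA(rec[, mk, drop = FALSE]))
    rec <- impute_missing(rec, markers = mk, n_iterations = n_iterations,
                          seed = seed)
  rec$MAP <- compute_map(rec$SBP, rec$DBP)
  list(records = rec, exclusions = inc$exclusions)
}
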