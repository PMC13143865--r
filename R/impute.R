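#' Chained random-forest imputation
#'
#' Iterative imputation by chained equations with a random-forest
#' conditional model for each marker, run separately within each sex.
#' Missing cells are initialized at the observed column mean; each sweep
#' revisits the incomplete columns (in order of increasing missingness) and
#' replaces the missing entries with random-forest predictions from all
#' other predictors (age, the remaining markers, and the chronic-disease
#' flags). Observed cells are never altered, and a fixed seed makes the
#' completed table fully reproducible.
#'
#' @param records Cohort data.frame (must contain `age` and `sex`; `age`
#'   must be complete).
#' @param markers Marker columns eligible for imputation.
#' @param n_iterations Number of chained sweeps (default 30).
#' @param seed Integer seed.
#' @param num_trees Trees per forest fit (default 10).
#' @param by_sex Impute within each sex separately (default TRUE).
#' @return The records with all targeted marker cells completed.
#' @export
impute_missing <- function(records,
                           markers = intersect(GENERATED_MARKERS, names(records)),
                           n_iterations = 30, seed = 1L, num_trees = 10,
                           by_sex = TRUE) {
  assert_cols(records, c("age", markers))
  if (anyNA(records$age)) stopf("age must be complete before imputation")
  flag_cols <- grep("^flag_", names(records), value = TRUE)
  groups <- if (by_sex && !is.null(records$sex)) split(seq_len(nrow(records)), records$sex)
            else list(all = seq_len(nrow(records)))
  fit_idx <- 0L
  for (idx in groups) {
    sub <- records[idx, , drop = FALSE]
    pred_cols <- c("age", markers, flag_cols)
    X <- sub[, pred_cols, drop = FALSE]
    for (fc in flag_cols) X[[fc]] <- as.numeric(X[[fc]])
    na_mask <- is.na(X)
    n_na <- colSums(na_mask[, markers, drop = FALSE])
    if (any(n_na == nrow(sub)))
      stopf("marker(s) entirely missing within a sex: %s",
            paste(markers[n_na == nrow(sub)], collapse = ", "))
    targets <- markers[n_na > 0]
    if (length(targets) == 0L) next
    targets <- targets[order(n_na[targets])]
    # mean initialization
    for (m in targets)
      X[[m]][na_mask[, m]] <- mean(X[[m]], na.rm = TRUE)
    for (it in seq_len(n_iterations)) {
      for (m in targets) {
        fit_idx <- fit_idx + 1L
        obs <- !na_mask[, m]
        train <- X[obs, , drop = FALSE]
        fml <- stats::reformulate(setdiff(pred_cols, m), response = m)
        rf <- ranger::ranger(fml, data = train, num.trees = num_trees,
                             seed = sub_seed(seed, fit_idx),
                             num.threads = 1L, respect.unordered.factors = TRUE)
        pred <- predict(rf, data = X[!obs, , drop = FALSE],
                        num.threads = 1L)$predictions
        X[[m]][!obs] <- pred
      }
    }
    for (m in targets) records[[m]][idx] <- X[[m]]
  }
  records
}
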