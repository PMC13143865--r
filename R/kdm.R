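#' Principal-component rotation of standardized markers
#'
#' Eigendecomposition of the covariance of the (already z-scored) training
#' matrix — on that scale covariance equals correlation. All components are
#' retained; degenerate (near-zero-variance) components are tolerated here
#' and handled downstream by [fit_kdm()]'s slope floor. Each eigenvector's
#' sign is fixed so its largest-magnitude loading is positive (or negative,
#' under the flipped convention), which makes fits reproducible across
#' platforms.
#'
#' @param x Numeric matrix or data.frame of standardized markers
#'   (n x p, n > p, no missing cells).
#' @param sign_convention `"positive"` (default) or `"negative"`: sign of
#'   the largest-magnitude loading of each eigenvector.
#' @return Object of class `pca_rotation`: `loadings` (p x p, orthonormal
#'   columns), `explained` (variance fractions, non-increasing, summing to
#'   1), `markers`, `sign_convention`.
#' @export
fit_pca <- function(x, sign_convention = c("positive", "negative")) {
  sign_convention <- match.arg(sign_convention)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("m", seq_len(ncol(x)))
  if (ncol(x) < 2L) stopf("need at least 2 markers")
  if (nrow(x) <= ncol(x)) stopf("need more rows than markers")
  if (anyNA(x)) stopf("missing cells in PCA input")
  cols <- lapply(seq_len(ncol(x)), function(j) x[, j])
  if (anyDuplicated(cols))
    stopf("rank-deficient input: duplicated marker columns")
  cv <- stats::cov(x)
  eg <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  load <- eg$vectors
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    flip <- if (sign_convention == "positive") load[i, j] < 0 else load[i, j] > 0
    if (flip) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(ncol(load))))
  structure(list(loadings = load, explained = vals / sum(vals),
                 markers = colnames(x), sign_convention = sign_convention),
            class = "pca_rotation")
}

#' Project standardized markers onto a fitted rotation
#'
#' @param rotation A `pca_rotation`.
#' @param x Standardized marker matrix/data.frame with the rotation's
#'   marker columns.
#' @return Score matrix (n x p).
#' @export
pca_scores <- function(rotation, x) {
  x <- as.matrix(x)
  if (!is.null(colnames(x)) && all(rotation$markers %in% colnames(x)))
    x <- x[, rotation$markers, drop = FALSE]
  else if (ncol(x) != length(rotation$markers))
    stopf("input has %d columns; rotation expects %d markers",
          ncol(x), length(rotation$markers))
  x %*% rotation$loadings
}

#' Per-component inverse regressions on chronological age
#'
#' For each principal component j, ordinary least squares of the score
#' `t_j` on chronological age gives the slope `k_j`, intercept `q_j`, and
#' residual standard error `s_j` (n - 2 denominator). Components whose
#' |slope| falls below `slope_floor` carry no age signal and are dropped
#' with a warning (their inverse predictions `(t - q)/k` would explode);
#' a perfect fit (`s = 0`) is floored at `s_floor` to keep the weights
#' finite and flagged.
#'
#' @param scores PC-score matrix (n x p).
#' @param ca Chronological age vector (years).
#' @param slope_floor Minimum |k| (PC units/year) for retention.
#' @param s_floor Lower bound applied to residual standard errors.
#' @return Object of class `kdm_params`: vectors `k`, `q`, `s` over the
#'   retained components, `retained` (column indices into the rotation),
#'   `s_floored` (logical), `n`.
#' @export
fit_kdm <- function(scores, ca, slope_floor = 1e-6, s_floor = 1e-8) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 10L) stopf("need at least 10 training records")
  if (length(ca) != n) stopf("scores and ca lengths differ")
  if (var(ca) == 0) stopf("chronological age has zero variance")
  X <- cbind(1, ca)
  k <- q <- s <- numeric(ncol(scores))
  for (j in seq_len(ncol(scores))) {
    fit <- lm.fit(X, scores[, j])
    q[j] <- fit$coefficients[1]
    k[j] <- fit$coefficients[2]
    s[j] <- sqrt(sum(fit$residuals^2) / (n - 2))
  }
  keep <- abs(k) >= slope_floor
  if (!any(keep))
    stopf("all components dropped: no age signal (|k| < %g)", slope_floor)
  if (any(!keep))
    warnf("dropping %d component(s) with |slope| < %g: %s",
          sum(!keep), slope_floor,
          paste(colnames(scores)[!keep] %||% which(!keep), collapse = ", "))
  floored <- s < s_floor & keep
  s[floored] <- s_floor
  structure(list(k = k[keep], q = q[keep], s = s[keep],
                 retained = which(keep), s_floored = floored[keep], n = n),
            class = "kdm_params")
}

#' Klemera-Doubal biological age from PC scores
#'
#' The estimator combines the per-component inverse predictions
#' `(t_j - q_j) / k_j` with weights `k_j^2 / s_j^2`:
#' \deqn{BA = \frac{\sum_j (t_j - q_j)\, k_j / s_j^2}{\sum_j (k_j/s_j)^2}}
#' which is algebraically the precision-weighted mean of the inverse
#' predictions. With a single retained component it reduces to
#' `(t - q) / k`.
#'
#' @param scores Score matrix over the retained components (n x m), or a
#'   length-m vector for one record.
#' @param params A `kdm_params` (or any list with `k`, `q`, `s`).
#' @return Biological-age vector (years).
#' @export
kdm_ba <- function(scores, params) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  scores <- as.matrix(scores)
  m <- length(params$k)
  if (m == 0L) stopf("empty KDM parameter set")
  if (ncol(scores) != m) stopf("score columns (%d) != retained PCs (%d)",
                               ncol(scores), m)
  w_num <- params$k / params$s^2
  num <- sweep(scores, 2, params$q) %*% w_num
  den <- sum((params$k / params$s)^2)
  as.numeric(num) / den
}

#' Normalized cardiovascular age acceleration
#'
#' `eta = (CA - BA) / CA`. Negative eta means the estimated vascular age
#' exceeds chronological age, i.e. faster-than-expected vascular aging.
#'
#' @param ca Chronological age (years), strictly positive.
#' @param ba Biological (vascular) age (years).
#' @return eta, dimensionless.
#' @export
compute_eta <- function(ca, ba) {
  if (any(ca <= 0)) stopf("chronological age must be positive")
  (ca - ba) / ca
}

#' Fit a sex-stratified vascular age model
#'
#' Composes the full training pipeline on the healthy training split of one
#' sex: natural-log transform of the skewed markers, train-frozen z-score
#' standardization, PCA rotation (all components), and per-component KDM
#' regressions on chronological age. The basic model uses exactly baPWV,
#' ABI and MAP.
#'
#' @param records Training records (raw marker scale, one sex's rows are
#'   selected via `sex`).
#' @param markers Marker panel; default the basic vascular triplet.
#' @param sex `"male"` or `"female"`.
#' @param tag Model tag (`"basic"`, `"expand"`, or a nested-intermediate
#'   label).
#' @param log_markers Subset of `markers` to log-transform; defaults to the
#'   canonical skewed list.
#' @param sign_convention Passed to [fit_pca()].
#' @param slope_floor Passed to [fit_kdm()].
#' @param seed Recorded in provenance (the fit itself is deterministic).
#' @return Object of class `vascular_age_model`.
#' @export
fit_vascular_age_model <- function(records, markers = VASC_MARKERS,
                                   sex = c("male", "female"), tag = "basic",
                                   log_markers = intersect(markers, LOG_MARKERS),
                                   sign_convention = "positive",
                                   slope_floor = 1e-6, seed = NA_integer_) {
  sex <- match.arg(sex)
  assert_cols(records, c("age", "sex", markers), "training records")
  rec <- records[records$sex == sex, , drop = FALSE]
  if (nrow(rec) == 0L) stopf("no training records for sex '%s'", sex)
  if (anyNA(rec[, markers, drop = FALSE]))
    stopf("markers must be complete in the training split (impute first)")
  rec <- log_transform(rec, markers = log_markers)
  std <- fit_standardizer(rec, markers, log_markers = log_markers)
  z <- apply_standardizer(std, rec)[, markers, drop = FALSE]
  rot <- fit_pca(z, sign_convention = sign_convention)
  sc <- pca_scores(rot, z)
  kdm <- fit_kdm(sc, rec$age, slope_floor = slope_floor)
  structure(list(version = "1.0", sex = sex, tag = tag, markers = markers,
                 log_markers = log_markers, standardization = std,
                 pca = rot, kdm = kdm,
                 provenance = list(n_train = nrow(rec), seed = seed)),
            class = "vascular_age_model")
}

#' Estimate biological vascular age for records
#'
#' Applies the model's frozen pipeline — log transform, z-score with the
#' training parameters, PCA rotation, KDM combination — to new records.
#'
#' @param model A `vascular_age_model`.
#' @param records Records with the model's markers complete (raw scale).
#' @return Biological-age vector (years).
#' @export
estimate_ba <- function(model, records) {
  assert_cols(records, model$markers)
  if (anyNA(records[, model$markers, drop = FALSE]))
    stopf("missing marker value(s); records must be complete for: %s",
          paste(model$markers, collapse = ", "))
  rec <- log_transform(records, markers = model$log_markers)
  z <- apply_standardizer(model$standardization, rec)[, model$markers, drop = FALSE]
  sc <- pca_scores(model$pca, z)[, model$kdm$retained, drop = FALSE]
  kdm_ba(sc, model$kdm)
}

#' Score a cohort: BA and eta per participant
#'
#' @param model A `vascular_age_model`.
#' @param records Records of the model's sex (rows of other sexes are
#'   dropped with a message-free filter).
#' @return Data.frame `id`, `age`, `ba`, `eta`, `model_tag` — one row per
#'   scored participant.
#' @export
score_cohort <- function(model, records) {
  rec <- if (!is.null(records$sex))
    records[records$sex == model$sex, , drop = FALSE] else records
  ba <- estimate_ba(model, rec)
  data.frame(id = rec$id %||% seq_len(nrow(rec)), age = rec$age, ba = ba,
             eta = compute_eta(rec$age, ba), model_tag = model$tag,
             stringsAsFactors = FALSE)
}

#' @export
print.vascular_age_model <- function(x, ...) {
  cat(sprintf("Vascular age model [%s, %s]\n", x$sex, x$tag))
  cat("  markers:", paste(x$markers, collapse = ", "), "\n")
  cat(sprintf("  retained PCs: %d of %d\n", length(x$kdm$k),
              length(x$markers)))
  cat(sprintf("  training n: %d\n", x$provenance$n_train))
  invisible(x)
}
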