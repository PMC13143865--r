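#' Restricted cubic spline basis
#'
#' Natural (restricted) cubic spline in the truncated-power
#' parameterization: column 1 is `x` itself and columns `2..k-1` are the
#' nonlinear terms
#' \deqn{[(x-t_j)_+^3 - (x-t_{k-1})_+^3 (t_k-t_j)/(t_k-t_{k-1})
#'       + (x-t_k)_+^3 (t_{k-1}-t_j)/(t_k-t_{k-1})] / (t_k-t_1)^2}
#' for `j = 1..k-2`, which is linear beyond both boundary knots. Default
#' knots sit at the conventional quantiles for `k = 5`:
#' 0.05, 0.275, 0.50, 0.725, 0.95.
#'
#' @param x Numeric vector.
#' @param k Number of knots (>= 3) when `knots` is not given.
#' @param knots Explicit knot locations (overrides `k`).
#' @return An n x (k-1) matrix with a `knots` attribute.
#' @export
rcs_basis <- function(x, k = 5, knots = NULL) {
  if (is.null(knots)) {
    if (k < 3) stopf("need at least 3 knots")
    probs <- switch(as.character(k),
                    "3" = c(0.10, 0.50, 0.90),
                    "4" = c(0.05, 0.35, 0.65, 0.95),
                    "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
                    "6" = c(0.05, 0.23, 0.41, 0.59, 0.77, 0.95),
                    seq(0.05, 0.95, length.out = k))
    if (length(unique(x[!is.na(x)])) < k)
      stopf("fewer distinct values (%d) than knots (%d)",
            length(unique(x[!is.na(x)])), k)
    knots <- unname(quantile(x, probs, na.rm = TRUE, type = 7))
  }
  k <- length(knots)
  if (any(diff(knots) <= 0)) stopf("knots must be strictly increasing")
  tk <- knots[k]; tk1 <- knots[k - 1L]
  norm <- (knots[k] - knots[1])^2
  pos3 <- function(u) pmax(u, 0)^3
  B <- matrix(NA_real_, length(x), k - 1L)
  B[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    B[, j + 1L] <- (pos3(x - tj) -
                    pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                    pos3(x - tk)  * (tk1 - tj) / (tk - tk1)) / norm
  }
  colnames(B) <- c("x", paste0("x", strrep("'", seq_len(k - 2L))))
  attr(B, "knots") <- knots
  B
}

#' Cox model on a restricted cubic spline of an exposure
#'
#' Fits `Surv(time, status) ~ rcs(x) + covariates` and reports the Wald
#' test that all nonlinear spline coefficients are jointly zero (the
#' nonlinearity test).
#'
#' @param time Follow-up time.
#' @param status Event indicator (0/1).
#' @param x Exposure entered as a spline.
#' @param covariates Optional data.frame of additional linear covariates.
#' @param k Number of knots.
#' @param knots Explicit knots (overrides `k`).
#' @return List: `fit` (the `coxph` object), `basis` knots, `nonlin_chisq`,
#'   `nonlin_df`, `nonlin_p`.
#' @export
rcs_cox <- function(time, status, x, covariates = NULL, k = 5, knots = NULL) {
  if (sum(status) == 0) stopf("no events")
  B <- rcs_basis(x, k = k, knots = knots)
  df <- data.frame(B, check.names = TRUE)
  spline_cols <- names(df)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  df$.time <- time; df$.status <- status
  fml <- stats::reformulate(setdiff(names(df), c(".time", ".status")),
                            response = quote(survival::Surv(.time, .status)))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  nl_idx <- seq(2L, length(spline_cols))
  b <- coef(fit)[nl_idx]
  V <- vcov(fit)[nl_idx, nl_idx, drop = FALSE]
  if (any(!is.finite(b)) || inherits(try(solve(V), silent = TRUE), "try-error"))
    stopf("nonlinearity test degenerate (collinear spline basis)")
  chisq <- drop(t(b) %*% solve(V, b))
  list(fit = fit, knots = attr(B, "knots"), spline_cols = spline_cols,
       nonlin_chisq = chisq, nonlin_df = length(nl_idx),
       nonlin_p = pchisq(chisq, length(nl_idx), lower.tail = FALSE))
}

#' Age cutoff from the spline-shaped age-CVD association
#'
#' Fits a Cox model of the event on a restricted cubic spline of
#' chronological age, references the spline-predicted log hazard to the
#' cohort median age, and returns the smallest age on an evaluation grid
#' from which the predicted log-HR stays positive with its pointwise Wald
#' lower confidence bound above zero — the "turning point" beyond which age
#' is decisively associated with elevated risk. Also reports the joint Wald
#' nonlinearity test.
#'
#' @param records Cohort data.frame.
#' @param time,status,age Column names.
#' @param k Number of knots.
#' @param grid_step Age-grid spacing (years).
#' @param conf Confidence level of the pointwise band.
#' @return List: `cutoff` (years, `NA` when the band never stabilizes
#'   above zero), `nonlin_p`, `grid` (data.frame age/loghr/lower/upper),
#'   `knots`.
#' @export
rcs_age_cutoff <- function(records, time = "followup_time",
                           status = "cvd_event", age = "age", k = 5,
                           grid_step = 0.5, conf = 0.95) {
  assert_cols(records, c(time, status, age))
  if (sum(records[[status]]) == 0) stopf("no events")
  rc <- rcs_cox(records[[time]], records[[status]], records[[age]], k = k)
  knots <- rc$knots
  ref <- median(records[[age]], na.rm = TRUE)
  grid <- seq(min(records[[age]], na.rm = TRUE),
              max(records[[age]], na.rm = TRUE), by = grid_step)
  Bg <- rcs_basis(grid, knots = knots)
  Br <- rcs_basis(ref, knots = knots)
  idx <- seq_along(rc$spline_cols)
  D <- sweep(Bg, 2, Br[1, ])
  beta <- coef(rc$fit)[idx]
  V <- vcov(rc$fit)[idx, idx, drop = FALSE]
  lhr <- drop(D %*% beta)
  se <- sqrt(rowSums((D %*% V) * D))
  zq <- qnorm(1 - (1 - conf) / 2)
  lower <- lhr - zq * se
  ok <- lower > 0
  # smallest grid age from which the lower band stays positive
  stays <- rev(cumprod(rev(ok))) == 1
  cutoff <- if (any(stays)) grid[which(stays)[1]] else NA_real_
  list(cutoff = cutoff, nonlin_p = rc$nonlin_p,
       grid = data.frame(age = grid, loghr = lhr,
                         lower = lower, upper = lhr + zq * se),
       knots = knots)
}
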