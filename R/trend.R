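# Exact null distribution of the Mann-Whitney U statistic for group sizes
# (m, n): integer counts of arrangements with U = 0..m*n (Gaussian-binomial
# coefficients), from the recursion c(m,n,u) = c(m-1,n,u-n) + c(m,n-1,u).
# Counts stay exact in doubles for the sizes handled here (total n <= 30).
mw_counts <- function(m, n) {
  # dp[[j + 1]] holds counts for U(i, j) at the current i
  dp <- vector("list", n + 1L)
  for (j in 0:n) dp[[j + 1L]] <- 1  # U(0, j) identically 0
  for (i in seq_len(m)) {
    new <- vector("list", n + 1L)
    new[[1L]] <- 1  # U(i, 0) identically 0
    for (j in seq_len(n)) {
      a <- c(rep(0, j), dp[[j + 1L]])           # c(i-1, j, u - j)
      b <- c(new[[j]], rep(0, j))               # c(i, j-1, u)
      len <- max(length(a), length(b))
      a <- c(a, rep(0, len - length(a)))
      b <- c(b, rep(0, len - length(b)))
      new[[j + 1L]] <- a + b
    }
    dp <- new
  }
  counts <- dp[[n + 1L]]
  length(counts) <- m * n + 1L  # pad with NA then zero-fill
  counts[is.na(counts)] <- 0
  counts
}

# Exact null distribution of the JT statistic for group sizes ns: under H0
# (no ties) JT is distributed as the independent sum of
# U(n1, n2), U(n1+n2, n3), ..., so the count vector is the convolution of
# the Mann-Whitney count vectors, and the total is the multinomial
# coefficient. Direct convolution keeps the integer counts exact.
jt_null_counts <- function(ns) {
  counts <- 1
  cum <- ns[1]
  for (j in 2:length(ns)) {
    u <- mw_counts(cum, ns[j])
    out <- rep(0, length(counts) + length(u) - 1L)
    for (i in seq_along(counts))
      out[i:(i + length(u) - 1L)] <- out[i:(i + length(u) - 1L)] + counts[i] * u
    counts <- out
    cum <- cum + ns[j]
  }
  counts
}

#' Jonckheere-Terpstra trend test
#'
#' Tests for a monotone trend of `x` across the ordered groups `g`. The
#' statistic is the sum over ordered group pairs (i < j) of Mann-Whitney
#' counts \#\{x_a < x_b\} (+ 1/2 per tie). The exact mode (default for
#' total n <= 30 with no ties) computes the full permutation null
#' distribution via the Mann-Whitney convolution decomposition, which
#' equals complete enumeration over all group assignments; otherwise a
#' normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param x Numeric response.
#' @param g Group labels; coerced to an ordered factor in the order of
#'   `levels(g)` (or sorted unique values).
#' @param alternative `"two.sided"`, `"increasing"` (x rises with g) or
#'   `"decreasing"`.
#' @param exact Force exact (`TRUE`) or approximate (`FALSE`) mode;
#'   `NULL` = auto.
#' @return List: `statistic` (JT), `p_value`, `method` (`"exact"` or
#'   `"normal"`), `direction` (+1/-1, sign of JT minus its null mean),
#'   `mean`, `sd` (null moments).
#' @export
jt_test <- function(x, g, alternative = c("two.sided", "increasing", "decreasing"),
                    exact = NULL) {
  alternative <- match.arg(alternative)
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]
  g <- if (is.factor(g)) droplevels(g[keep]) else factor(g[keep])
  ns <- as.integer(table(g))
  kg <- length(ns)
  if (kg < 2L) stopf("need at least 2 non-empty groups")
  N <- sum(ns)
  groups <- split(x, g)
  jt <- 0
  for (i in seq_len(kg - 1L)) for (j in (i + 1L):kg) {
    xi <- groups[[i]]; xj <- groups[[j]]
    cmp <- outer(xi, xj, "<")
    tie <- outer(xi, xj, "==")
    jt <- jt + sum(cmp) + 0.5 * sum(tie)
  }
  has_ties <- anyDuplicated(x) > 0L
  mu <- (N^2 - sum(ns^2)) / 4
  if (is.null(exact)) exact <- N <= 30 && !has_ties
  if (exact && has_ties) {
    warnf("ties present: falling back to the normal approximation")
    exact <- FALSE
  }
  if (exact) {
    counts <- jt_null_counts(ns)
    total <- sum(counts)
    supp <- seq_along(counts) - 1
    p_ge <- sum(counts[supp >= jt]) / total
    p_le <- sum(counts[supp <= jt]) / total
    p <- switch(alternative,
                increasing = p_ge, decreasing = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    sdv <- sqrt(sum(counts * (supp - mu)^2) / total)
    method <- "exact"
  } else {
    tab <- table(x)
    t1 <- sum(tab * (tab - 1) * (2 * tab + 5))
    n1 <- sum(ns * (ns - 1) * (2 * ns + 5))
    v <- (N * (N - 1) * (2 * N + 5) - n1 - t1) / 72 +
      sum(ns * (ns - 1) * (ns - 2)) * sum(tab * (tab - 1) * (tab - 2)) /
        (36 * N * (N - 1) * (N - 2)) +
      sum(ns * (ns - 1)) * sum(tab * (tab - 1)) / (8 * N * (N - 1))
    sdv <- sqrt(v)
    if (sdv == 0) stopf("degenerate JT null distribution (all values tied)")
    z_ge <- (jt - mu - 0.5) / sdv
    z_le <- (jt - mu + 0.5) / sdv
    p <- switch(alternative,
                increasing = pnorm(z_ge, lower.tail = FALSE),
                decreasing = pnorm(z_le),
                two.sided = min(1, 2 * min(pnorm(z_ge, lower.tail = FALSE),
                                           pnorm(z_le))))
    method <- "normal"
  }
  list(statistic = jt, p_value = p, method = method,
       direction = if (jt >= mu) 1 else -1, mean = mu, sd = sdv)
}

#' Difference and trend tests of a risk factor across ordered groups
#'
#' Computes a one-way ANOVA p-value and a Kruskal-Wallis p-value (both
#' always stored), picks the headline difference test by a per-group
#' Shapiro-Wilk normality screen, and adds the Jonckheere-Terpstra trend
#' test with the direction of the monotone trend.
#'
#' @param values Numeric risk-factor values.
#' @param groups Ordered group labels (e.g. eta tertiles Q1 < Q2 < Q3).
#' @param shapiro_alpha Per-group normality screen level.
#' @param jt_alternative Passed to [jt_test()] (default two-sided).
#' @return List: `anova_p`, `kw_p`, `normal` (screen result), `headline`
#'   (`"anova"` or `"kruskal"`), `headline_p`, `jt_stat`, `jt_p`,
#'   `direction`.
#' @export
trend_tests <- function(values, groups, shapiro_alpha = 0.05,
                        jt_alternative = "two.sided") {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- if (is.factor(groups)) droplevels(groups[keep]) else factor(groups[keep])
  if (nlevels(groups) < 2L) stopf("need at least 2 non-empty groups")
  sizes <- table(groups)
  if (any(sizes < 2L)) stopf("each group needs >= 2 observations")
  normal <- all(vapply(split(values, groups), function(v) {
    if (length(v) < 3L || length(v) > 5000L || var(v) == 0) return(FALSE)
    shapiro.test(v)$p.value > shapiro_alpha
  }, TRUE))
  anova_p <- tryCatch(
    summary(aov(values ~ groups))[[1]][["Pr(>F)"]][1],
    error = function(e) NA_real_)
  kw_p <- kruskal.test(values, groups)$p.value
  jt <- jt_test(values, groups, alternative = jt_alternative)
  list(anova_p = anova_p, kw_p = kw_p, normal = normal,
       headline = if (normal) "anova" else "kruskal",
       headline_p = if (normal) anova_p else kw_p,
       jt_stat = jt$statistic, jt_p = jt$p_value, direction = jt$direction)
}
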