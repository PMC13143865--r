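test_that("tertile assignment follows the half-open interval convention", {
  t9 <- tertile_assign(1:9)
  expect_equal(as.vector(table(t9$group)), c(3, 3, 3))
  expect_equal(as.character(t9$group[9]), "Q1")  # highest eta is Q1
  expect_equal(as.character(t9$group[1]), "Q3")
  # tie mass exactly at a cut joins the higher-eta group
  eta <- c(1, 2, 2, 2, 3, 4)
  ta <- tertile_assign(eta)
  expect_equal(ta$cuts[1], 2)
  expect_true(all(ta$group[eta == 2] == "Q2"))
  expect_error(tertile_assign(c(1, 1, 1, 2)), "distinct")
})

test_that("cox_fit enforces preconditions and reference symmetry", {
  set.seed(91)
  n <- 2000
  g <- factor(sample(c("Q1", "Q2", "Q3"), n, replace = TRUE),
              levels = c("Q1", "Q2", "Q3"))
  rate <- 0.03 * exp(0.4 * (g == "Q3"))
  tt <- rexp(n, rate)
  ev <- as.integer(tt <= 10)
  tt <- pmin(tt, 10)
  fit_q1 <- cox_fit(tt, ev, g)
  g3 <- relevel(g, "Q3")
  fit_q3 <- cox_fit(tt, ev, g3)
  hr_q3_vs_q1 <- fit_q1$hr[fit_q1$term == "Q3"]
  hr_q1_vs_q3 <- fit_q3$hr[fit_q3$term == "Q1"]
  expect_equal(hr_q1_vs_q3, 1 / hr_q3_vs_q1, tolerance = 1e-6)
  expect_error(cox_fit(tt, rep(0, n), g), "no events")
  expect_error(cox_fit(tt, ev, rep(1.5, n)), "constant")
  expect_warning(cox_fit(tt[1:60], ev[1:60], g[1:60]), "10 events")
})

test_that("the log-rank statistic matches trivial and powered cases", {
  # identical event/censoring patterns in both groups
  tt <- rep(c(1, 2, 3, 4, 5), 2)
  ev <- rep(c(1, 0, 1, 1, 0), 2)
  g <- rep(c("A", "B"), each = 5)
  lr <- logrank_by_group(tt, ev, g)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1, tolerance = 1e-12)
  expect_error(logrank_by_group(tt, ev, rep("A", 10)), "2 groups")
  # strong hazard separation
  set.seed(97)
  n <- 400
  g2 <- rep(c("lo", "hi"), each = n / 2)
  rate <- ifelse(g2 == "hi", 0.15, 0.03)
  t2 <- rexp(n, rate)
  e2 <- as.integer(t2 <= 10)
  lr2 <- logrank_by_group(pmin(t2, 10), e2, g2)
  expect_lt(lr2$p, 0.001)
})

test_that("two-group log-rank equals the Cox score test without ties", {
  set.seed(103)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.05 * exp(0.3 * x))
  ev <- as.integer(tt <= 10)
  tt <- pmin(tt, 10)
  lr <- logrank_by_group(tt, ev, x)
  fit <- attr(cox_fit(tt, ev, x), "fit")
  expect_equal(lr$chisq, unname(summary(fit)$sctest["test"]),
               tolerance = 1e-6)
})

test_that("the restricted spline basis is linear in the tails and continuous", {
  set.seed(107)
  x <- runif(600, 20, 70)
  B <- rcs_basis(x, k = 5)
  knots <- attr(B, "knots")
  expect_equal(length(knots), 5)
  expect_identical(B[, 1], x)
  below <- x < knots[1]
  expect_true(all(abs(B[below, -1]) == 0))
  # second finite difference far beyond the last knot ~ 0
  h <- 0.5
  far <- knots[5] + c(10, 10 + h, 10 + 2 * h)
  Bf <- rcs_basis(far, knots = knots)
  d2 <- Bf[1, ] - 2 * Bf[2, ] + Bf[3, ]
  expect_lt(max(abs(d2)), 1e-8)
  # continuity at the knots
  eps <- 1e-9
  for (kn in knots) {
    Bl <- rcs_basis(kn - eps, knots = knots)
    Br <- rcs_basis(kn + eps, knots = knots)
    expect_lt(max(abs(Bl - Br)), 1e-6)
  }
  expect_error(rcs_basis(rep(1:3, 5), k = 5), "distinct")
})

test_that("dropping the nonlinear spline terms reproduces the linear Cox fit", {
  set.seed(109)
  n <- 1500
  age <- runif(n, 20, 70)
  tt <- rexp(n, 0.002 * exp(0.05 * age))
  ev <- as.integer(tt <= 10)
  tt <- pmin(tt, 10)
  B <- rcs_basis(age, k = 5)
  lin_b <- coef(attr(cox_fit(tt, ev, B[, 1]), "fit"))
  lin_x <- coef(attr(cox_fit(tt, ev, age), "fit"))
  expect_equal(unname(lin_b), unname(lin_x), tolerance = 1e-12)
})

test_that("rcs_age_cutoff recovers a hinge in the age-hazard relation", {
  set.seed(113)
  n <- 5000
  age <- runif(n, 30, 70)  # change point near mid-distribution
  rate <- 0.003 * exp(0.12 * pmax(age - 50, 0))
  tt <- rexp(n, rate)
  df <- data.frame(age = age, followup_time = pmin(tt, 10),
                   cvd_event = as.integer(tt <= 10))
  cut <- rcs_age_cutoff(df)
  expect_false(is.na(cut$cutoff))
  expect_lt(abs(cut$cutoff - 50), 4)
  expect_error(rcs_age_cutoff(transform(df, cvd_event = 0)), "no events")
})

test_that("JT statistic and exact p match the textbook example", {
  tr <- trend_tests(c(1, 2, 3, 4, 5, 6), rep(c("g1", "g2", "g3"), each = 2),
                    jt_alternative = "increasing")
  expect_equal(tr$jt_stat, 12)
  expect_equal(tr$jt_p, 1 / 90)
  expect_equal(tr$direction, 1)
  # all-tied groups have a degenerate JT null distribution
  expect_error(trend_tests(rep(5, 9), rep(c("a", "b", "c"), each = 3)),
               "tied|degenerate")
})

test_that("JT exact and normal approximations agree for balanced groups", {
  set.seed(127)
  x <- sample(seq(0.01, 0.30, by = 0.01))  # 30 distinct values
  g <- rep(c("a", "b", "c"), each = 10)
  exact <- jt_test(x, g, alternative = "increasing", exact = TRUE)
  appr <- jt_test(x, g, alternative = "increasing", exact = FALSE)
  expect_equal(exact$method, "exact")
  expect_lt(abs(exact$p_value - appr$p_value), 0.02)
})

test_that("trend_tests picks the difference test by a normality screen", {
  set.seed(131)
  vals <- c(rnorm(30, 0), rnorm(30, 0.2), rnorm(30, 0.4))
  g <- rep(c("Q1", "Q2", "Q3"), each = 30)
  tr <- trend_tests(vals, g)
  expect_true(tr$headline %in% c("anova", "kruskal"))
  expect_equal(tr$headline_p, if (tr$normal) tr$anova_p else tr$kw_p)
  skewed <- exp(vals)
  tr2 <- trend_tests(skewed, g)
  expect_false(tr2$normal)
  expect_equal(tr2$headline, "kruskal")
})

test_that("agreement statistics match closed forms", {
  ca <- 30:60
  expect_equal(agreement_stats(ca, ca)$pearson_r, 1)
  expect_equal(agreement_stats(ca, ca)$no_intercept_slope, 1)
  expect_equal(agreement_stats(2 * ca, ca)$no_intercept_slope, 2)
  expect_equal(agreement_stats(100 - ca, ca)$pearson_r, -1)
  expect_error(agreement_stats(rep(1, 10), 1:10), "variance")
})

test_that("cumulative incidence is 1 - KM and handles edge cases", {
  # no events: flat at zero
  ci0 <- cumulative_incidence(rep(5, 4), rep(0, 4), rep("A", 4))
  expect_true(all(ci0$incidence == 0))
  # all fail at t = 1: step to 1
  ci1 <- cumulative_incidence(rep(1, 4), rep(1, 4), rep("A", 4))
  expect_equal(max(ci1$incidence), 1)
  expect_equal(ci1$incidence[ci1$time == 1], 1)
  # hand-computed product-limit table on 6 records with censoring
  tt <- 1:6; ev <- c(1, 0, 1, 1, 0, 1)
  ci <- cumulative_incidence(tt, ev, rep("A", 6))
  km <- c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3, 0)
  expect_equal(ci$incidence[ci$time %in% c(1, 3, 4, 6)], 1 - km,
               tolerance = 1e-12)
  # monotone non-decreasing within group
  expect_true(all(diff(ci$incidence) >= 0))
})

test_that("subgroup analysis reports non-estimable strata without failing", {
  set.seed(137)
  rec <- prepared_cohort(complete_spec(n_per_sex = 800, seed = 139))
  cohort <- split_dataset(rec, "cohort")
  cohort <- cohort[cohort$sex == "male", ]
  train <- split_dataset(rec, "healthy_training")
  sc <- score_cohort(fit_vascular_age_model(train, sex = "male"), cohort)
  out <- risk_subgroup_analysis(cohort, sc$eta,
                                c(SBP = 140, FBG = 7))
  expect_equal(nrow(out), 4)
  expect_true(all(out$stratum %in% c("low", "high")))
  # an empty stratum is non-estimable, not an exception
  out2 <- risk_subgroup_analysis(cohort, sc$eta, c(SBP = 5000))
  expect_true(is.na(out2$hr[out2$stratum == "high"]))
  expect_warning(
    risk_subgroup_analysis(cbind(cohort, eta = sc$eta), sc$eta,
                           c(eta = 0)), "exposure")
})

test_that("random-split strata give mutually compatible hazard ratios", {
  set.seed(149)
  overlaps <- 0L
  for (r in 1:10) {
    n <- 1500
    age <- runif(n, 20, 70)
    eta <- rnorm(n, 0, 0.15)
    rate <- 0.01 * exp(0.5 * -eta)
    tt <- rexp(n, rate)
    df <- data.frame(age = age, followup_time = pmin(tt, 10),
                     cvd_event = as.integer(tt <= 10),
                     coin = rbinom(n, 1, 0.5))
    out <- risk_subgroup_analysis(df, eta, c(coin = 0.5))
    ok <- out$hr[1] >= out$lo[2] && out$hr[1] <= out$hi[2] &&
      out$hr[2] >= out$lo[1] && out$hr[2] <= out$hi[1]
    overlaps <- overlaps + ok
  }
  expect_gte(overlaps, 9)
})

test_that("the survival report assembles the full battery coherently", {
  rec <- prepared_cohort(complete_spec(n_per_sex = 1200, seed = 151))
  cohort <- split_dataset(rec, "cohort")
  cohort_m <- cohort[cohort$sex == "male", ]
  train <- split_dataset(rec, "healthy_training")
  sc <- score_cohort(fit_vascular_age_model(train, sex = "male"), cohort_m)
  rep <- suppressWarnings(eta_survival_report(cohort_m, sc))
  expect_s3_class(rep, "survival_report")
  # CI contains the point estimate everywhere
  for (blk in list(rep$continuous$crude, rep$continuous$adjusted,
                   rep$tertile$crude, rep$tertile$adjusted)) {
    expect_true(all(blk$lo <= blk$hr & blk$hr <= blk$hi))
  }
  expect_equal(rep$tertile$adjusted$term, c("Q2", "Q3"))  # Q1 reference
  expect_true(rep$logrank$df == 2)
  expect_true(all(rep$incidence_curves$incidence >= 0 &
                    rep$incidence_curves$incidence <= 1))
  expect_gt(rep$agreement$pearson_r, 0)
  js1 <- serialize_report(rep)
  js2 <- serialize_report(suppressWarnings(eta_survival_report(cohort_m, sc)))
  expect_identical(js1, js2)
  expect_output(print(rep), "log-rank")
})
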