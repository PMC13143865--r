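test_that("PCA of uncorrelated unit-variance markers splits variance evenly", {
  set.seed(101)
  x <- cbind(a = rnorm(10000), b = rnorm(10000))
  rot <- fit_pca(x)
  expect_equal(rot$explained, c(0.5, 0.5), tolerance = 0.05)
  expect_equal(crossprod(rot$loadings), diag(2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(rot$explained), 1, tolerance = 1e-12)
})

test_that("PCA rejects duplicated marker columns", {
  set.seed(7)
  x <- cbind(m1 = rnorm(50), m2 = rnorm(50))
  x <- cbind(x, m3 = x[, "m1"])
  expect_error(fit_pca(x), "rank-deficient")
})

test_that("training PC scores are uncorrelated", {
  set.seed(3)
  z <- matrix(rnorm(600), ncol = 3)
  z <- scale(z %*% matrix(c(1, .5, .2, 0, 1, .4, 0, 0, 1), 3))
  rot <- fit_pca(z)
  sc <- pca_scores(rot, z)
  cc <- cor(sc)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-10)
})

test_that("per-PC regressions recover slope, intercept and residual SE", {
  set.seed(17)
  ca <- runif(1000, 20, 70)
  t1 <- 2 * ca + 5 + rnorm(1000, 0, 0.1)
  params <- fit_kdm(cbind(PC1 = t1), ca)
  se_k <- 0.1 / (sd(ca) * sqrt(999))
  expect_lt(abs(params$k - 2), 3 * se_k)
  expect_lt(abs(params$q - 5), 3 * se_k * sqrt(mean(ca^2)))
  expect_lt(abs(params$s - 0.1), 3 * 0.1 / sqrt(2 * 998))
})

test_that("flat and perfect-fit components are handled", {
  set.seed(5)
  ca <- runif(200, 20, 70)
  sc <- cbind(PC1 = 0.5 * ca + 1 + rnorm(200),
              PC2 = rep(2.5, 200))  # slope exactly 0: below the floor
  expect_warning(params <- fit_kdm(sc, ca), "dropping")
  expect_equal(params$retained, 1L)
  # exact linearity: s floored, flagged
  p2 <- fit_kdm(cbind(PC1 = 3 * ca - 2), ca)
  expect_equal(p2$s, 1e-8)
  expect_true(p2$s_floored)
  expect_error(suppressWarnings(fit_kdm(cbind(PC1 = rep(1, 200)), ca)),
               "no age signal")
})

test_that("the KDM estimator equals the weighted inverse-prediction mean", {
  # worked instance
  params <- list(k = c(1, 0.5), q = c(0, 10), s = c(1, 2))
  expect_equal(kdm_ba(c(50, 36), params), (50 * 1 + 52 * 0.0625) / 1.0625,
               tolerance = 1e-12)
  # random draws against the oracle
  set.seed(73)
  for (i in 1:200) {
    m <- sample(1:5, 1)
    params <- list(k = runif(m, -2, 2), q = rnorm(m, 0, 5),
                   s = runif(m, 0.1, 3))
    params$k[abs(params$k) < 0.05] <- 0.5
    t <- rnorm(m, 50 * params$k + params$q, 5)
    oracle <- sum((t - params$q) / params$k * (params$k / params$s)^2) /
      sum((params$k / params$s)^2)
    expect_equal(kdm_ba(t, params), oracle, tolerance = 1e-10)
  }
  # single-PC reduction
  expect_equal(kdm_ba(42, list(k = 1.3, q = -4, s = 0.7)), (42 + 4) / 1.3,
               tolerance = 1e-12)
})

test_that("BA is monotone in each score with direction sign(k)", {
  params <- list(k = c(0.8, -0.5, 1.2), q = c(1, 2, 3), s = c(1, 1.5, 0.7))
  base <- c(10, 5, 20)
  ba0 <- kdm_ba(base, params)
  for (j in 1:3) {
    up <- base; up[j] <- up[j] + 1
    expect_equal(sign(kdm_ba(up, params) - ba0), sign(params$k[j]))
  }
})

test_that("eta is the normalized age residual", {
  expect_equal(compute_eta(50, 50), 0)
  expect_equal(compute_eta(50, 55), -0.1)
  expect_equal(compute_eta(40, 30), 0.25)
  expect_error(compute_eta(0, 10), "positive")
  expect_true(compute_eta(60, 70) < 0)  # older vascular age => negative eta
})

test_that("a noise-free cohort yields BA identical to CA", {
  rec <- prepared_cohort(noise_free_spec(n_per_sex = 150, seed = 29))
  train <- split_dataset(rec, "healthy_training")
  for (sx in c("male", "female")) {
    model <- quiet_fit(train, sex = sx)
    sub <- rec[rec$sex == sx, ]
    ba <- estimate_ba(model, sub)
    expect_lt(max(abs(ba - sub$age)), 1e-8)
    expect_lt(max(abs(compute_eta(sub$age, ba))), 1e-9)
  }
})

test_that("refitting under the flipped sign convention leaves BA unchanged", {
  rec <- prepared_cohort(complete_spec(n_per_sex = 300, seed = 37))
  train <- split_dataset(rec, "healthy_training")
  m_pos <- fit_vascular_age_model(train, sex = "male")
  m_neg <- fit_vascular_age_model(train, sex = "male",
                                  sign_convention = "negative")
  expect_equal(m_neg$pca$loadings, -m_pos$pca$loadings, tolerance = 1e-12,
               ignore_attr = TRUE)
  probe <- rec[rec$sex == "male", ][1:100, ]
  expect_lt(max(abs(estimate_ba(m_pos, probe) - estimate_ba(m_neg, probe))),
            1e-10)
})

test_that("model fitting is deterministic and BA tracks CA out of sample", {
  rec <- prepared_cohort(complete_spec(n_per_sex = 700, seed = 41))
  train <- split_dataset(rec, "healthy_training")
  m1 <- fit_vascular_age_model(train, sex = "female")
  m2 <- fit_vascular_age_model(train, sex = "female")
  expect_identical(serialize_model(m1), serialize_model(m2))
  expect_equal(length(m1$kdm$k), 3L)  # three PCs from three markers
  heldout <- split_dataset(rec, "cohort")
  sc <- score_cohort(m1, heldout)
  ct <- cor.test(sc$ba, sc$age)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 1e-6)
})

test_that("model JSON round trip reproduces BA bitwise and validates input", {
  rec <- prepared_cohort(complete_spec(n_per_sex = 200, seed = 47))
  train <- split_dataset(rec, "healthy_training")
  model <- fit_vascular_age_model(train, sex = "male")
  path <- withr::local_tempfile(fileext = ".json")
  serialize_model(model, path)
  model2 <- load_model(path)
  probe <- rec[rec$sex == "male", ][1:20, ]
  expect_identical(estimate_ba(model, probe), estimate_ba(model2, probe))
  js <- serialize_model(model)
  expect_error(load_model(substr(js, 1, nchar(js) %/% 2)), "parse")
  broken <- jsonlite::fromJSON(js, simplifyVector = TRUE)
  broken$kdm$s <- NULL
  expect_error(load_model(jsonlite::toJSON(broken, auto_unbox = TRUE)),
               "missing 's'")
  wrongv <- jsonlite::fromJSON(js, simplifyVector = TRUE)
  wrongv$version <- "9.9"
  expect_error(load_model(jsonlite::toJSON(wrongv, auto_unbox = TRUE)),
               "version")
})

test_that("missing markers and empty parameter sets are rejected at scoring", {
  rec <- prepared_cohort(complete_spec(n_per_sex = 150, seed = 53))
  train <- split_dataset(rec, "healthy_training")
  model <- fit_vascular_age_model(train, sex = "male")
  probe <- rec[rec$sex == "male", ][1:5, ]
  probe$ABI[2] <- NA
  expect_error(estimate_ba(model, probe), "missing")
  expect_error(kdm_ba(c(1, 2), list(k = numeric(), q = numeric(),
                                    s = numeric())), "empty")
})
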