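# Shared fixtures: small cohort specs built in code.

# Noise-free spec: every marker sits exactly on its sex-specific line.
noise_free_spec <- function(n_per_sex = 250, seed = 3L) {
  trm <- default_marker_trends("male"); trm$sd <- 0
  trf <- default_marker_trends("female"); trf$sd <- 0
  cohort_spec(n_per_sex = n_per_sex,
              marker_trends = list(male = trm, female = trf),
              accel_sd = 0, missing_rate = 0, seed = seed)
}

# Default-condition spec without missingness (complete-case analyses).
complete_spec <- function(n_per_sex = 500, seed = 1L, ...) {
  cohort_spec(n_per_sex = n_per_sex, missing_rate = 0, seed = seed, ...)
}

# Generate + preprocess + split in one call.
prepared_cohort <- function(spec, seed = 1L, n_iterations = 5) {
  pp <- preprocess_cohort(generate_cohort(spec), seed = seed,
                          n_iterations = n_iterations)
  assign_splits(pp$records)
}

quiet_fit <- function(...) suppressWarnings(fit_vascular_age_model(...))

# Full-enumeration oracle for the Jonckheere-Terpstra exact p-value:
# every assignment of the observed values to groups of the given sizes.
enum_jt_p <- function(x, sizes, alternative = c("increasing", "decreasing")) {
  alternative <- match.arg(alternative)
  stopifnot(length(sizes) == 3L, sum(sizes) == length(x))
  jt_stat <- function(g1, g2, g3) {
    sum(outer(g1, g2, "<")) + sum(outer(g1, g3, "<")) +
      sum(outer(g2, g3, "<"))
  }
  obs <- jt_stat(x[seq_len(sizes[1])],
                 x[sizes[1] + seq_len(sizes[2])],
                 x[sizes[1] + sizes[2] + seq_len(sizes[3])])
  idx <- seq_along(x)
  total <- 0
  hits <- 0
  for (c1 in as.data.frame(combn(idx, sizes[1]))) {
    rest <- setdiff(idx, c1)
    for (c2 in as.data.frame(combn(rest, sizes[2]))) {
      c3 <- setdiff(rest, c2)
      s <- jt_stat(x[c1], x[c2], x[c3])
      total <- total + 1
      if (alternative == "increasing") {
        if (s >= obs) hits <- hits + 1
      } else {
        if (s <= obs) hits <- hits + 1
      }
    }
  }
  hits / total
}
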