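# Cortical signature: w-score normalization and contrast maps.

make_controls <- function(n = 200L, n_regions = 12L, seed = 5L,
                          age_slope = -0.01, sex_effect = 0.08,
                          noise_sd = 0.1) {
  set.seed(seed)
  age <- runif(n, 45, 80)
  sex <- rbinom(n, 1L, 0.5)
  regions <- sprintf("region_%03d", 1:n_regions)
  th <- sapply(seq_len(n_regions), function(r) {
    2.5 + 0.02 * r + age_slope * (age - 60) + sex_effect * sex +
      rnorm(n, sd = noise_sd)
  })
  colnames(th) <- regions
  df <- data.frame(subject_id = sprintf("c%03d", 1:n), group = "control",
                   age = age, sex = sex, duration = 0)
  cbind(df, as.data.frame(th))
}

test_that("w-score model recovers known coefficients and matches lm()", {
  controls <- make_controls(n = 200L, seed = 5L)
  m <- fit_wscore_model(controls)
  expect_identical(m$n_controls, 200L)
  for (r in c("region_001", "region_007")) {
    ref <- oracle_wscore_fit(controls, r)
    expect_equal(unname(m$coef[, r]), unname(ref$coef), tolerance = 1e-10)
    expect_equal(unname(m$resid_sd[r]), ref$sigma, tolerance = 1e-10)
    # recovered age slope within 2 SEs of the generating value
    expect_lt(abs(m$coef["age", r] - (-0.01)), 2 * ref$se["age"])
  }
})

test_that("degenerate control designs are rejected by name", {
  controls <- make_controls(n = 50L)
  controls$age <- 63
  expect_error(fit_wscore_model(controls), "age", class = "degenerate_design")
  controls2 <- make_controls(n = 50L)
  controls2$sex <- 1L
  expect_error(fit_wscore_model(controls2), "sex", class = "degenerate_design")
})

test_that("w-scores follow their definition and are centered in-sample", {
  controls <- make_controls(n = 120L, seed = 9L)
  m <- fit_wscore_model(controls)

  # a subject exactly at the model prediction has w = 0 everywhere; one
  # residual-SD above prediction in one region has w = 1 there
  subj <- controls[1L, ]
  pred <- as.numeric(m$coef["intercept", ]) +
    as.numeric(m$coef["age", ]) * subj$age +
    as.numeric(m$coef["sex", ]) * subj$sex
  regions <- m$regions
  subj[regions] <- as.list(pred)
  w0 <- apply_wscore(m, subj)
  expect_true(all(abs(w0) < 1e-10))
  subj[regions[3L]] <- pred[3L] + m$resid_sd[3L]
  w1 <- apply_wscore(m, subj)
  expect_equal(unname(w1[1L, 3L]), 1, tolerance = 1e-10)

  # in-sample controls: per-region mean w-score is numerically zero
  w_all <- apply_wscore(m, controls)
  expect_true(all(abs(colMeans(w_all)) < 1e-10))
})

test_that("w-scores are invariant to rescaling the thickness unit", {
  controls <- make_controls(n = 80L, seed = 3L)
  subjects <- make_controls(n = 20L, seed = 4L)
  regions <- sprintf("region_%03d", 1:12)
  w_mm <- apply_wscore(fit_wscore_model(controls), subjects)
  controls10 <- controls; subjects10 <- subjects
  controls10[regions] <- controls[regions] * 10
  subjects10[regions] <- subjects[regions] * 10
  w_tenth <- apply_wscore(fit_wscore_model(controls10), subjects10)
  expect_equal(w_mm, w_tenth, tolerance = 1e-9)
})

test_that("contrast map matches the two-sample t oracle and is antisymmetric", {
  set.seed(21)
  n_per <- 25L
  w <- rbind(matrix(rnorm(n_per * 10), n_per),
             matrix(rnorm(n_per * 10, mean = 0.4), n_per))
  colnames(w) <- sprintf("region_%03d", 1:10)
  groups <- rep(c("sporadic", "genetic"), each = n_per)
  dur <- rep(3, 2L * n_per)  # constant: duration drops from the design

  cm <- compute_contrast(w, groups, dur, "genetic", "sporadic")
  expect_identical(nrow(cm), 10L)
  t_ref <- vapply(seq_len(10L), function(r) {
    oracle_two_sample_t(w[groups == "genetic", r], w[groups == "sporadic", r])
  }, numeric(1L))
  expect_equal(cm$t, t_ref, tolerance = 1e-8)

  # antisymmetry under swapping target and reference
  cm_rev <- compute_contrast(w, groups, dur, "sporadic", "genetic")
  expect_equal(cm_rev$t, -cm$t, tolerance = 1e-10)

  # identical w-score rows give t = 0 everywhere
  w_same <- rbind(w[1:n_per, ], w[1:n_per, ])
  cm0 <- compute_contrast(w_same, groups, dur, "genetic", "sporadic")
  expect_true(all(abs(cm0$t) < 1e-10))

  # group with < 2 subjects fails
  expect_error(compute_contrast(w[c(1, 26:50), ], groups[c(1, 26:50)],
                                dur[c(1, 26:50)], "sporadic", "genetic"),
               class = "insufficient_data")
})

test_that("duration is adjusted for when it varies", {
  set.seed(31)
  n <- 60L
  dur <- runif(n, 1, 8)
  g <- rep(c(0, 1), each = n / 2)
  # w depends on duration only; any apparent group effect must vanish
  w <- matrix(0.5 * dur + rnorm(n, sd = 0.1), n, 4L)
  colnames(w) <- sprintf("region_%03d", 1:4)
  groups <- ifelse(g == 1, "genetic", "sporadic")
  cm_adj <- compute_contrast(w, groups, dur, "genetic", "sporadic")
  # per-region fit equals lm() t-statistic
  ref <- summary(lm(w[, 1L] ~ g + dur))$coefficients["g", "t value"]
  expect_equal(cm_adj$t[1L], unname(ref), tolerance = 1e-8)
})
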