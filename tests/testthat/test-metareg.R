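test_that("collinear points are interpolated exactly with zero residual tau2", {
  # three points on a line: WLS recovers the line, residual Q is zero
  x <- c(1, 2, 3)
  d <- 0.1 + 0.05 * x
  v <- c(0.04, 0.09, 0.02)
  fit <- meta_regress(d, v, x)
  expect_equal(fit$slope, 0.05, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-10)
  expect_equal(fit$tau2_residual, 0)
})

test_that("moderator preconditions are enforced and missing values dropped", {
  d <- c(0.1, 0.2, 0.3, 0.4); v <- rep(0.04, 4)
  expect_error(meta_regress(d, v, rep(1, 4)), "no moderator variance")
  expect_error(meta_regress(d[1:2], v[1:2], c(1, 2)), "at least 3")
  fit <- meta_regress(c(d, 0.5), c(v, 0.04), c(1, 2, 3, 4, NA))
  expect_equal(fit$n_used, 4)
  expect_equal(fit$n_dropped, 1)
})

test_that("Q_model is the squared slope z and its p-value is chi-square(1)", {
  set.seed(31)
  for (i in 1:10) {
    k <- sample(5:20, 1)
    x <- runif(k, 4, 18)
    eff <- random_effects(k)
    fit <- meta_regress(eff$d, eff$variance, x)
    expect_equal(fit$Q_model, (fit$slope / fit$slope_se)^2,
                 tolerance = 1e-9)
    expect_equal(fit$p, pchisq(fit$Q_model, 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("Q_model is invariant to affine rescaling of the moderator", {
  set.seed(32)
  x <- runif(12, 1, 20)
  eff <- random_effects(12)
  f1 <- meta_regress(eff$d, eff$variance, x)
  f2 <- meta_regress(eff$d, eff$variance, 3.6 * x - 40)
  expect_equal(f1$Q_model, f2$Q_model, tolerance = 1e-9)
  expect_equal(f1$slope, f2$slope * 3.6, tolerance = 1e-9)
  expect_equal(f1$tau2_residual, f2$tau2_residual, tolerance = 1e-9)
})

test_that("the intercept-only model nests the pooled random-effects estimate", {
  set.seed(33)
  eff <- random_effects(15)
  fit <- meta_regress(eff$d, eff$variance, x = NULL)
  pool <- pool_random_effects(eff$d, eff$variance, method = "DL")
  expect_equal(fit$intercept, pool$d, tolerance = 1e-10)
  expect_equal(fit$intercept_se, pool$se, tolerance = 1e-10)
  expect_equal(fit$tau2_residual, pool$tau2, tolerance = 1e-10)
})

test_that("slope, SE and residual tau2 agree with metafor's moderator fit", {
  set.seed(34)
  x <- runif(18, 4, 18)
  eff <- random_effects(18)
  eff$d <- eff$d + 0.03 * x
  ours <- meta_regress(eff$d, eff$variance, x, method = "DL")
  ref <- metafor::rma(yi = eff$d, vi = eff$variance, mods = ~x,
                      method = "DL")
  expect_equal(ours$slope, as.numeric(ref$beta[2]), tolerance = 1e-6)
  expect_equal(ours$slope_se, ref$se[2], tolerance = 1e-6)
  expect_equal(ours$tau2_residual, ref$tau2, tolerance = 1e-6)
  expect_equal(ours$Q_model, as.numeric(ref$QM), tolerance = 1e-6)

  ours_reml <- meta_regress(eff$d, eff$variance, x, method = "REML")
  ref_reml <- metafor::rma(yi = eff$d, vi = eff$variance, mods = ~x,
                           method = "REML")
  expect_equal(ours_reml$tau2_residual, ref_reml$tau2, tolerance = 1e-4)
  expect_equal(ours_reml$slope, as.numeric(ref_reml$beta[2]),
               tolerance = 1e-5)
})

test_that("a simulated age slope of 0.05 per year is recovered within 0.02", {
  set.seed(35)
  k <- 100
  x <- runif(k, 4, 18)
  v <- runif(k, 0.02, 0.08)
  d <- rnorm(k, 0.1 + 0.05 * x, sqrt(v + 0.04))
  fit <- meta_regress(d, v, x)
  expect_lt(abs(fit$slope - 0.05), 0.02)
})

test_that("permuted moderator labels reject near the nominal 5% rate", {
  set.seed(36)
  k <- 30
  x <- runif(k, 4, 18)
  v <- runif(k, 0.02, 0.08)
  d <- rnorm(k, 0.2 + 0.04 * x, sqrt(v + 0.03))
  reps <- 1000
  rej <- logical(reps)
  crit <- qchisq(0.95, 1)
  for (r in seq_len(reps)) {
    fit <- meta_regress(d, v, sample(x))
    rej[r] <- fit$Q_model > crit
  }
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.09)
})

test_that("the moderator suite runs both analyses and records skips", {
  ds <- generate_dataset(preset_mbi_review(seed = 9))
  suite <- run_moderator_suite(ds)
  expect_setequal(unique(suite$suite), c("all", "active_only"))
  for (s in c("all", "active_only"))
    expect_lte(sum(suite$suite == s), 21)  # 7 categories x 3 moderators
  expect_true(all(c("age_mean", "total_hours", "rob_score") %in%
                    suite$moderator))
  fitted <- is.na(suite$note) | suite$note == ""
  expect_true(all(suite$Q_model[fitted] >= 0))

  # all-missing moderator becomes a skip record, not an error
  ds2 <- ds
  ds2$studies$total_hours <- NA_real_
  suite2 <- run_moderator_suite(ds2, suites = "all")
  th <- suite2[suite2$moderator == "total_hours", ]
  expect_true(all(th$note != ""))
  expect_true(all(is.na(th$slope)))
})

test_that("positive age slope means larger effects in older samples", {
  set.seed(37)
  cfg <- sim_config(n_studies = 80, delta = 0, tau2 = 0,
                    arm_n_range = c(50, 80), category_probs = 1,
                    measures_per_category_range = c(1, 1),
                    multi_arm_prob = 0, seed = 38)
  ds <- generate_dataset(cfg)
  # add a deterministic age effect on the standardized scale
  age <- ds$studies$age_mean[match(ds$measures$study_id,
                                   ds$studies$study_id)]
  shift <- 0.05 * (age - 11)
  shift <- ifelse(ds$measures$direction == "lower_better", -shift, shift)
  ds$measures$mbi_post_mean <- ds$measures$mbi_post_mean + shift
  suite <- run_moderator_suite(ds, suites = "all")
  ages <- suite[suite$moderator == "age_mean" & suite$note == "", ]
  expect_true(all(ages$slope > 0))
})
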