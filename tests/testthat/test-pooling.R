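test_that("Cochran's Q matches hand computation and a re-summation oracle", {
  expect_equal(cochran_q(c(0.3, 0.3, 0.3), c(0.1, 0.2, 0.05))$Q, 0)

  q <- cochran_q(c(0, 1), c(0.1, 0.1))
  expect_equal(q$Q, 5)
  expect_equal(q$df, 1L)
  expect_equal(q$p_Q, pchisq(5, 1, lower.tail = FALSE))

  set.seed(3)
  for (i in 1:10) {
    k <- sample(3:12, 1)
    d <- rnorm(k); v <- runif(k, 0.02, 0.3)
    # brute-force oracle: explicit loop over the defining sum
    w <- 1 / v
    dbar <- sum(w * d) / sum(w)
    Q_oracle <- 0
    for (j in seq_len(k)) Q_oracle <- Q_oracle + w[j] * (d[j] - dbar)^2
    expect_equal(cochran_q(d, v)$Q, Q_oracle, tolerance = 1e-12)
  }
  expect_error(cochran_q(0.2, 0.1), "at least 2")
})

test_that("I-squared applies the truncated (Q - df)/Q rule", {
  expect_equal(i_squared(21.00, 10), 100 * 11 / 21)
  expect_equal(i_squared(4.21, 8), 0)   # Q below df truncates to 0
  expect_equal(i_squared(10, 10), 0)    # boundary Q = df
  expect_equal(i_squared(0, 5), 0)      # defined as 0 at Q = 0
  expect_true(all(i_squared(runif(50, 0, 100), 10) <= 100))
})

test_that("DerSimonian-Laird tau2 follows the method-of-moments closed form", {
  # Q < df truncates to zero
  expect_equal(dl_tau2(c(0.3, 0.31, 0.29), c(0.2, 0.2, 0.2)), 0)
  # continues the Q = 5 example: C = 10, tau2 = 0.4
  expect_equal(dl_tau2(c(0, 1), c(0.1, 0.1)), 0.4)
  # equal-variance closed form: tau2 = (Q - df) * v / (k - 1) when all v equal
  set.seed(4)
  d <- rnorm(8, 0, 0.5); v <- rep(0.07, 8)
  q <- cochran_q(d, v)
  C <- 8 / 0.07 - (8 / 0.07^2) / (8 / 0.07)
  expect_equal(dl_tau2(d, v), max(0, (q$Q - q$df) / C), tolerance = 1e-12)
})

test_that("random-effects pooling reproduces the worked example and nests fixed effect", {
  # single effect: identity with se = sqrt(v + tau2)
  p1 <- pool_random_effects(0.4, 0.09, tau2 = 0.01)
  expect_equal(p1$d, 0.4)
  expect_equal(p1$se, sqrt(0.10))

  p <- pool_random_effects(c(0, 1), c(0.1, 0.1), tau2 = 0.4)
  expect_equal(p$d, 0.5)
  expect_equal(p$se, 0.5)
  expect_equal(p$z, 1)
  expect_equal(p$ci_low, 0.5 - 1.959964 * 0.5)
  expect_equal(p$ci_high, 0.5 + 1.959964 * 0.5)
  expect_equal(p$p, 2 * pnorm(-1))

  # tau2 = 0 reduces exactly to inverse-variance fixed-effect pooling
  set.seed(5)
  d <- rnorm(6); v <- runif(6, 0.01, 0.2)
  p0 <- pool_random_effects(d, v, tau2 = 0)
  w <- 1 / v
  expect_equal(p0$d, sum(w * d) / sum(w), tolerance = 1e-12)
  expect_equal(p0$se, sqrt(1 / sum(w)), tolerance = 1e-12)
})

test_that("pooled estimate agrees with metafor's DL fit", {
  set.seed(6)
  eff <- random_effects(12)
  ours <- pool_random_effects(eff$d, eff$variance, method = "DL")
  ref <- metafor::rma(yi = eff$d, vi = eff$variance, method = "DL")
  expect_equal(ours$d, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(ours$se, ref$se, tolerance = 1e-8)
  expect_equal(ours$tau2, ref$tau2, tolerance = 1e-8)
  expect_equal(ours$Q, ref$QE, tolerance = 1e-8)
  expect_equal(ours$i2, ref$I2, tolerance = 1e-4)

  ours_reml <- pool_random_effects(eff$d, eff$variance, method = "REML")
  ref_reml <- metafor::rma(yi = eff$d, vi = eff$variance, method = "REML")
  expect_equal(ours_reml$tau2, ref_reml$tau2, tolerance = 1e-4)
  expect_equal(ours_reml$d, as.numeric(ref_reml$beta), tolerance = 1e-5)
})

test_that("pooled d lies within the range of its inputs and ignores input order", {
  set.seed(8)
  for (i in 1:20) {
    k <- sample(2:15, 1)
    d <- rnorm(k); v <- runif(k, 0.01, 0.3)
    p <- pool_random_effects(d, v)
    expect_gte(p$d, min(d)); expect_lte(p$d, max(d))
    ix <- sample(k)
    p2 <- pool_random_effects(d[ix], v[ix])
    expect_equal(p$d, p2$d, tolerance = 1e-12)
    expect_equal(p$tau2, p2$tau2, tolerance = 1e-12)
    # tau2 and i2 vanish together (same Q, df >= 1)
    expect_identical(p$tau2 > 0, p$i2 > 0)
  }
})

test_that("pool_by_category emits one row per category plus the all-measures row", {
  ds <- fixture_dataset()
  tbl <- pool_by_category(ds)
  expect_equal(tbl$label[1], "all_measures")
  expect_setequal(tbl$label,
                  c("all_measures", "mindfulness", "depression",
                    "anxiety_stress"))
  all_row <- tbl[tbl$label == "all_measures", ]
  expect_equal(all_row$k_studies, 2)
  expect_equal(all_row$n_comparisons, 4)   # composite units
  expect_equal(all_row$n_effects, 5)       # measure-level effects
  # B's mbi arm shared between two comparisons is counted once
  expect_equal(all_row$total_n, 20 + 20 + 10 + 10 + 12)
  # single-comparison categories keep their row with NA heterogeneity
  mind <- tbl[tbl$label == "mindfulness", ]
  expect_true(is.na(mind$Q) && is.na(mind$i2))
  expect_equal(mind$n_comparisons, 1)
})

test_that("control filters select the matching comparisons", {
  ds <- fixture_dataset()
  active <- pool_by_category(ds, control_filter = "active_only")
  # only B cmp2 (active_intervention) qualifies
  expect_equal(active[active$label == "all_measures", "n_comparisons"], 1)
  passive <- pool_by_category(ds, control_filter = "passive_only")
  expect_equal(passive[passive$label == "all_measures", "n_comparisons"], 3)
  expect_error(pool_by_category(ds, control_filter = "bogus"), "unknown")
  expect_warning(
    empty <- pool_by_category(ds, control_filter = "attention_placebo"),
    "no comparisons")
  expect_equal(nrow(empty), 0)
})

test_that("subgroup rows split by control subtype, multi-arm studies in several rows", {
  ds <- fixture_dataset()
  tbl <- subgroup_by_control(ds)
  expect_setequal(tbl$label,
                  c("wait_list", "no_contact", "active_intervention"))
  # study B appears in both its subtype rows
  expect_true(all(tbl$k_studies[tbl$label %in%
                                  c("no_contact", "active_intervention")] == 1))
  expect_gte(sum(tbl$k_studies), length(unique(ds$studies$study_id)))
})

test_that("subgroups simulated with inflated wait-list effects rank accordingly", {
  cfg <- sim_config(n_studies = 60, delta = 0.1, tau2 = 0.01,
                    arm_n_range = c(40, 80), category_probs = 1,
                    measures_per_category_range = c(1, 1),
                    multi_arm_prob = 0, seed = 99)
  ds <- generate_dataset(cfg)
  # inflate the observed post means of every wait-list comparison by a
  # constant on the standardized scale
  cmp <- comparison_table(ds)
  wl <- paste(cmp$study_id, cmp$comparison_id)[cmp$control_subtype ==
                                                 "wait_list"]
  ix <- paste(ds$measures$study_id, ds$measures$comparison_id) %in% wl
  bump <- ifelse(ds$measures$direction[ix] == "lower_better", -0.5, 0.5)
  ds$measures$mbi_post_mean[ix] <- ds$measures$mbi_post_mean[ix] + bump
  tbl <- subgroup_by_control(ds)
  expect_gt(tbl$d[tbl$label == "wait_list"],
            tbl$d[tbl$label == "no_contact"])
})
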