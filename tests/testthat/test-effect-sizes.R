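one_measure <- function(mbi, ctl, direction = "higher_better") {
  fixture_measure("s1", "c1", "ctl1", "m1", "mindfulness",
                  direction = direction, mbi = mbi, ctl = ctl)
}

test_that("ppc d equals change-score difference over pooled pretest SD", {
  cfg <- es_config()
  # equal changes in both arms -> 0 regardless of SDs
  es <- compute_ppc_d(one_measure(c(3, 2, 8, 9, 15), c(1, 7, 6, 2, 22)), cfg)
  expect_equal(es$d, 0)

  # S_pre = 2, d = (4 - 1)/2
  es <- compute_ppc_d(one_measure(c(10, 2, 14, 2, 20), c(10, 2, 11, 2, 20)),
                      cfg)
  expect_equal(es$d, 1.5)
  expect_equal(es$variance, 0.1 + 1.5^2 / 80)

  # unequal pretest SDs pool with Bessel weights: S_pre = sqrt(5)
  es <- compute_ppc_d(one_measure(c(0, 3, 2, 3, 10), c(0, 1, 0, 1, 10)), cfg)
  expect_equal(es$d, 2 / sqrt(5), tolerance = 1e-12)

  # lower-is-better flips the sign so positive d favours the MBI
  es <- compute_ppc_d(one_measure(c(20, 4, 15, 4, 20), c(20, 4, 19, 4, 20),
                                  direction = "lower_better"), cfg)
  expect_equal(es$d, 1.0)
})

test_that("optional small-sample correction multiplies by Hedges J", {
  m <- one_measure(c(10, 2, 14, 2, 20), c(10, 2, 11, 2, 20))
  d_plain <- compute_ppc_d(m, es_config())$d
  d_corr <- compute_ppc_d(m, es_config(hedges_correction = TRUE))$d
  expect_equal(d_corr, d_plain * (1 - 3 / (4 * 38 - 1)))
})

test_that("degenerate arm sizes are rejected", {
  expect_error(compute_ppc_d(one_measure(c(1, 1, 2, 1, 1), c(1, 1, 1, 1, 1))),
               "degenerate")
  expect_error(variance_ppc_d(0.2, 1, 20), "at least 2")
})

test_that("sampling variance follows the change-score formula", {
  expect_equal(variance_ppc_d(0, 20, 20, rho_prepost = 0.5), 0.10)
  # perfect pre/post correlation removes change-score noise
  expect_equal(variance_ppc_d(0, 20, 20, rho_prepost = 1 - 1e-12), 0,
               tolerance = 1e-10)
  # monotone in |d| at fixed n, rho
  ds <- seq(0, 2, by = 0.25)
  vs <- variance_ppc_d(ds, 15, 25, 0.5)
  expect_true(all(diff(vs) > 0))
  expect_error(variance_ppc_d(0, 10, 10, rho_prepost = 1), "rho_prepost")
})

test_that("d is invariant to rescaling the instrument and antisymmetric in arms", {
  set.seed(42)
  cfg <- es_config()
  for (i in 1:20) {
    mbi <- c(rnorm(1), runif(1, 0.5, 3), rnorm(1), runif(1, 0.5, 3),
             sample(5:50, 1))
    ctl <- c(rnorm(1), runif(1, 0.5, 3), rnorm(1), runif(1, 0.5, 3),
             sample(5:50, 1))
    d0 <- compute_ppc_d(one_measure(mbi, ctl), cfg)$d
    # scale invariance: multiply all means and SDs by c > 0
    cc <- runif(1, 0.1, 10)
    scaled <- one_measure(mbi * c(cc, cc, cc, cc, 1),
                          ctl * c(cc, cc, cc, cc, 1))
    expect_equal(compute_ppc_d(scaled, cfg)$d, d0, tolerance = 1e-12)
    # arm swap negates the raw d
    swapped <- one_measure(ctl, mbi)
    expect_equal(compute_ppc_d(swapped, cfg)$d, -d0, tolerance = 1e-12)
  }
})

test_that("category composites average d and combine variances at rho_measures", {
  cfg <- es_config()
  es <- compute_effect_sizes(fixture_dataset(), cfg)
  single <- es[es$measure_name == "dep_a", ]
  agg <- aggregate_category(single, cfg)
  expect_equal(agg$d, single$d)
  expect_equal(agg$variance, single$variance)
  expect_equal(agg$n_measures_averaged, 1L)

  # d's {0.2, 0.4} -> 0.3; v's {0.04, 0.09} at rho 1 -> 0.0625
  eff <- data.frame(study_id = "s", comparison_id = "c",
                    category = "attention", measure_name = c("a", "b"),
                    d = c(0.2, 0.4), variance = c(0.04, 0.09),
                    n_total = 40L)
  agg <- aggregate_category(eff, es_config(rho_measures = 1))
  expect_equal(agg$d, 0.3)
  expect_equal(agg$variance, 0.0625)
  expect_equal(agg$n_measures_averaged, 2L)

  mixed <- eff; mixed$category <- c("attention", "depression")
  expect_error(aggregate_category(mixed, cfg), "mixed categories")
})

test_that("composite variance matches a brute-force covariance-matrix oracle", {
  set.seed(7)
  for (rho in c(0, 0.3, 1)) {
    cfg <- es_config(rho_measures = rho)
    for (i in 1:10) {
      m <- sample(2:6, 1)
      eff <- data.frame(study_id = "s", comparison_id = "c",
                        category = "attention",
                        measure_name = sprintf("m%02d", 1:m),
                        d = rnorm(m), variance = runif(m, 0.01, 0.3),
                        n_total = 40L)
      # oracle: w' Sigma w with equal weights 1/m and the full
      # correlation-rho covariance matrix
      s <- sqrt(eff$variance)
      Sigma <- rho * outer(s, s)
      diag(Sigma) <- eff$variance
      w <- rep(1 / m, m)
      expect_equal(aggregate_category(eff, cfg)$variance,
                   drop(t(w) %*% Sigma %*% w), tolerance = 1e-12)
    }
  }
  # at rho = 1 the composite variance equals the mean of variances only
  # when all variances are equal
  eq <- data.frame(study_id = "s", comparison_id = "c", category = "a",
                   measure_name = c("x", "y"), d = c(0, 1),
                   variance = c(0.05, 0.05), n_total = 10L)
  eq$category <- "attention"
  expect_equal(aggregate_category(eq, es_config(rho_measures = 1))$variance,
               0.05)
})

test_that("dataset-level aggregation is order-independent and keyed correctly", {
  cfg <- es_config()
  es <- compute_effect_sizes(fixture_dataset(), cfg)
  comps <- aggregate_effects(es, cfg)
  # A: mindfulness composite of 2 + depression; B: one per comparison
  expect_equal(nrow(comps), 4)
  expect_equal(comps$n_measures_averaged[comps$study_id == "A" &
                                           comps$category == "mindfulness"],
               2L)
  # mindfulness composite d = mean(1.5, 1.0)
  expect_equal(comps$d[comps$category == "mindfulness"], 1.25)
  shuffled <- aggregate_effects(es[rev(seq_len(nrow(es))), ], cfg)
  expect_equal(comps, shuffled)
})
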