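test_that("REML returns zero between-study variance for identical effects", {
  expect_equal(reml_tau2(rep(0.3, 5), runif(5, 0.02, 0.1)), 0)
})

test_that("REML matches the brute-force grid oracle on the worked fixture", {
  y <- c(0.1, 0.5, 0.9); v <- c(0.04, 0.04, 0.04)
  t2 <- reml_tau2(y, v)
  expect_equal(t2, grid_reml_oracle(y, v), tolerance = 1e-6)

  # duplicating every study changes tau2 only per the REML equations
  t2_dup <- reml_tau2(rep(y, 2), rep(v, 2))
  expect_equal(t2_dup, grid_reml_oracle(rep(y, 2), rep(v, 2)), tolerance = 1e-6)
})

test_that("REML agrees with metafor's estimate", {
  skip_if_not_installed("metafor")
  set.seed(88)
  for (i in 1:10) {
    k <- sample(3:12, 1)
    y <- rnorm(k, 0.3, 0.3)
    v <- runif(k, 0.01, 0.2)
    fit <- metafor::rma(yi = y, vi = v, method = "REML", test = "knha",
                        control = list(threshold = 1e-10))
    expect_lt(abs(reml_tau2(y, v) - fit$tau2), 1e-7)
    pooled <- pool_hksj(y, v, reml_tau2(y, v))
    expect_lt(abs(pooled$mu - fit$beta[1]), 1e-7)
    expect_lt(abs(pooled$se_hksj - fit$se), 1e-7)
    expect_lt(abs(pooled$ci_low - fit$ci.lb), 1e-6)
  }
})

test_that("HKSJ pooling follows the weighted-dispersion formulas", {
  # zero dispersion: degenerate interval at the common value
  deg <- pool_hksj(rep(0.4, 4), c(0.05, 0.04, 0.03, 0.06), tau2 = 0)
  expect_equal(deg$mu, 0.4)
  expect_equal(deg$se_hksj, 0)
  expect_equal(deg$ci_low, 0.4)
  expect_equal(deg$ci_high, 0.4)

  # symmetry: k = 3 effects symmetric about 0.5 with equal variances
  expect_equal(pool_hksj(c(0.2, 0.5, 0.8), rep(0.04, 3), tau2 = 0.01)$mu, 0.5)

  # random k = 5 fixture against an independent transcription of the formulas
  set.seed(11)
  y <- rnorm(5, 0.3, 0.4); v <- runif(5, 0.02, 0.15); t2 <- 0.07
  res <- pool_hksj(y, v, t2)
  w <- 1 / (v + t2)
  mu <- sum(w * y) / sum(w)
  se <- sqrt(sum(w * (y - mu)^2) / (4 * sum(w)))
  expect_equal(res$mu, mu, tolerance = 1e-8)
  expect_equal(res$se_hksj, se, tolerance = 1e-8)
  expect_equal(res$ci_low, mu - qt(0.975, 4) * se, tolerance = 1e-8)
  expect_equal(res$ci_high, mu + qt(0.975, 4) * se, tolerance = 1e-8)
})

test_that("HKSJ interval width shrinks with k at fixed dispersion", {
  widths <- vapply(c(4, 8, 16, 32), function(k) {
    y <- rep(c(0.2, 0.6), k / 2)  # constant spread regardless of k
    res <- pool_hksj(y, rep(0.04, k), tau2 = 0.04)
    res$ci_high - res$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("heterogeneity reproduces the hand-derived Q and I2", {
  het <- heterogeneity(c(0.1, 0.5, 0.9), c(0.04, 0.04, 0.04))
  expect_equal(het$Q, 8.0, tolerance = 1e-12)
  expect_equal(het$I2, 75, tolerance = 1e-12)
  expect_equal(het$p_Q, pchisq(8, 2, lower.tail = FALSE))

  none <- heterogeneity(rep(0.4, 4), runif(4, 0.02, 0.1))
  expect_equal(none$Q, 0)
  expect_equal(none$I2, 0)
  expect_equal(none$p_Q, 1)
})

test_that("I2 is zero at the Q = k-1 boundary and invariant to rescaling", {
  # construct y with Q exactly k-1 = 1: two studies, equal v
  v <- c(0.1, 0.1)
  y <- c(0, sqrt(0.2))  # Q = (1/0.1)*2*(d/2)^2 = 5*d^2 = 1 when d^2 = 0.2
  expect_equal(heterogeneity(y, v)$Q, 1, tolerance = 1e-12)
  expect_equal(heterogeneity(y, v)$I2, 0)

  set.seed(5)
  y <- rnorm(6, 0.4, 0.3); v <- runif(6, 0.02, 0.2)
  for (c in c(0.1, 2, 13)) {
    expect_equal(heterogeneity(c * y, c^2 * v)$I2, heterogeneity(y, v)$I2,
                 tolerance = 1e-10)
  }
})

test_that("prediction intervals follow the t(k-2) convention", {
  # tau2 = 0: narrowest case, mu +/- t * se
  pi0 <- prediction_interval(0.3, 0.05, 0, k = 10)
  expect_equal(pi0$pi_low, 0.3 - qt(0.975, 8) * 0.05, tolerance = 1e-12)

  # worked fixture against a direct transcription
  pi <- prediction_interval(0.3, 0.05, 0.04, k = 10)
  half <- qt(0.975, 8) * sqrt(0.04 + 0.05^2)
  expect_equal(pi$pi_low, 0.3 - half, tolerance = 1e-8)
  expect_equal(pi$pi_high, 0.3 + half, tolerance = 1e-8)

  # monotone widening in tau2
  widths <- vapply(c(0, 0.05, 0.2, 1, 10), function(t2) {
    p <- prediction_interval(0.3, 0.05, t2, k = 10)
    p$pi_high - p$pi_low
  }, numeric(1))
  expect_true(all(diff(widths) > 0))

  expect_error(prediction_interval(0.3, 0.05, 0.04, k = 2),
               class = "cotmeta_input_error")

  # k-1 df variant available by configuration
  alt <- prediction_interval(0.3, 0.05, 0.04, k = 10, df = "k_minus_1")
  expect_equal(alt$pi_high, 0.3 + qt(0.975, 9) * sqrt(0.04 + 0.0025))
})

test_that("eligibility drops missing-SD studies and small groups with reasons", {
  trials <- list(
    a = two_arm_trial("a"), b = two_arm_trial("b"), c = two_arm_trial("c"),
    d = two_arm_trial("d"),
    # an outcome with only two contributing studies
    e = two_arm_trial("e", broad_domain = "mood"),
    f = two_arm_trial("f", broad_domain = "mood")
  )
  trials$d$cells$sd <- NA_real_
  elig <- eligible_groups(trials, meta_spec())
  expect_equal(nrow(elig$groups), 1L)
  expect_equal(elig$groups$outcome, "global_cognition")
  expect_equal(elig$groups$k, 3L)
  expect_true(any(elig$exclusions$trial_id == "d" &
                  elig$exclusions$reason == "missing means/SDs"))
  expect_true(any(elig$exclusions$outcome == "mood" &
                  elig$exclusions$reason == "fewer than 3 studies"))
})

test_that("a scope with no matching population yields an empty result", {
  trials <- list(a = two_arm_trial("a"), b = two_arm_trial("b"))
  elig <- eligible_groups(trials, meta_spec(populations = "dementia"))
  expect_equal(nrow(elig$groups), 0L)
  meta <- run_meta(trials, meta_spec(populations = "dementia"))
  expect_equal(nrow(meta), 0L)
})

test_that("an empty outcome selection is rejected", {
  expect_error(meta_spec(broad_outcomes = character()),
               class = "cotmeta_input_error")
})

test_that("run_meta bookkeeping: one pooled row, per-study detail of length k", {
  trials <- list(a = two_arm_trial("a", mean_e = 0.3),
                 b = two_arm_trial("b", mean_e = 0.5),
                 c = two_arm_trial("c", mean_e = 0.7))
  meta <- run_meta(trials, meta_spec())
  expect_equal(nrow(meta), 1L)
  expect_equal(meta$k, 3L)
  expect_equal(nrow(meta$per_study[[1]]), 3L)
  expect_equal(sum(meta$per_study[[1]]$weight), 1)
  expect_equal(meta$n_total, 180L)
  expect_lte(meta$pi_low, meta$ci_low)
  expect_gte(meta$pi_high, meta$ci_high)

  td <- tidy(meta)
  expect_equal(nrow(td), 3L)
  expect_true(all(c("outcome", "trial_id", "g", "weight") %in% names(td)))
  gl <- glance(meta)
  expect_false("per_study" %in% names(gl))
})

test_that("correlated outcomes are pre-combined so each study contributes once", {
  tr <- example_trial("combo")  # two memory measures, same participants
  trials <- list(combo = tr, a = two_arm_trial("a", broad_domain = "memory"),
                 b = two_arm_trial("b", broad_domain = "memory"))
  elig <- eligible_groups(trials, meta_spec())
  expect_equal(elig$groups$k, 3L)
  eff <- elig$groups$effects[[1]]
  combo_row <- eff[eff$trial_id == "combo", ]
  expect_true(combo_row$pooled_within_study)
  expect_equal(combo_row$measure_id, "m_recall+m_recognition")
  # composite equals combine_correlated of the two per-measure effects
  per_measure <- trial_effects(tr)
  expect_equal(combo_row$g, mean(per_measure$g), tolerance = 1e-12)
})
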