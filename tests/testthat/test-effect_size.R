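test_that("hedges_g matches hand-evaluated small-sample correction", {
  # mean_e=1, mean_c=0, sd=1, n=20+20: d = 1, J = 1 - 3/151
  eff <- hedges_g(1, 1, 20, 0, 1, 20)
  J <- 1 - 3 / 151
  expect_equal(eff$g, J, tolerance = 1e-12)
  expect_equal(eff$g, 0.9801, tolerance = 1e-4)
  expect_equal(eff$var, J^2 * (40 / 400 + 1 / 76), tolerance = 1e-12)
  expect_equal(eff$se, sqrt(eff$var))
  expect_equal(eff$ci_low, eff$g - qnorm(0.975) * eff$se)

  # identity case: equal means give g = 0 with a CI symmetric about 0
  null <- hedges_g(3.2, 1.4, 18, 3.2, 1.1, 22)
  expect_equal(null$g, 0)
  expect_equal(null$ci_low, -null$ci_high)
})

test_that("direction flip reverses the sign of g and leaves |g|, var unchanged", {
  set.seed(421)
  for (i in 1:25) {
    me <- rnorm(1); mc <- rnorm(1)
    se_ <- runif(1, 0.5, 2); sc <- runif(1, 0.5, 2)
    ne <- sample(5:50, 1); nc <- sample(5:50, 1)
    hi <- hedges_g(me, se_, ne, mc, sc, nc, direction = "higher_better")
    lo <- hedges_g(me, se_, ne, mc, sc, nc, direction = "lower_better")
    expect_equal(lo$g, -hi$g)
    expect_equal(lo$var, hi$var)
  }
})

test_that("hedges_g rejects degenerate cells naming the offending values", {
  expect_error(hedges_g(1, 1, 1, 0, 1, 20), class = "cotmeta_input_error")
  expect_error(hedges_g(1, 0, 20, 0, 1, 20), class = "cotmeta_input_error")
  err <- tryCatch(hedges_g(1, 1, 20, 0, NA, 20), error = identity)
  expect_match(conditionMessage(err), "sd_c=NA")
})

test_that("g variance approaches 1/n_e + 1/n_c for vanishing d at large n", {
  n <- 1e4
  eff <- hedges_g(1e-6, 1, n, 0, 1, n)
  expect_equal(eff$var, 2 / n, tolerance = 1e-3)
})

test_that("combine_subgroups performs inverse-variance fixed-effect pooling", {
  base <- hedges_g(c(0.5, 0.5), c(1, 1), c(20, 20), c(0, 0), c(1, 1), c(20, 20))
  base$g <- c(0.5, 0.5); base$var <- c(0.1, 0.1)
  base$trial_id <- "s"; base$measure_id <- "m"; base$time_point <- "post"
  out <- combine_subgroups(base)
  expect_equal(out$g, 0.5)
  expect_equal(out$var, 0.05)
  expect_true(out$pooled_within_study)
  expect_equal(out$n_exp, sum(base$n_exp))

  base$g <- c(0.2, 0.8)
  expect_equal(combine_subgroups(base)$g, 0.5)  # symmetry, equal variances

  # general case against the explicit weighted-mean formula
  base$g <- c(0.0, 0.6); base$var <- c(0.05, 0.10)
  w <- 1 / base$var
  expect_equal(combine_subgroups(base)$g, sum(w * base$g) / sum(w),
               tolerance = 1e-12)
  expect_equal(combine_subgroups(base)$var, 1 / sum(w), tolerance = 1e-12)
})

test_that("combine_subgroups of m identical effects keeps g and divides var by m", {
  for (m in 2:4) {
    eff <- hedges_g(rep(0.4, m), rep(1, m), rep(25, m),
                    rep(0, m), rep(1, m), rep(25, m))
    eff$trial_id <- "s"; eff$measure_id <- "m"; eff$time_point <- "post"
    out <- combine_subgroups(eff)
    expect_equal(out$g, eff$g[1])
    expect_equal(out$var, eff$var[1] / m)
  }
})

test_that("combine_subgroups refuses effects from different trials or measures", {
  eff <- hedges_g(c(0.5, 0.5), c(1, 1), c(20, 20), c(0, 0), c(1, 1), c(20, 20))
  eff$trial_id <- c("a", "b")
  expect_error(combine_subgroups(eff), class = "cotmeta_input_error")
})

test_that("combine_correlated implements the composite-outcome variance", {
  eff <- hedges_g(c(1, 1), c(1, 1), c(20, 20), c(0, 0), c(1, 1), c(20, 20))
  eff$trial_id <- "s"
  eff$g <- c(0.4, 0.6); eff$var <- c(0.1, 0.1)
  out <- combine_correlated(eff, r = 0.5)
  expect_equal(out$g, 0.5)
  expect_equal(out$var, 0.075)  # (1/4)(0.1 + 0.1 + 2*0.5*0.1)

  # r = 0: independent-average limit var = v/m
  expect_equal(combine_correlated(eff, r = 0)$var, 0.05)
  # r -> 1: no precision gain, var -> v
  expect_equal(combine_correlated(eff, r = 1 - 1e-12)$var, 0.1,
               tolerance = 1e-9)
})

test_that("composite variance is monotone nondecreasing in r", {
  eff <- hedges_g(c(1, 1, 1), c(1, 1, 1), c(20, 30, 40),
                  c(0, 0, 0), c(1, 1, 1), c(20, 30, 40))
  eff$trial_id <- "s"
  rs <- seq(-0.45, 0.95, by = 0.1)  # above -1/(m-1) = -0.5
  vars <- vapply(rs, function(r) combine_correlated(eff, r = r)$var, numeric(1))
  expect_true(all(diff(vars) >= 0))
})

test_that("a two-arm trial yields one unadjusted comparison identical to hedges_g", {
  tr <- two_arm_trial(mean_e = 0.7, sd_e = 1.2, n_e = 24L,
                      mean_c = 0.1, sd_c = 0.9, n_c = 26L)
  cmp <- pairwise_comparisons(tr, "m1", "post")
  expect_equal(nrow(cmp), 1L)
  expect_false(cmp$adjusted)
  ref <- hedges_g(0.7, 1.2, 24, 0.1, 0.9, 26)
  expect_equal(cmp$g, ref$g)
  expect_equal(cmp$var, ref$var)
  expect_equal(cmp$experimental_arm_id, "exp")
  expect_equal(cmp$control_arm_id, "ctl")
})

test_that("identical arms in a three-arm trial give zero effects throughout", {
  tr <- multi_arm_trial(means = c(1, 1, 1), sds = c(1, 1, 1), ns = c(30, 30, 30))
  cmp <- pairwise_comparisons(tr, "m1", "post")
  expect_equal(nrow(cmp), 3L)  # 2 exp-vs-ctl + 1 exp-vs-exp
  expect_equal(cmp$g, rep(0, 3))
  ec <- cmp[cmp$comparison_type == "experimental_vs_control", ]
  expect_true(all(ec$adjusted))
  expect_equal(pool_comparisons(cmp)$g, 0)
})

test_that("adjusted pooling reproduces the GLS oracle on a three-arm fixture", {
  means <- c(0.0, 0.5, 0.3); sds <- c(1.0, 1.2, 0.9); ns <- c(28, 31, 25)
  tr <- multi_arm_trial(means = means, sds = sds, ns = ns)
  pooled <- pool_comparisons(pairwise_comparisons(tr, "m1", "post"))
  oracle <- gls_oracle(means, sds, ns)
  expect_equal(pooled$g, oracle$mu, tolerance = 1e-8)
  expect_equal(pooled$var, oracle$var, tolerance = 1e-8)
  # distinct arms counted once: 28 control, 31 + 25 experimental
  expect_equal(pooled$n_ctl, 28L)
  expect_equal(pooled$n_exp, 56L)
})

test_that("experimental-vs-experimental comparisons are kept but not pooled", {
  tr <- multi_arm_trial(means = c(0, 0.6, 0.2), sds = c(1, 1, 1), ns = c(30, 30, 30))
  effs <- trial_effects(tr)
  expect_true("experimental_vs_experimental" %in% effs$comparison_type)
  pooled <- effs[effs$pooled_within_study, ]
  expect_equal(nrow(pooled), 1L)
  ee <- effs[effs$comparison_type == "experimental_vs_experimental", ]
  expect_false(any(ee$adjusted))
})

test_that("subgroup-only reporting is combined to one study effect", {
  tr <- two_arm_trial("sub")
  tr$cells <- tibble::tibble(
    arm_id = rep(c("ctl", "exp"), times = 2),
    measure_id = "m1", time_point = "post",
    subgroup = rep(c("men", "women"), each = 2),
    n = c(12L, 13L, 15L, 14L),
    mean = c(0.0, 0.45, 0.1, 0.62), sd = c(1, 1.1, 0.9, 1.2)
  )
  effs <- trial_effects(tr)
  expect_equal(nrow(effs), 1L)
  expect_true(effs$pooled_within_study)
  # equals the fixed-effect combination of the two subgroup effects
  g_m <- hedges_g(0.45, 1.1, 13, 0.0, 1.0, 12)
  g_w <- hedges_g(0.62, 1.2, 14, 0.1, 0.9, 15)
  w <- 1 / c(g_m$var, g_w$var)
  expect_equal(effs$g, sum(w * c(g_m$g, g_w$g)) / sum(w), tolerance = 1e-12)
  expect_equal(effs$n_exp + effs$n_ctl, 54L)
})
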