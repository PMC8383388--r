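# Fixture builders shared across the test files.  All fixtures are built in
# code; nothing is read from disk except what a test itself writes.

# A minimal two-arm trial with one measure and configurable cell values.
two_arm_trial <- function(trial_id = "t1", mean_e = 0.5, sd_e = 1, n_e = 30L,
                          mean_c = 0, sd_c = 1, n_c = 30L,
                          direction = "higher_better",
                          population = "mild_cognitive_impairment",
                          broad_domain = "global_cognition") {
  coded_trial(
    trial_id = trial_id,
    citation = list(authors = "Tester, T.", year = 2015L,
                    title = paste("Fixture trial", trial_id),
                    journal = "J Fixtures"),
    status = "verified",
    coding = list(design = "randomized_controlled_trial",
                  population = population,
                  intervention_type = "cognitive_training"),
    arms = tibble::tibble(
      arm_id = c("ctl", "exp"), role = c("control", "experimental"),
      intervention_label = c("waitlist", "cognitive_training")
    ),
    measures = tibble::tibble(
      measure_id = "m1", name = "Fixture scale", broad_domain = broad_domain,
      target = "participant", direction = direction, is_primary = TRUE
    ),
    cells = tibble::tibble(
      arm_id = c("ctl", "exp"), measure_id = "m1", time_point = "post",
      subgroup = NA_character_, n = c(n_c, n_e),
      mean = c(mean_c, mean_e), sd = c(sd_c, sd_e)
    )
  )
}

# A trial with one control and n_exp_arms experimental arms, all sharing the
# control; per-arm summary stats supplied as vectors (control first).
multi_arm_trial <- function(trial_id = "ma1", means, sds, ns) {
  n_arms <- length(means)
  arm_ids <- c("ctl", paste0("exp", seq_len(n_arms - 1)))
  coded_trial(
    trial_id = trial_id,
    citation = list(authors = "Tester, T.", year = 2016L,
                    title = "Multi-arm fixture", journal = "J Fixtures"),
    status = "verified",
    coding = list(design = "randomized_controlled_trial",
                  population = "dementia",
                  intervention_type = "cognitive_stimulation"),
    arms = tibble::tibble(
      arm_id = arm_ids,
      role = c("control", rep("experimental", n_arms - 1)),
      intervention_label = c("waitlist", rep("cognitive_stimulation", n_arms - 1))
    ),
    measures = tibble::tibble(
      measure_id = "m1", name = "Fixture scale", broad_domain = "global_cognition",
      target = "participant", direction = "higher_better", is_primary = TRUE
    ),
    cells = tibble::tibble(
      arm_id = arm_ids, measure_id = "m1", time_point = "post",
      subgroup = NA_character_, n = as.integer(ns), mean = means, sd = sds
    )
  )
}

# Independent GLS oracle for the multi-arm adjustment: builds the
# comparison covariance matrix from first principles (diagonal = Hedges' g
# variances, off-diagonal = shared-control covariance with the d-product
# correction) and solves mu = (1' S^-1 y)/(1' S^-1 1) directly.
gls_oracle <- function(means, sds, ns) {
  n_exp <- length(means) - 1
  d <- J <- v <- g <- numeric(n_exp)
  for (i in seq_len(n_exp)) {
    e <- i + 1
    df <- ns[e] + ns[1] - 2
    sp <- sqrt(((ns[e] - 1) * sds[e]^2 + (ns[1] - 1) * sds[1]^2) / df)
    d[i] <- (means[e] - means[1]) / sp
    J[i] <- 1 - 3 / (4 * df - 1)
    g[i] <- J[i] * d[i]
    v[i] <- J[i]^2 * ((ns[e] + ns[1]) / (ns[e] * ns[1]) + d[i]^2 / (2 * df))
  }
  S <- diag(v, n_exp)
  for (k in seq_len(n_exp)) {
    for (l in seq_len(n_exp)) {
      if (k == l) next
      N <- ns[1] + ns[k + 1] + ns[l + 1]
      S[k, l] <- J[k] * J[l] * (1 / ns[1] + d[k] * d[l] / (2 * (N - 2)))
    }
  }
  invS1 <- solve(S, rep(1, n_exp))
  list(mu = sum(invS1 * g) / sum(invS1), var = 1 / sum(invS1))
}

# Brute-force REML oracle: global grid then two local grid refinements.
grid_reml_oracle <- function(y, v, upper = 2, n_grid = 1e5) {
  ll <- function(t2) {
    w <- 1 / (v + t2)
    mu <- sum(w * y) / sum(w)
    -0.5 * (sum(log(v + t2)) + log(sum(w)) + sum(w * (y - mu)^2))
  }
  grid <- seq(0, upper, length.out = n_grid)
  best <- grid[which.max(vapply(grid, ll, numeric(1)))]
  step <- grid[2] - grid[1]
  for (i in 1:2) {
    grid <- seq(max(0, best - step), best + step, length.out = 1001)
    best <- grid[which.max(vapply(grid, ll, numeric(1)))]
    step <- grid[2] - grid[1]
  }
  best
}
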