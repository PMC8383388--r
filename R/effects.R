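effect_cols <- c("trial_id", "measure_id", "time_point",
                 "experimental_arm_id", "control_arm_id", "comparison_type",
                 "g", "var", "se", "ci_low", "ci_high", "n_exp", "n_ctl",
                 "adjusted", "pooled_within_study")

# Low-overhead constructor for effect tables (this sits on the hot path of
# the simulation harness, so plain lists + new_tibble, no quosure capture).
effect_tbl <- function(g, var, trial_id = NA_character_,
                       measure_id = NA_character_, time_point = NA_character_,
                       experimental_arm_id = NA_character_,
                       control_arm_id = NA_character_,
                       comparison_type = "experimental_vs_control",
                       n_exp = NA_integer_, n_ctl = NA_integer_,
                       adjusted = FALSE, pooled_within_study = FALSE,
                       conf_level = 0.95) {
  k <- length(g)
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(var)
  tibble::new_tibble(list(
    trial_id = rep_len(as.character(trial_id), k),
    measure_id = rep_len(as.character(measure_id), k),
    time_point = rep_len(as.character(time_point), k),
    experimental_arm_id = rep_len(as.character(experimental_arm_id), k),
    control_arm_id = rep_len(as.character(control_arm_id), k),
    comparison_type = rep_len(comparison_type, k),
    g = g, var = var, se = se, ci_low = g - z * se, ci_high = g + z * se,
    n_exp = rep_len(as.integer(n_exp), k), n_ctl = rep_len(as.integer(n_ctl), k),
    adjusted = rep_len(adjusted, k),
    pooled_within_study = rep_len(pooled_within_study, k)
  ), nrow = k)
}

empty_effects <- function() effect_tbl(g = double(), var = double())

# Recompute se/ci after a variance update.
finish_effect <- function(row, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  row$se <- sqrt(row$var)
  row$ci_low <- row$g - z * row$se
  row$ci_high <- row$g + z * row$se
  row
}

#' Hedges' g from two-group summary statistics
#'
#' Computes the small-sample-corrected standardized mean difference between
#' an experimental and a control group from per-group n, mean and SD:
#' `d = (mean_e - mean_c)/s_pooled`, `J = 1 - 3/(4*(n_e+n_c-2) - 1)`,
#' `g = J*d`, with variance
#' `var = J^2 * ((n_e+n_c)/(n_e*n_c) + d^2/(2*(n_e+n_c-2)))`.
#' For measures where lower scores are better the sign of `g` is flipped so
#' that a positive effect always favors the experimental condition.  The
#' 95% CI at the single-study level uses the normal multiplier.
#'
#' @param mean_e,sd_e,n_e Experimental-group mean, SD and sample size.
#' @param mean_c,sd_c,n_c Control-group mean, SD and sample size.
#' @param direction `"higher_better"` (default) or `"lower_better"`.
#' @param conf_level Confidence level for the per-study interval.
#' @return A one-row (or `length(mean_e)`-row, inputs are vectorized)
#'   effect tibble with columns `g`, `var`, `se`, `ci_low`, `ci_high`,
#'   `n_exp`, `n_ctl` plus provenance columns.
#' @examples
#' hedges_g(1, 1, 20, 0, 1, 20)
#' @export
hedges_g <- function(mean_e, sd_e, n_e, mean_c, sd_c, n_c,
                     direction = "higher_better", conf_level = 0.95) {
  k <- max(length(mean_e), length(mean_c))
  direction <- rep_len(direction, k)
  bad <- which(n_e < 2 | n_c < 2 | is.na(sd_e) | is.na(sd_c) | sd_e <= 0 | sd_c <= 0)
  if (length(bad)) {
    cot_stop(paste0(
      "invalid cell for standardized mean difference (need n >= 2 and sd > 0) at position ",
      bad[1L], ": n_e=", n_e[bad[1L]], ", n_c=", n_c[bad[1L]],
      ", sd_e=", sd_e[bad[1L]], ", sd_c=", sd_c[bad[1L]]
    ), class = "cotmeta_input_error")
  }
  if (any(!direction %in% c("higher_better", "lower_better"))) {
    cot_stop("direction must be 'higher_better' or 'lower_better'",
             class = "cotmeta_input_error")
  }
  df <- n_e + n_c - 2
  s_pooled <- sqrt(((n_e - 1) * sd_e^2 + (n_c - 1) * sd_c^2) / df)
  d <- (mean_e - mean_c) / s_pooled
  J <- 1 - 3 / (4 * df - 1)
  sgn <- ifelse(direction == "lower_better", -1, 1)
  g <- sgn * J * d
  v <- J^2 * ((n_e + n_c) / (n_e * n_c) + d^2 / (2 * df))
  effect_tbl(g = g, var = v, n_exp = n_e, n_ctl = n_c,
             conf_level = conf_level)
}

# Uncorrected d and its J for a pair of cells; used when building the
# shared-arm covariance matrix, where products of uncorrected d enter.
smd_raw <- function(mean_e, sd_e, n_e, mean_c, sd_c, n_c) {
  df <- n_e + n_c - 2
  s_pooled <- sqrt(((n_e - 1) * sd_e^2 + (n_c - 1) * sd_c^2) / df)
  list(d = (mean_e - mean_c) / s_pooled, J = 1 - 3 / (4 * df - 1))
}

fixed_effect_pool <- function(g, v) {
  w <- 1 / v
  list(g = sum(w * g) / sum(w), var = 1 / sum(w))
}

#' Combine effects from independent subgroups of one study
#'
#' When a study reports data only for disjoint subgroups (for example men
#' and women separately), the subgroup effects are combined into a single
#' study-level effect by an inverse-variance fixed-effect meta-analysis of
#' the subgroups.
#'
#' @param effects Effect tibble (rows from [hedges_g()] or
#'   [pairwise_comparisons()]) for disjoint subgroups of one trial, one
#'   measure, one time point.
#' @return A one-row effect tibble with `pooled_within_study = TRUE`;
#'   subgroup sample sizes are summed.
#' @export
combine_subgroups <- function(effects) {
  effects <- as_tibble(effects)
  if (nrow(effects) < 2) cot_stop("need at least two subgroup effects to combine",
                                  class = "cotmeta_input_error")
  for (col in c("trial_id", "measure_id", "time_point")) {
    vals <- unique(effects[[col]])
    vals <- vals[!is.na(vals)]
    if (length(vals) > 1) {
      cot_stop(paste0("subgroup effects must share one ", col, "; got: ",
                      paste(vals, collapse = ", ")), class = "cotmeta_input_error")
    }
  }
  fe <- fixed_effect_pool(effects$g, effects$var)
  effect_tbl(
    g = fe$g, var = fe$var,
    trial_id = effects$trial_id[1L], measure_id = effects$measure_id[1L],
    time_point = effects$time_point[1L],
    comparison_type = effects$comparison_type[1L],
    n_exp = sum(effects$n_exp), n_ctl = sum(effects$n_ctl),
    adjusted = any(effects$adjusted), pooled_within_study = TRUE
  )
}

# Covariance between two SMD comparisons that share an arm.  Leading term
# 1/n_shared, plus the d-product correction d_k*d_l/(2*(N-2)) with N the
# total n over the three distinct arms, scaled by both J factors.  The sign
# is negative when the shared arm enters the two comparisons with opposite
# orientation (minuend in one, subtrahend in the other).
shared_arm_cov <- function(n_shared, d_k, d_l, J_k, J_l, N, same_orientation) {
  s <- if (same_orientation) 1 else -1
  s * J_k * J_l * (1 / n_shared + d_k * d_l / (2 * (N - 2)))
}

#' Pairwise comparisons within a multi-arm trial
#'
#' For trials with more than one experimental and/or control group, computes
#' one Hedges' g per (experimental, control) pair and per (experimental,
#' experimental) pair at the given measure and time point.  When two or more
#' experimental-vs-control comparisons share an arm, their standard errors
#' are inflated so that a naive inverse-variance fixed-effect pooling of the
#' adjusted comparisons reproduces the generalized-least-squares estimate
#' (point estimate and variance) under the full shared-arm covariance
#' matrix.  Experimental-vs-experimental comparisons are reported but never
#' pooled against controls.
#'
#' @param trial A [coded_trial()].
#' @param measure_id Measure to compare on.
#' @param time_point Time point label.
#' @param subgroup Subgroup label, or `NA` for whole-sample cells.
#' @return Effect tibble with one row per comparison; `adjusted` is `TRUE`
#'   on rows whose SE carries the multi-arm inflation.  Zero rows when
#'   fewer than two arms have usable data.
#' @seealso [pool_comparisons()]
#' @export
pairwise_comparisons <- function(trial, measure_id, time_point, subgroup = NA) {
  mrow <- trial$measures[trial$measures$measure_id == measure_id, ]
  if (!nrow(mrow)) {
    cot_stop(paste0("trial ", trial$trial_id, " has no measure '", measure_id, "'"),
             class = "cotmeta_input_error")
  }
  direction <- mrow$direction[1L]
  all_cells <- trial$cells
  sg <- all_cells$subgroup
  sel <- all_cells$measure_id == measure_id &
    all_cells$time_point == time_point &
    (if (is.na(subgroup)) is.na(sg) else !is.na(sg) & sg == subgroup) &
    !is.na(all_cells$sd) & all_cells$sd > 0 & all_cells$n >= 2
  cells <- all_cells[sel, ]
  if (nrow(cells) < 2) return(empty_effects())
  cells$role <- trial$arms$role[match(cells$arm_id, trial$arms$arm_id)]

  exp_cells <- cells[cells$role %in% "experimental", ]
  ctl_cells <- cells[cells$role %in% "control", ]
  if (!nrow(exp_cells) || !nrow(ctl_cells)) {
    if (nrow(exp_cells) < 2) return(empty_effects())
  }

  # fast path: the plain two-arm trial
  if (nrow(exp_cells) == 1L && nrow(ctl_cells) == 1L) {
    eff <- hedges_g(exp_cells$mean, exp_cells$sd, exp_cells$n,
                    ctl_cells$mean, ctl_cells$sd, ctl_cells$n,
                    direction = direction)
    eff$trial_id <- trial$trial_id
    eff$measure_id <- measure_id
    eff$time_point <- time_point
    eff$experimental_arm_id <- exp_cells$arm_id
    eff$control_arm_id <- ctl_cells$arm_id
    return(eff)
  }

  rows <- list()
  meta <- list()  # per-comparison arm bookkeeping for covariance building
  add_cmp <- function(a, b, type) {
    # a = minuend (favored when g > 0 before direction flip), b = subtrahend
    eff <- hedges_g(a$mean, a$sd, a$n, b$mean, b$sd, b$n, direction = direction)
    raw <- smd_raw(a$mean, a$sd, a$n, b$mean, b$sd, b$n)
    eff$trial_id <- trial$trial_id
    eff$measure_id <- measure_id
    eff$time_point <- time_point
    eff$experimental_arm_id <- a$arm_id
    eff$control_arm_id <- b$arm_id
    eff$comparison_type <- type
    rows[[length(rows) + 1L]] <<- eff
    meta[[length(meta) + 1L]] <<- list(
      plus = a$arm_id, minus = b$arm_id, d = raw$d, J = raw$J,
      n = setNames(c(a$n, b$n), c(a$arm_id, b$arm_id)), type = type
    )
  }
  for (i in seq_len(nrow(exp_cells))) {
    for (j in seq_len(nrow(ctl_cells))) {
      add_cmp(exp_cells[i, ], ctl_cells[j, ], "experimental_vs_control")
    }
  }
  if (nrow(exp_cells) >= 2) {
    idx <- utils::combn(nrow(exp_cells), 2)
    for (p in seq_len(ncol(idx))) {
      add_cmp(exp_cells[idx[1, p], ], exp_cells[idx[2, p], ],
              "experimental_vs_experimental")
    }
  }
  out <- bind_rows(rows)

  ec <- which(out$comparison_type == "experimental_vs_control")
  if (length(ec) >= 2) {
    Sigma <- comparison_covariance(meta[ec], out$var[ec])
    vtilde <- adjusted_variances(Sigma)
    out$var[ec] <- vtilde
    out$adjusted[ec] <- TRUE
    out[ec, ] <- finish_effect(out[ec, ])
  }
  out
}

comparison_covariance <- function(meta, variances) {
  m <- length(meta)
  Sigma <- diag(variances, m)
  for (k in seq_len(m - 1)) {
    for (l in (k + 1):m) {
      a <- meta[[k]]; b <- meta[[l]]
      shared <- intersect(names(a$n), names(b$n))
      if (!length(shared)) next
      s <- shared[[1L]]
      same <- (s == a$plus) == (s == b$plus)
      N <- sum(a$n) + sum(b$n) - a$n[[s]]
      Sigma[k, l] <- Sigma[l, k] <- shared_arm_cov(
        a$n[[s]], a$d, b$d, a$J, b$J, N, same
      )
    }
  }
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev))) {
    cot_stop("shared-arm covariance matrix is not positive semidefinite",
             class = "cotmeta_input_error")
  }
  Sigma
}

# Adjusted per-comparison variances: 1/vtilde_k = (Sigma^-1 1)_k, so that
# naive fixed-effect pooling with weights 1/vtilde reproduces the GLS
# estimate mu = (1' Sigma^-1 y)/(1' Sigma^-1 1) and its variance exactly.
adjusted_variances <- function(Sigma) {
  w <- solve(Sigma, rep(1, nrow(Sigma)))
  if (any(w <= 0)) {
    cot_stop("multi-arm adjustment produced non-positive weights",
             class = "cotmeta_adjustment_error")
  }
  1 / w
}

#' Pool adjusted comparisons of one multi-arm trial
#'
#' Fixed-effect pooling of the (adjusted) experimental-vs-control
#' comparisons of one trial into a single study-level effect; by
#' construction of the adjustment this equals the GLS solution under the
#' shared-arm covariance matrix.
#'
#' @param effects Output of [pairwise_comparisons()] for one trial.
#' @return A one-row effect tibble (`pooled_within_study = TRUE` when more
#'   than one comparison contributed).  Distinct arms are each counted once
#'   in `n_exp`/`n_ctl`.
#' @export
pool_comparisons <- function(effects) {
  ec <- effects[effects$comparison_type == "experimental_vs_control", ]
  if (!nrow(ec)) cot_stop("no experimental-vs-control comparison to pool",
                          class = "cotmeta_input_error")
  if (nrow(ec) == 1L) return(ec)
  fe <- fixed_effect_pool(ec$g, ec$var)
  # count each distinct arm once
  n_exp <- sum(ec$n_exp[!duplicated(ec$experimental_arm_id)])
  n_ctl <- sum(ec$n_ctl[!duplicated(ec$control_arm_id)])
  effect_tbl(
    g = fe$g, var = fe$var,
    trial_id = ec$trial_id[1L], measure_id = ec$measure_id[1L],
    time_point = ec$time_point[1L],
    n_exp = n_exp, n_ctl = n_ctl,
    adjusted = TRUE, pooled_within_study = TRUE
  )
}

#' Composite effect over correlated outcomes of one study
#'
#' When one study contributes several effects for related outcomes measured
#' on the same participants (for example two depression scales), they are
#' combined into one composite: the mean of the effects, with variance
#' `(1/m^2) * (sum(var_i) + sum_{i != j} r * sqrt(var_i * var_j))`.  The
#' between-measure correlation defaults to r = 0.50.
#'
#' @param effects Effect tibble, all rows from the same trial.
#' @param r Assumed correlation between the outcome measures, in (-1, 1).
#' @return A one-row effect tibble; participant counts take the maximum over
#'   measures (the same people are measured on each).
#' @export
combine_correlated <- function(effects, r = 0.5) {
  effects <- as_tibble(effects)
  if (nrow(effects) < 2) cot_stop("need at least two effects to combine",
                                  class = "cotmeta_input_error")
  if (abs(r) >= 1) cot_stop("correlation r must satisfy |r| < 1",
                            class = "cotmeta_input_error")
  ids <- unique(effects$trial_id)
  ids <- ids[!is.na(ids)]
  if (length(ids) > 1) {
    cot_stop(paste0("correlated-outcome combining requires one trial; got: ",
                    paste(ids, collapse = ", ")), class = "cotmeta_input_error")
  }
  m <- nrow(effects)
  se_i <- sqrt(effects$var)
  cross <- outer(se_i, se_i)
  vsum <- sum(effects$var) + r * (sum(cross) - sum(diag(cross)))
  effect_tbl(
    g = mean(effects$g), var = vsum / m^2,
    trial_id = if (length(ids)) ids else NA_character_,
    measure_id = paste(effects$measure_id, collapse = "+"),
    time_point = effects$time_point[1L],
    n_exp = max(effects$n_exp), n_ctl = max(effects$n_ctl),
    adjusted = any(effects$adjusted), pooled_within_study = TRUE
  )
}

#' All effect estimates for one trial
#'
#' Computes the per-measure, per-time-point effect table of a trial:
#' whole-sample comparisons where available, otherwise per-subgroup
#' comparisons combined by fixed-effect meta-analysis; multi-arm
#' comparisons are adjusted and pooled within each reporting unit.
#'
#' @param trial A [coded_trial()].
#' @param pool_arms If `TRUE` (default) multi-arm comparisons are pooled to
#'   one row per measure/time point; otherwise all pairwise rows are kept.
#' @return Effect tibble (possibly zero rows when no usable cells exist).
#' @export
trial_effects <- function(trial, pool_arms = TRUE) {
  usable <- trial$cells[!is.na(trial$cells$sd), c("measure_id", "time_point")]
  combos <- usable[!duplicated(usable), ]
  rows <- purrr::pmap(combos, function(measure_id, time_point) {
    study_effect_one_measure(trial, measure_id, time_point, pool_arms)
  })
  out <- bind_rows(rows)
  if (!nrow(out)) empty_effects() else out
}

study_effect_one_measure <- function(trial, measure_id, time_point, pool_arms = TRUE) {
  cells <- trial$cells[trial$cells$measure_id == measure_id &
                       trial$cells$time_point == time_point &
                       !is.na(trial$cells$sd), ]
  has_whole <- any(is.na(cells$subgroup))
  if (has_whole) {
    cmp <- pairwise_comparisons(trial, measure_id, time_point, subgroup = NA)
    if (!nrow(cmp)) return(cmp)
    if (!pool_arms) return(cmp)
    if (nrow(cmp) == 1L) return(cmp)
    if (!any(cmp$comparison_type == "experimental_vs_control")) return(cmp)
    pooled <- pool_comparisons(cmp)
    return(bind_rows(
      pooled,
      cmp[cmp$comparison_type == "experimental_vs_experimental", ]
    ))
  }
  subgroups <- unique(cells$subgroup[!is.na(cells$subgroup)])
  per_sub <- purrr::map(subgroups, function(sg) {
    cmp <- pairwise_comparisons(trial, measure_id, time_point, subgroup = sg)
    if (!nrow(cmp)) return(NULL)
    pool_comparisons(cmp)
  })
  per_sub <- purrr::compact(per_sub)
  if (!length(per_sub)) return(empty_effects())
  if (length(per_sub) == 1L) return(per_sub[[1L]])
  combine_subgroups(bind_rows(per_sub))
}
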