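#' Define the scope of a meta-analysis
#'
#' The analysis scope mirrors the wizard a reviewer would fill in:
#' which populations, measurement targets and outcome domains to pool,
#' which time point to analyze, the assumed correlation between related
#' outcomes within a study, and the minimum number of contributing studies.
#'
#' @param populations Population codes to include (`NULL` = all).
#' @param targets Measurement targets to include; subset of
#'   `participant`, `caregiver`, `clinician`.
#' @param broad_outcomes Broad outcome domains to include (`NULL` = all).
#' @param specific_outcomes Specific measure names to include (`NULL` = all).
#' @param time_point Time point label to analyze (default `"post"`).
#' @param r Assumed correlation between related outcomes of one study.
#' @param min_k Minimum number of contributing studies per pooled outcome
#'   (default 3: outcomes with fewer studies are not pooled).
#' @param alpha_Q Significance threshold for the heterogeneity Q test
#'   (default 0.10); reported as a flag, never a gate on pooling.
#' @return An object of class `cot_spec`.
#' @export
meta_spec <- function(populations = NULL, targets = "participant",
                      broad_outcomes = NULL, specific_outcomes = NULL,
                      time_point = "post", r = 0.5, min_k = 3, alpha_Q = 0.10) {
  if (min_k < 2) cot_stop("min_k must be at least 2", class = "cotmeta_input_error")
  if (alpha_Q <= 0 || alpha_Q >= 1) cot_stop("alpha_Q must lie in (0, 1)",
                                             class = "cotmeta_input_error")
  if (abs(r) >= 1) cot_stop("r must satisfy |r| < 1", class = "cotmeta_input_error")
  if (!length(targets)) cot_stop("no targets selected", class = "cotmeta_input_error")
  bad <- setdiff(targets, c("participant", "caregiver", "clinician"))
  if (length(bad)) cot_stop(paste0("unknown target(s): ", paste(bad, collapse = ", ")),
                            class = "cotmeta_input_error")
  if (!is.null(broad_outcomes) && !length(broad_outcomes)) {
    cot_stop("no outcomes selected", class = "cotmeta_input_error")
  }
  structure(
    list(populations = populations, targets = targets,
         broad_outcomes = broad_outcomes, specific_outcomes = specific_outcomes,
         time_point = time_point, r = r, min_k = min_k, alpha_Q = alpha_Q),
    class = "cot_spec"
  )
}

#' Group study effects eligible for pooling
#'
#' Applies the pooling eligibility rules: only studies with usable numeric
#' data (means and SDs for each group at the analyzed time point)
#' contribute — a study without them is automatically excluded and logged;
#' within-study related outcomes in the same broad domain are pre-combined
#' (at correlation `spec$r`) so each study contributes one effect per
#' (outcome, population) group; and a group is pooled only when at least
#' `spec$min_k` studies contribute.
#'
#' @param trials Named list of [coded_trial()] objects.
#' @param spec A [meta_spec()].
#' @return List with `groups` — tibble of `outcome`, `population`, `k`, and
#'   an `effects` list-column (one combined effect row per study) — and
#'   `exclusions`, a tibble logging every excluded study or dropped group
#'   with its reason.
#' @export
eligible_groups <- function(trials, spec = meta_spec()) {
  if (!inherits(spec, "cot_spec")) cot_stop("spec must be a meta_spec()")
  excl <- list()
  note <- function(trial_id, outcome, population, reason) {
    excl[[length(excl) + 1L]] <<- tibble(
      trial_id = trial_id, outcome = outcome, population = population, reason = reason
    )
  }

  rows <- list()
  for (tr in trials) {
    pops <- as.character(tr$coding$population %||% character())
    if (!length(pops)) {
      note(tr$trial_id, NA_character_, NA_character_, "no population coded")
      next
    }
    if (!is.null(spec$populations)) pops <- intersect(pops, spec$populations)
    if (!length(pops)) next
    meas <- tr$measures[tr$measures$target %in% spec$targets, ]
    if (!is.null(spec$broad_outcomes)) {
      meas <- meas[meas$broad_domain %in% spec$broad_outcomes, ]
    }
    if (!is.null(spec$specific_outcomes)) {
      meas <- meas[meas$name %in% spec$specific_outcomes, ]
    }
    if (!nrow(meas)) next
    for (domain in unique(meas$broad_domain)) {
      dom_measures <- meas$measure_id[meas$broad_domain == domain]
      effs <- list()
      for (mid in dom_measures) {
        if (!trial_cells_usable(tr, mid, spec$time_point)) next
        eff <- study_effect_one_measure(tr, mid, spec$time_point)
        eff <- eff[eff$comparison_type == "experimental_vs_control", ]
        if (nrow(eff)) effs[[length(effs) + 1L]] <- eff
      }
      if (!length(effs)) {
        for (p in pops) {
          note(tr$trial_id, domain, p, "missing means/SDs")
        }
        next
      }
      combined <- if (length(effs) > 1L) {
        combine_correlated(bind_rows(effs), r = spec$r)
      } else {
        effs[[1L]]
      }
      for (p in pops) {
        row <- combined
        row$outcome <- domain
        row$population <- p
        rows[[length(rows) + 1L]] <- row
      }
    }
  }

  all_effects <- bind_rows(rows)
  groups <- if (nrow(all_effects)) {
    all_effects %>%
      tidyr::nest(effects = -c("outcome", "population")) %>%
      mutate(k = purrr::map_int(.data$effects, nrow))
  } else {
    tibble(outcome = character(), population = character(),
           effects = list(), k = integer())
  }
  keep <- groups$k >= spec$min_k
  for (i in which(!keep)) {
    note(NA_character_, groups$outcome[i], groups$population[i],
         paste0("fewer than ", spec$min_k, " studies"))
  }
  list(
    groups = groups[keep, , drop = FALSE],
    exclusions = if (length(excl)) bind_rows(excl) else tibble(
      trial_id = character(), outcome = character(),
      population = character(), reason = character()
    )
  )
}

trial_cells_usable <- function(trial, measure_id, time_point) {
  cells <- trial$cells
  sel <- cells$measure_id == measure_id & cells$time_point == time_point &
    !is.na(cells$sd) & cells$sd > 0 & cells$n >= 2
  if (!any(sel)) return(FALSE)
  role <- trial$arms$role[match(cells$arm_id[sel], trial$arms$arm_id)]
  any(role %in% "experimental") && any(role %in% "control")
}

# Restricted log-likelihood of the random-effects model at a given tau2
# (additive constants dropped).
reml_loglik <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
}

#' REML estimate of the between-study variance
#'
#' Maximizes the restricted log-likelihood of the random-effects model over
#' tau-squared by bounded scalar optimization on `[0, upper]` with
#' `upper = 10 * (max(v) + var(y))`, followed by a local refinement; the
#' boundary value 0 is compared explicitly.
#'
#' @param y Study effects (Hedges' g).
#' @param v Their sampling variances (all positive).
#' @param tol Convergence tolerance on tau-squared.
#' @return The nonnegative REML estimate of tau-squared.
#' @examples
#' reml_tau2(c(0.1, 0.5, 0.9), c(0.04, 0.04, 0.04))
#' @export
reml_tau2 <- function(y, v, tol = 1e-10) {
  k <- length(y)
  if (k < 2) cot_stop("REML needs at least 2 studies", class = "cotmeta_input_error")
  if (any(v <= 0)) cot_stop("all sampling variances must be positive",
                            class = "cotmeta_input_error")
  if (max(y) - min(y) < .Machine$double.eps^0.5) return(0)
  upper <- 10 * (max(v) + var(y))
  opt <- optimize(reml_loglik, c(0, upper), y = y, v = v,
                  maximum = TRUE, tol = tol)
  # local polish: optimize() brackets to ~tol; refine around the optimum
  lo <- max(0, opt$maximum - 1e-4)
  hi <- min(upper, opt$maximum + 1e-4)
  opt2 <- optimize(reml_loglik, c(lo, hi), y = y, v = v,
                   maximum = TRUE, tol = .Machine$double.eps^0.75)
  tau2 <- opt2$maximum
  if (reml_loglik(0, y, v) >= reml_loglik(tau2, y, v)) return(0)
  if (tau2 < 1e-8) 0 else tau2
}

#' Random-effects pooling with Hartung-Knapp-Sidik-Jonkman interval
#'
#' Pools study effects with inverse-variance random-effects weights
#' `w_i = 1/(v_i + tau2)` and computes the HKSJ standard error
#' `sqrt(sum(w_i (y_i - mu)^2) / ((k-1) * sum(w_i)))` with a
#' t(k-1) confidence interval.  When all effects coincide the HKSJ SE is 0
#' and the interval degenerates to the point (documented behavior; no
#' ad-hoc variance floor is applied).
#'
#' @inheritParams reml_tau2
#' @param tau2 Between-study variance (e.g. from [reml_tau2()]).
#' @param alpha One minus the confidence level.
#' @return List with `mu`, `se_hksj`, `ci_low`, `ci_high`, `weights`
#'   (normalized random-effects weights).
#' @export
pool_hksj <- function(y, v, tau2, alpha = 0.05) {
  k <- length(y)
  if (k < 2) cot_stop("pooling needs at least 2 studies", class = "cotmeta_input_error")
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu)^2) / (k - 1)
  se <- sqrt(q / sum(w))
  tcrit <- qt(1 - alpha / 2, df = k - 1)
  list(mu = mu, se_hksj = se, ci_low = mu - tcrit * se, ci_high = mu + tcrit * se,
       weights = w / sum(w))
}

#' Heterogeneity statistics
#'
#' Cochran's Q against the fixed-effect mean, its chi-square p-value on
#' k-1 degrees of freedom, and `I2 = max(0, 100 * (Q - (k-1))/Q)`.
#'
#' @inheritParams reml_tau2
#' @return List with `Q`, `p_Q`, `I2` (percent).
#' @examples
#' heterogeneity(c(0.1, 0.5, 0.9), c(0.04, 0.04, 0.04))
#' @export
heterogeneity <- function(y, v) {
  k <- length(y)
  if (k < 2) cot_stop("heterogeneity needs at least 2 studies",
                      class = "cotmeta_input_error")
  w <- 1 / v
  y_fe <- sum(w * y) / sum(w)
  Q <- sum(w * (y - y_fe)^2)
  p_Q <- pchisq(Q, df = k - 1, lower.tail = FALSE)
  I2 <- if (Q <= 0) 0 else max(0, 100 * (Q - (k - 1)) / Q)
  list(Q = Q, p_Q = p_Q, I2 = I2)
}

#' 95% prediction interval for the effect in a new study
#'
#' `mu +/- t(k-2, 1-alpha/2) * sqrt(tau2 + se^2)` (the k-2 degrees of
#' freedom convention; k-1 is available via configuration).  Quantifies the
#' range within which 95% of true study effects are expected to fall.
#'
#' @param mu Pooled estimate.
#' @param se_hksj Its HKSJ standard error.
#' @param tau2 Between-study variance.
#' @param k Number of studies (must be at least 3).
#' @param level Coverage level.
#' @param df `"k_minus_2"` (default) or `"k_minus_1"`.
#' @return List with `pi_low`, `pi_high`.
#' @export
prediction_interval <- function(mu, se_hksj, tau2, k, level = 0.95,
                                df = c("k_minus_2", "k_minus_1")) {
  df <- arg_match(df)
  if (k < 3) cot_stop("prediction interval needs at least 3 studies",
                      class = "cotmeta_input_error")
  nu <- if (df == "k_minus_2") k - 2 else k - 1
  tcrit <- qt(1 - (1 - level) / 2, df = nu)
  half <- tcrit * sqrt(tau2 + se_hksj^2)
  list(pi_low = mu - half, pi_high = mu + half)
}

#' Run the full random-effects meta-analysis
#'
#' For every eligible (outcome, population) group: combine within-study
#' structure (subgroups, multi-arm comparisons, correlated outcomes) to one
#' effect per study, estimate tau-squared by REML, pool with HKSJ
#' intervals, compute Q/I-squared and the 95% prediction interval.
#'
#' @param trials Named list of [coded_trial()] objects.
#' @param spec A [meta_spec()].
#' @return A `cot_meta` tibble with one row per pooled outcome x
#'   population: `outcome`, `population`, `k`, `n_total`, `mu`, `se_hksj`,
#'   `ci_low`, `ci_high`, `tau2`, `Q`, `p_Q`, `I2`, `het_significant`,
#'   `pi_low`, `pi_high` and a `per_study` list-column of contributing
#'   effects with their normalized weights.  The exclusion log is attached
#'   as attribute `"exclusions"`.
#' @examples
#' repo <- generate_repository(sim_config(n_studies = 5, seed = 7))
#' run_meta(repo, meta_spec(min_k = 3))
#' @export
run_meta <- function(trials, spec = meta_spec()) {
  elig <- eligible_groups(trials, spec)
  rows <- purrr::pmap(elig$groups, function(outcome, population, effects, k) {
    y <- effects$g
    v <- effects$var
    tau2 <- reml_tau2(y, v)
    pooled <- pool_hksj(y, v, tau2)
    het <- heterogeneity(y, v)
    pi <- if (k >= 3) prediction_interval(pooled$mu, pooled$se_hksj, tau2, k)
          else list(pi_low = NA_real_, pi_high = NA_real_)
    tibble(
      outcome = outcome, population = population, k = k,
      n_total = sum(effects$n_exp + effects$n_ctl),
      mu = pooled$mu, se_hksj = pooled$se_hksj,
      ci_low = pooled$ci_low, ci_high = pooled$ci_high,
      tau2 = tau2, Q = het$Q, p_Q = het$p_Q, I2 = het$I2,
      het_significant = het$p_Q < spec$alpha_Q,
      pi_low = pi$pi_low, pi_high = pi$pi_high,
      per_study = list(mutate(effects, weight = pooled$weights))
    )
  })
  out <- bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble(
      outcome = character(), population = character(), k = integer(),
      n_total = integer(), mu = double(), se_hksj = double(),
      ci_low = double(), ci_high = double(), tau2 = double(), Q = double(),
      p_Q = double(), I2 = double(), het_significant = logical(),
      pi_low = double(), pi_high = double(), per_study = list()
    )
  }
  attr(out, "exclusions") <- elig$exclusions
  attr(out, "spec") <- spec
  class(out) <- c("cot_meta", class(out))
  out
}

#' @export
print.cot_meta <- function(x, ...) {
  cat("<cot_meta> ", nrow(x), " pooled outcome(s)\n", sep = "")
  NextMethod()
  excl <- attr(x, "exclusions")
  if (!is.null(excl) && nrow(excl)) {
    cat("Exclusions: ", nrow(excl), " (see attr(., 'exclusions'))\n", sep = "")
  }
  invisible(x)
}

#' Per-study detail of a meta-analysis
#'
#' @param x A `cot_meta` result from [run_meta()].
#' @param ... Unused.
#' @return Tibble with one row per contributing study per pooled group,
#'   including its effect, CI and normalized pooling weight.
#' @method tidy cot_meta
#' @export
tidy.cot_meta <- function(x, ...) {
  x %>%
    select("outcome", "population", "per_study") %>%
    tidyr::unnest("per_study")
}

#' One-row-per-analysis summary of a meta-analysis
#'
#' @param x A `cot_meta` result from [run_meta()].
#' @param ... Unused.
#' @return The pooled-results tibble without the `per_study` list-column.
#' @method glance cot_meta
#' @export
glance.cot_meta <- function(x, ...) {
  out <- select(as_tibble(x), -"per_study")
  out
}
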