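#' Load the certainty-grading configuration
#'
#' Thresholds for the three certainty components (mean methodological
#' quality, heterogeneity, precision), the band-to-level rule, and the
#' effect-magnitude bands used in narratives.  All values live in an
#' editable YAML file so the rule engine can be recalibrated without code
#' changes.
#'
#' @param path Optional path to an alternative configuration file.
#' @return Named list of configuration values.
#' @export
grading_config <- function(path = NULL) {
  read_config("grading_config", path)
}

band_quality <- function(mean_q, cfg) {
  if (mean_q >= cfg$quality$favorable_min) "favorable"
  else if (mean_q >= cfg$quality$intermediate_min) "intermediate"
  else "unfavorable"
}

band_heterogeneity <- function(I2, cfg) {
  if (I2 < cfg$heterogeneity$favorable_max) "favorable"
  else if (I2 <= cfg$heterogeneity$intermediate_max) "intermediate"
  else "unfavorable"
}

band_precision <- function(n_total, cfg) {
  if (n_total >= cfg$precision$favorable_min) "favorable"
  else if (n_total >= cfg$precision$intermediate_min) "intermediate"
  else "unfavorable"
}

certainty_level <- function(bands, cfg) {
  n_unfav <- sum(bands == "unfavorable")
  if (all(bands == "favorable")) return("high")
  if (n_unfav >= cfg$level_rule$low_if_unfavorable_count) return("low")
  if (isTRUE(cfg$level_rule$low_if_quality_unfavorable) &&
      bands[["quality"]] == "unfavorable") return("low")
  "moderate"
}

#' Grade the certainty of a pooled finding
#'
#' Certainty (low / moderate / high) is a pure function of three banded
#' components: mean methodological quality of the contributing studies,
#' between-study heterogeneity (I-squared) and precision of the pooled
#' estimate (total participants).  With the default thresholds: high
#' requires all three bands favorable; low results from an unfavorable
#' quality band or any two unfavorable bands; everything else is moderate.
#'
#' @param pooled One row of a [run_meta()] result.
#' @param qualities [quality_table()] rows covering every contributing
#'   study of `pooled` (extra rows are ignored).
#' @param config Grading configuration from [grading_config()].
#' @return One-row tibble: `outcome`, `population`, `mean_quality`,
#'   `quality_band`, `heterogeneity_band`, `precision_band`, `level`.
#' @export
grade_certainty <- function(pooled, qualities, config = grading_config()) {
  contributing <- pooled$per_study[[1L]]$trial_id
  missing <- setdiff(contributing, qualities$trial_id)
  if (length(missing)) {
    cot_stop(paste0("missing quality score for contributing study: ",
                    paste(missing, collapse = ", ")),
             class = "cotmeta_input_error")
  }
  q <- qualities[qualities$trial_id %in% contributing, ]
  mean_q <- mean_quality(q, index = config$quality_index %||% "pedro")
  bands <- c(
    quality = band_quality(mean_q, config),
    heterogeneity = band_heterogeneity(pooled$I2, config),
    precision = band_precision(pooled$n_total, config)
  )
  tibble(
    outcome = pooled$outcome, population = pooled$population,
    mean_quality = mean_q,
    quality_band = bands[["quality"]],
    heterogeneity_band = bands[["heterogeneity"]],
    precision_band = bands[["precision"]],
    level = certainty_level(bands, config)
  )
}

magnitude_band <- function(g, cfg) {
  a <- abs(g)
  if (a < cfg$magnitude_bands$trivial_max) "trivial"
  else if (a < cfg$magnitude_bands$small_max) "small"
  else if (a < cfg$magnitude_bands$moderate_max) "moderate"
  else "large"
}

#' Rule-generated evidence summary for a pooled finding
#'
#' Maps certainty and statistical significance to a recommendation: no
#' recommendation for low-certainty evidence; a modest recommendation for
#' moderate certainty and a strong one for high certainty, in favor when
#' the pooled effect is positive with an HKSJ CI excluding zero and against
#' when it is negative with a CI excluding zero; a CI including zero yields
#' no recommendation regardless of certainty.  A narrative sentence is
#' assembled from editable templates.
#'
#' @param pooled One row of a [run_meta()] result.
#' @param rating The matching [grade_certainty()] row.
#' @param config Grading configuration.
#' @param templates Report template list (see [report_templates()]).
#' @return One-row tibble: `outcome`, `population`, `recommendation`,
#'   `magnitude`, `significant`, `certainty`, `narrative`.
#' @export
summarize_evidence <- function(pooled, rating, config = grading_config(),
                               templates = report_templates()) {
  excludes_zero <- pooled$ci_low > 0 || pooled$ci_high < 0
  strength <- switch(rating$level, high = "strong", moderate = "modest", low = NULL)
  recommendation <- if (is.null(strength) || !excludes_zero) {
    "none"
  } else if (pooled$mu > 0) {
    paste0(strength, "_for")
  } else {
    paste0(strength, "_against")
  }
  magnitude <- magnitude_band(pooled$mu, config)
  narrative <- glue::glue(
    templates$narrative,
    outcome = pooled$outcome, population = pooled$population,
    g = format(round_half_up(pooled$mu, 2), nsmall = 2),
    ci_low = format(round_half_up(pooled$ci_low, 2), nsmall = 2),
    ci_high = format(round_half_up(pooled$ci_high, 2), nsmall = 2),
    k = pooled$k, n_total = pooled$n_total,
    magnitude = magnitude, certainty = rating$level,
    recommendation_phrase = templates$recommendation_phrases[[recommendation]]
  )
  tibble(
    outcome = pooled$outcome, population = pooled$population,
    recommendation = recommendation, magnitude = magnitude,
    significant = excludes_zero, certainty = rating$level,
    narrative = as.character(narrative)
  )
}

#' Grade and summarize every pooled outcome
#'
#' Convenience wrapper applying [grade_certainty()] and
#' [summarize_evidence()] to each row of a meta-analysis result.
#'
#' @param meta A [run_meta()] result.
#' @param qualities [quality_table()] for the repository.
#' @param config Grading configuration.
#' @return Tibble joining the certainty rating and evidence summary per
#'   pooled outcome x population.
#' @export
grade_meta <- function(meta, qualities, config = grading_config()) {
  purrr::map_dfr(seq_len(nrow(meta)), function(i) {
    pooled <- meta[i, ]
    rating <- grade_certainty(pooled, qualities, config)
    summary <- summarize_evidence(pooled, rating, config)
    left_join(rating, summary, by = c("outcome", "population"))
  })
}
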