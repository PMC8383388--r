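#' Cohen's U3 non-overlap measure
#'
#' The percentage of cases from the experimental condition that exceeds the
#' mean of the control condition, under two unit-variance normal
#' distributions separated by `g`: `100 * pnorm(g)`.
#'
#' @param g Standardized mean difference (Hedges' g).
#' @return Percentage in (0, 100), full precision.
#' @examples
#' u3(0.5)  # ~69%
#' @export
u3 <- function(g) 100 * pnorm(g)

#' Percentage overlap of the two group distributions
#'
#' The overlapping coefficient of two unit-variance normal distributions
#' whose means differ by `g`: `100 * 2 * pnorm(-abs(g)/2)`.
#'
#' @inheritParams u3
#' @return Percentage in (0, 100], full precision; even in `g`.
#' @examples
#' overlap(0.5)  # ~80%
#' @export
overlap <- function(g) 100 * 2 * pnorm(-abs(g) / 2)

#' Probability of superiority (common language effect size)
#'
#' The probability that a person picked at random from the experimental
#' condition scores higher than a person picked at random from the control
#' condition: `100 * pnorm(g / sqrt(2))`.
#'
#' @inheritParams u3
#' @return Percentage in (0, 100), full precision.
#' @examples
#' prob_superiority(0.5)  # ~64%
#' @export
prob_superiority <- function(g) 100 * pnorm(g / sqrt(2))

#' Interpretation triple for a pooled effect
#'
#' @inheritParams u3
#' @return One-row tibble with `g`, `u3`, `overlap`, `prob_superiority`
#'   (full precision, percent scale).
#' @export
interpretation <- function(g) {
  tibble(g = g, u3 = u3(g), overlap = overlap(g),
         prob_superiority = prob_superiority(g))
}

#' Plain-language interpretation sentence
#'
#' Fills the report's sentence template with the three interpretation
#' percentages, each rounded half-up to an integer percent (tables retain
#' full precision; only narrative text rounds).
#'
#' @inheritParams u3
#' @param templates Template list from [report_templates()].
#' @return A single string.
#' @examples
#' interpretation_sentence(0.5)
#' @export
interpretation_sentence <- function(g, templates = report_templates()) {
  out <- glue::glue(
    templates$interpretation_sentence,
    u3 = round_half_up(u3(g)),
    overlap = round_half_up(overlap(g)),
    prob_superiority = round_half_up(prob_superiority(g))
  )
  stringr::str_squish(as.character(out))
}
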