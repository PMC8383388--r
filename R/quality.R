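# Evaluate one rule condition against a coding map: TRUE only when the item
# is coded and at least one of its codes is in `any_of`.  Missing items
# therefore never satisfy a condition (conservative scoring).
condition_holds <- function(cond, coding) {
  codes <- coding[[cond$item]]
  !is.null(codes) && any(as.character(codes) %in% as.character(cond$any_of))
}

rule_satisfied <- function(rule, coding) {
  all(purrr::map_lgl(rule$all_of, condition_holds, coding = coding))
}

#' Score a trial on the PEDro scale
#'
#' Evaluates the 11 PEDro items against a trial's coded design items using
#' the packaged rule table.  Item 1 (eligibility criteria) is recorded but
#' unscored; the total (0-10) counts satisfied items 2-11.  Several scale
#' items combine more than one coded response; an item whose inputs are not
#' coded scores unsatisfied.
#'
#' @param coding Named list of coded items (a trial's `$coding`).
#' @param rules_path Optional path to an alternative rule table.
#' @return List with `total` (integer 0-10) and `items` (tibble with
#'   `item`, `number`, `scored`, `satisfied`).
#' @examples
#' score_pedro(example_trial()$coding)$total
#' @export
score_pedro <- function(coding, rules_path = NULL) {
  rules <- read_config("rules_pedro", rules_path)
  items <- purrr::map_dfr(rules$items, function(it) {
    tibble(
      item = it$key, number = as.integer(it$number %||% NA),
      scored = isTRUE(it$scored),
      satisfied = rule_satisfied(it, coding)
    )
  })
  list(total = sum(items$satisfied & items$scored), items = items)
}

#' Score a trial on the Jadad scale
#'
#' Five additive points: randomization mentioned, appropriate randomization
#' method, blinding mentioned, appropriate blinding, and withdrawals
#' described.  Missing codings score 0 on the affected items.
#'
#' @inheritParams score_pedro
#' @return List with `total` (integer 0-5) and `items` tibble.
#' @export
score_jadad <- function(coding, rules_path = NULL) {
  rules <- read_config("rules_jadad", rules_path)
  items <- purrr::map_dfr(rules$items, function(it) {
    tibble(item = it$key, scored = isTRUE(it$scored),
           satisfied = rule_satisfied(it, coding))
  })
  list(total = sum(items$satisfied & items$scored), items = items)
}

#' Rate a trial with the Cochrane Risk of Bias tool
#'
#' Each of the seven domains is rated `low` when all of its low-risk
#' conditions hold, `high` when any high-risk condition holds (high takes
#' precedence), and `unclear` otherwise — so uncoded items leave a domain
#' unclear, never low.
#'
#' @inheritParams score_pedro
#' @return Tibble with columns `domain` and `rating`.
#' @export
score_rob <- function(coding, rules_path = NULL) {
  rules <- read_config("rules_rob", rules_path)
  purrr::map_dfr(rules$domains, function(dom) {
    high <- any(purrr::map_lgl(dom$high_when, condition_holds, coding = coding))
    low <- all(purrr::map_lgl(dom$low_when, condition_holds, coding = coding))
    tibble(domain = dom$key,
           rating = if (high) "high" else if (low) "low" else "unclear")
  })
}

#' All quality indices for one trial
#'
#' @param trial A [coded_trial()].
#' @return Object of class `cot_quality`: list with `trial_id`,
#'   `pedro_total`, `pedro_items`, `jadad_total`, `jadad_items`,
#'   `rob_domains`.
#' @export
quality_scores <- function(trial) {
  pedro <- score_pedro(trial$coding)
  jadad <- score_jadad(trial$coding)
  structure(
    list(
      trial_id = trial$trial_id,
      pedro_total = pedro$total, pedro_items = pedro$items,
      jadad_total = jadad$total, jadad_items = jadad$items,
      rob_domains = score_rob(trial$coding)
    ),
    class = "cot_quality"
  )
}

#' @export
print.cot_quality <- function(x, ...) {
  cat("<cot_quality> ", x$trial_id, ": PEDro ", x$pedro_total, "/10, Jadad ",
      x$jadad_total, "/5\n", sep = "")
  print(x$rob_domains)
  invisible(x)
}

#' Quality totals for a set of trials
#'
#' @param trials List of [coded_trial()] objects.
#' @return Tibble with one row per trial: `trial_id`, `pedro_total`,
#'   `jadad_total`, and one `rob_*` column per domain.
#' @export
quality_table <- function(trials) {
  purrr::map_dfr(trials, function(tr) {
    qs <- quality_scores(tr)
    rob <- setNames(qs$rob_domains$rating, paste0("rob_", qs$rob_domains$domain))
    bind_cols(
      tibble(trial_id = qs$trial_id, pedro_total = qs$pedro_total,
             jadad_total = qs$jadad_total),
      as_tibble(as.list(rob))
    )
  })
}

#' Mean methodological quality of a set of scored trials
#'
#' @param scores Tibble from [quality_table()] (or any data frame holding
#'   the chosen index's total column).
#' @param index `"pedro"` (default) or `"jadad"`.
#' @return The arithmetic mean of the index totals.
#' @export
mean_quality <- function(scores, index = c("pedro", "jadad")) {
  index <- arg_match(index)
  col <- paste0(index, "_total")
  if (!nrow(scores)) cot_stop("need at least one quality score", class = "cotmeta_input_error")
  mean(scores[[col]])
}
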