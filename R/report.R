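REPORT_SECTIONS <- c("overview", "disclaimer", "search_results",
                     "overall_summary", "detailed_report", "references",
                     "statistical_information")

#' Load the report boilerplate and sentence templates
#'
#' @param path Optional path to an alternative template file.
#' @return Named list of template strings.
#' @export
report_templates <- function(path = NULL) {
  read_config("report_templates", path)
}

#' Forest plot for one pooled outcome
#'
#' Study-level effects with 95% CIs, point size proportional to pooling
#' weight, and the pooled estimate as a diamond row with its HKSJ interval.
#'
#' @param pooled One row of a [run_meta()] result.
#' @return A ggplot object.
#' @export
forest_plot <- function(pooled) {
  studies <- pooled$per_study[[1L]] %>%
    mutate(label = .data$trial_id) %>%
    arrange(dplyr::desc(row_number()))
  pooled_row <- tibble(
    label = "Pooled (random effects)",
    g = pooled$mu, ci_low = pooled$ci_low, ci_high = pooled$ci_high
  )
  levels <- c(pooled_row$label, studies$label)
  studies$label <- factor(studies$label, levels = levels)
  pooled_row$label <- factor(pooled_row$label, levels = levels)
  ggplot2::ggplot() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      data = studies,
      ggplot2::aes(y = .data$label, xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2
    ) +
    ggplot2::geom_point(
      data = studies,
      ggplot2::aes(y = .data$label, x = .data$g, size = .data$weight),
      shape = 15, show.legend = FALSE
    ) +
    ggplot2::geom_point(
      data = pooled_row,
      ggplot2::aes(y = .data$label, x = .data$g),
      shape = 18, size = 5, colour = "#2c5d98"
    ) +
    ggplot2::geom_errorbarh(
      data = pooled_row,
      ggplot2::aes(y = .data$label, xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.1, colour = "#2c5d98"
    ) +
    ggplot2::labs(
      title = paste0(pooled$outcome, " — ", pooled$population),
      x = "Hedges' g (positive favors experimental)", y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Summary chart of effects and certainty
#'
#' One row per pooled outcome x population showing the effect estimate,
#' its HKSJ interval and the certainty of the finding (colour).
#'
#' @param results Joined tibble of pooled results and gradings (as built by
#'   [build_report()]), needing columns `outcome`, `population`, `mu`,
#'   `ci_low`, `ci_high`, `level`.
#' @return A ggplot object.
#' @export
summary_chart <- function(results) {
  results <- results %>%
    mutate(label = paste0(.data$outcome, " (", .data$population, ")"),
           certainty = factor(.data$level, levels = c("low", "moderate", "high")))
  ggplot2::ggplot(results,
                  ggplot2::aes(y = .data$label, x = .data$mu,
                               colour = .data$certainty)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.15
    ) +
    ggplot2::scale_colour_manual(
      values = c(low = "#c0392b", moderate = "#e67e22", high = "#27ae60"),
      drop = FALSE
    ) +
    ggplot2::labs(x = "Hedges' g (95% CI)", y = NULL, colour = "Certainty") +
    ggplot2::theme_minimal()
}

#' Autoplot methods for meta-analysis results
#'
#' For a single-row `cot_meta` object a forest plot is drawn; for several
#' rows the effects-by-certainty summary layout is used (without certainty
#' colouring when gradings are not attached).
#'
#' @param object A `cot_meta` result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cot_meta
#' @export
autoplot.cot_meta <- function(object, ...) {
  if (nrow(object) == 1L) return(forest_plot(object[1L, ]))
  summary_chart(mutate(glance(object), level = NA_character_))
}

#' Build the data-synthesis report
#'
#' Assembles the full report document with its seven sections in fixed
#' order: overview, disclaimer, search results, overall summary (effect x
#' certainty chart, per-domain recommendations and the interpretation
#' explanation), detailed report (per-outcome statistics, interpretation
#' sentence and forest plot), references (contributing trials) and
#' statistical information.
#'
#' @param spec The [meta_spec()] analyzed.
#' @param meta The [run_meta()] result.
#' @param gradings The matching [grade_meta()] tibble (may have zero rows
#'   when nothing pooled).
#' @param trials The repository trials (for the reference list).
#' @param templates Template list from [report_templates()].
#' @return Object of class `cot_report`: named list of sections, in
#'   report order.
#' @export
build_report <- function(spec, meta, gradings, trials,
                         templates = report_templates()) {
  results <- if (nrow(meta)) {
    left_join(glance(meta), gradings, by = c("outcome", "population"))
  } else {
    tibble()
  }
  contributing_ids <- if (nrow(meta)) {
    unique(tidy(meta)$trial_id)
  } else {
    character()
  }
  refs <- purrr::map_chr(
    trials[intersect(names(trials), contributing_ids)],
    ~ format_citation(.x$citation)
  )

  detailed <- purrr::map(seq_len(nrow(meta)), function(i) {
    pooled <- meta[i, ]
    list(
      outcome = pooled$outcome,
      population = pooled$population,
      statistics = select(as_tibble(pooled), -"per_study"),
      per_study = pooled$per_study[[1L]],
      interpretation = interpretation(pooled$mu),
      interpretation_sentence = interpretation_sentence(pooled$mu, templates),
      forest = forest_plot(pooled)
    )
  })

  doc <- list(
    overview = list(text = templates$overview),
    disclaimer = list(text = templates$disclaimer),
    search_results = list(
      text = paste0(
        "Scope: populations = ",
        paste(spec$populations %||% "all", collapse = ", "),
        "; targets = ", paste(spec$targets, collapse = ", "),
        "; outcomes = ", paste(spec$broad_outcomes %||% "all", collapse = ", "),
        "; time point = ", spec$time_point, "."
      ),
      n_outcomes = nrow(meta)
    ),
    overall_summary = if (nrow(meta)) {
      list(
        results = results,
        recommendations = if (nrow(results)) results$narrative else character(),
        chart = summary_chart(results)
      )
    } else {
      list(notice = templates$no_eligible_outcomes)
    },
    detailed_report = if (length(detailed)) detailed else
      list(notice = templates$no_eligible_outcomes),
    references = list(citations = unname(refs)),
    statistical_information = list(text = templates$statistical_information)
  )
  structure(doc[REPORT_SECTIONS], class = "cot_report")
}

#' @export
print.cot_report <- function(x, ...) {
  cat("<cot_report> sections: ", paste(names(x), collapse = ", "), "\n", sep = "")
  invisible(x)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  head_row <- paste0("<th>", html_escape(names(df)), "</th>", collapse = "")
  body <- apply(df, 1, function(r) {
    paste0("<td>", html_escape(as.character(r)), "</td>", collapse = "")
  })
  paste0("<table><tr>", head_row, "</tr>",
         paste0("<tr>", body, "</tr>", collapse = ""), "</table>")
}

embed_plot <- function(p, width = 7, height = 4) {
  file <- tempfile(fileext = ".png")
  on.exit(unlink(file))
  ggplot2::ggsave(file, p, width = width, height = height, dpi = 110)
  paste0("<img src=\"data:image/png;base64,",
         jsonlite::base64_enc(readBin(file, "raw", file.size(file))),
         "\" style=\"max-width:100%\"/>")
}

section_title <- function(key) {
  stringr::str_to_sentence(gsub("_", " ", key))
}

#' Render a report document to a self-contained HTML file
#'
#' Figures are embedded as base64 images; a machine-readable JSON companion
#' (same content minus the figures) is written alongside when
#' `json_companion` is `TRUE`.
#'
#' @param report A [build_report()] document.
#' @param file Output HTML path.
#' @param json_companion Write `<file>.json` with the tabular content.
#' @return Invisibly, `file`.
#' @export
render_report <- function(report, file, json_companion = TRUE) {
  parts <- c(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\">",
    "<title>Data synthesis report</title>",
    "<style>body{font-family:sans-serif;max-width:60em;margin:2em auto;}",
    "table{border-collapse:collapse;} td,th{border:1px solid #ccc;padding:4px 8px;}",
    "</style></head><body>",
    "<h1>Data synthesis report</h1>"
  )
  for (key in names(report)) {
    sec <- report[[key]]
    parts <- c(parts, paste0("<h2>", section_title(key), "</h2>"))
    parts <- c(parts, render_section(key, sec))
  }
  parts <- c(parts, "</body></html>")
  writeLines(parts, file)
  if (json_companion) {
    jsonlite::write_json(strip_plots(report), paste0(file, ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(file)
}

render_section <- function(key, sec) {
  if (key == "detailed_report" && is.null(sec$notice)) {
    return(unlist(purrr::map(sec, function(item) c(
      paste0("<h3>", html_escape(item$outcome), " — ",
             html_escape(item$population), "</h3>"),
      html_table(item$statistics),
      paste0("<p><em>", html_escape(item$interpretation_sentence), "</em></p>"),
      embed_plot(item$forest),
      "<h4>Contributing studies</h4>",
      html_table(item$per_study)
    ))))
  }
  out <- character()
  if (!is.null(sec$text)) out <- c(out, paste0("<p>", html_escape(sec$text), "</p>"))
  if (!is.null(sec$notice)) out <- c(out, paste0("<p>", html_escape(sec$notice), "</p>"))
  if (!is.null(sec$n_outcomes)) {
    out <- c(out, paste0("<p>Outcomes included in the meta-analysis: ",
                         sec$n_outcomes, "</p>"))
  }
  if (!is.null(sec$results)) out <- c(out, html_table(sec$results))
  if (!is.null(sec$recommendations) && length(sec$recommendations)) {
    out <- c(out, "<ul>", paste0("<li>", html_escape(sec$recommendations), "</li>"), "</ul>")
  }
  if (!is.null(sec$chart)) out <- c(out, embed_plot(sec$chart))
  if (!is.null(sec$citations)) {
    if (length(sec$citations)) {
      out <- c(out, "<ol>", paste0("<li>", html_escape(sec$citations), "</li>"), "</ol>")
    } else {
      out <- c(out, "<p>No contributing studies.</p>")
    }
  }
  out
}

strip_plots <- function(x) {
  if (inherits(x, "ggplot")) return(NULL)
  if (is.list(x) && !is.data.frame(x)) {
    out <- purrr::map(x, strip_plots)
    return(out[!purrr::map_lgl(out, is.null)])
  }
  x
}

#' Single-study results page
#'
#' The per-trial view: workflow status, citation and plain-language
#' summary, the item-level methodological quality tables with totals, and
#' the effect-size table per measure and time point (or a data-not-
#' available notice when the trial has no usable numeric cells).
#'
#' @param trial A [coded_trial()].
#' @param scores Optional [quality_scores()] for the trial (computed if
#'   omitted).
#' @param effects Optional [trial_effects()] table (computed if omitted).
#' @return Object of class `cot_study_page` (named list of sections).
#' @export
single_study_page <- function(trial, scores = NULL, effects = NULL) {
  scores <- scores %||% quality_scores(trial)
  effects <- effects %||% trial_effects(trial)
  structure(
    list(
      status = trial$status,
      citation = format_citation(trial$citation),
      summary_text = trial$summary_text,
      quality = list(
        pedro_total = scores$pedro_total, pedro_items = scores$pedro_items,
        jadad_total = scores$jadad_total, jadad_items = scores$jadad_items,
        rob_domains = scores$rob_domains
      ),
      effects = if (nrow(effects)) effects else NULL,
      effects_notice = if (nrow(effects)) NULL else "data not available"
    ),
    class = "cot_study_page"
  )
}

#' @export
print.cot_study_page <- function(x, ...) {
  cat("<cot_study_page> [", x$status, "] ", x$citation, "\n", sep = "")
  cat("PEDro ", x$quality$pedro_total, "/10, Jadad ", x$quality$jadad_total,
      "/5\n", sep = "")
  if (is.null(x$effects)) cat("Effects: ", x$effects_notice, "\n", sep = "")
  else print(x$effects)
  invisible(x)
}

#' Render a single-study page to HTML
#'
#' @param page A [single_study_page()].
#' @param file Output HTML path.
#' @return Invisibly, `file`.
#' @export
render_study_page <- function(page, file) {
  parts <- c(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\"><title>Study</title></head><body>",
    paste0("<p><strong>Status:</strong> ", html_escape(page$status), "</p>"),
    paste0("<p>", html_escape(page$citation), "</p>"),
    paste0("<p>", html_escape(page$summary_text), "</p>"),
    "<h2>Methodological quality</h2>",
    paste0("<p>PEDro total: ", page$quality$pedro_total, "/10</p>"),
    html_table(page$quality$pedro_items),
    paste0("<p>Jadad total: ", page$quality$jadad_total, "/5</p>"),
    html_table(page$quality$jadad_items),
    "<h3>Cochrane Risk of Bias</h3>",
    html_table(page$quality$rob_domains),
    "<h2>Effect sizes</h2>",
    if (is.null(page$effects)) paste0("<p>", page$effects_notice, "</p>")
    else html_table(page$effects),
    "</body></html>"
  )
  writeLines(parts, file)
  invisible(file)
}
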