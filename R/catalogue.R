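#' The coding item catalogue
#'
#' Trials are coded against a catalogue of data-extraction items, each with a
#' controlled vocabulary of response alternatives and a flag saying whether
#' several alternatives may be selected at once.  The catalogue is shipped as
#' an editable YAML file so that items and response alternatives can be added
#' without changing package code.
#'
#' @param path Optional path to a catalogue YAML file; by default the
#'   packaged catalogue is used.
#' @return A tibble with one row per item: `item_key`, `label`, `required`
#'   (needed before a trial can reach status `requirements_met`), `multi`
#'   (multi-select allowed) and `vocabulary` (list-column of allowed codes).
#' @examples
#' item_catalogue()
#' @export
item_catalogue <- function(path = NULL) {
  raw <- read_config("item_catalogue", path)
  items <- raw$items
  tibble(
    item_key = names(items),
    label = purrr::map_chr(items, ~ .x$label %||% NA_character_),
    required = purrr::map_lgl(items, ~ isTRUE(.x$required)),
    multi = purrr::map_lgl(items, ~ isTRUE(.x$multi)),
    vocabulary = purrr::map(items, ~ as.character(.x$vocabulary))
  )
}

# Violations of a coding map against the catalogue; empty tibble when clean.
check_coding <- function(coding, catalogue) {
  out <- list()
  keys <- names(coding) %||% character()
  unknown <- setdiff(keys, catalogue$item_key)
  for (k in unknown) {
    out[[length(out) + 1L]] <- c("unknown coding item", paste0("item '", k, "' not in catalogue"))
  }
  for (k in intersect(keys, catalogue$item_key)) {
    row <- catalogue[catalogue$item_key == k, ]
    codes <- as.character(coding[[k]])
    if (length(codes) > 1L && !row$multi) {
      out[[length(out) + 1L]] <- c(
        "multi-select not permitted",
        paste0("item '", k, "' allows one code, got ", length(codes))
      )
    }
    bad <- setdiff(codes, row$vocabulary[[1L]])
    if (length(bad)) {
      out[[length(out) + 1L]] <- c(
        "code outside vocabulary",
        paste0("item '", k, "': ", paste(bad, collapse = ", "))
      )
    }
  }
  violation_tbl(out)
}

violation_tbl <- function(pairs) {
  if (!length(pairs)) {
    return(tibble(rule = character(), detail = character()))
  }
  tibble(
    rule = purrr::map_chr(pairs, 1L),
    detail = purrr::map_chr(pairs, 2L)
  )
}
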