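#' Direction of each outcome for report-card flagging
#'
#' Whether a high rate is adverse (cesarean, induction, preterm birth, low
#' birth weight, neonatal mortality) or favourable (spontaneous vaginal
#' birth, VBAC, breastfeeding). Editable: pass a modified copy to
#' [build_report_card()].
#'
#' @return Tibble with `outcome` and `direction` (`"adverse"` or
#'   `"favourable"`).
#' @export
outcome_directions <- function() {
  tibble::tribble(
    ~outcome, ~direction,
    "svb", "favourable",
    "vbac", "favourable",
    "induction", "adverse",
    "ptb", "adverse",
    "lbw", "adverse",
    "cesarean", "adverse",
    "neonatal_mortality", "adverse",
    "bf_birth", "favourable",
    "bf_6mo", "favourable"
  )
}

#' Build the jurisdiction report card
#'
#' One row per jurisdiction combining the composite score (with rank and
#' quartile), workforce densities, access proportions, outcome rates, and
#' an extreme-quartile flag per outcome: a jurisdiction is flagged
#' `favourable` on an outcome when it sits in the best quartile (lowest
#' quartile of an adverse rate, or highest quartile of a favourable rate),
#' `unfavourable` in the converse extreme, and `none` otherwise. This is
#' the tabular equivalent of map exports in which the deepest shading
#' marks the highest integration quartile and green/red outlines mark the
#' favourable/unfavourable outcome extremes.
#'
#' @param scores A `miss_scores` tibble.
#' @param records A vital-records tibble.
#' @param directions Outcome direction table, default [outcome_directions()];
#'   every flagged outcome must have an entry.
#' @param outcomes Outcome columns to flag.
#' @return Tibble of class `miss_report_card`: identification and score
#'   columns, `density_cnm_cm`, `density_cpm`, access proportions, outcome
#'   rates, and one `flag_<outcome>` column per outcome.
#' @export
build_report_card <- function(scores, records,
                              directions = outcome_directions(),
                              outcomes = unname(miss_outcomes)) {
  scores <- tibble::as_tibble(scores)
  if (!"rank" %in% names(scores)) scores <- rank_jurisdictions(scores)
  if (!"quartile" %in% names(scores)) scores <- assign_quartiles(scores)
  joined <- dplyr::inner_join(
    scores[, c("jurisdiction", "total", "rank", "quartile")],
    tibble::as_tibble(records), by = "jurisdiction")
  if (nrow(joined) < 4) {
    stop("report card needs at least 4 joined jurisdictions", call. = FALSE)
  }
  unknown <- setdiff(outcomes, directions$outcome)
  if (length(unknown) > 0) {
    stop("no direction entry for outcome(s): ",
         paste(unknown, collapse = ", "),
         "; add rows to the directions table", call. = FALSE)
  }
  acc <- access_proportions(joined)
  card <- joined |>
    dplyr::mutate(
      density_cnm_cm = density_per_1000(.data$midwives_cnm_cm, .data$births_total),
      density_cpm = density_per_1000(.data$midwives_cpm, .data$births_total)
    ) |>
    dplyr::left_join(acc, by = "jurisdiction")
  dir_of <- stats::setNames(directions$direction, directions$outcome)
  for (oc in outcomes) {
    q <- quartile_category(card[[oc]])
    flag <- rep("none", nrow(card))
    if (dir_of[[oc]] == "adverse") {
      flag[q == "very_low"] <- "favourable"
      flag[q == "high"] <- "unfavourable"
    } else {
      flag[q == "high"] <- "favourable"
      flag[q == "very_low"] <- "unfavourable"
    }
    card[[paste0("flag_", oc)]] <- flag
  }
  card <- dplyr::arrange(card, .data$rank, .data$jurisdiction)
  class(card) <- c("miss_report_card", class(card))
  card
}

#' Serialise a report card
#'
#' CSV with one row per jurisdiction, or JSON keyed by jurisdiction code.
#'
#' @param card A `miss_report_card`.
#' @param path Output path; `.json` selects the keyed-JSON form, anything
#'   else CSV.
#' @return `path`, invisibly.
#' @export
write_report_card <- function(card, path) {
  if (tolower(tools::file_ext(path)) == "json") {
    rows <- purrr::transpose(as.list(tibble::as_tibble(card)))
    names(rows) <- card$jurisdiction
    jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(tibble::as_tibble(card), path)
  }
  invisible(path)
}
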