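#' Quartile category labels, from most to least restrictive environments
#' @format Character vector of length 4.
#' @export
miss_quartile_levels <- c("very_low", "low", "moderate", "high")

#' The 51 US jurisdictions (50 states plus DC)
#' @format Character vector of 51 two-letter codes.
#' @export
miss_jurisdictions <- sort(c(datasets::state.abb, "DC"))

domain_column <- function(domain) {
  gsub("[^a-z0-9]+", "_", tolower(domain))
}

#' Score per-jurisdiction regulatory profiles against a rubric
#'
#' A profile records, for one jurisdiction, which response option best
#' describes its regulatory environment on each rubric item. The composite
#' MISS total is the sum of the selected options' point values; domain
#' subtotals partition the same sum across the seven regulatory domains.
#'
#' @param profiles Tibble with columns `jurisdiction`, `item_id`,
#'   `option_code` (and optionally `provenance`), one row per
#'   jurisdiction-item.
#' @param rubric A [miss_rubric()].
#' @param strict If `TRUE` (default), every rubric item must be answered for
#'   every jurisdiction; missing items raise an error listing them. If
#'   `FALSE`, missing items are scored as their minimum-point option (the
#'   conservative reading that an unverifiable condition is maximally
#'   restrictive), with one warning per jurisdiction listing the imputed
#'   items.
#' @return A tibble of class `miss_scores`, one row per jurisdiction:
#'   `jurisdiction`, `total`, then one column per domain subtotal (snake
#'   case). Rank and quartile are added by [rank_jurisdictions()] and
#'   [assign_quartiles()].
#' @examples
#' rubric <- canonical_rubric()
#' best <- optimal_profile(rubric, "WA")
#' score_profiles(best, rubric)$total  # 100
#' @export
score_profiles <- function(profiles, rubric, strict = TRUE) {
  stopifnot(inherits(rubric, "miss_rubric"))
  profiles <- tibble::as_tibble(profiles)
  need <- setdiff(c("jurisdiction", "item_id", "option_code"), names(profiles))
  if (length(need) > 0) {
    stop("profiles table missing columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dup <- profiles |>
    dplyr::count(.data$jurisdiction, .data$item_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate responses for: ",
         paste(sprintf("%s/%s", dup$jurisdiction, dup$item_id), collapse = ", "),
         call. = FALSE)
  }
  unknown_items <- setdiff(profiles$item_id, rubric$items$item_id)
  if (length(unknown_items) > 0) {
    stop("profile responses reference items absent from the rubric: ",
         paste(unique(unknown_items), collapse = ", "), call. = FALSE)
  }

  opts <- rubric$options[, c("item_id", "code", "points")]
  scored <- profiles |>
    dplyr::left_join(opts, by = c("item_id", "option_code" = "code"))
  bad <- is.na(scored$points)
  if (any(bad)) {
    stop("unknown option codes: ",
         paste(unique(sprintf("%s/%s='%s'", scored$jurisdiction[bad],
                              scored$item_id[bad], scored$option_code[bad])),
               collapse = ", "), call. = FALSE)
  }

  # fill in unanswered items (strict: error; otherwise impute lowest option)
  grid <- tidyr::expand_grid(
    jurisdiction = unique(profiles$jurisdiction),
    item_id = rubric$items$item_id
  )
  missing <- dplyr::anti_join(grid, profiles, by = c("jurisdiction", "item_id"))
  if (nrow(missing) > 0) {
    if (strict) {
      msg <- missing |>
        dplyr::group_by(.data$jurisdiction) |>
        dplyr::summarise(ids = paste(.data$item_id, collapse = ", "),
                         .groups = "drop")
      stop("unanswered rubric items (strict mode):\n",
           paste(sprintf("  %s: %s", msg$jurisdiction, msg$ids), collapse = "\n"),
           call. = FALSE)
    }
    lowest <- rubric$options |>
      dplyr::group_by(.data$item_id) |>
      dplyr::slice_min(.data$raw_rank, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select("item_id", "points")
    imputed <- dplyr::left_join(missing, lowest, by = "item_id")
    for (j in unique(imputed$jurisdiction)) {
      warning(sprintf("jurisdiction %s: imputed lowest option for items %s", j,
                      paste(imputed$item_id[imputed$jurisdiction == j],
                            collapse = ", ")),
              call. = FALSE)
    }
    scored <- dplyr::bind_rows(
      scored[, c("jurisdiction", "item_id", "points")],
      imputed
    )
  }

  scored <- dplyr::left_join(scored,
                             rubric$items[, c("item_id", "domain")],
                             by = "item_id")
  by_domain <- scored |>
    dplyr::group_by(.data$jurisdiction, .data$domain) |>
    dplyr::summarise(subtotal = sum(.data$points), .groups = "drop") |>
    dplyr::mutate(domain = domain_column(.data$domain)) |>
    tidyr::pivot_wider(names_from = "domain", values_from = "subtotal",
                       values_fill = 0)
  # keep a stable domain-column order; absent domains appear as zero columns
  for (d in domain_column(miss_domains)) {
    if (!d %in% names(by_domain)) by_domain[[d]] <- 0
  }
  totals <- scored |>
    dplyr::group_by(.data$jurisdiction) |>
    dplyr::summarise(total = sum(.data$points), .groups = "drop")
  out <- dplyr::left_join(totals, by_domain, by = "jurisdiction") |>
    dplyr::select("jurisdiction", "total",
                  dplyr::all_of(domain_column(miss_domains))) |>
    dplyr::arrange(.data$jurisdiction)
  class(out) <- c("miss_scores", class(out))
  out
}

#' Build the profile selecting every item's optimal option
#'
#' Convenience for structural checks and examples: the profile of a
#' hypothetical jurisdiction whose laws match the instrument's optimum on
#' every item, which by construction scores `target_total`.
#'
#' @param rubric A [miss_rubric()].
#' @param jurisdiction Code for the hypothetical jurisdiction.
#' @return A profiles tibble (`jurisdiction`, `item_id`, `option_code`).
#' @export
optimal_profile <- function(rubric, jurisdiction = "XX") {
  rubric$options |>
    dplyr::group_by(.data$item_id) |>
    dplyr::slice_max(.data$raw_rank, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::transmute(jurisdiction = jurisdiction,
                     item_id = .data$item_id,
                     option_code = .data$code)
}

#' Rank jurisdictions by composite score
#'
#' Descending by total with competition ranking: tied jurisdictions share
#' the minimum rank of the tied block and the next rank is skipped
#' accordingly (totals 5, 5, 3 rank 1, 1, 3). Within a tie the display
#' order is alphabetical by jurisdiction code.
#'
#' @param scores A `miss_scores` tibble (from [score_profiles()]).
#' @return The same tibble with a `rank` column, ordered for display.
#' @export
rank_jurisdictions <- function(scores) {
  if (nrow(scores) < 1) stop("no scores to rank", call. = FALSE)
  if (anyDuplicated(scores$jurisdiction)) {
    stop("duplicate jurisdiction codes: ",
         paste(unique(scores$jurisdiction[duplicated(scores$jurisdiction)]),
               collapse = ", "), call. = FALSE)
  }
  out <- scores |>
    dplyr::mutate(rank = dplyr::min_rank(dplyr::desc(.data$total))) |>
    dplyr::arrange(.data$rank, .data$jurisdiction)
  class(out) <- unique(c("miss_scores", class(out)))
  out
}

#' Classify values into the four report-card quartile categories
#'
#' The percentile of each value is the share of values strictly below it,
#' times 100; categories are the bands below the 25th, 25th--49th,
#' 50th--74th and 75th-and-above percentiles, labelled very_low, low,
#' moderate and high. On n distinct values with n divisible by 4 the four
#' categories are exactly equal-sized.
#'
#' @param x Numeric vector, length at least 4.
#' @return Factor with levels [miss_quartile_levels].
#' @export
quartile_category <- function(x) {
  if (length(x) < 4) {
    stop("quartile categories need at least 4 values, got ", length(x),
         call. = FALSE)
  }
  if (anyNA(x)) stop("quartile_category: missing values", call. = FALSE)
  n <- length(x)
  pct <- 100 * (vapply(x, function(v) sum(x < v), numeric(1)) / n)
  cut(pct, breaks = c(-Inf, 25, 50, 75, Inf), right = FALSE,
      labels = miss_quartile_levels)
}

#' Assign quartile categories to a set of scores
#'
#' @param scores A `miss_scores` tibble.
#' @return The same tibble with a `quartile` factor column.
#' @seealso [quartile_category()] for the percentile convention.
#' @export
assign_quartiles <- function(scores) {
  out <- dplyr::mutate(scores, quartile = quartile_category(.data$total))
  class(out) <- unique(c("miss_scores", class(out)))
  out
}

#' Read and write profile and score tables
#'
#' Profiles CSV: columns `jurisdiction,item_id,option_code[,provenance]`,
#' UTF-8, header required. Scores CSV: `jurisdiction,total,rank,quartile`
#' plus one column per domain subtotal.
#'
#' @param path CSV path.
#' @return `read_profiles()` a profiles tibble; `write_profiles()` /
#'   `write_scores()` return `path` invisibly.
#' @export
read_profiles <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  need <- setdiff(c("jurisdiction", "item_id", "option_code"), names(df))
  if (length(need) > 0) {
    stop("profiles file '", path, "' missing columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  df
}

#' @rdname read_profiles
#' @param profiles,scores Tables to serialise.
#' @export
write_profiles <- function(profiles, path) {
  readr::write_csv(profiles, path)
  invisible(path)
}

#' @rdname read_profiles
#' @export
write_scores <- function(scores, path) {
  readr::write_csv(scores, path)
  invisible(path)
}
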