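#' Outcome columns carried in a vital-records table
#'
#' Rates are percentages of births except `neonatal_mortality`, which is
#' deaths within 27 days of birth per 1000 live births.
#'
#' @format Character vector of outcome column names.
#' @export
miss_outcomes <- c(
  svb = "svb",                             # spontaneous vaginal birth %
  vbac = "vbac",                           # vaginal birth after cesarean %
  induction = "induction",                 # induction of labour %
  ptb = "ptb",                             # preterm (<37 wk) birth %
  lbw = "lbw",                             # low birth weight (<2500 g) %
  cesarean = "cesarean",                   # cesarean section %
  neonatal_mortality = "neonatal_mortality", # per 1000 live births
  bf_birth = "bf_birth",                   # exclusive breastfeeding at birth %
  bf_6mo = "bf_6mo"                        # breastfeeding at 6 months %
)

#' Attendant-by-setting count columns in a vital-records table
#'
#' Births are cross-classified by attendant credential group (CNMs/CMs
#' versus CPMs and other direct-entry midwives, the two bins reported on US
#' birth certificates) and by setting (hospital, home, freestanding birth
#' center).
#' @format Character vector of 6 column names, `bas_<group>_<setting>`.
#' @export
miss_bas_columns <- as.vector(outer(
  c("cnm_cm", "cpm"), c("hospital", "home", "birth_center"),
  function(g, s) paste0("bas_", g, "_", s)
))

#' Midwives per 1000 births
#'
#' Workforce density: the number of midwives of a credential group in a
#' jurisdiction divided by its total births, times 1000.
#'
#' @param midwife_count Non-negative count (vectorised).
#' @param births_total Positive count of births (vectorised).
#' @return Density per 1000 births.
#' @examples
#' density_per_1000(10, 10000)  # 1.0
#' @export
density_per_1000 <- function(midwife_count, births_total) {
  if (any(births_total <= 0)) {
    stop("density undefined: births_total must be > 0", call. = FALSE)
  }
  if (any(midwife_count < 0)) {
    stop("midwife_count must be non-negative", call. = FALSE)
  }
  midwife_count / births_total * 1000
}

#' Consumer access to midwives across birth settings
#'
#' For each jurisdiction, the proportion of all births attended by each
#' credential group in each setting, plus two aggregates: all
#' midwife-attended births in any location (`prop_midwife_all`) and
#' midwife-led community births, i.e. home plus freestanding birth center
#' (`prop_midwife_community`).
#'
#' @param records Vital-records tibble with `jurisdiction`, `births_total`
#'   and the six [miss_bas_columns].
#' @return Tibble with one row per jurisdiction: `prop_<group>_<setting>`
#'   columns and the two aggregates, all in \[0, 1\].
#' @export
access_proportions <- function(records) {
  records <- tibble::as_tibble(records)
  need <- setdiff(c("jurisdiction", "births_total", miss_bas_columns),
                  names(records))
  if (length(need) > 0) {
    stop("records table missing columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(records$births_total <= 0)) {
    stop("access proportions undefined: births_total must be > 0", call. = FALSE)
  }
  cells <- as.matrix(records[, miss_bas_columns])
  if (any(cells < 0)) stop("negative attendant-setting counts", call. = FALSE)
  over <- rowSums(cells) > records$births_total
  if (any(over)) {
    stop("attendant-setting counts exceed total births for: ",
         paste(records$jurisdiction[over], collapse = ", "), call. = FALSE)
  }
  props <- cells / records$births_total
  colnames(props) <- sub("^bas_", "prop_", miss_bas_columns)
  community <- grepl("home|birth_center", colnames(props))
  tibble::tibble(
    jurisdiction = records$jurisdiction,
    tibble::as_tibble(props),
    prop_midwife_all = rowSums(props),
    prop_midwife_community = rowSums(props[, community, drop = FALSE])
  )
}

#' Percent change in the community-birth rate between two periods
#'
#' Relative change of the rate itself (not of counts):
#' `100 * (rate_t1 - rate_t0) / rate_t0`.
#'
#' @param rate_t0,rate_t1 Community-birth rates (percent of births) at the
#'   start and end of the period; `rate_t0` must be positive.
#' @return Percent change (vectorised); 72 means a 72% increase.
#' @export
community_birth_change <- function(rate_t0, rate_t1) {
  if (any(rate_t0 <= 0)) {
    stop("percent change undefined: rate_t0 must be > 0", call. = FALSE)
  }
  100 * (rate_t1 - rate_t0) / rate_t0
}

#' Read and write vital-records tables
#'
#' One row per jurisdiction-year. Columns: `jurisdiction`, `year`,
#' `births_total`, `midwives_cnm_cm`, `midwives_cpm`, the six
#' [miss_bas_columns], `pct_black_births`, `community_birth_rate`, and the
#' outcome rates in [miss_outcomes].
#'
#' @param path CSV path.
#' @param records Vital-records tibble.
#' @return `read_vitals()` a tibble; `write_vitals()` returns `path`
#'   invisibly.
#' @export
read_vitals <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_vitals(df)
  df
}

#' @rdname read_vitals
#' @export
write_vitals <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

validate_vitals <- function(records) {
  need <- setdiff(c("jurisdiction", "births_total", miss_bas_columns,
                    "pct_black_births", unname(miss_outcomes)),
                  names(records))
  if (length(need) > 0) {
    stop("vital-records table missing columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  pct_cols <- c("pct_black_births",
                setdiff(unname(miss_outcomes), "neonatal_mortality"))
  for (col in pct_cols) {
    if (any(records[[col]] < 0 | records[[col]] > 100, na.rm = TRUE)) {
      stop("column '", col, "' outside [0, 100]", call. = FALSE)
    }
  }
  if (any(records$neonatal_mortality < 0, na.rm = TRUE)) {
    stop("neonatal_mortality must be non-negative", call. = FALSE)
  }
  invisible(records)
}
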