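#' Average (tie-aware) ranks
#'
#' Ranks with ties receiving the mean of the positions they span, so that
#' ranks always sum to n(n+1)/2. Thin wrapper kept as an explicit step
#' because the rank correlation below is defined on these ranks.
#'
#' @param x Numeric vector, length at least 1, no missing values.
#' @return Numeric vector of ranks.
#' @export
average_ranks <- function(x) {
  if (length(x) == 0) stop("average_ranks: empty vector", call. = FALSE)
  if (anyNA(x)) stop("average_ranks: missing values", call. = FALSE)
  rank(x, ties.method = "average")
}

sig_flag <- function(p) {
  dplyr::case_when(p < 0.01 ~ "p<0.01", p < 0.05 ~ "p<0.05", TRUE ~ "ns")
}

#' Spearman rank correlation with a two-tailed t-approximation p-value
#'
#' The coefficient is the Pearson correlation of the average ranks of the
#' two vectors (so ties are handled by mid-ranks). The two-tailed p-value
#' uses the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' n - 2 degrees of freedom; `rho = +/-1` gives p = 0. For very small
#' samples (n <= 10, no ties) an exact permutation p-value is available.
#'
#' @param x,y Numeric vectors of equal length n >= 3 with no missing
#'   values; callers drop pairwise-incomplete observations first and report
#'   the n actually used.
#' @param label_x,label_y Names carried into the result row.
#' @param exact If `TRUE` and n <= 10, compute the p-value by full
#'   enumeration of permutations instead of the t approximation.
#' @return One-row tibble: `label_x`, `label_y`, `n`, `rho`,
#'   `p_two_tailed`, `sig_flag` (`ns`, `p<0.05` or `p<0.01`).
#' @examples
#' spearman_rho(1:4, c(2, 1, 4, 3))$rho  # 0.6
#' @export
spearman_rho <- function(x, y, label_x = "x", label_y = "y", exact = FALSE) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) {
    stop("missing values: drop pairwise-incomplete observations first",
         call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  rx <- average_ranks(x)
  ry <- average_ranks(y)
  rho <- stats::cor(rx, ry)
  rho <- max(-1, min(1, rho))
  if (exact && n <= 10) {
    p <- exact_spearman_p(rx, ry, rho)
  } else if (abs(rho) == 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  tibble::tibble(label_x = label_x, label_y = label_y, n = n,
                 rho = rho, p_two_tailed = p, sig_flag = sig_flag(p))
}

# two-sided permutation p: share of permutations of y's ranks whose |rho|
# is at least the observed |rho| (small-sample option, n <= 10)
exact_spearman_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  perms <- permutations_of(seq_len(n))
  rhos <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

permutations_of <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- permutations_of(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

#' Shapiro-Wilk normality gate
#'
#' The analysis pipeline uses rank correlations because state-level outcome
#' distributions are typically non-normal even when composite scores are
#' not; this helper is the gate that documents that choice for any vector.
#'
#' @param x Numeric vector, 3 <= n <= 5000, non-constant.
#' @param alpha Significance level for the flag (default 0.05).
#' @return One-row tibble: `W`, `p`, `is_normal` (`p > alpha`).
#' @export
normality_check <- function(x, alpha = 0.05) {
  n <- length(x)
  if (n < 3 || n > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000, got ", n, call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("normality test undefined for a constant vector",
                              call. = FALSE)
  sw <- stats::shapiro.test(x)
  tibble::tibble(W = unname(sw$statistic), p = sw$p.value,
                 is_normal = sw$p.value > alpha)
}

#' Correlate integration scores and midwifery access with outcomes
#'
#' Builds the full exposure-by-outcome table of Spearman correlations: the
#' exposures are the composite MISS total, the proportion of births
#' attended by midwives in hospital only, and the proportion of midwife-led
#' births in community settings (home + birth center); the outcomes default
#' to the nine perinatal indicators in [miss_outcomes]. Jurisdictions with
#' a missing value in a given pair are dropped for that cell only
#' (pairwise-complete), and each row records the n used.
#'
#' @param scores A `miss_scores` tibble (needs `jurisdiction`, `total`).
#' @param records A vital-records tibble (see [read_vitals()]).
#' @param outcomes Character vector of outcome columns.
#' @return Tibble of class `miss_correlations` with one row per
#'   exposure-outcome pair: `exposure`, `outcome`, `n`, `rho`,
#'   `p_two_tailed`, `sig_flag`.
#' @export
correlation_table <- function(scores, records,
                              outcomes = unname(miss_outcomes)) {
  joined <- dplyr::inner_join(
    tibble::as_tibble(scores)[, c("jurisdiction", "total")],
    tibble::as_tibble(records), by = "jurisdiction")
  if (nrow(joined) < 3) {
    stop("join of scores and records yields fewer than 3 jurisdictions",
         call. = FALSE)
  }
  acc <- access_proportions(joined)
  exposures <- tibble::tibble(
    jurisdiction = joined$jurisdiction,
    miss_total = joined$total,
    pct_midwife_hospital = 100 * (acc$prop_cnm_cm_hospital + acc$prop_cpm_hospital),
    pct_midwife_community = 100 * acc$prop_midwife_community
  )
  missing_out <- setdiff(outcomes, names(joined))
  if (length(missing_out) > 0) {
    stop("outcomes absent from records: ", paste(missing_out, collapse = ", "),
         call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    exposure = c("miss_total", "pct_midwife_hospital", "pct_midwife_community"),
    outcome = outcomes
  )
  out <- purrr::pmap(grid, function(exposure, outcome) {
    xv <- exposures[[exposure]]
    yv <- joined[[outcome]]
    keep <- !(is.na(xv) | is.na(yv))
    if (sum(keep) < 3) {
      stop(sprintf("cell %s x %s: fewer than 3 complete pairs",
                   exposure, outcome), call. = FALSE)
    }
    spearman_rho(xv[keep], yv[keep], label_x = exposure, label_y = outcome)
  }) |> purrr::list_rbind() |>
    dplyr::rename(exposure = "label_x", outcome = "label_y")
  class(out) <- c("miss_correlations", class(out))
  out
}

#' Serialise a correlation table with star annotations
#'
#' Writes the exposure-by-outcome table as CSV with the conventional star
#' annotations (`*` p < 0.05, `**` p < 0.01, two-tailed) appended to rho.
#'
#' @param ct A `miss_correlations` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_correlations <- function(ct, path) {
  stars <- c(ns = "", `p<0.05` = "*", `p<0.01` = "**")
  wide <- ct |>
    dplyr::mutate(cell = sprintf("%.3f%s", .data$rho, stars[.data$sig_flag])) |>
    dplyr::select("outcome", "exposure", "cell") |>
    tidyr::pivot_wider(names_from = "exposure", values_from = "cell")
  readr::write_csv(wide, path)
  invisible(path)
}
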