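#' Ordinary least squares on an explicit design matrix
#'
#' QR-based least squares with a hard rank check: a rank-deficient design
#' is an error, never silently resolved by a pseudo-inverse. The design
#' must include an intercept column (R-squared is computed against the
#' centered total sum of squares).
#'
#' @param design Numeric matrix, n rows, including an intercept column.
#' @param y Numeric response vector of length n.
#' @param weights Optional positive case weights (weighted least squares);
#'   default unweighted.
#' @return List: `coefficients` (named by design columns), `r2`,
#'   `fitted`, `residuals`, `n`, `p` (number of non-intercept columns).
#' @export
ols_fit <- function(design, y, weights = NULL) {
  design <- as.matrix(design)
  n <- nrow(design)
  if (length(y) != n) stop("design and y have different lengths", call. = FALSE)
  if (n <= ncol(design)) {
    stop("need more observations than design columns", call. = FALSE)
  }
  intercept_cols <- apply(design, 2, function(col) all(col == col[1] & col[1] != 0))
  if (!any(intercept_cols)) {
    stop("design must include an intercept column", call. = FALSE)
  }
  w <- weights %||% rep(1, n)
  if (length(w) != n || any(w <= 0)) {
    stop("weights must be positive and of length n", call. = FALSE)
  }
  s <- sqrt(w)
  qrd <- qr(design * s)
  if (qrd$rank < ncol(design)) {
    stop("rank-deficient design (rank ", qrd$rank, " < ", ncol(design),
         " columns)", call. = FALSE)
  }
  beta <- qr.coef(qrd, y * s)
  fitted <- drop(design %*% beta)
  resid <- y - fitted
  ss_res <- sum(w * resid^2)
  ybar <- sum(w * y) / sum(w)
  ss_tot <- sum(w * (y - ybar)^2)
  if (ss_tot == 0) stop("constant response: R-squared undefined", call. = FALSE)
  list(coefficients = stats::setNames(beta, colnames(design)),
       r2 = 1 - ss_res / ss_tot,
       fitted = fitted, residuals = resid,
       n = n, p = ncol(design) - sum(intercept_cols))
}

as_block <- function(block, n, prefix) {
  if (is.null(block)) return(NULL)
  m <- as.matrix(block)
  if (nrow(m) != n) stop("block has wrong number of rows", call. = FALSE)
  if (is.null(colnames(m))) {
    colnames(m) <- paste0(prefix, seq_len(ncol(m)))
  }
  m
}

#' Hierarchical (block-entry) regression with an R-squared-change F test
#'
#' Fits the restricted model `y ~ block1` and the full model
#' `y ~ block1 + block2`, both with an intercept, and tests the increment
#' in explained variance attributable to the second block:
#' \deqn{F_{change} = \frac{\Delta R^2 / q}{(1 - R^2_{full}) / (n - p - 1)}}
#' with q the number of block-2 predictors and p the total number of
#' non-intercept predictors; the p-value comes from the F(q, n - p - 1)
#' distribution. This is the design used to ask how much of the variance
#' in a perinatal outcome integration scores explain beyond the proportion
#' of non-Hispanic Black births (block 1).
#'
#' @param y Outcome vector.
#' @param block1 Matrix (or vector) of block-1 predictors, no intercept.
#' @param block2 Matrix (or vector) of block-2 predictors, no intercept.
#' @param outcome Name carried into the result.
#' @param weights Optional positive case weights, passed to [ols_fit()].
#' @return Object of class `miss_hfit`: a list with `outcome`, `n`,
#'   `r2_block1`, `r2_total`, `delta_r2`, `f_change`, `p_change`,
#'   `coefficients` (full model), `fitted`, `std_residuals`.
#'   [tidy()] and [glance()] methods give tibble views.
#' @export
hierarchical_r2_change <- function(y, block1, block2, outcome = "outcome",
                                   weights = NULL) {
  n <- length(y)
  b1 <- as_block(block1, n, "x1_")
  b2 <- as_block(block2, n, "x2_")
  if (is.null(b1) || is.null(b2)) stop("both blocks are required", call. = FALSE)
  intercept <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  fit1 <- ols_fit(cbind(intercept, b1), y, weights = weights)

  full_design <- cbind(intercept, b1, b2)
  # block 2 duplicating block 1 carries no new information: delta R^2 = 0,
  # F = 0, rather than a rank error on the full design
  qrd <- qr(full_design)
  if (qrd$rank < ncol(full_design)) {
    redundant <- qr(cbind(intercept, b1, b2))$rank == qr(cbind(intercept, b1))$rank
    if (!redundant) {
      stop("rank-deficient design (rank ", qrd$rank, " < ", ncol(full_design),
           " columns)", call. = FALSE)
    }
    fit_full <- fit1
    q <- ncol(b2)
    p_full <- fit1$p
    delta <- 0
    f_change <- 0
    p_change <- 1
  } else {
    fit_full <- ols_fit(full_design, y, weights = weights)
    q <- ncol(b2)
    p_full <- fit_full$p
    delta <- fit_full$r2 - fit1$r2
    df2 <- n - p_full - 1
    if (df2 <= 0) stop("no residual degrees of freedom", call. = FALSE)
    f_change <- (delta / q) / ((1 - fit_full$r2) / df2)
    p_change <- stats::pf(f_change, q, df2, lower.tail = FALSE)
  }

  sd_res <- stats::sd(fit_full$residuals)
  structure(
    list(outcome = outcome, n = n,
         r2_block1 = fit1$r2, r2_total = fit_full$r2,
         delta_r2 = delta, f_change = f_change, p_change = p_change,
         coefficients = fit_full$coefficients,
         fitted = fit_full$fitted,
         std_residuals = if (sd_res > 0) fit_full$residuals / sd_res
                         else fit_full$residuals),
    class = "miss_hfit"
  )
}

#' @export
print.miss_hfit <- function(x, ...) {
  cat(sprintf(
    "<miss_hfit> %s (n = %d)\n  R2 block 1 = %.3f, R2 total = %.3f, delta R2 = %.3f\n  F-change = %.3f, p = %.4g\n",
    x$outcome, x$n, x$r2_block1, x$r2_total, x$delta_r2, x$f_change, x$p_change))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the full-model coefficients of a hierarchical fit
#' @param x A `miss_hfit`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate`.
#' @export
tidy.miss_hfit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' One-row model summary of a hierarchical fit
#' @param x A `miss_hfit`.
#' @param ... Unused.
#' @return Tibble with `outcome`, `n`, `r2_block1`, `delta_r2`, `r2_total`,
#'   `f_change`, `p_change`, `sig_flag`.
#' @export
glance.miss_hfit <- function(x, ...) {
  tibble::tibble(outcome = x$outcome, n = x$n,
                 r2_block1 = x$r2_block1, delta_r2 = x$delta_r2,
                 r2_total = x$r2_total, f_change = x$f_change,
                 p_change = x$p_change, sig_flag = sig_flag(x$p_change))
}

#' Residual diagnostics for a hierarchical fit
#'
#' Checks the two assumptions reported for the block-entry models: the
#' standardized residuals are normally distributed (Shapiro-Wilk) and their
#' relationship with the standardized predicted values is linear with no
#' trend (their Pearson correlation, which is 0 by construction for an OLS
#' fit with intercept, is reported as a sanity check).
#'
#' @param fit A `miss_hfit`.
#' @param alpha Flagging level, default 0.05.
#' @return One-row tibble: `shapiro_p`, `normal_ok`, `cor_fitted_resid`,
#'   `linear_ok`.
#' @export
residual_diagnostics <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "miss_hfit"))
  r <- fit$std_residuals
  if (length(r) < 3) stop("need at least 3 residuals", call. = FALSE)
  sw_p <- stats::shapiro.test(r)$p.value
  fz <- fit$fitted
  cr <- if (stats::sd(fz) == 0 || stats::sd(r) == 0) 0 else
    stats::cor((fz - mean(fz)) / stats::sd(fz), r)
  tibble::tibble(shapiro_p = sw_p, normal_ok = sw_p > alpha,
                 cor_fitted_resid = cr, linear_ok = abs(cr) < 1e-8)
}

#' Fit the block-entry model for each outcome
#'
#' Convenience wrapper reproducing the shape of the published regression
#' table: for each outcome, % non-Hispanic Black births enters in block 1
#' and the raw MISS total in block 2; rows are the [glance()] summaries.
#' Listwise deletion within each outcome model.
#'
#' @param scores A `miss_scores` tibble.
#' @param records A vital-records tibble.
#' @param outcomes Outcome columns to model; defaults to the five in the
#'   published analysis.
#' @param standardize If `TRUE`, both predictors are z-scored before
#'   fitting (coefficient comparability; R-squared quantities unchanged).
#' @param weights Optional per-jurisdiction weights (e.g. births); default
#'   unweighted.
#' @return Tibble of class `miss_hierarchical_table`, one row per outcome.
#' @export
hierarchical_table <- function(scores, records,
                               outcomes = c("neonatal_mortality", "cesarean",
                                            "ptb", "lbw", "bf_birth"),
                               standardize = FALSE, weights = NULL) {
  joined <- dplyr::inner_join(
    tibble::as_tibble(scores)[, c("jurisdiction", "total")],
    tibble::as_tibble(records), by = "jurisdiction")
  out <- purrr::map(outcomes, function(oc) {
    if (!oc %in% names(joined)) {
      stop("outcome '", oc, "' absent from records", call. = FALSE)
    }
    keep <- stats::complete.cases(joined$total, joined$pct_black_births,
                                  joined[[oc]])
    dat <- joined[keep, ]
    x1 <- dat$pct_black_births
    x2 <- dat$total
    yv <- dat[[oc]]
    if (standardize) {
      x1 <- as.numeric(scale(x1)); x2 <- as.numeric(scale(x2))
    }
    fit <- hierarchical_r2_change(
      yv,
      block1 = matrix(x1, ncol = 1, dimnames = list(NULL, "pct_black_births")),
      block2 = matrix(x2, ncol = 1, dimnames = list(NULL, "miss_total")),
      outcome = oc, weights = if (is.null(weights)) NULL else weights[keep])
    glance(fit)
  }) |> purrr::list_rbind()
  class(out) <- c("miss_hierarchical_table", class(out))
  out
}
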