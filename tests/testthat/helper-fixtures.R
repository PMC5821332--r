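# Shared fixtures and independent oracles, built in code at test time.

# A tiny binary-option rubric: item i has options {0, max_i points}.
toy_rubric <- function(maxima, target_total = sum(maxima),
                       domains = rep(missr::miss_domains[1], length(maxima))) {
  n <- length(maxima)
  items <- tibble::tibble(
    item_id = sprintf("it%02d", seq_len(n)),
    stem = sprintf("toy item %d", seq_len(n)),
    domain = domains,
    midwife_types = rep(list(c("CNM", "CM", "CPM")), n),
    weight = rep(1L, n)
  )
  options <- purrr::map(seq_len(n), function(i) {
    tibble::tibble(item_id = items$item_id[i],
                   code = c("lo", "hi"), label = c("low", "high"),
                   raw_rank = c(0, 1), points = c(0, maxima[i]))
  }) |> purrr::list_rbind()
  missr::miss_rubric(items, options, target_total = target_total)
}

toy_profile <- function(rubric, codes, jurisdiction = "AA") {
  tibble::tibble(jurisdiction = jurisdiction,
                 item_id = rubric$items$item_id,
                 option_code = codes)
}

# Brute-force rank oracle: position averages found by exhaustive sorting.
oracle_ranks <- function(x) {
  s <- sort(x)
  vapply(x, function(v) mean(which(s == v)), numeric(1))
}

# Spearman oracle: covariance of oracle ranks, by the definitional sums.
oracle_spearman <- function(x, y) {
  rx <- oracle_ranks(x); ry <- oracle_ranks(y)
  n <- length(x)
  cxy <- sum((rx - mean(rx)) * (ry - mean(ry))) / n
  vx <- sum((rx - mean(rx))^2) / n
  vy <- sum((ry - mean(ry))^2) / n
  cxy / sqrt(vx * vy)
}

# All 720 permutations of 1..6, built by recursive insertion.
permn6 <- function() {
  perms <- matrix(1L, 1, 1)
  for (k in 2:6) {
    out <- matrix(0L, nrow(perms) * k, k)
    row <- 1
    for (i in seq_len(nrow(perms))) {
      for (pos in seq_len(k)) {
        out[row, ] <- append(perms[i, ], k, after = pos - 1)
        row <- row + 1
      }
    }
    perms <- out
  }
  perms
}

# OLS oracle: explicit normal-equations solve.
oracle_ols <- function(X, y) {
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- drop(X %*% beta)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  list(coefficients = drop(beta), r2 = 1 - rss / tss)
}

# Hierarchical oracle: explicit sum-of-squares decomposition of the nested
# fits, independent of the package's code path.
oracle_r2_change <- function(y, x1, x2) {
  n <- length(y)
  X1 <- cbind(1, x1)
  X2 <- cbind(1, x1, x2)
  rss1 <- sum((y - X1 %*% solve(t(X1) %*% X1, t(X1) %*% y))^2)
  rss2 <- sum((y - X2 %*% solve(t(X2) %*% X2, t(X2) %*% y))^2)
  tss <- sum((y - mean(y))^2)
  r2_1 <- 1 - rss1 / tss
  r2_2 <- 1 - rss2 / tss
  q <- ncol(as.matrix(x2))
  p_full <- ncol(X2) - 1
  f <- ((rss1 - rss2) / q) / (rss2 / (n - p_full - 1))
  list(r2_block1 = r2_1, r2_total = r2_2, delta_r2 = r2_2 - r2_1,
       f_change = f,
       p_change = stats::pf(f, q, n - p_full - 1, lower.tail = FALSE))
}

# Analytic variance of the synthetic composite score (as MISS/100) under a
# config: quadrature over the latent Beta distribution using the
# closed-form item response probabilities of the cumulative-logit rule.
analytic_score_moments <- function(config, rubric, n_grid = 2001) {
  grid <- seq(1e-6, 1 - 1e-6, length.out = n_grid)
  w <- stats::dbeta(grid, config$latent_shape[1], config$latent_shape[2])
  w <- w / sum(w)
  per_item <- split(rubric$options, rubric$options$item_id)
  mean_tot <- numeric(length(grid))
  var_tot <- numeric(length(grid))
  for (oi in per_item) {
    oi <- oi[order(oi$raw_rank), ]
    K <- nrow(oi)
    surv <- cbind(1, vapply(2:K, function(k) {
      stats::plogis(config$discrimination * (grid - (k - 1) / K))
    }, numeric(length(grid))), 0)
    probs <- surv[, 1:K, drop = FALSE] - surv[, 2:(K + 1), drop = FALSE]
    e1 <- probs %*% oi$points
    e2 <- probs %*% oi$points^2
    mean_tot <- mean_tot + e1
    var_tot <- var_tot + (e2 - e1^2)
  }
  mu <- sum(w * mean_tot)
  v <- sum(w * (var_tot + mean_tot^2)) - mu^2
  list(mean = mu, var = v)   # on the 0-100 points scale
}

beta_pct_var <- function(shape) {
  a <- shape[1]; b <- shape[2]
  100^2 * a * b / ((a + b)^2 * (a + b + 1))
}
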