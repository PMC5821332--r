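test_that("average ranks handle ties by mid-rank and always sum to n(n+1)/2", {
  expect_equal(average_ranks(c(3, 1, 2)), c(3, 1, 2))
  expect_equal(average_ranks(c(5, 5, 1)), c(2.5, 2.5, 1))
  expect_error(average_ranks(numeric(0)), "empty")
  set.seed(21)
  for (i in 1:20) {
    x <- sample(1:6, sample(3:30, 1), replace = TRUE)
    r <- average_ranks(x)
    expect_equal(sum(r), length(x) * (length(x) + 1) / 2)
  }
  # distinct values give a permutation of 1..n
  x <- sample(100, 12)
  expect_setequal(average_ranks(x), 1:12)
})

test_that("spearman_rho: monotone association, hand value, symmetry", {
  x <- 1:10
  m <- spearman_rho(x, x^2)
  expect_equal(m$rho, 1)
  expect_equal(m$p_two_tailed, 0)

  hand <- spearman_rho(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(hand$rho, 0.6, tolerance = 1e-12)

  set.seed(31)
  for (i in 1:15) {
    a <- rnorm(8); b <- rnorm(8)
    expect_equal(spearman_rho(a, b)$rho, spearman_rho(b, a)$rho,
                 tolerance = 1e-15)
  }
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  set.seed(32)
  for (i in 1:15) {
    a <- rnorm(12); b <- rnorm(12)
    base <- spearman_rho(a, b)$rho
    expect_equal(spearman_rho(exp(a), b)$rho, base, tolerance = 1e-12)
    expect_equal(spearman_rho(a, 3 * b - 7)$rho, base, tolerance = 1e-12)
    expect_equal(spearman_rho(rank(a), b)$rho, base, tolerance = 1e-12)
  }
})

test_that("spearman_rho matches the definitional oracle and the reference routine on tied data", {
  set.seed(33)
  for (i in 1:50) {
    n <- sample(5:25, 1)
    x <- sample(1:5, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    got <- spearman_rho(x, y)$rho
    expect_equal(got, oracle_spearman(x, y), tolerance = 1e-13)
    expect_equal(got, suppressWarnings(cor(x, y, method = "spearman")),
                 tolerance = 1e-13)
  }
})

test_that("spearman p-values: t approximation formula and exact permutation option", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  y <- c(2, 7, 1, 8, 2.8, 1.8)
  res <- spearman_rho(x, y)
  rho <- res$rho
  tstat <- rho * sqrt((6 - 2) / (1 - rho^2))
  expect_equal(res$p_two_tailed, 2 * pt(-abs(tstat), 4), tolerance = 1e-12)

  exact <- spearman_rho(x, y, exact = TRUE)
  expect_gte(exact$p_two_tailed, 0)
  expect_lte(exact$p_two_tailed, 1)
  # enumeration p for a perfect monotone pair: 2/n! two-sided
  perf <- spearman_rho(1:5, 2^(1:5), exact = TRUE)
  expect_equal(perf$p_two_tailed, 2 / factorial(5), tolerance = 1e-12)
})

test_that("spearman_rho rejects constants, length mismatches and missing values", {
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:4, 1:5), "equal length")
  expect_error(spearman_rho(c(1, NA, 3), 1:3), "missing")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("significance flags follow the two-tailed 0.05/0.01 conventions", {
  expect_identical(spearman_rho(1:20, 1:20)$sig_flag, "p<0.01")
  set.seed(35)
  r <- spearman_rho(rnorm(10), rnorm(10))
  expect_identical(r$sig_flag,
                   if (r$p_two_tailed < 0.01) "p<0.01"
                   else if (r$p_two_tailed < 0.05) "p<0.05" else "ns")
})

test_that("normality gate: normal samples usually pass, skewed samples usually fail", {
  expect_error(normality_check(rep(2, 10)), "constant")
  expect_error(normality_check(1:2), "3 <= n")
  expect_error(normality_check(rnorm(5001)), "3 <= n")

  pass <- 0; fail <- 0
  for (s in 1:100) {
    set.seed(s)
    z <- rnorm(500)
    if (normality_check(z)$is_normal) pass <- pass + 1
    if (!normality_check(z^2)$is_normal) fail <- fail + 1
  }
  expect_gte(pass, 90)
  expect_gte(fail, 90)
})

test_that("correlation_table has full exposure-by-outcome shape and finds planted effects", {
  study <- simulate_study(sim_config(n_jurisdictions = 200, seed = 61))
  ct <- correlation_table(study$scores, study$records)
  expect_equal(nrow(ct), 3 * length(miss_outcomes))
  expect_true(all(abs(ct$rho) <= 1))
  expect_true(all(ct$n == 200))

  bf <- dplyr::filter(ct, exposure == "miss_total", outcome == "bf_birth")
  expect_gt(bf$rho, 0)
  expect_lt(bf$p_two_tailed, 0.01)
  nm <- dplyr::filter(ct, exposure == "miss_total", outcome == "neonatal_mortality")
  expect_lt(nm$rho, 0)
})

test_that("correlation_table errors when the join is too small", {
  study <- simulate_study(sim_config(n_jurisdictions = 6, seed = 8))
  tiny <- study$scores[1:2, ]
  expect_error(correlation_table(tiny, study$records), "fewer than 3")
})

test_that("a null exposure-outcome pair rejects at close to the nominal 5% rate", {
  set.seed(71)
  hits <- 0
  for (r in 1:1000) {
    x <- rnorm(51); y <- rnorm(51)
    if (spearman_rho(x, y)$p_two_tailed < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 1000, 0.03)
  expect_lte(hits / 1000, 0.07)
})

test_that("correlation table serialises with star annotations", {
  study <- simulate_study(sim_config(n_jurisdictions = 12, seed = 13))
  ct <- correlation_table(study$scores, study$records)
  f <- withr::local_tempfile(fileext = ".csv")
  write_correlations(ct, f)
  wide <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(nrow(wide), length(miss_outcomes))
  expect_true(all(c("outcome", "miss_total") %in% names(wide)))
})
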