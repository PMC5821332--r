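test_that("ols_fit recovers exact fits and degenerate cases", {
  x <- 1:10
  y <- 3 + 2 * x
  fit <- ols_fit(cbind(1, x), y)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients), c(3, 2), tolerance = 1e-10)

  # response orthogonal to the centered predictor: zero slope, zero R2
  xc <- c(-1, 0, 1, -1, 0, 1)
  y0 <- c(1, -2, 1, 1, -2, 1)   # orthogonal to xc
  fit0 <- ols_fit(cbind(1, xc), y0)
  expect_equal(unname(fit0$coefficients[2]), 0, tolerance = 1e-12)
  expect_equal(fit0$r2, 0, tolerance = 1e-12)
})

test_that("ols_fit agrees with the normal-equations oracle on a hand dataset", {
  X <- cbind(1,
             c(1.2, 3.4, 2.2, 5.1, 4.4),
             c(0.3, 1.1, 2.9, 0.7, 1.8))
  y <- c(2.0, 4.5, 3.3, 7.1, 6.2)
  fit <- ols_fit(X, y)
  oracle <- oracle_ols(X, y)
  expect_equal(unname(fit$coefficients), unname(oracle$coefficients),
               tolerance = 1e-10)
  expect_equal(fit$r2, oracle$r2, tolerance = 1e-10)
})

test_that("ols_fit refuses rank-deficient or intercept-free designs", {
  x <- rnorm(10)
  expect_error(ols_fit(cbind(1, x, 2 * x), rnorm(10)), "rank-deficient")
  expect_error(ols_fit(cbind(x, x^2), rnorm(10)), "intercept")
  expect_error(ols_fit(cbind(1, x), rnorm(9)), "different lengths")
  expect_error(ols_fit(cbind(1, matrix(rnorm(30), 3)), rnorm(3)),
               "more observations")
})

test_that("weighted least squares reduces to lm(weights =)", {
  set.seed(41)
  x <- rnorm(20); y <- 1 + 2 * x + rnorm(20); w <- runif(20, 0.5, 3)
  fit <- ols_fit(cbind(1, x), y, weights = w)
  ref <- lm(y ~ x, weights = w)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-10)
  expect_equal(fit$r2, summary(ref)$r.squared, tolerance = 1e-10)
})

test_that("hierarchical R2 change: exact and degenerate cases", {
  set.seed(42)
  x1 <- rnorm(30); x2 <- rnorm(30)
  y <- 2 * x1 + 3 * x2
  fit <- hierarchical_r2_change(y, x1, x2)
  expect_equal(fit$r2_total, 1, tolerance = 1e-12)
  expect_gte(fit$delta_r2, 0)

  # block 2 duplicating block 1: no new information
  dup <- hierarchical_r2_change(2 * x1 + rnorm(30), x1, x1)
  expect_equal(dup$delta_r2, 0)
  expect_equal(dup$f_change, 0)
})

test_that("hierarchical R2 change matches the sum-of-squares oracle on a hand dataset", {
  y <- c(1.2, 2.3, 2.9, 4.1, 4.8, 6.3)
  x1 <- c(1, 2, 3, 4, 5, 6)
  x2 <- c(2.2, 1.1, 3.3, 2.0, 4.9, 3.1)
  fit <- hierarchical_r2_change(y, x1, x2)
  oracle <- oracle_r2_change(y, x1, x2)
  expect_equal(fit$r2_block1, oracle$r2_block1, tolerance = 1e-10)
  expect_equal(fit$r2_total, oracle$r2_total, tolerance = 1e-10)
  expect_equal(fit$delta_r2, oracle$delta_r2, tolerance = 1e-10)
  expect_equal(fit$f_change, oracle$f_change, tolerance = 1e-10)
  expect_equal(fit$p_change, oracle$p_change, tolerance = 1e-10)
  expect_equal(fit$delta_r2, fit$r2_total - fit$r2_block1, tolerance = 1e-12)
})

test_that("F-change p-value agrees with anova() on nested lm fits", {
  set.seed(43)
  x1 <- rnorm(40); x2 <- rnorm(40)
  y <- 1 + 0.5 * x1 + 0.3 * x2 + rnorm(40)
  fit <- hierarchical_r2_change(y, x1, x2)
  a <- anova(lm(y ~ x1), lm(y ~ x1 + x2))
  expect_equal(fit$f_change, a$F[2], tolerance = 1e-10)
  expect_equal(fit$p_change, a$`Pr(>F)`[2], tolerance = 1e-10)
})

test_that("adding predictors never reduces R2", {
  set.seed(44)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    x1 <- matrix(rnorm(n * 2), n)
    x2 <- matrix(rnorm(n), n)
    y <- rnorm(n)
    fit <- hierarchical_r2_change(y, x1, x2)
    expect_lte(fit$r2_block1, fit$r2_total + 1e-12)
    expect_gte(fit$delta_r2, -1e-12)
    expect_gte(fit$f_change, 0)
  }
})

test_that("tidy and glance views expose the fit in broom shape", {
  set.seed(45)
  fit <- hierarchical_r2_change(rnorm(20), rnorm(20), rnorm(20),
                                outcome = "ptb")
  td <- tidy(fit)
  expect_identical(names(td), c("term", "estimate"))
  expect_equal(nrow(td), 3)
  gl <- glance(fit)
  expect_identical(gl$outcome, "ptb")
  expect_equal(gl$delta_r2, fit$delta_r2)
  expect_true(gl$sig_flag %in% c("ns", "p<0.05", "p<0.01"))
})

test_that("residual diagnostics: OLS orthogonality and normality flags", {
  set.seed(46)
  x1 <- rnorm(100); x2 <- rnorm(100)
  fit <- hierarchical_r2_change(1 + x1 - x2 + rnorm(100), x1, x2)
  d <- residual_diagnostics(fit)
  expect_lt(abs(d$cor_fitted_resid), 1e-10)
  expect_true(d$linear_ok)

  normal_pass <- 0; cauchy_fail <- 0
  for (s in 1:100) {
    set.seed(s)
    x <- rnorm(200); z <- rnorm(200)
    fn <- hierarchical_r2_change(1 + x + 0.5 * z + rnorm(200), x, z)
    if (residual_diagnostics(fn)$normal_ok) normal_pass <- normal_pass + 1
    fc <- hierarchical_r2_change(1 + x + 0.5 * z + rcauchy(200), x, z)
    if (!residual_diagnostics(fc)$normal_ok) cauchy_fail <- cauchy_fail + 1
  }
  expect_gte(normal_pass, 90)
  expect_gte(cauchy_fail, 90)
})

test_that("hierarchical_table reproduces the block-entry table shape over outcomes", {
  study <- simulate_study(sim_config(seed = 47))
  tab <- hierarchical_table(study$scores, study$records)
  expect_equal(tab$outcome,
               c("neonatal_mortality", "cesarean", "ptb", "lbw", "bf_birth"))
  expect_true(all(tab$r2_block1 >= 0 & tab$r2_total <= 1))
  expect_equal(tab$delta_r2, tab$r2_total - tab$r2_block1, tolerance = 1e-12)
  # standardizing predictors leaves the variance partition unchanged
  tab_z <- hierarchical_table(study$scores, study$records, standardize = TRUE)
  expect_equal(tab_z$delta_r2, tab$delta_r2, tolerance = 1e-10)
})
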