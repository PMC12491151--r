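test_that("Wald ratio: point estimate, delta-method se, sign, errors", {
  w <- wald_ratio(1, 0.1, 0.3, 0.1)
  expect_equal(w$beta_mr, 0.3)
  expect_equal(w$se_mr, 0.1)
  w <- wald_ratio(0.5, 0.05, 0.25, 0.1)
  expect_equal(w$beta_mr, 0.5)
  expect_equal(w$se_mr, 0.2)
  expect_equal(wald_ratio(-0.5, 0.05, 0.25, 0.1)$beta_mr, -0.5)
  expect_error(wald_ratio(0, 0.1, 0.3, 0.1), "zero")
  # second-order form adds the exposure-noise term
  w2 <- wald_ratio(0.5, 0.05, 0.25, 0.1, second_order = TRUE)
  expect_equal(w2$se_mr, sqrt(0.1^2 / 0.25 + 0.25^2 * 0.05^2 / 0.5^4))
  expect_gt(w2$se_mr, 0.2)
  expect_equal(w$odds_ratio, exp(0.5))
})

test_that("IVW equals the weighted-least-squares oracle", {
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(2:12, 1)
    h <- make_harmonized(beta_x = runif(n, 0.05, 0.5),
                         se_x = runif(n, 0.01, 0.05),
                         beta_y = rnorm(n, 0.1, 0.05),
                         se_y = runif(n, 0.01, 0.08))
    m <- mr_ivw(h, mode = "fixed")
    fit <- lm(beta_y ~ 0 + beta_x, data = h, weights = 1 / h$se_y^2)
    expect_equal(m$beta_mr, unname(coef(fit)), tolerance = 1e-10)
    sigma <- summary(fit)$sigma
    expect_equal(m$se_mr,
                 unname(sqrt(diag(vcov(fit)))) / sigma, tolerance = 1e-10)
  }
})

test_that("IVW with one variant reduces to the Wald ratio; equal duplicate
           estimates shrink the fixed se by sqrt(2)", {
  h1 <- make_harmonized(0.4, 0.02, 0.12, 0.05)
  m1 <- mr_ivw(h1)
  w1 <- wald_ratio(0.4, 0.02, 0.12, 0.05)
  expect_equal(m1$beta_mr, w1$beta_mr)
  expect_equal(m1$se_mr, w1$se_mr)
  expect_equal(m1$method, "wald")

  h2 <- make_harmonized(c(0.4, 0.4), c(0.02, 0.02), c(0.12, 0.12),
                        c(0.05, 0.05))
  m2 <- mr_ivw(h2, mode = "fixed")
  expect_equal(m2$beta_mr, w1$beta_mr)
  expect_equal(m2$se_mr, w1$se_mr / sqrt(2))
})

test_that("multiplicative random-effects se never undercuts the fixed se
           and estimates are sign-flip invariant", {
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(3:10, 1)
    h <- make_harmonized(runif(n, 0.05, 0.5), runif(n, 0.01, 0.05),
                         rnorm(n, 0.1, 0.1), runif(n, 0.01, 0.08))
    expect_gte(mr_ivw(h, mode = "multiplicative_random")$se_mr,
               mr_ivw(h, mode = "fixed")$se_mr)
    flip <- sample(c(-1, 1), n, replace = TRUE)
    hf <- h
    hf$beta_x <- h$beta_x * flip
    hf$beta_y <- h$beta_y * flip
    expect_equal(mr_ivw(hf)$beta_mr, mr_ivw(h)$beta_mr, tolerance = 1e-12)
  }
})

test_that("Cochran's Q matches the hand-computed two-variant case and is
           zero for identical ratios", {
  h <- make_harmonized(c(1, 1), c(0.01, 0.01), c(0.1, 0.3), c(0.1, 0.1))
  q <- cochran_q(h)
  expect_equal(q$q_stat, 2)  # w = 100 each, ratios 0.1/0.3 about 0.2
  expect_equal(q$q_df, 1L)
  expect_equal(q$q_pval, pchisq(2, 1, lower.tail = FALSE))

  heq <- make_harmonized(c(0.2, 0.4), c(0.01, 0.01), c(0.1, 0.2),
                         c(0.05, 0.05))
  expect_equal(cochran_q(heq)$q_stat, 0, tolerance = 1e-12)
  expect_equal(cochran_q(heq)$q_pval, 1)
})

test_that("the Q test has nominal type-I error under homogeneity", {
  set.seed(314)
  pvals <- vapply(seq_len(1000), function(i) {
    n <- 6
    bx <- runif(n, 0.2, 0.5)
    by <- 0.25 * bx + rnorm(n, 0, 0.04)
    cochran_q(make_harmonized(bx, 0.001, by, 0.04))$q_pval
  }, numeric(1))
  rate <- mean(pvals < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("Egger fits exactly through collinear points and recovers an
           injected constant pleiotropy", {
  bx <- c(0.1, 0.2, 0.3)
  by <- 0.04 + 0.5 * bx
  e <- mr_egger(make_harmonized(bx, 0.01, by, 0.02))
  expect_true(e$computed)
  expect_equal(e$egger_intercept, 0.04, tolerance = 1e-10)
  expect_equal(e$egger_slope, 0.5, tolerance = 1e-10)

  set.seed(2024)
  ints <- vapply(seq_len(300), function(i) {
    n <- 25
    bxx <- runif(n, 0.1, 0.5)
    byy <- 0.3 * bxx + 0.05 + rnorm(n, 0, 0.03)
    mr_egger(make_harmonized(bxx, 0.005, byy, 0.03))$egger_intercept
  }, numeric(1))
  expect_lt(abs(mean(ints) - 0.05), 3 * sd(ints) / sqrt(length(ints)))
})

test_that("Egger with fewer than three variants is flagged, not an error", {
  e <- mr_egger(make_harmonized(c(0.1, 0.2), 0.01, c(0.1, 0.1), 0.02))
  expect_false(e$computed)
  expect_true(is.na(e$egger_intercept))
})

test_that("Egger intercept is near zero without pleiotropy", {
  set.seed(55)
  zs <- vapply(seq_len(200), function(i) {
    n <- 25
    bx <- runif(n, 0.1, 0.5)
    by <- 0.3 * bx + rnorm(n, 0, 0.03)
    e <- mr_egger(make_harmonized(bx, 0.005, by, 0.03))
    e$egger_intercept / e$egger_intercept_se
  }, numeric(1))
  expect_lt(abs(mean(zs)), 3 / sqrt(length(zs)) + 0.2)
  expect_lt(abs(sd(zs) - 1), 0.25)
})

test_that("Bonferroni threshold and significance tiers follow the printed
           levels", {
  expect_equal(signif(bonferroni_threshold(3083), 3), 1.62e-5)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(20), 2.5e-3)

  expect_equal(significance_tier(1e-6), "****")
  expect_equal(significance_tier(3e-4), "***")
  expect_equal(significance_tier(2e-3), "**")
  expect_equal(significance_tier(0.02), "*")
  expect_equal(significance_tier(0.05), "ns")
  # boundaries are half-open
  expect_equal(significance_tier(5e-4), "**")
  expect_equal(significance_tier(5e-3), "*")
  expect_equal(significance_tier(2e-5, bonferroni = 2e-5), "***")
})
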