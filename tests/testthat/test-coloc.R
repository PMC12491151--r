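test_that("log ABF matches the closed form and its limits", {
  # z = 0, se = 1, prior sd 0.15: 0.5 * log(1 / 1.0225)
  expect_equal(log_abf(0, 1, 0.15), 0.5 * log(1 / 1.0225),
               tolerance = 1e-10)
  expect_equal(log_abf(0, 1, 0.15), -0.01113, tolerance = 1e-3)
  # vanishing prior sd: no evidence either way
  expect_equal(log_abf(3, 1, 0), 0)
  # monotone in |z| at fixed se
  l <- log_abf(seq(0, 5, by = 0.5), 1, 0.15)
  expect_true(all(diff(l) > 0))
  expect_error(log_abf(1, 0, 0.15), "positive")
})

test_that("priors validate", {
  expect_error(coloc_priors(p12 = 1e-3), "p12")
  expect_error(coloc_priors(prior_sd_quant = 0), "positive")
  pr <- coloc_priors()
  expect_equal(pr$p1, 1e-4)
  expect_equal(pr$p12, 1e-5)
})

test_that("posteriors equal the brute-force configuration enumeration", {
  pr <- coloc_priors()
  set.seed(41)
  for (rep in 1:12) {
    n <- sample(1:20, 1)
    bx <- rnorm(n, 0, 0.1)
    by <- rnorm(n, 0, 0.1)
    h <- make_harmonized(bx, 0.03, by, 0.03)
    got <- coloc_abf(h, priors = pr)
    want <- coloc_enum_oracle(log_abf(bx, 0.03, pr$prior_sd_quant),
                              log_abf(by, 0.03, pr$prior_sd_quant),
                              pr$p1, pr$p2, pr$p12)
    expect_equal(c(got$ph0, got$ph1, got$ph2, got$ph3, got$ph4),
                 unname(want), tolerance = 1e-9)
    expect_equal(got$ph0 + got$ph1 + got$ph2 + got$ph3 + got$ph4, 1,
                 tolerance = 1e-9)
  }
})

test_that("a single null variant reproduces the five-term hand
           normalization", {
  pr <- coloc_priors()
  h <- make_harmonized(0, 1, 0, 1)
  got <- coloc_abf(h, priors = pr)
  a <- exp(log_abf(0, 1, pr$prior_sd_quant))
  w <- c(1, pr$p1 * a, pr$p2 * a, 0, pr$p12 * a * a)
  expect_equal(c(got$ph0, got$ph1, got$ph2, got$ph3, got$ph4), w / sum(w),
               tolerance = 1e-12)
  expect_equal(got$n_snps, 1)
})

test_that("posteriors are invariant to variant order and joint sign
           flips", {
  set.seed(43)
  n <- 15
  h <- make_harmonized(rnorm(n, 0.1, 0.1), 0.02, rnorm(n, 0.05, 0.1), 0.02)
  a <- coloc_abf(h)
  hp <- h[sample(n), ]
  class(hp) <- class(h)
  b <- coloc_abf(hp)
  expect_equal(a$ph4, b$ph4, tolerance = 1e-12)
  hs <- h
  flip <- sample(c(-1, 1), n, replace = TRUE)
  hs$beta_x <- h$beta_x * flip
  hs$beta_y <- h$beta_y * flip
  d <- coloc_abf(hs)
  expect_equal(c(a$ph0, a$ph3, a$ph4), c(d$ph0, d$ph3, d$ph4),
               tolerance = 1e-12)
})

test_that("classification thresholds follow the strong/medium rules", {
  expect_equal(classify_coloc(0.80), "strong")
  expect_equal(classify_coloc(0.60), "medium")
  expect_equal(classify_coloc(0.10), "none")
  expect_equal(classify_coloc(0.75), "medium")
  expect_equal(classify_coloc(0.50), "none")
})

test_that("shared-signal regions colocalize and distinct-signal regions
           do not (moderate replicates)", {
  ph4 <- vapply(1:40, function(i) {
    p <- simulate_pair(sim_config(seed = 80000 + i))
    coloc_abf(p$exposure, p$outcome)$ph4
  }, numeric(1))
  expect_gt(median(ph4), 0.75)

  r <- vapply(1:40, function(i) {
    p <- simulate_pair(sim_config(scenario = "H3",
                                  causal_index_exposure = 10,
                                  causal_index_outcome = 40,
                                  seed = 90000 + i))
    cr <- coloc_abf(p$exposure, p$outcome)
    c(cr$ph3, cr$ph4)
  }, numeric(2))
  expect_gt(median(r[1, ]), median(r[2, ]))

  modal <- vapply(1:25, function(i) {
    p <- simulate_pair(sim_config(scenario = "H0", seed = 95000 + i))
    cr <- coloc_abf(p$exposure, p$outcome)
    which.max(c(cr$ph0, cr$ph1, cr$ph2, cr$ph3, cr$ph4))
  }, numeric(1))
  expect_equal(unique(modal), 1)
})

test_that("trait types select the matching effect-size prior", {
  p <- simulate_pair(sim_config(seed = 66, outcome_trait_type = "binary"))
  r <- coloc_abf(p$exposure, p$outcome)
  h <- harmonized_retained(harmonize_pair(as.data.frame(p$exposure),
                                          as.data.frame(p$outcome)))
  manual <- coloc_abf(h, trait_type_x = "quantitative",
                      trait_type_y = "binary")
  expect_equal(r$ph4, manual$ph4, tolerance = 1e-12)
  different <- coloc_abf(h)  # both quantitative: different prior sd
  expect_false(isTRUE(all.equal(r$ph4, different$ph4, tolerance = 1e-6)))
})
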