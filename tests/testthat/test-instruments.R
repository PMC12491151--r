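test_that("the association p filter is strict at the boundary", {
  df <- tiny_sumstats_df(3)
  df$pval <- c(9.9e-6, 1e-5, 0.5)
  out <- filter_pval(df, 1e-5)
  expect_equal(out$variant_id, "rs1")
  expect_equal(nrow(filter_pval(df[0, ], 1e-5)), 0)
})

test_that("the MAF filter removes frequencies at or below the cutoff", {
  df <- tiny_sumstats_df(4)
  df$eaf <- c(0.995, 0.011, 0.5, 0.01)
  out <- filter_maf(df, 0.01)
  expect_setequal(out$variant_id, c("rs2", "rs3"))
})

test_that("the cis filter is inclusive at the window edge and
           chromosome-name tolerant", {
  loc <- gene_locus("G", "chr1", 2e6, 2.1e6)
  df <- tiny_sumstats_df(4)
  df$chrom <- c("1", "1", "2", "chr1")
  df$pos <- c(2e6 - 1e6, 2e6 - 1e6 - 1, 2.05e6, 2.1e6 + 1e6)
  out <- filter_cis(df, loc, window_bp = 1e6)
  expect_setequal(out$variant_id, c("rs1", "rs4"))
})

test_that("F statistic is the squared z and gates at the threshold", {
  expect_equal(compute_f_stat(0.1, 0.02), 25)
  expect_equal(compute_f_stat(0, 0.1), 0)
  df <- tiny_sumstats_df(2)
  df$beta <- c(0.1, 0.0999499)
  df$se <- c(1 / sqrt(1000), 0.0316227766)  # F = 10, F = 9.99
  f <- compute_f_stat(df$beta, df$se)
  expect_true(f[1] >= 10)
  expect_lt(f[2], 10)
  loc <- gene_locus("G", "1", 1, 1e6)
  df$pval <- 1e-8
  iv <- select_instruments(df, loc, simulate_ld(2, 0, df$variant_id))
  expect_false("rs2" %in% iv$instruments$variant_id)

  # variance-explained form agrees in order of magnitude
  f_r2 <- compute_f_stat(0.1, 0.02, method = "r2", eaf = 0.3, n = 10000)
  expect_gt(f_r2, 10)
})

test_that("greedy clumping keeps the most significant of a correlated
           pair and all mutually independent variants", {
  df <- tiny_sumstats_df(2)
  df$pval <- c(1e-6, 1e-8)
  r <- matrix(c(1, sqrt(0.5), sqrt(0.5), 1), 2)
  ld <- ld_matrix(r, df$variant_id)
  out <- greedy_clump(df, ld, r2_threshold = 0.001, window_kb = 10000)
  expect_equal(out$variant_id, "rs2")

  ld0 <- simulate_ld(3, 0, paste0("rs", 1:3))
  out0 <- greedy_clump(tiny_sumstats_df(3), ld0)
  expect_equal(nrow(out0), 3)
})

test_that("clumping matches the brute-force recursion on random
           instances", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:8, 1)
    df <- tiny_sumstats_df(n)
    df$pos <- sort(sample.int(2e7, n))
    df$pval <- runif(n, 1e-10, 1e-4)
    ld <- simulate_ld(n, runif(1, 0, 0.95), df$variant_id)
    thr <- sample(c(0.001, 0.1, 0.5), 1)
    win_kb <- sample(c(100, 5000, 10000), 1)
    got <- greedy_clump(df, ld, r2_threshold = thr, window_kb = win_kb)
    want <- clump_oracle(df$variant_id, df$pos, df$pval,
                         unclass(ld)^2, thr, win_kb * 1000)
    expect_setequal(got$variant_id, want)
  }
})

test_that("clumping is invariant to input row order", {
  set.seed(99)
  df <- tiny_sumstats_df(8)
  df$pval <- runif(8, 1e-9, 1e-5)
  ld <- simulate_ld(8, 0.8, df$variant_id)
  a <- greedy_clump(df, ld)
  b <- greedy_clump(df[sample(8), ], ld)
  expect_identical(a$variant_id, b$variant_id)
})

test_that("variants missing from the LD reference are dropped with a
           warning, or raise with missing_ld = 'error'", {
  df <- tiny_sumstats_df(3)
  ld <- simulate_ld(2, 0, df$variant_id[1:2])
  expect_warning(out <- greedy_clump(df, ld), "missing")
  expect_setequal(out$variant_id, c("rs1", "rs2"))
  expect_error(greedy_clump(df, ld, missing_ld = "error"), "missing")
})

test_that("marginal filters commute", {
  set.seed(5)
  df <- tiny_sumstats_df(30)
  df$pval <- runif(30, 0, 1e-4)
  df$eaf <- runif(30, 0.001, 0.999)
  df$pos <- sample.int(5e6, 30)
  loc <- gene_locus("G", "1", 2e6, 2.2e6)
  perms <- list(
    function(d) filter_cis(filter_maf(filter_pval(d)), loc),
    function(d) filter_pval(filter_cis(filter_maf(d), loc)),
    function(d) filter_maf(filter_pval(filter_cis(d, loc))))
  res <- lapply(perms, function(f) sort(f(df)$variant_id))
  expect_identical(res[[1]], res[[2]])
  expect_identical(res[[1]], res[[3]])
})

test_that("selection composes the filters with provenance flags and is
           idempotent", {
  p <- simulate_pair(sim_config(seed = 17))
  iv <- select_instruments(p$exposure, p$locus, p$ld)
  expect_true(all(c("passed_p", "passed_maf", "passed_cis", "clump_kept",
                    "passed_f") %in% names(iv$provenance)))
  expect_true(all(iv$instruments$pval < 1e-5))
  expect_true(all(iv$instruments$f_stat >= 10))
  expect_true(all(pmin(iv$instruments$eaf, 1 - iv$instruments$eaf) > 0.01))

  # all variants failing p => empty set, all flags false
  dead <- as.data.frame(p$exposure)
  dead$pval <- 0.5
  dead$beta <- 0.0001
  iv0 <- select_instruments(summary_stats(dead), p$locus, p$ld)
  expect_equal(nrow(iv0$instruments), 0)
  expect_false(any(iv0$provenance$passed_p))
  expect_false(any(iv0$provenance$clump_kept))

  # idempotent on its own output
  iv2 <- select_instruments(iv$instruments, p$locus, p$ld)
  expect_equal(iv2$instruments$variant_id, iv$instruments$variant_id)
})

test_that("the causal variant is retained in nearly all replicates under
           the default study conditions", {
  hits <- vapply(seq_len(150), function(i) {
    p <- simulate_pair(sim_config(seed = 60000 + i))
    iv <- select_instruments(p$exposure, p$locus, p$ld)
    p$truth$causal_id_exposure %in% iv$instruments$variant_id
  }, logical(1))
  # >= 95% with a two-binomial-SE Monte-Carlo allowance at 150 replicates
  expect_gte(mean(hits), 0.95 - 2 * sqrt(0.95 * 0.05 / 150))
})
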