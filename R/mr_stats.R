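#' Bonferroni-corrected significance threshold
#' @param n_tests Number of tests (e.g. proteins scanned).
#' @param alpha Family-wise error rate.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(n_tests, alpha = 0.05) {
  stopifnot(n_tests >= 1, alpha > 0, alpha < 1)
  alpha / n_tests
}

#' Star tier for an MR p-value
#'
#' Four half-open significance levels, from the Bonferroni bound down to
#' nominal: `p < bonferroni` gives `"****"`, `[bonferroni, 5e-4)` gives
#' `"***"`, `[5e-4, 5e-3)` gives `"**"`, `[5e-3, 0.05)` gives `"*"`, and
#' anything at or above 0.05 is `"ns"`.
#'
#' @param pval Numeric vector of p-values.
#' @param bonferroni Level-1 boundary; default 0.05 over 3,083 proteins.
#' @return Character vector of tiers.
#' @export
significance_tier <- function(pval, bonferroni = 0.05 / 3083) {
  out <- rep("ns", length(pval))
  out[pval < 0.05] <- "*"
  out[pval < 5e-3] <- "**"
  out[pval < 5e-4] <- "***"
  out[pval < bonferroni] <- "****"
  out[is.na(pval)] <- NA_character_
  out
}

.mr_result <- function(method, n_snp, beta_mr, se_mr,
                       protein_id = NA_character_,
                       outcome_id = NA_character_,
                       bonferroni = 0.05 / 3083, pval = NULL) {
  if (is.null(pval)) pval <- 2 * stats::pnorm(-abs(beta_mr / se_mr))
  structure(list(protein_id = protein_id, outcome_id = outcome_id,
                 method = method, n_snp = n_snp,
                 beta_mr = beta_mr, se_mr = se_mr, pval = pval,
                 odds_ratio = exp(beta_mr),
                 tier = significance_tier(pval, bonferroni)),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf(
    "MR (%s, %d SNP%s): beta = %.4g (se %.4g), OR = %.4g, p = %.3g [%s]\n",
    x$method, x$n_snp, if (x$n_snp == 1) "" else "s",
    x$beta_mr, x$se_mr, x$odds_ratio, x$pval, x$tier))
  invisible(x)
}

#' Wald-ratio causal estimate from a single instrument
#'
#' `beta_mr = beta_y / beta_x`. The default standard error is the
#' first-order delta method, `se_y / |beta_x|`, which ignores exposure
#' uncertainty (the usual two-sample default for strong instruments); the
#' second-order form adds the `se_x` term.
#'
#' @param beta_x,se_x Exposure effect and standard error.
#' @param beta_y,se_y Outcome effect and standard error.
#' @param second_order Use the second-order delta-method standard error.
#' @param ... Passed to the result constructor (`protein_id`,
#'   `outcome_id`, `bonferroni`).
#' @return An `mr_result`.
#' @export
wald_ratio <- function(beta_x, se_x, beta_y, se_y, second_order = FALSE,
                       ...) {
  if (!is.finite(beta_x) || beta_x == 0) {
    stop("Wald ratio undefined: exposure beta is zero")
  }
  beta_mr <- beta_y / beta_x
  se_mr <- if (second_order) {
    sqrt(se_y^2 / beta_x^2 + beta_y^2 * se_x^2 / beta_x^4)
  } else {
    se_y / abs(beta_x)
  }
  .mr_result("wald", 1L, beta_mr, se_mr, ...)
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines per-variant Wald ratios `b_j = beta_y_j / beta_x_j` with
#' weights `w_j = beta_x_j^2 / se_y_j^2`; algebraically the weighted
#' regression of `beta_y` on `beta_x` through the origin with weights
#' `1 / se_y^2`. The default multiplicative random-effects mode scales the
#' fixed-effect standard error by `max(1, sqrt(Q / (n_snp - 1)))`, so it
#' never undercuts the fixed-effect one. With a single retained variant
#' the estimate reduces to [wald_ratio()].
#'
#' @param h A `harmonized` table (only retained rows are used).
#' @param mode `"multiplicative_random"` (default) or `"fixed"`.
#' @param second_order Delta-method order for the single-variant
#'   (Wald-ratio) case; the second-order form accounts for exposure-side
#'   uncertainty and keeps interval coverage nominal when the causal
#'   effect is nonzero.
#' @param ... Passed to the result constructor.
#' @return An `mr_result` with an extra `q_stat` field (Cochran's Q about
#'   the IVW estimate).
#' @export
mr_ivw <- function(h, mode = c("multiplicative_random", "fixed"),
                   second_order = FALSE, ...) {
  mode <- match.arg(mode)
  d <- harmonized_retained(h)
  if (nrow(d) == 0) stop("no retained variants for IVW")
  if (any(d$beta_x == 0)) stop("IVW undefined: zero exposure beta")
  if (nrow(d) == 1) {
    return(wald_ratio(d$beta_x, d$se_x, d$beta_y, d$se_y,
                      second_order = second_order, ...))
  }
  w <- d$beta_x^2 / d$se_y^2
  if (!all(is.finite(w)) || sum(w) <= 0) {
    stop("IVW weights are zero or non-finite")
  }
  b <- d$beta_y / d$beta_x
  beta_mr <- sum(w * b) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  q <- sum(w * (b - beta_mr)^2)
  se_mr <- if (mode == "multiplicative_random") {
    se_fixed * max(1, sqrt(q / (nrow(d) - 1)))
  } else {
    se_fixed
  }
  out <- .mr_result("ivw", nrow(d), beta_mr, se_mr, ...)
  out$q_stat <- q
  out
}

#' Cochran's Q heterogeneity test about the IVW estimate
#'
#' `Q = sum_j w_j (b_j - beta_ivw)^2` with the IVW weights; under
#' homogeneity Q is chi-squared with `n_snp - 1` degrees of freedom.
#'
#' @param h A `harmonized` table.
#' @param beta_ivw Pooled estimate; recomputed (fixed-effect IVW) if
#'   omitted.
#' @return List with `q_stat`, `q_df`, `q_pval`, `n_snp`.
#' @export
cochran_q <- function(h, beta_ivw = NULL) {
  d <- harmonized_retained(h)
  if (nrow(d) < 2) {
    return(list(q_stat = NA_real_, q_df = NA_integer_, q_pval = NA_real_,
                n_snp = nrow(d)))
  }
  w <- d$beta_x^2 / d$se_y^2
  b <- d$beta_y / d$beta_x
  if (is.null(beta_ivw)) beta_ivw <- sum(w * b) / sum(w)
  q <- sum(w * (b - beta_ivw)^2)
  df <- nrow(d) - 1L
  list(q_stat = q, q_df = df,
       q_pval = stats::pchisq(q, df, lower.tail = FALSE),
       n_snp = nrow(d))
}

#' MR-Egger regression: directional-pleiotropy intercept and causal slope
#'
#' Weighted regression `beta_y = alpha + beta * beta_x` with weights
#' `1 / se_y^2`, after orienting every variant so `beta_x >= 0` (the
#' InSIDE convention). A nonzero intercept `alpha` indicates directional
#' horizontal pleiotropy. Standard errors use the multiplicative
#' random-effects scale `max(1, sigma)`; p-values are t-based with
#' `n_snp - 2` degrees of freedom. Requires at least 3 variants; with
#' fewer the result is flagged not-computed rather than raising an error.
#'
#' @param h A `harmonized` table.
#' @return List with `computed`, `n_snp`, `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_pval`, `egger_slope`,
#'   `egger_slope_se`, `egger_slope_pval`.
#' @export
mr_egger <- function(h) {
  d <- harmonized_retained(h)
  n <- nrow(d)
  empty <- list(computed = FALSE, n_snp = n,
                egger_intercept = NA_real_, egger_intercept_se = NA_real_,
                egger_intercept_pval = NA_real_, egger_slope = NA_real_,
                egger_slope_se = NA_real_, egger_slope_pval = NA_real_)
  if (n < 3) return(empty)
  flip <- sign(d$beta_x)
  flip[flip == 0] <- 1
  bx <- d$beta_x * flip
  by <- d$beta_y * flip
  w <- 1 / d$se_y^2

  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  coef <- solve(XtWX, crossprod(X, w * by))
  resid <- by - X %*% coef
  sigma2 <- sum(w * resid^2) / (n - 2)
  vc <- solve(XtWX) * max(1, sigma2)
  se <- sqrt(diag(vc))
  tval <- as.vector(coef) / se
  pval <- 2 * stats::pt(-abs(tval), df = n - 2)
  list(computed = TRUE, n_snp = n,
       egger_intercept = coef[1], egger_intercept_se = se[1],
       egger_intercept_pval = pval[1],
       egger_slope = coef[2], egger_slope_se = se[2],
       egger_slope_pval = pval[2])
}
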