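#' Priors for Bayesian colocalization
#'
#' Per-variant prior probabilities of association with trait 1 only
#' (`p1`), trait 2 only (`p2`), and both traits (`p12`), plus the
#' effect-size prior standard deviations used in the approximate Bayes
#' factor: 0.15 for quantitative traits (SD units) and 0.2 for binary
#' traits (log-odds units). These are the canonical defaults of the
#' single-causal-variant enumeration framework.
#'
#' @param p1,p2,p12 Per-variant priors; requires `0 < p12 <= min(p1, p2)`.
#' @param prior_sd_quant,prior_sd_binary Effect-size prior SDs.
#' @return A `coloc_priors` list.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         prior_sd_quant = 0.15, prior_sd_binary = 0.2) {
  if (p1 <= 0 || p2 <= 0 || p12 <= 0 || p12 > min(p1, p2)) {
    stop("priors must satisfy 0 < p12 <= min(p1, p2)")
  }
  if (prior_sd_quant <= 0 || prior_sd_binary <= 0) {
    stop("prior sds must be positive")
  }
  structure(list(p1 = p1, p2 = p2, p12 = p12,
                 prior_sd_quant = prior_sd_quant,
                 prior_sd_binary = prior_sd_binary),
            class = "coloc_priors")
}

#' Log approximate Bayes factor for a single association
#'
#' Wakefield's approximation: with `z = beta/se` and shrinkage
#' `r = prior_sd^2 / (se^2 + prior_sd^2)`,
#' `log ABF = 0.5 log(1 - r) + z^2 r / 2`.
#'
#' @param beta,se Effect estimate and standard error (`se > 0`).
#' @param prior_sd Prior standard deviation of the true effect.
#' @return Numeric vector of log Bayes factors (association vs null).
#' @export
log_abf <- function(beta, se, prior_sd) {
  if (any(se <= 0)) stop("se must be positive")
  if (prior_sd < 0) stop("prior_sd must be non-negative")
  z <- beta / se
  r <- prior_sd^2 / (se^2 + prior_sd^2)
  0.5 * log1p(-r) + z^2 * r / 2
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Classify a colocalization posterior
#' @param ph4 Posterior probability of a shared causal variant.
#' @return `"strong"` if `ph4 > 0.75`, `"medium"` if `0.5 < ph4 <= 0.75`,
#'   else `"none"`.
#' @export
classify_coloc <- function(ph4) {
  ifelse(ph4 > 0.75, "strong", ifelse(ph4 > 0.5, "medium", "none"))
}

#' Bayesian colocalization of two association signals in a region
#'
#' Assumes at most one causal variant per trait in the region and
#' enumerates the five hypotheses — H0 neither trait associated, H1 trait
#' 1 only, H2 trait 2 only, H3 both but at distinct variants, H4 a shared
#' causal variant. With per-variant log Bayes factors `l1_i`, `l2_i` and
#' `S1 = sum_i exp(l1_i)`, `S2 = sum_i exp(l2_i)`,
#' `S12 = sum_i exp(l1_i + l2_i)`, the unnormalized hypothesis weights are
#' `1`, `p1 S1`, `p2 S2`, `p1 p2 (S1 S2 - S12)`, and `p12 S12`. All
#' accumulation happens in log space via log-sum-exp; if floating-point
#' cancellation drives the H3 sum negative it is clamped to zero with a
#' warning.
#'
#' @param region_x,region_y `summary_stats` for the two traits over the
#'   region; they are restricted to shared variants and allele-harmonized
#'   with [harmonize_pair()] first. Alternatively pass a ready
#'   `harmonized` table as `region_x` (with `region_y` omitted).
#' @param priors A [coloc_priors()] list.
#' @param trait_type_x,trait_type_y Trait types selecting the effect-size
#'   prior SD; defaulted from the `summary_stats` metadata when available.
#' @return A `coloc_result`: list with `ph0`..`ph4`, `n_snps`, `call`, and
#'   the priors used.
#' @export
coloc_abf <- function(region_x, region_y = NULL, priors = coloc_priors(),
                      trait_type_x = NULL, trait_type_y = NULL) {
  if (inherits(region_x, "harmonized")) {
    h <- harmonized_retained(region_x)
  } else {
    if (is.null(trait_type_x)) {
      trait_type_x <- attr(region_x, "trait_type") %||% "quantitative"
    }
    if (is.null(trait_type_y)) {
      trait_type_y <- attr(region_y, "trait_type") %||% "quantitative"
    }
    h <- harmonized_retained(harmonize_pair(region_x, region_y))
  }
  if (is.null(trait_type_x)) trait_type_x <- "quantitative"
  if (is.null(trait_type_y)) trait_type_y <- "quantitative"
  if (nrow(h) == 0) stop("no shared variants for colocalization")

  sd1 <- if (trait_type_x == "binary") priors$prior_sd_binary else
    priors$prior_sd_quant
  sd2 <- if (trait_type_y == "binary") priors$prior_sd_binary else
    priors$prior_sd_quant

  l1 <- log_abf(h$beta_x, h$se_x, sd1)
  l2 <- log_abf(h$beta_y, h$se_y, sd2)
  ls1 <- .logsumexp(l1)
  ls2 <- .logsumexp(l2)
  ls12 <- .logsumexp(l1 + l2)

  # H3: sum over ordered pairs i != j equals S1*S2 - S12
  a <- ls1 + ls2
  lh3 <- if (ls12 >= a) {
    if (ls12 > a + 1e-9) {
      warning("H3 sum negative after cancellation; clamped to 0")
    }
    -Inf
  } else {
    a + log1p(-exp(ls12 - a))
  }

  lw <- c(h0 = 0,
          h1 = log(priors$p1) + ls1,
          h2 = log(priors$p2) + ls2,
          h3 = log(priors$p1) + log(priors$p2) + lh3,
          h4 = log(priors$p12) + ls12)
  post <- exp(lw - .logsumexp(lw))

  structure(list(ph0 = post[["h0"]], ph1 = post[["h1"]], ph2 = post[["h2"]],
                 ph3 = post[["h3"]], ph4 = post[["h4"]],
                 n_snps = nrow(h), call = classify_coloc(post[["h4"]]),
                 priors = priors),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf(
    "coloc (%d SNPs, p1=%g p2=%g p12=%g): PH0-PH4 = %s; call = %s\n",
    x$n_snps, x$priors$p1, x$priors$p2, x$priors$p12,
    paste(sprintf("%.3f", c(x$ph0, x$ph1, x$ph2, x$ph3, x$ph4)),
          collapse = " "),
    x$call))
  invisible(x)
}
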