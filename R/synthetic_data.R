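#' Configuration for a simulated exposure/outcome region
#'
#' Defines one cis region: `n_snps` variants with AR(1) linkage
#' disequilibrium (`r[i,j] = rho^|i-j|`), a single causal variant per
#' associated trait, and GWAS sampling noise scaled by sample size and
#' allele frequency. The `scenario` follows the five colocalization
#' hypotheses: `H0` no association with either trait, `H1` exposure only,
#' `H2` outcome only, `H3` both traits causal at distinct variants, `H4` a
#' shared causal variant. Under `H4` the outcome's effect at the shared
#' variant is `theta * causal_beta + pleiotropy_beta`; under `H2`/`H3` the
#' outcome's own causal variant carries an effect of magnitude
#' `theta * causal_beta` so that both signals are comparably powered.
#'
#' @param n_snps Number of variants in the region.
#' @param rho AR(1) LD decay parameter in `[0, 1)`.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param theta True causal effect of the exposure protein on the outcome
#'   (per SD of protein; log-odds scale for binary outcomes).
#' @param causal_index_exposure,causal_index_outcome 1-based positions of
#'   the causal variants within the region; `NULL` places them at the
#'   region's midpoint.
#' @param causal_beta Per-allele effect of the causal variant on the
#'   exposure, in SD units.
#' @param pleiotropy_beta Direct variant-to-outcome effect at the shared
#'   causal variant that bypasses the exposure (directional pleiotropy).
#' @param maf_range Interval within `(0, 0.5]` from which minor-allele
#'   frequencies are drawn uniformly.
#' @param palindrome_fraction Fraction of variants assigned A/T or C/G
#'   (strand-ambiguous) allele pairs.
#' @param scenario One of `"H0"`, `"H1"`, `"H2"`, `"H3"`, `"H4"`.
#' @param outcome_trait_type `"quantitative"` or `"binary"`; binary
#'   outcomes use the case-fraction-inflated standard-error model.
#' @param outcome_case_fraction Case fraction for binary outcomes.
#' @param chrom,region_start,snp_spacing Genomic placement of the region
#'   (variant `i` sits at `region_start + (i-1) * snp_spacing`).
#' @param seed Optional integer seed; the same seed reproduces the pair
#'   exactly.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps = 50, rho = 0.9,
                       n_exposure = 50000, n_outcome = 50000,
                       theta = 0.3,
                       causal_index_exposure = NULL,
                       causal_index_outcome = NULL,
                       causal_beta = 0.3, pleiotropy_beta = 0,
                       maf_range = c(0.05, 0.5),
                       palindrome_fraction = 0.1,
                       scenario = c("H4", "H0", "H1", "H2", "H3"),
                       outcome_trait_type = c("quantitative", "binary"),
                       outcome_case_fraction = 0.1,
                       chrom = "1", region_start = 1e6, snp_spacing = 5000,
                       seed = NULL) {
  scenario <- match.arg(scenario)
  outcome_trait_type <- match.arg(outcome_trait_type)
  if (is.null(causal_index_exposure)) {
    causal_index_exposure <- ceiling(n_snps / 2)
  }
  if (is.null(causal_index_outcome)) {
    causal_index_outcome <- ceiling(n_snps / 2)
  }
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    stop("maf_range must be an interval within (0, 0.5]")
  }
  if (causal_index_exposure > n_snps || causal_index_outcome > n_snps ||
      causal_index_exposure < 1 || causal_index_outcome < 1) {
    stop("causal indices must lie in 1..n_snps")
  }
  if (palindrome_fraction < 0 || palindrome_fraction > 1) {
    stop("palindrome_fraction must lie in [0, 1]")
  }
  if (scenario == "H4" && causal_index_exposure != causal_index_outcome) {
    stop("scenario H4 requires identical causal indices for both traits")
  }
  if (scenario == "H3" && causal_index_exposure == causal_index_outcome) {
    stop("scenario H3 requires distinct causal indices")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an AR(1) linkage-disequilibrium matrix
#'
#' `r[i,j] = rho^|i-j|`: a one-parameter family that is positive definite
#' by construction for `0 <= rho < 1` and gives direct control over how
#' hard the region is to clump.
#'
#' @param n_snps Matrix dimension.
#' @param rho Decay parameter in `[0, 1)`.
#' @param variant_ids Optional ids; defaults to `snp_1..snp_n`.
#' @return An `ld_matrix`.
#' @export
simulate_ld <- function(n_snps, rho, variant_ids = NULL) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  idx <- seq_len(n_snps)
  r <- rho^abs(outer(idx, idx, "-"))
  if (is.null(variant_ids)) variant_ids <- paste0("snp_", idx)
  ld_matrix(r, variant_ids)
}

# standard error of a marginal GWAS beta for a standardized quantitative
# trait, or the case-fraction-inflated analogue on the log-odds scale
.sim_se <- function(n, maf, trait_type, case_fraction = NULL) {
  if (trait_type == "binary") {
    phi <- case_fraction
    1 / sqrt(2 * n * phi * (1 - phi) * maf * (1 - maf))
  } else {
    1 / sqrt(2 * n * maf * (1 - maf))
  }
}

.PALINDROME_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                            ncol = 2, byrow = TRUE)
.NONPAL_PAIRS <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                          "G", "A", "G", "T", "T", "C", "T", "G"),
                        ncol = 2, byrow = TRUE)

#' Simulate a paired exposure/outcome region with ground truth
#'
#' Generates GWAS summary statistics for one protein (exposure) and one
#' disease (outcome) over a shared cis region. Marginal per-variant effects
#' are the LD propagation of the sparse causal effects, applied on the
#' noncentrality scale (`E[z] = R z_causal`, i.e. per-allele effects);
#' observed betas add multivariate normal noise with covariance
#' `diag(se) %*% R %*% diag(se)`, the sampling distribution of marginal
#' GWAS estimates from a single cohort; p-values use the two-sided normal
#' approximation.
#'
#' @param config A [sim_config()].
#' @param protein_id,outcome_id Trait labels for the generated tables.
#' @param exposure_source Source label stamped on the exposure table.
#' @return A list of class `sim_pair` with elements `exposure`, `outcome`
#'   (both `summary_stats`), `ld` (`ld_matrix`), `locus` (`gene_locus`),
#'   and `truth` (list: `theta`, `scenario`, `causal_id_exposure`,
#'   `causal_id_outcome`; `theta` is the realized protein-on-outcome effect,
#'   zero except under H4).
#' @export
simulate_pair <- function(config = sim_config(), protein_id = "protein_1",
                          outcome_id = "outcome_1",
                          exposure_source = "ukbppp-like") {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_exposure < 10 || config$n_outcome < 10) {
    stop("degenerate sample size (< 10)")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_snps
  ids <- paste0(protein_id, "_snp_", seq_len(n))
  pos <- config$region_start + (seq_len(n) - 1) * config$snp_spacing

  maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
  eaf <- ifelse(stats::runif(n) < 0.5, maf, 1 - maf)

  n_pal <- round(config$palindrome_fraction * n)
  pal_idx <- if (n_pal > 0) sample.int(n, n_pal) else integer(0)
  alleles <- .NONPAL_PAIRS[sample.int(nrow(.NONPAL_PAIRS), n, replace = TRUE), ,
                           drop = FALSE]
  if (n_pal > 0) {
    alleles[pal_idx, ] <- .PALINDROME_PAIRS[
      sample.int(nrow(.PALINDROME_PAIRS), n_pal, replace = TRUE), ,
      drop = FALSE]
  }

  R <- simulate_ld(n, config$rho, variant_ids = ids)

  b_x <- numeric(n)
  g_y <- numeric(n)
  sc <- config$scenario
  if (sc %in% c("H1", "H3", "H4")) {
    b_x[config$causal_index_exposure] <- config$causal_beta
  }
  if (sc == "H4") {
    g_y[config$causal_index_exposure] <-
      config$theta * config$causal_beta + config$pleiotropy_beta
  } else if (sc %in% c("H2", "H3")) {
    g_y[config$causal_index_outcome] <- config$theta * config$causal_beta
  }
  se_x <- .sim_se(config$n_exposure, maf, "quantitative")
  se_y <- .sim_se(config$n_outcome, maf, config$outcome_trait_type,
                  config$outcome_case_fraction)

  # LD propagation on the noncentrality (z) scale: E[z_j] = r_jc * z_c,
  # the per-allele-scale analogue of marginal-effect propagation. This
  # keeps the causal variant the strongest expected signal regardless of
  # neighbours' allele frequencies, and makes the Wald ratio equal theta
  # at every variant (the se scale factors cancel between traits).
  marg_x <- se_x * as.vector(unclass(R) %*% (b_x / se_x))
  marg_y <- se_y * as.vector(unclass(R) %*% (g_y / se_y))

  L <- chol(unclass(R))  # upper triangular: t(L) %*% z ~ MVN(0, R)
  beta_x <- marg_x + se_x * as.vector(t(L) %*% stats::rnorm(n))
  beta_y <- marg_y + se_y * as.vector(t(L) %*% stats::rnorm(n))

  make_tab <- function(beta, se, trait_id, trait_type, n_samp, n_cases,
                       source_label) {
    df <- data.frame(
      variant_id = ids, chrom = config$chrom, pos = pos,
      effect_allele = alleles[, 1], other_allele = alleles[, 2],
      eaf = eaf, beta = beta, se = se,
      pval = pmax(2 * stats::pnorm(-abs(beta / se)), .Machine$double.xmin),
      n = n_samp, stringsAsFactors = FALSE)
    if (!is.null(n_cases)) df$n_cases <- n_cases
    summary_stats(df, trait_type = trait_type, trait_id = trait_id,
                  source_label = source_label)
  }
  exposure <- make_tab(beta_x, se_x, protein_id, "quantitative",
                       config$n_exposure, NULL, exposure_source)
  n_cases <- if (config$outcome_trait_type == "binary") {
    round(config$n_outcome * config$outcome_case_fraction)
  } else NULL
  outcome <- make_tab(beta_y, se_y, outcome_id, config$outcome_trait_type,
                      config$n_outcome, n_cases, "synthetic-outcome")

  center <- if (sc %in% c("H1", "H3", "H4")) {
    pos[config$causal_index_exposure]
  } else {
    pos[ceiling(n / 2)]
  }
  locus <- gene_locus(protein_id, config$chrom,
                      max(1, center - 10000), center + 10000)

  truth <- list(
    theta = if (sc == "H4") config$theta else 0,
    scenario = sc,
    causal_id_exposure = if (sc %in% c("H1", "H3", "H4")) {
      ids[config$causal_index_exposure]
    } else NA_character_,
    causal_id_outcome = if (sc == "H4") {
      ids[config$causal_index_exposure]
    } else if (sc %in% c("H2", "H3")) {
      ids[config$causal_index_outcome]
    } else NA_character_
  )

  structure(list(exposure = exposure, outcome = outcome, ld = R,
                 locus = locus, truth = truth, config = config),
            class = "sim_pair")
}

#' Simulate a multi-protein study with known ground truth
#'
#' Generates independent cis regions for `n_proteins` proteins, each paired
#' with an outcome, from a shared configuration template. Per-protein
#' scenarios and causal effects can be overridden to mix null and non-null
#' proteins; everything is reproducible from `seed`.
#'
#' @param n_proteins Number of proteins (regions).
#' @param config Template [sim_config()]; per-protein seeds are derived
#'   from `seed`, overriding `config$seed`.
#' @param seed Integer master seed.
#' @param scenarios Optional character vector (recycled) of per-protein
#'   scenarios.
#' @param thetas Optional numeric vector (recycled) of per-protein causal
#'   effects.
#' @param outcome_id Outcome label shared by all pairs.
#' @return A list of class `sim_study`: `pairs` (list of `sim_pair`) and
#'   `truth` (data frame with one row per protein).
#' @export
simulate_study <- function(n_proteins, config = sim_config(), seed = 1,
                           scenarios = NULL, thetas = NULL,
                           outcome_id = "outcome_1") {
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_proteins)
  scenarios <- if (is.null(scenarios)) rep(config$scenario, n_proteins) else
    rep_len(scenarios, n_proteins)
  thetas <- if (is.null(thetas)) rep(config$theta, n_proteins) else
    rep_len(thetas, n_proteins)
  pairs <- vector("list", n_proteins)
  pids <- sprintf("P%03d", seq_len(n_proteins))
  for (i in seq_len(n_proteins)) {
    cfg <- config
    cfg$scenario <- scenarios[i]
    cfg$theta <- thetas[i]
    cfg$seed <- sub_seeds[i]
    if (cfg$scenario == "H3" &&
        cfg$causal_index_exposure == cfg$causal_index_outcome) {
      cfg$causal_index_outcome <-
        if (cfg$causal_index_exposure > cfg$n_snps / 2) 1L else cfg$n_snps
    }
    if (cfg$scenario == "H4") {
      cfg$causal_index_outcome <- cfg$causal_index_exposure
    }
    pairs[[i]] <- simulate_pair(cfg, protein_id = pids[i],
                                outcome_id = outcome_id)
  }
  names(pairs) <- pids
  truth <- data.frame(
    protein_id = pids,
    scenario = scenarios,
    theta = vapply(pairs, function(p) p$truth$theta, numeric(1)),
    causal_id_exposure = vapply(pairs, function(p)
      p$truth$causal_id_exposure, character(1)),
    causal_id_outcome = vapply(pairs, function(p)
      p$truth$causal_id_outcome, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(pairs = pairs, truth = truth), class = "sim_study")
}
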