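#' Full run configuration for a proteome-wide scan
#'
#' Collects every threshold the scan uses, with the published defaults:
#' instrument selection at `p < 1e-5`, MAF > 0.01, cis window 1 Mb,
#' clumping at `r^2 < 0.001` within 10,000 kb, F >= 10; the
#' candidate-protein rule `p < 5e-4` gating colocalization; Bonferroni
#' family-wise alpha 0.05 (denominator = proteins actually tested in the
#' run); and the colocalization priors.
#'
#' @param p_iv,maf,cis_bp,r2,window_kb,fmin Instrument-selection
#'   thresholds, see [iv_thresholds()].
#' @param candidate_p MR p-value below which a protein-outcome pair is a
#'   candidate and is taken to colocalization.
#' @param bonferroni_alpha Family-wise error rate for the Level-1 tier.
#' @param priors [coloc_priors()] for colocalization.
#' @param palindrome_eaf_window Passed to [harmonize_pair()].
#' @param ivw_mode IVW standard-error mode, see [mr_ivw()].
#' @param wald_second_order Use the second-order delta-method standard
#'   error when a single instrument remains (default `TRUE`: cis scans
#'   frequently reduce to one instrument, and ignoring exposure-side
#'   noise there undercovers whenever the causal effect is nonzero).
#' @param seed Seed recorded with the run (the scan itself is
#'   deterministic given its inputs).
#' @return A `run_config` list.
#' @export
run_config <- function(p_iv = 1e-5, maf = 0.01, cis_bp = 1e6, r2 = 0.001,
                       window_kb = 10000, fmin = 10, candidate_p = 5e-4,
                       bonferroni_alpha = 0.05, priors = coloc_priors(),
                       palindrome_eaf_window = c(0.42, 0.58),
                       ivw_mode = "multiplicative_random",
                       wald_second_order = TRUE, seed = 1L) {
  stopifnot(candidate_p >= 0, candidate_p <= 1,
            bonferroni_alpha > 0, bonferroni_alpha < 1)
  structure(list(
    thresholds = iv_thresholds(p_threshold = p_iv, maf_threshold = maf,
                               cis_window_bp = cis_bp, r2_threshold = r2,
                               window_kb = window_kb, f_threshold = fmin),
    candidate_p = candidate_p, bonferroni_alpha = bonferroni_alpha,
    priors = priors, palindrome_eaf_window = palindrome_eaf_window,
    ivw_mode = ivw_mode, wald_second_order = wald_second_order,
    seed = as.integer(seed)),
    class = "run_config")
}

# stable fingerprint of a config, embedded in outputs for provenance
config_hash <- function(config) {
  txt <- paste(deparse(config, control = "all"), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 997)) %%
            .Machine$integer.max)
}

.scan_row_template <- function() {
  data.frame(
    protein_id = NA_character_, outcome_id = NA_character_,
    exposure_source = NA_character_, status = NA_character_,
    method = NA_character_, n_snp = NA_integer_,
    beta_mr = NA_real_, se_mr = NA_real_, pval = NA_real_,
    odds_ratio = NA_real_, tier = NA_character_,
    q_stat = NA_real_, q_df = NA_integer_, q_pval = NA_real_,
    egger_intercept = NA_real_, egger_intercept_se = NA_real_,
    egger_intercept_pval = NA_real_, egger_slope = NA_real_,
    egger_slope_se = NA_real_,
    candidate = FALSE, coloc_nsnps = NA_integer_,
    ph0 = NA_real_, ph1 = NA_real_, ph2 = NA_real_, ph3 = NA_real_,
    ph4 = NA_real_, coloc_call = NA_character_,
    druggability_tier = NA_character_, target_type = NA_character_,
    stringsAsFactors = FALSE)
}

#' Run the full protein-outcome scan
#'
#' For every (protein, outcome) pair: select cis instruments, harmonize
#' against the outcome GWAS, estimate the causal effect (Wald ratio for a
#' single instrument, IVW otherwise), run Cochran's Q and MR-Egger
#' sensitivity analyses, assign the significance tier (Bonferroni
#' denominator = number of proteins tested in this run), run Bayesian
#' colocalization over the full cis region for candidates
#' (`p < candidate_p`), and annotate proteins with druggability tier and
#' target phase. Per-protein failures are isolated: the row is flagged in
#' `status` and the scan continues.
#'
#' @param study A `sim_study`, or a list of `sim_pair`-like lists (each
#'   with `exposure`, `outcome`, `ld`, `locus`).
#' @param config A [run_config()].
#' @param tier_table,phase_table Annotation tables for
#'   [annotate_targets()].
#' @return A `scan_result` data frame, one row per
#'   (protein, outcome, exposure source), ordered by protein then outcome
#'   id, with the config, its hash and the Bonferroni threshold as
#'   attributes.
#' @export
run_scan <- function(study, config = run_config(),
                     tier_table = load_druggability_table(),
                     phase_table = load_druggability_table()) {
  pairs <- if (inherits(study, "sim_study")) study$pairs else study
  stopifnot(length(pairs) > 0)

  n_proteins <- length(unique(vapply(
    pairs, function(p) attr(p$exposure, "trait_id"), character(1))))
  bonf <- bonferroni_threshold(n_proteins, config$bonferroni_alpha)

  rows <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    pair <- pairs[[i]]
    row <- .scan_row_template()
    row$protein_id <- attr(pair$exposure, "trait_id")
    row$outcome_id <- attr(pair$outcome, "trait_id")
    row$exposure_source <- attr(pair$exposure, "source_label")
    res <- tryCatch({
      iv <- select_instruments(pair$exposure, pair$locus, pair$ld,
                               thresholds = config$thresholds)
      if (nrow(iv$instruments) == 0) {
        row$status <- "no_instruments"
      } else {
        h <- harmonize_pair(iv$instruments, as.data.frame(pair$outcome),
                            config$palindrome_eaf_window)
        hr <- harmonized_retained(h)
        if (nrow(hr) == 0) {
          row$status <- "no_harmonized_variants"
        } else {
          mr <- mr_ivw(h, mode = config$ivw_mode,
                       second_order = config$wald_second_order,
                       bonferroni = bonf)
          row$status <- "ok"
          row$method <- mr$method
          row$n_snp <- mr$n_snp
          row$beta_mr <- mr$beta_mr
          row$se_mr <- mr$se_mr
          row$pval <- mr$pval
          row$odds_ratio <- mr$odds_ratio
          row$tier <- mr$tier
          qq <- cochran_q(h)
          row$q_stat <- qq$q_stat
          row$q_df <- qq$q_df
          row$q_pval <- qq$q_pval
          eg <- mr_egger(h)
          if (eg$computed) {
            row$egger_intercept <- eg$egger_intercept
            row$egger_intercept_se <- eg$egger_intercept_se
            row$egger_intercept_pval <- eg$egger_intercept_pval
            row$egger_slope <- eg$egger_slope
            row$egger_slope_se <- eg$egger_slope_se
          }
          row$candidate <- is.finite(mr$pval) && mr$pval < config$candidate_p
          if (row$candidate) {
            cl <- coloc_abf(pair$exposure, pair$outcome,
                            priors = config$priors)
            row$coloc_nsnps <- cl$n_snps
            row$ph0 <- cl$ph0; row$ph1 <- cl$ph1; row$ph2 <- cl$ph2
            row$ph3 <- cl$ph3; row$ph4 <- cl$ph4
            row$coloc_call <- cl$call
          }
        }
      }
      row
    }, error = function(e) {
      row$status <- paste0("error: ", conditionMessage(e))
      row
    })
    rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  ann <- annotate_targets(out$protein_id, tier_table, phase_table)
  out$druggability_tier <- ann$druggability_tier
  out$target_type <- ann$target_type
  out <- out[order(out$protein_id, out$outcome_id, out$exposure_source), ,
             drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("scan_result", "data.frame"),
            config = config, config_hash = config_hash(config),
            bonferroni = bonf, n_proteins_tested = n_proteins)
}

#' Pivot a scan result into a protein-by-outcome matrix
#'
#' Missing (protein, outcome) pairs — never scanned, failed, or (for
#' `ph4`) non-candidate — appear as the explicit missing marker `NA`,
#' never as zero.
#'
#' @param scan A `scan_result`.
#' @param statistic `"tier"`, `"beta"`, or `"ph4"`.
#' @return Matrix with proteins as rows and outcomes as columns
#'   (character for `tier`, numeric otherwise).
#' @export
export_matrix <- function(scan, statistic = c("tier", "beta", "ph4")) {
  statistic <- match.arg(statistic)
  col <- c(tier = "tier", beta = "beta_mr", ph4 = "ph4")[[statistic]]
  proteins <- sort(unique(scan$protein_id))
  outcomes <- sort(unique(scan$outcome_id))
  fill <- if (statistic == "tier") NA_character_ else NA_real_
  m <- matrix(fill, nrow = length(proteins), ncol = length(outcomes),
              dimnames = list(proteins, outcomes))
  idx <- cbind(match(scan$protein_id, proteins),
               match(scan$outcome_id, outcomes))
  m[idx] <- scan[[col]]
  m
}

#' Write the standard scan output files
#'
#' `scan_results.tsv` (all rows), `coloc_results.tsv` (candidate rows
#' with posteriors), `annotation.tsv`, and one `matrix_<stat>.tsv` per
#' requested statistic, each with the run configuration serialized into
#' `#` header lines.
#'
#' @param scan A `scan_result`.
#' @param dir Output directory (created if needed).
#' @param matrices Statistics to export as matrices.
#' @return Character vector of written paths, invisibly.
#' @export
write_scan_outputs <- function(scan, dir,
                               matrices = c("tier", "beta", "ph4")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- attr(scan, "config")
  hdr <- list(config_hash = attr(scan, "config_hash"),
              bonferroni = attr(scan, "bonferroni"),
              n_proteins_tested = attr(scan, "n_proteins_tested"),
              candidate_p = cfg$candidate_p,
              p_iv = cfg$thresholds$p_threshold,
              r2 = cfg$thresholds$r2_threshold,
              window_kb = cfg$thresholds$window_kb,
              fmin = cfg$thresholds$f_threshold,
              maf = cfg$thresholds$maf_threshold,
              cis_bp = cfg$thresholds$cis_window_bp,
              p1 = cfg$priors$p1, p2 = cfg$priors$p2, p12 = cfg$priors$p12,
              seed = cfg$seed)
  paths <- character(0)
  p <- file.path(dir, "scan_results.tsv")
  write_results(scan, p, config = hdr); paths <- c(paths, p)
  cand <- scan[scan$candidate %in% TRUE, , drop = FALSE]
  p <- file.path(dir, "coloc_results.tsv")
  write_results(cand[, c("protein_id", "outcome_id", "coloc_nsnps",
                         "ph0", "ph1", "ph2", "ph3", "ph4", "coloc_call")],
                p, config = hdr)
  paths <- c(paths, p)
  p <- file.path(dir, "annotation.tsv")
  write_results(unique(scan[, c("protein_id", "druggability_tier",
                                "target_type")]), p, config = hdr)
  paths <- c(paths, p)
  for (stat in matrices) {
    m <- export_matrix(scan, stat)
    df <- data.frame(protein_id = rownames(m), as.data.frame(m),
                     check.names = FALSE)
    p <- file.path(dir, sprintf("matrix_%s.tsv", stat))
    write_results(df, p, config = hdr)
    paths <- c(paths, p)
  }
  invisible(paths)
}
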