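#' Instrument-selection thresholds
#'
#' Defaults follow common proteome-wide cis-MR practice: genome-wide
#' suggestive association `p < 1e-5` (strict), minor-allele frequency
#' strictly above 0.01 (variants with MAF <= 0.01 are removed), a cis
#' window of gene footprint +/- 1 Mb (boundaries inclusive), greedy LD
#' clumping at `r^2 < 0.001` within 10,000 kb, and a weak-instrument
#' cutoff of F >= 10.
#'
#' @param p_threshold Association p-value cutoff (strict `<`).
#' @param maf_threshold Minor-allele-frequency cutoff (strict `>`).
#' @param cis_window_bp Cis window in bp around the gene footprint.
#' @param r2_threshold Clumping r-squared cutoff (variants with
#'   `r^2 >= r2_threshold` to a kept index variant are removed).
#' @param window_kb Clumping distance window in kilobases.
#' @param f_threshold Minimum instrument F statistic.
#' @return Named list of thresholds.
#' @export
iv_thresholds <- function(p_threshold = 1e-5, maf_threshold = 0.01,
                          cis_window_bp = 1e6, r2_threshold = 0.001,
                          window_kb = 10000, f_threshold = 10) {
  stopifnot(p_threshold > 0, p_threshold <= 1,
            maf_threshold >= 0, maf_threshold < 0.5,
            cis_window_bp >= 0, r2_threshold > 0, r2_threshold <= 1,
            window_kb > 0, f_threshold >= 0)
  list(p_threshold = p_threshold, maf_threshold = maf_threshold,
       cis_window_bp = cis_window_bp, r2_threshold = r2_threshold,
       window_kb = window_kb, f_threshold = f_threshold)
}

#' Keep variants below an association p-value threshold (strict)
#' @param table A `summary_stats` object or compatible data frame.
#' @param p_threshold Cutoff; rows with `pval < p_threshold` are retained.
#' @return The filtered table (possibly empty).
#' @export
filter_pval <- function(table, p_threshold = 1e-5) {
  table[table$pval < p_threshold, , drop = FALSE]
}

#' Remove low-minor-allele-frequency variants
#'
#' MAF is `min(eaf, 1 - eaf)`; variants with MAF less than or equal to the
#' threshold are removed.
#'
#' @inheritParams filter_pval
#' @param maf_threshold Cutoff; rows with `maf > maf_threshold` are kept.
#' @return The filtered table.
#' @export
filter_maf <- function(table, maf_threshold = 0.01) {
  maf <- pmin(table$eaf, 1 - table$eaf)
  table[maf > maf_threshold, , drop = FALSE]
}

#' Keep cis variants: within a window of the encoding gene's footprint
#'
#' Retains variants on the locus chromosome with position in
#' `[start - window_bp, end + window_bp]`, boundaries inclusive.
#' Chromosome names are normalized (`chr1` and `1` compare equal).
#'
#' @inheritParams filter_pval
#' @param locus A [gene_locus()].
#' @param window_bp Window size in bp (default 1 Mb).
#' @return The filtered table.
#' @export
filter_cis <- function(table, locus, window_bp = 1e6) {
  stopifnot(inherits(locus, "gene_locus"))
  same_chr <- .norm_chrom(table$chrom) == .norm_chrom(locus$chrom)
  in_win <- table$pos >= locus$start - window_bp &
    table$pos <= locus$end + window_bp
  table[same_chr & in_win, , drop = FALSE]
}

#' Instrument-strength F statistic
#'
#' Computed per variant as the squared z statistic, `(beta/se)^2`. The
#' alternative form based on explained variance,
#' `r2 (n - 2) / (1 - r2)` with `r2 = 2 maf (1 - maf) beta^2`
#' (standardized trait), is available via `method = "r2"`.
#'
#' @param beta,se Effect estimate and standard error.
#' @param method `"z2"` (default) or `"r2"`.
#' @param eaf,n Allele frequency and sample size, required for `"r2"`.
#' @return Numeric vector of F statistics.
#' @export
compute_f_stat <- function(beta, se, method = c("z2", "r2"),
                           eaf = NULL, n = NULL) {
  method <- match.arg(method)
  if (method == "z2") return((beta / se)^2)
  if (is.null(eaf) || is.null(n)) stop("method 'r2' requires eaf and n")
  maf <- pmin(eaf, 1 - eaf)
  r2 <- 2 * maf * (1 - maf) * beta^2
  r2 <- pmin(r2, 1 - 1e-12)
  r2 * (n - 2) / (1 - r2)
}

#' Greedy LD clumping
#'
#' Iteratively keeps the most significant remaining variant (p-value
#' ties — which arise when p underflows at extreme z — are broken by
#' larger `|beta/se|`, then smaller position, then variant id, so the
#' result is independent of input row order) and removes all other
#' variants within `window_kb`
#' kilobases whose squared correlation with it is at least `r2_threshold`.
#' Output rows are ordered by position.
#'
#' @inheritParams filter_pval
#' @param ld An `ld_matrix` covering (at least) the table's variants.
#' @param r2_threshold Removal cutoff on r-squared.
#' @param window_kb Distance window in kb within which removal applies.
#' @param missing_ld What to do with variants absent from `ld`:
#'   `"drop"` (default, with a warning) or `"error"`.
#' @return The clumped table, ordered by position.
#' @export
greedy_clump <- function(table, ld, r2_threshold = 0.001, window_kb = 10000,
                         missing_ld = c("drop", "error")) {
  missing_ld <- match.arg(missing_ld)
  if (nrow(table) == 0) return(table)
  present <- table$variant_id %in% rownames(ld)
  if (!all(present)) {
    if (missing_ld == "error") {
      stop("variant(s) missing from LD reference: ",
           paste(table$variant_id[!present], collapse = ", "))
    }
    warning(sum(!present), " variant(s) missing from LD reference; dropped")
    table <- table[present, , drop = FALSE]
  }
  if (nrow(table) == 0) return(table)

  r2 <- unclass(ld)[table$variant_id, table$variant_id, drop = FALSE]^2
  window_bp <- window_kb * 1000
  # secondary ranking key: |z| keeps the ordering meaningful where p
  # underflows to the same floor value
  neg_abs_z <- if (all(c("beta", "se") %in% names(table))) {
    -abs(table$beta / table$se)
  } else {
    rep(0, nrow(table))
  }
  active <- rep(TRUE, nrow(table))
  keep <- logical(nrow(table))
  while (any(active)) {
    cand <- which(active)
    ord <- order(table$pval[cand], neg_abs_z[cand], table$pos[cand],
                 table$variant_id[cand])
    idx <- cand[ord[1]]
    keep[idx] <- TRUE
    active[idx] <- FALSE
    close_by <- abs(table$pos - table$pos[idx]) <= window_bp
    active[active & close_by & r2[, idx] >= r2_threshold] <- FALSE
  }
  out <- table[keep, , drop = FALSE]
  out[order(out$pos, out$variant_id), , drop = FALSE]
}

#' Select cis-pQTL instruments for one protein
#'
#' Applies, in order: association p-value filter, MAF filter, cis-window
#' filter, greedy LD clumping, and the weak-instrument F filter. Provenance
#' flags record each decision for every input variant.
#'
#' @param table Exposure `summary_stats` for the protein.
#' @param locus The protein's [gene_locus()].
#' @param ld An `ld_matrix` for the region.
#' @param thresholds An [iv_thresholds()] list.
#' @param f_method F-statistic formula passed to [compute_f_stat()].
#' @param missing_ld Passed to [greedy_clump()].
#' @return An `instrument_set`: list with `protein_id`, `instruments`
#'   (retained rows plus `f_stat`, ordered by position), `provenance`
#'   (all input variants with logical flags `passed_p`, `passed_maf`,
#'   `passed_cis`, `clump_kept`, `passed_f`), and `thresholds`.
#' @export
select_instruments <- function(table, locus, ld,
                               thresholds = iv_thresholds(),
                               f_method = "z2",
                               missing_ld = "drop") {
  stopifnot(inherits(locus, "gene_locus"))
  df <- as.data.frame(table)
  prov <- data.frame(variant_id = df$variant_id, stringsAsFactors = FALSE)
  prov$passed_p <- df$pval < thresholds$p_threshold
  prov$passed_maf <- pmin(df$eaf, 1 - df$eaf) > thresholds$maf_threshold
  prov$passed_cis <- .norm_chrom(df$chrom) == .norm_chrom(locus$chrom) &
    df$pos >= locus$start - thresholds$cis_window_bp &
    df$pos <= locus$end + thresholds$cis_window_bp

  pre <- df[prov$passed_p & prov$passed_maf & prov$passed_cis, , drop = FALSE]
  clumped <- greedy_clump(pre, ld, r2_threshold = thresholds$r2_threshold,
                          window_kb = thresholds$window_kb,
                          missing_ld = missing_ld)
  prov$clump_kept <- prov$variant_id %in% clumped$variant_id

  f_all <- compute_f_stat(df$beta, df$se, method = f_method,
                          eaf = df$eaf, n = df$n)
  prov$passed_f <- f_all >= thresholds$f_threshold

  kept <- prov$clump_kept & prov$passed_f
  inst <- df[kept, , drop = FALSE]
  inst$f_stat <- f_all[kept]
  inst <- inst[order(inst$pos, inst$variant_id), , drop = FALSE]
  rownames(inst) <- NULL

  structure(list(protein_id = attr(table, "trait_id") %||% locus$gene_id,
                 instruments = inst, provenance = prov,
                 thresholds = thresholds),
            class = "instrument_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("instrument_set for '%s': %d instrument(s) from %d variant(s)\n",
              x$protein_id, nrow(x$instruments), nrow(x$provenance)))
  if (nrow(x$instruments)) {
    print(x$instruments[, c("variant_id", "pos", "beta", "se", "pval",
                            "f_stat")])
  }
  invisible(x)
}
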