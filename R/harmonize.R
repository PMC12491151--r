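.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Is an allele pair palindromic (strand-ambiguous)?
#' @param effect_allele,other_allele Single-base alleles.
#' @return Logical vector: `TRUE` for A/T and C/G pairs.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  unname(.COMPLEMENT[effect_allele] == other_allele)
}

#' Harmonize exposure and outcome effects onto a common effect allele
#'
#' Joins the two tables on `variant_id` and orients every outcome record
#' to the exposure's effect allele:
#' * identical allele pair, same orientation — kept unchanged;
#' * alleles swapped — outcome beta sign-flipped and `eaf_y := 1 - eaf_y`;
#' * palindromic pair (A/T or C/G) — allele labels cannot resolve strand,
#'   so allele frequency decides: if either trait's EAF falls inside the
#'   open ambiguity window the variant is dropped, otherwise the outcome is
#'   oriented so both EAFs fall on the same side of 0.5;
#' * irreconcilable allele pairs — dropped.
#'
#' All input variants appear in the output with an `action_taken` audit
#' column; downstream estimators use only the retained
#' (`kept`/`flipped`) rows, see [harmonized_retained()].
#'
#' @param exposure_rows,outcome_rows `summary_stats` objects or data
#'   frames with columns `variant_id`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`.
#' @param palindrome_eaf_window Open interval of effect-allele frequencies
#'   within which a palindromic variant is deemed unresolvable.
#' @return A `harmonized` data frame with columns `variant_id`,
#'   `effect_allele`, `other_allele` (exposure orientation), `beta_x`,
#'   `se_x`, `eaf_x`, `beta_y`, `se_y`, `eaf_y`, `action_taken`.
#' @export
harmonize_pair <- function(exposure_rows, outcome_rows,
                           palindrome_eaf_window = c(0.42, 0.58)) {
  ex <- as.data.frame(exposure_rows)
  oy <- as.data.frame(outcome_rows)
  need <- c("variant_id", "effect_allele", "other_allele", "eaf", "beta", "se")
  stopifnot(all(need %in% names(ex)), all(need %in% names(oy)))
  shared <- intersect(ex$variant_id, oy$variant_id)
  if (length(shared) == 0) stop("no overlapping variants to harmonize")
  ex <- ex[match(shared, ex$variant_id), , drop = FALSE]
  oy <- oy[match(shared, oy$variant_id), , drop = FALSE]
  lo <- palindrome_eaf_window[1]
  hi <- palindrome_eaf_window[2]

  n <- length(shared)
  beta_y <- oy$beta
  eaf_y <- oy$eaf
  action <- character(n)

  pal_x <- is_palindromic(ex$effect_allele, ex$other_allele)
  same_pair <- oy$effect_allele == ex$effect_allele &
    oy$other_allele == ex$other_allele
  swapped <- oy$effect_allele == ex$other_allele &
    oy$other_allele == ex$effect_allele

  for (i in seq_len(n)) {
    if (pal_x[i]) {
      if (!(same_pair[i] || swapped[i])) {
        action[i] <- "dropped_allele_mismatch"
      } else if ((ex$eaf[i] > lo && ex$eaf[i] < hi) ||
                 (oy$eaf[i] > lo && oy$eaf[i] < hi)) {
        action[i] <- "dropped_palindrome_ambiguous"
      } else if ((ex$eaf[i] - 0.5) * (oy$eaf[i] - 0.5) > 0) {
        action[i] <- "kept"
      } else {
        beta_y[i] <- -beta_y[i]
        eaf_y[i] <- 1 - eaf_y[i]
        action[i] <- "flipped"
      }
    } else if (same_pair[i]) {
      action[i] <- "kept"
    } else if (swapped[i]) {
      beta_y[i] <- -beta_y[i]
      eaf_y[i] <- 1 - eaf_y[i]
      action[i] <- "flipped"
    } else {
      action[i] <- "dropped_allele_mismatch"
    }
  }

  out <- data.frame(
    variant_id = shared,
    effect_allele = ex$effect_allele, other_allele = ex$other_allele,
    beta_x = ex$beta, se_x = ex$se, eaf_x = ex$eaf,
    beta_y = beta_y, se_y = oy$se, eaf_y = eaf_y,
    action_taken = action, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("harmonized", "data.frame")
  out
}

#' Retained rows of a harmonized table
#' @param h A `harmonized` table from [harmonize_pair()].
#' @return Rows with `action_taken` `kept` or `flipped`.
#' @export
harmonized_retained <- function(h) {
  h[h$action_taken %in% c("kept", "flipped"), , drop = FALSE]
}
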