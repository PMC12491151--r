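.TIER_LEVELS <- c("Tier 1", "Tier 2", "Tier 3A", "Tier 3B", "none")
.TYPE_LEVELS <- c("Successful Target", "Clinical trial Target",
                  "Preclinical/Patented", "Literature-reported target",
                  "Discontinued Target", "none")

#' Bundled druggability annotation table
#'
#' Transcription of the published table mapping MR-prioritized proteins to
#' druggable-genome tiers (Tier 1: targets of licensed compounds and
#' clinical candidates; Tier 2: close homologues of such targets with
#' drug-like binders; Tier 3A/3B: more distantly druggable genes) and to
#' Therapeutic Target Database development phases. Missing entries
#' (printed as "/") are returned as `"none"`.
#'
#' @param path Override the bundled fixture path.
#' @return Data frame with columns `protein`, `druggability_tier`,
#'   `target_type`.
#' @export
load_druggability_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table2_druggability.tsv",
                        package = "protmr", mustWork = TRUE)
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          check.names = FALSE)
  df$druggability_tier[df$druggability_tier == "/"] <- "none"
  df$target_type[df$target_type == "/"] <- "none"
  bad_tier <- setdiff(unique(df$druggability_tier), .TIER_LEVELS)
  bad_type <- setdiff(unique(df$target_type), .TYPE_LEVELS)
  if (length(bad_tier) || length(bad_type)) {
    stop("unknown annotation value(s): ",
         paste(c(bad_tier, bad_type), collapse = ", "))
  }
  df
}

#' Bundled outcome-study design table
#'
#' Transcription of the published design table: 33 hematologic-malignancy
#' outcome GWAS (27 from FinnGen, 6 from UK Biobank) with case and control
#' counts.
#'
#' @param path Override the bundled fixture path.
#' @return Data frame with columns `outcome`, `source`, `dataset`,
#'   `n_cases`, `n_controls`.
#' @export
load_outcome_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_outcomes.tsv",
                        package = "protmr", mustWork = TRUE)
  }
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, quote = "")
}

#' Bundled exposure-panel design table
#'
#' Sample sizes, assayed-protein counts and instrumented-protein counts
#' for the two proteomics panels the scan design emulates, plus the count
#' of proteins instrumented in both.
#'
#' @return List with data frames `panels` and `overlap`.
#' @export
load_exposure_panels <- function() {
  panels <- utils::read.table(
    system.file("extdata", "exposure_panels.tsv", package = "protmr",
                mustWork = TRUE),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  overlap <- utils::read.table(
    system.file("extdata", "panel_overlap.tsv", package = "protmr",
                mustWork = TRUE),
    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  list(panels = panels, overlap = overlap)
}

#' Number of distinct proteins in a two-panel scan
#'
#' Inclusion-exclusion over two exposure sources:
#' `n_1 + n_2 - n_shared`. This is the denominator of the scan's
#' Bonferroni correction.
#'
#' @param n_source1,n_source2 Proteins instrumented per source.
#' @param n_shared Proteins instrumented in both.
#' @return Integer count.
#' @export
scan_protein_count <- function(n_source1, n_source2, n_shared) {
  stopifnot(n_shared <= min(n_source1, n_source2))
  n_source1 + n_source2 - n_shared
}

.norm_symbol <- function(x) toupper(trimws(as.character(x)))

#' Annotate proteins with druggability tier and target development phase
#'
#' Left-joins on protein symbol, case-insensitively and after whitespace
#' trimming; proteins absent from a table get `"none"`. Every input
#' protein yields exactly one record.
#'
#' @param proteins Character vector of protein symbols.
#' @param tier_table Data frame with columns `protein`,
#'   `druggability_tier` (defaults to the bundled table).
#' @param phase_table Data frame with columns `protein`, `target_type`
#'   (defaults to the bundled table).
#' @return Data frame with columns `protein_id`, `druggability_tier`,
#'   `target_type`, one row per input protein.
#' @export
annotate_targets <- function(proteins,
                             tier_table = load_druggability_table(),
                             phase_table = load_druggability_table()) {
  lookup <- function(tab, value_col) {
    key <- .norm_symbol(tab$protein)
    dup <- unique(key[duplicated(key)])
    if (length(dup)) {
      conflict <- vapply(dup, function(k) {
        length(unique(tab[[value_col]][key == k])) > 1
      }, logical(1))
      if (any(conflict)) {
        stop("conflicting annotation values for protein(s): ",
             paste(dup[conflict], collapse = ", "))
      }
    }
    idx <- match(.norm_symbol(proteins), key)
    out <- tab[[value_col]][idx]
    out[is.na(out)] <- "none"
    out
  }
  data.frame(protein_id = as.character(proteins),
             druggability_tier = lookup(tier_table, "druggability_tier"),
             target_type = lookup(phase_table, "target_type"),
             stringsAsFactors = FALSE)
}

#' Summarize annotation records by tier and development phase
#'
#' @param records Output of [annotate_targets()] (or any data frame with
#'   `druggability_tier` and `target_type` columns).
#' @return List: `n_proteins`, `n_tier_assigned` (tier not `"none"`),
#'   `by_tier` (named counts over the closed tier vocabulary, fixed
#'   order), `n_phase_assigned` (target type not `"none"`), `by_type`
#'   (named counts over the closed phase vocabulary).
#' @export
summarize_counts <- function(records) {
  tier <- factor(records$druggability_tier, levels = .TIER_LEVELS)
  type <- factor(records$target_type, levels = .TYPE_LEVELS)
  by_tier <- table(tier)
  by_type <- table(type)
  list(
    n_proteins = nrow(records),
    n_tier_assigned = sum(records$druggability_tier != "none"),
    by_tier = by_tier[setdiff(.TIER_LEVELS, "none")],
    n_phase_assigned = sum(records$target_type != "none"),
    by_type = by_type[setdiff(.TYPE_LEVELS, "none")]
  )
}
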