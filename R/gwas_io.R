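#' Default column-name synonym map for GWAS summary statistics
#'
#' Consortium summary-statistic files name the same columns differently
#' (`rsid` vs `snp`, `sebeta` vs `standard_error`, ...). Readers in this
#' package resolve headers against a synonym map: a named list whose names
#' are the canonical column names and whose elements are character vectors
#' of accepted (case-insensitive) synonyms. Override entries by passing a
#' partial map to [read_summary_stats()], or load one from YAML with
#' [read_column_map()].
#'
#' @return Named list of character vectors.
#' @export
default_column_map <- function() {
  list(
    variant_id    = c("variant_id", "snp", "rsid", "rsids", "id", "markername"),
    chrom         = c("chrom", "chr", "chromosome", "#chrom"),
    pos           = c("pos", "position", "bp", "base_pair_location"),
    effect_allele = c("effect_allele", "ea", "alt", "allele1", "a1"),
    other_allele  = c("other_allele", "oa", "ref", "allele0", "allele2", "a2"),
    eaf           = c("eaf", "effect_allele_frequency", "af", "a1freq", "freq1"),
    beta          = c("beta", "effect", "b"),
    se            = c("se", "standard_error", "sebeta", "stderr"),
    pval          = c("pval", "p", "p_value", "pvalue", "p.value"),
    n             = c("n", "samplesize", "n_total", "num_samples"),
    n_cases       = c("n_cases", "ncase", "ncases", "cases")
  )
}

#' Read a column-synonym map from a YAML config file
#'
#' The file holds a mapping `canonical: [synonym, ...]` under an optional
#' top-level key `column_map`. Entries merge over [default_column_map()].
#'
#' @param path Path to a YAML file.
#' @return Named list of character vectors usable as a `column_map`.
#' @export
read_column_map <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$column_map)) cfg <- cfg$column_map
  map <- default_column_map()
  for (nm in names(cfg)) map[[nm]] <- as.character(cfg[[nm]])
  map
}

.required_sumstat_cols <- c(
  "variant_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pval", "n"
)

.resolve_columns <- function(header, column_map) {
  out <- character(0)
  lower <- tolower(header)
  for (canon in names(column_map)) {
    hit <- which(lower %in% tolower(column_map[[canon]]))
    if (length(hit)) out[canon] <- header[hit[1]]
  }
  out
}

#' Construct a summary-statistics table
#'
#' Builds the package's per-trait container for GWAS summary statistics:
#' a data frame of per-variant association records plus trait metadata
#' carried as attributes. Rows violating hard invariants (non-positive
#' standard error, allele frequency outside (0,1), identical alleles,
#' alleles that are not single A/C/G/T bases, p-value outside (0,1],
#' duplicated variant id) are dropped and tallied.
#'
#' @param data Data frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`
#'   (and optionally `n_cases`).
#' @param trait_type `"quantitative"` (protein levels, betas in SD units)
#'   or `"binary"` (disease outcomes, betas on the log-odds scale).
#' @param trait_id,source_label Free-text trait metadata.
#' @param pz_tol Warn-only tolerance for the consistency of `pval` with
#'   `2*pnorm(-|beta/se|)`: rows where the two disagree by more than
#'   `pz_tol` orders of magnitude are counted in a warning (consortium
#'   files round p-values, so this never rejects).
#' @return A `summary_stats` object (a data frame with attributes
#'   `trait_id`, `trait_type`, `source_label`, and `rejections`, a named
#'   integer vector counting dropped rows per rule).
#' @export
summary_stats <- function(data, trait_type = c("quantitative", "binary"),
                          trait_id = "trait", source_label = "",
                          pz_tol = 1) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(.required_sumstat_cols, names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(data, stringsAsFactors = FALSE)
  df$variant_id <- as.character(df$variant_id)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(trimws(as.character(df$effect_allele)))
  df$other_allele <- toupper(trimws(as.character(df$other_allele)))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    df[[col]] <- as.numeric(df[[col]])
  }

  rej <- c(bad_se = 0L, bad_eaf = 0L, bad_alleles = 0L, bad_pval = 0L,
           duplicate_id = 0L)
  bases <- c("A", "C", "G", "T")

  # p-values that underflowed to exactly 0 (z far in the tail) are the
  # strongest signals, not invalid rows: clamp to the smallest positive
  # double instead of rejecting
  zero_p <- is.finite(df$pval) & df$pval == 0
  if (any(zero_p)) {
    df$pval[zero_p] <- .Machine$double.xmin
    warning(sum(zero_p), " zero p-value(s) clamped to smallest positive double")
  }

  bad_se <- !is.finite(df$se) | df$se <= 0
  bad_eaf <- !is.finite(df$eaf) | df$eaf <= 0 | df$eaf >= 1
  bad_alleles <- !(df$effect_allele %in% bases) |
    !(df$other_allele %in% bases) |
    df$effect_allele == df$other_allele
  bad_pval <- !is.finite(df$pval) | df$pval <= 0 | df$pval > 1
  drop <- bad_se | bad_eaf | bad_alleles | bad_pval
  rej["bad_se"] <- sum(bad_se)
  rej["bad_eaf"] <- sum(bad_eaf & !bad_se)
  rej["bad_alleles"] <- sum(bad_alleles & !bad_se & !bad_eaf)
  rej["bad_pval"] <- sum(bad_pval & !bad_se & !bad_eaf & !bad_alleles)
  df <- df[!drop, , drop = FALSE]

  dup <- duplicated(df$variant_id)
  rej["duplicate_id"] <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL

  if (nrow(df) == 0) stop("no rows left after validation for trait '",
                          trait_id, "'")

  # warn-only z/p consistency: consortium files round p-values
  p_expected <- 2 * stats::pnorm(-abs(df$beta / df$se))
  comparable <- p_expected > 1e-300 & df$pval > 1e-300
  off <- comparable &
    abs(log10(p_expected) - log10(df$pval)) > pz_tol
  if (any(off)) {
    warning(sum(off), " row(s) have pval inconsistent with |beta/se| ",
            "beyond ", pz_tol, " order(s) of magnitude (kept)")
  }

  structure(df,
            class = c("summary_stats", "data.frame"),
            trait_id = trait_id, trait_type = trait_type,
            source_label = source_label, rejections = rej)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("summary_stats: trait '%s' (%s, source '%s'), %d variants\n",
              attr(x, "trait_id"), attr(x, "trait_type"),
              attr(x, "source_label"), nrow(x)))
  rej <- attr(x, "rejections")
  if (!is.null(rej) && sum(rej) > 0) {
    cat("  rejected rows:",
        paste(sprintf("%s=%d", names(rej)[rej > 0], rej[rej > 0]),
              collapse = ", "), "\n")
  }
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Number of rows dropped during validation
#' @param x A `summary_stats` object.
#' @return Named integer vector of per-rule rejection counts.
#' @export
rejections <- function(x) attr(x, "rejections")

.detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited file with a header line, resolves column
#' names through a synonym map, and validates the table with
#' [summary_stats()].
#'
#' @inheritParams summary_stats
#' @param path Path to a TSV/CSV file.
#' @param column_map Synonym map; entries override [default_column_map()].
#' @param sep Field separator; `NULL` (default) autodetects tab vs comma
#'   from the header line.
#' @return A `summary_stats` object.
#' @export
read_summary_stats <- function(path, trait_type = c("quantitative", "binary"),
                               trait_id = NULL, source_label = "",
                               column_map = NULL, sep = NULL, pz_tol = 1) {
  trait_type <- match.arg(trait_type)
  if (is.null(sep)) sep <- .detect_sep(path)
  map <- default_column_map()
  if (!is.null(column_map)) for (nm in names(column_map)) {
    map[[nm]] <- as.character(column_map[[nm]])
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE)
  found <- .resolve_columns(names(raw), map)
  missing_cols <- setdiff(.required_sumstat_cols, names(found))
  if (length(missing_cols)) {
    stop("file '", path, "' is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- raw[, unname(found), drop = FALSE]
  names(df) <- names(found)
  if (is.null(trait_id)) {
    trait_id <- sub("\\.[^.]*$", "", basename(path))
  }
  summary_stats(df, trait_type = trait_type, trait_id = trait_id,
                source_label = source_label, pz_tol = pz_tol)
}

#' Write a summary-statistics table (or any result table) as TSV
#'
#' Values round-trip losslessly to at least 10 significant digits. An
#' optional configuration list is serialized verbatim into `#`-prefixed
#' header lines for provenance.
#'
#' @param table Data frame (including `summary_stats` objects).
#' @param path Output path.
#' @param config Optional named list written as `# key: value` header lines.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config)) {
    flat <- unlist(config)
    writeLines(sprintf("# %s: %s", names(flat), as.character(flat)), con)
  }
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  for (col in names(df)[num]) {
    v <- df[[col]]
    df[[col]] <- ifelse(is.na(v), NA_character_, sprintf("%.15g", v))
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_results()]
#' @param path Path to the TSV file.
#' @return Data frame (header comment lines skipped).
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "#",
                    check.names = FALSE)
}

#' Construct a validated LD matrix
#'
#' @param r Square numeric matrix of signed correlations.
#' @param variant_ids Character vector of variant ids, in matrix order.
#' @param tol Tolerance for the symmetry/unit-diagonal/bound checks.
#' @return An `ld_matrix`: the matrix with dimnames set to `variant_ids`.
#' @export
ld_matrix <- function(r, variant_ids = rownames(r), tol = 1e-8) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square")
  if (is.null(variant_ids) || length(variant_ids) != nrow(r)) {
    stop("variant_ids length must match LD matrix dimension")
  }
  if (any(!is.finite(r))) stop("LD matrix contains non-finite values")
  if (max(abs(r - t(r))) > tol) stop("LD matrix is not symmetric")
  if (max(abs(diag(r) - 1)) > tol) stop("LD matrix diagonal must be 1")
  if (max(abs(r)) > 1 + tol) stop("LD correlations must satisfy |r| <= 1")
  dimnames(r) <- list(variant_ids, variant_ids)
  class(r) <- c("ld_matrix", "matrix", "array")
  r
}

#' Read an LD matrix from TSV (first row and column are variant ids)
#' @param path Path to the TSV file.
#' @inheritParams ld_matrix
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path, tol = 1e-8) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(raw)
  if (nrow(m) != ncol(m)) stop("LD matrix file is not square")
  if (!identical(rownames(m), colnames(m))) {
    stop("LD matrix row and column ids disagree")
  }
  ld_matrix(m, rownames(m), tol = tol)
}

#' Write an LD matrix as TSV
#' @param ld An `ld_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  df <- as.data.frame(formatC(unclass(ld), digits = 15, format = "g"),
                      check.names = FALSE)
  rownames(df) <- rownames(ld)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("variant_id", colnames(ld)), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Describe the genomic footprint of a protein-coding gene
#'
#' Coordinates are 1-based and inclusive, matching GWAS summary-statistic
#' convention; the cis window for instrument selection extends from this
#' footprint.
#'
#' @param gene_id Gene or protein identifier.
#' @param chrom Chromosome (with or without a `chr` prefix).
#' @param start,end 1-based inclusive gene start/end.
#' @return A `gene_locus` list.
#' @export
gene_locus <- function(gene_id, chrom, start, end) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (!is.finite(start) || !is.finite(end) || start > end) {
    stop("gene_locus requires start <= end")
  }
  structure(list(gene_id = as.character(gene_id),
                 chrom = as.character(chrom),
                 start = start, end = end),
            class = "gene_locus")
}

#' Read gene loci from a TSV with columns gene_id, chrom, start, end
#' @param path Path to the TSV file.
#' @return Named list of `gene_locus` objects.
#' @export
read_gene_loci <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  loci <- lapply(seq_len(nrow(df)), function(i) {
    gene_locus(df$gene_id[i], df$chrom[i], df$start[i], df$end[i])
  })
  names(loci) <- df$gene_id
  loci
}

# strip chr prefix, case-fold: "chr1"/"Chr1"/"1" compare equal
.norm_chrom <- function(x) sub("^chr", "", tolower(as.character(x)))
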