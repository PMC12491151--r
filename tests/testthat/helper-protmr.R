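# shared fixtures and independent oracles, built in code

# minimal well-formed summary-stat data frame
tiny_sumstats_df <- function(n = 3) {
  data.frame(
    variant_id = paste0("rs", seq_len(n)),
    chrom = "1",
    pos = 1000 * seq_len(n),
    effect_allele = rep(c("A", "C", "G"), length.out = n),
    other_allele = rep(c("G", "T", "A"), length.out = n),
    eaf = seq(0.2, 0.4, length.out = n),
    beta = seq(0.1, 0.3, length.out = n),
    se = rep(0.05, n),
    pval = 2 * pnorm(-abs(seq(0.1, 0.3, length.out = n) / 0.05)),
    n = 10000,
    stringsAsFactors = FALSE)
}

# independent greedy-clump oracle: plain set recursion over id vectors
clump_oracle <- function(ids, pos, pval, r2, thr, window_bp) {
  if (length(ids) == 0) return(character(0))
  o <- order(pval, pos, ids)
  best <- o[1]
  conflict <- r2[best, ] >= thr & abs(pos - pos[best]) <= window_bp
  conflict[best] <- TRUE
  rest <- !conflict
  c(ids[best],
    clump_oracle(ids[rest], pos[rest], pval[rest],
                 r2[rest, rest, drop = FALSE], thr, window_bp))
}

# independent five-hypothesis enumeration in plain (non-log) arithmetic:
# loop over single-variant configurations for H1/H2, ordered pairs for
# H3, the diagonal for H4
coloc_enum_oracle <- function(l1, l2, p1, p2, p12) {
  a1 <- exp(l1)
  a2 <- exp(l2)
  n <- length(a1)
  w <- c(h0 = 1, h1 = 0, h2 = 0, h3 = 0, h4 = 0)
  for (i in seq_len(n)) {
    w["h1"] <- w["h1"] + p1 * a1[i]
    w["h2"] <- w["h2"] + p2 * a2[i]
    w["h4"] <- w["h4"] + p12 * a1[i] * a2[i]
    for (j in seq_len(n)) {
      if (i != j) w["h3"] <- w["h3"] + p1 * p2 * a1[i] * a2[j]
    }
  }
  w / sum(w)
}

# harmonized table with exact, fully matching alleles
make_harmonized <- function(beta_x, se_x, beta_y, se_y,
                            eaf = rep(0.3, length(beta_x))) {
  n <- length(beta_x)
  h <- data.frame(
    variant_id = paste0("rs", seq_len(n)),
    effect_allele = "A", other_allele = "G",
    beta_x = beta_x, se_x = se_x, eaf_x = eaf,
    beta_y = beta_y, se_y = se_y, eaf_y = eaf,
    action_taken = "kept", stringsAsFactors = FALSE)
  class(h) <- c("harmonized", "data.frame")
  h
}

# run one simulated region through instrument selection, harmonization
# and causal estimation; NA row if no instrument survives
sim_mr_once <- function(cfg, second_order = TRUE) {
  p <- simulate_pair(cfg)
  iv <- select_instruments(p$exposure, p$locus, p$ld)
  if (nrow(iv$instruments) == 0) return(c(NA_real_, NA_real_, NA_real_))
  h <- harmonize_pair(iv$instruments, as.data.frame(p$outcome))
  if (nrow(harmonized_retained(h)) == 0) {
    return(c(NA_real_, NA_real_, NA_real_))
  }
  m <- mr_ivw(h, second_order = second_order)
  c(m$beta_mr, m$se_mr, m$pval)
}
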