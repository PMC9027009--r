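# Independent, direct evaluations of the three screening criteria, coded
# from the stated rules on raw genotype/presence vectors. Deliberately
# scalar and naive; these are the oracles the detector implementations are
# checked against, so they must not share code with R/.

# allele frequency of ref / alt over called genotypes; NULL when none called
oracle_freqs <- function(g) {
  g <- g[!is.na(g)]
  if (!length(g)) return(NULL)
  ref <- (2 * sum(g == 0) + sum(g == 1)) / (2 * length(g))
  c(ref = ref, alt = 1 - ref)
}

# criterion 1: some allele with freq >= f_fix in the homogametic sex and a
# signed between-sex difference >= d_min. Returns "XY", "ZW" or NA.
# Both-directions (opposite fixation) is directionally ambiguous -> NA.
oracle_freq_diff <- function(gF, gM, f_fix = 0.95, d_min = 0.4,
                             min_called = 1) {
  if (sum(!is.na(gF)) < min_called || sum(!is.na(gM)) < min_called)
    return(NA_character_)
  fF <- oracle_freqs(gF); fM <- oracle_freqs(gM)
  hit <- function(homo, hetero)
    any(homo >= f_fix & homo - hetero >= d_min)
  xy <- hit(fF, fM)
  zw <- hit(fM, fF)
  if (xy && zw) return(NA_character_)
  if (xy) "XY" else if (zw) "ZW" else NA_character_
}

# criterion 2: homozygous in all of the homogametic sex and heterozygous in
# at least half (het_frac) of the heterogametic sex, over called calls.
oracle_het_diff <- function(gF, gM, het_frac = 0.5, min_called = 1) {
  nF <- sum(!is.na(gF)); nM <- sum(!is.na(gM))
  if (nF < min_called || nM < min_called) return(NA_character_)
  hetF <- sum(gF == 1, na.rm = TRUE); hetM <- sum(gM == 1, na.rm = TRUE)
  xy <- hetF == 0 && hetM >= het_frac * nM
  zw <- hetM == 0 && hetF >= het_frac * nF
  if (xy && zw) return(NA_character_)  # possible only when het_frac = 0
  if (xy) "XY" else if (zw) "ZW" else NA_character_
}

# criterion 3 on presence vectors (TRUE/FALSE/NA): completely absent in one
# sex, present in every individual of the other; strict about unknowns up
# to max_missing per sex.
oracle_sex_limited <- function(pF, pM, max_missing = 0) {
  unkF <- sum(is.na(pF)); unkM <- sum(is.na(pM))
  if (unkF > max_missing || unkM > max_missing) return(NA_character_)
  xy <- !any(pF, na.rm = TRUE) && all(pM, na.rm = TRUE) &&
    any(pM, na.rm = TRUE)
  zw <- !any(pM, na.rm = TRUE) && all(pF, na.rm = TRUE) &&
    any(pF, na.rm = TRUE)
  if (xy) "XY" else if (zw) "ZW" else NA_character_
}

# all genotype-code assignments of length n over {0, 1, 2, NA}
enumerate_geno <- function(n) {
  grid <- expand.grid(rep(list(c(0L, 1L, 2L, NA_integer_)), n))
  lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, ], use.names = FALSE))
}

# all presence assignments of length n over {TRUE, FALSE, NA}
enumerate_presence <- function(n) {
  grid <- expand.grid(rep(list(c(TRUE, FALSE, NA)), n))
  lapply(seq_len(nrow(grid)), function(i) unlist(grid[i, ], use.names = FALSE))
}
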