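# Positional placement of validation primers on tag sequences. Two designs:
#
#   SD (sequence difference): both primers sit on conserved (polymorphism
#   free) footprints flanking the target SNP, so both sexes amplify and the
#   SNP is read out by sequencing the product.
#
#   PA (presence/absence, allele-specific): each primer is anchored with its
#   3'-terminal base on a sex-specific SNP, carrying the male-specific (Y)
#   allele (complemented on the reverse primer), so only the Y haplotype
#   amplifies and sexing is read out as band / no band on a gel.
#
# Placements are purely positional; no thermodynamic screening is done. A
# Wallace-rule melting temperature (2 degrees per A/T + 4 per G/C) is
# reported informationally.
#
# Coordinates are 0-based half-open on the tag's plus strand. The forward
# primer footprint [fs, fe) reads the plus strand; the reverse primer is the
# reverse complement of its footprint [rs, re), so its 3'-terminal base
# pairs with plus-strand position rs.

revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
          collapse = ""),
    character(1), USE.NAMES = FALSE)
}

wallace_tm <- function(primer) {
  b <- strsplit(toupper(primer), "")[[1]]
  2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
}

primer_proposal <- function(tag_id, type, seq, fwd, rev, anchored = NULL) {
  fwd_seq <- substr(seq, fwd[1] + 1L, fwd[2])
  rev_seq <- revcomp(substr(seq, rev[1] + 1L, rev[2]))
  structure(list(tag_id = tag_id, type = type,
                 fwd_start = fwd[1], fwd_end = fwd[2],
                 rev_start = rev[1], rev_end = rev[2],
                 fwd_seq = fwd_seq, rev_seq = rev_seq,
                 product_size = rev[2] - fwd[1],
                 anchored_snps = anchored,
                 tm_fwd = wallace_tm(fwd_seq), tm_rev = wallace_tm(rev_seq)),
            class = "primer_proposal")
}

#' @export
print.primer_proposal <- function(x, ...) {
  cat(sprintf("%s primer pair on %s (product %d bp)\n", x$type, x$tag_id,
              x$product_size))
  cat(sprintf("  F [%d,%d) %s (Tm %d)\n", x$fwd_start, x$fwd_end, x$fwd_seq,
              x$tm_fwd))
  cat(sprintf("  R [%d,%d) %s (Tm %d)\n", x$rev_start, x$rev_end, x$rev_seq,
              x$tm_rev))
  if (!is.null(x$anchored_snps))
    cat("  3'-anchored SNP offsets:", paste(x$anchored_snps, collapse = ", "),
        "\n")
  invisible(x)
}

#' Propose an SD (sequence-difference) primer pair
#'
#' Places the forward primer on the leftmost conserved footprint ending at
#' least `min_flank` bases upstream of the target SNP and the reverse primer
#' on the rightmost conserved footprint starting at least `min_flank` bases
#' downstream, maximising the product. Footprints may not cover any
#' polymorphic offset, so both haplotypes amplify. Returns `NULL` when no
#' valid placement exists.
#'
#' @param sequence tag sequence (plus strand).
#' @param snp_offsets 0-based offsets of all polymorphic sites on the tag.
#' @param target_site 0-based offset of the SNP the product must span; must
#'   be one of `snp_offsets`.
#' @param primer_len primer length in bp (default 20).
#' @param min_flank minimum bases between a primer footprint and the target
#'   SNP (default 10).
#' @param tag_id tag identifier carried into the proposal.
#' @return a `primer_proposal` or `NULL`.
#' @export
propose_sd_primers <- function(sequence, snp_offsets, target_site,
                               primer_len = 20L, min_flank = 10L,
                               tag_id = "tag") {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  stopifnot(target_site %in% snp_offsets, target_site < L)
  conserved <- function(start) {
    !any(snp_offsets >= start & snp_offsets < start + primer_len)
  }
  # forward: leftmost footprint with fs + primer_len + min_flank <= target
  fs_max <- target_site - min_flank - primer_len
  fs <- NA_integer_
  if (fs_max >= 0) {
    for (s in 0:fs_max) {
      if (conserved(s)) { fs <- s; break }
    }
  }
  # reverse: rightmost footprint with rs >= target + 1 + min_flank
  rs_min <- target_site + 1L + min_flank
  rs <- NA_integer_
  if (rs_min + primer_len <= L) {
    for (s in rev(seq(rs_min, L - primer_len))) {
      if (conserved(s)) { rs <- s; break }
    }
  }
  if (is.na(fs) || is.na(rs)) return(NULL)
  primer_proposal(tag_id, "SD", sequence,
                  fwd = c(fs, fs + primer_len), rev = c(rs, rs + primer_len))
}

#' Propose a PA (allele-specific, 3'-anchored) primer pair
#'
#' Requires at least two SNPs with known male-specific (Y) alleles on the
#' tag. The forward primer's footprint ends on one SNP with the male allele
#' as its 3'-terminal base; the reverse primer's footprint starts on a
#' second, downstream SNP so that its 3'-terminal base (on the reverse
#' complement) is the complement of the male allele there. The X haplotype
#' mismatches both primers at their 3' termini and does not amplify.
#' Anchor pairs are searched leftmost-forward / rightmost-reverse (widest
#' product first); returns `NULL` when no pair fits `primer_len` within the
#' sequence.
#'
#' Primer sequences are built from the Y haplotype: every SNP inside a
#' footprint carries its male allele when known.
#'
#' @param sequence tag sequence (plus strand, X/reference haplotype).
#' @param male_alleles named character vector mapping 0-based SNP offset to
#'   the male-specific allele, e.g. `c("30" = "T", "120" = "A")`. An NA
#'   allele is an error.
#' @param primer_len primer length in bp (default 20).
#' @param tag_id tag identifier carried into the proposal.
#' @return a `primer_proposal` with `anchored_snps = c(forward, reverse)`
#'   offsets, or `NULL`.
#' @export
propose_pa_primer <- function(sequence, male_alleles, primer_len = 20L,
                              tag_id = "tag") {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (anyNA(male_alleles))
    stop("male allele missing for anchored site(s): ",
         paste(names(male_alleles)[is.na(male_alleles)], collapse = ", "))
  offs <- sort(as.integer(names(male_alleles)))
  if (length(offs) < 2L) return(NULL)
  male_alleles <- toupper(male_alleles[as.character(offs)])
  stopifnot(all(offs < L), all(male_alleles %in% c("A", "C", "G", "T")))

  # Y haplotype: substitute the male allele at every known SNP
  y_hap <- sequence
  for (k in seq_along(offs))
    substr(y_hap, offs[k] + 1L, offs[k] + 1L) <- male_alleles[[k]]

  for (i in offs) {                 # forward anchor, leftmost first
    if (i - primer_len + 1L < 0L) next
    for (j in rev(offs)) {          # reverse anchor, rightmost first
      if (j <= i || j + primer_len > L) next
      prop <- primer_proposal(tag_id, "PA", y_hap,
                              fwd = c(i - primer_len + 1L, i + 1L),
                              rev = c(j, j + primer_len),
                              anchored = c(forward = i, reverse = j))
      return(prop)
    }
  }
  NULL
}

#' Simulate exact-match annealing of a primer pair on a haplotype
#'
#' Checks whether both primers of a proposal match a haplotype sequence
#' exactly over their footprints (forward on the plus strand, reverse as the
#' reverse complement). Used by the design invariants: an SD pair must
#' anneal on both haplotypes, a PA pair only on the Y haplotype, and the X
#' haplotype must mismatch a PA pair at a 3'-terminal base.
#'
#' @param proposal a `primer_proposal`.
#' @param haplotype full tag sequence of the haplotype.
#' @return list with `fwd_match`, `rev_match` (logical), `amplifies` (both
#'   match), and `fwd_3prime_match` / `rev_3prime_match` for the terminal
#'   bases.
#' @export
anneal <- function(proposal, haplotype) {
  haplotype <- toupper(haplotype)
  f_site <- substr(haplotype, proposal$fwd_start + 1L, proposal$fwd_end)
  r_site <- revcomp(substr(haplotype, proposal$rev_start + 1L,
                           proposal$rev_end))
  f_ok <- f_site == proposal$fwd_seq
  r_ok <- r_site == proposal$rev_seq
  list(fwd_match = f_ok, rev_match = r_ok, amplifies = f_ok && r_ok,
       fwd_3prime_match = substr(f_site, nchar(f_site), nchar(f_site)) ==
         substr(proposal$fwd_seq, nchar(proposal$fwd_seq),
                nchar(proposal$fwd_seq)),
       rev_3prime_match = substr(r_site, nchar(r_site), nchar(r_site)) ==
         substr(proposal$rev_seq, nchar(proposal$rev_seq),
                nchar(proposal$rev_seq)))
}
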