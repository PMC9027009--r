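# Per-locus, per-sex summary statistics. All three detectors consume these:
# per-site allele frequencies and het/hom counts split by phenotypic sex,
# and per-tag presence counts. Unknown-sex individuals never enter any
# denominator.

#' Per-site, per-sex genotype statistics
#'
#' For every SNP site, computes per phenotypic sex the number of called
#' individuals, the reference-allele frequency over `2 * n_called` alleles
#' (called individuals only), and heterozygote / homozygote counts. A site
#' is flagged uninformative unless it has at least `min_called` called
#' individuals in each sex; the screening criteria are meaningless on
#' near-empty genotype columns.
#'
#' @param dataset a `sexmark_dataset` with at least one male and one female.
#' @param min_called minimum called individuals per sex for a site to be
#'   informative (default 5).
#' @return data.frame with one row per site: `tag_id`, `site_index`,
#'   `n_called_F`, `n_called_M`, `ref_freq_F`, `ref_freq_M`, `n_het_F`,
#'   `n_het_M`, `n_hom_F`, `n_hom_M`, `informative`.
#' @export
site_sex_stats <- function(dataset, min_called = 5L) {
  check_two_sexes(dataset)
  g <- dataset$geno
  one_sex <- function(cols) {
    gs <- g[, cols, drop = FALSE]
    called <- !is.na(gs)
    n_called <- as.integer(rowSums(called))
    n_het <- as.integer(rowSums(gs == 1L, na.rm = TRUE))
    n_hom_ref <- as.integer(rowSums(gs == 0L, na.rm = TRUE))
    ref_alleles <- 2L * n_hom_ref + n_het
    ref_freq <- ifelse(n_called > 0L, ref_alleles / (2 * n_called), NA_real_)
    list(n_called = n_called, n_het = n_het, n_hom = n_called - n_het,
         ref_freq = ref_freq)
  }
  f <- one_sex(sex_cols(dataset, "female"))
  m <- one_sex(sex_cols(dataset, "male"))
  data.frame(tag_id = dataset$sites$tag_id,
             site_index = dataset$sites$site_index,
             n_called_F = f$n_called, n_called_M = m$n_called,
             ref_freq_F = f$ref_freq, ref_freq_M = m$ref_freq,
             n_het_F = f$n_het, n_het_M = m$n_het,
             n_hom_F = f$n_hom, n_hom_M = m$n_hom,
             informative = f$n_called >= min_called & m$n_called >= min_called)
}

#' Statistics for a single site
#'
#' Convenience wrapper around [site_sex_stats()] for one `(tag_id,
#' site_index)` pair. Degenerate inputs (e.g. all calls missing in one sex)
#' yield an uninformative row, never an error.
#'
#' @param dataset a `sexmark_dataset`.
#' @param tag_id,site_index site identifier (0-based offset).
#' @inheritParams site_sex_stats
#' @return one-row data.frame as in [site_sex_stats()].
#' @export
compute_site_stats <- function(dataset, tag_id, site_index, min_called = 5L) {
  stats <- site_sex_stats(dataset, min_called = min_called)
  row <- stats[stats$tag_id == tag_id & stats$site_index == site_index, ,
               drop = FALSE]
  if (nrow(row) != 1L) stop("no such site: ", tag_id, ":", site_index)
  rownames(row) <- NULL
  row
}

#' Per-tag, per-sex presence statistics
#'
#' Counts, per phenotypic sex, the individuals in which each tag is present,
#' absent, or of unknown presence. The three counts sum to the number of
#' individuals of that sex.
#'
#' @param dataset a `sexmark_dataset`.
#' @return data.frame with one row per tag: `tag_id`, `n_present_F`,
#'   `n_absent_F`, `n_unknown_F`, `n_present_M`, `n_absent_M`, `n_unknown_M`.
#' @export
tag_presence_stats <- function(dataset) {
  check_two_sexes(dataset)
  p <- dataset$presence
  one_sex <- function(cols) {
    ps <- p[, cols, drop = FALSE]
    data.frame(present = as.integer(rowSums(ps, na.rm = TRUE)),
               absent = as.integer(rowSums(!ps, na.rm = TRUE)),
               unknown = as.integer(rowSums(is.na(ps))))
  }
  f <- one_sex(sex_cols(dataset, "female"))
  m <- one_sex(sex_cols(dataset, "male"))
  data.frame(tag_id = rownames(p),
             n_present_F = f$present, n_absent_F = f$absent,
             n_unknown_F = f$unknown,
             n_present_M = m$present, n_absent_M = m$absent,
             n_unknown_M = m$unknown)
}

#' Presence statistics for a single tag
#'
#' @param dataset a `sexmark_dataset`.
#' @param tag_id tag identifier.
#' @return one-row data.frame as in [tag_presence_stats()].
#' @export
compute_tag_presence <- function(dataset, tag_id) {
  stats <- tag_presence_stats(dataset)
  row <- stats[stats$tag_id == tag_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("no such tag: ", tag_id)
  rownames(row) <- NULL
  row
}
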