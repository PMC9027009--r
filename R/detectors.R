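# The three screening criteria for sex-linked markers, stated for an XY
# system (males heterogametic); the ZW form is the exact mirror with the
# sexes swapped:
#
#   1. allele-frequency difference — some allele has frequency >= f_fix in
#      females and exceeds its male frequency by >= d_min;
#   2. heterozygosity contrast — homozygous in all called females and
#      heterozygous in at least a fraction het_frac of called males;
#   3. sex-limited occurrence — the tag is completely absent in females and
#      present in all males.
#
# Approaches 1-2 operate on SNP sites, approach 3 on whole tags.

#' Detection thresholds
#'
#' @param f_fix minimum frequency of the near-fixed allele in the homogametic
#'   sex (default 0.95, inclusive).
#' @param d_min minimum between-sex frequency difference for that allele
#'   (default 0.4, inclusive). The difference is signed — the homogametic sex
#'   must carry the allele at the higher frequency, matching the
#'   two-copies-vs-one-copy rationale — unless `abs_diff = TRUE`.
#' @param het_frac minimum fraction of heterogametic-sex individuals that are
#'   heterozygous (default 0.5, i.e. "at least half", inclusive).
#' @param min_called minimum called individuals per sex for a site to be
#'   informative (default 5).
#' @param max_missing_presence maximum individuals of unknown tag presence
#'   tolerated per sex in the sex-limited criterion (default 0: "all" and
#'   "completely absent" are taken literally, so any unknown fails the tag).
#' @param abs_diff if TRUE, criterion 1 uses the absolute frequency
#'   difference instead of the signed one.
#' @return a `detection_params` list.
#' @export
detection_params <- function(f_fix = 0.95, d_min = 0.4, het_frac = 0.5,
                             min_called = 5L, max_missing_presence = 0L,
                             abs_diff = FALSE) {
  stopifnot(f_fix >= 0, f_fix <= 1, d_min >= 0, d_min <= 1,
            het_frac >= 0, het_frac <= 1, min_called >= 0,
            max_missing_presence >= 0)
  structure(list(f_fix = f_fix, d_min = d_min, het_frac = het_frac,
                 min_called = as.integer(min_called),
                 max_missing_presence = as.integer(max_missing_presence),
                 abs_diff = isTRUE(abs_diff)),
            class = "detection_params")
}

EPS <- 1e-9  # guards >= comparisons against floating-point representation

empty_records <- function() {
  data.frame(tag_id = character(), site_index = integer(),
             approach = character(), pattern = character(),
             n_called_F = integer(), n_called_M = integer(),
             ref_freq_F = numeric(), ref_freq_M = numeric(),
             n_het_F = integer(), n_het_M = integer(),
             n_present_F = integer(), n_present_M = integer(),
             n_absent_F = integer(), n_absent_M = integer())
}

site_record <- function(stats, approach, pattern) {
  data.frame(tag_id = stats$tag_id, site_index = stats$site_index,
             approach = approach, pattern = pattern,
             n_called_F = stats$n_called_F, n_called_M = stats$n_called_M,
             ref_freq_F = stats$ref_freq_F, ref_freq_M = stats$ref_freq_M,
             n_het_F = stats$n_het_F, n_het_M = stats$n_het_M,
             n_present_F = NA_integer_, n_present_M = NA_integer_,
             n_absent_F = NA_integer_, n_absent_M = NA_integer_)
}

tag_record <- function(pstats, pattern) {
  data.frame(tag_id = pstats$tag_id, site_index = NA_integer_,
             approach = "sex_limited", pattern = pattern,
             n_called_F = NA_integer_, n_called_M = NA_integer_,
             ref_freq_F = NA_real_, ref_freq_M = NA_real_,
             n_het_F = NA_integer_, n_het_M = NA_integer_,
             n_present_F = pstats$n_present_F, n_present_M = pstats$n_present_M,
             n_absent_F = pstats$n_absent_F, n_absent_M = pstats$n_absent_M)
}

# vectorised core of criterion 1; returns "XY", "ZW" or NA per stats row
freq_diff_pattern <- function(stats, params) {
  hit_dir <- function(f_homo, f_hetero) {
    # does some allele satisfy: freq >= f_fix in the homogametic sex and a
    # frequency difference >= d_min with the heterogametic sex?
    d_ref <- f_homo - f_hetero
    d_alt <- (1 - f_homo) - (1 - f_hetero)
    if (params$abs_diff) {
      d_ref <- abs(d_ref); d_alt <- abs(d_alt)
    }
    (f_homo >= params$f_fix - EPS & d_ref >= params$d_min - EPS) |
      ((1 - f_homo) >= params$f_fix - EPS & d_alt >= params$d_min - EPS)
  }
  xy <- hit_dir(stats$ref_freq_F, stats$ref_freq_M)
  zw <- hit_dir(stats$ref_freq_M, stats$ref_freq_F)
  # Complete opposite fixation (e.g. all females hom_ref, all males hom_alt)
  # satisfies both directions; such a site is sex-differentiated but
  # directionally ambiguous under diploid XY/ZW inheritance, so it yields no
  # record rather than an arbitrary pattern.
  both <- !is.na(xy) & !is.na(zw) & xy & zw
  out <- rep(NA_character_, nrow(stats))
  out[!is.na(xy) & xy & !both] <- "XY"
  out[!is.na(zw) & zw & !both] <- "ZW"
  out[!stats$informative] <- NA_character_
  out
}

# vectorised core of criterion 2
het_diff_pattern <- function(stats, params) {
  xy <- stats$n_het_F == 0L &
    stats$n_het_M >= params$het_frac * stats$n_called_M - EPS
  zw <- stats$n_het_M == 0L &
    stats$n_het_F >= params$het_frac * stats$n_called_F - EPS
  both <- xy & zw  # only possible when het_frac == 0 and no hets anywhere
  out <- rep(NA_character_, nrow(stats))
  out[xy & !both] <- "XY"
  out[zw & !both] <- "ZW"
  out[!stats$informative] <- NA_character_
  out
}

# vectorised core of criterion 3
sex_limited_pattern <- function(pstats, params) {
  k <- params$max_missing_presence
  ok_unknown <- pstats$n_unknown_F <= k & pstats$n_unknown_M <= k
  xy <- pstats$n_present_F == 0L & pstats$n_absent_M == 0L &
    pstats$n_present_M > 0L & ok_unknown
  zw <- pstats$n_present_M == 0L & pstats$n_absent_F == 0L &
    pstats$n_present_F > 0L & ok_unknown
  out <- rep(NA_character_, nrow(pstats))
  out[xy] <- "XY"
  out[zw] <- "ZW"
  out
}

#' Criterion 1: sex difference in allele frequency
#'
#' Emits an XY record iff some allele has frequency `>= f_fix` in females and
#' a (signed) frequency difference `>= d_min` over males; ZW by the mirrored
#' criterion. Uninformative sites yield no record.
#'
#' @param stats a one-row stats data.frame from [compute_site_stats()] or a
#'   row of [site_sex_stats()].
#' @param params a [detection_params()] object.
#' @return a one-row detection record data.frame, or `NULL`.
#' @export
detect_by_allele_frequency <- function(stats, params = detection_params()) {
  pattern <- freq_diff_pattern(stats, params)
  if (is.na(pattern)) return(NULL)
  site_record(stats, "freq_diff", pattern)
}

#' Criterion 2: sex difference in heterozygosity
#'
#' Emits an XY record iff all called females are homozygous and at least a
#' fraction `het_frac` of called males ("at least half" by default) are
#' heterozygous; ZW mirrored.
#'
#' @inheritParams detect_by_allele_frequency
#' @return a one-row detection record data.frame, or `NULL`.
#' @export
detect_by_heterozygosity <- function(stats, params = detection_params()) {
  pattern <- het_diff_pattern(stats, params)
  if (is.na(pattern)) return(NULL)
  site_record(stats, "het_diff", pattern)
}

#' Criterion 3: sex-limited tag occurrence
#'
#' Emits an XY (male-limited) record iff the tag is present in no female and
#' absent in no male; ZW (female-limited) mirrored. Under the strict default
#' any individual of unknown presence in either sex fails the tag;
#' `max_missing_presence` relaxes this explicitly.
#'
#' @param pstats a one-row presence-stats data.frame from
#'   [compute_tag_presence()] or a row of [tag_presence_stats()].
#' @param params a [detection_params()] object.
#' @return a one-row detection record data.frame, or `NULL`.
#' @export
detect_by_sex_limited <- function(pstats, params = detection_params()) {
  pattern <- sex_limited_pattern(pstats, params)
  if (is.na(pattern)) return(NULL)
  tag_record(pstats, pattern)
}

#' Build a marker catalog from a dataset
#'
#' Runs all three detectors over every site and tag and collects the
#' detection records. A tag detected by several approaches keeps one record
#' per approach but counts once among distinct tags. Approaches 1-2 are
#' tallied in both SNPs and tags; approach 3 only in tags (it has no per-SNP
#' resolution).
#'
#' @param dataset a `sexmark_dataset` with at least one male and one female.
#' @param params a [detection_params()] object.
#' @return a `marker_catalog`: list with `records` (data.frame of detection
#'   records) and `params`.
#' @export
build_catalog <- function(dataset, params = detection_params()) {
  check_two_sexes(dataset)
  stats <- site_sex_stats(dataset, min_called = params$min_called)
  pstats <- tag_presence_stats(dataset)

  recs <- list(empty_records())
  p1 <- freq_diff_pattern(stats, params)
  if (any(!is.na(p1)))
    recs <- c(recs, list(site_record(stats[!is.na(p1), , drop = FALSE],
                                     "freq_diff", p1[!is.na(p1)])))
  p2 <- het_diff_pattern(stats, params)
  if (any(!is.na(p2)))
    recs <- c(recs, list(site_record(stats[!is.na(p2), , drop = FALSE],
                                     "het_diff", p2[!is.na(p2)])))
  p3 <- sex_limited_pattern(pstats, params)
  if (any(!is.na(p3)))
    recs <- c(recs, list(tag_record(pstats[!is.na(p3), , drop = FALSE],
                                    p3[!is.na(p3)])))
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  marker_catalog(records, params = params)
}

#' Construct a marker catalog from detection records
#'
#' Useful for set-accounting on externally supplied detection records (e.g.
#' published per-approach tag lists) as well as internally by
#' [build_catalog()].
#'
#' @param records data.frame with at least `tag_id`, `site_index`,
#'   `approach` (`freq_diff|het_diff|sex_limited`), `pattern` (`XY|ZW`);
#'   missing statistic columns are filled with NA.
#' @param params optional [detection_params()] provenance.
#' @return a `marker_catalog`.
#' @export
marker_catalog <- function(records, params = detection_params()) {
  template <- empty_records()
  records <- as.data.frame(records)
  stopifnot(all(c("tag_id", "approach", "pattern") %in% names(records)))
  stopifnot(all(records$approach %in% c("freq_diff", "het_diff", "sex_limited")),
            all(records$pattern %in% c("XY", "ZW")))
  for (nm in setdiff(names(template), names(records)))
    records[[nm]] <- template[[nm]][NA_integer_][seq_len(nrow(records))]
  records <- records[, names(template), drop = FALSE]
  key <- paste(records$tag_id,
               ifelse(is.na(records$site_index), "tag", records$site_index),
               records$approach)
  if (anyDuplicated(key))
    stop("duplicate detection records for the same (site-or-tag, approach)")
  structure(list(records = records, params = params),
            class = "marker_catalog")
}

#' Distinct tags in a catalog
#' @param catalog a `marker_catalog`.
#' @return character vector of unique tag ids across all records.
#' @export
distinct_tags <- function(catalog) unique(catalog$records$tag_id)

#' Per-approach and per-pattern tallies
#'
#' @param catalog a `marker_catalog`.
#' @return list with `n_records`, `n_distinct_tags`, `snps_by_approach`
#'   (site-level records per approach), `tags_by_approach` (distinct tags per
#'   approach) and `tags_by_pattern`.
#' @export
catalog_tallies <- function(catalog) {
  rec <- catalog$records
  app <- c("freq_diff", "het_diff", "sex_limited")
  snps <- vapply(app, function(a)
    sum(rec$approach == a & !is.na(rec$site_index)), integer(1))
  tags <- vapply(app, function(a)
    length(unique(rec$tag_id[rec$approach == a])), integer(1))
  pat <- vapply(c(XY = "XY", ZW = "ZW"), function(p)
    length(unique(rec$tag_id[rec$pattern == p])), integer(1))
  list(n_records = nrow(rec),
       n_distinct_tags = length(distinct_tags(catalog)),
       snps_by_approach = snps, tags_by_approach = tags,
       tags_by_pattern = pat)
}

#' @export
print.marker_catalog <- function(x, ...) {
  t <- catalog_tallies(x)
  cat("marker catalog:", t$n_records, "detection records on",
      t$n_distinct_tags, "distinct tags\n")
  cat("  SNPs by approach:",
      paste(names(t$snps_by_approach), t$snps_by_approach, collapse = ", "),
      "\n")
  cat("  tags by approach:",
      paste(names(t$tags_by_approach), t$tags_by_approach, collapse = ", "),
      "\n")
  invisible(x)
}

#' Classify the heterogametic system
#'
#' Assigns each distinct tag a pattern (XY if all its records are XY, ZW if
#' all ZW; tags with conflicting records are excluded from both tallies) and
#' calls the system XY when the XY fraction is at least `majority`, ZW when
#' at most `1 - majority`, ambiguous otherwise (including an empty catalog).
#'
#' @param catalog a `marker_catalog`.
#' @param majority fraction of one pattern required to call the system
#'   (default 0.8).
#' @return a `system_call` list: `n_xy_tags`, `n_zw_tags`, `n_mixed_tags`,
#'   `fraction_xy`, `called_system`.
#' @export
classify_system <- function(catalog, majority = 0.8) {
  rec <- catalog$records
  pat_by_tag <- tapply(rec$pattern, rec$tag_id, function(p)
    if (all(p == "XY")) "XY" else if (all(p == "ZW")) "ZW" else "mixed")
  n_xy <- sum(pat_by_tag == "XY")
  n_zw <- sum(pat_by_tag == "ZW")
  n_mixed <- sum(pat_by_tag == "mixed")
  frac <- if (n_xy + n_zw > 0) n_xy / (n_xy + n_zw) else NA_real_
  called <- if (is.na(frac)) "ambiguous"
    else if (frac >= majority) "XY"
    else if (frac <= 1 - majority) "ZW"
    else "ambiguous"
  structure(list(n_xy_tags = n_xy, n_zw_tags = n_zw, n_mixed_tags = n_mixed,
                 fraction_xy = frac, called_system = called),
            class = "system_call")
}

#' @export
print.system_call <- function(x, ...) {
  cat("system call:", x$called_system,
      sprintf("(%d XY tags, %d ZW tags, fraction XY = %s)\n",
              x$n_xy_tags, x$n_zw_tags,
              ifelse(is.na(x$fraction_xy), "NA",
                     formatC(x$fraction_xy, digits = 4, format = "f"))))
  invisible(x)
}
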