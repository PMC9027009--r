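params1 <- detection_params(min_called = 1)

stats_of <- function(F, M, min_called = 1) {
  site_sex_stats(one_site_dataset(F, M), min_called = min_called)
}

test_that("allele-frequency criterion: thresholds are inclusive and signed", {
  # females fixed ref, males 0.5 -> XY
  r <- detect_by_allele_frequency(stats_of(rep(0L, 10), rep(1L, 10)), params1)
  expect_equal(r$pattern, "XY")
  expect_equal(r$approach, "freq_diff")

  # exactly at both thresholds: freq_F = 0.95, freq_M = 0.55 -> still XY
  F <- c(rep(0L, 9), 1L)                     # 19/20 ref alleles = 0.95
  M <- c(rep(0L, 1), rep(1L, 9))             # 11/20 = 0.55
  r2 <- detect_by_allele_frequency(stats_of(F, M), params1)
  expect_equal(r2$pattern, "XY")

  # just under the difference threshold -> none
  M3 <- c(rep(0L, 2), rep(1L, 8))            # 12/20 = 0.60, diff 0.35
  expect_null(detect_by_allele_frequency(stats_of(F, M3), params1))

  # no differentiation -> none
  expect_null(detect_by_allele_frequency(stats_of(rep(1L, 10), rep(1L, 10)),
                                         params1))

  # mirrored: males fixed, females 0.5 -> ZW
  rz <- detect_by_allele_frequency(stats_of(rep(1L, 10), rep(0L, 10)), params1)
  expect_equal(rz$pattern, "ZW")

  # opposite fixation satisfies both readings -> directionally ambiguous
  expect_null(detect_by_allele_frequency(stats_of(rep(0L, 10), rep(2L, 10)),
                                         params1))

  # uninformative stats -> no record
  expect_null(detect_by_allele_frequency(
    stats_of(rep(NA_integer_, 4), rep(1L, 4), min_called = 1), params1))
})

test_that("heterozygosity criterion: 'at least half' at the boundary", {
  # 21 females hom, 11 / 22 males het: exactly half (inclusive) -> XY
  r <- detect_by_heterozygosity(
    stats_of(rep(0L, 21), c(rep(1L, 11), rep(0L, 11))), params1)
  expect_equal(r$pattern, "XY")

  # 10 / 22 males het: below ceiling(22 / 2) = 11 -> none
  # (oracle: brute-force threshold scan over integer het counts)
  thr <- min(which(vapply(0:22, function(k) 2 * k >= 22, logical(1)))) - 1L
  expect_equal(thr, 11L)
  expect_null(detect_by_heterozygosity(
    stats_of(rep(0L, 21), c(rep(1L, 10), rep(0L, 12))), params1))

  # a single het female disqualifies regardless of males
  expect_null(detect_by_heterozygosity(
    stats_of(c(1L, rep(0L, 20)), rep(1L, 22)), params1))

  # odd male count: 3 of 5 called males is at least half, 2 of 5 is not
  expect_equal(detect_by_heterozygosity(
    stats_of(rep(0L, 5), c(rep(1L, 3), 0L, 0L)), params1)$pattern, "XY")
  expect_null(detect_by_heterozygosity(
    stats_of(rep(0L, 5), c(rep(1L, 2), 0L, 0L, 0L)), params1))

  # mirror
  expect_equal(detect_by_heterozygosity(
    stats_of(rep(1L, 10), rep(2L, 10)), params1)$pattern, "ZW")
})

test_that("sex-limited criterion is strict about absence and unknowns", {
  pres <- function(F, M) {
    ds <- toy_dataset(list(list(F = rep(0L, length(F)),
                                M = rep(0L, length(M)))),
                      presence_tags = list(cand = list(F = F, M = M)))
    compute_tag_presence(ds, "cand")
  }
  r <- detect_by_sex_limited(pres(rep(FALSE, 21), rep(TRUE, 22)), params1)
  expect_equal(r$pattern, "XY")
  expect_true(is.na(r$site_index))

  # one absent male breaks "present in all males"
  expect_null(detect_by_sex_limited(
    pres(rep(FALSE, 21), c(FALSE, rep(TRUE, 21))), params1))
  # present in everyone: not sex-limited
  expect_null(detect_by_sex_limited(
    pres(rep(TRUE, 21), rep(TRUE, 22)), params1))
  # one unknown male fails under the strict default ...
  punk <- pres(rep(FALSE, 21), c(NA, rep(TRUE, 21)))
  expect_null(detect_by_sex_limited(punk, params1))
  # ... but passes with an explicit relaxation
  relaxed <- detection_params(min_called = 1, max_missing_presence = 1)
  expect_equal(detect_by_sex_limited(punk, relaxed)$pattern, "XY")
  # mirror: female-limited -> ZW
  expect_equal(detect_by_sex_limited(
    pres(rep(TRUE, 21), rep(FALSE, 22)), params1)$pattern, "ZW")
})

test_that("build_catalog deduplicates tags but keeps per-approach records", {
  # one site that satisfies both site-level criteria
  ds <- one_site_dataset(F = rep(0L, 10), M = rep(1L, 10))
  cat1 <- build_catalog(ds, params1)
  expect_equal(nrow(cat1$records), 2L)
  expect_setequal(cat1$records$approach, c("freq_diff", "het_diff"))
  expect_equal(length(distinct_tags(cat1)), 1L)
  t <- catalog_tallies(cat1)
  expect_equal(unname(t$snps_by_approach[c("freq_diff", "het_diff")]),
               c(1L, 1L))
  expect_true(t$n_distinct_tags <= sum(t$tags_by_approach))
})

test_that("classify_system majorities and degenerate cases", {
  mk <- function(n_xy, n_zw) {
    marker_catalog(data.frame(
      tag_id = sprintf("t%04d", seq_len(n_xy + n_zw)),
      site_index = NA_integer_,
      approach = "sex_limited",
      pattern = rep(c("XY", "ZW"), c(n_xy, n_zw))))
  }
  expect_equal(classify_system(mk(0, 10))$called_system, "ZW")
  amb <- classify_system(mk(5, 5))
  expect_equal(amb$called_system, "ambiguous")
  expect_equal(amb$fraction_xy, 0.5)
  empty <- classify_system(marker_catalog(data.frame(
    tag_id = character(), site_index = integer(),
    approach = character(), pattern = character())))
  expect_equal(empty$called_system, "ambiguous")
  expect_equal(empty$n_xy_tags + empty$n_zw_tags, 0L)
  expect_true(is.na(empty$fraction_xy))
})

test_that("detector decisions equal the direct-criterion oracles (sampled)", {
  # exhaustive enumeration for <= 2 per sex here; <= 3 in the acceptance suite
  for (nF in 1:2) for (nM in 1:2) {
    gF <- enumerate_geno(nF)
    gM <- enumerate_geno(nM)
    combos <- expand.grid(f = seq_along(gF), m = seq_along(gM))
    geno_list <- lapply(seq_len(nrow(combos)), function(i)
      list(F = gF[[combos$f[i]]], M = gM[[combos$m[i]]]))
    ds <- toy_dataset(geno_list,
                      tag_ids = sprintf("cfg%04d", seq_along(geno_list)))
    stats <- site_sex_stats(ds, min_called = 1)
    cat <- build_catalog(ds, params1)
    for (i in seq_along(geno_list)) {
      tg <- sprintf("cfg%04d", i)
      rec <- cat$records[cat$records$tag_id == tg, ]
      got_freq <- rec$pattern[rec$approach == "freq_diff"]
      got_het <- rec$pattern[rec$approach == "het_diff"]
      exp_freq <- oracle_freq_diff(geno_list[[i]]$F, geno_list[[i]]$M)
      exp_het <- oracle_het_diff(geno_list[[i]]$F, geno_list[[i]]$M)
      expect_equal(if (length(got_freq)) got_freq else NA_character_,
                   exp_freq, info = paste("freq cfg", nF, nM, i))
      expect_equal(if (length(got_het)) got_het else NA_character_,
                   exp_het, info = paste("het cfg", nF, nM, i))
    }
  }
})

test_that("raising thresholds never adds detections (monotonicity)", {
  ds <- simulate_dataset(simulation_config(
    n_males = 12, n_females = 12, n_autosomal_sites = 150,
    n_sexlinked_sites = 15, n_limited_tags = 5, recomb_prob = 0.2,
    genotyping_error = 0.05, missing_rate = 0.1, seed = 99))$dataset
  base <- detection_params(f_fix = 0.8, d_min = 0.3, het_frac = 0.4)
  rec0 <- build_catalog(ds, base)$records
  key <- function(r) paste(r$tag_id, r$site_index, r$approach)
  for (p in list(detection_params(f_fix = 0.95, d_min = 0.3, het_frac = 0.4),
                 detection_params(f_fix = 0.8, d_min = 0.5, het_frac = 0.4),
                 detection_params(f_fix = 0.8, d_min = 0.3, het_frac = 0.7))) {
    rec1 <- build_catalog(ds, p)$records
    expect_true(all(key(rec1[rec1$approach != "sex_limited", ]) %in%
                      key(rec0[rec0$approach != "sex_limited", ])))
  }
})

test_that("sex-label swap mirrors every record and flips the system call", {
  sim <- simulate_dataset(simulation_config(
    n_males = 15, n_females = 14, n_autosomal_sites = 100,
    n_sexlinked_sites = 20, n_limited_tags = 8, recomb_prob = 0.1,
    genotyping_error = 0.02, missing_rate = 0.05, seed = 5))
  cat_xy <- build_catalog(sim$dataset)
  cat_zw <- build_catalog(swap_sex_labels(sim$dataset))
  flip <- function(p) ifelse(p == "XY", "ZW", "XY")
  key <- function(r) paste(r$tag_id, r$site_index, r$approach, r$pattern)
  mirrored <- cat_zw$records
  mirrored$pattern <- flip(mirrored$pattern)
  expect_setequal(key(cat_xy$records), key(mirrored))
  expect_equal(classify_system(cat_zw)$called_system, "ZW")
  expect_equal(classify_system(cat_xy)$called_system, "XY")
  expect_equal(classify_system(cat_zw)$n_zw_tags,
               classify_system(cat_xy)$n_xy_tags)
})
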