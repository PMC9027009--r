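test_that("genotype table reader: shape, unknown samples, skip accounting", {
  lines <- c(
    "tag_id\tsite\tref\talt\ts1\ts2\ts3\ts4",
    "t1\t5\tA\tT\t0/0\t0/1\t1/1\t./.",
    "t1\t9\tC\tG\t0/0\t0/0\t0/1\t0/1",
    "t2\t0\tA\tT,G\t0/0\t0/0\t0/0\t0/0",  # triallelic, skipped
    "t2\t3\tG\tC\t1/1\t./.\t0/1\t0/0")
  gt_path <- write_tsv_lines(lines)
  sm_path <- toy_sex_map_file(c("s1", "s2", "s3"), c("M", "F", "m"))

  expect_warning(ds <- read_genotype_table(gt_path, sm_path),
                 "absent from sex map")
  expect_s3_class(ds, "sexmark_dataset")
  expect_equal(unname(dataset_dims(ds)), c(4L, 3L, 2L))
  expect_equal(ds$individuals$phenotype,
               c("male", "female", "male", "unknown"))

  # skip count oracle: an independent line scan for non-single-nt alleles
  body <- strsplit(lines[-1], "\t")
  n_bad <- sum(vapply(body, function(f)
    nchar(f[3]) != 1 || nchar(f[4]) != 1 || grepl(",", f[4]), logical(1)))
  expect_equal(attr(ds, "skipped"), n_bad)
  expect_equal(n_bad, 1L)

  # genotype values survived the trip
  expect_equal(unname(ds$geno["t1:5", ]), c(0L, 1L, 2L, NA))
  expect_equal(unname(ds$geno["t2:3", ]), c(2L, NA, 1L, 0L))
})

test_that("genotype table reader rejects bad inputs", {
  sm <- toy_sex_map_file(c("s1", "s2"), c("M", "F"))
  dup <- write_tsv_lines(c("tag_id\tsite\tref\talt\ts1\ts1",
                           "t1\t0\tA\tT\t0/0\t0/1"))
  expect_error(read_genotype_table(dup, sm), "duplicated sample columns")
  badtok <- write_tsv_lines(c("tag_id\tsite\tref\talt\ts1\ts2",
                              "t1\t0\tA\tT\t0/2\t0/1"))
  expect_error(read_genotype_table(badtok, sm), "genotype token")
  empty <- write_tsv_lines(character())
  expect_error(read_genotype_table(empty, sm))
  badsex <- write_tsv_lines(c("s1\tmaybe"))
  gt <- write_tsv_lines(c("tag_id\tsite\tref\talt\ts1",
                          "t1\t0\tA\tT\t0/0"))
  expect_error(read_genotype_table(gt, badsex), "invalid sex token")
})

test_that("round trip preserves calls and phenotypes; no invented calls", {
  for (seed in 1:3) {
    ds <- random_dataset(seed = seed)
    gt <- tempfile(fileext = ".tsv"); sm <- tempfile(fileext = ".tsv")
    write_genotype_table(ds, gt, sex_map_path = sm)
    back <- read_genotype_table(gt, sm)
    expect_identical(back$geno, ds$geno)
    expect_identical(back$individuals, ds$individuals)
    expect_identical(back$sites, ds$sites)
    # reader never invents calls: token scan vs non-missing count
    toks <- unlist(strsplit(readLines(gt)[-1], "\t"))
    n_tokens <- sum(toks %in% c("0/0", "0/1", "1/1"))
    expect_equal(sum(!is.na(back$geno)), n_tokens)
  }
})

test_that("VCF reader filters to biallelic SNVs and handles odd GT values", {
  skip_if_not_installed("VariantAnnotation")
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=t1>", "##contig=<ID=t2>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "t1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t./.",
    "t1\t20\t.\tC\tG,A\t.\tPASS\t.\tGT\t0/0\t0/1\t1/2",  # triallelic: skip
    "t2\t5\t.\tG\tC\t.\tPASS\t.\tGT\t1/1\t./1\t./.",     # ./1 half-called
    "t2\t8\t.\tT\tA\t.\tPASS\t.\tGT\t0|1\t1/0\t./.")
  path <- write_tsv_lines(vcf, tempfile(fileext = ".vcf"))
  sm <- toy_sex_map_file(c("s1", "s2", "s3"), c("M", "F", "F"))
  ds <- read_vcf(path, sm)
  expect_equal(nrow(ds$sites), 3L)           # 3 biallelic of 4 records
  expect_equal(attr(ds, "skipped"), 1L)
  expect_equal(ds$sites$site_index, c(9L, 4L, 7L))  # POS - 1

  # manual parse oracle for the half-called and phased records
  expect_equal(unname(ds$geno["t2:4", ]), c(2L, NA, NA))  # ./1 -> missing
  expect_equal(unname(ds$geno["t2:7", ]), c(1L, 1L, NA))  # 0|1 and 1/0 -> het

  # s3 is all-missing but retained
  expect_true("s3" %in% ds$individuals$id)
  expect_true(all(is.na(ds$geno[, "s3"])))
  # presence derived from genotypes: s3 has no call on any tag
  expect_false(any(ds$presence[, "s3"]))

  expect_error(read_vcf(path, toy_sex_map_file("zz", "M")), "no overlap")
})

test_that("marker report: deterministic, sorted, header-only when empty", {
  empty <- marker_catalog(data.frame(tag_id = character(),
                                     site_index = integer(),
                                     approach = character(),
                                     pattern = character()))
  f1 <- tempfile()
  write_marker_report(empty, f1)
  expect_length(readLines(f1), 1L)  # header only

  rec <- data.frame(tag_id = c("tB", "tA", "tA"),
                    site_index = c(NA, 4L, 1L),
                    approach = c("sex_limited", "het_diff", "freq_diff"),
                    pattern = "XY")
  cat3 <- marker_catalog(rec)
  f2 <- tempfile(); f3 <- tempfile()
  write_marker_report(cat3, f2)
  write_marker_report(cat3, f3)
  lines <- readLines(f2)
  expect_length(lines, 4L)
  got <- vapply(strsplit(lines[-1], "\t"), function(x)
    paste(x[1], x[2]), character(1))
  expect_equal(got, c("tA 2", "tA 5", "tB tag"))  # 1-based site, tag last
  expect_identical(readLines(f2), readLines(f3)) # byte-identical rewrite
})

test_that("BLAST tabular reader orders hits and parses edge E-values", {
  hits_path <- write_tsv_lines(c(
    paste("q1", "s2", "99", "100", "1", "0", "1", "100", "200", "101",
          "1e-10", "180", sep = "\t"),
    paste("q1", "s1", "100", "100", "0", "0", "1", "100", "1", "100",
          "1e-30", "200", sep = "\t"),
    paste("q2", "s3", "100", "90", "0", "0", "1", "90", "5", "94",
          "0.0", "170", sep = "\t")))
  hits <- read_blast_tabular(hits_path)
  expect_equal(hits$evalue[hits$qseqid == "q1"], c(1e-30, 1e-10))
  expect_identical(hits$evalue[hits$qseqid == "q2"], 0)  # exact zero

  empty <- write_tsv_lines(character())
  expect_equal(nrow(read_blast_tabular(empty)), 0L)

  bad <- write_tsv_lines("q1\ts1\t100")
  expect_error(read_blast_tabular(bad), "12")
})

test_that("presence matrix file overrides derived presence", {
  gt <- write_tsv_lines(c("tag_id\tsite\tref\talt\ts1\ts2",
                          "t1\t0\tA\tT\t0/0\t0/1"))
  sm <- toy_sex_map_file(c("s1", "s2"), c("M", "F"))
  pm <- write_tsv_lines(c("tag_id\ts1\ts2", "t1\t0\tNA", "t9\t1\t0"))
  ds <- read_genotype_table(gt, sm, presence_path = pm)
  expect_false(ds$presence["t1", "s1"])
  expect_true(is.na(ds$presence["t1", "s2"]))
  expect_true(ds$presence["t9", "s1"])
})
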