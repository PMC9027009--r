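# Small in-code fixtures shared across test files.

# Build a dataset from per-sex genotype-code vectors for a set of sites.
# geno_by_site: list of list(F = c(...), M = c(...)) integer codes
# (0 hom_ref, 1 het, 2 hom_alt, NA missing); all sites share the same
# individuals. Optionally a presence list tag -> list(F =, M =) of
# TRUE/FALSE/NA for extra site-less tags.
toy_dataset <- function(geno_by_site, presence_tags = NULL,
                        tag_ids = NULL) {
  n_f <- length(geno_by_site[[1]]$F)
  n_m <- length(geno_by_site[[1]]$M)
  ids <- c(sprintf("F%02d", seq_len(n_f)), sprintf("M%02d", seq_len(n_m)))
  individuals <- data.frame(
    id = ids, phenotype = rep(c("female", "male"), c(n_f, n_m)))
  if (is.null(tag_ids)) tag_ids <- sprintf("tag%02d", seq_along(geno_by_site))
  sites <- data.frame(tag_id = tag_ids, site_index = 0L, ref = "A", alt = "T")
  geno <- do.call(rbind, lapply(geno_by_site, function(g) c(g$F, g$M)))
  presence <- NULL
  if (!is.null(presence_tags)) {
    presence <- do.call(rbind, lapply(presence_tags, function(p) c(p$F, p$M)))
    rownames(presence) <- names(presence_tags)
    colnames(presence) <- ids
  }
  new_dataset(individuals, sites, geno, presence = presence)
}

# one-site convenience
one_site_dataset <- function(F, M) toy_dataset(list(list(F = F, M = M)))

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

toy_sex_map_file <- function(ids, sexes, path = tempfile(fileext = ".tsv")) {
  writeLines(paste(ids, sexes, sep = "\t"), path)
  path
}

# random dataset used by round-trip / property tests
random_dataset <- function(n_f = 6, n_m = 6, n_sites = 30, missing = 0.1,
                           seed = 1) {
  withr::with_seed(seed, {
    ids <- c(sprintf("F%02d", seq_len(n_f)), sprintf("M%02d", seq_len(n_m)))
    individuals <- data.frame(
      id = ids, phenotype = rep(c("female", "male"), c(n_f, n_m)))
    sites <- data.frame(tag_id = sprintf("t%03d", seq_len(n_sites)),
                        site_index = sample(0:99, n_sites, replace = TRUE),
                        ref = sample(c("A", "C"), n_sites, TRUE),
                        alt = sample(c("G", "T"), n_sites, TRUE))
    geno <- matrix(sample(c(0:2, NA), n_sites * (n_f + n_m), TRUE,
                          prob = c((1 - missing) / 3, (1 - missing) / 3,
                                   (1 - missing) / 3, missing)),
                   nrow = n_sites)
    new_dataset(individuals, sites, geno)
  })
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
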