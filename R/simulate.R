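# Truth-tracked simulator for genotype catalogs with the structure the
# screening assumes: two phenotypic-sex classes, fully (or, with
# recombination leakage, partially) sex-differentiated SNP loci under XY or
# ZW inheritance, Y-(or W-)limited tags, autosomal background loci in
# Hardy-Weinberg proportions, genotype-class errors, missing calls and a
# planted fraction of sex-reversed individuals.
#
# The sex-linked model is a fully differentiated gonosomal allele with a
# per-carrier recombination/leakage probability r (the heterogametic carrier
# is homozygous for the homogametic allele with probability r) rather than
# an explicit genetic map; r stands in for distance from the
# sex-determining region.

#' Simulation configuration
#'
#' Defaults mirror the motivating study design where they are stated: 22
#' phenotypic males and 21 females in the discovery sample. Noise defaults
#' are modest rates typical of de-novo GBS genotyping (1% genotype-class
#' error, 5% missing calls, 5% recombination leakage); the acceptance
#' properties override them explicitly where a clean world is specified.
#'
#' @param n_males,n_females phenotypic sample sizes (default 22 / 21).
#' @param n_autosomal_sites background HWE SNP sites, one per tag
#'   (default 1000).
#' @param n_sexlinked_sites fully sex-differentiated SNP sites, one per tag
#'   (default 50).
#' @param n_limited_tags Y- (or W-)limited tags without SNP sites
#'   (default 20).
#' @param system `"XY"` or `"ZW"`.
#' @param recomb_prob r, per sex-linked site probability that a
#'   heterogametic carrier is recombinant, i.e. homozygous (default 0.05).
#' @param genotyping_error e, per-call probability of flipping the genotype
#'   class uniformly to one of the other two (default 0.01).
#' @param missing_rate m, per-call missing probability; also the presence
#'   dropout rate of limited tags in carriers (default 0.05).
#' @param freq_range range of autosomal reference-allele frequencies, drawn
#'   uniformly (default `c(0.05, 0.95)`).
#' @param reversal_fraction rho, fraction of individuals whose genetic sex
#'   opposes their phenotype label; `floor(rho * n)` individuals are drawn
#'   without replacement (default 0).
#' @param seed integer RNG seed; same seed, same dataset, byte for byte.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_males = 22L, n_females = 21L,
                              n_autosomal_sites = 1000L,
                              n_sexlinked_sites = 50L,
                              n_limited_tags = 20L,
                              system = c("XY", "ZW"),
                              recomb_prob = 0.05,
                              genotyping_error = 0.01,
                              missing_rate = 0.05,
                              freq_range = c(0.05, 0.95),
                              reversal_fraction = 0,
                              seed = 1L) {
  system <- match.arg(system)
  rates <- c(recomb_prob, genotyping_error, missing_rate, reversal_fraction)
  stopifnot(all(rates >= 0), all(rates <= 1),
            n_males >= 0, n_females >= 0, n_autosomal_sites >= 0,
            n_sexlinked_sites >= 0, n_limited_tags >= 0,
            length(freq_range) == 2L, freq_range[1] <= freq_range[2],
            freq_range[1] >= 0, freq_range[2] <= 1)
  structure(list(n_males = as.integer(n_males),
                 n_females = as.integer(n_females),
                 n_autosomal_sites = as.integer(n_autosomal_sites),
                 n_sexlinked_sites = as.integer(n_sexlinked_sites),
                 n_limited_tags = as.integer(n_limited_tags),
                 system = system, recomb_prob = recomb_prob,
                 genotyping_error = genotyping_error,
                 missing_rate = missing_rate, freq_range = freq_range,
                 reversal_fraction = reversal_fraction,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a genotype dataset with known truth
#'
#' Generates phenotype labels, plants sex reversals (genetic sex opposing
#' the label for a `reversal_fraction` subset), draws genotypes per the
#' locus class, then applies genotype-class error and missingness. The
#' phenotype labels — not the genetic sexes — are what the detectors see,
#' mirroring a field study where phenotype is the observable and reversal
#' is the discovery.
#'
#' Locus classes (XY; ZW is the mirror):
#' * sex-linked SNP (tags `S...`): genetic females hom_ref; genetic males
#'   het, except recombinants (probability `recomb_prob`) which are hom_ref;
#' * autosomal SNP (tags `A...`): HWE genotypes at a frequency drawn from
#'   `freq_range`, for everyone;
#' * limited tag (tags `L...`, no SNP sites): present iff carrier of the
#'   male-limited chromosome, minus dropout at `missing_rate`.
#'
#' @param config a [simulation_config()].
#' @return list with `dataset` (a `sexmark_dataset`) and `truth` (list of
#'   data.frames `individuals` (id, phenotype, genetic_sex, reversed),
#'   `sites` (tag_id, site_index, class, true_ref_freq) and `tags`
#'   (tag_id, class)).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(cfg) {
  n <- cfg$n_males + cfg$n_females
  ids <- sprintf("ind%03d", seq_len(n))
  phenotype <- rep(c("male", "female"), c(cfg$n_males, cfg$n_females))
  genetic <- phenotype
  n_rev <- floor(cfg$reversal_fraction * n)
  reversed <- rep(FALSE, n)
  if (n_rev > 0) {
    flip <- sample.int(n, n_rev)
    reversed[flip] <- TRUE
    genetic[flip] <- ifelse(phenotype[flip] == "male", "female", "male")
  }
  # the heterogametic carrier: genetic males in XY, genetic females in ZW
  carrier <- if (cfg$system == "XY") genetic == "male" else genetic == "female"

  n_auto <- cfg$n_autosomal_sites
  n_sl <- cfg$n_sexlinked_sites
  auto_tags <- sprintf("A%05d", seq_len(n_auto))
  sl_tags <- sprintf("S%05d", seq_len(n_sl))
  lim_tags <- sprintf("L%05d", seq_len(cfg$n_limited_tags))

  n_sites <- n_sl + n_auto
  sites <- data.frame(
    tag_id = c(sl_tags, auto_tags),
    site_index = rep(0L, n_sites),
    ref = rep("A", n_sites), alt = rep("T", n_sites))
  geno <- matrix(NA_integer_, nrow = n_sites, ncol = n)

  # sex-linked sites: carriers het unless recombinant; non-carriers hom_ref
  if (n_sl > 0) {
    sl <- matrix(0L, nrow = n_sl, ncol = n)
    recomb <- matrix(stats::runif(n_sl * sum(carrier)) < cfg$recomb_prob,
                     nrow = n_sl)
    sl[, carrier] <- ifelse(recomb, 0L, 1L)
    geno[seq_len(n_sl), ] <- sl
  }
  # autosomal sites: HWE at a drawn reference frequency
  p_auto <- numeric(0)
  if (n_auto > 0) {
    p_auto <- stats::runif(n_auto, cfg$freq_range[1], cfg$freq_range[2])
    q <- 1 - p_auto
    probs <- cbind(p_auto^2, 2 * p_auto * q, q^2)  # hom_ref, het, hom_alt
    u <- matrix(stats::runif(n_auto * n), nrow = n_auto)
    g <- (u > probs[, 1]) + (u > probs[, 1] + probs[, 2])
    geno[n_sl + seq_len(n_auto), ] <- as.integer(g)
  }

  # genotype-class error: flip to one of the other two classes uniformly
  if (cfg$genotyping_error > 0 && n_sites > 0) {
    err <- matrix(stats::runif(n_sites * n) < cfg$genotyping_error,
                  nrow = n_sites)
    shift <- matrix(sample(c(1L, 2L), n_sites * n, replace = TRUE),
                    nrow = n_sites)
    geno[err] <- (geno[err] + shift[err]) %% 3L
  }
  # missingness
  if (cfg$missing_rate > 0 && n_sites > 0) {
    miss <- matrix(stats::runif(n_sites * n) < cfg$missing_rate,
                   nrow = n_sites)
    geno[miss] <- NA_integer_
  }

  # limited tags: present iff carrier, with dropout at missing_rate
  all_tags <- c(sl_tags, auto_tags, lim_tags)
  presence <- derive_presence(sites$tag_id, geno, all_tags, ids)
  if (cfg$n_limited_tags > 0) {
    pres_lim <- matrix(rep(carrier, each = cfg$n_limited_tags),
                       nrow = cfg$n_limited_tags)
    if (cfg$missing_rate > 0) {
      drop <- matrix(stats::runif(length(pres_lim)) < cfg$missing_rate,
                     nrow = nrow(pres_lim))
      pres_lim <- pres_lim & !drop
    }
    presence[lim_tags, ] <- pres_lim
  }

  dataset <- new_dataset(
    individuals = data.frame(id = ids, phenotype = phenotype),
    sites = sites, geno = geno, presence = presence)

  truth <- list(
    individuals = data.frame(id = ids, phenotype = phenotype,
                             genetic_sex = genetic, reversed = reversed),
    sites = data.frame(tag_id = sites$tag_id, site_index = sites$site_index,
                       class = rep(c("sexlinked_snp", "autosomal"),
                                   c(n_sl, n_auto)),
                       true_ref_freq = c(rep(NA_real_, n_sl), p_auto)),
    tags = data.frame(tag_id = all_tags,
                      class = rep(c("sexlinked_snp", "autosomal",
                                    "limited_tag"),
                                  c(n_sl, n_auto, cfg$n_limited_tags))))
  list(dataset = dataset, truth = truth)
}

#' Score a catalog against simulation truth
#'
#' @param truth truth list from [simulate_dataset()].
#' @param catalog a `marker_catalog` built from the matching dataset.
#' @return list with `recall` (named: `freq_diff` and `het_diff` over
#'   planted sex-linked SNP sites, `sex_limited` over planted limited tags),
#'   `false_positives` (named: autosomal sites detected per site-level
#'   approach, autosomal or sex-linked-SNP tags hit by `sex_limited`), and
#'   `confusion` (table of truth class x detection approach over records).
#' @export
evaluate_detection <- function(truth, catalog) {
  rec <- catalog$records
  site_class <- truth$sites$class[match(paste(rec$tag_id, rec$site_index),
                                        paste(truth$sites$tag_id,
                                              truth$sites$site_index))]
  tag_class <- truth$tags$class[match(rec$tag_id, truth$tags$tag_id)]
  if (anyNA(tag_class))
    stop("catalog contains tags absent from the truth table")
  cls <- ifelse(rec$approach == "sex_limited", tag_class, site_class)

  sl_sites <- truth$sites$tag_id[truth$sites$class == "sexlinked_snp"]
  lim_tags <- truth$tags$tag_id[truth$tags$class == "limited_tag"]
  recall_site <- function(approach) {
    if (!length(sl_sites)) return(NA_real_)
    hit <- rec$tag_id[rec$approach == approach & cls %in% "sexlinked_snp"]
    length(unique(hit)) / length(sl_sites)
  }
  recall <- c(freq_diff = recall_site("freq_diff"),
              het_diff = recall_site("het_diff"),
              sex_limited = if (!length(lim_tags)) NA_real_ else
                length(unique(rec$tag_id[rec$approach == "sex_limited" &
                                           cls %in% "limited_tag"])) /
                length(lim_tags))
  fp <- c(freq_diff = sum(rec$approach == "freq_diff" & cls %in% "autosomal"),
          het_diff = sum(rec$approach == "het_diff" & cls %in% "autosomal"),
          sex_limited = sum(rec$approach == "sex_limited" &
                              !cls %in% "limited_tag"))
  list(recall = recall, false_positives = fp,
       confusion = table(truth_class = cls, approach = rec$approach))
}
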