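# Core container: a genotype catalog with phenotypic-sex metadata.
#
# Genotype classes are encoded as integers throughout the package:
#   0 = hom_ref, 1 = het, 2 = hom_alt, NA = missing.
# Site coordinates are 0-based half-open internally; human-readable reports
# use 1-based positions.

GENO_LEVELS <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
SEX_LEVELS <- c("male", "female", "unknown")

#' Construct a genotype Dataset
#'
#' Bundles individuals (with phenotypic sex), biallelic SNP sites grouped on
#' tags, a per-individual genotype matrix, and a per-tag presence matrix into
#' the container every downstream stage consumes.
#'
#' @param individuals data.frame with columns `id` (unique character) and
#'   `phenotype` (one of `"male"`, `"female"`, `"unknown"`).
#' @param sites data.frame with columns `tag_id`, `site_index` (0-based offset
#'   within the tag), `ref`, `alt` (single nucleotides). May have zero rows.
#' @param geno integer matrix, `nrow(sites)` x `nrow(individuals)`, coded
#'   0 = hom_ref, 1 = het, 2 = hom_alt, NA = missing. A character matrix of
#'   `"0/0"`, `"0/1"`, `"1/1"`, `"./."` tokens is accepted and recoded.
#' @param presence optional logical matrix (tags x individuals; NA = unknown
#'   presence) with rownames naming tags. When `NULL`, presence is derived
#'   from the genotypes: a tag is present in a sample iff it has at least one
#'   non-missing call at any of its sites.
#' @param tag_sequences optional named character vector of tag sequences.
#' @return An object of class `sexmark_dataset`.
#' @export
new_dataset <- function(individuals, sites, geno, presence = NULL,
                        tag_sequences = NULL) {
  individuals <- as.data.frame(individuals)
  stopifnot(all(c("id", "phenotype") %in% names(individuals)))
  individuals$id <- as.character(individuals$id)
  individuals$phenotype <- as.character(individuals$phenotype)
  if (anyDuplicated(individuals$id))
    stop("duplicated individual ids: ",
         paste(unique(individuals$id[duplicated(individuals$id)]), collapse = ", "))
  bad <- setdiff(unique(individuals$phenotype), SEX_LEVELS)
  if (length(bad))
    stop("invalid phenotype value(s): ", paste(bad, collapse = ", "))

  sites <- as.data.frame(sites)
  if (nrow(sites) == 0L)
    sites <- data.frame(tag_id = character(), site_index = integer(),
                        ref = character(), alt = character())
  stopifnot(all(c("tag_id", "site_index", "ref", "alt") %in% names(sites)))
  sites$tag_id <- as.character(sites$tag_id)
  sites$site_index <- as.integer(sites$site_index)
  ord <- seq_len(nrow(sites))
  if (nrow(sites)) {
    if (any(nchar(sites$ref) != 1L) || any(nchar(sites$alt) != 1L))
      stop("sites must be biallelic SNPs with single-nucleotide ref and alt")
    # offsets strictly increasing within each tag
    ord <- order(match(sites$tag_id, unique(sites$tag_id)), sites$site_index)
    sites <- sites[ord, , drop = FALSE]
    dup <- duplicated(paste(sites$tag_id, sites$site_index))
    if (any(dup))
      stop("duplicated (tag_id, site_index) pairs")
  }
  rownames(sites) <- NULL

  if (is.character(geno)) geno <- recode_gt_tokens(geno)
  geno <- matrix(as.integer(geno), nrow = nrow(sites),
                 ncol = nrow(individuals))
  geno <- geno[ord, , drop = FALSE]  # keep rows aligned with sorted sites
  dimnames(geno) <- list(site_key(sites$tag_id, sites$site_index),
                         individuals$id)
  if (any(!is.na(geno) & !(geno %in% 0:2)))
    stop("genotype codes must be 0, 1, 2 or NA")

  tag_ids <- unique(c(sites$tag_id, rownames(presence)))
  if (is.null(presence)) {
    presence <- derive_presence(sites$tag_id, geno, tag_ids, individuals$id)
  } else {
    presence <- as.matrix(presence)
    if (is.null(rownames(presence)))
      stop("presence matrix needs tag rownames")
    storage.mode(presence) <- "logical"
    miss_tags <- setdiff(tag_ids, rownames(presence))
    if (length(miss_tags)) {
      derived <- derive_presence(sites$tag_id, geno, miss_tags, individuals$id)
      presence <- rbind(presence, derived)
    }
    presence <- presence[tag_ids, individuals$id, drop = FALSE]
  }

  if (!is.null(tag_sequences)) {
    stopifnot(!is.null(names(tag_sequences)))
    tag_sequences <- toupper(as.character(stats::setNames(tag_sequences,
                                                          names(tag_sequences))))
    # site offsets must fall inside a supplied sequence
    for (tg in intersect(names(tag_sequences), sites$tag_id)) {
      off <- sites$site_index[sites$tag_id == tg]
      if (any(off >= nchar(tag_sequences[[tg]])))
        stop("site offset beyond sequence length for tag ", tg)
    }
  }

  structure(list(individuals = individuals, sites = sites, geno = geno,
                 presence = presence, tag_sequences = tag_sequences),
            class = "sexmark_dataset")
}

site_key <- function(tag_id, site_index) {
  if (!length(tag_id)) return(character())
  paste0(tag_id, ":", site_index)
}

derive_presence <- function(site_tags, geno, tag_ids, ind_ids) {
  pres <- matrix(FALSE, nrow = length(tag_ids), ncol = length(ind_ids),
                 dimnames = list(tag_ids, ind_ids))
  if (length(site_tags)) {
    n_called <- rowsum(1L * !is.na(geno), group = site_tags, reorder = FALSE)
    keep <- intersect(rownames(n_called), tag_ids)
    pres[keep, ] <- n_called[keep, , drop = FALSE] > 0L
  }
  pres
}

recode_gt_tokens <- function(x) {
  out <- match(x, c("0/0", "0/1", "1/1")) - 1L
  bad <- is.na(out) & !(x %in% c("./.", NA_character_))
  if (any(bad))
    stop("genotype token outside {0/0, 0/1, 1/1, ./.}: ",
         paste(utils::head(unique(x[bad]), 5), collapse = ", "))
  dim(out) <- dim(x)
  out
}

gt_token <- function(code) {
  tok <- c("0/0", "0/1", "1/1")[code + 1L]
  tok[is.na(tok)] <- "./."
  tok
}

#' @export
print.sexmark_dataset <- function(x, ...) {
  ph <- table(factor(x$individuals$phenotype, SEX_LEVELS))
  cat("sexmark dataset:", nrow(x$individuals), "individuals (",
      ph[["male"]], "M /", ph[["female"]], "F /", ph[["unknown"]], "U ),",
      nrow(x$sites), "SNP sites on", nrow(x$presence), "tags\n")
  invisible(x)
}

#' Number of individuals / sites / tags in a dataset
#' @param dataset a `sexmark_dataset`.
#' @return named integer vector.
#' @export
dataset_dims <- function(dataset) {
  c(individuals = nrow(dataset$individuals), sites = nrow(dataset$sites),
    tags = nrow(dataset$presence))
}

# column indices of individuals of a given phenotype
sex_cols <- function(dataset, sex) {
  which(dataset$individuals$phenotype == sex)
}

check_two_sexes <- function(dataset) {
  n_m <- length(sex_cols(dataset, "male"))
  n_f <- length(sex_cols(dataset, "female"))
  if (n_m < 1L || n_f < 1L)
    stop("dataset must contain at least one male and one female ",
         "with known phenotype (", n_m, " males, ", n_f, " females)")
  invisible(TRUE)
}

#' Swap male and female phenotype labels
#'
#' Utility used by the XY/ZW mirror properties: every male becomes female and
#' vice versa; unknowns are untouched. Genotypes and presence are unchanged.
#'
#' @param dataset a `sexmark_dataset`.
#' @return the relabeled dataset.
#' @export
swap_sex_labels <- function(dataset) {
  ph <- dataset$individuals$phenotype
  dataset$individuals$phenotype <-
    ifelse(ph == "male", "female", ifelse(ph == "female", "male", ph))
  dataset
}
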