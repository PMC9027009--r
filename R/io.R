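# Readers and writers for the plain-text formats the pipeline touches:
# genotype table TSV (the canonical internal dialect), sample-sex map,
# tag presence matrix, VCF (converted on read), BLAST tabular (outfmt 6),
# marker report TSV and confirmed-marker BED.

#' Read a sample-to-sex map
#'
#' Two-column TSV (no header required; a `sample<TAB>sex` header line is
#' tolerated) mapping sample id to phenotypic sex. Tokens `M`, `F`, `U`
#' (case-insensitive; `male`/`female`/`unknown` also accepted). Any other
#' token is an error rather than a silent unknown, so sample-sheet bugs
#' surface immediately.
#'
#' @param path TSV file path.
#' @return named character vector sample -> `"male"|"female"|"unknown"`.
#' @export
read_sex_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(tab) < 2L) stop("sex map must have two columns (sample, sex)")
  if (tolower(tab[1, 2]) %in% c("sex", "phenotype"))
    tab <- tab[-1, , drop = FALSE]
  if (nrow(tab) == 0L) stop("empty sex map: ", path)
  tok <- tolower(tab[[2]])
  sex <- c(m = "male", male = "male", f = "female", female = "female",
           u = "unknown", unknown = "unknown")[tok]
  if (anyNA(sex))
    stop("invalid sex token(s) in map: ",
         paste(unique(tab[[2]][is.na(sex)]), collapse = ", "))
  if (anyDuplicated(tab[[1]]))
    stop("duplicated sample ids in sex map")
  stats::setNames(unname(sex), tab[[1]])
}

make_individuals <- function(sample_ids, sex_map) {
  phenotype <- unname(sex_map[sample_ids])
  missing <- is.na(phenotype)
  if (any(missing)) {
    warning("sample(s) absent from sex map, set to unknown: ",
            paste(sample_ids[missing], collapse = ", "))
    phenotype[missing] <- "unknown"
  }
  data.frame(id = sample_ids, phenotype = phenotype)
}

#' Read a genotype table
#'
#' Canonical input dialect: a TSV with header
#' `tag_id  site  ref  alt  <sample1> <sample2> ...` where `site` is the
#' 0-based offset of the SNP within its tag and genotype tokens are
#' `0/0`, `0/1`, `1/1`, `./.`. Rows that are not biallelic SNPs (multi-base
#' or comma-separated alleles) are skipped and counted in the skip report
#' attached as attribute `"skipped"`.
#'
#' @param path genotype table path.
#' @param sex_map_path sample-sex map path (see [read_sex_map()]). Samples in
#'   the table but not in the map become `unknown` with a warning.
#' @param presence_path optional tag presence matrix TSV (`tag_id` column then
#'   one 0/1/NA column per sample) overriding genotype-derived presence.
#' @return a `sexmark_dataset`; attribute `"skipped"` holds the number of
#'   non-biallelic rows dropped.
#' @export
read_genotype_table <- function(path, sex_map_path, presence_path = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "")
  if (nrow(tab) == 0L && ncol(tab) == 0L) stop("empty genotype table: ", path)
  need <- c("tag_id", "site", "ref", "alt")
  if (!all(need %in% names(tab)))
    stop("genotype table header must start with: ", paste(need, collapse = ", "))
  sample_ids <- names(tab)[!names(tab) %in% need]
  if (!length(sample_ids)) stop("genotype table has no sample columns")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample columns: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))

  ok <- grepl("^[ACGTacgt]$", tab$ref) & grepl("^[ACGTacgt]$", tab$alt)
  n_skipped <- sum(!ok)
  tab <- tab[ok, , drop = FALSE]

  sex_map <- read_sex_map(sex_map_path)
  individuals <- make_individuals(sample_ids, sex_map)
  sites <- data.frame(tag_id = tab$tag_id, site_index = as.integer(tab$site),
                      ref = toupper(tab$ref), alt = toupper(tab$alt))
  geno <- as.matrix(tab[, sample_ids, drop = FALSE])

  presence <- if (!is.null(presence_path)) read_presence_matrix(presence_path)
  ds <- new_dataset(individuals, sites, geno, presence = presence)
  attr(ds, "skipped") <- n_skipped
  ds
}

#' Write a dataset in the genotype-table dialect
#'
#' Inverse of [read_genotype_table()]: round-tripping preserves genotype
#' calls, site definitions and sample order.
#'
#' @param dataset a `sexmark_dataset`.
#' @param path output TSV path.
#' @param sex_map_path optional path to also write the sample-sex map.
#' @param presence_path optional path to also write the tag presence matrix.
#' @return invisibly, `path`.
#' @export
write_genotype_table <- function(dataset, path, sex_map_path = NULL,
                                 presence_path = NULL) {
  toks <- matrix(gt_token(dataset$geno), nrow = nrow(dataset$sites))
  out <- cbind(data.frame(tag_id = dataset$sites$tag_id,
                          site = dataset$sites$site_index,
                          ref = dataset$sites$ref, alt = dataset$sites$alt),
               as.data.frame(toks))
  names(out) <- c("tag_id", "site", "ref", "alt", dataset$individuals$id)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sex_map_path)) {
    sex <- c(male = "M", female = "F", unknown = "U")[dataset$individuals$phenotype]
    utils::write.table(data.frame(dataset$individuals$id, unname(sex)),
                       sex_map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(presence_path)) {
    pm <- dataset$presence
    out <- data.frame(tag_id = rownames(pm),
                      matrix(as.integer(pm), nrow = nrow(pm)),
                      check.names = FALSE)
    names(out) <- c("tag_id", colnames(pm))
    utils::write.table(out, presence_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  invisible(path)
}

#' Read a tag presence matrix
#'
#' TSV with a `tag_id` column then one column per sample holding 1 (present),
#' 0 (absent) or NA (unknown).
#'
#' @param path TSV path.
#' @return logical matrix tags x samples with NA for unknown presence.
#' @export
read_presence_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, na.strings = c("NA", "."))
  stopifnot("tag_id" %in% names(tab))
  m <- as.matrix(tab[, setdiff(names(tab), "tag_id"), drop = FALSE])
  storage.mode(m) <- "logical"
  rownames(m) <- as.character(tab$tag_id)
  m
}

#' Read a VCF into a dataset
#'
#' Converts a GT-bearing VCF to the internal genotype-table representation.
#' Only biallelic SNV records are retained; the tag id is taken from CHROM
#' and the 0-based site offset from POS - 1 (VCF POS is 1-based within the
#' tag sequence). Half-called genotypes (e.g. `./1`) are treated as missing.
#' Tag presence is derived from the genotypes (present iff any non-missing
#' call on the tag) unless `presence_path` overrides it.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param sex_map_path sample-sex map path.
#' @param presence_path optional presence matrix TSV.
#' @return a `sexmark_dataset`; attribute `"skipped"` counts non-biallelic
#'   or non-SNV records dropped.
#' @export
read_vcf <- function(path, sex_map_path, presence_path = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf() requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  if (!"GT" %in% rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf))))
    stop("VCF has no GT genotype field")
  gt <- VariantAnnotation::geno(vcf)$GT
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  n_alt <- S4Vectors::elementNROWS(altl)
  alt1 <- rep(NA_character_, length(ref))
  alt1[n_alt == 1L] <- as.character(unlist(altl[n_alt == 1L]))
  keep <- n_alt == 1L & nchar(ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L &
    alt1 %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)

  sample_ids <- colnames(gt)
  sex_map <- read_sex_map(sex_map_path)
  if (!any(sample_ids %in% names(sex_map)))
    stop("no overlap between VCF samples and sex map")
  individuals <- make_individuals(sample_ids, sex_map)

  gt <- gt[keep, , drop = FALSE]
  code <- gt_to_code(gt)
  sites <- data.frame(tag_id = as.character(GenomeInfoDb::seqnames(rr))[keep],
                      site_index = BiocGenerics::start(rr)[keep] - 1L,
                      ref = ref[keep], alt = alt1[keep])
  presence <- if (!is.null(presence_path)) read_presence_matrix(presence_path)
  ds <- new_dataset(individuals, sites, code, presence = presence)
  attr(ds, "skipped") <- n_skipped
  ds
}

# VCF GT strings -> integer genotype codes; anything half-called or
# multi-allelic becomes NA (missing)
gt_to_code <- function(gt) {
  norm <- gsub("\\|", "/", gt)
  out <- match(norm, c("0/0", "0/1", "1/1")) - 1L
  out[norm == "1/0"] <- 1L
  dim(out) <- dim(gt)
  out
}

#' Write a marker report
#'
#' One TSV row per detection record: tag, 1-based site position (or `tag` for
#' presence/absence hits), approach, XY/ZW pattern and the supporting
#' statistics. Rows are sorted by (tag_id, site) so repeated writes of the
#' same catalog are byte-identical.
#'
#' @param catalog a `marker_catalog` (see [build_catalog()]).
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_marker_report <- function(catalog, path) {
  rec <- catalog$records
  ord <- order(rec$tag_id, rec$site_index, rec$approach, na.last = FALSE,
               method = "radix")
  rec <- rec[ord, , drop = FALSE]
  rec$site <- ifelse(is.na(rec$site_index), "tag",
                     as.character(rec$site_index + 1L))
  cols <- c("tag_id", "site", "approach", "pattern",
            "n_called_F", "n_called_M", "ref_freq_F", "ref_freq_M",
            "n_het_F", "n_het_M", "n_present_F", "n_present_M",
            "n_absent_F", "n_absent_M")
  out <- rec[, cols]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) ifelse(is.na(x), "NA",
                                                  format(x, digits = 10)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read BLAST tabular output (outfmt 6)
#'
#' Parses the 12-column tabular dialect (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`). Hits are
#' returned ordered by query, then ascending E-value, then descending
#' bitscore, then subject id, so "best hit" and "second hit" are
#' deterministic.
#'
#' @param path tabular alignment file; an empty file yields zero hits.
#' @return data.frame of hits with the 12 standard columns.
#' @export
read_blast_tabular <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  info <- file.info(path)
  if (is.na(info$size)) stop("no such file: ", path)
  if (info$size == 0L) {
    out <- as.data.frame(stats::setNames(
      c(list(character(), character()), rep(list(numeric()), 10)), cols))
    return(out)
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(tab) != 12L)
    stop("expected 12 tab-separated columns (outfmt 6), got ", ncol(tab))
  names(tab) <- cols
  for (nm in cols[3:12]) {
    v <- suppressWarnings(as.numeric(tab[[nm]]))
    if (anyNA(v)) stop("unparseable numeric value in column ", nm)
    tab[[nm]] <- v
  }
  tab[order(tab$qseqid, tab$evalue, -tab$bitscore, tab$sseqid,
            method = "radix"), , drop = FALSE]
}

#' Write confirmed markers as BED
#'
#' Emits 0-based half-open subject intervals for confirmed tags, using each
#' tag's best hit. Reverse-strand hits (sstart > send) are normalised with
#' strand `-`.
#'
#' @param records confirmation records from [confirm_to_reference()].
#' @param path output BED path.
#' @return invisibly, `path`.
#' @export
write_confirmed_bed <- function(records, path) {
  conf <- records[records$confirmed & !is.na(records$subject_id), , drop = FALSE]
  lo <- pmin(conf$sstart, conf$send)
  hi <- pmax(conf$sstart, conf$send)
  bed <- data.frame(chrom = conf$subject_id, start = lo - 1L, end = hi,
                    name = conf$tag_id, score = round(conf$bitscore),
                    strand = ifelse(conf$sstart <= conf$send, "+", "-"))
  bed <- bed[order(bed$chrom, bed$start, bed$name, method = "radix"), ]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
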