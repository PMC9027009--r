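# Genotypic sexing from a validated marker panel, and flagging of
# discordance between genotypic and phenotypic sex (putative sex reversal).
#
# Marker evidence under an XY system:
#   SD (sequence-difference) marker, site-level:
#     heterozygous -> heterogametic (genetic male); homozygous -> genetic
#     female; missing -> no evidence.
#   PA (presence/absence) marker, tag-level:
#     tag present -> carries the Y (genetic male); absent -> genetic female;
#     unknown presence -> no evidence.
# Under ZW the heterogametic carrier is the genetic female.

#' Define a marker panel
#'
#' @param tag_id character vector of tag ids.
#' @param site_index 0-based site offsets; NA for tag-level (PA) markers.
#' @param marker_type `"SD"` (site heterozygosity) or `"PA"` (tag presence)
#'   per marker.
#' @param system `"XY"` or `"ZW"`; one system for the whole panel.
#' @return a `marker_panel` data.frame.
#' @export
marker_panel <- function(tag_id, site_index = NA_integer_, marker_type,
                         system = c("XY", "ZW")) {
  system <- match.arg(system)
  stopifnot(length(tag_id) >= 1L, all(marker_type %in% c("SD", "PA")))
  entries <- data.frame(tag_id = as.character(tag_id),
                        site_index = as.integer(site_index),
                        marker_type = marker_type)
  if (any(entries$marker_type == "SD" & is.na(entries$site_index)))
    stop("SD markers need a site_index")
  structure(list(entries = entries, system = system), class = "marker_panel")
}

#' Call genotypic sex from a marker panel
#'
#' For each individual, every panel marker contributes evidence for the
#' heterogametic or homogametic genotype (or none, when missing). The
#' genetic sex is the side holding a strict majority of the non-missing
#' evidence (`> majority` as a fraction); ties or fewer than `min_markers`
#' pieces of evidence leave the individual uncalled — never guessed. With
#' `any_y = TRUE` a single piece of heterogametic evidence suffices (the
#' "one Y allele is enough" reading).
#'
#' @param dataset a `sexmark_dataset`.
#' @param panel a [marker_panel()].
#' @param min_markers minimum non-missing evidence count to call (default 1).
#' @param majority fraction that must be exceeded for a call (default 0.5 =
#'   strict majority).
#' @param any_y if TRUE, any heterogametic evidence assigns the
#'   heterogametic sex regardless of majority.
#' @return data.frame with one row per individual: `individual_id`,
#'   `phenotype`, `n_support_heterogametic`, `n_support_homogametic`,
#'   `n_missing`, `inferred` (`genetic_male`/`genetic_female`/`uncalled`),
#'   `discordant`.
#' @export
call_genotypic_sex <- function(dataset, panel, min_markers = 1L,
                               majority = 0.5, any_y = FALSE) {
  entries <- panel$entries
  n_ind <- nrow(dataset$individuals)

  evid <- matrix(NA_integer_, nrow = nrow(entries), ncol = n_ind)  # 1=heterogametic, 0=homogametic
  missing_markers <- character()
  for (i in seq_len(nrow(entries))) {
    e <- entries[i, ]
    if (e$marker_type == "SD") {
      key <- site_key(e$tag_id, e$site_index)
      if (!key %in% rownames(dataset$geno)) {
        missing_markers <- c(missing_markers, key); next
      }
      g <- dataset$geno[key, ]
      evid[i, ] <- ifelse(is.na(g), NA_integer_, as.integer(g == 1L))
    } else {
      if (!e$tag_id %in% rownames(dataset$presence)) {
        missing_markers <- c(missing_markers, e$tag_id); next
      }
      p <- dataset$presence[e$tag_id, ]
      evid[i, ] <- ifelse(is.na(p), NA_integer_, as.integer(p))
    }
  }
  if (length(missing_markers))
    stop("panel markers absent from dataset: ",
         paste(missing_markers, collapse = ", "))

  n_het <- colSums(evid == 1L, na.rm = TRUE)
  n_hom <- colSums(evid == 0L, na.rm = TRUE)
  n_miss <- colSums(is.na(evid))
  n_evid <- n_het + n_hom

  heterogametic <- if (panel$system == "XY") "genetic_male" else "genetic_female"
  homogametic <- if (panel$system == "XY") "genetic_female" else "genetic_male"
  inferred <- rep("uncalled", n_ind)
  callable <- n_evid >= min_markers
  inferred[callable & n_het / pmax(n_evid, 1L) > majority] <- heterogametic
  inferred[callable & n_hom / pmax(n_evid, 1L) > majority] <- homogametic
  if (any_y) inferred[callable & n_het > 0L] <- heterogametic

  phen <- dataset$individuals$phenotype
  phen_genetic <- c(male = "genetic_male", female = "genetic_female",
                    unknown = NA_character_)[phen]
  discordant <- inferred != "uncalled" & !is.na(phen_genetic) &
    inferred != phen_genetic

  data.frame(individual_id = dataset$individuals$id,
             phenotype = phen,
             n_support_heterogametic = n_het,
             n_support_homogametic = n_hom,
             n_missing = n_miss,
             inferred = inferred,
             discordant = discordant)
}

#' Summarize putative sex reversals
#'
#' @param calls data.frame from [call_genotypic_sex()].
#' @return list with `n_individuals`, `n_called`, `n_discordant`,
#'   `discordant_ids`, `n_discordant_by_phenotype` (named vector over
#'   male/female), and `fraction_discordant` among called individuals (NA
#'   when nothing was called).
#' @export
summarize_reversals <- function(calls) {
  called <- calls$inferred != "uncalled"
  disc <- calls[calls$discordant, , drop = FALSE]
  by_phen <- vapply(c(male = "male", female = "female"), function(s)
    sum(disc$phenotype == s), integer(1))
  list(n_individuals = nrow(calls),
       n_called = sum(called),
       n_discordant = nrow(disc),
       discordant_ids = disc$individual_id,
       n_discordant_by_phenotype = by_phen,
       fraction_discordant = if (sum(called)) nrow(disc) / sum(called)
                             else NA_real_)
}
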