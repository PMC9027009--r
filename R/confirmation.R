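# Alignment-based confirmation of putative markers. Consumes pre-computed
# BLAST tabular hits; running the aligner is out of scope. Two rules:
#
#   top-hit rule   — a tag is confirmed iff its best (lowest-E) hit against
#                    the reference has E <= e_max (inclusive);
#   margin rule    — for gene matching, the best hit must additionally beat
#                    the second hit by >= margin_orders orders of magnitude,
#                    and its E must be strictly below e_max.

#' Confirmation thresholds
#'
#' @param e_max E-value cutoff for the best hit (default 1e-20; inclusive for
#'   the top-hit rule, strict for the margin rule, as the two rules are
#'   stated).
#' @param margin_orders minimum number of orders of magnitude separating the
#'   best from the second hit under the margin rule (default 5).
#' @return a `confirmation_params` list.
#' @export
confirmation_params <- function(e_max = 1e-20, margin_orders = 5) {
  stopifnot(e_max > 0, margin_orders >= 0)
  structure(list(e_max = e_max, margin_orders = margin_orders),
            class = "confirmation_params")
}

# best and second-best hit per query; ties at identical E break by higher
# bitscore, then subject id, for determinism
rank_hits <- function(hits) {
  hits <- hits[order(hits$qseqid, hits$evalue, -hits$bitscore, hits$sseqid,
                     method = "radix"), , drop = FALSE]
  first <- !duplicated(hits$qseqid)
  rank <- sequence(rle(hits$qseqid)$lengths)
  list(best = hits[first, , drop = FALSE],
       second = hits[rank == 2L, , drop = FALSE])
}

approaches_by_tag <- function(catalog) {
  rec <- catalog$records
  tapply(rec$approach, rec$tag_id, function(a)
    paste(sort(unique(a)), collapse = ","))
}

confirmation_frame <- function(catalog, best, ok, rule) {
  tags <- distinct_tags(catalog)
  idx <- match(tags, best$qseqid)
  apps <- approaches_by_tag(catalog)
  data.frame(tag_id = tags,
             confirmed = !is.na(idx) & ok[idx],
             rule = rule,
             approaches = unname(apps[tags]),
             subject_id = best$sseqid[idx],
             evalue = best$evalue[idx],
             bitscore = best$bitscore[idx],
             sstart = best$sstart[idx],
             send = best$send[idx])
}

#' Confirm putative markers against a reference (top-hit rule)
#'
#' Each catalog tag is confirmed iff its best hit has `evalue <= e_max`.
#' Tags without hits are unconfirmed; hit queries absent from the catalog
#' are ignored with a message.
#'
#' @param catalog a `marker_catalog`.
#' @param hits data.frame from [read_blast_tabular()].
#' @param params a [confirmation_params()] object.
#' @return data.frame of confirmation records: `tag_id`, `confirmed`,
#'   `rule`, `approaches` (provenance from the catalog), best-hit snapshot
#'   columns.
#' @export
confirm_to_reference <- function(catalog, hits,
                                 params = confirmation_params()) {
  orphan <- setdiff(unique(hits$qseqid), distinct_tags(catalog))
  if (length(orphan))
    message(length(orphan), " hit quer",
            if (length(orphan) == 1) "y" else "ies",
            " not in catalog, ignored")
  rk <- rank_hits(hits)
  ok <- rk$best$evalue <= params$e_max
  confirmation_frame(catalog, rk$best, ok, "top_hit_e")
}

#' Match markers to a gene (margin rule)
#'
#' A tag matches iff its best hit has `evalue < e_max` (strict) and either
#' has no second hit (a unique hit is unambiguous) or beats the second hit
#' by at least `margin_orders` orders of magnitude:
#' `best_E <= second_E * 10^-margin_orders`. When best and second E-values
#' are both exactly zero the margin is decided by bitscore (best must be
#' strictly higher); a best E of zero always passes the `e_max` cutoff.
#'
#' @inheritParams confirm_to_reference
#' @return data.frame of confirmation records with `rule = "margin_rule"`.
#' @export
match_to_gene <- function(catalog, hits, params = confirmation_params()) {
  rk <- rank_hits(hits)
  best <- rk$best
  sec_idx <- match(best$qseqid, rk$second$qseqid)
  sec_e <- rk$second$evalue[sec_idx]
  sec_bs <- rk$second$bitscore[sec_idx]
  margin_ok <- is.na(sec_e) |
    ifelse(best$evalue == 0 & sec_e == 0,
           best$bitscore > sec_bs,
           best$evalue <= sec_e * 10^(-params$margin_orders))
  ok <- best$evalue < params$e_max & margin_ok
  confirmation_frame(catalog, best, ok, "margin_rule")
}

#' Summarize a confirmation report
#'
#' Tallies confirmed tags overall and per detection approach, in two ways:
#' with multiplicity (`confirmed_by_approach`: a tag found by several
#' approaches counts under each) and by unique attribution
#' (`confirmed_by_primary_approach`: each tag is attributed to its
#' highest-priority approach in the order frequency difference >
#' heterozygosity > sex-limited, so the counts partition the confirmed set
#' and sum to `n_confirmed`).
#'
#' @param records confirmation records from [confirm_to_reference()] or
#'   [match_to_gene()].
#' @return list with `n_tags`, `n_confirmed`, `percent_confirmed`,
#'   `confirmed_by_approach` and `confirmed_by_primary_approach` (named
#'   integer vectors).
#' @export
confirmation_summary <- function(records) {
  app <- c("freq_diff", "het_diff", "sex_limited")
  conf <- records[records$confirmed, , drop = FALSE]
  by_app <- vapply(app, function(a)
    sum(grepl(a, conf$approaches, fixed = TRUE)), integer(1))
  primary <- vapply(strsplit(conf$approaches, ","), function(a)
    app[min(match(a, app))], character(1))
  by_primary <- vapply(app, function(a) sum(primary == a), integer(1))
  list(n_tags = nrow(records),
       n_confirmed = nrow(conf),
       percent_confirmed = if (nrow(records)) 100 * nrow(conf) / nrow(records)
                           else NA_real_,
       confirmed_by_approach = by_app,
       confirmed_by_primary_approach = by_primary)
}
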