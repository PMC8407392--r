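# Putative laterally-transferred-gene calling by best-hit taxonomy: a gene
# is called when the top of its ranked hit list lies outside the recipient's
# taxonomic lineage at the evaluation rank while any within-lineage hits
# score below a fraction of the best bit score.

#' LGT calling configuration
#'
#' @param rank Rank at which "outside the lineage" is evaluated (default
#'   `"phylum"`).
#' @param bitscore_fraction Within-lineage hits at or above this fraction of
#'   the best bit score defeat a call (default 0.90).
#' @param exclude_self Drop hits from the query's own genome first.
#' @param rule `"and"` (default, conjunctive: best hit outside AND no
#'   within-lineage hit inside the band) or `"or"` (disjunctive: some
#'   outside hit inside the band AND the best within-lineage hit below the
#'   overall best).
#' @return List of class `ltg_config`.
#' @export
ltg_config <- function(rank = "phylum", bitscore_fraction = 0.90,
                       exclude_self = TRUE, rule = c("and", "or")) {
  rule <- match.arg(rule)
  if (!rank %in% LINEAGE_RANKS) {
    stop("rank must be one of: ", paste(LINEAGE_RANKS, collapse = ", "))
  }
  if (bitscore_fraction <= 0 || bitscore_fraction > 1) {
    stop("bitscore_fraction must be in (0, 1]")
  }
  structure(list(rank = rank, bitscore_fraction = bitscore_fraction,
                 exclude_self = exclude_self, rule = rule),
            class = "ltg_config")
}

# TRUE when two lineages agree at every rank from domain down to `rank`.
# Missing ranks on either side count as agreement (no evidence of being
# outside).
.same_lineage_at <- function(a, b, rank) {
  upto <- seq_len(match(rank, LINEAGE_RANKS))
  cmp <- a[upto] == b[upto]
  all(cmp | is.na(cmp))
}

#' Call putative laterally transferred genes from a hit table
#'
#' Hits are grouped by query gene, self-genome hits removed, and a gene is
#' called when the best remaining hit lies outside the recipient lineage at
#' the configured rank and every within-lineage hit scores below
#' `bitscore_fraction` of the best bit score.  A tie at the top spanning
#' inside and outside the lineage is conservative: no call.  Hits with
#' unknown subject lineage are excluded from the evaluation.
#'
#' @param hits A `hit_table` (see [read_hit_table()]) of hits for genes of
#'   one recipient genome.
#' @param recipient_lineage Parsed lineage vector of the recipient genome.
#' @param config An [ltg_config()].
#' @param annotation Optional named vector gene -> COG letter.
#' @return Data frame of calls: `gene`, `recipient_genome`, `donor_gene`,
#'   `donor_genome`, `donor_lineage`, `cross_domain`, `best_bit`,
#'   `best_within_bit` (`NA` when no within-lineage hit), `cog`.
#' @export
call_ltg <- function(hits, recipient_lineage, config = ltg_config(),
                     annotation = NULL) {
  stopifnot(inherits(config, "ltg_config"))
  empty <- data.frame(gene = character(0), recipient_genome = character(0),
                      donor_gene = character(0),
                      donor_genome = character(0),
                      donor_lineage = character(0), cross_domain = logical(0),
                      best_bit = numeric(0), best_within_bit = numeric(0),
                      cog = character(0), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  if (config$exclude_self) {
    hits <- hits[hits$subject_genome != hits$query_genome, , drop = FALSE]
  }
  hits <- hits[hits$lineage_known, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[order(hits$query_gene, -hits$bitscore, hits$subject_gene), ,
               drop = FALSE]
  calls <- list()
  for (gene in unique(hits$query_gene)) {
    h <- hits[hits$query_gene == gene, , drop = FALSE]
    within <- vapply(h$subject_lineage, function(s)
      .same_lineage_at(parse_lineage(s), recipient_lineage, config$rank),
      logical(1L), USE.NAMES = FALSE)
    best_bit <- h$bitscore[1L]
    top <- which(h$bitscore == best_bit)
    if (any(within[top]) && any(!within[top])) next  # ambiguous top tie
    outside <- which(!within)
    if (!length(outside)) next
    best_within <- if (any(within)) max(h$bitscore[within]) else NA_real_
    called <- if (config$rule == "and") {
      !within[1L] &&
        (is.na(best_within) ||
           best_within < config$bitscore_fraction * best_bit)
    } else {
      any(h$bitscore[outside] >= config$bitscore_fraction * best_bit) &&
        (is.na(best_within) || best_within < best_bit)
    }
    if (!called) next
    don <- outside[1L]
    don_lin <- parse_lineage(h$subject_lineage[don])
    calls[[length(calls) + 1L]] <- data.frame(
      gene = gene, recipient_genome = h$query_genome[1L],
      donor_gene = h$subject_gene[don],
      donor_genome = h$subject_genome[don],
      donor_lineage = h$subject_lineage[don],
      cross_domain = !identical(unname(don_lin["domain"]),
                                unname(recipient_lineage["domain"])),
      best_bit = best_bit, best_within_bit = best_within,
      cog = if (!is.null(annotation) && gene %in% names(annotation)) {
        unname(annotation[gene])
      } else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(calls)) return(empty)
  do.call(rbind, c(calls, list(make.row.names = FALSE)))
}

#' Summarize LGT donors
#'
#' @param calls Output of [call_ltg()] (possibly rbind-ed over genomes).
#' @param superphylum_phyla Optional character vector of phylum names
#'   treated as the recipient superphylum, for the within-superphylum
#'   fraction.
#' @return List with `n_calls`, `cross_domain_fraction`, `donor_domains`
#'   and `donor_phyla` tables, and `within_superphylum_fraction` (`NA`
#'   without a clade set).
#' @export
donor_summary <- function(calls, superphylum_phyla = NULL) {
  if (nrow(calls) == 0L) {
    return(list(n_calls = 0L, cross_domain_fraction = 0,
                donor_domains = table(character(0)),
                donor_phyla = table(character(0)),
                within_superphylum_fraction = NA_real_))
  }
  lin <- lapply(calls$donor_lineage, parse_lineage)
  domains <- vapply(lin, `[[`, character(1L), "domain")
  phyla <- vapply(lin, function(l) {
    p <- l[["phylum"]]
    if (is.na(p)) "unclassified" else p
  }, character(1L))
  list(n_calls = nrow(calls),
       cross_domain_fraction = mean(calls$cross_domain),
       donor_domains = table(domains),
       donor_phyla = table(phyla),
       within_superphylum_fraction = if (is.null(superphylum_phyla)) {
         NA_real_
       } else {
         mean(phyla %in% superphylum_phyla)
       })
}

#' Functional profile of LGT calls
#'
#' @param calls Output of [call_ltg()].
#' @param annotation Named vector gene -> COG letter (may be partial); when
#'   `NULL` the `cog` column of `calls` is used.
#' @return List with `proportions` (over annotated calls, summing to 1),
#'   `n_annotated` and `n_unannotated`.
#' @export
ltg_category_profile <- function(calls, annotation = NULL) {
  cats <- if (is.null(annotation)) {
    calls$cog
  } else {
    unname(annotation[calls$gene])
  }
  known <- !is.na(cats)
  props <- if (any(known)) {
    t <- table(cats[known])
    stats::setNames(as.numeric(t) / sum(t), names(t))
  } else {
    stats::setNames(numeric(0), character(0))
  }
  list(proportions = props, n_annotated = sum(known),
       n_unannotated = sum(!known))
}

#' Precision and recall of LGT calls against injected truth
#'
#' With no injected transfers recall is reported as 1.0 and, with no calls,
#' precision as `NA` (undefined), the documented empty-case convention.
#'
#' @param calls Output of [call_ltg()].
#' @param truth Either a `sim_truth` with an `lgt` element or the `lgt`
#'   data frame from [inject_lgt()].
#' @return List with `precision`, `recall`, `n_calls`, `n_injected`,
#'   `n_true_positive`.
#' @export
ltg_recovery_report <- function(calls, truth) {
  lgt <- if (inherits(truth, "sim_truth")) truth$lgt else truth
  injected <- if (is.null(lgt)) character(0) else lgt$gene
  called <- calls$gene
  tp <- length(intersect(called, injected))
  list(precision = if (length(called)) tp / length(called) else NA_real_,
       recall = if (length(injected)) tp / length(injected) else 1.0,
       n_calls = length(called), n_injected = length(injected),
       n_true_positive = tp)
}
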