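# Pairwise genome relatedness: Smith-Waterman local alignment with
# Karlin-Altschul E-values, fragment-based average nucleotide identity
# (ANI), percentage of conserved proteins (POCP), and the taxonomic novelty
# classification built on the ANI < 95% / POCP > 50% conventions.

#' Alignment scoring scheme
#'
#' Nucleotide mode uses unit scores (match +1, mismatch -1, gap open -2,
#' gap extend -1) with the exact ungapped Karlin-Altschul lambda = ln 3 for
#' that scheme under uniform base composition; protein mode uses BLOSUM62
#' with the published gapped constants (lambda = 0.267, K = 0.041, gap
#' 11/1).  E-values use the explicit search space m * n; the goal is
#' monotone correctness of E-values, not bit-level parity with any search
#' engine.
#'
#' @param mode `"nt"` or `"aa"`.
#' @param match,mismatch Scores for nucleotide mode.
#' @param gap_open,gap_extend Gap penalties (<= 0).
#' @param lambda,K Karlin-Altschul constants.
#' @return List of class `align_scoring`.
#' @export
align_scoring <- function(mode = c("nt", "aa"), match = 1, mismatch = -1,
                          gap_open = -2, gap_extend = -1,
                          lambda = NULL, K = NULL) {
  mode <- match.arg(mode)
  if (gap_open > 0 || gap_extend > 0) stop("gap penalties must be <= 0")
  if (mode == "aa") {
    gap_open <- -11; gap_extend <- -1
    if (is.null(lambda)) lambda <- 0.267
    if (is.null(K)) K <- 0.041
  } else {
    if (is.null(lambda)) lambda <- log(3)
    if (is.null(K)) K <- 0.34
  }
  if (lambda <= 0 || K <= 0) stop("lambda and K must be > 0")
  structure(list(mode = mode, match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K), class = "align_scoring")
}

.subst_matrix <- function(scoring) {
  if (scoring$mode == "aa" && scoring$match == 1 &&
      scoring$mismatch == -1) {
    # unit scores requested explicitly for aa (clustering convention)
    letters_aa <- c(.AA20, "B", "J", "Z", "X", "*")
    m <- matrix(scoring$mismatch, length(letters_aa), length(letters_aa),
                dimnames = list(letters_aa, letters_aa))
    diag(m) <- scoring$match
    return(m)
  }
  if (scoring$mode == "aa") {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    return(e$BLOSUM62)
  }
  Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                           mismatch = scoring$mismatch,
                                           baseOnly = FALSE)
}

.bit_score <- function(score, scoring) {
  (scoring$lambda * score - log(scoring$K)) / log(2)
}

.alignment_evalue <- function(score, m, n, scoring) {
  scoring$K * m * n * exp(-scoring$lambda * score)
}

# Vectorized alignment of many patterns against one subject.
.align_many <- function(patterns, subject, scoring, type = "local") {
  al <- Biostrings::pairwiseAlignment(
    pattern = patterns, subject = subject, type = type,
    substitutionMatrix = .subst_matrix(scoring),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
  cols <- nchar(as.character(Biostrings::pattern(al)))
  nm <- Biostrings::nmatch(al)
  list(score = Biostrings::score(al), nmatch = nm, aln_length = cols,
       identity = 100 * nm / cols)
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman local alignment; identity is matches over alignment
#' columns (gaps included) and the E-value is
#' `K * m * n * exp(-lambda * score)` with `m`, `n` the input lengths.
#'
#' @param a,b Sequences (single strings) of the same alphabet.
#' @param scoring An [align_scoring()].
#' @return List with `score`, `identity` (percent), `aln_length` (columns)
#'   and `evalue`.
#' @export
local_align <- function(a, b, scoring = align_scoring("nt")) {
  a <- seq_chars(a)[[1L]]; b <- seq_chars(b)[[1L]]
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  is_nt <- function(s) !grepl(sprintf("[^%s]", .NT_ALLOWED), s)
  if (scoring$mode == "nt" && (!is_nt(a) || !is_nt(b))) {
    stop("alphabet mismatch: nucleotide scoring on non-nucleotide input")
  }
  set_of <- function(s) {
    if (scoring$mode == "nt") Biostrings::DNAStringSet(s)
    else Biostrings::AAStringSet(s)
  }
  al <- .align_many(set_of(a), set_of(b)[[1L]], scoring)
  list(score = al$score, identity = al$identity,
       aln_length = al$aln_length,
       evalue = .alignment_evalue(al$score, nchar(a), nchar(b), scoring))
}

#' Average nucleotide identity between two genomes
#'
#' Genome A is cut into consecutive 1,020-bp fragments, each locally aligned
#' against genome B; fragments are retained when identity is >= 30% over an
#' alignment covering >= 70% of the fragment, and ANI is the mean identity
#' of retained fragments.  With `symmetric = TRUE` (default) the mean of
#' both directions is returned.  When no fragment survives the filter the
#' result is `NA` ("undefined", not 0).
#'
#' @param genomeA,genomeB Named character vectors or `DNAStringSet`s of
#'   contigs.
#' @param scoring An [align_scoring()] in nucleotide mode.
#' @param fragment_length Fragment size in bp (default 1020).
#' @param min_identity,min_coverage Retention filter (defaults 30, 0.70).
#' @param symmetric Average both directions.
#' @return ANI percentage, or `NA_real_` when undefined.
#' @export
compute_ani <- function(genomeA, genomeB, scoring = align_scoring("nt"),
                        fragment_length = 1020L, min_identity = 30,
                        min_coverage = 0.70, symmetric = TRUE) {
  one_way <- function(A, B) {
    A <- seq_chars(A); B <- seq_chars(B)
    if (!length(A) || !length(B) || all(nchar(A) == 0L)) {
      stop("genomes must be non-empty")
    }
    frags <- unlist(lapply(A, function(contig) {
      L <- nchar(contig)
      if (L <= fragment_length) return(contig)
      starts <- seq(1L, L - fragment_length + 1L, by = fragment_length)
      substring(contig, starts, starts + fragment_length - 1L)
    }), use.names = FALSE)
    fset <- Biostrings::DNAStringSet(frags)
    best_id <- rep(NA_real_, length(frags))
    best_cov <- rep(0, length(frags))
    for (contig in B) {
      al <- .align_many(fset, Biostrings::DNAString(contig), scoring)
      better <- is.na(best_id) | al$identity > best_id
      cov <- al$aln_length / nchar(frags)
      best_id[better] <- al$identity[better]
      best_cov[better] <- cov[better]
    }
    keep <- !is.na(best_id) & best_id >= min_identity &
      best_cov >= min_coverage
    if (!any(keep)) return(NA_real_)
    mean(best_id[keep])
  }
  ab <- one_way(genomeA, genomeB)
  if (!symmetric) return(ab)
  ba <- one_way(genomeB, genomeA)
  if (is.na(ab) && is.na(ba)) return(NA_real_)
  mean(c(ab, ba), na.rm = TRUE)
}

#' Percentage of conserved proteins between two proteomes
#'
#' A protein counts as conserved when it has a hit in the other proteome
#' with E-value < 1e-5, identity >= 40% and an aligned region covering
#' >= 50% of the query length.  `POCP = ((C1/T1) + (C2/T2))/2 * 100`.
#'
#' @param protA,protB Proteomes ([Biostrings::AAStringSet] or named
#'   character).
#' @param scoring An [align_scoring()] in protein mode.
#' @param max_evalue,min_identity,min_coverage Conservation criteria.
#' @return List of class `pocp_result`: `C1`, `C2`, `T1`, `T2`, `pocp`.
#' @export
compute_pocp <- function(protA, protB, scoring = align_scoring("aa"),
                         max_evalue = 1e-5, min_identity = 40,
                         min_coverage = 0.5) {
  A <- seq_chars(protA); B <- seq_chars(protB)
  if (!length(A) || !length(B)) stop("empty proteome")
  conserved <- function(queries, targets) {
    qset <- Biostrings::AAStringSet(queries)
    hit <- rep(FALSE, length(queries))
    for (tg in targets) {
      todo <- which(!hit)
      if (!length(todo)) break
      al <- .align_many(qset[todo], Biostrings::AAString(tg), scoring)
      ev <- .alignment_evalue(al$score, nchar(queries[todo]), nchar(tg),
                              scoring)
      ok <- ev < max_evalue & al$identity >= min_identity &
        al$aln_length >= min_coverage * nchar(queries[todo])
      hit[todo[ok]] <- TRUE
    }
    sum(hit)
  }
  C1 <- conserved(A, B)
  C2 <- conserved(B, A)
  structure(list(C1 = C1, C2 = C2, T1 = length(A), T2 = length(B),
                 pocp = ((C1 / length(A)) + (C2 / length(B))) / 2 * 100),
            class = "pocp_result")
}

#' Taxonomic novelty classification from ANI and POCP
#'
#' POCP < 50 indicates an unrepresented family; POCP > 50 with ANI < 95
#' (or undefined ANI) an unrepresented species within a represented family;
#' POCP > 50 with ANI > 95 a represented species.  Boundary values (POCP
#' exactly 50, ANI exactly 95) fall into the less-novel class with a
#' warning, since the rules are strict inequalities in both directions.
#'
#' @param ani ANI percentage or `NA` (undefined).
#' @param pocp POCP percentage (must be defined).
#' @return One of `"represented species"`,
#'   `"unrepresented species, represented family"`,
#'   `"unrepresented family"`.
#' @export
classify_novelty <- function(ani, pocp) {
  if (is.na(pocp)) stop("pocp must be defined")
  if (pocp == 50) {
    warning("POCP exactly at the 50% boundary; treated as > 50 (the less ",
            "novel side)")
  }
  if (pocp < 50) return("unrepresented family")
  if (!is.na(ani) && ani == 95) {
    warning("ANI exactly at the 95% boundary; classified as represented ",
            "species")
    return("represented species")
  }
  if (is.na(ani) || ani < 95) {
    return("unrepresented species, represented family")
  }
  "represented species"
}
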