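# Readers and writers for the external formats the pipeline touches:
# FASTA (nt/aa), Newick, TSV presence/absence matrices, lineage tables and
# BLAST outfmt-6-style hit tables.  Parsers never silently drop rows; dropped
# or flagged counts travel in a "load_summary" attribute.

#' Taxonomic ranks, from domain down to species
#'
#' Rank order used throughout the package for lineage strings and
#' rank-limited comparisons.
#' @export
LINEAGE_RANKS <- c("domain", "phylum", "class", "order", "family",
                   "genus", "species")

.RANK_PREFIX <- c(d = "domain", p = "phylum", c = "class", o = "order",
                  f = "family", g = "genus", s = "species")

.NT_ALLOWED <- "ACGTRYSWKMBDHVN"
.AA_ALLOWED <- "ACDEFGHIKLMNPQRSTVWYBJZX*"

# ---------------------------------------------------------------------------
# FASTA

#' Read a FASTA file into a validated string set
#'
#' Sequences are upper-cased on read.  Record ids (the header up to the first
#' whitespace) must be unique and non-empty; sequences must be non-empty and
#' drawn from the declared alphabet plus IUPAC ambiguity codes.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nt"` for nucleotide, `"aa"` for amino acid.
#' @return A [Biostrings::DNAStringSet] (`nt`) or [Biostrings::AAStringSet]
#'   (`aa`) named by record id, with header descriptions in
#'   `S4Vectors::mcols(x)$description`.
#' @export
read_fasta <- function(path, alphabet = c("nt", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(raw))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  allowed <- if (alphabet == "nt") .NT_ALLOWED else .AA_ALLOWED
  bad <- regexpr(sprintf("[^%s]", gsub("\\*", "\\\\*", allowed)), seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("illegal character '%s' at position %d of record '%s'",
                 substr(seqs[i], bad[i], bad[i]), bad[i], ids[i]))
  }
  names(seqs) <- ids
  out <- if (alphabet == "nt") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  S4Vectors::mcols(out)$description <- desc
  out
}

#' Write sequences to FASTA
#'
#' @param x A named character vector or an `XStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) {
    if (is.null(names(x)) || any(names(x) == ""))
      stop("sequences must be named")
    x <- Biostrings::BStringSet(x)
  }
  Biostrings::writeXStringSet(x, filepath = path, width = 70L)
  invisible(path)
}

# Coerce an XStringSet or character vector to a named character vector.
seq_chars <- function(x) {
  if (is.character(x)) return(x)
  stats::setNames(as.character(x), names(x))
}

# ---------------------------------------------------------------------------
# Newick

#' Parse a Newick tree string or file
#'
#' Leaf labels are preserved; branch lengths are optional; polytomies are
#' allowed.  Unbalanced parentheses are reported with the character offset of
#' the first violation, and duplicate leaf labels are an error.
#'
#' @param text Newick string (must end in `;`).
#' @param file Alternatively, a file containing one Newick tree.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply `text` or `file`")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0L)) {
    stop("unbalanced parentheses: unmatched ')' at offset ",
         which(depth < 0L)[1L])
  }
  if (depth[length(depth)] != 0L) {
    stop("unbalanced parentheses: ", depth[length(depth)],
         " '(' left open at offset ", length(depth))
  }
  if (!endsWith(text, ";")) stop("Newick string must end with ';'")
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("failed to parse Newick string")
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "))
  }
  tr
}

#' Serialize a tree to Newick
#'
#' @param tree An [ape::phylo] tree.
#' @param file Optional output path; if `NULL` the string is returned.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

# ---------------------------------------------------------------------------
# Gene-family presence/absence matrices

#' Construct a validated gene-family presence/absence matrix
#'
#' Rows are genomes, columns are gene families, entries are strictly 0/1.
#' All-zero family columns are rejected: an absent-everywhere family carries
#' no placement information.
#'
#' @param m Binary matrix with genome rownames and family colnames.
#' @param annotation Optional named character vector mapping family id to a
#'   COG category letter.
#' @return The validated integer matrix, with `annotation` attached as an
#'   attribute when given.
#' @export
gene_family_matrix <- function(m, annotation = NULL) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix must have genome rownames and family colnames")
  if (anyDuplicated(rownames(m)))
    stop("duplicate genome id(s) in matrix")
  if (anyDuplicated(colnames(m)))
    stop("duplicate family id(s) in matrix")
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% c(0L, 1L)))
    stop("presence matrix entries must be strictly 0/1")
  zero <- colSums(m) == 0L
  if (any(zero)) {
    stop("all-zero family column(s): ",
         paste(colnames(m)[zero], collapse = ", "))
  }
  if (!is.null(annotation)) {
    if (is.null(names(annotation))) stop("annotation must be named by family")
    attr(m, "annotation") <- annotation
  }
  m
}

#' Read a presence/absence matrix from TSV
#'
#' Expected layout: header row of family ids, first column genome ids,
#' cells 0/1.
#'
#' @param path TSV path.
#' @param drop_empty Drop all-zero family columns instead of rejecting the
#'   file (`FALSE`, the default, rejects).
#' @return Validated binary matrix (see [gene_family_matrix()]).  When
#'   columns are dropped their count is recorded in the `"load_summary"`
#'   attribute.
#' @export
read_presence_matrix <- function(path, drop_empty = FALSE) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", row.names = NULL)
  if (ncol(df) < 2L) stop("presence matrix needs >= 1 family column")
  genomes <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  bad <- !(vals %in% c("0", "1"))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow = nrow(vals)), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary cell '%s' at genome '%s', family '%s'",
                 vals[idx[1L], idx[2L]], genomes[idx[1L]],
                 colnames(vals)[idx[2L]]))
  }
  m <- matrix(as.integer(vals), nrow = nrow(vals),
              dimnames = list(genomes, colnames(vals)))
  n_dropped <- 0L
  if (drop_empty) {
    zero <- colSums(m) == 0L
    n_dropped <- sum(zero)
    m <- m[, !zero, drop = FALSE]
  }
  m <- gene_family_matrix(m)
  attr(m, "load_summary") <- list(n_genomes = nrow(m), n_families = ncol(m),
                                  n_dropped_columns = n_dropped)
  m
}

#' Write a presence/absence matrix to TSV
#'
#' @param m Binary matrix (genomes x families).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(m, path) {
  df <- data.frame(genome = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Lineages

#' Parse a semicolon-delimited lineage string
#'
#' Accepts GTDB-style `x__` prefixes (optional) or bare names mapped
#' positionally from domain downwards.  Empty tokens are explicit rank gaps.
#' Rank order must be strictly descending (domain > phylum > ...), and the
#' domain must be present.
#'
#' @param s Lineage string, e.g. `"d__Archaea;p__Micrarchaeota"`.
#' @return Named character vector over [LINEAGE_RANKS], `NA` at gaps.
#' @export
parse_lineage <- function(s) {
  out <- stats::setNames(rep(NA_character_, length(LINEAGE_RANKS)),
                         LINEAGE_RANKS)
  tokens <- strsplit(s, ";", fixed = TRUE)[[1L]]
  tokens <- trimws(tokens)
  last <- 0L
  for (tok in tokens) {
    if (grepl("^[a-z]__", tok)) {
      pre <- substr(tok, 1L, 1L)
      rank <- .RANK_PREFIX[pre]
      if (is.na(rank)) stop("unknown rank prefix '", pre, "__' in: ", s)
      i <- match(rank, LINEAGE_RANKS)
      if (i <= last) {
        stop("out-of-order rank '", rank, "' in lineage: ", s)
      }
      val <- sub("^[a-z]__", "", tok)
      if (nzchar(val)) out[i] <- val
      last <- i
    } else {
      i <- last + 1L
      if (i > length(LINEAGE_RANKS)) stop("too many ranks in lineage: ", s)
      if (nzchar(tok)) out[i] <- tok
      last <- i
    }
  }
  if (is.na(out["domain"])) stop("lineage lacks a domain: ", s)
  out
}

#' Format a lineage vector as a prefixed string
#'
#' @param l Named character vector as returned by [parse_lineage()].
#' @return `"d__...;p__...;..."` string, gaps kept as empty fields up to the
#'   deepest named rank.
#' @export
lineage_to_string <- function(l) {
  deepest <- max(which(!is.na(l)), 1L)
  pre <- names(.RANK_PREFIX)[match(LINEAGE_RANKS, .RANK_PREFIX)]
  toks <- paste0(pre[seq_len(deepest)], "__",
                 ifelse(is.na(l[seq_len(deepest)]), "", l[seq_len(deepest)]))
  paste(toks, collapse = ";")
}

#' Read a genome-to-lineage table
#'
#' Two tab-separated columns without header: genome id, lineage string.
#'
#' @param path TSV path.
#' @return Named list of parsed lineage vectors, one per genome.
#' @export
read_lineages <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("lineage table needs 2 columns")
  if (anyDuplicated(df[[1L]])) {
    stop("duplicate genome id(s) in lineage table: ",
         paste(unique(df[[1L]][duplicated(df[[1L]])]), collapse = ", "))
  }
  out <- lapply(df[[2L]], parse_lineage)
  names(out) <- df[[1L]]
  out
}

#' Write a genome-to-lineage table
#'
#' @param lineages Named list of lineage vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lineages <- function(lineages, path) {
  lines <- vapply(lineages, lineage_to_string, character(1L))
  utils::write.table(data.frame(names(lineages), lines), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Hit tables

.HIT_COLS <- c("query_gene", "subject_gene", "pident", "length", "mismatch",
               "gapopen", "qstart", "qend", "sstart", "send", "evalue",
               "bitscore")

#' Derive a genome id from a gene id
#'
#' Default delimiter rule used throughout the package: everything before the
#' first `|`.  BLAST tabular output has no genome column, so the genome must
#' be recoverable from the sequence id.
#'
#' @param id Character vector of gene ids.
#' @param delim Delimiter (default `"|"`).
#' @return Character vector of genome ids.
#' @export
genome_of <- function(id, delim = "|") {
  vapply(strsplit(id, delim, fixed = TRUE), `[[`, character(1L), 1L)
}

#' Read a BLAST outfmt-6-style hit table
#'
#' Standard 12-column tabular rows; extra columns are ignored.  Genome ids
#' are recovered from gene ids via `genome_from` and rows are joined with a
#' lineage table.  Rows whose subject genome lacks a lineage are kept and
#' flagged (`lineage_known = FALSE`), with the count surfaced in a warning
#' and the `"load_summary"` attribute.
#'
#' @param path TSV path; an empty file yields an empty table.
#' @param lineages Named list of lineage vectors (see [read_lineages()]), or
#'   `NULL` to skip the join.
#' @param genome_from Function mapping a gene id vector to genome ids.
#' @return A `data.frame` of class `hit_table` with the 12 standard columns
#'   plus `query_genome`, `subject_genome`, `subject_lineage` (string) and
#'   `lineage_known`.
#' @export
read_hit_table <- function(path, lineages = NULL, genome_from = genome_of) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(.HIT_COLS)), .HIT_COLS))
    num <- setdiff(.HIT_COLS, c("query_gene", "subject_gene"))
    for (cc in num) df[[cc]] <- numeric(0)
    return(.finish_hit_table(df, lineages, genome_from))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(parts)
  if (any(nfld < 12L)) {
    stop("line ", which(nfld < 12L)[1L], ": expected >= 12 tab-separated ",
         "fields, got ", nfld[which(nfld < 12L)[1L]])
  }
  m <- t(vapply(parts, function(p) p[1:12], character(12L)))
  df <- data.frame(query_gene = m[, 1L], subject_gene = m[, 2L],
                   stringsAsFactors = FALSE)
  for (j in 3:12) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v)) {
      stop("line ", which(is.na(v))[1L], ": malformed numeric field '",
           m[which(is.na(v))[1L], j], "' in column ", .HIT_COLS[j])
    }
    df[[.HIT_COLS[j]]] <- v
  }
  .finish_hit_table(df, lineages, genome_from)
}

.finish_hit_table <- function(df, lineages, genome_from) {
  df$query_genome <- if (nrow(df)) genome_from(df$query_gene) else character(0)
  df$subject_genome <- if (nrow(df)) genome_from(df$subject_gene)
                       else character(0)
  known <- df$subject_genome %in% names(lineages)
  df$subject_lineage <- rep(NA_character_, nrow(df))
  if (!is.null(lineages) && any(known)) {
    df$subject_lineage[known] <- vapply(
      lineages[df$subject_genome[known]], lineage_to_string, character(1L))
  }
  df$lineage_known <- known
  n_unknown <- if (is.null(lineages)) 0L else sum(!known)
  if (!is.null(lineages) && n_unknown > 0L) {
    warning(n_unknown, " hit row(s) with unknown subject lineage (kept, ",
            "flagged)")
  }
  attr(df, "load_summary") <- list(n_rows = nrow(df),
                                   n_unknown_lineage = n_unknown)
  class(df) <- c("hit_table", "data.frame")
  df
}

#' Write a hit table in 12-column BLAST tabular format
#'
#' @param hits A `hit_table` (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits[, .HIT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
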