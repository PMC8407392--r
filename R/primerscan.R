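# Degenerate-primer mismatch screening: ungapped sliding of an IUPAC primer
# over both strands of a target, reporting the minimum-mismatch placement.
# Primer-template annealing mismatches are conventionally counted without
# indels, so no gapped alignment is attempted.

.IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))

.IUPAC_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
                 H = "D", V = "B", N = "N")

# Compatibility lookup: compat[primer_base, target_base] <- sets intersect.
.IUPAC_COMPAT <- local({
  codes <- names(.IUPAC)
  m <- matrix(FALSE, length(codes), length(codes),
              dimnames = list(codes, codes))
  for (a in codes) {
    for (b in codes) {
      m[a, b] <- length(intersect(.IUPAC[[a]], .IUPAC[[b]])) > 0L
    }
  }
  m
})

#' Expand an IUPAC nucleotide code
#'
#' @param code Single IUPAC character.
#' @return Character vector of the concrete bases it stands for.
#' @export
iupac_expand <- function(code) {
  out <- .IUPAC[[toupper(code)]]
  if (is.null(out)) stop("invalid IUPAC code: ", code)
  out
}

#' Test IUPAC compatibility of a primer base against a target base
#'
#' Two codes are compatible iff their expansion sets intersect; `N` on
#' either side matches everything.
#'
#' @param primer_base,target_base Single IUPAC characters.
#' @return Logical.
#' @export
iupac_compatible <- function(primer_base, target_base) {
  p <- toupper(primer_base); t <- toupper(target_base)
  if (is.na(match(p, names(.IUPAC)))) {
    stop("invalid IUPAC code: ", primer_base)
  }
  if (is.na(match(t, names(.IUPAC)))) {
    stop("invalid IUPAC code: ", target_base)
  }
  .IUPAC_COMPAT[p, t]
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' @param s Nucleotide string (IUPAC codes allowed).
#' @return The reverse complement string.
#' @export
revcomp <- function(s) {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  comp <- .IUPAC_COMP[chars]
  if (anyNA(comp)) {
    stop("invalid IUPAC code: ", chars[is.na(comp)][1L])
  }
  paste(rev(unname(comp)), collapse = "")
}

# Mismatch counts for every ungapped placement of primer_chars along
# target_chars (single strand).
.slide_mismatches <- function(primer_chars, target_chars) {
  m <- length(primer_chars)
  n <- length(target_chars) - m + 1L
  mm <- integer(n)
  for (j in seq_len(m)) {
    compat <- .IUPAC_COMPAT[primer_chars[j], target_chars[j:(j + n - 1L)]]
    mm <- mm + !compat
  }
  unname(mm)
}

#' Scan a degenerate primer along both strands of a target
#'
#' The primer slides without indels over the target and its reverse
#' complement; per placement, mismatches are primer positions whose IUPAC
#' code is incompatible with the target base.  The minimum-mismatch
#' placement is returned; ties are broken leftmost, plus strand first.
#'
#' @param primer Primer string (IUPAC codes allowed).
#' @param target Target string (must be at least primer length).
#' @return List of class `primer_match`: `mismatches`, `position` (1-based
#'   on the reported strand), `strand` (`"+"`/`"-"`), `primer`, `site` (the
#'   target substring at the placement) and `alignment` (display string).
#' @export
scan_primer <- function(primer, target) {
  primer <- toupper(seq_chars(primer)[[1L]])
  target <- toupper(seq_chars(target)[[1L]])
  pc <- strsplit(primer, "", fixed = TRUE)[[1L]]
  if (nchar(target) < length(pc)) {
    stop("primer (", length(pc), " nt) longer than target (",
         nchar(target), " nt)")
  }
  bad <- setdiff(unique(pc), names(.IUPAC))
  if (length(bad)) stop("invalid IUPAC code in primer: ", bad[1L])
  strands <- c("+" = target, "-" = revcomp(target))
  best <- NULL
  for (st in names(strands)) {
    tc <- strsplit(strands[[st]], "", fixed = TRUE)[[1L]]
    mm <- .slide_mismatches(pc, tc)
    pos <- which.min(mm)  # leftmost minimum on this strand
    if (is.null(best) || mm[pos] < best$mismatches) {
      site <- substr(strands[[st]], pos, pos + length(pc) - 1L)
      marks <- vapply(seq_along(pc), function(j)
        if (.IUPAC_COMPAT[pc[j], substr(site, j, j)]) "|" else " ",
        character(1L))
      best <- list(mismatches = mm[pos], position = pos, strand = st,
                   primer = primer, site = site,
                   alignment = paste(primer, paste(marks, collapse = ""),
                                     site, sep = "\n"))
    }
  }
  structure(best, class = "primer_match")
}

#' Minimal mismatch matrix of primers against targets
#'
#' @param primers Named character vector (or `XStringSet`) of primers.
#' @param targets Named character vector (or `XStringSet`) of targets.
#' @return List with `matrix` (primer x target minimal mismatch counts),
#'   `matches` (data frame of per-pair best placements) and
#'   `primers_with_mismatch` (per target, how many primers have >= 1
#'   mismatch).
#' @export
mismatch_matrix <- function(primers, targets) {
  primers <- seq_chars(primers); targets <- seq_chars(targets)
  if (!length(primers) || !length(targets)) stop("non-empty lists required")
  if (is.null(names(primers))) names(primers) <- paste0("P", seq_along(primers))
  if (is.null(names(targets))) names(targets) <- paste0("S", seq_along(targets))
  m <- matrix(NA_integer_, length(primers), length(targets),
              dimnames = list(names(primers), names(targets)))
  rows <- list()
  for (i in names(primers)) {
    for (j in names(targets)) {
      hit <- scan_primer(primers[[i]], targets[[j]])
      m[i, j] <- hit$mismatches
      rows[[length(rows) + 1L]] <- data.frame(
        primer = i, target = j, mismatches = hit$mismatches,
        position = hit$position, strand = hit$strand,
        stringsAsFactors = FALSE)
    }
  }
  list(matrix = m,
       matches = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       primers_with_mismatch = colSums(m >= 1L))
}
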