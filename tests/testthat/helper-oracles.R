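# Independent brute-force oracles and small fixture builders shared across
# the suite.  Oracles deliberately avoid the package's own code paths.

# Naive two-strand ungapped primer scan (double loop over placements).
naive_primer_min <- function(primer, target) {
  pc <- strsplit(toupper(primer), "")[[1]]
  expand <- list(A = "A", C = "C", G = "G", T = "T",
                 R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                 W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                 B = c("C", "G", "T"), D = c("A", "G", "T"),
                 H = c("A", "C", "T"), V = c("A", "C", "G"),
                 N = c("A", "C", "G", "T"))
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  rc <- function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    paste(rev(unname(comp[ch])), collapse = "")
  }
  best <- length(pc)
  for (tgt in c(toupper(target), rc(target))) {
    tc <- strsplit(tgt, "")[[1]]
    for (pos in seq_len(length(tc) - length(pc) + 1)) {
      mm <- 0L
      for (j in seq_along(pc)) {
        a <- expand[[pc[j]]]; b <- expand[[tc[pos + j - 1]]]
        if (length(intersect(a, b)) == 0) mm <- mm + 1L
      }
      if (mm < best) best <- mm
    }
  }
  best
}

# Exhaustive Dollo oracle: minimum losses over all internal-state
# assignments with at most one 0->1 transition (root presence counts as the
# gain on the root stem).  `profiles` is a tips x P 0/1 matrix.
dollo_oracle_losses <- function(tree, profiles) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  internal <- (nt + 1L):nn
  edges <- tree$edge
  P <- ncol(profiles)
  best <- rep(Inf, P)
  for (mask in 0:(2^length(internal) - 1L)) {
    istate <- as.integer(intToBits(mask))[seq_along(internal)]
    state <- matrix(0L, nrow = nn, ncol = P)
    state[seq_len(nt), ] <- profiles[tree$tip.label, , drop = FALSE]
    state[internal, ] <- istate
    gains <- state[nt + 1L, ]  # root presence = gain on the stem
    losses <- integer(P)
    for (e in seq_len(nrow(edges))) {
      p <- edges[e, 1L]; ch <- edges[e, 2L]
      gains <- gains + (state[p, ] == 0L & state[ch, ] == 1L)
      losses <- losses + (state[p, ] == 1L & state[ch, ] == 0L)
    }
    ok <- gains <= 1L
    best[ok] <- pmin(best[ok], losses[ok])
  }
  best
}

# Exhaustive pan/core enumeration over all genome orderings.
pan_core_exhaustive <- function(m) {
  G <- nrow(m)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  orders <- perms(seq_len(G))
  pan <- core <- matrix(0L, nrow = length(orders), ncol = G)
  for (p in seq_along(orders)) {
    for (n in seq_len(G)) {
      rows <- m[orders[[p]][seq_len(n)], , drop = FALSE]
      pan[p, n] <- sum(colSums(rows) > 0)
      core[p, n] <- sum(colSums(rows) == n)
    }
  }
  list(pan = pan, core = core)
}

random_protein <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                  "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Point-mutate a fraction of positions of a nucleotide string.
mutate_dna <- function(s, frac) {
  ch <- strsplit(s, "")[[1]]
  k <- round(frac * length(ch))
  if (k == 0) return(s)
  pos <- sample(length(ch), k)
  for (i in pos) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# Minimal hand-built hit table row for LGT/SSN tests.
hit_row <- function(query_gene, subject_gene, bitscore, pident = 50,
                    evalue = 1e-20, lineage = NA_character_) {
  data.frame(query_gene = query_gene, subject_gene = subject_gene,
             pident = pident, length = 100, mismatch = 0, gapopen = 0,
             qstart = 1, qend = 100, sstart = 1, send = 100,
             evalue = evalue, bitscore = bitscore,
             query_genome = genome_of(query_gene),
             subject_genome = genome_of(subject_gene),
             subject_lineage = lineage,
             lineage_known = !is.na(lineage),
             stringsAsFactors = FALSE)
}

as_hit_table <- function(...) {
  df <- do.call(rbind, list(...))
  class(df) <- c("hit_table", "data.frame")
  df
}
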