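# Alignment-free phylogeny by the composition-vector method: k-mer counting
# with a (k-2)-order Markov background subtraction, cosine-based
# dissimilarities, neighbor joining, and the rooted-tree queries (MRCA,
# closest-reference selection) used to pick reference genomes.

.NT4 <- c("A", "C", "G", "T")

.valid_chars <- function(alphabet) {
  switch(alphabet,
         nt = .NT4,
         aa = .AA20,
         any = NULL,
         stop("unknown alphabet: ", alphabet))
}

#' Count k-mers over sliding windows
#'
#' Windows containing a character outside `valid_chars` (ambiguity codes,
#' for instance) are skipped.  Counts are summed over all records.
#'
#' @param sequence Character vector of sequences (or an `XStringSet`).
#' @param k Window length, >= 1.
#' @param valid_chars Characters allowed inside a window; `NULL` accepts
#'   everything.
#' @return Named integer vector of k-mer counts.  Sequences shorter than `k`
#'   contribute nothing; if no window is usable an empty vector is returned
#'   with a warning.
#' @export
count_kmers <- function(sequence, k, valid_chars = NULL) {
  sequence <- seq_chars(sequence)
  stopifnot(k >= 1L)
  acc <- list()
  for (s in sequence) {
    L <- nchar(s)
    if (L < k) next
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    n <- L - k + 1L
    win <- vapply(seq_len(k), function(j) chars[j:(j + n - 1L)],
                  character(n))
    if (n == 1L) win <- matrix(win, nrow = 1L)
    if (!is.null(valid_chars)) {
      ok <- matrix(win %in% valid_chars, nrow = n)
      keep <- rowSums(ok) == k
      win <- win[keep, , drop = FALSE]
    }
    if (nrow(win) == 0L) next
    kmers <- do.call(paste0, as.data.frame(win, stringsAsFactors = FALSE))
    acc[[length(acc) + 1L]] <- table(kmers)
  }
  if (!length(acc)) {
    warning("no usable window of length ", k)
    return(stats::setNames(integer(0), character(0)))
  }
  tot <- Reduce(function(a, b) {
    keys <- union(names(a), names(b))
    out <- stats::setNames(numeric(length(keys)), keys)
    out[names(a)] <- a
    out[names(b)] <- out[names(b)] + b
    out
  }, lapply(acc, function(t) stats::setNames(as.numeric(t), names(t))))
  out <- as.integer(tot)
  names(out) <- names(tot)
  out[order(names(out))]
}

#' Compute a composition vector
#'
#' For pooled k-mer frequencies `f`, the (k-2)-order Markov background
#' predicts `q(a1..ak) = f(a1..ak-1) * f(a2..ak) / f(a2..ak-1)`; the stored
#' component for each k-mer is `(f - q)/q` where `q > 0` (and 0, hence
#' dropped, otherwise).  Subtracting the background removes shared
#' compositional bias so that the remaining signal reflects lineage-specific
#' k-mer usage.
#'
#' @param records Sequences (character vector or `XStringSet`).
#' @param k k-mer length, >= 3 (the background needs (k-2)-mers).
#' @param alphabet `"aa"` (default, proteome convention), `"nt"`, or
#'   `"any"` (no ambiguity filtering).
#' @return Object of class `composition_vector`: list with `k` and `scores`
#'   (sparse named numeric of nonzero components).
#' @export
composition_vector <- function(records, k = 4L, alphabet = c("aa", "nt",
                                                             "any")) {
  alphabet <- match.arg(alphabet)
  if (k < 3L) stop("k must be >= 3 (background needs (k-2)-mers)")
  valid <- .valid_chars(alphabet)
  ck <- count_kmers(records, k, valid)
  ck1 <- suppressWarnings(count_kmers(records, k - 1L, valid))
  ck2 <- suppressWarnings(count_kmers(records, k - 2L, valid))
  if (!length(ck2) || sum(ck2) == 0L) {
    stop("no (k-2)-mer support: combined usable length < ", k - 2L)
  }
  fk <- ck / sum(ck)
  fk1 <- ck1 / sum(ck1)
  fk2 <- ck2 / sum(ck2)
  # support = every k-mer with q > 0, i.e. every prefix/suffix (k-1)-mer
  # pair overlapping on a supported (k-2)-mer; unobserved k-mers in the
  # support carry component (0 - q)/q = -1, so absence is informative
  k1 <- names(fk1)
  mid_of <- substr(k1, 2L, k - 1L)
  pre_of <- substr(k1, 1L, k - 2L)
  last_of <- substr(k1, k - 1L, k - 1L)
  xs_by_mid <- split(seq_along(k1), mid_of)
  ys_by_pre <- split(seq_along(k1), pre_of)
  kmers <- character(0)
  qv <- numeric(0)
  for (m in names(fk2)) {
    xi <- xs_by_mid[[m]]
    yi <- ys_by_pre[[m]]
    if (is.null(xi) || is.null(yi)) next
    kv <- as.vector(outer(k1[xi], last_of[yi], paste0))
    kmers <- c(kmers, kv)
    qv <- c(qv, as.vector(outer(unname(fk1[xi]), unname(fk1[yi]))) /
              unname(fk2[[m]]))
  }
  fv <- unname(fk[kmers])
  fv[is.na(fv)] <- 0
  comp <- (fv - qv) / qv
  names(comp) <- kmers
  comp <- comp[comp != 0]
  comp <- comp[order(names(comp))]
  structure(list(k = as.integer(k), scores = comp),
            class = "composition_vector")
}

#' Dissimilarity between two composition vectors
#'
#' `D = (1 - C)/2` where `C` is the cosine correlation over the union of
#' stored k-mers (absent keys contribute 0), so `D` lies in \[0, 1\].
#'
#' @param a,b `composition_vector`s with the same `k`.
#' @return Dissimilarity in \[0, 1\].
#' @export
cv_distance <- function(a, b) {
  stopifnot(inherits(a, "composition_vector"),
            inherits(b, "composition_vector"))
  if (a$k != b$k) stop("composition vectors have different k")
  na <- sqrt(sum(a$scores^2))
  nb <- sqrt(sum(b$scores^2))
  if (na == 0 || nb == 0) stop("zero-norm composition vector")
  shared <- intersect(names(a$scores), names(b$scores))
  C <- sum(a$scores[shared] * b$scores[shared]) / (na * nb)
  D <- (1 - C) / 2
  min(max(D, 0), 1)
}

#' Pairwise composition-vector distance matrix
#'
#' @param genomes Named list: genome id -> sequences (character vector or
#'   `XStringSet`; typically the genome's proteome).
#' @param k k-mer length (default 4).
#' @param alphabet Passed to [composition_vector()].
#' @return Symmetric labelled matrix of dissimilarities with zero diagonal.
#' @export
build_distance_matrix <- function(genomes, k = 4L,
                                  alphabet = c("aa", "nt", "any")) {
  alphabet <- match.arg(alphabet)
  if (length(genomes) < 2L) stop("need >= 2 genomes")
  if (is.null(names(genomes))) stop("genomes must be named")
  cvs <- lapply(names(genomes), function(g) {
    tryCatch(composition_vector(genomes[[g]], k, alphabet),
             error = function(e)
               stop("genome '", g, "': ", conditionMessage(e)))
  })
  n <- length(genomes)
  D <- matrix(0, n, n, dimnames = list(names(genomes), names(genomes)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- cv_distance(cvs[[i]], cvs[[j]])
    }
  }
  D
}

#' Write a distance matrix as square TSV
#'
#' @param D Labelled symmetric matrix.
#' @param path Output path.
#' @param phylip Prepend a PHYLIP-style count line.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(D, path, phylip = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (phylip) writeLines(as.character(nrow(D)), con)
  utils::write.table(data.frame(id = rownames(D), D, check.names = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration; negative estimated branch lengths are clamped
#' to zero.  Two labels yield a single edge whose leaf-to-leaf path equals
#' the input distance.
#'
#' @param D Labelled symmetric matrix (or `dist`).
#' @return An unrooted [ape::phylo] tree (a single edge for two labels).
#' @export
neighbor_joining <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  if (is.null(rownames(D))) stop("distance matrix must be labelled")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-12,
                        check.attributes = FALSE))) {
    stop("distance matrix must be symmetric")
  }
  n <- nrow(D)
  if (n < 2L) stop("need >= 2 labels")
  if (n == 2L) {
    tr <- list(edge = matrix(c(3L, 3L, 1L, 2L), ncol = 2L),
               tip.label = rownames(D),
               edge.length = rep(D[1L, 2L] / 2, 2L), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(D))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Root a tree on an outgroup
#'
#' The root is placed on the edge separating the outgroup leaves from the
#' ingroup.
#'
#' @param tree An [ape::phylo] tree.
#' @param outgroup Character vector of outgroup leaf labels.
#' @return A rooted tree.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing)) {
    stop("outgroup leaves not in tree: ", paste(missing, collapse = ", "))
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

# Per-node sets of descendant tip labels (index = node number).
.tips_below <- function(tree) {
  idx <- .tree_index(tree)
  out <- vector("list", idx$n_node)
  for (i in seq_len(idx$n_tip)) out[[i]] <- tree$tip.label[i]
  for (nd in rev(idx$preorder)) {
    kids <- idx$children[[nd]]
    if (length(kids)) out[[nd]] <- unlist(out[kids], use.names = FALSE)
  }
  out
}

#' Most recent common ancestor of a leaf set
#'
#' @param tree Rooted [ape::phylo] tree.
#' @param leaves Non-empty character vector of leaf labels.
#' @return Node number (a tip number for a single leaf), named with the
#'   node's label.
#' @export
mrca_node <- function(tree, leaves) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted; root it first")
  if (length(leaves) == 0L) stop("leaves must be non-empty")
  unknown <- setdiff(leaves, tree$tip.label)
  if (length(unknown)) {
    stop("unknown leaf label(s): ", paste(unknown, collapse = ", "))
  }
  if (length(unique(leaves)) == 1L) {
    nd <- match(leaves[1L], tree$tip.label)
  } else {
    nd <- ape::getMRCA(tree, unique(leaves))
  }
  stats::setNames(nd, node_label(tree, nd))
}

#' Select the phylogenetically closest reference leaf
#'
#' Walks from the query leaf towards the root; at the first ancestor whose
#' clade contains at least one reference, the reference in that clade
#' attaching most basally (fewest edges from that ancestor) is returned,
#' with lexicographic tie-breaking.
#'
#' @param tree Rooted [ape::phylo] tree.
#' @param query Query leaf label (not a reference).
#' @param references Non-empty character vector of reference leaf labels.
#' @return The selected reference label.
#' @export
select_closest_reference <- function(tree, query, references) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted; root it first")
  if (!query %in% tree$tip.label) stop("unknown query leaf: ", query)
  references <- setdiff(unique(references), query)
  if (!length(references)) stop("references must be non-empty")
  if (!any(references %in% tree$tip.label)) {
    stop("no reference present in the tree")
  }
  references <- intersect(references, tree$tip.label)
  idx <- .tree_index(tree)
  below <- .tips_below(tree)
  # edge-count depth of every node, reused to rank candidate references
  depth <- integer(idx$n_node)
  for (nd in idx$preorder) {
    if (nd == idx$root) next
    depth[nd] <- depth[idx$parent[nd]] + 1L
  }
  nd <- match(query, tree$tip.label)
  while (nd != idx$root) {
    nd <- idx$parent[nd]
    cand <- intersect(below[[nd]], references)
    if (length(cand)) {
      tipno <- match(cand, tree$tip.label)
      dist_up <- depth[tipno] - depth[nd]
      cand <- cand[order(dist_up, cand)]
      return(cand[1L])
    }
  }
  stop("no reference found below the root")  # unreachable after checks
}
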