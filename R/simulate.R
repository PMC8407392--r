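# Synthetic-data generator: seeded trees, gene-content histories evolving
# under single-origin gains and branch-wise losses, proteome/genome
# sequences, injected lateral transfers with known donors, and 16S primer
# fixtures with planted mismatch counts.  Every downstream stage is testable
# against the truth log this module emits.

#' Simulation configuration
#'
#' Defaults describe a loss-dominant regime: each branch removes a sizeable
#' fraction of the inherited families while novel gains are rare, so losses
#' outnumber gains in the resulting histories, as expected for streamlined
#' symbiont genomes.
#'
#' @param n_leaves Number of genomes (tree leaves), >= 2.
#' @param seed Integer seed; fixing it fixes every output byte.
#' @param root_family_count Gene families present at the root.
#' @param gain_rate Expected number of novel single-origin families gained
#'   per branch (Poisson).
#' @param loss_prob Per-family, per-branch loss probability in \[0, 1\].
#' @param mutation_rate Expected per-site substitution probability on a
#'   branch of mean length (0.1); substitution probability on a branch of
#'   length `t` is `1 - exp(-(mutation_rate / 0.1) * t)`.
#' @param protein_length_mean Mean protein length in residues.
#' @param lgt_count Number of donor genes to inject as lateral transfers.
#' @param primer_count Number of degenerate primers in the primer fixture.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_leaves = 8L, seed = 1L, root_family_count = 200L,
                       gain_rate = 0.5, loss_prob = 0.25,
                       mutation_rate = 0.05, protein_length_mean = 150L,
                       lgt_count = 0L, primer_count = 5L) {
  cfg <- list(n_leaves = as.integer(n_leaves), seed = as.integer(seed),
              root_family_count = as.integer(root_family_count),
              gain_rate = gain_rate, loss_prob = loss_prob,
              mutation_rate = mutation_rate,
              protein_length_mean = as.integer(protein_length_mean),
              lgt_count = as.integer(lgt_count),
              primer_count = as.integer(primer_count))
  probs <- c(loss_prob = cfg$loss_prob, mutation_rate = cfg$mutation_rate)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    stop(names(probs)[bad][1L], " must be in [0, 1], got ",
         probs[bad][1L])
  }
  counts <- c(root_family_count = cfg$root_family_count,
              lgt_count = cfg$lgt_count, primer_count = cfg$primer_count)
  if (any(counts < 0L)) stop(names(counts)[counts < 0L][1L], " must be >= 0")
  if (cfg$gain_rate < 0) stop("gain_rate must be >= 0")
  if (cfg$n_leaves < 2L) stop("n_leaves must be >= 2")
  structure(cfg, class = "sim_config")
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

# Fixed back-translation table: one codon per residue, chosen once.
.CODON <- c(A = "GCT", C = "TGC", D = "GAT", E = "GAA", F = "TTT",
            G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
            M = "ATG", N = "AAT", P = "CCG", Q = "CAG", R = "CGT",
            S = "TCT", T = "ACC", V = "GTG", W = "TGG", Y = "TAT")

node_label <- function(tree, node) {
  nl <- tree$node.label
  if (is.null(nl)) nl <- paste0("N", seq_len(tree$Nnode))
  c(tree$tip.label, nl)[node]
}

#' Simulate a rooted binary tree
#'
#' Leaves are labelled `G1...Gn`; branch lengths are exponential with mean
#' 0.1; internal nodes are labelled `N1...`.
#'
#' @param config A [sim_config()].
#' @return A rooted [ape::phylo] tree.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_leaves < 2L) stop("n_leaves must be >= 2")
  set.seed(config$seed)
  tr <- ape::rtree(config$n_leaves, rooted = TRUE,
                   tip.label = paste0("G", seq_len(config$n_leaves)),
                   br = function(n) stats::rexp(n, rate = 10))
  tr$node.label <- paste0("N", seq_len(tr$Nnode))
  tr
}

# children[[node]] = integer vector of child nodes; preorder = node visit
# order from the root down.
.tree_index <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  children <- vector("list", nn)
  parent <- integer(nn)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; ch <- tree$edge[i, 2L]
    children[[p]] <- c(children[[p]], ch)
    parent[ch] <- p
  }
  root <- nt + 1L
  preorder <- integer(0)
  stack <- root
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    preorder <- c(preorder, nd)
    kids <- children[[nd]]
    if (length(kids)) stack <- c(stack, rev(kids))
  }
  edge_len <- numeric(nn)
  if (!is.null(tree$edge.length)) {
    edge_len[tree$edge[, 2L]] <- tree$edge.length
  }
  list(children = children, parent = parent, root = root,
       preorder = preorder, n_tip = nt, n_node = nn, edge_len = edge_len)
}

#' Evolve gene-family content along a tree
#'
#' The root carries `root_family_count` families.  On every branch each
#' inherited family is lost independently with probability `loss_prob`, and
#' a Poisson(`gain_rate`) number of novel families arises; gains are
#' single-origin (never re-gained), so the histories are Dollo-compatible by
#' construction.  The presence/absence matrix contains the families
#' surviving in at least one leaf; the truth log records every event,
#' including families that died out entirely.
#'
#' @param tree Rooted tree from [simulate_tree()].
#' @param config A [sim_config()].
#' @return List with `matrix` (leaf presence/absence, see
#'   [gene_family_matrix()]) and `truth`, a `sim_truth` list holding the
#'   tree, the event log (`branch`, `family`, `type`), per-node content and
#'   per-family true gain nodes.
#' @export
evolve_gene_content <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  idx <- .tree_index(tree)
  set.seed(config$seed + 1L)
  n_fam <- config$root_family_count
  fam_id <- function(i) sprintf("F%05d", i)
  content <- vector("list", idx$n_node)
  gain_node <- integer(0)

  root_fams <- seq_len(n_fam)
  content[[idx$root]] <- root_fams
  gain_node[root_fams] <- idx$root
  events <- list(data.frame(
    branch = node_label(tree, idx$root),
    family = fam_id(root_fams),
    type = if (n_fam) "gain" else character(0),
    stringsAsFactors = FALSE))

  for (nd in idx$preorder) {
    if (nd == idx$root) next
    inherited <- content[[idx$parent[nd]]]
    lost <- inherited[stats::runif(length(inherited)) < config$loss_prob]
    n_new <- stats::rpois(1L, config$gain_rate)
    new <- if (n_new > 0L) n_fam + seq_len(n_new) else integer(0)
    n_fam <- n_fam + n_new
    gain_node[new] <- nd
    content[[nd]] <- c(setdiff(inherited, lost), new)
    lab <- node_label(tree, nd)
    ev <- data.frame(
      branch = rep(lab, length(lost) + length(new)),
      family = fam_id(c(lost, new)),
      type = rep(c("loss", "gain"), c(length(lost), length(new))),
      stringsAsFactors = FALSE)
    events[[length(events) + 1L]] <- ev
  }
  events <- do.call(rbind, events)

  leaf_fams <- sort(unique(unlist(content[seq_len(idx$n_tip)])))
  m <- matrix(0L, nrow = idx$n_tip, ncol = length(leaf_fams),
              dimnames = list(tree$tip.label, fam_id(leaf_fams)))
  for (i in seq_len(idx$n_tip)) {
    m[i, match(intersect(content[[i]], leaf_fams), leaf_fams)] <- 1L
  }
  node_content <- lapply(content, fam_id)
  names(node_content) <- node_label(tree, seq_len(idx$n_node))
  truth <- structure(list(
    tree = tree, events = events, node_content = node_content,
    gain_node = stats::setNames(node_label(tree, gain_node),
                                fam_id(seq_along(gain_node))),
    lgt = NULL, primer_truth = NULL), class = "sim_truth")
  list(matrix = gene_family_matrix(m), truth = truth)
}

.mutate_protein <- function(chars, p) {
  if (p <= 0) return(chars)
  hit <- which(stats::runif(length(chars)) < p)
  for (i in hit) {
    chars[i] <- sample(setdiff(.AA20, chars[i]), 1L)
  }
  chars
}

#' Emit proteome and genome sequences for simulated gene content
#'
#' Each family gets a random prototype protein at the root; copies then
#' accumulate substitutions branch by branch down the tree (per-site
#' probability `1 - exp(-(mutation_rate/0.1) * branch_length)`), so
#' divergence grows with path length and sister genomes stay most similar.
#' Genome nucleotide sequences are the back-translated genes (fixed
#' one-codon-per-residue table) joined by 50 nt of i.i.d. random spacer.
#'
#' @param matrix Presence/absence matrix over the tree's leaves.
#' @param tree Rooted tree containing every matrix genome as a leaf.
#' @param config A [sim_config()].
#' @return List with `proteomes` (named list of [Biostrings::AAStringSet],
#'   gene ids `genome|family`) and `genomes` (a [Biostrings::DNAStringSet],
#'   one sequence per genome).
#' @export
emit_sequences <- function(matrix, tree, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(rownames(matrix) %in% tree$tip.label)) {
    stop("matrix genomes must be tree leaves")
  }
  idx <- .tree_index(tree)
  set.seed(config$seed + 2L)
  fams <- colnames(matrix)
  rate <- config$mutation_rate / 0.1
  # leaf_seq[[family]][genome] = evolved protein string
  leaf_seq <- vector("list", length(fams))
  names(leaf_seq) <- fams
  for (f in seq_along(fams)) {
    len <- max(30L, stats::rpois(1L, config$protein_length_mean))
    proto <- sample(.AA20, len, replace = TRUE)
    node_seq <- vector("list", idx$n_node)
    node_seq[[idx$root]] <- proto
    for (nd in idx$preorder) {
      if (nd == idx$root) next
      p <- 1 - exp(-rate * idx$edge_len[nd])
      node_seq[[nd]] <- .mutate_protein(node_seq[[idx$parent[nd]]], p)
    }
    leaf_seq[[f]] <- stats::setNames(
      vapply(seq_len(idx$n_tip), function(i)
        paste(node_seq[[i]], collapse = ""), character(1L)),
      tree$tip.label)
  }
  proteomes <- list()
  genome_seqs <- character(0)
  for (g in rownames(matrix)) {
    present <- fams[matrix[g, ] == 1L]
    prots <- vapply(present, function(f) leaf_seq[[f]][[g]], character(1L))
    names(prots) <- paste0(g, "|", present)
    proteomes[[g]] <- Biostrings::AAStringSet(prots)
    genes_nt <- vapply(prots, function(s) {
      paste(.CODON[strsplit(s, "")[[1L]]], collapse = "")
    }, character(1L))
    spacers <- vapply(seq_len(length(genes_nt) + 1L), function(i)
      paste(sample(c("A", "C", "G", "T"), 50L, replace = TRUE),
            collapse = ""), character(1L))
    pieces <- character(2L * length(genes_nt) + 1L)
    pieces[seq(1L, length(pieces), by = 2L)] <- spacers
    if (length(genes_nt)) {
      pieces[seq(2L, length(pieces) - 1L, by = 2L)] <- genes_nt
    }
    genome_seqs[[g]] <- paste(pieces, collapse = "")
  }
  list(proteomes = proteomes,
       genomes = Biostrings::DNAStringSet(genome_seqs))
}

#' Build a pool of donor genes with lineages
#'
#' Random unrelated proteins grouped into donor genomes, each with a stated
#' lineage, for use with [inject_lgt()].
#'
#' @param lineage_strings Named character vector: donor genome id ->
#'   lineage string.
#' @param genes_per_genome Genes per donor genome.
#' @param protein_length Donor protein length (residues).
#' @param seed Integer seed.
#' @return List with `donors` (data frame: `gene`, `genome`, `lineage`,
#'   `sequence`), `proteomes` (named list of AAStringSet) and `lineages`
#'   (named list of parsed lineage vectors).
#' @export
donor_pool <- function(lineage_strings, genes_per_genome = 10L,
                       protein_length = 150L, seed = 1L) {
  set.seed(seed)
  rows <- list(); proteomes <- list()
  for (g in names(lineage_strings)) {
    seqs <- vapply(seq_len(genes_per_genome), function(i)
      paste(sample(.AA20, protein_length, replace = TRUE), collapse = ""),
      character(1L))
    ids <- paste0(g, "|D", seq_len(genes_per_genome))
    proteomes[[g]] <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
    rows[[g]] <- data.frame(gene = ids, genome = g,
                            lineage = lineage_strings[[g]], sequence = seqs,
                            stringsAsFactors = FALSE)
  }
  list(donors = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       proteomes = proteomes,
       lineages = lapply(lineage_strings, parse_lineage))
}

#' Inject lateral gene transfers into recipient proteomes
#'
#' `lgt_count` donor genes are copied verbatim into randomly chosen
#' recipient proteomes under new ids `recipient|LGTk`, and the truth map of
#' injected gene to donor lineage is returned.
#'
#' @param proteomes Named list of recipient [Biostrings::AAStringSet]s.
#' @param donors Donor gene table (`gene`, `genome`, `lineage`, `sequence`),
#'   as in [donor_pool()]`$donors`.
#' @param config A [sim_config()]; `lgt_count` genes are drawn without
#'   replacement.
#' @return List with `proteomes` (modified) and `lgt`, a data frame
#'   (`gene`, `recipient`, `donor_gene`, `donor_genome`, `donor_lineage`).
#' @export
inject_lgt <- function(proteomes, donors, config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$lgt_count
  if (k == 0L) {
    return(list(proteomes = proteomes,
                lgt = data.frame(gene = character(0),
                                 recipient = character(0),
                                 donor_gene = character(0),
                                 donor_genome = character(0),
                                 donor_lineage = character(0))))
  }
  if (is.null(donors) || nrow(donors) == 0L) {
    stop("empty donor pool with lgt_count > 0")
  }
  if (k > nrow(donors)) stop("lgt_count exceeds available donor genes")
  set.seed(config$seed + 3L)
  pick <- sample(nrow(donors), k)
  recipients <- sample(names(proteomes), k, replace = TRUE)
  new_ids <- paste0(recipients, "|LGT", seq_len(k))
  for (i in seq_len(k)) {
    add <- Biostrings::AAStringSet(stats::setNames(
      donors$sequence[pick[i]], new_ids[i]))
    proteomes[[recipients[i]]] <- c(proteomes[[recipients[i]]], add)
  }
  list(proteomes = proteomes,
       lgt = data.frame(gene = new_ids, recipient = recipients,
                        donor_gene = donors$gene[pick],
                        donor_genome = donors$genome[pick],
                        donor_lineage = donors$lineage[pick],
                        stringsAsFactors = FALSE))
}

#' Emulate an all-vs-all similarity search over proteomes
#'
#' Every gene of every genome is locally aligned against every gene of every
#' other genome (self-genome hits excluded) and the results are converted to
#' BLAST-tabular-style hit rows with bit scores and E-values; rows are
#' sorted by query gene and descending bit score.  Quadratic in total gene
#' count: intended for desk-scale synthetic sets.
#'
#' @param proteomes Named list of [Biostrings::AAStringSet]s.
#' @param lineages Named list of lineage vectors per genome (passed through
#'   to the hit rows).
#' @param scoring An [align_scoring()] (protein mode by default).
#' @param max_evalue Rows with larger E-value are dropped (default 10).
#' @return A `hit_table` data frame (see [read_hit_table()]).
#' @export
emulate_hit_table <- function(proteomes, lineages = NULL,
                              scoring = align_scoring("aa"),
                              max_evalue = 10) {
  if (length(proteomes) < 2L) stop("need >= 2 genomes")
  rows <- list()
  for (qg in names(proteomes)) {
    qset <- proteomes[[qg]]
    if (length(qset) == 0L) next
    for (sg in setdiff(names(proteomes), qg)) {
      sset <- proteomes[[sg]]
      for (j in seq_along(sset)) {
        al <- .align_many(qset, sset[[j]], scoring, type = "local")
        ev <- .alignment_evalue(al$score, Biostrings::width(qset),
                                Biostrings::width(sset)[j], scoring)
        keep <- which(ev <= max_evalue)
        if (!length(keep)) next
        rows[[length(rows) + 1L]] <- data.frame(
          query_gene = names(qset)[keep],
          subject_gene = names(sset)[j],
          pident = round(al$identity[keep], 2),
          length = al$aln_length[keep],
          mismatch = al$aln_length[keep] - al$nmatch[keep],
          gapopen = 0L, qstart = 1L, qend = al$aln_length[keep],
          sstart = 1L, send = al$aln_length[keep],
          evalue = ev[keep],
          bitscore = round(.bit_score(al$score[keep], scoring), 1),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    df <- utils::read.table(text = "", col.names = .HIT_COLS)
  } else {
    df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    df <- df[order(df$query_gene, -df$bitscore, df$subject_gene), ,
             drop = FALSE]
    rownames(df) <- NULL
  }
  .finish_hit_table(df, lineages, genome_of)
}

# --------------------------------------------------------------------------
# Primer fixture

# Independent naive mismatch scan used only to certify planted fixtures.
.naive_min_mismatch <- function(primer, target) {
  pc <- strsplit(primer, "")[[1L]]
  best <- length(pc)
  for (tgt in c(target, revcomp(target))) {
    tc <- strsplit(tgt, "")[[1L]]
    for (pos in seq_len(length(tc) - length(pc) + 1L)) {
      mm <- 0L
      for (j in seq_along(pc)) {
        if (!iupac_compatible(pc[j], tc[pos + j - 1L])) mm <- mm + 1L
      }
      if (mm < best) best <- mm
    }
  }
  best
}

.realize_site <- function(primer_chars, n_mismatch) {
  site <- vapply(primer_chars, function(b)
    sample(iupac_expand(b), 1L), character(1L))
  if (n_mismatch > 0L) {
    eligible <- which(vapply(primer_chars, function(b)
      length(setdiff(c("A", "C", "G", "T"), iupac_expand(b))) > 0L,
      logical(1L)))
    pos <- sample(eligible, n_mismatch)
    for (i in pos) {
      site[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                iupac_expand(primer_chars[i])), 1L)
    }
  }
  paste(site, collapse = "")
}

#' Generate a 16S-like primer-screening fixture with planted truth
#'
#' Builds `primer_count` degenerate primers and three synthetic target
#' sequences; for every primer/target pair a binding site with a known
#' number of mismatches (0-5) is planted, including degenerate positions,
#' and the first primer's site in the first target is planted in
#' reverse-complement orientation.  Each planted count is certified as the
#' global two-strand minimum with an independent naive scan before the
#' fixture is returned.
#'
#' @param config A [sim_config()] (`primer_count >= 1`).
#' @return List with `primers` (named character), `targets`
#'   ([Biostrings::DNAStringSet]), `truth` (primer x target matrix of
#'   minimal mismatch counts) and `sites` (planting positions/strands).
#' @export
generate_primer_fixture <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  np <- config$primer_count
  if (np < 1L) stop("primer_count must be >= 1")
  set.seed(config$seed + 4L)
  nt <- 3L
  plen <- 18L
  primers <- character(np)
  for (i in seq_len(np)) {
    pc <- sample(c("A", "C", "G", "T"), plen, replace = TRUE)
    deg_pos <- sample(seq_len(plen), 2L)
    pc[deg_pos] <- sample(c("R", "Y", "S", "W", "K", "M"), 2L,
                          replace = TRUE)
    primers[i] <- paste(pc, collapse = "")
  }
  names(primers) <- paste0("P", seq_len(np))
  slot <- 40L
  tlen <- np * slot + 100L
  truth <- matrix(NA_integer_, nrow = np, ncol = nt,
                  dimnames = list(names(primers), paste0("S", seq_len(nt))))
  targets <- character(nt)
  sites <- list()
  for (t in seq_len(nt)) {
    for (attempt in 1:25) {
      tgt <- sample(c("A", "C", "G", "T"), tlen, replace = TRUE)
      planted <- integer(np)
      site_rows <- list()
      for (i in seq_len(np)) {
        m <- sample(0:5, 1L)
        site <- .realize_site(strsplit(primers[i], "")[[1L]], m)
        strand <- "+"
        if (i == 1L && t == 1L) {
          site <- revcomp(site)
          strand <- "-"
        }
        pos <- (i - 1L) * slot + 10L
        tgt[pos:(pos + plen - 1L)] <- strsplit(site, "")[[1L]]
        planted[i] <- m
        site_rows[[i]] <- data.frame(primer = names(primers)[i],
                                     target = paste0("S", t), pos = pos,
                                     strand = strand, mismatches = m,
                                     stringsAsFactors = FALSE)
      }
      tgt_str <- paste(tgt, collapse = "")
      ok <- all(vapply(seq_len(np), function(i)
        .naive_min_mismatch(primers[i], tgt_str) == planted[i],
        logical(1L)))
      if (ok) {
        targets[t] <- tgt_str
        truth[, t] <- planted
        sites[[t]] <- do.call(rbind, site_rows)
        break
      }
      if (attempt == 25L) stop("failed to plant a certified primer fixture")
    }
  }
  names(targets) <- paste0("S", seq_len(nt))
  list(primers = primers, targets = Biostrings::DNAStringSet(targets),
       truth = truth, sites = do.call(rbind, sites))
}

#' Run the full simulator
#'
#' Convenience wrapper: tree, gene content, sequences, optional lateral
#' transfers from a default bacterial/archaeal donor pool, and the primer
#' fixture, all under one seed.
#'
#' @param config A [sim_config()].
#' @param recipient_lineage Lineage string shared by the simulated genomes.
#' @param donor_lineages Named character vector of donor genome lineages
#'   used when `lgt_count > 0`.
#' @return List with `tree`, `matrix`, `proteomes`, `genomes`, `lineages`,
#'   `primer_fixture` and `truth` (a `sim_truth` with `lgt` and
#'   `primer_truth` filled in).
#' @export
simulate_dataset <- function(config = sim_config(),
                             recipient_lineage =
                               "d__Archaea;p__Simarchaeota",
                             donor_lineages = c(
                               DON1 = "d__Bacteria;p__Firmicutes",
                               DON2 = "d__Archaea;p__Euryarchaeota")) {
  tree <- simulate_tree(config)
  gc <- evolve_gene_content(tree, config)
  seqs <- emit_sequences(gc$matrix, tree, config)
  lineages <- stats::setNames(
    rep(list(parse_lineage(recipient_lineage)), nrow(gc$matrix)),
    rownames(gc$matrix))
  truth <- gc$truth
  proteomes <- seqs$proteomes
  pool <- NULL
  if (config$lgt_count > 0L) {
    pool <- donor_pool(donor_lineages, seed = config$seed + 5L)
    inj <- inject_lgt(proteomes, pool$donors, config)
    proteomes <- inj$proteomes
    truth$lgt <- inj$lgt
    lineages <- c(lineages, pool$lineages)
  }
  pf <- generate_primer_fixture(config)
  truth$primer_truth <- pf$truth
  list(tree = tree, matrix = gc$matrix, proteomes = proteomes,
       genomes = seqs$genomes, donor_pool = pool, lineages = lineages,
       primer_fixture = pf, truth = truth)
}
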