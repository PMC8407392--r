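# Dollo-parsimony ancestral gene-content reconstruction: each family
# originates exactly once (at the MRCA of its carriers) and may then be lost
# any number of times; losses are placed on the minimal branch set excising
# every absence subtree below the gain.  Branch identity is the child node's
# label; the root's stem is itself a branch so root-content gains are
# countable events.

#' Dollo-parsimony reconstruction of gene gain and loss
#'
#' For every family the gain is placed at the most recent common ancestor of
#' the leaves possessing it (the terminal branch for a single carrier, the
#' root stem for a universal family) and one loss is placed on the stem of
#' each maximal subtree below that gain in which the family is entirely
#' absent.  This is the minimum-loss assignment under the single-gain
#' constraint.  Polytomies are allowed; each absent child branch of a
#' polytomy carries its own loss.
#'
#' @param tree Rooted [ape::phylo] tree whose leaves cover all matrix
#'   genomes.
#' @param matrix Presence/absence matrix (see [gene_family_matrix()]; all
#'   families present in at least one genome).
#' @return Object of class `dollo_reconstruction`: list with `tree`,
#'   `state` (node x family 0/1 matrix, rownames = node labels),
#'   `gain_branch` (family -> branch label), `losses` (data frame `branch`,
#'   `family`) and `node_labels`.
#' @export
dollo_reconstruct <- function(tree, matrix) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  offenders <- setdiff(rownames(matrix), tree$tip.label)
  if (length(offenders)) {
    stop("matrix genome(s) missing from tree: ",
         paste(offenders, collapse = ", "))
  }
  matrix <- gene_family_matrix(matrix[, , drop = FALSE])
  idx <- .tree_index(tree)
  nn <- idx$n_node
  fams <- colnames(matrix)
  # presence-below counts per node, accumulated tips-up
  cnt <- matrix(0L, nrow = nn, ncol = length(fams))
  cnt[match(rownames(matrix), tree$tip.label), ] <- matrix
  for (nd in rev(idx$preorder)) {
    kids <- idx$children[[nd]]
    if (length(kids)) {
      cnt[nd, ] <- colSums(cnt[kids, , drop = FALSE])
    }
  }
  depth <- integer(nn)
  for (nd in idx$preorder) {
    if (nd != idx$root) depth[nd] <- depth[idx$parent[nd]] + 1L
  }
  m_tot <- cnt[idx$root, ]
  # gain node per family: deepest node ancestral to all carriers, i.e. the
  # deepest node whose below-count equals the total carrier count
  gain_node <- vapply(seq_along(fams), function(j) {
    cand <- which(cnt[, j] == m_tot[j])
    cand[which.max(depth[cand])]
  }, integer(1L))
  labels <- node_label(tree, seq_len(nn))
  # state: present iff inside the gain clade with at least one carrier below
  in_clade <- matrix(FALSE, nrow = nn, ncol = length(fams))
  in_clade[cbind(gain_node, seq_along(fams))] <- TRUE
  for (nd in idx$preorder) {
    if (nd == idx$root) next
    in_clade[nd, ] <- in_clade[nd, ] | in_clade[idx$parent[nd], ]
  }
  state <- in_clade & (cnt > 0L)
  # losses: edges parent present -> child absent (child within the clade)
  loss_list <- list()
  for (nd in idx$preorder) {
    if (nd == idx$root) next
    p <- idx$parent[nd]
    lost <- which(state[p, ] & in_clade[nd, ] & cnt[nd, ] == 0L)
    if (length(lost)) {
      loss_list[[length(loss_list) + 1L]] <- data.frame(
        branch = labels[nd], family = fams[lost], stringsAsFactors = FALSE)
    }
  }
  losses <- if (length(loss_list)) {
    do.call(rbind, c(loss_list, list(make.row.names = FALSE)))
  } else {
    data.frame(branch = character(0), family = character(0))
  }
  state_m <- matrix(as.integer(state), nrow = nn,
                    dimnames = list(labels, fams))
  structure(list(tree = tree, state = state_m,
                 gain_branch = stats::setNames(labels[gain_node], fams),
                 losses = losses, node_labels = labels,
                 matrix = matrix),
            class = "dollo_reconstruction")
}

#' Per-branch gain and loss counts
#'
#' The root stem is itself a branch, so families already present in the
#' ancestral genome appear as gains on the stem.  Because figures of the
#' Fig-3 kind display the ancestral (MRCA) content on the node and mark
#' only lineage events as gains, the totals also report `novel_gains`,
#' the gain count excluding the root stem -- the quantity comparable to a
#' printed gains-versus-losses headline.
#'
#' @param recon A [dollo_reconstruct()] result.
#' @return Data frame (`branch`, `n_gained`, `n_lost`, `is_root_stem`)
#'   covering every branch including the root stem, with grand totals
#'   (`gains`, `novel_gains`, `losses`) in attribute `"totals"`.
#' @export
branch_event_counts <- function(recon) {
  stopifnot(inherits(recon, "dollo_reconstruction"))
  branches <- recon$node_labels
  root_label <- branches[length(recon$tree$tip.label) + 1L]
  gains <- table(factor(recon$gain_branch, levels = branches))
  losses <- table(factor(recon$losses$branch, levels = branches))
  out <- data.frame(branch = branches,
                    n_gained = as.integer(gains),
                    n_lost = as.integer(losses),
                    is_root_stem = branches == root_label,
                    stringsAsFactors = FALSE)
  attr(out, "totals") <- c(
    gains = sum(out$n_gained),
    novel_gains = sum(out$n_gained[!out$is_root_stem]),
    losses = sum(out$n_lost))
  out
}

#' Ancestral and leaf gene-content sizes
#'
#' @param recon A [dollo_reconstruct()] result.
#' @return Data frame (`node`, `is_leaf`, `n_families`); leaf values equal
#'   the input matrix row sums.
#' @export
ancestral_content_sizes <- function(recon) {
  stopifnot(inherits(recon, "dollo_reconstruction"))
  n_tip <- length(recon$tree$tip.label)
  data.frame(node = recon$node_labels,
             is_leaf = seq_along(recon$node_labels) <= n_tip,
             n_families = as.integer(rowSums(recon$state)),
             stringsAsFactors = FALSE)
}

#' COG-category profile of gain and loss events
#'
#' Tally of events by functional category: each family contributes its gain
#' once and one count per loss event.  Families without annotation are
#' pooled as `"unknown"`.  Each distribution sums to 1.
#'
#' @param recon A [dollo_reconstruct()] result.
#' @param annotation Named character vector family -> COG letter (may be
#'   partial or `NULL`).
#' @return List with `gains` and `losses`, each a named numeric proportion
#'   vector over categories (including `"unknown"` when applicable).
#' @export
category_event_profile <- function(recon, annotation = NULL) {
  stopifnot(inherits(recon, "dollo_reconstruction"))
  cat_of <- function(fams) {
    if (is.null(annotation)) return(rep("unknown", length(fams)))
    out <- unname(annotation[fams])
    out[is.na(out)] <- "unknown"
    out
  }
  prop <- function(categories) {
    if (!length(categories)) return(stats::setNames(numeric(0),
                                                    character(0)))
    t <- table(categories)
    stats::setNames(as.numeric(t) / sum(t), names(t))
  }
  list(gains = prop(cat_of(names(recon$gain_branch))),
       losses = prop(cat_of(recon$losses$family)))
}

#' Compare a Dollo reconstruction against simulation truth
#'
#' The truth log is replayed (independently of the reconstruction code
#' path) to derive, per family surviving in the leaf matrix, the observable
#' gain node -- the MRCA of its surviving carriers -- and the set of
#' unmasked true losses: loss events whose parent node retains surviving
#' carriers elsewhere and lies within the observable gain clade.  A loss
#' masked by the extinction of every other copy below its parent is not
#' recoverable from leaf data even in principle.
#'
#' @param recon A [dollo_reconstruct()] result.
#' @param truth A `sim_truth` from [evolve_gene_content()].
#' @return List of counts and fractions: `gain_observable_match` (fraction
#'   of families whose reconstructed gain equals the observable gain node),
#'   `gain_exact_match` (fraction equal to the true gain node),
#'   `n_true_losses`, `n_unmasked_losses`, `unmasked_recovered` (fraction
#'   of unmasked losses reconstructed), `n_recon_losses`, `n_recon_gains`.
#' @export
gainloss_recovery_report <- function(recon, truth) {
  stopifnot(inherits(recon, "dollo_reconstruction"),
            inherits(truth, "sim_truth"))
  tree <- truth$tree
  idx <- .tree_index(tree)
  labels <- node_label(tree, seq_len(idx$n_node))
  node_of <- stats::setNames(seq_len(idx$n_node), labels)
  fams <- colnames(recon$matrix)
  # observable gain node from truth: deepest common ancestor of carriers,
  # via explicit root paths (no reuse of the Dollo count machinery)
  path_to_root <- function(nd) {
    p <- nd
    while (nd != idx$root) {
      nd <- idx$parent[nd]
      p <- c(p, nd)
    }
    p
  }
  tip_paths <- lapply(seq_len(idx$n_tip), path_to_root)
  obs_gain <- vapply(fams, function(f) {
    carriers <- which(recon$matrix[, f] == 1L)
    carriers <- match(rownames(recon$matrix)[carriers], tree$tip.label)
    common <- Reduce(intersect, tip_paths[carriers])
    labels[common[1L]]  # paths are leaf-to-root, first shared = deepest
  }, character(1L))
  gain_obs_match <- mean(recon$gain_branch[fams] == obs_gain)
  true_gain <- truth$gain_node[fams]
  gain_exact <- mean(recon$gain_branch[fams] == true_gain)

  ev <- truth$events
  losses <- ev[ev$type == "loss" & ev$family %in% fams, , drop = FALSE]
  # surviving-carriers-below count per node, from the leaf matrix only
  surv <- matrix(0L, nrow = idx$n_node, ncol = length(fams),
                 dimnames = list(labels, fams))
  surv[match(rownames(recon$matrix), tree$tip.label), ] <- recon$matrix
  for (nd in rev(idx$preorder)) {
    kids <- idx$children[[nd]]
    if (length(kids)) surv[nd, ] <- colSums(surv[kids, , drop = FALSE])
  }
  is_ancestor_or_self <- function(anc, nd) {
    while (TRUE) {
      if (nd == anc) return(TRUE)
      if (nd == idx$root) return(FALSE)
      nd <- idx$parent[nd]
    }
  }
  unmasked <- logical(nrow(losses))
  for (i in seq_len(nrow(losses))) {
    child <- node_of[[losses$branch[i]]]
    parent <- idx$parent[child]
    f <- losses$family[i]
    unmasked[i] <- surv[parent, f] > 0L &&
      is_ancestor_or_self(node_of[[obs_gain[[f]]]], parent)
  }
  recon_key <- paste(recon$losses$branch, recon$losses$family)
  truth_key <- paste(losses$branch, losses$family)[unmasked]
  list(gain_observable_match = gain_obs_match,
       gain_exact_match = gain_exact,
       n_true_losses = nrow(losses),
       n_unmasked_losses = sum(unmasked),
       unmasked_recovered = if (sum(unmasked)) {
         mean(truth_key %in% recon_key)
       } else NA_real_,
       n_recon_losses = nrow(recon$losses),
       n_recon_gains = length(recon$gain_branch))
}
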