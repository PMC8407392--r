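# Sequence similarity networks: threshold edge filtering (E-value and
# percent identity), transitive >90%-identity metanode collapsing, and
# component/degree summaries.

.ssn_graph <- function(nodes, edges, thresholds) {
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, thresholds = thresholds),
            class = "ssn_graph")
}

#' Build a sequence similarity network from a hit table
#'
#' An undirected edge is kept iff `evalue <= evalue_cutoff` and
#' `pident >= identity_cutoff`; self-pairs are dropped and reciprocal
#' duplicates merged, retaining the better (smaller) E-value.  Every
#' sequence appearing in the input remains a node, so singletons survive
#' filtering.
#'
#' @param hits A `hit_table` (or data frame with `query_gene`,
#'   `subject_gene`, `pident`, `evalue`, `bitscore`).
#' @param evalue_cutoff E-value threshold (default 1e-5).
#' @param identity_cutoff Percent-identity threshold (default 35).
#' @return Object of class `ssn_graph`: `nodes` (data frame `id`,
#'   `members` list-column), `edges` (data frame `from`, `to`, `identity`,
#'   `evalue`, `bitscore`) and the thresholds used.
#' @export
build_ssn <- function(hits, evalue_cutoff = 1e-5, identity_cutoff = 35) {
  ids <- sort(unique(c(hits$query_gene, hits$subject_gene)))
  keep <- hits$query_gene != hits$subject_gene &
    hits$evalue <= evalue_cutoff & hits$pident >= identity_cutoff
  h <- hits[keep, , drop = FALSE]
  if (nrow(h)) {
    a <- pmin(h$query_gene, h$subject_gene)
    b <- pmax(h$query_gene, h$subject_gene)
    key <- paste(a, b, sep = "\r")
    ord <- order(key, h$evalue, -h$bitscore)
    h <- h[ord, , drop = FALSE]
    first <- !duplicated(key[ord])
    edges <- data.frame(from = a[ord][first], to = b[ord][first],
                        identity = h$pident[first], evalue = h$evalue[first],
                        bitscore = h$bitscore[first],
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        identity = numeric(0), evalue = numeric(0),
                        bitscore = numeric(0))
  }
  nodes <- data.frame(id = ids, stringsAsFactors = FALSE)
  nodes$members <- as.list(ids)
  .ssn_graph(nodes, edges,
             list(evalue = evalue_cutoff, identity = identity_cutoff))
}

#' Collapse high-identity sequences into metanodes
#'
#' Union-find over edges with identity strictly above `collapse_identity`
#' (default 90): each transitive-closure class becomes one metanode
#' carrying the member list, and edges between metanodes inherit the best
#' (smallest E-value) underlying edge.  Member lists are disjoint and cover
#' every original sequence.  Transitive closure means single-linkage
#' chaining: a 95% and a 92% edge merge three sequences even if the outer
#' pair is less similar.
#'
#' @param graph An `ssn_graph` from [build_ssn()].
#' @param collapse_identity Strict collapse threshold (default 90).
#' @return A collapsed `ssn_graph`; metanodes are named after their
#'   lexicographically first member.
#' @export
collapse_metanodes <- function(graph, collapse_identity = 90) {
  stopifnot(inherits(graph, "ssn_graph"))
  ids <- graph$nodes$id
  parent <- stats::setNames(seq_along(ids), ids)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  high <- graph$edges[graph$edges$identity > collapse_identity, ,
                      drop = FALSE]
  for (i in seq_len(nrow(high))) {
    ra <- find(match(high$from[i], ids))
    rb <- find(match(high$to[i], ids))
    if (ra != rb) parent[rb] <- ra
  }
  root <- vapply(seq_along(ids), find, integer(1L))
  members <- lapply(split(seq_along(ids), root), function(ii)
    unlist(graph$nodes$members[ii], use.names = FALSE))
  meta_id <- vapply(members, function(m) min(m), character(1L))
  node_meta <- stats::setNames(meta_id[as.character(root)], ids)
  nodes <- data.frame(id = unname(meta_id), stringsAsFactors = FALSE)
  nodes$members <- unname(lapply(members, sort))
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  e <- graph$edges
  if (nrow(e)) {
    ef <- unname(node_meta[e$from])
    et <- unname(node_meta[e$to])
    keep <- ef != et
    e <- e[keep, , drop = FALSE]
    a <- pmin(ef[keep], et[keep]); b <- pmax(ef[keep], et[keep])
    key <- paste(a, b, sep = "\r")
    ord <- order(key, e$evalue, -e$bitscore)
    first <- !duplicated(key[ord])
    e <- data.frame(from = a[ord][first], to = b[ord][first],
                    identity = e$identity[ord][first],
                    evalue = e$evalue[ord][first],
                    bitscore = e$bitscore[ord][first],
                    stringsAsFactors = FALSE)
  }
  .ssn_graph(nodes, e, c(graph$thresholds,
                         list(collapse = collapse_identity)))
}

#' Component and degree summary of a similarity network
#'
#' @param graph An `ssn_graph`.
#' @return List with `n_nodes`, `n_edges`, `n_components`,
#'   `component_sizes`, `degree` (named) and `hubs` (nodes of maximal
#'   degree; empty for an edgeless graph).
#' @export
graph_stats <- function(graph) {
  stopifnot(inherits(graph, "ssn_graph"))
  if (nrow(graph$nodes) == 0L) {
    return(list(n_nodes = 0L, n_edges = 0L, n_components = 0L,
                component_sizes = integer(0),
                degree = stats::setNames(integer(0), character(0)),
                hubs = character(0)))
  }
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to"), drop = FALSE], directed = FALSE,
    vertices = graph$nodes$id)
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  hubs <- if (any(deg > 0)) names(deg)[deg == max(deg)] else character(0)
  list(n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
       n_components = comp$no,
       component_sizes = sort(as.integer(comp$csize), decreasing = TRUE),
       degree = deg, hubs = sort(hubs))
}

#' Write a similarity network as node and edge TSVs
#'
#' @param graph An `ssn_graph`.
#' @param nodes_path,edges_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_ssn <- function(graph, nodes_path, edges_path) {
  nodes <- data.frame(
    id = graph$nodes$id,
    n_members = lengths(graph$nodes$members),
    members = vapply(graph$nodes$members, paste, character(1L),
                     collapse = ","))
  utils::write.table(nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(graph$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(nodes_path, edges_path))
}
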