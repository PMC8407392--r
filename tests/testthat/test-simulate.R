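# Synthetic-data generator: determinism, Dollo-compatible content
# histories, sequence divergence structure, LGT injection, primer planting.

test_that("simulated trees are rooted, labelled and deterministic", {
  cfg <- sim_config(n_leaves = 2, seed = 11)
  cherry <- simulate_tree(cfg)
  expect_equal(sort(cherry$tip.label), c("G1", "G2"))
  expect_true(ape::is.rooted(cherry))

  cfg8 <- sim_config(n_leaves = 8, seed = 5)
  tr <- simulate_tree(cfg8)
  expect_equal(tr$Nnode, 7L)  # rooted binary: n - 1 internal nodes
  expect_true(all(tr$edge.length > 0))
  expect_identical(write_newick(simulate_tree(cfg8)),
                   write_newick(simulate_tree(cfg8)))

  expect_error(sim_config(n_leaves = 1), "n_leaves")
  expect_error(sim_config(loss_prob = 1.5), "loss_prob")
})

test_that("gene content without gains or losses is the root set", {
  cfg <- sim_config(n_leaves = 5, seed = 3, root_family_count = 40,
                    gain_rate = 0, loss_prob = 0)
  tr <- simulate_tree(cfg)
  gc <- evolve_gene_content(tr, cfg)
  expect_equal(dim(gc$matrix), c(5L, 40L))
  expect_true(all(gc$matrix == 1L))
  expect_equal(sum(gc$truth$events$type == "loss"), 0L)
})

test_that("total loss leaves only terminal-branch gains", {
  cfg <- sim_config(n_leaves = 4, seed = 9, root_family_count = 30,
                    gain_rate = 3, loss_prob = 1)
  tr <- simulate_tree(cfg)
  gc <- evolve_gene_content(tr, cfg)
  ev <- gc$truth$events
  # every family surviving at a leaf was gained on that leaf's own branch
  for (fam in colnames(gc$matrix)) {
    carriers <- rownames(gc$matrix)[gc$matrix[, fam] == 1]
    gained_on <- ev$branch[ev$family == fam & ev$type == "gain"]
    expect_equal(carriers, gained_on)
  }
})

test_that("every simulated family has exactly one gain (Dollo property)", {
  for (s in 1:3) {
    cfg <- sim_config(n_leaves = 6, seed = s, root_family_count = 50,
                      gain_rate = 2, loss_prob = 0.3)
    gc <- evolve_gene_content(simulate_tree(cfg), cfg)
    gains <- gc$truth$events[gc$truth$events$type == "gain", ]
    expect_equal(anyDuplicated(gains$family), 0L)
    expect_true(all(colnames(gc$matrix) %in% gains$family))
  }
})

test_that("root-family retention matches the branchwise binomial model", {
  cfg <- sim_config(n_leaves = 4, seed = 21, root_family_count = 2000,
                    gain_rate = 0, loss_prob = 0.2)
  tr <- simulate_tree(cfg)
  gc <- evolve_gene_content(tr, cfg)
  idx <- panarch:::.tree_index(tr)
  depth <- integer(idx$n_node)
  for (nd in idx$preorder) {
    if (nd != idx$root) depth[nd] <- depth[idx$parent[nd]] + 1L
  }
  for (leaf in seq_len(idx$n_tip)) {
    d <- depth[leaf]
    expected <- (1 - cfg$loss_prob)^d
    se <- sqrt(expected * (1 - expected) / 2000)
    observed <- sum(gc$matrix[tr$tip.label[leaf],
                              intersect(sprintf("F%05d", 1:2000),
                                        colnames(gc$matrix))]) / 2000
    expect_lt(abs(observed - expected), 3 * se + 1e-12)
  }
})

test_that("sequences are deterministic and track the tree structure", {
  cfg0 <- sim_config(n_leaves = 4, seed = 2, root_family_count = 20,
                     mutation_rate = 0, protein_length_mean = 60,
                     loss_prob = 0, gain_rate = 0)
  tr <- simulate_tree(cfg0)
  gc <- evolve_gene_content(tr, cfg0)
  sq <- emit_sequences(gc$matrix, tr, cfg0)
  # zero mutation: all genome copies of a family identical
  for (fam in colnames(gc$matrix)[1:5]) {
    copies <- vapply(names(sq$proteomes), function(g)
      as.character(sq$proteomes[[g]][[paste0(g, "|", fam)]]), "")
    expect_equal(length(unique(copies)), 1L)
  }
  # same seed, same bytes
  sq2 <- emit_sequences(gc$matrix, tr, cfg0)
  expect_identical(as.character(sq$genomes), as.character(sq2$genomes))

  cfg <- sim_config(n_leaves = 6, seed = 13, root_family_count = 120,
                    mutation_rate = 0.08, loss_prob = 0, gain_rate = 0,
                    protein_length_mean = 80)
  tr <- simulate_tree(cfg)
  gc <- evolve_gene_content(tr, cfg)
  sq <- emit_sequences(gc$matrix, tr, cfg)
  paths <- ape::cophenetic.phylo(tr)
  pairs <- which(upper.tri(paths), arr.ind = TRUE)
  closest <- pairs[which.min(paths[pairs]), ]
  farthest <- pairs[which.max(paths[pairs]), ]
  frac_ident <- function(g1, g2) {
    fams <- colnames(gc$matrix)[1:100]
    mean(vapply(fams, function(fam) {
      a <- strsplit(as.character(sq$proteomes[[g1]][[paste0(g1, "|", fam)]]),
                    "")[[1]]
      b <- strsplit(as.character(sq$proteomes[[g2]][[paste0(g2, "|", fam)]]),
                    "")[[1]]
      mean(a == b)
    }, numeric(1)))
  }
  labs <- rownames(paths)
  expect_gt(frac_ident(labs[closest[1]], labs[closest[2]]),
            frac_ident(labs[farthest[1]], labs[farthest[2]]))
})

test_that("LGT injection copies donor genes verbatim with full truth", {
  cfg0 <- sim_config(n_leaves = 4, seed = 6, root_family_count = 15,
                     protein_length_mean = 60, lgt_count = 0)
  tr <- simulate_tree(cfg0)
  gc <- evolve_gene_content(tr, cfg0)
  sq <- emit_sequences(gc$matrix, tr, cfg0)
  pool <- donor_pool(c(DX = "d__Bacteria;p__Firmicutes"), seed = 4)

  none <- inject_lgt(sq$proteomes, pool$donors, cfg0)
  expect_identical(lapply(none$proteomes, as.character),
                   lapply(sq$proteomes, as.character))

  cfg5 <- sim_config(n_leaves = 4, seed = 6, root_family_count = 15,
                     protein_length_mean = 60, lgt_count = 5)
  inj <- inject_lgt(sq$proteomes, pool$donors, cfg5)
  expect_equal(nrow(inj$lgt), 5L)
  new_total <- sum(lengths(inj$proteomes)) - sum(lengths(sq$proteomes))
  expect_equal(new_total, 5L)
  for (i in 1:5) {
    rec <- inj$lgt$recipient[i]
    got <- as.character(inj$proteomes[[rec]][[inj$lgt$gene[i]]])
    want <- pool$donors$sequence[pool$donors$gene == inj$lgt$donor_gene[i]]
    expect_identical(got, want)
  }
  expect_error(inject_lgt(sq$proteomes, pool$donors[0, ], cfg5),
               "empty donor pool")
})

test_that("emulated hit tables rank verbatim copies first", {
  prot <- list(
    gA = Biostrings::AAStringSet(c("gA|p1" = "MKLVDEWAARNDCEQGHILK")),
    gB = Biostrings::AAStringSet(c("gB|p1" = "MKLVDEWAARNDCEQGHILK")))
  lins <- list(gA = parse_lineage("d__Archaea"),
               gB = parse_lineage("d__Archaea"))
  h <- emulate_hit_table(prot, lins)
  expect_equal(nrow(h), 2L)  # one best hit each way, self-genome excluded
  expect_true(all(h$pident == 100))

  prot$gC <- Biostrings::AAStringSet()  # empty proteome -> no query rows
  h2 <- emulate_hit_table(prot, lins)
  expect_false("gC" %in% h2$query_genome)
})

test_that("primer fixtures carry certified planted mismatch counts", {
  cfg <- sim_config(seed = 31, primer_count = 4)
  pf <- generate_primer_fixture(cfg)
  expect_equal(dim(pf$truth), c(4L, 3L))
  expect_true(all(pf$truth >= 0 & pf$truth <= 5))
  expect_true(any(pf$sites$strand == "-"))  # reverse-orientation case
  # deterministic under the seed
  pf2 <- generate_primer_fixture(cfg)
  expect_identical(pf$primers, pf2$primers)
  expect_identical(as.character(pf$targets), as.character(pf2$targets))
})
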