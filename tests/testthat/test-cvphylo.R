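# Composition vectors, distances, neighbor joining and rooted-tree queries.

test_that("k-mer counting slides windows and skips ambiguity codes", {
  expect_equal(count_kmers("ACGT", 4), c(ACGT = 1L))
  counts <- count_kmers("ACGTACGT", 2)
  expect_equal(counts[c("AC", "CG", "GT", "TA")],
               c(AC = 2L, CG = 2L, GT = 2L, TA = 1L))
  expect_equal(sum(counts), 7L)  # L - k + 1
  skipped <- count_kmers("ACNGT", 2, valid_chars = c("A", "C", "G", "T"))
  expect_equal(sort(names(skipped)), c("AC", "GT"))
  expect_warning(count_kmers("AC", 4), "no usable window")
})

test_that("composition vector matches the hand-computed toy", {
  cv <- composition_vector("AAAB", k = 3, alphabet = "any")
  # direct evaluation of (f - q)/q with f3(AAA)=f3(AAB)=1/2,
  # f2(AA)=2/3, f2(AB)=1/3, f1(A)=3/4: q(AAA)=16/27, q(AAB)=8/27
  expect_equal(cv$scores[["AAA"]], (1 / 2 - 16 / 27) / (16 / 27))
  expect_equal(cv$scores[["AAB"]], (1 / 2 - 8 / 27) / (8 / 27))
  expect_equal(unname(cv$scores), c(-0.15625, 0.6875))
})

test_that("composition vector depends on frequencies, not record count", {
  set.seed(1)
  s <- random_dna(600)
  once <- composition_vector(s, 4, "nt")
  twice <- composition_vector(c(s, s), 4, "nt")
  expect_equal(once$scores, twice$scores)
})

test_that("background subtraction shrinks components for i.i.d. input", {
  set.seed(42)
  short <- composition_vector(random_dna(1e3), 4, "nt")
  long <- composition_vector(random_dna(1e5), 4, "nt")
  expect_lt(mean(abs(long$scores)), mean(abs(short$scores)))
})

test_that("cv_distance is a bounded symmetric premetric", {
  set.seed(5)
  a <- composition_vector(random_dna(800), 4, "nt")
  expect_equal(cv_distance(a, a), 0)
  for (i in 1:10) {
    x <- composition_vector(random_dna(500), 4, "nt")
    y <- composition_vector(random_dna(500), 4, "nt")
    d <- cv_distance(x, y)
    expect_equal(d, cv_distance(y, x))
    expect_gte(d, 0); expect_lte(d, 1)
  }
  # orthogonal and antipodal bounds, via hand-built vectors
  mk <- function(scores) structure(list(k = 3L, scores = scores),
                                   class = "composition_vector")
  expect_equal(cv_distance(mk(c(AAA = 1)), mk(c(CCC = 1))), 0.5)
  v <- c(AAA = 0.4, ABC = -0.7)
  expect_equal(cv_distance(mk(v), mk(-v)), 1)
  expect_error(cv_distance(mk(c(AAA = 0)[0]), mk(v)), "zero-norm")
})

test_that("distance matrices separate copies from noise and stay symmetric", {
  set.seed(8)
  base <- random_protein(2000)
  genomes <- list(A = base, B = base, C = random_protein(2000))
  D <- build_distance_matrix(genomes, k = 4, alphabet = "aa")
  expect_equal(D["A", "B"], 0)
  expect_lt(D["A", "B"], D["A", "C"])
  expect_identical(D, t(D))
  expect_equal(diag(D), c(A = 0, B = 0, C = 0))
})

test_that("neighbor joining recovers additive trees and closed forms", {
  # generating tree ((A:1,B:2):1,(C:1,D:1):2)
  D <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  D["A", "B"] <- 3; D["C", "D"] <- 2
  D["A", "C"] <- D["A", "D"] <- 5
  D["B", "C"] <- D["B", "D"] <- 6
  D <- D + t(D)
  tr <- neighbor_joining(D)
  # topology AB|CD and branch lengths reproduce the input path distances
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[rownames(D),
                                                           colnames(D)]),
               unname(D))
  expect_equal(as.numeric(ape::dist.topo(
    tr, ape::unroot(read_newick("((A:1,B:2):1,(C:1,D:1):2);")))), 0)

  # three taxa: closed-form branch lengths v_A = (dAB + dAC - dBC)/2 etc.
  D3 <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- neighbor_joining(D3)
  cp <- as.matrix(ape::cophenetic.phylo(tr3))
  expect_equal(cp["A", "B"], 0.3)
  expect_equal(cp["A", "C"], 0.5)
  expect_equal(cp["B", "C"], 0.6)

  # two taxa: a single edge carrying the full distance
  D2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("X", "Y"),
                                                     c("X", "Y")))
  tr2 <- neighbor_joining(D2)
  expect_equal(sum(tr2$edge.length), 0.4)

  Dbad <- D; Dbad[1, 2] <- 99
  expect_error(neighbor_joining(Dbad), "symmetric")
})

test_that("NJ is consistent on random additive binary trees", {
  set.seed(99)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1))
    D <- as.matrix(ape::cophenetic.phylo(tr))
    rec <- neighbor_joining(D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), rec)), 0)
  }
})

test_that("MRCA queries behave on rooted trees and reject unrooted ones", {
  tr <- read_newick("((A,B),C);")
  expect_equal(names(mrca_node(tr, "A")), "A")
  ab <- mrca_node(tr, c("A", "B"))
  expect_equal(sort(panarch:::node_label(
    tr, panarch:::.tree_index(tr)$children[[unname(ab)]])), c("A", "B"))
  tr4 <- read_newick("((A,B),(C,D));")
  expect_equal(unname(mrca_node(tr4, c("A", "C"))),
               length(tr4$tip.label) + 1L)  # the root
  expect_error(mrca_node(tr4, "Z"), "unknown leaf")
  expect_error(mrca_node(ape::unroot(ape::rtree(5)), c("t1", "t2")),
               "root")
})

test_that("closest-reference selection walks to the first reference clade", {
  tr <- read_newick("(((Q1,Q2),R1),R2);")
  expect_equal(select_closest_reference(tr, "Q1", c("R1", "R2")), "R1")
  expect_equal(select_closest_reference(tr, "Q1", "R2"), "R2")
  # query sister to a reference
  tr2 <- read_newick("((Q,R1),R2);")
  expect_equal(select_closest_reference(tr2, "Q", c("R1", "R2")), "R1")
  # basal attachment preferred, lexicographic ties
  tr3 <- read_newick("((Q,((R3,R4),R2)),X);")
  expect_equal(select_closest_reference(tr3, "Q", c("R2", "R3", "R4")),
               "R2")
  expect_error(select_closest_reference(tr, "Q1", "Z9"), "no reference")
})
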