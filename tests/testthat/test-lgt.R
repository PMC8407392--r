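# Best-hit taxonomy LGT rule: worked cases, order invariance, band
# monotonicity, summaries and recovery bookkeeping.

dpann_lin <- parse_lineage("d__Archaea;p__Simarchaeota")
inside <- "d__Archaea;p__Simarchaeota;c__X"
outside_domain <- "d__Bacteria;p__Firmicutes"
outside_phylum <- "d__Archaea;p__Euryarchaeota"

test_that("the three worked hit-table cases follow the 90% band rule", {
  # all hits within the recipient phylum: no call
  h1 <- as_hit_table(
    hit_row("R|g1", "A|s1", 100, lineage = inside),
    hit_row("R|g1", "B|s2", 80, lineage = inside))
  expect_equal(nrow(call_ltg(h1, dpann_lin)), 0L)

  # best outside at 100 bits, best within at 80 < 0.9 * 100: call
  h2 <- as_hit_table(
    hit_row("R|g1", "X|s1", 100, lineage = outside_domain),
    hit_row("R|g1", "B|s2", 80, lineage = inside))
  calls <- call_ltg(h2, dpann_lin)
  expect_equal(nrow(calls), 1L)
  expect_true(calls$cross_domain)
  expect_equal(calls$donor_genome, "X")
  expect_equal(calls$best_within_bit, 80)

  # within-lineage hit inside the band (95 >= 90): no call
  h3 <- as_hit_table(
    hit_row("R|g1", "X|s1", 100, lineage = outside_domain),
    hit_row("R|g1", "B|s2", 95, lineage = inside))
  expect_equal(nrow(call_ltg(h3, dpann_lin)), 0L)
})

test_that("self hits, top ties and rank choice are handled", {
  # self-genome hit excluded before evaluation
  h <- as_hit_table(
    hit_row("R|g1", "R|self", 200, lineage = inside),
    hit_row("R|g1", "X|s1", 100, lineage = outside_domain),
    hit_row("R|g1", "B|s2", 50, lineage = inside))
  expect_equal(nrow(call_ltg(h, dpann_lin)), 1L)

  # top-score tie spanning inside and outside: conservative no-call
  tie <- as_hit_table(
    hit_row("R|g1", "X|s1", 100, lineage = outside_domain),
    hit_row("R|g1", "B|s2", 100, lineage = inside))
  expect_equal(nrow(call_ltg(tie, dpann_lin)), 0L)

  # same-domain different-phylum donor is outside at rank phylum but not
  # cross-domain
  hp <- as_hit_table(hit_row("R|g1", "E|s1", 90,
                             lineage = outside_phylum))
  cp <- call_ltg(hp, dpann_lin)
  expect_equal(nrow(cp), 1L)
  expect_false(cp$cross_domain)
})

test_that("calls are invariant to input row order and monotone in f", {
  rows <- list(
    hit_row("R|g1", "X|s1", 100, lineage = outside_domain),
    hit_row("R|g1", "B|s2", 85, lineage = inside),
    hit_row("R|g2", "B|s3", 70, lineage = inside),
    hit_row("R|g2", "X|s4", 60, lineage = outside_domain),
    hit_row("R|g3", "X|s5", 40, lineage = outside_domain))
  h <- do.call(as_hit_table, rows)
  set.seed(30)
  for (i in 1:5) {
    shuffled <- h[sample(nrow(h)), ]
    class(shuffled) <- class(h)
    expect_equal(call_ltg(shuffled, dpann_lin)$gene,
                 call_ltg(h, dpann_lin)$gene)
  }
  # raising f loosens the within-lineage bound and can only grow the set
  calls_by_f <- lapply(c(0.8, 0.9, 0.95), function(f)
    call_ltg(h, dpann_lin, ltg_config(bitscore_fraction = f))$gene)
  expect_true(all(calls_by_f[[1]] %in% calls_by_f[[2]]))
  expect_true(all(calls_by_f[[2]] %in% calls_by_f[[3]]))
})

test_that("rank nesting: a class-level call is also a phylum-level call", {
  same_phylum_diff_class <- "d__Archaea;p__Simarchaeota;c__Other"
  h <- as_hit_table(
    hit_row("R|g1", "C|s1", 100, lineage = same_phylum_diff_class),
    hit_row("R|g1", "X|s2", 100, lineage = outside_phylum))
  recip <- parse_lineage("d__Archaea;p__Simarchaeota;c__X")
  at_class <- call_ltg(h, recip, ltg_config(rank = "class"))
  at_phylum <- call_ltg(h, recip, ltg_config(rank = "phylum"))
  # at class rank both hits are outside -> call; at phylum only one is
  # outside and there is a within-lineage top tie -> no call
  expect_equal(nrow(at_class), 1L)
  expect_equal(nrow(at_phylum), 0L)
})

test_that("donor summaries and category profiles add up", {
  calls <- do.call(rbind, lapply(1:11, function(i) {
    data.frame(gene = paste0("R|g", i), recipient_genome = "R",
               donor_gene = "d", donor_genome = "D",
               donor_lineage = if (i <= 5) outside_domain
                               else outside_phylum,
               cross_domain = i <= 5, best_bit = 100,
               best_within_bit = NA_real_, cog = NA_character_,
               stringsAsFactors = FALSE)
  }))
  s <- donor_summary(calls, superphylum_phyla = "Simarchaeota")
  expect_equal(s$cross_domain_fraction, 5 / 11, tolerance = 1e-12)
  expect_equal(sum(s$donor_phyla), nrow(calls))
  expect_equal(s$within_superphylum_fraction, 0)

  ann <- c("R|g1" = "J", "R|g2" = "J", "R|g3" = "L")
  prof <- ltg_category_profile(calls, ann)
  expect_equal(prof$proportions[["J"]], 2 / 3)
  expect_equal(prof$proportions[["L"]], 1 / 3)
  expect_equal(prof$n_unannotated, 8L)
  expect_equal(sum(prof$proportions), 1)

  empty <- donor_summary(calls[0, ])
  expect_equal(empty$n_calls, 0L)
  expect_equal(empty$cross_domain_fraction, 0)
})

test_that("recovery report uses the documented empty-case sentinels", {
  no_calls <- data.frame(gene = character(0))
  rep0 <- ltg_recovery_report(no_calls, NULL)
  expect_true(is.na(rep0$precision))
  expect_equal(rep0$recall, 1.0)

  truth <- data.frame(gene = c("R|LGT1", "R|LGT2"))
  calls <- data.frame(gene = c("R|LGT1", "R|g9"))
  r <- ltg_recovery_report(calls, truth)
  expect_equal(r$precision, 0.5)
  expect_equal(r$recall, 0.5)
  expect_equal(r$n_true_positive, 1L)
})
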