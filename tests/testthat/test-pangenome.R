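# Gene-family clustering, permutation curves, regression fits, openness
# classification and core/accessory/unique partitions.

test_that("greedy clustering groups homologs and separates strangers", {
  set.seed(2)
  g1 <- c("p1" = random_protein(120), "p2" = random_protein(120),
          "p3" = random_protein(120))
  names(g1) <- paste0("gA|", names(g1))
  g2 <- g1
  names(g2) <- sub("gA", "gB", names(g2))
  m <- cluster_families(list(gA = g1, gB = g2))
  expect_equal(ncol(m), 3L)
  expect_true(all(m == 1L))

  # two unrelated random 200-mers stay apart at the 30% cutoff
  set.seed(3)
  solo <- list(gA = c("gA|x" = random_protein(200)),
               gB = c("gB|y" = random_protein(200)))
  expect_equal(ncol(cluster_families(solo)), 2L)

  # a 50%-identity mutant joins its parent family
  set.seed(4)
  a <- random_protein(100)
  chars <- strsplit(a, "")[[1]]
  pos <- sample(100, 50)
  for (i in pos) chars[i] <- sample(setdiff(panarch:::.AA20, chars[i]), 1)
  a_prime <- paste(chars, collapse = "")
  one <- cluster_families(list(gA = c("gA|a" = a, "gA|a2" = a_prime)))
  expect_equal(ncol(one), 1L)
  expect_error(cluster_families(list()), "empty")
})

test_that("permutation curves cover degenerate family layouts", {
  m_same <- gene_family_matrix(matrix(1L, 3, 4, dimnames = list(
    paste0("g", 1:3), paste0("f", 1:4))))
  cur <- permutation_curves(m_same, n_permutations = 10, seed = 1)
  expect_true(all(cur$pan == 4L))
  expect_true(all(cur$core == 4L))

  m_disj <- gene_family_matrix(diag(3L) %x% matrix(1L, 1, 2) |>
    `dimnames<-`(list(paste0("g", 1:3), paste0("f", 1:6))))
  cur2 <- permutation_curves(m_disj, n_permutations = 20, seed = 1)
  for (n in 1:3) expect_true(all(cur2$pan[, n] == 2L * n))
  expect_true(all(cur2$core[, 2:3] == 0L))
})

test_that("exhaustive permutation curves equal brute-force enumeration", {
  set.seed(11)
  m <- matrix(rbinom(15, 1, 0.5), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("f", 1:5)))
  m[, colSums(m) == 0] <- 1L
  m <- gene_family_matrix(m)
  mine <- permutation_curves(m, exhaustive = TRUE)
  oracle <- pan_core_exhaustive(m)
  for (n in 1:3) {
    expect_equal(sort(mine$pan[, n]), sort(oracle$pan[, n]))
    expect_equal(sort(mine$core[, n]), sort(oracle$core[, n]))
  }
  # random sampling draws from the same per-n value sets
  rnd <- permutation_curves(m, n_permutations = 50, seed = 2)
  for (n in 1:3) {
    expect_true(all(rnd$pan[, n] %in% oracle$pan[, n]))
  }
})

test_that("pan curves are monotone within every permutation", {
  set.seed(12)
  m <- matrix(rbinom(60, 1, 0.4), nrow = 6,
              dimnames = list(paste0("g", 1:6), paste0("f", 1:10)))
  m[, colSums(m) == 0] <- 1L
  cur <- permutation_curves(gene_family_matrix(m), 40, seed = 3)
  expect_true(all(apply(cur$pan, 1, function(r) all(diff(r) >= 0))))
  expect_true(all(apply(cur$core, 1, function(r) all(diff(r) <= 0))))
  expect_equal(cur$pan[, 1], cur$core[, 1])  # one genome: union == intersection
})

test_that("power-law fits recover exact generating parameters", {
  n <- 1:8
  pan <- matrix(10 * n^0.5, nrow = 1)
  core <- matrix(rev(sort(100 * exp(-0.5 * n))), nrow = 1)
  curves <- pan_core_curves(pan, core)
  fit <- fit_power_law(curves)
  expect_equal(fit$kappa, 10, tolerance = 1e-9)
  expect_equal(fit$gamma, 0.5, tolerance = 1e-9)
  expect_equal(predict_pan_size(fit, 4), 20, tolerance = 1e-8)

  flat <- pan_core_curves(matrix(7, 1, 5), matrix(7, 1, 5))
  fit_flat <- fit_power_law(flat)
  expect_equal(fit_flat$gamma, 0, tolerance = 1e-12)
  expect_equal(fit_flat$kappa, 7, tolerance = 1e-9)
})

test_that("exponential fits recover parameters and truncate the zero tail", {
  n <- 1:8
  curves <- pan_core_curves(matrix(10 * n, nrow = 1),
                            matrix(100 * exp(-0.5 * n), nrow = 1))
  fit <- fit_exponential(curves)
  expect_equal(fit$kappa_c, 100, tolerance = 1e-9)
  expect_equal(fit$rate, 0.5, tolerance = 1e-9)
  expect_equal(fit$tau_c, 2, tolerance = 1e-9)

  core0 <- c(80, 40, 20, 0, 0)
  curves0 <- pan_core_curves(matrix(1:5 * 10, nrow = 1),
                             matrix(core0, nrow = 1))
  fit0 <- fit_exponential(curves0)
  expect_equal(fit0$fit_points$n, 1:3)  # zero tail dropped
  expect_error(fit_exponential(pan_core_curves(matrix(1:3 * 10, nrow = 1),
                                               matrix(c(5, 0, 0), nrow = 1))),
               "3 positive")
})

test_that("openness classification follows the gamma rules", {
  expect_equal(as.character(classify_openness(power_law_fit(423.919,
                                                            0.983))),
               "open")
  expect_equal(as.character(classify_openness(power_law_fit(100, -0.1))),
               "closed")
  expect_equal(as.character(classify_openness(power_law_fit(100, 0))),
               "closed")
  expect_warning(lab <- classify_openness(power_law_fit(10, 1.2)),
                 "super-linear")
  expect_equal(as.character(lab), "open")
  expect_equal(attr(classify_openness(power_law_fit(1, 0.7)), "gamma"), 0.7)
})

test_that("core extinction point solves kappa_c e^(-rate n) < 1", {
  expect_equal(core_extinction_point(exponential_fit(26457.4, 3.342)), 4L)
  expect_equal(core_extinction_point(exponential_fit(0.5, 1)), 1L)
  expect_equal(core_extinction_point(exponential_fit(exp(10), 1)), 11L)
  expect_error(core_extinction_point(exponential_fit(10, -1)),
               "non-decaying")
})

test_that("matrix partitions are disjoint, exhaustive and hand-checkable", {
  m_same <- gene_family_matrix(matrix(1L, 3, 5, dimnames = list(
    paste0("g", 1:3), paste0("f", 1:5))))
  p1 <- partition_matrix(m_same)
  expect_equal(unname(p1$totals), c(5L, 0L, 0L, 5L))

  m_disj <- gene_family_matrix(diag(3L) |>
    `dimnames<-`(list(paste0("g", 1:3), paste0("f", 1:3))))
  p2 <- partition_matrix(m_disj)
  expect_equal(unname(p2$totals[["unique"]]), 3L)
  expect_equal(p2$totals[["core"]], 0L)

  # hand-enumerated toy: f1 everywhere, f2 in g1+g2, f3 only g3
  m <- gene_family_matrix(matrix(c(1, 1, 1, 1, 1, 0, 0, 0, 1), 3,
                                 dimnames = list(paste0("g", 1:3),
                                                 paste0("f", 1:3))))
  p3 <- partition_matrix(m)
  expect_equal(unname(p3$totals), c(1L, 1L, 1L, 3L))
  expect_equal(p3$per_genome$core, c(1L, 1L, 1L))
  expect_equal(p3$per_genome$unique, c(0L, 0L, 1L))
  expect_equal(sum(p3$totals[c("core", "accessory", "unique")]),
               p3$totals[["total"]])
})
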