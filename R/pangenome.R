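# Pan/core-genome machinery: greedy identity clustering of gene families,
# permutation-based accumulation curves, the Heaps-law power fit Ps = kappa *
# n^gamma with the open/closed rule on gamma, the exponential core decay
# Fc = kappa_c * exp(-rate * n), and core/accessory/unique partitions.

#' Cluster proteomes into gene families by greedy centroid clustering
#'
#' Sequences are sorted by length (descending, lexicographic id tie-break);
#' each sequence joins the first existing centroid whose global-alignment
#' identity (matches / alignment columns) reaches `identity_cutoff`,
#' otherwise it founds a new family.
#'
#' @param proteomes Named list of [Biostrings::AAStringSet]s (or named
#'   character vectors), one per genome.
#' @param identity_cutoff Fractional identity threshold (default 0.30).
#' @param scoring An [align_scoring()]; nucleotide-style unit scores are the
#'   documented clustering convention (match +1, mismatch -1, gap -2).
#' @return Presence/absence matrix (see [gene_family_matrix()]) with a
#'   `"membership"` attribute mapping gene id to family id.
#' @export
cluster_families <- function(proteomes, identity_cutoff = 0.30,
                             scoring = align_scoring("aa", match = 1,
                                                     mismatch = -1,
                                                     gap_open = 0,
                                                     gap_extend = -2)) {
  if (length(proteomes) == 0L) stop("empty proteome set")
  pooled <- unlist(lapply(names(proteomes), function(g) {
    s <- seq_chars(proteomes[[g]])
    stats::setNames(s, names(s))
  }))
  if (length(pooled) == 0L) stop("no sequences to cluster")
  genome <- genome_of(names(pooled))
  ord <- order(-nchar(pooled), names(pooled))
  pooled <- pooled[ord]
  genome <- genome[ord]
  centroids <- character(0)
  membership <- integer(length(pooled))
  subst <- .subst_matrix(scoring)
  for (i in seq_along(pooled)) {
    assigned <- 0L
    if (length(centroids)) {
      al <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::AAStringSet(centroids),
        subject = Biostrings::AAString(pooled[i]),
        type = "global", substitutionMatrix = subst,
        gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
      cols <- nchar(as.character(Biostrings::pattern(al)))
      ident <- Biostrings::nmatch(al) / cols
      hit <- which(ident >= identity_cutoff)
      if (length(hit)) assigned <- hit[1L]
    }
    if (assigned == 0L) {
      centroids <- c(centroids, pooled[i])
      assigned <- length(centroids)
    }
    membership[i] <- assigned
  }
  fam_ids <- sprintf("FAM%04d", seq_along(centroids))
  m <- matrix(0L, nrow = length(proteomes), ncol = length(centroids),
              dimnames = list(names(proteomes), fam_ids))
  for (i in seq_along(pooled)) m[genome[i], membership[i]] <- 1L
  out <- gene_family_matrix(m)
  attr(out, "membership") <- stats::setNames(fam_ids[membership],
                                             names(pooled))
  out
}

#' Construct pan/core curve object
#'
#' @param pan,core Numeric matrices (permutations x n) of pan and core sizes.
#' @return Object of class `pan_core_curves` with per-n mean/median summary.
#' @export
pan_core_curves <- function(pan, core) {
  pan <- as.matrix(pan); core <- as.matrix(core)
  stopifnot(all(dim(pan) == dim(core)))
  if (any(apply(pan, 1L, function(r) any(diff(r) < 0)))) {
    stop("pan sizes must be non-decreasing within each permutation")
  }
  if (any(apply(core, 1L, function(r) any(diff(r) > 0)))) {
    stop("core sizes must be non-increasing within each permutation")
  }
  n <- ncol(pan)
  structure(list(
    pan = pan, core = core, n_genomes = n, n_permutations = nrow(pan),
    summary = data.frame(n = seq_len(n),
                         pan_mean = colMeans(pan),
                         pan_median = apply(pan, 2L, stats::median),
                         core_mean = colMeans(core),
                         core_median = apply(core, 2L, stats::median))),
    class = "pan_core_curves")
}

.all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .all_perms(n - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Pan/core accumulation curves over genome permutations
#'
#' For each permutation of the genomes, `pan(n)` is the number of families
#' in the union of the first `n` genomes and `core(n)` the number in their
#' intersection.  Random orderings avoid bias from the sequential addition
#' order; all permutations are retained.
#'
#' @param matrix Presence/absence matrix (>= 2 genomes).
#' @param n_permutations Number of random orderings (default 300).
#' @param seed Integer seed.
#' @param exhaustive Enumerate all `n!` orderings instead of sampling
#'   (guarded to <= 7 genomes).
#' @return A [pan_core_curves()] object.
#' @export
permutation_curves <- function(matrix, n_permutations = 300L, seed = 1L,
                               exhaustive = FALSE) {
  G <- nrow(matrix)
  if (G < 2L) stop("need >= 2 genomes")
  logical_m <- matrix == 1L
  if (exhaustive) {
    if (G > 7L) stop("exhaustive enumeration limited to <= 7 genomes")
    orders <- .all_perms(G)
  } else {
    set.seed(seed)
    orders <- lapply(seq_len(n_permutations), function(i) sample.int(G))
  }
  P <- length(orders)
  pan <- matrix(0L, nrow = P, ncol = G)
  core <- matrix(0L, nrow = P, ncol = G)
  for (p in seq_len(P)) {
    acc_union <- rep(FALSE, ncol(matrix))
    acc_inter <- rep(TRUE, ncol(matrix))
    ord <- orders[[p]]
    for (n in seq_len(G)) {
      row <- logical_m[ord[n], ]
      acc_union <- acc_union | row
      acc_inter <- acc_inter & row
      pan[p, n] <- sum(acc_union)
      core[p, n] <- sum(acc_inter)
    }
  }
  pan_core_curves(pan, core)
}

# Mean or median pan/core sizes per n from a curves object.
.curve_points <- function(curves, what = c("pan", "core"),
                          stat = c("mean", "median")) {
  what <- match.arg(what); stat <- match.arg(stat)
  stopifnot(inherits(curves, "pan_core_curves"))
  curves$summary[[paste0(what, "_", stat)]]
}

#' Construct a power-law pan-genome model directly
#'
#' @param kappa Coefficient (> 0).
#' @param gamma Exponent.
#' @param fit_points Optional data frame of the (n, size) pairs fitted.
#' @param residual Optional root-mean-square log-scale residual.
#' @return Object of class `power_law_fit`; evaluate with
#'   [predict_pan_size()].
#' @export
power_law_fit <- function(kappa, gamma, fit_points = NULL, residual = NA) {
  if (kappa <= 0) stop("kappa must be > 0")
  structure(list(kappa = kappa, gamma = gamma, fit_points = fit_points,
                 residual = residual), class = "power_law_fit")
}

#' Evaluate a power-law pan-genome model
#' @param fit A [power_law_fit()].
#' @param n Number of genomes.
#' @return Predicted pan-genome size `kappa * n^gamma`.
#' @export
predict_pan_size <- function(fit, n) {
  stopifnot(inherits(fit, "power_law_fit"))
  fit$kappa * n^fit$gamma
}

#' Fit the Heaps-law power model to mean pan curves
#'
#' Ordinary least squares of `log(mean pan)` on `log(n)`:
#' `kappa = exp(intercept)`, `gamma = slope`.  The model is exactly
#' linearizable, so the log-linear fit is deterministic and reproducible.
#'
#' @param curves A [pan_core_curves()] object.
#' @param stat `"mean"` (default) or `"median"` curve.
#' @return A [power_law_fit()].
#' @export
fit_power_law <- function(curves, stat = c("mean", "median")) {
  y <- .curve_points(curves, "pan", match.arg(stat))
  n <- seq_along(y)
  if (length(unique(n)) < 3L) stop("need >= 3 distinct n values")
  if (any(y <= 0)) stop("pan sizes must be positive for the log-log fit")
  fit <- stats::lm(log(y) ~ log(n))
  co <- stats::coef(fit)
  power_law_fit(kappa = exp(unname(co[1L])), gamma = unname(co[2L]),
                fit_points = data.frame(n = n, size = y),
                residual = sqrt(mean(stats::residuals(fit)^2)))
}

#' Construct an exponential core-decay model directly
#'
#' @param kappa_c Coefficient (> 0).
#' @param rate Decay rate `r` (the printed form `kappa_c * e^(-r n)`);
#'   `tau_c = 1/rate`.
#' @param fit_points,residual Optional fit provenance.
#' @return Object of class `exponential_fit`.
#' @export
exponential_fit <- function(kappa_c, rate, fit_points = NULL,
                            residual = NA) {
  if (kappa_c <= 0) stop("kappa_c must be > 0")
  structure(list(kappa_c = kappa_c, rate = rate,
                 tau_c = if (rate != 0) 1 / rate else Inf,
                 fit_points = fit_points, residual = residual),
            class = "exponential_fit")
}

#' Evaluate an exponential core-decay model
#' @param fit An [exponential_fit()].
#' @param n Number of genomes.
#' @return Predicted core size `kappa_c * exp(-rate * n)`.
#' @export
predict_core_size <- function(fit, n) {
  stopifnot(inherits(fit, "exponential_fit"))
  fit$kappa_c * exp(-fit$rate * n)
}

#' Fit the exponential decay model to mean core curves
#'
#' Least squares of `log(mean core)` on `n`; the zero tail is truncated at
#' the first `n` whose mean core is 0 (a vanished core carries no further
#' information on the decay).
#'
#' @param curves A [pan_core_curves()] object.
#' @param stat `"mean"` (default) or `"median"` curve.
#' @return An [exponential_fit()].
#' @export
fit_exponential <- function(curves, stat = c("mean", "median")) {
  y <- .curve_points(curves, "core", match.arg(stat))
  n <- seq_along(y)
  first_zero <- which(y == 0)[1L]
  if (!is.na(first_zero)) {
    y <- y[seq_len(first_zero - 1L)]
    n <- n[seq_len(first_zero - 1L)]
  }
  if (length(n) < 3L) {
    stop("need >= 3 positive mean core sizes after truncating the zero ",
         "tail (", length(n), " left)")
  }
  fit <- stats::lm(log(y) ~ n)
  co <- stats::coef(fit)
  exponential_fit(kappa_c = exp(unname(co[1L])), rate = -unname(co[2L]),
                  fit_points = data.frame(n = n, size = y),
                  residual = sqrt(mean(stats::residuals(fit)^2)))
}

#' Classify pan-genome openness from the power-law exponent
#'
#' `gamma` in (0, 1) means every added genome still contributes new
#' families (an "open" pan-genome, the more open the closer to 1);
#' `gamma <= 0` means the pan-genome has stopped growing ("closed"; the
#' boundary `gamma = 0`, a flat curve, adds nothing and is classified
#' closed).  `gamma >= 1` is labelled open with a warning, as super-linear
#' growth falls outside the usual regime.
#'
#' @param fit A [power_law_fit()].
#' @return `"open"` or `"closed"`, with the degree of openness (`gamma`)
#'   attached as attribute `"gamma"`.
#' @export
classify_openness <- function(fit) {
  stopifnot(inherits(fit, "power_law_fit"))
  g <- fit$gamma
  label <- if (g > 0 && g < 1) {
    "open"
  } else if (g >= 1) {
    warning("gamma >= 1 (super-linear growth); labelled open")
    "open"
  } else {
    "closed"
  }
  structure(label, gamma = g)
}

#' Number of genomes at which the fitted core genome vanishes
#'
#' Smallest integer `n >= 1` with `kappa_c * exp(-rate * n) < 1`, i.e. the
#' point where the fitted core drops below a single gene family.
#'
#' @param fit An [exponential_fit()] with `rate > 0`.
#' @return Integer count.
#' @export
core_extinction_point <- function(fit) {
  stopifnot(inherits(fit, "exponential_fit"))
  if (fit$rate <= 0) stop("rate must be > 0 (non-decaying core)")
  n <- max(1L, floor(log(fit$kappa_c) / fit$rate) + 1L)
  while (predict_core_size(fit, n) >= 1) n <- n + 1L
  while (n > 1L && predict_core_size(fit, n - 1L) < 1) n <- n - 1L
  n
}

#' Partition families into core, accessory and unique classes
#'
#' Core families occur in all genomes (strict 100% rule), unique families in
#' exactly one, accessory families in between.  The classes are disjoint and
#' exhaustive.
#'
#' @param matrix Presence/absence matrix (>= 2 genomes).
#' @return List with `totals` (named counts incl. `total`) and `per_genome`
#'   data frame of per-genome core/accessory/unique counts.
#' @export
partition_matrix <- function(matrix) {
  G <- nrow(matrix)
  if (G < 2L) stop("need >= 2 genomes")
  occ <- colSums(matrix)
  class_of <- ifelse(occ == G, "core", ifelse(occ == 1L, "unique",
                                              "accessory"))
  per_genome <- data.frame(
    genome = rownames(matrix),
    core = vapply(seq_len(G), function(i)
      sum(matrix[i, ] == 1L & class_of == "core"), integer(1L)),
    accessory = vapply(seq_len(G), function(i)
      sum(matrix[i, ] == 1L & class_of == "accessory"), integer(1L)),
    unique = vapply(seq_len(G), function(i)
      sum(matrix[i, ] == 1L & class_of == "unique"), integer(1L)),
    stringsAsFactors = FALSE)
  totals <- c(core = sum(class_of == "core"),
              accessory = sum(class_of == "accessory"),
              unique = sum(class_of == "unique"),
              total = length(class_of))
  list(totals = totals, per_genome = per_genome,
       family_class = stats::setNames(class_of, colnames(matrix)))
}
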