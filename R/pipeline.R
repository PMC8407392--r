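# End-to-end orchestration over the synthetic demonstration: simulate ->
# families -> tree -> gain/loss -> ANI/POCP -> LGT -> SSN -> primers, with
# every output file listed in a checksummed manifest.

#' Pipeline configuration
#'
#' Collects the per-stage parameters defined by the individual modules plus
#' stage toggles.  All-vs-all alignment stages are quadratic, so the hit
#' emulation subsamples `hit_genes_per_genome` genes per genome and the ANI
#' demonstration truncates genomes to `ani_max_bases` (desk-scale guards;
#' set them higher for fuller runs).
#'
#' @param sim A [sim_config()].
#' @param k Composition-vector k-mer length.
#' @param cv_alphabet `"aa"` or `"nt"` composition-vector mode.
#' @param identity_cutoff Family-clustering identity cutoff.
#' @param n_permutations Pan/core permutations.
#' @param ltg An [ltg_config()].
#' @param evalue_cutoff,identity_cutoff_ssn,collapse_identity SSN
#'   thresholds.
#' @param hit_genes_per_genome Genes per genome entering hit emulation.
#' @param ani_max_bases Bases per genome entering the ANI stage.
#' @param stages Character vector of stages to run, in dependency order.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), k = 4L,
                            cv_alphabet = "aa", identity_cutoff = 0.30,
                            n_permutations = 300L, ltg = ltg_config(),
                            evalue_cutoff = 1e-5,
                            identity_cutoff_ssn = 35,
                            collapse_identity = 90,
                            hit_genes_per_genome = 15L,
                            ani_max_bases = 6000L,
                            stages = c("simulate", "pangenome", "cvtree",
                                       "gainloss", "taxmetrics", "lgt",
                                       "ssn", "primers")) {
  structure(list(sim = sim, k = as.integer(k), cv_alphabet = cv_alphabet,
                 identity_cutoff = identity_cutoff,
                 n_permutations = as.integer(n_permutations), ltg = ltg,
                 evalue_cutoff = evalue_cutoff,
                 identity_cutoff_ssn = identity_cutoff_ssn,
                 collapse_identity = collapse_identity,
                 hit_genes_per_genome = as.integer(hit_genes_per_genome),
                 ani_max_bases = as.integer(ani_max_bases),
                 stages = stages), class = "pipeline_config")
}

#' Validate a pipeline configuration
#'
#' Violations are returned as data, not raised; an empty character vector
#' means the configuration satisfies every stage's preconditions.
#'
#' @param config A [pipeline_config()] (or a bare list shaped like one).
#' @return Character vector of violation messages.
#' @export
validate_config <- function(config) {
  v <- character(0)
  say <- function(msg) v <<- c(v, msg)
  s <- config$sim
  if (!is.null(s)) {
    if (s$loss_prob < 0 || s$loss_prob > 1) {
      say(sprintf("sim$loss_prob = %g outside [0, 1]", s$loss_prob))
    }
    if (s$mutation_rate < 0 || s$mutation_rate > 1) {
      say(sprintf("sim$mutation_rate = %g outside [0, 1]", s$mutation_rate))
    }
    if (s$gain_rate < 0) say("sim$gain_rate must be >= 0")
    if (s$n_leaves < 2) say("sim$n_leaves must be >= 2")
    if (s$lgt_count < 0) say("sim$lgt_count must be >= 0")
  } else {
    say("sim config missing")
  }
  if (config$k < 3) say("k must be >= 3 for composition vectors")
  if (config$identity_cutoff < 0 || config$identity_cutoff > 1) {
    say(sprintf("identity_cutoff = %g outside [0, 1]",
                config$identity_cutoff))
  }
  if (config$n_permutations < 1) say("n_permutations must be >= 1")
  if (config$identity_cutoff_ssn < 0 || config$identity_cutoff_ssn > 100) {
    say("identity_cutoff_ssn outside [0, 100]")
  }
  if (config$evalue_cutoff <= 0) say("evalue_cutoff must be > 0")
  known <- c("simulate", "pangenome", "cvtree", "gainloss", "taxmetrics",
             "lgt", "ssn", "primers")
  bad <- setdiff(config$stages, known)
  if (length(bad)) say(paste("unknown stage(s):", paste(bad, collapse = ", ")))
  v
}

.pipeline_need <- function(state, what, stage) {
  if (is.null(state[[what]])) {
    stop("stage '", stage, "' requires missing upstream output '", what,
         "' (enable the producing stage)")
  }
  state[[what]]
}

#' Run the synthetic demonstration pipeline
#'
#' Executes the enabled stages in dependency order, writes every stage
#' output under `out_dir`, and finishes with `manifest.tsv` listing each
#' file with its MD5 checksum plus the seed and parameters used.  Fixing
#' the seed fixes every output byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest data frame.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  violations <- validate_config(config)
  if (length(violations)) {
    stop("invalid configuration:\n  ", paste(violations, collapse = "\n  "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list()
  files <- character(0)
  emit <- function(path) files <<- c(files, path)
  log_stage <- function(stage) {
    message("[panarch] stage ", stage)
  }
  for (stage in config$stages) {
    log_stage(stage)
    if (stage == "simulate") {
      ds <- simulate_dataset(config$sim)
      state$dataset <- ds
      p <- file.path(out_dir, "tree.nwk")
      write_newick(ds$tree, p); emit(p)
      p <- file.path(out_dir, "presence.tsv")
      write_presence_matrix(ds$matrix, p); emit(p)
      p <- file.path(out_dir, "lineages.tsv")
      write_lineages(ds$lineages, p); emit(p)
      p <- file.path(out_dir, "genomes.fna")
      write_fasta(ds$genomes, p); emit(p)
      for (g in names(ds$proteomes)) {
        p <- file.path(out_dir, paste0(g, ".faa"))
        write_fasta(ds$proteomes[[g]], p); emit(p)
      }
      p <- file.path(out_dir, "truth_events.tsv")
      utils::write.table(ds$truth$events, p, sep = "\t", quote = FALSE,
                         row.names = FALSE); emit(p)
    } else if (stage == "pangenome") {
      ds <- .pipeline_need(state, "dataset", stage)
      curves <- permutation_curves(ds$matrix, config$n_permutations,
                                   seed = config$sim$seed)
      pl <- fit_power_law(curves)
      ex <- tryCatch(fit_exponential(curves), error = function(e) NULL)
      part <- partition_matrix(ds$matrix)
      state$pangenome <- list(curves = curves, power = pl,
                              exponential = ex, partition = part)
      p <- file.path(out_dir, "pan_core_curves.tsv")
      utils::write.table(curves$summary, p, sep = "\t", quote = FALSE,
                         row.names = FALSE); emit(p)
      p <- file.path(out_dir, "pangenome_fit.txt")
      writeLines(c(
        sprintf("kappa\t%.6g", pl$kappa),
        sprintf("gamma\t%.6g", pl$gamma),
        sprintf("openness\t%s", as.character(classify_openness(pl))),
        if (!is.null(ex)) sprintf("kappa_c\t%.6g", ex$kappa_c),
        if (!is.null(ex)) sprintf("core_rate\t%.6g", ex$rate),
        sprintf("core_families\t%d", part$totals[["core"]]),
        sprintf("accessory_families\t%d", part$totals[["accessory"]]),
        sprintf("unique_families\t%d", part$totals[["unique"]])), p)
      emit(p)
    } else if (stage == "cvtree") {
      ds <- .pipeline_need(state, "dataset", stage)
      input <- if (config$cv_alphabet == "aa") {
        lapply(ds$proteomes, seq_chars)
      } else {
        lapply(names(ds$proteomes), function(g)
          seq_chars(ds$genomes[g]))
      }
      names(input) <- names(ds$proteomes)
      D <- build_distance_matrix(input, k = config$k,
                                 alphabet = config$cv_alphabet)
      nj_tree <- neighbor_joining(D)
      state$cvtree <- list(D = D, tree = nj_tree)
      p <- file.path(out_dir, "cv_distances.tsv")
      write_distance_matrix(D, p); emit(p)
      p <- file.path(out_dir, "cv_nj.nwk")
      write_newick(nj_tree, p); emit(p)
    } else if (stage == "gainloss") {
      ds <- .pipeline_need(state, "dataset", stage)
      recon <- dollo_reconstruct(ds$tree, ds$matrix)
      events <- branch_event_counts(recon)
      sizes <- ancestral_content_sizes(recon)
      recovery <- gainloss_recovery_report(recon, ds$truth)
      state$gainloss <- list(recon = recon, events = events,
                             sizes = sizes, recovery = recovery)
      p <- file.path(out_dir, "branch_events.tsv")
      utils::write.table(events, p, sep = "\t", quote = FALSE,
                         row.names = FALSE); emit(p)
      p <- file.path(out_dir, "node_sizes.tsv")
      utils::write.table(sizes, p, sep = "\t", quote = FALSE,
                         row.names = FALSE); emit(p)
    } else if (stage == "taxmetrics") {
      ds <- .pipeline_need(state, "dataset", stage)
      gg <- rownames(ds$matrix)[1:2]
      trim <- function(s) substr(s, 1L, config$ani_max_bases)
      ani <- compute_ani(stats::setNames(trim(seq_chars(ds$genomes[gg[1]])),
                                         gg[1]),
                         stats::setNames(trim(seq_chars(ds$genomes[gg[2]])),
                                         gg[2]))
      pocp <- compute_pocp(ds$proteomes[[gg[1]]], ds$proteomes[[gg[2]]])
      label <- classify_novelty(ani, pocp$pocp)
      state$taxmetrics <- list(pair = gg, ani = ani, pocp = pocp,
                               label = label)
      p <- file.path(out_dir, "taxmetrics.tsv")
      utils::write.table(
        data.frame(genomeA = gg[1], genomeB = gg[2],
                   ani = ifelse(is.na(ani), "undefined", ani),
                   pocp = pocp$pocp, label = label), p, sep = "\t",
        quote = FALSE, row.names = FALSE); emit(p)
    } else if (stage == "lgt") {
      ds <- .pipeline_need(state, "dataset", stage)
      keep_genes <- function(set, g) {
        ids <- names(set)
        lgt_ids <- if (!is.null(ds$truth$lgt)) {
          intersect(ids, ds$truth$lgt$gene)
        } else character(0)
        pick <- utils::head(ids, config$hit_genes_per_genome)
        set[unique(c(pick, lgt_ids))]
      }
      prots <- lapply(names(ds$proteomes), function(g)
        keep_genes(ds$proteomes[[g]], g))
      names(prots) <- names(ds$proteomes)
      if (!is.null(ds$donor_pool)) {
        prots <- c(prots, lapply(ds$donor_pool$proteomes, function(s)
          utils::head(s, config$hit_genes_per_genome)))
      }
      hits <- emulate_hit_table(prots, ds$lineages)
      state$hits <- hits
      recipients <- rownames(ds$matrix)
      calls <- do.call(rbind, lapply(recipients, function(g) {
        call_ltg(hits[hits$query_genome == g, , drop = FALSE],
                 ds$lineages[[g]], config$ltg)
      }))
      recovery <- ltg_recovery_report(calls, ds$truth)
      state$lgt <- list(calls = calls, summary = donor_summary(calls),
                        recovery = recovery)
      p <- file.path(out_dir, "hits.tsv")
      write_hit_table(hits, p); emit(p)
      p <- file.path(out_dir, "ltg_calls.tsv")
      utils::write.table(calls, p, sep = "\t", quote = FALSE,
                         row.names = FALSE); emit(p)
    } else if (stage == "ssn") {
      hits <- .pipeline_need(state, "hits", stage)
      graph <- build_ssn(hits, config$evalue_cutoff,
                         config$identity_cutoff_ssn)
      meta <- collapse_metanodes(graph, config$collapse_identity)
      state$ssn <- list(graph = graph, meta = meta,
                        stats = graph_stats(meta))
      write_ssn(meta, file.path(out_dir, "ssn_nodes.tsv"),
                file.path(out_dir, "ssn_edges.tsv"))
      emit(file.path(out_dir, "ssn_nodes.tsv"))
      emit(file.path(out_dir, "ssn_edges.tsv"))
    } else if (stage == "primers") {
      ds <- .pipeline_need(state, "dataset", stage)
      pf <- ds$primer_fixture
      mm <- mismatch_matrix(pf$primers, pf$targets)
      state$primers <- list(fixture = pf, result = mm,
                            truth_agreement =
                              all(mm$matrix == pf$truth))
      p <- file.path(out_dir, "primer_mismatches.tsv")
      utils::write.table(
        data.frame(primer = rownames(mm$matrix), mm$matrix,
                   check.names = FALSE), p, sep = "\t", quote = FALSE,
        row.names = FALSE); emit(p)
    }
  }
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE)
  attr(manifest, "seed") <- config$sim$seed
  mpath <- file.path(out_dir, "manifest.tsv")
  utils::write.table(cbind(manifest, seed = config$sim$seed), mpath,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(state = state, manifest = manifest,
                 manifest_path = mpath))
}
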