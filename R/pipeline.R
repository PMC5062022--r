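# End-to-end orchestration of the survey workflow on synthetic data:
# CLPP -> primer design -> in-silico PCR -> RFLP dereplication ->
# identity classification -> NJ tree. Every stage seed derives from the one
# global seed, so a run is fully reproducible.

#' Configure an end-to-end pipeline run
#'
#' Bundles the parameters of every stage; defaults match the survey design
#' the package emulates (95-well AWCD divisor, 0.25 richness threshold, AluI
#' RFLP, novelty thresholds 70/75, 20-clone libraries).
#'
#' @param seed Global integer seed; all stage seeds derive from it.
#' @param n_taxa Taxa in the simulated protein family used for primer design.
#' @param n_community_taxa Taxa (references/templates) behind the clone
#'   library.
#' @param sub_rate Per-site substitution rate of the family.
#' @param n_clones Clones per library.
#' @param error_rate Per-base clone error rate.
#' @param n_samples Environmental samples for the CLPP stage.
#' @param substrate_classes Substrate classes to profile.
#' @param noise_sd Plate read noise sd.
#' @param window,min_mean_ic Primer-design block search parameters.
#' @param max_mismatch Mismatches tolerated per primer site in the PCR stage.
#' @param min_len,max_len Amplicon length bounds (nt).
#' @param bin_width RFLP gel bin width (bp).
#' @param low_threshold,novel_threshold Novelty thresholds (percent
#'   identity).
#' @param n_bootstrap Bootstrap replicates for the tree stage.
#' @param flank_length Background flank length around each template cds.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_taxa = 40, n_community_taxa = 8,
                            sub_rate = 0.2, n_clones = 20, error_rate = 0.01,
                            n_samples = 3, substrate_classes = c("C", "N", "P", "S"),
                            noise_sd = 0.05, window = 9, min_mean_ic = 3,
                            max_mismatch = 0, min_len = 100, max_len = 2000,
                            bin_width = 20, low_threshold = 70,
                            novel_threshold = 75, n_bootstrap = 100,
                            flank_length = 150) {
  stopifnot(low_threshold < novel_threshold, min_len <= max_len,
            n_community_taxa <= n_taxa)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic survey pipeline
#'
#' Simulates a GH1-like family and phenotype plates, profiles the plates
#' (AWCD, richness, Shannon, per-substrate significance, substrate
#' clustering), designs degenerate primers from the family alignment,
#' amplifies templates in silico, simulates and dereplicates a clone library
#' by AluI RFLP, classifies every clone against the reference panel
#' (identity, catalytic glutamates, novelty), tabulates the genus/division
#' community and builds a bootstrapped NJ tree of the dereplicated clone
#' proteins. Identical seeds give identical results.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory: per-stage TSV/newick outputs are
#'   written there.
#' @return Object of class `gh1_pipeline` (a list of per-stage results).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config

  # --- stage 1: family simulation -----------------------------------------
  fspec <- family_spec(n_taxa = cfg$n_taxa, sub_rate = cfg$sub_rate,
                       seed = split_seed(cfg$seed, 11L))
  family <- simulate_protein_family(fspec)

  # --- stage 2: CLPP -------------------------------------------------------
  samples <- sprintf("S%d", seq_len(cfg$n_samples))
  readings <- do.call(rbind, lapply(seq_along(samples), function(i) {
    do.call(rbind, lapply(seq_along(cfg$substrate_classes), function(j) {
      spec <- plate_spec(cfg$substrate_classes[j], noise_sd = cfg$noise_sd,
                         seed = split_seed(cfg$seed, 20L + 10L * i + j))
      simulate_plate(spec, samples[i])
    }))
  }))
  clpp <- clpp_summary(readings)
  sig <- NULL
  cluster <- NULL
  if (cfg$n_samples >= 2) {
    cls <- cfg$substrate_classes[1]
    r1 <- readings[readings$sample_id == samples[1] &
                     readings$substrate_class == cls, ]
    r2 <- readings[readings$sample_id == samples[2] &
                     readings$substrate_class == cls, ]
    m <- cbind(corrected_by_replicate(r1), corrected_by_replicate(r2))
    grp <- rep(samples[1:2], each = ncol(m) / 2)
    sig <- substrate_significance(m, grp)
    prof <- vapply(samples, function(s)
      corrected_profile(readings[readings$sample_id == s &
                                   readings$substrate_class == cls, ]),
      numeric(nrow(m)))
    cluster <- cluster_substrates(prof)
  }

  # --- stage 3: primer design ---------------------------------------------
  design <- design_primers(family$proteins, window = cfg$window,
                           min_mean_ic = cfg$min_mean_ic)
  pair <- design$pairs[[1]]

  # --- stage 4: in-silico PCR on labelled templates ------------------------
  idx <- seq_len(cfg$n_community_taxa)
  templates <- lapply(idx, function(i) {
    cds <- reverse_translate(family$proteins[[i]],
                             seed = split_seed(cfg$seed, 40L + i))
    emb <- embed_in_background(cds, flank_length = cfg$flank_length,
                               seed = split_seed(cfg$seed, 60L + i))
    amp <- predict_amplicons(emb$template, pair,
                             max_mismatch = cfg$max_mismatch,
                             min_len = cfg$min_len, max_len = cfg$max_len)
    if (nrow(amp) == 0) stopf("PCR stage: no amplicon on template %d", i)
    list(taxon = family$labels$taxon[i], genus = family$labels$genus[i],
         division = family$labels$division[i], template = emb$template,
         amp_start = amp$start[1], amp_end = amp$end[1])
  })

  # --- stage 5: clone library + RFLP dereplication -------------------------
  library_sim <- simulate_clone_library(templates, n_clones = cfg$n_clones,
                                        error_rate = cfg$error_rate,
                                        seed = split_seed(cfg$seed, 80L))
  derep <- dereplicate_clones(library_sim$clones, bin_width = cfg$bin_width)

  # --- stage 6: classification --------------------------------------------
  panel <- reference_panel(id = family$labels$taxon[idx],
                           protein = unname(family$proteins[idx]),
                           name = paste(family$labels$genus[idx], "sp."),
                           genus = family$labels$genus[idx],
                           division = family$labels$division[idx])
  hits <- lapply(library_sim$clones, best_hit, panel = panel)
  hit_df <- data.frame(
    clone_id = names(library_sim$clones),
    reference_id = vapply(hits, `[[`, "", "reference_id"),
    genus = vapply(hits, `[[`, "", "genus"),
    division = vapply(hits, `[[`, "", "division"),
    identity = vapply(hits, function(h) as.numeric(h$identity), 0),
    frame = vapply(hits, `[[`, "", "frame"),
    stringsAsFactors = FALSE, row.names = NULL)
  cat_ok <- vapply(seq_along(hits), function(i) {
    h <- hits[[i]]
    ref <- panel$protein[panel$id == h$reference_id]
    prot <- six_frame_translate(library_sim$clones[[i]])[[h$frame]]
    isTRUE(catalytic_check(prot, ref, fspec$catalytic_cols))
  }, TRUE)
  hit_df$catalytic_ok <- cat_ok
  nov <- classify_novelty(hit_df$identity, cfg$low_threshold,
                          cfg$novel_threshold)
  hit_df$low_identity <- nov$low_identity
  hit_df$novel <- nov$novel
  community <- community_table(hit_df)

  # --- stage 7: NJ tree of dereplicated clone proteins ---------------------
  tree <- NULL
  reps <- derep$representatives
  if (length(reps) >= 4) {
    prots <- vapply(names(reps), function(id) {
      h <- hits[[id]]
      six_frame_translate(reps[[id]])[[h$frame]]
    }, "")
    tree <- bootstrap_support(prots, n_replicates = cfg$n_bootstrap,
                              seed = split_seed(cfg$seed, 90L))
  }

  result <- structure(list(
    config = cfg, family = family, readings = readings, clpp = clpp,
    significance = sig, substrate_clusters = cluster, design = design,
    primer_pair = pair, templates = templates, clones = library_sim$clones,
    truth = library_sim$truth, dereplication = derep, hits = hit_df,
    novelty_fractions = c(
      low_identity = 100 * mean(hit_df$low_identity),
      novel = 100 * mean(hit_df$novel)),
    community = community, tree = tree), class = "gh1_pipeline")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.table(clpp, file.path(outdir, "clpp_summary.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(hit_df, file.path(outdir, "clone_hits.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(derep$groups, file.path(outdir, "rflp_groups.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write_fasta(library_sim$clones, file.path(outdir, "clones.fasta"), "dna")
    if (!is.null(tree))
      write_newick(tree$tree, file.path(outdir, "clone_tree.nwk"))
  }
  result
}

#' @export
print.gh1_pipeline <- function(x, ...) {
  cat("GH1 beta-glucosidase survey pipeline (synthetic run)\n")
  cat(sprintf("  seed %d | %d taxa | %d clones at error rate %.3g\n",
              x$config$seed, x$config$n_taxa, x$config$n_clones,
              x$config$error_rate))
  cat(sprintf("  primer pair: %s / %s (expected amplicon %d nt)\n",
              x$primer_pair$forward$sequence, x$primer_pair$reverse$sequence,
              x$primer_pair$expected_amplicon))
  cat(sprintf("  RFLP groups: %d | low-identity %.1f%% | novel %.1f%%\n",
              length(x$dereplication$representatives),
              x$novelty_fractions[["low_identity"]],
              x$novelty_fractions[["novel"]]))
  cat(sprintf("  community: %d genera in %d divisions\n",
              x$community$n_genera, x$community$n_divisions))
  invisible(x)
}
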