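# Synthetic GH1-like data with known ground truth.
#
# Every downstream stage (primer design, in-silico PCR, RFLP, classification,
# phylogenetics, CLPP) is testable without environmental samples: the
# generator emulates (i) a protein family sharing two conserved 9-residue
# anchor blocks flanking the catalytic glutamates, (ii) clone libraries drawn
# from genus-labelled references with point errors, and (iii) BIOLOG-style
# phenotype plates with sample-specific substrate activities plus noise.

# Built-in genus/division panel used to label synthetic taxa. Divisions follow
# the vocabulary used for GH1 surveys; the three Proteobacteria classes are
# distinct divisions.
gh1_taxon_panel <- function() {
  data.frame(
    genus = c("Flavobacterium", "Pedobacter", "Sphingobacterium", "Cytophaga",
              "Cellulophaga", "Clostridium", "Paenibacillus", "Bacillus",
              "Streptomyces", "Actinospica", "Vibrio", "Alteromonas",
              "Burkholderia", "Azospirillum", "Devosia", "Sinorhizobium",
              "Meiothermus", "Verrucomicrobiae", "Exiguobacterium",
              "Hymenobacter"),
    division = c("Bacteroidetes", "Bacteroidetes", "Bacteroidetes",
                 "Bacteroidetes", "Bacteroidetes", "Firmicutes", "Firmicutes",
                 "Firmicutes", "Actinobacteria", "Actinobacteria",
                 "gamma-Proteobacteria", "gamma-Proteobacteria",
                 "beta-Proteobacteria", "alpha-Proteobacteria",
                 "alpha-Proteobacteria", "alpha-Proteobacteria",
                 "Deinococcus", "Chlamydiae", "Firmicutes", "Bacteroidetes"),
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic GH1-like protein family
#'
#' Describes the ancestor geometry: two conserved anchor peptides (defaults
#' `TLYHWDLPQ` at column 40 and `DNFEWAEGY` at column 331, 291 residues
#' between block starts, so the predicted amplicon is 900 nt, close to the
#' ~876 bp fragment family-wide GH1 primers amplify) and two catalytic
#' glutamate columns exactly 200 residues apart (defaults 120 and 320), both
#' inside the amplified region and clear of the anchor blocks. Outside the conserved positions, each taxon
#' substitutes residues i.i.d. at `sub_rate`.
#'
#' @param ancestor_length Ancestor length in residues.
#' @param blocks List of `list(peptide, start)` conserved blocks (1-based
#'   start columns).
#' @param catalytic_cols Two column indices carrying the catalytic glutamates.
#' @param n_taxa Number of taxa to simulate.
#' @param taxon_labels Optional data.frame with columns `taxon`, `genus`,
#'   `division`; defaults to a built-in panel recycled over taxa.
#' @param sub_rate Per-site substitution probability outside conserved
#'   positions, in `[0, 1]`.
#' @param seed Integer seed driving all randomness of the family.
#' @return Object of class `family_spec`.
#' @export
family_spec <- function(ancestor_length = 450,
                        blocks = list(list(peptide = "TLYHWDLPQ", start = 40L),
                                      list(peptide = "DNFEWAEGY", start = 331L)),
                        catalytic_cols = c(120L, 320L),
                        n_taxa = 247,
                        taxon_labels = NULL,
                        sub_rate = 0.2,
                        seed = 1L) {
  if (sub_rate < 0 || sub_rate > 1) stopf("sub_rate must be in [0, 1]")
  conserved <- integer(0)
  for (b in blocks) {
    res <- seq_to_chars(b$peptide)
    if (!all(res %in% AA_ALPHABET20))
      stopf("block peptide %s is not over the 20-residue alphabet", b$peptide)
    idx <- b$start:(b$start + length(res) - 1L)
    if (max(idx) > ancestor_length) stopf("block extends past the ancestor")
    if (any(idx %in% conserved)) stopf("conserved blocks overlap")
    conserved <- c(conserved, idx)
  }
  if (any(catalytic_cols %in% conserved) ||
      anyDuplicated(catalytic_cols) > 0)
    stopf("catalytic columns overlap a block or each other")
  if (any(catalytic_cols > ancestor_length)) stopf("catalytic column out of range")
  if (is.null(taxon_labels)) {
    panel <- gh1_taxon_panel()
    k <- ((seq_len(n_taxa) - 1L) %% nrow(panel)) + 1L
    taxon_labels <- data.frame(taxon = sprintf("T%03d", seq_len(n_taxa)),
                               genus = panel$genus[k],
                               division = panel$division[k],
                               stringsAsFactors = FALSE)
  }
  stopifnot(nrow(taxon_labels) == n_taxa)
  structure(list(ancestor_length = as.integer(ancestor_length), blocks = blocks,
                 catalytic_cols = as.integer(catalytic_cols),
                 n_taxa = as.integer(n_taxa), taxon_labels = taxon_labels,
                 sub_rate = sub_rate, seed = as.integer(seed)),
            class = "family_spec")
}

conserved_positions <- function(spec) {
  idx <- unlist(lapply(spec$blocks, function(b)
    b$start:(b$start + nchar(b$peptide) - 1L)))
  sort(c(idx, spec$catalytic_cols))
}

#' Simulate a GH1-like protein family
#'
#' Draws a random ancestor, writes the conserved anchor peptides at their
#' columns and glutamate at both catalytic columns, then derives each taxon by
#' substituting non-conserved sites i.i.d. at `sub_rate`, uniformly over the
#' 19 alternative residues. Identical seeds give byte-identical families.
#'
#' @param spec A [family_spec()].
#' @return Object of class `gh1_family`: list with `proteins` (named character
#'   vector), `labels` (taxon/genus/division data.frame), `ancestor`, `spec`.
#' @export
simulate_protein_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  with_seed(split_seed(spec$seed, 1L), {
    anc <- sample(AA_ALPHABET20, spec$ancestor_length, replace = TRUE)
    for (b in spec$blocks) {
      res <- seq_to_chars(b$peptide)
      anc[b$start:(b$start + length(res) - 1L)] <- res
    }
    anc[spec$catalytic_cols] <- "E"
    cons <- conserved_positions(spec)
    free <- setdiff(seq_len(spec$ancestor_length), cons)
    proteins <- vapply(seq_len(spec$n_taxa), function(i) {
      s <- anc
      if (spec$sub_rate > 0 && length(free) > 0) {
        hit <- free[runif(length(free)) < spec$sub_rate]
        if (length(hit) > 0)
          s[hit] <- vapply(s[hit], function(a)
            sample(setdiff(AA_ALPHABET20, a), 1L), "")
      }
      chars_to_seq(s)
    }, "")
    names(proteins) <- spec$taxon_labels$taxon
    structure(list(proteins = proteins, labels = spec$taxon_labels,
                   ancestor = chars_to_seq(anc), spec = spec),
              class = "gh1_family")
  })
}

#' @export
print.gh1_family <- function(x, ...) {
  cat(sprintf("Synthetic GH1-like family: %d taxa x %d residues, sub_rate %.2f\n",
              length(x$proteins), nchar(x$ancestor), x$spec$sub_rate))
  cat(sprintf("  anchor blocks: %s\n",
              paste(vapply(x$spec$blocks, function(b)
                sprintf("%s@%d", b$peptide, b$start), ""), collapse = ", ")))
  invisible(x)
}

#' Reverse-translate a protein into a concrete coding sequence
#'
#' Picks one codon per residue, uniformly at random from the standard genetic
#' code (or a user table). Translating the output with the standard code
#' recovers the input exactly.
#'
#' @param protein Protein string over the 20-residue alphabet.
#' @param codon_table Optional named list: residue -> character vector of
#'   allowed codons. Defaults to all standard codons.
#' @param seed Optional integer seed.
#' @return Nucleotide string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein, codon_table = NULL, seed = NULL) {
  res <- seq_to_chars(toupper(protein))
  bad <- setdiff(res, AA_ALPHABET20)
  if (length(bad) > 0)
    stopf("unknown residue(s): %s", paste(bad, collapse = ", "))
  tab <- codon_table %||% codons_by_residue()
  with_seed(seed, {
    paste(vapply(res, function(a) {
      codons <- tab[[a]]
      if (is.null(codons)) stopf("codon table lacks residue %s", a)
      codons[sample.int(length(codons), 1L)]
    }, ""), collapse = "")
  })
}

#' Embed a coding sequence in random flanking background
#'
#' Builds `flank + cds + flank` with i.i.d. random flank bases at the given GC
#' fraction, and reports 1-based inclusive coordinates such that
#' `substr(template, start, end)` is exactly the cds.
#'
#' @param cds Coding nucleotide string.
#' @param flank_length Flank length (>= 0) on each side.
#' @param gc_fraction GC fraction of the flanks.
#' @param seed Optional integer seed.
#' @return List with `template`, `start`, `end`.
#' @export
embed_in_background <- function(cds, flank_length = 100, gc_fraction = 0.5,
                                seed = NULL) {
  stopifnot(flank_length >= 0, gc_fraction >= 0, gc_fraction <= 1)
  with_seed(seed, {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    flank <- function(n) if (n == 0) "" else
      paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
    left <- flank(flank_length); right <- flank(flank_length)
    list(template = paste0(left, cds, right),
         start = as.integer(flank_length + 1),
         end = as.integer(flank_length + nchar(cds)))
  })
}

plate_wells <- function() {
  as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))  # A1..A12, B1..H12
}

#' Specification of synthetic BIOLOG-style phenotype plates
#'
#' One spec per substrate class, at the class sizes of the PM plate system:
#' carbon 190, nitrogen 95, phosphorus 59, sulfur 35 substrates. Substrates
#' are laid out on 96-well plates with well A1 as the blank and up to 95
#' substrate wells per plate.
#'
#' @param substrate_class One of `"C"`, `"N"`, `"P"`, `"S"`.
#' @param n_substrates Number of substrates; defaults to the class size.
#' @param activity Per-substrate mean corrected OD (length `n_substrates`);
#'   if `NULL`, drawn once uniformly on `[0, 1]` under `seed`.
#' @param blank Blank-well signal level (OD).
#' @param noise_sd Gaussian read noise sd; readings are truncated at 0.
#' @param replicates Number of replicate plates (default 3).
#' @param seed Integer seed.
#' @return Object of class `plate_spec`.
#' @export
plate_spec <- function(substrate_class = c("C", "N", "P", "S"),
                       n_substrates = NULL, activity = NULL, blank = 0.05,
                       noise_sd = 0.05, replicates = 3, seed = 1L) {
  substrate_class <- match.arg(substrate_class)
  class_sizes <- c(C = 190L, N = 95L, P = 59L, S = 35L)
  n_substrates <- as.integer(n_substrates %||% class_sizes[[substrate_class]])
  if (n_substrates < 1) stopf("n_substrates must be positive")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (is.null(activity))
    activity <- with_seed(split_seed(seed, 5L), runif(n_substrates))
  stopifnot(length(activity) == n_substrates, all(activity >= 0))
  structure(list(substrate_class = substrate_class, n_substrates = n_substrates,
                 activity = activity, blank = blank, noise_sd = noise_sd,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "plate_spec")
}

#' Simulate replicate phenotype-plate readings
#'
#' Each replicate reads every well as `blank + activity + N(0, noise_sd)`,
#' truncated at 0 (plate readers report non-negative absorbance); the blank
#' well A1 carries the blank signal only, and wells beyond the substrate count
#' on the last plate carry blank signal. Identical seeds give identical
#' readings.
#'
#' @param spec A [plate_spec()].
#' @param sample_id Sample label.
#' @return Long-format data.frame: `sample_id`, `substrate_class`, `plate_id`,
#'   `replicate`, `well`, `substrate` (1-based index, `NA` for blank/unused
#'   wells), `od`.
#' @export
simulate_plate <- function(spec, sample_id) {
  stopifnot(inherits(spec, "plate_spec"))
  wells <- plate_wells()
  sub_wells <- setdiff(wells, "A1")  # 95 substrate wells per plate
  n_plates <- ceiling(spec$n_substrates / 95)
  with_seed(split_seed(spec$seed, 6L), {
    out <- list()
    for (p in seq_len(n_plates)) {
      first <- (p - 1L) * 95L + 1L
      idx <- first:min(first + 94L, spec$n_substrates)
      substrate <- rep(NA_integer_, 96L)
      substrate[match(sub_wells[seq_along(idx)], wells)] <- idx
      act <- rep(0, 96L)
      act[!is.na(substrate)] <- spec$activity[substrate[!is.na(substrate)]]
      for (r in seq_len(spec$replicates)) {
        noise <- if (spec$noise_sd > 0) rnorm(96L, 0, spec$noise_sd) else 0
        od <- pmax(spec$blank + act + noise, 0)
        out[[length(out) + 1L]] <- data.frame(
          sample_id = sample_id, substrate_class = spec$substrate_class,
          plate_id = sprintf("PM%s%d", spec$substrate_class, p),
          replicate = r, well = wells, substrate = substrate, od = od,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

#' Simulate a clone library from labelled templates
#'
#' Draws `n_clones` clones, each the amplicon region of one template with
#' i.i.d. point errors at `error_rate` (uniform over the three alternative
#' bases), and records the ground truth: source taxon, genus, division and
#' the true RFLP group of the source amplicon (AluI digest pattern identity).
#'
#' @param templates List of template records, each a list with `taxon`,
#'   `genus`, `division`, `template` (nt string), `amp_start`, `amp_end`
#'   (1-based inclusive amplicon coordinates).
#' @param n_clones Number of clones (default 20, one library's worth).
#' @param error_rate Per-base point error probability.
#' @param seed Integer seed.
#' @return List with `clones` (named character vector) and `truth`
#'   (data.frame: `clone_id`, `taxon`, `genus`, `division`, `rflp_group`).
#' @export
simulate_clone_library <- function(templates, n_clones = 20, error_rate = 0.01,
                                   seed = 1L) {
  if (length(templates) == 0) stopf("need at least one template")
  amplicons <- vapply(templates, function(t)
    substr(t$template, t$amp_start, t$amp_end), "")
  true_groups <- pattern_group(lapply(amplicons, digest_sequence))
  bases <- c("A", "C", "G", "T")
  with_seed(split_seed(seed, 7L), {
    src <- sample.int(length(templates), n_clones, replace = TRUE)
    clones <- vapply(seq_len(n_clones), function(i) {
      s <- seq_to_chars(amplicons[[src[i]]])
      if (error_rate > 0) {
        hit <- which(runif(length(s)) < error_rate)
        if (length(hit) > 0)
          s[hit] <- vapply(s[hit], function(b) sample(setdiff(bases, b), 1L), "")
      }
      chars_to_seq(s)
    }, "")
    ids <- sprintf("clone%03d", seq_len(n_clones))
    names(clones) <- ids
    truth <- data.frame(
      clone_id = ids,
      taxon = vapply(templates[src], `[[`, "", "taxon"),
      genus = vapply(templates[src], `[[`, "", "genus"),
      division = vapply(templates[src], `[[`, "", "division"),
      rflp_group = true_groups[src],
      stringsAsFactors = FALSE)
    list(clones = clones, truth = truth)
  })
}
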