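# Conserved-motif detection and CODEHOP-style degenerate primer design.
#
# The design route mirrors how family-wide PCR primers for glycoside
# hydrolases are built in practice: profile an alignment of family proteins,
# find short blocks where nearly every sequence agrees, take the
# maximum-probability consensus peptide of each block, back-translate it into
# a degenerate oligonucleotide (codon union per residue, minimal IUPAC code
# per position) and replace fully degenerate positions with inosine to keep
# the enumerated degeneracy low.

# codons (character vectors) per amino acid, from the standard genetic code
codons_by_residue <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) gc <<- split(names(Biostrings::GENETIC_CODE),
                                  unname(Biostrings::GENETIC_CODE))
    gc
  }
})

#' Per-column residue frequencies and information content of an alignment
#'
#' Computes, for every column of a protein multiple sequence alignment,
#' gap-excluded residue frequencies and the information content
#' `IC = log2(20) + sum(f * log2(f))` in bits (no small-sample correction).
#' A perfectly conserved column scores `log2(20) ~ 4.32` bits; a column
#' uniform over all 20 residues scores 0.
#'
#' @param alignment Character vector of aligned protein sequences (equal
#'   lengths; residues and `-` gaps).
#' @return An object of class `column_profiles`: a list with `n_col`,
#'   `freq` (list of named frequency vectors) and `ic` (numeric vector).
#' @export
column_profiles <- function(alignment) {
  stopifnot(is.character(alignment), length(alignment) >= 1)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L)
    stopf("ragged alignment: row lengths %s", paste(unique(lens), collapse = ", "))
  mat <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  bad <- setdiff(unique(as.vector(mat)), c(AA_ALPHABET20, "-", "."))
  if (length(bad) > 0)
    stopf("alignment contains non-residue symbols: %s", paste(bad, collapse = ", "))
  freq <- vector("list", ncol(mat))
  ic <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[col %in% AA_ALPHABET20]
    if (length(col) == 0) {
      freq[[j]] <- setNames(numeric(0), character(0))
      ic[j] <- 0
      next
    }
    f <- table(col) / length(col)
    f <- setNames(as.numeric(f), names(f))
    f <- f[order(names(f))]
    freq[[j]] <- f
    ic[j] <- log2(20) + sum(f * log2(f))
  }
  structure(list(n_col = ncol(mat), freq = freq, ic = ic),
            class = "column_profiles")
}

#' Find conserved blocks in a profiled alignment
#'
#' Slides a fixed-length window over the column profiles and keeps windows in
#' which every position has at most `max_variants_per_pos` residues above the
#' frequency floor and whose mean information content reaches `min_mean_ic`.
#' Overlapping candidate windows are resolved greedily, best first, so each
#' conserved region is reported once. Blocks are ranked by mean information
#' content (ties: longer, then left-most).
#'
#' @param profiles A `column_profiles` object.
#' @param window Window length in residues (>= 4). Default 9, the length of
#'   the canonical GH1 anchor peptides.
#' @param min_mean_ic Minimum mean per-column information content (bits).
#' @param max_variants_per_pos Maximum residues above `freq_floor` allowed at
#'   any position of the window.
#' @param freq_floor Frequency below which a residue is ignored when counting
#'   variants.
#' @return List of `conserved_block` objects, ranked; each has `start`
#'   (1-based column), `length`, `residue_sets`, `consensus` (most frequent
#'   residue per position, ties broken alphabetically) and `score` (mean IC).
#' @export
find_conserved_blocks <- function(profiles, window = 9, min_mean_ic = 3,
                                  max_variants_per_pos = 3, freq_floor = 0.1) {
  stopifnot(inherits(profiles, "column_profiles"))
  if (window < 4) stopf("window must be >= 4")
  if (window > profiles$n_col)
    stopf("window (%d) exceeds alignment length (%d)", window, profiles$n_col)
  n_var <- vapply(profiles$freq, function(f) sum(f > freq_floor), 0L)
  starts <- seq_len(profiles$n_col - window + 1L)
  cand <- list()
  for (s in starts) {
    idx <- s:(s + window - 1L)
    if (any(n_var[idx] > max_variants_per_pos) || any(n_var[idx] == 0L)) next
    score <- mean(profiles$ic[idx])
    if (score < min_mean_ic) next
    consensus <- vapply(profiles$freq[idx], function(f) {
      names(f)[which.max(f)]  # names pre-sorted: ties fall alphabetically
    }, "")
    sets <- lapply(profiles$freq[idx], function(f) sort(names(f)[f > freq_floor]))
    cand[[length(cand) + 1L]] <- structure(
      list(start = as.integer(s), length = as.integer(window),
           residue_sets = sets,
           consensus = chars_to_seq(consensus), score = score),
      class = "conserved_block")
  }
  if (length(cand) == 0) return(list())
  ord <- order(-vapply(cand, function(b) b$score, 0),
               -vapply(cand, function(b) as.numeric(b$length), 0),
               vapply(cand, function(b) as.numeric(b$start), 0))
  cand <- cand[ord]
  kept <- list()
  occupied <- logical(profiles$n_col)
  for (b in cand) {
    idx <- b$start:(b$start + b$length - 1L)
    if (any(occupied[idx])) next
    occupied[idx] <- TRUE
    kept[[length(kept) + 1L]] <- b
  }
  kept
}

#' @export
print.conserved_block <- function(x, ...) {
  cat(sprintf("Conserved block at column %d (%d aa): %s  [mean IC %.2f bits]\n",
              x$start, x$length, x$consensus, x$score))
  invisible(x)
}

#' Back-translate a peptide into a degenerate primer with inosine
#'
#' For every residue, takes the position-wise union of all its standard
#' codons and writes each position's base set as the minimal IUPAC code.
#' Positions whose set is all four bases are written as inosine (`I`), the
#' universal-pairing nucleoside, which lowers the enumerated degeneracy.
#' Two- and three-base sets stay as IUPAC codes. The result is
#' `3 * nchar(peptide)` nt long (before any optional 5' clamp).
#'
#' @param peptide Peptide string over the 20-residue alphabet.
#' @param clamp5 Optional concrete 5' clamp prepended verbatim (default none).
#' @return Degenerate primer string.
#' @examples
#' back_translate_degenerate("TLYHWDLPQ")
#' # "ACIYTITAYCAYTGGGAYYTICCICAR"
#' @export
back_translate_degenerate <- function(peptide, clamp5 = "") {
  stopifnot(is.character(peptide), length(peptide) == 1L, nchar(peptide) >= 1)
  res <- seq_to_chars(toupper(peptide))
  bad <- setdiff(res, AA_ALPHABET20)
  if (length(bad) > 0)
    stopf("unknown residue(s): %s", paste(bad, collapse = ", "))
  tab <- codons_by_residue()
  out <- vapply(res, function(a) {
    codons <- strsplit(tab[[a]], "", fixed = TRUE)
    chars_to_seq(vapply(1:3, function(p) {
      set <- sort(unique(vapply(codons, `[[`, "", p)))
      if (length(set) == 4L) "I" else SET_TO_IUPAC[[paste(set, collapse = "")]]
    }, ""))
  }, "")
  paste0(clamp5, paste(out, collapse = ""))
}

#' Construct a degenerate primer record
#'
#' Bundles a primer sequence with its name, direction and the three design
#' statistics (degeneracy, expected GC, Tm).
#'
#' @param name Primer name.
#' @param sequence Primer string over the degenerate alphabet (5' to 3').
#' @param direction `"forward"` or `"reverse"`.
#' @return Object of class `degenerate_primer`.
#' @export
degenerate_primer <- function(name, sequence, direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  check_primer_alphabet(sequence)
  structure(list(name = name, sequence = sequence, direction = direction,
                 length = nchar(sequence),
                 degeneracy = primer_degeneracy(sequence),
                 gc = gc_content(sequence),
                 tm = melting_temp(sequence)),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("%s (%d, %s): 5' %s 3'  deg=%d  GC=%.1f%%  Tm=%.1fC\n",
              x$name, x$length, x$direction, x$sequence,
              x$degeneracy, x$gc, x$tm))
  invisible(x)
}

#' Rank primer pairs from conserved blocks
#'
#' Builds, for every upstream/downstream block combination, a forward primer
#' (back-translated upstream consensus) and a reverse primer (degenerate
#' reverse complement of the back-translated downstream consensus), and ranks
#' the pairs by total degeneracy (ascending), then melting-temperature
#' difference, then GC difference, then block positions. The expected
#' amplicon spans the forward-block start to the reverse-block end:
#' `3 * (start_r - start_f) + 3 * length_r` nt.
#'
#' @param blocks List of `conserved_block` objects (at least two at distinct
#'   positions).
#' @param name_prefix Prefix for auto-generated primer names.
#' @return List of `primer_pair` objects, best first. Each holds `forward`,
#'   `reverse` (class `degenerate_primer`) and `expected_amplicon` (nt).
#' @export
rank_primer_pairs <- function(blocks, name_prefix = "BGL") {
  if (length(blocks) < 2)
    stopf("need at least one upstream and one downstream block")
  pairs <- list()
  for (i in seq_along(blocks)) for (j in seq_along(blocks)) {
    bf <- blocks[[i]]; br <- blocks[[j]]
    if (bf$start >= br$start) next
    fwd <- degenerate_primer(paste0(name_prefix, "F", length(pairs) + 1L),
                             back_translate_degenerate(bf$consensus), "forward")
    rev <- degenerate_primer(
      paste0(name_prefix, "R", length(pairs) + 1L),
      reverse_complement_degenerate(back_translate_degenerate(br$consensus)),
      "reverse")
    pairs[[length(pairs) + 1L]] <- structure(
      list(forward = fwd, reverse = rev,
           forward_block = bf, reverse_block = br,
           expected_amplicon = as.integer(3 * (br$start - bf$start) +
                                            3 * br$length)),
      class = "primer_pair")
  }
  if (length(pairs) == 0) stopf("no upstream/downstream block combination found")
  key <- vapply(pairs, function(p) {
    c(p$forward$degeneracy * p$reverse$degeneracy,
      abs(p$forward$tm - p$reverse$tm),
      abs(p$forward$gc - p$reverse$gc),
      p$forward_block$start, p$reverse_block$start)
  }, numeric(5))
  ord <- do.call(order, as.data.frame(t(key)))
  pairs[ord]
}

#' @export
print.primer_pair <- function(x, ...) {
  print(x$forward); print(x$reverse)
  cat(sprintf("expected amplicon: %d nt (blocks at columns %d and %d)\n",
              x$expected_amplicon, x$forward_block$start, x$reverse_block$start))
  invisible(x)
}

#' Design degenerate primers from a protein alignment
#'
#' Convenience wrapper: profiles the alignment, finds conserved blocks,
#' restricts to the most conserved ones and ranks the resulting primer
#' pairs. Blocks are selected by conservation first and primer pairs by
#' degeneracy/Tm/GC second, mirroring how family-wide degenerate primers are
#' designed in practice: anchor peptides must be conserved before a
#' low-degeneracy back-translation is of any use.
#'
#' @inheritParams find_conserved_blocks
#' @param alignment Character vector of aligned protein sequences.
#' @param n_top_blocks Number of top-ranked blocks admitted to pairing
#'   (default 2: the two most conserved anchors).
#' @param name_prefix Prefix for primer names.
#' @return List with `profiles`, `blocks` (all found, ranked) and `pairs`
#'   (ranked, built from the top blocks).
#' @export
design_primers <- function(alignment, window = 9, min_mean_ic = 3,
                           max_variants_per_pos = 3, freq_floor = 0.1,
                           n_top_blocks = 2, name_prefix = "BGL") {
  profiles <- column_profiles(alignment)
  blocks <- find_conserved_blocks(profiles, window = window,
                                  min_mean_ic = min_mean_ic,
                                  max_variants_per_pos = max_variants_per_pos,
                                  freq_floor = freq_floor)
  top <- blocks[seq_len(min(n_top_blocks, length(blocks)))]
  list(profiles = profiles, blocks = blocks,
       pairs = rank_primer_pairs(top, name_prefix = name_prefix))
}
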