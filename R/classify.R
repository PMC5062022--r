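# Clone translation, identity search against a reference panel,
# catalytic-residue verification, novelty classification and community
# tabulation.
#
# Identity search is a self-contained local alignment (BLOSUM62, affine
# gaps) of all six clone reading frames against a user- or
# synthetically-supplied protein panel, so no remote database is needed;
# published identity tables can also be consumed directly via
# read_identity_table() to tabulate novelty and community structure.

#' Translate a nucleotide sequence in all six frames
#'
#' Frames +1, +2, +3 on the given strand and -1, -2, -3 on the reverse
#' complement, under the standard genetic code; trailing partial codons are
#' dropped and any codon containing an ambiguous base translates to `X`.
#'
#' @param sequence Nucleotide string (length >= 3) over A, C, G, T, N.
#' @return Named character vector of the six protein frames
#'   (`+1`, `+2`, `+3`, `-1`, `-2`, `-3`).
#' @export
six_frame_translate <- function(sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 3) stopf("sequence shorter than one codon")
  strands <- c(`+` = sequence,
               `-` = as.character(
                 Biostrings::reverseComplement(Biostrings::DNAString(sequence))))
  out <- character(0)
  for (st in names(strands)) {
    s <- strands[[st]]
    for (f in 1:3) {
      n_codon <- (nchar(s) - f + 1L) %/% 3L
      prot <- if (n_codon < 1) "" else as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, f, f + 3L * n_codon - 1L)),
        if.fuzzy.codon = "X"))
      out[[paste0(st, f)]] <- prot
    }
  }
  out
}

#' Assemble a reference panel
#'
#' @param id Reference ids.
#' @param protein Protein sequences.
#' @param name Nearest-neighbour organism names (default the ids).
#' @param genus,division Taxonomic labels.
#' @return data.frame of class `reference_panel`.
#' @export
reference_panel <- function(id, protein, name = id, genus, division) {
  stopifnot(length(id) == length(protein), all(nchar(genus) > 0))
  out <- data.frame(id = id, protein = toupper(protein), name = name,
                    genus = genus, division = division,
                    stringsAsFactors = FALSE)
  class(out) <- c("reference_panel", "data.frame")
  out
}

#' Best local-alignment hit of a clone against a reference panel
#'
#' Aligns all six translation frames of the clone against every panel protein
#' with a local (Smith-Waterman) alignment under BLOSUM62 and affine gap
#' penalties, and returns the highest-scoring combination. Percent identity
#' is identical aligned residue pairs over aligned columns excluding gaps,
#' rounded half-up to an integer. Ties are broken deterministically: panel
#' order (scan refs by ascending id first), then frame order.
#'
#' @param clone Clone nucleotide string.
#' @param panel A [reference_panel()].
#' @param gap_opening,gap_extension Affine gap penalties (Biostrings
#'   convention, positive costs). Defaults 10 and 4.
#' @return Object of class `identity_hit`: list with `reference_id`, `name`,
#'   `genus`, `division`, `identity` (integer percent), `alignment_length`,
#'   `frame`, `score`.
#' @export
best_hit <- function(clone, panel, gap_opening = 10, gap_extension = 4) {
  stopifnot(inherits(panel, "reference_panel"))
  if (nrow(panel) == 0) stopf("empty reference panel")
  panel <- panel[order(panel$id), , drop = FALSE]
  frames <- six_frame_translate(clone)
  frames <- frames[nchar(frames) > 0]
  best <- NULL
  for (i in seq_len(nrow(panel))) {
    subject <- Biostrings::AAString(panel$protein[i])
    for (f in names(frames)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(frames[[f]]), subject, type = "local",
        substitutionMatrix = "BLOSUM62",
        gapOpening = gap_opening, gapExtension = gap_extension)
      sc <- Biostrings::score(aln)
      if (is.null(best) || sc > best$score) {
        nm <- Biostrings::nmatch(aln); nmm <- Biostrings::nmismatch(aln)
        best <- structure(list(
          reference_id = panel$id[i], name = panel$name[i],
          genus = panel$genus[i], division = panel$division[i],
          identity = as.integer(round_half_up(100 * nm / (nm + nmm))),
          alignment_length = nm + nmm, frame = f, score = sc,
          alignment = aln), class = "identity_hit")
      }
    }
  }
  best
}

#' @export
print.identity_hit <- function(x, ...) {
  cat(sprintf("best hit: %s (%s, %s)  identity %d%% over %d aa  frame %s\n",
              x$reference_id, x$genus, x$division, x$identity,
              x$alignment_length, x$frame))
  invisible(x)
}

#' Verify the two catalytic glutamates of a GH1 hit
#'
#' GH1 beta-glucosidases carry an acid/base and a nucleophile glutamate about
#' 200 residues apart. Given a clone protein (best frame) and its reference
#' with known catalytic positions, the clone is locally aligned to the
#' reference, the catalytic columns are mapped onto the clone, and the check
#' passes iff both mapped residues are `E` and their separation on the clone
#' is within `separation +/- tolerance`. A fragment not spanning both columns
#' fails with attribute `partial = TRUE`.
#'
#' @param protein Clone protein (best frame).
#' @param reference Reference protein sequence.
#' @param ref_catalytic_pos Two 1-based positions of the glutamates on the
#'   reference.
#' @param separation Expected separation in residues, default 200.
#' @param tolerance Allowed deviation, default 40.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return Logical; attribute `partial` marks fragments that do not span both
#'   columns.
#' @export
catalytic_check <- function(protein, reference, ref_catalytic_pos,
                            separation = 200, tolerance = 40,
                            gap_opening = 10, gap_extension = 4) {
  stopifnot(length(ref_catalytic_pos) == 2)
  if (any(ref_catalytic_pos < 1) || any(ref_catalytic_pos > nchar(reference)))
    stopf("catalytic positions fall outside the reference")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein), Biostrings::AAString(reference),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  p_chars <- seq_to_chars(as.character(Biostrings::alignedPattern(aln)))
  s_chars <- seq_to_chars(as.character(Biostrings::alignedSubject(aln)))
  s_pos <- Biostrings::start(Biostrings::subject(aln)) - 1L
  p_pos <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  mapped <- rep(NA_integer_, 2)   # clone positions of the catalytic columns
  residue <- rep(NA_character_, 2)
  for (k in seq_along(p_chars)) {
    if (s_chars[k] != "-") s_pos <- s_pos + 1L
    if (p_chars[k] != "-") p_pos <- p_pos + 1L
    hit <- which(ref_catalytic_pos == s_pos & s_chars[k] != "-")
    for (h in hit) {
      if (p_chars[k] != "-") {
        mapped[h] <- p_pos
        residue[h] <- p_chars[k]
      }
    }
  }
  if (anyNA(mapped)) {
    return(structure(FALSE, partial = TRUE))
  }
  ok <- all(residue == "E") &&
    abs(abs(diff(mapped)) - separation) <= tolerance
  structure(ok, partial = FALSE)
}

#' Classify novelty from percent identity
#'
#' `low_identity` flags hits below 70% identity to any known sequence;
#' `novel` flags candidate novel OTUs at 75% or less. Low identity implies
#' novel.
#'
#' @param identity Numeric vector of percent identities in `[0, 100]`.
#' @param low_threshold Strict lower threshold, default 70.
#' @param novel_threshold Inclusive novelty threshold, default 75.
#' @return data.frame: `identity`, `low_identity`, `novel`.
#' @export
classify_novelty <- function(identity, low_threshold = 70,
                             novel_threshold = 75) {
  if (any(identity < 0 | identity > 100))
    stopf("identity must lie in [0, 100]")
  if (low_threshold >= novel_threshold)
    stopf("low-identity threshold must be below the novelty threshold")
  data.frame(identity = identity,
             low_identity = identity < low_threshold,
             novel = identity <= novel_threshold)
}

#' Extract the genus token from an organism name
#'
#' Strips square brackets, takes the first whitespace-separated token and
#' drops `sp.`-style qualifiers, so `"Flavobacterium sp."` gives
#' `"Flavobacterium"` and `"[Clostridium] termitidis"` gives `"Clostridium"`.
#'
#' @param name Character vector of organism names.
#' @return Character vector of genus tokens.
#' @export
extract_genus <- function(name) {
  if (any(!nzchar(trimws(name)))) stopf("empty organism name")
  vapply(strsplit(trimws(gsub("[][]", "", name)), "\\s+"), `[[`, "", 1L)
}

#' Tabulate the genus/division community structure of a clone library
#'
#' Counts clones per genus and per division and reports the distinct counts.
#' The three Proteobacteria classes (alpha, beta, gamma) are treated as
#' distinct divisions.
#'
#' @param hits data.frame with columns `genus` and `division` (one row per
#'   clone), e.g. from [read_identity_table()] or assembled from
#'   [best_hit()] results.
#' @return Object of class `community_table`: list with `genus_counts`,
#'   `division_counts`, `n_genera`, `n_divisions`, `n_clones`.
#' @export
community_table <- function(hits) {
  if (!all(c("genus", "division") %in% names(hits)))
    stopf("hits must have genus and division columns")
  if (any(is.na(hits$genus)) || any(is.na(hits$division)))
    stopf("unlabelled hit: genus/division missing")
  gc <- table(hits$genus)
  dc <- table(hits$division)
  structure(list(genus_counts = gc, division_counts = dc,
                 n_genera = length(gc), n_divisions = length(dc),
                 n_clones = nrow(hits)),
            class = "community_table")
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("%d clones in %d genera across %d divisions\n",
              x$n_clones, x$n_genera, x$n_divisions))
  print(x$division_counts)
  invisible(x)
}

#' Read a clone-identity table
#'
#' Reads a TSV with columns `library`, `clone_id`, `nearest_neighbor`,
#' `division`, `identity` (percent integers), the format of published clone
#' survey tables, and derives the `genus` column with [extract_genus()]. The
#' package ships an example three-habitat GH1 beta-glucosidase survey
#' (Himalayan cold-desert soil `KD`, cow dung `CD`, compost `CM`; 20 clones
#' each) at `system.file("extdata", "clone_identities.tsv", package =
#' "gh1profiler")`.
#'
#' @param path Path to the TSV file.
#' @return data.frame with the file's columns plus `genus`.
#' @export
read_identity_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("library", "clone_id", "nearest_neighbor", "division", "identity")
  if (!all(needed %in% names(tab)))
    stopf("identity table must have columns: %s", paste(needed, collapse = ", "))
  if (any(tab$identity < 0 | tab$identity > 100))
    stopf("identity values must lie in [0, 100]")
  tab$genus <- extract_genus(tab$nearest_neighbor)
  tab
}
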