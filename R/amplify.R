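# In-silico PCR with degenerate/inosine primers and restriction-digest
# (RFLP) simulation for clone dereplication.
#
# Coordinates are 1-based inclusive throughout, so
# substr(template, start, end) is exactly the predicted product. Amplicons
# include both primer footprints, as real PCR products do.

#' Find degenerate-primer binding sites on a template strand
#'
#' Scans every position of the plus strand and reports those where the primer
#' matches with at most `max_mismatch` positions failing [iupac_match()]. To
#' locate a reverse primer, pass its [reverse_complement_degenerate()] (as
#' [predict_amplicons()] does).
#'
#' @param template Template string over A, C, G, T, N.
#' @param primer Primer string over the degenerate alphabet (5' to 3', plus
#'   strand orientation).
#' @param max_mismatch Maximum tolerated mismatches, default 0.
#' @param permissive_n Should template `N` match any primer symbol?
#' @return data.frame with `start`, `end` (1-based inclusive) and
#'   `mismatches`; zero rows when the primer is longer than the template or
#'   nothing matches.
#' @export
find_primer_sites <- function(template, primer, max_mismatch = 0,
                              permissive_n = FALSE) {
  check_primer_alphabet(primer)
  tmpl <- seq_to_chars(toupper(template))
  bad <- setdiff(unique(tmpl), c("A", "C", "G", "T", "N"))
  if (length(bad) > 0)
    stopf("template contains invalid base(s): %s", paste(bad, collapse = ", "))
  pr <- seq_to_chars(primer)
  k <- length(pr)
  empty <- data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0))
  if (k > length(tmpl)) return(empty)
  # logical match matrix: rows = primer positions, cols = the 5 template bases
  lut <- sapply(c("A", "C", "G", "T", "N"), function(b)
    vapply(pr, iupac_match, TRUE, base = b, permissive_n = permissive_n))
  lut <- matrix(lut, nrow = k,
                dimnames = list(NULL, c("A", "C", "G", "T", "N")))
  hits <- lapply(seq_len(length(tmpl) - k + 1L), function(s) {
    mm <- sum(!lut[cbind(seq_len(k), match(tmpl[s:(s + k - 1L)],
                                           colnames(lut)))])
    if (mm <= max_mismatch) c(s, s + k - 1L, mm) else NULL
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) return(empty)
  data.frame(start = hits[, 1], end = hits[, 2], mismatches = hits[, 3])
}

#' Predict PCR amplicons for a primer pair on a template
#'
#' Locates the forward primer on the plus strand and the reverse primer as
#' its degenerate reverse complement downstream, and reports every product
#' `[forward start, reverse-site end]` whose length lies within the bounds.
#'
#' @param template Template string over A, C, G, T, N.
#' @param pair A `primer_pair`, or a list with `forward`/`reverse` entries
#'   that are either `degenerate_primer` objects or plain primer strings
#'   (both 5' to 3').
#' @param max_mismatch Maximum mismatches tolerated per primer site.
#' @param min_len,max_len Product length bounds in nt.
#' @param permissive_n Should template `N` match?
#' @return data.frame: `start`, `end` (1-based inclusive), `length`,
#'   `fwd_mismatches`, `rev_mismatches`.
#' @export
predict_amplicons <- function(template, pair, max_mismatch = 0,
                              min_len = 1, max_len = Inf,
                              permissive_n = FALSE) {
  if (min_len > max_len) stopf("min_len must be <= max_len")
  pseq <- function(p) if (inherits(p, "degenerate_primer")) p$sequence else p
  fwd <- pseq(pair$forward)
  rev <- reverse_complement_degenerate(pseq(pair$reverse))
  fsites <- find_primer_sites(template, fwd, max_mismatch, permissive_n)
  rsites <- find_primer_sites(template, rev, max_mismatch, permissive_n)
  out <- list()
  for (i in seq_len(nrow(fsites))) for (j in seq_len(nrow(rsites))) {
    if (rsites$start[j] <= fsites$start[i]) next
    len <- rsites$end[j] - fsites$start[i] + 1L
    if (len < min_len || len > max_len) next
    out[[length(out) + 1L]] <- data.frame(
      start = fsites$start[i], end = rsites$end[j], length = len,
      fwd_mismatches = fsites$mismatches[i],
      rev_mismatches = rsites$mismatches[j])
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0), fwd_mismatches = integer(0),
                      rev_mismatches = integer(0)))
  do.call(rbind, out)
}

#' Define a restriction enzyme
#'
#' @param name Enzyme name.
#' @param site Concrete recognition site (A/C/G/T).
#' @param offset Cut offset within the site (0 = before the first base).
#'   AluI is `AGCT` with offset 2 (`AG^CT`), the default enzyme of
#'   [digest_sequence()].
#' @return Object of class `restriction_enzyme`.
#' @export
restriction_enzyme <- function(name, site, offset) {
  site <- toupper(site)
  if (!all(seq_to_chars(site) %in% c("A", "C", "G", "T")))
    stopf("recognition site must be concrete bases")
  if (offset < 0 || offset > nchar(site))
    stopf("cut offset must lie within the site")
  structure(list(name = name, site = site, offset = as.integer(offset)),
            class = "restriction_enzyme")
}

#' Digest a sequence to completion with a restriction enzyme
#'
#' Cuts at every occurrence of the recognition site (scanning all positions,
#' so overlapping sites are honoured) at `site start + offset`, simulating
#' complete digestion. Fragment lengths always sum to the input length.
#'
#' @param sequence Nucleotide string over A, C, G, T.
#' @param enzyme A [restriction_enzyme()]; default AluI (`AG^CT`).
#' @return Object of class `fragment_pattern`: list with `fragments`
#'   (template order) and `gel` (sorted fragment-length multiset).
#' @export
digest_sequence <- function(sequence,
                            enzyme = restriction_enzyme("AluI", "AGCT", 2L)) {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  sequence <- toupper(sequence)
  if (!all(seq_to_chars(sequence) %in% c("A", "C", "G", "T")))
    stopf("sequence must be over A, C, G, T")
  n <- nchar(sequence)
  starts <- gregexpr(enzyme$site, sequence, fixed = TRUE)[[1]]
  cuts <- if (starts[1] == -1L) integer(0) else
    as.integer(starts) + enzyme$offset - 1L  # cut after this position
  cuts <- cuts[cuts >= 1L & cuts < n]
  bounds <- c(0L, sort(unique(cuts)), n)
  fragments <- diff(bounds)
  structure(list(fragments = fragments, gel = sort(fragments)),
            class = "fragment_pattern")
}

#' Group fragment patterns by gel mobility
#'
#' Models finite gel resolution by binning each fragment length to
#' `round(length / bin_width)`; two digests fall in the same group iff their
#' binned, sorted fragment multisets are identical. Group ids are assigned in
#' order of first appearance, so grouping is deterministic.
#'
#' @param patterns List of `fragment_pattern` objects (or bare numeric
#'   fragment-length vectors).
#' @param bin_width Bin width in bp (default 20, about the resolution of a 3%
#'   agarose gel in the RFLP size range).
#' @return Integer group ids, one per pattern.
#' @export
pattern_group <- function(patterns, bin_width = 20) {
  if (length(patterns) == 0) stopf("empty pattern list")
  if (bin_width < 1) stopf("bin_width must be >= 1")
  keys <- vapply(patterns, function(p) {
    lens <- if (inherits(p, "fragment_pattern")) p$fragments else p
    paste(sort(round(lens / bin_width)), collapse = ",")
  }, "")
  match(keys, unique(keys))
}

#' Dereplicate clones by RFLP pattern
#'
#' Digests every clone, groups the fragment patterns by gel mobility and
#' keeps one representative per group (the first clone id in input order),
#' mirroring how identical clones are removed before sequencing.
#'
#' @param clones Named character vector of clone sequences.
#' @param enzyme A [restriction_enzyme()]; default AluI.
#' @param bin_width Gel-resolution bin width in bp.
#' @return List with `representatives` (named character vector), `groups`
#'   (data.frame `clone_id`, `group`) and `group_sizes` (table).
#' @export
dereplicate_clones <- function(clones,
                               enzyme = restriction_enzyme("AluI", "AGCT", 2L),
                               bin_width = 20) {
  stopifnot(length(clones) > 0)
  ids <- names(clones) %||% as.character(seq_along(clones))
  groups <- pattern_group(lapply(clones, digest_sequence, enzyme = enzyme),
                          bin_width = bin_width)
  rep_idx <- vapply(seq_len(max(groups)), function(g) which(groups == g)[1], 1L)
  list(representatives = setNames(clones[rep_idx], ids[rep_idx]),
       groups = data.frame(clone_id = ids, group = groups,
                           stringsAsFactors = FALSE),
       group_sizes = table(groups))
}
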