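# Degenerate nucleotide alphabet with inosine.
#
# The primer alphabet is the 15 IUPAC codes plus inosine (I). Inosine is a
# universal-pairing base: for template matching it behaves like N, but it is a
# single synthesisable nucleoside, so it counts 1 toward degeneracy and 0
# toward GC content. Biostrings' DNA alphabet has no inosine, so this small
# machinery is implemented here.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  I = c("A", "C", "G", "T")
)

# key: sorted base set collapsed to a string -> IUPAC code ("ACGT" -> N)
SET_TO_IUPAC <- local({
  codes <- setdiff(names(IUPAC_SETS), "I")
  setNames(codes, vapply(IUPAC_SETS[codes],
                         function(s) paste(sort(s), collapse = ""), ""))
})

# Set-wise complement; inosine complements to inosine.
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", V = "B", D = "H", H = "D", N = "N", I = "I"
)

check_primer_alphabet <- function(x) {
  bad <- setdiff(unique(seq_to_chars(x)), names(IUPAC_SETS))
  if (length(bad) > 0)
    stopf("invalid primer symbol(s): %s", paste(bad, collapse = ", "))
  invisible(x)
}

#' Reverse-complement a degenerate primer sequence
#'
#' Reverses the sequence and complements every IUPAC code set-wise
#' (R to Y, K to M, B to V, ...); inosine complements to inosine.
#' Applying the function twice is the identity.
#'
#' @param x A primer string over the alphabet A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N,I.
#' @return The reverse complement, same alphabet.
#' @examples
#' reverse_complement_degenerate("ACIYTITAYCAYTGGGAYYTICCICAR")
#' @export
reverse_complement_degenerate <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  check_primer_alphabet(x)
  chars_to_seq(rev(unname(IUPAC_COMPLEMENT[seq_to_chars(x)])))
}

#' Does a degenerate primer symbol match a template base?
#'
#' A primer symbol matches a template base if the base belongs to the symbol's
#' IUPAC base set. Inosine pairs with all four bases. A template `N` is an
#' unknown base and, by default, conservatively fails every match; set
#' `permissive_n = TRUE` to let it match any symbol.
#'
#' @param symbol Primer symbol (degenerate alphabet, may be inosine).
#' @param base Template base: A, C, G, T or N.
#' @param permissive_n Should a template N match? Default `FALSE`.
#' @return Logical.
#' @examples
#' iupac_match("Y", "C")  # TRUE
#' iupac_match("I", "A")  # TRUE
#' @export
iupac_match <- function(symbol, base, permissive_n = FALSE) {
  if (!symbol %in% names(IUPAC_SETS))
    stopf("invalid primer symbol: %s", symbol)
  if (!base %in% c("A", "C", "G", "T", "N"))
    stopf("invalid template base: %s", base)
  if (base == "N") return(isTRUE(permissive_n))
  base %in% IUPAC_SETS[[symbol]]
}

#' Degeneracy of a degenerate primer
#'
#' The number of distinct concrete oligonucleotides the primer represents:
#' the product over positions of the base-set cardinality. Inosine is a single
#' synthesisable nucleoside and counts as 1.
#'
#' @param x Primer string over the degenerate alphabet.
#' @return Integer degeneracy.
#' @examples
#' primer_degeneracy("ACIYTITAYCAYTGGGAYYTICCICAR")  # 64
#' @export
primer_degeneracy <- function(x) {
  check_primer_alphabet(x)
  chars <- seq_to_chars(x)
  sizes <- vapply(chars, function(s) if (s == "I") 1L else length(IUPAC_SETS[[s]]), 1L)
  as.integer(prod(sizes))
}

#' Expected GC content of a degenerate primer
#'
#' Each position contributes the fraction of its base set that is G or C
#' (so Y contributes 1/2, S contributes 1); inosine contributes 0.
#'
#' @param x Primer string over the degenerate alphabet.
#' @return GC content in percent.
#' @export
gc_content <- function(x) {
  check_primer_alphabet(x)
  chars <- seq_to_chars(x)
  frac <- vapply(chars, function(s) {
    if (s == "I") return(0)
    set <- IUPAC_SETS[[s]]
    sum(set %in% c("G", "C")) / length(set)
  }, 0)
  100 * sum(frac) / length(frac)
}

#' Melting temperature of a degenerate primer
#'
#' Uses the salt-free GC-fraction formula
#' `Tm = 64.9 + 41 * (E[G+C] - 16.4) / N`, where `E[G+C]` is the expected
#' number of G/C bases under the degenerate base sets (inosine contributes 0)
#' and `N` the primer length. Composition-only and deterministic; appropriate
#' for the 17-27 nt primers this package designs.
#'
#' @param x Primer string over the degenerate alphabet; length >= 8.
#' @return Melting temperature in degrees Celsius.
#' @export
melting_temp <- function(x) {
  check_primer_alphabet(x)
  n <- nchar(x)
  if (n < 8) stopf("primer too short for the Tm formula (%d nt < 8)", n)
  egc <- gc_content(x) / 100 * n
  64.9 + 41 * (egc - 16.4) / n
}
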