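# Shared fixtures and independent oracles.

# Enumerate every concrete oligo a degenerate primer represents (inosine is
# itself a synthesisable base, so I expands to "I") and count them.
brute_force_degeneracy <- function(primer) {
  sets <- lapply(strsplit(primer, "")[[1]], function(s) {
    if (s == "I") "I" else gh1profiler:::IUPAC_SETS[[s]]
  })
  nrow(unique(expand.grid(sets, stringsAsFactors = FALSE)))
}

random_degenerate_primer <- function(len) {
  paste(sample(names(gh1profiler:::IUPAC_SETS), len, replace = TRUE),
        collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

translate_std <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     if.fuzzy.codon = "X"))
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# small family + templates used by several amplification/classification tests
small_family <- function(n_taxa = 8, sub_rate = 0.25, seed = 11) {
  simulate_protein_family(family_spec(n_taxa = n_taxa, sub_rate = sub_rate,
                                      seed = seed))
}

anchor_pair <- function() {
  list(forward = back_translate_degenerate("TLYHWDLPQ"),
       reverse = reverse_complement_degenerate(
         back_translate_degenerate("DNFEWAEGY")))
}

family_templates <- function(family, n = length(family$proteins),
                             flank = 120, seed = 21) {
  pair <- anchor_pair()
  lapply(seq_len(n), function(i) {
    cds <- reverse_translate(family$proteins[[i]], seed = seed + 2 * i)
    emb <- embed_in_background(cds, flank_length = flank, seed = seed + 2 * i + 1)
    amp <- predict_amplicons(emb$template, pair)
    stopifnot(nrow(amp) == 1)
    list(taxon = family$labels$taxon[i], genus = family$labels$genus[i],
         division = family$labels$division[i], template = emb$template,
         amp_start = amp$start[1], amp_end = amp$end[1])
  })
}

identity_fixture <- function() {
  read_identity_table(system.file("extdata", "clone_identities.tsv",
                                  package = "gh1profiler"))
}
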