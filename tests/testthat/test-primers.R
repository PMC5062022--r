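test_that("column information content matches the logo statistics", {
  aln <- c("WD", "WE")
  prof <- column_profiles(aln)
  expect_equal(prof$ic[1], log2(20))               # perfectly conserved
  expect_equal(prof$ic[2], log2(20) - 1)           # half D, half E: 1 bit
  uniform <- vapply(gh1profiler:::AA_ALPHABET20, identity, "")
  expect_equal(column_profiles(uniform)$ic, 0)     # uniform over 20 residues
  expect_error(column_profiles(c("WDA", "WD")), "ragged")
  # row permutation changes nothing
  fam <- small_family(n_taxa = 12, seed = 8)
  p1 <- column_profiles(fam$proteins)
  p2 <- column_profiles(sample(fam$proteins))
  expect_equal(p1$ic, p2$ic)
})

test_that("conserved-block search recovers the anchor peptides", {
  # identical copies: every window is maximal; tie-break picks column 1
  aln <- rep("MTLYHWDLPQRS", 4)
  b <- find_conserved_blocks(column_profiles(aln), window = 9)
  expect_equal(b[[1]]$score, log2(20))
  expect_identical(b[[1]]$consensus, substr(aln[1], b[[1]]$start,
                                            b[[1]]$start + 8))
  # synthetic family at defaults: the two anchors rank on top
  fam <- simulate_protein_family(family_spec(n_taxa = 60, sub_rate = 0.25,
                                             seed = 13))
  blocks <- find_conserved_blocks(column_profiles(fam$proteins))
  expect_identical(blocks[[1]]$consensus, "TLYHWDLPQ")
  expect_identical(blocks[[2]]$consensus, "DNFEWAEGY")
  expect_identical(c(blocks[[1]]$start, blocks[[2]]$start), c(40L, 331L))
  # a 50/50 column bars the window when only one variant is allowed
  mixed <- c("WWWWWWWWD", "WWWWWWWWE")
  expect_length(find_conserved_blocks(column_profiles(mixed), window = 9,
                                      max_variants_per_pos = 1), 0)
  expect_error(find_conserved_blocks(column_profiles(mixed), window = 10),
               "exceeds")
})

test_that("degenerate back-translation reproduces the published anchors", {
  expect_identical(back_translate_degenerate("TLYHWDLPQ"),
                   "ACIYTITAYCAYTGGGAYYTICCICAR")
  expect_identical(nchar(back_translate_degenerate("TLYHWDLPQ")), 27L)
  expect_identical(back_translate_degenerate("W"), "TGG")
  expect_identical(back_translate_degenerate("DNFEWAEGY"),
                   "GAYAAYTTYGARTGGGCIGARGGITAY")
  expect_identical(
    reverse_complement_degenerate(back_translate_degenerate("DNFEWAEGY")),
    "RTAICCYTCIGCCCAYTCRAARTTRTC")
  expect_identical(back_translate_degenerate("AC", clamp5 = "GCGCC"),
                   paste0("GCGCC", back_translate_degenerate("AC")))
  expect_error(back_translate_degenerate("TLB"), "unknown residue")
})

test_that("back-translation covers every concrete codon of the peptide", {
  set.seed(3)
  tab <- split(names(Biostrings::GENETIC_CODE),
               unname(Biostrings::GENETIC_CODE))
  for (i in 1:10) {
    pep <- paste(sample(gh1profiler:::AA_ALPHABET20, 6, replace = TRUE),
                 collapse = "")
    deg <- strsplit(back_translate_degenerate(pep), "")[[1]]
    concrete <- strsplit(reverse_translate(pep, seed = i), "")[[1]]
    expect_true(all(mapply(iupac_match, deg, concrete)))
    # and position-wise for every codon of every residue
    res <- strsplit(pep, "")[[1]]
    for (k in seq_along(res)) for (cod in tab[[res[k]]]) {
      cc <- strsplit(cod, "")[[1]]
      expect_true(all(mapply(iupac_match, deg[(3 * k - 2):(3 * k)], cc)))
    }
  }
})

test_that("degenerate reverse complement is a set-wise involution", {
  expect_identical(reverse_complement_degenerate("ACGT"), "ACGT")
  set.seed(4)
  for (i in 1:20) {
    p <- random_degenerate_primer(sample(5:20, 1))
    expect_identical(reverse_complement_degenerate(
      reverse_complement_degenerate(p)), p)
  }
  expect_error(reverse_complement_degenerate("ACGZ"), "invalid")
})

test_that("degeneracy is the product of base-set sizes, inosine counting once", {
  expect_identical(primer_degeneracy("ATG"), 1L)
  expect_identical(primer_degeneracy("NN"), 16L)
  expect_identical(primer_degeneracy("ACIYTITAYCAYTGGGAYYTICCICAR"), 64L)
  set.seed(5)
  for (i in 1:20) {
    a <- random_degenerate_primer(sample(3:8, 1))
    b <- random_degenerate_primer(sample(3:8, 1))
    expect_identical(primer_degeneracy(paste0(a, b)),
                     primer_degeneracy(a) * primer_degeneracy(b))
    expect_identical(primer_degeneracy(a), brute_force_degeneracy(a))
  }
})

test_that("expected GC and Tm follow their closed forms", {
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("AT"), 0)
  expect_equal(gc_content("RY"), 50)
  expect_equal(melting_temp(paste0(strrep("G", 10), strrep("A", 10))),
               64.9 + 41 * (10 - 16.4) / 20)
  expect_equal(melting_temp(strrep("A", 20)), 64.9 + 41 * (-16.4) / 20)
  # composition-only: position order is irrelevant
  expect_equal(melting_temp("ACGTACGTAC"), melting_temp("CCAAGGTTAC"))
  expect_error(melting_temp("ACGT"), "too short")
})

test_that("primer pairs rank by degeneracy, then Tm and GC balance", {
  mk <- function(consensus, start) {
    structure(list(start = start, length = nchar(consensus),
                   residue_sets = as.list(strsplit(consensus, "")[[1]]),
                   consensus = consensus, score = log2(20)),
              class = "conserved_block")
  }
  b_trp <- mk("WWW", 10L)          # Trp-only primer: degeneracy 1
  b_up <- mk("TLYHWDLPQ", 20L)     # degeneracy 64
  b_down <- mk("DNFEWAEGY", 300L)  # degeneracy 64
  pairs <- rank_primer_pairs(list(b_trp, b_up, b_down))
  expect_length(pairs, 3)
  degs <- vapply(pairs, function(p)
    p$forward$degeneracy * p$reverse$degeneracy, 0L)
  expect_identical(degs, sort(degs))                  # degeneracy first
  expect_identical(degs[1:2], c(64L, 64L))
  dtm <- vapply(pairs, function(p) abs(p$forward$tm - p$reverse$tm), 0)
  expect_lte(dtm[1], dtm[2])                          # then Tm balance
  expect_identical(pairs[[3]]$forward_block$start, 20L)
  expect_identical(pairs[[1]]$expected_amplicon,
                   as.integer(3 * (pairs[[1]]$reverse_block$start -
                                     pairs[[1]]$forward_block$start) + 27))
  single <- rank_primer_pairs(list(b_up, b_down))
  expect_length(single, 1)
  expect_identical(single[[1]]$expected_amplicon, 3L * (300L - 20L) + 27L)
  expect_error(rank_primer_pairs(list(b_up)), "at least one")
})

test_that("design_primers rediscovers the anchor pair on a synthetic family", {
  fam <- simulate_protein_family(family_spec(n_taxa = 40, sub_rate = 0.2,
                                             seed = 3))
  des <- design_primers(fam$proteins)
  best <- des$pairs[[1]]
  expect_identical(best$forward$sequence, "ACIYTITAYCAYTGGGAYYTICCICAR")
  expect_identical(best$reverse$sequence, "RTAICCYTCIGCCCAYTCRAARTTRTC")
  expect_identical(best$expected_amplicon, 900L)
})
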