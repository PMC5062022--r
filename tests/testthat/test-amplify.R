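test_that("IUPAC matching follows the base-set semantics", {
  expect_true(iupac_match("Y", "C"))
  expect_false(iupac_match("Y", "A"))
  expect_true(iupac_match("R", "G"))
  for (b in c("A", "C", "G", "T")) expect_true(iupac_match("I", b))
  expect_false(iupac_match("N", "N"))              # unknown template base
  expect_true(iupac_match("N", "N", permissive_n = TRUE))
  expect_error(iupac_match("Z", "A"), "invalid primer symbol")
  expect_error(iupac_match("A", "U"), "invalid template base")
})

test_that("primer-site search honours mismatch budgets and strand scanning", {
  tmpl <- paste0(strrep("A", 30), "ACGCTGTACCACTGGGACTTACCGCAA", strrep("A", 30))
  fwd <- back_translate_degenerate("TLYHWDLPQ")
  hit <- find_primer_sites(tmpl, fwd)
  expect_identical(hit$start, 31L)
  expect_identical(hit$end, 57L)
  expect_identical(hit$mismatches, 0L)
  expect_identical(nrow(find_primer_sites(strrep("A", 50), "TGG")), 0L)
  # one seeded mismatch: found at budget 1, invisible at 0
  mut <- tmpl
  substr(mut, 35, 35) <- "A"   # TGT -> TAT breaks the Y=C/T position? no: pos35 is C of TAC
  substr(mut, 36, 36) <- "C"
  expect_identical(nrow(find_primer_sites(mut, fwd, max_mismatch = 0)), 0L)
  expect_identical(find_primer_sites(mut, fwd, max_mismatch = 1)$start, 31L)
  # primer longer than template: empty, not an error
  expect_identical(nrow(find_primer_sites("ACGT", fwd)), 0L)
})

test_that("amplicon prediction spans forward start to reverse-site end", {
  fam <- small_family(n_taxa = 3, sub_rate = 0.2, seed = 6)
  cds <- reverse_translate(fam$proteins[[1]], seed = 7)
  emb <- embed_in_background(cds, flank_length = 100, seed = 8)
  amp <- predict_amplicons(emb$template, anchor_pair())
  expect_identical(nrow(amp), 1L)
  expect_identical(amp$length, 3L * (331L - 40L) + 27L)   # 900 nt
  expect_identical(amp$start, emb$start + 3L * 39L)
  # the reverse block peptide is encoded at the 3' end of the product
  prod <- substr(emb$template, amp$start, amp$end)
  expect_identical(translate_std(substr(prod, 900 - 26, 900)), "DNFEWAEGY")
  # no reverse site downstream -> no product
  half <- substr(emb$template, 1, amp$start + 100)
  expect_identical(nrow(predict_amplicons(half, anchor_pair())), 0L)
  expect_error(predict_amplicons(emb$template, anchor_pair(),
                                 min_len = 10, max_len = 5), "min_len")
})

test_that("duplicated forward sites yield one product each", {
  core <- "TGGAAAGGGAAATTTCCA"                 # W K G K F P
  fwd <- "TGGAAAGGG"
  rev <- reverse_complement_degenerate("TTTCCA")  # binds the TTTCCA site
  tmpl <- paste0("AAAA", core, "CCCCAA", core, "GGGG")
  amp <- predict_amplicons(tmpl, list(forward = fwd, reverse = rev))
  expect_identical(nrow(amp), 3L)   # f1-r1, f1-r2, f2-r2
})

test_that("restriction digestion cuts every site and conserves length", {
  expect_identical(digest_sequence("AAAGCTAA")$fragments, c(4L, 4L))
  expect_identical(digest_sequence("AGCTAGCT")$fragments, c(2L, 4L, 2L))
  expect_identical(digest_sequence("ACGTACGT")$fragments, 8L)
  set.seed(9)
  for (i in 1:50) {
    s <- random_dna(sample(10:500, 1))
    fr <- digest_sequence(s)$fragments
    expect_identical(sum(fr), nchar(s))
    expect_true(all(fr >= 1))
  }
  expect_error(digest_sequence("ACGN"), "A, C, G, T")
  expect_error(restriction_enzyme("X", "AGCT", 9), "within the site")
})

test_that("gel grouping bins fragment lengths and is an equivalence", {
  expect_identical(pattern_group(list(c(100, 200), c(100, 200))), c(1L, 1L))
  expect_identical(pattern_group(list(c(100, 200), c(105, 195))), c(1L, 1L))
  expect_identical(pattern_group(list(c(100, 200), c(100, 300))), c(1L, 2L))
  # order within the digest does not matter (gel view is a sorted multiset)
  expect_identical(pattern_group(list(c(300, 100), c(100, 300))), c(1L, 1L))
  expect_error(pattern_group(list()), "empty")
})

test_that("dereplication keeps one representative per RFLP group", {
  same <- setNames(rep("AGCTAAAGCTTT", 5), paste0("c", 1:5))
  d <- dereplicate_clones(same)
  expect_length(d$representatives, 1)
  expect_identical(names(d$representatives), "c1")
  # error-free synthetic library: group count equals the truth
  fam <- small_family(n_taxa = 6, sub_rate = 0.25, seed = 10)
  tmpl <- family_templates(fam)
  lib <- simulate_clone_library(tmpl, n_clones = 30, error_rate = 0, seed = 11)
  d2 <- dereplicate_clones(lib$clones)
  expect_identical(length(d2$representatives),
                   length(unique(lib$truth$rflp_group[
                     match(names(lib$clones), lib$truth$clone_id)])))
  # clones in the same truth group always land in the same observed group
  obs <- d2$groups$group[match(lib$truth$clone_id, d2$groups$clone_id)]
  expect_identical(unname(outer(obs, obs, "==") >=
                            outer(lib$truth$rflp_group, lib$truth$rflp_group, "==")),
                   matrix(TRUE, 30, 30))
})
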