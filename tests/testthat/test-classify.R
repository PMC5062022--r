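test_that("six-frame translation follows the standard code and ambiguity rules", {
  fr <- six_frame_translate("ATGTGG")
  expect_identical(fr[["+1"]], "MW")
  expect_identical(six_frame_translate("ATNGGG")[["+1"]], "XG")
  # frame -1 of s equals frame +1 of the reverse complement
  s <- random_dna(31)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_identical(six_frame_translate(s)[["-1"]],
                   six_frame_translate(rc)[["+1"]])
  expect_length(six_frame_translate("ATGTGGA"), 6)
  expect_error(six_frame_translate("AT"), "codon")
})

test_that("best hit finds the encoding reference at full identity", {
  fam <- small_family(n_taxa = 4, sub_rate = 0.3, seed = 14)
  panel <- reference_panel(id = fam$labels$taxon,
                           protein = unname(fam$proteins),
                           genus = fam$labels$genus,
                           division = fam$labels$division)
  frag <- substr(fam$proteins[[2]], 40, 339)
  clone <- reverse_translate(frag, seed = 15)
  hit <- best_hit(clone, panel)
  expect_identical(hit$reference_id, fam$labels$taxon[2])
  expect_identical(hit$identity, 100L)
  expect_identical(hit$genus, fam$labels$genus[2])
  expect_gte(hit$alignment_length, nchar(frag))
  expect_error(best_hit(clone, panel[0, ]), "empty")
})

test_that("identical references resolve to the lowest id", {
  prot <- paste(rep("MTLYHWDLPQAKWGE", 4), collapse = "")
  panel <- reference_panel(id = c("refB", "refA"), protein = c(prot, prot),
                           genus = c("G1", "G2"), division = c("D", "D"))
  hit <- best_hit(reverse_translate(substr(prot, 1, 40), seed = 1), panel)
  expect_identical(hit$reference_id, "refA")
})

test_that("clones at 1% error are attributed to their source taxon", {
  fam <- small_family(n_taxa = 5, sub_rate = 0.3, seed = 16)
  tmpl <- family_templates(fam)
  lib <- simulate_clone_library(tmpl, n_clones = 30, error_rate = 0.01,
                                seed = 17)
  panel <- reference_panel(id = fam$labels$taxon[1:5],
                           protein = unname(fam$proteins[1:5]),
                           genus = fam$labels$genus[1:5],
                           division = fam$labels$division[1:5])
  pred <- vapply(lib$clones, function(cl) best_hit(cl, panel)$reference_id, "")
  expect_gte(mean(pred == lib$truth$taxon), 0.95)
})

test_that("catalytic-glutamate verification maps columns through the alignment", {
  spec <- family_spec(n_taxa = 3, sub_rate = 0.2, seed = 18)
  fam <- simulate_protein_family(spec)
  ref <- fam$proteins[[1]]
  frag <- substr(ref, 40, 339)                    # spans both glutamates
  expect_true(catalytic_check(frag, ref, spec$catalytic_cols))
  # E -> Q at the first catalytic column
  mut <- frag
  substr(mut, spec$catalytic_cols[1] - 39, spec$catalytic_cols[1] - 39) <- "Q"
  expect_false(catalytic_check(mut, ref, spec$catalytic_cols))
  # fragment not spanning both columns: fails, flagged partial
  short <- substr(ref, 40, 200)
  res <- catalytic_check(short, ref, spec$catalytic_cols)
  expect_false(res)
  expect_true(attr(res, "partial"))
  expect_error(catalytic_check(frag, ref, c(1, 9999)), "outside")
})

test_that("novelty thresholds are <70 (low) and <=75 (novel)", {
  nv <- classify_novelty(c(69, 70, 75, 76))
  expect_identical(nv$low_identity, c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(nv$novel, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(!nv$low_identity | nv$novel))   # low implies novel
  expect_error(classify_novelty(101), "0, 100")
  expect_error(classify_novelty(50, low_threshold = 80, novel_threshold = 75),
               "below")
})

test_that("genus extraction strips brackets and qualifiers", {
  expect_identical(extract_genus("Flavobacterium sp."), "Flavobacterium")
  expect_identical(extract_genus("[Clostridium] termitidis"), "Clostridium")
  expect_identical(extract_genus("Clostridium] termitidis"), "Clostridium")
  expect_identical(extract_genus("Vibrio vulnificus"), "Vibrio")
  expect_error(extract_genus(""), "empty")
})

test_that("community tabulation reproduces the published library structure", {
  tab <- identity_fixture()
  cd <- community_table(tab[tab$library == "CD", ])
  expect_identical(cd$n_genera, 14L)
  expect_identical(cd$n_divisions, 3L)
  cm <- community_table(tab[tab$library == "CM", ])
  expect_identical(cm$n_genera, 19L)
  expect_identical(cm$n_divisions, 6L)
  kd <- community_table(tab[tab$library == "KD", ])
  expect_identical(kd$n_divisions, 6L)
  expect_identical(sum(cd$genus_counts), 20L)
  one <- community_table(data.frame(genus = "Vibrio",
                                    division = "gamma-Proteobacteria"))
  expect_identical(c(one$n_genera, one$n_divisions), c(1L, 1L))
  expect_error(community_table(data.frame(genus = NA, division = "D")),
               "unlabelled")
})
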