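test_that("back-translation round-trips and respects codon preferences", {
  expect_identical(back_translate("M"), "ATG")
  tab <- codon_table_ecoli()
  set.seed(101)
  for (i in 1:20) {
    p <- random_protein(sample(5:30, 1))
    expect_identical(translate_dna(back_translate(p, tab)), p)
  }
  # preferred codons: without constraints each residue gets its top codon
  expect_identical(back_translate("KVG", tab), "AAAGTGGGC")
  # rare codons avoided: Ile never encoded ATA (usage 0.07 < 0.10)
  dna <- back_translate(strrep("I", 10), tab)
  expect_false(grepl("ATA", dna, fixed = TRUE))
})

test_that("back-translation avoids forbidden motifs on both strands", {
  # brute-force oracle: all Leu x Glu codon pairs avoiding CTCGAG either strand
  leu <- codons_by_aa[["L"]]; glu <- codons_by_aa[["E"]]
  ok <- outer(leu, glu, Vectorize(function(l, e) {
    s <- paste0(l, e)
    !grepl("CTCGAG", s) && !grepl("CTCGAG", as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s))))
  }))
  allowed <- outer(leu, glu, paste0)[ok]
  out <- back_translate("LE", forbidden_motifs = "CTCGAG")
  expect_true(out %in% allowed)

  # reverse-strand avoidance: GAATTC is palindromic, but check a
  # non-palindromic motif appears on neither strand
  out2 <- back_translate("ASAS", forbidden_motifs = c("GCTCTTC", "GCAGC"))
  rc2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(out2)))
  expect_false(grepl("GCAGC", out2) || grepl("GCAGC", rc2))

  # unsatisfiable: both Lys codons forbidden
  expect_error(back_translate("GKG", forbidden_motifs = c("AAA", "AAG")),
               "motif constraints")
})

test_that("silent site placement handles identity, single-sub and impossible cases", {
  sacI <- restriction_enzymes("SacI")
  ident <- find_silent_site_placements("GAGCTC", sacI, c(1, 6))
  expect_true(length(ident) >= 1)
  expect_identical(ident[[1]]$offset, 1L)
  expect_identical(nrow(ident[[1]]$substitutions), 0L)

  xho <- find_silent_site_placements("CTGGAG", "XhoI", c(1, 6))
  expect_identical(nrow(xho[[1]]$substitutions), 1L)
  expect_identical(apply_placement("CTGGAG", xho[[1]]), "CTCGAG")

  expect_length(find_silent_site_placements("TGGTGG", "EcoRI", c(1, 6)), 0)
  expect_error(find_silent_site_placements("TGGTGG", "EcoRI", c(1, 5)),
               "shorter than site")
})

test_that("silent placements are synonymous and match exhaustive enumeration", {
  set.seed(202)
  enzymes <- c("SacI", "XhoI", "PstI", "KpnI", "SapI", "Mva1269I")
  for (i in 1:12) {
    p <- random_protein(4)
    dna <- back_translate(p)
    for (enz in enzymes) {
      site <- restriction_enzymes(enz)
      got <- find_silent_site_placements(dna, site, c(1, 12))
      want <- oracle_silent_placements(dna, site$recognition, c(1, 12))
      got_tab <- data.frame(
        offset = vapply(got, function(x) x$offset, 1L),
        min_subs = vapply(got, function(x) nrow(x$substitutions), 1L))
      got_tab <- got_tab[order(got_tab$offset), ]
      want <- want[order(want$offset), ]
      expect_equal(got_tab$offset, want$offset, info = paste(p, enz))
      expect_equal(got_tab$min_subs, want$min_subs, info = paste(p, enz))
      for (pl in got) {
        edited <- apply_placement(dna, pl)
        expect_identical(translate_dna(edited), p)
        expect_true(grepl(iupac_to_regex(site$recognition),
                          substr(edited, pl$offset, pl$offset + site$length - 1)))
      }
    }
  }
})

test_that("placements are sorted by cost then offset and reject stale sequences", {
  dna <- back_translate("LELE")
  pls <- find_silent_site_placements(dna, "XhoI", c(1, 12))
  costs <- vapply(pls, function(x) nrow(x$substitutions), 1L)
  offs <- vapply(pls, function(x) x$offset, 1L)
  expect_true(all(diff(costs) >= 0))
  expect_true(all(diff(offs[costs == costs[1]]) > 0))
  pl <- pls[[which(costs > 0)[1]]]
  mutated <- sub("C", "A", dna)
  if (mutated != dna) {
    sub_pos <- pl$substitutions$position[1]
    broken <- paste0(substr(dna, 1, sub_pos - 1), "N",
                     substr(dna, sub_pos + 1, nchar(dna)))
    expect_error(apply_placement(broken, pl), "inconsistent")
  }
})

test_that("site counting is IUPAC-aware, double-stranded and circular-aware", {
  ecoRI <- restriction_enzymes("EcoRI")
  expect_identical(count_site_occurrences("GAATTCAAGAATTC", ecoRI), 2L)
  # palindrome counted once per offset even though it matches both strands
  expect_identical(count_site_occurrences("GAATTC", ecoRI), 1L)
  # non-palindromic site found on the reverse strand
  expect_identical(count_site_occurrences("GAAGAGC", restriction_enzymes("SapI")), 1L)
  # junction-only match in circular mode
  expect_identical(count_site_occurrences("AATTCGG", ecoRI, circular = TRUE), 1L)
  expect_identical(count_site_occurrences("AATTCGG", ecoRI, circular = FALSE), 0L)
  # fully ambiguous site: one count per forward offset
  expect_identical(count_site_occurrences("ACGTACGTAC",
                                          restriction_site("any", "NNNNNN")), 5L)
  # ambiguity codes respected (Y = C or T)
  site <- restriction_site("test", "GAYTC")
  expect_identical(count_site_occurrences("GACTCGATTC", site), 2L)
})

test_that("engineered example scaffold carries each cassette enzyme exactly once", {
  spec <- example_scaffold()
  eng <- engineer_scaffold(spec)
  expect_identical(translate_dna(eng$gene), spec$protein_sequence)
  for (enz in eng$enzymes) {
    expect_identical(count_site_occurrences(eng$construct,
                                            restriction_enzymes(enz)), 1L)
  }
  # placements recorded for the four CDR-cassette enzymes
  expect_setequal(names(eng$placements), spec$cassette_sites$enzyme)
})

test_that("scaffold specs validate their region tiling", {
  regions <- data.frame(label = c("FR1", "CDR1"), start = c(1, 6), end = c(5, 9))
  expect_s3_class(scaffold_spec("MKVLGWGQG", regions,
                                data.frame(enzyme = "SacI", boundary = 6)),
                  "scaffold_spec")
  bad <- data.frame(label = c("FR1", "CDR1"), start = c(1, 7), end = c(5, 9))
  expect_error(scaffold_spec("MKVLGWGQG", bad, NULL), "tile")
  expect_equal(region_range(example_scaffold(), "CDR2"), c(49, 58))
})
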