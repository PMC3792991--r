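test_that("shipped default designs satisfy every compositional constraint", {
  expect_identical(nrow(validate_design(default_cdr2_design())), 0L)
  expect_identical(nrow(validate_design(default_cdr3_design())), 0L)
})

test_that("validation reports violations with position and measured value", {
  d3 <- default_cdr3_design()
  # inject cysteine at one CDR3 position
  f <- d3$positions[[2]]$freq
  f <- c(f * (1 - 0.05), C = 0.05)
  d3$positions[[2]] <- position_frequency("CDR3.2", f)
  rep <- validate_design(d3)
  expect_true(any(rep$rule == "excluded_C" & rep$position == "CDR3.2"))
  expect_equal(rep$value[rep$rule == "excluded_C"], 0.05, tolerance = 1e-12)

  # hydrophobic cap: push summed V/I/L/M/F to 0.30
  d2 <- default_cdr2_design()
  f <- d2$positions[[1]]$freq
  f <- f[!(names(f) %in% c("L", "V"))]
  f <- f / sum(f) * 0.70
  f <- c(f, V = 0.15, L = 0.15)
  d2$positions[[1]] <- position_frequency("CDR2.1", f)
  rep2 <- validate_design(d2)
  hyd <- rep2[rep2$rule == "hydrophobic_cap", ]
  expect_identical(hyd$position, "CDR2.1")
  expect_equal(hyd$value, 0.30, tolerance = 1e-9)

  # wrong position count under the CDR2 profile
  d2b <- default_cdr2_design()
  d2b$positions <- d2b$positions[1:3]
  expect_true("n_positions" %in% validate_design(d2b)$rule)
})

test_that("clone probabilities multiply per position and vanish off support", {
  pos <- list(position_frequency("p1", c(A = 0.5, G = 0.5)),
              position_frequency("p2", c(Y = 0.9, S = 0.1)))
  d <- cdr_design("toy", pos)
  expect_equal(clone_probability(d, "AY"), 0.45)
  expect_equal(sum(sapply(c("AY", "AS", "GY", "GS"),
                          function(s) clone_probability(d, s))), 1)
  expect_identical(clone_probability(d, "AW"), 0)
  expect_error(clone_probability(d, "A"), "length")
  single <- cdr_design("w", list(position_frequency("p1", c(W = 1))))
  expect_identical(clone_probability(single, "W"), 1)
})

test_that("diversity, extremes and normalization agree with exhaustive enumeration", {
  set.seed(303)
  for (i in 1:8) {
    d <- random_design(n_pos = 3, n_aa = sample(2:5, 1))
    enum <- oracle_enumerate_design(d)
    expect_equal(theoretical_diversity(d), nrow(enum))
    expect_equal(sum(enum$probability), 1, tolerance = 1e-12)
    expect_equal(extreme_probability(d, "most_common"), max(enum$probability))
    expect_equal(extreme_probability(d, "rarest"), min(enum$probability))
    # coverage bounds implied by the extremes
    expect_gte(extreme_probability(d, "most_common") * theoretical_diversity(d), 1)
    expect_lte(extreme_probability(d, "rarest") * theoretical_diversity(d), 1)
  }
  expect_identical(theoretical_diversity(
    cdr_design("w", list(position_frequency("p1", c(W = 1))))), 1)
})

test_that("combined cassette rarity multiplies and rounds to 3 significant figures", {
  expect_identical(combined_rarity(334, 727000), 2.43e8)
  expect_identical(combined_rarity(1, 1), 1)
  expect_identical(combined_rarity(2, 3), 6)
  expect_error(combined_rarity(0.5, 10))
  expect_equal(one_in_n(extreme_probability(default_cdr2_design())),
               signif(1 / extreme_probability(default_cdr2_design()), 3))
})

test_that("oligo specs use one stop-free codon per amino acid with exact fractions", {
  spec <- compile_oligo_spec(default_cdr3_design(),
                             left_site = "PstI", right_site = "KpnI")
  stops <- c("TAA", "TAG", "TGA")
  for (nm in names(spec$positions)) {
    p <- spec$positions[[nm]]
    expect_identical(anyDuplicated(p$aa), 0L)
    expect_false(any(p$codon %in% stops))
    expect_true(all(vapply(seq_len(nrow(p)),
                           function(i) translate_dna(p$codon[i]) == p$aa[i],
                           TRUE)))
  }
  d3 <- default_cdr3_design()
  for (j in seq_along(d3$positions)) {
    f <- d3$positions[[j]]$freq
    f <- f[f > 0]
    p <- spec$positions[[j]]
    expect_equal(setNames(p$fraction, p$aa), f[p$aa])
  }
  # flanks carry the cassette sites verbatim
  expect_true(startsWith(spec$left_flank, "CTGCAG"))
  expect_true(endsWith(spec$right_flank, "GGTACC"))
  # fixed FDY tail encoded in frame just before the right site
  expect_identical(translate_dna(substr(spec$right_flank, 1,
                                        nchar(spec$right_flank) - 6)), "FDY")
  # single-residue position gets the table's top codon
  g <- cdr_design("g", list(position_frequency("p1", c(G = 1))))
  expect_identical(compile_oligo_spec(g)$positions[[1]]$codon, "GGC")
})

test_that("assembled inserts stay inside the design support", {
  spec <- compile_oligo_spec(default_cdr2_design(),
                             left_site = "XhoI", right_site = "SacI")
  ins <- assemble_insert(spec, "YSDY")
  core <- substr(ins, nchar(spec$left_flank) + 1, nchar(ins) - nchar(spec$right_flank))
  expect_identical(translate_dna(core), "YSDY")
  expect_error(assemble_insert(spec, "YSDC"), "support")
})

test_that("frequency designs survive CSV and JSON round trips", {
  d <- default_cdr3_design()
  csv <- tempfile(fileext = ".csv")
  write_frequency_csv(d, csv)
  d_csv <- read_frequency_csv(csv, name = "CDR3", constraint_profile = "CDR3",
                              fixed_flanks = list(left = "", right = "FDY"))
  expect_identical(nrow(validate_design(d_csv)), 0L)
  for (j in seq_along(d$positions)) {
    f_csv <- d_csv$positions[[j]]$freq
    f_csv <- f_csv[f_csv > 0]
    f_ref <- d$positions[[j]]$freq
    f_ref <- f_ref[f_ref > 0]
    expect_equal(f_csv[order(names(f_csv))], f_ref[order(names(f_ref))],
                 tolerance = 1e-12)
  }
  js <- tempfile(fileext = ".json")
  write_frequency_json(d, js)
  d_js <- read_frequency_json(js)
  expect_identical(d_js$constraint_profile, "CDR3")
  expect_identical(nrow(validate_design(d_js)), 0L)
  expect_equal(clone_probability(d_js, "YSGDNTS"),
               clone_probability(d, "YSGDNTS"), tolerance = 1e-12)
})
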