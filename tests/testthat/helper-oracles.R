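# Independent brute-force oracles used across the test files. These are
# deliberately written against first principles (exhaustive enumeration,
# direct simulation), not by calling the implementation under test.

IUPAC_REGEX <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

iupac_to_regex <- function(recognition) {
  paste0("^", paste(IUPAC_REGEX[strsplit(recognition, "")[[1]]], collapse = ""), "$")
}

# Standard genetic code inverted: amino acid -> all codons
codons_by_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

# Exhaustive enumeration: for every offset of `recognition` inside `window`
# (1-based inclusive nt range of in-frame `dna`), the minimum number of base
# substitutions over ALL synonymous codon assignments of the codons the
# window touches such that the recognition pattern (IUPAC) matches at that
# offset. Returns data.frame(offset, min_subs), feasible offsets only.
oracle_silent_placements <- function(dna, recognition, window) {
  L <- nchar(recognition)
  protein <- strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(dna))), "")[[1]]
  c1 <- (window[1] - 1L) %/% 3L + 1L
  c2 <- (window[2] - 1L) %/% 3L + 1L
  combos <- expand.grid(lapply(c1:c2, function(ci) codons_by_aa[[protein[ci]]]),
                        stringsAsFactors = FALSE)
  regions <- do.call(paste0, combos)
  region_start <- (c1 - 1L) * 3L + 1L
  orig <- substr(dna, region_start, c2 * 3L)
  orig_chars <- strsplit(orig, "")[[1]]
  char_mat <- do.call(rbind, strsplit(regions, ""))
  diffs <- rowSums(sweep(char_mat, 2, orig_chars, FUN = "!="))
  pat <- iupac_to_regex(recognition)
  out <- list()
  for (off in window[1]:(window[2] - L + 1L)) {
    seg <- substr(regions, off - region_start + 1L, off - region_start + L)
    hit <- grepl(pat, seg)
    if (any(hit)) {
      out[[length(out) + 1L]] <- data.frame(offset = off,
                                            min_subs = as.integer(min(diffs[hit])))
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(offset = integer(), min_subs = integer())
}

# Exhaustive support enumeration of a small cdr_design: all sequences with
# nonzero probability and their probabilities computed by direct product.
oracle_enumerate_design <- function(design) {
  supports <- lapply(design$positions, function(p) p$freq[p$freq > 0])
  grid <- expand.grid(lapply(supports, names), stringsAsFactors = FALSE)
  seqs <- do.call(paste0, grid)
  probs <- Reduce(`*`, lapply(seq_along(supports), function(j) {
    unname(supports[[j]][grid[[j]]])
  }))
  data.frame(sequence = seqs, probability = probs, stringsAsFactors = FALSE)
}

# Random small design for property tests (no constraint profile)
random_design <- function(n_pos, n_aa = 4, alphabet = c("A", "G", "S", "Y", "D", "T", "N", "W")) {
  positions <- lapply(seq_len(n_pos), function(j) {
    aa <- sample(alphabet, n_aa)
    w <- runif(n_aa)
    position_frequency(paste0("p", j), setNames(w / sum(w), aa))
  })
  cdr_design("random", positions)
}

# Monte-Carlo oracle for expected number of distinct clones
mc_expected_distinct <- function(prob_classes, n_draws, reps) {
  p <- rep(prob_classes$p, prob_classes$count)
  ids <- seq_along(p)
  counts <- replicate(reps, length(unique(sample(ids, n_draws, replace = TRUE,
                                                 prob = p))))
  list(mean = mean(counts), se = sd(counts) / sqrt(reps))
}

random_protein <- function(n) {
  paste(sample(setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], ""), n,
               replace = TRUE), collapse = "")
}
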