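AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
HYDROPHOBIC <- c("V", "I", "L", "M", "F")
POSITIVE <- c("K", "R", "H")

#' Per-position amino-acid frequency
#'
#' @param position_label label for the randomized position (e.g. `"CDR3.2"`).
#' @param freq named numeric vector of amino-acid frequencies; must sum to 1
#'   and contain no stop symbol.
#' @return An object of class `position_frequency`.
#' @export
position_frequency <- function(position_label, freq) {
  stopifnot(is.numeric(freq), !is.null(names(freq)))
  names(freq) <- toupper(names(freq))
  if ("*" %in% names(freq)) stop("stop symbol not allowed in a frequency design")
  if (!all(names(freq) %in% AA20)) {
    stop("unknown residues: ", paste(setdiff(names(freq), AA20), collapse = ", "))
  }
  if (any(freq < 0) || abs(sum(freq) - 1) > 1e-9) {
    stop("frequencies at '", position_label, "' must be >= 0 and sum to 1 (got ",
         format(sum(freq)), ")")
  }
  structure(list(position_label = position_label, freq = freq),
            class = "position_frequency")
}

#' CDR cassette randomization design
#'
#' An ordered set of per-position amino-acid frequency tables plus the fixed
#' residues flanking them, with a named constraint profile. The `"CDR2"`
#' profile requires exactly 4 randomized positions; the `"CDR3"` profile
#' requires 7 randomized positions inside a 10-residue loop whose last three
#' residues are the fixed Phe-Asp-Tyr (FDY) tail, and excludes C, I, M and K
#' from every randomized position. Both profiles cap the summed frequency of
#' the hydrophobic residues V, I, L, M, F at 0.25 per position.
#'
#' @param name design name.
#' @param positions list of [position_frequency()] objects.
#' @param fixed_flanks list with elements `left` and `right`: fixed residues
#'   on either side of the randomized stretch (may be empty strings).
#' @param constraint_profile `"CDR2"`, `"CDR3"`, or `"none"`.
#' @return An object of class `cdr_design`.
#' @seealso [validate_design()], [default_cdr2_design()], [default_cdr3_design()]
#' @export
cdr_design <- function(name, positions, fixed_flanks = list(left = "", right = ""),
                       constraint_profile = c("none", "CDR2", "CDR3")) {
  constraint_profile <- match.arg(constraint_profile)
  stopifnot(is.list(positions),
            all(vapply(positions, inherits, TRUE, "position_frequency")))
  structure(list(name = name, positions = positions, fixed_flanks = fixed_flanks,
                 constraint_profile = constraint_profile),
            class = "cdr_design")
}

#' @export
print.cdr_design <- function(x, ...) {
  cat(sprintf("<cdr_design> %s (%s profile): %d randomized positions, flanks '%s'/'%s'\n",
              x$name, x$constraint_profile, length(x$positions),
              x$fixed_flanks$left, x$fixed_flanks$right))
  invisible(x)
}

n_positions <- function(design) length(design$positions)

freq_matrix <- function(design) {
  mat <- matrix(0, nrow = length(AA20), ncol = n_positions(design),
                dimnames = list(AA20,
                                vapply(design$positions,
                                       function(p) p$position_label, "")))
  for (j in seq_along(design$positions)) {
    f <- design$positions[[j]]$freq
    mat[names(f), j] <- f
  }
  mat
}

#' Validate a CDR design against its constraint profile
#'
#' Checks the compositional rules of the design's constraint profile and
#' returns a report of violations; it never throws. Rules: frequencies sum
#' to 1 per position (all profiles); hydrophobic residues (V, I, L, M, F)
#' at most 0.25 summed per position (CDR2/CDR3); CDR2: exactly 4 positions,
#' no positively charged residues (K, R, H); CDR3: exactly 7 positions, a
#' fixed FDY right flank completing a 10-residue loop, and zero frequency
#' for C, I, M and K everywhere.
#'
#' @param design a [cdr_design()].
#' @return data.frame with columns `rule`, `position`, `value`, `message`;
#'   zero rows iff the design is valid.
#' @export
validate_design <- function(design) {
  v <- list()
  add <- function(rule, position, value, message) {
    v[[length(v) + 1L]] <<- data.frame(rule = rule, position = position,
                                       value = value, message = message,
                                       stringsAsFactors = FALSE)
  }
  for (p in design$positions) {
    s <- sum(p$freq)
    if (abs(s - 1) > 1e-9) {
      add("normalized", p$position_label, s, "frequencies do not sum to 1")
    }
  }
  profile <- design$constraint_profile
  if (profile %in% c("CDR2", "CDR3")) {
    for (p in design$positions) {
      h <- sum(p$freq[intersect(names(p$freq), HYDROPHOBIC)])
      if (h > 0.25 + 1e-9) {
        add("hydrophobic_cap", p$position_label, h,
            "summed V/I/L/M/F frequency exceeds 0.25")
      }
    }
  }
  if (profile == "CDR2") {
    if (n_positions(design) != 4L) {
      add("n_positions", design$name, n_positions(design),
          "CDR2 profile requires exactly 4 randomized positions")
    }
    for (p in design$positions) {
      pos <- sum(p$freq[intersect(names(p$freq), POSITIVE)])
      if (pos > 1e-12) {
        add("no_positive_charge", p$position_label, pos,
            "positively charged residues present in CDR2")
      }
    }
  }
  if (profile == "CDR3") {
    if (n_positions(design) != 7L) {
      add("n_positions", design$name, n_positions(design),
          "CDR3 profile requires exactly 7 randomized positions")
    }
    loop_len <- n_positions(design) + nchar(design$fixed_flanks$right)
    if (design$fixed_flanks$right != "FDY" || loop_len != 10L) {
      add("fdy_tail", design$name, loop_len,
          "CDR3 loop must be 10 residues ending in fixed FDY")
    }
    for (p in design$positions) {
      for (aa in c("C", "I", "M", "K")) {
        val <- if (aa %in% names(p$freq)) p$freq[[aa]] else 0
        if (val > 1e-12) {
          add(paste0("excluded_", aa), p$position_label, val,
              paste0(aa, " must have zero frequency in CDR3"))
        }
      }
    }
  }
  if (length(v) == 0L) {
    return(data.frame(rule = character(), position = character(),
                      value = numeric(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

#' Default illustrative CDR2 design
#'
#' Four randomized positions biased toward Tyr/Ser/Gly (binding-favourable),
#' no positively charged residues, hydrophobics well under the 25% cap.
#' These numbers are an illustrative default satisfying the design rules,
#' not a published table; supply your own via [read_frequency_csv()] or
#' [read_frequency_json()].
#'
#' @return A [cdr_design()] with the `"CDR2"` profile.
#' @export
default_cdr2_design <- function() {
  base <- c(Y = 0.20, S = 0.20, G = 0.15, D = 0.10, N = 0.10,
            T = 0.10, A = 0.05, W = 0.05, L = 0.03, V = 0.02)
  tweak <- list(
    c(),                                  # pos 1: base
    c(S = 0.25, G = 0.20, Y = 0.10),      # pos 2: small/flexible
    c(D = 0.15, N = 0.12, T = 0.08),      # pos 3: polar
    c()                                   # pos 4: base
  )
  positions <- lapply(seq_along(tweak), function(j) {
    f <- base
    f[names(tweak[[j]])] <- tweak[[j]]
    f <- f / sum(f)
    position_frequency(paste0("CDR2.", j), f)
  })
  cdr_design("CDR2", positions,
             fixed_flanks = list(left = "AIS", right = "STY"),
             constraint_profile = "CDR2")
}

#' Default illustrative CDR3 design
#'
#' Seven randomized positions inside a 10-residue loop ending in the fixed
#' FDY tail. Cys, Ile, Met and Lys are excluded everywhere; Arg and His are
#' kept at very low frequency; hydrophobics are capped below 25%; Ala is
#' omitted in favour of Ser/Gly flexibility. Illustrative default, not a
#' published table.
#'
#' @return A [cdr_design()] with the `"CDR3"` profile.
#' @export
default_cdr3_design <- function() {
  base <- c(Y = 0.15, S = 0.15, G = 0.15, D = 0.10, N = 0.08, T = 0.08,
            Q = 0.05, E = 0.05, W = 0.04, P = 0.04, H = 0.03, R = 0.02,
            V = 0.03, L = 0.02, F = 0.01)
  tweak <- list(
    c(G = 0.20, S = 0.18, Y = 0.07),      # pos 1: loop entry, flexible
    c(),                                  # pos 2: base
    c(Y = 0.18, W = 0.06, F = 0.02),      # pos 3: aromatic-leaning
    c(),                                  # pos 4: base
    c(D = 0.14, E = 0.07, N = 0.10),      # pos 5: acidic-leaning
    c(),                                  # pos 6: base
    c(S = 0.20, G = 0.18, P = 0.06)       # pos 7: pre-tail, flexible
  )
  positions <- lapply(seq_along(tweak), function(j) {
    f <- base
    f[names(tweak[[j]])] <- tweak[[j]]
    f <- f / sum(f)
    position_frequency(paste0("CDR3.", j), f)
  })
  cdr_design("CDR3", positions,
             fixed_flanks = list(left = "", right = "FDY"),
             constraint_profile = "CDR3")
}

#' Probability of one clone sequence under a design
#'
#' The product over randomized positions of the designed frequency of the
#' residue found there; 0 if any residue is outside the design's support.
#'
#' @param design a [cdr_design()].
#' @param sequence residue string over the randomized positions only (length
#'   must equal the number of randomized positions).
#' @return Probability in `[0, 1]`.
#' @examples
#' clone_probability(default_cdr3_design(), "YSGDNTS")
#' @export
clone_probability <- function(design, sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) != n_positions(design)) {
    stop("sequence length ", nchar(sequence), " != ",
         n_positions(design), " randomized positions")
  }
  res <- strsplit(sequence, "")[[1]]
  prod(vapply(seq_along(res), function(j) {
    f <- design$positions[[j]]$freq
    if (res[j] %in% names(f)) f[[res[j]]] else 0
  }, 1.0))
}

#' Theoretical diversity of a design
#'
#' Number of distinct sequences with nonzero probability: the product over
#' positions of the number of residues with nonzero frequency.
#'
#' @param design a [cdr_design()].
#' @return Count (double, since products can exceed integer range).
#' @export
theoretical_diversity <- function(design) {
  prod(vapply(design$positions, function(p) sum(p$freq > 0), 1.0))
}

#' Most common / rarest clone probability
#'
#' Product over positions of the maximum (resp. minimum nonzero) designed
#' frequency. The reciprocal is the expected "one clone in N" spacing of
#' that sequence in the library.
#'
#' @param design a [cdr_design()].
#' @param mode `"most_common"` or `"rarest"`.
#' @return Probability.
#' @seealso [one_in_n()]
#' @export
extreme_probability <- function(design, mode = c("most_common", "rarest")) {
  mode <- match.arg(mode)
  prod(vapply(design$positions, function(p) {
    f <- p$freq[p$freq > 0]
    if (mode == "most_common") max(f) else min(f)
  }, 1.0))
}

#' "One in N" report for a clone probability
#'
#' @param p probability > 0.
#' @param digits significant figures (default 3, matching the convention of
#'   reporting e.g. 2.43e8).
#' @return N = `signif(1/p, digits)`.
#' @export
one_in_n <- function(p, digits = 3) {
  stopifnot(p > 0)
  signif(1 / p, digits)
}

#' Combined rarity of two independent cassettes
#'
#' If the most common CDR2 combination occurs once per `n2` clones and the
#' most common CDR3 combination once per `n3` clones, and the two cassettes
#' are ligated independently, the most common combined clone occurs once per
#' `n2 * n3` clones (reported to 3 significant figures).
#'
#' @param n2,n3 clones-per-occurrence for the two cassettes (both >= 1).
#' @return `signif(n2 * n3, 3)`.
#' @examples
#' combined_rarity(334, 727000)  # 2.43e8
#' @export
combined_rarity <- function(n2, n3) {
  stopifnot(n2 >= 1, n3 >= 1)
  signif(n2 * n3, 3)
}

#' Compile a trinucleotide oligo specification
#'
#' Assigns exactly one codon per allowed amino acid at each randomized
#' position (the codon-choice rule: highest usage in `codon_choice`, never a
#' stop), with mixing fractions equal to the designed amino-acid
#' frequencies, and constant flanking DNA that carries the cassette
#' restriction sites verbatim around the back-translated fixed flank
#' residues.
#'
#' @param design a [cdr_design()].
#' @param codon_choice a [codon_table()].
#' @param left_site,right_site [restriction_site()]s (or enzyme names) to
#'   embed verbatim in the constant flanks.
#' @return An object of class `trimer_oligo_spec`: list with `positions`
#'   (per position: data.frame `aa`, `codon`, `fraction`), `left_flank`,
#'   `right_flank`.
#' @export
compile_oligo_spec <- function(design, codon_choice = codon_table_ecoli(),
                               left_site = NULL, right_site = NULL) {
  issues <- validate_design(design)
  if (nrow(issues)) {
    stop("design is invalid: ", paste(unique(issues$message), collapse = "; "))
  }
  stops <- c("TAA", "TAG", "TGA")
  positions <- lapply(design$positions, function(p) {
    f <- p$freq[p$freq > 0]
    codons <- vapply(names(f), function(aa) codons_for(codon_choice, aa)[1], "")
    if (any(codons %in% stops)) stop("stop codon selected at ", p$position_label)
    data.frame(aa = names(f), codon = unname(codons), fraction = unname(f),
               stringsAsFactors = FALSE)
  })
  names(positions) <- vapply(design$positions, function(p) p$position_label, "")
  flank_dna <- function(res, site, side) {
    dna <- if (nchar(res)) back_translate(res, codon_choice) else ""
    if (is.null(site)) return(dna)
    if (is.character(site)) site <- restriction_enzymes(site)
    if (side == "left") paste0(site$recognition, dna) else paste0(dna, site$recognition)
  }
  structure(list(
    design_name = design$name,
    positions = positions,
    left_flank = flank_dna(design$fixed_flanks$left, left_site, "left"),
    right_flank = flank_dna(design$fixed_flanks$right, right_site, "right")
  ), class = "trimer_oligo_spec")
}

#' @export
print.trimer_oligo_spec <- function(x, ...) {
  cat(sprintf("<trimer_oligo_spec> %s: %d randomized positions\n",
              x$design_name, length(x$positions)))
  cat("  5' flank:", x$left_flank, "\n")
  for (nm in names(x$positions)) {
    p <- x$positions[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                paste(sprintf("%s(%s)=%.3f", p$aa, p$codon, p$fraction),
                      collapse = " ")))
  }
  cat("  3' flank:", x$right_flank, "\n")
  invisible(x)
}

#' Assemble the DNA insert for one clone
#'
#' Concatenates the oligo spec's flanks with the per-position trimer codons
#' of the given randomized-residue sequence.
#'
#' @param spec a `trimer_oligo_spec`.
#' @param sequence residue string over the randomized positions.
#' @return DNA string.
#' @export
assemble_insert <- function(spec, sequence) {
  res <- strsplit(toupper(sequence), "")[[1]]
  stopifnot(length(res) == length(spec$positions))
  trimers <- vapply(seq_along(res), function(j) {
    p <- spec$positions[[j]]
    i <- match(res[j], p$aa)
    if (is.na(i)) stop("residue ", res[j], " not in support of position ",
                       names(spec$positions)[j])
    p$codon[i]
  }, "")
  paste0(spec$left_flank, paste(trimers, collapse = ""), spec$right_flank)
}
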