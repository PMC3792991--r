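#' Codon usage tables
#'
#' A codon table maps each amino acid (1-letter code, `*` for stop) to its
#' codons and their within-amino-acid usage fractions. Usage fractions per
#' amino acid must sum to 1. Codons whose usage fraction falls below
#' `rare_threshold` are treated as rare and avoided during back-translation
#' unless needed to satisfy a motif constraint.
#'
#' @param x data.frame with columns `aa`, `codon`, `weight`.
#' @param rare_threshold within-amino-acid usage fraction below which a codon
#'   counts as rare. Default 0.10.
#' @return An object of class `codon_table` (a data.frame).
#' @examples
#' tab <- codon_table_ecoli()
#' head(tab)
#' @export
codon_table <- function(x, rare_threshold = 0.10) {
  stopifnot(is.data.frame(x), all(c("aa", "codon", "weight") %in% names(x)))
  x$aa <- toupper(x$aa)
  x$codon <- toupper(x$codon)
  bad <- x$codon[Biostrings::GENETIC_CODE[x$codon] != x$aa]
  if (length(bad) || anyNA(Biostrings::GENETIC_CODE[x$codon])) {
    stop("codons do not translate to their amino acid: ",
         paste(unique(bad), collapse = ", "))
  }
  sums <- tapply(x$weight, x$aa, sum)
  off <- sums[abs(sums - 1) > 1e-9]
  if (length(off)) {
    stop("usage weights do not sum to 1 for: ", paste(names(off), collapse = ", "))
  }
  # deterministic order: descending weight, then alphabetical codon
  x <- x[order(x$aa, -x$weight, x$codon), , drop = FALSE]
  rownames(x) <- NULL
  structure(x, class = c("codon_table", "data.frame"),
            rare_threshold = rare_threshold)
}

#' @describeIn codon_table Built-in Escherichia coli K-12 usage table
#'   (within-amino-acid fractions, rounded; renormalized to sum exactly to 1).
#' @export
codon_table_ecoli <- function(rare_threshold = 0.10) {
  raw <- list(
    A = c(GCG = 0.36, GCC = 0.27, GCA = 0.21, GCT = 0.16),
    R = c(CGC = 0.40, CGT = 0.38, CGG = 0.10, CGA = 0.06, AGA = 0.04, AGG = 0.02),
    N = c(AAC = 0.55, AAT = 0.45),
    D = c(GAT = 0.63, GAC = 0.37),
    C = c(TGC = 0.55, TGT = 0.45),
    Q = c(CAG = 0.65, CAA = 0.35),
    E = c(GAA = 0.69, GAG = 0.31),
    G = c(GGC = 0.40, GGT = 0.34, GGG = 0.15, GGA = 0.11),
    H = c(CAT = 0.57, CAC = 0.43),
    I = c(ATT = 0.51, ATC = 0.42, ATA = 0.07),
    L = c(CTG = 0.50, TTA = 0.13, TTG = 0.13, CTC = 0.10, CTT = 0.10, CTA = 0.04),
    K = c(AAA = 0.76, AAG = 0.24),
    M = c(ATG = 1.00),
    F = c(TTT = 0.57, TTC = 0.43),
    P = c(CCG = 0.52, CCA = 0.19, CCT = 0.16, CCC = 0.13),
    S = c(AGC = 0.28, TCC = 0.15, TCG = 0.15, TCT = 0.15, AGT = 0.15, TCA = 0.12),
    T = c(ACC = 0.44, ACG = 0.26, ACT = 0.17, ACA = 0.13),
    W = c(TGG = 1.00),
    Y = c(TAT = 0.57, TAC = 0.43),
    V = c(GTG = 0.37, GTT = 0.26, GTC = 0.20, GTA = 0.17),
    "*" = c(TAA = 0.64, TGA = 0.29, TAG = 0.07)
  )
  df <- do.call(rbind, lapply(names(raw), function(aa) {
    w <- raw[[aa]] / sum(raw[[aa]])
    data.frame(aa = aa, codon = names(w), weight = unname(w))
  }))
  codon_table(df, rare_threshold = rare_threshold)
}

#' Read a codon table from TSV
#'
#' Expects tab-separated columns `aa`, `codon`, `weight`.
#'
#' @param path file path.
#' @inheritParams codon_table
#' @return A `codon_table`.
#' @export
read_codon_table <- function(path, rare_threshold = 0.10) {
  codon_table(utils::read.delim(path, stringsAsFactors = FALSE),
              rare_threshold = rare_threshold)
}

#' Codons available for one amino acid
#'
#' @param table a `codon_table`.
#' @param aa single amino-acid letter.
#' @param include_rare if `FALSE`, codons below the table's rare threshold are
#'   dropped (unless all codons of the amino acid are rare).
#' @return Character vector of codons, highest usage first.
#' @export
codons_for <- function(table, aa, include_rare = TRUE) {
  rows <- table[table$aa == toupper(aa), , drop = FALSE]
  if (nrow(rows) == 0L) stop("no codons for amino acid '", aa, "'")
  if (!include_rare) {
    keep <- rows$weight >= attr(table, "rare_threshold")
    if (any(keep)) rows <- rows[keep, , drop = FALSE]
  }
  rows$codon
}

#' Translate a DNA coding sequence
#'
#' @param dna DNA string; length must be a multiple of 3.
#' @return Amino-acid string (standard genetic code; `*` for stop).
#' @export
translate_dna <- function(dna) {
  dna <- toupper(dna)
  stopifnot(nchar(dna) %% 3 == 0)
  if (nchar(dna) == 0L) return("")
  codons <- substring(dna, seq(1, nchar(dna), 3), seq(3, nchar(dna), 3))
  paste(Biostrings::GENETIC_CODE[codons], collapse = "")
}
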