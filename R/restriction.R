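IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

iupac_base_match <- function(base, code) {
  base %in% IUPAC_SETS[[code]]
}

# does concrete sequence `x` match IUPAC pattern `pat` (equal lengths)?
iupac_seq_match <- function(x, pat) {
  xs <- strsplit(toupper(x), "")[[1]]
  ps <- strsplit(toupper(pat), "")[[1]]
  length(xs) == length(ps) && all(mapply(iupac_base_match, xs, ps))
}

reverse_complement <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

#' Restriction site definition
#'
#' @param enzyme_name enzyme name, e.g. `"SacI"`.
#' @param recognition recognition sequence over the IUPAC DNA alphabet.
#' @return An object of class `restriction_site`.
#' @examples
#' restriction_site("EcoRI", "GAATTC")
#' @export
restriction_site <- function(enzyme_name, recognition) {
  recognition <- toupper(recognition)
  chars <- strsplit(recognition, "")[[1]]
  if (length(chars) == 0L || !all(chars %in% names(IUPAC_SETS))) {
    stop("recognition sequence must be non-empty IUPAC DNA: ", recognition)
  }
  structure(list(enzyme_name = enzyme_name, recognition = recognition,
                 length = nchar(recognition)),
            class = "restriction_site")
}

#' @export
print.restriction_site <- function(x, ...) {
  cat(sprintf("<restriction_site> %s  %s (%d nt)\n",
              x$enzyme_name, x$recognition, x$length))
  invisible(x)
}

#' Built-in restriction enzymes
#'
#' Recognition sequences for the enzymes used in the modular dAb scaffold
#' (SacI/XhoI flank the CDR2 cassette, PstI/KpnI the CDR3 cassette,
#' SapI/Mva1269I the whole gene) plus a few common cloning enzymes.
#'
#' @param name optional enzyme name; if given, returns that single
#'   [restriction_site()].
#' @return A data.frame (`name`, `recognition`), or a `restriction_site`.
#' @export
restriction_enzymes <- function(name = NULL) {
  tab <- data.frame(
    name = c("SacI", "XhoI", "PstI", "KpnI", "SapI", "Mva1269I",
             "EcoRI", "NcoI", "NotI", "BamHI", "HindIII"),
    recognition = c("GAGCTC", "CTCGAG", "CTGCAG", "GGTACC", "GCTCTTC",
                    "GAATGC", "GAATTC", "CCATGG", "GCGGCCGC", "GGATCC",
                    "AAGCTT"),
    stringsAsFactors = FALSE
  )
  if (is.null(name)) return(tab)
  i <- match(name, tab$name)
  if (is.na(i)) stop("unknown enzyme '", name, "'; supply a TSV via read_enzyme_table()")
  restriction_site(tab$name[i], tab$recognition[i])
}

#' Read enzyme definitions from TSV
#'
#' Tab-separated columns `name`, `recognition`; overrides/extends the
#' built-in table.
#'
#' @param path file path.
#' @return data.frame with columns `name`, `recognition`.
#' @export
read_enzyme_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "recognition") %in% names(tab)))
  for (r in tab$recognition) restriction_site("x", r)  # validate alphabet
  tab
}

#' Count restriction-site occurrences
#'
#' IUPAC-aware scan of both strands. In circular mode the origin-spanning
#' junction (length `site$length - 1`) is also scanned. A site matching at
#' one offset on both strands (a palindrome) is counted once.
#'
#' @param vector_dna DNA string (concrete A/C/G/T).
#' @param site a [restriction_site()] or enzyme name.
#' @param circular treat `vector_dna` as circular.
#' @return Integer count of distinct match offsets.
#' @examples
#' count_site_occurrences("GAATTCAAGAATTC", restriction_enzymes("EcoRI"))
#' @export
count_site_occurrences <- function(vector_dna, site, circular = FALSE) {
  if (is.character(site)) site <- restriction_enzymes(site)
  dna <- toupper(vector_dna)
  stopifnot(nchar(dna) > 0)
  L <- site$length
  n <- nchar(dna)
  subject <- if (circular && n >= 2) {
    paste0(dna, substr(dna, 1, min(L - 1, n)))
  } else {
    dna
  }
  offs <- function(pattern) {
    if (nchar(subject) < nchar(pattern)) return(integer(0))
    m <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                  Biostrings::DNAString(subject),
                                  fixed = FALSE)
    Biostrings::start(m)
  }
  hits <- union(offs(site$recognition), offs(reverse_complement(site$recognition)))
  if (circular) hits <- unique((hits - 1L) %% n + 1L)
  length(hits[hits <= n])
}
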