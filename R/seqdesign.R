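# Motif check used during back-translation: does any forbidden motif occur
# on either strand of `dna`?  Returns the first offending motif or NULL.
find_forbidden <- function(dna, forbidden_motifs) {
  for (m in forbidden_motifs) {
    if (grepl(m, dna, fixed = TRUE)) return(m)
    rc <- reverse_complement(m)
    if (grepl(rc, dna, fixed = TRUE)) return(m)
  }
  NULL
}

#' Back-translate a protein to DNA under codon preferences
#'
#' Chooses, per residue, the highest-usage codon that is not rare (below the
#' table's rare threshold), falling back to lower-ranked or rare codons only
#' when needed to avoid a forbidden motif on either strand. The search is a
#' depth-first backtracking walk over codon choices, so the result is
#' deterministic for a given table and motif set.
#'
#' @param protein amino-acid string (20-letter alphabet).
#' @param table a [codon_table()]; default [codon_table_ecoli()].
#' @param forbidden_motifs character vector of concrete DNA motifs that must
#'   not occur on either strand of the output.
#' @return DNA string whose translation equals `protein`.
#' @examples
#' back_translate("MKV")
#' @export
back_translate <- function(protein, table = codon_table_ecoli(),
                           forbidden_motifs = character()) {
  protein <- toupper(protein)
  stopifnot(nchar(protein) > 0)
  residues <- strsplit(protein, "")[[1]]
  if (any(residues == "*")) stop("protein contains a stop symbol")
  forbidden_motifs <- toupper(forbidden_motifs)
  maxlen <- if (length(forbidden_motifs)) max(nchar(forbidden_motifs)) else 0L

  # candidate codons per residue: non-rare first (by usage), then rare
  cand <- lapply(residues, function(aa) {
    non_rare <- codons_for(table, aa, include_rare = FALSE)
    all_c <- codons_for(table, aa, include_rare = TRUE)
    c(non_rare, setdiff(all_c, non_rare))
  })

  n <- length(residues)
  choice <- integer(n)
  i <- 1L
  deepest <- 0L
  prefix <- character(n + 1L)
  prefix[1L] <- ""
  while (i >= 1L && i <= n) {
    choice[i] <- choice[i] + 1L
    if (choice[i] > length(cand[[i]])) {
      choice[i] <- 0L
      i <- i - 1L
      next
    }
    trial <- paste0(prefix[i], cand[[i]][choice[i]])
    # only the tail can contain a newly created motif
    tail_len <- min(nchar(trial), maxlen + 2L)
    tail_seq <- substr(trial, nchar(trial) - tail_len + 1L, nchar(trial))
    if (is.null(find_forbidden(tail_seq, forbidden_motifs))) {
      prefix[i + 1L] <- trial
      deepest <- max(deepest, i)
      i <- i + 1L
    }
  }
  if (i < 1L) {
    win <- substr(protein, max(1L, deepest - 3L), min(n, deepest + 1L))
    stop("cannot satisfy motif constraints near residue ", deepest + 1L,
         " (window '", win, "')")
  }
  dna <- prefix[n + 1L]
  stopifnot(translate_dna(dna) == protein)
  dna
}

# 1-based codon index containing nucleotide position p (frame = 0 means the
# coding frame starts at position 1)
codon_index <- function(p, frame = 0L) (p - 1L - frame) %/% 3L + 1L

#' Find silent placements of a restriction site
#'
#' Enumerates, for every offset of the recognition sequence inside `window`,
#' all synonymous codon combinations of the codons the site overlaps, and
#' returns the minimum-substitution synonymous placement per feasible offset.
#' Placements are sorted by (number of substitutions, offset); ties among
#' equal-cost codon assignments are broken deterministically (codon usage
#' order). All coordinates are 1-based inclusive.
#'
#' @param dna in-frame coding DNA (frame starts at position 1).
#' @param site a [restriction_site()] or enzyme name.
#' @param window integer length-2 vector `c(start, end)` of the nucleotide
#'   range in which the recognition sequence must fit entirely.
#' @param table a [codon_table()] giving the synonymous codons to consider.
#' @return list of `site_placement` objects (possibly empty): each has
#'   `offset`, `substitutions` (data.frame `position`, `from`, `to`),
#'   `enzyme`, `recognition`.
#' @examples
#' find_silent_site_placements("CTGGAG", restriction_enzymes("XhoI"), c(1, 6))
#' @export
find_silent_site_placements <- function(dna, site, window,
                                        table = codon_table_ecoli()) {
  if (is.character(site)) site <- restriction_enzymes(site)
  dna <- toupper(dna)
  stopifnot(nchar(dna) %% 3 == 0, length(window) == 2)
  window <- as.integer(window)
  stopifnot(window[1] >= 1, window[2] <= nchar(dna))
  L <- site$length
  if (window[2] - window[1] + 1L < L) {
    stop("window (", window[1], ":", window[2], ") shorter than site length ", L)
  }
  protein <- translate_dna(dna)
  if (grepl("*", protein, fixed = TRUE)) stop("dna contains an internal stop codon")
  residues <- strsplit(protein, "")[[1]]

  placements <- list()
  for (off in window[1]:(window[2] - L + 1L)) {
    c1 <- codon_index(off)
    c2 <- codon_index(off + L - 1L)
    idx <- c1:c2
    cand <- lapply(idx, function(ci) codons_for(table, residues[ci]))
    grid <- expand.grid(rev(cand), stringsAsFactors = FALSE)[, length(idx):1, drop = FALSE]
    region_start <- (c1 - 1L) * 3L + 1L
    orig_region <- substr(dna, region_start, c2 * 3L)
    best <- NULL
    for (r in seq_len(nrow(grid))) {
      region <- paste(unlist(grid[r, ]), collapse = "")
      seg <- substr(region, off - region_start + 1L, off - region_start + L)
      if (!iupac_seq_match(seg, site$recognition)) next
      subs <- which(strsplit(region, "")[[1]] != strsplit(orig_region, "")[[1]])
      if (is.null(best) || length(subs) < best$n) {
        best <- list(region = region, subs = subs, n = length(subs))
      }
    }
    if (!is.null(best)) {
      pos <- region_start + best$subs - 1L
      subs_df <- if (length(pos)) {
        data.frame(position = pos,
                   from = substring(dna, pos, pos),
                   to = substring(best$region, best$subs, best$subs),
                   stringsAsFactors = FALSE)
      } else {
        data.frame(position = integer(), from = character(), to = character(),
                   stringsAsFactors = FALSE)
      }
      placements[[length(placements) + 1L]] <- structure(
        list(offset = off,
             substitutions = subs_df,
             enzyme = site$enzyme_name,
             recognition = site$recognition),
        class = "site_placement")
    }
  }
  ord <- order(vapply(placements, function(p) nrow(p$substitutions), 1L),
               vapply(placements, function(p) p$offset, 1L))
  placements[ord]
}

#' @export
print.site_placement <- function(x, ...) {
  cat(sprintf("<site_placement> %s (%s) at %d; %d substitution(s)\n",
              x$enzyme, x$recognition, x$offset, nrow(x$substitutions)))
  if (nrow(x$substitutions)) {
    apply(x$substitutions, 1, function(s)
      cat(sprintf("  %s>%s at %s\n", s[["from"]], s[["to"]], s[["position"]])))
  }
  invisible(x)
}

#' Apply a silent site placement to a DNA sequence
#'
#' @param dna DNA string.
#' @param placement a `site_placement` from [find_silent_site_placements()].
#' @return The edited DNA string; translation is unchanged.
#' @export
apply_placement <- function(dna, placement) {
  dna <- toupper(dna)
  subs <- placement$substitutions
  if (nrow(subs) == 0L) return(dna)
  have <- substring(dna, subs$position, subs$position)
  bad <- which(have != subs$from)
  if (length(bad)) {
    stop("placement inconsistent with sequence at position ",
         subs$position[bad[1]], " (expected ", subs$from[bad[1]],
         ", found ", have[bad[1]], ")")
  }
  chars <- strsplit(dna, "")[[1]]
  chars[subs$position] <- subs$to
  paste(chars, collapse = "")
}

#' Scaffold specification
#'
#' A protein sequence tiled exactly by labelled regions (frameworks FR1-FR4
#' and CDR1-CDR3), plus the cassette enzymes to be engineered at region
#' boundaries.
#'
#' @param protein_sequence amino-acid string.
#' @param regions data.frame `label`, `start`, `end` (1-based inclusive,
#'   residue coordinates) tiling the protein without gaps or overlap.
#' @param cassette_sites data.frame `enzyme`, `boundary` where `boundary` is a
#'   residue position: the enzyme's recognition site is placed silently in a
#'   window of codons centred on that boundary.
#' @return An object of class `scaffold_spec`.
#' @export
scaffold_spec <- function(protein_sequence, regions, cassette_sites) {
  protein_sequence <- toupper(protein_sequence)
  regions <- regions[order(regions$start), , drop = FALSE]
  n <- nchar(protein_sequence)
  if (regions$start[1] != 1L || regions$end[nrow(regions)] != n ||
      (nrow(regions) > 1 && any(regions$start[-1] != regions$end[-nrow(regions)] + 1L))) {
    stop("regions must tile the protein exactly")
  }
  structure(list(protein_sequence = protein_sequence, regions = regions,
                 cassette_sites = cassette_sites),
            class = "scaffold_spec")
}

#' @export
print.scaffold_spec <- function(x, ...) {
  cat("<scaffold_spec>", nchar(x$protein_sequence), "aa;",
      nrow(x$regions), "regions;", nrow(x$cassette_sites), "cassette sites\n")
  print(x$regions, row.names = FALSE)
  invisible(x)
}

#' Region boundaries of a scaffold
#'
#' @param spec a [scaffold_spec()].
#' @param label region label.
#' @return c(start, end) residue coordinates.
#' @export
region_range <- function(spec, label) {
  i <- match(label, spec$regions$label)
  if (is.na(i)) stop("no region '", label, "'")
  c(spec$regions$start[i], spec$regions$end[i])
}

#' Example single-domain antibody scaffold
#'
#' An illustrative VH3-type domain-antibody scaffold: germline-style
#' frameworks, a CDR1 carrying the solubilising Asp residues typical of
#' aggregation-resistant dAbs, a CDR2 with four positions to randomize and a
#' 10-residue CDR3 ending in the FDY motif with seven positions to randomize.
#' Residues adjacent to the CDR boundaries were chosen so each cassette
#' enzyme has an in-frame synonymous anchor (Leu-Glu for XhoI, Glu-Leu for
#' SacI, Leu-Gln for PstI, Gly-Thr for KpnI). Cassette enzymes: XhoI/SacI
#' around CDR2, PstI/KpnI around CDR3.
#'
#' @return A [scaffold_spec()].
#' @export
example_scaffold <- function() {
  fr1 <- "EVQLLESGGGLVQPGGSLRLSCAAS"   # 25
  cdr1 <- "GFDFDEDMS"                  # 9  (DED triad; D replacing the upper-core Ile)
  fr2 <- "WVRQAPGKGLEWVS"              # 14 (LE -> XhoI anchor)
  cdr2 <- "AISGSGGSTY"                 # 10 (4 of these randomized in the library)
  fr3 <- "ELDSVKGRFTISRDNSKNTLYLQMNSLRAEDTAVYYCALQ"  # 40 (EL/LQ anchors)
  cdr3 <- "SGSYGSSFDY"                 # 10 (7 randomized + fixed FDY tail)
  fr4 <- "WGQGTLVTVSS"                 # 11 (GT -> KpnI anchor)
  parts <- c(FR1 = fr1, CDR1 = cdr1, FR2 = fr2, CDR2 = cdr2,
             FR3 = fr3, CDR3 = cdr3, FR4 = fr4)
  ends <- cumsum(nchar(parts))
  regions <- data.frame(label = names(parts),
                        start = c(1L, head(ends, -1) + 1L),
                        end = ends, stringsAsFactors = FALSE)
  cdr2r <- c(regions$start[4], regions$end[4])
  cdr3r <- c(regions$start[6], regions$end[6])
  sites <- data.frame(
    enzyme = c("XhoI", "SacI", "PstI", "KpnI"),
    boundary = c(cdr2r[1], cdr2r[2] + 1L, cdr3r[1], cdr3r[2] + 1L),
    stringsAsFactors = FALSE
  )
  scaffold_spec(paste(parts, collapse = ""), regions, sites)
}

#' Engineer cassette restriction sites into a scaffold gene
#'
#' Back-translates the scaffold protein with all cassette (and flank) sites
#' forbidden, then introduces each cassette site by the cheapest synonymous
#' placement within a window of `flank_codons` codons either side of its
#' declared boundary. A candidate placement is rejected if applying it would
#' leave any engineered enzyme with more than one occurrence on the full
#' construct (5' flank + gene + 3' flank, both strands, IUPAC-aware).
#'
#' @param spec a [scaffold_spec()].
#' @param table a [codon_table()].
#' @param flank5,flank3 constant flanking DNA; the defaults carry the SapI and
#'   Mva1269I sites used to clone the whole gene.
#' @param flank_codons half-width, in codons, of the placement window.
#' @return list with `gene` (engineered CDS), `construct`
#'   (`flank5 + gene + flank3`), `placements`, `flank5`, `flank3`,
#'   `enzymes` (all engineered enzyme names, including flank enzymes).
#' @examples
#' \donttest{
#' eng <- engineer_scaffold(example_scaffold())
#' sapply(eng$enzymes, function(e) count_site_occurrences(eng$construct, e))
#' }
#' @export
engineer_scaffold <- function(spec, table = codon_table_ecoli(),
                              flank5 = "TTCTGCTCTTCGGCC",
                              flank3 = "GGCAGAATGCAGTT",
                              flank_codons = 5L) {
  flank_enzymes <- c("SapI", "Mva1269I")
  enzymes <- c(spec$cassette_sites$enzyme, flank_enzymes)
  recs <- vapply(enzymes, function(e) restriction_enzymes(e)$recognition, "")
  gene <- back_translate(spec$protein_sequence, table, forbidden_motifs = recs)

  n_aa <- nchar(spec$protein_sequence)
  placements <- list()
  for (k in seq_len(nrow(spec$cassette_sites))) {
    enz <- spec$cassette_sites$enzyme[k]
    b <- spec$cassette_sites$boundary[k]
    lo_codon <- max(1L, b - flank_codons)
    hi_codon <- min(n_aa, b + flank_codons)
    window <- c((lo_codon - 1L) * 3L + 1L, hi_codon * 3L)
    cands <- find_silent_site_placements(gene, enz, window, table)
    placed <- FALSE
    for (p in cands) {
      trial_gene <- apply_placement(gene, p)
      trial_construct <- paste0(flank5, trial_gene, flank3)
      counts <- vapply(seq_along(enzymes), function(j) {
        count_site_occurrences(trial_construct, restriction_enzymes(enzymes[j]))
      }, 1L)
      expected <- ifelse(enzymes %in% c(spec$cassette_sites$enzyme[seq_len(k)],
                                        flank_enzymes), 1L, 0L)
      if (all(counts == expected)) {
        gene <- trial_gene
        placements[[enz]] <- p
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("no admissible silent placement for ", enz, " near residue ", b)
    }
  }
  list(gene = gene, construct = paste0(flank5, gene, flank3),
       placements = placements, flank5 = flank5, flank3 = flank3,
       enzymes = enzymes)
}
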