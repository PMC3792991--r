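#' Read a frequency design from CSV
#'
#' CSV layout: first column `aa` (one-letter residues), remaining columns one
#' per randomized position; cells are frequencies (blank/0 = absent).
#'
#' @param path CSV file.
#' @param name design name.
#' @param constraint_profile passed to [cdr_design()].
#' @param fixed_flanks passed to [cdr_design()].
#' @return A [cdr_design()].
#' @export
read_frequency_csv <- function(path, name = "design",
                               constraint_profile = "none",
                               fixed_flanks = list(left = "", right = "")) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(names(tab)[1] == "aa")
  positions <- lapply(names(tab)[-1], function(col) {
    f <- tab[[col]]
    f[is.na(f)] <- 0
    keep <- f > 0
    position_frequency(col, setNames(f[keep], tab$aa[keep]))
  })
  cdr_design(name, positions, fixed_flanks = fixed_flanks,
             constraint_profile = constraint_profile)
}

#' Write a frequency design to CSV
#'
#' @param design a [cdr_design()].
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_frequency_csv <- function(design, path) {
  mat <- freq_matrix(design)
  df <- data.frame(aa = rownames(mat), mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a frequency design as JSON
#'
#' JSON layout: object with `name`, `constraint_profile`, `fixed_flanks`
#' (`left`, `right`) and `positions` (array of `{label, freq: {aa: p}}`).
#'
#' @param path JSON file.
#' @return [read_frequency_json()] returns a [cdr_design()].
#' @export
read_frequency_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  positions <- lapply(seq_len(nrow(obj$positions)), function(i) {
    f <- unlist(obj$positions$freq[i, , drop = TRUE])
    f <- f[!is.na(f) & f > 0]
    position_frequency(obj$positions$label[i], f)
  })
  cdr_design(obj$name, positions,
             fixed_flanks = as.list(obj$fixed_flanks),
             constraint_profile = obj$constraint_profile)
}

#' @rdname read_frequency_json
#' @param design a [cdr_design()].
#' @export
write_frequency_json <- function(design, path) {
  mat <- freq_matrix(design)
  obj <- list(
    name = design$name,
    constraint_profile = design$constraint_profile,
    fixed_flanks = design$fixed_flanks,
    positions = data.frame(label = colnames(mat),
                           freq = I(as.data.frame(t(mat))))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector (DNA or protein).
#' @param path output file.
#' @param type `"dna"` or `"aa"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, type = c("dna", "aa")) {
  type <- match.arg(type)
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  set <- if (type == "dna") Biostrings::DNAStringSet(sequences)
         else Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read FASTA as plain character vector
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_dna <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  setNames(as.character(set), names(set))
}

#' @rdname read_fasta_dna
#' @export
read_fasta_aa <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  setNames(as.character(set), names(set))
}

#' Export a trimer oligo spec
#'
#' Writes a JSON description plus (optionally) a plain-text synthesis sheet.
#'
#' @param spec a `trimer_oligo_spec`.
#' @param json_path output JSON path.
#' @param sheet_path optional plain-text synthesis sheet path.
#' @return `json_path`, invisibly.
#' @export
write_oligo_spec <- function(spec, json_path, sheet_path = NULL) {
  jsonlite::write_json(
    list(design_name = spec$design_name,
         left_flank = spec$left_flank, right_flank = spec$right_flank,
         positions = spec$positions),
    json_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(sheet_path)) {
    con <- file(sheet_path, "w")
    on.exit(close(con))
    writeLines(sprintf("Trimer synthesis sheet: %s", spec$design_name), con)
    writeLines(sprintf("5' constant: %s", spec$left_flank), con)
    for (nm in names(spec$positions)) {
      p <- spec$positions[[nm]]
      writeLines(sprintf("%s\t%s", nm,
                         paste(sprintf("%s:%s:%.4f", p$aa, p$codon, p$fraction),
                               collapse = "\t")), con)
    }
    writeLines(sprintf("3' constant: %s", spec$right_flank), con)
  }
  invisible(json_path)
}
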