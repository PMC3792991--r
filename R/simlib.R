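# Derive a reproducible per-operation seed from a root seed and a tag, so
# different operations driven by one root seed use distinct streams.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Sample a clone pool from CDR designs
#'
#' Draws `n` clones independently; at each randomized position the residue
#' is multinomial with the designed frequencies.
#'
#' @param design2,design3 [cdr_design()]s for the two cassettes.
#' @param n number of clones.
#' @param seed root seed for reproducibility.
#' @return data.frame with columns `cdr2`, `cdr3` (randomized residues only)
#'   and `clone` (the two joined by `":"`).
#' @export
sample_library <- function(design2, design3, n, seed = 1L) {
  draw <- function(design) {
    cols <- lapply(design$positions, function(p) {
      f <- p$freq[p$freq > 0]
      sample(names(f), n, replace = TRUE, prob = f)
    })
    do.call(paste0, cols)
  }
  with_seed(derive_seed(seed, "sample_library"), {
    cdr2 <- draw(design2)
    cdr3 <- draw(design3)
  })
  data.frame(cdr2 = cdr2, cdr3 = cdr3,
             clone = paste(cdr2, cdr3, sep = ":"),
             stringsAsFactors = FALSE)
}

#' Simulate colony formation with construction errors
#'
#' Each input clone gives one colony. With probability `frameshift_rate` the
#' colony carries a frameshifted insert (a single-nucleotide indel placed
#' uniformly inside the `hotspot` window, mimicking error clustering near
#' the reverse-primer annealing repeat); otherwise, with probability
#' `double_rate`, the colony was co-transformed with a second, independently
#' drawn plasmid ("double"); else it is "good".
#'
#' @param clones character vector of clone identifiers (e.g. the `clone`
#'   column of [sample_library()]).
#' @param double_rate probability a correct colony carries two plasmids.
#'   Default 5/19, the observed double-read fraction among correct clones.
#' @param frameshift_rate probability of a frameshifted insert. Default
#'   8/24, the observed frameshift fraction.
#' @param hotspot integer `c(start, end)` nucleotide window (1-based,
#'   inclusive) in which frameshift indels fall.
#' @param seed root seed.
#' @return data.frame with columns `plasmid1`, `plasmid2` (NA unless
#'   double), `category` (`good`/`double`/`frameshift`),
#'   `frameshift_position` (NA unless frameshift).
#' @export
simulate_construction <- function(clones, double_rate = 5 / 19,
                                  frameshift_rate = 8 / 24,
                                  hotspot = c(181L, 216L), seed = 1L) {
  stopifnot(double_rate >= 0, double_rate <= 1,
            frameshift_rate >= 0, frameshift_rate <= 1)
  if (frameshift_rate > 0 &&
      (length(hotspot) != 2L || hotspot[2] < hotspot[1])) {
    stop("frameshift_rate > 0 requires a non-empty hotspot window")
  }
  n <- length(clones)
  with_seed(derive_seed(seed, "simulate_construction"), {
    is_fs <- runif(n) < frameshift_rate
    is_double <- !is_fs & runif(n) < double_rate
    second <- rep(NA_character_, n)
    k <- sum(is_double)
    if (k > 0) second[is_double] <- clones[sample.int(n, k, replace = TRUE)]
    fs_pos <- rep(NA_integer_, n)
    if (any(is_fs)) {
      fs_pos[is_fs] <- sample(seq.int(hotspot[1], hotspot[2]),
                              sum(is_fs), replace = TRUE)
    }
  })
  data.frame(
    plasmid1 = clones,
    plasmid2 = second,
    category = ifelse(is_fs, "frameshift", ifelse(is_double, "double", "good")),
    frameshift_position = fs_pos,
    stringsAsFactors = FALSE
  )
}

#' Simulate QC sequencing of picked colonies
#'
#' Picks `n_picked` colonies uniformly without replacement; each picked
#' colony independently fails sequencing with probability `fail_rate`.
#' Double colonies that sequence successfully are reported as good with a
#' double read.
#'
#' @param colonies data.frame from [simulate_construction()].
#' @param n_picked number of colonies to sequence (<= rows of `colonies`).
#' @param fail_rate per-colony sequencing failure probability.
#' @param seed root seed.
#' @return A [qc_summary()].
#' @export
simulate_qc <- function(colonies, n_picked, fail_rate = 2 / 24, seed = 1L) {
  n_picked <- as.integer(n_picked)
  stopifnot(n_picked <= nrow(colonies), fail_rate >= 0, fail_rate <= 1)
  with_seed(derive_seed(seed, "simulate_qc"), {
    picked <- colonies[sample.int(nrow(colonies), n_picked), , drop = FALSE]
    failed <- runif(n_picked) < fail_rate
  })
  cat_ok <- picked$category[!failed]
  qc_summary(
    n_sampled = n_picked,
    n_good = sum(cat_ok %in% c("good", "double")),
    n_double = sum(cat_ok == "double"),
    n_frameshift = sum(cat_ok == "frameshift"),
    n_failed = sum(failed)
  )
}

#' Remove non-infective (frameshifted) colonies
#'
#' Frameshifted inserts cannot make the antibody-pIII fusion, so with a
#' trypsin-cleavable helper pIII their phages lose infectivity on trypsin
#' elution; good and double colonies are retained.
#'
#' @param colonies data.frame from [simulate_construction()].
#' @return The subset of `colonies` that stays infective.
#' @export
trypsin_filter <- function(colonies) {
  colonies[colonies$category != "frameshift", , drop = FALSE]
}

#' Panning selection model
#'
#' @param capture_weights non-negative per-clone capture weights (at least
#'   one positive).
#' @param rounds number of panning rounds (>= 1).
#' @param background elution background added to every weight (models
#'   nonspecifically retained phage).
#' @return An object of class `panning_model`.
#' @export
panning_model <- function(capture_weights, rounds = 1L, background = 0) {
  stopifnot(all(capture_weights >= 0), any(capture_weights > 0),
            rounds >= 1, background >= 0)
  structure(list(capture_weights = capture_weights, rounds = as.integer(rounds),
                 background = background),
            class = "panning_model")
}

#' Simulate panning enrichment
#'
#' One round multiplies each clone frequency by its effective capture
#' weight (weight + background) and renormalizes; the expected enrichment
#' of clone i is `w_i / sum(f_j * w_j)`. If `n_eluted` is given, the eluted
#' pool is drawn multinomially each round and frequencies are the observed
#' fractions; otherwise the deterministic expectation is propagated.
#'
#' @param frequencies normalized pre-selection clone frequencies.
#' @param model a [panning_model()] with weights matching `frequencies`.
#' @param n_eluted optional eluted-pool size per round (stochastic mode).
#' @param seed root seed (stochastic mode).
#' @return Numeric vector of post-selection frequencies.
#' @export
simulate_panning <- function(frequencies, model, n_eluted = NULL, seed = 1L) {
  stopifnot(inherits(model, "panning_model"),
            length(frequencies) == length(model$capture_weights),
            all(frequencies >= 0), abs(sum(frequencies) - 1) < 1e-9)
  w <- model$capture_weights + model$background
  f <- frequencies
  run_round <- function(f) {
    m <- f * w
    tot <- sum(m)
    if (tot <= 0) stop("all effective capture weights are zero on the support")
    if (is.null(n_eluted)) {
      m / tot
    } else {
      as.vector(rmultinom(1, n_eluted, prob = m / tot)) / n_eluted
    }
  }
  if (is.null(n_eluted)) {
    for (r in seq_len(model$rounds)) f <- run_round(f)
  } else {
    with_seed(derive_seed(seed, "simulate_panning"), {
      for (r in seq_len(model$rounds)) f <- run_round(f)
    })
  }
  f
}

#' Serialize colonies to FASTA + JSON sidecar
#'
#' Writes plasmid sequences (or identifiers) as FASTA and the per-colony
#' categories and frameshift positions as a JSON sidecar.
#'
#' @param colonies data.frame from [simulate_construction()].
#' @param fasta_path,json_path output paths.
#' @param sequences optional named DNA sequences keyed by clone identifier;
#'   if omitted, no FASTA is written and colony metadata go to JSON only.
#' @return `json_path`, invisibly.
#' @export
write_colonies <- function(colonies, fasta_path, json_path, sequences = NULL) {
  if (!is.null(sequences)) {
    seqs <- sequences[colonies$plasmid1]
    names(seqs) <- sprintf("colony%d", seq_len(nrow(colonies)))
    write_fasta(seqs, fasta_path, type = "dna")
  }
  jsonlite::write_json(colonies, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(json_path)
}
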