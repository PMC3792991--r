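#' QC sequencing summary
#'
#' Counts of sequenced colonies by category. Good, frameshift and failed
#' must add up to the number sampled; "double" counts the subset of good
#' colonies whose trace shows two superimposed reads (co-transformation with
#' two plasmids).
#'
#' @param n_sampled,n_good,n_double,n_frameshift,n_failed non-negative counts.
#' @return An object of class `qc_summary`.
#' @examples
#' qc_summary(24, 14, 5, 8, 2)  # the canonical 24-colony QC sample
#' @export
qc_summary <- function(n_sampled, n_good, n_double, n_frameshift, n_failed) {
  counts <- c(n_sampled = n_sampled, n_good = n_good, n_double = n_double,
              n_frameshift = n_frameshift, n_failed = n_failed)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (n_good + n_frameshift + n_failed != n_sampled) {
    stop("n_good + n_frameshift + n_failed must equal n_sampled (",
         n_good + n_frameshift + n_failed, " != ", n_sampled, ")")
  }
  if (n_double > n_good) stop("n_double cannot exceed n_good")
  structure(as.list(counts), class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf(
    "<qc_summary> %d sampled: %d good (%d double reads), %d frameshift, %d failed\n",
    x$n_sampled, x$n_good, x$n_double, x$n_frameshift, x$n_failed))
  invisible(x)
}

#' Titer pair (untreated vs trypsin-treated)
#'
#' CFU counts at the same dilution, with and without trypsin treatment.
#' With a helper phage carrying a trypsin-cleavable pIII, only particles
#' displaying the antibody-pIII fusion stay infective after trypsin.
#'
#' @param cfu_untreated,cfu_trypsin colony-forming unit counts (>= 0).
#' @return An object of class `titer_pair`.
#' @export
titer_pair <- function(cfu_untreated, cfu_trypsin) {
  stopifnot(cfu_untreated >= 0, cfu_trypsin >= 0)
  if (cfu_trypsin > cfu_untreated) {
    warning("trypsin-treated CFU exceeds untreated CFU")
  }
  structure(list(cfu_untreated = cfu_untreated, cfu_trypsin = cfu_trypsin),
            class = "titer_pair")
}

#' Expected copies of a clone among n transformants
#'
#' @param p clone probability in `[0, 1]`.
#' @param n_transformants number of independent transformants (>= 0).
#' @return `n_transformants * p`.
#' @examples
#' expected_copies(2e-5, 1e5)  # rarest-clone coverage check
#' @export
expected_copies <- function(p, n_transformants) {
  stopifnot(p >= 0, p <= 1, n_transformants >= 0)
  n_transformants * p
}

#' Expected number of distinct clones sampled
#'
#' For probability classes (each class: `count` clones of identical
#' probability `p`), the expected number of distinct clones seen in
#' `n_draws` independent draws is `sum(count * (1 - (1 - p)^n))`, with the
#' Poisson approximation `sum(count * (1 - exp(-n * p)))` also reported
#' (accurate when `n * p` is small).
#'
#' @param prob_classes data.frame with columns `p` (per-clone probability)
#'   and `count` (number of clones in the class); `sum(p * count)` must be 1
#'   within 1e-6.
#' @param n_draws number of draws (>= 0).
#' @return list with `exact` and `poisson` expected distinct-clone counts.
#' @examples
#' expected_distinct(data.frame(p = 0.25, count = 4), 4)$exact  # 2.734375
#' @export
expected_distinct <- function(prob_classes, n_draws) {
  stopifnot(is.data.frame(prob_classes),
            all(c("p", "count") %in% names(prob_classes)), n_draws >= 0)
  tot <- sum(prob_classes$p * prob_classes$count)
  if (abs(tot - 1) > 1e-6) {
    stop("probability classes are not normalized: sum(p * count) = ",
         format(tot, digits = 10))
  }
  list(
    exact = sum(prob_classes$count * (1 - (1 - prob_classes$p)^n_draws)),
    poisson = sum(prob_classes$count * (1 - exp(-n_draws * prob_classes$p)))
  )
}

#' Functional library size from QC sequencing
#'
#' Corrects an estimated transformant count for clones that cannot display a
#' functional antibody: frameshifted and failed clones are discounted, while
#' each double-read colony contributes a second correct plasmid on top of
#' the good count. The corrected size is
#' `estimated_size * (n_good + n_double) / n_sampled`, reported to 2
#' significant figures.
#'
#' @param estimated_size estimated number of transformants (> 0).
#' @param qc a [qc_summary()].
#' @return Corrected library size (2 significant figures).
#' @examples
#' functional_size(7.8e7, qc_summary(24, 14, 5, 8, 2))  # 6.2e7
#' @export
functional_size <- function(estimated_size, qc) {
  stopifnot(inherits(qc, "qc_summary"), estimated_size > 0)
  if (qc$n_sampled == 0) stop("empty QC sample")
  signif(estimated_size * (qc$n_good + qc$n_double) / qc$n_sampled, 2)
}

#' Display level from a trypsin titration pair
#'
#' Fraction of phage particles displaying the antibody fusion, estimated as
#' the ratio of trypsin-resistant to untreated infective titer.
#'
#' @param t a [titer_pair()].
#' @return Fraction in `[0, 1]` (can exceed 1 if counts are noisy).
#' @examples
#' display_level(titer_pair(1000, 64))  # 0.064
#' @export
display_level <- function(t) {
  stopifnot(inherits(t, "titer_pair"))
  if (t$cfu_untreated == 0) stop("untreated CFU is zero")
  t$cfu_trypsin / t$cfu_untreated
}

#' Phage titer from absorbance
#'
#' Spectrophotometric titer of filamentous phage:
#' `(A269 - A320) * constant / genome_length` virions per mL, with the
#' protocol constant 6e16 by default.
#'
#' @param a269,a320 absorbance at 269 nm and 320 nm.
#' @param genome_length phagemid genome length in nucleotides (> 0).
#' @param constant protocol constant (default `6e16`).
#' @return Virions per mL; negative differences warn and floor at zero.
#' @examples
#' titer_from_absorbance(0.1, 0.0, 8000)  # 7.5e11
#' @export
titer_from_absorbance <- function(a269, a320, genome_length, constant = 6e16) {
  stopifnot(genome_length > 0)
  diff <- a269 - a320
  if (diff < 0) {
    warning("A269 < A320; returning zero")
    diff <- 0
  }
  diff * constant / genome_length
}
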