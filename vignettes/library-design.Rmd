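---
title: "Designing and quality-controlling a synthetic single-domain antibody library"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and quality-controlling a synthetic single-domain antibody library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdabkit)
```

## The problem

A synthetic phage-display library starts from a single, well-behaved
antibody framework and introduces diversity only where it pays off: the
complementarity determining regions (CDRs). For single heavy-chain variable
domains (dAbs), which aggregate easily, the composition of the randomized
positions matters as much as their number. sdabkit implements the
computational side of building such a library:

1. **Scaffold gene engineering** — back-translate the scaffold protein with
   sensible codons, then carve unique restriction sites around each CDR by
   synonymous substitutions, so CDR cassettes can be exchanged by plain
   restriction cloning (`seqdesign` functions).
2. **Diversity design** — per-position amino-acid frequency tables realized
   by trinucleotide ("trimer") synthesis, validated against compositional
   rules, and compiled into stop-free oligo specifications (`diversity`
   functions).
3. **Library statistics** — clone probabilities, theoretical diversity,
   expected coverage, QC-corrected functional library size, display level
   and spectrophotometric phage titer (`libstats` functions).
4. **A seeded simulator** of construction, QC sequencing and panning, the
   synthetic stand-in for every wet-lab step (`simlib` functions).
5. **Biophysical characterization fits** — sigmoidal thermal melts (Tm at
   the inflection) and the 1:1 ITC binding isotherm (KD, effective
   stoichiometry, enthalpy, active fraction) (`biophys` functions).

## Scaffold engineering

`back_translate()` chooses, deterministically, the highest-usage codon per
residue from a codon table (`codon_table_ecoli()` ships standard E. coli
K-12 usage fractions). Codons below the `rare_threshold` (default 0.10 of
within-amino-acid usage) are avoided; they are only used when a forbidden
motif — typically the recognition sequences of the enzymes that must stay
unique — cannot otherwise be avoided on either strand. The search is
depth-first with backtracking, so failures are explicit and name the
blocking residue window.

`find_silent_site_placements()` enumerates every synonymous codon
combination over the codons a recognition site overlaps (at most three to
four codons, a few hundred combinations) and reports the
minimum-substitution placement per feasible offset, sorted by cost then
offset; ties among equal-cost codon assignments are broken by codon-usage
order, so results are reproducible. Matching is IUPAC-aware and
`count_site_occurrences()` scans both strands, counting a palindromic match
at one offset once; circular mode also scans the origin-spanning junction.

All user-facing coordinates are 1-based inclusive, the R convention.

`example_scaffold()` is an *illustrative* VH3-type domain-antibody
scaffold, not a published sequence: germline-style frameworks, a CDR1
carrying the solubilizing Asp cluster typical of aggregation-resistant
dAbs, and boundary-adjacent residues chosen so that each cassette enzyme
has an in-frame synonymous anchor (Leu-Glu for XhoI, Glu-Leu for SacI,
Leu-Gln for PstI, Gly-Thr for KpnI). `engineer_scaffold()` back-translates
with all six enzyme motifs forbidden, then places the four cassette sites
within five codons of their declared boundaries, rejecting any placement
that would leave an engineered enzyme occurring more than once on the full
construct (5' and 3' flanks carry the SapI and Mva1269I sites used to clone
the whole gene).

```{r scaffold}
eng <- engineer_scaffold(example_scaffold())
sapply(eng$enzymes, function(e) count_site_occurrences(eng$construct, e))
```

## Diversity design

The package deliberately treats the numeric content of a frequency table as
**user configuration**: published designs rarely tabulate their exact
per-position numbers in machine-readable form, and inventing them as ground
truth would be worse than shipping a documented illustrative default. The
defaults (`default_cdr2_design()`, `default_cdr3_design()`) obey the
compositional rules the package validates:

* hydrophobic residues (V, I, L, M, F) at most 25% summed per randomized
  position — lowers aggregation propensity while retaining hydrophobic
  binding contributions;
* CDR2: exactly 4 randomized positions, no positively charged residues
  (K, R, H) — positive charge promotes polyreactivity;
* CDR3: exactly 7 randomized positions in a 10-residue loop ending in the
  fixed Phe-Asp-Tyr (FDY) tail prominent in functional human repertoires;
  no Cys (unpaired disulfides), no Ile/Met/Lys (rare in functional CDR3s,
  hydrophobic or positively charged); Arg and His only at low frequency;
  Ala omitted in favour of Ser/Gly flexibility;
* frequencies biased toward Tyr/Ser/Gly, the residues with the best
  documented contribution to antigen binding.

`validate_design()` returns a violation report (never throws), so tables
read from CSV/JSON (`read_frequency_csv()`, `read_frequency_json()`) can be
audited before use.

Clone-level statistics follow from the independence of positions:
`clone_probability()` is the product of per-position frequencies,
`theoretical_diversity()` the product of support sizes, and
`extreme_probability()` the product of per-position maxima (or nonzero
minima). "One in N" spacings are reported to 3 significant figures
(`one_in_n()`), and `combined_rarity()` multiplies the spacings of the two
cassettes under the modelling assumption that the two ligations are
independent:

```{r rarity}
combined_rarity(334, 727000)
```

`compile_oligo_spec()` converts a validated design into a trimer synthesis
specification: exactly one codon per allowed amino acid (highest-usage
rule), mixing fractions equal to the designed frequencies, and constant
flanks carrying the cassette restriction sites verbatim. Because the codon
set contains no stop codon — in particular no amber TAG — no realizable
insert can encode an in-frame stop, which the tests confirm on 10^5
sampled clones.

## Library-scale statistics

* `expected_copies(p, n)` = `n * p`: how often a clone of probability `p`
  appears among `n` transformants.
* `expected_distinct()` uses the exact binomial formula
  `sum(count * (1 - (1 - p)^n))` per probability class, with the Poisson
  approximation reported alongside (they agree within 1% when
  `max(n * p) <= 0.01`).
* `functional_size(estimated, qc)` corrects a transformant-count estimate
  using a QC sequencing sample: frameshifted and failed clones are
  discounted, and each "double read" colony (two superimposed clean traces,
  i.e. a co-transformed colony) contributes one extra correct plasmid:
  `estimated * (n_good + n_double) / n_sampled`, 2 significant figures.
  With the canonical 24-colony sample (14 good, 5 doubles, 8 frameshift,
  2 failed) a 7.8e7 estimate becomes 6.2e7.
* `display_level()` is the ratio of trypsin-resistant to untreated
  infective titer. With a helper phage whose pIII carries a trypsin
  cleavage site, only particles displaying the antibody fusion stay
  infective after trypsin, so the ratio estimates the displaying fraction.
* `titer_from_absorbance(a269, a320, genome_length)` implements the
  standard two-wavelength virion count
  `(A269 - A320) * 6e16 / genome_length`; the constant is configurable.

## The construction simulator

`sample_library()` draws clones per-position multinomially.
`simulate_construction()` assigns each colony a category: frameshift (rate
default 8/24, the canonical observed fraction), else double (rate default
5/19, the observed double-read fraction among correct clones), else good.
Frameshift positions are single-nucleotide indels placed uniformly inside a
declared hotspot window, mimicking the observed clustering of synthesis
errors near the reverse-primer annealing repeat downstream of CDR2; the
default window (nt 181–216) is the corresponding stretch of the example
construct and is plain configuration. `simulate_qc()` picks colonies
uniformly without replacement and applies an independent sequencing-failure
rate; doubles sequence as good-with-double-read. `trypsin_filter()` removes
frameshift colonies (no functional fusion pIII). `simulate_panning()`
multiplies frequencies by capture weights and renormalizes (the expected
enrichment of clone *i* is `w_i / sum(f_j w_j)`), with an optional
multinomial eluted-pool draw.

Double colonies contribute both plasmids to diversity accounting but only
one (chosen uniformly) to any single-colony propagation, matching the
observation that progeny of a co-transformed colony eventually harbor one
plasmid.

Every simulator accepts a root seed; per-operation streams are derived from
it with a fixed documented hash (`seed * 48271 + hash(tag) mod 2^31 - 1`),
so whole pipelines are exactly reproducible from one integer.

## Biophysical fits

**Thermal melts.** `fit_melting()` fits a four-parameter logistic
(pre-/post-transition baselines, inflection Tm, width) by Levenberg–
Marquardt least squares with starts derived from data quantiles; a
sloped-baseline variant is available by flag. A flat signal (apparent
amplitude below five times the point-to-point noise) raises an explicit
no-transition error rather than returning a meaningless Tm.
`refolding_fraction()` is the second-to-first ramp amplitude ratio; 1 means
the two heating curves overlap, i.e. complete refolding. The synthetic
generator defaults (Tm 45.9 °C, width 2.2 °C, 25–85 °C at 0.5 °C spacing,
1% amplitude noise) emulate a marginally stable dAb melt; recovery tests
show the fitted Tm lands within 0.5 °C of truth on every one of 100 seeds.

**ITC.** `itc_expected_heats()` implements the 1:1 isotherm with the
standard perfusion correction: each injection displaces its own volume of
instantaneously mixed cell contents, totals are updated, the bound complex
solves the mass-action quadratic with binding-site concentration
`n_eff * [cell]`, and the measured heat is the enthalpy times the net new
complex in the cell. The closed-form root is cross-checked against an
independent bisection solver to 1e-10 relative everywhere tested.
`fit_itc()` runs bounded Levenberg–Marquardt over (log KD, n_eff, ΔH) from
five log-spaced KD starts and reports standard errors from the fit
covariance; non-convergence and boundary-pinned KD are flagged, and designs
whose titrant cannot approach saturation are flagged low-information rather
than silently fitted. `n_eff` absorbs stoichiometry times active fraction:
with a nominal 1:1 stoichiometry, `n_eff = 0.77` reads as 77% active cell
material.

The synthetic ITC default is an informative design for a micromolar binder:
truth KD 5 µM, ΔH −40 kJ/mol, 350 µM nominal cell loading with a 0.77
active fraction, 3.5 mM syringe titrant, 20 × 2 µL injections into a 200 µL
cell — Wiseman c ≈ 54, final molar ratio ≈ 2.6, noise 2% of the largest
heat. Note that a role-reversed design with a titrant far more dilute than
the cell material (tens of µM against hundreds of µM) cannot reach
saturation and is exactly the case the low-information flag exists for; the
fitter itself is role-agnostic about which binding partner is where.

At this noise level the fit is unbiased (zero-noise series refit to machine
precision) but KD carries an intrinsic relative standard error near 10%
from the fit covariance; recovery is therefore asserted on the median over
seeds (median |log(KD_fit/KD_true)| < 0.15 across KD 0.5–50 µM and c-values
1–500), while `n_eff` is recovered to a few percent.

## What the synthetic data do and do not show

The generators emulate: per-position multinomial sampling of trimer-built
cassettes, categorical construction errors with a positional hotspot,
uniform colony picking with independent sequencing failure, multiplicative
panning enrichment, logistic melts with additive Gaussian noise, and 1:1
binding heats with injection-displacement dilution. They do **not** emulate
sequence-dependent synthesis error rates, ligation or transformation bias,
phage growth competition, ELISA signal, aggregation kinetics during
melting (irreversible unfolding appears only as a reduced second-ramp
amplitude), baseline drift or injection-timing artefacts in ITC, or
lysozyme dimerization. Passing recovery tests therefore demonstrates the
correctness and precision of the estimators under their stated noise
models, not instrument-grade robustness on real traces.

## Numerical choices and problem sizes

* Exhaustive placement enumeration is exact for windows up to four codons
  (at most ~1300 combinations); tests compare it against an independent
  enumeration oracle over every 4-codon window of a 30-codon stretch for
  six enzymes.
* Diversity normalization and support counts are verified by full
  enumeration on designs of up to 6 positions; coverage formulas against
  10^4-replicate Monte-Carlo at 10^2 and 10^3 draws.
* Fits use `minpack.lm::nls.lm` with ftol 1e-15 so that noiseless
  self-consistency holds to machine precision and melting fits are
  invariant (to 1e-9 in Tm) under affine rescaling of the signal axis.
* Recovery suites use 100 seeds for both melts and ITC; the full test suite
  runs in about half a minute.
* Stop-codon audits sample 10^5 clones; marginal-frequency recovery uses
  10^5 draws with 4-sigma binomial bounds.

## Known limitations

* The shipped frequency tables and the example scaffold are illustrative;
  real designs should be loaded from the user's own CSV/JSON and FASTA.
* `back_translate()` optimizes codon usage only (no GC window, secondary
  structure or splice-motif handling).
* The ITC model assumes a single site class and instantaneous mixing; no
  competitive or sequential-site models.
* The panning model is a single multiplicative capture weight per clone;
  no avidity, washing kinetics or antigen depletion.
* Kabat numbering and automatic CDR detection are out of scope; regions are
  user-labelled.
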