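---
title: "Methods: microevolution of cis-regulatory elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microevolution of cis-regulatory elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crekit)
```

# The analysis in one page

The package studies a short regulatory element (a promoter or enhancer,
typically 0.5–2 kb) sampled as multiple haplotypes from each of several
closely related species, aligned into one column frame. Bases are
dichotomised into those inside transcription-factor binding sites (TFBSs)
and those outside (NTFBSs) under one of four independent annotation methods,
substitutions are split into fixed (between-species, parsimony-mapped to
tree branches) and polymorphic (within-species), and the cross-tabulation of
the two dichotomies yields the binding-site adaptation of the
McDonald–Kreitman framework: if TFBS bases are under positive selection,
their fixed:polymorphic ratio should exceed that of NTFBS bases; a Fisher
exact test judges the 2×2 table. Complementary per-base relative-rate
estimators quantify how much faster or slower annotated bases evolve.

# Statistics and conventions

## Site filter

All diversity statistics use *complete deletion*: any column carrying a gap
in the analysed sequence set is dropped, and `N` is treated as missing (the
column is dropped too). This is a conservative choice; the alternative
(counting `N` as a fourth observed state, or pairwise deletion) is not
offered because the downstream substitution catalog also excludes gapped
columns, and keeping the two filters identical makes fixed and polymorphic
counts refer to the same sites.

## Diversity and neutrality tests

* π — mean pairwise differences per site over all C(n,2) pairs, with a
  large-sample sampling standard deviation.
* θ_W = S/(a₁L), a₁ = Σ_{i<n} 1/i.
* Tajima's D from π (total, per pair) and S with the 1989 variance
  constants; **undefined (NA), never 0, when S = 0**.
* Fu & Li's D uses external-branch mutations (derived singletons) when an
  outgroup sequence is supplied; otherwise the starred variant D* from
  unpolarised singletons is computed and the variant is recorded in the
  output, since the two are not interchangeable. (Curiosity: for n = 4 the
  site-pattern constraint makes D* numerically equal to Tajima's D; they
  diverge for n ≥ 5.)
* hd = (n/(n−1))(1 − Σp²), over complete-deletion columns.
* Multi-allelic sites: S counts the site once, η counts (alleles − 1), π
  counts per-pair mismatches — hence S ≤ η always.

## Conservation index

For each base b with count n among the s sequences carrying a base at a
column, CI(b) = (n/s)(log₂(1/s) − log₂(n/s))/log₂(1/s); unrepresented bases
score 0, a monomorphic column totals 1. The position total is algebraically
1 − H/log₂(s) with H the Shannon entropy — this identity is asserted to
1e−12 in the test suite and serves as the independent oracle. Two readings
of s exist: sequences with a base at the column (default; keeps CI = 1
attainable at partially gapped columns) or the full alignment depth
(`count_gaps_in_s = TRUE`). Columns with fewer than two bases report NA.
The profile report smooths with a centred 11-column window by default
(the source material does not state its smoothing; 11 is narrow enough to
keep a 30 bp constrained block visible).

## Annotation methods

* **Exact scan** (`patch_scan`): every occurrence (overlaps included) of
  every library site of length ≥ 5; no mismatches. Strict but
  false-negative prone.
* **PWM scan** (`match_scan`): min–max normalised information-weighted
  similarity — with f(i,b) the column frequencies and
  I(i) = Σ_b f(i,b)·ln(4 f(i,b)), the score of a window is
  (Σ I(i) f(i,bᵢ) − min)/(max − min) where min/max substitute the
  per-position minimum/maximum frequencies. A hit needs score 1.0 over the
  5 consecutive core positions *and* ≥ 0.7 overall. The named tools this
  emulates are proprietary-era software; equivalence is defined by these
  cutoffs, not bitwise output. Cores default to the maximal-information
  5-window when not supplied. A fully degenerate matrix is an error; a
  degenerate stretch inside an informative matrix scores 1 (any base is a
  "perfect" match there, consistent with the limit of the formula).
* **DNase-I footprints**: an externally supplied interval track, static
  across species.
* **Phylogenetic footprinting** (`phylo_footprint`): a column with an
  outgroup base is *well-aligned* iff it lies in ≥ 1 stretch of 6
  consecutive outgroup bases of which ≥ 5 equal an ingroup base at the same
  column; qualifying stretches merge. Outgroup-gap columns are treated as
  poorly aligned (they cannot satisfy the definition); this resolves the
  open question of which frame the footprints live in — we keep alignment
  columns throughout, and expose `lift_track()` for the ungapped reading.
* Reverse-complement scanning is off by default (`both_strands = TRUE` to
  enable); the source material is silent on strand handling and a
  single-strand default keeps the worked examples reproducible.
* Overlapping sites are kept individually; every TFBS/NTFBS dichotomy is
  taken from the union mask, so shared bases count once.

## Substitution catalog

Fixed substitutions come from Fitch parsimony run per column over the
species tree, with each species contributing its **allele set** as the leaf
state: a column where two species' allele sets overlap can always be
explained without a fixed difference (ancestral polymorphism subsequently
fixed) and is never counted as one. Ties in the bottom-up sets are resolved
deterministically on the way down (parent state if available, else the
alphabetically first state); gaps travel as a fifth state so internal nodes
have complete sequences, but events are only counted at columns free of
gaps and missing data, and only when both endpoint states are bases.

Every event is classified against the annotation of the relevant sequence
*before* and *after* the change — ancestral node sequences are rescanned
for the scan-based methods, so a substitution that creates a site in the
derived sequence is a **gain**, one that destroys an ancestral site a
**loss**, one that does both (converts one site into another) a
**change**, one inside a site present on both sides **in_site**, all else
**none**. "Affects a TFBS" therefore means: hits a site present before or
after the change. For static tracks (DNase, phylogenetic footprints) the
classification reduces to mask membership.

The chronology rule: when several substitutions on one branch eliminate the
same pre-existing site only the first is counted as the loss, and when
several jointly form a new site only the last is counted as the gain. The
true temporal order within a branch is unknowable, so "first/last" is a
stated convention: left-to-right column order. All events stay in the
catalog with a `counted` flag, so raw counts remain auditable.

Polymorphic events take the species' majority allele as the reference
state, one event per extra allele per segregating column. The singleton
filter flags variants carried by exactly one haplotype as not counted
(weakly deleterious changes inflate the polymorphism class as samples
grow); species in the exemption set — typically those represented by a
single line — keep their singletons.

**Known limitation — root polarity.** On an unrooted (or root-adjacent)
branch, parsimony cannot orient a state change: a gain on one child of the
root is indistinguishable from a loss on the other. The recovery tests
therefore score identifiable cases (terminal-branch events); real analyses
should root the tree with an outgroup. Either way the *count* of
site-affecting substitutions is unaffected — only the gain/loss label flips
— which is why the equilibrium estimator below averages gains and losses.

## Selection tests

* `mk_fisher_test`: two-tailed Fisher exact P by probability-mass summation
  over the hypergeometric support (the dominant convention in
  population-genetics software); one-sided tails available. NA on a zero
  margin.
* `equilibrium_relative_rate`: under gain/loss equilibrium half the
  gain-or-loss substitutions occurred in TFBS bases, so
  T = (gains+losses)/2 + changes estimates TFBS-resident fixed
  substitutions, and T/(N·f) their rate relative to NTFBSs (f = TFBS base
  fraction, averaged unweighted across species on each species' own
  ungapped sequence). Note this form is mildly conservative (biased toward
  1) as an estimator of a per-base rate ratio because its denominator
  includes the excess substitutions themselves; the odds-form
  `footprint_relative_rate` (subs_in/f)/(subs_out/(1−f)) is the consistent
  estimator and is the one used for parameter-recovery validation.
* `composition_expected_chisq`: O vs E = N·f, df = 1, Yates correction off
  by default (toggleable). The published chi-squared statistics for the
  motivating data are not reproducible from the printed marginal counts
  under this or the Yates form; the module reports the plain O/E statistic
  from stated inputs and does not tune toward the printed values.
* `gain_loss_excess_test`: exact two-sided binomial test at p = ½.
* Turnover rows ("making new" vs "destroying") are tested as their own 2×2;
  "other changes" enter only the equilibrium estimator, matching the
  published table layout. One published P-value (the ZE DNase row) equals
  the one-sided tail of its table and cannot be matched by any two-tailed
  convention; the acceptance suite documents this discrepancy rather than
  switching conventions per row.

# The synthetic-data generator

`simulate_dataset()` draws a uniform-random root sequence, plants
non-overlapping exact motif instances from a (toy, fully synthetic) library,
and evolves species sequences along the tree under a Jukes–Cantor-style
model: each column substitutes on a branch of length b with probability
1 − exp(−b·m), m = `tfbs_rate_multiplier` inside planted sites and 1
outside. Within-species polymorphism is layered on by a Kingman coalescent
per species (mutation rate θ/2 per unit coalescent time, θ =
`theta_within` × length), so the neutral site-frequency spectrum — and the
null behaviour of Tajima's and Fu & Li's statistics — is correct, including
the expected excess of singletons. Optional explicit turnover writes a
library site into a site-free stretch (gain) or breaks one substitution in
a still-intact site (loss), recorded with intervals in the truth. Indels
are species-level deletions with geometric lengths (mean 3) placed outside
planted sites by default, so alignment columns stay identifiable and rate
inference is not confounded by alignment artifacts; insertions are not
modelled (a deletion-only history is what a column-preserving aligner
would return anyway).

Defaults describe a world resembling the motivating study design: 2–8
species, a handful of haplotypes per species, ~1 kb elements, per-site
within-species θ of a few ×10⁻³ (typical for *Drosophila* non-coding DNA),
~10 planted sites covering ~10% of the bases.

What a green simulation test establishes — and what it does not: the
generator has no recombination, no selection beyond the rate multiplier,
no PWM-mediated binding-strength evolution, no insertion history, and its
planted sites are exact library matches. Recovery results therefore
validate the *accounting machinery* (parsimony mapping, classification,
chronology, estimators), not robustness to alignment error or motif
degeneracy in real data.

Determinism: a config's integer seed drives one global RNG stream;
identical configs give byte-identical FASTA/BED/newick/TSV outputs.

# Validation layout

Every operation with a worked example is tested against an independent
oracle: brute-force pairwise scans for π/θ/hd, an in-test re-derivation of
the Tajima and Fu & Li formulas, `stats::fisher.test` against the
enumeration-based Fisher test (exhaustively for all 2×2 tables with N ≤ 40,
up to the symmetries of the table), the entropy identity for the
conservation index, exhaustive minimum-change enumeration for Fitch
parsimony on all 3–5-leaf rooted shapes, and window enumeration for the
phylogenetic footprint. Simulation calibrations check that neutral data
give mean Tajima's D ≈ 0, that a planted rate multiplier of 2 is recovered
by the odds-form relative rate, and that the MK test holds its nominal size.
The acceptance suite recomputes the published worked arithmetic from the
fixture tables shipped under `inst/extdata/`.

# Known limitations

* Parsimony, not probabilistic ancestral reconstruction; multiple-hit
  corrections are out of scope (the catalog counts minimum-change events).
* The root-polarity ambiguity above; supply an outgroup where possible.
* PWM scores carry no p-value calibration; cutoffs are the definition.
* Indel evolution is not modelled as events (gapped columns are simply
  excluded from substitution accounting).
* The packaged motif library is a synthetic toy: results on it exercise the
  machinery, and say nothing about any real transcription factor.
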