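---
title: "Verifying combinatorial promoter libraries from long reads: methods"
author: "combilib developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying combinatorial promoter libraries from long reads: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combilib)
```

## The model

A combinatorial promoter library is described by an ordered set of gene
slots, each with a list of candidate promoter parts. Parts carry a closed
category label (`strong`, `medium`, `weak`, `inducible`); the default
library has ten candidates per slot in the ratio 4:2:2:2, three slots
(*pcbC*, *pclA*, *penDE*), and hence a design space of 1,000 promoter
combinations. Under random equimolar assembly, the chance of a slot
receiving a promoter of category $c$ is the fraction of the slot's
candidates in $c$ — this is the null distribution every bias test is
referred to. Promoter strength values are carried as optional metadata
only; all statistics run on categories, which keeps the null well defined
when strengths are unknown or unmeasured.

## Read identification

Reads are aligned against a reference database of every promoter, every
combined CDS+terminator unit, and decoy regions. Decoys exist so that reads
of foreign or backbone DNA are recognised rather than misassigned; each
decoy carries a class:

* `full` — a complete backbone region (e.g. the AmpR cassette, ColE1, the
  multigene-assembly marker cassette). Its presence in a chain marks an
  **undigested** plasmid.
* `scar` — a short vector remnant that a correctly digested fragment may
  legitimately retain between a restriction site and the cassette.
* `contaminant` — foreign DNA (lambda phage). Any chain containing one is
  unidentifiable; chains containing *nothing but* decoys are dropped as
  decoy reads.

Identification proceeds in fixed order:

1. **Chaining.** Alignment records are grouped per read and sorted by
   forward-strand read coordinate. Overlapping alignments to the same
   region collapse to the highest-scoring one; non-overlapping repeats are
   kept (the same promoter can genuinely occur at two slots). The chain is
   canonicalised by overall orientation (majority aligned strand); both
   orders are tried during template matching, so verdicts are invariant
   under reverse-complementing the read.
2. **Template match.** The ordered region names must read as
   promoter/unit pairs: all slots in design order for a multigene verdict
   (no backbone allowed — the multigene digest removes it), or exactly one
   cassette for single-gene verdicts, optionally flanked by backbone
   segments. Two promoters immediately upstream of one unit yield
   `unidentified` with reason `ambiguous` — no score arbitration is
   attempted. A promoter that is not a candidate for its slot fails with
   `slot_assignment`.
3. **Length rule.** The read's total length must lie within 15 % of the
   summed *full* lengths of the regions in its chain, boundary inclusive.
   The denominator is the region-length sum (not the aligned-length sum)
   and the numerator the raw read length; with few-percent error rates,
   indels move the ratio by well under a percent on multi-kilobase reads.
4. **End anchoring** (digested single-gene candidates only). The read must
   start and finish within 50 bp of the first and last regions'
   extremities, measured as the absolute difference between the read
   overhang and the unaligned region remainder at each end. This blocks a
   multigene read with a partially recovered chain from being counted as a
   single-gene read. Inclusive at exactly 50 bp. Multigene reads face the
   template + length rules only, and interior gaps between chained
   segments are deliberately unconstrained.

On success, the promoter recorded for each slot is the segment immediately
upstream of that slot's unit in canonical order. Undigested singles are
tabulated alongside digested ones by default but keep their own verdict, so
a user can exclude them with one argument.

When two templates could in principle fit, the longer one wins by
construction (the multigene test runs on the full chain; a genuine
multigene chain never reduces to a single-cassette match because the extra
segments would remain). Chains matching nothing report the first failure
reason in a fixed priority (contaminant, template/ambiguous, length,
end_anchor), which makes rejection statistics interpretable.

## The synthetic world

`synthetic_world()` builds a fully specified surrogate library whose digest
fragments land inside the documented size-selection windows *by
construction*. Those windows are: multigene 5,616–6,117 bp; single-gene
2,062–2,229 (*pcbC*), 2,549–2,716 (*pclA*), 1,885–2,052 bp (*penDE*). Two
observations pin the geometry:

* each single-gene window is 167 bp wide, and the multigene window is
  501 = 3 × 167 bp wide — exactly the spread of three independent promoter
  choices if promoter lengths span ≤ 167 bp;
* the windows are mutually consistent **only if** each digested single-gene
  fragment retains a gene-specific vector remnant beyond its
  promoter+unit cassette: putting every cassette in a common
  1,872–2,039 bp range makes the multigene window the exact 3-fold sum,
  and the single windows are that range shifted by +190, +677 and +13 bp
  for *pcbC*, *pclA*, *penDE* respectively.

The generator therefore uses promoter lengths evenly spaced over
600–759 bp (realistic for yeast promoter parts), unit lengths 1,273 /
1,280 / 1,272 bp, and per-gene scar remnants of 190, 677 and 13 bp. The two
long remnants are reference regions of class `scar` (so they align and the
end anchor sees a clean boundary); the 13 bp remnant stays below any
alignable score and is absorbed by the 50 bp anchor tolerance. Undigested
singles append the full single-assembly backbone (AmpR cassette + ColE1).
With this geometry nothing is ever rejected by `digest_and_select()` at
default settings — the windows become a verifiable invariant rather than a
filter — while the boundary behaviour of the window rule itself is tested
with hand-built fragments.

Reads are full-fragment, uniformly stranded, with independent per-base
substitution/insertion/deletion errors (defaults 3 % / 2 % / 2 %,
a stand-in for nanopore consensus reads; no published rates exist for the
original run, so these are a modelling choice, not an estimate).
Contaminants default to 5 % of reads, drawn from the lambda surrogate and
backbone regions. Class proportions default to an equimolar pool of the
four libraries (multigene + three singles at 25 % each) with 10 % of each
single library escaping digestion. All randomness flows from explicit
seeds through a save/restore RNG scope; identical seeds give byte-identical
output.

What a green simulation test does **not** establish: robustness to
chimeric or truncated reads, quality-score effects, basecaller artefacts,
or real nanopore error structure (homopolymer-biased indels). The error
model is i.i.d. per base by design.

## The aligner

`naive_align()` is an exact affine-gap local aligner (Smith–Waterman /
Gotoh, score-only forward pass plus an anchored reverse pass to recover
start coordinates, implemented in C++). Scoring is match +1, mismatch −1,
gap of length $k$ costs $1 + k$ (existence 1, extension 1), mirroring a
unit-cost external-aligner configuration; the exact substitution matrix of
the original run is not published, and this divergence is deliberate and
documented. Both query strands are searched, records below `min_score = 50`
are dropped, and after each hit the covered read interval is masked and the
search repeated (up to `max_hits`), so duplicated parts are reported at
every occurrence. An optional exact k-mer prefilter (on in the pipeline
wrapper: `k = 13`, ≥ 2 shared k-mers per region/strand) skips hopeless
region/strand pairs; at few-percent error rates a truly present region
shares hundreds of exact 13-mers, so the filter affects speed, not results,
and a test asserts exactly that. The aligner is O(nm) per region and meant
for test-scale data; production users parse external `-fTAB` output, whose
0-based start+length coordinates are preserved internally (minus-strand
query starts converted to forward-strand coordinates).

## Statistics

**Incorporation bias.** Per gene slot and construction stage, observed
category counts are tested against the null with
$X^2 = \sum_c (O_c - E_c)^2 / E_c$ over categories with nonzero null mass,
$\mathrm{dof} = k - 1$, upper-tail χ² p-value. When any $E_c < 5$ (the
standard rule of thumb) the p-value is recomputed by exact multinomial
enumeration — summing the null probability of every outcome whose statistic
is at least the observed one — with a Monte Carlo fallback above
$5\times10^5$ compositions; the `method` field reports which value is
authoritative. Tests are run per gene (pooling across genes is possible but
not claimed to match the original analysis); Benjamini–Hochberg adjusted
p-values are reported alongside raw ones as a convenience, raw p remaining
primary.

**Producer enrichment.** A 2×2 table — producers with/without the category
at the slot versus the sequenced library stage — is tested with a two-sided
Fisher's exact test computed by direct hypergeometric enumeration (all
tables with the observed margins whose point probability does not exceed
the observed one within a $10^{-7}$ relative tolerance). The odds ratio is
the sample $(ad)/(bc)$ with $\infty$ when $bc = 0$, not the conditional
MLE.

## Assay arithmetic

Growth inhibition is
$100\,(1 - \frac{\mathrm{OD18}_s/\mathrm{OD0}_s}{\mathrm{OD18}_c/\mathrm{OD0}_c})$
percent; negative values (growth promotion) are flagged, never clamped,
because screens legitimately observe them. Calibration curves are ordinary
least squares of counts on concentration over the detected linear range:
the longest contiguous run of standards whose consecutive log–log slopes
deviate from 1 by less than 0.1 (ties resolved toward more points, then
lower concentrations). That rule is this package's formalisation of a
by-eye spreadsheet choice; it excludes a saturated top standard
automatically, and a large intercept relative to the counts also breaks
log–log linearity and is rejected rather than silently fitted.
Quantification inverts the fitted line; values below the intercept report
zero with a flag; LOD/LOQ flags fire below signal-to-noise 3:1 and 10:1.
All concentrations normalise internally to pg ml⁻¹ (the standard series
10 ng ml⁻¹ … 100 µg ml⁻¹ is the default calibration design).

## Numerical and design choices

* The 15 % and 50 bp comparisons are inclusive at the boundary (with a
  $10^{-12}$ guard against floating-point noise on the ratio).
* The decoy flag requires a chain to contain *no* promoter or gene-unit
  segment; mixed chains (contaminant + genuine part hits) are
  `unidentified` instead, keeping them out of count tables either way.
* Equal-score overlap collapses keep the record encountered first in
  score order (stable, deterministic).
* `design_space_size()` errors on a slot-less design rather than returning
  the empty product.
* Exact multinomial enumeration uses the χ² statistic as the extremity
  ordering, the conventional choice; its conservativeness under the null
  is asserted by exhaustive computation at small n.

## Limitations

* No per-junction validation of Golden Gate fusion sites; correctness is
  assessed at sequence-composition level only.
* No consensus/polishing; each read is classified independently.
* The synthetic lambda genome is a random 3 kb surrogate, adequate for
  exercising decoy routing but not a real phage sequence.
* The aligner's scoring matrix is a documented approximation of the
  external aligner's; alignment-dependent edge cases near `min_score`
  may differ from a LAST run.
* Runtime: classifying a 500-read simulated run takes on the order of a
  minute on one CPU; the aligner is not meant for full sequencing runs.
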