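---
title: "Reconstructing NHEJ translocation junctions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing NHEJ translocation junctions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nhejTransloc)
```

## The biological problem

Two simultaneous double-strand breaks (DSBs) on different chromosomes can be
joined *in trans* by classical, Ku-dependent nonhomologous end-joining
(NHEJ), producing a reciprocal translocation.  In the yeast assay system this
package models, the two breaks are made by the HO and I-SceI endonucleases,
both of which leave 4-nt 3'-protruding single-stranded ends.  Selection
recovers only junctions that preserve a functional intron spanning the
breakpoint, so the recoverable sequence space is narrow: deletions are short,
microhomologies do not exceed 5 nt, and every junction can be interpreted as
a small set of end-processing steps — annealing of the two overhangs (or of
one overhang with flanking sequence), limited trimming, templated gap-filling
synthesis, and ligation.

The package answers three questions about such data:

1. **Reconstruction** — which minimal repair event explains an observed
   junction sequence exactly?
2. **Classification** — which mechanistic class does that event belong to?
3. **Cohort statistics** — how do repair-type mixtures and translocation
   frequencies compare across genotypes?

## The junction model

All sequences are handled on the top strand; the bottom strand is its
reverse complement.  A junction forms between a *left* end (3' overhang on
the top strand) and a *right* end (3' overhang on the bottom strand).  An
explanation is parameterised by

* `trimLeftProt`, `trimRightProt` — nucleotides removed from the 3' termini
  of the two protruding strands;
* `trimLeftRec`, `trimRightRec` — nucleotides removed from the recessed
  strands (for the right end, this is its top strand, so it shifts the
  junction point);
* `insertionTop` — top-strand bases attributable to neither parent.

An explanation is valid when the trimmed left top strand, the insertion and
the trimmed right top strand concatenate to the observed junction exactly.
Given such a *string family*, the engine completes it with the minimal
bottom-strand trims that make the annealed intermediate geometrically
coherent: bottom strands may not overlap, and every retained right-bottom
base lying under retained top sequence must either Watson-Crick pair with it
or be the template of an inserted base.  The completion yields the physical
annotation used downstream: pairing length, microhomology at the joint,
templated-fill flags, and the bottom-strand fill.

### The tolerated mismatch

One mismatched base pair is tolerated inside the pairing (the biological
situation is a mismatch created by annealing and resolved afterwards by
mismatch repair, so the observed junction may carry either parental allele at
that position).  Two numerical rules matter here and were genuinely open
design choices:

* at most **one** mismatch disqualifies nothing; two disqualify the pairing;
* the tolerated mismatch must be **internal** — both neighbouring positions
  must be paired.  Without this restriction, a microhomology junction with a
  one-strand gap can always be re-read as a longer pairing carrying a
  terminal mismatch, and the two mechanistic classes collapse into each
  other.  The single mismatch the assay system actually produces (a T:G
  inside a 3-bp pairing) is internal, so the rule costs nothing.

### Parsimony ranking

The chosen explanation minimises, in order: total edited nucleotides (all
four trims plus the insertion length); then maximal microhomology; then
tolerated mismatches; then untemplated before templated insertions are
penalised; finally junction-ambiguous bases are attributed to the left end
(the standard indel left-alignment convention), which makes the order total
and the winner deterministic.  The published interpretations of the assay's
canonical junction classes are all recovered as unique minima under this
order (`test-explain.R` checks this against an independent exhaustive
search).

## The repair taxonomy

For partially complementary overhangs:

| Type | Signature |
|------|-----------|
| I    | both overhangs intact; 1- or 2-nt tip pairing; gaps filled by templated insertion (the +CA/+AT signature) |
| II   | >= 4-nt microhomology between one overhang and the other end's flank, with deletion |
| III  | one terminal base trimmed from each protruding strand; >= 3-bp pairing with at most one internal mismatch; no insertion; direct ligation |
| IV   | one protruding strand degraded; synthesis across the intact opposite overhang bridges the ends |

For completely non-complementary overhangs: Type I (templated fill on both
strands with no pairing), Type II (microhomology plus fill on exactly one
strand), Type III (microhomology, no fill).

Type IV deserves a note.  Its literal reading — blunt one end completely,
then copy the opposite overhang — is *string-ambiguous* with "trim all but
one base, form a 1-bp pairing, fill the gap": whenever the two overhang tips
can pair (always true in the partial assay), the last base of the blunted
strand equals the first templated base.  Minimal-edit reconstruction
therefore keeps one overhang base, and the classifier's end-bridging clause
accepts near-complete removal (>= 3 of 4 nt) with a <= 1-bp pairing.  The
classification is invariant under the ambiguity.

Precedence when one explanation satisfies several clauses is I > III > IV >
II (partial) and I > II > III (non-complementary), preferring readings that
preserve more end structure.  Junctions fitting no clause are reported as
unclassifiable, never dropped; co-optimal explanations mapping to different
types flag the junction as ambiguous.

## The assay fixtures

The published junction-flank panels exist only as figure images, so the
shipped end sequences are **synthetic reconstructions**, derived rather than
transcribed: the I-SceI overhang (`ATAA`) follows from its published 18-bp
recognition sequence; the HO-side overhang (`TGTT`) and the flanks are the
unique solution consistent with the assay's published repair signatures —
the templated `+CA`/`+AT` fill after 2-nt tip pairing, the 3-bp pairing
containing one internal T:G mismatch after symmetric 1-nt trimming, and a
4-nt `ATAA` microhomology patch in the HO-side flank.  Inverting the I-SceI
site flips its junction-facing overhang to `TTAT`, which cannot anneal with
`TGTT` in any register — exactly the non-complementary configuration.  The
configuration files label these sequences as transcribed-unverified, and
nothing in the statistics depends on the literal flank letters beyond the
signature constraints above.

Search bounds default to 25 nt of deletion and 6 nt of insertion: selection
requires a functional intron, so extensively resected junctions are not
recoverable, and observed microhomologies never exceed 5 nt.  Both bounds
are user-configurable per assay file.

## What the simulator emulates — and what it does not

`simulateJunction()` executes each mechanism literally (anneal at the
type-specific register, trim, fill templated gaps, ligate), and
`simulateCohort()` draws types i.i.d. from a per-genotype mixture; default
profiles use the published per-type counts divided by cohort size.  Each
junction is generated on its own RNG substream derived from the seed and the
junction index, so cohorts are reproducible regardless of iteration order.
Type II sites are sampled among precomputed annealing sites of the overhang
(or its retained tail) in the opposing flank; sites whose pairing would
extend across the whole overhang are excluded for one-strand-fill types,
because such junctions are mechanistically no-fill events.  If an assay
configuration offers no suitable site, the simulator raises a configuration
error rather than fabricating sequence.

Per-type trim and insertion distributions beyond the canonical signatures
are not published; the simulator therefore generates the canonical signature
of each type (with the mismatch-repair allele drawn with probability
`mmrResolutionProb`).  It does **not** simulate sequencing error,
chromatogram noise, clonal duplicates, or repair outcomes outside the
taxonomy.  Passing round-trip tests consequently demonstrate internal
consistency of generator and classifier under the study's conditions, not
robustness to artefacts real Sanger data may contain.

`simulatePlating()` models the frequency assay: the pre-induction plate
counts all cells; survivors and selected translocants are binomial draws.
The frequency estimator (selective / nonselective colonies, dilution
corrected) is exactly unbiased under this model, and the test suite verifies
it to within three Monte-Carlo standard errors at the wild-type frequency
0.27 x 10^-3 over 500 replicates.

## Cohort statistics

* **Frequencies** are pure ratios with explicit dilution factors (default 1,
  since the study reports "appropriate dilutions" without values).
* **Medians** are the headline replicate summary, with standard deviations
  alongside.
* **Fold changes** report the ratio of the larger to the smaller median,
  rounded to the nearest integer below 100 and to one significant figure
  above (so 298 reports as 300), with the direction relative to the
  reference.
* **Mann-Whitney** comparisons use the exact permutation distribution when
  the smaller group has at most 8 observations and no ties (the study's
  replicate counts are in this range), and the tie-corrected normal
  approximation otherwise; both routes delegate to `stats::wilcox.test`,
  and the test suite checks the exact route against full enumeration of
  labelings.
* **Repair-type distributions** are compared by Pearson chi-square on the
  counts table without continuity correction (`stats::chisq.test`), with a
  flag when any expected count is below 5 (routine here, as cohorts are a
  few dozen junctions).  The package reports its own p-values; the
  significance annotations printed alongside the original tables are not
  reproducible from the printed counts with a standard 2 x k test, and no
  attempt is made to match them.
* **Percentages** in report tables are always rendered from counts (never
  the reverse) by rounding half away from zero.  The original tables mix two
  rounding conventions across rows; nearest-integer reproduces the rows this
  package asserts and is applied uniformly.

## Karyotype arithmetic

`translocatedSizes()` predicts translocated-chromosome sizes as sums of
parental fragment lengths (break-to-end distances in kb), with junction
indels invisible at gel resolution.  Material conservation (translocated
sizes sum to parental lengths) holds identically.  Fragment lengths are
configuration: the partial-assay model reproduces the observed 596- and
811-kb bands, the non-complementary model the 1450- and 730-kb bands; the
published band sizes for the latter are rounded to the kb and are mutually
inconsistent by 1 kb with the genome chromosome lengths, so the shipped
configuration uses fragment lengths that sum exactly.

## Problem sizes and determinism

The test-suite and acceptance computations use: 1000 random junctions for
the enumerate-and-rank versus exhaustive-search comparison, 15 junctions per
type per system for truth recovery, cohorts of 24 for the wild-type
round-trip, 500 plating replicates for estimator bias, and 100 random
karyotype models for conservation — sizes chosen to hold Monte-Carlo noise
well below the effects being checked while keeping the default run fast.
Every stochastic computation takes an explicit seed, and
`simulate -> classify -> report` is byte-reproducible for a fixed seed.

## Worked example

```{r example}
assay <- builtinAssay("partial")
junction <- paste0(assay@leftEnd@duplexTop, "CA", assay@rightEnd@duplexTop)
cl <- classifyJunction(junction, assay)
cl$type
cl$explanation
```

```{r cohort}
res <- runPipeline("WT", 24, "partial", seed = 1)
res$truthAgreement
res$classified$distribution
```

## Known limitations

* Per-junction validation against the original sequenced translocants is
  impossible from text: those sequences are published as images.  The
  package validates against the derived signatures and printed count tables
  instead.
* The explanation engine emits one canonical (minimal) bottom-strand
  completion per string family; physically larger resections that produce
  the same sequence are cost-dominated and not enumerated.
* Microhomologies are sought between the left end's protruding strand and
  the right end's sequence; the mirror orientation (right overhang into the
  left flank) is not part of the shipped assays' repair spectrum.
* The assay geometry text notes that 1-nt tip pairing generates 2-nt gaps;
  the arithmetic for a 4-nt overhang implies 3-nt gaps in that register.
  The classifier keys on intact overhangs plus templated fill rather than a
  fixed gap size, so this discrepancy does not affect classification.
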