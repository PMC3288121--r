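---
title: "Helitron discovery and structural analysis: models and methods"
author: "helitronr maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Helitron discovery and structural analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helitronr)
```

## The problem

Helitrons are DNA transposons thought to move by rolling-circle replication.
Unlike classical DNA transposons they create no target-site duplication and
carry no terminal inverted repeats, which makes them hard to find. What they
do have is a set of structural hallmarks: a TC-motif at the 5'-terminus, a
CTRR-motif at the 3'-terminus, a 16-20 bp palindromic region that can form a
10-12 bp hairpin just upstream of the 3'-end, and a strong preference for
inserting between an adenine and a thymidine of the host sequence. In maize,
two families (helA and helB) are distinguished by their terminal consensus
sequences; elements frequently carry captured fragments of host genes, and
many elements contain more than one terminal structure.

`helitronr` turns the motif-based discovery strategy built on those hallmarks
into a reusable, testable toolkit, together with the downstream structural
analyses: pseudo-terminus classification, multi-termini profiling,
nested-transposition read-out prediction, homology-based copy-number tiers
and boundary validation, and inference of stepwise gene-fragment
capture/loss histories.

## Terminal motif model

Each terminus is described by a motif expression over the DNA alphabet with
character classes and bounded quantifiers; `"."` means exactly one of
A/C/G/T. Nine built-in patterns are shipped (`helitron_patterns("all")`):
a loose 5'/3' pair per family for a sensitive first pass, a strict pair per
family for the confident second pass, and the pseudo 3'-terminus consensus
for helA, in which the otherwise invariant CTAG has decayed to CTAT.

Three numerical choices matter here:

* **N never matches**, including at wildcard positions. On gapped or masked
  assemblies this keeps calling conservative; a single N inside an otherwise
  perfect terminus kills the hit.
* **Variable quantifiers are enumerated exhaustively**, so *every* distinct
  match length at a start position is reported rather than one greedy match.
  Downstream pairing picks the element end among them; multiple termini are
  biological signal, not noise to collapse.
* **Both strands are scanned by default.** The source discovery strategy is
  silent on strand; scanning both is this package's choice, and
  `strand_mode = "forward"` restores the single-strand behaviour.

One quirk is preserved verbatim: the loose helA 3' pattern begins `CCCGT`
while the strict one begins `CCGT`. Whether the extra C was intentional in
the original screen is unknowable from the printed patterns, so both are
implemented exactly as printed and the strictness-containment property is
asserted only where the context makes it well-defined.

## Pairing termini into elements

A call is made for every 5'-terminus locus that has a same-family,
same-strand 3'-terminus hit ending strictly less than 20 kb downstream
(`max_span_bp`, measured 5'-hit start to 3'-hit end; the source rule
"less than 20 kb between two candidates" does not fix the measurement
endpoints, and start-to-end is the conservative reading). Among multiple
in-range 3'-hits the **farthest** becomes the element end: internal 3'
structures are pseudo termini of one larger element, not separate elements.
Intervening 5'- and 3'-hits are recorded as multiple-termini counts.
Distinct termini are identified by their element-proximal anchor (start for
5', end for 3'), so quantifier-length variants of one motif collapse to one
locus. A 3'-hit in range of two upstream 5'-hits is deliberately assigned
to both, and the overlap is visible in the output.

AT-flank and hairpin results are annotations, never filters — the original
screen filtered on termini only. The hairpin search scores candidate stems
as `stem length - mismatches` (defaults: stem 8-10, loop <= 4, <= 1
mismatch, 50 bp window), realizing the canonical 16-20 bp palindrome. Ties
are broken by fewer mismatches first, then smaller distance to the 3'-end,
then longer stem. The mismatch tie-break is one deliberate refinement over
a pure distance tie-break: without it, a perfect planted palindrome would
systematically be reported as a one-mismatch-padded longer stem, which
contradicts the intended reading of the score.

"Putative autonomous" is a structural proxy only: length > 10 kb and no
overlap with a user-supplied mask of other long transposons. No ORF or
protein-domain annotation is attempted (out of scope).

## Pseudo termini and nested read-out

Real 3'-termini end in the conserved CTAG (as CTAGT in the motifs); pseudo
3'-termini carry the decayed CTAT. The pseudo consensus is scanned
genome-wide; with `exclude_real = TRUE` (default) any pseudo match whose
locus overlaps a strict real 3'-terminus match is reported as real
(`ctag_intact = TRUE`) instead of entering the pseudo set. This implements
the ambiguous "avoiding 3'-termini that ended in a guanine base" exclusion
in the only way that cannot swallow real termini; the flag exposes the
alternative reading. Pseudo 5'-termini are indistinguishable from real ones
at the sequence level, so 5'-hits inside element bodies are classified by
position alone.

Nested-transposition products are predicted by pure interval bookkeeping: a
read-out launched from one element's 5'-terminus in a nested configuration
copies everything through the outermost element's final 3'-terminus. The
product therefore carries every 3'-terminus at or downstream of the launch
point and every 5'-terminus in that span; the remnant keeps the complement,
and product + remnant always equals the configuration totals. For the
canonical three-level configuration launched from the innermost 5' this
yields a product with three 3'-termini and a remnant with two 5'-termini —
the proposed origin of multiple-termini elements. No replication chemistry
is modeled; the evidence this mirrors is structural.

## Local similarity search

The homology engine is a deliberately transparent BLASTN stand-in: exact
11-mer seeds, per-diagonal maximal-scoring ungapped segments (match +1,
mismatch -2), chaining of collinear segments across gaps up to 20 bp within
a 15-diagonal band (gap -3 per bp), and per-locus merging keeping the best
score. Identity is computed over aligned columns, coverage over query
length. All parameters are exposed.

Consequences to be aware of:

* Sensitivity is that of exact 11-mer seeding: alignments much below ~70%
  identity can lack seeds and be missed. The discovery thresholds
  (5'-probe > 25 bp at > 70%, 3'-probe > 25 bp at > 80%, pairing < 20 kb)
  are applied after alignment, as in the source criteria.
* The ungapped-plus-chaining model absorbs small indels but will split
  alignments at large insertions. Segment decomposition relies on exactly
  this behaviour.
* Copy-number tiers follow the standard table: coverage/identity > 95/95,
  > 90/90, > 85/85, and the relaxed tier of aligned length > 200 bp at
  identity > 80% ("coverage" in that row is a length, and is implemented as
  aligned length). Distinct loci are counted greedily by score with no
  subject overlap; counts must be non-decreasing from strict to relaxed
  tiers and a violation warns.
* Boundary validation extends each copy's locus outward until windowed
  column identity across copies drops below 60% over 10 bp. Column identity
  is the fraction of copy *pairs* agreeing, not the majority-base fraction:
  with few copies the majority fraction of unrelated columns hovers near
  0.56, uncomfortably close to the 0.6 threshold, while pairwise agreement
  sits near 0.25 and makes the divergence point sharp. Identical flanks
  (tandem duplications) never diverge and are flagged unresolvable.

The dual-route check for this module is a brute-force ungapped
dynamic-programming oracle (all diagonals, all segments, via `outer()`)
kept in the test helpers, structurally independent of the scanning code.

## Capture and loss histories

Related elements are decomposed into shared segment blocks: all-vs-all
local alignments define breakpoints, breakpoints are propagated across
elements to a fixed point (snapping tolerance 10 bp), atomic segments are
linked through the alignments and transitively clustered into block ids
(>= 85% identity, >= 50 bp by default; shorter fragments are treated as
indel noise). Each element becomes an ordered block string; runs of blocks
with identical adjacency everywhere are merged.

Event inference is string editing on block strings: one contiguous novel
run inserted is a `capture`, one contiguous run deleted is a `loss`, a
full string embedded in another is a `nested_insertion`. Every emitted
edge must replay exactly on the block strings (checked internally).
Because a capture read forward is a loss read backward, the paired edges
stay flagged ambiguous unless a third element that shares the parent
configuration — and lacks the inserted run — orients them; that is the
three-or-more-element parsimony the source analyses used. Minimal-event
explanations are shortest paths in the resulting graph.

Hypothetical intermediate elements are represented in the container
(`hypothetical_nodes`) but are never synthesized automatically: at desk
scale there is no orientation evidence to trigger the synthesis reliably,
so the package reports nested-insertion edges and ambiguity flags and
leaves intermediate postulation to the analyst.

## The synthetic world

`generate_genome()` states the world the tests live in: i.i.d. background
at GC 0.47 (maize-like), element lengths log-uniform over 128-20,874 bp
(the documented observed range, with the observed small-size skew), termini
sampled uniformly from the strict pattern languages (so every quantifier
variant is exercised), an always-planted 16 bp perfect palindrome directly
upstream of the 3'-terminus, A...T host dinucleotides at every insertion
site, captured fragments copied from the background (donor recorded), a
decayed CTAT pseudo 3'-terminus in 28.7% of helAs and an extra internal
5'-terminus in 17.6% (the documented multi-termini fractions; helBs never
multi-termini), nesting at 10%, and both strands at 50%. Probabilities are
realized as deterministic proportions (`round(p * n)`, randomly assigned)
so truth fractions are reproducible, and one seed fixes everything.

Two deliberate choices deserve emphasis:

* **Insertion sites sit at least the pairing span (20 kb) apart.** Closer
  same-family neighbours would be *merged into one call by the pairing rule
  itself* — that is correct behaviour, not a recovery failure — so the
  planted-recovery world keeps elements separable. Likewise the recovery
  suites use a callable length range (< 20 kb) and nesting off, because an
  element longer than the span limit, or a child whose call legitimately
  extends to its parent's farther 3'-terminus, is unrecoverable *by
  definition of the rules being tested*, not by implementation defect. The
  generator's defaults keep the documented 128-20,874 bp range regardless.
* **The history simulator keeps event footprints >= 100 bp apart.** When
  two sequential captures land adjacently, their union is one contiguous
  novel run and the one-step explanation is genuinely minimal — no
  inference procedure could prefer the two-step truth. Recovery is
  therefore tested in the identifiable regime; compressed histories are
  correctly reported as shorter explanations.

What a green test does *not* establish: performance on real repeat
landscapes (no retrotransposon background beyond opaque mask intervals, no
terminus sequence decay beyond the planted CTAT pseudo termini, no
sequencing error), and none of the genome-wide counts from real maize data.

## Degenerate inputs and determinism

Empty FASTA files warn and return empty sets; duplicate ids and non-IUPAC
characters are errors naming the offender; IUPAC ambiguity codes become N.
Unsorted hit sets are an error rather than silently re-sorted, keeping
`pair_termini` deterministic; identical inputs give identical call lists
regardless of tie order. Orphan 5'-termini are logged, not dropped
silently. All CLI randomness flows from `--seed`, and every output
directory carries a manifest with parameters, input checksums and version.
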