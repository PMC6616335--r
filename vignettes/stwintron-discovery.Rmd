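---
title: "Finding and splicing spliceosomal twin introns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding and splicing spliceosomal twin introns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stwinscan)
```

## The model

A canonical fungal U2 intron carries three conserved elements: a 6-nt
**donor** at the 5' splice site (consensus `GURWGY`), a 6-nt element
around the lariat **branchpoint** adenosine (`RYURAY`; the adenosine is
position 5), and a 3-nt **acceptor** at the 3' splice site (`YAG`).  A
*spliceosomal twin intron* (stwintron) is a complex intervening sequence
in which an internal U2 intron interrupts one of those three elements of
an external U2 intron.  The class names the interrupted element — `[D]`
donor, `[L]` branchpoint element, `[A]` acceptor — and the split index
gives the insertion point: a `[D5,6]` stwintron has its internal intron
between the fifth and sixth donor nucleotide (`GURWG|Y`).  Because the
interrupted element is unusable, the external intron can only be excised
*after* the internal one: splicing is obligatorily inside-out.

Ascomycete introns are small and are paired by **intron definition**:
a donor pairs with the nearest compatible branchpoint/acceptor.  The
package encodes this as four testable principles
(`distance_rules()`, `validate_intron()`, `find_introns()`):

1. minimum intron length 42 nt;
2. branchpoint-to-acceptor distance at least 4 nt;
3. the donor-to-branchpoint distance strictly exceeds the
   branchpoint-to-acceptor distance;
4. paired splice sites are those nearest one another, subject to 1–3.

Distances are measured between elements, exclusive on both sides.  The
donor-to-branchpoint window defaults to 25–120 nt — consistent with a
mean intron length near 73 nt and the rarity of introns beyond 160 nt —
and the branchpoint-to-acceptor window to 4–24 nt.  The 24-nt upper
bound comes from the operational screening pattern rather than from
prose, and is configurable.  Where principle 3's "distance between
donor and branchpoint element" could be read either element-to-element
or donor-start-to-branch-A, we adopt element-to-element, which is the
arithmetic the screening pattern itself encodes.

Two consensus profiles are exposed rather than adjudicating between the
circulating donor variants: `"strict"` (`GTRWGY` / `RYTRAY` / `YAG`)
and `"relaxed"` (`GTRWGH` / `DYTRAY` / `HAG`).  `N` never matches any
motif position — conservative behaviour on draft assemblies.

## The search pattern

A stwintron of a given class and split is described by five degenerate
motifs: the internal intron's three elements plus the two *hybrid*
motifs in which the interrupted external element contributes its prefix
and suffix.  `build_stwintron_pattern()` assembles them with the rule
windows as gaps; for `[D5,6]` with the relaxed profile it serialises to

```{r}
pattern_to_string(build_stwintron_pattern(stwintron_class("D", 5)))
```

Because the hybrid pieces abut the internal intron, the external
intron's gap windows measured on the primary sequence equal the
post-excision distances, so the same `(25,120)`/`(4,24)` windows apply
on both sides.  `scan_gapped()` enumerates *every* placement satisfying
the per-position base sets and gap windows (overlaps included,
deterministic ordering); a deliberately naive `brute_force_scan()`
provides the independent oracle the tests compare against.  The raw
pattern is only a pre-filter: `scan_for_stwintrons()` then excises the
internal intron in silico and requires that the rejoined external
intron carry an uninterrupted consensus donor/branchpoint/acceptor and
pass `validate_intron()` on the rejoined sequence.  `[L]`-class calls
are emitted flagged `hypothetical`: that class is a structural
possibility without published experimental support.

## The splicing engine

`splice_to_completion()` repeatedly applies `splice_step()`, which
**re-scans the whole current sequence** with `find_introns()` rather
than patching coordinates — reconstituted donors and newly contiguous
second-order introns must be *discovered*, exactly as the spliceosome
sees them.  Every nucleotide of every intermediate maps back to a
primary-transcript coordinate (`rna_species()` provenance), so each
excision's *primary footprint* is known.  A footprint of one contiguous
segment is a standard intron; two segments mean the intron's donor (or
other element) was reconstituted by a previous excision (the external
intron of a stwintron); three or more segments mark a "second order"
intron that never existed contiguously in the primary transcript
(`detect_second_order()` reports the count).

With `branch = TRUE` the step branches on every rule-passing
(branchpoint, acceptor) alternative for the *leftmost* donor —
the mechanism behind exon skipping is alternative 3' splice sites, so
alternative donors are deliberately out of scope.  Intermediates
reached by different orders with identical sequence and provenance are
merged, making the result a DAG whose leaves are mature products;
`classify_products()` reports a skip when one leaf equals another minus
one contiguous internal primary segment.  `enumerate_orders()` explores
all excision sequences; `max_nodes` (default 10,000) guards against
branch explosion on low-complexity input.

## What the fixture generator emulates

The generators plant four architectures with machine-readable truth:

* `plant_stwintron()`: `exon–[D5,6]–exon`, internal/external introns of
  75/76 nt by default (the experimentally confirmed *A. nidulans*
  geometry), inside a continuous synthetic reading frame whose phase is
  configurable (default 1).
* `plant_alt_acceptor_fixture("downstream_acceptor")`: the *A. niger*
  situation — a second `CAG`, with its own branchpoint element, 26 nt
  downstream of the primary internal acceptor.  The secondary internal
  intron is 29 nt longer at its 3' end; after its excision the
  reconstituted donor sits only 23 nt from the external branchpoint
  element, so the 25–120 window (not an assumption coded by hand, but
  `validate_intron()` run on the candidate) blocks the primary pairing
  and the donor pairs with intron 2's acceptor, skipping the 15-nt
  exon II.
* `plant_alt_acceptor_fixture("external_acceptor")`: the *N. crassa*
  variation — the alternative internal 3' site *is* the external
  acceptor; exon II is 33 nt.
* `plant_dual_is_fixture()`: a stwintron plus a standard intron nested
  inside a discontinuous second-order intron whose donor, branchpoint
  element and acceptor only become contiguous after three excisions;
  four reactions reach the mature mRNA and the final footprint has
  three segments.

Non-element sequence (exons, intron interiors, spacers) comes from a
Markov chain that never emits the dinucleotides `AG`, `GT`, `TA` or
`TG` and fixes `C` at both ends of every filler.  This excludes donors,
acceptors, branchpoint elements and stop codons from all non-planted
positions, including across filler boundaries, so the truth annotation
is exhaustive by construction: recovery tests can assert *exact*
coordinates and *zero* false positives without rejection loops.
`random_background()` additionally offers the plainer i.i.d. background
with donor-motif rejection sampling for "natural" scans where false
positives are tallied rather than asserted.  One sampled-motif
constraint is applied in the dual-IS architecture: intron 2's donor may
not realise as `GTAAGx`, because its positions 3–5 would then offer an
acceptor-like `AAG` a legal 5 nt downstream of the second-order
branchpoint element.  Every generator re-runs the splicing engine on
its output and refuses to return a fixture whose behaviour deviates
from its own truth annotation.

Geometry not fixed by the published architectures was chosen once from
the distance windows themselves: flanking exons are 80 nt (long enough
that pattern elements cannot bridge adjacent features, short enough to
keep fixtures near 0.3–0.5 kb); the dual-IS spacers are 60/10/3/5 nt so
that the rejoined second-order gaps (70 and 8 nt) sit comfortably
inside the windows while every premature distance falls outside them;
the *A. niger*-style external interior is 52 nt so that the primary
external pairing is valid (52 ∈ 25–120), the post-secondary pairing is
blocked (23 < 25), and the internal donor cannot reach the external
branchpoint (122 > 120).

What the fixtures do **not** emulate: realistic base composition
(fillers avoid four dinucleotides entirely), imperfect splice sites
(the real *A. niger* intron-2 donor `GUAAAU` does not match the
consensus; fixtures plant consensus-conforming donors so the retention
path is visible to the deterministic matcher), polypyrimidine tracts,
and expression-level evidence.  Passing recovery on fixtures therefore
demonstrates correctness of the pattern algebra, pairing rules and
splice bookkeeping — not sensitivity/specificity on real genomes, where
manual curation of candidates remains necessary.

## Numerical and interface choices

* Coordinates are 1-based inclusive throughout the R API (the
  IRanges/Biostrings convention); GFF3 emits them unchanged and BED
  output converts to 0-based half-open at the boundary.  Gap windows
  keep the element-end-to-element-start semantics of the pattern
  string.
* When several branchpoint placements serve the same acceptor, the one
  nearest the acceptor wins (U2 scans proximal to the 3' site); the
  choice only matters for reporting the branch adenosine, not for the
  intron span.
* Overlapping donors each yield at most one canonical call; overlapping
  calls are all reported and downstream logic decides.
* Match ordering is total-span start, then lexicographic element
  starts — byte-identical across runs.
* Test problem sizes: oracle equivalence uses 100 seeded 2-kb
  backgrounds; recovery uses 50 seeded genomes with 1–3 planted
  stwintrons each.  These sizes exercise every code path while keeping
  the default suite under a minute.

## Known limitations

Only deterministic consensus matching is implemented — no PWM or
log-odds scoring, no U12 introns, no exon-definition pairing (never
described in ascomycetes), no kinetic or co-transcriptional modelling,
and no ortholog- or expression-based curation; `curate_orf_context()`
covers only the reading-frame criterion.  Scanning real chromosomes
works (multi-record FASTA, both strands) but candidate lists from
genome-scale scans are pre-filters for curation, not final calls.
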