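# stwinscan

Discovery and in-silico splicing of **spliceosomal twin introns
(stwintrons)** — complex intervening sequences in which an internal U2
intron interrupts one of the three canonical splicing elements of an
external U2 intron, so the external intron only becomes splicable after
the internal one has been excised.  Stwintrons occur widely in
filamentous fungi and take part in exon skipping and in the evolution
of intron structure; finding them and reasoning about their multi-step
excision is the job this package does, for anyone calling intron–exon
structure in fungal (or other intron-definition) genomes.

## What it computes

A U2 intron is modelled by its donor (`GURWGY`), branchpoint element
(`RYURAY`, branch adenosine at position 5) and acceptor (`YAG`), with
relaxed variants `GURWGH` / `DYURAY` / `HAG`, paired across the intron
by **intron definition** under four rules: minimum length 42 nt;
branchpoint→acceptor gap in 4–24 nt; donor→branchpoint gap in
25–120 nt and strictly larger than the branchpoint→acceptor gap; a
donor pairs with the nearest acceptor satisfying all of the above.

A stwintron of class `[D]`, `[L]` or `[A]` (named for the interrupted
element) is searched with a five-element degenerate gapped pattern —
the internal intron's elements plus two class-specific *hybrid* motifs.
For the `[D5,6]` class (internal intron between donor nt 5 and 6) the
pattern is

```
GTRWGGTRWGH(25,120)DYTRAY(4,24)HAGH(25,120)DYTRAY(4,24)HAG
```

Pattern hits are verified by in-silico excision: the internal intron is
removed and the rejoined external intron must carry an uninterrupted
consensus and pass the distance rules.  A splicing engine then excises
introns iteratively (re-scanning after every step, so reconstituted
donors are *discovered*), optionally branching on alternative 3' splice
sites, and returns the full splice graph with per-nucleotide coordinate
provenance — from which exon skipping and discontinuous "second order"
introns (excisable only after several prior reactions) are identified.

## Worked example

```r
library(stwinscan)

## a synthetic genome with one planted [D5,6] stwintron
## (75-nt internal / 76-nt external intron) and truth annotations
fix <- plant_stwintron(seed = 3)

scan_for_stwintrons(fix$seq, stwintron_class("D", 5))[[1]]
#> <stwintron_call> [D5,6] 80-230 (+) internal 85-159

graph <- splice_to_completion(fix$seq)
graph
#> <splice_graph> 3 nodes, 2 events, root S1, 1 leaves
for (e in graph$edges) print(e$event)
#> <splice_event> excises 75 nt; primary segments: 85-159; flags: standard,internal_of_stwintron
#> <splice_event> excises 76 nt; primary segments: 80-84,160-230; flags: external_of_stwintron
```

The scanner recovers the planted stwintron at positions 80–230 with its
internal intron at 85–159.  Splicing takes the obligatory two steps:
the 75-nt internal intron first (one contiguous primary segment), which
reconstitutes the external donor; then the 76-nt external intron, whose
excised footprint maps to *two* primary segments because its donor was
split in the primary transcript.

A dual intervening sequence — a stwintron and a standard intron nested
inside a discontinuous second-order intron — needs four reactions, the
last excising an intron whose footprint has three primary segments:

```r
dual <- plant_dual_is_fixture(seed = 5)
splice_to_completion(dual$seq)
#> <splice_graph> 5 nodes, 4 events, root S1, 1 leaves
detect_second_order(splice_to_completion(dual$seq)$edges[[4]]$event)
#> $discontinuous
#> [1] TRUE
#> $n_segments
#> [1] 3
```

A command-line interface wraps the same functions:

```sh
exec/stwinscan scan --fasta genome.fa --class D --split 5 --profile relaxed --out calls.gff3
exec/stwinscan splice --fasta transcript.fa --branch --out graph.json
```

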