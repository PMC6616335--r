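## Shared helpers for building deterministic test sequences.

REL <- consensus_profile("relaxed")
RULES <- distance_rules()

## A literal canonical intron: donor GTAAGC, branchpoint GCTAAC, acceptor
## CAG, all-C interiors (C runs can never hold a splice element).
literal_intron <- function(gA = 50, gB = 10) {
  paste0("GTAAGC", strrep("C", gA), "GCTAAC", strrep("C", gB), "CAG")
}

## Events of a linear (non-branching) graph, in excision order.
chain_events <- function(graph) lapply(graph$edges, `[[`, "event")

leaf_seqs <- function(graph) {
  vapply(graph$leaves, function(id) graph$nodes[[id]]$seq, character(1))
}

## Every edge must excise a GT...AG intron from its parent species.
expect_gt_ag_edges <- function(graph) {
  for (e in graph$edges) {
    parent <- graph$nodes[[e$from]]$seq
    span <- e$event$intron$span
    excised <- substr(parent, span[1], span[2])
    expect_identical(substr(excised, 1, 2), "GT")
    expect_identical(substr(excised, nchar(excised) - 1, nchar(excised)), "AG")
  }
}

## Length conservation: every edge removes exactly its intron's length,
## and child provenance is the parent's minus the excised footprint.
expect_conservation <- function(graph) {
  for (e in graph$edges) {
    parent <- graph$nodes[[e$from]]
    child <- graph$nodes[[e$to]]
    span <- e$event$intron$span
    expect_identical(nchar(parent$seq) - nchar(child$seq),
                     span[2] - span[1] + 1L)
    expect_identical(child$provenance,
                     parent$provenance[-(span[1]:span[2])])
  }
}
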