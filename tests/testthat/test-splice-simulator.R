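test_that("rna_species enforces the provenance invariants", {
  sp <- rna_species("ACGT")
  expect_identical(sp$provenance, 1:4)
  expect_error(rna_species("ACGT", c(1, 2, 3)), "one entry per nucleotide")
  expect_error(rna_species("ACGT", c(1, 3, 3, 4)), "strictly increasing")
})

test_that("one splice step excises the internal intron and reconstitutes the donor", {
  fix <- plant_stwintron(seed = 3)
  sp <- rna_species(fix$seq)
  steps <- splice_step(sp, REL, RULES, branch = FALSE)
  expect_length(steps, 1)
  ev <- steps[[1]]$event
  expect_identical(ev$intron$span, fix$features[[1]]$internal_span)
  expect_true(ev$flags$standard)
  expect_identical(ev$n_segments, 1L)
  ## the rejoined donor matches the profile on the child species
  child <- steps[[1]]$child
  expect_true(matches_at(REL$donor, child$seq, fix$features[[1]]$total_span[1]))

  ## intron-free species
  expect_identical(splice_step(rna_species(strrep("CA", 50))), list())
})

test_that("branching exposes alternative 3' splice sites 29 nt apart", {
  fix <- plant_alt_acceptor_fixture(seed = 1, variant = "downstream_acceptor")
  steps <- splice_step(rna_species(fix$seq), REL, RULES, branch = TRUE)
  expect_length(steps, 2)
  expect_false(steps[[1]]$event$flags$alternative_acceptor)
  expect_true(steps[[2]]$event$flags$alternative_acceptor)
  spans <- lapply(steps, function(st) st$event$intron$span)
  expect_identical(spans[[1]][1], spans[[2]][1])          # same donor
  expect_identical(spans[[2]][2] - spans[[1]][2], 29L)    # 3'-extended
})

test_that("a plain stwintron splices in two steps with a 2-segment external intron", {
  fix <- plant_stwintron(seed = 3)
  g <- splice_to_completion(fix$seq, REL, RULES)
  expect_length(g$nodes, 3)
  expect_length(g$edges, 2)
  evs <- chain_events(g)
  expect_true(evs[[1]]$flags$standard)
  so <- detect_second_order(evs[[2]])
  expect_true(so$discontinuous)
  expect_identical(so$n_segments, 2L)
  expect_true(evs[[2]]$flags$external_of_stwintron)
  expect_true(evs[[1]]$flags$internal_of_stwintron)
  expect_false(detect_second_order(evs[[1]])$discontinuous)
  expect_identical(g$nodes[[g$leaves]]$seq, fix$mature)
  expect_conservation(g)
  expect_gt_ag_edges(g)
})

test_that("the dual intervening sequence needs four reactions ending in a 3-piece intron", {
  fix <- plant_dual_is_fixture(seed = 5)
  g <- splice_to_completion(fix$seq, REL, RULES)
  expect_length(g$nodes, 5)
  expect_length(g$edges, 4)
  last <- chain_events(g)[[4]]
  expect_true(last$flags$second_order)
  so <- detect_second_order(last)
  expect_true(so$discontinuous)
  expect_identical(so$n_segments, 3L)
  ## the three pieces: donor upstream of the stwintron, branchpoint
  ## element between stwintron and intron 2, acceptor behind intron 2
  fp <- last$primary_footprint
  expect_identical(fp[1, 1], fix$features$d0_span[1])
  expect_identical(fp[3, 2], fix$features$acc0_span[2])
  expect_identical(g$nodes[[g$leaves]]$seq, fix$mature)
  expect_conservation(g)
  expect_gt_ag_edges(g)
})

test_that("the external intron is never excisable before its internal intron", {
  for (s in c(3, 17)) {
    fix <- plant_stwintron(seed = s)
    truth <- fix$features[[1]]
    for (ord in enumerate_orders(fix$seq, REL, RULES)) {
      internal_idx <- which(vapply(ord, function(e) {
        e$n_segments == 1L &&
          identical(e$primary_footprint[1, ], truth$internal_span)
      }, logical(1)))
      external_idx <- which(vapply(ord, function(e) e$n_segments == 2L,
                                   logical(1)))
      expect_true(length(internal_idx) == 1 && length(external_idx) == 1)
      expect_lt(internal_idx, external_idx)
    }
  }
})

test_that("branch simulation yields exactly the retained and skipped products", {
  for (variant in c("downstream_acceptor", "external_acceptor")) {
    fix <- plant_alt_acceptor_fixture(seed = 2, variant = variant)
    g <- splice_to_completion(fix$seq, REL, RULES, branch = TRUE)
    expect_length(g$leaves, 2)
    expect_setequal(unname(leaf_seqs(g)), c(fix$mature_retain, fix$mature_skip))
    rep <- classify_products(g)
    expect_identical(nrow(rep$skips), 1L)
    expect_identical(rep$skips$length, fix$expected$skip_len)
    expect_identical(rep$skips$start, fix$features$exon2_span[1])
    expect_identical(rep$skips$end, fix$features$exon2_span[2])
    expect_conservation(g)
    expect_gt_ag_edges(g)
  }
  ## single-leaf graphs report no skip
  plain <- splice_to_completion(plant_stwintron(seed = 3)$seq, REL, RULES)
  expect_identical(nrow(classify_products(plain)$skips), 0L)
})

test_that("every excision order of the dual IS ends with the second-order intron", {
  fix <- plant_dual_is_fixture(seed = 5)
  orders <- enumerate_orders(fix$seq, REL, RULES)
  expect_length(orders, 3)
  expect_true(all(vapply(orders, function(o) {
    o[[length(o)]]$n_segments == 3L
  }, logical(1))))
  ## orders exist where intron 2 precedes the external intron
  i2 <- fix$features$intron2_span
  precedes <- vapply(orders, function(o) {
    idx_i2 <- which(vapply(o, function(e) {
      e$n_segments == 1L && identical(e$primary_footprint[1, ], i2)
    }, logical(1)))
    idx_ext <- which(vapply(o, function(e) e$n_segments == 2L, logical(1)))
    idx_i2 < idx_ext
  }, logical(1))
  expect_true(any(precedes))
  expect_false(all(precedes))
  ## a single canonical intron has exactly one order of length 1
  single <- paste0(strrep("C", 20), literal_intron(), strrep("C", 20))
  expect_identical(lengths(enumerate_orders(single, REL, RULES)), 1L)
})

test_that("mature provenance maps back to the planted exon coordinates", {
  fix <- plant_dual_is_fixture(seed = 8)
  g <- splice_to_completion(fix$seq, REL, RULES)
  leaf <- g$nodes[[g$leaves]]
  dual <- fix$features$dual_span
  expect_identical(leaf$provenance,
                   setdiff(seq_len(nchar(fix$seq)), dual[1]:dual[2]))
  ## duplicate intermediates merge: the graph guard trips on demand
  expect_error(splice_to_completion(fix$seq, REL, RULES, max_nodes = 2),
               "max_nodes")
})
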