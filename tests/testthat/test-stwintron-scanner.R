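test_that("hybrid patterns are built per class and split", {
  ## [D5,6] with the relaxed profile reproduces the canonical screen
  p56 <- build_stwintron_pattern(stwintron_class("D", 5), REL, RULES)
  expect_identical(pattern_to_string(p56),
                   "GTRWGGTRWGH(25,120)DYTRAY(4,24)HAGH(25,120)DYTRAY(4,24)HAG")

  ## [D1,2]: 1-nt donor prefix, 5-nt donor suffix around the acceptor
  p12 <- build_stwintron_pattern(stwintron_class("D", 1), REL, RULES)
  expect_identical(p12$elements[[1]]$pattern, "GGTRWGH")
  expect_identical(p12$elements[[3]]$pattern, "HAGTRWGH")

  ## [A2,3]: external donor and branchpoint lead; acceptor is interrupted
  pa <- build_stwintron_pattern(stwintron_class("A", 2), REL, RULES)
  expect_identical(vapply(pa$elements, `[[`, character(1), "pattern"),
                   c("GTRWGH", "DYTRAY", "HAGTRWGH", "DYTRAY", "HAGG"))

  ## [L] builds but is flagged hypothetical on calls
  pl <- build_stwintron_pattern(stwintron_class("L", 3), REL, RULES)
  expect_identical(pl$elements[[2]]$pattern, "DYTGTRWGH")

  expect_error(stwintron_class("D", 6), "1\\.\\.5")
  expect_error(stwintron_class("A", 3), "1\\.\\.2")
})

test_that("planted stwintrons are recovered exactly and class-exclusively", {
  fix <- plant_stwintron(seed = 3)
  truth <- fix$features[[1]]

  calls <- scan_for_stwintrons(fix$seq, stwintron_class("D", 5), REL, RULES)
  expect_length(calls, 1)
  call <- calls[[1]]
  expect_identical(call$total_span, truth$total_span)
  expect_identical(call$internal_span, truth$internal_span)
  expect_identical(call$element_starts, truth$element_starts)
  expect_identical(call$interrupted, "donor")
  expect_false(call$hypothetical)

  ## the same genome yields nothing under other class/split scans
  expect_length(scan_for_stwintrons(fix$seq, stwintron_class("D", 1), REL, RULES), 0)
  expect_length(scan_for_stwintrons(fix$seq, stwintron_class("A", 1), REL, RULES), 0)
  expect_length(scan_for_stwintrons(fix$seq, stwintron_class("A", 2), REL, RULES), 0)

  ## degenerate input
  expect_length(scan_for_stwintrons(strrep("A", 500)), 0)
})

test_that("the rejoined external intron always matches the uninterrupted consensus", {
  for (s in c(2, 8, 13)) {
    fix <- plant_stwintron(seed = s, n_features = 2)
    for (call in scan_for_stwintrons(fix$seq, fix$stw_class, REL, RULES)) {
      rejoined <- paste0(substr(fix$seq, 1, call$internal_span[1] - 1),
                         substr(fix$seq, call$internal_span[2] + 1, nchar(fix$seq)))
      ext <- call$external_rejoined
      expect_true(matches_at(REL$donor, rejoined, ext$donor[1]))
      expect_true(validate_intron(ext, RULES)$valid)
      expect_identical(substr(rejoined, ext$span[2] - 1, ext$span[2]), "AG")
    }
  }
})

test_that("reverse-strand scanning reports forward coordinates with a strand flag", {
  fix <- plant_stwintron(seed = 6)
  n <- nchar(fix$seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fix$seq)))
  expect_length(scan_for_stwintrons(rc, strand = "+"), 0)
  calls <- scan_for_stwintrons(rc, strand = "both")
  expect_length(calls, 1)
  expect_identical(calls[[1]]$strand, "-")
  fwd <- fix$features[[1]]$total_span
  expect_identical(calls[[1]]$total_span,
                   c(n - fwd[2] + 1L, n - fwd[1] + 1L))
})

test_that("ORF-context curation keeps in-frame candidates and drops stop-joined ones", {
  fix <- plant_stwintron(seed = 11, phase = 2)
  calls <- scan_for_stwintrons(fix$seq, fix$stw_class, REL, RULES)
  kept <- curate_orf_context(calls, fix$seq, window = 60)
  expect_length(kept, 1)
  expect_true(fix$phase %in% kept[[1]]$orf_phases)

  ## counter-fixture: excision joins stop codons in every frame
  block <- substr(fix$seq, fix$features[[1]]$total_span[1],
                  fix$features[[1]]$total_span[2])
  bad <- paste0(strrep("C", 60), "CTAAA", block, "TAAATAAC", strrep("C", 60))
  bad_calls <- scan_for_stwintrons(bad, fix$stw_class, REL, RULES)
  expect_length(bad_calls, 1)
  ## junction reads ...CTAAA|TAAATAAC...: TAA stops 4 nt apart hit all
  ## three frames
  expect_length(curate_orf_context(bad_calls, bad, window = 60), 0)

  expect_identical(curate_orf_context(list(), fix$seq, 60), list())
  expect_error(curate_orf_context(calls, fix$seq, window = 2), "at least 3")
})

test_that("multi-feature genomes are fully recovered with zero extra calls", {
  for (s in 1:6) {
    n_feat <- (s %% 3L) + 1L
    fix <- plant_stwintron(seed = 20 + s, n_features = n_feat)
    calls <- scan_for_stwintrons(fix$seq, fix$stw_class, REL, RULES)
    expect_length(calls, n_feat)
    for (i in seq_len(n_feat)) {
      expect_identical(calls[[i]]$total_span, fix$features[[i]]$total_span)
      expect_identical(calls[[i]]$element_starts,
                       fix$features[[i]]$element_starts)
    }
  }
})
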