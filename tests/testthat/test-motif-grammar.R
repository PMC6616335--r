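test_that("IUPAC motifs compile with per-position base sets and normalisation", {
  m <- compile_motif("GTRWGY")
  expect_s3_class(m, "degenerate_motif")
  expect_identical(m$length, 6L)
  expect_identical(m$allowed[[3]], c("A", "G"))
  expect_identical(m$allowed[[4]], c("A", "T"))
  ## RNA alphabet and lower case normalise to the same motif
  expect_identical(compile_motif("gurwgy"), m)
  expect_error(compile_motif("GTQ"), "position 3")
  expect_error(compile_motif(""), "non-empty")
})

test_that("matches_at honours allowed sets, rejects N, checks bounds", {
  don <- compile_motif("GTRWGY")
  expect_true(matches_at(don, "GTAAGT", 1))
  expect_false(matches_at(don, "GTCAGT", 1))   # C not in R
  expect_false(matches_at(compile_motif("YAG"), "NAG", 1))  # N never matches
  expect_true(matches_at(compile_motif("YAG"), "xCAGx", 2))
  expect_error(matches_at(don, "GTAAG", 1), "out of range")
  expect_error(matches_at(don, "GTAAGT", 2), "out of range")
})

test_that("pattern strings parse to elements and gap windows and serialise back", {
  txt <- "GTRWGGTRWGH(25,120)DYTRAY(4,24)HAGH(25,120)DYTRAY(4,24)HAG"
  p <- parse_pattern_string(txt)
  expect_identical(vapply(p$elements, `[[`, integer(1), "length"),
                   c(11L, 6L, 4L, 6L, 3L))
  expect_identical(unname(p$gaps[, 1]), c(25L, 4L, 25L, 4L))
  expect_identical(unname(p$gaps[, 2]), c(120L, 24L, 120L, 24L))
  expect_identical(pattern_to_string(p), txt)

  abutting <- parse_pattern_string("GT(0,0)AG")
  expect_length(abutting$elements, 2)
  expect_identical(unname(abutting$gaps[1, ]), c(0L, 0L))

  expect_error(parse_pattern_string("GT(5,3)AG"), "min <= max")
  expect_error(parse_pattern_string("GT(1,2)"), "end with a motif")
  expect_error(parse_pattern_string("GT(1,2)(3,4)AG"), "alternate")
})

test_that("scan_gapped enumerates all overlapping placements deterministically", {
  p <- gapped_pattern(list("AG"), list())
  hits <- scan_gapped(p, "AGAG")
  expect_identical(vapply(hits, `[[`, integer(1), "start"), c(1L, 3L))

  ## all placements within a gap window are reported
  p2 <- gapped_pattern(list("GT", "AG"), list(c(0, 10)))
  hits2 <- scan_gapped(p2, "GTCCAGCCAG")
  expect_identical(lapply(hits2, `[[`, "element_starts"),
                   list(c(1L, 5L), c(1L, 9L)))

  expect_identical(scan_gapped(p2, ""), list())
  ## byte-identical determinism
  expect_identical(scan_gapped(p2, "GTCCAGCCAG"), scan_gapped(p2, "GTCCAGCCAG"))
})

test_that("brute-force oracle agrees with the indexed scanner", {
  pat <- build_stwintron_pattern(stwintron_class("D", 5), REL, RULES)
  ## planted fixture: exactly the truth match, identically in both scanners
  fix <- plant_stwintron(seed = 1)
  m_fast <- scan_gapped(pat, fix$seq)
  m_ref <- brute_force_scan(pat, fix$seq)
  expect_identical(m_fast, m_ref)
  expect_length(m_fast, 1)
  expect_identical(m_fast[[1]]$element_starts, fix$features[[1]]$element_starts)

  ## random sequences (seed 7 among them), including the RNA-alphabet copy
  for (s in c(7, 11, 23)) {
    sq <- random_background(2000, 0.5, seed = s)
    expect_identical(scan_gapped(pat, sq), brute_force_scan(pat, sq))
    expect_identical(scan_gapped(pat, chartr("T", "U", sq)),
                     scan_gapped(pat, sq))
  }
  ## guard and trivial cases
  expect_error(brute_force_scan(pat, strrep("A", 10001)), "10 kb")
  expect_identical(brute_force_scan(pat, strrep("A", 50)), list())
})
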