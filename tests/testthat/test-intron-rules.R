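test_that("consensus profiles enforce the element invariants", {
  strict <- consensus_profile("strict")
  relaxed <- consensus_profile("relaxed")
  expect_identical(strict$donor$pattern, "GTRWGY")
  expect_identical(strict$branchpoint$pattern, "RYTRAY")
  expect_identical(strict$acceptor$pattern, "YAG")
  expect_identical(relaxed$donor$pattern, "GTRWGH")
  expect_identical(relaxed$branchpoint$pattern, "DYTRAY")
  expect_identical(relaxed$acceptor$pattern, "HAG")
  ## every strict-matching site also matches the relaxed profile
  expect_true(all(vapply(seq_len(6), function(i) {
    all(strict$donor$allowed[[i]] %in% relaxed$donor$allowed[[i]])
  }, logical(1))))
  expect_error(consensus_profile(branchpoint = "RYTRGY"), "branch adenosine")
  expect_error(consensus_profile(acceptor = "YAT"), "end in G")
  expect_error(consensus_profile(donor = "GTRWG"), "6 nt")
})

test_that("validate_intron enumerates violated principles independently", {
  rules <- distance_rules()
  ## donor-bp gap 25, bp-acc gap 24: every rule satisfied, 25 > 24 holds
  ok <- intron_call(1, 1 + 6 + 25, 1 + 6 + 25 + 6 + 24)
  expect_identical(validate_intron(ok, rules),
                   list(valid = TRUE, violations = character(0)))

  ## donor-bp gap of 24 falls below the window
  short_gap <- intron_call(1, 31, 31 + 6 + 4)
  expect_identical(validate_intron(short_gap, rules)$violations, "donor_bp_gap")

  ## a 41-nt intron with gaps that pass under a loosened donor window
  ## violates only the minimum length
  loose <- distance_rules(donor_bp_gap = c(20, 120))
  short <- intron_call(1, 1 + 6 + 22, 1 + 6 + 22 + 6 + 4)  # 41 nt
  expect_identical(short$span[2] - short$span[1] + 1L, 41L)
  expect_identical(validate_intron(short, loose)$violations, "min_len")

  ## principle 3: donor-bp must exceed bp-acc strictly
  inverted <- distance_rules(donor_bp_gap = c(4, 120), bp_acc_gap = c(4, 120),
                             min_intron_len = 20)
  eq_gaps <- intron_call(1, 1 + 6 + 10, 1 + 6 + 10 + 6 + 10)
  expect_identical(validate_intron(eq_gaps, inverted)$violations, "principle3")
  lax <- distance_rules(donor_bp_gap = c(4, 120), bp_acc_gap = c(4, 120),
                        min_intron_len = 20, enforce_principle3 = FALSE)
  expect_true(validate_intron(eq_gaps, lax)$valid)
})

test_that("find_introns pairs each donor with its nearest rule-passing acceptor", {
  ## two disjoint literal introns in an inert background
  i1 <- literal_intron()          # 75 nt
  i2 <- literal_intron(51, 10)    # 76 nt
  seq <- paste0(strrep("C", 30), i1, strrep("C", 40), i2, strrep("C", 30))
  calls <- find_introns(seq, REL, RULES)
  expect_length(calls, 2)
  expect_identical(calls[[1]]$span, c(31L, 105L))
  expect_identical(calls[[2]]$span, c(146L, 221L))
  expect_identical(calls[[1]]$branch_a, 31L + 56L + 4L)
  ## every returned call passes validation
  for (cl in calls) expect_true(validate_intron(cl, RULES)$valid)

  ## nearest pairing: a second CAG beyond the first valid one is ignored
  seq2 <- paste0(strrep("C", 10), literal_intron(), "CCCCCAG", strrep("C", 10))
  call2 <- find_introns(seq2, REL, RULES)
  expect_length(call2, 1)
  expect_identical(call2[[1]]$span[2], 10L + 75L)

  ## intron-free input
  expect_identical(find_introns(strrep("CA", 200), REL, RULES), list())
})

test_that("stwintron fixtures expose only the internal intron to canonical calling", {
  fix <- plant_stwintron(seed = 4)
  calls <- find_introns(fix$seq, REL, RULES)
  ## the external donor is interrupted, so only the internal intron is seen
  expect_length(calls, 1)
  expect_identical(calls[[1]]$span, fix$features[[1]]$internal_span)
})

test_that("widening the distance windows never loses a donor and moves acceptors only nearer", {
  wider <- distance_rules(donor_bp_gap = c(20, 140), bp_acc_gap = c(4, 30))
  for (s in 1:5) {
    ## natural (non-sanitised) background so organic calls arise
    sq <- random_background(3000, 0.45, seed = 100 + s)
    base <- find_introns(sq, REL, RULES)
    wide <- find_introns(sq, REL, wider)
    donors_base <- vapply(base, function(cl) cl$donor[1], integer(1))
    donors_wide <- vapply(wide, function(cl) cl$donor[1], integer(1))
    expect_true(all(donors_base %in% donors_wide))
    for (cl in base) {
      m <- wide[[match(cl$donor[1], donors_wide)]]
      expect_lte(m$acceptor[2], cl$acceptor[2])
    }
  }
})

test_that("acceptor alternatives come back nearest-first and all validate", {
  fix <- plant_alt_acceptor_fixture(seed = 9, variant = "downstream_acceptor")
  d <- fix$features$stw$internal_span[1]
  alts <- find_acceptor_alternatives(fix$seq, d, REL, RULES)
  expect_length(alts, 2)
  ends <- vapply(alts, function(cl) cl$span[2], integer(1))
  expect_identical(ends, sort(ends))
  expect_identical(ends[2] - ends[1], 29L)   # 26-nt offset + 3-nt acceptor
  for (cl in alts) expect_true(validate_intron(cl, RULES)$valid)
  expect_error(find_acceptor_alternatives(fix$seq, d + 1, REL, RULES),
               "no donor")
})
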