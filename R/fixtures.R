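## ---------------------------------------------------------------------
## Synthetic genomes with planted introns, stwintrons, alternative-
## acceptor variants and dual intervening sequences, plus truth
## annotations.  All sampling is seeded; fixtures are byte-reproducible.
## ---------------------------------------------------------------------

#' Seeded random background sequence
#'
#' Independent-and-identically-distributed bases at a target GC fraction.
#' With `motif_free = TRUE` the sequence is rejection-sampled until no
#' occurrence of the profile's donor motif remains (occurrences are
#' resampled in place, up to 100 rounds), so that a pattern scan over the
#' background alone can never fire.
#'
#' @param len Length in nt (> 0).
#' @param gc GC fraction in `[0, 1]`.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param motif_free Remove all donor-motif occurrences?
#' @param profile [consensus_profile()] supplying the donor motif.
#' @return Character scalar.
#' @export
random_background <- function(len, gc = 0.5, seed = NULL, motif_free = FALSE,
                              profile = consensus_profile()) {
  len <- as.integer(len)
  if (is.na(len) || len <= 0L) stop("background length must be positive")
  run <- function() {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    chars <- sample(names(p), len, replace = TRUE, prob = p)
    if (motif_free) {
      for (round in 1:100) {
        sites <- motif_sites_chars(profile$donor, chars)
        if (length(sites) == 0L) break
        for (s in sites) {
          chars[s:(s + 5L)] <- sample(names(p), 6L, replace = TRUE, prob = p)
        }
      }
      if (length(motif_sites_chars(profile$donor, chars)) > 0L) {
        stop("could not produce a donor-motif-free background")
      }
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

## Filler sequence that cannot take part in any splice element: the
## dinucleotides AG, GT, TA and TG never occur, which excludes donors
## (need GT), acceptors (need AG), branchpoint elements (need T followed
## by A/G at positions 3-4) and all three stop codons in every frame.
## Both ends are fixed to C so that no element motif can straddle a
## filler boundary either.
safe_filler <- function(len) {
  len <- as.integer(len)
  if (len <= 0L) return("")
  if (len == 1L) return("C")
  trans <- list(A = c("A", "C", "T"), C = c("A", "C", "G", "T"),
                G = c("A", "C", "G"), T = c("C", "T"))
  chars <- character(len)
  chars[1] <- "C"
  for (i in 2:len) {
    opts <- trans[[chars[i - 1L]]]
    chars[i] <- opts[sample.int(length(opts), 1L)]
  }
  chars[len] <- "C"
  chars
}

filler_str <- function(len) paste(safe_filler(len), collapse = "")

## One uniformly sampled realisation of a degenerate motif.
sample_motif <- function(motif) {
  paste(vapply(motif$allowed,
               function(s) s[sample.int(length(s), 1L)], character(1)),
        collapse = "")
}

## Pick element-to-element gaps for a canonical intron of a given total
## length under the distance rules (donor 6 + gA + bp 6 + gB + acceptor 3).
choose_gaps <- function(len, rules = distance_rules()) {
  if (len < rules$min_intron_len) {
    stop(sprintf("intron length %d violates min_len (%d nt)",
                 len, rules$min_intron_len))
  }
  spare <- len - 15L
  lo <- max(rules$bp_acc_gap[1], spare - rules$donor_bp_gap[2])
  hi <- min(rules$bp_acc_gap[2], spare - rules$donor_bp_gap[1])
  if (rules$enforce_principle3) hi <- min(hi, (spare - 1L) %/% 2L)
  if (hi < lo) {
    stop(sprintf("no gap split of a %d-nt intron satisfies the distance windows",
                 len))
  }
  gB <- max(lo, min(10L, hi))
  c(gA = spare - gB, gB = gB)
}

## Canonical intron sequence with annotated relative spans (1-based).
make_intron_seq <- function(len = NULL, gA = NULL, gB = NULL,
                            profile = consensus_profile(),
                            rules = distance_rules(),
                            donor_seq = NULL, acc_seq = NULL) {
  if (is.null(gA) || is.null(gB)) {
    g <- choose_gaps(len, rules)
    gA <- g[["gA"]]; gB <- g[["gB"]]
  }
  gA <- as.integer(gA); gB <- as.integer(gB)
  len <- 15L + gA + gB
  donor_seq <- donor_seq %||% sample_motif(profile$donor)
  bp_seq <- sample_motif(profile$branchpoint)
  acc_seq <- acc_seq %||% sample_motif(profile$acceptor)
  list(seq = paste0(donor_seq, filler_str(gA), bp_seq, filler_str(gB), acc_seq),
       len = len, gA = unname(gA), gB = unname(gB),
       donor = c(1L, 6L), bp = c(7L + gA, 12L + gA),
       acc = c(len - 2L, len), donor_seq = donor_seq)
}

## Donor-disrupted stwintron block.  `interior` optionally replaces the
## external-intron interior (g3 nt between the rejoined donor and the
## external branchpoint element).
stw_block_d <- function(split = 5L, internal_len = 75L, g3 = NULL,
                        gB3 = NULL, external_len = NULL,
                        profile = consensus_profile(),
                        rules = distance_rules(),
                        interior = NULL, internal_acc = NULL) {
  if (is.null(g3) || is.null(gB3)) {
    g <- choose_gaps(external_len, rules)
    g3 <- g[["gA"]]; gB3 <- g[["gB"]]
  }
  g3 <- as.integer(g3); gB3 <- as.integer(gB3)
  ext_donor <- sample_motif(profile$donor)
  internal <- make_intron_seq(internal_len, profile = profile, rules = rules,
                              acc_seq = internal_acc)
  interior <- interior %||% filler_str(g3)
  stopifnot(nchar(interior) == g3)
  ext_bp <- sample_motif(profile$branchpoint)
  ext_acc <- sample_motif(profile$acceptor)
  prefix <- substr(ext_donor, 1L, split)
  suffix <- substr(ext_donor, split + 1L, 6L)
  seq <- paste0(prefix, internal$seq, suffix, interior, ext_bp,
                filler_str(gB3), ext_acc)
  ## relative coordinates (1-based within the block)
  I <- split + 1L                      # internal intron start
  E <- split + internal$len            # internal intron end
  list(seq = seq, split = split, len = nchar(seq),
       internal_len = internal$len,
       external_len = nchar(seq) - internal$len,
       g3 = g3, gB3 = gB3, gA1 = internal$gA, gB1 = internal$gB,
       internal_span = c(I, E),
       element_starts = c(1L,                       # hybrid donor piece
                          I + internal$bp[1] - 1L,  # internal branchpoint
                          I + internal$acc[1] - 1L, # hybrid acceptor piece
                          E + (6L - split) + g3 + 1L,       # external bp
                          E + (6L - split) + g3 + 7L + gB3) # external acceptor
  )
}

## Absolute-coordinate truth for one planted stwintron.
stw_truth <- function(block, offset) {
  es <- block$element_starts + offset
  list(total_span = c(offset + 1L, offset + block$len),
       internal_span = block$internal_span + offset,
       element_starts = es,
       split = block$split,
       internal_len = block$internal_len,
       external_len = block$external_len)
}

#' Plant donor-disrupted stwintrons in a synthetic genome
#'
#' Builds `exon - stwintron - exon - ...` genomes with 1 or more planted
#' `[D split,split+1]` stwintrons at rule-passing geometries (defaults:
#' 75-nt internal, 76-nt external intron) inside a continuous synthetic
#' open reading frame.  Exons and intron interiors are built from
#' element-free filler (see the package vignette), so the truth
#' annotation is exhaustive: the scanner must find the planted features
#' and nothing else.
#'
#' @param seed Integer seed.
#' @param n_features Number of planted stwintrons (>= 1).
#' @param internal_len,external_len Intron lengths in nt.
#' @param split Donor split point (default 5, i.e. `[D5,6]`).
#' @param exon_len Approximate exon length in nt.
#' @param phase Codon phase of the first stwintron junction (0/1/2).
#' @param profile A [consensus_profile()].
#' @param rules A [distance_rules()].
#' @param verify Re-run the splicing engine on the genome and error if it
#'   does not reproduce the truth (default TRUE).
#' @return List with `seq_id`, `seq`, `features` (truth spans per
#'   stwintron), `mature` (expected fully spliced sequence), `phase`, and
#'   `expected` (splice-graph shape: `n_nodes`, `n_events`).
#' @export
plant_stwintron <- function(seed = 1L, n_features = 1L,
                            internal_len = 75L, external_len = 76L,
                            split = 5L, exon_len = 80L, phase = 1L,
                            profile = consensus_profile(),
                            rules = distance_rules(), verify = TRUE) {
  stopifnot(n_features >= 1L, exon_len >= 30L)
  fix <- withr::with_seed(as.integer(seed), {
    len0 <- exon_len - (exon_len %% 3L) + (phase %% 3L)
    exons <- c(filler_str(len0),
               replicate(n_features, filler_str(exon_len)))
    blocks <- replicate(n_features, {
      stw_block_d(split, internal_len, external_len = external_len,
                  profile = profile, rules = rules)
    }, simplify = FALSE)
    seqs <- character(0)
    features <- list()
    offset <- 0L
    for (i in seq_len(n_features)) {
      seqs <- c(seqs, exons[i])
      offset <- offset + nchar(exons[i])
      features[[i]] <- stw_truth(blocks[[i]], offset)
      seqs <- c(seqs, blocks[[i]]$seq)
      offset <- offset + blocks[[i]]$len
    }
    seqs <- c(seqs, exons[n_features + 1L])
    list(seq_id = sprintf("stw_fixture_%d", seed),
         seq = paste(seqs, collapse = ""),
         features = features,
         mature = paste(exons, collapse = ""),
         phase = phase %% 3L,
         stw_class = stwintron_class("D", split),
         expected = list(n_nodes = 2L * n_features + 1L,
                         n_events = 2L * n_features))
  })
  if (verify) verify_chain(fix, profile, rules)
  fix
}

## Shared generator check: the splicing engine must reproduce the
## expected chain and mature product, else the fixture is invalid.
verify_chain <- function(fix, profile, rules, branch = FALSE) {
  g <- splice_to_completion(fix$seq, profile, rules, branch = branch)
  if (length(g$nodes) != fix$expected$n_nodes ||
      length(g$edges) != fix$expected$n_events) {
    stop(sprintf("fixture self-check failed: got %d nodes / %d events, expected %d / %d",
                 length(g$nodes), length(g$edges),
                 fix$expected$n_nodes, fix$expected$n_events))
  }
  matured <- vapply(g$leaves, function(id) g$nodes[[id]]$seq, character(1))
  if (!fix$mature %in% matured) {
    stop("fixture self-check failed: expected mature product not produced")
  }
  invisible(fix)
}

#' Plant an alternative-acceptor (exon skipping) fixture
#'
#' Architecture: `exon I - [D5,6] stwintron - exon II - standard intron 2
#' - exon III`.  The internal intron of the stwintron has *two* 3' splice
#' options, so branching simulation yields two mature products: exon II
#' retained, or skipped together with intron 2 inside a 3'-extended
#' "secondary" stwintron.
#'
#' Two variants are provided:
#' * `"downstream_acceptor"`: a second `CAG`, with its own branchpoint
#'   element, sits `offset` nt (default 26) downstream of the primary
#'   internal acceptor, extending the secondary internal intron by
#'   `offset + 3` nt at its 3' end.  After its excision the reconstituted
#'   external donor sits too close to the external branchpoint to pair
#'   (the donor-branchpoint window fails), so it pairs with intron 2's
#'   acceptor instead.  Skipped exon II defaults to 15 nt.
#' * `"external_acceptor"`: the alternative internal 3' splice site *is*
#'   the external intron's acceptor; its excision reconstitutes a donor
#'   at the exon II boundary which pairs with intron 2's acceptor.
#'   Skipped exon II defaults to 33 nt.
#'
#' @param seed Integer seed.
#' @param variant See above.
#' @param exon2_len Length of the skippable exon II (default 15 or 33 by
#'   variant).
#' @param offset Gap in nt between primary and secondary internal
#'   acceptor (`"downstream_acceptor"` only).
#' @param internal_len Primary internal intron length.
#' @param intron2_len Standard intron 2 length.
#' @param exon_len Flanking exon length.
#' @param profile,rules,verify As in [plant_stwintron()].
#' @return Fixture list; `expected` includes `skip_len` and `n_leaves`.
#' @export
plant_alt_acceptor_fixture <- function(seed = 1L,
                                       variant = c("downstream_acceptor",
                                                   "external_acceptor"),
                                       exon2_len = NULL, offset = 26L,
                                       internal_len = 75L, intron2_len = 50L,
                                       exon_len = 80L,
                                       profile = consensus_profile(),
                                       rules = distance_rules(),
                                       verify = TRUE) {
  variant <- match.arg(variant)
  exon2_len <- as.integer(exon2_len %||%
                            switch(variant, downstream_acceptor = 15L,
                                   external_acceptor = 33L))
  offset <- as.integer(offset)
  fix <- withr::with_seed(as.integer(seed), {
    if (variant == "downstream_acceptor") {
      gB2 <- 10L
      g3 <- 52L
      ## the secondary acceptor's own branchpoint element must fit
      ## strictly between the primary acceptor and the secondary
      ## acceptor, with a legal branchpoint-acceptor gap
      if (offset - gB2 - 7L < 0L) {
        stop(sprintf(
          "offset %d nt leaves no room for a distinct branchpoint element (need >= %d)",
          offset, gB2 + 7L))
      }
      bp2 <- sample_motif(profile$branchpoint)
      interior <- paste0(filler_str(offset - gB2 - 7L), bp2,
                         filler_str(gB2), "CAG",
                         filler_str(g3 - offset - 2L))
      block <- stw_block_d(5L, internal_len, g3 = g3, gB3 = 10L,
                           profile = profile, rules = rules,
                           interior = interior, internal_acc = "CAG")
      sec_ext <- offset + 3L      # 3' extension of the secondary internal
    } else {
      g3 <- 36L
      block <- stw_block_d(5L, internal_len, g3 = g3, gB3 = 10L,
                           profile = profile, rules = rules)
      sec_ext <- NULL
    }
    intron2 <- make_intron_seq(intron2_len, profile = profile, rules = rules)
    exon1 <- filler_str(exon_len)
    exon2 <- filler_str(exon2_len)
    exon3 <- filler_str(exon_len)
    seq <- paste0(exon1, block$seq, exon2, intron2$seq, exon3)
    S <- nchar(exon1)
    stw <- stw_truth(block, S)
    i2_off <- S + block$len + exon2_len
    ## geometry preconditions for the intended branch structure
    int_donor_end <- stw$internal_span[1] + 5L
    ext_bp_start <- stw$element_starts[4]
    if (variant == "downstream_acceptor") {
      ## (i) the internal donor must NOT reach the external acceptor
      if (ext_bp_start - int_donor_end - 1L <= rules$donor_bp_gap[2]) {
        stop("geometry conflict: internal donor can reach the external branchpoint")
      }
      ## (ii) after secondary excision the reconstituted donor must NOT
      ## pair with the primary external acceptor
      sec_donor_end <- stw$internal_span[2] + sec_ext + 1L
      if (ext_bp_start - sec_donor_end - 1L >= rules$donor_bp_gap[1]) {
        stop("geometry conflict: secondary stwintron donor still pairs with the primary acceptor")
      }
    }
    list(seq_id = sprintf("altacc_%s_%d", variant, seed),
         seq = seq, variant = variant,
         features = list(stw = stw,
                         exon2_span = c(S + block$len + 1L, i2_off),
                         intron2_span = c(i2_off + 1L, i2_off + intron2$len)),
         mature_retain = paste0(exon1, exon2, exon3),
         mature_skip = paste0(exon1, exon3),
         mature = paste0(exon1, exon2, exon3),
         expected = list(skip_len = exon2_len, n_leaves = 2L))
  })
  if (verify) {
    g <- splice_to_completion(fix$seq, profile, rules, branch = TRUE)
    matured <- vapply(g$leaves, function(id) g$nodes[[id]]$seq, character(1))
    if (length(g$leaves) != 2L ||
        !all(c(fix$mature_retain, fix$mature_skip) %in% matured)) {
      stop("fixture self-check failed: branch simulation did not yield the two expected products")
    }
  }
  fix
}

#' Plant a dual intervening sequence (second-order intron) fixture
#'
#' Architecture: `exon I - [ second-order donor .. [D5,6] stwintron ..
#' second-order branchpoint .. intron 2 .. second-order acceptor ] -
#' exon II`.  The outermost ("second order") intron is discontinuous in
#' the primary transcript -- its donor, branchpoint element and acceptor
#' are separated by the nested stwintron and intron 2 -- and becomes a
#' contiguous, rule-passing intron only after three prior excisions.
#' Four consecutive splicing reactions produce the mature mRNA; the
#' fourth excises the second-order intron, whose primary footprint has 3
#' segments.
#'
#' The generator asserts non-premature-splicability: at every
#' intermediate stage before the third excision, the second-order donor
#' has no rule-passing pairing (the distances to reachable branchpoint
#' elements fall outside the donor-branchpoint window).
#'
#' @param seed Integer seed.
#' @param internal_len Internal intron length of the nested stwintron.
#' @param g3,gB3 External-intron interior and branchpoint-acceptor gaps.
#' @param gap_a Second-order donor to stwintron distance.
#' @param gap_b Stwintron to second-order branchpoint distance.
#' @param gap_c Second-order branchpoint to intron 2 distance.
#' @param gap_d Intron 2 to second-order acceptor distance.
#' @param intron2_gA,intron2_gB Element gaps of intron 2.
#' @param exon_len Flanking exon length.
#' @param profile,rules,verify As in [plant_stwintron()].
#' @return Fixture list; `expected` records the 5-node 4-event chain and
#'   the 3-segment final excision.
#' @export
plant_dual_is_fixture <- function(seed = 5L, internal_len = 75L,
                                  g3 = 56L, gB3 = 10L,
                                  gap_a = 60L, gap_b = 10L,
                                  gap_c = 3L, gap_d = 5L,
                                  intron2_gA = 45L, intron2_gB = 4L,
                                  exon_len = 80L,
                                  profile = consensus_profile(),
                                  rules = distance_rules(),
                                  verify = TRUE) {
  fix <- withr::with_seed(as.integer(seed), {
    d0 <- sample_motif(profile$donor)
    bp0 <- sample_motif(profile$branchpoint)
    acc0 <- sample_motif(profile$acceptor)
    block <- stw_block_d(5L, internal_len, g3 = g3, gB3 = gB3,
                         profile = profile, rules = rules)
    ## intron 2 sits only gap_c nt after the second-order branchpoint, so
    ## its donor must not carry an acceptor-like triplet at positions 3-5
    ## (GTAAGx would offer the second-order donor a premature 3' site)
    repeat {
      i2_donor <- sample_motif(profile$donor)
      if (substr(i2_donor, 3L, 4L) != "AA") break
    }
    intron2 <- make_intron_seq(gA = intron2_gA, gB = intron2_gB,
                               profile = profile, rules = rules,
                               donor_seq = i2_donor)
    exon1 <- filler_str(exon_len)
    exon2 <- filler_str(exon_len)
    seq <- paste0(exon1, d0, filler_str(gap_a), block$seq,
                  filler_str(gap_b), bp0, filler_str(gap_c), intron2$seq,
                  filler_str(gap_d), acc0, exon2)

    X <- nchar(exon1)
    d0_span <- c(X + 1L, X + 6L)
    S <- X + 6L + gap_a                       # stwintron offset
    stw <- stw_truth(block, S)
    bp0_start <- S + block$len + gap_b + 1L
    i2_start <- bp0_start + 6L + gap_c
    acc0_start <- i2_start + intron2$len + gap_d
    dual_span <- c(d0_span[1], acc0_start + 2L)

    ## --- premature-splicability checks (donor-branchpoint window) ----
    int_bp <- stw$element_starts[2]
    ext_bp <- stw$element_starts[4]
    gap_to <- function(bp_start, removed) bp_start - removed - d0_span[2] - 1L
    checks <- c(
      primary_internal_bp = gap_to(int_bp, 0L),
      after_internal_ext_bp = gap_to(ext_bp, block$internal_len),
      after_stw_intron2_bp = gap_to(i2_start + 6L + intron2$gA, block$len)
    )
    if (any(checks <= rules$donor_bp_gap[2] & checks >= rules$donor_bp_gap[1])) {
      stop("premature splicability: the second-order donor can pair before the stwintron and intron 2 are gone")
    }
    so_gA <- gap_a + gap_b                     # after stw + intron 2 removed
    so_gB <- gap_c + gap_d
    if (so_gA < rules$donor_bp_gap[1] || so_gA > rules$donor_bp_gap[2] ||
        so_gB < rules$bp_acc_gap[1] || so_gB > rules$bp_acc_gap[2] ||
        (rules$enforce_principle3 && so_gA <= so_gB)) {
      stop("geometry conflict: the rejoined second-order intron fails the distance rules")
    }

    list(seq_id = sprintf("dual_is_%d", seed), seq = seq,
         features = list(stw = stw,
                         d0_span = d0_span,
                         bp0_span = c(bp0_start, bp0_start + 5L),
                         intron2_span = c(i2_start, i2_start + intron2$len - 1L),
                         acc0_span = c(acc0_start, acc0_start + 2L),
                         dual_span = dual_span),
         mature = paste0(exon1, exon2),
         expected = list(n_nodes = 5L, n_events = 4L,
                         last_event_segments = 3L))
  })
  if (verify) {
    g <- verify_chain(fix, profile, rules)
    g <- splice_to_completion(fix$seq, profile, rules)
    last <- g$edges[[length(g$edges)]]$event
    if (!isTRUE(last$flags$second_order) || last$n_segments != 3L) {
      stop("fixture self-check failed: final excision is not a 3-segment second-order intron")
    }
  }
  fix
}

#' Write a fixture to disk
#'
#' Emits `genome.fa` (FASTA), `truth.gff3` (planted feature spans) and
#' `truth.json` (full truth list including the expected splice-graph
#' shape and mature sequence).  Output bytes are deterministic given the
#' fixture.
#'
#' @param fix A fixture list from one of the `plant_*` generators.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "genome.fa")
  gff <- file.path(dir, "truth.gff3")
  js <- file.path(dir, "truth.json")
  dna <- Biostrings::DNAStringSet(stats::setNames(fix$seq, fix$seq_id))
  Biostrings::writeXStringSet(dna, fa)
  truth_gff(fix, gff)
  jsonlite::write_json(fix[setdiff(names(fix), "stw_class")], js,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(fasta = fa, gff3 = gff, json = js))
}

## GFF3 truth writer: one row per planted span.
truth_gff <- function(fix, path) {
  rows <- list()
  add <- function(type, span, id) {
    rows[[length(rows) + 1L]] <<- data.frame(type = type, start = span[1],
                                             end = span[2], id = id)
  }
  i <- 0L
  walk <- function(x) {
    nms <- names(x) %||% rep("", length(x))
    for (k in seq_along(x)) {
      el <- x[[k]]
      if (is.list(el) && !is.null(el$total_span)) {
        i <<- i + 1L
        add("twin_intron", el$total_span, sprintf("stw%d", i))
        add("intron", el$internal_span, sprintf("stw%d_internal", i))
      } else if (is.numeric(el) && length(el) == 2L && grepl("span", nms[k])) {
        add("region", el, nms[k])
      } else if (is.list(el)) {
        walk(el)
      }
    }
  }
  walk(fix$features)
  if (length(rows) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = fix$seq_id,
    ranges = IRanges::IRanges(
      start = vapply(rows, function(r) r$start, numeric(1)),
      end = vapply(rows, function(r) r$end, numeric(1))
    ),
    type = vapply(rows, function(r) r$type, character(1)),
    ID = vapply(rows, function(r) r$id, character(1))
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
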