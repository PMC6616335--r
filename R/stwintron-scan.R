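#' Stwintron class descriptor
#'
#' A spliceosomal twin intron (stwintron) is a complex intervening
#' sequence in which an internal U2 intron interrupts one of the three
#' canonical elements of an external U2 intron.  The class names the
#' interrupted element -- `D` (donor), `L` (lariat branchpoint element),
#' `A` (acceptor) -- and `split` gives the insertion point: a `[D5,6]`
#' stwintron carries its internal intron between the fifth and sixth
#' nucleotide of the external donor.
#'
#' Evidence exists for the `D` and `A` classes; `L`-class calls are
#' flagged hypothetical in all output.
#'
#' @param kind `"D"`, `"L"` or `"A"`.
#' @param split Integer insertion point within the interrupted element:
#'   1--5 for `D` and `L` (6-nt elements), 1--2 for `A` (3-nt element).
#' @return Object of class `stwintron_class`.
#' @export
stwintron_class <- function(kind = c("D", "L", "A"), split = 5L) {
  kind <- match.arg(kind)
  split <- as.integer(split)
  max_split <- if (kind == "A") 2L else 5L
  if (is.na(split) || split < 1L || split > max_split) {
    stop(sprintf("split for class [%s] must lie in 1..%d", kind, max_split))
  }
  structure(list(kind = kind, split = split), class = "stwintron_class")
}

#' @export
print.stwintron_class <- function(x, ...) {
  cat(sprintf("<stwintron_class> [%s%d,%d]%s\n", x$kind, x$split, x$split + 1L,
              if (x$kind == "L") " (hypothetical)" else ""))
  invisible(x)
}

#' Build the class-specific hybrid search pattern for a stwintron
#'
#' Five degenerate motifs describe a stwintron: the three canonical
#' elements of the internal intron, the two non-interrupted elements of
#' the external intron, and -- characteristic of the class -- two *hybrid*
#' motifs in which the interrupted external element contributes its
#' prefix/suffix around the internal intron's donor and acceptor.  For
#' the `[D5,6]` class with the relaxed profile this yields the literal
#' screen `GTRWGGTRWGH(25,120)DYTRAY(4,24)HAGH(25,120)DYTRAY(4,24)HAG`.
#'
#' Gap windows are taken from `rules`; for the interrupted element the
#' windows apply to the *post-excision* (rejoined) distances, which by
#' construction equal the pre-excision distances flanking the hybrid
#' pieces.
#'
#' @param stw_class A [stwintron_class()].
#' @param profile A [consensus_profile()].
#' @param rules A [distance_rules()].
#' @return A [gapped_pattern()] of five elements.
#' @export
build_stwintron_pattern <- function(stw_class = stwintron_class("D", 5L),
                                    profile = consensus_profile(),
                                    rules = distance_rules()) {
  stopifnot(inherits(stw_class, "stwintron_class"),
            inherits(profile, "consensus_profile"))
  d <- profile$donor$pattern
  b <- profile$branchpoint$pattern
  a <- profile$acceptor$pattern
  s <- stw_class$split
  gDB <- rules$donor_bp_gap
  gBA <- rules$bp_acc_gap
  switch(stw_class$kind,
    D = gapped_pattern(
      list(paste0(substr(d, 1L, s), d), b, paste0(a, substr(d, s + 1L, 6L)), b, a),
      list(gDB, gBA, gDB, gBA)
    ),
    L = gapped_pattern(
      list(d, paste0(substr(b, 1L, s), d), b, paste0(a, substr(b, s + 1L, 6L)), a),
      list(gDB, gDB, gBA, gBA)
    ),
    A = gapped_pattern(
      list(d, b, paste0(substr(a, 1L, s), d), b, paste0(a, substr(a, s + 1L, 3L))),
      list(gDB, gBA, gDB, gBA)
    )
  )
}

## Interpret one 5-element pattern match as internal/external intron
## coordinates on the primary sequence.  Returns NULL if the geometry is
## inconsistent (cannot happen for matches produced by the class pattern).
match_to_call <- function(m, stw_class) {
  s <- stw_class$split
  e <- m$element_starts
  switch(stw_class$kind,
    D = list(
      internal = intron_call(e[1] + s, e[2], e[3]),
      ext_donor_pieces = rbind(c(e[1], e[1] + s - 1L),
                               c(e[3] + 3L, e[3] + 3L + (6L - s) - 1L)),
      ext_bp = c(e[4], e[4] + 5L),
      ext_acc = c(e[5], e[5] + 2L),
      interrupted = "donor"
    ),
    L = list(
      internal = intron_call(e[2] + s, e[3], e[4]),
      ext_donor_pieces = rbind(c(e[1], e[1] + 5L)),
      ext_bp_pieces = rbind(c(e[2], e[2] + s - 1L),
                            c(e[4] + 3L, e[4] + 3L + (6L - s) - 1L)),
      ext_acc = c(e[5], e[5] + 2L),
      interrupted = "branchpoint"
    ),
    A = list(
      internal = intron_call(e[3] + s, e[4], e[5]),
      ext_donor_pieces = rbind(c(e[1], e[1] + 5L)),
      ext_bp = c(e[2], e[2] + 5L),
      ext_acc_pieces = rbind(c(e[3], e[3] + s - 1L),
                             c(e[5] + 3L, e[5] + 3L + (3L - s) - 1L)),
      interrupted = "acceptor"
    )
  )
}

## Excise [from, to] (1-based inclusive) from a string.
excise_string <- function(seq, from, to) {
  paste0(substr(seq, 1L, from - 1L), substr(seq, to + 1L, nchar(seq)))
}

#' Scan a sequence for stwintron candidates of one class
#'
#' Runs the class-specific hybrid pattern over the sequence, then applies
#' the mandatory excision-and-rejoin verification: the internal intron
#' must pass [validate_intron()] as-is, and after in-silico excision of
#' the internal intron the rejoined external intron must carry an
#' uninterrupted donor/branchpoint/acceptor matching the profile and pass
#' [validate_intron()] on the rejoined sequence.  The raw pattern is only
#' a pre-filter; the splicing model is the definition.
#'
#' @param seq Subject sequence (one record).
#' @param stw_class A [stwintron_class()].
#' @param profile A [consensus_profile()].
#' @param rules A [distance_rules()].
#' @param strand `"+"` scans the given strand only; `"both"` additionally
#'   scans the reverse complement and reports those calls with
#'   forward-strand coordinates and `strand = "-"`.
#' @return List of `stwintron_call` objects, sorted by total start.  Each
#'   has the class, the `internal` [intron_call()], `external_span`
#'   (including the nested internal intron), the interrupted element's
#'   piece spans, `hybrid_spans` (the two hybrid pattern elements),
#'   `total_span`, `strand`, and `hypothetical` (TRUE for class `L`).
#' @export
scan_for_stwintrons <- function(seq, stw_class = stwintron_class("D", 5L),
                                profile = consensus_profile(),
                                rules = distance_rules(),
                                strand = c("+", "both")) {
  strand <- match.arg(strand)
  seq <- normalize_seq(seq)
  calls <- scan_stwintrons_fwd(seq, stw_class, profile, rules)
  if (strand == "both") {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    n <- nchar(seq)
    rev_calls <- lapply(scan_stwintrons_fwd(rc, stw_class, profile, rules),
                        flip_call, n = n)
    calls <- c(calls, rev_calls)
  }
  calls[order(vapply(calls, function(cl) cl$total_span[1], integer(1)))]
}

scan_stwintrons_fwd <- function(seq, stw_class, profile, rules) {
  pattern <- build_stwintron_pattern(stw_class, profile, rules)
  matches <- scan_gapped(pattern, seq)
  out <- list()
  for (m in matches) {
    call <- verify_stwintron_match(m, seq, stw_class, profile, rules)
    if (!is.null(call)) out[[length(out) + 1L]] <- call
  }
  out
}

## Map a call on the reverse complement back to forward coordinates.
flip_span <- function(span, n) c(n - span[2] + 1L, n - span[1] + 1L)

flip_call <- function(call, n) {
  call$total_span <- flip_span(call$total_span, n)
  call$external_span <- flip_span(call$external_span, n)
  call$internal_span <- flip_span(call$internal_span, n)
  call$hybrid_spans <- t(apply(call$hybrid_spans, 1L, flip_span, n = n))[2:1, , drop = FALSE]
  call$strand <- "-"
  call
}

verify_stwintron_match <- function(m, seq, stw_class, profile, rules) {
  parts <- match_to_call(m, stw_class)
  internal <- parts$internal
  if (!validate_intron(internal, rules)$valid) return(NULL)

  ## in-silico excision of the internal intron; external coordinates on
  ## the rejoined sequence
  rejoined <- excise_string(seq, internal$span[1], internal$span[2])
  shift <- function(pos) {
    ifelse(pos > internal$span[2], pos - intron_length(internal), pos)
  }
  e <- m$element_starts
  ext <- switch(stw_class$kind,
    D = intron_call(e[1], shift(e[4]), shift(e[5])),
    L = intron_call(e[1], e[2], shift(e[5])),
    A = intron_call(e[1], e[2], e[3])
  )
  if (!validate_intron(ext, rules)$valid) return(NULL)
  ## the rejoined elements must match the uninterrupted consensus
  if (!matches_at(profile$donor, rejoined, ext$donor[1])) return(NULL)
  if (!matches_at(profile$branchpoint, rejoined, ext$bp[1])) return(NULL)
  if (!matches_at(profile$acceptor, rejoined, ext$acceptor[1])) return(NULL)

  hybrid <- switch(stw_class$kind,
    D = rbind(c(e[1], e[1] + stw_class$split + 5L),
              c(e[3], e[3] + 2L + (6L - stw_class$split))),
    L = rbind(c(e[2], e[2] + stw_class$split + 5L),
              c(e[4], e[4] + 2L + (6L - stw_class$split))),
    A = rbind(c(e[3], e[3] + stw_class$split + 5L),
              c(e[5], e[5] + 2L + (3L - stw_class$split)))
  )
  structure(
    list(stw_class = stw_class,
         internal = internal,
         internal_span = internal$span,
         external_span = c(m$start, m$end),
         external_rejoined = ext,
         interrupted = parts$interrupted,
         hybrid_spans = hybrid,
         element_starts = e,
         total_span = c(m$start, m$end),
         strand = "+",
         hypothetical = stw_class$kind == "L"),
    class = "stwintron_call"
  )
}

#' @export
print.stwintron_call <- function(x, ...) {
  cat(sprintf("<stwintron_call> [%s%d,%d] %d-%d (%s) internal %d-%d%s\n",
              x$stw_class$kind, x$stw_class$split, x$stw_class$split + 1L,
              x$total_span[1], x$total_span[2], x$strand,
              x$internal_span[1], x$internal_span[2],
              if (isTRUE(x$hypothetical)) " [hypothetical]" else ""))
  invisible(x)
}

#' Tabulate stwintron calls
#'
#' @param calls List of `stwintron_call` objects.
#' @return `data.frame` with one row per call.
#' @export
stwintron_calls_to_df <- function(calls) {
  if (length(calls) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      internal_start = integer(0), internal_end = integer(0),
                      class = character(0), strand = character(0)))
  }
  data.frame(
    start = vapply(calls, function(x) x$total_span[1], integer(1)),
    end = vapply(calls, function(x) x$total_span[2], integer(1)),
    internal_start = vapply(calls, function(x) x$internal_span[1], integer(1)),
    internal_end = vapply(calls, function(x) x$internal_span[2], integer(1)),
    class = vapply(calls, function(x)
      sprintf("%s%d,%d", x$stw_class$kind, x$stw_class$split,
              x$stw_class$split + 1L), character(1)),
    strand = vapply(calls, `[[`, character(1), "strand")
  )
}

#' Filter stwintron calls by open-reading-frame context
#'
#' Retains candidates that separate (known or putative) coding sequence:
#' after simulated full excision of the candidate, at least one reading
#' frame must cross the new exon-exon junction without a stop codon
#' within `window` nt on either side.  Each retained call is annotated
#' with the surviving frames and the corresponding intron phases.
#'
#' @param calls List of `stwintron_call` objects (forward strand).
#' @param seq The subject sequence the calls were made on.
#' @param window Context half-width in nt (>= 3).
#' @return The retained calls, each with added fields `orf_frames`
#'   (surviving 0-based frame offsets) and `orf_phases` (intron phase per
#'   surviving frame).
#' @export
curate_orf_context <- function(calls, seq, window = 60L) {
  window <- as.integer(window)
  if (window < 3L) stop("window must be at least 3 nt")
  seq <- normalize_seq(seq)
  stops <- c("TAA", "TAG", "TGA")
  keep <- list()
  for (call in calls) {
    spliced <- excise_string(seq, call$total_span[1], call$total_span[2])
    j <- call$total_span[1] - 1L          # last exonic base before the junction
    lo <- max(1L, j - window + 1L)
    hi <- min(nchar(spliced), j + window)
    frames <- integer(0)
    phases <- integer(0)
    for (o in 0:2) {
      starts <- seq.int(1L + o, nchar(spliced) - 2L, by = 3L)
      starts <- starts[starts >= lo & starts + 2L <= hi]
      codons <- substring(spliced, starts, starts + 2L)
      if (!any(codons %in% stops)) {
        frames <- c(frames, o)
        phases <- c(phases, (j - o) %% 3L)
      }
    }
    if (length(frames)) {
      call$orf_frames <- frames
      call$orf_phases <- phases
      keep[[length(keep) + 1L]] <- call
    }
  }
  keep
}
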