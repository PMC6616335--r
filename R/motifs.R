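#' Compile a degenerate IUPAC nucleotide motif
#'
#' A degenerate motif is a fixed-length pattern over the IUPAC nucleotide
#' alphabet.  Each position expands to the set of unambiguous bases it
#' allows (e.g. `R = {A,G}`, `Y = {C,T}`, `W = {A,T}`, `D = {A,G,T}`,
#' `H = {A,C,T}`).  RNA input is accepted: `U` is normalised to `T`, and
#' case is folded to upper case.
#'
#' An `N` in a *subject* sequence never matches any motif position, even a
#' motif `N`: allowed sets are expanded over `{A,C,G,T}` only, which gives
#' conservative calls on draft assemblies.
#'
#' @param pattern Character scalar, e.g. `"GTRWGY"`.
#' @return An object of class `degenerate_motif` with elements `pattern`
#'   (normalised string), `length`, and `allowed` (list of per-position
#'   base sets).
#' @examples
#' m <- compile_motif("GURWGY")   # RNA alphabet is fine
#' m$allowed[[3]]                 # "A" "G"
#' @export
compile_motif <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern) ||
      nchar(pattern) == 0L) {
    stop("motif pattern must be a single non-empty string")
  }
  pat <- chartr("U", "T", toupper(pattern))
  chars <- strsplit(pat, "", fixed = TRUE)[[1]]
  code <- Biostrings::IUPAC_CODE_MAP
  bad <- which(!chars %in% names(code))
  if (length(bad)) {
    stop(sprintf("invalid IUPAC code '%s' at position %d of motif '%s'",
                 chars[bad[1]], bad[1], pattern))
  }
  allowed <- lapply(chars, function(ch) strsplit(code[[ch]], "", fixed = TRUE)[[1]])
  structure(
    list(pattern = pat, length = length(chars), allowed = allowed),
    class = "degenerate_motif"
  )
}

#' @export
print.degenerate_motif <- function(x, ...) {
  cat("<degenerate_motif> ", x$pattern, " (", x$length, " nt)\n", sep = "")
  invisible(x)
}

## Normalise a subject sequence: upper case, U -> T.  Validation of the
## alphabet is left to the matcher (unknown characters simply never match).
normalize_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chartr("U", "T", toupper(seq))
}

#' Test a motif at one position of a sequence
#'
#' @param motif A [compile_motif()] result.
#' @param seq Character scalar (DNA/RNA; normalised internally).
#' @param pos 1-based start position; must satisfy
#'   `1 <= pos <= nchar(seq) - motif$length + 1`.
#' @return `TRUE` iff every base at `pos + i - 1` lies in the allowed set of
#'   motif position `i`.  `N` (or any non-ACGT character) never matches.
#' @export
matches_at <- function(motif, seq, pos) {
  stopifnot(inherits(motif, "degenerate_motif"))
  seq <- normalize_seq(seq)
  if (pos < 1L || pos > nchar(seq) - motif$length + 1L) {
    stop(sprintf("position %d out of range for a %d-nt motif on a %d-nt sequence",
                 pos, motif$length, nchar(seq)))
  }
  chars <- strsplit(substr(seq, pos, pos + motif$length - 1L), "", fixed = TRUE)[[1]]
  all(mapply(function(ch, set) ch %in% set, chars, motif$allowed))
}

## All 1-based start positions where `motif` matches `chars` (a character
## vector of single bases).  Vectorised over positions.
motif_sites_chars <- function(motif, chars) {
  n <- length(chars)
  L <- motif$length
  if (n < L) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  for (i in seq_len(L)) {
    ok <- ok & (chars[i:(n - L + i)] %in% motif$allowed[[i]])
  }
  which(ok)
}

#' All start positions of a degenerate motif in a sequence
#'
#' @inheritParams matches_at
#' @return Sorted integer vector of 1-based start positions (overlaps
#'   included).
#' @export
motif_sites <- function(motif, seq) {
  seq <- normalize_seq(seq)
  motif_sites_chars(motif, strsplit(seq, "", fixed = TRUE)[[1]])
}

#' Parse a gapped-pattern string
#'
#' The textual format alternates motif literals with `(min,max)` gap
#' windows, e.g. the five-element screen used for donor-disrupted twin
#' introns: `"GTRWGGTRWGH(25,120)DYTRAY(4,24)HAGH(25,120)DYTRAY(4,24)HAG"`.
#' Gaps are measured in nucleotides from the end of one element to the
#' start of the next (exclusive on both sides), so `(0,0)` means abutting
#' elements.
#'
#' @param text Pattern string.
#' @return An object of class `gapped_pattern`: `elements` (list of
#'   [compile_motif()] motifs) and `gaps` (two-column integer matrix of
#'   `min`/`max` windows, one row per adjacent element pair).
#' @export
parse_pattern_string <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  tokens <- regmatches(text, gregexpr("\\([0-9]+,[0-9]+\\)|[A-Za-z]+", text))[[1]]
  if (sum(nchar(tokens)) != nchar(text)) {
    stop("malformed pattern string: unparseable characters present")
  }
  is_gap <- startsWith(tokens, "(")
  if (length(tokens) == 0L || is_gap[1] || is_gap[length(tokens)]) {
    stop("pattern string must start and end with a motif literal")
  }
  if (!all(is_gap == rep(c(FALSE, TRUE), length.out = length(tokens)))) {
    stop("pattern string must alternate motif literals and (min,max) gaps")
  }
  elements <- lapply(tokens[!is_gap], compile_motif)
  gaps <- t(vapply(tokens[is_gap], function(tok) {
    as.integer(strsplit(gsub("[()]", "", tok), ",", fixed = TRUE)[[1]])
  }, integer(2)))
  gapped_pattern(elements, gaps)
}

#' Construct a gapped pattern from motifs and gap windows
#'
#' @param elements List of [compile_motif()] motifs (or pattern strings).
#' @param gaps Two-column matrix (or list of length-2 vectors) of
#'   `(min, max)` inter-element gap windows; one row fewer than elements.
#' @return A `gapped_pattern` object.
#' @export
gapped_pattern <- function(elements, gaps) {
  elements <- lapply(elements, function(e) {
    if (inherits(e, "degenerate_motif")) e else compile_motif(e)
  })
  if (is.list(gaps)) gaps <- do.call(rbind, gaps)
  if (length(elements) == 1L) {
    gaps <- matrix(integer(0), ncol = 2)
  }
  gaps <- matrix(as.integer(gaps), ncol = 2,
                 dimnames = list(NULL, c("min", "max")))
  if (nrow(gaps) != length(elements) - 1L) {
    stop("need exactly one gap window per adjacent element pair")
  }
  if (nrow(gaps) && any(gaps[, 1] < 0L | gaps[, 1] > gaps[, 2])) {
    stop("gap windows must satisfy 0 <= min <= max")
  }
  structure(list(elements = elements, gaps = gaps), class = "gapped_pattern")
}

#' Serialise a gapped pattern back to its textual form
#'
#' Inverse of [parse_pattern_string()].
#' @param pattern A `gapped_pattern`.
#' @return Character scalar.
#' @export
pattern_to_string <- function(pattern) {
  stopifnot(inherits(pattern, "gapped_pattern"))
  k <- length(pattern$elements)
  out <- character(0)
  for (i in seq_len(k)) {
    out <- c(out, pattern$elements[[i]]$pattern)
    if (i < k) {
      out <- c(out, sprintf("(%d,%d)", pattern$gaps[i, 1], pattern$gaps[i, 2]))
    }
  }
  paste(out, collapse = "")
}

#' @export
print.gapped_pattern <- function(x, ...) {
  cat("<gapped_pattern> ", pattern_to_string(x), "\n", sep = "")
  invisible(x)
}

## Assemble match records from element start positions.
make_match <- function(starts, lens) {
  ends <- starts + lens - 1L
  structure(
    list(element_starts = starts, element_ends = ends,
         start = starts[1], end = ends[length(ends)]),
    class = "pattern_match"
  )
}

## Deterministic ordering: by total start, then lexicographically by the
## remaining element starts.
order_matches <- function(matches) {
  if (length(matches) <= 1L) return(matches)
  keys <- vapply(matches, function(m) {
    paste(sprintf("%09d", m$element_starts), collapse = "")
  }, character(1))
  matches[order(keys)]
}

#' Scan a sequence with a gapped pattern
#'
#' Enumerates *every* placement of the pattern's elements that satisfies
#' all per-position base sets and all inter-element gap windows.
#' Overlapping matches are all reported; downstream callers filter.  The
#' result is deterministic: matches are sorted by total start, then
#' lexicographically by element starts.
#'
#' @param pattern A `gapped_pattern`.
#' @param seq Subject sequence (DNA or RNA; normalised internally).
#' @return List of `pattern_match` objects, each with `element_starts`,
#'   `element_ends`, `start`, `end` (1-based, inclusive).
#' @seealso [brute_force_scan()] for the reference implementation.
#' @export
scan_gapped <- function(pattern, seq) {
  stopifnot(inherits(pattern, "gapped_pattern"))
  seq <- normalize_seq(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- length(pattern$elements)
  lens <- vapply(pattern$elements, `[[`, integer(1), "length")
  sites <- lapply(pattern$elements, motif_sites_chars, chars = chars)
  if (any(lengths(sites) == 0L)) return(list())

  res <- list()
  recurse <- function(idx, starts) {
    if (idx > k) {
      res[[length(res) + 1L]] <<- make_match(starts, lens)
      return(invisible())
    }
    prev_end <- starts[idx - 1L] + lens[idx - 1L] - 1L
    lo <- prev_end + 1L + pattern$gaps[idx - 1L, 1]
    hi <- prev_end + 1L + pattern$gaps[idx - 1L, 2]
    for (p in sites[[idx]][sites[[idx]] >= lo & sites[[idx]] <= hi]) {
      recurse(idx + 1L, c(starts, p))
    }
  }
  for (p in sites[[1]]) recurse(2L, p)
  order_matches(res)
}

#' Brute-force reference scanner
#'
#' Independent oracle for [scan_gapped()]: a plain nested-loop enumeration
#' that tries every start position for the first element and every
#' position inside the declared gap window for each subsequent element,
#' testing the motif with [matches_at()] at each candidate.  Guarded to
#' sequences of at most 10 kb.
#'
#' @inheritParams scan_gapped
#' @return Same contract and ordering as [scan_gapped()].
#' @export
brute_force_scan <- function(pattern, seq) {
  stopifnot(inherits(pattern, "gapped_pattern"))
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  if (n > 10000L) stop("brute_force_scan is guarded to sequences <= 10 kb")
  if (n == 0L) return(list())
  k <- length(pattern$elements)
  lens <- vapply(pattern$elements, `[[`, integer(1), "length")

  res <- list()
  recurse <- function(idx, starts) {
    if (idx > k) {
      res[[length(res) + 1L]] <<- make_match(starts, lens)
      return(invisible())
    }
    prev_end <- starts[idx - 1L] + lens[idx - 1L] - 1L
    lo <- max(1L, prev_end + 1L + pattern$gaps[idx - 1L, 1])
    hi <- min(n - lens[idx] + 1L, prev_end + 1L + pattern$gaps[idx - 1L, 2])
    if (hi < lo) return(invisible())
    for (p in lo:hi) {
      if (matches_at(pattern$elements[[idx]], seq, p)) {
        recurse(idx + 1L, c(starts, p))
      }
    }
  }
  if (n >= lens[1]) {
    for (p in seq_len(n - lens[1] + 1L)) {
      if (matches_at(pattern$elements[[1]], seq, p)) recurse(2L, p)
    }
  }
  order_matches(res)
}

#' Tabulate pattern matches
#'
#' @param matches Result of [scan_gapped()] or [brute_force_scan()].
#' @return `data.frame` with one row per match: `start`, `end`, and
#'   `e<i>_start` columns for each element.
#' @export
matches_to_df <- function(matches) {
  if (length(matches) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  k <- length(matches[[1]]$element_starts)
  df <- data.frame(
    start = vapply(matches, `[[`, integer(1), "start"),
    end = vapply(matches, `[[`, integer(1), "end")
  )
  for (i in seq_len(k)) {
    df[[sprintf("e%d_start", i)]] <-
      vapply(matches, function(m) m$element_starts[i], integer(1))
  }
  df
}
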