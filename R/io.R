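## ---------------------------------------------------------------------
## Readers/writers: FASTA in, GFF3/BED/JSON/DOT out, YAML rule configs.
## Internal coordinates are 1-based inclusive; BED output is converted
## to 0-based half-open by the BED exporter.
## ---------------------------------------------------------------------

#' Read sequences from a FASTA file
#'
#' Wraps [Biostrings::readBStringSet()] (gzip handled transparently).
#' Sequences are upper-cased, `U` is normalised to `T`, and the alphabet
#' is validated against the IUPAC nucleotide codes; record order is
#' preserved.
#'
#' @param path FASTA file (optionally gzipped).
#' @return Named character vector of DNA sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  seqs <- vapply(seq_along(set), function(i) {
    s <- normalize_seq(as.character(set[[i]]))
    bad <- regmatches(s, regexpr(sprintf("[^%s]",
                        paste(names(Biostrings::IUPAC_CODE_MAP), collapse = "")), s))
    if (length(bad)) {
      stop(sprintf("record %d (%s): invalid character '%s'",
                   i, names(set)[i], bad))
    }
    s
  }, character(1))
  ## first whitespace-delimited token is the record id
  stats::setNames(seqs, sub("\\s.*$", "", names(set)))
}

## Lengths and splice roles of the five pattern elements per class.
pattern_element_info <- function(stw_class) {
  s <- stw_class$split
  switch(stw_class$kind,
    D = list(lens = c(s + 6L, 6L, 3L + (6L - s), 6L, 3L),
             types = c("splice_donor", "branch_point", "splice_acceptor",
                       "branch_point", "splice_acceptor"),
             hybrid = c(TRUE, FALSE, TRUE, FALSE, FALSE)),
    L = list(lens = c(6L, s + 6L, 6L, 3L + (6L - s), 3L),
             types = c("splice_donor", "splice_donor", "branch_point",
                       "splice_acceptor", "splice_acceptor"),
             hybrid = c(FALSE, TRUE, FALSE, TRUE, FALSE)),
    A = list(lens = c(6L, 6L, s + 6L, 6L, 3L + (3L - s)),
             types = c("splice_donor", "branch_point", "splice_donor",
                       "branch_point", "splice_acceptor"),
             hybrid = c(FALSE, FALSE, TRUE, FALSE, TRUE))
  )
}

class_tag <- function(stw_class) {
  sprintf("%s%d,%d", stw_class$kind, stw_class$split, stw_class$split + 1L)
}

#' Write stwintron calls as GFF3
#'
#' One `twin_intron` parent per call, with `intron` children (internal
#' and external) and one child per pattern element, typed
#' `splice_donor` / `branch_point` / `splice_acceptor` (hybrid elements
#' carry `hybrid=true`).  Coordinates are 1-based inclusive.  The parent
#' records the class tag (`stw_class=D5,6`), the element starts in the
#' scanned frame and, for reverse-strand calls, the scanned sequence
#' length, so that [read_calls_gff()] reconstructs the calls exactly.
#'
#' @param calls List of `stwintron_call` objects.
#' @param seq_id Sequence (record) identifier.
#' @param path Output path.
#' @param seq_len Length of the scanned sequence; required when any call
#'   is on the reverse strand.
#' @return Invisibly, `path`.
#' @export
write_calls_gff <- function(calls, seq_id, path, seq_len = NA_integer_) {
  rows <- list()
  add <- function(type, span, strand, id, parent = NA, extra = character(0)) {
    attrs <- c(sprintf("ID=%s", id),
               if (!is.na(parent)) sprintf("Parent=%s", parent),
               extra)
    rows[[length(rows) + 1L]] <<- sprintf(
      "%s\tstwinscan\t%s\t%d\t%d\t.\t%s\t.\t%s",
      seq_id, type, span[1], span[2], strand, paste(attrs, collapse = ";"))
  }
  for (i in seq_along(calls)) {
    call <- calls[[i]]
    if (call$strand == "-" && is.na(seq_len)) {
      stop("seq_len is required to emit reverse-strand calls")
    }
    pid <- sprintf("stw%d", i)
    info <- pattern_element_info(call$stw_class)
    ## a literal comma in an attribute value must be %-escaped in GFF3
    extra <- c(sprintf("stw_class=%s",
                       gsub(",", "%2C", class_tag(call$stw_class), fixed = TRUE)),
               sprintf("element_starts=%s",
                       paste(call$element_starts, collapse = " ")),
               if (isTRUE(call$hypothetical)) "hypothetical=true",
               if (call$strand == "-") sprintf("scanned_length=%d", seq_len))
    add("twin_intron", call$total_span, call$strand, pid, extra = extra)
    add("intron", call$internal_span, call$strand,
        paste0(pid, ".internal"), pid)
    add("intron", call$external_span, call$strand,
        paste0(pid, ".external"), pid)
    ## element children in the forward frame
    for (k in seq_len(5L)) {
      span <- c(call$element_starts[k],
                call$element_starts[k] + info$lens[k] - 1L)
      if (call$strand == "-") span <- flip_span(span, seq_len)
      add(info$types[k], span, call$strand,
          sprintf("%s.e%d", pid, k), pid,
          extra = if (info$hybrid[k]) "hybrid=true")
    }
  }
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}

#' Read stwintron calls back from GFF3
#'
#' Inverse of [write_calls_gff()]: reconstructs the full call objects
#' from the parent features' class tag and element starts.
#'
#' @param path GFF3 file written by [write_calls_gff()].
#' @return List of `stwintron_call` objects.
#' @export
read_calls_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  parents <- gr[gr$type == "twin_intron"]
  lapply(seq_along(parents), function(i) {
    p <- parents[i]
    tag <- p$stw_class
    kind <- substr(tag, 1L, 1L)
    split <- as.integer(sub(",.*$", "", substr(tag, 2L, nchar(tag))))
    cls <- stwintron_class(kind, split)
    e <- as.integer(strsplit(p$element_starts, " ", fixed = TRUE)[[1]])
    strand <- as.character(BiocGenerics::strand(p))
    call <- rebuild_stwintron_call(cls, e)
    if (strand == "-") {
      call <- flip_call(call, as.integer(p$scanned_length))
    }
    call$hypothetical <- isTRUE(as.logical(p$hypothetical %||% FALSE)) ||
      kind == "L"
    call
  })
}

## Geometry-only reconstruction of a call from its element starts in the
## scanned frame (no sequence checks -- used by the GFF reader; the
## scanner runs the full verification in verify_stwintron_match()).
rebuild_stwintron_call <- function(stw_class, element_starts) {
  info <- pattern_element_info(stw_class)
  m <- make_match(element_starts, info$lens)
  parts <- match_to_call(m, stw_class)
  internal <- parts$internal
  shift <- function(pos) {
    ifelse(pos > internal$span[2], pos - intron_length(internal), pos)
  }
  e <- element_starts
  ext <- switch(stw_class$kind,
    D = intron_call(e[1], shift(e[4]), shift(e[5])),
    L = intron_call(e[1], e[2], shift(e[5])),
    A = intron_call(e[1], e[2], e[3])
  )
  s <- stw_class$split
  hybrid <- switch(stw_class$kind,
    D = rbind(c(e[1], e[1] + s + 5L), c(e[3], e[3] + 2L + (6L - s))),
    L = rbind(c(e[2], e[2] + s + 5L), c(e[4], e[4] + 2L + (6L - s))),
    A = rbind(c(e[3], e[3] + s + 5L), c(e[5], e[5] + 2L + (3L - s)))
  )
  structure(
    list(stw_class = stw_class, internal = internal,
         internal_span = internal$span,
         external_span = c(m$start, m$end),
         external_rejoined = ext, interrupted = parts$interrupted,
         hybrid_spans = hybrid, element_starts = e,
         total_span = c(m$start, m$end), strand = "+",
         hypothetical = stw_class$kind == "L"),
    class = "stwintron_call"
  )
}

#' Write stwintron calls as BED6
#'
#' Total spans only, 0-based half-open, sorted by start; names follow
#' the class tag.  The BED start is always the GFF3 start minus one.
#'
#' @param calls List of `stwintron_call` objects.
#' @param seq_id Sequence identifier.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(calls, seq_id, path) {
  if (length(calls) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  df <- stwintron_calls_to_df(calls)
  df <- df[order(df$start, df$end), , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   seq_id, df$start - 1L, df$end,
                   sprintf("stw_%s_%d", gsub(",", "_", df$class),
                           seq_len(nrow(df))),
                   df$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Load distance rules from a YAML config
#'
#' Recognised keys: `min_intron_len`, `donor_bp_gap` (two integers),
#' `bp_acc_gap`, `enforce_principle3`.  Missing keys keep the defaults,
#' which reproduce the published screening parameters exactly.
#'
#' @param path YAML file.
#' @return A [distance_rules()] object.
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) stop(sprintf("rules file not found: %s", path))
  y <- yaml::read_yaml(path)
  d <- distance_rules()
  distance_rules(
    min_intron_len = y$min_intron_len %||% d$min_intron_len,
    donor_bp_gap = unlist(y$donor_bp_gap) %||% d$donor_bp_gap,
    bp_acc_gap = unlist(y$bp_acc_gap) %||% d$bp_acc_gap,
    enforce_principle3 = y$enforce_principle3 %||% d$enforce_principle3
  )
}

#' Serialise a splice graph to JSON
#'
#' Nodes carry sequences and provenance; edges carry intron spans (on
#' the parent species), primary footprints and event flags.
#'
#' @param graph A [splice_to_completion()] result.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_splice_graph_json <- function(graph, path) {
  obj <- list(
    root = graph$root,
    leaves = graph$leaves,
    nodes = lapply(graph$nodes, function(n) {
      list(seq = n$seq, provenance = n$provenance)
    }),
    edges = lapply(graph$edges, function(e) {
      list(from = e$from, to = e$to,
           intron_span = e$event$intron$span,
           primary_footprint = apply(e$event$primary_footprint, 1L,
                                     identity, simplify = FALSE),
           n_segments = e$event$n_segments,
           flags = e$event$flags)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Render a splice graph in DOT format
#'
#' @param graph A [splice_to_completion()] result.
#' @return Character vector of DOT lines.
#' @export
graph_to_dot <- function(graph) {
  esc <- function(x) gsub('"', '\\"', x, fixed = TRUE)
  c("digraph splice_graph {",
    sprintf('  "%s" [label="%s\\n%d nt"%s];',
            names(graph$nodes), esc(names(graph$nodes)),
            vapply(graph$nodes, function(n) nchar(n$seq), integer(1)),
            ifelse(names(graph$nodes) %in% graph$leaves,
                   ", shape=doublecircle", "")),
    vapply(graph$edges, function(e) {
      on <- names(Filter(isTRUE, e$event$flags))
      sprintf('  "%s" -> "%s" [label="-%d nt %s"];', e$from, e$to,
              intron_length(e$event$intron), paste(on, collapse = ","))
    }, character(1)),
    "}")
}
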