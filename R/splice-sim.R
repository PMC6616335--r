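#' Construct an RNA species with coordinate provenance
#'
#' An RNA species is a (possibly partially spliced) transcript whose
#' every nucleotide maps back to a coordinate on the primary transcript.
#' The primary transcript itself has identity provenance.
#'
#' @param seq Transcript sequence (DNA/RNA alphabet; normalised).
#' @param provenance Integer vector, one strictly increasing primary
#'   coordinate per current position.  Defaults to identity.
#' @param label Identifier carried into graphs and reports.
#' @return Object of class `rna_species`.
#' @export
rna_species <- function(seq, provenance = NULL, label = "primary") {
  seq <- normalize_seq(seq)
  if (is.null(provenance)) provenance <- seq_len(nchar(seq))
  provenance <- as.integer(provenance)
  if (length(provenance) != nchar(seq)) {
    stop("provenance must have one entry per nucleotide")
  }
  if (length(provenance) > 1L && any(diff(provenance) <= 0L)) {
    stop("provenance must be strictly increasing")
  }
  structure(list(seq = seq, provenance = provenance, label = label),
            class = "rna_species")
}

#' @export
print.rna_species <- function(x, ...) {
  cat(sprintf("<rna_species> %s: %d nt (primary %d-%d)\n",
              x$label, nchar(x$seq),
              if (length(x$provenance)) x$provenance[1] else NA_integer_,
              if (length(x$provenance)) x$provenance[length(x$provenance)] else NA_integer_))
  invisible(x)
}

## Split a sorted integer vector into maximal contiguous runs; returns a
## two-column matrix of (start, end) primary segments.
runs_of <- function(x) {
  if (length(x) == 0L) return(matrix(integer(0), ncol = 2))
  brk <- c(0L, which(diff(x) > 1L), length(x))
  t(vapply(seq_len(length(brk) - 1L), function(i) {
    c(x[brk[i] + 1L], x[brk[i + 1L]])
  }, integer(2)))
}

## Build a splice event from the parent species and the intron excised
## from it (coordinates on the parent).
make_event <- function(species, intron, alternative = FALSE) {
  idx <- intron$span[1]:intron$span[2]
  footprint <- runs_of(species$provenance[idx])
  nseg <- nrow(footprint)
  structure(
    list(intron = intron,
         primary_footprint = footprint,
         n_segments = nseg,
         flags = list(
           standard = nseg == 1L,
           external_of_stwintron = nseg == 2L,
           second_order = nseg >= 3L,
           internal_of_stwintron = FALSE,   # filled in at graph level
           alternative_acceptor = alternative
         )),
    class = "splice_event"
  )
}

#' @export
print.splice_event <- function(x, ...) {
  segs <- apply(x$primary_footprint, 1L, function(s) paste(s, collapse = "-"))
  on <- names(Filter(isTRUE, x$flags))
  cat(sprintf("<splice_event> excises %d nt; primary segments: %s; flags: %s\n",
              intron_length(x$intron), paste(segs, collapse = ","),
              paste(on, collapse = ",")))
  invisible(x)
}

#' Classify an excised intron as discontinuous in the primary transcript
#'
#' An intron is "second order" in the strong sense when it did not exist
#' contiguously in the primary transcript: its excised footprint maps to
#' two or more distinct primary segments.  The external intron of a plain
#' donor-disrupted stwintron maps to 2 segments (its donor was split by
#' the internal intron); the dual-intervening-sequence intron assembled
#' by three prior excisions maps to 3 (donor, branchpoint element and
#' acceptor each contributed separately).
#'
#' @param event A `splice_event`.
#' @return List with `discontinuous` (TRUE iff >= 2 primary segments)
#'   and `n_segments`.
#' @export
detect_second_order <- function(event) {
  stopifnot(inherits(event, "splice_event"))
  list(discontinuous = event$n_segments >= 2L, n_segments = event$n_segments)
}

## Excise an intron from a species, propagating provenance.
apply_event <- function(species, intron, label) {
  idx <- intron$span[1]:intron$span[2]
  rna_species(excise_string(species$seq, intron$span[1], intron$span[2]),
              species$provenance[-idx], label)
}

#' Perform one round of in-silico splicing
#'
#' Re-scans the full current sequence with [find_introns()] (splice sites
#' reconstituted by earlier excisions must be *discovered*, not tracked)
#' and excises one intron per child:
#'
#' * `branch = FALSE`: at most one child -- the leftmost valid intron.
#' * `branch = TRUE`: one child per valid (branchpoint, acceptor)
#'   alternative for the *leftmost* donor with a valid pairing
#'   ([find_acceptor_alternatives()]); children that do not use the
#'   nearest acceptor are flagged `alternative_acceptor`.
#'
#' @param species An [rna_species()].
#' @param profile A [consensus_profile()].
#' @param rules A [distance_rules()].
#' @param branch Branch on alternative 3' splice sites?
#' @return List of `list(event = splice_event, child = rna_species)`;
#'   empty when no valid intron remains.
#' @export
splice_step <- function(species, profile = consensus_profile(),
                        rules = distance_rules(), branch = FALSE) {
  stopifnot(inherits(species, "rna_species"))
  calls <- find_introns(species$seq, profile, rules)
  if (length(calls) == 0L) return(list())
  if (!branch) {
    intron <- calls[[1]]
    ev <- make_event(species, intron)
    child <- apply_event(species, intron, paste0(species$label, ".1"))
    return(list(list(event = ev, child = child)))
  }
  alts <- find_acceptor_alternatives(species$seq, calls[[1]]$donor[1],
                                     profile, rules)
  lapply(seq_along(alts), function(i) {
    ev <- make_event(species, alts[[i]], alternative = i > 1L)
    list(event = ev,
         child = apply_event(species, alts[[i]],
                             paste0(species$label, ".", i)))
  })
}

species_key <- function(species) {
  paste(species$seq, paste(species$provenance, collapse = ","), sep = "|")
}

#' Splice a primary transcript to completion
#'
#' Breadth-first expansion of [splice_step()] until every leaf is free of
#' valid introns.  Species reached by different excision orders with
#' identical sequence *and* provenance are merged, so the result is a
#' directed acyclic graph, not a tree.  After construction, events whose
#' excised footprint later turns out to have filled the gap of a
#' discontinuous descendant excision are flagged `internal_of_stwintron`.
#'
#' @param primary An [rna_species()] (or a character sequence).
#' @param profile A [consensus_profile()].
#' @param rules A [distance_rules()].
#' @param branch Branch on alternative 3' splice sites?
#' @param max_nodes Guard against branch explosion on low-complexity
#'   input; exceeded -> error.
#' @return Object of class `splice_graph`: `nodes` (named list of
#'   species), `edges` (list of `list(from, to, event)`), `root`, and
#'   `leaves` (node ids of mature products).
#' @export
splice_to_completion <- function(primary, profile = consensus_profile(),
                                 rules = distance_rules(), branch = FALSE,
                                 max_nodes = 10000L) {
  if (is.character(primary)) primary <- rna_species(primary)
  stopifnot(inherits(primary, "rna_species"), max_nodes > 0L)
  primary$label <- "S1"
  nodes <- list(S1 = primary)
  keys <- stats::setNames("S1", species_key(primary))
  edges <- list()
  queue <- "S1"
  while (length(queue)) {
    id <- queue[1]
    queue <- queue[-1]
    steps <- splice_step(nodes[[id]], profile, rules, branch)
    for (st in steps) {
      key <- species_key(st$child)
      if (!is.na(keys[key])) {
        to <- unname(keys[key])
      } else {
        if (length(nodes) >= max_nodes) {
          stop(sprintf("splice graph exceeded max_nodes = %d (%d nodes so far)",
                       max_nodes, length(nodes)))
        }
        to <- paste0("S", length(nodes) + 1L)
        st$child$label <- to
        nodes[[to]] <- st$child
        keys[key] <- to
        queue <- c(queue, to)
      }
      edges[[length(edges) + 1L]] <- list(from = id, to = to, event = st$event)
    }
  }
  graph <- structure(
    list(nodes = nodes, edges = edges, root = "S1",
         leaves = setdiff(names(nodes),
                          vapply(edges, `[[`, character(1), "from"))),
    class = "splice_graph"
  )
  flag_internal_events(graph)
}

## Mark events that fill the inter-segment gap of a downstream
## discontinuous excision: these are the internal introns whose removal
## reconstituted the later intron's split element.
flag_internal_events <- function(graph) {
  if (length(graph$edges) < 2L) return(graph)
  ## ancestor node sets per node
  anc <- list()
  for (id in names(graph$nodes)) anc[[id]] <- character(0)
  repeat {
    changed <- FALSE
    for (e in graph$edges) {
      new <- union(anc[[e$to]], c(e$from, anc[[e$from]]))
      if (length(new) > length(anc[[e$to]])) {
        anc[[e$to]] <- new
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  for (j in seq_along(graph$edges)) {
    ej <- graph$edges[[j]]
    if (ej$event$n_segments < 2L) next
    fp <- ej$event$primary_footprint
    gaps <- cbind(fp[-nrow(fp), 2] + 1L, fp[-1L, 1] - 1L)
    for (i in seq_along(graph$edges)) {
      ei <- graph$edges[[i]]
      if (!(ei$to %in% c(ej$from, anc[[ej$from]]))) next
      fpi <- ei$event$primary_footprint
      inside <- any(apply(gaps, 1L, function(g) {
        all(fpi[, 1] >= g[1] & fpi[, 2] <= g[2])
      }))
      if (inside) {
        graph$edges[[i]]$event$flags$internal_of_stwintron <- TRUE
      }
    }
  }
  graph
}

#' @export
print.splice_graph <- function(x, ...) {
  cat(sprintf("<splice_graph> %d nodes, %d events, root %s, %d leaves\n",
              length(x$nodes), length(x$edges), x$root, length(x$leaves)))
  invisible(x)
}

#' Compare mature products of a splice graph
#'
#' Pairwise comparison of leaf species.  When one leaf equals another
#' with a single contiguous internal block of primary positions deleted,
#' an exon-skip is reported with the skipped segment's primary
#' coordinates and length.  Event counts and flags per leaf are also
#' summarised.
#'
#' @param graph A completed [splice_to_completion()] graph.
#' @return List with `leaves` (data.frame: id, length, n_events) and
#'   `skips` (data.frame: long/short leaf ids, skipped segment start,
#'   end, length).
#' @export
classify_products <- function(graph) {
  stopifnot(inherits(graph, "splice_graph"))
  ## events per leaf = events on any path root -> leaf; for a DAG count
  ## the excised footprints, which are path-invariant
  excised_of <- function(id) {
    prim <- graph$nodes[[graph$root]]$provenance
    setdiff(prim, graph$nodes[[id]]$provenance)
  }
  leaves <- data.frame(
    id = graph$leaves,
    length = vapply(graph$leaves, function(id) nchar(graph$nodes[[id]]$seq),
                    integer(1)),
    n_excised_segments = vapply(graph$leaves, function(id) {
      nrow(runs_of(sort(excised_of(id))))
    }, integer(1))
  )
  skips <- data.frame(long_leaf = character(0), short_leaf = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0))
  ids <- graph$leaves
  for (a in ids) for (b in ids) {
    if (a == b) next
    pa <- graph$nodes[[a]]$provenance
    pb <- graph$nodes[[b]]$provenance
    if (length(pb) >= length(pa)) next
    if (!all(pb %in% pa)) next
    missing <- runs_of(setdiff(pa, pb))
    if (nrow(missing) != 1L) next
    ## internal block: the shorter leaf must keep material on both sides
    if (missing[1, 1] <= pb[1] || missing[1, 2] >= pb[length(pb)]) next
    skips <- rbind(skips, data.frame(
      long_leaf = a, short_leaf = b,
      start = missing[1, 1], end = missing[1, 2],
      length = missing[1, 2] - missing[1, 1] + 1L
    ))
  }
  list(leaves = leaves, skips = skips)
}

#' Enumerate all valid excision orders
#'
#' Depth-first enumeration over every sequence of canonical excisions
#' ([find_introns()] at each state, any call may go next) until no valid
#' intron remains.  Events are identified by their primary-coordinate
#' footprints, so the same physical intron is recognised across states.
#'
#' @param primary An [rna_species()] or character sequence.
#' @param profile A [consensus_profile()].
#' @param rules A [distance_rules()].
#' @param max_orders Guard; exceeded -> error.
#' @return List of orders; each order is a list of `splice_event`s in
#'   excision sequence.
#' @export
enumerate_orders <- function(primary, profile = consensus_profile(),
                             rules = distance_rules(), max_orders = 1000L) {
  if (is.character(primary)) primary <- rna_species(primary)
  orders <- list()
  recurse <- function(species, trail) {
    calls <- find_introns(species$seq, profile, rules)
    if (length(calls) == 0L) {
      if (length(orders) >= max_orders) {
        stop(sprintf("more than max_orders = %d excision orders", max_orders))
      }
      orders[[length(orders) + 1L]] <<- trail
      return(invisible())
    }
    for (intron in calls) {
      ev <- make_event(species, intron)
      recurse(apply_event(species, intron, species$label),
              c(trail, list(ev)))
    }
  }
  recurse(primary, list())
  orders
}
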