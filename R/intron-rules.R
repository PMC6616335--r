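#' Canonical U2 splice-site consensus profiles
#'
#' The three conserved elements of a fungal U2 intron are the 6-nt donor
#' at the 5' splice site, the 6-nt element around the lariat branchpoint
#' adenosine, and the 3-nt acceptor at the 3' splice site.  Two named
#' profiles are provided, both derived from the statistical consensus for
#' *Aspergillus nidulans* introns:
#'
#' * `"strict"`:  donor `GTRWGY`, branchpoint `RYTRAY`, acceptor `YAG`.
#' * `"relaxed"`: donor `GTRWGH`, branchpoint `DYTRAY`, acceptor `HAG`
#'   (i.e. `D` instead of `R` at branchpoint position 1, `H` instead of
#'   `Y` at the variable donor/acceptor positions).
#'
#' The donor consensus circulates both as `GURWGY` and as `GURWGH`; rather
#' than adjudicating, both forms are exposed as the two named profiles.
#' Position 5 of the branchpoint element is invariantly the branch
#' adenosine.
#'
#' @param name `"strict"` or `"relaxed"`, or pass explicit motifs.
#' @param donor,branchpoint,acceptor Optional overrides (IUPAC strings);
#'   donor and branchpoint must be 6 nt, acceptor 3 nt ending in `G`, and
#'   branchpoint position 5 must be exactly `A`.
#' @return An object of class `consensus_profile` with compiled
#'   `degenerate_motif` fields `donor`, `branchpoint`, `acceptor` and a
#'   `name`.
#' @export
consensus_profile <- function(name = c("relaxed", "strict"),
                              donor = NULL, branchpoint = NULL,
                              acceptor = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    strict  = list(donor = "GTRWGY", branchpoint = "RYTRAY", acceptor = "YAG"),
    relaxed = list(donor = "GTRWGH", branchpoint = "DYTRAY", acceptor = "HAG")
  )
  donor <- compile_motif(donor %||% defaults$donor)
  branchpoint <- compile_motif(branchpoint %||% defaults$branchpoint)
  acceptor <- compile_motif(acceptor %||% defaults$acceptor)
  if (donor$length != 6L) stop("donor element must be 6 nt")
  if (branchpoint$length != 6L) stop("branchpoint element must be 6 nt")
  if (!identical(branchpoint$allowed[[5]], "A")) {
    stop("branchpoint position 5 must be the invariant branch adenosine (A)")
  }
  if (acceptor$length != 3L) stop("acceptor element must be 3 nt")
  if (!identical(acceptor$allowed[[3]], "G")) {
    stop("acceptor element must end in G")
  }
  structure(
    list(name = name, donor = donor, branchpoint = branchpoint,
         acceptor = acceptor),
    class = "consensus_profile"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.consensus_profile <- function(x, ...) {
  cat("<consensus_profile> ", x$name,
      ": donor=", x$donor$pattern,
      " branchpoint=", x$branchpoint$pattern,
      " acceptor=", x$acceptor$pattern, "\n", sep = "")
  invisible(x)
}

#' Intron-definition distance rules
#'
#' Encodes the four principles used when calling fungal intron-exon
#' structure by hand:
#'
#' 1. a minimum intron length (42 nt in *A. nidulans*);
#' 2. a branchpoint-to-acceptor distance window, minimum 4 nt (the upper
#'    bound 24 nt is taken from the operational screening pattern);
#' 3. the donor-to-branchpoint distance is strictly greater than the
#'    branchpoint-to-acceptor distance;
#' 4. splice sites pair across the intron with the nearest compatible
#'    partner ("intron definition"); this principle lives in
#'    [find_introns()], subject to the first three.
#'
#' The donor-to-branchpoint window defaults to 25--120 nt, consistent with
#' a mean intron length of 73 nt and the rarity of introns above 160 nt.
#' All distances are measured between elements, i.e. from the last base of
#' the upstream element (exclusive) to the first base of the downstream
#' element (exclusive).
#'
#' @param min_intron_len Minimum intron length in nt.
#' @param donor_bp_gap Length-2 vector: donor-to-branchpoint gap window.
#' @param bp_acc_gap Length-2 vector: branchpoint-to-acceptor gap window.
#' @param enforce_principle3 Require `donor_bp_gap > bp_acc_gap` strictly.
#' @return Object of class `distance_rules`.
#' @export
distance_rules <- function(min_intron_len = 42L,
                           donor_bp_gap = c(25L, 120L),
                           bp_acc_gap = c(4L, 24L),
                           enforce_principle3 = TRUE) {
  donor_bp_gap <- as.integer(donor_bp_gap)
  bp_acc_gap <- as.integer(bp_acc_gap)
  stopifnot(
    length(donor_bp_gap) == 2L, length(bp_acc_gap) == 2L,
    min_intron_len >= 0L,
    donor_bp_gap[1] >= 0L, donor_bp_gap[1] <= donor_bp_gap[2],
    bp_acc_gap[1] >= 0L, bp_acc_gap[1] <= bp_acc_gap[2]
  )
  structure(
    list(min_intron_len = as.integer(min_intron_len),
         donor_bp_gap = donor_bp_gap,
         bp_acc_gap = bp_acc_gap,
         enforce_principle3 = isTRUE(enforce_principle3)),
    class = "distance_rules"
  )
}

#' @export
print.distance_rules <- function(x, ...) {
  cat("<distance_rules> min_len=", x$min_intron_len,
      " donor-bp=(", x$donor_bp_gap[1], ",", x$donor_bp_gap[2], ")",
      " bp-acc=(", x$bp_acc_gap[1], ",", x$bp_acc_gap[2], ")",
      if (x$enforce_principle3) " principle3" else "", "\n", sep = "")
  invisible(x)
}

#' Construct an intron call
#'
#' Coordinates are 1-based inclusive on the subject sequence.  The branch
#' adenosine sits at position 5 of the branchpoint element.
#'
#' @param donor_start,bp_start,acceptor_start Start coordinates of the
#'   donor (6 nt), branchpoint element (6 nt) and acceptor (3 nt).
#' @param phase Codon phase 0/1/2 or `NA` when unknown.
#' @return Object of class `intron_call` with spans `donor`, `bp`,
#'   `acceptor`, the `branch_a` coordinate, and the full intron `span`
#'   (donor start to acceptor end).
#' @export
intron_call <- function(donor_start, bp_start, acceptor_start, phase = NA) {
  donor_start <- as.integer(donor_start)
  bp_start <- as.integer(bp_start)
  acceptor_start <- as.integer(acceptor_start)
  stopifnot(donor_start + 6L <= bp_start, bp_start + 6L <= acceptor_start)
  structure(
    list(donor = c(donor_start, donor_start + 5L),
         bp = c(bp_start, bp_start + 5L),
         acceptor = c(acceptor_start, acceptor_start + 2L),
         branch_a = bp_start + 4L,
         span = c(donor_start, acceptor_start + 2L),
         phase = phase),
    class = "intron_call"
  )
}

#' @export
print.intron_call <- function(x, ...) {
  cat(sprintf("<intron_call> %d-%d (%d nt) donor@%d bp@%d (branch A %d) acceptor@%d\n",
              x$span[1], x$span[2], x$span[2] - x$span[1] + 1L,
              x$donor[1], x$bp[1], x$branch_a, x$acceptor[1]))
  invisible(x)
}

intron_length <- function(call) call$span[2] - call$span[1] + 1L

## Element-to-element gaps of a call (exclusive both sides).
call_gaps <- function(call) {
  c(donor_bp = call$bp[1] - call$donor[2] - 1L,
    bp_acc = call$acceptor[1] - call$bp[2] - 1L)
}

#' Validate an intron call against distance rules
#'
#' @param call An [intron_call()].
#' @param rules A [distance_rules()] object.
#' @return List with `valid` (logical) and `violations`, a character
#'   vector drawn from `"min_len"`, `"donor_bp_gap"`, `"bp_acc_gap"`,
#'   `"principle3"`.
#' @export
validate_intron <- function(call, rules = distance_rules()) {
  stopifnot(inherits(call, "intron_call"), inherits(rules, "distance_rules"))
  g <- call_gaps(call)
  violations <- character(0)
  if (intron_length(call) < rules$min_intron_len) {
    violations <- c(violations, "min_len")
  }
  if (g["donor_bp"] < rules$donor_bp_gap[1] || g["donor_bp"] > rules$donor_bp_gap[2]) {
    violations <- c(violations, "donor_bp_gap")
  }
  if (g["bp_acc"] < rules$bp_acc_gap[1] || g["bp_acc"] > rules$bp_acc_gap[2]) {
    violations <- c(violations, "bp_acc_gap")
  }
  if (rules$enforce_principle3 && !(g["donor_bp"] > g["bp_acc"])) {
    violations <- c(violations, "principle3")
  }
  list(valid = length(violations) == 0L, violations = violations)
}

## All valid (branchpoint, acceptor) pairings for one donor.  For each
## candidate acceptor (ascending, i.e. nearest first) the branchpoint
## closest to the acceptor among rule-passing placements is chosen -- U2
## scans proximal to the 3' site.  Returns a list of intron_call objects;
## with all_acceptors = FALSE only the nearest valid acceptor is kept
## (principle 4, intron definition).
donor_pairings <- function(donor_start, bp_sites, acc_sites, rules,
                           all_acceptors = FALSE) {
  donor_end <- donor_start + 5L
  out <- list()
  for (a in acc_sites[acc_sites > donor_end]) {
    if (a + 2L - donor_start + 1L < rules$min_intron_len) next
    ## branchpoint window induced by both gap rules
    b_lo <- max(donor_end + 1L + rules$donor_bp_gap[1],
                a - 6L - rules$bp_acc_gap[2])
    b_hi <- min(donor_end + 1L + rules$donor_bp_gap[2],
                a - 6L - rules$bp_acc_gap[1])
    cand <- bp_sites[bp_sites >= b_lo & bp_sites <= b_hi]
    if (rules$enforce_principle3 && length(cand)) {
      gap1 <- cand - donor_end - 1L
      gap2 <- a - cand - 6L - 1L
      cand <- cand[gap1 > gap2]
    }
    if (length(cand) == 0L) next
    out[[length(out) + 1L]] <- intron_call(donor_start, max(cand), a)
    if (!all_acceptors) break
  }
  out
}

#' Find canonical U2 introns under intron definition
#'
#' Scans the sequence 5' to 3' for donor-motif occurrences; each donor is
#' paired with the nearest acceptor (smallest intron) for which a
#' rule-passing branchpoint exists -- principle 4, subject to principles
#' 1--3 via [validate_intron()].  When several branchpoint placements
#' serve the chosen acceptor, the one nearest the acceptor wins.  Donors
#' with no valid partner yield nothing.
#'
#' @param seq Subject sequence.
#' @param profile A [consensus_profile()].
#' @param rules A [distance_rules()].
#' @return List of [intron_call()] objects sorted by intron start.
#' @export
find_introns <- function(seq, profile = consensus_profile(),
                         rules = distance_rules()) {
  stopifnot(inherits(profile, "consensus_profile"))
  seq <- normalize_seq(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  donors <- motif_sites_chars(profile$donor, chars)
  if (length(donors) == 0L) return(list())
  bps <- motif_sites_chars(profile$branchpoint, chars)
  accs <- motif_sites_chars(profile$acceptor, chars)
  ## acceptor coordinate used throughout is the element start; the intron
  ## ends at acceptor start + 2
  calls <- list()
  for (d in donors) {
    hit <- donor_pairings(d, bps, accs, rules, all_acceptors = FALSE)
    if (length(hit)) calls[[length(calls) + 1L]] <- hit[[1]]
  }
  calls[order(vapply(calls, function(cl) cl$span[1], integer(1)))]
}

#' All alternative acceptor pairings for one donor
#'
#' Companion to [find_introns()] used by the branching splice simulator:
#' returns *every* acceptor in the window that can be paired with this
#' donor under the rules (nearest first), each with its
#' acceptor-proximal branchpoint.
#'
#' @param seq Subject sequence.
#' @param donor_start 1-based start of a donor-motif occurrence.
#' @inheritParams find_introns
#' @return List of [intron_call()] objects, nearest acceptor first.
#' @export
find_acceptor_alternatives <- function(seq, donor_start,
                                       profile = consensus_profile(),
                                       rules = distance_rules()) {
  seq <- normalize_seq(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!matches_at(profile$donor, seq, donor_start)) {
    stop(sprintf("no donor-motif occurrence at position %d", donor_start))
  }
  bps <- motif_sites_chars(profile$branchpoint, chars)
  accs <- motif_sites_chars(profile$acceptor, chars)
  donor_pairings(donor_start, bps, accs, rules, all_acceptors = TRUE)
}
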