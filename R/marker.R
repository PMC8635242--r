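# Virtual PCR and restriction digestion.
#
# Primers are matched exactly (the published assays are presence/absence
# assays, not allele-specific 3'-mismatch PCR); enzymes are described by a
# recognition sequence plus a top-strand cut offset, which covers both the
# blunt/overhang palindromic cutters (NlaIII: CATG, offset 0) and distance
# cutters (MboII: GAAGA(8/7), offset 8).

.as_primer <- function(x, role = NA_character_) {
  if (is.character(x)) x <- list(name = x, seq = x)
  stopifnot(is.list(x), !is.null(x$seq))
  x$seq <- toupper(x$seq)
  if (nchar(x$seq) < 15L) {
    stop("primer ", x$name %||% x$seq, " is shorter than 15 nt")
  }
  if (grepl("[^ACGT]", x$seq)) {
    stop("primer ", x$name %||% x$seq, " contains non-ACGT characters")
  }
  x$role <- role
  x$allele_tag <- x$allele_tag %||% NA_character_
  x
}

#' Locate primer binding sites on a template
#'
#' Exact-match search: plus-strand hits are occurrences of the primer
#' itself; minus-strand hits (where the primer would bind the bottom
#' strand) are occurrences of the primer's reverse complement on the
#' given (top) strand.
#'
#' @param template Template DNA (single string).
#' @param primer A primer (character, or a list with `name`/`seq` as in the
#'   marker registry).
#' @return Data frame with columns `position` (1-based start of the
#'   occurrence on the top strand) and `strand` (`"+"` or `"-"`). Zero rows
#'   if the primer is absent.
#' @export
find_primer_sites <- function(template, primer) {
  stopifnot(nchar(template) > 0L)
  p <- .as_primer(primer)
  plus <- motif_starts(template, p$seq)
  minus <- motif_starts(template, revcomp(p$seq))
  data.frame(
    position = c(plus, minus),
    strand = c(rep("+", length(plus)), rep("-", length(minus))),
    stringsAsFactors = FALSE)
}

#' Simulate PCR amplification
#'
#' Pairs every plus-strand forward-primer site with every minus-strand
#' reverse-primer site lying 3' of it and emits one amplicon per pair with
#' product length at most `max_product`. The length cap models failed long
#' extension: with the default 1500 nt, the pairing that would have to read
#' through the 3.78-kb retroelement insertion yields no product, exactly as
#' on a gel.
#'
#' @param template Template DNA (single string).
#' @param forward Forward primer (character or registry-style list).
#' @param reverses One reverse primer or a list of reverse primers; each may
#'   carry an `allele_tag` that is copied onto its products.
#' @param max_product Maximum product length in nt (default 1500).
#' @return Data frame of amplicons: `start`, `end` (1-based, inclusive, on
#'   the template), `length`, `forward`, `reverse`, `allele_tag`,
#'   `sequence`. Zero rows when no pairing amplifies.
#' @export
simulate_pcr <- function(template, forward, reverses, max_product = 1500L) {
  fwd <- .as_primer(forward, "forward")
  if (is.character(reverses)) {
    reverses <- lapply(reverses, identity)
  } else if (!is.null(reverses$seq)) {
    reverses <- list(reverses)
  }
  stopifnot(length(reverses) >= 1L)
  f_hits <- motif_starts(template, fwd$seq)
  out <- list()
  for (rev in reverses) {
    rp <- .as_primer(rev, "reverse")
    r_starts <- motif_starts(template, revcomp(rp$seq))
    for (f in f_hits) {
      for (s in r_starts) {
        e <- s + nchar(rp$seq) - 1L
        len <- e - f + 1L
        if (len < nchar(fwd$seq) + nchar(rp$seq) || len > max_product) next
        out[[length(out) + 1L]] <- data.frame(
          start = f, end = e, length = len,
          forward = fwd$name %||% fwd$seq,
          reverse = rp$name %||% rp$seq,
          allele_tag = rp$allele_tag,
          sequence = substr(template, f, e),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      length = integer(), forward = character(),
                      reverse = character(), allele_tag = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Find restriction cut positions on a linear sequence
#'
#' Scans for the recognition sequence on both strands and reports top-strand
#' cut coordinates: a cut coordinate `c` means the phosphodiester bond after
#' base `c` is cleaved. For a plus-strand site ending at `e` the cut falls
#' after `e + cut_offset`; for a minus-strand site whose reverse complement
#' starts at `s` on the top strand, after `s - 1 - cut_offset`. Palindromic
#' recognition sequences are scanned on the plus strand only (each site is
#' its own reverse complement). Cuts outside `[1, len - 1]` are dropped.
#'
#' @param seq DNA sequence (single string, linear).
#' @param enzyme A list with `recognition`, `cut_offset` (relative to the
#'   recognition 3' end on the strand carrying it) and `palindromic`.
#' @return Sorted integer vector of unique cut coordinates.
#' @export
#' @examples
#' mboII <- list(recognition = "GAAGA", cut_offset = 8L, palindromic = FALSE)
#' find_cut_sites("NNNNNGAAGANNNNNNNNNN", mboII)  # cut after position 18
find_cut_sites <- function(seq, enzyme) {
  stopifnot(nchar(enzyme$recognition) >= 4L, enzyme$cut_offset >= 0L)
  n <- nchar(seq)
  k <- nchar(enzyme$recognition)
  plus <- motif_starts(seq, enzyme$recognition)
  cuts <- plus + k - 1L + enzyme$cut_offset
  if (!isTRUE(enzyme$palindromic)) {
    minus <- motif_starts(seq, revcomp(enzyme$recognition))
    cuts <- c(cuts, minus - 1L - enzyme$cut_offset)
  }
  sort(unique(cuts[cuts >= 1L & cuts <= n - 1L]))
}

#' Digest an amplicon and report the fragment pattern
#'
#' Complete digestion at every internal site, with one refinement: cuts
#' falling within `end_protect` nt of either amplicon end are suppressed.
#' Restriction enzymes cleave recognition sites close to duplex termini
#' inefficiently, and the resulting terminal slivers are below gel
#' visibility; modelling them as uncut is what makes simulated patterns
#' match observed band sizes (the H4-NlaIII reverse primer itself contains
#' a CATG site 14 nt from the product end that is never seen as a cut on a
#' gel).
#'
#' @param seq Amplicon sequence (single string).
#' @param enzyme Enzyme definition, as for [find_cut_sites()].
#' @param end_protect Minimum distance (nt) of an effective cut from either
#'   amplicon end; default 15.
#' @return A list of class `band_pattern`: `fragments` (lengths, sorted
#'   descending; the undigested length if there are no cuts), `cuts` (the
#'   effective cut coordinates) and `length` (amplicon length).
#' @export
digest_amplicon <- function(seq, enzyme, end_protect = 15L) {
  n <- nchar(seq)
  cuts <- find_cut_sites(seq, enzyme)
  cuts <- cuts[cuts >= end_protect & (n - cuts) >= end_protect]
  frags <- diff(c(0L, cuts, n))
  structure(list(fragments = sort(frags, decreasing = TRUE),
                 cuts = cuts, length = n),
            class = "band_pattern")
}

#' @export
print.band_pattern <- function(x, ...) {
  cat("<band_pattern> ", paste(x$fragments, collapse = " + "), " bp (",
      x$length, " bp total)\n", sep = "")
  invisible(x)
}

# does the observed fragment multiset match one expected pattern?
.pattern_matches <- function(observed, expected, tolerance) {
  if (length(observed) != length(expected)) return(FALSE)
  o <- sort(observed, decreasing = TRUE)
  e <- sort(expected, decreasing = TRUE)
  all(abs(o - e) <= tolerance * e)
}

#' Match an observed band pattern against a marker's expected classes
#'
#' Every observed fragment must match the corresponding expected fragment
#' within `tolerance * expected_size` (relative sizing error of gel
#' electrophoresis). A class with several indistinguishable expected
#' patterns (the 775/777 bp Pro-Ins products) matches if any of them does.
#'
#' @param observed A `band_pattern` from [digest_amplicon()], or a numeric
#'   vector of fragment lengths.
#' @param marker One marker entry of a [default_marker_registry()].
#' @param tolerance Relative size tolerance (default 0.01, i.e. 1%).
#' @return A list with `class` (the allele class name, or `"ambiguous"` if
#'   more than one class survives, or `"unscored"` if none does) and
#'   `candidates` (all surviving class names).
#' @export
match_band_pattern <- function(observed, marker, tolerance = 0.01) {
  if (inherits(observed, "band_pattern")) observed <- observed$fragments
  stopifnot(length(marker$classes) >= 1L)
  hits <- vapply(marker$classes, function(cl) {
    any(vapply(cl$fragments,
               function(e) .pattern_matches(observed, e, tolerance), NA))
  }, NA)
  candidates <- vapply(marker$classes[hits], `[[`, "", "class")
  cls <- if (length(candidates) == 1L) candidates
         else if (length(candidates) > 1L) "ambiguous"
         else "unscored"
  list(class = cls, candidates = candidates)
}
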