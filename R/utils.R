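#' Reverse complement of a DNA string
#'
#' Thin character-in/character-out wrapper around
#' [Biostrings::reverseComplement()].
#'
#' @param x A single DNA string (A/C/G/T).
#' @return A single character string, the reverse complement of `x`.
#' @export
#' @examples
#' revcomp("GAAGA")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a coding sequence up to the first stop codon
#'
#' Uses the standard genetic code ([Biostrings::GENETIC_CODE]). Trailing
#' bases that do not fill a codon are ignored.
#'
#' @param cds A single DNA string, assumed to start in frame.
#' @return A list with `protein` (amino acids up to, excluding, the first
#'   stop), `stopped` (TRUE if a stop codon was reached) and `n_codons_read`
#'   (codons consumed including the stop, if any).
#' @export
translate_to_stop <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  n <- nchar(cds) %/% 3L
  if (n == 0L) {
    return(list(protein = "", stopped = FALSE, n_codons_read = 0L))
  }
  starts <- seq(1L, by = 3L, length.out = n)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at)) {
    k <- stop_at[1L]
    list(protein = paste(aa[seq_len(k - 1L)], collapse = ""),
         stopped = TRUE, n_codons_read = k)
  } else {
    list(protein = paste(aa, collapse = ""), stopped = FALSE,
         n_codons_read = n)
  }
}

#' Round half away from zero to a fixed number of decimals
#'
#' `round()` in R rounds half to even; published frequency tables in plant
#' genetics are conventionally rounded half-up, so 98.95 prints as 99.0.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so deterministic fixture construction never perturbs user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Uniform random DNA as a character vector of single bases.
random_bases <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

# Random in-frame coding sequence with no stop codons, as single bases.
SENSE_CODONS <- NULL  # filled lazily; GENETIC_CODE needs Biostrings loaded

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

random_codons <- function(n_codons) {
  cods <- sample(sense_codons(), n_codons, replace = TRUE)
  unlist(strsplit(cods, ""), use.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Find all (possibly overlapping) occurrences of a fixed motif in a character
# DNA string; returns start positions.
motif_starts <- function(seq, motif) {
  if (nchar(seq) < nchar(motif)) return(integer(0))
  hits <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq))
  BiocGenerics::start(hits)
}
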