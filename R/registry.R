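# Marker registry: the five published GmSALT3 haplotype-specific markers.
#
# Three indel markers (Pro-Ins, H2-Ins, H5-Del) score product length; two
# CAPS markers (H3-MboII, H4-NlaIII) score restriction fragment patterns.
# Each allele class carries the haplotype set it is compatible with, which
# is what `call_haplotype()` intersects.

.mk_class <- function(class, fragments, haplotypes) {
  # fragments: list of expected fragment-length vectors (a class may have
  # more than one indistinguishable pattern, e.g. the 775/777 bp products)
  list(class = class, fragments = fragments, haplotypes = haplotypes)
}

#' Default marker registry for the five GmSALT3 functional markers
#'
#' Returns the packaged definitions of the three indel markers (Pro-Ins,
#' H2-Ins, H5-Del) and the two CAPS markers (H3-MboII, H4-NlaIII): primer
#' sequences, restriction enzymes with their cut-offset geometry, and the
#' expected band-pattern-to-haplotype table used for genotype calling.
#'
#' The 775 and 777 bp Pro-Ins products differ by only 2 nt at ~776 bp and
#' are not resolvable on agarose, so they are pre-merged into the single
#' allele class `"insertion-present"`.
#'
#' @return A list of class `marker_registry`; one element per marker with
#'   fields `name`, `type` (`"indel"` or `"CAPS"`), `forward`, `reverses`
#'   (each a list with `name`, `seq` and optional `allele_tag`), optional
#'   `enzyme` (`name`, `recognition`, `cut_offset`, `palindromic`) and
#'   `classes` (allele classes with expected fragment patterns and
#'   compatible haplotypes).
#' @export
#' @examples
#' names(default_marker_registry())
default_marker_registry <- function() {
  reg <- list(
    "Pro-Ins" = list(
      name = "Pro-Ins", type = "indel",
      forward = list(name = "Pro-Ins-F", seq = "GGGTTGTGCCTAAATAGCA"),
      reverses = list(list(name = "Pro-Ins-R", seq = "AAGGAAGAGCGTGGTTCA")),
      enzyme = NULL,
      classes = list(
        .mk_class("623", list(623), c("H1", "H2")),
        .mk_class("insertion-present", list(775, 777), c("H3", "H4", "H5"))
      )
    ),
    "H2-Ins" = list(
      name = "H2-Ins", type = "indel",
      forward = list(name = "H2-Ins-F", seq = "GCGGGAGTAATGTTATCGG"),
      reverses = list(
        list(name = "H2-Ins-R/H1", seq = "CGATTAGCTCCACCAACCCT",
             allele_tag = "H1-type"),
        list(name = "H2-Ins-R/H2", seq = "GTCGTATCTTGGGAGAGGAG",
             allele_tag = "H2-specific")
      ),
      enzyme = NULL,
      classes = list(
        .mk_class("364", list(364), c("H1", "H3", "H4", "H5")),
        .mk_class("565", list(565), "H2")
      )
    ),
    "H3-MboII" = list(
      name = "H3-MboII", type = "CAPS",
      forward = list(name = "H3-MboII-F", seq = "TATGGTGGCTAAGCAGGTG"),
      reverses = list(list(name = "H3-MboII-R", seq = "CAGTGAGTTCGGTAAGTTGC")),
      enzyme = list(name = "MboII", recognition = "GAAGA", cut_offset = 8L,
                    palindromic = FALSE),
      classes = list(
        .mk_class("three-fragment", list(c(125, 119, 52)), "H3"),
        .mk_class("two-fragment", list(c(244, 52)), c("H1", "H2", "H4", "H5"))
      )
    ),
    "H4-NlaIII" = list(
      name = "H4-NlaIII", type = "CAPS",
      forward = list(name = "H4-NlaIII-F",
                     seq = "AAAGCGCATAAGTTATAACACAAAAT"),
      reverses = list(list(name = "H4-NlaIII-R",
                           seq = "GAATGTAACCCTATCATGTCTGTCA")),
      enzyme = list(name = "NlaIII", recognition = "CATG", cut_offset = 0L,
                    palindromic = TRUE),
      classes = list(
        .mk_class("four-fragment", list(c(111, 87, 42, 22)), "H4"),
        .mk_class("two-fragment", list(c(133, 129)), c("H1", "H2")),
        .mk_class("three-fragment", list(c(133, 87, 42)), c("H3", "H5"))
      )
    ),
    "H5-Del" = list(
      name = "H5-Del", type = "indel",
      forward = list(name = "H5-Del-F", seq = "CTGTCCATCACGGCTTTCC"),
      reverses = list(list(name = "H5-Del-R", seq = "CTATAGTAGGTCCACCTGAGAA")),
      enzyme = NULL,
      classes = list(
        .mk_class("210", list(210), "H5"),
        .mk_class("214", list(214), c("H1", "H2", "H3", "H4"))
      )
    )
  )
  class(reg) <- "marker_registry"
  reg
}

#' Write a marker registry to YAML
#'
#' @param registry A `marker_registry` (see [default_marker_registry()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_marker_registry <- function(registry, path) {
  plain <- lapply(unclass(registry), function(m) {
    m$classes <- lapply(m$classes, function(cl) {
      cl$fragments <- lapply(cl$fragments, as.integer)
      cl
    })
    m
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Read a marker registry from YAML
#'
#' @param path Path to a YAML registry written by [write_marker_registry()]
#'   (or hand-authored in the same schema).
#' @return A `marker_registry` list.
#' @export
read_marker_registry <- function(path) {
  reg <- yaml::read_yaml(path)
  reg <- lapply(reg, function(m) {
    stopifnot(!is.null(m$forward$seq), !is.null(m$reverses))
    m$classes <- lapply(m$classes, function(cl) {
      cl$fragments <- lapply(cl$fragments, as.numeric)
      cl$haplotypes <- as.character(cl$haplotypes)
      cl
    })
    m
  })
  class(reg) <- "marker_registry"
  reg
}

#' @export
print.marker_registry <- function(x, ...) {
  cat("<marker_registry> ", length(x), " markers:\n", sep = "")
  for (m in x) {
    enz <- if (is.null(m$enzyme)) "" else paste0(" + ", m$enzyme$name)
    cat(sprintf("  %-9s %-5s %d reverse primer(s)%s; classes: %s\n",
                m$name, m$type, length(m$reverses), enz,
                paste(vapply(m$classes, `[[`, "", "class"),
                      collapse = ", ")))
  }
  invisible(x)
}
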