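# Combining per-marker allele classes into a haplotype call.

ALL_HAPS <- c("H1", "H2", "H3", "H4", "H5")

.class_haps <- function(marker, class) {
  for (cl in marker$classes) if (cl$class == class) return(cl$haplotypes)
  NULL
}

#' Combine marker results into a haplotype call
#'
#' Intersects the haplotype sets compatible with each marker's allele
#' class. Ambiguous or unscored markers contribute the universal set
#' `{H1..H5}`; an empty intersection flags conflicting assay evidence and
#' assigns no haplotype.
#'
#' @param results Named character vector or list, marker name to allele
#'   class (as returned by [match_band_pattern()]).
#' @param registry A [default_marker_registry()].
#' @return List of class `haplotype_call`: `candidates` (haplotype ids),
#'   `unique`, `call` (the haplotype when unique, else `NA`),
#'   `conflicting`, and `response` (`"tolerant"` iff the candidate set is
#'   exactly `{H1}`, `"sensitive"` iff it is non-empty and excludes H1,
#'   otherwise `"unknown"`).
#' @export
call_haplotype <- function(results, registry = default_marker_registry()) {
  stopifnot(length(results) >= 1L)
  cand <- ALL_HAPS
  for (mname in names(results)) {
    cls <- results[[mname]]
    if (cls %in% c("ambiguous", "unscored", "het")) next
    haps <- .class_haps(registry[[mname]], cls)
    if (is.null(haps)) {
      stop("class ", cls, " is not defined for marker ", mname)
    }
    cand <- intersect(cand, haps)
  }
  conflicting <- length(cand) == 0L
  uniq <- length(cand) == 1L
  response <- if (uniq && cand == "H1") "tolerant"
              else if (!conflicting && !("H1" %in% cand)) "sensitive"
              else "unknown"
  structure(list(candidates = cand, unique = uniq,
                 call = if (uniq) cand else NA_character_,
                 conflicting = conflicting, response = response),
            class = "haplotype_call")
}

#' @export
print.haplotype_call <- function(x, ...) {
  cat("<haplotype_call> ",
      if (x$conflicting) "conflicting marker evidence"
      else paste0("{", paste(x$candidates, collapse = ","), "} -> ",
                  x$response),
      "\n", sep = "")
  invisible(x)
}

#' Two-marker tolerant/sensitive screen
#'
#' The minimal published screen: Pro-Ins separates H1/H2 from H3-H5 and
#' H2-Ins separates H1 from H2, so the pair suffices to predict salt
#' response. The 623 bp Pro-Ins class together with the 364 bp H2-Ins
#' class predicts tolerant (H1); any other scored combination predicts
#' sensitive; an ambiguous or unscored marker yields `"unknown"`.
#'
#' @param pro_ins Allele class of the Pro-Ins marker (`"623"` or
#'   `"insertion-present"`).
#' @param h2_ins Allele class of the H2-Ins marker (`"364"` or `"565"`).
#' @return `"tolerant"`, `"sensitive"` or `"unknown"`.
#' @export
minimal_marker_screen <- function(pro_ins, h2_ins) {
  bad <- c("ambiguous", "unscored", "het")
  if (pro_ins %in% bad || h2_ins %in% bad) return("unknown")
  if (pro_ins == "623" && h2_ins == "364") "tolerant" else "sensitive"
}

#' Genotype a single template with the marker panel
#'
#' Runs in-silico PCR (and digestion for CAPS markers) for every marker in
#' the registry and scores the resulting band patterns.
#'
#' @param template Template DNA (single string).
#' @param registry A [default_marker_registry()].
#' @param max_product Maximum PCR product length (default 1500 nt).
#' @param tolerance Band-size matching tolerance (default 0.01).
#' @return List with `marker_results` (named character vector of allele
#'   classes; two simultaneously matching product classes at one marker
#'   are reported as `"het"`), `bands` (list of observed fragment-length
#'   vectors) and `call` (the [call_haplotype()] result).
#' @export
genotype_template <- function(template,
                              registry = default_marker_registry(),
                              max_product = 1500L, tolerance = 0.01) {
  classes <- character(0)
  bands <- list()
  for (m in registry) {
    amps <- simulate_pcr(template, m$forward, m$reverses, max_product)
    if (nrow(amps) == 0L) {
      classes[m$name] <- "unscored"
      bands[[m$name]] <- numeric(0)
      next
    }
    if (!is.null(m$enzyme)) {
      # CAPS marker: digest the product (assays use a single amplicon)
      bp <- digest_amplicon(amps$sequence[1L], m$enzyme)
      bands[[m$name]] <- bp$fragments
      classes[m$name] <- match_band_pattern(bp, m, tolerance)$class
    } else {
      # indel marker: each product is one band; score each product and
      # report het if two different allele classes amplify
      per <- vapply(amps$length,
                    function(L) match_band_pattern(L, m, tolerance)$class,
                    "")
      per <- unique(per)
      bands[[m$name]] <- sort(amps$length, decreasing = TRUE)
      classes[m$name] <- if (length(per) == 1L) per else "het"
    }
  }
  list(marker_results = classes, bands = bands,
       call = call_haplotype(classes, registry))
}

#' Genotype a panel of templates
#'
#' Applies [genotype_template()] to each sequence; per-accession failures
#' are isolated and reported as unscored rather than aborting the panel.
#'
#' @param templates Named character vector of template sequences (names =
#'   accession ids).
#' @param registry A [default_marker_registry()].
#' @param max_product,tolerance Passed to [genotype_template()].
#' @return List of class `panel_genotypes`: `calls` (data frame with one
#'   row per accession: per-marker classes, candidate set, call, response)
#'   and `summary` (table of calls).
#' @export
genotype_panel <- function(templates,
                           registry = default_marker_registry(),
                           max_product = 1500L, tolerance = 0.01) {
  if (length(templates) == 0L) {
    return(structure(list(
      calls = data.frame(accession = character(), call = character(),
                         response = character(), stringsAsFactors = FALSE),
      summary = table(character())), class = "panel_genotypes"))
  }
  ids <- names(templates) %||% sprintf("seq%03d", seq_along(templates))
  rows <- lapply(seq_along(templates), function(i) {
    res <- tryCatch(
      genotype_template(templates[[i]], registry, max_product, tolerance),
      error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(accession = ids[i], candidates = NA_character_,
                        call = NA_character_, response = "unknown",
                        conflicting = NA, stringsAsFactors = FALSE))
    }
    out <- data.frame(accession = ids[i],
                      candidates = paste(res$call$candidates,
                                         collapse = ","),
                      call = res$call$call,
                      response = res$call$response,
                      conflicting = res$call$conflicting,
                      stringsAsFactors = FALSE)
    for (mn in names(res$marker_results)) out[[mn]] <- res$marker_results[[mn]]
    out
  })
  calls <- do.call(rbind, rows)
  structure(list(calls = calls,
                 summary = table(calls$call, useNA = "ifany")),
            class = "panel_genotypes")
}

#' @export
print.panel_genotypes <- function(x, ...) {
  cat("<panel_genotypes> ", nrow(x$calls), " accessions\n", sep = "")
  print(x$summary)
  invisible(x)
}
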