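# Tracing a marker-defined allele backward through a cultivar pedigree.
#
# Semantics: the "source" of a focal cultivar's haplotype is every maximal
# (furthest-back) genotyped ancestor carrying the same haplotype that is
# reachable along parent edges on which every genotyped intermediate also
# carries it. Ungenotyped nodes (seed unavailable) are pass-through; a
# genotyped ancestor with a different haplotype blocks its branch.

#' Validate a pedigree and build a traceable DAG
#'
#' Checks acyclicity (a self-parent is a one-node cycle) and resolves
#' parent references; parents that are named but have no row of their own
#' are auto-registered as ungenotyped founders with a warning.
#'
#' @param nodes Data frame with columns `name`, `parent1`, `parent2`
#'   (NA for founders), `genotyped` (logical), `haplotype` (NA when not
#'   genotyped) and optionally `phenotype`.
#' @return A list of class `pedigree`: `nodes` (completed data frame) and
#'   `parents` (named list of parent name vectors).
#' @export
validate_pedigree <- function(nodes) {
  req <- c("name", "parent1", "parent2", "genotyped", "haplotype")
  stopifnot(is.data.frame(nodes), all(req %in% names(nodes)))
  if (anyDuplicated(nodes$name)) {
    stop("duplicated node name(s): ",
         paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", "))
  }
  referenced <- setdiff(stats::na.omit(c(nodes$parent1, nodes$parent2)),
                        nodes$name)
  if (length(referenced)) {
    warning("parent(s) not listed as nodes, registered as ungenotyped ",
            "founders: ", paste(referenced, collapse = ", "))
    extra <- data.frame(name = referenced, parent1 = NA_character_,
                        parent2 = NA_character_, genotyped = FALSE,
                        haplotype = NA_character_, stringsAsFactors = FALSE)
    for (col in setdiff(names(nodes), names(extra))) extra[[col]] <- NA
    nodes <- rbind(nodes, extra[names(nodes)])
  }
  parents <- stats::setNames(lapply(seq_len(nrow(nodes)), function(i) {
    p <- c(nodes$parent1[i], nodes$parent2[i])
    p[!is.na(p)]
  }), nodes$name)

  # cycle check by iterative elimination of founder-like nodes
  remaining <- nodes$name
  repeat {
    removable <- remaining[vapply(remaining, function(n) {
      !any(parents[[n]] %in% remaining)
    }, NA)]
    if (!length(removable)) break
    remaining <- setdiff(remaining, removable)
  }
  if (length(remaining)) {
    stop("pedigree contains a cycle involving: ",
         paste(remaining, collapse = ", "))
  }
  structure(list(nodes = nodes, parents = parents), class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat("<pedigree> ", nrow(x$nodes), " nodes, ",
      sum(x$nodes$genotyped), " genotyped\n", sep = "")
  invisible(x)
}

# consistent-reachable ancestors of `from`: traversal passes through
# ungenotyped nodes and genotyped nodes carrying `hap`; blocked otherwise.
# Returns list(reachable = names, via = parent-pointer list for one
# witnessing path each).
.consistent_ancestors <- function(ped, from, hap) {
  geno <- stats::setNames(ped$nodes$genotyped, ped$nodes$name)
  hap_of <- stats::setNames(ped$nodes$haplotype, ped$nodes$name)
  seen <- character(0)
  via <- list()
  frontier <- from
  while (length(frontier)) {
    nxt <- character(0)
    for (u in frontier) {
      for (p in ped$parents[[u]]) {
        if (p %in% seen) next
        if (geno[[p]] && !identical(hap_of[[p]], hap)) next  # blocked
        seen <- c(seen, p)
        via[[p]] <- u
        nxt <- c(nxt, p)
      }
    }
    frontier <- nxt
  }
  list(reachable = seen, via = via)
}

.witness_path <- function(via, from, node) {
  path <- node
  while (node != from) {
    node <- via[[node]]
    path <- c(node, path)
  }
  path
}

#' Trace the source of a focal cultivar's haplotype
#'
#' Returns every maximal ancestor that could have contributed the focal
#' haplotype: a genotyped ancestor carrying the focal haplotype, reachable
#' along a parent path on which every genotyped intermediate carries it,
#' and with no further such ancestor above it. When no genotyped matching
#' ancestor exists, the allele is first observed in the focal cultivar
#' itself and `{focal}` is returned.
#'
#' @param ped A [validate_pedigree()] result.
#' @param focal Name of the focal node; must be genotyped.
#' @return List of class `allele_trace`: `focal`, `haplotype`,
#'   `candidates` (character vector of source names) and `paths` (one
#'   witnessing child-to-ancestor path per candidate).
#' @export
trace_allele <- function(ped, focal) {
  stopifnot(inherits(ped, "pedigree"))
  i <- match(focal, ped$nodes$name)
  if (is.na(i)) stop("unknown focal node: ", focal)
  if (!ped$nodes$genotyped[i]) stop("focal node ", focal,
                                    " is not genotyped")
  hap <- ped$nodes$haplotype[i]
  geno <- stats::setNames(ped$nodes$genotyped, ped$nodes$name)
  hap_of <- stats::setNames(ped$nodes$haplotype, ped$nodes$name)

  reach <- .consistent_ancestors(ped, focal, hap)
  matching <- reach$reachable[vapply(reach$reachable, function(n) {
    geno[[n]] && identical(hap_of[[n]], hap)
  }, NA)]
  if (!length(matching)) {
    return(structure(list(focal = focal, haplotype = hap,
                          candidates = focal,
                          paths = stats::setNames(list(focal), focal)),
                     class = "allele_trace"))
  }
  maximal <- matching[vapply(matching, function(g) {
    up <- .consistent_ancestors(ped, g, hap)
    !any(vapply(up$reachable, function(n) {
      geno[[n]] && identical(hap_of[[n]], hap)
    }, NA))
  }, NA)]
  paths <- stats::setNames(
    lapply(maximal, function(g) .witness_path(reach$via, focal, g)),
    maximal)
  structure(list(focal = focal, haplotype = hap,
                 candidates = unname(maximal), paths = paths),
            class = "allele_trace")
}

#' @export
print.allele_trace <- function(x, ...) {
  cat("<allele_trace> ", x$focal, " (", x$haplotype, ") <- {",
      paste(x$candidates, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Annotated pedigree report
#'
#' Per-node listing of haplotype, predicted salt response (H1 tolerant,
#' any other haplotype sensitive, ungenotyped unknown) and, for requested
#' focal nodes, the traced allele source.
#'
#' @param ped A [validate_pedigree()] result.
#' @param focal Character vector of focal node names to trace (only
#'   genotyped nodes are traceable).
#' @return Data frame: `name`, `genotyped`, `haplotype`,
#'   `predicted_response`, `allele_source` (comma-joined candidates, NA
#'   for non-focal nodes).
#' @export
annotate_pedigree_report <- function(ped, focal = character(0)) {
  stopifnot(inherits(ped, "pedigree"))
  nodes <- ped$nodes
  out <- data.frame(
    name = nodes$name,
    genotyped = nodes$genotyped,
    haplotype = nodes$haplotype,
    predicted_response = ifelse(!nodes$genotyped, "ungenotyped",
                                ifelse(nodes$haplotype == "H1",
                                       "tolerant", "sensitive")),
    allele_source = NA_character_,
    stringsAsFactors = FALSE)
  for (f in focal) {
    tr <- trace_allele(ped, f)
    out$allele_source[out$name == f] <- paste(tr$candidates,
                                              collapse = ",")
  }
  out
}
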