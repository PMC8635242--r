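# Shared fixtures (built once per test run) and independent brute-force
# oracles used by the property tests.

.fixture_cache <- new.env(parent = emptyenv())

cached_hs <- function() {
  if (is.null(.fixture_cache$hs)) {
    .fixture_cache$hs <- build_haplotype_sequences()
  }
  .fixture_cache$hs
}

cached_vm <- function() {
  if (is.null(.fixture_cache$vm)) {
    .fixture_cache$vm <- generate_variant_matrix(seed = 1,
                                                 haplotypes = cached_hs())
  }
  .fixture_cache$vm
}

# hand-build a variant_matrix for unit tests
make_vm <- function(sites, geno, accessions = colnames(geno)) {
  sites$decoy <- logical(nrow(sites))
  sites$decoy_rule <- rep(NA_character_, nrow(sites))
  structure(list(
    sites = sites,
    geno = geno,
    accessions = data.frame(id = accessions, haplotype = NA_character_,
                            stringsAsFactors = FALSE),
    model = NULL, locus_id = "toy"), class = "variant_matrix")
}

toy_sites <- function(n, pos = seq_len(n), ref = rep("A", n),
                      alt = rep("G", n)) {
  data.frame(id = sprintf("s%02d", seq_len(n)), pos = pos, ref = ref,
             alt = alt,
             kind = ifelse(nchar(ref) == nchar(alt), "SNP",
                           ifelse(nchar(alt) > nchar(ref), "insertion",
                                  "deletion")),
             label = rep(NA_character_, n), stringsAsFactors = FALSE)
}

# brute-force haplotype grouping: all-pairs identity of classifiable columns
oracle_group <- function(geno) {
  homo <- apply(geno, 2L, function(g) all(g %in% c("0/0", "1/1")))
  ids <- colnames(geno)[homo]
  if (!length(ids)) return(list())
  n <- length(ids)
  comp <- seq_len(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && identical(geno[, ids[i]], geno[, ids[j]])) {
        comp[comp == comp[j]] <- comp[i]
      }
    }
  }
  unname(lapply(split(ids, comp), sort))
}

# brute-force allele tracing by exhaustive path enumeration
oracle_trace <- function(ped, focal) {
  nodes <- ped$nodes
  hap <- nodes$haplotype[nodes$name == focal]
  geno <- stats::setNames(nodes$genotyped, nodes$name)
  hap_of <- stats::setNames(nodes$haplotype, nodes$name)
  paths <- list()
  walk <- function(path) {
    u <- path[length(path)]
    for (p in ped$parents[[u]]) {
      paths[[length(paths) + 1L]] <<- c(path, p)
      walk(c(path, p))
    }
  }
  walk(focal)
  consistent <- function(path) {
    inner <- path[-c(1L, length(path))]
    all(!geno[inner] | hap_of[inner] == hap)
  }
  end <- vapply(paths, function(p) p[length(p)], "")
  ends_match <- vapply(paths, function(p) {
    e <- p[length(p)]
    geno[[e]] && identical(hap_of[[e]], hap)
  }, NA)
  ok <- vapply(paths, consistent, NA) & ends_match
  matching <- unique(end[ok])
  if (!length(matching)) return(focal)
  # a matching node strictly inside a consistent path to another matching
  # node is not maximal
  inner_nodes <- unique(unlist(lapply(paths[ok], function(p) {
    p[-c(1L, length(p))]
  })))
  sort(setdiff(matching, inner_nodes))
}

# random small pedigree with partial genotyping, for the oracle comparison
random_pedigree <- function(n_nodes, haps = c("H1", "H2", "H5")) {
  name <- sprintf("N%02d", seq_len(n_nodes))
  parent1 <- parent2 <- rep(NA_character_, n_nodes)
  for (i in seq_len(n_nodes)) {
    if (i > 1L && stats::runif(1) < 0.8) {
      parent1[i] <- name[sample.int(i - 1L, 1L)]
    }
    if (i > 2L && stats::runif(1) < 0.6) {
      p2 <- name[sample.int(i - 1L, 1L)]
      if (!identical(p2, parent1[i])) parent2[i] <- p2
    }
  }
  genotyped <- stats::runif(n_nodes) < 0.6
  haplotype <- ifelse(genotyped, sample(haps, n_nodes, replace = TRUE),
                      NA_character_)
  # children point at parents, so reverse for child-on-top orientation
  data.frame(name = name, parent1 = parent1, parent2 = parent2,
             genotyped = genotyped, haplotype = haplotype,
             stringsAsFactors = FALSE)[n_nodes:1, ]
}
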