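# Filtering, grouping, labelling and CDS-level collapse.

test_that("filter boundaries are read literally from the published rules", {
  # MAF exactly 0.01 is discarded (inclusive-discard)
  geno <- matrix("0/0", 2L, 100L,
                 dimnames = list(c("s01", "s02"), sprintf("A%03d", 1:100)))
  geno[1L, 1L] <- "1/1"        # MAF 1/100 = 0.01 -> out
  geno[2L, 1:2] <- "1/1"       # MAF 0.02 -> in
  vm <- make_vm(toy_sites(2L), geno)
  fl <- filter_sites(vm)
  expect_identical(fl$sites$retained, c(FALSE, TRUE))
  expect_match(fl$sites$reason[1L], "MAF")

  # indel length boundary: 11 inserted nt out, 10 retained
  sites <- toy_sites(2L, ref = c("A", "A"),
                     alt = c(paste0("A", strrep("C", 11L)),
                             paste0("A", strrep("C", 10L))))
  geno <- matrix(rep(c("1/1", "0/0"), each = 2L), 2L, 2L,
                 dimnames = list(sites$id, c("A1", "A2")))
  fl <- filter_sites(make_vm(sites, geno))
  expect_identical(fl$sites$retained, c(FALSE, TRUE))
  expect_match(fl$sites$reason[1L], "indel")

  # a site with no called genotypes is rejected for missingness
  geno <- matrix(c("./.", "./.", "1/1", "0/0"), 2L, 2L, byrow = TRUE,
                 dimnames = list(c("s01", "s02"), c("A1", "A2")))
  fl <- filter_sites(make_vm(toy_sites(2L), geno))
  expect_identical(fl$sites$retained, c(FALSE, TRUE))
  expect_match(fl$sites$reason[1L], "missing")

  # MAF over called alleles only: 1 alt hom among 2 called of 10 = 0.5
  geno <- matrix("./.", 1L, 10L,
                 dimnames = list("s01", sprintf("A%02d", 1:10)))
  geno[1L, 1:2] <- c("1/1", "0/0")
  fl <- filter_sites(make_vm(toy_sites(1L), geno), missing_max = 0.9)
  expect_identical(fl$sites$maf, 0.5)
  expect_true(fl$sites$retained)
})

test_that("filtering is idempotent and tolerates an empty site list", {
  vm <- cached_vm()
  once <- filter_sites(vm)$retained
  twice <- filter_sites(once)$retained
  expect_identical(once$sites, twice$sites)
  expect_identical(once$geno, twice$geno)
  empty <- make_vm(toy_sites(0L),
                   matrix(character(0), 0L, 3L,
                          dimnames = list(NULL, c("A1", "A2", "A3"))))
  expect_identical(nrow(filter_sites(empty)$sites), 0L)
})

test_that("each decoy site is removed by exactly the rule it violates", {
  vm <- cached_vm()
  fl <- filter_sites(vm)
  dec <- fl$sites[fl$sites$decoy, ]
  expect_identical(nrow(dec), 6L)
  expect_false(any(dec$retained))
  rule_pat <- c(maf = "^MAF<=0.01$", missing = "^missing>0.1$",
                indel_len = "^indel>10bp$")
  for (i in seq_len(nrow(dec))) {
    # a single reason, and the designed one
    expect_match(dec$reason[i], rule_pat[[dec$decoy_rule[i]]])
  }
  expect_identical(sum(fl$sites$retained), 57L)
})

test_that("grouping matches the brute-force all-pairs oracle", {
  for (seed in 1:12) {
    set.seed(seed)
    n_sites <- sample(2:10, 1L)
    n_acc <- sample(2:8, 1L)
    geno <- matrix(sample(c("0/0", "1/1", "0/1", "./."), n_sites * n_acc,
                          replace = TRUE, prob = c(0.5, 0.35, 0.08, 0.07)),
                   n_sites, n_acc,
                   dimnames = list(sprintf("s%02d", seq_len(n_sites)),
                                   sprintf("A%02d", seq_len(n_acc))))
    vm <- make_vm(toy_sites(n_sites), geno)
    got <- group_haplotypes(vm)
    got_members <- lapply(got$groups, function(g) sort(g$members))
    want <- oracle_group(geno)
    expect_identical(
      got_members[order(vapply(got_members, `[`, "", 1L))],
      unname(want[order(vapply(want, `[`, "", 1L))]),
      label = paste("seed", seed))
    expect_identical(got$n_classifiable, length(unlist(want)))
  }
})

test_that("grouping handles degenerate panels and ignores accession order", {
  single <- make_vm(toy_sites(3L),
                    matrix("0/0", 3L, 1L,
                           dimnames = list(sprintf("s%02d", 1:3), "A1")))
  expect_length(group_haplotypes(single)$groups, 1L)

  geno <- matrix("0/0", 3L, 2L,
                 dimnames = list(sprintf("s%02d", 1:3), c("A1", "A2")))
  geno[2L, 2L] <- "1/1"
  expect_length(group_haplotypes(make_vm(toy_sites(3L), geno))$groups, 2L)

  vm <- cached_vm()
  shuf <- vm
  perm <- sample(ncol(vm$geno))
  shuf$geno <- vm$geno[, perm]
  shuf$accessions <- vm$accessions[perm, ]
  a <- group_haplotypes(vm)
  b <- group_haplotypes(shuf)
  expect_identical(lapply(a$groups, function(g) sort(g$members)),
                   lapply(b$groups, function(g) sort(g$members)))

  # a duplicated accession lands in exactly one existing group
  dup <- vm
  dup$geno <- cbind(vm$geno, DUP = vm$geno[, 1L])
  sizes_a <- vapply(a$groups, `[[`, 0L, "size")
  sizes_b <- vapply(group_haplotypes(dup)$groups, `[[`, 0L, "size")
  expect_identical(sum(sizes_b) - sum(sizes_a), 1L)
  expect_identical(sum(sizes_b != sizes_a[seq_along(sizes_b)] ), 1L)
})

test_that("default fixture yields six labelled groups collapsing to five", {
  vm <- cached_vm()
  res <- haplotype_pipeline(vm, cached_hs())
  expect_length(res$groups$groups, 6L)
  expect_setequal(unname(res$labels),
                  c("H1", "H2", "H3", "H4", "H5-1", "H5-2"))
  expect_setequal(unname(res$merged), c("H1", "H2", "H3", "H4", "H5"))
  truth <- vm$accessions$haplotype[match(res$assignment$accession,
                                         vm$accessions$id)]
  ok <- !is.na(res$assignment$label)
  expect_true(all(res$assignment$label[ok] == truth[ok]))
})

test_that("CDS extraction reports the designed functional consequences", {
  hs <- cached_hs()
  h1 <- extract_cds(haplotype_sequence(hs, "H1"), hs$model)
  expect_length(h1$flags, 0L)
  expect_identical(nchar(h1$protein) + 1L, hs$model$cds_len %/% 3L)

  h4 <- extract_cds(haplotype_sequence(hs, "H4"), hs$model)
  expect_true("splice_disrupted" %in% h4$flags)

  h2 <- extract_cds(haplotype_sequence(hs, "H2"), hs$model)
  expect_true("premature_stop" %in% h2$flags)
  expect_false("frameshift" %in% h2$flags)  # 3780 is a multiple of 3

  h51 <- extract_cds(haplotype_sequence(hs, "H5-1"), hs$model)
  h52 <- extract_cds(haplotype_sequence(hs, "H5-2"), hs$model)
  expect_true("frameshift" %in% h51$flags)
  expect_identical(h51$cds, h52$cds)
  expect_identical(h51$protein, h52$protein)

  # destroying the start codon is flagged
  broken <- haplotype_sequence(hs, "H1")
  v <- data.frame(id = "kill_atg", label = "kill_atg", pos = 1L, ref = "A",
                  alt = "C", kind = "SNP", carriers = "H1",
                  in_matrix = FALSE)
  broken$sequence <- apply_variants(broken$sequence, v, hs$model)
  broken$variants <- v
  expect_true("no_start" %in% extract_cds(broken, hs$model)$flags)
})

test_that("CDS collapse merges H5 sublineages and nothing else", {
  hs <- cached_hs()
  merged <- collapse_by_cds(c("H1", "H2", "H3", "H4", "H5-1", "H5-2"), hs)
  expect_identical(unname(merged[c("H5-1", "H5-2")]), c("H5", "H5"))
  expect_identical(unname(merged[c("H1", "H2", "H3", "H4")]),
                   c("H1", "H2", "H3", "H4"))
  # idempotent: merging the merged labels changes nothing
  expect_warning(again <- collapse_by_cds(unname(merged), hs), "H5")
  expect_identical(unname(again[c("H1", "H2")]), c("H1", "H2"))
  # never merges labels whose proteins differ
  prot <- vapply(c("H1", "H2", "H3", "H4"), function(h) {
    extract_cds(haplotype_sequence(hs, h), hs$model)$protein
  }, "")
  expect_identical(anyDuplicated(prot), 0L)
})

test_that("functional impact classification follows the precedence order", {
  hs <- cached_hs()
  got <- vapply(names(hs$sequences), function(h) {
    classify_functional_impact(haplotype_sequence(hs, h), hs$model)
  }, "")
  expect_identical(unname(got),
                   c("full_length", "retro_truncated",
                     "coding_substitution", "splice_disrupted",
                     "frameshift", "frameshift"))
})
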