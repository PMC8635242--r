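# The deterministic synthetic locus and the seeded panel generators.

test_that("haplotype templates carry the designed structural variants", {
  hs <- cached_hs()
  L1 <- nchar(hs$sequences[["H1"]])
  # the retroelement insertion is exactly 3.78 kb
  expect_identical(nchar(hs$sequences[["H2"]]), L1 + 3780L)
  # H3/H4 share a 148-nt promoter insertion + TCGA; H5 carries 150 + TCGA
  expect_identical(nchar(hs$sequences[["H3"]]), L1 + 148L + 4L)
  expect_identical(nchar(hs$sequences[["H5-1"]]), L1 + 150L + 4L - 4L)
  # H5 is 4 nt shorter than H3 across the exon-2 amplicon window
  reg <- default_marker_registry()
  m <- reg[["H5-Del"]]
  len_h3 <- simulate_pcr(hs$sequences[["H3"]], m$forward, m$reverses)$length
  len_h5 <- simulate_pcr(hs$sequences[["H5-1"]], m$forward,
                         m$reverses)$length
  expect_identical(len_h3 - len_h5, 4L)
})

test_that("applying each haplotype's variants to H1 reproduces its template", {
  hs <- cached_hs()
  for (h in names(hs$sequences)) {
    v <- hs$variants[variant_carried(hs$variants, h), , drop = FALSE]
    expect_identical(apply_variants(hs$sequences[["H1"]], v, hs$model),
                     hs$sequences[[h]], label = h)
  }
  expect_identical(sum(variant_carried(hs$variants, "H1")), 0L)
})

test_that("locus construction is deterministic and validates its config", {
  hs2 <- build_haplotype_sequences()
  expect_identical(hs2$sequences, cached_hs()$sequences)
  cfg <- default_locus_config()
  cfg$prom_ins_len_h34 <- 0L
  expect_error(build_haplotype_sequences(cfg), "Pro-Ins")
  cfg2 <- default_locus_config()
  cfg2$retro_anchor <- 2500L  # outside the H2-Ins primer window
  expect_error(build_haplotype_sequences(cfg2), "H2-Ins")
})

test_that("variant matrix: 53 SNPs + 4 indels define the six haplotypes", {
  vm <- cached_vm()
  real <- vm$sites[!vm$sites$decoy, ]
  expect_identical(nrow(real), 57L)
  expect_identical(sum(real$kind == "SNP"), 53L)
  expect_identical(sum(real$kind != "SNP"), 4L)
  expect_true(all(abs(nchar(real$ref) - nchar(real$alt)) <= 10L))
  expect_identical(ncol(vm$geno), 279L)
  # joint patterns over the clean accessions define exactly 6 haplotypes
  clean <- apply(vm$geno[real$id, ], 2L,
                 function(g) all(g %in% c("0/0", "1/1")))
  pat <- apply(vm$geno[real$id, clean], 2L, paste, collapse = "")
  expect_identical(length(unique(pat)), 6L)
})

test_that("variant matrix generation is seed-reproducible and validated", {
  hs <- cached_hs()
  a <- generate_variant_matrix(seed = 42, haplotypes = hs)
  b <- generate_variant_matrix(seed = 42, haplotypes = hs)
  c <- generate_variant_matrix(seed = 43, haplotypes = hs)
  expect_identical(a$geno, b$geno)
  expect_false(identical(a$geno, c$geno))
  expect_error(generate_variant_matrix(hap_freqs = c(H1 = 0.6, H2 = 0.5),
                                       seed = 1, haplotypes = hs),
               "sum to 1")
  expect_error(generate_variant_matrix(missing_rate = 1, seed = 1,
                                       haplotypes = hs), "missing_rate")
  expect_error(generate_variant_matrix(haplotypes = hs), "seed")
})

test_that("degenerate haplotype frequencies behave", {
  hs <- cached_hs()
  one <- generate_variant_matrix(n_accessions = 1L, seed = 7,
                                 missing_rate = 0, haplotypes = hs)
  expect_identical(ncol(one$geno), 1L)
  h1only <- generate_variant_matrix(
    n_accessions = 20L, hap_freqs = c(H1 = 1), seed = 7, missing_rate = 0,
    n_decoy_sites = 0L, haplotypes = hs)
  expect_true(all(h1only$geno == "0/0"))
})

test_that("breeding panel respects its conditional phenotype model", {
  p <- generate_breeding_panel(seed = 5)
  expect_identical(nrow(p), 536L)
  sc <- as.matrix(p[grep("^score", names(p))])
  expect_true(all(sc[p$phenotype == "tolerant", ] %in% 1:2))
  expect_true(all(sc[p$phenotype == "sensitive", ] %in% 3:5))
  # non-H1 lines are deterministically sensitive at the default
  # p_sensitive_given_nonH1 = 1
  expect_true(all(p$phenotype[p$haplotype != "H1"] == "sensitive"))
  p_all_tol <- generate_breeding_panel(n_lines = 50L,
                                       p_tolerant_given_H1 = 1, seed = 5)
  expect_true(all(p_all_tol$phenotype[p_all_tol$haplotype == "H1"] ==
                    "tolerant"))
  expect_identical(generate_breeding_panel(seed = 11),
                   generate_breeding_panel(seed = 11))
  expect_error(generate_breeding_panel(region_hap_table =
                                         default_region_hap_table()[0, ],
                                       seed = 1), "region")
  expect_error(generate_breeding_panel(), "seed")
})

test_that("pedigree fixture encodes the four cultivars and 19 ancestors", {
  nodes <- build_pedigree_fixture()
  expect_identical(nrow(nodes), 23L)
  expect_identical(nodes$haplotype[nodes$name == "Zhonghuang 30"], "H1")
  expect_identical(nodes$haplotype[nodes$name == "Zhonghuang 39"], "H2")
  expect_false(nodes$genotyped[nodes$name == "Yudou 8"])
  expect_s3_class(validate_pedigree(nodes), "pedigree")  # acyclic
})
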