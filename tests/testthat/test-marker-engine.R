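# In-silico PCR and restriction digestion.

test_that("primer site search finds exact matches on both strands", {
  hs <- cached_hs()
  reg <- default_marker_registry()
  hits <- find_primer_sites(hs$sequences[["H1"]], reg[["Pro-Ins"]]$forward)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$strand, "+")

  expect_identical(nrow(find_primer_sites("ACGTACGTACGTACGTACGT",
                                          "TTTTTTTTTTTTTTTT")), 0L)

  p <- "GGGTTGTGCCTAAATAGCA"
  both <- paste0("AAAA", p, "TTTT", revcomp(p), "AAAA")
  hits <- find_primer_sites(both, p)
  expect_setequal(hits$strand, c("+", "-"))
})

test_that("H2-Ins allele-specific products carry their tags and lengths", {
  hs <- cached_hs()
  m <- default_marker_registry()[["H2-Ins"]]
  on_h2 <- simulate_pcr(hs$sequences[["H2"]], m$forward, m$reverses)
  expect_identical(nrow(on_h2), 1L)
  expect_identical(on_h2$length, 565L)
  expect_identical(on_h2$allele_tag, "H2-specific")

  on_h1 <- simulate_pcr(hs$sequences[["H1"]], m$forward, m$reverses)
  expect_identical(on_h1$length, 364L)
  expect_identical(on_h1$allele_tag, "H1-type")

  # both primer sites exist on H2, but the F x R/H1 product would have to
  # span the 3.78-kb insertion: suppressed at the default length cap,
  # present when the cap is lifted
  wide <- simulate_pcr(hs$sequences[["H2"]], m$forward, m$reverses,
                       max_product = 10000L)
  expect_setequal(wide$length, c(565L, 364L + 3780L))
})

test_that("cut-site geometry follows the offset-cutter conventions", {
  mboII <- list(recognition = "GAAGA", cut_offset = 8L, palindromic = FALSE)
  nlaIII <- list(recognition = "CATG", cut_offset = 0L, palindromic = TRUE)
  toy <- paste0(strrep("N", 5L), "GAAGA", strrep("N", 10L))
  expect_identical(find_cut_sites(toy, mboII), 18L)
  expect_identical(digest_amplicon(toy, mboII, end_protect = 0L)$fragments,
                   c(18L, 2L))
  expect_identical(find_cut_sites("AACATGAA", nlaIII), 6L)
  # minus-strand MboII site: TCTTC starting at 12 cuts after 12 - 1 - 8 = 3
  toy2 <- paste0(strrep("A", 11L), "TCTTC", strrep("A", 6L))
  expect_identical(find_cut_sites(toy2, mboII), 3L)
  expect_identical(find_cut_sites("ACGTACGTACGT", mboII), integer(0))
})

test_that("digestion conserves length and is strand-symmetric", {
  mboII <- list(recognition = "GAAGA", cut_offset = 8L, palindromic = FALSE)
  nlaIII <- list(recognition = "CATG", cut_offset = 0L, palindromic = TRUE)
  set.seed(99)
  for (i in 1:40) {
    n <- sample(60:400, 1L)
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    for (enz in list(mboII, nlaIII)) {
      d <- digest_amplicon(s, enz)
      expect_identical(sum(d$fragments), nchar(s))
      d_rc <- digest_amplicon(revcomp(s), enz)
      if (!isTRUE(enz$palindromic)) {
        # distance cutter: both strands are scanned, mirroring is exact
        expect_identical(d$fragments, d_rc$fragments)
      } else {
        # palindromic 3'-overhang cutter: a site [p, p+3] cuts after p+3
        # forward and after n-p+1 on the reverse complement, i.e. every
        # boundary maps through c -> n - c + 4; sums are conserved
        expect_identical(sum(d_rc$fragments), nchar(s))
        k <- nchar(enz$recognition)
        mapped <- nchar(s) - find_cut_sites(s, enz) + k
        mapped <- sort(mapped[mapped >= 1L & mapped <= nchar(s) - 1L])
        direct <- find_cut_sites(revcomp(s), enz)
        direct <- direct[(nchar(s) - direct + k) >= 1L &
                           (nchar(s) - direct + k) <= nchar(s) - 1L]
        expect_identical(direct, mapped)
      }
    }
  }
  expect_identical(digest_amplicon("ACGTACGTACGTACGT", mboII)$fragments, 16L)
})

test_that("the fixture reproduces the complete published size table", {
  hs <- cached_hs()
  reg <- default_marker_registry()
  sizes <- function(marker, hap) {
    simulate_pcr(hs$sequences[[hap]], reg[[marker]]$forward,
                 reg[[marker]]$reverses)$length
  }
  frags <- function(marker, hap) {
    amp <- simulate_pcr(hs$sequences[[hap]], reg[[marker]]$forward,
                        reg[[marker]]$reverses)
    digest_amplicon(amp$sequence[1L], reg[[marker]]$enzyme)$fragments
  }
  expect_identical(vapply(names(hs$sequences), sizes, 0L,
                          marker = "Pro-Ins"),
                   c(H1 = 623L, H2 = 623L, H3 = 775L, H4 = 775L,
                     `H5-1` = 777L, `H5-2` = 777L))
  expect_identical(vapply(names(hs$sequences), sizes, 0L,
                          marker = "H2-Ins"),
                   c(H1 = 364L, H2 = 565L, H3 = 364L, H4 = 364L,
                     `H5-1` = 364L, `H5-2` = 364L))
  expect_identical(vapply(names(hs$sequences), sizes, 0L,
                          marker = "H5-Del"),
                   c(H1 = 214L, H2 = 214L, H3 = 214L, H4 = 214L,
                     `H5-1` = 210L, `H5-2` = 210L))
  for (h in names(hs$sequences)) {
    expect_identical(sizes("H3-MboII", h), 296L, label = h)
    expect_identical(sizes("H4-NlaIII", h), 262L, label = h)
  }
  expect_identical(frags("H3-MboII", "H3"), c(125L, 119L, 52L))
  for (h in c("H1", "H2", "H4", "H5-1", "H5-2")) {
    expect_identical(frags("H3-MboII", h), c(244L, 52L), label = h)
  }
  expect_identical(frags("H4-NlaIII", "H4"), c(111L, 87L, 42L, 22L))
  for (h in c("H1", "H2")) {
    expect_identical(frags("H4-NlaIII", h), c(133L, 129L), label = h)
  }
  for (h in c("H3", "H5-1", "H5-2")) {
    expect_identical(frags("H4-NlaIII", h), c(133L, 87L, 42L), label = h)
  }
})

test_that("inserting k nt between primer sites grows the product by k", {
  hs <- cached_hs()
  m <- default_marker_registry()[["H5-Del"]]
  for (k in c(1L, 7L, 30L)) {
    ins <- data.frame(id = "ins", label = "ins", pos = 520L, ref = "",
                      alt = "", kind = "insertion", carriers = "H1",
                      in_matrix = FALSE)
    anchor <- substr(hs$sequences[["H1"]],
                     locus_to_str(520L, hs$model$promoter_len),
                     locus_to_str(520L, hs$model$promoter_len))
    ins$ref <- anchor
    ins$alt <- paste0(anchor, strrep("A", k))
    tpl <- apply_variants(hs$sequences[["H1"]], ins, hs$model)
    expect_identical(simulate_pcr(tpl, m$forward, m$reverses)$length,
                     214L + k)
  }
})

test_that("band matching merges 775/777 and reports ambiguity honestly", {
  reg <- default_marker_registry()
  pro <- reg[["Pro-Ins"]]
  expect_identical(match_band_pattern(775, pro)$class, "insertion-present")
  expect_identical(match_band_pattern(777, pro)$class, "insertion-present")
  expect_identical(match_band_pattern(623, pro)$class, "623")
  h5 <- reg[["H5-Del"]]
  # 212 bp sits within 1% of both 210 and 214
  expect_identical(match_band_pattern(212, h5)$class, "ambiguous")
  expect_setequal(match_band_pattern(212, h5)$candidates, c("210", "214"))
  expect_identical(match_band_pattern(500, h5)$class, "unscored")
  nla <- reg[["H4-NlaIII"]]
  expect_identical(match_band_pattern(c(129, 133), nla)$class,
                   "two-fragment")
  expect_identical(match_band_pattern(c(133, 129, 5), nla)$class,
                   "unscored")
})
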