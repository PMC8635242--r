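# Phenotype classification, frequency tables, concordance, trends.

test_that("chlorosis classification uses the modal score, ties sensitive", {
  expect_identical(classify_phenotype(rep(1L, 18L)),
                   list(class = 1L, response = "tolerant"))
  expect_identical(classify_phenotype(c(3, 3, 4)),
                   list(class = 3L, response = "sensitive"))
  expect_identical(classify_phenotype(c(2, 2, 3, 3)),
                   list(class = 3L, response = "sensitive"))
  expect_identical(classify_phenotype(c(1, 1, 2, 2))$class, 2L)
  expect_error(classify_phenotype(c(2, 6)), "1..5")
  expect_error(classify_phenotype(c(1.5)), "1..5")
})

test_that("release years bin into the published decade scheme", {
  expect_identical(decade_bin(c(1956, 2011, 1979, 1950, 1999, 2000, 2012)),
                   c("1950s", "2000s", "1970s", "1950s", "1990s", "2000s",
                     "2000s"))
  expect_identical(decade_bin(1949), "pre-1950")
  expect_identical(decade_bin(2013), "2010s")
})

test_that("frequency tables reproduce the printed validation percentages", {
  panel <- data.frame(
    haplotype = rep(c("H1", "H2", "H3", "H5"), c(188L, 220L, 1L, 127L)))
  ft <- frequency_table(panel)
  pct <- stats::setNames(ft$pct, ft$haplotype)
  expect_identical(pct[["H1"]], 35.1)
  expect_identical(pct[["H2"]], 41.0)
  expect_identical(pct[["H5"]], 23.7)
  expect_identical(pct[["H3"]], 0.2)
  expect_true(all(ft$n == 536L))
})

test_that("frequency table edge cases and rounding invariants hold", {
  one <- frequency_table(data.frame(haplotype = "H2", region = "NR"),
                         "region")
  expect_identical(one$pct, 100)
  four <- frequency_table(data.frame(haplotype = rep(c("H1", "H2", "H4",
                                                       "H5"), 3L)))
  expect_true(all(four$pct == 25))
  # percentages per group sum to 100 within rounding slack
  set.seed(31)
  for (i in 1:10) {
    panel <- data.frame(
      haplotype = sample(c("H1", "H2", "H3", "H4", "H5"), 97L,
                         replace = TRUE, prob = stats::runif(5)),
      region = sample(c("NR", "HHR", "SR"), 97L, replace = TRUE))
    ft <- frequency_table(panel, "region")
    sums <- tapply(ft$pct, ft$region, sum)
    n_h <- tapply(ft$pct, ft$region, length)
    expect_true(all(abs(sums - 100) <= 0.05 * n_h))
  }
  # unclassified entries excluded from denominators, reported separately
  panel <- data.frame(haplotype = c("H1", "H1", NA, "H2"))
  ft <- frequency_table(panel)
  expect_identical(unique(ft$n), 3L)
  expect_identical(unname(attr(ft, "unclassified")), 1L)
})

test_that("concordance recovers the printed validation accuracies", {
  panel <- data.frame(
    haplotype = rep(c("H1", "H1", "H2", "H5", "H3"),
                    c(186L, 2L, 220L, 127L, 1L)),
    phenotype = rep(c("tolerant", "sensitive", "sensitive", "sensitive",
                      "sensitive"), c(186L, 2L, 220L, 127L, 1L)))
  cc <- concordance(panel)
  expect_identical(cc$pct_tolerant, 98.9)
  expect_identical(cc$pct_sensitive, 100)
  expect_identical(cc$n_sensitive_lines, 350L)
  expect_identical(sum(cc$confusion), 536L)

  perfect <- data.frame(haplotype = c("H1", "H2"),
                        phenotype = c("tolerant", "sensitive"))
  expect_identical(concordance(perfect)$pct_tolerant, 100)
  expect_identical(concordance(perfect)$pct_sensitive, 100)

  flipped <- data.frame(haplotype = c("H1", "H2"),
                        phenotype = c("sensitive", "tolerant"))
  expect_identical(concordance(flipped)$accuracy_tolerant, 0)
  expect_identical(concordance(flipped)$accuracy_sensitive, 0)

  only_h1 <- data.frame(haplotype = "H1", phenotype = "tolerant")
  expect_true(is.na(concordance(only_h1)$accuracy_sensitive))
})

test_that("trend summaries report endpoint changes per haplotype", {
  freq <- expand.grid(region = "NR",
                      decade = c("1970s", "1980s", "1990s", "2000s"),
                      haplotype = c("H1", "H2"),
                      stringsAsFactors = FALSE)
  freq$pct <- c(60.5, 52, 45, 39.3, 23.7, 30, 40, 48.8)
  tr <- trend_summary(freq, "NR")
  h1 <- tr[tr$haplotype == "H1", ]
  expect_identical(h1$start_pct, 60.5)
  expect_identical(h1$end_pct, 39.3)
  expect_identical(h1$change, -21.2)
  expect_identical(h1$direction, "down")
  expect_identical(tr$change[tr$haplotype == "H2"], 25.1)

  const <- data.frame(region = "NR", decade = c("1970s", "1980s"),
                      haplotype = "H1", pct = 50)
  expect_identical(trend_summary(const, "NR")$change, 0)
  expect_identical(nrow(trend_summary(const, "NR")), 1L)

  single <- data.frame(region = "NR", decade = "1970s", haplotype = "H1",
                       pct = 50)
  expect_error(trend_summary(single, "NR"), "insufficient timepoints")
})
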