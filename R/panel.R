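# Panel summaries: chlorosis phenotype classification, haplotype frequency
# tables by eco-region and release decade, concordance, temporal trends.

#' Classify a line's salt response from plant-level chlorosis scores
#'
#' The line-level chlorosis class is the modal plant score, ties resolved
#' toward the larger (more sensitive) score — conservative for tolerance
#' claims. Scores 1-2 are tolerant, 3-5 sensitive.
#'
#' @param scores Integer vector of plant-level chlorosis scores in 1..5
#'   (1 healthy .. 5 dead); at least one score.
#' @return List with `class` (1-5) and `response` (`"tolerant"` or
#'   `"sensitive"`).
#' @export
#' @examples
#' classify_phenotype(c(2, 2, 3, 3))  # tie -> class 3, sensitive
classify_phenotype <- function(scores) {
  stopifnot(length(scores) >= 1L)
  if (any(is.na(scores)) || any(scores != round(scores)) ||
      any(scores < 1 | scores > 5)) {
    stop("chlorosis scores must be integers in 1..5")
  }
  tab <- table(factor(scores, levels = 1:5))
  modal <- as.integer(names(tab)[tab == max(tab)])
  cls <- max(modal)
  list(class = cls, response = if (cls <= 2L) "tolerant" else "sensitive")
}

#' Bin a release year into a breeding decade
#'
#' Decades run 1950-1959 ("1950s") through 1990-1999; releases from
#' 2000-2012 are pooled as "2000s" (the few 2011/2012 releases are merged
#' with the 2000s), later years as "2010s", and pre-1950 years as
#' "pre-1950".
#'
#' @param year Integer vector of release years.
#' @return Character vector of decade labels.
#' @export
decade_bin <- function(year) {
  stopifnot(!any(is.na(year)))
  vapply(as.integer(year), function(y) {
    if (y < 1950L) "pre-1950"
    else if (y <= 2012L) paste0(min(y - y %% 10L, 2000L), "s")
    else "2010s"
  }, "")
}

#' Haplotype frequency table by grouping keys
#'
#' Counts and percentages (rounded half-up to one decimal, the convention
#' of published frequency tables) of each haplotype within each group.
#' Entries without a haplotype call are excluded from denominators and
#' reported in the `unclassified` attribute.
#'
#' @param panel Data frame with a `haplotype` column and any grouping
#'   columns.
#' @param group_by Character vector of grouping column names (may be
#'   empty for a panel-wide table).
#' @return Data frame of class `frequency_table`: grouping keys,
#'   `haplotype`, `count`, `n` (group size) and `pct`; attribute
#'   `unclassified` holds the per-group number of entries without a call.
#' @export
frequency_table <- function(panel, group_by = character(0)) {
  stopifnot(is.data.frame(panel), "haplotype" %in% names(panel),
            all(group_by %in% names(panel)))
  has_call <- !is.na(panel$haplotype)
  key <- if (length(group_by)) {
    interaction(panel[group_by], drop = TRUE, sep = "\r")
  } else factor(rep("all", nrow(panel)))
  rows <- list()
  uncl <- list()
  for (g in levels(key)) {
    sel <- key == g & has_call
    n <- sum(sel)
    uncl[[g]] <- sum(key == g & !has_call)
    if (n == 0L) {
      warning("group ", gsub("\r", "/", g), " has no classified entries; ",
              "omitted")
      next
    }
    tab <- table(panel$haplotype[sel])
    keyvals <- strsplit(g, "\r", fixed = TRUE)[[1L]]
    for (h in names(tab)) {
      row <- if (length(group_by)) {
        as.list(stats::setNames(keyvals, group_by[seq_along(keyvals)]))
      } else list()
      row$haplotype <- h
      row$count <- as.integer(tab[[h]])
      row$n <- n
      row$pct <- round_half_up(100 * tab[[h]] / n, 1L)
      rows[[length(rows) + 1L]] <- as.data.frame(row,
                                                 stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "unclassified") <- unlist(uncl)
  class(out) <- c("frequency_table", class(out))
  out
}

#' Genotype-phenotype concordance of a validation panel
#'
#' Prediction accuracy of the marker haplotype for salt response:
#' `accuracy_tolerant` is the fraction of H1 lines that phenotype
#' tolerant, `accuracy_sensitive` the fraction of non-H1 lines that
#' phenotype sensitive. Percentages are rounded half-up to one decimal.
#'
#' @param panel Data frame with `haplotype` and `phenotype`
#'   (`"tolerant"`/`"sensitive"`) columns; every row must have both.
#' @return List of class `concordance`: `accuracy_tolerant`,
#'   `accuracy_sensitive` (proportions, `NA` when the denominator is
#'   zero), `pct_tolerant`, `pct_sensitive` (half-up percentages),
#'   `confusion` (2x2 predicted x observed counts), `n_tolerant_lines`,
#'   `n_sensitive_lines`, `n`.
#' @export
concordance <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("haplotype", "phenotype") %in% names(panel)))
  if (any(is.na(panel$haplotype)) || any(is.na(panel$phenotype))) {
    stop("every entry needs both a haplotype call and a phenotype")
  }
  pred <- ifelse(panel$haplotype == "H1", "tolerant", "sensitive")
  obs <- panel$phenotype
  lv <- c("tolerant", "sensitive")
  confusion <- table(predicted = factor(pred, lv), observed = factor(obs, lv))
  n_h1 <- sum(pred == "tolerant")
  n_non <- sum(pred == "sensitive")
  acc_t <- if (n_h1 > 0L) confusion["tolerant", "tolerant"] / n_h1
           else NA_real_
  acc_s <- if (n_non > 0L) confusion["sensitive", "sensitive"] / n_non
           else NA_real_
  structure(list(
    accuracy_tolerant = acc_t,
    accuracy_sensitive = acc_s,
    pct_tolerant = if (is.na(acc_t)) NA_real_
                   else round_half_up(100 * acc_t, 1L),
    pct_sensitive = if (is.na(acc_s)) NA_real_
                    else round_half_up(100 * acc_s, 1L),
    confusion = confusion,
    n_tolerant_lines = sum(obs == "tolerant"),
    n_sensitive_lines = sum(obs == "sensitive"),
    n = nrow(panel)), class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat("<concordance> tolerant-class accuracy ",
      ifelse(is.na(x$pct_tolerant), "NA", paste0(x$pct_tolerant, "%")),
      ", sensitive-class accuracy ",
      ifelse(is.na(x$pct_sensitive), "NA", paste0(x$pct_sensitive, "%")),
      " (n = ", x$n, ")\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' Per-haplotype frequency change over a decade window
#'
#' Reports, for one region, each haplotype's percentage in the first and
#' last decade of the window and the signed change in percentage points.
#' No significance test is attached.
#'
#' @param freq A [frequency_table()] grouped by (at least) `region` and
#'   `decade`.
#' @param region Region to summarise.
#' @param from,to Optional first/last decade labels; default to the
#'   earliest and latest decade present for the region.
#' @return Data frame: `haplotype`, `from`, `to`, `start_pct`, `end_pct`,
#'   `change` (percentage points), `direction`.
#' @export
trend_summary <- function(freq, region, from = NULL, to = NULL) {
  stopifnot(all(c("region", "decade", "haplotype", "pct") %in% names(freq)))
  fr <- freq[freq$region == region, , drop = FALSE]
  decades <- sort(unique(fr$decade))
  if (length(decades) < 2L) stop("insufficient timepoints: need >= 2 decades")
  from <- from %||% decades[1L]
  to <- to %||% decades[length(decades)]
  stopifnot(from %in% decades, to %in% decades, from != to)
  haps <- sort(unique(fr$haplotype))
  pct_at <- function(h, d) {
    v <- fr$pct[fr$haplotype == h & fr$decade == d]
    if (length(v)) v[1L] else 0
  }
  out <- data.frame(
    haplotype = haps,
    from = from, to = to,
    start_pct = vapply(haps, pct_at, 0, d = from),
    end_pct = vapply(haps, pct_at, 0, d = to),
    stringsAsFactors = FALSE)
  out$change <- round_half_up(out$end_pct - out$start_pct, 1L)
  out$direction <- ifelse(out$change > 0, "up",
                          ifelse(out$change < 0, "down", "flat"))
  rownames(out) <- NULL
  out
}
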