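# Synthetic GmSALT3-like locus.
#
# The real locus sequence is not redistributable, so the packaged fixture is
# seeded random DNA with primer landing sites, restriction motifs and variant
# positions placed so that every published marker size is reproduced by the
# in-silico PCR/digest engine. Coordinates are 1-based locus coordinates:
# the A of the ATG is +1, the promoter base immediately 5' of it is -1, and
# there is no position 0.

HAPLOTYPE_IDS <- c("H1", "H2", "H3", "H4", "H5-1", "H5-2")
MERGED_LABELS <- c("H1", "H2", "H3", "H4", "H5")

#' Convert locus coordinates to reference-string positions
#'
#' Locus coordinates place the A of the start codon at +1 and promoter bases
#' at negative positions (no position 0). String positions are plain 1-based
#' indices into the H1 reference sequence.
#'
#' @param pos Integer vector of locus coordinates (negative or positive,
#'   never 0).
#' @param promoter_len Promoter length in nt (locus positions
#'   `-promoter_len .. -1`).
#' @return Integer vector of string positions.
#' @export
locus_to_str <- function(pos, promoter_len) {
  stopifnot(all(pos != 0L))
  ifelse(pos < 0L, pos + promoter_len + 1L, pos + promoter_len)
}

#' @rdname locus_to_str
#' @param str_pos Integer vector of 1-based string positions.
#' @export
str_to_locus <- function(str_pos, promoter_len) {
  ifelse(str_pos <= promoter_len, str_pos - promoter_len - 1L,
         str_pos - promoter_len)
}

#' Gene model of the synthetic locus
#'
#' @param config A locus configuration, see [default_locus_config()].
#' @return A list of class `gene_model` with the locus id, promoter span,
#'   exon spans (locus coordinates, closed intervals), derived intron spans,
#'   promoter length and total reference length.
#' @export
gene_model <- function(config = default_locus_config()) {
  exons <- config$exon_spans
  stopifnot(length(exons) >= 1L)
  starts <- vapply(exons, `[`, 0L, 1L)
  ends <- vapply(exons, `[`, 0L, 2L)
  stopifnot(all(diff(starts) > 0), all(ends >= starts),
            all(starts[-1L] > ends[-length(ends)]))
  cds_len <- sum(ends - starts + 1L)
  stopifnot(cds_len %% 3L == 0L)
  introns <- if (length(exons) > 1L) {
    lapply(seq_len(length(exons) - 1L), function(i) {
      c(ends[i] + 1L, starts[i + 1L] - 1L)
    })
  } else list()
  structure(list(
    locus_id = config$locus_id,
    promoter_span = c(-config$promoter_len, -1L),
    exon_spans = exons,
    intron_spans = introns,
    promoter_len = config$promoter_len,
    cds_len = cds_len,
    length = config$locus_len
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$locus_id, ": ", x$length, " nt reference, promoter ",
      x$promoter_len, " nt, ", length(x$exon_spans), " exons (CDS ",
      x$cds_len, " nt)\n", sep = "")
  invisible(x)
}

#' Default configuration of the synthetic locus
#'
#' All geometry needed to build the haplotype templates: promoter length,
#' exon spans, primer landing coordinates for the five markers, anchors of
#' the structural and diagnostic variants, and the insertion lengths. The
#' defaults satisfy every published marker size simultaneously:
#' Pro-Ins 623/775/777, H2-Ins 364/565, H3-MboII 296 with fragments
#' 244+52 or 125+119+52, H4-NlaIII 262 with fragments 133+129, 133+87+42 or
#' 111+87+42+22, and H5-Del 214/210.
#'
#' @param base_seed Integer seed for the deterministic construction of the
#'   background sequence (fixed default; the fixture is a constant, not a
#'   random object).
#' @return A named list understood by [build_haplotype_sequences()] and
#'   [gene_model()].
#' @export
default_locus_config <- function(base_seed = 104729L) {
  list(
    locus_id = "GmSALT3syn",
    promoter_len = 800L,
    locus_len = 3100L,
    exon_spans = list(c(1L, 150L), c(451L, 600L), c(901L, 1400L),
                      c(1701L, 2100L)),
    # primer 5' landing coordinates (locus coords of the leftmost template
    # base of the site; reverse primers bind the minus strand, so the site
    # holds the reverse complement of the primer)
    primer_sites = list(
      "Pro-Ins-F" = -651L, "Pro-Ins-R" = -46L,
      "H5-Del-F" = 481L, "H5-Del-R" = 673L,
      "H2-Ins-F" = 950L, "H2-Ins-R/H1" = 1294L,
      "H4-NlaIII-F" = 791L, "H4-NlaIII-R" = 1028L,
      "H3-MboII-F" = 1721L, "H3-MboII-R" = 1997L
    ),
    # variant anchors (locus coords)
    prom_ins_anchor = -147L,    # ~150 bp promoter insertion (after anchor)
    tcga_anchor = -103L,        # TCGA promoter insertion (after anchor)
    retro_anchor = 1100L,       # 3.78-kb retroelement insertion, exon 3
    tgct_start = 540L,          # TGCT deletion, exon 2 (deleted 540..543)
    splice_pos = 900L,          # last base of intron 2: AG > AT
    exon4_sub_pos = 1832L,      # GC > TG substitution, exon 4
    shared345_pos = 1010L,      # SNP shared by H3/H4/H5, exon 3
    prom_ins_len_h34 = 148L,    # H3/H4 promoter insertion length (nt)
    prom_ins_len_h5 = 150L,     # H5 promoter insertion length (nt)
    retro_len = 3780L,          # retroelement insertion length (nt)
    base_seed = as.integer(base_seed)
  )
}

# ---- internal construction helpers -----------------------------------------

# character-vector stamp at locus coordinate `pos`
.stamp <- function(chars, pos, text, promoter_len) {
  s <- locus_to_str(pos, promoter_len)
  idx <- s:(s + nchar(text) - 1L)
  chars[idx] <- strsplit(text, "")[[1L]]
  chars
}

.span_str <- function(pos, len, promoter_len) {
  s <- locus_to_str(pos, promoter_len)
  s:(s + len - 1L)
}

# CDS index of a string position (NA outside exons); exon spans in locus
# coords, positions in string coords
.cds_index <- function(str_pos, model) {
  P <- model$promoter_len
  loc <- str_to_locus(str_pos, P)
  off <- 0L
  for (ex in model$exon_spans) {
    if (loc >= ex[1L] && loc <= ex[2L]) return(off + loc - ex[1L] + 1L)
    off <- off + ex[2L] - ex[1L] + 1L
  }
  NA_integer_
}

# Would setting base `b` at string position `sp` leave a stop codon in the
# H1 reading frame? Positions outside exons are always safe.
.makes_stop <- function(chars, sp, b, model) {
  ci <- .cds_index(sp, model)
  if (is.na(ci)) return(FALSE)
  off <- (ci - 1L) %% 3L
  idx <- vapply(c(-off, 1L - off, 2L - off), function(d) {
    # map codon-relative CDS index back to string position
    .cds_to_str(ci + d, model)
  }, 0L)
  cod <- chars[idx]
  cod[idx == sp] <- b
  paste(cod, collapse = "") %in% c("TAA", "TAG", "TGA")
}

.cds_to_str <- function(ci, model) {
  off <- 0L
  for (ex in model$exon_spans) {
    w <- ex[2L] - ex[1L] + 1L
    if (ci <= off + w) {
      return(locus_to_str(ex[1L] + (ci - off - 1L), model$promoter_len))
    }
    off <- off + w
  }
  stop("CDS index out of range")
}

# Remove unwanted occurrences of `motifs` from `chars` within string window
# [w1, w2], keeping occurrences that start at `allowed` string positions.
# `overlays` is a list of named character vectors (string pos -> base) that
# must also be scanned (variant alleles that could combine with background
# bases to create a site). Mutations are only applied to non-protected
# positions and never create a stop codon in the H1 frame.
.scrub_window <- function(chars, w1, w2, motifs, allowed, protected, model,
                          overlays = list(NULL)) {
  for (iter in 1:200) {
    changed <- FALSE
    for (ov in overlays) {
      view <- chars
      if (!is.null(ov)) view[as.integer(names(ov))] <- ov
      seq <- paste(view[w1:w2], collapse = "")
      for (motif in motifs) {
        hits <- w1 - 1L + motif_starts(seq, motif)
        for (h in setdiff(hits, allowed)) {
          span <- h:(h + nchar(motif) - 1L)
          free <- setdiff(span, protected)
          if (!length(free))

            stop("cannot scrub motif ", motif, " at protected site ", h)
          sp <- free[1L]
          for (b in setdiff(c("A", "C", "G", "T"), view[sp])) {
            if (!.makes_stop(chars, sp, b, model)) {
              chars[sp] <- b
              changed <- TRUE
              break
            }
          }
        }
      }
      if (changed) break  # re-derive views after any edit
    }
    if (!changed) return(chars)
  }
  stop("motif scrub failed to converge")
}

# ---- variant table ---------------------------------------------------------

# Build the 57-site matrix panel plus the template-only structural variants.
# refs are read from the finished base sequence.
.build_variant_table <- function(base_chars, config) {
  P <- config$promoter_len
  at <- function(pos) base_chars[locus_to_str(pos, P)]
  span <- function(pos, len) {
    paste(base_chars[.span_str(pos, len, P)], collapse = "")
  }
  transition <- c(A = "G", G = "A", C = "T", T = "C")

  rows <- list()
  add <- function(id, label, pos, ref, alt, kind, carriers,
                  in_matrix = TRUE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, label = label, pos = as.integer(pos), ref = ref, alt = alt,
      kind = kind, carriers = paste(carriers, collapse = ","),
      in_matrix = in_matrix, stringsAsFactors = FALSE)
  }
  snp <- function(id, label, pos, carriers, alt = NULL) {
    r <- at(pos)
    add(id, label, pos, r, alt %||% unname(transition[r]), "SNP", carriers)
  }
  H345 <- c("H3", "H4", "H5-1", "H5-2")
  H5b <- c("H5-1", "H5-2")

  # template-only structural variants (too long for the short-indel panel)
  ins_h34 <- with_seed(config$base_seed + 1L, {
    paste(random_bases(config$prom_ins_len_h34), collapse = "")
  })
  ins_h5 <- with_seed(config$base_seed + 2L, {
    paste(random_bases(config$prom_ins_len_h5), collapse = "")
  })
  retro <- .build_retro_insert(config)
  add("sv_prom_ins_h34", "promoter_150bp_ins", config$prom_ins_anchor,
      at(config$prom_ins_anchor),
      paste0(at(config$prom_ins_anchor), ins_h34), "insertion",
      c("H3", "H4"), in_matrix = FALSE)
  add("sv_prom_ins_h5", "promoter_150bp_ins", config$prom_ins_anchor,
      at(config$prom_ins_anchor),
      paste0(at(config$prom_ins_anchor), ins_h5), "insertion",
      H5b, in_matrix = FALSE)
  add("sv_retro", "retro_3.78kb_ins", config$retro_anchor,
      at(config$retro_anchor),
      paste0(at(config$retro_anchor), retro), "insertion",
      "H2", in_matrix = FALSE)

  # the four short indels of the matrix panel
  add("iv_tcga", "promoter_TCGA_ins", config$tcga_anchor,
      at(config$tcga_anchor), paste0(at(config$tcga_anchor), "TCGA"),
      "insertion", H345)
  tg_anchor <- config$tgct_start - 1L
  add("iv_tgct", "exon2_TGCT_del", tg_anchor, span(tg_anchor, 5L),
      at(tg_anchor), "deletion", H5b)
  add("iv_h52_intron1", "intron1_2bp_del", 420L, span(420L, 3L), at(420L),
      "deletion", "H5-2")
  add("iv_h4_intron3", "intron3_2bp_del", 1636L, span(1636L, 3L), at(1636L),
      "deletion", "H4")

  # diagnostic SNPs
  snp("sv_ex4_a", "exon4_GC>TG_a", config$exon4_sub_pos, "H3", alt = "T")
  snp("sv_ex4_b", "exon4_GC>TG_b", config$exon4_sub_pos + 1L, "H3",
      alt = "G")
  snp("sv_splice", "intron2_AG>AT", config$splice_pos, "H4", alt = "T")
  snp("sv_sh345", "exon3_shared_H3H4H5", config$shared345_pos, H345,
      alt = "G")

  # the 10 intron-1 SNPs separating H5-2 from H5-1
  p52 <- seq(165L, 390L, by = 25L)
  for (i in seq_along(p52)) {
    snp(sprintf("h52_snp_%02d", i), "intron1_H5-2", p52[i], "H5-2")
  }

  # background SNPs carried along with each lineage
  fill <- function(prefix, label, positions, carriers) {
    for (i in seq_along(positions)) {
      snp(sprintf("%s_%02d", prefix, i), label, positions[i], carriers)
    }
  }
  fill("sh345", "promoter_shared_H3H4H5",
       c(-785L, -765L, -745L, -725L, -705L, -685L), H345)
  fill("h2", "H2_linked",
       c(-675L, -20L, 700L, 715L, 730L, 1420L, 1440L, 2120L), "H2")
  fill("h5", "H5_shared",
       c(745L, 760L, 775L, 1460L, 1480L, 2140L, 2160L), H5b)
  fill("h3", "H3_private",
       c(-15L, 1500L, 1520L, 2180L, 2200L, 2220L), "H3")
  fill("h4", "H4_private",
       c(-10L, 1540L, 1560L, 2240L, 2260L, 2280L), "H4")
  fill("h45", "H4_H5_shared", c(1580L, 1600L, 1620L), c("H4", H5b))
  fill("h35", "H3_H5_shared", c(-5L, 1660L, 1680L), c("H3", H5b))

  do.call(rbind, rows)
}

# retroelement insertion: random interior, an in-frame stop early (the
# truncation the insertion causes) and the H2-specific reverse primer site
.build_retro_insert <- function(config) {
  ins <- with_seed(config$base_seed + 3L, random_bases(config$retro_len))
  # reading frame: insert base o is CDS position 500 + o, so offsets with
  # o %% 3 == 2 start codons; 32 and 41 both do
  ins <- .stamp_offsets(ins, 32L, "TAA")
  ins <- .stamp_offsets(ins, 41L, "TGA")
  rh2 <- default_marker_registry()[["H2-Ins"]]$reverses[[2L]]$seq
  ins <- .stamp_offsets(ins, 395L, revcomp(rh2))
  paste(ins, collapse = "")
}

.stamp_offsets <- function(chars, start, text) {
  chars[start:(start + nchar(text) - 1L)] <- strsplit(text, "")[[1L]]
  chars
}

# ---- public builder --------------------------------------------------------

#' Does a haplotype carry a given variant?
#'
#' @param variants The variant table of a haplotype set.
#' @param haplotype A haplotype id (`"H1"`, `"H2"`, ..., `"H5-2"`).
#' @return Logical vector over the rows of `variants`.
#' @export
variant_carried <- function(variants, haplotype) {
  vapply(strsplit(variants$carriers, ","), function(cc) haplotype %in% cc,
         NA)
}

#' Apply a variant list to a reference sequence
#'
#' Variants use VCF-style anchored alleles: a SNP has single-base `ref` and
#' `alt`; an insertion has `alt = ref anchor base + inserted text`; a
#' deletion has `ref = anchor base + deleted text`. Positions are locus
#' coordinates of the anchor base. Variants must not overlap.
#'
#' @param reference Reference sequence (single character string).
#' @param variants Data frame with columns `pos`, `ref`, `alt`.
#' @param model A [gene_model()] (supplies the promoter offset).
#' @return The edited sequence as a single string.
#' @export
apply_variants <- function(reference, variants, model) {
  if (nrow(variants) == 0L) return(reference)
  ord <- order(variants$pos, decreasing = TRUE)
  out <- reference
  for (i in ord) {
    sp <- locus_to_str(variants$pos[i], model$promoter_len)
    ref <- variants$ref[i]
    found <- substr(out, sp, sp + nchar(ref) - 1L)
    if (found != ref) {
      stop(sprintf("variant %s at %d: reference mismatch (%s vs %s)",
                   variants$id[i] %||% "?", variants$pos[i], found, ref))
    }
    out <- paste0(substr(out, 1L, sp - 1L), variants$alt[i],
                  substr(out, sp + nchar(ref), nchar(out)))
  }
  out
}

#' Build the haplotype template sequences of the synthetic locus
#'
#' Deterministically constructs the H1 reference plus the H2, H3, H4, H5-1
#' and H5-2 templates. The construction stamps the marker primer landing
#' sites and restriction motifs onto seeded random background DNA, scrubs
#' accidental restriction sites from the two CAPS amplicon windows, and
#' verifies that in-silico PCR with the packaged registry reproduces every
#' published product and fragment size.
#'
#' @param config Locus geometry, see [default_locus_config()].
#' @return A list of class `haplotype_set` with elements `sequences` (named
#'   character vector of the six templates), `variants` (the variant table;
#'   57 matrix sites plus 3 template-only structural variants), `model`
#'   (the [gene_model()]) and `config`.
#' @export
#' @examples
#' hs <- build_haplotype_sequences()
#' nchar(hs$sequences[["H2"]]) - nchar(hs$sequences[["H1"]])
build_haplotype_sequences <- function(config = default_locus_config()) {
  .validate_locus_config(config)
  model <- gene_model(config)
  P <- config$promoter_len
  L <- config$locus_len

  chars <- with_seed(config$base_seed, {
    x <- random_bases(L)
    cds <- random_codons(model$cds_len %/% 3L)
    off <- 0L
    for (ex in config$exon_spans) {
      w <- ex[2L] - ex[1L] + 1L
      x[.span_str(ex[1L], w, P)] <- cds[(off + 1L):(off + w)]
      off <- off + w
    }
    x
  })

  reg <- default_marker_registry()
  pseq <- function(marker, which) {
    if (which == "F") reg[[marker]]$forward$seq
    else reg[[marker]]$reverses[[which]]$seq
  }
  stamps <- list(
    list(-651L, pseq("Pro-Ins", "F")),
    list(-46L, revcomp(pseq("Pro-Ins", 1L))),
    list(481L, pseq("H5-Del", "F")),
    list(673L, revcomp(pseq("H5-Del", 1L))),
    list(950L, pseq("H2-Ins", "F")),
    list(1294L, revcomp(pseq("H2-Ins", 1L))),
    list(791L, pseq("H4-NlaIII", "F")),
    list(1028L, revcomp(pseq("H4-NlaIII", 1L))),
    list(1721L, pseq("H3-MboII", "F")),
    list(1997L, revcomp(pseq("H3-MboII", 1L))),
    # start / stop codons
    list(1L, "ATG"), list(2098L, "TAA"),
    # canonical GT..AG intron boundaries (intron 2 acceptor is the H4
    # splice target)
    list(151L, "GT"), list(449L, "AG"),
    list(601L, "GT"), list(899L, "AG"),
    list(1401L, "GT"), list(1699L, "AG"),
    # restriction-site scaffolding: constitutive NlaIII site (133 cut),
    # H3/H4/H5 SNP target CATC>CATG (220 cut), intron-2 acceptor context
    # CAGG>CATG (111 cut), H1 GCAAGA that the H3 GC>TG turns into a second
    # MboII site (125 cut), constitutive MboII site (244 cut)
    list(920L, "CATG"), list(924L, "C"),
    list(1007L, "CATC"), list(1011L, "T"),
    list(898L, "C"), list(901L, "G"),
    list(1832L, "GCAAGA"), list(1740L, "C"),
    list(1951L, "C"), list(1952L, "GAAGA"),
    # deleted TGCT of the H5 frameshift
    list(540L, "TGCT")
  )
  for (st in stamps) chars <- .stamp(chars, st[[1L]], st[[2L]], P)

  protected <- sort(unique(unlist(lapply(stamps, function(st) {
    .span_str(st[[1L]], nchar(st[[2L]]), P)
  }))))

  sp <- function(pos) locus_to_str(pos, P)
  # scrub accidental MboII sites (either strand) from the H3-MboII amplicon
  h3_overlay <- stats::setNames(c("T", "G"), c(sp(1832L), sp(1833L)))
  chars <- .scrub_window(
    chars, sp(1721L), sp(2016L), motifs = c("GAAGA", "TCTTC"),
    allowed = c(sp(1952L), sp(1833L)), protected = protected, model = model,
    overlays = list(NULL, h3_overlay))
  # scrub accidental NlaIII sites from the H4-NlaIII amplicon; the site
  # embedded in the reverse primer (ending 14 nt from the amplicon end) is
  # unavoidable and handled by terminal protection in digest_amplicon()
  h4_overlay <- stats::setNames("T", sp(900L))
  s345_overlay <- stats::setNames("G", sp(1010L))
  chars <- .scrub_window(
    chars, sp(791L), sp(1052L), motifs = "CATG",
    allowed = c(sp(920L), sp(1035L), sp(898L), sp(1007L)),
    protected = protected, model = model,
    overlays = list(NULL, h4_overlay, s345_overlay))

  base <- paste(chars, collapse = "")
  variants <- .build_variant_table(chars, config)

  sequences <- vapply(HAPLOTYPE_IDS, function(h) {
    apply_variants(base, variants[variant_carried(variants, h), , drop = FALSE],
                   model)
  }, "")

  hs <- structure(list(sequences = sequences, variants = variants,
                       model = model, config = config),
                  class = "haplotype_set")
  .assert_marker_sizes(hs, reg)
  hs
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("<haplotype_set> ", length(x$sequences), " templates (",
      paste(names(x$sequences), collapse = ", "), ")\n", sep = "")
  cat("  reference length ", nchar(x$sequences[[1L]]), " nt; ",
      sum(x$variants$in_matrix), " matrix sites + ",
      sum(!x$variants$in_matrix), " structural variants\n", sep = "")
  invisible(x)
}

.validate_locus_config <- function(config) {
  ps <- config$primer_sites
  if (config$prom_ins_len_h34 < 1L || config$prom_ins_len_h5 < 1L) {
    stop("constraint violation for marker Pro-Ins: promoter insertion ",
         "length must be >= 1 (the 623 vs 775/777 bp products collapse)")
  }
  if (config$retro_len < 1L) {
    stop("constraint violation for marker H2-Ins: retroelement insertion ",
         "length must be >= 1")
  }
  inside <- function(x, a, b) x > a && x < b
  if (!inside(config$prom_ins_anchor, ps[["Pro-Ins-F"]] + 18L,
              ps[["Pro-Ins-R"]]) ||
      !inside(config$tcga_anchor, ps[["Pro-Ins-F"]] + 18L,
              ps[["Pro-Ins-R"]])) {
    stop("constraint violation for marker Pro-Ins: promoter insertions ",
         "must lie between the primer sites")
  }
  if (!inside(config$tgct_start, ps[["H5-Del-F"]] + 18L, ps[["H5-Del-R"]])) {
    stop("constraint violation for marker H5-Del: TGCT deletion must lie ",
         "between the primer sites")
  }
  if (!inside(config$retro_anchor, ps[["H2-Ins-F"]] + 18L,
              ps[["H2-Ins-R/H1"]])) {
    stop("constraint violation for marker H2-Ins: retroelement anchor must ",
         "lie between H2-Ins-F and H2-Ins-R/H1")
  }
  invisible(TRUE)
}

# Verify the finished templates reproduce the full published size table and
# that no primer has stray binding sites. Cheap (a few dozen pattern
# scans); runs once per build.
.assert_marker_sizes <- function(hs, reg) {
  expected <- list(
    "Pro-Ins" = c("H1" = 623, "H2" = 623, "H3" = 775, "H4" = 775,
                  "H5-1" = 777, "H5-2" = 777),
    "H2-Ins" = c("H1" = 364, "H2" = 565, "H3" = 364, "H4" = 364,
                 "H5-1" = 364, "H5-2" = 364),
    "H3-MboII" = c("H1" = 296, "H2" = 296, "H3" = 296, "H4" = 296,
                   "H5-1" = 296, "H5-2" = 296),
    "H4-NlaIII" = c("H1" = 262, "H2" = 262, "H3" = 262, "H4" = 262,
                    "H5-1" = 262, "H5-2" = 262),
    "H5-Del" = c("H1" = 214, "H2" = 214, "H3" = 214, "H4" = 214,
                 "H5-1" = 210, "H5-2" = 210)
  )
  digests <- list(
    "H3-MboII" = list("H1" = c(244, 52), "H3" = c(125, 119, 52)),
    "H4-NlaIII" = list("H1" = c(133, 129), "H3" = c(133, 87, 42),
                       "H4" = c(111, 87, 42, 22))
  )
  for (mname in names(expected)) {
    m <- reg[[mname]]
    for (h in names(expected[[mname]])) {
      amps <- simulate_pcr(hs$sequences[[h]], m$forward, m$reverses)
      if (nrow(amps) != 1L || amps$length[1L] != expected[[mname]][[h]]) {
        stop(sprintf("fixture self-check failed: %s on %s gave %s, not %d",
                     mname, h,
                     paste(amps$length, collapse = "/"),
                     expected[[mname]][[h]]))
      }
      dg <- digests[[mname]][[h]]
      if (!is.null(dg)) {
        frags <- digest_amplicon(amps$sequence[1L], m$enzyme)$fragments
        if (!identical(as.numeric(frags), as.numeric(dg))) {
          stop(sprintf("fixture self-check failed: %s digest on %s gave %s",
                       mname, h, paste(frags, collapse = "+")))
        }
      }
    }
  }
  invisible(TRUE)
}
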