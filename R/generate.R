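# Seeded generators for the three study panels: the landrace resequencing
# matrix, the phenotyped breeding panel, and the cultivar pedigree.

#' Default landrace haplotype frequencies
#'
#' The three published marginals (H1 37.3%, H4 21.8%, H5 29.7%) plus a
#' fixed split of the remainder over H2/H3 and of H5 over its two intron-1
#' sublineages.
#'
#' @return Named numeric vector over the six haplotypes, summing to 1.
#' @export
default_landrace_freqs <- function() {
  c("H1" = 0.373, "H2" = 0.054, "H3" = 0.058, "H4" = 0.218,
    "H5-1" = 0.150, "H5-2" = 0.147)
}

#' Default region-by-haplotype composition of the modern breeding panel
#'
#' Row weights give the share of lines per eco-region (NR northern, HHR
#' Huanghuai, SR southern); the haplotype columns give within-region
#' frequencies. Values reproduce the published regional percentages (NR:
#' H2 73.3%, H5 7.6%; HHR: H1 67.0%, H5 19.3%; SR: H5 56.7%, H1 41.3%,
#' one H3 line) with region weights set so the panel-wide marginals land
#' near 35.1% H1 / 41.0% H2 / 23.7% H5 / 0.2% H3.
#'
#' @return Data frame with columns `region`, `weight`, `H1`..`H5`.
#' @export
default_region_hap_table <- function() {
  data.frame(
    region = c("NR", "HHR", "SR"),
    weight = c(0.52, 0.21, 0.27),
    H1 = c(0.191, 0.670, 0.413),
    H2 = c(0.733, 0.137, 0.000),
    H3 = c(0.000, 0.000, 0.020),
    H4 = c(0.000, 0.000, 0.000),
    H5 = c(0.076, 0.193, 0.567),
    stringsAsFactors = FALSE)
}

#' Generate a landrace variant matrix
#'
#' Emulates a gene-region resequencing panel: 57 retained-class sites (53
#' SNPs and 4 short indels) whose joint genotype patterns define exactly the
#' six haplotypes, plus `n_decoy_sites` sites that each violate exactly one
#' of the published filter rules (minor allele frequency <= 0.01, missing
#' fraction > 0.1, indel length > 10 bp). Accession haplotypes are drawn
#' multinomially from `hap_freqs`; genotypes are homozygous (inbred lines)
#' with a small per-cell missing rate.
#'
#' @param n_accessions Number of accessions (default 279).
#' @param hap_freqs Named haplotype proportions over
#'   `H1, H2, H3, H4, H5-1, H5-2`; must sum to 1.
#' @param n_decoy_sites Number of filter-violating decoy sites (default 6).
#' @param missing_rate Per-cell probability of a missing genotype call
#'   (default 0.005); must be < 1.
#' @param seed Integer seed (mandatory).
#' @param haplotypes A `haplotype_set`; built fresh if omitted.
#' @return A list of class `variant_matrix`: `sites` (data frame: id, pos,
#'   ref, alt, kind, label, decoy, decoy_rule), `geno` (character matrix,
#'   sites x accessions, entries `0/0`, `1/1`, `0/1`, `./.`), `accessions`
#'   (id and true haplotype), `model`, `locus_id`.
#' @export
generate_variant_matrix <- function(n_accessions = 279L,
                                    hap_freqs = default_landrace_freqs(),
                                    n_decoy_sites = 6L,
                                    missing_rate = 0.005,
                                    seed,
                                    haplotypes = build_haplotype_sequences()) {
  if (missing(seed)) stop("seed is mandatory")
  if (abs(sum(hap_freqs) - 1) > 1e-9) {
    stop("hap_freqs must sum to 1 (got ", sum(hap_freqs), ")")
  }
  if (missing_rate >= 1) stop("missing_rate must be < 1")
  stopifnot(n_accessions >= 1L, n_decoy_sites >= 0L)
  unknown <- setdiff(names(hap_freqs), HAPLOTYPE_IDS)
  if (length(unknown)) stop("unknown haplotypes: ",
                            paste(unknown, collapse = ", "))

  hs <- haplotypes
  P <- hs$model$promoter_len
  base <- hs$sequences[["H1"]]
  panel <- hs$variants[hs$variants$in_matrix, , drop = FALSE]

  with_seed(seed, {
    haps <- sample(names(hap_freqs), n_accessions, replace = TRUE,
                   prob = hap_freqs)
    acc <- sprintf("LR%03d", seq_len(n_accessions))

    carrier <- sapply(HAPLOTYPE_IDS, function(h)
      variant_carried(panel, h))  # sites x haplotypes

    geno <- matrix("0/0", nrow(panel), n_accessions,
                   dimnames = list(panel$id, acc))
    for (j in seq_len(n_accessions)) {
      geno[carrier[, haps[j]], j] <- "1/1"
    }
    # sprinkle missing calls
    if (missing_rate > 0 && n_accessions > 1L) {
      miss <- matrix(stats::runif(length(geno)) < missing_rate,
                     nrow(geno))
      geno[miss] <- "./."
    }
    sites <- data.frame(id = panel$id, pos = panel$pos, ref = panel$ref,
                        alt = panel$alt, kind = panel$kind,
                        label = panel$label, decoy = FALSE,
                        decoy_rule = NA_character_,
                        stringsAsFactors = FALSE)

    if (n_decoy_sites > 0L) {
      pool <- setdiff(c(-695L, 425L, 708L, 1690L,
                        seq(2102L, 2298L, by = 2L)),
                      sites$pos)
      stopifnot(length(pool) >= n_decoy_sites)
      rules <- rep(c("maf", "missing", "indel_len"),
                   length.out = n_decoy_sites)
      transition <- c(A = "G", G = "A", C = "T", T = "C")
      drows <- list()
      dgeno <- matrix("0/0", n_decoy_sites, n_accessions,
                      dimnames = list(NULL, acc))
      for (k in seq_len(n_decoy_sites)) {
        pos <- pool[k]
        ref <- substr(base, locus_to_str(pos, P), locus_to_str(pos, P))
        if (rules[k] == "indel_len") {
          alt <- paste0(ref, paste(random_bases(11L), collapse = ""))
          kind <- "insertion"
        } else {
          alt <- unname(transition[ref])
          kind <- "SNP"
        }
        g <- rep("0/0", n_accessions)
        if (rules[k] == "maf") {
          g[sample.int(n_accessions, 1L)] <- "1/1"
        } else if (rules[k] == "missing") {
          g[sample.int(n_accessions,
                       min(n_accessions,
                           ceiling(0.12 * n_accessions)))] <- "./."
          n_called <- sum(g != "./.")
          if (n_called > 0L) {
            g[g != "./."][seq_len(max(1L, round(0.3 * n_called)))] <- "1/1"
          }
        } else {
          g[sample.int(n_accessions,
                       min(n_accessions,
                           max(2L, round(0.2 * n_accessions))))] <- "1/1"
        }
        dgeno[k, ] <- g
        drows[[k]] <- data.frame(
          id = sprintf("decoy_%02d", k), pos = pos, ref = ref, alt = alt,
          kind = kind, label = paste0("decoy_", rules[k]), decoy = TRUE,
          decoy_rule = rules[k], stringsAsFactors = FALSE)
      }
      dsites <- do.call(rbind, drows)
      rownames(dgeno) <- dsites$id
      sites <- rbind(sites, dsites)
      geno <- rbind(geno, dgeno)
    }

    ord <- order(sites$pos)
    structure(list(sites = sites[ord, , drop = FALSE],
                   geno = geno[ord, , drop = FALSE],
                   accessions = data.frame(id = acc, haplotype = haps,
                                           stringsAsFactors = FALSE),
                   model = hs$model, locus_id = hs$config$locus_id),
              class = "variant_matrix")
  })
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat("<variant_matrix> ", nrow(x$sites), " sites x ", ncol(x$geno),
      " accessions (", sum(x$sites$decoy), " decoys)\n", sep = "")
  invisible(x)
}

#' Generate a phenotyped breeding panel
#'
#' Simulates a marker-validation panel: each line receives an eco-region, a
#' haplotype drawn from the within-region composition, a latent salt
#' response (tolerant for H1 with probability `p_tolerant_given_H1`,
#' sensitive for non-H1 with probability `p_sensitive_given_nonH1`) and 3
#' pots x 6 plants of chlorosis scores: tolerant lines draw per-plant
#' scores uniformly from \{1, 2\}, sensitive lines from \{3, 4, 5\}.
#'
#' @param n_lines Number of breeding lines (default 536).
#' @param region_hap_table Data frame with `region`, `weight` and haplotype
#'   columns, see [default_region_hap_table()].
#' @param p_tolerant_given_H1 P(phenotype tolerant | H1); default 186/188.
#' @param p_sensitive_given_nonH1 P(phenotype sensitive | non-H1);
#'   default 1.
#' @param seed Integer seed (mandatory).
#' @param n_pots,plants_per_pot Experimental layout (defaults 3 and 6).
#' @return Data frame: `id`, `class`, `region`, `release_year`,
#'   `haplotype`, `phenotype`, and score columns `score1..score18`.
#' @export
generate_breeding_panel <- function(n_lines = 536L,
                                    region_hap_table =
                                      default_region_hap_table(),
                                    p_tolerant_given_H1 = 186 / 188,
                                    p_sensitive_given_nonH1 = 1,
                                    seed,
                                    n_pots = 3L, plants_per_pot = 6L) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(region_hap_table) || nrow(region_hap_table) == 0L) {
    stop("region_hap_table must have at least one region")
  }
  hap_cols <- setdiff(colnames(region_hap_table), c("region", "weight"))
  probs <- as.matrix(region_hap_table[, hap_cols, drop = FALSE])
  if (any(probs < 0 | probs > 1) ||
      any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("per-region haplotype proportions must lie in [0,1] and sum to 1")
  }
  stopifnot(p_tolerant_given_H1 >= 0, p_tolerant_given_H1 <= 1,
            p_sensitive_given_nonH1 >= 0, p_sensitive_given_nonH1 <= 1)
  n_scores <- n_pots * plants_per_pot

  with_seed(seed, {
    region <- sample(region_hap_table$region, n_lines, replace = TRUE,
                     prob = region_hap_table$weight)
    hap <- vapply(region, function(r) {
      i <- match(r, region_hap_table$region)
      sample(hap_cols, 1L, prob = probs[i, ])
    }, "")
    tol <- ifelse(hap == "H1",
                  stats::runif(n_lines) < p_tolerant_given_H1,
                  stats::runif(n_lines) >= p_sensitive_given_nonH1)
    scores <- t(vapply(tol, function(t) {
      if (t) sample(1:2, n_scores, replace = TRUE)
      else sample(3:5, n_scores, replace = TRUE)
    }, integer(n_scores)))
    colnames(scores) <- paste0("score", seq_len(n_scores))
    cbind(
      data.frame(id = sprintf("BL%04d", seq_len(n_lines)),
                 class = "breeding_line", region = region,
                 release_year = sample(2013:2017, n_lines, replace = TRUE),
                 haplotype = hap,
                 phenotype = ifelse(tol, "tolerant", "sensitive"),
                 stringsAsFactors = FALSE),
      as.data.frame(scores))
  })
}

#' The packaged cultivar pedigree
#'
#' Encodes the four focal cultivars (Zhonghuang 13, Wenfeng 7, Zhonghuang
#' 30, Zhonghuang 39) and 19 ancestral lines with parent edges, haplotype
#' calls and genotyped flags. Nodes whose seed was unavailable are
#' ungenotyped (`genotyped = FALSE`, haplotype `NA`). Cultivars named in
#' the published account are wired as described; the remaining ancestors
#' are synthetic placeholder lines whose names and positions only serve to
#' complete the graph.
#'
#' @return Data frame: `name`, `parent1`, `parent2` (NA for founders),
#'   `genotyped`, `haplotype`, `phenotype`.
#' @export
build_pedigree_fixture <- function() {
  n <- function(name, p1, p2, hap, pheno = NA_character_) {
    data.frame(name = name, parent1 = p1, parent2 = p2,
               genotyped = !is.na(hap), haplotype = hap,
               phenotype = pheno, stringsAsFactors = FALSE)
  }
  NAc <- NA_character_
  rbind(
    # focal cultivars
    n("Zhonghuang 13", "Yudou 8", "Zhongzuo 90052-76", "H1", "tolerant"),
    n("Wenfeng 7", "Jüxuan 23", "Qihuang 1", "H1", "tolerant"),
    n("Zhonghuang 30", "Zhongpin 661", "Zhongdou 19", "H1", "tolerant"),
    n("Zhonghuang 39", "Zhongpin 661", "Zhongdou 19", "H2", "sensitive"),
    # Zhonghuang 13 side
    n("Yudou 8", "Zhengzhou 135", "Shanxian Dahuangdou", NAc),
    n("Zhongzuo 90052-76", "58-161", "Beijing Xiaohei", NAc),
    n("Zhengzhou 135", "Zhengzhou Dajiaoya", "Tongshan Tianedan", "H1",
      "tolerant"),
    n("58-161", "Jinyuan", "Qingyuan Heidou", "H1", "tolerant"),
    n("Shanxian Dahuangdou", NAc, NAc, "H2", "sensitive"),
    n("Beijing Xiaohei", "Jüxuan 23", "Huixian Niumaohuang", "H2",
      "sensitive"),
    n("Zhengzhou Dajiaoya", NAc, NAc, NAc),
    n("Tongshan Tianedan", NAc, NAc, NAc),
    n("Jinyuan", NAc, NAc, NAc),
    n("Qingyuan Heidou", NAc, NAc, NAc),
    n("Huixian Niumaohuang", NAc, NAc, NAc),
    # Wenfeng 7 side
    n("Jüxuan 23", NAc, NAc, "H1", "tolerant"),
    n("Qihuang 1", "Niumaohuang", "Jinan Tiejiaqing", "H5", "sensitive"),
    n("Niumaohuang", NAc, NAc, NAc),
    n("Jinan Tiejiaqing", NAc, NAc, NAc),
    # Zhonghuang 30 / 39 side
    n("Zhongpin 661", "Zhengzhou 135", "W82", NAc),
    n("W82", NAc, NAc, "H2", "sensitive"),
    n("Zhongdou 19", "Qihuang 1", "Yanhuang 2", "H5", "sensitive"),
    n("Yanhuang 2", NAc, NAc, NAc)
  )
}
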