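# Readers and writers for the interchange formats: FASTA templates, a VCF
# v4.2 subset for the variant matrix, and CSV for panels and pedigrees.

#' Read DNA sequences from a FASTA file
#'
#' Sequences are uppercased on read. An empty file yields an empty record
#' set; a file whose first non-empty line is not a header is rejected with
#' the offending line number.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) return(stats::setNames(character(0), character(0)))
  first <- nonblank[1L]
  if (!startsWith(lines[first], ">")) {
    stop("malformed FASTA header at line ", first, ": ", lines[first])
  }
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Write DNA sequences to a FASTA file
#'
#' Wraps sequence lines at 60 columns; round-trips byte-stably with
#' [read_fasta()].
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(toupper(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

.gt_normalise <- function(gt, n_alt, site_id) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- character(length(gt))
  for (i in seq_along(gt)) {
    g <- gt[i]
    if (is.na(g) || g %in% c(".", "./.")) { out[i] <- "./."; next }
    al <- strsplit(g, "/", fixed = TRUE)[[1L]]
    if (length(al) == 1L) al <- c(al, al)
    if (any(al == ".")) { out[i] <- "./."; next }
    av <- suppressWarnings(as.integer(al))
    if (any(is.na(av)) || any(av < 0L) || any(av > n_alt)) {
      stop("unknown allele code '", g, "' at site ", site_id)
    }
    out[i] <- paste(sort(av), collapse = "/")
  }
  out
}

#' Read a variant matrix from a VCF file
#'
#' Supports the VCF v4.2 subset written by [write_vcf()]: GT genotypes
#' (`0/0`, `1/1`, `0/1`, `./.`), with multi-allelic records split into one
#' biallelic site record per ALT allele (genotypes carrying a different
#' ALT become `0/0` for that split record, mixed genotypes `0/1`).
#' Locus coordinates (promoter negative) are restored from the `LC` INFO
#' key when present, otherwise string POS is used.
#'
#' @param path Path to a VCF file.
#' @return A `variant_matrix` (see [generate_variant_matrix()]); `model`
#'   is `NULL` for externally produced files.
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(vcf, getINFO = TRUE)
  if (is.null(dim(fx))) {
    fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
  }
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  fmt <- vcf@gt
  if (is.null(fmt) || !"FORMAT" %in% colnames(fmt)) {
    stop("VCF has no genotype (FORMAT) section")
  }
  if (!all(grepl("(^|:)GT(:|$)", fmt[, "FORMAT"]))) {
    stop("GT subfield missing from FORMAT")
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  info <- fix$INFO %||% rep(NA_character_, nrow(fix))
  info_get <- function(s, key) {
    m <- regmatches(s, regexec(paste0("(?:^|;)", key, "=([^;]+)"), s,
                               perl = TRUE))[[1L]]
    if (length(m) == 2L) m[2L] else NA_character_
  }

  sites <- list()
  geno <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    lc <- suppressWarnings(as.integer(info_get(info[i], "LC")))
    lb <- info_get(info[i], "LB")
    raw <- .gt_normalise(gt[i, ], length(alts),
                         paste0(fix$CHROM[i], ":", fix$POS[i]))
    for (k in seq_along(alts)) {
      g <- vapply(raw, function(x) {
        if (x == "./.") return("./.")
        av <- as.integer(strsplit(x, "/", fixed = TRUE)[[1L]])
        hit <- sum(av == k)
        if (hit == 2L) "1/1" else if (hit == 1L) "0/1" else "0/0"
      }, "", USE.NAMES = FALSE)
      kind <- if (nchar(fix$REF[i]) == nchar(alts[k])) "SNP"
              else if (nchar(alts[k]) > nchar(fix$REF[i])) "insertion"
              else "deletion"
      id <- if (!is.na(fix$ID[i]) && fix$ID[i] != "." &&
                length(alts) == 1L) fix$ID[i]
            else sprintf("%s_%s_%d", fix$CHROM[i], fix$POS[i], k)
      sites[[length(sites) + 1L]] <- data.frame(
        id = id, pos = if (!is.na(lc)) lc else as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k], kind = kind,
        label = lb, decoy = FALSE, decoy_rule = NA_character_,
        stringsAsFactors = FALSE)
      geno[[length(geno) + 1L]] <- g
    }
  }
  sites <- do.call(rbind, sites)
  gmat <- do.call(rbind, geno)
  dimnames(gmat) <- list(sites$id, samples)
  structure(list(sites = sites, geno = gmat,
                 accessions = data.frame(id = samples,
                                         haplotype = NA_character_,
                                         stringsAsFactors = FALSE),
                 model = NULL, locus_id = fix$CHROM[1L]),
            class = "variant_matrix")
}

#' Write a variant matrix as VCF v4.2
#'
#' POS is emitted in 1-based reference-string coordinates (VCF forbids
#' non-positive positions); the signed locus coordinate of each site is
#' preserved in the `LC` INFO key and the promoter offset in a
#' `##locus_offset` header line.
#'
#' @param x A `variant_matrix`.
#' @param path Output path.
#' @param header_extra Optional character vector of extra `##` header
#'   lines (e.g. run provenance).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, header_extra = character(0)) {
  stopifnot(inherits(x, "variant_matrix"))
  P <- if (!is.null(x$model)) x$model$promoter_len else 0L
  ref_len <- if (!is.null(x$model)) x$model$length else max(x$sites$pos)
  pos_out <- if (P > 0L) locus_to_str(x$sites$pos, P) else x$sites$pos
  stopifnot(all(pos_out >= 1L))
  hdr <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=salthap_", as.character(utils::packageVersion("salthap"))),
    sprintf("##contig=<ID=%s,length=%d>", x$locus_id, ref_len),
    sprintf("##locus_offset=%d", P),
    "##INFO=<ID=LC,Number=1,Type=Integer,Description=\"Locus coordinate (ATG A = +1, promoter negative)\">",
    "##INFO=<ID=LB,Number=1,Type=String,Description=\"Site label\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    header_extra,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(x$geno)), collapse = "\t"))
  body <- vapply(seq_len(nrow(x$sites)), function(i) {
    paste(c(x$locus_id, pos_out[i], x$sites$id[i], x$sites$ref[i],
            x$sites$alt[i], ".", "PASS",
            sprintf("LC=%d;LB=%s", x$sites$pos[i],
                    if (is.na(x$sites$label[i])) "." else x$sites$label[i]),
            "GT", x$geno[i, ]), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write a phenotyped panel CSV
#'
#' Schema: `id`, `class`, `region`, `release_year`, `haplotype`,
#' `phenotype`, `score1..scoreN`. Scores must be integers 1-5; release
#' years, when present, must fall within the plausible breeding window
#' 1923-2017. Lines starting with `#` are treated as comments.
#'
#' @param path File path.
#' @return [read_panel_csv()]: the panel data frame.
#' @export
read_panel_csv <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE,
                           comment.char = "#")
  score_cols <- grep("^score[0-9]+$", names(panel), value = TRUE)
  if (length(score_cols)) {
    sc <- unlist(panel[score_cols], use.names = FALSE)
    sc <- sc[!is.na(sc)]
    if (any(sc != round(sc)) || any(sc < 1 | sc > 5)) {
      stop("chlorosis scores must be integers in 1..5")
    }
  }
  if ("release_year" %in% names(panel)) {
    yr <- panel$release_year[!is.na(panel$release_year)]
    if (length(yr) && (any(yr < 1923) || any(yr > 2017))) {
      stop("release_year outside the plausible window 1923..2017")
    }
  }
  panel
}

#' @rdname read_panel_csv
#' @param panel Panel data frame (see [generate_breeding_panel()]).
#' @param header Optional character vector of `#` comment lines written
#'   before the table.
#' @return [write_panel_csv()]: `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(panel, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a pedigree CSV
#'
#' Schema: `child`, `parent1`, `parent2`, `genotyped`, `haplotype`
#' (optionally `phenotype`); empty parent fields denote founders.
#'
#' @param path File path.
#' @return [read_pedigree_csv()]: node data frame as accepted by
#'   [validate_pedigree()].
#' @export
read_pedigree_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        na.strings = c("NA", ""))
  stopifnot(all(c("child", "parent1", "parent2", "genotyped",
                  "haplotype") %in% names(df)))
  names(df)[names(df) == "child"] <- "name"
  df$genotyped <- as.logical(df$genotyped)
  df
}

#' @rdname read_pedigree_csv
#' @param nodes Pedigree node data frame (column `name` or `child`).
#' @param header Optional `#` comment lines.
#' @return [write_pedigree_csv()]: `path`, invisibly.
#' @export
write_pedigree_csv <- function(nodes, path, header = character(0)) {
  df <- nodes
  if ("name" %in% names(df)) names(df)[names(df) == "name"] <- "child"
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
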