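---
title: "Haplotype markers for the soybean salt-tolerance locus: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype markers for the soybean salt-tolerance locus: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salthap)
```

## The biology being modelled

*GmSALT3* is a major soybean salt-tolerance gene: the full-length allele
(haplotype H1) limits Na^+^ and Cl^−^ accumulation in shoots, while a set
of loss-of-function haplotypes (H2–H5) leaves plants salt-sensitive. The
haplotypes are defined by a small number of diagnostic lesions:

* **H2** — a ~3.78-kb retroelement insertion in the transcribed region
  that truncates the protein;
* **H3** — a GC>TG substitution in exon 4 (plus shared promoter
  insertions);
* **H4** — an AG>AT substitution at the splice acceptor of intron 2;
* **H5** — a 4-bp (TGCT) frameshift deletion in exon 2, occurring on two
  distinct intron-1 backgrounds (H5-1, H5-2) that produce identical coding
  sequence and are therefore reported as one haplotype;
* H3–H5 additionally share a ~150-bp insertion at promoter position −147
  and a TCGA insertion at −103.

Because H1 against H2–H5 separates tolerant from sensitive germplasm, five
PCR-based assays — three indel markers (Pro-Ins, H2-Ins, H5-Del) and two
CAPS markers (H3-*Mbo*II, H4-*Nla*III) — suffice to genotype a breeding
panel on agarose/polyacrylamide gels. `salthap` implements that entire
workflow in silico: variant-matrix haplotyping, virtual PCR and
digestion, haplotype calling, panel summaries, and pedigree tracing.

## The synthetic locus

The true genomic sequence of the locus is not redistributable, so the
package constructs a synthetic stand-in
(`build_haplotype_sequences()`): seeded random DNA of 3,100 nt (800 nt
promoter, four exons totalling a 1,200-nt CDS, canonical GT..AG introns)
onto which the primer landing sites, restriction motifs and variant
anchors are stamped. Coordinates are 1-based locus coordinates — the A of
the ATG is +1, the promoter base 5′ of it is −1, there is no position 0 —
with closed intervals.

The geometry is fully determined by the published assay sizes, which the
builder verifies after construction:

| marker | products / fragments |
|---|---|
| Pro-Ins | 623 (H1/H2), 775 (H3/H4), 777 (H5) |
| H2-Ins | 364 (H1, H3–H5), 565 (H2-specific) |
| H3-*Mbo*II | 296 → 244+52 (non-H3), 125+119+52 (H3) |
| H4-*Nla*III | 262 → 133+129 (H1/H2), 133+87+42 (H3/H5), 111+87+42+22 (H4) |
| H5-Del | 214 (non-H5), 210 (H5) |

Three published numbers leave the design genuinely open, and the package
resolves them once:

* The 775/777-bp Pro-Ins products are printed without saying which
  haplotype yields which. Here H3/H4 carry a 148-nt promoter insertion
  (623 + 148 + 4 = 775) and H5 a 150-nt insertion (777). The two
  products differ by 2 nt at ~776 bp — below gel resolution — so the
  registry pre-merges them into one `insertion-present` allele class.
* The "~150 bp" insertion and the retroelement interior are synthetic
  random sequence; the retroelement is exactly 3,780 nt and carries an
  early in-frame stop, which is what truncates the H2 protein.
* The H5 cDNA is not forced to the real 714 nt (that would require the
  true exon structure); what is preserved is the *identity* of the H5-1
  and H5-2 coding sequences, which is what justifies merging them.

The exon 4 substitution is modelled so that only its second base falls
inside the created *Mbo*II site (H1 `GCAAGA` → H3 `TGAAGA`), the splice
substitution converts the intron-2 acceptor context `CAGG` into a
*Nla*III `CATG`, and an exon-3 SNP shared by H3/H4/H5 creates the second
constitutive-for-them `CATG`. A deterministic scrubber removes accidental
recognition sites from the two CAPS amplicon windows (in every haplotype
overlay) without ever touching a stamped position or introducing an
in-frame stop.

## The emulated resequencing panel

`generate_variant_matrix()` emulates a 279-landrace gene-region matrix:
57 retained-class sites — 53 SNPs and 4 short (≤10 bp) indels — whose
joint homozygous patterns define exactly six haplotypes, plus decoy sites
that each violate exactly one filter rule. The two long structural
variants (the ~150-bp promoter insertion and the 3.78-kb retroelement)
are deliberately *not* matrix sites: they exceed any short-indel filter,
and enter haplotyping through linked short variants, exactly as a
short-read panel would see them.

Haplotype draw frequencies default to the published landrace marginals
(H1 37.3%, H4 21.8%, H5 29.7%); the remainder and the H5-1/H5-2 split
are not printed anywhere and are fixed package choices (H2 5.4%, H3
5.8%, H5-1 15.0%, H5-2 14.7%). The per-cell missing rate defaults to
0.005 — high enough that unclassified accessions occur, far too low to
push any designed site over the 0.1 missingness threshold at n = 279.

The generator draws plant-level chlorosis scores
(`generate_breeding_panel()`) uniformly from {1, 2} for tolerant lines
and {3, 4, 5} for sensitive lines: only the class boundaries are
published, not the score distributions. The genotype–phenotype link
defaults to P(tolerant | H1) = 186/188 and
P(sensitive | non-H1) = 1, the published validation outcome. Regional
compositions follow the printed breeding-line percentages, with region
weights (NR 0.52, HHR 0.21, SR 0.27) fixed once so the panel-wide
marginals land near 35.1/41.0/23.7%.

What the generator does **not** emulate: linkage decay and recombination
within the locus (haplotypes are drawn as intact units), sequencing and
genotyping error beyond uniform missingness, heterozygous residuals,
population structure among accessions, and the real (undeposited)
positions of the 57 sites. Passing tests therefore demonstrate the
correctness of the algorithms under the stated study conditions, not
robustness to messy field data.

## Filtering and grouping semantics

The filter is read literally from the published rule: discard SNPs with
minor allele frequency ≤ 0.01 (boundary discarded), sites with missing
fraction > 0.1 (boundary retained), and indels longer than 10 bp
(boundary retained). MAF is computed over called alleles only; a site
with no calls has missing fraction 1 and falls to the missingness rule.

Accessions with any heterozygous or missing call at a retained site are
reported `unclassified` rather than imputed — the panels are inbred
lines and no assignment rule is published. Groups are labelled through
the diagnostic variants (TCGA, TGCT, exon-4, splice, intron-1 indel)
rather than full-vector matching, so regenerating the fixture under a
different seed cannot silently relabel groups. `collapse_by_cds()`
merges labels only on byte-identical extracted CDS, which by
construction merges exactly H5-1/H5-2.

## The marker engine's numerical choices

* **Exact primer matching.** The published assays are presence/absence
  assays; allele specificity comes from a binding site existing or not
  (H2-Ins), never from 3′-mismatch discrimination, so no mismatch model
  is needed.
* **`max_product = 1500` nt.** Models the ~1 kb practical extension of a
  50-s Taq protocol: it must pass the 777-bp product and suppress the
  ~4.1-kb pairing that would otherwise read through the retroelement.
* **Enzyme models.** *Mbo*II is the distance cutter GAAGA(8/…): a
  plus-strand site ending at `e` cuts after `e + 8`, a minus-strand site
  whose reverse complement starts at `s` cuts after `s − 1 − 8`.
  *Nla*III is palindromic CATG with cut offset 0 (CATG↓), scanned on one
  strand since every site is its own reverse complement. Fragment
  lengths are top-strand cut-to-cut distances — gel sizes are single
  numbers per fragment.
* **Terminal protection (`end_protect = 15` nt).** Cuts falling within
  15 nt of an amplicon end are suppressed. This models inefficient
  cleavage near duplex termini and the invisibility of terminal slivers
  on a gel, and it is load-bearing: the H4-*Nla*III *reverse primer
  itself* contains a CATG site 14 nt from the product end, so without
  terminal protection no template could ever produce the published
  133+129 pattern.
* **Strand symmetry.** With both strands scanned, distance-cutter
  digests are exactly invariant under reverse complement. For a
  palindromic overhang cutter the top-strand boundary of an off-centre
  site genuinely shifts by the 4-nt overhang under reverse complement
  (boundaries map through `c → n − c + 4`); the tests check exactly
  that geometry.
* **Size tolerance 1%.** Observed fragments match an expected size
  within 1% of the expected length, the sizing accuracy of the gels in
  question; 210 vs 214 bp remains resolvable, while a 212-bp
  measurement is honestly reported `ambiguous`.

Haplotype calling intersects the per-marker compatibility sets;
ambiguous or unscored markers contribute the universal set, and an empty
intersection is surfaced as conflicting assay evidence (a QC signal, not
something to repair). The two-marker screen (Pro-Ins + H2-Ins) predicts
tolerant exactly for the 623 + 364 combination.

## Panel summaries

Line-level chlorosis class is the modal plant score over 3 pots × 6
plants, with ties resolved toward the more sensitive score —
conservative for tolerance claims, since no aggregation rule is
published. Classes 1–2 are tolerant, 3–5 sensitive. Percentages are
rounded half-up to one decimal, matching the printed tables; release
decades bin as 1950s…1990s with 2000–2012 pooled as "2000s". Eco-region
comes from metadata labels, never from latitude: the published latitude
bands overlap. Trend summaries report start/end percentages and signed
changes only; no significance test is attached because none is
published.

## Pedigree tracing

The "source" of a focal cultivar's allele is every *maximal* genotyped
ancestor carrying the focal haplotype that is reachable along parent
edges on which every genotyped intermediate also carries it; ungenotyped
nodes (seed unavailable) are pass-through, and a genotyped ancestor with
a different haplotype blocks its branch. When both parental lines are
consistent, all maximal candidates are returned — the published reading
reports exactly such a disjunction for Zhonghuang 13 (Zhengzhou 135 *or*
58-161). The packaged 23-node pedigree encodes the named cultivars and
relations; ancestors not named in the published account are synthetic
placeholder lines wired only to complete the graph, and no inference of
ungenotyped nodes' haplotypes is attempted beyond pass-through.

## Problem sizes and verification

The test suite builds everything it checks at run time: the 279-accession
matrix with 6 decoys, a 536-line phenotyped panel, the 23-node pedigree,
and 100 seeded panel replicates for the parameter-recovery property
(estimated regional haplotype frequencies fall inside exact 95% binomial
intervals of the generating truth in well over 93% of region × haplotype
cells). Brute-force oracles — all-pairs identity grouping on small
matrices and exhaustive path enumeration on small random pedigrees —
cross-check the production algorithms.

## Known limitations

* The locus is synthetic: positions, flanking sequence and the 57-site
  placement are constructions, not the real gene, and only the published
  assay arithmetic constrains them.
* Heterozygotes are detected and reported but never phased or imputed;
  novel haplotypes outside H1–H5 are reported `unscored` by design.
* The digestion model is complete digestion with terminal protection;
  partial digests, heteroduplexes and primer-dimer artefacts are out of
  scope.
* Frequency trends are descriptive; the package deliberately attaches no
  selection-coefficient estimate or test.
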