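# salthap

Haplotype classification and functional-marker genotyping for the soybean
salt-tolerance locus *GmSALT3*.

## The problem

*GmSALT3* controls shoot Na⁺/Cl⁻ exclusion in soybean. Its full-length
allele (haplotype **H1**) confers salt tolerance; four loss-of-function
haplotypes leave plants sensitive: **H2** (a ~3.78-kb retroelement
insertion truncating the protein), **H3** (an exon-4 GC>TG substitution),
**H4** (an intron-2 splice-acceptor AG>AT substitution) and **H5** (an
exon-2 TGCT frameshift deletion, found on two intron-1 backgrounds H5-1
and H5-2 with identical coding sequence). Because tolerant vs sensitive is
H1 vs not-H1, a handful of PCR assays — three indel markers (Pro-Ins,
H2-Ins, H5-Del) and two CAPS markers (H3-*Mbo*II, H4-*Nla*III) — can
genotype whole breeding programmes on a gel.

`salthap` is for breeders and population geneticists who want that
workflow as tested, reusable code:

* **Variant haplotyping** — filter a gene-region variant matrix
  (MAF ≤ 0.01 discarded, missing > 0.1 discarded, indels > 10 bp
  discarded), partition homozygous accessions by genotype-vector
  identity, label groups by diagnostic variants, and merge
  coding-equivalent haplotypes (H5-1/H5-2 → H5) by byte-identical CDS.
* **Marker engine** — exact-match virtual PCR (`simulate_pcr()`, with a
  product-length cap modelling failed long extension) and restriction
  digestion (`digest_amplicon()`) for distance cutters (*Mbo*II,
  GAAGA(8)) and palindromic cutters (*Nla*III, CATG↓), plus band-pattern
  matching with gel-realistic size tolerance.
* **Genotype calling** — per-marker allele classes intersected into a
  haplotype call (`call_haplotype()`), the published two-marker
  tolerant/sensitive screen (`minimal_marker_screen()`), whole-panel
  genotyping.
* **Panel analysis** — chlorosis-score phenotype classification (modal
  plant score, ties sensitive; 1–2 tolerant, 3–5 sensitive), haplotype
  frequency tables by eco-region/decade, genotype–phenotype concordance,
  temporal trend summaries.
* **Pedigree tracing** — maximal consistent-ancestor search for the
  source of a cultivar's allele through partially genotyped pedigrees.
* **Synthetic fixtures** — a deterministic *GmSALT3*-like locus whose six
  haplotype templates reproduce every published assay size, plus seeded
  generators for a 279-landrace variant matrix, a 536-line phenotyped
  breeding panel, and the 23-node cultivar pedigree.

## Worked example

```r
library(salthap)

hs <- build_haplotype_sequences()
hs
#> <haplotype_set> 6 templates (H1, H2, H3, H4, H5-1, H5-2)
#>   reference length 3100 nt; 57 matrix sites + 3 structural variants

# CAPS assay on the H4 template: amplify, digest, call
m   <- default_marker_registry()[["H4-NlaIII"]]
amp <- simulate_pcr(hs$sequences[["H4"]], m$forward, m$reverses)
digest_amplicon(amp$sequence, m$enzyme)
#> <band_pattern> 111 + 87 + 42 + 22 bp (262 bp total)
genotype_template(hs$sequences[["H4"]])$call
#> <haplotype_call> {H4} -> sensitive

# landrace matrix -> filter -> group -> label -> CDS merge
vm <- generate_variant_matrix(seed = 1, haplotypes = hs)
haplotype_pipeline(vm, hs)
#> <haplotype_result> 6 groups -> 5 merged haplotypes

# genotype-phenotype concordance of a validation panel
panel <- data.frame(
  haplotype = rep(c("H1","H1","H2","H5","H3"), c(186, 2, 220, 127, 1)),
  phenotype = rep(c("tolerant","sensitive","sensitive","sensitive",
                    "sensitive"), c(186, 2, 220, 127, 1)))
concordance(panel)
#> <concordance> tolerant-class accuracy 98.9%, sensitive-class accuracy 100% (n = 536)
#>            observed
#> predicted   tolerant sensitive
#>   tolerant       186         2
#>   sensitive        0       348

# where did Zhonghuang 13's tolerance allele come from?
ped <- validate_pedigree(build_pedigree_fixture())
trace_allele(ped, "Zhonghuang 13")
#> <allele_trace> Zhonghuang 13 (H1) <- {Zhengzhou 135, 58-161}
```

The `<band_pattern>` is the gel lane you would photograph: the H4
amplicon (262 bp) cut by *Nla*III into four fragments, the pattern that
uniquely identifies H4. The concordance object reports prediction
accuracy of the H1/non-H1 marker call against the chlorosis phenotype —
186 of 188 H1 lines tolerant (98.9%), all 348 genotyped non-H1 lines
sensitive (100%). The trace returns both maximal consistent ancestors,
because either grandparental line could have contributed the H1 allele.

A command-line wrapper over the same functions ships in
`inst/scripts/salthap-cli.R` with `simulate`, `haplotype`, `genotype`,
`panel` and `pedigree` subcommands.

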