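# mitostr

Copy-number variation of short tandem repeats in circular mitochondrial
genomes.

## The problem

Deep amplicon sequencing of a single animal's mitochondrial DNA (10^4–10^5×
coverage is routine for a ~15 kb mt genome) reveals that the dominant form of
intra-individual sequence heterogeneity is not point substitution but
**copy-number variation (CNV) of short tandem repeats (STRs)** — gains and
losses of whole repeat units at homopolymers like `[A]10` and dinucleotide
runs like `[TA]9`. In AT-rich tick mitochondrial genomes these loci are
abundant, the variation concentrates at a modest number of positions, and
unit gains/losses inside protein-coding genes are frameshifts that truncate
the protein. The same genomes carry a transposon-like element: a segment
flanked by two tandem-repeat arrays whose units are mutual reverse
complements (inverted repeats), observed in both reference and inverted
orientation within one individual.

`mitostr` is for researchers analysing this kind of data. It provides:

* **Circular annotation model** — 1-based inclusive coordinates with
  wrap-around (`end < start`), strand-aware feature extraction, and
  validation that a *precise annotation* tiles both strands of the circle
  with zero gaps and zero overlaps.
* **STR catalogue** — maximal primitive-unit repeat scanning with the
  `[unit]n` notation and the `m x n` (unit length × copy number)
  classification; a `1 x n` STR is a homopolymer.
* **Pileup dialect I/O** — the classic samtools pileup base-column encoding
  (`.`, `,`, `ACGT`, `+N<seq>`, `-N<seq>`, `*`, `^X`, `$`), with bit-exact
  write∘parse round-trips and left-normalisation of indels onto the STR
  anchor column.
* **CNV calling** — per-locus allele tables ordered by depth; the
  **alternative-allele ratio**

      r = (total depth − reference-allele depth) / total depth

  where the reference allele is the most frequent; selection of loci with
  `r > 1%` (configurable); classification of every allele as whole-unit CNV,
  substitution, other indel or deletion placeholder; a SNP scan.
* **Coding consequence** — apply a ±k-unit change inside a CDS and translate
  under the invertebrate mitochondrial genetic code (NCBI table 5) to the
  first stop, reporting frameshift truncations (CDS bp, protein aa).
* **Repeat architecture** — decomposition of tandem-repeat arrays into named
  unit types (e.g. `[R34]l-[R28]m-[R34]n` hybrids), reverse-complement unit
  matching, detection of inverted-repeat flanked elements, and read-level
  junction counting for the inverted orientation.
* **Synthetic data** — a replication-slippage simulator (lazy reflecting
  random walk on copy number) generating genomes, deep pileups and read sets
  with known truth, used by the test suite for end-to-end closure.

Two published data tables ship as plain-text fixtures: the precise
annotation of the *Dermacentor silvarum* mt genome (15,094 bp; reference
MN347015) and the 20-locus STR allele/depth table from one individual.

## Worked example

```r
library(mitostr)

tabs  <- read_str_allele_fixture()            # packaged 20-locus table
calls <- str_variant_calls(tabs, threshold = 0.01)
calls[calls$position %in% c(1810, 3441, 7324),
      c("position","ref_label","class","total_depth","alt_ratio","selected")]
#>   position ref_label class total_depth  alt_ratio selected
#> 1     1810      [G]8 1 x 8      362080 0.02638643     TRUE
#> 3     3441      [A]8 1 x 8      639117 0.31367183     TRUE
#> 8     7324     [TA]9 2 x 9      100694 0.07190101     TRUE

attr(calls, "tables")[["1810"]]
#> <allele_table> [G]8 at 1810: depth 362080, alt ratio 0.0264
#>    label raw_label          class copies delta_copies  depth
#> 1   [G]8       Ref      reference      8            0 352526
#> 2   [G]9       +1G cnv_whole_unit      9            1   6177
#> 3   [G]7       -1G cnv_whole_unit      7           -1   3116
#> ...
```

The `[G]8` reference at position 1810 (inside COI) carries a `+1G` insertion
allele — the `[G]9` variant, 6177 of 362,080 reads. All 20 fixture loci
exceed the 1% rule; the highest ratio, 31.4%, is at position 3441.

```r
ann <- load_annotation_table(mitostr_example("dsilvarum_annotation.tsv"))
validate_strand_coverage(ann)
#> strand +: 0 gap(s), 0 overlap(s)
#> strand -: 0 gap(s), 0 overlap(s)
#> annotation tiles both strands completely

find_ir_elements(ann)[[1]]
#> <transposon_like_element> IRs 5825-5987 / 9391-9559, insert 5988-9390:
#>   ND1, tRNA-Leu, 16S rRNA, tRNA-Val, 12S rRNA, CR1, tRNA-Ile, tRNA-Gln
```

The annotated repeats R2 (5825–5987) and R1 (9391–9559) flank the
translocated gene block from ND1 through tRNA-Gln — the transposon-like
element, whose inversion state can be counted from reads with
`inversion_junction_support()`.

A command-line front end covers the same stages:

```sh
Rscript exec/mitostr call --fixture --threshold 0.01 --out out/
Rscript exec/mitostr simulate --seed 5 --depth 2000 --out sim/
Rscript exec/mitostr validate-annotation
```

## Vignette

`vignettes/mitostr-methods.Rmd` describes the models and the design
decisions: the selection statistic, the slippage simulator and what it does
and does not emulate, indel normalisation, junction-probe design, numerical
conventions and known limitations.
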