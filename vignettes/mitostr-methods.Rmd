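---
title: "mitostr: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitostr: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mitostr` analyses intra-individual sequence heterogeneity of small circular
genomes — in practice, arthropod mitochondrial genomes sequenced to
10^4–10^5× depth by long-PCR amplicon sequencing. This vignette explains the
models it implements, the tunable parameters, the synthetic-data generator
used for validation, and the design choices taken where the design was
genuinely open.

## The data model

**Circular coordinates.** All coordinates are 1-based and inclusive, on the
major coding strand (J-strand) read 5'→3'. A feature with `end < start`
wraps the replication origin; its length is `(N − start + 1) + end` for a
genome of size `N`. A *precise annotation* is a partition of both strands
into named features at 1-bp resolution: `validate_strand_coverage()` builds
a per-strand coverage vector over the circle and reports every uncovered
(gap) or doubly covered (overlap) interval. Features annotated at the DNA
rather than RNA level (flagged `DNARegion`) intentionally duplicate sequence
covered by RNA-level features and are excluded from the tiling check. When
no genome sequence is supplied, `N` is inferred as the maximum annotated
coordinate — the annotation tables this package ingests never state `N`
explicitly.

**STR loci.** An STR is a maximal run of a *primitive* repeat unit (one that
is not itself a power of a shorter word, so `AAAA` is `[A]4`, never
`[AA]2`), positioned at the first nucleotide of the run and classified by
unit length `m` and copy number `n` as an `m x n` STR. Maximality is
enforced at base resolution on the left: a run is reported only where the
preceding base breaks the period. This is deliberately stronger than
whole-unit maximality — it is what makes one periodic tract yield exactly
one locus (`ATATATATAT` is `[AT]5`, not also `[TA]4` one base in). A
consequence worth knowing: a tract with a partial-unit flank mirrors under
reverse complement to a locus whose anchor may shift by up to `m − 1` bases
with a rotated unit; copy number and the rotation class of the unit are the
mirror-invariant quantities.

**Default scan thresholds.** Homopolymers (`m = 1`) require `n ≥ 5`;
`m ≥ 2` requires `n ≥ 3` and an array of at least 8 bp; units up to 6 bp
are scanned. Published deep-pileup STR tables in this domain contain only
loci with `n ≥ 6`, so these defaults recover all of them while suppressing
the two-copy noise that saturates AT-rich sequence. No published minimum
exists — this is a package decision, exposed as configuration.

## Pileup accounting and CNV calling

The classic samtools pileup base-column dialect is parsed exactly: `.`/`,`
reference matches (strand case collapsed), `ACGT` substitutions, `+N<seq>` /
`-N<seq>` indels *attached to the preceding read base*, `*` the
deletion-consumed placeholder, `^X` (with its mapping-quality byte) and `$`
read boundaries. A read carrying an indel is counted once, as the indel
allele; with that convention the per-label counts of every column sum to the
column depth, which the parser enforces. Typeset label variants found in
published tables (spaces, Unicode minus) are normalised to the ASCII dialect
before parsing, so fixtures flow through the same code path as real pileup.

Aligners report homopolymer indels at arbitrary offsets within an array, so
before tallying, `left_normalize_indels()` moves indel evidence from any
column inside a catalogued array to the column at the array's first
position, relabelling the corresponding share of the anchor's
reference-match tally (depths are conserved — the same reads, renamed).
One allele table per locus is then built from the single anchor column,
matching the one-row-per-position layout of published tables.

**Allele expansion.** An insertion or deletion of `k` bases with
`k ≡ 0 (mod m)` whose sequence is a whole-number repetition of the unit —
*up to rotation*, since the indel can be reported at any phase of the array
— becomes the concrete STR allele `[unit]_{n ± k/m}` (class
`cnv_whole_unit`). Single-base mismatches are `substitution`; everything
else is `other_indel` or the `placeholder` `*`, and none of those ever
contributes to copy-number classification.

**Selection statistic.** The reference allele of a locus is its most
frequent allele (at deep coverage of one individual this is the genome's own
STR), and the alternative-allele ratio is

\[ r = \frac{\text{total depth} - \text{reference depth}}{\text{total depth}} \in [0, 1). \]

All alternative alleles — substitutions included — enter the numerator; a
locus is *selected* when `r` exceeds the threshold (default 0.01, i.e. the
1% rule). The SNP scan reuses the same 1% figure as a per-allele frequency
threshold because no separate substitution threshold is established for this
kind of data; both are configurable. Human-readable output rounds ratios to
0.1 percentage points; TSV output keeps full precision. Ties in allele depth
order deterministically by expanded label.

## Coding consequence

Copy-number changes inside a CDS are applied in *sequence space*: the
gene's CDS is extracted (reverse-complemented for N-strand genes), the array
located at its in-CDS offset (any rotation phase of the unit is accepted),
resized, and translated codon-by-codon under NCBI genetic code table 5
(invertebrate mitochondrial: `TAA`/`TAG` stop, `TGA` = Trp, `AGA`/`AGG` =
Ser, `ATA` = Met). Working in sequence space sidesteps circular-coordinate
shifts entirely. The change is classified by `Δbases mod 3`: `in_frame`
(or `synonymous_length` at Δ = 0) when divisible by three, otherwise
`frameshift_truncation` with the truncated CDS length (bp, stop included)
and protein length (aa, stop excluded), or `stop_loss` when no stop is
reached — the latter reported as a result, not an error, because
mitochondrial genes commonly end on polyadenylation-completed stops. Code
table 5 is a package decision (the organisms are ticks); the source tables
never name a translation table.

The reference annotation carries a known internal inconsistency: the COI
feature is annotated at 1537 bp while its CDS is described as 1524 bp for a
"308-aa" protein (1524/3 = 508). The fixture stores the published
coordinates verbatim; translation always runs to the first stop, which makes
the downstream frameshift lengths self-consistent regardless.

## Repeat architecture

**Array decomposition** matches a library of named unit types greedily left
to right (longest unit first, preferring to continue the current block),
with a configurable per-unit mismatch budget and one trailing partial unit
permitted and counted as one copy — the field convention for
Sanger-consensus repeat arrays. Reconstruction is exact by construction and
checked property-style. A Sanger consensus of a heterogeneous array is
modelled as the modal decomposition over a read multiset.

**Inverted-repeat elements.** Two detection modes. With an annotation,
repeat features (`R<number>`) are paired and the insert reported as the
ordered genes between them (composite antisense segments, intergenic filler
and the repeats themselves excluded). On raw sequence, a seed-and-extend
scan finds maximal reverse-complementary segment pairs: exact `k`-mer seeds
are grouped by anti-diagonal (`left_pos + right_end` is constant along a
pair), merged, extended base-by-base, and filtered — periodic arms echo the
true pair on every diagonal congruent modulo the unit length, so pairs whose
arms lie ≥ 90% inside a longer pair's arms are dropped. The scan is
linear-coordinate; an IR pair spanning the origin is not reported.

**Junction support.** The orientation of the insert is witnessed by exact
read containment of four probes. A probe must span the *entire* IR arm plus
`k` bases of unique flank on each side: because the arms are mutual reverse
complements, a probe covering only part of an arm equals the reverse
complement of the opposite junction's probe and cannot distinguish
orientation once both read strands are scanned. This is the in-silico
counterpart of needing 250 bp reads to resolve ~170 bp arrays, and it is a
deliberate strengthening of a flank-only junction design, which we found to
be orientation-ambiguous. Counts are reported as evidence for the two
states, never as a genotype call; whether the two arrays of one element have
equal copy numbers is left undetermined when reads cannot phase both.

## The synthetic world

The generator emulates the statistical structure the analysis assumes — and
only that:

* **Genome**: 15,000 bp circle at AT fraction 0.78 (typical of the AT-rich
  tick mt genomes this tooling targets; a configuration default, not a
  measured value), with planted STRs (defaults `[G]8`, `[A]9`, `[TA]9` —
  the unit classes of the published loci) and one IR element (two 34-bp ×
  5 arrays, mutually reverse-complementary, flanking a 600 bp insert —
  array geometry matching the `34 x 5` elements seen in real genomes).
  Planted boundary bases are pinned so each run is maximal and each IR pair
  is exactly the maximal reverse-complement pair, making planted coordinates
  the unambiguous ground truth.
* **Slippage**: copy number evolves by a lazy random walk — per event, +1
  with probability `p`, −1 with probability `p` (reflected at one copy),
  else unchanged — for `g` events; the exact distribution is computed by
  convolution and drives multinomial allele counts at each planted locus.
  This minimal model reproduces the ±1-dominant allele spectra of real deep
  pileups (successive ± classes falling by roughly an order of magnitude).
  It is a *stated model*, not an estimate: no per-locus mitochondrial STR
  mutation rate is established, so defaults (`p = 0.01`, `g = 3`,
  `e = 1e-4`) are illustrative.
* **Pileup**: columns at STR positions draw from the slippage distribution;
  a configurable number of background columns carry substitution noise at
  rate `e`. Whole-genome columns at 10^5× would be gigabytes of text, so
  background noise is sampled at a set of columns rather than genome-wide.
* **Reads**: uniform circular sampling from the reference or the
  element-inverted genome, a stated fraction of molecules inverted,
  forward-strand reporting, no quality model.

A green closure test therefore establishes that the pipeline recovers the
frequencies and structures *this* world plants — multinomial sampling error,
exact repeat units, no alignment artefacts. It does not establish robustness
to sequencing-error profiles, PCR chimeras, alignment ambiguity beyond
homopolymer left-shifting, or impure repeat units; approximate-repeat
tolerance in the scanner is a configuration hook deliberately left
unimplemented. Seeds are mandatory for every stochastic operation, and the
CLI refuses to simulate without one.

## Numerical and convention notes

* Statistical test tolerances are 3 binomial standard deviations at the
  simulated depth; the slippage model is validated against an independent
  10^6-sample Monte-Carlo walk, classwise at 3σ.
* Zero depth at a locus yields an empty-table flag, not an error; the
  alternative-allele ratio is undefined (error) only when explicitly
  requested on an empty table.
* `apply_cnv()` on an origin-wrapping array returns a genome rotated to
  start at the array; callers needing fixed coordinates should rotate first.
* Identical expanded alleles observed under different raw labels (e.g.
  `+2TA` and `+2AT` at two phases) merge; their raw labels are preserved
  in the table.
* Deleting an entire array (or more) is a domain error everywhere: a locus
  must retain at least one copy.

## Known limitations

* Exact-match repeat scanning only; no impure/approximate STRs.
* IR detection does not cross the origin and has no mismatch tolerance in
  the seed stage (only in array decomposition).
* No statistical significance model for heteroplasmy ratios — selection is
  a plain threshold rule, as in the source analyses.
* BAM/SAM alignment, base qualities and assembly are out of scope; the
  pipeline consumes pileup text.
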