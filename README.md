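# intronaut

Detection of self-splicing group I (and group II) introns that interrupt
bacterial tRNA genes.

## The problem

Some bacterial tRNA genes — especially in phyla with highly reduced
genomes — are interrupted by group I introns, self-splicing ribozymes that
excise themselves from the precursor transcript.  When the intron sits at
an unusual position of the anticodon loop, such as between tRNA positions
35 and 36 (inside the anticodon itself), standard annotation tools either
report the gene as missing or mis-assign it: moving the inferred splice
boundary two nucleotides slides the anticodon reading frame, turning an
asparagine tRNA (anticodon GUU, intron at 35/36) into an apparent
threonine tRNA (UGU at 33/34), or an aspartate tRNA (GUC) into an alanine
tRNA (UGC).  Both frames satisfy the local splicing rules, so sequence
context alone cannot decide.

intronaut is for genome annotators and comparative genomicists who need
these calls right.  Given genome FASTA files and covariance-model hit
tables (Infernal `--tblout`), it:

* enumerates every splice boundary `(a, b)` near a hit that satisfies the
  group I rules — the 5′ exon ends on U, the intron ends on the ωG, and
  the spliced product folds into a tRNA cloverleaf with the junction
  inside the 7-nt anticodon loop (positions 32–38, anticodon 34–36);
* ranks the surviving boundary frames by local alignment against
  intron-less tRNA homologs (blastn-short-style scoring: match +1,
  mismatch −3, gap of length *k* costing 5 + 2*k*, query coverage > 75%),
  selecting by homolog score, anticodon agreement, minimal shift, then
  leftmost start;
* resolves the CAU-anticodon ambiguity (Met / fMet / Ile2) from homolog
  labels, never from sequence;
* verifies or corrects external (tFind/ARAGORN-style) predictions, calls
  group II introns from ARAGORN × RF00029 overlap, classifies every
  intron's host locus (tRNA / rRNA / tmRNA / CDS / IStron-like / unknown),
  scans introns > 500 bp for homing-endonuclease ORFs, and aggregates
  per-phylum retention rates, insertion-site matrices, copy-number and
  length statistics;
* ships a synthetic-genome generator with full ground-truth bookkeeping,
  so the entire pipeline is testable offline.

Everything is tibble-in/tibble-out and pipe-friendly; plots are ggplot2.

## Worked example

Plant an Asn (GUU) tRNA interrupted at 35/36 by a 220-nt "trap" intron —
one whose terminal `GTG` creates a second structurally valid frame two
nucleotides upstream — and resolve it:

```r
library(intronaut)

fx <- make_fixture("GTT", "35/36", 220, seed = 141, trap = TRUE, db = "both")

ctx <- extract_context(fx$candidate, fx$genomes)
enumerate_boundaries(ctx)[, c("a", "b", "site", "anticodon")]
#> # A tibble: 6 × 4
#>       a     b site  anticodon
#>   <int> <int> <chr> <chr>
#> 1   398   613 36/37 CCT
#> 2   398   618 33/34 TGT
#> 3   398   620 33/34 TAA
#> 4   400   618 34/35 TTG
#> 5   400   620 35/36 GTT
#> 6   400   624 37/38 CTG
```

Several frames pass the U/ωG/fold rules, including the true Asn frame
(35/36, GTT) and the Thr-like trap frame (33/34, TGT).  The homolog
database decides:

```r
true_db    <- fx$trna_db[startsWith(fx$trna_db$id, "true"), ]
shifted_db <- fx$trna_db[startsWith(fx$trna_db$id, "shifted"), ]

resolve(fx$candidate, fx$genomes, true_db)[, c("site", "anticodon", "amino_acid")]
#> # A tibble: 1 × 3
#>   site  anticodon amino_acid
#>   <chr> <chr>     <chr>
#> 1 35/36 GTT       Asn

resolve(fx$candidate, fx$genomes, shifted_db)[, c("site", "anticodon", "amino_acid")]
#> # A tibble: 1 × 3
#>   site  anticodon amino_acid
#>   <chr> <chr>     <chr>
#> 1 33/34 TGT       Thr
```

With informative homologs the call is Asn (GUU) at 35/36; with a database
containing only the shifted-frame homolog the resolver reproduces — by
design — the Thr (UGU) 33/34 miscall that boundary-naive tools make.
Whole-survey runs go through `run_simulate()` → `run_detect()` →
`run_stats()` (or the `inst/cli/intronaut.R` front end with the
`simulate` / `detect` / `adjust` / `stats` subcommands), emitting a calls
TSV, GFF3 features and per-figure statistics tables.

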