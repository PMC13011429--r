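---
title: "Detecting self-splicing introns in bacterial tRNA genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting self-splicing introns in bacterial tRNA genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronaut)
library(dplyr)
```

## The problem

Group I introns are self-splicing ribozymes that occasionally interrupt
bacterial tRNA genes.  When the insertion point falls at an unusual place in
the anticodon loop -- notably between positions 35 and 36, inside the
anticodon itself -- standard tRNA annotation tools either miss the gene
entirely or call the wrong isoacceptor: shifting the inferred splice
boundary by two nucleotides slides the anticodon reading frame, so an
asparagine tRNA (anticodon GUU, intron at 35/36) can be reported as a
threonine tRNA (UGU, intron at 33/34), and an aspartate tRNA (GUC) as an
alanine tRNA (UGC).  Both frames satisfy the local sequence rules, so the
genomic sequence alone cannot decide between them.

intronaut implements the resolution protocol around this ambiguity: it
post-processes covariance-model intron hits, enumerates every splice
boundary compatible with the group I chemistry, and lets intron-less tRNA
homologs arbitrate between competing frames.  It also classifies the host
locus of each intron (tRNA, rRNA, tmRNA, protein-coding gene, IStron-like,
unknown), annotates homing-endonuclease ORFs, and aggregates survey-level
statistics.

## The boundary model

A group I intron in a tRNA gene obeys three constraints used jointly:

1. **5'-exon terminal U.** The exon base immediately before the intron is a
   uridine (T in the DNA alphabet used throughout the package).
2. **omega-G.** The intron's last base is the guanosine whose recognition
   completes exon ligation.
3. **Structural restoration.** Excising the intron must yield a sequence
   that folds into a canonical tRNA cloverleaf, with the splice junction
   inside the 7-nt anticodon loop (loop positions numbered 32--38, the
   anticodon at 34--36).

Given a candidate interval $[s, e)$ from a covariance-model hit,
`enumerate_boundaries()` scans every pair $(a, b)$ with
$a \in [s - w, s + w]$, $b \in [e - w, e + w]$ (window $w = 10$ nt by
default; observed model-versus-true shifts are a few nucleotides, so the
window has ample margin) and keeps the pairs satisfying all three
constraints, with a minimum intron length of 50 nt to prune degenerate
excisions.  The insertion-site label "$N$/$N{+}1$" is derived from the loop
index of the last 5'-exon base; e.g. a cut after loop position 35 is the
site 35/36.

Several boundary pairs typically survive.  `resolve()` ranks them by
aligning each candidate mature tRNA against a database of intron-less tRNA
homologs and selecting by, in order: (1) highest homolog alignment score,
(2) anticodon equal to the top homolog's anticodon, (3) smallest total
boundary shift, (4) leftmost start.  Criteria (3) and (4) exist only to make
output deterministic; in practice the homolog score separates frames, which
is exactly what makes the two-frame trap decidable.  With an empty or
uninformative homolog database the frames are genuinely undecidable and the
package reports nothing (or, for externally supplied calls, the status
`"unverified"`) rather than guessing.

### The cloverleaf validator

Covariance-model folding is out of scope, so structure validation is a
layout search over canonical bacterial tRNA geometries: 7-bp acceptor stem,
1--2 nt spacer, 3--4-bp D stem with a 7--11-nt loop, 0--1 nt spacer, 5-bp
anticodon stem with its fixed 7-nt loop, a 3--23-nt variable region, 5-bp T
stem with a fixed 7-nt loop, and up to 4 trailing nucleotides.  A placement
is accepted when each stem reaches its complementarity threshold counting
Watson--Crick and G:T wobble pairs: at least 6/7 in the acceptor stem, 4/5
in the anticodon and T stems, and $k{-}1$ of $k$ in the D stem.  Among
accepted placements the one maximising total stem pairs wins; placements
that tie on pairs are discriminated by presence of the invariant U33 (a T
at loop position 2 -- the most conserved base in tRNA, which a spurious
placement shows only by chance), then by the leftmost anticodon loop.
Without the U33 criterion a chance placement a few bases to the left can
tie a genuine one and silently relabel the anticodon frame.  An ambiguous
base (N) inside any stem or the
anticodon loop invalidates a placement outright.  The thresholds are
deliberately permissive for canonical bacterial tRNAs and strict enough
that random sequence essentially never folds (the chance that a random
placement passes the acceptor-stem test alone is under one percent);
production users can substitute an external validator and feed its calls
through `adjust_external_call()`.

### Alignment scoring

Homolog search uses Smith--Waterman local alignment with the classic
short-query parameters: match +1, mismatch -3, a gap of length $k$ costing
$5 + 2k$, and a shared exact 7-mer required before any alignment is
attempted.  Identity is matches over aligned columns (gap columns
included); coverage is the aligned fraction of the query, and hits must
exceed 75% query coverage to count.  Because identity is computed over
gapped columns it can differ by a point or two from other tools' values on
gapped alignments.  Raw scores rather than E-values rank hits: reference
sets here are small and fixed, so a significance model would add nothing.

The flanking check -- requiring tRNA-like sequence on both sides of a
candidate before resolution -- accepts a side when its best local alignment
against the reference set scores at least 12.  Under this scoring,
unrelated 400-nt flanks top out around score 10, while genuine exon
fragments of homologs at ~90% identity score 16 or more, so 12 sits in the
separation gap with margin on both sides.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `evalue_max` | 1e-4 | -- | covariance-model hit filter (strict `<`) |
| `overlap_frac` | 0.5 | fraction | reciprocal overlap defining "same locus" in dedup |
| `flank` | 400 | nt | genomic context on each side of a candidate |
| `window` | 10 | nt | boundary-shift search radius per side |
| `min_intron_len` | 50 | nt | smallest admissible intron |
| `min_coverage` | 75 | % | homolog query-coverage threshold (strict `>`) |
| `min_side_score` | 12 | score | flanking-tRNA evidence per side |
| `heg_len` | 500 | bp | group I length gate for ORF scanning |
| `orf_min` | 300 | nt | minimal reported ORF |
| `domain_evalue` | 0.01 | -- | domain-label threshold |
| `min_genomes` | 20 | genomes | phylum plotting threshold |

The e-value, coverage, flank, HEG-length, domain and phylum thresholds are
the survey protocol's stated values; the window, minimum intron length,
dedup overlap and flanking score are this package's own choices, fixed once
as documented above.

## Host classification and HEGs

`classify_host()` consumes externally produced hit tables (it never runs
the searches itself).  rRNA and tmRNA require model hits on both sides of
the intron within 1,000-nt flanks; protein-coding hosts require
same-subject blastx-style hits on both sides within 4,000 nt; a TnpB
annotation within the 4,000-nt flank marks an IStron-like element.  tmRNA
additionally accepts partial evidence -- an intron can truncate the tmRNA
at its T loop so badly that the model only fires on one side -- implemented
as a hit whose intron-facing end lies within 30 nt of the boundary plus a
short (>= 20 nt) same-model fragment opposite.  Those two numbers are
placeholders for an undocumented judgment call and are flagged as such in
the evidence string.  When evidence supports several categories the
priority order tRNA > rRNA > tmRNA > CDS > IStron-like wins, on the
principle that structured-RNA evidence is stronger than translated-homology
evidence, and the conflict is logged.

ORFs are sought on the sense strand only (introns are transcribed with
their host gene), in all three frames, with bacterial starts ATG/GTG/TTG,
and only in group I introns longer than 500 bp (group II introns are always
scanned).  Every start-to-stop span of at least 300 nt is reported; domain
labels from an hmmscan-style table attach only below E = 0.01, with the
homing-endonuclease families LAGLIDADG (PF03161), PD-(D/E)XK (PF11645) and
HNH (PF01844), plus reverse transcriptase, flagged explicitly.

## What the synthetic generator emulates

`make_survey()` and `make_fixture()` generate the study conditions every
test runs under:

* tRNA genes with perfectly complementary random stems in the canonical
  72-nt layout, the requested anticodon, and the invariant U33;
* introns of 184--894 nt (the survey-like range, mean about 257 nt via a
  shifted exponential), always ending in the omega-G, planted at sites
  32/33--37/38 subject to the U-before-cut rule;
* trap fixtures reproducing the two-frame geometry: an intron ending in
  GTG combined with the invariant U33 guarantees a second valid frame two
  nucleotides upstream whose anticodon reads TG plus the base at position
  36 -- the exact Asn-to-Thr / Asp-to-Ala confusion; non-trap introns have
  their terminal-adjacent bases chosen so no such alternative frame exists;
* homolog databases holding two independently degraded intron-less copies
  of each planted tRNA (real databases carry many homologs per family),
  mutated only outside the anticodon triplet so the anticodon-match logic
  stays exercised, at 92% identity by default;
* candidate hit tables with up to +-2 nt boundary jitter, per-genome copy
  numbers with a survey-like overdispersed tail (mean 1.6, sd about 1.7,
  median 1), about 40% group I retention in the 35/36-enriched phylum, a
  second phylum carrying group II introns, and a third small phylum that
  falls below the 20-genome plotting threshold;
* host-locus fixtures for the classifier, including tmRNA partial-evidence
  cases.

The generator audits itself: every truth record is re-derived from the
emitted FASTA by slicing and refolding at generation time, and a fixed seed
gives byte-identical output.

What the generator does **not** emulate: realistic genomic base
composition (background is i.i.d. uniform -- no rule in the pipeline reads
composition), covariance-model score distributions, intron secondary
structure (only the terminal G matters to the rules), sequencing or
assembly artefacts, and real phylogenetic correlation between homologs.
Passing tests therefore demonstrate the correctness of the boundary logic,
frame arbitration, classification rules and statistics on sequences that
satisfy the stated model -- not the sensitivity of covariance-model search
on real genomes, which lies upstream of this package.

## The group II path

Group II introns in tRNAs are called from the overlap between
ARAGORN-style tRNA intron intervals and group II covariance-model hits.
The group I U/omega-G rules do not apply; the external segmentation is
trusted as long as the spliced product folds and its anticodon matches the
top intron-less homolog, and only when homology disagrees are boundaries
re-enumerated (within +-5 nt) and re-selected by homolog score.  Trusting
the external boundaries first matters: with imperfect homologs, a frame
shifted one base in both directions can out-score the true frame by
chance, and alignment score alone would then move a correct external call.
The splice junction is not restricted to the anticodon loop, so a group II
site may come out as "D-loop".

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open everywhere; every emitted or
  ingested file is 1-based inclusive.  The conversion lives in exactly one
  pair of functions, making the round trip a bijection by construction.
* Dedup keeps the higher-scoring hit of any same-target, same-strand pair
  with reciprocal overlap >= 0.5; score ties break by lower e-value, then
  leftmost start, so output order is deterministic.
* Copy-number standard deviations are sample (n-1) estimates; a class with
  one qualifying genome reports sd 0 with a degeneracy flag rather than NA.
* Subgroup score ties break lexicographically by model name, with a log
  message.
* A candidate within `flank` of a contig end gets a truncated context and
  a flag, not an error.
* CAT-anticodon calls never guess between Met, fMet and Ile2: the label is
  copied from the top-scoring CAT-anticodon homolog, or reported as "Met?"
  with an unresolved flag when no such homolog exists.

## Problem sizes

The shipped validation runs use 100 contexts for the enumeration-oracle
comparison, 200 planted fixtures for recovery, 50 trap fixtures per
database condition, 100 host-locus fixtures, and a 57-genome synthetic
survey -- sizes chosen so the whole suite completes in a few minutes on a
single core while every count is large enough to leave no room for
coincidental passes.

## Known limitations

* The cloverleaf validator models canonical bacterial layouts only; tRNAs
  with extreme D-loop or variable-region geometry (and all archaeal or
  eukaryotic variants) are out of scope.
* Loop-relative numbering reproduces anticodon-loop site labels without
  full Sprinzl numbering; the single observed D-loop insertion is labelled
  categorically.
* BLAST bit scores and E-values are not reproduced; ranking is by raw
  Smith--Waterman score, which preserves order on the short, fixed
  reference sets used here.
* The tmRNA partial-evidence thresholds are placeholders, as discussed.
* Boundary arbitration is only as good as the homolog database; with only
  wrong-frame homologs present the package reproduces (by design) the same
  two-base miscall documented for boundary-naive annotation tools.
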