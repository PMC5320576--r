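---
title: "How phagesift separates viral from background reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How phagesift separates viral from background reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phagesift enriches for viral sequence by *subtraction*: instead of asking
"does this read look viral?" (hopeless for novel viruses), it asks "does
this read look like anything we know is *not* the target?" and keeps
whatever fails that test. This vignette explains the model behind each
stage, the parameters that matter, what the bundled simulator does and does
not emulate, and the numerical choices made where the design was genuinely
open.

## Stage 1 — the masked background genome

The background genome is the concatenation of all non-target records the
user supplies (GenBank flat files, or FASTA with GFF3 annotations). Before
concatenation, coding regions whose annotations identify them as viral in
origin are replaced with `N`s.

Why mask at all? A bacterial chromosome routinely carries one or more
prophages. If those regions stay in the background, reads deriving from an
active copy of the same (or a related) phage map to them and are
subtracted — the pipeline would silently discard its own target. Masking
with `N` removes those regions from play twice over: no seed k-mer
containing `N` enters the index, and `N` never counts as a match during
extension.

Design choices where annotation practice is messy:

* **Keyword matching is case-insensitive substring search.** Defaults are
  `phage` and `viral`, so "Bacteriophage P2 integrase", "prophage
  repressor" and "PHAGE tail fiber" all trigger masking. Annotation
  free-text is too inconsistent for exact-word matching; substring search
  maximises recall, and over-masking costs little (a slightly smaller
  background) while under-masking costs the target itself. The keyword
  list is configurable; we deliberately did not extend the default list
  beyond the two canonical words — additions like `integrase` or `virus`
  are easy to supply but also start matching host genes
  (e.g. "integrase-like recombinase") whose masking the user should opt
  into consciously.
* **Searched qualifiers are `product`, `note` and `function`.** Gene names
  are excluded by default: two-letter gene symbols produce too many
  accidental substring hits. Configurable.
* **Only coding-region (CDS) features are maskable by default**, matching
  how public annotations mark prophage genes; a configuration switch
  admits other feature kinds (e.g. `misc_feature` prophage regions).
* **Coordinates** are 1-based inclusive throughout (GenBank convention);
  the BED mask log converts to 0-based half-open on output. Compound
  `join()` locations are masked interval by interval; overlapping
  intervals are masked once (union semantics), and pre-existing `N`s are
  never counted as newly masked. Masking preserves record lengths exactly
  and is idempotent.
* **Duplicate record ids across input files are an error**, not silently
  renamed — the mask log must stay unambiguous.

## Stage 2 — mismatch-tolerant subtractive mapping

The built-in mapper is ungapped seed-and-extend against a hash index of
every background k-mer (forward strand; the read is also tried as its
reverse complement).

A placement *maps* when both hold:

* identity ≥ `min_identity` (default **0.90**) over the aligned region;
* aligned fraction ≥ `min_aligned_fraction` (default **0.80**) of the read
  (placements hanging off a record end are clipped, which lowers this).

The defaults are deliberately *tolerant of mismatches*: the genome used as
background is rarely the sequenced strain, and subtraction should remove
host reads despite strain-level variation. Tolerance trades in one
direction only — a host read that survives filtering is recoverable later
(contigs can be recognised as host and discarded after assembly), whereas
a viral read that is wrongly subtracted is gone. The same asymmetry is why
the mapper is **ungapped**: a read spanning an indel fails the
aligned-fraction test and leans toward retention.

Numerical details that make runs reproducible and auditable:

* Seeds are exact `seed_length`-mers (default **15**) taken at *every*
  read offset. A placement with at most m mismatches over an L bp read is
  guaranteed to contain a clean seed whenever m < (L − k + 1)/k — for
  150 bp reads and k = 15, up to 9 mismatches (identity ≥ 0.94). Between
  that bound and the 0.90 threshold, seeding is near-lossless for the
  substitution rates the tolerance is designed for (a 2% substitution rate
  puts ~3 mismatches on a 150 bp read; ten or more is a > 3-sigma
  excursion), and the test suite checks the mapper's decisions against a
  brute-force all-offsets scan.
* `N` counts as a mismatch on either side of the alignment; seed k-mers
  containing `N` are skipped.
* Ties between equally identical placements break lexicographically:
  target id, then start, then forward strand.
* Reads shorter than the seed produce an unmapped verdict and a warning,
  never an error mid-stream.
* Base qualities are ignored; quality trimming is a user-side
  preprocessing decision.

**Filter policies.** `pair_level` (default) removes a pair when *either*
mate maps — appropriate when sequencing a viral isolate, where a mate that
matches the host brands the whole fragment as host-derived. `read_level`
judges each read independently and keeps surviving mates as singletons —
appropriate for complex metagenomes, where a chimeric-looking pair may
straddle a real phage–host junction. Removal percentages count all bp of
removed units (under `pair_level`, both mates of a removed pair), which is
the bookkeeping that matches what the assembler never sees.

External mappers plug in via SAM: a read is mapped iff any of its
alignment lines lacks the unmapped flag; identity and aligned fraction are
recovered from CIGAR + `NM` where present.

## Stage 3 — assembly and contig statistics

Retained reads are assembled on a canonical-k-mer de Bruijn graph
(default k = **31**, odd so no k-mer is its own reverse complement).
Maximal unbranched paths become contigs after three cleaning steps:

1. **Error-haze removal.** When the weighted-median k-mer multiplicity
   indicates real coverage (≥ 4), k-mers seen once are dropped; at 20×
   coverage a true k-mer is practically never a singleton, while most
   sequencing-error k-mers are.
2. **Tip clipping.** Dead-end paths of singleton k-mers shorter than 2k —
   the stubs left by errors near read ends.
3. **Bubble removal on unitigs.** Interior read errors create short
   parallel paths (bubbles) whose k-mers can be seen two or three times;
   judged k-mer by k-mer they are indistinguishable from Poisson dips in
   true coverage, and a fixed count cutoff either lets them shatter the
   graph or clips real sequence. phagesift therefore judges coverage on
   *compressed unitigs*, where noise averages out: when the median
   multiplicity is ≥ 8, short unitigs (< 4k bp) whose mean k-mer coverage
   is at most a quarter of the median are removed and the graph rebuilt so
   the flanking unitigs merge. Iterated at most three times; all
   thresholds configurable via `cov_cutoff` (an explicit integer cutoff
   disables the adaptive behaviour).

Contigs are reported in canonical orientation (lexicographically smaller
strand), ordered by length then sequence, so output is byte-identical
across runs. `read_support` is estimated from total k-mer multiplicity
divided by the k-mers a read of mean length contributes.

**Statistics.** Reported statistics (count, max length, N50, total bp)
cover contigs ≥ 1000 bp by default, while the full contig set is written
to disk. N50 conventions vary, so phagesift documents its choice: sort
lengths descending; N50 is the length of the contig at which the
cumulative sum first reaches half the total. For the contig set
{5400, 1087} this yields N50 = 5400.

## The simulator: what it emulates, and what it does not

`simulate_genomes()` builds a host genome (default 200 kb) carrying a
contiguous prophage (default 30 kb) that *replaces* a host window — so the
emitted record length equals the configured host length — plus an
autonomous free phage (default 40 kb). The prophage span is tiled with CDS
features whose products contain "phage"/"viral", with inter-feature gaps
(80 bp) far below the span a read needs to anchor an alignment, so the
default masking policy blinds the background to the entire prophage. A few
non-viral host CDSs are annotated for contrast. `simulate_reads()` samples
mate pairs (default 10 000) with Gaussian insert sizes (400 ± 40 bp),
random strands, i.i.d. substitution errors (default 1%) and constant
qualities, at configurable origin fractions (default 20% free phage, 10%
prophage, remainder host backbone). Every read carries a truth label.

Deliberate simplifications, chosen so the discriminating experiments are
sharp rather than realistic:

* sequences are i.i.d. uniform ACGT — no GC skew, no repeats, no shared
  genes between phage and host (the generator additionally verifies the
  free phage shares at most a tolerated handful of 15-mers with the host
  backbone and regenerates otherwise);
* substitution-only errors, matching the mapper's ungapped model — no
  indels, no quality-dependent error profile;
* host inserts never straddle the prophage boundary and prophage inserts
  stay wholly inside it, keeping truth labels unambiguous;
* no community structure: one host, one prophage, one free phage.

Passing the simulated contracts therefore demonstrates the *mechanism* —
masking decides whether prophage reads survive; subtraction removes
essentially all host reads at 1% divergence; the assembler reconstructs a
40 kb genome at 20× — not performance on real metagenomes, where shared
genes, repeats and uneven coverage blur every one of those lines.

## Problem sizes used by the checks

The test-suite and acceptance-script runs use the default community
(10 000 pairs against a 200 kb host) for the masking contract; 500 reads
against 20 kb for mapper-oracle agreement; 1000 reads for masked-region
invisibility; a 40 kb phage at 20× for assembly recovery; and a reduced
community (2 000 pairs, 60 kb host) for the byte-identical determinism
check, which is scale-free. These sizes are the package's choice of a
desk-scale experiment: large enough for the binomial rates to be sharp,
small enough to run routinely.

## Known limitations

* Masking only consumes *existing* annotations; an unannotated prophage
  stays in the background and will absorb its own reads. De novo prophage
  prediction belongs to dedicated tools.
* The ungapped mapper underestimates similarity across indels; external
  mappers can be substituted via SAM import where that matters.
* The assembler performs no scaffolding, gap filling or circularity
  detection; terminally redundant phage genomes assemble into contigs
  slightly longer than the genome.
* Background curation is by file choice: "all bacteria except taxon X" is
  expressed simply by which genomes the user supplies.
* With external sequencing data for a known phage–host pair (e.g. a
  *Pseudomonas* phage against the PAO1 reference with phage CDSs masked),
  the pipeline should remove roughly the host-derived fraction of pairs;
  such a comparison requires downloading the raw data and is left as an
  optional external validation, not part of the test suite.
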