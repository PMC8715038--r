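---
title: "isforge: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{isforge: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isforge)
```

isforge is a desk-scale toolkit around insertion-sequence (IS) based
random transposon mutagenesis in bacteria, of the kind used to turn a
genomically stabilised *Corynebacterium glutamicum* chassis into a random
insertion mutagenesis platform. It covers four computational problems
that come up in such a project — designing scarless "genome healing"
deletions of IS elements by comparative genomics, modelling the Bxb1
serine-integrase genetic switch that keeps the transposase silent during
cloning, calling insertion sites from long reads of marker-anchored
enrichment libraries, and quantifying target-site preference — plus a
synthetic-data generator that emulates the whole experiment so every
stage runs and is testable without any external data.

All internal coordinates are 0-based half-open on both reads and
references; BED output is native to that convention, and any 1-based
coordinate in printed summaries is labelled as such. Chromosomes and
plasmids are circular by default; windows and arms wrap the origin.

## Genome healing

An IS element disrupting a locus can be removed scarlessly if a related
donor genome carries the syntenous region without the element: the
deletion construct is then amplified from the donor, restoring the
ancestral allele. The implemented procedure:

1. extract the element with 2,500-bp flanks from the target;
2. locate each flank in every donor by seeded local alignment (exact
   15-mer seeds, banded affine-gap Smith–Waterman extension, band 50;
   scores match +1 / mismatch −1 / gap open −2 / extend −1, all
   configurable);
3. require the two hits to be co-linear on one donor strand with a
   junction gap below 10% of the element length — the operational
   definition of "syntenous region present, element absent". The
   threshold is a package choice: no numeric synteny rule is standard,
   and this is the minimal one; it is exposed as `max_gap_frac`;
4. compute identity over the 750-bp windows directly abutting the healed
   junction (windows start exactly at the junction — the natural choice,
   since those are the bases the construct will recreate), by banded
   *global* alignment, with identity defined as matches / alignment
   columns and gap columns counted as mismatches. This is the
   conservative reading of "percent identity": a 750-bp window with 7
   substitutions scores 743/750 = 0.99067 and passes the > 0.99 gate; 10
   substitutions (740/750 = 0.98667) fail it;
5. rank passing donors by combined identity (pooled matches over pooled
   columns of both windows); ranking is a total order (ties break on
   donor id, then coordinate), so donor input order never affects the
   selection;
6. emit homology arms from the donor sequence flanking the junction.
   The default arm length is 550 bp, the midpoint of the conventional
   500–600 bp range; an ambiguous base shrinks the arm within the range
   or fails the design. When no donor passes the gate, the fallback is a
   conventional deletion with arms from the target itself, removing a
   user-supplied CDS + promoter interval (promoter extents are an input,
   not computed).

The wildtype-as-donor case (an element absent from the wildtype genome)
needs no special handling: the wildtype is simply passed as another
donor.

Because the flank queries end exactly at the element boundaries, the
junction coordinate in the donor is pinned by the alignment's query-end
trimming and cannot over-run into unrelated sequence; this is why a
perfect donor yields window identities of exactly 1.0 ("healing
closure", which the test suite asserts by excising the element in silico
and re-running the search).

## The genetic switch

The Bxb1 integrase recombines a bacterial attachment site attB with a
phage site attP, forming the hybrids attL and attR; without a
directionality factor the reaction is one-way. A promoter placed between
attB and attP in inverted orientation is flipped by recombination — a
genetic switch that turns transposase expression on only in the strain
expressing the integrase.

`apply_switch()` models this at sequence level: the crossover is placed
at the centre of each supplied site, between the two bases of the
central dinucleotide (standard serine-integrase geometry; sites must
have even length), and the segment between the two crossover points is
reverse-complemented in place. Everything else follows from sequence
arithmetic: the hybrid attL/attR appear at the former site loci, total
length is conserved, and duplex base composition (A+T and C+G pair
counts) is conserved — single-strand counts swap A with T and C with G
inside the inverted segment, so the duplex counts are the meaningful
invariant. The function verifies that the construct actually carries the
claimed attB/attP sequences, which makes unidirectionality structural:
on its own output the substrate check fails ("no attB/attP substrate").
Direct-repeat geometry (excision) is rejected as out of modelled scope.

`integrate_plasmid()` uses the same crossover geometry to insert a
circular attP plasmid at a genomic attB, conserving total length and
bracketing the insertion with attL/attR; the attB is consumed, so
re-integration at the same locus errors.

`scan_attB()` finds degenerate attB-like sites — the kind of partially
conserved cryptic site that can sit in a housekeeping gene such as
*groEL* and attract whole-plasmid co-integration. Each position on both
strands is scored as the sum of user weights at positions matching a
reference site. A central-dinucleotide match is reported separately but
not required, since observed cryptic sites can lack conservation even
there. The reference site and weights are deliberately user
configuration: published attachment-site sequences vary by context, and
the package does not hard-code one as ground truth; tests use synthetic
sites with a GT central dinucleotide.

## Junction calling

Enrichment libraries are built by half-nested amplification anchored in
the selection marker: an outer biotinylated primer ~500 nt upstream of
the element's inverted repeat (IR), then a nested primer 150 bp from the
marker's 3′ end. Informative reads therefore run 150 bp of marker, the
24-bp IR, then genomic DNA from the junction outward.

`call_junctions()` consumes local alignments (PAF or SAM) of such reads
against the delivery plasmid and the genome. Per read:

* orientation is normalised from the marker alignment's strand, so
  reverse-sequenced reads are transparent;
* the read-space position of the IR outer edge is obtained by projecting
  the known marker end through the marker alignment;
* the junction coordinate is the projection of that position through the
  adjacent genomic alignment.

Projection rather than raw block edges matters: local aligners both
over-run junctions by a few chance-matching bases and trim noisy ends
back to the last cleanly matching stretch. Over-runs in the bundled
aligner are structurally gapless (see below), so projection through them
is exact; trimmed stubs are extrapolated colinearly, accurate to the
stub's indel imbalance (±1–2 bp at 5% error). The gates reflect this
asymmetry: over-extension beyond the IR is bounded by `tolerance`
(default 10 bp) — and more than `backbone_threshold` (50 bp) of plasmid
backbone beyond the IR reclassifies the read as whole-plasmid
co-integration, the signature of integrase capture at a cryptic attB —
while under-extension away from the junction is allowed up to
`end_slack` (150 bp), because end trimming is routine at long-read error
rates. Reads with a marker anchor but no adjacent genomic block are
`ambiguous`; reads with no marker anchor are skipped and counted.

The strand-specific coordinate convention: a `+` insertion at `pos` has
its 8-bp target window at `[pos, pos+8)`; a `−` insertion at `pos` has
it at the reverse complement of `[pos−8, pos)`. The simulator records
truth in the same convention, which is what makes exact closed-loop
tests possible.

`collapse_sites()` merges transposition events on the same strand within
`position_tolerance` (default 3 bp, reflecting long-read junction
jitter) by single linkage; the site coordinate is the modal junction
position, with ties broken towards the event with the smallest
`|gap_on_read|` (the estimate extrapolated over the shortest stub) and
then the smallest coordinate, and single-read sites within twice the
tolerance of a multi-read site are absorbed into it. On clean data every
gap is zero and the rule reduces to "mode, ties to the smallest". Sites
keep singletons; `min_reads_for_motif` (default 2) only marks which
sites feed the target-site analysis. When a published site total is
compared against this output, note that totals with and without
singletons are both available (`read_count >= 1` versus `>= 2`); which
one a given report used is often ambiguous, so both are worth quoting.

`assign_replichore()` splits the circular chromosome at oriC and the
terminus; on replichore 1 (oriC → ter, clockwise) a `+` insertion lies
on the leading strand, on replichore 2 the assignment inverts. The raw
`+`/`−` partition is also always available as the `orientation` column,
since published leading/lagging splits do not always state which
definition was used. `positional_summary()` bins the chromosome and
renders the classic polar plot (leading outer ring, lagging inner).

## Target-site preference

`extract_octamers()` pulls the strand-specific 8-bp windows at sites
passing the read filter, dropping windows with ambiguous bases and (on
linear contigs) windows over an end. `position_matrix()` gives
per-position base counts and information content `2 − H` bits, with the
WebLogo small-sample correction `e(n) = 3/(2·ln2·n)` available but off
by default (so the arithmetic in examples stays exact; switch it on for
WebLogo parity). The background is assumed uniform — the WebLogo
default; a GC-weighted background is a possible extension, not
implemented. `tetramer_frequencies()` tabulates the central 4-mer
(octamer positions 3–6) and flags whether any single tetramer exceeds a
ceiling (default 20% of insertions), the practical test for "no dominant
target motif". Logos are rendered with base graphics, letters stacked by
frequency × information. Octamers are counted once per site
(unweighted); read-weighted counting would conflate site preference with
library depth.

## The synthetic-data generator

The generator emulates the structure of the real experiment, not its
biology in detail:

* **genome**: i.i.d. bases at a set GC (default 0.538, a
  *C. glutamicum*-like chromosome; default length 3,034,563 bp — tests
  and the acceptance script pass 40–300 kb explicitly and say so below);
* **insertions**: every position × strand is scored as the product of
  PWM weights over its 8-bp target window and `n` sites (default 3,207,
  a realistic library) are drawn without replacement proportional to
  score, orientation uniform (no strand bias is the null the field
  expects); same-strand draws closer than 4 bp are rejected so truth
  sites stay distinct under the 3-bp merge tolerance. The default PWM
  encodes the empirically observed preference shape: T-biased positions
  3–4, A-biased 5–6, strong discrimination against G/C at 4–5, slight
  G/C tendency at the outer positions. Insertion is modelled as element
  plus duplication of the 8-bp target (`tsd_len` configurable); the
  duplicated window *is* the analysed octamer, so reads built from the
  reference junction are exact;
* **reads**: 150-bp marker tail + 24-bp IR + genomic sequence from the
  junction outward, length drawn log-normally with mean 10,000 bp
  (sdlog 0.49, so the 5th–95th percentile spans roughly 4–20 kb — the
  "approximately 10 kb" fragmentation gives only the centre), errors at
  a configurable total rate split substitution:insertion:deletion =
  2:1:1 (a simple declared long-read-like mix), each read
  reverse-complemented with probability 1/2, constant FASTQ qualities.
  Everything is byte-reproducible under one seed.

What the generator does **not** emulate: realistic long-read error
profiles (homopolymer compression, quality-correlated errors), PCR
chimeras, capture efficiency, multi-copy IS backgrounds, or biological
hotspots beyond the PWM. Passing closed-loop tests therefore shows the
pipeline's logic is correct under declared noise, not that it is robust
to every real-data artefact.

`naive_align()` closes the loop in tests: exact k-mer seeding (k = 15),
co-linear seed chaining anchored at the cluster's median diagonal,
banded global alignment of inter-seed segments, and exact-match terminal
extension. The design is deliberate: free local extension can over-run a
junction through chance gapped matches, which would break exact junction
recovery; chained extension can over-run only gaplessly, which
projection tolerates exactly. It is a test utility, not a production
long-read aligner — real data should be mapped with a long-read mapper
and imported via `read_alignments()`. Circular references are indexed
doubled so origin-crossing reads map as single blocks.

## Numerical choices and degenerate inputs

* Alignment scoring defaults: +1/−1 with affine −2/−1 gaps (BLAST-like
  at desk scale); the oracle-equality tests use linear −2 gaps in both
  routes, matching the classical Smith–Waterman formulation.
* Banded DP with band ≥ combined sequence length degenerates to the full
  matrix; that is how the kernel is validated against a full
  Smith–Waterman oracle written independently in plain R.
* Tie-breaks are deterministic everywhere: best local hit to the lowest
  donor coordinate; BED rows by coordinate then `+` before `−`; site
  modes as described above.
* Degenerate inputs error loudly: empty FASTA, duplicate ids, non-DNA
  characters, odd-length attachment sites, zero-length features, oriC
  coinciding with the terminus, empty octamer sets.
* Problem sizes in the test suite and acceptance script are desk-scale
  by design — 40–300 kb genomes, 100–2,000 insertions, 1,000-read
  oracle checks — chosen so the full suite runs in a couple of minutes
  while every property is still measured at meaningful n. The
  PWM-recovery check runs the full pipeline error-free on a neutral
  (GC 0.5) genome so that the recovered matrix is compared against the
  generator's PWM without background or aligner-noise confounds; read
  noise is exercised separately by the recall/precision check.

## Limitations

Healing assumes a single syntenous donor segment; rearranged donors
(inversions across the junction) are excluded by the co-linearity rule
rather than resolved. The switch model is sequence-only: no integrase
kinetics, no attL/attR repression effects, no directionality-factor
reversal. Junction calling assumes one marker geometry per library;
multi-junction reads are emitted per junction and flagged in the event
table rather than reassembled. The logo renderer is a simple base-graphics
implementation, adequate for inspection rather than publication
typography.
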